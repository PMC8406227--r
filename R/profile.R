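# KO-based pathway-completeness scoring and marker-gene copy matrices for
# partial genomes (MAGs and SAGs).

# named integer vector of KO copies for one genome
.ko_copies <- function(ko_df, genome_id) {
  sub <- ko_df[ko_df$genome_id == genome_id, ]
  stats::setNames(sub$copies, sub$ko)
}

#' Pathway completeness of one genome
#'
#' The fraction of a pathway's defining KOs present in the genome:
#' `|defining KOs present| / |defining KOs|`.  Presence/absence semantics —
#' extra copies of a KO never inflate completeness.
#'
#' @param kos_present character vector of KO ids present in the genome (or a
#'   named copy-number vector; names are used).
#' @param defining_kos nonempty character vector of KO ids defining the
#'   pathway.
#' @return completeness fraction in `[0, 1]`.
#' @examples
#' pathway_completeness(c("K00001", "K00002"), c("K00001", "K00002", "K00003", "K00004"))
#' @export
pathway_completeness <- function(kos_present, defining_kos) {
  if (!length(defining_kos)) .err("pathway has an empty defining KO set")
  defining_kos <- unique(defining_kos)
  if (!is.null(names(kos_present))) kos_present <- names(kos_present)
  length(intersect(unique(kos_present), defining_kos)) / length(defining_kos)
}

#' Pathway-completeness matrix
#'
#' Scores every genome against every pathway definition.  Genomes listed in
#' `genome_ids` but absent from the annotation table get an all-zero row with
#' a warning (partial genomes routinely lack any annotated KO).
#'
#' @param ko_df KO annotation triples from [read_ko_table()].
#' @param pathways pathway definitions from [read_pathway_defs()].
#' @param genome_ids optional explicit genome id vector (defaults to the
#'   genomes present in `ko_df`).
#' @return numeric matrix (genome x pathway) of completeness fractions.
#' @export
completeness_matrix <- function(ko_df, pathways, genome_ids = NULL) {
  if (anyDuplicated(pathways$pathway_id)) .err("duplicate pathway ids")
  if (is.null(genome_ids)) genome_ids <- unique(ko_df$genome_id)
  if (anyDuplicated(genome_ids)) .err("duplicate genome ids")
  absent <- setdiff(genome_ids, unique(ko_df$genome_id))
  if (length(absent)) {
    warning(sprintf("no KO annotations for genome(s) %s; scoring all-zero",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  m <- matrix(0, length(genome_ids), nrow(pathways),
              dimnames = list(genome_ids, pathways$pathway_id))
  for (g in genome_ids) {
    kos <- names(.ko_copies(ko_df, g))
    m[g, ] <- vapply(pathways$kos, function(def) pathway_completeness(kos, def),
                     numeric(1))
  }
  m
}

#' Marker-gene copy-number matrix
#'
#' Entry (genome, marker) is the summed copy number over the marker's KO
#' list.
#'
#' @param ko_df KO annotation triples from [read_ko_table()].
#' @param markers marker definitions from [read_marker_defs()].
#' @param genome_ids optional explicit genome id vector.
#' @return integer matrix (genome x marker).
#' @export
marker_gene_matrix <- function(ko_df, markers, genome_ids = NULL) {
  if (anyDuplicated(markers$marker_id)) .err("duplicate marker ids")
  if (any(lengths(markers$kos) == 0L)) .err("marker with an empty KO list")
  if (is.null(genome_ids)) genome_ids <- unique(ko_df$genome_id)
  if (anyDuplicated(genome_ids)) .err("duplicate genome ids")
  m <- matrix(0L, length(genome_ids), nrow(markers),
              dimnames = list(genome_ids, markers$marker_id))
  for (g in genome_ids) {
    copies <- .ko_copies(ko_df, g)
    m[g, ] <- vapply(markers$kos, function(def) {
      as.integer(sum(copies[names(copies) %in% def]))
    }, integer(1))
  }
  m
}
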