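# Readers and writers for every external format the pipeline touches.
# All readers validate strictly: silent coercion is the classic corruption
# source in amplicon pipelines, so malformed cells are hard errors that name
# the offending record.

.IUPAC_LETTERS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                    "V", "H", "D", "B", "N")

# Normalize raw FASTA sequences: uppercase, strip gap characters, RNA U -> T.
.normalize_seq <- function(x) {
  x <- toupper(x)
  x <- gsub("[-. ]", "", x)
  gsub("U", "T", x, fixed = TRUE)
}

.check_iupac <- function(seqs, ids, context) {
  bad <- regexpr(sprintf("[^%s]", paste(.IUPAC_LETTERS, collapse = "")), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    .err("non-IUPAC character '%s' at position %d of sequence '%s' in %s",
         substr(seqs[i], bad[i], bad[i]), bad[i], ids[i], context)
  }
  invisible(TRUE)
}

#' Read a FASTA file of DNA sequences
#'
#' Sequences are normalized on read: uppercased, gap characters (`-`, `.`,
#' spaces) stripped, and `U` mapped to `T`.  Wrapped and unwrapped FASTA are
#' both accepted.  Ambiguity codes are retained (they score as mismatches in
#' identity computations).
#'
#' @param path path to a FASTA file.
#' @return named character vector of normalized sequences; names are the
#'   header ids (first whitespace-delimited token), with any remaining header
#'   text kept in the `"descriptions"` attribute.
#' @export
read_fasta <- function(path) {
  if (!.is_string(path)) .err("'path' must be a single file path")
  if (!file.exists(path)) .err("FASTA file not found: '%s'", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .err("empty FASTA file: '%s'", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) .err("FASTA record with empty id in '%s'", path)
  if (anyDuplicated(ids)) {
    .err("duplicate FASTA id(s) in '%s': %s", path,
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- .normalize_seq(as.character(set))
  if (any(!nzchar(seqs))) {
    .err("zero-length sequence for id '%s' in '%s'", ids[which(!nzchar(seqs))[1L]], path)
  }
  .check_iupac(seqs, ids, sprintf("'%s'", path))
  names(seqs) <- ids
  attr(seqs, "descriptions") <- stats::setNames(desc, ids)
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences (as from [read_fasta()]).
#' @param path output path.
#' @param width line-wrap width; `Inf` writes unwrapped lines.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    .err("sequences must be named by id")
  }
  desc <- attr(seqs, "descriptions")
  .write_atomic(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    for (i in seq_along(seqs)) {
      id <- names(seqs)[i]
      hdr <- if (!is.null(desc) && nzchar(desc[[id]])) paste(id, desc[[id]]) else id
      writeLines(paste0(">", hdr), con)
      s <- seqs[[i]]
      if (is.finite(width) && nchar(s) > width) {
        starts <- seq(1L, nchar(s), by = width)
        s <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
      }
      writeLines(s, con)
    }
  }, path)
}

#' Read an ASV x sample count table
#'
#' Expects a TSV with ASV ids in the first column and sample ids in the header
#' row.  Coercion is strict: any negative, non-integer or non-numeric cell is
#' a hard error naming the row and column.
#'
#' @param path path to a TSV file.
#' @return integer matrix with ASV ids as row names and sample ids as column
#'   names.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) .err("count table not found: '%s'", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) .err("count table '%s' needs an id column plus >=1 sample column", path)
  ids <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(ids)) {
    .err("duplicate ASV id(s) in '%s': %s", path,
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    .err("duplicate sample id(s) in '%s': %s", path,
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  m <- matrix(0L, nrow = length(ids), ncol = length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad)) {
      .err("invalid count '%s' at row '%s', column '%s' in '%s' (must be a nonnegative integer)",
           raw[bad[1L]], ids[bad[1L]], samples[j], path)
    }
    m[, j] <- as.integer(num)
  }
  m
}

#' Write a count table as TSV
#'
#' @param counts integer matrix (ASV rows x sample columns).
#' @param path output path.
#' @param id_column name for the first (ASV id) column.
#' @return the path, invisibly.
#' @export
write_count_table <- function(counts, path, id_column = "asv_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write_tsv(df, path)
}

.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read an ASV taxonomy table
#'
#' TSV with an `asv_id` column and rank columns `domain` through `genus`.
#' Empty strings, `NA` and tokens such as "unclassified"/"unknown" are treated
#' as unresolved ranks.
#'
#' @param path path to a TSV file.
#' @return data frame with `asv_id` plus the six rank columns (`NA` where
#'   unresolved).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) .err("taxonomy table not found: '%s'", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("asv_id", .TAX_RANKS)
  miss <- setdiff(need, colnames(df))
  if (length(miss)) .err("taxonomy table '%s' missing column(s): %s",
                         path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$asv_id)) {
    .err("duplicate asv_id(s) in taxonomy '%s'", path)
  }
  out <- df[, need]
  for (r in .TAX_RANKS) {
    v <- trimws(out[[r]])
    v[v == "" | is.na(v) | tolower(v) %in% c("na", "unclassified", "unknown", "unresolved")] <- NA
    out[[r]] <- v
  }
  out
}

#' Read tabular BLAST results and retain one best hit per query
#'
#' Accepts conventional 12-column tabular output (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' A 13th column, when present, is taken as the subject description (the
#' environment source text); alternatively supply a sidecar id-to-description
#' table via `descriptions`.  Per query, the hit with the highest bitscore is
#' kept; ties are broken by lexicographically smallest subject id.
#'
#' @param path path to the tabular file.
#' @param descriptions optional data frame with columns `subject_id`,
#'   `description`, or a named character vector.
#' @return data frame with one row per query: `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `bitscore`,
#'   `subject_description`.  An empty file yields a zero-row data frame.
#' @export
read_blast_tab <- function(path, descriptions = NULL) {
  if (!file.exists(path)) .err("BLAST tabular file not found: '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), alignment_length = integer(),
                      bitscore = numeric(), subject_description = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 12L)) {
    .err("malformed BLAST tabular row at line %d of '%s' (fewer than 12 columns)",
         which(n < 12L)[1L], path)
  }
  get <- function(k) vapply(fields, `[[`, character(1), k)
  pident <- suppressWarnings(as.numeric(get(3L)))
  alen <- suppressWarnings(as.numeric(get(4L)))
  bits <- suppressWarnings(as.numeric(get(12L)))
  bad <- which(is.na(pident) | is.na(alen) | is.na(bits))
  if (length(bad)) .err("malformed BLAST tabular row at line %d of '%s' (non-numeric field)",
                        bad[1L], path)
  if (any(pident < 0 | pident > 100)) {
    .err("percent identity outside [0,100] at line %d of '%s'",
         which(pident < 0 | pident > 100)[1L], path)
  }
  if (any(alen < 1)) .err("alignment length < 1 at line %d of '%s'", which(alen < 1)[1L], path)
  inline_desc <- ifelse(n >= 13L, vapply(fields, function(f) f[13L], character(1)), "")
  hits <- data.frame(query_id = get(1L), subject_id = get(2L),
                     percent_identity = pident,
                     alignment_length = as.integer(alen), bitscore = bits,
                     subject_description = inline_desc, stringsAsFactors = FALSE)
  if (!is.null(descriptions)) {
    if (is.data.frame(descriptions)) {
      descriptions <- stats::setNames(descriptions$description, descriptions$subject_id)
    }
    found <- hits$subject_id %in% names(descriptions)
    hits$subject_description[found] <- unname(descriptions[hits$subject_id[found]])
  }
  # best hit per query: max bitscore, ties to lexicographically smallest subject
  hits <- hits[order(hits$query_id, -hits$bitscore, hits$subject_id), ]
  best <- hits[!duplicated(hits$query_id), ]
  rownames(best) <- NULL
  best
}

## ---- sample table (Table-1-like layout) -------------------------------------

.SENTINELS <- c("BDL", "ADL", "BMQL", "ND", "NA")

# Parse one quantity cell: a number (commas allowed), "BMQL (4.4)",
# a "lo-hi" range (flagged, midpoint value), or a sentinel token.
# Sentinels never coerce to numerics: value is NA and the flag records why.
.parse_quantity <- function(x, field) {
  raw <- trimws(x)
  tok <- toupper(gsub("\\.", "", raw))
  out <- list(value = NA_real_, flag = "ok", limit = NA_real_)
  if (!nzchar(raw)) {
    out$flag <- "nd"
    return(out)
  }
  if (grepl("^BMQL", tok)) {
    out$flag <- "bmql"
    lim <- regmatches(raw, regexpr("[0-9]+\\.?[0-9]*", raw))
    if (length(lim)) out$limit <- as.numeric(lim)
    return(out)
  }
  if (tok %in% .SENTINELS) {
    out$flag <- switch(tok, BDL = "bdl", ADL = "adl", ND = "nd", "NA" = "na")
    return(out)
  }
  num_pat <- "[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?"
  clean <- gsub(",", "", raw)
  if (grepl(sprintf("^%s$", num_pat), clean)) {
    out$value <- as.numeric(clean)
    return(out)
  }
  if (grepl(sprintf("^%s\\s*[-–]\\s*%s$", num_pat, num_pat), clean)) {
    ends <- as.numeric(regmatches(clean, gregexpr(num_pat, clean))[[1L]])
    out$value <- mean(ends)
    out$flag <- "range"
    return(out)
  }
  .err("unknown sentinel token '%s' in column '%s'", raw, field)
}

.parse_pcr <- function(x, id) {
  tok <- toupper(gsub("[. ]", "", trimws(x)))
  tok <- chartr("−–", "--", tok)
  switch(tok,
         "+" = "positive",
         "-" = "negative",
         "NC" = "no_cells",
         .err("unknown PCR status token '%s' for sample '%s'", x, id))
}

.parse_seq <- function(x, id) {
  tok <- toupper(gsub("[. ]", "", trimws(x)))
  tok <- chartr("−–", "--", tok)
  switch(tok,
         "+" = "success",
         "-" = "failed",
         "NA" = "not_applicable",
         .err("unknown sequencing status token '%s' for sample '%s'", x, id))
}

#' Read a sample overview table
#'
#' Reads a TSV transcription of a drilling-expedition sample overview with
#' columns `sample_id`, `lithology`, `cell_density`, `pcr`, `seq`, `pfc_int`,
#' `pfc_ext`.  Sentinel tokens (`BDL` below detection limit, `ADL` above
#' detection limit, `BMQL` below minimum quantification limit with an optional
#' parenthesised limit, `n.d.` not determined, `n.a.` not applicable, and
#' `n.c.` no cells detected in the PCR column) are recognised
#' case-insensitively and mapped to typed sentinel flags, never to zero.
#' Depth in meters below seafloor is parsed from the trailing token of the
#' sample id (`hole-core-depth`).
#'
#' @param path path to the TSV file.
#' @return data frame with columns `sample_id`, `lithology`, `depth_mbsf`,
#'   `cell_density`, `cell_density_flag`, `cell_density_limit`, `pcr_status`,
#'   `seq_status`, `pfc_interior`, `pfc_interior_flag`, `pfc_exterior`,
#'   `pfc_exterior_flag`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) .err("sample table not found: '%s'", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "lithology", "cell_density", "pcr", "seq",
            "pfc_int", "pfc_ext")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) .err("sample table '%s' missing column(s): %s",
                         path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) .err("duplicate sample_id(s) in '%s'", path)

  n <- nrow(df)
  cd <- lapply(df$cell_density, .parse_quantity, field = "cell_density")
  pi_ <- lapply(df$pfc_int, .parse_quantity, field = "pfc_int")
  pe <- lapply(df$pfc_ext, .parse_quantity, field = "pfc_ext")
  pcr <- vapply(seq_len(n), function(i) .parse_pcr(df$pcr[i], df$sample_id[i]),
                character(1))
  seqs <- vapply(seq_len(n), function(i) .parse_seq(df$seq[i], df$sample_id[i]),
                 character(1))
  bad <- which(pcr == "no_cells" & seqs != "not_applicable")
  if (length(bad)) {
    .err("sample '%s': no cells detected in FACS but sequencing status is '%s' (must be n.a.)",
         df$sample_id[bad[1L]], seqs[bad[1L]])
  }
  depth <- suppressWarnings(as.numeric(sub("^.*-", "", df$sample_id)))
  data.frame(
    sample_id = df$sample_id,
    lithology = df$lithology,
    depth_mbsf = depth,
    cell_density = vapply(cd, `[[`, numeric(1), "value"),
    cell_density_flag = vapply(cd, `[[`, character(1), "flag"),
    cell_density_limit = vapply(cd, `[[`, numeric(1), "limit"),
    pcr_status = pcr,
    seq_status = seqs,
    pfc_interior = vapply(pi_, `[[`, numeric(1), "value"),
    pfc_interior_flag = vapply(pi_, `[[`, character(1), "flag"),
    pfc_exterior = vapply(pe, `[[`, numeric(1), "value"),
    pfc_exterior_flag = vapply(pe, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE
  )
}

## ---- genome annotations and definitions ------------------------------------

#' Read a genome KO-annotation table
#'
#' TSV of `genome_id`, `ko`, `copies` triples (one row per KO per genome).
#'
#' @param path path to the TSV file.
#' @return data frame with those three columns; `copies` integer `>= 1`.
#' @export
read_ko_table <- function(path) {
  if (!file.exists(path)) .err("KO table not found: '%s'", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("genome_id", "ko", "copies")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) .err("KO table '%s' missing column(s): %s",
                         path, paste(miss, collapse = ", "))
  copies <- suppressWarnings(as.numeric(df$copies))
  bad <- which(is.na(copies) | copies < 1 | copies != floor(copies))
  if (length(bad)) {
    .err("invalid copy number '%s' for genome '%s', KO '%s' in '%s' (integer >= 1 required)",
         df$copies[bad[1L]], df$genome_id[bad[1L]], df$ko[bad[1L]], path)
  }
  key <- paste(df$genome_id, df$ko)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    .err("duplicate genome/KO entry '%s' in '%s'", d, path)
  }
  data.frame(genome_id = df$genome_id, ko = df$ko,
             copies = as.integer(copies), stringsAsFactors = FALSE)
}

#' Read a genome metadata table
#'
#' TSV describing each partial genome: `genome_id`, `genome_type` (`MAG` or
#' `SAG`), `completeness_estimate` and `contamination_estimate` (0-100, from
#' upstream single-copy-gene tools), `has_viral_evidence` (0/1; derived
#' upstream from viral-detection categories 1-2), `has_ssu` (0/1).
#'
#' @param path path to the TSV file.
#' @return validated data frame.
#' @export
read_genome_table <- function(path) {
  if (!file.exists(path)) .err("genome table not found: '%s'", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("genome_id", "genome_type", "completeness_estimate",
            "contamination_estimate", "has_viral_evidence", "has_ssu")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) .err("genome table '%s' missing column(s): %s",
                         path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$genome_id)) .err("duplicate genome_id(s) in '%s'", path)
  if (!all(df$genome_type %in% c("MAG", "SAG"))) {
    .err("genome_type must be 'MAG' or 'SAG' in '%s'", path)
  }
  for (col in c("completeness_estimate", "contamination_estimate")) {
    v <- as.numeric(df[[col]])
    if (any(is.na(v) | v < 0 | v > 100)) .err("%s outside [0,100] in '%s'", col, path)
    df[[col]] <- v
  }
  df$has_viral_evidence <- as.logical(as.integer(df$has_viral_evidence))
  df$has_ssu <- as.logical(as.integer(df$has_ssu))
  df[, need]
}

.read_ko_defs <- function(path, id_col, what) {
  if (!file.exists(path)) .err("%s definition table not found: '%s'", what, path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c(id_col, "name", "kos")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) .err("%s table '%s' missing column(s): %s",
                         what, path, paste(miss, collapse = ", "))
  if (anyDuplicated(df[[id_col]])) .err("duplicate %s id(s) in '%s'", what, path)
  kos <- lapply(strsplit(df$kos, ","), function(v) unique(trimws(v[nzchar(trimws(v))])))
  empty <- which(lengths(kos) == 0L)
  if (length(empty)) {
    .err("%s '%s' has an empty KO list in '%s' (line %d)",
         what, df[[id_col]][empty[1L]], path, empty[1L] + 1L)
  }
  out <- df[, c(id_col, "name")]
  out$kos <- I(kos)
  out
}

#' Read a pathway definition table
#'
#' TSV with columns `pathway_id`, `name`, `kos` (comma-separated KO ids
#' defining the pathway).  A default definition set covering common carbon,
#' nitrogen, sulfur and respiratory pathways ships with the package; see
#' [default_pathway_file()].  Definitions are data, not code: edit freely.
#'
#' @param path path to the TSV file.
#' @return data frame with `pathway_id`, `name` and list column `kos`.
#' @export
read_pathway_defs <- function(path = default_pathway_file()) {
  .read_ko_defs(path, "pathway_id", "pathway")
}

#' Read a marker-gene definition table
#'
#' TSV with columns `marker_id`, `name`, `kos` (comma-separated KO ids whose
#' copy numbers are summed per marker).  A default table covering the common
#' metabolic marker genes ships with the package; see [default_marker_file()].
#'
#' @param path path to the TSV file.
#' @return data frame with `marker_id`, `name` and list column `kos`.
#' @export
read_marker_defs <- function(path = default_marker_file()) {
  .read_ko_defs(path, "marker_id", "marker")
}

#' Path to the packaged pathway definition table
#' @return file path.
#' @export
default_pathway_file <- function() {
  system.file("extdata", "pathway_definitions.tsv", package = "asvorigin",
              mustWork = TRUE)
}

#' Path to the packaged marker-gene definition table
#' @return file path.
#' @export
default_marker_file <- function() {
  system.file("extdata", "marker_definitions.tsv", package = "asvorigin",
              mustWork = TRUE)
}

#' Path to the packaged drilling-expedition sample overview fixture
#'
#' A transcription of the 29-sample screening overview (lithology, cell
#' density, PCR/sequencing status, PFC tracer concentrations) used as the
#' worked example for [summarize_screening()].
#'
#' @return file path.
#' @export
atlantis_sample_file <- function() {
  system.file("extdata", "atlantis_table1.tsv", package = "asvorigin",
              mustWork = TRUE)
}
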