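# Pairwise global sequence identity and thresholded matching of ASVs against
# control collections and whitelists.  The aligner is Needleman-Wunsch with
# free end gaps (Biostrings pairwiseAlignment, type "overlap"); the identity
# definition and all tie-breaking live here.

.pkg_cache <- new.env(parent = emptyenv())

# Substitution matrix over IUPAC DNA letters: +1 only for exact A/C/G/T
# matches, -1 everywhere else, so ambiguity codes (including N-N) count as
# mismatches.
.identity_submat <- function() {
  if (is.null(.pkg_cache$submat)) {
    m <- matrix(-1, length(.IUPAC_LETTERS), length(.IUPAC_LETTERS),
                dimnames = list(.IUPAC_LETTERS, .IUPAC_LETTERS))
    diag(m)[1:4] <- 1
    .pkg_cache$submat <- m
  }
  .pkg_cache$submat
}

#' Identity-scoring parameters
#'
#' Parameters controlling pairwise identity computation and thresholded
#' matching.  The alignment is global with optional free end gaps, scored
#' match +1, mismatch -1 (ambiguity codes count as mismatches), gap -2 per
#' column.  Identity is the number of matched columns divided by a
#' denominator chosen by `denominator`:
#'
#' * `"global"` (default): all columns of the full-span alignment, terminal
#'   overhangs included — a short exact fragment of a longer sequence scores
#'   well below 1 unless the lengths are comparable.
#' * `"overlap"`: columns of the aligned overlap region only.
#'
#' For the near-equal-length amplicons of a single primer set the two
#' denominators agree.
#'
#' @param threshold identity fraction at or above which a match is called
#'   (default 0.99, the conventional screening threshold for amplicon
#'   contaminant matching).
#' @param end_gaps_free logical; if `TRUE` (default) terminal gaps are not
#'   penalised in the alignment score.
#' @param kmer_k word size of the shared-k-mer prescreen (default 8).
#' @param denominator `"global"` or `"overlap"`, see above.
#' @param use_prescreen logical; if `TRUE` (default) pairs sharing no k-mer
#'   are skipped without alignment.  The prescreen is an optimisation only:
#'   a pair with identity at typical thresholds always shares k-mers, and
#'   the property suite asserts equivalence with exhaustive alignment.
#' @return an object of class `identity_params`.
#' @export
identity_params <- function(threshold = 0.99, end_gaps_free = TRUE,
                            kmer_k = 8, denominator = c("global", "overlap"),
                            use_prescreen = TRUE) {
  denominator <- match.arg(denominator)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    .err("identity threshold must be in (0, 1]")
  }
  if (!is.numeric(kmer_k) || kmer_k < 4) .err("kmer_k must be >= 4")
  structure(list(threshold = threshold, end_gaps_free = isTRUE(end_gaps_free),
                 kmer_k = as.integer(kmer_k), denominator = denominator,
                 use_prescreen = isTRUE(use_prescreen)),
            class = "identity_params")
}

.check_dna <- function(x, what) {
  if (!is.character(x) || any(is.na(x))) .err("%s must be character DNA", what)
  if (any(!nzchar(x))) .err("%s contains an empty sequence", what)
  .check_iupac(x, if (is.null(names(x))) seq_along(x) else names(x), what)
}

# Vectorized identity of each element of `a` against the matching element of
# `b` (recycled if length 1).  Each pair is canonically ordered
# (lexicographically smaller string first) before alignment so that identity
# is symmetric by construction even when the optimum alignment is not unique.
.pair_identity <- function(a, b, params) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  swap <- a > b
  p <- ifelse(swap, b, a)
  s <- ifelse(swap, a, b)
  type <- if (params$end_gaps_free) "overlap" else "global"
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(p), Biostrings::DNAStringSet(s),
    type = type, substitutionMatrix = .identity_submat(),
    gapOpening = 0, gapExtension = 2)
  pa <- Biostrings::pattern(aln)
  su <- Biostrings::subject(aln)
  cols <- nchar(as.character(pa))  # aligned columns of the overlap region
  if (params$denominator == "global" && params$end_gaps_free) {
    left <- pmax(BiocGenerics::start(pa) - 1L, BiocGenerics::start(su) - 1L)
    right <- pmax(nchar(p) - BiocGenerics::end(pa),
                  nchar(s) - BiocGenerics::end(su))
    cols <- cols + left + right
  }
  Biostrings::nmatch(aln) / cols
}

#' Global pairwise sequence identity
#'
#' Identity of two DNA sequences under an end-gap-free global alignment; see
#' [identity_params()] for the exact definition.  Symmetric
#' (`global_identity(a, b) == global_identity(b, a)`), reflexive (1 on self)
#' and bounded in `[0, 1]`.
#'
#' @param a,b DNA sequence strings (normalized, nonempty).
#' @param params an [identity_params()] object.
#' @return identity fraction in `[0, 1]`.
#' @examples
#' global_identity("ACGTACGT", "ACGTACGT")  # 1
#' @export
global_identity <- function(a, b, params = identity_params()) {
  .check_dna(a, "'a'")
  .check_dna(b, "'b'")
  if (length(a) != 1L || length(b) != 1L) .err("'a' and 'b' must be single sequences")
  unname(.pair_identity(a, b, params))
}

# unique k-mers of each sequence, as character vectors
.kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

# indices of `candidates` sharing >= 1 k-mer with `query`
.prescreen_pass <- function(query, candidates, k) {
  qk <- .kmer_sets(query, k)[[1L]]
  if (!length(qk)) return(seq_along(candidates))  # too short to screen
  ck <- .kmer_sets(candidates, k)
  which(vapply(ck, function(v) length(v) == 0L || any(v %in% qk), logical(1)))
}

.CONTROL_TYPES <- c("ntc", "drill_fluid", "seawater")

#' Assemble a control collection
#'
#' Bundles the three contamination-evidence sequence sets: no-template
#' controls (`ntc`), drilling-fluid controls (`drill_fluid`) and seawater
#' controls (`seawater`).  At least one set must be nonempty; ids must be
#' unique within each set.
#'
#' @param ntc,drill_fluid,seawater named character vectors of normalized
#'   sequences (as from [read_fasta()]), or `NULL`.
#' @return an object of class `control_collection` (a named list).
#' @export
control_collection <- function(ntc = NULL, drill_fluid = NULL, seawater = NULL) {
  sets <- list(ntc = ntc, drill_fluid = drill_fluid, seawater = seawater)
  for (ty in .CONTROL_TYPES) {
    s <- sets[[ty]]
    if (is.null(s) || length(s) == 0L) {
      sets[[ty]] <- character()
      next
    }
    .check_dna(s, sprintf("control set '%s'", ty))
    if (is.null(names(s)) || any(!nzchar(names(s)))) {
      .err("control set '%s' must be named by sequence id", ty)
    }
    if (anyDuplicated(names(s))) .err("duplicate ids in control set '%s'", ty)
  }
  if (all(lengths(sets) == 0L)) .err("at least one control set must be nonempty")
  structure(sets, class = "control_collection")
}

#' Best control match for a query sequence
#'
#' Searches all control sets for the highest-identity sequence at or above
#' `params$threshold`.  Ties are broken by control-type precedence
#' `ntc > drill_fluid > seawater`, then by lexicographic control sequence id.
#'
#' @param query a single DNA sequence string (optionally named by its ASV id).
#' @param controls a [control_collection()].
#' @param params an [identity_params()] object.
#' @return one-row data frame (`query_id`, `control_type`, `control_seq_id`,
#'   `identity`) or `NULL` when no control reaches the threshold.
#' @export
best_control_match <- function(query, controls, params = identity_params()) {
  if (!inherits(controls, "control_collection")) {
    controls <- do.call(control_collection, as.list(controls))
  }
  .check_dna(query, "'query'")
  qid <- if (!is.null(names(query))) names(query)[1L] else NA_character_
  query <- unname(query[1L])
  cand <- data.frame(control_type = character(), control_seq_id = character(),
                     identity = numeric(), stringsAsFactors = FALSE)
  for (ty in .CONTROL_TYPES) {
    set <- controls[[ty]]
    if (!length(set)) next
    keep <- if (params$use_prescreen) {
      .prescreen_pass(query, set, params$kmer_k)
    } else {
      seq_along(set)
    }
    if (!length(keep)) next
    ids <- .pair_identity(unname(set[keep]), query, params)
    hit <- which(ids >= params$threshold)
    if (length(hit)) {
      cand <- rbind(cand, data.frame(control_type = ty,
                                     control_seq_id = names(set)[keep][hit],
                                     identity = ids[hit],
                                     stringsAsFactors = FALSE))
    }
  }
  if (!nrow(cand)) return(NULL)
  prec <- match(cand$control_type, .CONTROL_TYPES)
  cand <- cand[order(-cand$identity, prec, cand$control_seq_id), ]
  out <- cand[1L, ]
  out <- cbind(query_id = qid, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Whitelist membership test
#'
#' Tests whether a query sequence belongs to the "likely indigenous"
#' whitelist.  In `exact_sequence` mode membership is normalized string
#' equality; in `identity_threshold` mode membership requires best identity
#' `>= params$threshold` against any whitelist entry; in `id` mode (for
#' bare-id whitelists without sequences) membership is by ASV id.
#'
#' @param query a single DNA sequence string, named by its ASV id (the name is
#'   required for `id` mode).
#' @param whitelist named character vector of whitelist sequences, or (for
#'   `id` mode only) an unnamed character vector of bare ASV ids.
#' @param match_mode `"exact_sequence"`, `"identity_threshold"` or `"id"`.
#' @param params an [identity_params()] object (used in threshold mode).
#' @return list with `hit` (logical) and `evidence` (one-row data frame with
#'   `control_type = "whitelist"` when matched in threshold mode, else `NULL`).
#' @export
in_whitelist <- function(query, whitelist,
                         match_mode = c("exact_sequence", "identity_threshold", "id"),
                         params = identity_params()) {
  match_mode <- match.arg(match_mode)
  if (is.null(whitelist) || !length(whitelist)) .err("whitelist is empty")
  qid <- if (!is.null(names(query))) names(query)[1L] else NA_character_
  bare <- is.null(names(whitelist))
  if (match_mode == "id") {
    ids <- if (bare) whitelist else names(whitelist)
    if (is.na(qid)) .err("id-mode whitelist matching needs a named query")
    return(list(hit = qid %in% ids, evidence = NULL))
  }
  if (bare) {
    .err("bare-id whitelist cannot be used with sequence match mode '%s'", match_mode)
  }
  .check_dna(query, "'query'")
  query <- unname(query[1L])
  if (match_mode == "exact_sequence") {
    return(list(hit = query %in% unname(whitelist), evidence = NULL))
  }
  keep <- if (params$use_prescreen) {
    .prescreen_pass(query, whitelist, params$kmer_k)
  } else {
    seq_along(whitelist)
  }
  if (!length(keep)) return(list(hit = FALSE, evidence = NULL))
  ids <- .pair_identity(unname(whitelist[keep]), query, params)
  hit <- which(ids >= params$threshold)
  if (!length(hit)) return(list(hit = FALSE, evidence = NULL))
  ord <- order(-ids[hit], names(whitelist)[keep][hit])
  best <- hit[ord[1L]]
  list(hit = TRUE,
       evidence = data.frame(query_id = qid, control_type = "whitelist",
                             control_seq_id = names(whitelist)[keep][best],
                             identity = ids[best], stringsAsFactors = FALSE))
}
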