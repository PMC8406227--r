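# Post-classification reporting: per-sample origin-category profiles,
# decontaminated family-level composition, drilling-tracer comparison and
# screening-success accounting.

#' Per-sample origin-category read fractions
#'
#' Reads-weighted fraction of each origin category per sample.  Fractions of
#' samples with at least one read sum to 1; zero-read samples are flagged and
#' left as `NA` rather than divided.
#'
#' @param counts integer count matrix (ASV rows x sample columns).
#' @param calls origin calls from [classify_table()] covering every row.
#' @return data frame with `sample_id`, one fraction column per category
#'   (`subsurface`, `possibly_subsurface`, `likely_contaminant`,
#'   `contaminant`), `total_reads` and `zero_reads`.
#' @export
category_abundance <- function(counts, calls) {
  asv_ids <- rownames(counts)
  if (!all(asv_ids %in% calls$asv_id)) .err("origin calls do not cover all table rows")
  cat_of <- factor(stats::setNames(calls$category, calls$asv_id)[asv_ids],
                   levels = .ORIGIN_CATEGORIES)
  by_cat <- rowsum(counts, cat_of)                  # category x sample sums
  full <- matrix(0, length(.ORIGIN_CATEGORIES), ncol(counts),
                 dimnames = list(.ORIGIN_CATEGORIES, colnames(counts)))
  full[rownames(by_cat), ] <- by_cat
  totals <- colSums(counts)
  frac <- sweep(full, 2, totals, "/")
  frac[, totals == 0] <- NA_real_
  out <- data.frame(sample_id = colnames(counts), t(frac),
                    total_reads = as.integer(totals),
                    zero_reads = totals == 0,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

# Display label for one taxonomy row: family when resolved, otherwise the
# deepest resolved rank prefixed with its rank letter, e.g. "(p) Chloroflexi"
# for an ASV resolved only to phylum.
.family_label <- function(tax_row) {
  if (!is.na(tax_row[["family"]])) return(tax_row[["family"]])
  up <- c("order", "class", "phylum", "domain")
  for (r in up) {
    if (!is.na(tax_row[[r]])) {
      return(sprintf("(%s) %s", substr(r, 1, 1), tax_row[[r]]))
    }
  }
  "unknown bacteria"
}

#' Family-level relative abundance of a decontaminated table
#'
#' Aggregates a contaminant-filtered count table to family-level relative
#' abundances.  ASVs unresolved at family level get a "(p) Phylum"-style
#' fallback label at the deepest resolved rank; ASVs missing from the
#' taxonomy are placed in an "unknown bacteria" bucket with a warning.
#' Families whose relative abundance is below `min_overall_fraction` in every
#' sample are collapsed into an `"other family"` row.
#'
#' @param counts filtered integer count matrix.
#' @param taxonomy data frame from [read_taxonomy()].
#' @param min_overall_fraction collapse threshold (default 0.001, i.e. 0.1%).
#' @return numeric matrix (family x sample) whose nonzero columns each sum
#'   to 1.
#' @export
family_composition <- function(counts, taxonomy, min_overall_fraction = 0.001) {
  asv_ids <- rownames(counts)
  idx <- match(asv_ids, taxonomy$asv_id)
  if (anyNA(idx)) {
    warning(sprintf("taxonomy missing for %d ASV(s); assigned to 'unknown bacteria'",
                    sum(is.na(idx))), call. = FALSE)
  }
  labels <- vapply(seq_along(asv_ids), function(i) {
    if (is.na(idx[i])) return("unknown bacteria")
    .family_label(taxonomy[idx[i], ])
  }, character(1))
  agg <- rowsum(counts, labels)
  totals <- colSums(agg)
  rel <- sweep(agg, 2, pmax(totals, 1), "/")  # zero-read samples stay all-zero
  if (min_overall_fraction > 0) {
    minor <- apply(rel, 1, max) < min_overall_fraction
    if (any(minor)) {
      other <- colSums(rel[minor, , drop = FALSE])
      rel <- rbind(rel[!minor, , drop = FALSE], "other family" = other)
    }
  }
  rel
}

# all permutations of 1..n as an (n!) x n integer matrix
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(p), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(p) + seq_len(nrow(p))
    out[rows, 1L] <- i
    out[rows, -1L] <- p + (p >= i)
  }
  out
}

# Spearman rank correlation with an exact two-sided permutation p-value for
# n <= max_exact_n (ties handled by average ranks), asymptotic otherwise.
.rank_correlation <- function(x, y, max_exact_n = 8L) {
  n <- length(x)
  xr <- rank(x)
  yr <- rank(y)
  if (stats::sd(xr) == 0 || stats::sd(yr) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, method = "degenerate"))
  }
  rho <- stats::cor(xr, yr)
  if (n <= max_exact_n) {
    xs <- as.numeric(scale(xr))
    ys <- as.numeric(scale(yr))
    perm <- .permutations(n)
    rhos <- (matrix(ys[perm], nrow(perm), n) %*% xs) / (n - 1)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p_value = p, method = "exact_permutation")
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    list(rho = rho, p_value = ct$p.value, method = "spearman_asymptotic")
  }
}

#' Compare indigenous read fraction with drilling-fluid tracer
#'
#' Rank correlation between each sample's indigenous-origin read fraction
#' (`subsurface + possibly_subsurface`) and its interior perfluorocarbon
#' (PFC) tracer concentration.  Samples whose tracer value is a sentinel
#' (below detection limit, not determined, ...) are excluded by default;
#' `bdl_policy = "zero"` instead substitutes 0 for below-detection values.
#' With at most 8 usable samples the p-value is an exact two-sided
#' permutation p-value over all orderings.
#'
#' @param profiles category profiles from [category_abundance()].
#' @param samples sample table from [read_sample_table()].
#' @param bdl_policy `"exclude"` (default) or `"zero"`.
#' @return list report: `status` (`"ok"` or `"insufficient_data"`), `n_used`,
#'   `n_excluded`, and for `"ok"` also `rho`, `p_value`, `method`,
#'   `sample_ids`.
#' @export
tracer_comparison <- function(profiles, samples,
                              bdl_policy = c("exclude", "zero")) {
  bdl_policy <- match.arg(bdl_policy)
  m <- merge(profiles, samples, by = "sample_id")
  tracer <- m$pfc_interior
  flag <- m$pfc_interior_flag
  if (bdl_policy == "zero") tracer[flag == "bdl"] <- 0
  indig <- m$subsurface + m$possibly_subsurface
  usable <- !is.na(tracer) & !is.na(indig)
  n_used <- sum(usable)
  n_excluded <- nrow(m) - n_used
  if (n_used < 3L) {
    return(list(status = "insufficient_data", n_used = n_used,
                n_excluded = n_excluded))
  }
  ord <- order(m$sample_id[usable])  # order-invariant result
  x <- indig[usable][ord]
  y <- tracer[usable][ord]
  rc <- .rank_correlation(x, y)
  list(status = "ok", n_used = n_used, n_excluded = n_excluded,
       rho = rc$rho, p_value = rc$p_value, method = rc$method,
       sample_ids = m$sample_id[usable][ord])
}

#' Classify lithology text as sediment or crust
#'
#' Substring heuristic (free-text lithology containing "sand" is sediment,
#' everything else crust) with an optional per-sample override map.
#'
#' @param lithology character vector of lithology descriptions.
#' @param sample_id matching sample ids (needed only when `overrides` used).
#' @param overrides named character vector `sample_id -> "sediment"|"crust"`.
#' @return character vector of `"sediment"`/`"crust"`.
#' @export
classify_lithology <- function(lithology, sample_id = NULL, overrides = NULL) {
  cls <- ifelse(grepl("sand", lithology, ignore.case = TRUE), "sediment", "crust")
  if (!is.null(overrides) && !is.null(sample_id)) {
    hit <- sample_id %in% names(overrides)
    cls[hit] <- unname(overrides[sample_id[hit]])
  }
  cls
}

#' Screening-success accounting
#'
#' Counts, over a screened sample set: samples screened, samples yielding
#' cell-like particles (PCR status not `no_cells`), PCR-positive samples,
#' successfully sequenced samples and their sediment/crust split, and the
#' overall efficiency (sequenced / screened, as a percentage).
#'
#' @param samples sample table from [read_sample_table()].
#' @param overrides optional lithology override map for
#'   [classify_lithology()].
#' @return list: `n_screened`, `n_cells_detected`, `n_pcr_positive`,
#'   `n_sequenced`, `n_sequenced_sediment`, `n_sequenced_crust`,
#'   `efficiency_percent` (full precision) and
#'   `efficiency_percent_rounded` (half-up to integer).
#' @export
summarize_screening <- function(samples, overrides = NULL) {
  if (!nrow(samples)) .err("sample table is empty")
  n_screened <- nrow(samples)
  n_cells <- sum(samples$pcr_status != "no_cells")
  n_pcr <- sum(samples$pcr_status == "positive")
  seq_ok <- samples$seq_status == "success"
  n_seq <- sum(seq_ok)
  lith <- classify_lithology(samples$lithology[seq_ok],
                             samples$sample_id[seq_ok], overrides)
  out <- list(
    n_screened = n_screened,
    n_cells_detected = n_cells,
    n_pcr_positive = n_pcr,
    n_sequenced = n_seq,
    n_sequenced_sediment = sum(lith == "sediment"),
    n_sequenced_crust = sum(lith == "crust"),
    efficiency_percent = 100 * n_seq / n_screened,
    efficiency_percent_rounded = round_half_up(100 * n_seq / n_screened)
  )
  if (!(out$n_sequenced <= out$n_pcr_positive &&
        out$n_pcr_positive <= out$n_cells_detected &&
        out$n_cells_detected <= out$n_screened)) {
    .err("inconsistent screening counts: sequenced <= PCR-positive <= cells detected <= screened must hold")
  }
  out
}

#' Viral-evidence summary over partial genomes
#'
#' Fraction of genomes with upstream viral evidence, per genome type and
#' combined, at full precision with a half-up 1-decimal display percentage.
#'
#' @param genomes genome metadata from [read_genome_table()].
#' @return data frame with rows per `genome_type` plus `"combined"`:
#'   `genome_type`, `n_genomes`, `n_viral`, `fraction`, `percent_display`.
#' @export
summarize_viral_evidence <- function(genomes) {
  if (!nrow(genomes)) .err("genome table is empty")
  one <- function(label, sub) {
    data.frame(genome_type = label, n_genomes = nrow(sub),
               n_viral = sum(sub$has_viral_evidence),
               fraction = sum(sub$has_viral_evidence) / nrow(sub),
               stringsAsFactors = FALSE)
  }
  parts <- lapply(sort(unique(genomes$genome_type)),
                  function(ty) one(ty, genomes[genomes$genome_type == ty, ]))
  out <- do.call(rbind, c(parts, list(one("combined", genomes))))
  out$percent_display <- round_half_up(100 * out$fraction, 1)
  rownames(out) <- NULL
  out
}
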