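# The four-category ASV origin classifier: the contamination-screening
# decision procedure for low-biomass subsurface amplicon surveys.
#
# An ASV that is >= 99% identical to a no-template-control, drilling-fluid or
# seawater control sequence is a contaminant, unless it is on the "likely
# indigenous" whitelist, in which case the environment of its closest database
# match adjudicates between possibly-subsurface and likely-contaminant.
# ASVs without control matches are classed by environment evidence alone.

.ORIGIN_CATEGORIES <- c("subsurface", "possibly_subsurface",
                        "likely_contaminant", "contaminant")

#' Environment keyword map
#'
#' Classifies the free-text environment description of an ASV's closest
#' database match as subsurface-like or contaminant-like by case-insensitive
#' substring matching.  The keyword lists replace the manual environment
#' adjudication a curator would perform; when both classes match, the
#' contaminant keywords win (the conservative reading for screening).
#'
#' @param subsurface_keywords lowercase substrings indicating a subsurface
#'   habitat.
#' @param contaminant_keywords lowercase substrings indicating a
#'   contamination source.
#' @return an object of class `environment_map`.
#' @export
environment_map <- function(
    subsurface_keywords = c("subsurface", "sediment", "hydrothermal",
                            "serpentinite", "aquifer", "hot spring",
                            "borehole", "crustal fluid"),
    contaminant_keywords = c("skin", "human", "reagent", "laboratory",
                             "drilling", "kit", "grease")) {
  subsurface_keywords <- tolower(subsurface_keywords)
  contaminant_keywords <- tolower(contaminant_keywords)
  if (length(intersect(subsurface_keywords, contaminant_keywords))) {
    .err("environment keyword lists must be disjoint")
  }
  structure(list(subsurface_keywords = subsurface_keywords,
                 contaminant_keywords = contaminant_keywords),
            class = "environment_map")
}

#' Classify an environment description
#'
#' @param description free-text environment source of the closest match, or
#'   `NA` when the ASV has no database hit.
#' @param env_map an [environment_map()].
#' @return one of `"subsurface_like"`, `"contaminant_like"`, `"ambiguous"`,
#'   `"absent"`.
#' @export
classify_environment <- function(description, env_map = environment_map()) {
  vapply(description, function(d) {
    if (is.na(d) || !nzchar(trimws(d))) return("absent")
    d <- tolower(d)
    has <- function(keys) any(vapply(keys, grepl, logical(1), x = d, fixed = TRUE))
    contam <- has(env_map$contaminant_keywords)
    subsur <- has(env_map$subsurface_keywords)
    if (contam) "contaminant_like"           # contaminant keywords win ties
    else if (subsur) "subsurface_like"
    else "ambiguous"
  }, character(1), USE.NAMES = FALSE)
}

#' Classifier parameters
#'
#' @param identity_threshold identity fraction for control matching (default
#'   0.99).
#' @param abundance_gate_reads optional integer; when set, environment
#'   evidence is consulted only for ASVs with total reads above the gate
#'   (below-gate ASVs take the ambiguous/absent branch of their rule).  The
#'   default is `NULL` (classify everything): the gate exists to reproduce
#'   screening workflows that BLAST only abundant taxa, e.g. `5000`.
#' @param whitelist_match_mode how whitelist membership is tested; see
#'   [in_whitelist()].
#' @param unknown_env_policy_matched category assigned to whitelisted,
#'   control-matching ASVs whose environment evidence is ambiguous or absent.
#'   Default `"likely_contaminant"` — conservative, matching a
#'   discard-on-doubt screening stance.
#' @param unknown_env_policy_unmatched category for non-control-matching ASVs
#'   with ambiguous/absent environment evidence.  Default
#'   `"possibly_subsurface"`.
#' @param identity an [identity_params()] object; its threshold is kept in
#'   sync with `identity_threshold`.
#' @return an object of class `classifier_params`.
#' @export
classifier_params <- function(identity_threshold = 0.99,
                              abundance_gate_reads = NULL,
                              whitelist_match_mode = c("exact_sequence",
                                                       "identity_threshold", "id"),
                              unknown_env_policy_matched = "likely_contaminant",
                              unknown_env_policy_unmatched = "possibly_subsurface",
                              identity = NULL) {
  whitelist_match_mode <- match.arg(whitelist_match_mode)
  ok <- c("possibly_subsurface", "likely_contaminant")
  if (!unknown_env_policy_matched %in% ok ||
      !unknown_env_policy_unmatched %in% ok) {
    .err("unknown-environment policies must be one of: %s", paste(ok, collapse = ", "))
  }
  if (is.null(identity)) {
    identity <- identity_params(threshold = identity_threshold)
  } else {
    identity$threshold <- identity_threshold
  }
  if (!is.null(abundance_gate_reads)) {
    if (!is.numeric(abundance_gate_reads) || abundance_gate_reads < 0) {
      .err("abundance_gate_reads must be a nonnegative number or NULL")
    }
    abundance_gate_reads <- as.numeric(abundance_gate_reads)
  }
  structure(list(identity_threshold = identity_threshold,
                 abundance_gate_reads = abundance_gate_reads,
                 whitelist_match_mode = whitelist_match_mode,
                 unknown_env_policy_matched = unknown_env_policy_matched,
                 unknown_env_policy_unmatched = unknown_env_policy_unmatched,
                 identity = identity),
            class = "classifier_params")
}

.empty_call <- function() {
  data.frame(asv_id = character(), category = character(),
             rule_fired = character(), control_type = character(),
             control_seq_id = character(), identity = numeric(),
             whitelisted = logical(), env_class = character(),
             stringsAsFactors = FALSE)
}

#' Classify a single ASV's origin
#'
#' Applies the deterministic rule cascade:
#'
#' * **R1** — control match at or above threshold and not whitelisted:
#'   `contaminant`.
#' * **R2** — control match but whitelisted: subsurface-like environment gives
#'   `possibly_subsurface`; contaminant-like gives `likely_contaminant`;
#'   ambiguous/absent falls to `unknown_env_policy_matched`.
#' * **R3** — no control match: contaminant-like environment gives
#'   `likely_contaminant`; a subsurface-like environment or whitelist
#'   membership gives `subsurface`; otherwise `unknown_env_policy_unmatched`.
#'
#' A whitelisted ASV can therefore never receive the hard `contaminant` call,
#' though it can still be `likely_contaminant`.
#'
#' @param query single DNA sequence string, named by ASV id.
#' @param total_reads total read count of the ASV across samples (used only
#'   by the optional abundance gate).
#' @param controls a [control_collection()], or `NULL`.
#' @param whitelist whitelist sequences/ids (see [in_whitelist()]), or `NULL`.
#' @param env_class precomputed environment class from
#'   [classify_environment()], or `"absent"`.
#' @param params a [classifier_params()] object.
#' @return one-row data frame: `asv_id`, `category`, `rule_fired`,
#'   `control_type`, `control_seq_id`, `identity`, `whitelisted`, `env_class`.
#' @export
classify_asv <- function(query, total_reads = Inf, controls = NULL,
                         whitelist = NULL, env_class = "absent",
                         params = classifier_params()) {
  has_controls <- !is.null(controls) && any(lengths(unclass(controls)) > 0L)
  has_wl <- !is.null(whitelist) && length(whitelist) > 0L
  if (!has_controls && !has_wl) {
    .err("classifier needs at least one evidence source: controls or whitelist")
  }
  if (!env_class %in% c("subsurface_like", "contaminant_like", "ambiguous", "absent")) {
    .err("invalid env_class '%s'", env_class)
  }
  asv_id <- if (!is.null(names(query))) names(query)[1L] else NA_character_

  ev <- if (has_controls) best_control_match(query, controls, params$identity) else NULL
  wl <- if (has_wl) {
    in_whitelist(query, whitelist, params$whitelist_match_mode, params$identity)$hit
  } else {
    FALSE
  }

  gated <- !is.null(params$abundance_gate_reads) &&
    is.finite(total_reads) && total_reads <= params$abundance_gate_reads
  env_eff <- if (gated) "absent" else env_class

  if (!is.null(ev) && !wl) {
    category <- "contaminant"; rule <- "R1"
  } else if (!is.null(ev) && wl) {
    if (env_eff == "subsurface_like") {
      category <- "possibly_subsurface"; rule <- "R2_env_subsurface"
    } else if (env_eff == "contaminant_like") {
      category <- "likely_contaminant"; rule <- "R2_env_contaminant"
    } else {
      category <- params$unknown_env_policy_matched; rule <- "R2_policy_default"
    }
  } else {
    if (env_eff == "contaminant_like") {
      category <- "likely_contaminant"; rule <- "R3_env_contaminant"
    } else if (env_eff == "subsurface_like" || wl) {
      category <- "subsurface"; rule <- "R3_subsurface"
    } else {
      category <- params$unknown_env_policy_unmatched; rule <- "R3_policy_default"
    }
  }
  data.frame(asv_id = asv_id, category = category, rule_fired = rule,
             control_type = if (is.null(ev)) NA_character_ else ev$control_type,
             control_seq_id = if (is.null(ev)) NA_character_ else ev$control_seq_id,
             identity = if (is.null(ev)) NA_real_ else ev$identity,
             whitelisted = wl, env_class = env_class,
             stringsAsFactors = FALSE)
}

#' Classify every ASV of a count table
#'
#' @param counts integer count matrix (ASV rows x sample columns), as from
#'   [read_count_table()].
#' @param seqs named character vector of ASV sequences covering every row.
#' @param controls a [control_collection()], or `NULL`.
#' @param whitelist whitelist sequences/ids, or `NULL`.
#' @param blast best-hit table from [read_blast_tab()], or `NULL` (no
#'   environment evidence).
#' @param env_map an [environment_map()].
#' @param params a [classifier_params()] object.
#' @return data frame of origin calls, one row per ASV in table row order.
#' @export
classify_table <- function(counts, seqs, controls = NULL, whitelist = NULL,
                           blast = NULL, env_map = environment_map(),
                           params = classifier_params()) {
  asv_ids <- rownames(counts)
  if (is.null(asv_ids)) .err("count matrix must have ASV row names")
  missing <- setdiff(asv_ids, names(seqs))
  if (length(missing)) {
    .err("no sequence supplied for ASV(s): %s", paste(missing, collapse = ", "))
  }
  env <- rep("absent", length(asv_ids))
  names(env) <- asv_ids
  if (!is.null(blast) && nrow(blast)) {
    hit <- blast[blast$query_id %in% asv_ids, ]
    env[hit$query_id] <- classify_environment(hit$subject_description, env_map)
  }
  totals <- rowSums(counts)
  calls <- lapply(asv_ids, function(id) {
    classify_asv(stats::setNames(seqs[[id]], id), total_reads = totals[[id]],
                 controls = controls, whitelist = whitelist,
                 env_class = env[[id]], params = params)
  })
  out <- do.call(rbind, c(list(.empty_call()), calls))
  rownames(out) <- NULL
  out
}

#' Remove contaminant-category ASVs from a count table
#'
#' Drops rows called `contaminant` or `likely_contaminant` and reports, per
#' sample, the fraction of reads removed and whether the sample lost its
#' entire read count (fully excluded).
#'
#' @param counts integer count matrix.
#' @param calls origin calls from [classify_table()] covering every row.
#' @return list with `counts` (filtered matrix) and `report` (data frame:
#'   `sample_id`, `reads_before`, `reads_after`, `fraction_removed`,
#'   `fully_excluded`).
#' @export
filter_contaminants <- function(counts, calls) {
  asv_ids <- rownames(counts)
  if (!all(asv_ids %in% calls$asv_id)) {
    .err("origin calls do not cover all table rows")
  }
  cat_of <- stats::setNames(calls$category, calls$asv_id)[asv_ids]
  drop <- cat_of %in% c("contaminant", "likely_contaminant")
  filtered <- counts[!drop, , drop = FALSE]
  before <- colSums(counts)
  after <- colSums(filtered)
  report <- data.frame(
    sample_id = colnames(counts),
    reads_before = as.integer(before),
    reads_after = as.integer(after),
    fraction_removed = ifelse(before > 0, (before - after) / before, 0),
    fully_excluded = before > 0 & after == 0,
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  list(counts = filtered, report = report)
}
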