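# Seeded synthetic-data generator producing every input the pipeline
# consumes, with recorded ground truth.  The generator's job is to create a
# *separable* regime: contaminant ASVs appear verbatim in the control sets,
# indigenous ASVs stay below a pairwise-identity ceiling against everything
# else, so classifier precision/recall against truth is exactly measurable.

.SUBSURFACE_DESCRIPTIONS <- c(
  "serpentinite-hosted subsurface fluid clone",
  "deep marine sediment clone",
  "terrestrial subsurface aquifer isolate",
  "hydrothermal vent chimney clone",
  "basaltic borehole crustal fluid clone"
)

.CONTAMINANT_DESCRIPTIONS <- c(
  "human skin microbiome isolate",
  "laboratory reagent contaminant clone",
  "drilling grease sample clone",
  "DNA extraction kit contaminant"
)

.CONTAMINANT_TAXA <- data.frame(
  domain = "Bacteria",
  phylum = c("Proteobacteria", "Proteobacteria", "Actinobacteriota",
             "Firmicutes", "Proteobacteria"),
  class = c("Gammaproteobacteria", "Gammaproteobacteria", "Actinobacteria",
            "Bacilli", "Alphaproteobacteria"),
  order = c("Oceanospirillales", "Alteromonadales", "Propionibacteriales",
            "Bacillales", "Sphingomonadales"),
  family = c("Halomonadaceae", "Shewanellaceae", "Propionibacteriaceae",
             "Staphylococcaceae", "Sphingomonadaceae"),
  genus = c("Halomonas", "Shewanella", "Cutibacterium", "Staphylococcus",
            "Sphingomonas"),
  stringsAsFactors = FALSE
)

.INDIGENOUS_FAMILIES <- data.frame(
  domain = "Bacteria",
  phylum = c("Acidobacteriota", "Chloroflexi", "Dadabacteria",
             "Nitrospirota", "Patescibacteria", "Gemmatimonadota"),
  class = c("Acidobacteriae", "Dehalococcoidia", "Dadabacteriia",
            "Nitrospiria", "Microgenomatia", "Gemmatimonadetes"),
  order = c("Acidobacteriales", "Dehalococcoidales", "Dadabacteriales",
            "Nitrospirales", NA, "Gemmatimonadales"),
  family = c("Acidobacteriaceae", "Dehalococcoidaceae", NA,
             "Nitrospiraceae", NA, "Gemmatimonadaceae"),
  genus = NA_character_,
  stringsAsFactors = FALSE
)

#' Synthetic-community generator parameters
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 20 indigenous and 10 contaminant ASVs of 370 nt (V4V5-like
#' amplicon length), 8 samples sequenced to 50,000 reads each with planted
#' contaminant read fractions spanning 0 to 1, a whitelist drawn from the
#' indigenous pool, and control sets in which the no-template control is
#' dominated by its first two taxa (110 and 21 reads of a 147-read control,
#' the canonical reagent-contamination signature).
#'
#' @param n_indigenous number of indigenous ASVs.
#' @param n_contaminant number of contaminant ASVs.
#' @param asv_length amplicon length in nt.
#' @param n_samples number of samples.
#' @param read_depth reads per sample.
#' @param contaminant_fraction per-sample planted contaminant read fraction
#'   (recycled to `n_samples`).
#' @param whitelist_fraction fraction of the indigenous pool whitelisted.
#' @param whitelist_decoys number of contaminant ASVs additionally placed on
#'   the whitelist (decoys exercising the whitelist-exception rules).
#' @param n_variants number of near-threshold contaminant variants added to
#'   the ASV pool.
#' @param variant_substitutions substitutions carried by each variant
#'   (3 over 370 nt gives identity 367/370, just above a 0.99 threshold).
#' @param ntc_dominant_reads read counts attributed to the two dominant
#'   no-template-control taxa.
#' @param ntc_total_reads total no-template-control read count.
#' @param env_hit_rate fraction of ASVs given a database best hit with an
#'   environment description.
#' @param lognormal_sigma sigma of the log-normal indigenous
#'   relative-abundance model.
#' @param max_pairwise_identity separability ceiling: indigenous ASVs must
#'   stay below this identity to every other sequence (default 0.97).
#' @param seed mandatory RNG seed; same seed, same community, byte for byte.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_indigenous = 20, n_contaminant = 10,
                             asv_length = 370, n_samples = 8,
                             read_depth = 50000,
                             contaminant_fraction = seq(0, 1, length.out = n_samples),
                             whitelist_fraction = 0.5, whitelist_decoys = 0,
                             n_variants = 0, variant_substitutions = 3,
                             ntc_dominant_reads = c(110, 21),
                             ntc_total_reads = 147,
                             env_hit_rate = 0.75,
                             lognormal_sigma = 1,
                             max_pairwise_identity = 0.97,
                             seed) {
  if (missing(seed) || !is.numeric(seed)) .err("a numeric RNG seed is mandatory")
  contaminant_fraction <- rep_len(contaminant_fraction, n_samples)
  if (any(contaminant_fraction < 0 | contaminant_fraction > 1)) {
    .err("contaminant fractions must lie in [0, 1]")
  }
  if (read_depth < 0) .err("read_depth must be >= 0")
  if (n_indigenous < 1 || n_contaminant < 1) {
    .err("need at least one indigenous and one contaminant ASV")
  }
  if (whitelist_fraction < 0 || whitelist_fraction > 1) {
    .err("whitelist_fraction must lie in [0, 1]")
  }
  structure(list(n_indigenous = as.integer(n_indigenous),
                 n_contaminant = as.integer(n_contaminant),
                 asv_length = as.integer(asv_length),
                 n_samples = as.integer(n_samples),
                 read_depth = as.integer(read_depth),
                 contaminant_fraction = contaminant_fraction,
                 whitelist_fraction = whitelist_fraction,
                 whitelist_decoys = as.integer(whitelist_decoys),
                 n_variants = as.integer(n_variants),
                 variant_substitutions = as.integer(variant_substitutions),
                 ntc_dominant_reads = ntc_dominant_reads,
                 ntc_total_reads = ntc_total_reads,
                 env_hit_rate = env_hit_rate,
                 lognormal_sigma = lognormal_sigma,
                 max_pairwise_identity = max_pairwise_identity,
                 seed = as.integer(seed)),
            class = "generator_params")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_dna <- function(seq, n_subs) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(chars), n_subs)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Generate `n` sequences of length L pairwise below the identity ceiling
# (also below the ceiling against `against`).  Uniform random DNA virtually
# always satisfies the ceiling; rejection sampling guards the guarantee.
.generate_distinct <- function(n, L, ceiling, against = character(), params_id) {
  out <- character(0)
  attempts <- 0L
  while (length(out) < n) {
    attempts <- attempts + 1L
    if (attempts > 50L * n) {
      .err("cannot generate %d sequences of length %d below pairwise identity %.2f",
           n, L, ceiling)
    }
    cand <- .random_dna(L)
    others <- c(out, against)
    if (length(others)) {
      ids <- .pair_identity(others, cand, params_id)
      if (any(ids >= ceiling)) next
    }
    out <- c(out, cand)
  }
  out
}

# Exhaustive separability certificate: every contaminant-origin ASV must
# reach the classification threshold against some control; every indigenous
# ASV must stay below the ceiling against every control.  Run before truth
# is written so downstream precision/recall tests cannot pass vacuously.
.verify_separability <- function(seqs, truth, controls, params) {
  idp <- identity_params(threshold = 0.99, use_prescreen = FALSE)
  ctrl <- unlist(lapply(unclass(controls)[.CONTROL_TYPES], unname))
  for (i in seq_along(seqs)) {
    ids <- .pair_identity(ctrl, seqs[[i]], idp)
    best <- max(ids)
    if (truth$true_origin[i] == "contaminant") {
      if (best < idp$threshold) {
        .err("separability violated: contaminant ASV '%s' has max control identity %.4f",
             names(seqs)[i], best)
      }
    } else if (best >= params$max_pairwise_identity) {
      .err("separability violated: indigenous ASV '%s' has max control identity %.4f",
           names(seqs)[i], best)
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic community with recorded truth
#'
#' Produces ASV sequences, control collections seeded verbatim with the
#' contaminant pool, a whitelist, a best-hit environment table, a taxonomy
#' and per-ASV truth.  Contaminant ASVs are copied into exactly one control
#' set each (round-robin over NTC, drilling fluid, seawater); optional
#' near-threshold variants carry a stated substitution count relative to a
#' contaminant.  Before returning, an exhaustive pairwise-identity
#' certificate checks the separable-regime guarantees and errors if they do
#' not hold.
#'
#' @param params a [generator_params()] object.
#' @return list with `seqs`, `controls` (a [control_collection()]),
#'   `whitelist`, `blast` (best-hit data frame), `taxonomy`, `truth`
#'   (data frame `asv_id`, `true_origin`), `ntc_weights` and `params`.
#' @export
make_community <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  idp <- identity_params(use_prescreen = FALSE)
  L <- params$asv_length
  id_ceiling <- params$max_pairwise_identity

  cont <- .generate_distinct(params$n_contaminant, L, id_ceiling, params_id = idp)
  names(cont) <- sprintf("contam_%03d", seq_along(cont))
  indi <- .generate_distinct(params$n_indigenous, L, id_ceiling, against = cont,
                             params_id = idp)
  names(indi) <- sprintf("indig_%03d", seq_along(indi))

  # near-threshold variants of contaminants join the ASV pool as contaminants
  vars <- character(0)
  if (params$n_variants > 0) {
    src <- rep_len(seq_along(cont), params$n_variants)
    vars <- vapply(src, function(i) .mutate_dna(cont[[i]], params$variant_substitutions),
                   character(1))
    names(vars) <- sprintf("variant_%03d", seq_along(vars))
  }
  seqs <- c(indi, cont, vars)

  truth <- data.frame(
    asv_id = names(seqs),
    true_origin = c(rep("indigenous", length(indi)),
                    rep("contaminant", length(cont) + length(vars))),
    stringsAsFactors = FALSE
  )

  # controls: each contaminant lands verbatim in one set, round-robin
  assign_to <- rep_len(.CONTROL_TYPES, length(cont))
  sets <- lapply(.CONTROL_TYPES, function(ty) {
    s <- cont[assign_to == ty]
    if (length(s)) {
      names(s) <- sprintf("%s_%03d", ty, seq_along(s))
    }
    s
  })
  names(sets) <- .CONTROL_TYPES
  controls <- control_collection(ntc = sets$ntc, drill_fluid = sets$drill_fluid,
                                 seawater = sets$seawater)

  # no-template-control read weights: two dominant taxa carry the bulk
  k <- length(sets$ntc)
  ntc_weights <- if (k) {
    dom <- rep_len(params$ntc_dominant_reads, min(2L, k))
    rest <- max(params$ntc_total_reads - sum(dom), 0)
    w <- c(dom, if (k > 2L) rep(ceiling(rest / (k - 2L)), k - 2L))
    stats::setNames(w[seq_len(k)], names(sets$ntc))
  } else {
    stats::setNames(numeric(0), character(0))
  }

  # whitelist: indigenous subset plus optional contaminant decoys
  n_wl <- floor(params$whitelist_fraction * length(indi))
  wl <- indi[seq_len(n_wl)]
  if (params$whitelist_decoys > 0) {
    wl <- c(wl, cont[seq_len(min(params$whitelist_decoys, length(cont)))])
  }

  # environment best-hit table consistent with truth
  hit <- stats::runif(length(seqs)) < params$env_hit_rate
  desc <- ifelse(truth$true_origin == "indigenous",
                 sample(.SUBSURFACE_DESCRIPTIONS, length(seqs), replace = TRUE),
                 sample(.CONTAMINANT_DESCRIPTIONS, length(seqs), replace = TRUE))
  blast <- data.frame(
    query_id = names(seqs)[hit],
    subject_id = sprintf("DB%05d", seq_len(sum(hit))),
    percent_identity = round(stats::runif(sum(hit), 90, 100), 2),
    alignment_length = L,
    bitscore = round(stats::runif(sum(hit), 300, 700), 1),
    subject_description = desc[hit],
    stringsAsFactors = FALSE
  )

  # taxonomy: indigenous ASVs from subsurface clades (some unresolved beyond
  # phylum), contaminants from the classic contaminant genera
  itax <- .INDIGENOUS_FAMILIES[rep_len(seq_len(nrow(.INDIGENOUS_FAMILIES)),
                                       length(indi)), ]
  ctax <- .CONTAMINANT_TAXA[rep_len(seq_len(nrow(.CONTAMINANT_TAXA)),
                                    length(cont) + length(vars)), ]
  taxonomy <- cbind(data.frame(asv_id = names(seqs), stringsAsFactors = FALSE),
                    rbind(itax, ctax))
  rownames(taxonomy) <- NULL

  .verify_separability(seqs, truth, controls, params)

  list(seqs = seqs, controls = controls, whitelist = wl, blast = blast,
       taxonomy = taxonomy, truth = truth, ntc_weights = ntc_weights,
       params = params)
}

#' Draw per-sample read counts for a synthetic community
#'
#' Per sample, reads are multinomial: the planted contaminant fraction of
#' probability mass is split uniformly over contaminant-origin ASVs and the
#' remainder over indigenous ASVs with log-normal relative abundances (drawn
#' once per community).  The expected contaminant read fraction equals the
#' planted value exactly.
#'
#' @param community output of [make_community()].
#' @param params the same [generator_params()] object.
#' @return list with `counts` (integer matrix ASV x sample) and
#'   `sample_truth` (data frame `sample_id`,
#'   `planted_contaminant_fraction`, `realized_contaminant_fraction`).
#' @export
sample_counts <- function(community, params) {
  set.seed(params$seed + 1L)
  seqs <- community$seqs
  is_cont <- community$truth$true_origin == "contaminant"
  n_cont <- sum(is_cont)
  n_indi <- sum(!is_cont)
  indi_w <- stats::rlnorm(n_indi, meanlog = 0, sdlog = params$lognormal_sigma)
  indi_w <- indi_w / sum(indi_w)
  sample_ids <- sprintf("S%02d", seq_len(params$n_samples))
  counts <- matrix(0L, length(seqs), params$n_samples,
                   dimnames = list(names(seqs), sample_ids))
  for (j in seq_len(params$n_samples)) {
    f <- params$contaminant_fraction[j]
    prob <- numeric(length(seqs))
    prob[is_cont] <- f / n_cont
    prob[!is_cont] <- (1 - f) * indi_w
    if (params$read_depth > 0) {
      counts[, j] <- as.integer(stats::rmultinom(1L, params$read_depth, prob))
    }
  }
  realized <- colSums(counts[is_cont, , drop = FALSE]) /
    pmax(colSums(counts), 1L)
  list(counts = counts,
       sample_truth = data.frame(
         sample_id = sample_ids,
         planted_contaminant_fraction = params$contaminant_fraction,
         realized_contaminant_fraction = as.numeric(realized),
         stringsAsFactors = FALSE))
}

#' Synthetic drilling-tracer values
#'
#' Tracer concentration as a strictly increasing function of the planted
#' contaminant fraction (heavily contaminated samples carry more drilling
#' fluid), with optional log-scale noise.  With `noise_sd = 0` and distinct
#' planted fractions the values are strictly monotone in the fractions.
#'
#' @param contaminant_fraction per-sample planted contaminant fraction.
#' @param noise_sd standard deviation of log10-scale noise (default 0).
#' @param seed RNG seed.
#' @return numeric tracer concentrations (pg per cm^3 scale).
#' @export
make_tracer <- function(contaminant_fraction, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  10^(1 + 4 * contaminant_fraction +
        stats::rnorm(length(contaminant_fraction), 0, noise_sd))
}

#' Construct synthetic genome annotations with planted truth
#'
#' Builds a KO annotation table whose pathway-completeness and marker-copy
#' matrices equal the planted targets exactly.  Each completeness target must
#' be expressible as `k / |defining KOs|` for its pathway; pathways or
#' markers with overlapping KO sets can make targets jointly unachievable,
#' which is detected by scoring the constructed annotations and reported as
#' an error.
#'
#' @param pathways pathway definitions (as from [read_pathway_defs()]).
#' @param completeness_targets numeric matrix (genome x pathway) of planted
#'   fractions; dimnames required.
#' @param markers optional marker definitions.
#' @param marker_targets optional integer matrix (genome x marker) of planted
#'   copy numbers.
#' @param genome_type per-genome type (`"MAG"`/`"SAG"`, recycled).
#' @param viral_flags per-genome logical viral-evidence flags (recycled).
#' @param seed RNG seed (controls which defining KOs are withheld).
#' @return list with `ko` (annotation triples), `genomes` (metadata table)
#'   and `truth` (the planted targets).
#' @export
make_genomes <- function(pathways, completeness_targets, markers = NULL,
                         marker_targets = NULL, genome_type = "SAG",
                         viral_flags = FALSE, seed = 1L) {
  set.seed(seed)
  genome_ids <- rownames(completeness_targets)
  if (is.null(genome_ids)) .err("completeness_targets needs genome row names")
  if (!setequal(colnames(completeness_targets), pathways$pathway_id)) {
    .err("completeness_targets columns must match pathway ids")
  }
  rows <- list()
  for (g in genome_ids) {
    kos <- character(0)
    for (p in seq_len(nrow(pathways))) {
      def <- pathways$kos[[p]]
      target <- completeness_targets[g, pathways$pathway_id[p]]
      k <- target * length(def)
      if (abs(k - round(k)) > 1e-9) {
        .err("target %.4f for genome '%s', pathway '%s' is not expressible as k/%d",
             target, g, pathways$pathway_id[p], length(def))
      }
      k <- as.integer(round(k))
      if (k > 0) kos <- c(kos, sample(def, k))
    }
    kos <- unique(kos)
    copies <- stats::setNames(rep(1L, length(kos)), kos)
    if (!is.null(markers) && !is.null(marker_targets)) {
      for (m in seq_len(nrow(markers))) {
        target <- marker_targets[g, markers$marker_id[m]]
        if (target > 0) {
          first <- markers$kos[[m]][1L]
          extra <- markers$kos[[m]][-1L]
          copies <- copies[!names(copies) %in% extra]
          copies[first] <- as.integer(target)
        } else {
          copies <- copies[!names(copies) %in% markers$kos[[m]]]
        }
      }
    }
    if (length(copies)) {
      rows[[g]] <- data.frame(genome_id = g, ko = names(copies),
                              copies = as.integer(copies),
                              stringsAsFactors = FALSE)
    }
  }
  ko_df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(genome_id = character(), ko = character(), copies = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(ko_df) <- NULL

  got <- suppressWarnings(completeness_matrix(ko_df, pathways,
                                              genome_ids = genome_ids))
  got <- got[rownames(completeness_targets), colnames(completeness_targets),
             drop = FALSE]
  if (!isTRUE(all.equal(unname(got), unname(completeness_targets),
                        tolerance = 1e-12))) {
    .err("planted completeness targets are not jointly achievable (overlapping KO definitions?)")
  }
  if (!is.null(markers) && !is.null(marker_targets)) {
    gm <- marker_gene_matrix(ko_df, markers, genome_ids = genome_ids)
    gm <- gm[rownames(marker_targets), colnames(marker_targets), drop = FALSE]
    if (!identical(unname(gm), unname(apply(marker_targets, c(1, 2), as.integer)))) {
      .err("planted marker copy targets are not jointly achievable (overlapping KO definitions?)")
    }
  }
  genomes <- data.frame(
    genome_id = genome_ids,
    genome_type = rep_len(genome_type, length(genome_ids)),
    completeness_estimate = round(stats::runif(length(genome_ids), 1, 60), 1),
    contamination_estimate = round(stats::runif(length(genome_ids), 0, 2), 2),
    has_viral_evidence = rep_len(viral_flags, length(genome_ids)),
    has_ssu = rep_len(TRUE, length(genome_ids)),
    stringsAsFactors = FALSE
  )
  list(ko = ko_df, genomes = genomes,
       truth = list(completeness = completeness_targets,
                    marker_copies = marker_targets))
}
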