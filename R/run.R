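# Pipeline orchestration: each run_* function wraps one pipeline stage,
# reads/writes the on-disk formats, and logs a manifest (package version,
# resolved parameters, seed, input checksums) for reproducibility.  A thin
# command-line front end over these functions ships in exec/asvorigin.

.dataset_files <- c(
  seqs = "asvs.fasta", ntc = "controls_ntc.fasta",
  drill_fluid = "controls_drill_fluid.fasta",
  seawater = "controls_seawater.fasta", whitelist = "whitelist.fasta",
  blast = "blast_hits.tsv", counts = "counts.tsv", taxonomy = "taxonomy.tsv",
  samples = "samples.tsv", truth_asv = "truth_asv.tsv",
  truth_samples = "truth_samples.tsv"
)

# strip S3 classes recursively so parameter objects serialise as plain lists
.unclass_deep <- function(x) {
  if (is.list(x)) lapply(x, .unclass_deep) else x
}

.manifest <- function(outdir, stage, params, inputs = character()) {
  params <- .unclass_deep(unclass(params))
  inputs <- inputs[file.exists(inputs)]
  write_json_report(list(
    package = "asvorigin",
    version = as.character(utils::packageVersion("asvorigin")),
    stage = stage,
    params = params,
    input_checksums = as.list(tools::md5sum(inputs))
  ), file.path(outdir, sprintf("manifest_%s.json", stage)))
}

.prepare_outdir <- function(outdir, force) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force) {
    .err("output directory '%s' is not empty (use force = TRUE to overwrite)", outdir)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  invisible(outdir)
}

#' Simulate a complete synthetic dataset on disk
#'
#' Writes every input the classification pipeline consumes — ASV FASTA,
#' control FASTAs, whitelist, best-hit table, count table, taxonomy, a sample
#' table whose interior-tracer column carries the synthetic tracer — plus the
#' ground-truth tables and a manifest.
#'
#' @param outdir output directory.
#' @param params a [generator_params()] object.
#' @param tracer_noise_sd log-scale tracer noise (default 0: noise-free,
#'   strictly monotone in the planted contaminant fraction).
#' @param force overwrite a nonempty output directory.
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(outdir, params, tracer_noise_sd = 0, force = FALSE) {
  .prepare_outdir(outdir, force)
  community <- make_community(params)
  drawn <- sample_counts(community, params)
  tracer <- make_tracer(drawn$sample_truth$planted_contaminant_fraction,
                        noise_sd = tracer_noise_sd, seed = params$seed + 2L)

  f <- function(name) file.path(outdir, .dataset_files[[name]])
  write_fasta(community$seqs, f("seqs"))
  for (ty in .CONTROL_TYPES) {
    set <- community$controls[[ty]]
    if (length(set)) write_fasta(set, f(ty))
  }
  if (length(community$whitelist)) write_fasta(community$whitelist, f("whitelist"))
  blast12 <- data.frame(
    qseqid = community$blast$query_id, sseqid = community$blast$subject_id,
    pident = community$blast$percent_identity,
    length = community$blast$alignment_length,
    mismatch = 0L, gapopen = 0L, qstart = 1L,
    qend = community$blast$alignment_length, sstart = 1L,
    send = community$blast$alignment_length, evalue = 0,
    bitscore = community$blast$bitscore,
    sdesc = community$blast$subject_description,
    stringsAsFactors = FALSE
  )
  .write_atomic(function(tmp) {
    utils::write.table(blast12, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }, f("blast"))
  write_count_table(drawn$counts, f("counts"))
  write_tsv(community$taxonomy, f("taxonomy"))

  st <- drawn$sample_truth
  lith <- rep_len(c("carbonate sand", "serpentinized harzburgite"), nrow(st))
  write_tsv(data.frame(
    sample_id = st$sample_id, lithology = lith, cell_density = "n.d.",
    pcr = "+", seq = "+",
    pfc_int = format(tracer, scientific = TRUE, digits = 8),
    pfc_ext = "n.d.", stringsAsFactors = FALSE
  ), f("samples"))
  write_tsv(community$truth, f("truth_asv"))
  st$tracer <- tracer
  write_tsv(st, f("truth_samples"))
  .manifest(outdir, "simulate",
            c(unclass(params), list(tracer_noise_sd = tracer_noise_sd)))
  invisible(outdir)
}

.load_dataset <- function(dir) {
  f <- function(name) file.path(dir, .dataset_files[[name]])
  need <- c("seqs", "counts")
  for (name in need) {
    if (!file.exists(f(name))) .err("dataset file missing: '%s'", f(name))
  }
  ctrl <- list()
  for (ty in .CONTROL_TYPES) {
    ctrl[[ty]] <- if (file.exists(f(ty))) read_fasta(f(ty)) else NULL
  }
  list(
    seqs = read_fasta(f("seqs")),
    controls = if (any(!vapply(ctrl, is.null, logical(1)))) {
      control_collection(ctrl$ntc, ctrl$drill_fluid, ctrl$seawater)
    } else {
      NULL
    },
    whitelist = if (file.exists(f("whitelist"))) read_fasta(f("whitelist")) else NULL,
    blast = if (file.exists(f("blast"))) read_blast_tab(f("blast")) else NULL,
    counts = read_count_table(f("counts")),
    taxonomy = if (file.exists(f("taxonomy"))) read_taxonomy(f("taxonomy")) else NULL,
    samples = if (file.exists(f("samples"))) read_sample_table(f("samples")) else NULL,
    truth_asv = if (file.exists(f("truth_asv"))) {
      utils::read.delim(f("truth_asv"), stringsAsFactors = FALSE)
    } else {
      NULL
    },
    truth_samples = if (file.exists(f("truth_samples"))) {
      utils::read.delim(f("truth_samples"), stringsAsFactors = FALSE)
    } else {
      NULL
    }
  )
}

#' Classify a dataset directory and write decontamination outputs
#'
#' Runs the four-category classifier over a dataset directory (as written by
#' [run_simulate()], or assembled by hand with the same file names), filters
#' contaminant categories, and writes `calls.tsv`, `filtered_counts.tsv` and
#' `removal_report.tsv`.  When ground truth is present, an `evaluation.json`
#' with contaminant-category precision/recall and planted-vs-realized removal
#' fractions is written as well.
#'
#' @param data_dir dataset directory.
#' @param outdir output directory (default: a `classify` subdirectory).
#' @param params a [classifier_params()] object.
#' @param env_map an [environment_map()].
#' @param force overwrite a nonempty output directory.
#' @return list with `calls`, `filtered` (counts), `report`, `evaluation`
#'   (or `NULL`), invisibly.
#' @export
run_classify <- function(data_dir, outdir = file.path(data_dir, "classify"),
                         params = classifier_params(),
                         env_map = environment_map(), force = FALSE) {
  ds <- .load_dataset(data_dir)
  .prepare_outdir(outdir, force)
  calls <- classify_table(ds$counts, ds$seqs, ds$controls, ds$whitelist,
                          ds$blast, env_map, params)
  filt <- filter_contaminants(ds$counts, calls)
  write_tsv(calls, file.path(outdir, "calls.tsv"))
  write_count_table(filt$counts, file.path(outdir, "filtered_counts.tsv"))
  write_tsv(filt$report, file.path(outdir, "removal_report.tsv"))

  evaluation <- NULL
  if (!is.null(ds$truth_asv)) {
    truth_cont <- ds$truth_asv$asv_id[ds$truth_asv$true_origin == "contaminant"]
    called_cont <- calls$asv_id[calls$category == "contaminant"]
    tp <- length(intersect(called_cont, truth_cont))
    precision <- if (length(called_cont)) tp / length(called_cont) else NA_real_
    recall <- if (length(truth_cont)) tp / length(truth_cont) else NA_real_
    evaluation <- list(contaminant_precision = precision,
                       contaminant_recall = recall,
                       n_true_contaminant = length(truth_cont),
                       n_called_contaminant = length(called_cont))
    if (!is.null(ds$truth_samples)) {
      m <- merge(filt$report, ds$truth_samples, by = "sample_id")
      evaluation$max_abs_removal_error <-
        max(abs(m$fraction_removed - m$planted_contaminant_fraction))
    }
    write_json_report(evaluation, file.path(outdir, "evaluation.json"))
  }
  .manifest(outdir, "classify", unclass(params),
            inputs = file.path(data_dir, .dataset_files))
  invisible(list(calls = calls, filtered = filt$counts, report = filt$report,
                 evaluation = evaluation))
}

#' Summarize a classified dataset
#'
#' Writes per-sample origin-category profiles, decontaminated family-level
#' composition, the tracer comparison and — when a sample table is present —
#' the screening-success summary.
#'
#' @param data_dir dataset directory (with a completed `classify`
#'   subdirectory, or pass `classify_dir`).
#' @param classify_dir directory holding classification outputs.
#' @param outdir output directory.
#' @param min_family_fraction collapse threshold for
#'   [family_composition()]; 0 disables collapsing.
#' @param bdl_policy tracer sentinel policy, see [tracer_comparison()].
#' @param force overwrite a nonempty output directory.
#' @return list with `profiles`, `families`, `tracer`, `screening`,
#'   invisibly.
#' @export
run_summarize <- function(data_dir, classify_dir = file.path(data_dir, "classify"),
                          outdir = file.path(data_dir, "summary"),
                          min_family_fraction = 0.001,
                          bdl_policy = "exclude", force = FALSE) {
  ds <- .load_dataset(data_dir)
  calls_path <- file.path(classify_dir, "calls.tsv")
  if (!file.exists(calls_path)) .err("no classification output at '%s'", calls_path)
  calls <- utils::read.delim(calls_path, stringsAsFactors = FALSE)
  filtered <- read_count_table(file.path(classify_dir, "filtered_counts.tsv"))
  .prepare_outdir(outdir, force)

  profiles <- category_abundance(ds$counts, calls)
  write_tsv(profiles, file.path(outdir, "category_profiles.tsv"))

  families <- NULL
  if (!is.null(ds$taxonomy)) {
    families <- family_composition(filtered, ds$taxonomy, min_family_fraction)
    fam_df <- data.frame(family = rownames(families), families,
                         check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(fam_df, file.path(outdir, "family_composition.tsv"))
  }
  tracer <- screening <- NULL
  if (!is.null(ds$samples)) {
    tracer <- tracer_comparison(profiles, ds$samples, bdl_policy = bdl_policy)
    write_json_report(tracer, file.path(outdir, "tracer_report.json"))
    screening <- summarize_screening(ds$samples)
    write_json_report(screening, file.path(outdir, "screening_summary.json"))
  }
  .manifest(outdir, "summarize",
            list(min_family_fraction = min_family_fraction,
                 bdl_policy = bdl_policy))
  invisible(list(profiles = profiles, families = families, tracer = tracer,
                 screening = screening))
}

#' Profile genome annotations
#'
#' Computes the pathway-completeness and marker-gene matrices for a KO
#' annotation table and writes them alongside a viral-evidence summary.
#'
#' @param ko_path KO annotation TSV (see [read_ko_table()]).
#' @param genome_path genome metadata TSV (see [read_genome_table()]), or
#'   `NULL` to skip the viral summary.
#' @param outdir output directory.
#' @param pathway_path pathway definition TSV (packaged default).
#' @param marker_path marker definition TSV (packaged default).
#' @param force overwrite a nonempty output directory.
#' @return list with `completeness`, `markers`, `viral`, invisibly.
#' @export
run_profile <- function(ko_path, genome_path = NULL, outdir,
                        pathway_path = default_pathway_file(),
                        marker_path = default_marker_file(), force = FALSE) {
  ko <- read_ko_table(ko_path)
  pathways <- read_pathway_defs(pathway_path)
  markers <- read_marker_defs(marker_path)
  genomes <- if (!is.null(genome_path)) read_genome_table(genome_path) else NULL
  .prepare_outdir(outdir, force)
  ids <- if (!is.null(genomes)) genomes$genome_id else NULL
  comp <- completeness_matrix(ko, pathways, genome_ids = ids)
  mark <- marker_gene_matrix(ko, markers, genome_ids = ids)
  write_tsv(data.frame(genome_id = rownames(comp), comp, check.names = FALSE),
            file.path(outdir, "pathway_completeness.tsv"))
  write_tsv(data.frame(genome_id = rownames(mark), mark, check.names = FALSE),
            file.path(outdir, "marker_genes.tsv"))
  viral <- NULL
  if (!is.null(genomes)) {
    viral <- summarize_viral_evidence(genomes)
    write_tsv(viral, file.path(outdir, "viral_summary.tsv"))
  }
  .manifest(outdir, "profile", list(pathway_path = pathway_path,
                                    marker_path = marker_path),
            inputs = c(ko_path, genome_path, pathway_path, marker_path))
  invisible(list(completeness = comp, markers = mark, viral = viral))
}
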