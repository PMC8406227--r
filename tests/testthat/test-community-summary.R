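test_that("category profiles are reads-weighted and sum to one", {
  counts <- rbind(a = c(100L, 50L, 0L), b = c(0L, 50L, 0L))
  colnames(counts) <- c("s1", "s2", "s0")
  calls <- data.frame(asv_id = c("a", "b"),
                      category = c("subsurface", "contaminant"),
                      stringsAsFactors = FALSE)
  prof <- category_abundance(counts, calls)
  expect_identical(prof$subsurface, c(1, 0.5, NA))
  expect_identical(prof$contaminant, c(0, 0.5, NA))
  expect_identical(prof$zero_reads, c(FALSE, FALSE, TRUE))
  sums <- rowSums(prof[1:2, c("subsurface", "possibly_subsurface",
                              "likely_contaminant", "contaminant")])
  expect_equal(unname(sums), c(1, 1), tolerance = 1e-9)
})

test_that("family composition aggregates, collapses and labels fallbacks", {
  counts <- rbind(a1 = c(6000L, 3000L), a2 = c(3995L, 6995L),
                  a3 = c(5L, 5L), a4 = c(0L, 0L))
  colnames(counts) <- c("s1", "s2")
  taxonomy <- data.frame(
    asv_id = c("a1", "a2", "a3"),
    domain = "Bacteria",
    phylum = c("Acidobacteriota", "Chloroflexi", "Nitrospirota"),
    class = c("Acidobacteriae", NA, "Nitrospiria"),
    order = c("Acidobacteriales", NA, NA),
    family = c("Acidobacteriaceae", NA, "Nitrospiraceae"),
    genus = NA_character_, stringsAsFactors = FALSE)
  expect_warning(fam <- family_composition(counts, taxonomy), "unknown bacteria")
  expect_true("(p) Chloroflexi" %in% rownames(fam))
  expect_true("other family" %in% rownames(fam))          # a3: max 0.05% < 0.1%
  expect_false("Nitrospiraceae" %in% rownames(fam))
  expect_equal(unname(colSums(fam)), c(1, 1), tolerance = 1e-12)

  # single family holding all reads
  one <- family_composition(counts[1, , drop = FALSE], taxonomy)
  expect_identical(dim(one), c(1L, 2L))
  expect_true(all(one == 1))

  # collapsing disabled keeps every family
  all_fam <- suppressWarnings(
    family_composition(counts, taxonomy, min_overall_fraction = 0))
  expect_true("Nitrospiraceae" %in% rownames(all_fam))
})

test_that("tracer comparison is exact, order-invariant and sentinel-aware", {
  prof <- data.frame(sample_id = sprintf("S%02d", 1:6),
                     subsurface = c(0.9, 0.75, 0.6, 0.45, 0.3, 0.15),
                     possibly_subsurface = 0.05,
                     likely_contaminant = 0, contaminant = 0,
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = prof$sample_id,
                        pfc_interior = c(10, 30, 90, 270, 810, 2430),
                        pfc_interior_flag = "ok", stringsAsFactors = FALSE)
  rep1 <- tracer_comparison(prof, samples)
  expect_identical(rep1$status, "ok")
  expect_identical(rep1$rho, -1)
  expect_identical(rep1$method, "exact_permutation")
  expect_equal(rep1$p_value, 2 / factorial(6))

  shuffled <- samples[c(4, 1, 6, 2, 5, 3), ]
  expect_identical(tracer_comparison(prof[c(2, 5, 1, 3, 6, 4), ], shuffled), rep1)

  samples$pfc_interior_flag <- "bdl"
  samples$pfc_interior <- NA_real_
  bdl <- tracer_comparison(prof, samples)
  expect_identical(bdl$status, "insufficient_data")
  expect_identical(bdl$n_excluded, 6L)
})

test_that("screening summary counts statuses and splits lithology", {
  tab <- read_sample_table(atlantis_sample_file())
  s <- summarize_screening(tab)
  expect_identical(s$n_screened, 29L)
  expect_identical(s$n_cells_detected, 18L)
  expect_identical(s$n_pcr_positive, 9L)
  expect_identical(s$n_sequenced, 8L)
  expect_identical(s$n_sequenced_sediment, 3L)
  expect_identical(s$n_sequenced_crust, 5L)
  expect_identical(s$efficiency_percent_rounded, 28)
  # counting chain holds and survives row permutation
  expect_true(s$n_sequenced <= s$n_pcr_positive &&
                s$n_pcr_positive <= s$n_cells_detected &&
                s$n_cells_detected <= s$n_screened)
  expect_identical(summarize_screening(tab[sample(nrow(tab)), ]), s)
  # override map can reclassify a sequenced sample
  s2 <- summarize_screening(tab, overrides = c(`74A-1R1-0.5` = "crust"))
  expect_identical(s2$n_sequenced_sediment, 2L)
})

test_that("viral-evidence fractions are computed per type and combined", {
  genomes <- data.frame(
    genome_id = sprintf("g%03d", 1:260),
    genome_type = c(rep("MAG", 33), rep("SAG", 227)),
    has_viral_evidence = c(rep(TRUE, 9), rep(FALSE, 24),
                           rep(TRUE, 60), rep(FALSE, 167)),
    stringsAsFactors = FALSE)
  v <- summarize_viral_evidence(genomes)
  expect_identical(v$n_viral[v$genome_type == "MAG"], 9L)
  expect_identical(v$n_viral[v$genome_type == "SAG"], 60L)
  comb <- v[v$genome_type == "combined", ]
  expect_equal(comb$fraction, 69 / 260)
  expect_identical(comb$percent_display, 26.5)

  none <- genomes; none$has_viral_evidence <- FALSE
  expect_identical(summarize_viral_evidence(none)$fraction, c(0, 0, 0))
  all_v <- genomes; all_v$has_viral_evidence <- TRUE
  expect_identical(summarize_viral_evidence(all_v)$fraction, c(1, 1, 1))
})
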