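test_that("generation is deterministic under seed and differs across seeds", {
  p <- small_params(seed = 7)
  c1 <- make_community(p)
  c2 <- make_community(small_params(seed = 7))
  expect_identical(c1, c2)
  c3 <- make_community(small_params(seed = 8))
  expect_false(identical(c1$seqs, c3$seqs))
  d1 <- sample_counts(c1, p)
  d2 <- sample_counts(c2, p)
  expect_identical(d1, d2)
})

test_that("the separable regime is certified by exhaustive pairwise identity", {
  p <- small_params(seed = 13)
  cm <- make_community(p)
  idp <- identity_params(use_prescreen = FALSE)
  ctrl <- c(cm$controls$ntc, cm$controls$drill_fluid, cm$controls$seawater)
  for (i in seq_along(cm$seqs)) {
    ids <- vapply(ctrl, function(s) global_identity(cm$seqs[[i]], s, idp),
                  numeric(1))
    if (cm$truth$true_origin[i] == "contaminant") {
      expect_identical(max(ids), 1)      # verbatim copy in some control set
    } else {
      expect_lt(max(ids), 0.97)
    }
  }
  # whitelist is drawn from the indigenous pool
  expect_true(all(names(cm$whitelist) %in%
                    cm$truth$asv_id[cm$truth$true_origin == "indigenous"]))
})

test_that("near-threshold variants sit just above the 99% threshold", {
  p <- generator_params(n_indigenous = 4, n_contaminant = 2, asv_length = 370,
                        n_samples = 2, read_depth = 100, n_variants = 2,
                        variant_substitutions = 3, seed = 17)
  cm <- make_community(p)
  variants <- grep("^variant_", names(cm$seqs), value = TRUE)
  expect_length(variants, 2)
  for (v in variants) {
    hit <- best_control_match(cm$seqs[v], cm$controls)
    expect_false(is.null(hit))
    expect_equal(hit$identity, 367 / 370)
  }
  expect_true(all(cm$truth$true_origin[cm$truth$asv_id %in% variants] ==
                    "contaminant"))
})

test_that("planted fractions bound the multinomial draws", {
  p <- generator_params(n_indigenous = 5, n_contaminant = 3, asv_length = 100,
                        n_samples = 3, read_depth = 5000,
                        contaminant_fraction = c(0, 0.2, 1), seed = 19)
  cm <- make_community(p)
  drawn <- sample_counts(cm, p)
  is_cont <- cm$truth$true_origin == "contaminant"
  cont_reads <- colSums(drawn$counts[is_cont, , drop = FALSE])
  expect_identical(unname(cont_reads[1]), 0)           # planted 0
  expect_identical(unname(cont_reads[3]), 5000)        # planted 1
  expect_identical(drawn$sample_truth$realized_contaminant_fraction[c(1, 3)],
                   c(0, 1))
})

test_that("realized fractions converge to planted values with depth", {
  deviation_at_depth <- function(depth, seed) {
    p <- generator_params(n_indigenous = 5, n_contaminant = 3, asv_length = 100,
                          n_samples = 2, read_depth = depth,
                          contaminant_fraction = c(0.3, 0.7), seed = seed)
    cm <- make_community(p)
    st <- sample_counts(cm, p)$sample_truth
    max(abs(st$realized_contaminant_fraction - st$planted_contaminant_fraction))
  }
  shallow <- mean(vapply(1:5, function(s) deviation_at_depth(200, s), 0))
  deep <- mean(vapply(1:5, function(s) deviation_at_depth(50000, s), 0))
  expect_lt(deep, shallow)
  expect_lt(deep, 0.01)
})

test_that("synthetic tracer is monotone in contamination and seeded", {
  frac <- seq(0, 1, length.out = 8)
  t1 <- make_tracer(frac, noise_sd = 0, seed = 23)
  expect_identical(stats::cor(rank(t1), rank(frac)), 1)
  expect_true(all(diff(t1) > 0))
  expect_identical(t1, make_tracer(frac, noise_sd = 0, seed = 23))
  expect_false(identical(t1, make_tracer(frac, noise_sd = 0.5, seed = 23)))
})

test_that("planted genomes score back their targets exactly", {
  pathways <- data.frame(pathway_id = c("tca", "wl"),
                         name = c("TCA", "WL"), stringsAsFactors = FALSE)
  pathways$kos <- I(list(sprintf("K%05d", 1:8), sprintf("K%05d", 101:112)))
  targets <- rbind(gA = c(tca = 1, wl = 10 / 12),
                   gB = c(tca = 0.5, wl = 0),
                   gC = c(tca = 0, wl = 0))
  markers <- data.frame(marker_id = c("m1", "m2", "m3"),
                        name = c("x", "y", "z"), stringsAsFactors = FALSE)
  markers$kos <- I(list("K00900", c("K00901", "K00902"), "K00903"))
  mtargets <- rbind(gA = c(m1 = 3L, m2 = 1L, m3 = 0L),
                    gB = c(m1 = 0L, m2 = 0L, m3 = 0L),
                    gC = c(m1 = 0L, m2 = 0L, m3 = 0L))
  g <- make_genomes(pathways, targets, markers, mtargets, seed = 29)
  comp <- suppressWarnings(
    completeness_matrix(g$ko, pathways, genome_ids = rownames(targets)))
  expect_identical(unname(comp), unname(targets))
  expect_equal(comp["gA", "wl"], 10 / 12)
  mark <- marker_gene_matrix(g$ko, markers, genome_ids = rownames(mtargets))
  expect_identical(unname(mark), unname(mtargets))
  # all-zero genome row comes back all-zero
  expect_true(all(comp["gC", ] == 0))

  bad <- targets
  bad["gA", "tca"] <- 0.3                    # 2.4 of 8 KOs: not achievable
  expect_error(make_genomes(pathways, bad, seed = 29), "not expressible")
})
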