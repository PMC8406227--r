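test_that("environment keyword classification follows the map", {
  expect_identical(classify_environment("Serpentinite-hosted subsurface fluid"),
                   "subsurface_like")
  expect_identical(classify_environment("human skin microbiome"),
                   "contaminant_like")
  # contaminant keywords win when both classes match
  expect_identical(classify_environment("drilling fluid from a subsurface borehole"),
                   "contaminant_like")
  expect_identical(classify_environment("soil clone"), "ambiguous")
  expect_identical(classify_environment(NA_character_), "absent")
  expect_error(environment_map(subsurface_keywords = "grease"), "disjoint")
})

test_that("classify_asv fires the documented rule cascade", {
  set.seed(61)
  ntc_seq <- rand_dna(200)
  controls <- control_collection(ntc = c(ntc1 = ntc_seq))

  # R1: control match, not whitelisted -> contaminant
  r1 <- classify_asv(c(a1 = ntc_seq), controls = controls)
  expect_identical(r1$category, "contaminant")
  expect_identical(r1$rule_fired, "R1")
  expect_identical(r1$control_type, "ntc")

  # R2: control match + whitelisted, subsurface-like env -> possibly_subsurface
  sw_seq <- rand_dna(250)
  near <- mutate_seq(sw_seq, 2)          # 248/250 = 0.992 >= 0.99
  ctl2 <- control_collection(seawater = c(sw1 = sw_seq))
  r2 <- classify_asv(c(a2 = near), controls = ctl2, whitelist = c(w1 = near),
                     env_class = "subsurface_like")
  expect_identical(r2$category, "possibly_subsurface")
  expect_identical(r2$rule_fired, "R2_env_subsurface")
  expect_true(r2$whitelisted)

  # R2 ambiguous env falls to the matched-policy default (likely_contaminant)
  r2d <- classify_asv(c(a2 = near), controls = ctl2, whitelist = c(w1 = near),
                      env_class = "ambiguous")
  expect_identical(r2d$category, "likely_contaminant")

  # R3: no control match, subsurface-like env -> subsurface
  other <- rand_dna(200)
  r3 <- classify_asv(c(a3 = other), controls = controls,
                     env_class = "subsurface_like")
  expect_identical(r3$category, "subsurface")
  expect_true(is.na(r3$control_type))

  # R3 default: no control match, no environment evidence
  r3d <- classify_asv(c(a4 = other), controls = controls)
  expect_identical(r3d$category, "possibly_subsurface")
  expect_identical(r3d$rule_fired, "R3_policy_default")

  # R3: contaminant-like env beats whitelist membership
  r3c <- classify_asv(c(a5 = other), controls = controls,
                      whitelist = c(w2 = other), env_class = "contaminant_like")
  expect_identical(r3c$category, "likely_contaminant")

  expect_error(classify_asv(c(a6 = other)), "evidence")
})

test_that("a whitelisted ASV can never be a hard contaminant", {
  set.seed(67)
  ntc_seq <- rand_dna(180)
  controls <- control_collection(ntc = c(n1 = ntc_seq))
  for (env in c("subsurface_like", "contaminant_like", "ambiguous", "absent")) {
    call <- classify_asv(c(x = ntc_seq), controls = controls,
                         whitelist = c(w = ntc_seq), env_class = env)
    expect_false(call$category == "contaminant")
  }
})

test_that("the abundance gate suppresses environment evidence below the gate", {
  set.seed(71)
  seqs <- c(low = rand_dna(150), high = rand_dna(150))
  controls <- control_collection(ntc = c(n1 = rand_dna(150)))
  params <- classifier_params(abundance_gate_reads = 5000)
  low <- classify_asv(seqs["low"], total_reads = 100, controls = controls,
                      env_class = "contaminant_like", params = params)
  expect_identical(low$category, "possibly_subsurface")   # default branch
  high <- classify_asv(seqs["high"], total_reads = 6000, controls = controls,
                       env_class = "contaminant_like", params = params)
  expect_identical(high$category, "likely_contaminant")
})

test_that("classify_table covers every row, in order, permutation-invariantly", {
  set.seed(73)
  ntc_seq <- rand_dna(200)
  sw_seq <- rand_dna(200)
  wl_near <- mutate_seq(sw_seq, 1)
  free1 <- rand_dna(200)
  free2 <- rand_dna(200)
  seqs <- c(a_r1 = ntc_seq, b_r2 = wl_near, c_r3s = free1, d_r3d = free2)
  controls <- control_collection(ntc = c(n1 = ntc_seq), seawater = c(s1 = sw_seq))
  blast <- data.frame(query_id = c("b_r2", "c_r3s"),
                      subject_id = c("X1", "X2"), percent_identity = 99,
                      alignment_length = 200L, bitscore = 400,
                      subject_description = c("serpentinite-hosted subsurface",
                                              "terrestrial subsurface aquifer"),
                      stringsAsFactors = FALSE)
  counts <- matrix(10L, 4, 2, dimnames = list(names(seqs), c("s1", "s2")))
  calls <- classify_table(counts, seqs, controls, whitelist = c(w = wl_near),
                          blast = blast)
  expect_identical(calls$asv_id, names(seqs))
  expect_identical(calls$category,
                   c("contaminant", "possibly_subsurface", "subsurface",
                     "possibly_subsurface"))

  perm <- c(3, 1, 4, 2)
  calls_p <- classify_table(counts[perm, ], seqs, controls,
                            whitelist = c(w = wl_near), blast = blast)
  expect_identical(calls_p[order(calls_p$asv_id), ],
                   calls[order(calls$asv_id), ], ignore_attr = TRUE)

  # identical inputs -> byte-identical output
  expect_identical(classify_table(counts, seqs, controls,
                                  whitelist = c(w = wl_near), blast = blast),
                   calls)

  expect_error(classify_table(counts, seqs[-1], controls), "a_r1")
})

test_that("rule structure: no controls means no hard contaminants; all-NTC means all contaminants", {
  set.seed(79)
  seqs <- stats::setNames(vapply(1:5, function(i) rand_dna(150), ""),
                          paste0("a", 1:5))
  counts <- matrix(5L, 5, 1, dimnames = list(names(seqs), "s1"))
  calls_wl <- classify_table(counts, seqs, controls = NULL, whitelist = seqs)
  expect_false(any(calls_wl$category == "contaminant"))

  controls <- control_collection(ntc = stats::setNames(unname(seqs),
                                                       paste0("n", 1:5)))
  calls_all <- classify_table(counts, seqs, controls)
  expect_true(all(calls_all$category == "contaminant"))
})

test_that("filter_contaminants removes categories, conserves reads and flags exclusions", {
  set.seed(83)
  seqs <- c(k1 = rand_dna(100), k2 = rand_dna(100), k3 = rand_dna(100))
  counts <- matrix(c(80L, 20L, 0L,
                     0L, 50L, 0L,
                     20L, 30L, 10L), nrow = 3, byrow = TRUE,
                   dimnames = list(names(seqs), c("sA", "sB", "sC")))
  calls <- data.frame(asv_id = names(seqs),
                      category = c("subsurface", "contaminant", "likely_contaminant"),
                      stringsAsFactors = FALSE)
  out <- filter_contaminants(counts, calls)
  expect_identical(rownames(out$counts), "k1")
  expect_true(all(out$counts <= counts["k1", , drop = FALSE]))
  expect_equal(out$report$fraction_removed, c(0.2, 0.8, 1))
  expect_identical(out$report$fully_excluded, c(FALSE, FALSE, TRUE))
  # total removed reads equals the sum over removed rows
  expect_identical(sum(out$report$reads_before - out$report$reads_after),
                   sum(counts[c("k2", "k3"), ]))

  none <- data.frame(asv_id = names(seqs), category = "subsurface",
                     stringsAsFactors = FALSE)
  expect_identical(filter_contaminants(counts, none)$counts, counts)
})

test_that("planted contaminant read fractions are recovered exactly by construction", {
  set.seed(89)
  counts <- rbind(ind = c(80L, 400L), con = c(20L, 100L))
  colnames(counts) <- c("s1", "s2")
  calls <- data.frame(asv_id = c("ind", "con"),
                      category = c("subsurface", "contaminant"),
                      stringsAsFactors = FALSE)
  out <- filter_contaminants(counts, calls)
  expect_identical(out$report$fraction_removed, c(0.2, 0.2))
})

test_that("lowering the identity threshold only grows the control-matched set", {
  set.seed(97)
  base <- rand_dna(200)
  controls <- control_collection(ntc = c(n1 = base))
  queries <- lapply(0:10, function(k) c(x = mutate_seq(base, k)))
  thresholds <- seq(1.0, 0.9, by = -0.01)
  prev <- -1L
  for (th in thresholds) {
    p <- identity_params(threshold = th)
    matched <- sum(vapply(queries, function(q) {
      !is.null(best_control_match(q, controls, p))
    }, logical(1)))
    expect_gte(matched, prev)
    prev <- matched
  }
})
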