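test_that("global identity matches hand-aligned substitution cases", {
  set.seed(11)
  a <- rand_dna(100)
  expect_identical(global_identity(a, a), 1)
  b1 <- mutate_seq(a, 1)
  expect_equal(global_identity(a, b1), 0.99)    # 99 matches / 100 columns
  b2 <- mutate_seq(a, 2)
  expect_equal(global_identity(a, b2), 0.98)
  expect_error(global_identity("", a), "empty")
})

test_that("identity is symmetric, reflexive and bounded on random pairs", {
  set.seed(23)
  for (i in 1:40) {
    a <- rand_dna(sample(40:90, 1))
    b <- rand_dna(sample(40:90, 1))
    ab <- global_identity(a, b)
    expect_identical(ab, global_identity(b, a))
    expect_gte(ab, 0)
    expect_lte(ab, 1)
    expect_identical(global_identity(a, a), 1)
  }
})

test_that("a short fragment of a longer sequence does not score 1 by default", {
  set.seed(5)
  long <- rand_dna(300)
  frag <- substr(long, 101, 160)
  default <- global_identity(frag, long)
  expect_lt(default, 0.5)
  overlap <- global_identity(frag, long,
                             identity_params(denominator = "overlap"))
  expect_identical(overlap, 1)
})

test_that("ambiguity codes count as mismatches", {
  a <- paste(rep("ACGT", 10), collapse = "")
  n_version <- sub("C", "N", a)
  expect_equal(global_identity(a, n_version), 39 / 40)
})

test_that("best_control_match applies threshold, max and tie-break rules", {
  set.seed(31)
  q <- rand_dna(200)
  controls <- control_collection(
    ntc = c(n2 = q, n1 = q),                       # both identical to query
    seawater = c(sw1 = mutate_seq(q, 2)))          # 0.99
  hit <- best_control_match(c(asv1 = q), controls)
  expect_identical(hit$control_type, "ntc")
  expect_identical(hit$identity, 1)
  expect_identical(hit$control_seq_id, "n1")       # lexicographic tie-break

  # precedence applies at equal identity across sets
  controls2 <- control_collection(ntc = c(n1 = q), seawater = c(s1 = q))
  expect_identical(best_control_match(q, controls2)$control_type, "ntc")

  # 3 substitutions over 200 nt = 0.985: below the 0.99 threshold
  controls3 <- control_collection(ntc = c(n1 = mutate_seq(q, 3)))
  expect_null(best_control_match(q, controls3))
  expect_identical(
    best_control_match(q, controls3, identity_params(threshold = 0.98))$identity,
    197 / 200)
})

test_that("whitelist matching honours match mode", {
  set.seed(41)
  wl_seq <- rand_dna(250)
  wl <- c(wl1 = wl_seq)
  expect_true(in_whitelist(c(q = wl_seq), wl, "exact_sequence")$hit)

  near <- mutate_seq(wl_seq, 1)                    # 249/250 = 0.996
  expect_false(in_whitelist(c(q = near), wl, "exact_sequence")$hit)
  thr <- in_whitelist(c(q = near), wl, "identity_threshold")
  expect_true(thr$hit)
  expect_equal(thr$evidence$identity, 249 / 250)
  expect_identical(thr$evidence$control_type, "whitelist")

  expect_true(in_whitelist(c(wl1 = rand_dna(50)), c("wl1", "wl2"), "id")$hit)
  expect_error(in_whitelist(c(q = near), c("wl1", "wl2"), "exact_sequence"),
               "bare-id")
  expect_error(in_whitelist(c(q = near), character(), "exact_sequence"), "empty")
})

test_that("k-mer prescreen never changes the matched set", {
  set.seed(53)
  controls_seqs <- stats::setNames(vapply(1:15, function(i) rand_dna(150), ""),
                                   sprintf("c%02d", 1:15))
  controls <- control_collection(ntc = controls_seqs)
  # queries: random, exact control copies, and near-threshold variants
  queries <- c(
    vapply(1:30, function(i) rand_dna(150), ""),
    unname(controls_seqs[1:5]),
    vapply(1:5, function(i) mutate_seq(controls_seqs[[i]], 1), ""))
  with_pre <- lapply(queries, best_control_match, controls = controls,
                     params = identity_params(use_prescreen = TRUE))
  without <- lapply(queries, best_control_match, controls = controls,
                    params = identity_params(use_prescreen = FALSE))
  expect_identical(with_pre, without)
  expect_gt(sum(!vapply(with_pre, is.null, logical(1))), 0)
})
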