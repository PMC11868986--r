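test_that("score_variant enforces REF match and allele sanity", {
  ref <- c(c1 = "ACGTACGTACGTACGTACGT")
  pwm <- random_pwm(3)
  v <- data.frame(chrom = "c1", pos0 = 10L, id = "x", ref = "G", alt = "T")
  r <- score_variant(pwm, ref, v, half_window = 5)
  expect_identical(r$variant_id, "x")
  expect_true(r$direction %in% c("loss", "gain", "none"))
  v_bad <- v
  v_bad$ref <- "A"
  expect_error(score_variant(pwm, ref, v_bad, half_window = 5),
               "REF_MISMATCH")
  v_same <- v
  v_same$alt <- "G"
  expect_error(score_variant(pwm, ref, v_same, half_window = 5),
               "ref == alt")
})

test_that("affinity p-value hits its trivial bounds", {
  pwm <- random_pwm(2)
  bg <- new_background()
  null <- score_null(pwm, bg, flank_left = 2, flank_right = 2,
                     mode = "exact")
  expect_equal(affinity_pvalue(-1e6, pwm, bg, null = null), 1)
  expect_equal(affinity_pvalue(1e6, pwm, bg, null = null), 0)
})

test_that("exact p-values equal independent brute-force enumeration", {
  set.seed(51)
  bgv <- c(0.3, 0.2, 0.2, 0.3)
  bg <- new_background(bgv)
  for (i in 1:8) {
    L <- sample(1:3, 1)
    len <- sample(max(3, L):5, 1)
    f <- sample(seq_len(len), 1)
    pwm <- random_pwm(L)
    w_ok <- min(f, len - L + 1) >= max(1, f - L + 1)
    if (!w_ok) next
    null <- score_null(pwm, bg, flank_left = f - 1, flank_right = len - f,
                       mode = "exact")
    enum <- oracle_enumerate(pwm, len, f, bgv)
    for (s in quantile(as.vector(enum$S), c(0.05, 0.5, 0.95))) {
      expect_equal(as.numeric(affinity_pvalue(s, pwm, bg, null = null)),
                   oracle_affinity_p(s, enum, bgv), tolerance = 1e-12)
    }
    ws <- paste(sample(BASES, len, TRUE), collapse = "")
    pair <- sample(BASES, 2)
    expect_equal(
      as.numeric(rank_pvalue(pwm, ws, f - 1, pair[1], pair[2], bg,
                             null = null)),
      oracle_rank_p(pwm, ws, f, pair[1], pair[2], bgv), tolerance = 1e-12)
  }
})

test_that("Monte Carlo p-values agree with exact within 3 SE", {
  set.seed(52)
  bg <- new_background()
  pwm <- random_pwm(2)
  exact <- score_null(pwm, bg, 2, 2, mode = "exact")
  mc <- score_null(pwm, bg, 2, 2, mode = "mc", n_mc = 1e5, seed = 8)
  for (s in quantile(exact$surv_x, c(0.1, 0.5, 0.9))) {
    pe <- as.numeric(affinity_pvalue(s, pwm, bg, null = exact))
    pm <- affinity_pvalue(s, pwm, bg, null = mc)
    expect_lt(abs(as.numeric(pm) - pe), 3 * max(attr(pm, "se"), 1e-4))
  }
})

test_that("rank p-value degenerate contracts hold", {
  pwm <- random_pwm(2)
  bg <- new_background()
  expect_equal(rank_pvalue(pwm, "ACGTA", 2L, "C", "C", bg, mode = "exact"),
               1)
  # allele-blind motif: uniform columns score every allele identically
  blind <- new_pwm(matrix(0.25, 2, 4))
  p <- rank_pvalue(blind, "ACGTA", 2L, "A", "G", bg, mode = "exact")
  expect_equal(as.numeric(p), 1)
})

test_that("call_disrupting applies both gates exactly", {
  res <- data.frame(
    variant_id = c("a", "b", "c"), motif_name = "m",
    score_ref = 1, score_alt = 0, direction = "loss",
    p_ref = c(0.0005, 0.002, 0.0005),
    p_alt = c(0.2, 0.002, 0.2),
    p_rank = c(0.004, 0.001, 0.04))
  out <- call_disrupting(res, alpha_affinity = 0.001, alpha_rank = 0.05,
                         n_tests = 10)
  # a: min(p) < 0.001 and 0.004 < 0.05/10 -> kept
  # b: affinity gate fails; c: 0.04 >= 0.005 -> dropped
  expect_identical(out$kept$variant_id, "a")
  expect_identical(out$results$kept, c(TRUE, FALSE, FALSE))
  expect_equal(out$summary$n[out$summary$motif == "m"], 1L)
  expect_error(call_disrupting(res, n_tests = 0), "n_tests")
})

test_that("disruption_test recovers manifest deltas and direction", {
  sc <- simulate_scenario(seed = 3, n_peaks = 40, n_causal = 3,
                          n_null = 10, write = FALSE)
  res <- disruption_test(sc$pwm, sc$reference, sc$variants,
                         background = sc$background, n_mc = 2e4, seed = 5)
  causal <- sc$variants[sc$variants$is_causal, ]
  for (i in seq_len(nrow(causal))) {
    row <- res[res$variant_id == causal$id[i], ]
    expect_equal(row$score_ref - row$score_alt,
                 causal$true_delta_score[i], tolerance = 1e-12)
    expect_identical(row$direction,
                     if (causal$true_delta_score[i] > 0) "loss" else "gain")
  }
})

test_that("affinity p-values are super-uniform under the background", {
  # exact null, scan length 5: p-values of background draws can exceed
  # but never undershoot the uniform law
  set.seed(53)
  pwm <- random_pwm(3)
  bg <- new_background()
  null <- score_null(pwm, bg, 2, 2, mode = "exact")
  draws <- matrix(sample.int(4L, 2000 * 5, TRUE), ncol = 5)
  scores <- regsnap:::allele_best_scores(log_odds(pwm, bg), draws, 3L)
  focal <- sample.int(4L, 2000, TRUE)
  s <- scores[cbind(seq_len(2000), focal)]
  p <- vapply(s, function(x)
    as.numeric(affinity_pvalue(x, pwm, bg, null = null)), 0)
  grid <- seq(0.01, 0.99, by = 0.01)
  emp <- vapply(grid, function(t) mean(p <= t), 0)
  expect_true(all(emp <= grid + 3 * sqrt(grid * (1 - grid) / 2000) + 1e-9))
})
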