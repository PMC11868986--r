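test_that("best_match_score: single-base motif is the allele's log-odds", {
  bg <- new_background(c(0.3, 0.2, 0.2, 0.3))
  p <- new_pwm(matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4))
  lo <- log_odds(p, bg)
  r <- best_match_score(p, "ACGTACGT", 3L, "A", half_window = 2L,
                        background = bg)
  # best of the allele itself (+) and its complement read on the minus
  # strand at the same position
  expect_equal(r$score, max(lo[1, "A"], lo[1, "T"]))
})

test_that("best_match_score equals the exhaustive window oracle", {
  set.seed(11)
  bgv <- c(0.3, 0.2, 0.2, 0.3)
  bg <- new_background(bgv)
  for (i in 1:30) {
    L <- sample(2:4, 1)
    hw <- sample(3:6, 1)
    n <- sample(15:25, 1)
    seq <- paste(sample(BASES, n, TRUE), collapse = "")
    focal <- sample(seq_len(n) - 1L, 1)
    allele <- sample(BASES, 1)
    p <- random_pwm(L)
    got <- tryCatch(best_match_score(p, seq, focal, allele,
                                     half_window = hw, background = bg),
                    error = function(e) NULL)
    want <- oracle_best_match(p, seq, focal, allele, hw, bgv)
    if (is.null(got)) {
      expect_identical(want, -Inf)  # no valid window
    } else {
      expect_equal(got$score, want, tolerance = 1e-12)
    }
  }
})

test_that("strand coherence: reverse-complemented scan mirrors the score", {
  set.seed(12)
  bg <- new_background()
  for (i in 1:10) {
    seq <- paste(sample(BASES, 30, TRUE), collapse = "")
    p <- random_pwm(3)
    focal <- sample(5:24, 1)
    allele <- sample(BASES, 1)
    a <- best_match_score(p, seq, focal, allele, half_window = 5,
                          background = bg)
    b <- best_match_score(p, oracle_revcomp(seq), 29L - focal,
                          COMP[[allele]], half_window = 5,
                          background = bg)
    expect_equal(a$score, b$score, tolerance = 1e-12)
  }
})

test_that("motif wider than the scannable span errors", {
  p <- random_pwm(9)
  expect_error(best_match_score(p, "ACGTACGT", 3L, "A", half_window = 2L),
               "no valid scoring window")
})

test_that("pwm_similarity: identity, reverse complement, brute force", {
  set.seed(13)
  q <- random_pwm(8, "q")
  self <- pwm_similarity(q, q)
  expect_equal(self$similarity, 1.0, tolerance = 1e-12)
  expect_identical(self$offset, 0L)
  expect_identical(self$strand, "+")
  rc <- pwm_revcomp(q)
  rc$name <- "q_rc"
  m <- pwm_similarity(q, rc)
  expect_equal(m$similarity, 1.0, tolerance = 1e-12)
  expect_identical(m$strand, "-")
  for (i in 1:10) {
    a <- random_pwm(8, "a")
    b <- random_pwm(sample(5:10, 1), "b")
    expect_equal(pwm_similarity(a, b)$similarity,
                 oracle_similarity(a, b), tolerance = 1e-12)
  }
  expect_error(pwm_similarity(random_pwm(3), random_pwm(8), min_overlap = 4),
               "min_overlap")
})

test_that("pwm_similarity is symmetric in its arguments", {
  set.seed(14)
  for (i in 1:5) {
    a <- random_pwm(7, "a")
    b <- random_pwm(7, "b")
    expect_equal(pwm_similarity(a, b)$similarity,
                 pwm_similarity(b, a)$similarity, tolerance = 1e-12)
  }
})

test_that("match_to_database recovers the generator and honors sim_min", {
  set.seed(15)
  gen <- scenario_pwm()
  db <- scenario_motif_db(gen, n_decoys = 5, seed = 3)
  # a noisy copy of the generator as the discovered query
  noisy <- new_pwm((gen$probs * 0.9 + 0.025), name = "disc")
  m <- match_to_database(list(noisy), db, sim_min = 0.75)
  expect_identical(m$db_name[1], "TFA")
  expect_true(all(diff(m$similarity) <= 0))
  # impossible threshold drops everything (and logs)
  expect_message(
    m2 <- match_to_database(list(noisy), lapply(db[-1], identity),
                            sim_min = 1.0),
    "no database match")
  expect_equal(nrow(m2), 0L)
  # duplicate database entries are both reported
  m3 <- match_to_database(list(noisy), list(gen, gen), sim_min = 0.75)
  expect_equal(nrow(m3), 2L)
  expect_error(match_to_database(list(noisy), list()), "empty")
})
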