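test_that("simulate_reference: determinism, GC control, degenerate input", {
  a <- simulate_reference(10000, 0.5, seed = 7)
  b <- simulate_reference(10000, 0.5, seed = 7)
  expect_identical(a$reference, b$reference)
  expect_false(identical(
    a$reference, simulate_reference(10000, 0.5, seed = 8)$reference))
  big <- simulate_reference(100000, 0.6, seed = 1)
  gc_obs <- sum(big$background$base_freqs[c("C", "G")])
  expect_lt(abs(gc_obs - 0.6), 3 * sqrt(0.6 * 0.4 / 100000) + 1e-4)
  expect_error(simulate_reference(10000, 0.0), "gc")
  expect_error(simulate_reference(100, 0.5), "length")
})

test_that("haplotype panel hits planted r2 targets", {
  sim <- simulate_haplotype_panel(
    2000, list(list(n_snps = 2, target_r2 = 0.5)), seed = 3)
  r2 <- compute_r2(sim$panel, "b01_s001", "b01_s002")
  expect_gte(r2, 0.45)
  expect_lte(r2, 0.55)
  expect_identical(sim$manifest$target_r2, 0.5)
})

test_that("single founder gives perfect within-block LD", {
  sim <- simulate_haplotype_panel(
    200, list(list(n_snps = 4, founder_haps = 1)), seed = 5)
  ids <- sim$panel$variants$id
  for (i in 2:4)
    expect_equal(compute_r2(sim$panel, ids[1], ids[i]), 1,
                 tolerance = 1e-12)
})

test_that("across-block r2 has expectation zero", {
  r2s <- vapply(1:20, function(sd) {
    sim <- simulate_haplotype_panel(
      5000, list(list(n_snps = 2, target_r2 = 0.9),
                 list(n_snps = 2, target_r2 = 0.9)), seed = sd)
    compute_r2(sim$panel, "b01_s001", "b02_s001")
  }, 0)
  expect_lt(mean(r2s), 0.01)
})

test_that("panel generation validates its inputs", {
  expect_error(simulate_haplotype_panel(
    40, list(list(n_snps = 2, target_r2 = 0.5))), "n_hap")
  expect_error(simulate_haplotype_panel(
    100, list(list(n_snps = 1, target_r2 = numeric(0)))), ">= 2 SNPs")
  expect_error(simulate_haplotype_panel(
    100, list(list(n_snps = 2, target_r2 = 1.5))), "\\[0, 1\\]")
})

test_that("peak planting: exact counts, heights, enrichment, errors", {
  ref <- simulate_reference(30000, 0.41, seed = 2)
  pwm <- scenario_pwm()
  pk0 <- simulate_chipseq_peaks(ref$reference, pwm, 50, 0, seed = 3)
  expect_equal(nrow(pk0$manifest), 0L)
  pk <- simulate_chipseq_peaks(ref$reference, pwm, 100, 0.8, seed = 3)
  expect_equal(nrow(pk$manifest), 80L)
  expect_true(all(pk$peaks$height > 0))
  # planted instances rescore higher with the generating PWM than
  # unplanted peaks (scoring oracle from the scanning module)
  lo <- log_odds(pwm, ref$background)
  seqs <- select_top_peaks(pk$peaks, n = 100, flank = 20,
                           reference = pk$reference)
  planted <- names(seqs) %in% pk$manifest$peak_id
  scores <- vapply(seqs, function(s) regsnap:::best_site(lo, s)$score, 0)
  expect_gt(mean(scores[planted]), mean(scores[!planted]) + 5)
  wide <- new_pwm(matrix(0.25, 70, 4))
  expect_error(simulate_chipseq_peaks(ref$reference, wide, 10, 0.5),
               "wider")
})

test_that("planted variants: construction truth round-trips exactly", {
  ref <- simulate_reference(30000, 0.41, seed = 2)
  pwm <- scenario_pwm()
  pk <- simulate_chipseq_peaks(ref$reference, pwm, 100, 0.8, seed = 3)
  bg <- background_from_sequences(pk$reference)
  v <- plant_disrupting_variants(pwm, pk$reference, pk$manifest,
                                 n_causal = 10, n_null = 30, seed = 4,
                                 background = bg)
  causal <- v[v$is_causal, ]
  expect_equal(nrow(causal), 10L)
  expect_true(all(abs(causal$true_delta_score) > 0))
  # round trip: recompute delta from the emitted reference and alleles
  lo <- log_odds(pwm, bg)
  for (i in seq_len(nrow(causal))) {
    sr <- best_match_score(pwm, pk$reference[[1]], causal$pos0[i],
                           causal$ref[i], half_window = 20, lo = lo)
    sa <- best_match_score(pwm, pk$reference[[1]], causal$pos0[i],
                           causal$alt[i], half_window = 20, lo = lo)
    expect_equal(sr$score - sa$score, causal$true_delta_score[i],
                 tolerance = 1e-12)
  }
  # null variants keep their distance from planted sites
  nulls <- v[!v$is_causal, ]
  for (p in nulls$pos0)
    expect_true(all(p < pk$manifest$site_start0 - 100 |
                      p > pk$manifest$site_start0 + 12 + 100))
  expect_error(plant_disrupting_variants(pwm, pk$reference, pk$manifest,
                                         n_causal = 100, n_null = 0),
               "insufficient")
  expect_error(plant_disrupting_variants(pwm, pk$reference, pk$manifest,
                                         n_causal = 0, n_null = 0),
               "at least one")
})

test_that("eQTL tables: planted effects replicate, nulls stay null", {
  ref <- simulate_reference(30000, 0.41, seed = 2)
  pwm <- scenario_pwm()
  pk <- simulate_chipseq_peaks(ref$reference, pwm, 100, 0.8, seed = 3)
  v <- plant_disrupting_variants(pwm, pk$reference, pk$manifest, 5, 100,
                                 seed = 4)
  eq <- simulate_eqtl_tables(v, n_datasets = 3, n_true = 5, seed = 6)
  expect_length(eq$tables, 3L)
  ev <- integrate_eqtl(v$id, eq$tables, q_max = 0.001)
  causal_ev <- ev[ev$variant_id %in% v$id[v$is_causal] & !is.na(ev$gene), ]
  expect_true(all(causal_ev$n_significant_datasets == 3L))
  expect_true(all(causal_ev$replicated))
  # null variants essentially never pass the gate
  null_ev <- ev[ev$variant_id %in% v$id[!v$is_causal], ]
  expect_lte(sum(null_ev$n_significant_datasets > 0), 1L)
  expect_error(simulate_eqtl_tables(v, n_datasets = 1, n_true = 2),
               "n_datasets")
  expect_error(simulate_eqtl_tables(v, n_datasets = 2, n_true = 50),
               "n_true")
})

test_that("annotations: causal evidence, flips, and errors", {
  v <- data.frame(id = sprintf("v%03d", 1:150))
  causal <- v$id[1:100]
  ann0 <- simulate_annotations(v, causal, flip_prob = 0, seed = 1)
  c0 <- ann0[ann0$variant_id %in% causal, ]
  expect_true(all(regulome_pass(c0$regulomedb_category)))
  expect_true(all(evidence_score(c0) == 4L))
  expect_false(any(regulome_pass(
    ann0$regulomedb_category[!ann0$variant_id %in% causal])))
  # flip_prob = 0.1: mean score ~ 4 * 0.9 = 3.6 within 3 SE
  ann1 <- simulate_annotations(v, causal, flip_prob = 0.1, seed = 2)
  sc <- evidence_score(ann1[ann1$variant_id %in% causal, ])
  se <- sqrt(4 * 0.1 * 0.9 / 100)
  expect_lt(abs(mean(sc) - 3.6), 3 * se)
  expect_error(simulate_annotations(v, c("v001", "ghost")), "unknown")
  expect_error(simulate_annotations(v, causal, flip_prob = 0.6),
               "flip_prob")
})

test_that("scenario emission is seed-deterministic (byte-identical)", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_scenario(d1, seed = 11, n_peaks = 30, plant_frac = 0.5,
                    n_causal = 2, n_null = 10, n_hap = 60)
  simulate_scenario(d2, seed = 11, n_peaks = 30, plant_frac = 0.5,
                    n_causal = 2, n_null = 10, n_hap = 60)
  for (f in setdiff(list.files(d1), "config.txt")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
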