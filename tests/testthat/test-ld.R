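make_hap_pair <- function(nAB, nAb, naB, nab) {
  x <- c(rep(1, nAB + nAb), rep(0, naB + nab))
  y <- c(rep(1, nAB), rep(0, nAb), rep(1, naB), rep(0, nab))
  cbind(x, y)
}

test_that("compute_r2 matches hand-computed haplotype cases", {
  # counts AB=40, Ab=10, aB=10, ab=40: D = 0.4 - 0.25 = 0.15,
  # r2 = 0.15^2 / 0.25^2 = 0.36
  m <- make_hap_pair(40, 10, 10, 40)
  panel <- panel_from_matrix(m)
  expect_equal(compute_r2(panel, "v1", "v2"), 0.36, tolerance = 1e-12)
  # balanced counts: D = 0
  m <- make_hap_pair(25, 25, 25, 25)
  expect_equal(compute_r2(panel_from_matrix(m), "v1", "v2"), 0,
               tolerance = 1e-12)
  # identical columns: perfect LD
  m <- cbind(rep(c(0, 1), 30), rep(c(0, 1), 30))
  expect_equal(compute_r2(panel_from_matrix(m), "v1", "v2"), 1,
               tolerance = 1e-12)
})

test_that("compute_r2 errors on monomorphic variants and tiny overlap", {
  m <- cbind(rep(1L, 60), rep(c(0L, 1L), 30))
  expect_error(compute_r2(panel_from_matrix(m), "v1", "v2"), "monomorphic")
  m2 <- make_hap_pair(5, 2, 2, 5)
  expect_warning(r <- compute_r2(panel_from_matrix(m2), "v1", "v2"),
                 "fewer than")
  expect_true(is.na(r))
})

test_that("r2 is symmetric, label-swap invariant and bounded", {
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(rbinom(200, 1, runif(1, 0.2, 0.8)), ncol = 2)
    if (length(unique(m[, 1])) < 2 || length(unique(m[, 2])) < 2) next
    p <- panel_from_matrix(m)
    r12 <- compute_r2(p, "v1", "v2")
    expect_equal(r12, compute_r2(p, "v2", "v1"), tolerance = 1e-12)
    expect_gte(r12, 0)
    expect_lte(r12, 1)
    # swapping allele labels at one site leaves r2 unchanged
    m2 <- m
    m2[, 1] <- 1L - m2[, 1]
    expect_equal(compute_r2(panel_from_matrix(m2), "v1", "v2"), r12,
                 tolerance = 1e-12)
  }
})

test_that("EM on unphased genotypes matches the phased estimate", {
  # dominated configuration: one haplotype class (aB) absent, so double
  # heterozygotes resolve unambiguously and EM reaches the phased MLE
  m <- rbind(matrix(c(1, 1), 470, 2, byrow = TRUE),
             matrix(c(1, 0), 30, 2, byrow = TRUE),
             matrix(c(0, 0), 500, 2, byrow = TRUE))
  p <- panel_from_matrix(m)
  phased <- compute_r2(p, "v1", "v2")
  unph <- p
  unph$phased <- FALSE
  expect_equal(compute_r2(unph, "v1", "v2"), phased, tolerance = 1e-6)
  # general case: EM still lands close to the phased estimate
  sim <- simulate_haplotype_panel(
    2000, list(list(n_snps = 2, target_r2 = 0.8)), seed = 5)
  up2 <- sim$panel
  up2$phased <- FALSE
  expect_equal(compute_r2(up2, "b01_s001", "b01_s002"),
               compute_r2(sim$panel, "b01_s001", "b01_s002"),
               tolerance = 0.01)
})

test_that("expand_ld recovers planted proxies and is threshold-monotone", {
  sim <- simulate_haplotype_panel(
    2000, list(list(n_snps = 4, target_r2 = c(1, 0.5, 0.1))), seed = 9)
  ex <- expand_ld(sim$panel, "b01_s001", r2_min = 0.3, window = 5e5)
  expect_true(ex[[1]]$found)
  mem <- ex[[1]]$members
  expect_true("b01_s001" %in% mem$variant_id)
  expect_equal(mem$r2[mem$variant_id == "b01_s001"], 1)
  # index + proxies at ~1.0 and ~0.5; the ~0.1 proxy excluded
  expect_setequal(mem$variant_id, c("b01_s001", "b01_s002", "b01_s003"))
  expect_true(all(mem$r2 >= 0.3))
  # raising the threshold never adds members
  for (thr in c(0.5, 0.8, 0.95)) {
    mem_t <- expand_ld(sim$panel, "b01_s001", r2_min = thr)[[1]]$members
    expect_true(all(mem_t$variant_id %in% mem$variant_id))
  }
  # absent index SNP: flagged empty result, not an error
  expect_message(ex2 <- expand_ld(sim$panel, "nosuch"), "absent")
  expect_false(ex2[[1]]$found)
  expect_equal(nrow(ex2[[1]]$members), 0L)
})

test_that("expand_ld with no polymorphic neighbors returns the index only", {
  m <- cbind(rep(c(0L, 1L), 30), rep(0L, 60))
  p <- panel_from_matrix(m)
  mem <- expand_ld(p, "v1")[[1]]$members
  expect_identical(mem$variant_id, "v1")
})

test_that("VCF round trip: simulated panel -> write_vcf -> read_panel", {
  sim <- simulate_haplotype_panel(
    60, list(list(n_snps = 3, founder_haps = 2),
             list(n_snps = 2, target_r2 = 0.7)), seed = 4)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$panel$variants, path, haplotypes = sim$panel$matrix)
  back <- read_panel(path)
  expect_true(back$phased)
  expect_identical(back$variants$id, sim$panel$variants$id)
  expect_identical(back$variants$pos0, sim$panel$variants$pos0)
  expect_equal(unname(back$matrix), unname(sim$panel$matrix))
})

test_that("read_panel skips multiallelic records and excludes indels", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr1", "100", "snp1", "A", "G", ".", "PASS", ".", "GT",
          "0|1", "1|1", sep = "\t"),
    paste("chr1", "200", "multi", "A", "G,T", ".", "PASS", ".", "GT",
          "0|1", "0|2", sep = "\t"),
    paste("chr1", "300", "indel", "AT", "A", ".", "PASS", ".", "GT",
          "0|0", "0|1", sep = "\t"),
    paste("chr1", "400", "snp2", "C", "T", ".", "PASS", ".", "GT",
          ".|.", "0|1", sep = "\t")), path)
  expect_message(p <- read_panel(path), "multiallelic")
  expect_setequal(p$variants$id, c("snp1", "snp2"))
  expect_identical(unname(p$matrix[, "snp1"]), c(0L, 1L, 1L, 1L))
  expect_identical(unname(p$matrix[, "snp2"]), c(NA, NA, 0L, 1L))
  # split mode keeps both alleles of the multiallelic record
  p2 <- suppressMessages(read_panel(path, split_multiallelic = TRUE))
  expect_true(all(c("multi_alt1", "multi_alt2") %in% p2$variants$id))
  # region filter (1-based inclusive)
  p3 <- suppressMessages(read_panel(path, region = "chr1:350-450"))
  expect_identical(p3$variants$id, "snp2")
  expect_error(read_panel(path, region = "chr1:900-950"), "empty region")
})

test_that("ld_table flattens results and counts unique members", {
  sim <- simulate_haplotype_panel(
    100, list(list(n_snps = 3, target_r2 = c(1, 1))), seed = 2)
  tab <- ld_table(expand_ld(sim$panel, "b01_s001"))
  expect_equal(attr(tab, "n_unique"), 3L)
  expect_true(all(tab$index_id == "b01_s001"))
})
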