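test_that("regulome_pass recognizes the category-1 family", {
  expect_true(regulome_pass("1b"))
  expect_true(regulome_pass("1f"))
  expect_false(regulome_pass("2a"))
  expect_false(regulome_pass("7"))
  expect_error(regulome_pass("x9"), "malformed")
})

test_that("evidence_score counts the four flags", {
  rec <- data.frame(promoter_mark = c(TRUE, FALSE, TRUE),
                    enhancer_mark = c(TRUE, FALSE, FALSE),
                    dnase_protein = c(TRUE, FALSE, FALSE),
                    motif_change = c(TRUE, FALSE, TRUE))
  expect_identical(evidence_score(rec), c(4L, 0L, 2L))
})

gene_model_fixture <- data.frame(
  chrom = "c1",
  start = c(1000L, 1100L, 1800L),
  end = c(2000L, 1300L, 1900L),
  name = c("gA", "gA_e1", "gA_e2"),
  type = c("gene", "exon", "exon"),
  gene = "gA")

test_that("classify_context applies exon > intron > intergenic precedence", {
  ctx <- function(pos) classify_context(
    data.frame(chrom = "c1", pos0 = pos), gene_model_fixture)
  expect_identical(ctx(1200L), "exonic")
  expect_identical(ctx(1500L), "intronic")
  expect_identical(ctx(11000L), "intergenic")
  expect_identical(ctx(999L), "intergenic")
  expect_identical(ctx(1000L), "intronic")   # half-open gene start
  expect_identical(ctx(2000L), "intergenic") # half-open gene end
})

mk_hits <- function(ids, p_rank = 1e-4) {
  data.frame(variant_id = ids, motif_name = "TFA", p_rank = p_rank,
             direction = "loss")
}

mk_ann <- function(ids, cat = "1a", score = 4L) {
  data.frame(variant_id = ids, regulomedb_category = cat,
             promoter_mark = score >= 1, enhancer_mark = score >= 2,
             dnase_protein = score >= 3, motif_change = score >= 4)
}

mk_ev <- function(ids, nsig = 3L) {
  data.frame(variant_id = ids, gene = "gA",
             n_significant_datasets = nsig, replicated = nsig >= 2,
             direction = 1L, min_q = 1e-6)
}

test_that("rank_variants gates, orders and tie-breaks as documented", {
  hits <- mk_hits(c("causal", "decoy1", "decoy2", "tie_a", "tie_b"))
  ev <- rbind(mk_ev(c("causal", "tie_a", "tie_b")),
              mk_ev("decoy1", nsig = 0L))   # decoy1 fails eQTL gate
  ann <- rbind(mk_ann("causal", score = 4L),
               mk_ann("decoy1", score = 4L),
               mk_ann("decoy2", cat = "2b"),  # fails regulome gate
               mk_ann(c("tie_a", "tie_b"), score = 2L))
  out <- rank_variants(hits, ev, ann)
  expect_identical(out$variant_id[which(out$rank == 1)], "causal")
  # decoys retained but unranked
  expect_true(all(is.na(out$rank[out$variant_id %in%
                                   c("decoy1", "decoy2")])))
  # equal score and p_rank: lexicographic tie-break
  ranked <- out[!is.na(out$rank), ]
  ta <- ranked$rank[ranked$variant_id == "tie_a"]
  tb <- ranked$rank[ranked$variant_id == "tie_b"]
  expect_lt(ta, tb)
  expect_identical(sort(ranked$rank), seq_len(nrow(ranked)))
})

test_that("rank_variants handles empty gates and missing annotations", {
  hits <- mk_hits("v1")
  ev <- mk_ev("v1", nsig = 0L)
  out <- rank_variants(hits, ev, mk_ann("v1"))
  expect_true(all(is.na(out$rank)))
  expect_equal(nrow(out), 1L)
  # missing annotation row: flags treated as all-false, logged
  expect_message(
    out2 <- rank_variants(mk_hits("v2"), mk_ev("v2"),
                          mk_ann("other")), "no annotation")
  expect_equal(out2$evidence_score, 0L)
  expect_false(out2$passes_regulome)
})

test_that("rank_variants attaches genomic context when a gene model is given", {
  vs <- data.frame(id = "v1", chrom = "c1", pos0 = 1500L)
  out <- rank_variants(mk_hits("v1"), mk_ev("v1"), mk_ann("v1"),
                       variants = vs, gene_model = gene_model_fixture)
  expect_identical(out$context, "intronic")
})

test_that("gate tightening never adds ranked variants", {
  set.seed(71)
  ids <- sprintf("v%02d", 1:20)
  hits <- mk_hits(ids, p_rank = runif(20, 1e-6, 1e-3))
  ev <- mk_ev(ids, nsig = sample(0:3, 20, TRUE))
  ann <- mk_ann(ids, cat = sample(c("1a", "1b", "2a"), 20, TRUE),
                score = sample(0:4, 20, TRUE))
  loose <- rank_variants(hits, ev, ann, min_datasets = 1L)
  tight <- rank_variants(hits, ev, ann, min_datasets = 2L)
  expect_true(all(tight$variant_id[!is.na(tight$rank)] %in%
                    loose$variant_id[!is.na(loose$rank)]))
})

test_that("summarize_hits: counts, co-disruption matrix, contexts", {
  hits <- data.frame(
    variant_id = c("s1", "s2", "s3", "s1", "s2"),
    motif_name = c("TF_A", "TF_A", "TF_A", "TF_B", "TF_B"))
  s <- summarize_hits(hits)
  expect_equal(s$per_tf$n[s$per_tf$motif == "TF_A"], 3L)
  expect_equal(s$co_disruption["TF_A", "TF_B"], 2L)
  expect_identical(s$co_disruption, t(s$co_disruption))
  expect_true(all(diag(s$co_disruption) == 0))
  expect_equal(sum(s$per_tf$n / sum(s$per_tf$n) * 100), 100)
  one <- summarize_hits(data.frame(variant_id = "x", motif_name = "T"))
  expect_equal(one$per_tf$percent, 100)
  vs <- data.frame(id = c("s1", "s2", "s3"), chrom = "c1",
                   pos0 = c(1200L, 1500L, 9000L))
  ctx <- summarize_hits(hits, vs, gene_model_fixture)$context
  expect_equal(as.integer(ctx[c("exonic", "intronic", "intergenic")]),
               c(1L, 1L, 1L))
})
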