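# Variant prioritization: the two selection gates (brain eQTL support and
# RegulomeDB category 1), the additive 0-4 evidence score from promoter /
# enhancer / DNase / motif-change annotations, genomic-context
# classification, and the per-TF summary tables.

#' Does a RegulomeDB category pass the category-1 gate?
#'
#' @param category Category string(s) such as `"1a"`, `"2b"`, `"7"`.
#' @return Logical: `TRUE` iff the category is in the 1a-1f family.
#' @export
regulome_pass <- function(category) {
  ok <- grepl("^[1-7][a-f]?$", category)
  if (any(!ok))
    stop("malformed RegulomeDB category: ",
         paste(unique(category[!ok]), collapse = ", "))
  startsWith(category, "1")
}

EVIDENCE_FLAGS <- c("promoter_mark", "enhancer_mark", "dnase_protein",
                    "motif_change")

#' Additive evidence score (0-4)
#'
#' Counts how many of the four annotation features are present: promoter
#' histone marks, enhancer histone marks, DNase protein binding, motif
#' changes.
#'
#' @param record `data.frame` (one or more rows) with the four logical
#'   flag columns.
#' @return Integer vector of scores in 0..4.
#' @export
evidence_score <- function(record) {
  stopifnot(all(EVIDENCE_FLAGS %in% names(record)))
  as.integer(rowSums(record[, EVIDENCE_FLAGS, drop = FALSE]))
}

#' Classify a variant's genomic context
#'
#' Precedence exonic > intronic > intergenic: a variant inside any exon is
#' exonic; inside a gene but outside exons, intronic; otherwise intergenic.
#' Intervals are 0-based half-open.
#'
#' @param variant One-row `data.frame` (`chrom`, `pos0`).
#' @param gene_model Gene model `data.frame` (`chrom`, `start`, `end`,
#'   `type` in `"gene"`/`"exon"`).
#' @return One of `"exonic"`, `"intronic"`, `"intergenic"`.
#' @export
classify_context <- function(variant, gene_model) {
  pos <- variant$pos0
  g <- gene_model[gene_model$chrom == variant$chrom, , drop = FALSE]
  hit <- function(type) any(g$type == type & g$start <= pos & pos < g$end)
  if (hit("exon")) "exonic" else if (hit("gene")) "intronic"
  else "intergenic"
}

#' Score, filter and rank candidate variants
#'
#' Applies the two selection gates — significant brain eQTL association
#' (q < 0.001 in at least `min_datasets` dataset(s)) and a RegulomeDB
#' category-1 annotation — then orders survivors by evidence score
#' (descending), rank p-value (ascending) and variant id (lexicographic
#' tie-break). Variants failing a gate are retained in the output without a
#' rank. Filtered candidates with no annotation row are treated as
#' all-false flags and logged.
#'
#' @param disruption_hits `data.frame` of kept disruption results (from
#'   [call_disrupting()]`$kept`); columns `variant_id`, `motif_name`,
#'   `p_rank`, `direction`.
#' @param evidence_summaries `data.frame` from [integrate_eqtl()].
#' @param annotations Annotation `data.frame` (see
#'   [simulate_annotations()] for the schema).
#' @param min_datasets Datasets required for the eQTL gate (default 1;
#'   set 2 to require replication).
#' @param variants,gene_model Optional variant table (`id`, `chrom`,
#'   `pos0`) and gene model; when both are given a `context` column
#'   (exonic / intronic / intergenic / other) is added.
#' @return `data.frame`, one row per candidate variant: gates, evidence
#'   score, `rank` (`NA` if unranked), the TF hits collapsed into
#'   `tf_hits`, and optionally `context`.
#' @export
rank_variants <- function(disruption_hits, evidence_summaries, annotations,
                          min_datasets = 1L, variants = NULL,
                          gene_model = NULL) {
  ids <- unique(disruption_hits$variant_id)
  rows <- lapply(ids, function(v) {
    hits <- disruption_hits[disruption_hits$variant_id == v, , drop = FALSE]
    ev <- evidence_summaries[evidence_summaries$variant_id == v &
                               !is.na(evidence_summaries$gene), ,
                             drop = FALSE]
    passes_eqtl <- any(ev$n_significant_datasets >= min_datasets)
    ann <- annotations[annotations$variant_id == v, , drop = FALSE]
    if (!nrow(ann)) {
      message("rank_variants: no annotation for ", v,
              "; treating flags as all-false")
      ann <- data.frame(variant_id = v, regulomedb_category = "7",
                        promoter_mark = FALSE, enhancer_mark = FALSE,
                        dnase_protein = FALSE, motif_change = FALSE,
                        stringsAsFactors = FALSE)
    }
    data.frame(variant_id = v,
               passes_eqtl = passes_eqtl,
               passes_regulome = regulome_pass(ann$regulomedb_category[1L]),
               evidence_score = evidence_score(ann[1L, , drop = FALSE]),
               p_rank = min(hits$p_rank),
               tf_hits = paste(paste0(hits$motif_name, ":", hits$direction),
                               collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(variant_id = character(), passes_eqtl = logical(),
                      passes_regulome = logical(),
                      evidence_score = integer(), p_rank = numeric(),
                      tf_hits = character(), rank = integer()))
  if (!is.null(variants) && !is.null(gene_model)) {
    out$context <- vapply(out$variant_id, function(v) {
      row <- variants[variants$id == v, , drop = FALSE]
      if (!nrow(row)) return("other")
      classify_context(row[1L, ], gene_model)
    }, character(1L))
  }
  out$rank <- NA_integer_
  sel <- which(out$passes_eqtl & out$passes_regulome)
  if (length(sel)) {
    o <- sel[order(-out$evidence_score[sel], out$p_rank[sel],
                   out$variant_id[sel])]
    out$rank[o] <- seq_along(o)
  }
  out[order(is.na(out$rank), out$rank, out$variant_id), , drop = FALSE]
}

#' Summarize disruption hits
#'
#' Per-TF hit counts with percentages (count / total hits), a symmetric
#' co-disruption matrix counting variants shared between motif pairs (zero
#' diagonal by convention), and the genomic-context distribution.
#'
#' @param hits `data.frame` of kept disruption results (`variant_id`,
#'   `motif_name`).
#' @param variants Optional variant `data.frame` (`id`, `chrom`, `pos0`)
#'   for context classification.
#' @param gene_model Optional gene model for context classification.
#' @return List with `per_tf` (`motif`, `n`, `percent`), `co_disruption`
#'   (matrix), `context` (named counts; `NULL` without a gene model).
#' @export
summarize_hits <- function(hits, variants = NULL, gene_model = NULL) {
  if (!nrow(hits))
    return(list(per_tf = data.frame(motif = character(), n = integer(),
                                    percent = numeric()),
                co_disruption = matrix(0, 0, 0), context = NULL))
  per_tf <- as.data.frame(table(motif = hits$motif_name),
                          stringsAsFactors = FALSE)
  names(per_tf)[2L] <- "n"
  total <- length(unique(paste(hits$variant_id, hits$motif_name)))
  per_tf$percent <- 100 * per_tf$n / total
  per_tf <- per_tf[order(-per_tf$n, per_tf$motif), , drop = FALSE]
  motifs <- sort(unique(hits$motif_name))
  co <- matrix(0L, length(motifs), length(motifs),
               dimnames = list(motifs, motifs))
  by_var <- split(hits$motif_name, hits$variant_id)
  for (ms in by_var) {
    ms <- unique(ms)
    if (length(ms) < 2L) next
    for (i in seq_along(ms)) for (j in seq_along(ms)) {
      if (i != j) co[ms[i], ms[j]] <- co[ms[i], ms[j]] + 1L
    }
  }
  context <- NULL
  if (!is.null(variants) && !is.null(gene_model)) {
    vs <- unique(hits$variant_id)
    ctx <- vapply(vs, function(v) {
      row <- variants[variants$id == v, , drop = FALSE]
      if (!nrow(row)) return("other")
      classify_context(row[1L, ], gene_model)
    }, character(1L))
    context <- table(factor(ctx, levels = c("exonic", "intronic",
                                            "intergenic", "other")))
  }
  list(per_tf = per_tf, co_disruption = co, context = context)
}
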