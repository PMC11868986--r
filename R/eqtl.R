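# eQTL evidence integration: within-dataset Benjamini-Hochberg adjustment,
# the q < 0.001 significance gate, and cross-dataset replication flags.

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment with monotonicity enforcement (wraps
#' `stats::p.adjust(method = "BH")`). Empty input returns empty output.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Integrate eQTL evidence across datasets
#'
#' Joins candidate disrupting variants to per-dataset eQTL summary tables,
#' computes BH q-values within each dataset separately, counts in how many
#' datasets each variant-gene pair is significant (`q < q_max`), and flags
#' replication (significant in at least two datasets). Effect directions
#' are the per-dataset signs of beta (risk-allele oriented as supplied).
#' Variants absent from every table are reported with empty evidence.
#'
#' @param variant_ids Character vector of candidate variant ids.
#' @param eqtl_tables A single `data.frame` or list of `data.frame`s with
#'   columns `variant`, `gene`, `beta`, `p`, `dataset`.
#' @param q_max Significance threshold on the q-value (default 0.001,
#'   applied strictly: `q < q_max`).
#' @return `data.frame` with one row per variant-gene pair:
#'   `variant_id`, `gene`, `n_significant_datasets`, `replicated`,
#'   `direction` (consensus sign over significant datasets), `min_q`, plus
#'   one `q_<dataset>` column per dataset. Variants without any eQTL row
#'   appear once with `gene = NA`.
#' @export
integrate_eqtl <- function(variant_ids, eqtl_tables, q_max = 0.001) {
  if (is.data.frame(eqtl_tables)) eqtl_tables <- list(eqtl_tables)
  tab <- do.call(rbind, lapply(eqtl_tables, function(t) {
    stopifnot(all(c("variant", "gene", "beta", "p", "dataset") %in%
                    names(t)))
    t[, c("variant", "gene", "beta", "p", "dataset")]
  }))
  dup <- duplicated(tab[, c("variant", "gene", "dataset")])
  if (any(dup)) {
    d <- tab[dup, c("variant", "gene", "dataset")]
    stop("duplicated (variant, gene, dataset) rows: ",
         paste(utils::head(apply(d, 1L, paste, collapse = "/"), 5L),
               collapse = ", "))
  }
  # q-values within each dataset
  tab$q <- rep(NA_real_, nrow(tab))
  for (ds in unique(tab$dataset)) {
    sel <- tab$dataset == ds
    tab$q[sel] <- bh_fdr(tab$p[sel])
  }
  datasets <- sort(unique(tab$dataset))
  tab <- tab[tab$variant %in% variant_ids, , drop = FALSE]
  rows <- list()
  if (nrow(tab)) {
    key <- paste(tab$variant, tab$gene, sep = "\r")
    for (k in unique(key)) {
      sub <- tab[key == k, , drop = FALSE]
      sig <- sub$q < q_max
      qs <- stats::setNames(rep(NA_real_, length(datasets)),
                            sprintf("q_%s", datasets))
      qs[sprintf("q_%s", sub$dataset)] <- sub$q
      dir <- if (any(sig)) {
        s <- sign(sub$beta[sig])
        if (all(s >= 0)) 1L else if (all(s <= 0)) -1L else 0L
      } else NA_integer_
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(variant_id = sub$variant[1L], gene = sub$gene[1L],
                   n_significant_datasets = sum(sig),
                   replicated = sum(sig) >= 2L,
                   direction = dir, min_q = min(sub$q),
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(qs)))
    }
  }
  absent <- setdiff(variant_ids, tab$variant)
  for (v in absent) {
    base <- data.frame(variant_id = v, gene = NA_character_,
                       n_significant_datasets = 0L, replicated = FALSE,
                       direction = NA_integer_, min_q = NA_real_,
                       stringsAsFactors = FALSE)
    if (length(datasets)) {
      qs <- stats::setNames(rep(NA_real_, length(datasets)),
                            sprintf("q_%s", datasets))
      base <- cbind(base, as.data.frame(as.list(qs)))
    }
    rows[[length(rows) + 1L]] <- base
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    qs <- if (length(datasets))
      stats::setNames(as.list(rep(NA_real_, length(datasets))),
                      sprintf("q_%s", datasets))
    else list()
    out <- cbind(data.frame(variant_id = character(), gene = character(),
                            n_significant_datasets = integer(),
                            replicated = logical(), direction = integer(),
                            min_q = numeric(), stringsAsFactors = FALSE),
                 as.data.frame(qs)[0, , drop = FALSE])
    return(out)
  }
  out[order(out$variant_id, out$gene), , drop = FALSE]
}
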