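# Allele-specific binding disruption statistics: per-allele best-match
# scores, affinity p-values (is either allele significantly bound?), rank
# p-values (do the alleles differ?), and the significance filter combining
# both. Null distributions are computed either exactly (full enumeration of
# background sequences, feasible for short scans) or by seeded Monte Carlo;
# one null sample per (motif, scan geometry) serves every variant, every
# allele and every allele pair.

# Best achievable score per focal allele for each background sequence:
# max over all windows overlapping the focal position, both strands.
# seqmat is n x len (integer codes); f is the 1-based focal column.
#' @noRd
allele_best_scores <- function(lo, seqmat, f) {
  L <- nrow(lo)
  len <- ncol(seqmat)
  n <- nrow(seqmat)
  w_lo <- max(1L, f - L + 1L)
  w_hi <- min(f, len - L + 1L)
  if (w_hi < w_lo) stop("no valid scoring window for this geometry")
  S <- matrix(-Inf, n, 4L)
  for (w in w_lo:w_hi) {
    Fp <- numeric(n)
    Fm <- numeric(n)
    for (j in seq_len(L)) {
      p_plus <- w + j - 1L
      if (p_plus != f) Fp <- Fp + lo[j, ][seqmat[, p_plus]]
      p_minus <- w + L - j
      if (p_minus != f) Fm <- Fm + lo[j, ][5L - seqmat[, p_minus]]
    }
    jf <- f - w + 1L
    jfm <- w + L - f
    for (b in 1:4) {
      S[, b] <- pmax(S[, b], Fp + lo[jf, b])
      S[, b] <- pmax(S[, b], Fm + lo[jfm, 5L - b])
    }
  }
  S
}

#' Null distribution of allele-specific best-match scores
#'
#' Builds the background null for a given motif and scan geometry: either
#' exact (weighted enumeration of all background flank sequences; allowed
#' only when `4^scan_len <= 4^10`) or Monte Carlo (`n_mc` seeded draws from
#' the background). The result carries, per background sequence, the best
#' score attainable with each of the four bases substituted at the focal
#' position, and is reused by both [affinity_pvalue()] and
#' [rank_pvalue()].
#'
#' @param pwm A `pwm` object.
#' @param background A `background_model`.
#' @param flank_left,flank_right Scanned bases left/right of the focal
#'   position.
#' @param mode `"exact"` or `"mc"`.
#' @param n_mc Monte Carlo sample size (default `1e5`, giving SE at
#'   p = 0.001 of about `1e-4`).
#' @param seed Integer seed for Monte Carlo draws.
#' @param pseudocount Passed to [log_odds()].
#' @param site_frac Importance-sampling mixture fraction: this share of the
#'   Monte Carlo draws is sampled from motif-planted sequences (random
#'   window and strand) instead of the background, with self-normalized
#'   importance weights restoring the background law. Extends the
#'   resolvable tail far below `1/n_mc`, which the rank test needs when
#'   both alleles score deep in the null tail (strong planted sites).
#'   Default 0 (pure background sampling).
#' @return Object of class `score_null` with elements `S` (n x 4 matrix),
#'   `weights`, `bg`, `mode`, `n`.
#' @export
score_null <- function(pwm, background = new_background(),
                       flank_left = 20L, flank_right = 20L,
                       mode = c("mc", "exact"), n_mc = 1e5, seed = NULL,
                       pseudocount = 1e-4, site_frac = 0) {
  mode <- match.arg(mode)
  lo <- log_odds(pwm, background, pseudocount)
  len <- as.integer(flank_left) + 1L + as.integer(flank_right)
  f <- as.integer(flank_left) + 1L
  bg <- background$base_freqs
  if (mode == "exact") {
    if (len > 10L)
      stop("exact mode limited to scan length <= 10 (4^len enumeration)")
    grid <- as.matrix(expand.grid(rep(list(1:4), len - 1L),
                                  KEEP.OUT.ATTRS = FALSE))
    seqmat <- matrix(1L, nrow(grid), len)
    if (len > 1L) seqmat[, -f] <- grid
    weights <- if (len > 1L) exp(rowSums(matrix(log(bg)[grid],
                                                nrow(grid)))) else 1
    S <- allele_best_scores(lo, seqmat, f)
    finish_null(S, weights, bg, "exact")
  } else {
    with_seed(seed, {
      seqmat <- matrix(sample.int(4L, n_mc * len, replace = TRUE,
                                  prob = bg), n_mc, len)
      if (site_frac > 0) {
        L <- nrow(lo)
        w_lo <- max(1L, f - L + 1L)
        w_hi <- min(f, len - L + 1L)
        wins <- as.matrix(expand.grid(w = w_lo:w_hi, s = 1:2))
        n_site <- round(n_mc * site_frac)
        site_rows <- (n_mc - n_site + 1L):n_mc
        pick <- sample.int(nrow(wins), n_site, replace = TRUE)
        for (k in seq_len(nrow(wins))) {
          rows <- site_rows[pick == k]
          if (!length(rows)) next
          w <- wins[k, "w"]
          inst <- vapply(seq_len(L), function(j)
            sample.int(4L, length(rows), replace = TRUE,
                       prob = pwm$probs[j, ]), integer(length(rows)))
          inst <- matrix(inst, nrow = length(rows))
          if (wins[k, "s"] == 2L)
            inst <- (5L - inst)[, rev(seq_len(L)), drop = FALSE]
          seqmat[rows, w:(w + L - 1L)] <- inst
        }
        # self-normalized importance weights: bg(x) / q(x) with
        # q = (1 - site_frac) bg + site_frac * mean over (window, strand)
        # of the motif-planted law (flank positions only; focal excluded)
        lo0 <- log2(pwm$probs) - matrix(log2(bg), nrow(pwm$probs), 4L,
                                        byrow = TRUE)
        ratio <- numeric(n_mc)
        for (k in seq_len(nrow(wins))) {
          w <- wins[k, "w"]
          F0 <- numeric(n_mc)
          for (j in seq_len(L)) {
            p_pos <- if (wins[k, "s"] == 1L) w + j - 1L else w + L - j
            if (p_pos == f) next
            base <- if (wins[k, "s"] == 1L) seqmat[, p_pos]
                    else 5L - seqmat[, p_pos]
            F0 <- F0 + lo0[j, ][base]
          }
          ratio <- ratio + 2^F0
        }
        ratio <- ratio / nrow(wins)
        u <- 1 / ((1 - site_frac) + site_frac * ratio)
        weights <- u / sum(u)
      } else {
        weights <- rep(1 / n_mc, n_mc)
      }
      S <- allele_best_scores(lo, seqmat, f)
      finish_null(S, weights, bg, "mc")
    })
  }
}

# Attach the marginal survival function of the best score (focal base drawn
# from the background) to a null object. survival(x) = P(S >= x).
#' @noRd
finish_null <- function(S, weights, bg, mode) {
  pool <- as.vector(S)
  w <- rep(weights, 4L) * rep(unname(bg), each = nrow(S))
  o <- order(pool)
  null <- structure(list(S = S, weights = weights, bg = bg, mode = mode,
                         n = nrow(S), surv_x = pool[o],
                         surv_cw = cumsum(w[o]), gfloor = 0.5 * min(w)),
                    class = "score_null")
  # cached log affinity ranks of the null scores themselves (per focal
  # allele); the rank-test statistic is a difference of two of its columns
  null$logp <- matrix(log(null_survival(null, pool)), nrow = nrow(S))
  null
}

# P(S_null >= x), with a small tolerance so float jitter between scoring
# code paths cannot flip tie inclusion; floored at half the smallest
# atom so log transforms stay finite.
#' @noRd
null_survival <- function(null, x, floor_p = TRUE) {
  j <- findInterval(x - 1e-9, null$surv_x, left.open = TRUE)
  below <- ifelse(j >= 1L, null$surv_cw[pmax(j, 1L)], 0)
  total <- null$surv_cw[length(null$surv_cw)]
  p <- pmin(pmax(total - below, 0), 1)
  if (floor_p) pmax(p, null$gfloor) else p
}

#' Affinity p-value of an observed best-match score
#'
#' Probability that a random background sequence of the same scan length
#' attains a best-match score at least as high as the observed one (the
#' focal base is drawn from the background like every other position). A
#' small value means the observed allele looks like a genuine binding site
#' rather than background.
#'
#' @param score Observed best-match score (log2 units).
#' @param pwm,background,mode,n_mc,seed,pseudocount See [score_null()].
#' @param flank_left,flank_right Scan geometry (defaults: half-window 20 on
#'   each side).
#' @param null Optional precomputed [score_null()] (overrides the other
#'   null parameters).
#' @return p-value in `[0, 1]`; Monte Carlo estimates carry an `"se"`
#'   attribute (binomial standard error).
#' @export
affinity_pvalue <- function(score, pwm, background = new_background(),
                            mode = c("mc", "exact"), n_mc = 1e5,
                            seed = NULL, flank_left = 20L,
                            flank_right = 20L, pseudocount = 1e-4,
                            null = NULL) {
  if (is.null(null)) {
    mode <- match.arg(mode)
    null <- score_null(pwm, background, flank_left, flank_right, mode,
                       n_mc, seed, pseudocount)
  }
  p <- null_survival(null, score, floor_p = FALSE)
  if (null$mode == "mc")
    attr(p, "se") <- sqrt(p * (1 - p) / null$n)
  p
}

#' Rank p-value for an allelic change in binding likelihood
#'
#' Tests whether the two alleles occupy significantly different ranks in
#' the background score distribution. Null: background sequences of the
#' same scan geometry with the reference and alternate alleles substituted
#' at the focal position; statistic
#' `|log p_aff(S_ref) - log p_aff(S_alt)|`, where `p_aff` is the marginal
#' affinity survival function of the same null (floored at half its
#' smallest atom so logs stay finite). The p-value is the null probability
#' of a rank change at least as large as observed. Identical alleles, or a
#' motif blind to the focal base, return 1 (no test). The raw score
#' difference `|S_ref - S_alt|` is not used directly because its null
#' saturates at the maximum attainable column contrast (each allele's best
#' window migrates to a focal column that favors it), which would leave the
#' test powerless; the rank transform restores power while preserving every
#' degenerate-case contract.
#'
#' @param pwm A `pwm` object.
#' @param reference_window Scanned sequence (the focal position +/- the
#'   half-window, already extracted).
#' @param focal_offset 0-based offset of the variant base within
#'   `reference_window`.
#' @param ref_allele,alt_allele The two alleles.
#' @param background,mode,n_mc,seed,pseudocount See [score_null()].
#' @param null Optional precomputed [score_null()].
#' @return p-value in `[0, 1]`; Monte Carlo estimates carry an `"se"`
#'   attribute.
#' @export
rank_pvalue <- function(pwm, reference_window, focal_offset, ref_allele,
                        alt_allele, background = new_background(),
                        mode = c("mc", "exact"), n_mc = 1e5, seed = NULL,
                        pseudocount = 1e-4, null = NULL) {
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  if (identical(ref_allele, alt_allele)) return(1)
  len <- nchar(reference_window)
  f0 <- as.integer(focal_offset)
  lo <- log_odds(pwm, background, pseudocount)
  s_ref <- best_match_score(pwm, reference_window, f0, ref_allele,
                            half_window = len, lo = lo)$score
  s_alt <- best_match_score(pwm, reference_window, f0, alt_allele,
                            half_window = len, lo = lo)$score
  if (is.null(null)) {
    mode <- match.arg(mode)
    null <- score_null(pwm, background, flank_left = f0,
                       flank_right = len - 1L - f0, mode = mode,
                       n_mc = n_mc, seed = seed, pseudocount = pseudocount)
  }
  obs <- abs(log(null_survival(null, s_ref)) -
               log(null_survival(null, s_alt)))
  a <- match(ref_allele, DNA_BASES)
  b <- match(alt_allele, DNA_BASES)
  diffs <- abs(null$logp[, a] - null$logp[, b])
  p <- sum(null$weights * (diffs >= obs - 1e-9))
  p <- min(max(p, 0), 1)
  if (null$mode == "mc")
    attr(p, "se") <- sqrt(p * (1 - p) / null$n)
  p
}

#' Allele-specific scores for one variant against one motif
#'
#' Scores the reference and alternate alleles with [best_match_score()] on
#' the `+/- half_window` sequence around the variant. The reference allele
#' must match the FASTA base at the variant position (`REF_MISMATCH`
#' otherwise); scans near contig ends are truncated. Multiallelic variants
#' should be supplied as one row per alternate allele.
#'
#' @param pwm A `pwm` object.
#' @param reference Named character vector of contigs.
#' @param variant One-row `data.frame` (`chrom`, `pos0`, `id`, `ref`,
#'   `alt`).
#' @param half_window Scan half-window (default 20).
#' @param background,pseudocount Scoring parameters.
#' @return One-row `data.frame`: `variant_id`, `motif_name`, `score_ref`,
#'   `score_alt`, `direction` (`loss`/`gain`/`none`), best-window fields.
#' @export
score_variant <- function(pwm, reference, variant, half_window = 20L,
                          background = new_background(),
                          pseudocount = 1e-4) {
  seq <- reference[[variant$chrom]]
  if (is.null(seq)) stop("reference lacks contig ", variant$chrom)
  if (identical(toupper(variant$ref), toupper(variant$alt)))
    stop("degenerate variant ", variant$id, ": ref == alt")
  fasta_base <- toupper(substr(seq, variant$pos0 + 1L, variant$pos0 + 1L))
  if (fasta_base != toupper(variant$ref))
    stop("REF_MISMATCH at ", variant$id, ": FASTA has ", fasta_base,
         ", variant claims ", variant$ref)
  lo <- log_odds(pwm, background, pseudocount)
  sr <- best_match_score(pwm, seq, variant$pos0, variant$ref,
                         half_window = half_window, lo = lo)
  sa <- best_match_score(pwm, seq, variant$pos0, variant$alt,
                         half_window = half_window, lo = lo)
  direction <- if (sa$score < sr$score) "loss"
               else if (sa$score > sr$score) "gain" else "none"
  data.frame(variant_id = variant$id, motif_name = pwm$name,
             score_ref = sr$score, score_alt = sa$score,
             direction = direction,
             ref_window_start = sr$window_start, ref_strand = sr$strand,
             alt_window_start = sa$window_start, alt_strand = sa$strand,
             stringsAsFactors = FALSE)
}

#' Score a variant table against motifs, with p-values
#'
#' Batch driver: for each motif, builds one [score_null()] per scan
#' geometry (shared across variants) and computes per-variant allele
#' scores, affinity p-values for both alleles, and the rank p-value.
#'
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param reference Named character vector of contigs.
#' @param variants Variant `data.frame` (`chrom`, `pos0`, `id`, `ref`,
#'   `alt`).
#' @param half_window Scan half-window (default 20).
#' @param background A `background_model`.
#' @param mode,n_mc,seed,pseudocount Null-distribution parameters (see
#'   [score_null()]).
#' @param site_frac Importance-sampling mixture fraction for Monte Carlo
#'   nulls (default 0.5; see [score_null()]). Ignored in exact mode.
#' @return `data.frame` with one row per variant x motif:
#'   scores, `p_ref`, `p_alt`, `p_rank`, `direction`.
#' @export
disruption_test <- function(pwms, reference, variants, half_window = 20L,
                            background = new_background(),
                            mode = c("mc", "exact"), n_mc = 1e5,
                            seed = NULL, pseudocount = 1e-4,
                            site_frac = 0.5) {
  mode <- match.arg(mode)
  if (is_pwm(pwms)) pwms <- list(pwms)
  out <- list()
  for (m in seq_along(pwms)) {
    pwm <- pwms[[m]]
    nulls <- new.env(parent = emptyenv())
    scored <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, , drop = FALSE]
      seq <- reference[[v$chrom]]
      fl <- min(half_window, v$pos0)
      fr <- min(half_window, nchar(seq) - 1L - v$pos0)
      sc <- score_variant(pwm, reference, v, half_window, background,
                          pseudocount)
      sc$fl <- fl
      sc$fr <- fr
      sc
    }))
    # one null per scan geometry (variants near contig ends get their own)
    for (key in unique(paste(scored$fl, scored$fr, sep = "_"))) {
      sel <- paste(scored$fl, scored$fr, sep = "_") == key
      fl <- scored$fl[sel][1L]
      fr <- scored$fr[sel][1L]
      null <- score_null(pwm, background, fl, fr, mode = mode, n_mc = n_mc,
                         seed = if (is.null(seed)) NULL
                                else derive_seed(seed,
                                                 paste0(pwm$name, key)),
                         pseudocount = pseudocount,
                         site_frac = if (mode == "mc") site_frac else 0)
      scored$p_ref[sel] <- null_survival(null, scored$score_ref[sel],
                                         floor_p = FALSE)
      scored$p_alt[sel] <- null_survival(null, scored$score_alt[sel],
                                         floor_p = FALSE)
      obs <- abs(log(null_survival(null, scored$score_ref[sel])) -
                   log(null_survival(null, scored$score_alt[sel])))
      idx <- which(sel)
      vref <- toupper(variants$ref[idx])
      valt <- toupper(variants$alt[idx])
      for (j in seq_along(idx)) {
        a <- match(vref[j], DNA_BASES)
        b <- match(valt[j], DNA_BASES)
        scored$p_rank[idx[j]] <- if (a == b) 1 else
          min(max(sum(null$weights *
                        (abs(null$logp[, a] - null$logp[, b]) >=
                           obs[j] - 1e-9)), 0), 1)
      }
    }
    scored$fl <- NULL
    scored$fr <- NULL
    out[[m]] <- scored
  }
  do.call(rbind, out)
}

#' Call TF binding-disrupting variants
#'
#' Applies the two significance gates: at least one allele must show a
#' significant binding likelihood (`min(p_ref, p_alt) < alpha_affinity`,
#' default 0.001 — potential TF occupancy of at least one allele), and the
#' allelic difference must be significant after Bonferroni correction
#' (`p_rank < alpha_rank / n_tests`, default 0.05 over the number of
#' scored SNP x motif pairs).
#'
#' @param results `data.frame` from [disruption_test()].
#' @param alpha_affinity Affinity gate level (default 0.001).
#' @param alpha_rank Family-wise rank gate level before Bonferroni division
#'   (default 0.05).
#' @param n_tests Bonferroni denominator; defaults to `nrow(results)`,
#'   overridable (e.g., for per-TF correction).
#' @return List with `results` (input plus logical `kept`), `kept` (the
#'   surviving rows) and `summary` (per-motif counts by direction).
#' @export
call_disrupting <- function(results, alpha_affinity = 0.001,
                            alpha_rank = 0.05, n_tests = nrow(results)) {
  if (is.null(n_tests) || n_tests < 1L) stop("n_tests must be >= 1")
  keep <- pmin(results$p_ref, results$p_alt) < alpha_affinity &
    results$p_rank < alpha_rank / n_tests
  results$kept <- keep
  kept <- results[keep, , drop = FALSE]
  summary <- if (nrow(kept)) {
    agg <- as.data.frame(table(motif = kept$motif_name,
                               direction = kept$direction))
    agg <- agg[agg$Freq > 0, , drop = FALSE]
    names(agg)[3L] <- "n"
    agg
  } else data.frame(motif = character(), direction = character(),
                    n = integer())
  list(results = results, kept = kept, summary = summary)
}
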