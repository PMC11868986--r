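# De novo motif discovery from top ChIP-seq peaks: a documented, simplified
# seed-and-refine scheme (k-mer seeds scored by one-sided Fisher enrichment
# against per-sequence dinucleotide shuffles, one EM refinement pass into a
# PWM, greedy acceptance with site masking) with held-out enrichment
# p-values and Benjamini-Hochberg FDR filtering.

#' @noRd
revcomp_vec <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Select top peaks and extract their flanked sequences
#'
#' Ranks peaks by height (ties broken by coordinate), keeps the top `n`,
#' and extracts the summit (or interval midpoint) +/- `flank` bases from
#' the reference, uppercased. Sequences with more than 10% non-ACGT bases
#' are dropped and logged.
#'
#' @param peaks Peak `data.frame` (`chrom`, `start`, `end`, `name`,
#'   `height`; optional `summit` offset from `start`).
#' @param n Number of top peaks (default 500).
#' @param flank Bases on each side of the summit (default 20).
#' @param reference Named character vector of contigs.
#' @return Named character vector of sequences (length `2 * flank + 1`),
#'   ordered by decreasing height.
#' @export
select_top_peaks <- function(peaks, n = 500L, flank = 20L, reference) {
  if (!nrow(peaks)) stop("empty peak set")
  o <- order(-peaks$height, peaks$chrom, peaks$start)
  top <- peaks[o, , drop = FALSE][seq_len(min(n, nrow(peaks))), ,
                                  drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(top))) {
    ctg <- reference[[top$chrom[i]]]
    if (is.null(ctg)) stop("reference lacks contig ", top$chrom[i])
    summit <- if (!is.null(top$summit)) top$start[i] + top$summit[i]
              else top$start[i] + (top$end[i] - top$start[i]) %/% 2L
    s0 <- max(1L, summit - flank + 1L)
    s1 <- min(nchar(ctg), summit + flank + 1L)
    s <- toupper(substr(ctg, s0, s1))
    frac_bad <- 1 - sum(strsplit(s, "")[[1L]] %in% DNA_BASES) / nchar(s)
    if (frac_bad > 0.1) {
      message("select_top_peaks: dropping ", top$name[i],
              " (non-ACGT fraction ", round(frac_bad, 2), ")")
      next
    }
    out[top$name[i]] <- s
  }
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-path shuffle: returns a random permutation of
#' the input that preserves the exact dinucleotide (and hence
#' mononucleotide) counts.
#'
#' @param sequence DNA string over A/C/G/T, length >= 3.
#' @param seed Optional integer seed (same seed, same shuffle).
#' @return Shuffled sequence of the same length.
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 3L) stop("sequence must have length >= 3")
  if (any(!chars %in% DNA_BASES))
    stop("sequence contains non-ACGT characters")
  verts <- unique(chars)
  if (length(verts) == 1L) return(sequence)
  with_seed(seed, {
    last <- chars[n]
    adj <- split(chars[-1L], chars[-n])
    inner <- setdiff(verts, last)
    repeat {
      last_edge <- stats::setNames(
        vapply(inner, function(v) {
          e <- adj[[v]]
          e[sample.int(length(e), 1L)]
        }, character(1L)), inner)
      ok <- TRUE
      for (v in inner) {
        cur <- v; seen <- character(0)
        while (cur != last) {
          if (cur %in% seen) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- last_edge[[cur]]
        }
        if (!ok) break
      }
      if (ok) break
    }
    out_edges <- lapply(verts, function(v) {
      e <- adj[[v]] %||% character(0)
      if (v != last && length(e)) {
        i <- match(last_edge[[v]], e)
        e <- e[-i]
        if (length(e) > 1L) e <- e[sample.int(length(e))]
        e <- c(e, last_edge[[v]])
      } else if (length(e) > 1L) {
        e <- e[sample.int(length(e))]
      }
      e
    })
    names(out_edges) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    res <- character(n)
    res[1L] <- chars[1L]
    cur <- chars[1L]
    for (i in 2:n) {
      nxt <- out_edges[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      res[i] <- nxt
      cur <- nxt
    }
    paste(res, collapse = "")
  })
}

# Per-sequence sets of distinct k-mers (both strands). Reverse complement
# is taken once per sequence (plain string ops; no S4 overhead).
#' @noRd
kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    rc <- revcomp(s)
    subs <- c(substring(s, 1:(n - k + 1L), k:n),
              substring(rc, 1:(n - k + 1L), k:n))
    subs <- subs[!grepl("[^ACGT]", subs)]
    unique(subs)
  })
}

# One-sided Fisher (hypergeometric) enrichment p-value for presence counts
# a of n_pos positives vs b of n_bg backgrounds.
#' @noRd
fisher_presence_p <- function(a, b, n_pos, n_bg) {
  stats::phyper(a - 1, a + b, n_pos + n_bg - a - b, n_pos,
                lower.tail = FALSE)
}

# Build an initial PWM of width w around a k-mer seed (dominant-base 0.7).
#' @noRd
seed_pwm <- function(kmer, w) {
  k <- nchar(kmer)
  pad_l <- (w - k) %/% 2L
  probs <- matrix(0.25, nrow = w, ncol = 4L)
  enc <- seq_to_int(kmer)
  for (j in seq_len(k)) {
    probs[pad_l + j, ] <- 0.1
    probs[pad_l + j, enc[j]] <- 0.7
  }
  new_pwm(probs, name = kmer)
}

# One EM(-like) refinement pass: align the best site per sequence under the
# current PWM and rebuild column frequencies with a pseudocount.
#' @noRd
refine_pwm <- function(pwm, seqs, pseudocount = 0.5) {
  lo <- log_odds(pwm, new_background())
  L <- nrow(lo)
  counts <- matrix(pseudocount, nrow = L, ncol = 4L)
  n_sites <- 0L
  for (s in seqs) {
    hit <- best_site(lo, s)
    if (!is.finite(hit$score) || hit$score <= 0) next
    site <- substr(s, hit$start, hit$start + L - 1L)
    if (hit$strand == "-") site <- revcomp(site)
    enc <- seq_to_int(site)
    if (anyNA(enc)) next
    counts[cbind(seq_len(L), enc)] <- counts[cbind(seq_len(L), enc)] + 1
    n_sites <- n_sites + 1L
  }
  if (n_sites < 2L) return(pwm)
  new_pwm(counts / rowSums(counts), name = pwm$name, source = "discovered",
          nsites = n_sites)
}

# Mask (with N) the best motif site in each sequence scoring at or above
# the presence threshold.
#' @noRd
mask_sites <- function(seqs, pwm, threshold) {
  lo <- log_odds(pwm, new_background())
  L <- nrow(lo)
  vapply(seqs, function(s) {
    hit <- best_site(lo, s)
    if (is.finite(hit$score) && hit$score >= threshold)
      substr(s, hit$start, hit$start + L - 1L) <-
        paste(rep("N", L), collapse = "")
    s
  }, character(1L), USE.NAMES = FALSE)
}

#' @noRd
presence_threshold <- function(pwm, frac = 0.75) {
  lo <- log_odds(pwm, new_background())
  frac * sum(apply(lo, 1L, max))
}

#' Discover enriched motifs from positive sequences
#'
#' Simplified seed-and-refine discovery (a documented stand-in for
#' STREME-class tools, exposing the same `nmotifs` / `minw` / `maxw`
#' parameters): positive sequences are split 50/50 into a discovery and a
#' held-out set, each with per-sequence dinucleotide-shuffled backgrounds.
#' For each width, k-mer seeds (`k = min(w, 8)`) are scored by one-sided
#' Fisher presence enrichment in the discovery set versus its shuffles; the
#' best seed is extended to the target width and refined into a PWM by one
#' EM pass over best-site alignments. Up to `nmotifs` motifs are accepted
#' greedily, masking each accepted motif's sites before the next round.
#' Each accepted motif's reported `enrichment_p` is computed on the
#' held-out split only. Widths are capped at `width_cap` (default 12) for
#' desk-scale runtime.
#'
#' @param pos_seqs Character vector of >= 20 positive sequences
#'   (e.g., from [select_top_peaks()]).
#' @param seed Integer seed.
#' @param nmotifs Maximum motifs returned (default 5).
#' @param minw,maxw Width range (defaults 6 and 20; widths above
#'   `width_cap` are not enumerated).
#' @param width_cap Maximum enumerated width (default 12).
#' @param presence_frac Fraction of the maximum achievable log-odds score
#'   defining site presence (default 0.75).
#' @return List of `discovered_motif` objects: `pwm`, `enrichment_p`,
#'   `q_value` (`NA` until [motif_fdr_filter()]), `seed_kmer`.
#' @export
discover_motifs <- function(pos_seqs, seed = 1L, nmotifs = 5L, minw = 6L,
                            maxw = 20L, width_cap = 12L,
                            presence_frac = 0.75) {
  if (length(pos_seqs) < 20L)
    stop("need at least 20 positive sequences for discovery")
  widths <- seq(as.integer(minw), min(as.integer(maxw),
                                      as.integer(width_cap)))
  with_seed(seed, {
    n <- length(pos_seqs)
    perm <- sample.int(n)
    half <- n %/% 2L
    disc <- toupper(pos_seqs[perm[seq_len(half)]])
    held <- toupper(pos_seqs[perm[(half + 1L):n]])
    disc_bg <- vapply(disc, dinucleotide_shuffle, character(1L),
                      USE.NAMES = FALSE)
    held_bg <- vapply(held, dinucleotide_shuffle, character(1L),
                      USE.NAMES = FALSE)
    masked <- disc
    accepted <- list()
    ks <- unique(pmin(widths, 8L))
    bg_tabs <- lapply(stats::setNames(ks, ks), function(k)
      table(unlist(kmer_sets(disc_bg, k))))
    for (iter in seq_len(as.integer(nmotifs))) {
      best <- NULL
      for (w in widths) {
        k <- min(w, 8L)
        pos_sets <- kmer_sets(masked, k)
        pos_tab <- table(unlist(pos_sets))
        if (!length(pos_tab)) next
        bg_tab <- bg_tabs[[as.character(k)]]
        kmers <- names(pos_tab)
        a <- as.integer(pos_tab)
        b <- as.integer(bg_tab[kmers])
        b[is.na(b)] <- 0L
        p <- fisher_presence_p(a, b, length(masked), length(disc_bg))
        o <- order(p, -a, kmers)[1L]
        if (is.null(best) || p[o] < best$p)
          best <- list(kmer = kmers[o], w = w, p = p[o])
      }
      if (is.null(best) || best$p >= 0.5) break
      pwm0 <- seed_pwm(best$kmer, best$w)
      pwm0$name <- sprintf("motif_%d_w%d", iter, best$w)
      pwm1 <- refine_pwm(pwm0, masked)
      pwm1$name <- pwm0$name
      accepted[[length(accepted) + 1L]] <-
        structure(list(pwm = pwm1, enrichment_p = NA_real_,
                       q_value = NA_real_, seed_kmer = best$kmer,
                       discovery_p = best$p),
                  class = "discovered_motif")
      masked <- mask_sites(masked, pwm1,
                           presence_threshold(pwm1, presence_frac))
    }
    # held-out enrichment, independent of seed selection
    for (i in seq_along(accepted)) {
      pwm <- accepted[[i]]$pwm
      thr <- presence_threshold(pwm, presence_frac)
      lo <- log_odds(pwm, new_background())
      hits <- function(ss) sum(vapply(ss, function(s) {
        h <- best_site(lo, s)
        is.finite(h$score) && h$score >= thr
      }, logical(1L)))
      a <- hits(held)
      b <- hits(held_bg)
      accepted[[i]]$enrichment_p <-
        fisher_presence_p(a, b, length(held), length(held_bg))
    }
    accepted
  })
}

#' Filter discovered motifs by FDR
#'
#' Benjamini-Hochberg adjustment across the held-out enrichment p-values;
#' motifs with `q <= alpha` are retained with their `q_value` filled in.
#'
#' @param motifs List of `discovered_motif` objects.
#' @param alpha FDR level (default 0.05).
#' @return Retained motifs (possibly empty list).
#' @export
motif_fdr_filter <- function(motifs, alpha = 0.05) {
  if (!length(motifs)) return(list())
  p <- vapply(motifs, `[[`, numeric(1L), "enrichment_p")
  if (anyNA(p)) stop("held-out enrichment p-values not computed")
  q <- stats::p.adjust(p, method = "BH")
  keep <- which(q <= alpha)
  out <- motifs[keep]
  for (i in seq_along(out)) out[[i]]$q_value <- q[keep[i]]
  out
}
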