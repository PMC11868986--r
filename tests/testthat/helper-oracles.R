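# Independent brute-force oracles used to freeze expected values. These
# deliberately share no code with the package internals: plain loops over
# strings, full enumeration of background sequences, naive alignment
# scans.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp <- function(s) {
  paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# Naive best-match score: every window overlapping the focal base within
# focal +/- half_window, both strands, plain loops.
oracle_best_match <- function(pwm, seq, focal0, allele, half_window,
                              bg = rep(0.25, 4), pc = 1e-4) {
  probs <- pwm$probs
  L <- nrow(probs)
  lo <- log2((probs + pc) / (1 + 4 * pc))
  for (b in 1:4) lo[, b] <- lo[, b] - log2(bg[b])
  chars <- strsplit(toupper(seq), "")[[1]]
  chars[focal0 + 1] <- allele
  n <- length(chars)
  s0 <- max(1, focal0 + 1 - half_window)
  s1 <- min(n, focal0 + 1 + half_window)
  best <- -Inf
  for (w in s0:(s1 - L + 1)) {
    if (w < 1 || w + L - 1 > s1) next
    if (!(w <= focal0 + 1 && focal0 + 1 <= w + L - 1)) next
    sp <- 0
    sm <- 0
    for (j in 1:L) {
      bj <- match(chars[w + j - 1], BASES)
      sp <- sp + lo[j, bj]
      bmj <- match(COMP[chars[w + L - j]], BASES)
      sm <- sm + lo[j, bmj]
    }
    best <- max(best, sp, sm)
  }
  best
}

# Enumerate every background sequence of length len; returns a list with
# the per-sequence probability and the best allele-substituted scores
# (focal at 1-based position f).
oracle_enumerate <- function(pwm, len, f, bg = rep(0.25, 4), pc = 1e-4,
                             half_window = len) {
  grid <- expand.grid(rep(list(1:4), len))
  n <- nrow(grid)
  prob <- apply(grid, 1, function(r) prod(bg[r]))
  S <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    seq <- paste(BASES[as.integer(grid[i, ])], collapse = "")
    for (b in 1:4)
      S[i, b] <- oracle_best_match(pwm, seq, f - 1, BASES[b],
                                   half_window, bg, pc)
  }
  list(prob = prob, S = S)
}

# Exact affinity p-value by enumeration: focal base is background-random.
oracle_affinity_p <- function(score, enum, bg = rep(0.25, 4)) {
  p <- 0
  for (b in 1:4)
    p <- p + sum(enum$prob * bg[b] * (enum$S[, b] >= score - 1e-9))
  p
}

# Exact rank p-value by enumeration, mirroring the package's statistic
# definition (|log survival(S_ref) - log survival(S_alt)|, survival floored
# at half its smallest atom) with independent code.
oracle_rank_p <- function(pwm, window_seq, f, ref, alt, bg = rep(0.25, 4),
                          pc = 1e-4) {
  len <- nchar(window_seq)
  enum <- oracle_enumerate(pwm, len, f, bg, pc)
  pool <- as.vector(enum$S)
  pw <- rep(enum$prob, 4) * rep(bg, each = nrow(enum$S))
  gfun <- function(x) max(sum(pw[pool >= x - 1e-9]), 0.5 * min(pw))
  a <- match(ref, BASES)
  b <- match(alt, BASES)
  if (a == b) return(1)
  sr <- oracle_best_match(pwm, window_seq, f - 1, ref, len, bg, pc)
  sa <- oracle_best_match(pwm, window_seq, f - 1, alt, len, bg, pc)
  obs <- abs(log(gfun(sr)) - log(gfun(sa)))
  d <- abs(vapply(enum$S[, a], function(x) log(gfun(x)), 0) -
             vapply(enum$S[, b], function(x) log(gfun(x)), 0))
  sum(enum$prob * (d >= obs - 1e-9))
}

# Naive PWM column-correlation alignment over all offsets and strands.
oracle_similarity <- function(q, t, min_overlap = 4) {
  rc <- function(p) p[rev(seq_len(nrow(p))), c(4, 3, 2, 1)]
  best <- -Inf
  for (tp in list(t$probs, rc(t$probs))) {
    lq <- nrow(q$probs)
    lt <- nrow(tp)
    for (o in (-(lt - min_overlap)):(lq - min_overlap)) {
      qi <- max(1, 1 + o):min(lq, lt + o)
      if (length(qi) < min_overlap) next
      r <- suppressWarnings(cor(as.vector(q$probs[qi, , drop = FALSE]),
                                as.vector(tp[qi - o, , drop = FALSE])))
      if (!is.na(r)) best <- max(best, r)
    }
  }
  best
}

# Two-locus r2 from explicit haplotype vectors.
oracle_r2 <- function(x, y) {
  pA <- mean(x)
  pB <- mean(y)
  D <- mean(x == 1 & y == 1) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

oracle_dinuc_counts <- function(s) {
  chars <- strsplit(s, "")[[1]]
  table(paste0(chars[-length(chars)], chars[-1]))
}

# Build a genotype panel directly from a haplotype matrix.
panel_from_matrix <- function(mat, phased = TRUE, chrom = "chr1") {
  nv <- ncol(mat)
  variants <- data.frame(chrom = chrom, pos0 = seq_len(nv) * 100L,
                         id = paste0("v", seq_len(nv)),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  regsnap::new_genotype_panel(variants, mat, phased = phased,
                              samples = paste0("s", seq_len(nrow(mat) / 2)))
}

# Small random PWM.
random_pwm <- function(L, name = "rp") {
  p <- matrix(stats::rgamma(L * 4, 1), ncol = 4)
  regsnap::new_pwm(p / rowSums(p), name = name)
}
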