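# Position weight matrices: construction, validation, IUPAC consensus
# conversion, log-odds transformation, and minimal MEME-format I/O.

#' Construct a position weight matrix (PWM)
#'
#' A PWM stores per-position base probabilities (columns A, C, G, T) for a
#' transcription factor binding motif. Rows must sum to 1 within `1e-9`
#' after construction; inputs within `1e-3` of 1 are renormalized.
#'
#' @param probs Numeric L x 4 matrix of base probabilities, column order
#'   A, C, G, T.
#' @param name Motif identifier.
#' @param source Free-text provenance label (database, experiment, ...).
#' @param nsites Optional number of aligned sites the matrix was built from.
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(probs, name = "motif", source = NA_character_,
                    nsites = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("PWM must have 4 columns (A,C,G,T)")
  if (nrow(probs) < 1L) stop("PWM must have at least one position")
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("PWM entries must be finite and non-negative")
  rs <- rowSums(probs)
  bad <- which(abs(rs - 1) > 1e-3)
  if (length(bad))
    stop("PWM row(s) not summing to 1: ", paste(bad, collapse = ", "))
  probs <- probs / rs
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(list(name = name, source = source, probs = probs,
                 nsites = if (is.null(nsites)) NA_integer_
                          else as.integer(nsites)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%d positions, source: %s)\n", x$name,
              nrow(x$probs), x$source))
  print(round(x$probs, 3))
  invisible(x)
}

#' @rdname new_pwm
#' @param x Object to test or print.
#' @export
is_pwm <- function(x) inherits(x, "pwm")

#' @noRd
pwm_length <- function(pwm) nrow(pwm$probs)

#' Reverse complement of a PWM
#'
#' Reverses positions and swaps complementary base columns, giving the motif
#' read on the opposite strand.
#'
#' @param pwm A [new_pwm()] object.
#' @return A `pwm` object.
#' @export
pwm_revcomp <- function(pwm) {
  p <- pwm$probs[rev(seq_len(nrow(pwm$probs))), c(4L, 3L, 2L, 1L),
                 drop = FALSE]
  new_pwm(p, name = pwm$name, source = pwm$source, nsites = pwm$nsites)
}

#' Total information content of a PWM in bits
#'
#' Sum over positions of `2 + sum(p * log2(p))` (uniform background).
#'
#' @param pwm A `pwm` object.
#' @return Information content in bits.
#' @export
pwm_information <- function(pwm) {
  p <- pwm$probs
  sum(apply(p, 1L, function(r) {
    r <- r[r > 0]
    2 + sum(r * log2(r))
  }))
}

#' Majority-base consensus string of a PWM
#'
#' @param pwm A `pwm` object.
#' @return Character string of the most probable base per position.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 1L, which.max)], collapse = "")
}

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Build a PWM from an IUPAC consensus string
#'
#' Each column is uniform over the bases allowed by the IUPAC code and zero
#' elsewhere; pseudocounts are applied later, at log-odds construction, not
#' here. For example the NRF1-family palindromic response element
#' `"YGCGCAYGCGCR"` yields a 12-column matrix whose first column is
#' C/T at probability 0.5 each.
#'
#' @param iupac Character string over the 15 IUPAC nucleotide codes.
#' @param name Motif name.
#' @return A `pwm` object.
#' @export
from_consensus <- function(iupac, name = iupac) {
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1L]]
  if (!length(chars)) stop("empty consensus string")
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad))
    stop("non-IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  probs <- t(vapply(chars, function(ch) {
    allowed <- IUPAC_MAP[[ch]]
    p <- stats::setNames(numeric(4L), DNA_BASES)
    p[allowed] <- 1 / length(allowed)
    p
  }, numeric(4L)))
  new_pwm(probs, name = name, source = "consensus")
}

#' Construct a background base-composition model
#'
#' Zero-order (independent bases) or first-order (dinucleotide transition)
#' null model for motif scoring and p-values.
#'
#' @param base_freqs Numeric 4-vector of base frequencies (A,C,G,T); must be
#'   strictly positive; normalized to sum to 1.
#' @param transition Optional 4 x 4 row-stochastic matrix for a first-order
#'   model.
#' @return An object of class `background_model`.
#' @export
new_background <- function(base_freqs = rep(0.25, 4L), transition = NULL) {
  base_freqs <- as.numeric(base_freqs)
  if (length(base_freqs) != 4L || any(!is.finite(base_freqs)) ||
      any(base_freqs <= 0))
    stop("base_freqs must be 4 strictly positive frequencies")
  base_freqs <- base_freqs / sum(base_freqs)
  names(base_freqs) <- DNA_BASES
  ord <- 0L
  if (!is.null(transition)) {
    transition <- as.matrix(transition)
    if (!all(dim(transition) == c(4L, 4L)) ||
        any(abs(rowSums(transition) - 1) > 1e-6))
      stop("transition must be a 4x4 row-stochastic matrix")
    ord <- 1L
  }
  structure(list(order = ord, base_freqs = base_freqs,
                 transition = transition),
            class = "background_model")
}

#' Estimate a zero-order background from sequences
#'
#' @param sequences Character vector of DNA sequences (e.g., a reference).
#' @param pseudocount Count added per base to avoid zero frequencies.
#' @return A `background_model`.
#' @export
background_from_sequences <- function(sequences, pseudocount = 1) {
  tab <- table(factor(strsplit(paste(toupper(sequences), collapse = ""),
                               "", fixed = TRUE)[[1L]], levels = DNA_BASES))
  new_background(as.numeric(tab) + pseudocount)
}

#' Log-odds score matrix of a PWM
#'
#' Entry `(i, b)` is `log2(((p_ib + pc) / (1 + 4 pc)) / bg_b)`: the motif
#' probability with a small additive pseudocount against the background base
#' frequency. The default pseudocount `1e-4` keeps strong penalties for
#' zero-probability bases while avoiding minus infinity.
#'
#' @param pwm A `pwm` object.
#' @param background A `background_model` (zero-order frequencies are used).
#' @param pseudocount Positive additive pseudocount (default `1e-4`).
#' @return L x 4 numeric matrix of log2 scores.
#' @export
log_odds <- function(pwm, background = new_background(),
                     pseudocount = 1e-4) {
  if (!is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  bg <- background$base_freqs
  if (any(bg <= 0)) stop("background frequencies must be positive")
  p <- (pwm$probs + pseudocount) / (1 + 4 * pseudocount)
  sweep(log2(p), 2L, log2(bg), `-`)
}

# ---------------------------------------------------------------------------
# Minimal MEME motif format I/O

#' Read motifs from a minimal MEME-format file
#'
#' Parses the minimal motif interchange format: a version line, optional
#' ALPHABET / strands / background lines, and one `MOTIF` block per matrix
#' with a `letter-probability matrix:` header followed by one
#' whitespace-separated row of four probabilities per motif position.
#' Rows must sum to 1 within `1e-3`; offending rows are reported by index.
#'
#' @param path Path to a MEME-format file.
#' @return List of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  motif_idx <- grep("^MOTIF\\s+", lines)
  if (!length(motif_idx)) stop("no MOTIF blocks found in ", path)
  out <- vector("list", length(motif_idx))
  for (k in seq_along(motif_idx)) {
    i <- motif_idx[k]
    name <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[i])), "\\s+")[[1L]][1L]
    j <- i + 1L
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines))
      stop("MOTIF '", name, "': missing letter-probability matrix header")
    hdr <- lines[j]
    wm <- regmatches(hdr, regexec("w=\\s*(\\d+)", hdr))[[1L]]
    nm <- regmatches(hdr, regexec("nsites=\\s*(\\d+)", hdr))[[1L]]
    w <- if (length(wm) == 2L) as.integer(wm[2L]) else NA_integer_
    nsites <- if (length(nm) == 2L) as.integer(nm[2L]) else NULL
    rows <- list(); j <- j + 1L
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (ln == "" || grepl("^(MOTIF|URL)", lines[j])) break
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
      if (length(vals) != 4L || any(is.na(vals))) break
      rows[[length(rows) + 1L]] <- vals
      j <- j + 1L
    }
    if (!length(rows)) stop("MOTIF '", name, "': no matrix rows")
    probs <- do.call(rbind, rows)
    if (!is.na(w) && nrow(probs) != w)
      stop("MOTIF '", name, "': expected ", w, " rows, found ", nrow(probs))
    bad <- which(abs(rowSums(probs) - 1) > 1e-3)
    if (length(bad))
      stop("MOTIF '", name, "': row(s) not summing to 1: ",
           paste(bad, collapse = ", "))
    out[[k]] <- new_pwm(probs, name = name, source = path, nsites = nsites)
  }
  out
}

#' Write motifs to a minimal MEME-format file
#'
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param path Output path.
#' @param background Optional `background_model` written to the header.
#' @return `path`, invisibly. `read_meme(write_meme(x))` reproduces the
#'   probabilities to within `1e-6` per entry.
#' @export
write_meme <- function(pwms, path, background = new_background()) {
  if (is_pwm(pwms)) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  bg <- background$base_freqs
  cat("MEME version 4\n\nALPHABET= ACGT\n\nstrands: + -\n\n",
      "Background letter frequencies\n",
      sprintf("A %.6f C %.6f G %.6f T %.6f\n\n", bg[1], bg[2], bg[3], bg[4]),
      sep = "", file = con)
  for (p in pwms) {
    ns <- if (is.na(p$nsites)) 20L else p$nsites
    cat(sprintf("MOTIF %s\nletter-probability matrix: alength= 4 w= %d nsites= %d E= 0\n",
                p$name, nrow(p$probs), ns), file = con)
    utils::write.table(format(p$probs, digits = 8, scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    cat("\n", file = con)
  }
  invisible(path)
}
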