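# PWM scanning: allele-specific best-match scores around a focal base,
# generic best-site search, and column-correlation motif comparison.

# Score all length-L windows (both strands) of an integer-encoded sequence
# against a log-odds matrix. Windows containing non-ACGT bases score -Inf.
# Returns matrix with columns start (1-based local), strand (1 = +, 2 = -),
# score.
#' @noRd
window_scores <- function(lo, enc, starts = NULL) {
  L <- nrow(lo)
  n <- length(enc)
  if (is.null(starts)) starts <- seq_len(n - L + 1L)
  if (!length(starts) || n < L)
    return(matrix(numeric(0), ncol = 3L,
                  dimnames = list(NULL, c("start", "strand", "score"))))
  plus <- numeric(length(starts))
  minus <- numeric(length(starts))
  for (j in seq_len(L)) {
    b_plus <- enc[starts + j - 1L]
    b_minus <- 5L - enc[starts + L - j]
    sp <- lo[j, ][b_plus]
    sm <- lo[j, ][b_minus]
    sp[is.na(sp)] <- -Inf
    sm[is.na(sm)] <- -Inf
    plus <- plus + sp
    minus <- minus + sm
  }
  rbind(cbind(start = starts, strand = 1, score = plus),
        cbind(start = starts, strand = 2, score = minus))
}

# Deterministic argmax over window scores: highest score, ties by smaller
# start, then plus strand.
#' @noRd
pick_best_window <- function(ws) {
  o <- order(-ws[, "score"], ws[, "start"], ws[, "strand"])[1L]
  ws[o, ]
}

#' Best allele-specific motif match around a focal position
#'
#' Substitutes `allele` at `focal_pos`, then scores every length-L window
#' that overlaps the focal base and lies within `focal_pos +/- half_window`
#' (truncated at contig ends), on both strands, returning the maximum
#' log-odds window sum. Ties are broken by smaller window start, then plus
#' strand. This is the per-allele score underlying the binding-disruption
#' statistics.
#'
#' @param pwm A [new_pwm()] object.
#' @param sequence Single contig sequence (character string).
#' @param focal_pos 0-based position of the variant base within `sequence`.
#' @param allele Single base ("A", "C", "G" or "T") substituted at
#'   `focal_pos`.
#' @param half_window Bases scanned on each side of the focal position
#'   (default 20).
#' @param background,pseudocount Passed to [log_odds()].
#' @param lo Optional precomputed log-odds matrix (overrides
#'   `background`/`pseudocount`).
#' @return List with `score` (log2 units), `window_start` (0-based genomic),
#'   `strand` ("+" or "-").
#' @export
best_match_score <- function(pwm, sequence, focal_pos, allele,
                             half_window = 20L,
                             background = new_background(),
                             pseudocount = 1e-4, lo = NULL) {
  if (is.null(lo)) lo <- log_odds(pwm, background, pseudocount)
  L <- nrow(lo)
  n <- nchar(sequence)
  f1 <- as.integer(focal_pos) + 1L
  if (f1 < 1L || f1 > n) stop("focal_pos outside sequence")
  allele <- toupper(allele)
  if (!allele %in% DNA_BASES) stop("allele must be one of A/C/G/T")
  s0 <- max(1L, f1 - as.integer(half_window))
  s1 <- min(n, f1 + as.integer(half_window))
  enc <- seq_to_int(substr(sequence, s0, s1))
  enc[f1 - s0 + 1L] <- match(allele, DNA_BASES)
  local_f <- f1 - s0 + 1L
  w_lo <- max(1L, local_f - L + 1L)
  w_hi <- min(local_f, length(enc) - L + 1L)
  if (w_hi < w_lo)
    stop("no valid scoring window: motif wider than scannable span")
  ws <- window_scores(lo, enc, starts = w_lo:w_hi)
  best <- pick_best_window(ws)
  list(score = unname(best["score"]),
       window_start = unname(best["start"]) + s0 - 2L,
       strand = c("+", "-")[best["strand"]])
}

# Best site anywhere in a sequence (no focal constraint); used by motif
# discovery and by the peak-planting round-trip checks.
#' @noRd
best_site <- function(lo, sequence) {
  enc <- seq_to_int(sequence)
  if (length(enc) < nrow(lo))
    return(list(score = -Inf, start = NA_integer_, strand = NA_character_))
  ws <- window_scores(lo, enc)
  best <- pick_best_window(ws)
  list(score = unname(best["score"]),
       start = unname(as.integer(best["start"])),
       strand = c("+", "-")[best["strand"]])
}

#' Column-correlation similarity between two PWMs
#'
#' Slides `target` (and its reverse complement) along `query` over all
#' ungapped offsets with at least `min_overlap` aligned columns and reports
#' the alignment maximizing the Pearson correlation of the flattened aligned
#' probability columns — a reduced form of standard motif-comparison tools.
#'
#' @param query,target `pwm` objects.
#' @param min_overlap Minimum aligned columns (default 4).
#' @return List (class `motif_match`): `query_name`, `db_name`, `offset`
#'   (target start relative to query start, in the reported orientation),
#'   `strand`, `similarity`.
#' @export
pwm_similarity <- function(query, target, min_overlap = 4L) {
  lq <- pwm_length(query)
  lt <- pwm_length(target)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap > min(lq, lt))
    stop("min_overlap exceeds the shorter motif; no alignment possible")
  best <- list(similarity = -Inf, offset = NA_integer_, strand = NA_character_)
  for (strand in c("+", "-")) {
    tp <- if (strand == "+") target$probs else pwm_revcomp(target)$probs
    for (o in seq(-(lt - min_overlap), lq - min_overlap)) {
      qi <- max(1L, 1L + o):min(lq, lt + o)
      ti <- qi - o
      r <- suppressWarnings(stats::cor(as.vector(query$probs[qi, , drop = FALSE]),
                                       as.vector(tp[ti, , drop = FALSE])))
      if (!is.na(r) && r > best$similarity)
        best <- list(similarity = r, offset = o, strand = strand)
    }
  }
  if (!is.finite(best$similarity)) best$similarity <- 0
  structure(list(query_name = query$name, db_name = target$name,
                 offset = best$offset, strand = best$strand,
                 similarity = best$similarity),
            class = "motif_match")
}

#' Match discovered motifs against a motif database
#'
#' For each discovered PWM, reports every database PWM whose
#' [pwm_similarity()] is at least `sim_min`, sorted by decreasing
#' similarity. Discovered motifs with no match are dropped from downstream
#' scanning and logged. Duplicate database entries are reported separately
#' (no deduplication).
#'
#' @param discovered List of `pwm` objects (e.g., from [discover_motifs()]).
#' @param db List of database `pwm` objects.
#' @param sim_min Minimum similarity (default 0.75).
#' @param min_overlap Passed to [pwm_similarity()].
#' @return `data.frame` with columns `query_name`, `db_name`, `offset`,
#'   `strand`, `similarity`.
#' @export
match_to_database <- function(discovered, db, sim_min = 0.75,
                              min_overlap = 4L) {
  if (is_pwm(discovered)) discovered <- list(discovered)
  if (is_pwm(db)) db <- list(db)
  if (!length(db)) stop("motif database is empty")
  rows <- list()
  for (q in discovered) {
    ms <- lapply(db, function(t) pwm_similarity(q, t, min_overlap))
    sims <- vapply(ms, `[[`, numeric(1L), "similarity")
    keep <- which(sims >= sim_min)
    if (!length(keep)) {
      message("match_to_database: motif '", q$name,
              "' has no database match at sim_min=", sim_min, "; dropped")
      next
    }
    keep <- keep[order(-sims[keep])]
    rows[[length(rows) + 1L]] <- data.frame(
      query_name = q$name,
      db_name = vapply(ms[keep], `[[`, character(1L), "db_name"),
      offset = vapply(ms[keep], `[[`, integer(1L), "offset"),
      strand = vapply(ms[keep], `[[`, character(1L), "strand"),
      similarity = sims[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(query_name = character(), db_name = character(),
                      offset = integer(), strand = character(),
                      similarity = numeric()))
  do.call(rbind, rows)
}
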