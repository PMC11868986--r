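# Shared low-level helpers: base encoding, reverse complements, seeded RNG,
# small file I/O wrappers. Internal coordinates are 0-based half-open
# throughout; VCF/FASTA interfaces convert at the boundary.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
seq_to_int <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], DNA_BASES)
  v
}

#' @noRd
int_to_seq <- function(v) paste(DNA_BASES[v], collapse = "")

#' @noRd
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                                       collapse = ""))
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# All generator/Monte-Carlo determinism flows through this.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  force(code)
}

# Derive a child seed from a root seed and a stage label; keeps every stage's
# stream independent while reproducible from one root seed. Result < 2^31.
#' @noRd
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587) + 1L
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a reference genome from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a named
#' character vector of uppercase contig sequences, the in-memory reference
#' representation used across the package.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a reference genome to FASTA
#'
#' @param reference Named character vector of contig sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' @noRd
read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  data.table = FALSE, ...))
}

#' @noRd
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @noRd
log_msg <- function(..., logfile = NULL) {
  txt <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  message(txt)
  if (!is.null(logfile)) cat(txt, "\n", file = logfile, append = TRUE, sep = "")
}
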