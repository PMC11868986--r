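# Genotype panels and linkage disequilibrium: VCF input, pairwise r2
# (direct haplotype counts when phased, EM haplotype-frequency estimation
# when not), and LD expansion of index SNPs.

#' Construct a genotype panel
#'
#' @param variants `data.frame` with columns `chrom`, `pos0` (0-based),
#'   `id`, `ref`, `alt`.
#' @param matrix Haplotype x variant matrix of allele codes 0/1/`NA`
#'   (two rows per sample).
#' @param phased Logical; whether haplotype phase is known.
#' @param samples Sample identifiers (one per haplotype pair).
#' @return Object of class `genotype_panel`.
#' @export
new_genotype_panel <- function(variants, matrix, phased, samples) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos0", "id", "ref", "alt") %in% names(variants)),
            nrow(matrix) == 2L * length(samples),
            ncol(matrix) == nrow(variants))
  for (ch in unique(variants$chrom)) {
    p <- variants$pos0[variants$chrom == ch]
    # non-decreasing: split multiallelic records legitimately share a
    # position
    if (is.unsorted(p, strictly = FALSE))
      stop("positions must be sorted within chromosome ", ch)
  }
  if (!all(matrix %in% c(0L, 1L, NA)))
    stop("allele codes must be 0, 1 or NA")
  colnames(matrix) <- variants$id
  structure(list(variants = variants, matrix = matrix,
                 phased = isTRUE(phased), samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d variants x %d haplotypes (%d samples, %s)\n",
              nrow(x$variants), nrow(x$matrix), length(x$samples),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' Read a genotype panel from VCF
#'
#' Loads biallelic SNPs from a VCF 4.2 file into a [new_genotype_panel()].
#' Multiallelic records are skipped and logged unless
#' `split_multiallelic = TRUE`, in which case each alternate allele becomes
#' its own biallelic pseudo-variant (id suffixed `_altK`). Indels are
#' excluded by default. Missing genotypes become `NA` allele codes.
#'
#' @param vcf_path Path to a VCF file (uncompressed or bgzipped).
#' @param region Optional region string `"chrom:start-end"` (1-based
#'   inclusive).
#' @param split_multiallelic Split multiallelic records instead of skipping.
#' @param include_indels Keep non-SNP records.
#' @return A `genotype_panel`.
#' @export
read_panel <- function(vcf_path, region = NULL, split_multiallelic = FALSE,
                       include_indels = FALSE) {
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos1 <- GenomicRanges::start(rr)
  ids <- names(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  samples <- colnames(gt)
  if (!is.null(region)) {
    m <- regexec("^([^:]+):(\\d+)-(\\d+)$", region)[[1L]]
    rm_ <- regmatches(region, regexec("^([^:]+):(\\d+)-(\\d+)$", region))[[1L]]
    if (length(rm_) != 4L) stop("region must be 'chrom:start-end'")
    keep <- chrom == rm_[2L] & pos1 >= as.integer(rm_[3L]) &
      pos1 <= as.integer(rm_[4L])
    if (!any(keep)) stop("empty region: ", region)
    chrom <- chrom[keep]; pos1 <- pos1[keep]; ids <- ids[keep]
    ref <- ref[keep]; altl <- altl[keep]
    gt <- gt[keep, , drop = FALSE]
  }
  n_alt <- S4Vectors::elementNROWS(altl)
  var_rows <- list()
  hap_cols <- list()
  phased_all <- TRUE
  for (i in seq_along(ids)) {
    alts <- as.character(altl[[i]])
    if (n_alt[i] > 1L && !split_multiallelic) {
      message("read_panel: skipping multiallelic record ", ids[i])
      next
    }
    gts <- gt[i, ]
    phased_i <- !any(grepl("/", gts, fixed = TRUE))
    phased_all <- phased_all && phased_i
    parts <- strsplit(gsub("\\|", "/", gts), "/", fixed = FALSE)
    a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, "")))
    for (k in seq_len(max(1L, n_alt[i]))) {
      if (k > length(alts)) break
      if (!include_indels && (nchar(ref[i]) != 1L || nchar(alts[k]) != 1L)) {
        message("read_panel: excluding indel record ", ids[i])
        next
      }
      code <- function(a) ifelse(is.na(a), NA_integer_,
                                 ifelse(a == k, 1L, 0L))
      id_k <- if (n_alt[i] > 1L) paste0(ids[i], "_alt", k) else ids[i]
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        chrom = chrom[i], pos0 = pos1[i] - 1L, id = id_k,
        ref = ref[i], alt = alts[k], stringsAsFactors = FALSE)
      hap_cols[[length(hap_cols) + 1L]] <-
        as.integer(rbind(code(a1), code(a2)))
    }
  }
  if (!length(var_rows)) stop("no usable biallelic SNP records in ", vcf_path)
  variants <- do.call(rbind, var_rows)
  mat <- do.call(cbind, hap_cols)
  o <- order(variants$chrom, variants$pos0)
  new_genotype_panel(variants[o, , drop = FALSE], mat[, o, drop = FALSE],
                     phased = phased_all, samples = samples)
}

#' @noRd
panel_column <- function(panel, id) {
  j <- match(id, panel$variants$id)
  if (is.na(j)) stop("variant not in panel: ", id)
  panel$matrix[, j]
}

# EM estimation of two-locus haplotype frequencies from unphased genotype
# counts; returns c(pAB, pAb, paB, pab). Only double heterozygotes are
# phase-ambiguous.
#' @noRd
em_haplotype_freqs <- function(gA, gB, tol = 1e-8, max_iter = 100L) {
  n <- table(factor(gA, levels = 0:2), factor(gB, levels = 0:2))
  N <- sum(n)
  pA <- mean(gA) / 2
  pB <- mean(gB) / 2
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  p <- pmax(p, 1e-12); p <- p / sum(p)
  for (it in seq_len(max_iter)) {
    w <- p["AB"] * p["ab"] / (p["AB"] * p["ab"] + p["Ab"] * p["aB"])
    if (!is.finite(w)) w <- 0.5
    eAB <- 2 * n[3, 3] + n[3, 2] + n[2, 3] + n[2, 2] * w
    eAb <- 2 * n[3, 1] + n[3, 2] + n[2, 1] + n[2, 2] * (1 - w)
    eaB <- 2 * n[1, 3] + n[2, 3] + n[1, 2] + n[2, 2] * (1 - w)
    eab <- 2 * n[1, 1] + n[2, 1] + n[1, 2] + n[2, 2] * w
    p_new <- stats::setNames(as.numeric(c(eAB, eAb, eaB, eab)),
                             c("AB", "Ab", "aB", "ab")) / (2 * N)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  p
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Computes `r2 = D^2 / (pA (1-pA) pB (1-pB))` where
#' `D = pAB - pA pB` from two-locus haplotype frequencies. Phased panels use
#' direct haplotype counts; unphased panels estimate haplotype frequencies
#' by EM over double heterozygotes (tolerance `1e-8`, at most 100
#' iterations). Haplotypes missing either allele are dropped
#' (pairwise-complete); pairs with fewer than `min_haps` complete
#' haplotypes return `NA` with a warning.
#'
#' @param panel A `genotype_panel`.
#' @param v1,v2 Variant ids.
#' @param min_haps Minimum complete haplotypes (default 20).
#' @return r-squared in `[0, 1]`, or `NA` if too few complete haplotypes.
#' @export
compute_r2 <- function(panel, v1, v2, min_haps = 20L) {
  x <- panel_column(panel, v1)
  y <- panel_column(panel, v2)
  if (panel$phased) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_haps) {
      warning("compute_r2: fewer than ", min_haps,
              " complete haplotypes for (", v1, ", ", v2, "); skipped")
      return(NA_real_)
    }
    x <- x[ok]; y <- y[ok]
    pA <- mean(x); pB <- mean(y)
    if (pA %in% c(0, 1) || pB %in% c(0, 1))
      stop("r2 undefined: monomorphic variant in (", v1, ", ", v2, ")")
    pAB <- mean(x == 1L & y == 1L)
    D <- pAB - pA * pB
  } else {
    ns <- length(panel$samples)
    gA <- x[2 * seq_len(ns) - 1L] + x[2 * seq_len(ns)]
    gB <- y[2 * seq_len(ns) - 1L] + y[2 * seq_len(ns)]
    ok <- !is.na(gA) & !is.na(gB)
    if (2L * sum(ok) < min_haps) {
      warning("compute_r2: fewer than ", min_haps,
              " complete haplotypes for (", v1, ", ", v2, "); skipped")
      return(NA_real_)
    }
    gA <- gA[ok]; gB <- gB[ok]
    pA <- mean(gA) / 2; pB <- mean(gB) / 2
    if (pA %in% c(0, 1) || pB %in% c(0, 1))
      stop("r2 undefined: monomorphic variant in (", v1, ", ", v2, ")")
    p <- em_haplotype_freqs(gA, gB)
    pA <- p["AB"] + p["Ab"]; pB <- p["AB"] + p["aB"]
    D <- p["AB"] - pA * pB
  }
  unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' Expand index SNPs into LD sets
#'
#' For each index SNP, finds all panel variants within `window` bases whose
#' r-squared with the index is at least `r2_min` (inclusive threshold; the
#' boundary convention is configurable via `r2_min`). The index SNP is
#' always a member with `r2 = 1`. Index SNPs absent from the panel produce
#' an empty, flagged result rather than an error. Monomorphic or
#' low-completeness candidate pairs are skipped and logged.
#'
#' @param panel A `genotype_panel`.
#' @param index_snps Character vector of index SNP ids.
#' @param r2_min Minimum r-squared (default 0.3).
#' @param window Bases searched on each side of the index SNP (default
#'   500 kb).
#' @return List of `ld_expansion` objects, each with `index_id`, `found`,
#'   `window` and a `members` data.frame (`variant_id`, `chrom`, `pos0`,
#'   `r2`).
#' @export
expand_ld <- function(panel, index_snps, r2_min = 0.3, window = 5e5) {
  lapply(index_snps, function(idx) {
    j <- match(idx, panel$variants$id)
    if (is.na(j)) {
      message("expand_ld: index SNP ", idx, " absent from panel")
      return(structure(list(index_id = idx, found = FALSE, window = window,
                            members = data.frame(variant_id = character(),
                                                 chrom = character(),
                                                 pos0 = integer(),
                                                 r2 = numeric())),
                       class = "ld_expansion"))
    }
    v <- panel$variants
    cand <- which(v$chrom == v$chrom[j] &
                    abs(v$pos0 - v$pos0[j]) <= window & v$id != idx)
    rows <- data.frame(variant_id = idx, chrom = v$chrom[j],
                       pos0 = v$pos0[j], r2 = 1, stringsAsFactors = FALSE)
    for (k in cand) {
      col <- panel$matrix[, k]
      p <- mean(col, na.rm = TRUE)
      if (is.nan(p) || p %in% c(0, 1)) next  # monomorphic candidate
      r2 <- tryCatch(suppressWarnings(compute_r2(panel, idx, v$id[k])),
                     error = function(e) NA_real_)
      if (!is.na(r2) && r2 >= r2_min)
        rows <- rbind(rows, data.frame(variant_id = v$id[k],
                                       chrom = v$chrom[k], pos0 = v$pos0[k],
                                       r2 = r2, stringsAsFactors = FALSE))
    }
    structure(list(index_id = idx, found = TRUE, window = window,
                   members = rows[order(rows$pos0), , drop = FALSE]),
              class = "ld_expansion")
  })
}

#' Flatten LD expansion results to a table
#'
#' @param expansions List returned by [expand_ld()].
#' @return `data.frame` with `index_id`, `variant_id`, `chrom`, `pos0`,
#'   `r2`; attribute `n_unique` holds the union count of member ids
#'   (index SNPs included).
#' @export
ld_table <- function(expansions) {
  rows <- lapply(expansions, function(e) {
    if (!nrow(e$members)) return(NULL)
    cbind(index_id = e$index_id, e$members)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(index_id = character(), variant_id = character(),
                      chrom = character(), pos0 = integer(), r2 = numeric())
  attr(out, "n_unique") <- length(unique(out$variant_id))
  out
}

#' Write a variant table (optionally with haplotypes) as VCF 4.2
#'
#' @param variants `data.frame` with `chrom`, `pos0`, `id`, `ref`, `alt`.
#' @param path Output path.
#' @param haplotypes Optional haplotype x variant 0/1 matrix with an even
#'   number of rows; consecutive row pairs become phased sample genotypes.
#' @param sample_prefix Prefix for generated sample names.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, haplotypes = NULL,
                      sample_prefix = "S") {
  con <- file(path, "w")
  on.exit(close(con))
  cat("##fileformat=VCFv4.2\n", file = con)
  for (ch in unique(variants$chrom))
    cat(sprintf("##contig=<ID=%s>\n", ch), file = con)
  cat("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">\n",
      file = con)
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  ns <- 0L
  if (!is.null(haplotypes)) {
    stopifnot(nrow(haplotypes) %% 2L == 0L)
    ns <- nrow(haplotypes) / 2L
    hdr <- c(hdr, "FORMAT", sprintf("%s%04d", sample_prefix, seq_len(ns)))
  }
  cat(paste(hdr, collapse = "\t"), "\n", sep = "", file = con)
  o <- order(variants$chrom, variants$pos0)
  for (i in o) {
    fields <- c(variants$chrom[i], variants$pos0[i] + 1L, variants$id[i],
                variants$ref[i], variants$alt[i], ".", "PASS", ".")
    if (!is.null(haplotypes)) {
      a1 <- haplotypes[2 * seq_len(ns) - 1L, i]
      a2 <- haplotypes[2 * seq_len(ns), i]
      gts <- paste0(ifelse(is.na(a1), ".", a1), "|",
                    ifelse(is.na(a2), ".", a2))
      fields <- c(fields, "GT", gts)
    }
    cat(paste(fields, collapse = "\t"), "\n", sep = "", file = con)
  }
  invisible(path)
}

#' Read a simple variant table from VCF (sites only)
#'
#' @param path VCF path.
#' @return `data.frame` with `chrom`, `pos0`, `id`, `ref`, `alt`
#'   (multiallelic ALT fields expanded to one row per allele).
#' @export
read_variants <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("no variant records in ", path)
  f <- strsplit(body, "\t", fixed = TRUE)
  rows <- lapply(f, function(x) {
    alts <- strsplit(x[5L], ",", fixed = TRUE)[[1L]]
    data.frame(chrom = x[1L], pos0 = as.integer(x[2L]) - 1L, id = x[3L],
               ref = x[4L], alt = alts, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
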