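# Synthetic-data generators: every pipeline input (reference, haplotype
# panel, ChIP-seq peaks, disrupting variants, eQTL tables, annotations,
# gene model) with planted ground truth recorded in a simulation manifest.
# Same seed => byte-identical outputs; all randomness is locally seeded.

#' Simulate a reference sequence and background model
#'
#' Draws an i.i.d. sequence over A/C/G/T with expected G+C fraction `gc`
#' and returns it together with a zero-order background model estimated
#' from the emitted sequence.
#'
#' @param length Sequence length in bases (>= 1000).
#' @param gc Target G+C fraction, strictly inside (0, 1).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param contig Contig name.
#' @return List with `reference` (named character vector) and `background`
#'   (a [new_background()]).
#' @export
simulate_reference <- function(length, gc = 0.41, seed = 1L,
                               contig = "sim1") {
  length <- as.integer(length)
  if (is.na(length) || length < 1000L) stop("length must be >= 1000")
  if (!is.finite(gc) || gc <= 0 || gc >= 1)
    stop("gc must be strictly inside (0, 1)")
  with_seed(seed, {
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    bases <- sample.int(4L, length, replace = TRUE, prob = probs)
    seq <- int_to_seq(bases)
    reference <- stats::setNames(seq, contig)
    list(reference = reference,
         background = background_from_sequences(seq))
  })
}

#' Simulate a phased haplotype panel with block LD structure
#'
#' Haplotypes are generated independently per block (so across-block r2 has
#' expectation zero). Two block flavors are supported, both giving
#' controllable LD:
#'
#' * `target_r2` given: the block's first SNP is the planted index SNP with
#'   allele frequency 0.5; each subsequent SNP copies it with a flip
#'   probability `eps = (1 - sqrt(target_r2)) / 2`, whose expected
#'   r-squared is exactly the target.
#' * otherwise: founder-haplotype resampling — `founder_haps` derived
#'   founders plus the ancestral all-reference haplotype, each emitted
#'   haplotype copying one founder; with a single founder every
#'   within-block pair is in perfect LD (r2 = 1).
#'
#' @param n_hap Number of haplotypes (even, >= 50).
#' @param blocks List of blocks; each a list with `n_snps` (>= 2), and
#'   either `target_r2` (numeric vector of length `n_snps - 1`, values in
#'   \[0, 1\]) or `founder_haps` (count >= 1).
#' @param seed Integer seed.
#' @param chrom Contig name for emitted variants.
#' @param start0 0-based position of the first SNP.
#' @param snp_spacing,block_spacing Base spacing within/between blocks.
#' @param reference Optional reference (named character vector); when given,
#'   REF alleles match the reference base at each position.
#' @return List with `panel` (a [new_genotype_panel()]) and `manifest`
#'   (`data.frame` of planted proxies: `index_id`, `proxy_id`,
#'   `target_r2`).
#' @export
simulate_haplotype_panel <- function(n_hap, blocks, seed = 1L,
                                     chrom = "sim1", start0 = 1000L,
                                     snp_spacing = 100L,
                                     block_spacing = 5000L,
                                     reference = NULL) {
  n_hap <- as.integer(n_hap)
  if (n_hap < 50L) stop("n_hap must be >= 50")
  if (n_hap %% 2L != 0L) stop("n_hap must be even (haplotypes pair into samples)")
  with_seed(seed, {
    cols <- list(); vars <- list(); proxies <- list()
    pos <- as.integer(start0)
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      n_snps <- as.integer(blk$n_snps)
      if (is.na(n_snps) || n_snps < 2L) stop("each block needs >= 2 SNPs")
      mat <- matrix(0L, nrow = n_hap, ncol = n_snps)
      ids <- sprintf("b%02d_s%03d", b, seq_len(n_snps))
      if (!is.null(blk$target_r2)) {
        t <- as.numeric(blk$target_r2)
        if (length(t) != n_snps - 1L)
          stop("target_r2 must have length n_snps - 1")
        if (any(t < 0 | t > 1)) stop("target_r2 values must lie in [0, 1]")
        x <- stats::rbinom(n_hap, 1L, 0.5)
        tries <- 0L
        while (length(unique(x)) < 2L && tries < 10L) {
          x <- stats::rbinom(n_hap, 1L, 0.5); tries <- tries + 1L
        }
        if (length(unique(x)) < 2L)
          stop("monomorphic planted index SNP in block ", b)
        mat[, 1L] <- x
        for (s in seq_len(n_snps - 1L)) {
          eps <- (1 - sqrt(t[s])) / 2
          flip <- stats::rbinom(n_hap, 1L, eps)
          mat[, s + 1L] <- as.integer(xor(x, flip))
          proxies[[length(proxies) + 1L]] <- data.frame(
            index_id = ids[1L], proxy_id = ids[s + 1L], target_r2 = t[s],
            stringsAsFactors = FALSE)
        }
      } else {
        f <- as.integer(blk$founder_haps %||% 2L)
        if (is.na(f) || f < 1L) stop("founder_haps must be >= 1")
        founders <- rbind(rep(0L, n_snps),
                          matrix(stats::rbinom(f * n_snps, 1L, 0.5),
                                 nrow = f))
        if (f == 1L) founders[2L, ] <- 1L
        zero_cols <- which(colSums(founders) == 0L)
        for (z in zero_cols) founders[1L + sample.int(f, 1L), z] <- 1L
        assign_f <- sample.int(f + 1L, n_hap, replace = TRUE)
        mat <- founders[assign_f, , drop = FALSE]
      }
      positions <- pos + (seq_len(n_snps) - 1L) * as.integer(snp_spacing)
      ref_alt <- t(vapply(positions, function(p) {
        if (!is.null(reference)) {
          rb <- toupper(substr(reference[[1L]], p + 1L, p + 1L))
          if (!rb %in% DNA_BASES) rb <- "A"
        } else rb <- sample(DNA_BASES, 1L)
        ab <- sample(setdiff(DNA_BASES, rb), 1L)
        c(rb, ab)
      }, character(2L)))
      vars[[b]] <- data.frame(chrom = chrom, pos0 = positions, id = ids,
                              ref = ref_alt[, 1L], alt = ref_alt[, 2L],
                              stringsAsFactors = FALSE)
      cols[[b]] <- mat
      pos <- positions[n_snps] + as.integer(block_spacing)
    }
    variants <- do.call(rbind, vars)
    mat <- do.call(cbind, cols)
    panel <- new_genotype_panel(variants, mat, phased = TRUE,
                                samples = sprintf("S%04d",
                                                  seq_len(n_hap / 2L)))
    manifest <- if (length(proxies)) do.call(rbind, proxies) else
      data.frame(index_id = character(), proxy_id = character(),
                 target_r2 = numeric())
    list(panel = panel, manifest = manifest)
  })
}

#' Simulate ChIP-seq peaks with planted motif instances
#'
#' Places `n_peaks` non-overlapping fixed-width peaks in a region of the
#' reference, embeds one motif instance (sampled from the PWM, random
#' strand) at the summit of `round(plant_frac * n_peaks)` randomly chosen
#' peaks, and draws log-normal peak heights with a +1 sigma shift on the
#' log scale for planted peaks so that ranking by height enriches for
#' planted signal.
#'
#' @param reference Named character vector (single contig used).
#' @param pwm Generating motif (a `pwm`); must not be wider than
#'   `peak_width`.
#' @param n_peaks Number of peaks.
#' @param plant_frac Fraction of peaks receiving a motif instance, in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @param region_start0 0-based start of the peak region.
#' @param peak_width,peak_gap Peak geometry in bases.
#' @return List with `reference` (motif instances written in), `peaks`
#'   (`data.frame`: `chrom`, `start`, `end`, `name`, `height`, `strand`)
#'   and `manifest` (`data.frame`: `peak_id`, `offset` within peak,
#'   `strand`, `site_start0` genomic, `instance`).
#' @export
simulate_chipseq_peaks <- function(reference, pwm, n_peaks, plant_frac,
                                   seed = 1L, region_start0 = 0L,
                                   peak_width = 61L, peak_gap = 39L) {
  if (plant_frac < 0 || plant_frac > 1) stop("plant_frac must be in [0, 1]")
  L <- pwm_length(pwm)
  if (L > peak_width) stop("PWM wider than peak width")
  contig <- names(reference)[1L]
  seq <- reference[[1L]]
  span <- n_peaks * (peak_width + peak_gap)
  if (region_start0 + span > nchar(seq))
    stop("peak region extends past reference end")
  with_seed(seed, {
    starts <- region_start0 + (seq_len(n_peaks) - 1L) *
      (peak_width + peak_gap)
    n_plant <- round(plant_frac * n_peaks)
    planted <- sort(sample.int(n_peaks, n_plant))
    heights <- stats::rlnorm(n_peaks, meanlog = 2, sdlog = 0.5)
    heights[planted] <- stats::rlnorm(n_plant, meanlog = 2.5, sdlog = 0.5)
    man <- list()
    for (i in planted) {
      inst <- int_to_seq(vapply(seq_len(L), function(j)
        sample.int(4L, 1L, prob = pwm$probs[j, ]), integer(1L)))
      strand <- sample(c("+", "-"), 1L)
      offset <- (peak_width - L) %/% 2L
      site0 <- starts[i] + offset
      embedded <- if (strand == "+") inst else revcomp(inst)
      substr(seq, site0 + 1L, site0 + L) <- embedded
      man[[length(man) + 1L]] <- data.frame(
        peak_id = sprintf("peak%04d", i), offset = offset, strand = strand,
        site_start0 = site0, instance = inst, stringsAsFactors = FALSE)
    }
    reference[[1L]] <- seq
    peaks <- data.frame(chrom = contig, start = starts,
                        end = starts + peak_width,
                        name = sprintf("peak%04d", seq_len(n_peaks)),
                        height = heights, strand = ".",
                        stringsAsFactors = FALSE)
    manifest <- if (length(man)) do.call(rbind, man) else
      data.frame(peak_id = character(), offset = integer(),
                 strand = character(), site_start0 = integer(),
                 instance = character())
    list(reference = reference, peaks = peaks, manifest = manifest)
  })
}

#' Plant TF-binding-disrupting variants with known score effects
#'
#' Causal variants are placed inside planted motif instances at the PWM
#' column of maximal information content, with the alternate allele chosen
#' as the least probable base there (maximally disrupting). Null variants
#' are placed at least `null_clearance` bases away from every planted site.
#' Each causal variant's `true_delta_score` is recomputed from the emitted
#' reference with [best_match_score()] (ref minus alt), so downstream
#' scoring can be checked against the manifest exactly.
#'
#' @param pwm Generating motif.
#' @param reference Named character vector carrying the planted instances.
#' @param sites Manifest `data.frame` from [simulate_chipseq_peaks()].
#' @param n_causal,n_null Counts of causal / null variants (sum >= 1).
#' @param seed Integer seed.
#' @param background,half_window Scoring parameters for the recorded
#'   delta scores.
#' @param null_clearance Minimum distance from any planted site (bases).
#' @param target_genes Gene names cycled over causal variants.
#' @return List with `variants` (`data.frame`: `chrom`, `pos0`, `id`,
#'   `ref`, `alt`, `is_causal`, `true_delta_score`, `target_gene`).
#' @export
plant_disrupting_variants <- function(pwm, reference, sites, n_causal,
                                      n_null, seed = 1L,
                                      background = new_background(),
                                      half_window = 20L,
                                      null_clearance = 100L,
                                      target_genes = c("geneA", "geneB")) {
  if (n_causal + n_null < 1L) stop("need at least one variant")
  if (n_causal > nrow(sites))
    stop("insufficient planted sites for n_causal")
  contig <- names(reference)[1L]
  seq <- reference[[1L]]
  L <- pwm_length(pwm)
  ic <- apply(pwm$probs, 1L, function(r) {
    r <- r[r > 0]; 2 + sum(r * log2(r))
  })
  jstar <- which.max(ic)
  lo <- log_odds(pwm, background)
  with_seed(seed, {
    pick <- sample.int(nrow(sites), n_causal)
    rows <- list()
    for (k in seq_along(pick)) {
      s <- sites[pick[k], ]
      pos0 <- if (s$strand == "+") s$site_start0 + jstar - 1L
              else s$site_start0 + L - jstar
      ref_b <- substr(seq, pos0 + 1L, pos0 + 1L)
      worst <- DNA_BASES[order(pwm$probs[jstar, ])]
      if (s$strand == "-") worst <- chartr("ACGT", "TGCA", worst)
      alt_b <- setdiff(worst, ref_b)[1L]
      if (identical(alt_b, ref_b))
        stop("degenerate variant: ref == alt")
      sr <- best_match_score(pwm, seq, pos0, ref_b,
                             half_window = half_window, lo = lo)
      sa <- best_match_score(pwm, seq, pos0, alt_b,
                             half_window = half_window, lo = lo)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = contig, pos0 = pos0, id = sprintf("causal_%02d", k),
        ref = ref_b, alt = alt_b, is_causal = TRUE,
        true_delta_score = sr$score - sa$score,
        target_gene = target_genes[(k - 1L) %% length(target_genes) + 1L],
        stringsAsFactors = FALSE)
    }
    # exclusion zones around every planted site
    excl_lo <- sites$site_start0 - null_clearance
    excl_hi <- sites$site_start0 + L + null_clearance
    n_len <- nchar(seq)
    candidates <- setdiff(seq.int(half_window + 1L,
                                  n_len - half_window - 1L),
                          unlist(mapply(seq.int, pmax(excl_lo, 0L),
                                        pmin(excl_hi, n_len - 1L),
                                        SIMPLIFY = FALSE)))
    if (length(candidates) < n_null)
      stop("reference too small for ", n_null, " null variants")
    null_pos <- sort(sample(candidates, n_null))
    for (k in seq_len(n_null)) {
      pos0 <- null_pos[k]
      ref_b <- substr(seq, pos0 + 1L, pos0 + 1L)
      alt_b <- sample(setdiff(DNA_BASES, ref_b), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = contig, pos0 = pos0, id = sprintf("null_%03d", k),
        ref = ref_b, alt = alt_b, is_causal = FALSE,
        true_delta_score = NA_real_, target_gene = NA_character_,
        stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, rows)
    variants[order(variants$pos0), , drop = FALSE]
  })
}

#' Simulate per-dataset eQTL summary tables with planted effects
#'
#' Every variant receives one variant-gene association row per dataset.
#' Planted (causal) variant-gene pairs get p-values small enough to survive
#' Benjamini-Hochberg at q < 0.001 in every dataset, with a
#' direction-consistent effect size drawn from `beta_range`; all other rows
#' draw p uniformly on (0, 1).
#'
#' @param variants Variant `data.frame` from
#'   [plant_disrupting_variants()] (columns `id`, `is_causal`,
#'   `target_gene`).
#' @param n_datasets Number of independent datasets (>= 2).
#' @param n_true Number of planted variant-gene effects (taken from the
#'   causal variants; must not exceed their count).
#' @param beta_range Absolute effect-size range for planted effects.
#' @param seed Integer seed.
#' @param decoy_genes Gene labels assigned to non-planted rows.
#' @return List with `tables` (named list of `data.frame`s with columns
#'   `variant`, `gene`, `beta`, `p`, `dataset`) and `manifest`
#'   (planted effects).
#' @export
simulate_eqtl_tables <- function(variants, n_datasets = 3L, n_true,
                                 beta_range = c(0.2, 0.8), seed = 1L,
                                 decoy_genes = c("geneC", "geneD")) {
  n_datasets <- as.integer(n_datasets)
  if (n_datasets < 2L) stop("n_datasets must be >= 2")
  causal <- variants[which(variants$is_causal), , drop = FALSE]
  if (n_true > nrow(variants))
    stop("n_true exceeds available variants")
  if (n_true > nrow(causal))
    stop("n_true exceeds available causal variants")
  with_seed(seed, {
    planted <- causal[seq_len(n_true), , drop = FALSE]
    signs <- sample(c(-1, 1), n_true, replace = TRUE)
    datasets <- sprintf("brain_ds%d", seq_len(n_datasets))
    tables <- list(); man <- list()
    for (d in seq_len(n_datasets)) {
      gene <- ifelse(is.na(variants$target_gene),
                     decoy_genes[(seq_len(nrow(variants)) %% length(decoy_genes)) + 1L],
                     variants$target_gene)
      beta <- stats::rnorm(nrow(variants), 0, 0.1)
      p <- stats::runif(nrow(variants))
      tab <- data.frame(variant = variants$id, gene = gene, beta = beta,
                        p = p, dataset = datasets[d],
                        stringsAsFactors = FALSE)
      if (n_true > 0L) {
        ix <- match(planted$id, tab$variant)
        tab$p[ix] <- 10^-stats::runif(n_true, 8, 12)
        tab$beta[ix] <- signs * stats::runif(n_true, beta_range[1L],
                                             beta_range[2L])
        man[[d]] <- data.frame(variant_id = planted$id,
                               gene = planted$target_gene,
                               dataset = datasets[d], beta = tab$beta[ix],
                               p = tab$p[ix], stringsAsFactors = FALSE)
      }
      tables[[datasets[d]]] <- tab
    }
    manifest <- if (length(man)) do.call(rbind, man) else
      data.frame(variant_id = character(), gene = character(),
                 dataset = character(), beta = numeric(), p = numeric())
    list(tables = tables, manifest = manifest)
  })
}

#' Simulate a regulatory annotation table
#'
#' Causal variants receive a category in 1a-1f and all four evidence flags
#' (promoter histone marks, enhancer histone marks, DNase protein binding,
#' motif change) set, each flag independently flipped with probability
#' `flip_prob`. Other variants receive categories >= 2 and sparse flags.
#'
#' @param variants Variant `data.frame` (column `id`).
#' @param causal_ids Ids to treat as causal; must all exist in `variants`.
#' @param flip_prob Per-flag flip probability, in \[0, 0.5).
#' @param seed Integer seed.
#' @param sparse_rate Per-flag TRUE probability for non-causal variants.
#' @return `data.frame` with `variant_id`, `regulomedb_category`, and the
#'   four logical evidence flags.
#' @export
simulate_annotations <- function(variants, causal_ids, flip_prob = 0.05,
                                 seed = 1L, sparse_rate = 0.15) {
  if (flip_prob < 0 || flip_prob >= 0.5)
    stop("flip_prob must be in [0, 0.5)")
  missing_ids <- setdiff(causal_ids, variants$id)
  if (length(missing_ids))
    stop("unknown variant id(s) in causal_ids: ",
         paste(missing_ids, collapse = ", "))
  with_seed(seed, {
    n <- nrow(variants)
    is_causal <- variants$id %in% causal_ids
    cat1 <- paste0("1", sample(letters[1:6], n, replace = TRUE))
    cat_other <- sample(c("2a", "2b", "3a", "4", "5", "6", "7"), n,
                        replace = TRUE)
    flags <- matrix(FALSE, nrow = n, ncol = 4L)
    for (j in 1:4) {
      base <- ifelse(is_causal, TRUE,
                     stats::runif(n) < sparse_rate)
      flip <- is_causal & (stats::runif(n) < flip_prob)
      flags[, j] <- xor(base, flip)
    }
    data.frame(variant_id = variants$id,
               regulomedb_category = ifelse(is_causal, cat1, cat_other),
               promoter_mark = flags[, 1L], enhancer_mark = flags[, 2L],
               dnase_protein = flags[, 3L], motif_change = flags[, 4L],
               stringsAsFactors = FALSE)
  })
}

#' Simulate a simple gene model
#'
#' Places `n_genes` genes with `n_exons` exons each in a region of the
#' reference; used for genomic-context classification (exonic / intronic /
#' intergenic).
#'
#' @param reference Named character vector.
#' @param n_genes,n_exons Gene model size.
#' @param region_start0 0-based start of the gene region.
#' @param gene_length,gene_gap,exon_length Geometry in bases.
#' @return `data.frame` with `chrom`, `start`, `end`, `name`, `type`
#'   (`"gene"` or `"exon"`), `gene`.
#' @export
simulate_gene_model <- function(reference, n_genes = 2L, n_exons = 3L,
                                region_start0 = 0L, gene_length = 3000L,
                                gene_gap = 1000L, exon_length = 200L) {
  contig <- names(reference)[1L]
  n_len <- nchar(reference[[1L]])
  rows <- list()
  for (g in seq_len(n_genes)) {
    gs <- region_start0 + (g - 1L) * (gene_length + gene_gap)
    ge <- gs + gene_length
    if (ge > n_len) stop("gene model extends past reference end")
    gname <- sprintf("gene%s", LETTERS[g])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = contig, start = gs, end = ge, name = gname, type = "gene",
      gene = gname, stringsAsFactors = FALSE)
    step <- gene_length %/% n_exons
    for (e in seq_len(n_exons)) {
      es <- gs + (e - 1L) * step
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = contig, start = es, end = es + exon_length,
        name = sprintf("%s_exon%d", gname, e), type = "exon", gene = gname,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write peaks as BED6 (score column = peak height)
#'
#' @param peaks Peak `data.frame` (`chrom`, `start`, `end`, `name`,
#'   `height`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- peaks[, c("chrom", "start", "end", "name", "height", "strand")]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read BED6 peaks (score column = peak height)
#'
#' @param path BED6 path.
#' @return Peak `data.frame` as in [write_peaks_bed()].
#' @export
read_peaks_bed <- function(path) {
  x <- as.data.frame(data.table::fread(path, header = FALSE,
                                       data.table = FALSE))
  if (ncol(x) < 5L) stop("expected BED with at least 5 columns")
  out <- data.frame(chrom = as.character(x[[1L]]), start = as.integer(x[[2L]]),
                    end = as.integer(x[[3L]]), name = as.character(x[[4L]]),
                    height = as.numeric(x[[5L]]),
                    strand = if (ncol(x) >= 6L) as.character(x[[6L]]) else ".",
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("peak with end <= start")
  if (any(!is.finite(out$height))) stop("non-finite peak height")
  out
}

#' Write / read a gene model as BED12-like TSV
#'
#' The gene model round-trips through a 6-column TSV (`chrom`, `start`,
#' `end`, `name`, `type`, `gene`).
#'
#' @param genes Gene model `data.frame` from [simulate_gene_model()].
#' @param path File path.
#' @return `path` / the gene model `data.frame`.
#' @export
write_gene_model <- function(genes, path) write_tsv(genes, path)

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  g <- read_tsv(path)
  stopifnot(all(c("chrom", "start", "end", "type", "gene") %in% names(g)))
  g
}
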