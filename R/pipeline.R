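# Pipeline orchestration: the default synthetic scenario (every input file
# with planted ground truth), flat key-value config handling, the staged
# end-to-end run (ld-expand -> discover -> match -> score -> call -> eqtl
# -> prioritize), and the JSON run report with the filter funnel.

#' The scenario's generating motif
#'
#' A 12-bp GC-rich palindromic consensus (NRF1-like response element) with
#' per-column dominant-base probability 0.95 (total information content
#' about 19.6 bits) — a realistic strong-TF PWM.
#'
#' @param dominance Probability of the consensus base per column.
#' @return A `pwm` named `"TFA"`.
#' @export
scenario_pwm <- function(dominance = 0.95) {
  cons <- "TGCGCATGCGCA"
  enc <- seq_to_int(cons)
  probs <- matrix((1 - dominance) / 3, nrow = length(enc), ncol = 4L)
  probs[cbind(seq_along(enc), enc)] <- dominance
  new_pwm(probs, name = "TFA", source = "scenario")
}

#' Random decoy motif database around a generating PWM
#'
#' @param pwm The generating motif (listed first).
#' @param n_decoys Number of random decoy PWMs.
#' @param seed Integer seed.
#' @return List of `pwm` objects.
#' @export
scenario_motif_db <- function(pwm = scenario_pwm(), n_decoys = 10L,
                              seed = 1L) {
  with_seed(seed, {
    decoys <- lapply(seq_len(n_decoys), function(i) {
      w <- sample(8:12, 1L)
      probs <- matrix(stats::rgamma(w * 4L, shape = 0.6), nrow = w)
      probs <- probs / rowSums(probs)
      new_pwm(probs, name = sprintf("decoy_%02d", i), source = "scenario")
    })
    c(list(pwm), decoys)
  })
}

#' Generate the default synthetic scenario
#'
#' Emits every pipeline input with planted ground truth: a reference with
#' motif-planted ChIP-seq peaks, a phased haplotype panel with LD blocks,
#' causal and null variants, per-dataset eQTL tables, an annotation table,
#' a gene model, a motif database and a ready-to-run pipeline config. The
#' defaults are the package's stated test world: 100 peaks with 80%
#' planting, 5 causal + 200 null variants, 3 brain eQTL datasets,
#' annotation flip probability 0.05.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Root integer seed; per-stage seeds are derived from it.
#' @param n_peaks,plant_frac,n_causal,n_null,n_datasets,n_hap,flip_prob,beta_range
#'   Scenario parameters (see the generator functions).
#' @param reference_length,gc Reference geometry.
#' @param pwm Generating motif (default [scenario_pwm()]).
#' @param write Write files to `outdir` (set `FALSE` for in-memory use).
#' @return Invisible list with all in-memory objects, the `manifest`, and
#'   `paths` of written files.
#' @export
simulate_scenario <- function(outdir = tempfile("scenario"), seed = 1L,
                              n_peaks = 100L, plant_frac = 0.8,
                              n_causal = 5L, n_null = 200L,
                              n_datasets = 3L, n_hap = 200L,
                              flip_prob = 0.05, beta_range = c(0.2, 0.8),
                              reference_length = 50000L, gc = 0.41,
                              pwm = scenario_pwm(), write = TRUE) {
  ref_sim <- simulate_reference(reference_length, gc,
                                seed = derive_seed(seed, "reference"))
  genes <- simulate_gene_model(ref_sim$reference, n_genes = 2L,
                               region_start0 = 1000L)
  pk <- simulate_chipseq_peaks(ref_sim$reference, pwm, n_peaks, plant_frac,
                               seed = derive_seed(seed, "peaks"),
                               region_start0 = 10000L)
  blocks <- list(
    list(n_snps = 8L, target_r2 = c(1, 0.8, 0.5, 0.45, 0.35, 0.1, 0.05)),
    list(n_snps = 8L, founder_haps = 2L),
    list(n_snps = 8L, target_r2 = c(0.9, 0.6, 0.5, 0.3, 0.2, 0.1, 0.02)),
    list(n_snps = 8L, founder_haps = 3L))
  pan <- simulate_haplotype_panel(n_hap, blocks,
                                  seed = derive_seed(seed, "panel"),
                                  chrom = names(pk$reference)[1L],
                                  start0 = 22000L, block_spacing = 2000L,
                                  reference = pk$reference)
  background <- background_from_sequences(pk$reference)
  variants <- plant_disrupting_variants(pwm, pk$reference, pk$manifest,
                                        n_causal, n_null,
                                        seed = derive_seed(seed, "variants"),
                                        background = background)
  eq <- simulate_eqtl_tables(variants, n_datasets,
                             n_true = sum(variants$is_causal),
                             beta_range = beta_range,
                             seed = derive_seed(seed, "eqtl"))
  causal_ids <- variants$id[variants$is_causal]
  annotations <- simulate_annotations(variants, causal_ids, flip_prob,
                                      seed = derive_seed(seed, "annot"))
  db <- scenario_motif_db(pwm, seed = derive_seed(seed, "db"))
  manifest <- list(seed = seed,
                   planted_proxies = pan$manifest,
                   planted_motif_sites = pk$manifest,
                   causal_variants = variants[variants$is_causal,
                                              c("id", "true_delta_score",
                                                "target_gene")],
                   eqtl_effects = eq$manifest,
                   annotation_truth = data.frame(variant_id = causal_ids,
                                                 category1 = TRUE))
  paths <- NULL
  if (write) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outdir, x)
    paths <- list(fasta = fp("reference.fa"), panel = fp("panel.vcf"),
                  index_snps = fp("index_snps.tsv"),
                  peaks = fp("peaks.bed"), motif_db = fp("motif_db.meme"),
                  variants = fp("variants.vcf"),
                  eqtl = vapply(names(eq$tables), function(d)
                    fp(paste0("eqtl_", d, ".tsv")), character(1L)),
                  annotations = fp("annotations.tsv"),
                  genes = fp("genes.tsv"), manifest = fp("manifest.json"),
                  config = fp("config.txt"))
    write_reference(pk$reference, paths$fasta)
    write_vcf(pan$panel$variants, paths$panel,
              haplotypes = pan$panel$matrix)
    index_ids <- pan$panel$variants$id[grepl("_s001$",
                                             pan$panel$variants$id)]
    write_tsv(pan$panel$variants[pan$panel$variants$id %in% index_ids, ],
              paths$index_snps)
    write_peaks_bed(pk$peaks, paths$peaks)
    write_meme(db, paths$motif_db, background)
    write_vcf(variants[, c("chrom", "pos0", "id", "ref", "alt")],
              paths$variants)
    for (d in names(eq$tables))
      write_tsv(eq$tables[[d]], fp(paste0("eqtl_", d, ".tsv")))
    write_tsv(annotations, paths$annotations)
    write_gene_model(genes, paths$genes)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    cfg <- c(fasta = paths$fasta, vcf = paths$variants,
             panel = paths$panel, index_snps = paths$index_snps,
             peaks = paths$peaks, motif_db = paths$motif_db,
             eqtl = paste(paths$eqtl, collapse = ","),
             annotations = paths$annotations, genes = paths$genes,
             seed = seed)
    writeLines(paste0(names(cfg), ": ", cfg), paths$config)
  }
  invisible(list(reference = pk$reference, background = background,
                 panel = pan$panel, peaks = pk$peaks, variants = variants,
                 eqtl_tables = eq$tables, annotations = annotations,
                 genes = genes, motif_db = db, pwm = pwm,
                 manifest = manifest, paths = paths, outdir = outdir))
}

PIPELINE_DEFAULTS <- list(
  r2_min = 0.3, window = 5e5, half_window = 20L, alpha_affinity = 0.001,
  alpha_rank = 0.05, nmotifs = 5L, minw = 6L, maxw = 20L,
  motif_fdr = 0.05, q_max = 0.001, sim_min = 0.75, n_mc = 1e5,
  top_peaks = 500L, flank = 20L, min_datasets = 1L, seed = 1L)

#' Read a flat key-value pipeline config
#'
#' One `key: value` pair per line (YAML-style flat mapping); `#` comments
#' and blank lines ignored. Unknown keys are kept (paths); known numeric
#' parameters are coerced.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*?)\\s*$",
                                  lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  cfg <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
  for (k in intersect(names(cfg), names(PIPELINE_DEFAULTS)))
    cfg[[k]] <- as.numeric(cfg[[k]])
  cfg
}

#' @noRd
config_get <- function(config, key) {
  config[[key]] %||% PIPELINE_DEFAULTS[[key]]
}

#' Run the full pipeline
#'
#' Stages, in order: LD expansion (if a panel and index SNPs are supplied),
#' motif discovery (skipped and logged if pre-discovered motifs are
#' supplied), database matching, allele-specific scoring, disruption
#' calling, eQTL integration (gracefully empty if no tables), and
#' prioritization. Every stage writes a TSV into the run directory, logs
#' its row count and seed, and all randomness derives from the single root
#' seed, so reruns with the same config reproduce all outputs.
#'
#' @param config Named list or path to a [read_config()] file. Path keys:
#'   `fasta`, `vcf` (variants to score), `motif_db`; optional `panel`,
#'   `index_snps`, `peaks`, `motifs`, `eqtl` (comma-separated),
#'   `annotations`, `genes`. Parameter keys as in the package defaults.
#' @param outdir Run directory (created).
#' @return Invisible list with the stage objects and `outdir`.
#' @export
run_pipeline <- function(config, outdir = tempfile("run")) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "pipeline.log")
  seed <- as.integer(config_get(config, "seed"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  reference <- stage("reference", read_reference(config$fasta))
  background <- background_from_sequences(reference)
  counts <- list()

  # -- LD expansion (optional pre-stage) -----------------------------------
  ld <- NULL
  if (!is.null(config$panel) && !is.null(config$index_snps)) {
    ld <- stage("ld-expand", {
      panel <- read_panel(config$panel)
      idx <- read_tsv(config$index_snps)$id
      ex <- expand_ld(panel, idx, r2_min = config_get(config, "r2_min"),
                      window = config_get(config, "window"))
      tab <- ld_table(ex)
      write_tsv(tab, file.path(outdir, "ld_expansion.tsv"))
      tab
    })
    counts$ld_snps <- attr(ld, "n_unique")
    log_msg("ld-expand: ", counts$ld_snps, " unique SNPs", logfile = logfile)
  }

  # -- motif discovery (skipped when motifs are supplied) ------------------
  if (!is.null(config$motifs)) {
    log_msg("discover: skipped, motifs supplied", logfile = logfile)
    retained <- lapply(read_meme(config$motifs), function(p)
      structure(list(pwm = p, enrichment_p = NA_real_, q_value = NA_real_,
                     seed_kmer = NA_character_), class = "discovered_motif"))
  } else if (!is.null(config$peaks)) {
    retained <- stage("discover", {
      peaks <- read_peaks_bed(config$peaks)
      pos <- select_top_peaks(peaks, n = config_get(config, "top_peaks"),
                              flank = config_get(config, "flank"),
                              reference = reference)
      found <- discover_motifs(pos, seed = derive_seed(seed, "discover"),
                               nmotifs = config_get(config, "nmotifs"),
                               minw = config_get(config, "minw"),
                               maxw = config_get(config, "maxw"))
      motif_fdr_filter(found, alpha = config_get(config, "motif_fdr"))
    })
    if (length(retained))
      write_meme(lapply(retained, `[[`, "pwm"),
                 file.path(outdir, "discovered.meme"), background)
  } else stop("config needs either 'motifs' or 'peaks'")
  counts$motifs_retained <- length(retained)
  log_msg("discover: ", length(retained), " motifs retained",
          logfile = logfile)

  # -- database matching ---------------------------------------------------
  db <- stage("match", read_meme(config$motif_db))
  matches <- stage("match", match_to_database(
    lapply(retained, `[[`, "pwm"), db,
    sim_min = config_get(config, "sim_min")))
  write_tsv(matches, file.path(outdir, "matches.tsv"))
  scan_names <- unique(matches$db_name)
  scan_pwms <- db[vapply(db, `[[`, "", "name") %in% scan_names]
  counts$matched_db_motifs <- length(scan_pwms)
  log_msg("match: ", length(scan_pwms), " database motifs matched",
          logfile = logfile)

  # -- allele-specific scoring and calling ---------------------------------
  variants <- stage("score", read_variants(config$vcf))
  results <- if (length(scan_pwms)) {
    stage("score", disruption_test(
      scan_pwms, reference, variants,
      half_window = config_get(config, "half_window"),
      background = background, mode = "mc",
      n_mc = config_get(config, "n_mc"),
      seed = derive_seed(seed, "score")))
  } else data.frame(variant_id = character(), motif_name = character(),
                    score_ref = numeric(), score_alt = numeric(),
                    direction = character(), p_ref = numeric(),
                    p_alt = numeric(), p_rank = numeric())
  write_tsv(results, file.path(outdir, "scores.tsv"))
  counts$pairs_scored <- nrow(results)
  called <- stage("call", call_disrupting(
    results, alpha_affinity = config_get(config, "alpha_affinity"),
    alpha_rank = config_get(config, "alpha_rank"),
    n_tests = max(1L, nrow(results))))
  write_tsv(called$results, file.path(outdir, "calls.tsv"))
  counts$pairs_kept <- nrow(called$kept)
  counts$variants_called <- length(unique(called$kept$variant_id))
  log_msg("call: ", counts$variants_called, " variants called disrupting",
          logfile = logfile)

  # -- eQTL integration ----------------------------------------------------
  evidence <- if (!is.null(config$eqtl)) {
    stage("eqtl", {
      tabs <- lapply(strsplit(config$eqtl, ",")[[1L]], read_tsv)
      integrate_eqtl(unique(called$kept$variant_id), tabs,
                     q_max = config_get(config, "q_max"))
    })
  } else {
    log_msg("eqtl: no tables supplied; gate passes nothing",
            logfile = logfile)
    integrate_eqtl(unique(called$kept$variant_id), list(
      data.frame(variant = character(), gene = character(),
                 beta = numeric(), p = numeric(), dataset = character())))
  }
  write_tsv(evidence, file.path(outdir, "evidence.tsv"))
  counts$eqtl_pass <- length(unique(
    evidence$variant_id[evidence$n_significant_datasets >=
                          config_get(config, "min_datasets")]))

  # -- prioritization ------------------------------------------------------
  annotations <- if (!is.null(config$annotations))
    read_tsv(config$annotations)
  else data.frame(variant_id = character(), regulomedb_category = character(),
                  promoter_mark = logical(), enhancer_mark = logical(),
                  dnase_protein = logical(), motif_change = logical())
  gene_model <- if (!is.null(config$genes)) read_gene_model(config$genes)
                else NULL
  ranked <- stage("prioritize", rank_variants(
    called$kept, evidence, annotations,
    min_datasets = config_get(config, "min_datasets"),
    variants = variants, gene_model = gene_model))
  write_tsv(ranked, file.path(outdir, "ranked.tsv"))
  counts$regulome_pass <- sum(ranked$passes_eqtl & ranked$passes_regulome)
  counts$ranked <- sum(!is.na(ranked$rank))
  log_msg("prioritize: ", counts$ranked, " variants ranked",
          logfile = logfile)

  summaries <- summarize_hits(called$kept, variants, gene_model)
  run_info <- list(seed = seed, counts = counts,
                   params = stats::setNames(
                     lapply(names(PIPELINE_DEFAULTS), config_get,
                            config = config), names(PIPELINE_DEFAULTS)))
  jsonlite::write_json(run_info, file.path(outdir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(outdir = outdir, ld = ld, retained = retained,
                 matches = matches, results = results, called = called,
                 evidence = evidence, ranked = ranked,
                 summaries = summaries, counts = counts))
}

#' Build the run report
#'
#' Reads a completed run directory and produces `report.json` plus a
#' human-readable summary: per-TF hit counts, the co-disruption matrix,
#' the context distribution (when a gene model was configured), and the
#' filter funnel (scored pairs, variants called, eQTL survivors,
#' annotation survivors, ranked variants). Regenerating the report is
#' deterministic.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Invisible report list.
#' @export
make_report <- function(run_dir) {
  info_path <- file.path(run_dir, "run_info.json")
  if (!file.exists(info_path))
    stop("incomplete run directory: missing run_info.json")
  info <- jsonlite::read_json(info_path, simplifyVector = TRUE)
  calls <- read_tsv(file.path(run_dir, "calls.tsv"))
  kept <- calls[which(calls$kept), , drop = FALSE]
  ranked <- read_tsv(file.path(run_dir, "ranked.tsv"))
  summaries <- summarize_hits(kept)
  funnel <- list(pairs_scored = nrow(calls),
                 variants_called = length(unique(kept$variant_id)),
                 eqtl_pass = info$counts$eqtl_pass %||% 0L,
                 regulome_pass = info$counts$regulome_pass %||% 0L,
                 ranked = sum(!is.na(ranked$rank)))
  report <- list(seed = info$seed, funnel = funnel,
                 per_tf = summaries$per_tf,
                 co_disruption = summaries$co_disruption,
                 top_ranked = utils::head(
                   ranked[!is.na(ranked$rank), , drop = FALSE], 10L))
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor")
  lines <- c("== regsnap run report ==",
             sprintf("seed: %s", info$seed),
             "filter funnel:",
             sprintf("  %-16s %d", names(funnel), unlist(funnel)),
             "top ranked variants:",
             utils::capture.output(print(report$top_ranked,
                                         row.names = FALSE)))
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(report)
}
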