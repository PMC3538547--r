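# End-to-end orchestration: fixture generation -> amplicon extraction ->
# read simulation -> leave-k-out -> threshold calibration -> coverage of
# query reads -> (optional) two-region combination, with TSV outputs and
# a run manifest.

#' Default pipeline configuration
#'
#' @param fixture List of [fixture_spec()] arguments describing the
#'   synthetic data set.
#' @param window Length-2 integer vector: first and last base of the
#'   amplicon window in root-sequence coordinates (`NULL` = positions 11
#'   to `seq_len - 10`, leaving primer-sized margins).
#' @param read List of [read_config()] arguments for the main
#'   sequencing strategy.
#' @param lko List of [lko_config()] arguments (seed is derived from the
#'   pipeline seed).
#' @param e_grid Desired-FPR grid for calibration.
#' @param alpha Binomial significance level.
#' @param queries_per_species Query reads generated per species for the
#'   coverage evaluation.
#' @param combine_windows Optional list with elements `a` and `b`, each
#'   a length-2 base-coordinate window: queries are additionally
#'   classified from 100 nt single-end reads of the two windows and the
#'   predictions combined.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fixture = list(), window = NULL,
                            read = list(), lko = list(),
                            e_grid = default_fpr_grid(), alpha = 0.05,
                            queries_per_species = 2L,
                            combine_windows = NULL, seed = 1L) {
  structure(
    list(fixture = fixture, window = window, read = read, lko = lko,
         e_grid = e_grid, alpha = alpha,
         queries_per_species = as.integer(queries_per_species),
         combine_windows = combine_windows, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys mirror the
#'   [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, cfg)
}

window_from_bases <- function(bases, sim, ref_id) {
  map <- attr(sim, "root_col_map")
  primer_window(ref_id, map[bases[1L]], map[bases[2L]])
}

region_reads <- function(sim_aligned, window, rcfg) {
  if (!(window$reference_id %in% sim_aligned$ids)) {
    # query alignments share the fixture's column space; re-anchor the
    # window on a row of the target alignment
    window$reference_id <- sim_aligned$ids[1L]
  }
  amps <- extract_amplicons(sim_aligned, window)
  amps <- filter_amplicon_lengths(amps)
  reads <- if (rcfg$mode == "paired") {
    make_paired_read(amps, rcfg)
  } else {
    make_single_read(amps, rcfg)
  }
  ambiguity_filter(reads, rcfg)$reads
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full design-evaluation pipeline on synthetic data
#'
#' Generates the fixture taxonomy and alignment, excises amplicons for
#' the primer window, simulates reads (the training sequences are
#' trimmed to the same region by the same rules), runs species-exclusion
#' leave-k-out tests, calibrates per-rank confidence thresholds over the
#' desired-FPR grid, classifies freshly generated query reads with the
#' original non-redundant training set, computes gap-corrected coverage
#' and the FPR/coverage curve, and (optionally) combines predictions
#' from two sub-regions. All tabular outputs are written as TSV; a JSON
#' manifest records the configuration, seeds and output checksums. Runs
#' are byte-identical given equal configuration.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return A list with every intermediate object: `sim`, `window`,
#'   `reads`, `lko`, `thresholds`, `env_results`, `coverages`, `curve`,
#'   `summary`, and (if configured) `combined`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  fx_args <- config$fixture
  if (is.null(fx_args$seed)) {
    fx_args$seed <- derive_seed(config$seed, "fixture")
  }
  fx <- do.call(fixture_spec, fx_args)
  tax <- gen_taxonomy(fx)
  sim <- gen_alignment(fx, tax)

  bases <- config$window
  if (is.null(bases)) bases <- c(11L, fx$seq_len - 10L)
  ref_id <- sim$training$id[1L]
  window <- window_from_bases(bases, sim, ref_id)
  rcfg <- do.call(read_config, config$read)
  reads <- region_reads(sim$aligned, window, rcfg)

  # self-test: the region-trimmed read strings serve as both training
  # sequences and test queries, with species-level exclusion
  ts <- sim$training
  ts <- ts[match(reads$id, ts$id), , drop = FALSE]
  ts$sequence <- reads$sequence
  class(ts) <- c("training_set", "data.frame")

  lko_args <- config$lko
  if (is.null(lko_args$seed)) {
    lko_args$seed <- derive_seed(config$seed, "lko")
  }
  lcfg <- do.call(lko_config, lko_args)
  run <- run_lko(ts, ts, lcfg)
  thresholds <- calibrate_thresholds(run, config$e_grid,
                                     alpha = config$alpha)

  # query ("environmental") reads, classified against the original
  # non-redundant training set
  queries <- gen_queries(fx, sim, n_per_species = config$queries_per_species)
  qreads <- region_reads(queries$aligned, window, rcfg)
  nr <- build_nonredundant_set(trim_to_genus(ts), cluster_identical(ts))
  model <- train_classifier(nr, word_size = lcfg$word_size)
  env_results <- classify_batch(qreads, model,
                                bootstrap = lcfg$bootstrap,
                                seed = derive_seed(config$seed, "env"))
  coverages <- coverage_table(env_results, thresholds)
  curve <- fpr_coverage_curve(coverages)
  summary_df <- summarize_bins(run, thresholds, env_results)

  combined <- NULL
  if (!is.null(config$combine_windows)) {
    scfg <- read_config(rcfg$read_length, mode = "single-forward")
    resAB <- lapply(config$combine_windows[c("a", "b")], function(b) {
      w <- window_from_bases(b, sim, ref_id)
      tr <- region_reads(sim$aligned, w, scfg)
      tsr <- sim$training[match(tr$id, sim$training$id), , drop = FALSE]
      tsr$sequence <- tr$sequence
      class(tsr) <- c("training_set", "data.frame")
      nrr <- build_nonredundant_set(trim_to_genus(tsr),
                                    cluster_identical(tsr))
      mdl <- train_classifier(nrr, word_size = lcfg$word_size)
      qr <- region_reads(queries$aligned, w, scfg)
      classify_batch(qr, mdl, bootstrap = lcfg$bootstrap,
                     seed = derive_seed(config$seed, "combine"))
    })
    combined <- combine_predictions(resAB$a, resAB$b)
  }

  out <- list(config = config, fixture = fx, sim = sim, window = window,
              reads = reads, training = ts, lko = run,
              thresholds = thresholds, queries = queries,
              env_results = env_results, coverages = coverages,
              curve = curve, summary = summary_df, combined = combined)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    files <- c(files, write_taxonomy_table(
      ts, file.path(out_dir, "taxonomy.tsv")))
    files <- c(files, write_lko_results(
      run, file.path(out_dir, "lko_results.tsv")))
    files <- c(files, write_thresholds(
      thresholds, file.path(out_dir, "thresholds.tsv")))
    sm <- summary_df
    files <- c(files, write_summary(sm, file.path(out_dir, "summary.tsv")))
    cv <- coverages
    cv$ct <- format_ct(cv$ct)
    files <- c(files, write_tsv(cv, file.path(out_dir, "coverage.tsv")))
    cu <- curve
    cu$ct <- format_ct(cu$ct)
    files <- c(files, write_tsv(cu, file.path(out_dir, "curve.tsv")))
    files <- c(files, write_classifications(
      env_results, file.path(out_dir, "env_classifications.tsv")))
    if (!is.null(combined)) {
      files <- c(files, write_tsv(as.data.frame(combined),
                                  file.path(out_dir, "combined.tsv")))
    }
    manifest <- list(
      tool = "ampligauge",
      version = as.character(utils::packageVersion("ampligauge")),
      seed = config$seed,
      config = unclass(config),
      outputs = as.list(tools::md5sum(unlist(files))),
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(out)
}
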