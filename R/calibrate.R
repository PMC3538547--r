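# Scoring of leave-k-out predictions, conservative binomial selection of
# confidence thresholds for desired false-prediction rates, and
# taxonomy-gap-corrected coverage.

#' Lower bounds of the 21 confidence bins
#'
#' Confidence scores are binned in intervals of size 5 — `[0-4]`,
#' `[5-9]`, ..., `[95-99]` — except confidence 100, which forms its own
#' interval of size 1.
#'
#' @return Integer vector `c(0, 5, ..., 95, 100)`.
#' @export
confidence_bins <- function() {
  c(seq(0L, 95L, by = 5L), 100L)
}

conf_bin_index <- function(conf) {
  if (any(conf < 0L | conf > 100L, na.rm = TRUE)) {
    stop("confidence outside 0..100")
  }
  idx <- as.integer(conf) %/% 5L + 1L
  idx[conf == 100L] <- 21L
  idx
}

canonical_taxon <- function(x, synonyms = NULL) {
  if (is.null(synonyms)) return(x)
  bare <- strip_rank_prefix(x)
  i <- match(bare, synonyms$name)
  hit <- !is.na(i) & !is.na(x)
  x[hit] <- paste0(rank_of_prefixed(x[hit]), "__",
                   synonyms$canonical[i[hit]])
  x
}

#' Score predictions at a rank as true, false, or neither
#'
#' A prediction at rank R is true when the predicted and reference names
#' match (or are synonymous); false when both carry the rank but names
#' differ, or when the rank is present only in the prediction; and
#' neither — contributing to no error count — when the prediction lacks
#' the rank.
#'
#' @param pred,ref Character vectors of prefixed taxon names at the rank
#'   (`NA` where absent), recycled to common length.
#' @param synonyms Optional data frame with columns `name` and
#'   `canonical` mapping equivalent (unprefixed) taxon names.
#' @return Character vector of `"TP"`, `"FP"`, `"NEITHER"`.
#' @export
score_prediction <- function(pred, ref, synonyms = NULL) {
  pred <- canonical_taxon(pred, synonyms)
  ref <- canonical_taxon(ref, synonyms)
  out <- rep("NEITHER", length(pred))
  has_p <- !is.na(pred)
  out[has_p & !is.na(ref) & pred == ref] <- "TP"
  out[has_p & (is.na(ref) | pred != ref)] <- "FP"
  out
}

#' False prediction rate
#'
#' `FPR = FP / (TP + FP)`; `NA` when no predictions were made at the
#' rank.
#'
#' @param tp,fp True and false prediction counts.
#' @return The rate, or `NA` for `TP + FP = 0`.
#' @export
fpr <- function(tp, fp) {
  ifelse(tp + fp == 0, NA_real_, fp / (tp + fp))
}

#' Bin scored predictions of one repeat into confidence intervals
#'
#' @param results One repeat's rows of an `lko_run` results table (must
#'   contain `<rank>`, `conf_<rank>` and `ref_<rank>` columns).
#' @param rank The rank to score.
#' @param synonyms Optional synonym map (see [score_prediction()]).
#' @return A `confidence_histogram` data frame: `bin_lower`, `tp`, `fp`
#'   (21 rows).
#' @export
bin_confidences <- function(results, rank, synonyms = NULL) {
  outcome <- score_prediction(results[[rank]],
                              results[[paste0("ref_", rank)]], synonyms)
  conf <- results[[paste0("conf_", rank)]]
  scored <- outcome != "NEITHER"
  idx <- conf_bin_index(conf[scored])
  tp <- tabulate(idx[outcome[scored] == "TP"], nbins = 21L)
  fp <- tabulate(idx[outcome[scored] == "FP"], nbins = 21L)
  structure(data.frame(bin_lower = confidence_bins(), tp = tp, fp = fp),
            class = c("confidence_histogram", "data.frame"))
}

#' Pick a conservative confidence threshold for a desired FPR
#'
#' For every non-empty bin the probability of observing at most the
#' bin's TP count under `Binomial(TP + FP, 1 - e)` is computed. Scanning
#' bins downwards from confidence 100, the first bin where this
#' probability is at most `alpha` fails the test, and the lower bound of
#' the bin above it is returned as the threshold — conservatively
#' assuming all confidence scores fall into the threshold bin. If no bin
#' fails the threshold is 0; if the 100 bin itself fails, no threshold
#' can attain the desired FPR and `Inf` is returned.
#'
#' @param hist A [bin_confidences()] histogram.
#' @param e Desired false prediction rate, in (0, 1).
#' @param alpha Significance level of the per-bin binomial test.
#' @return Threshold in `{0, 5, ..., 95, 100}`, or `Inf` (unattainable).
#' @export
pick_threshold <- function(hist, e, alpha = 0.05) {
  if (e <= 0 || e >= 1) stop("e must be in (0, 1)")
  n <- hist$tp + hist$fp
  for (i in 21L:1L) {
    if (n[i] == 0L) next
    p <- stats::pbinom(hist$tp[i], n[i], 1 - e)
    if (p <= alpha) {
      if (i == 21L) return(Inf)
      return(hist$bin_lower[i + 1L])
    }
  }
  0
}

#' Median threshold over repeats
#'
#' The median of per-repeat thresholds, with unattainable (`Inf`)
#' ordered above 100; for an even number of repeats the larger middle
#' value is taken, keeping the combined threshold conservative.
#'
#' @param cts Numeric vector of per-repeat thresholds.
#' @return The median threshold.
#' @export
median_threshold <- function(cts) {
  if (length(cts) == 0L) stop("no thresholds to take a median over")
  s <- sort(cts)  # Inf sorts last
  s[length(s) %/% 2L + 1L]
}

#' Default grid of desired false prediction rates
#'
#' Twelve values spanning 0.001 to 0.95.
#'
#' @return Numeric vector.
#' @export
default_fpr_grid <- function() {
  c(0.001, 0.005, 0.01, 0.02, 0.05, 0.10, 0.15, 0.20, 0.30, 0.50,
    0.75, 0.95)
}

#' Calibrate rank-specific confidence thresholds from a leave-k-out run
#'
#' For every rank and every desired FPR in the grid, a threshold is
#' picked per repeat with [pick_threshold()] and combined with
#' [median_threshold()]. The low-count flag marks thresholds whose
#' median number of predictions in the threshold bin is below 10.
#'
#' @param run An `lko_run`.
#' @param e_grid Desired FPR values.
#' @param alpha Per-bin binomial significance level.
#' @param ranks Ranks to calibrate (default phylum through genus).
#' @param synonyms Optional synonym map.
#' @return A `threshold_table` data frame: `rank`, `e`, `ct` (`Inf` =
#'   unattainable), `low_count`. The per-rank, per-repeat histograms are
#'   attached as attribute `"histograms"`.
#' @export
calibrate_thresholds <- function(run, e_grid = default_fpr_grid(),
                                 alpha = 0.05,
                                 ranks = tax_ranks()[-1L],
                                 synonyms = NULL) {
  reps <- sort(unique(run$results$rep))
  hists <- lapply(stats::setNames(ranks, ranks), function(rk) {
    lapply(reps, function(r) {
      bin_confidences(run$results[run$results$rep == r, , drop = FALSE],
                      rk, synonyms)
    })
  })
  rows <- list()
  for (rk in ranks) {
    hs <- hists[[rk]]
    counts <- vapply(hs, function(h) h$tp + h$fp, numeric(21L))
    med_count <- apply(matrix(counts, nrow = 21L), 1L, stats::median)
    for (e in e_grid) {
      cts <- vapply(hs, pick_threshold, numeric(1L), e = e, alpha = alpha)
      ct <- median_threshold(cts)
      low <- if (is.finite(ct)) {
        med_count[match(ct, confidence_bins())] < 10
      } else {
        NA
      }
      rows[[length(rows) + 1L]] <- data.frame(
        rank = rk, e = e, ct = ct, low_count = low,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "histograms") <- hists
  class(out) <- c("threshold_table", "data.frame")
  out
}

rank_passes <- function(results, rank, ct) {
  conf <- results[[paste0("conf_", rank)]]
  !is.na(conf) & conf >= ct
}

#' Gap-corrected classification coverage at a threshold
#'
#' Coverage at rank R and threshold `ct` is `n / (S - gap_excluded)`:
#' `n` counts sequences predicted at R with confidence at least `ct`
#' that also pass the thresholds of all coarser ranks (predictions
#' passing a fine threshold while failing a coarser one carry a high
#' error rate and are excluded from the numerator); `S` is the number of
#' sequences with any prediction; `gap_excluded` subtracts sequences
#' classified to places in the hierarchy that omit rank R, which could
#' never receive a prediction there.
#'
#' @param results A `classification_set`.
#' @param rank The rank whose coverage is computed.
#' @param ct Confidence threshold (0–100, or `Inf` for an unattainable
#'   threshold, giving coverage 0).
#' @param thresholds_above Named numeric vector of thresholds for coarser
#'   ranks (used for the rank-consistency exclusion); ranks the
#'   prediction omits are skipped.
#' @return A `coverage_report` list: `rank`, `ct`, `n`, `S`,
#'   `gap_excluded`, `inconsistent_excluded`, `coverage`.
#' @export
coverage <- function(results, rank, ct, thresholds_above = NULL) {
  ok <- !results$failed
  S <- sum(ok)
  gap <- ok & is.na(results[[rank]])
  denom <- S - sum(gap)
  if (denom <= 0L) stop("coverage denominator is not positive")
  if (is.infinite(ct)) {
    cand <- rep(FALSE, nrow(results))
  } else {
    cand <- ok & rank_passes(results, rank, ct)
  }
  consistent <- rep(TRUE, nrow(results))
  for (rk in names(thresholds_above)) {
    if (rank_depth(rk) >= rank_depth(rank)) next
    ct_up <- thresholds_above[[rk]]
    has <- !is.na(results[[rk]])
    fails <- has & (is.infinite(ct_up) |
                      !rank_passes(results, rk, ct_up))
    consistent <- consistent & !fails
  }
  n <- sum(cand & consistent)
  structure(
    list(rank = rank, ct = ct, n = n, S = S, gap_excluded = sum(gap),
         inconsistent_excluded = sum(cand & !consistent),
         coverage = n / denom),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage at %s (ct=%s): %d/%d (gap-excl %d, inconsistent %d) = %.3f\n",
              x$rank, format(x$ct), x$n, x$S - x$gap_excluded,
              x$gap_excluded, x$inconsistent_excluded, x$coverage))
  invisible(x)
}

#' Coverage of query classifications over a calibrated threshold table
#'
#' For each (rank, desired FPR) entry of the threshold table, computes
#' [coverage()] with the same-`e` thresholds of all coarser calibrated
#' ranks applied as the rank-consistency rule.
#'
#' @param results A `classification_set` of query reads.
#' @param thresholds A [calibrate_thresholds()] table.
#' @param ids Optional character vector restricting the evaluation to a
#'   subset of query IDs (e.g. sequences covering all compared regions).
#' @return A data frame: `rank`, `e`, `ct`, `n`, `S`, `gap_excluded`,
#'   `inconsistent_excluded`, `coverage`.
#' @export
coverage_table <- function(results, thresholds, ids = NULL) {
  if (!is.null(ids)) {
    results <- results[results$query_id %in% ids, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(thresholds)), function(i) {
    rk <- thresholds$rank[i]
    e <- thresholds$e[i]
    above <- thresholds[thresholds$e == e &
                          rank_depth(thresholds$rank) < rank_depth(rk), ,
                        drop = FALSE]
    cv <- coverage(results, rk, thresholds$ct[i],
                   stats::setNames(above$ct, above$rank))
    data.frame(rank = rk, e = e, ct = thresholds$ct[i], n = cv$n,
               S = cv$S, gap_excluded = cv$gap_excluded,
               inconsistent_excluded = cv$inconsistent_excluded,
               coverage = cv$coverage, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

format_ct <- function(ct) {
  ifelse(is.infinite(ct), "unattainable",
         format(ct, trim = TRUE, scientific = FALSE))
}

#' Write calibrated thresholds as TSV
#'
#' @param thresholds A [calibrate_thresholds()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  df <- as.data.frame(thresholds)
  df$ct <- format_ct(df$ct)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-bin summary table of a leave-k-out run
#'
#' One row per (rank, confidence bin C): median interval TP and FP
#' counts over repeats, interval precision and FPR (percent), the
#' desired-FPR values whose calibrated threshold equals C, the coverage
#' of the query set for the cumulative interval `[C, 100]`, and
#' cumulative TP/FP/precision/FPR computed as suffix sums of the
#' interval medians.
#'
#' @param run An `lko_run`.
#' @param thresholds A [calibrate_thresholds()] table built from `run`.
#' @param env_results Optional `classification_set` of query reads for
#'   the coverage column (`NA` otherwise). Coverage here is per-rank
#'   (gap-corrected, without the cross-rank consistency rule, whose
#'   thresholds vary by row).
#' @param ranks Ranks to include.
#' @param synonyms Optional synonym map.
#' @return A data frame in the per-bin summary schema.
#' @export
summarize_bins <- function(run, thresholds, env_results = NULL,
                           ranks = tax_ranks()[-1L], synonyms = NULL) {
  hists <- attr(thresholds, "histograms")
  if (is.null(hists)) {
    thresholds <- calibrate_thresholds(run, unique(thresholds$e),
                                       ranks = ranks, synonyms = synonyms)
    hists <- attr(thresholds, "histograms")
  }
  rows <- list()
  for (rk in intersect(ranks, names(hists))) {
    hs <- hists[[rk]]
    tpm <- apply(vapply(hs, `[[`, numeric(21L), "tp"), 1L, stats::median)
    fpm <- apply(vapply(hs, `[[`, numeric(21L), "fp"), 1L, stats::median)
    cum_tp <- rev(cumsum(rev(tpm)))
    cum_fp <- rev(cumsum(rev(fpm)))
    th <- thresholds[thresholds$rank == rk, , drop = FALSE]
    for (i in 1L:21L) {
      C <- confidence_bins()[i]
      es <- th$e[is.finite(th$ct) & th$ct == C]
      env_cov <- NA_real_
      if (!is.null(env_results)) {
        env_cov <- 100 * coverage(env_results, rk, C)$coverage
      }
      rows[[length(rows) + 1L]] <- data.frame(
        rank = rk, confidence = C,
        Interval_TP = tpm[i], Interval_FP = fpm[i],
        Interval_precision = 100 * (1 - fpr(tpm[i], fpm[i])),
        Interval_FPR = 100 * fpr(tpm[i], fpm[i]),
        threshold_for_FPR = paste(es, collapse = ";"),
        Env_coverage = env_cov,
        Cumulative_TP = cum_tp[i], Cumulative_FP = cum_fp[i],
        Cumulative_precision = 100 * (1 - fpr(cum_tp[i], cum_fp[i])),
        Cumulative_FPR = 100 * fpr(cum_tp[i], cum_fp[i]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the per-bin summary as TSV
#'
#' @param summary A [summarize_bins()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Desired-FPR versus coverage curve
#'
#' Pairs each desired FPR with the coverage achieved at its calibrated
#' threshold; within each rank the curve ends at the first point where a
#' threshold of 0 is reached (an unattainable threshold contributes
#' coverage 0).
#'
#' @param coverages A [coverage_table()] data frame.
#' @param plot Draw a base-graphics plot of the curves.
#' @return The (truncated) data frame, invisibly when plotting.
#' @export
fpr_coverage_curve <- function(coverages, plot = FALSE) {
  parts <- lapply(split(coverages, coverages$rank), function(df) {
    df <- df[order(df$e), , drop = FALSE]
    zero <- which(df$ct == 0)
    if (length(zero)) df <- df[seq_len(zero[1L]), , drop = FALSE]
    df
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (plot) {
    ranks_in <- unique(out$rank)
    graphics::plot(NULL, xlim = range(out$e), ylim = c(0, 1),
                   xlab = "desired FPR", ylab = "coverage")
    for (i in seq_along(ranks_in)) {
      d <- out[out$rank == ranks_in[i], ]
      graphics::lines(d$e, d$coverage, col = i, type = "b", pch = 16)
    }
    graphics::legend("bottomright", legend = ranks_in,
                     col = seq_along(ranks_in), lty = 1, pch = 16)
    return(invisible(out))
  }
  out
}
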