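test_that("predictions are scored TP, FP or NEITHER by the stated rules", {
  expect_identical(score_prediction("family__F1", "family__F1"), "TP")
  # rank present only in the prediction counts as false
  expect_identical(score_prediction("family__F1", NA_character_), "FP")
  expect_identical(score_prediction("family__F1", "family__F2"), "FP")
  # rank absent from the prediction contributes to neither count
  expect_identical(score_prediction(NA_character_, "family__F1"),
                   "NEITHER")
  syn <- data.frame(name = c("F1", "F1b"), canonical = "F1")
  expect_identical(score_prediction("family__F1b", "family__F1", syn),
                   "TP")
})

test_that("the false prediction rate is FP over all predictions", {
  expect_equal(fpr(19, 1), 0.05)
  expect_equal(fpr(25, 0), 0)
  expect_true(is.na(fpr(0, 0)))
})

test_that("confidences land in the documented bins", {
  expect_equal(ampligauge:::conf_bin_index(c(0, 4, 5, 99, 100)),
               c(1L, 1L, 2L, 20L, 21L))
  expect_error(ampligauge:::conf_bin_index(101), "0..100")

  res <- data.frame(
    rep = 1, test_id = c("a", "b", "c", "d"),
    ref_genus = "genus__G1",
    genus = c("genus__G1", "genus__G1", "genus__G1", "genus__G2"),
    conf_genus = c(97L, 97L, 97L, 4L),
    stringsAsFactors = FALSE
  )
  h <- bin_confidences(res, "genus")
  expect_equal(h$tp[h$bin_lower == 95], 3)
  expect_equal(h$fp[h$bin_lower == 0], 1)
  expect_equal(sum(h$tp) + sum(h$fp), 4)
  empty <- bin_confidences(res[0, ], "genus")
  expect_true(all(empty$tp == 0) && all(empty$fp == 0))
})

test_that("threshold selection follows the conservative binomial scan", {
  # all bins pure TP: nothing fails, maximal coverage at threshold 0
  h <- make_hist(tp = rep(5, 21), fp = rep(0, 21))
  expect_equal(pick_threshold(h, e = 0.05), 0)

  # a 50/50 bin right under a clean 100 bin fails at e = 0.05
  tp <- rep(0, 21); fp <- rep(0, 21)
  tp[21] <- 100
  tp[20] <- 50; fp[20] <- 50
  h2 <- make_hist(tp, fp)
  expect_lte(pbinom(50, 100, 0.95), 0.05)  # premise of the example
  expect_equal(pick_threshold(h2, e = 0.05), 100)

  # the 100 bin itself failing means no threshold attains the FPR
  tp3 <- rep(0, 21); fp3 <- rep(0, 21); fp3[21] <- 20
  h3 <- make_hist(tp3, fp3)
  expect_equal(pbinom(0, 20, 0.95), 0.05^20)
  expect_identical(pick_threshold(h3, e = 0.05), Inf)

  # empty bins are skipped in the downward scan
  tp4 <- rep(0, 21); fp4 <- rep(0, 21)
  tp4[21] <- 30
  tp4[18] <- 5; fp4[18] <- 15  # bins 19, 20 empty
  h4 <- make_hist(tp4, fp4)
  expect_equal(pick_threshold(h4, e = 0.05), confidence_bins()[19])
})

test_that("median thresholds are conservative for even repeat counts", {
  expect_equal(median_threshold(c(90, 95, 95)), 95)
  expect_equal(median_threshold(c(90, 95)), 95)
  expect_identical(median_threshold(rep(Inf, 100)), Inf)
  expect_equal(median_threshold(c(Inf, 50, 60)), 60)
  expect_error(median_threshold(numeric(0)), "no thresholds")
})

test_that("threshold picking matches the brute-force oracle on random histograms", {
  set.seed(99)
  for (i in 1:100) {
    tp <- rpois(21, lambda = sample(c(0, 2, 20), 21, replace = TRUE))
    fp <- rpois(21, lambda = sample(c(0, 1, 5), 21, replace = TRUE))
    h <- make_hist(tp, fp)
    e <- sample(default_fpr_grid(), 1)
    expect_identical(pick_threshold(h, e), oracle_pick_threshold(h, e))
  }
})

test_that("coverage applies Eq. 2 with gap correction and rank consistency", {
  # 50 of 100 pass at genus, no gaps, no inconsistency
  res <- make_results(100, genus = "G1",
                      conf_genus = c(rep(90L, 50), rep(10L, 50)),
                      family = "F1", conf_family = 95L)
  cv <- coverage(res, "genus", ct = 50)
  expect_equal(cv$coverage, 0.50)
  expect_equal(cv$S, 100)

  # 10 of 100 classified into a childless phylum: class denominator 90
  res2 <- make_results(100, genus = c(rep("G1", 90), rep(NA, 10)),
                       conf_genus = c(rep(80L, 90), rep(NA, 10)),
                       class_ = c(rep("C1", 90), rep(NA, 10)),
                       conf_class = c(rep(80L, 90), rep(NA, 10)))
  cv2 <- coverage(res2, "class", ct = 50)
  expect_equal(cv2$gap_excluded, 10)
  expect_equal(cv2$coverage, 90 / 90)

  # passing class CT = 50 while failing phylum CT = 60 is excluded
  res3 <- make_results(1, genus = "G1", conf_genus = 52L,
                       class_ = "C1", conf_class = 52L,
                       phylum = "P1", conf_phylum = 55L)
  cv3 <- coverage(res3, "class", ct = 50,
                  thresholds_above = c(phylum = 60))
  expect_equal(cv3$n, 0)
  expect_equal(cv3$inconsistent_excluded, 1)
  # an unattainable threshold yields coverage zero
  expect_equal(coverage(res, "genus", ct = Inf)$coverage, 0)
  all_failed <- make_results(3, genus = NA, conf_genus = NA,
                             failed = TRUE)
  expect_error(coverage(all_failed, "genus", 50), "denominator")
})

test_that("coverage is non-increasing in the threshold", {
  set.seed(77)
  res <- make_results(200, genus = "G1",
                      conf_genus = sample(0:100, 200, replace = TRUE))
  cts <- confidence_bins()
  cov <- vapply(cts, function(ct) coverage(res, "genus", ct)$coverage, 0)
  expect_true(all(diff(cov) <= 0))
})

test_that("the per-bin summary has consistent interval and cumulative columns", {
  set.seed(31)
  fx <- fixture_spec(seed = 8)
  sim <- gen_alignment(fx)
  run <- run_lko(sim$training, sim$training,
                 lko_config(bootstrap = 30, repeats = 2, seed = 2))
  th <- calibrate_thresholds(run, e_grid = c(0.05, 0.2))
  sm <- summarize_bins(run, th)
  for (rk in unique(sm$rank)) {
    s <- sm[sm$rank == rk, ]
    expect_equal(s$Cumulative_TP, rev(cumsum(rev(s$Interval_TP))))
    expect_equal(s$Cumulative_FP, rev(cumsum(rev(s$Interval_FP))))
    nz <- !is.na(s$Interval_FPR)
    expect_equal(s$Interval_precision[nz], 100 - s$Interval_FPR[nz])
  }
  # thresholds marked in the summary agree with the threshold table
  for (i in which(nzchar(sm$threshold_for_FPR))) {
    es <- as.numeric(strsplit(sm$threshold_for_FPR[i], ";")[[1]])
    for (e in es) {
      expect_equal(
        th$ct[th$rank == sm$rank[i] & th$e == e], sm$confidence[i])
    }
  }
})

test_that("the FPR/coverage curve truncates at threshold zero and is monotone", {
  covs <- data.frame(
    rank = "genus",
    e = c(0.01, 0.05, 0.1, 0.5, 0.75),
    ct = c(100, 95, 50, 0, 0),
    coverage = c(0.2, 0.4, 0.6, 0.9, 0.9)
  )
  cur <- fpr_coverage_curve(covs)
  expect_equal(nrow(cur), 4L)  # ends at the first ct = 0 point
  expect_true(all(diff(cur$coverage) >= 0))
  single <- fpr_coverage_curve(covs[2, ])
  expect_equal(nrow(single), 1L)
})
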