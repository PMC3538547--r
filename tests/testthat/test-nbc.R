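test_that("word extraction skips ambiguous characters and maps U to T", {
  expect_identical(sequence_words("ACGTACGTA", 8),
                   c("acgtacgt", "cgtacgta"))
  # the spacer of a fused read never yields words
  expect_length(sequence_words(paste0(strrep("A", 7), "N", strrep("C", 7)), 8),
                0L)
  expect_identical(sequence_words("ACGUACGU", 8), "acgtacgt")
  expect_length(sequence_words("ACGT", 8), 0L)
})

test_that("word priors and conditionals follow the pseudocount formulas", {
  ts <- make_ts(c("s1", "s2"), c("ACGTACGTCC", "ACGTACGTGG"),
                c("G1", "G2"))
  m <- train_classifier(ts)
  # word present in both sequences: P(w) = (2 + 0.5) / (2 + 1)
  i <- match("acgtacgt", m$words)
  expect_equal(m$P[i], 2.5 / 3)
  # word present in one sequence
  j <- match("cgtacgtc", m$words)
  expect_equal(m$P[j], 1.5 / 3)
  # absent words fall to the prior floor 0.5 / (N + 1)
  expect_equal(m$log_unseen, log(0.5 / 3))
  # conditional: m(w) + P(w) over M + 1
  expect_equal(word_conditional(m, "acgtacgt", "genus__G1"),
               (1 + 2.5 / 3) / 2)
  # genus not containing the word: m = 0
  expect_equal(word_conditional(m, "cgtacgtc", "genus__G2"),
               (0 + 1.5 / 3) / 2)
})

test_that("training validates input", {
  ts <- make_ts("s1", "ACG", "G1")
  expect_error(train_classifier(ts), "s1")
  ts2 <- make_ts("s1", "ACGTACGTAC", "G1")
  ts2$genus <- NA_character_
  expect_error(train_classifier(ts2), "genus")
})

test_that("a single-genus model classifies anything to it at confidence 100", {
  ts <- make_ts(c("s1", "s2"), random_dna(2, 60), c("G1", "G1"))
  m <- train_classifier(ts)
  res <- classify_read("TTTTTTTTTTTT", m, bootstrap = 50, seed = 1)
  expect_identical(res$genus, "genus__G1")
  expect_true(all(res$confidence == 100L, na.rm = TRUE))
})

test_that("disjoint-word genera are recovered at confidence 100", {
  set.seed(11)
  ts <- make_ts(sprintf("s%d", 1:4),
                c(strrep("AC", 30), strrep("AG", 30),
                  strrep("TC", 30), strrep("TG", 30)),
                c("G1", "G2", "G3", "G4"))
  m <- train_classifier(ts)
  res <- classify_batch(ts[, c("id", "sequence")], m,
                        bootstrap = 100, seed = 2)
  expect_identical(res$genus, ts$genus)
  expect_true(all(res$conf_genus == 100L))
})

test_that("a symmetric two-genus query splits genus confidence but keeps the family", {
  set.seed(21)
  s1 <- random_dna(1, 40)
  s2 <- random_dna(1, 40)
  ts <- make_ts(c("s1", "s2"), c(s1, s2), c("G1", "G2"),
                family = "F1")
  # query: one valid word from each training sequence, separated by N
  query <- paste0(substr(s1, 1, 8), "N", substr(s2, 1, 8))
  stopifnot(length(sequence_words(query)) == 2L)
  m <- train_classifier(ts)
  res <- classify_read(query, m, bootstrap = 1000, seed = 3)
  expect_equal(res$confidence[["family"]], 100L)
  expect_lt(abs(res$confidence[["genus"]] - 50), 3 * sqrt(0.25 / 1000) * 100)
})

test_that("one bootstrap iteration yields only confidences 0 or 100", {
  ts <- make_ts(c("s1", "s2"), random_dna(2, 50), c("G1", "G2"))
  m <- train_classifier(ts)
  res <- classify_read(random_dna(1, 30), m, bootstrap = 1, seed = 4)
  expect_true(all(res$confidence %in% c(0L, 100L), na.rm = TRUE))
})

test_that("parent confidence is at least each child's and tallies sum to the trial count", {
  set.seed(31)
  fx <- fixture_spec(seed = 9)
  sim <- gen_alignment(fx)
  m <- train_classifier(trim_to_genus(sim$training))
  for (q in sample(nrow(sim$training), 5)) {
    res <- classify_read(sim$training$sequence[q], m, bootstrap = 60,
                         seed = q)
    expect_equal(sum(res$tally), 60L)
    conf <- res$confidence[!is.na(res$confidence)]
    expect_true(all(diff(conf) <= 0L))  # coarse-to-fine, non-increasing
  }
})

test_that("classification is deterministic given a seed and order-stable in batches", {
  ts <- make_ts(sprintf("s%d", 1:6), random_dna(6, 80),
                rep(c("G1", "G2", "G3"), 2))
  m <- train_classifier(ts)
  reads <- data.frame(id = sprintf("q%d", 1:4),
                      sequence = random_dna(4, 60),
                      stringsAsFactors = FALSE)
  r1 <- classify_batch(reads, m, bootstrap = 80, seed = 5)
  r2 <- classify_batch(reads, m, bootstrap = 80, seed = 5)
  expect_identical(r1, r2)
  perm <- c(3, 1, 4, 2)
  r3 <- classify_batch(reads[perm, ], m, bootstrap = 80, seed = 5)
  rownames(r3) <- NULL
  expect_identical(r3, {
    x <- r1[perm, ]
    rownames(x) <- NULL
    x
  })
  # a read with no valid words is a recorded failure, not an error
  r4 <- classify_batch(data.frame(id = "nn", sequence = "NNNNNNNNNN"),
                       m, bootstrap = 10, seed = 1)
  expect_true(r4$failed)
})

test_that("bootstrap confidences converge to the exact single-draw tally", {
  set.seed(41)
  s1 <- random_dna(1, 30)
  s2 <- random_dna(1, 30)
  ts <- make_ts(c("s1", "s2"), c(s1, s2), c("G1", "G2"))
  # 3 words drawn from G1's sequence, 1 from G2's: expect 75% G1 wins
  query <- paste0(substr(s1, 1, 10), "N", substr(s2, 1, 8))
  W <- length(sequence_words(query))
  stopifnot(W <= 12, W %/% 8 <= 1)
  shares <- oracle_single_draw_shares(c(s1, s2), c("G1", "G2"), query)
  m <- train_classifier(ts)
  res <- classify_read(query, m, bootstrap = 10000, seed = 6)
  p_hat <- res$tally[match("genus__G1", m$genera)] / 10000
  se <- sqrt(shares[["G1"]] * (1 - shares[["G1"]]) / 10000)
  expect_lt(abs(p_hat - shares[["G1"]]), 3 * se + 1e-9)
  expect_equal(shares[["G1"]], 0.75)
})
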