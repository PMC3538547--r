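# Shared builders and independent oracles used across the suite.

# quick training set: lineage derived from a genus label, one family per
# `fam` argument, species defaults to one per genus
make_ts <- function(ids, seqs, genus, species = NULL,
                    family = NULL, phylum = NULL) {
  n <- length(ids)
  if (is.null(species)) species <- paste0(genus, "_sp1")
  if (is.null(family)) family <- "F1"
  if (is.null(phylum)) phylum <- "P1"
  family <- rep_len(family, n)
  phylum <- rep_len(phylum, n)
  ts <- training_set(n)
  ts$id <- ids
  ts$sequence <- toupper(seqs)
  ts$domain <- "domain__Bacteria"
  ts$phylum <- paste0("phylum__", phylum)
  ts$class <- paste0("class__C", sub("P", "", phylum))
  ts$order <- paste0("order__O", sub("P", "", phylum))
  ts$family <- paste0("family__", family)
  ts$genus <- paste0("genus__", genus)
  ts$species <- species
  ts
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, "")
}

# confidence histogram from explicit tp/fp vectors (length 21)
make_hist <- function(tp, fp) {
  structure(data.frame(bin_lower = confidence_bins(), tp = tp, fp = fp),
            class = c("confidence_histogram", "data.frame"))
}

# Independent brute-force threshold oracle: evaluates the binomial tail
# probability of every bin by summing density terms, collects the
# failing bins, and applies the top-down scan rule on the full 21-bin
# vector. Kept deliberately separate from pick_threshold's
# implementation (explicit dbinom sum, vectorised failure mask).
oracle_pick_threshold <- function(hist, e, alpha = 0.05) {
  n <- hist$tp + hist$fp
  pvals <- rep(NA_real_, 21L)
  for (i in seq_len(21L)) {
    if (n[i] == 0L) next
    pvals[i] <- sum(stats::dbinom(0:hist$tp[i], n[i], 1 - e))
  }
  fails <- which(!is.na(pvals) & pvals <= alpha)
  if (length(fails) == 0L) return(0)
  top_fail <- max(fails)
  if (top_fail == 21L) return(Inf)
  hist$bin_lower[top_fail + 1L]
}

# Exact enumeration oracle for single-word bootstrap draws (n_draw = 1):
# the probability that each genus wins a trial, computed directly from
# the word-count formulas with equal tie splitting.
oracle_single_draw_shares <- function(train_seqs, train_genus, query,
                                      word_size = 8L) {
  words_per_seq <- lapply(train_seqs, sequence_words, word_size = word_size)
  N <- length(train_seqs)
  genera <- sort(unique(train_genus))
  M <- vapply(genera, function(g) sum(train_genus == g), 0L)
  qw <- sequence_words(query, word_size)
  shares <- stats::setNames(numeric(length(genera)), genera)
  for (w in qw) {
    n_w <- sum(vapply(words_per_seq, function(ws) w %in% ws, TRUE))
    P <- (n_w + 0.5) / (N + 1)
    logp <- vapply(seq_along(genera), function(gi) {
      m <- sum(vapply(which(train_genus == genera[gi]),
                      function(i) w %in% words_per_seq[[i]], TRUE))
      log((m + P) / (M[gi] + 1))
    }, 0)
    win <- which(logp >= max(logp) - 1e-12)
    shares[win] <- shares[win] + (1 / length(qw)) / length(win)
  }
  shares
}

# a tiny classification_set builder for coverage/combine tests
make_results <- function(n, genus, conf_genus,
                         family = NULL, conf_family = NULL,
                         phylum = "P1", conf_phylum = 100L,
                         class_ = NULL, conf_class = NULL,
                         order_ = NULL, conf_order = NULL,
                         failed = FALSE, ids = NULL) {
  df <- ampligauge:::empty_classification_set(n)
  df$query_id <- if (is.null(ids)) sprintf("q%03d", seq_len(n)) else ids
  pref <- function(r, x) ifelse(is.na(x), NA_character_,
                                paste0(r, "__", x))
  df$domain <- "domain__Bacteria"
  df$conf_domain <- 100L
  df$phylum <- pref("phylum", rep_len(phylum, n))
  df$conf_phylum <- rep_len(as.integer(conf_phylum), n)
  if (!is.null(class_)) {
    df$class <- pref("class", rep_len(class_, n))
    df$conf_class <- rep_len(as.integer(conf_class), n)
  }
  if (!is.null(order_)) {
    df$order <- pref("order", rep_len(order_, n))
    df$conf_order <- rep_len(as.integer(conf_order), n)
  }
  if (!is.null(family)) {
    df$family <- pref("family", rep_len(family, n))
    df$conf_family <- rep_len(as.integer(conf_family), n)
  }
  df$genus <- pref("genus", rep_len(genus, n))
  df$conf_genus <- rep_len(as.integer(conf_genus), n)
  df$failed <- rep_len(failed, n)
  df
}
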