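# Word-based naive Bayesian taxonomic classifier (RDP-style), with
# bootstrap confidence values. Genus is the unit of assignment; coarser
# ranks inherit confidence as the share of bootstrap trials whose winning
# genus lies under the taxon.

#' Distinct valid words of a sequence
#'
#' Words are overlapping k-mers over `{A,C,G,T}` (U is treated as T);
#' words containing any other character — including the `N` spacer of a
#' fused paired read — are skipped. Only distinct words are returned.
#'
#' @param sequence A single sequence string.
#' @param word_size Word length (default 8).
#' @return Character vector of distinct valid words (possibly empty).
#' @export
sequence_words <- function(sequence, word_size = 8L) {
  s <- chartr("u", "t", tolower(sequence))
  n <- nchar(s)
  if (n < word_size) return(character(0))
  starts <- seq_len(n - word_size + 1L)
  w <- substring(s, starts, starts + word_size - 1L)
  unique(w[grepl("^[acgt]+$", w)])
}

# restore-on-exit seeded RNG scope
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# deterministic 31-bit seed from a base seed and a string key
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(as.character(key))) h <- (h * 31 + b) %% m
  as.integer((h + (as.numeric(seed) %% m) * 2654435) %% m)
}

#' Train the word model of the naive Bayesian classifier
#'
#' Word priors are `P(w) = (n(w) + 0.5) / (N + 1)` where `n(w)` counts
#' training sequences containing the word and `N` is the number of
#' training sequences; genus conditionals are
#' `p(w|G) = (m(w) + P(w)) / (M + 1)` with `m(w)` the count of genus-`G`
#' sequences containing `w` and `M` the genus size.
#'
#' @param ts A [training_set()] with sequences attached and a genus for
#'   every record.
#' @param word_size Word length (default 8).
#' @return A `word_model` object.
#' @export
train_classifier <- function(ts, word_size = 8L) {
  if (anyNA(ts$genus)) {
    stop("every training record needs a genus; missing for: ",
         paste(utils::head(ts$id[is.na(ts$genus)], 5L), collapse = ", "))
  }
  short <- nchar(ts$sequence) < word_size
  if (any(short)) {
    stop("sequence shorter than word size: ",
         paste(utils::head(ts$id[short], 5L), collapse = ", "))
  }
  words_list <- lapply(ts$sequence, sequence_words, word_size = word_size)
  build_word_model(words_list, ts, word_size)
}

# Build a model from precomputed per-sequence distinct-word lists.
# Separated from train_classifier so leave-k-out can rebuild models for
# many training subsets without re-extracting words. The per-genus word
# counts m(w, G) are held sparsely: where m = 0 the log conditional
# numerator defaults to log(P(w)), so only genera actually containing a
# word need storage.
build_word_model <- function(words_list, ts, word_size) {
  genera <- sort(unique(ts$genus))
  gi <- match(ts$genus, genera)
  N <- length(words_list)
  G <- length(genera)
  all_w <- unlist(words_list, use.names = FALSE)
  words <- sort(unique(all_w))
  wi <- match(all_w, words)
  n_w <- tabulate(wi, nbins = length(words))
  M <- tabulate(gi, nbins = G)
  P <- (n_w + 0.5) / (N + 1)
  # aggregate m(w, G) over (word, genus) pairs, then index by word
  key <- (wi - 1) * G + rep.int(gi, lengths(words_list))
  agg <- sort(unique(key))
  m_pair <- tabulate(match(key, agg), nbins = length(agg))
  pair_w <- (agg - 1) %/% G + 1
  pair_g <- (agg - 1) %% G + 1
  ord <- seq_along(agg)  # agg sorted => grouped by word already
  entries <- vector("list", length(words))
  grp <- split(ord, pair_w)
  for (k in names(grp)) {
    idx <- grp[[k]]
    w <- as.integer(k)
    entries[[w]] <- list(g = pair_g[idx],
                         logmp = log(m_pair[idx] + P[w]))
  }
  lineages <- unique(as.data.frame(ts)[, lineage_cols(), drop = FALSE])
  lineages <- lineages[match(genera, lineages$genus), , drop = FALSE]
  rownames(lineages) <- NULL
  structure(
    list(word_size = as.integer(word_size), words = words,
         n_w = n_w, N = N, M = M, P = P, entries = entries,
         genera = genera, lineages = lineages,
         logM1 = log(M + 1), log_unseen = log(0.5 / (N + 1))),
    class = "word_model"
  )
}

#' Word conditional probability under a trained model
#'
#' Returns `p(w|G) = (m(w) + P(w)) / (M + 1)` for a word and genus.
#'
#' @param model A `word_model`.
#' @param word A word string (lower case, length `word_size`).
#' @param genus A prefixed genus name present in the model.
#' @return The conditional probability.
#' @export
word_conditional <- function(model, word, genus) {
  gi <- match(genus, model$genera)
  if (is.na(gi)) stop("unknown genus: ", genus)
  wi <- match(word, model$words)
  num <- if (is.na(wi)) {
    0.5 / (model$N + 1)
  } else {
    ent <- model$entries[[wi]]
    hit <- match(gi, ent$g)
    if (is.na(hit)) model$P[wi] else exp(ent$logmp[hit])
  }
  num / (model$M[gi] + 1)
}

#' @export
print.word_model <- function(x, ...) {
  cat("word_model: N =", x$N, "sequences,", length(x$genera),
      "genera,", length(x$words), "distinct", x$word_size, "nt words\n")
  invisible(x)
}

argmax_random_tie <- function(score) {
  mx <- max(score)
  cand <- which(score >= mx - 1e-9)
  if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
}

#' Classify a single read
#'
#' The point assignment is the genus maximizing the sum of log word
#' conditionals over the read's distinct valid words. Each bootstrap
#' trial redraws `max(1, floor(W/8))` of the `W` words uniformly with
#' replacement and recomputes the winner; the confidence attached to each
#' taxon on the point-assignment lineage is the rounded percentage of
#' trials whose winning genus lies under that taxon. Ties are broken
#' uniformly at random under the seeded stream.
#'
#' @param sequence The read sequence.
#' @param model A `word_model` from [train_classifier()].
#' @param bootstrap Number of bootstrap iterations.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A list: `failed` (no valid words), `genus`, `lineage` and
#'   `confidence` (named by rank, `NA` where the hierarchy omits the
#'   rank), and `tally` (per-genus trial counts).
#' @export
classify_read <- function(sequence, model, bootstrap = 100L, seed = NULL) {
  wq <- sequence_words(sequence, model$word_size)
  W <- length(wq)
  G <- length(model$genera)
  if (W == 0L) {
    return(list(failed = TRUE, genus = NA_character_,
                lineage = rep(NA_character_, 6L),
                confidence = rep(NA_integer_, 6L), tally = integer(G)))
  }
  rows <- match(wq, model$words)
  L <- matrix(model$log_unseen, nrow = W, ncol = G)
  for (r in seq_len(W)) {
    if (is.na(rows[r])) next
    L[r, ] <- log(model$P[rows[r]])
    ent <- model$entries[[rows[r]]]
    L[r, ent$g] <- ent$logmp
  }
  with_rng_seed(seed, {
    point <- argmax_random_tie(.colSums(L, W, G) - W * model$logM1)
    n_draw <- max(1L, W %/% 8L)
    tally <- integer(G)
    base <- n_draw * model$logM1
    for (i in seq_len(bootstrap)) {
      s <- sample.int(W, n_draw, replace = TRUE)
      win <- argmax_random_tie(.colSums(L[s, , drop = FALSE], n_draw, G) -
                                 base)
      tally[win] <- tally[win] + 1L
    }
  })
  lin <- unlist(model$lineages[point, ], use.names = FALSE)
  names(lin) <- lineage_cols()
  conf <- rep(NA_integer_, 6L)
  names(conf) <- lineage_cols()
  for (r in seq_along(lin)) {
    if (is.na(lin[r])) next
    under <- !is.na(model$lineages[[r]]) & model$lineages[[r]] == lin[r]
    # round half up: thresholds are integer percentages
    conf[r] <- as.integer(floor(100 * sum(tally[under]) / bootstrap + 0.5))
  }
  list(failed = FALSE, genus = model$genera[point], lineage = lin,
       confidence = conf, tally = tally)
}

empty_classification_set <- function(n = 0L) {
  df <- data.frame(query_id = character(n), stringsAsFactors = FALSE)
  for (r in lineage_cols()) {
    df[[r]] <- rep(NA_character_, n)
    df[[paste0("conf_", r)]] <- rep(NA_integer_, n)
  }
  df$failed <- rep(FALSE, n)
  class(df) <- c("classification_set", "data.frame")
  df
}

#' Classify a batch of reads
#'
#' Deterministic given `seed`: each read's bootstrap stream is seeded from
#' the base seed and the read ID, so a permuted input yields the permuted
#' identical output and parallel execution is order-stable. Reads with no
#' valid words are recorded as failures, not errors.
#'
#' @param reads A `sim_reads` data frame (or any data frame with `id` and
#'   `sequence` columns).
#' @param model A `word_model`.
#' @param bootstrap Number of bootstrap iterations per read.
#' @param seed Integer base seed.
#' @return A `classification_set` data frame: `query_id`, per-rank taxon
#'   and `conf_<rank>` columns, and a `failed` flag.
#' @export
classify_batch <- function(reads, model, bootstrap = 100L, seed = 1L) {
  n <- nrow(reads)
  out <- empty_classification_set(n)
  out$query_id <- reads$id
  for (i in seq_len(n)) {
    res <- classify_read(reads$sequence[i], model, bootstrap,
                         seed = derive_seed(seed, reads$id[i]))
    out$failed[i] <- res$failed
    if (res$failed) next
    for (r in lineage_cols()) {
      out[[r]][i] <- res$lineage[[r]]
      out[[paste0("conf_", r)]][i] <- res$confidence[[r]]
    }
  }
  out
}

#' Write a classification set as TSV
#'
#' @param results A `classification_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a classification set written by [write_classifications()]
#'
#' @param path Input path.
#' @return A `classification_set`.
#' @export
read_classifications <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  for (r in lineage_cols()) {
    cc <- paste0("conf_", r)
    df[[cc]] <- suppressWarnings(as.integer(df[[cc]]))
    df[[r]][df[[r]] == "NA" | df[[r]] == ""] <- NA_character_
  }
  df$failed <- as.logical(df$failed)
  class(df) <- c("classification_set", "data.frame")
  df
}
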