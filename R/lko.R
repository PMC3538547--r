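# Leave-k-out precision experiments: every training sequence of the test
# sequence's species is removed before classification, with redundancy
# removal that keeps identical sequences only when they belong to
# different genera.

#' Relate test sequences to same-species training sequences
#'
#' @param test,train [training_set()]s carrying species annotations
#'   (every test record must have one).
#' @return An `exclusion_table`: list with `rows` (named list, test ID ->
#'   character vector of same-species training IDs) and
#'   `absent_species_ids` (test IDs whose species has no training
#'   sequence). Matching is exact on the normalized species name.
#' @export
build_exclusion_table <- function(test, train) {
  if (anyNA(test$species)) {
    stop("test record lacks species annotation: ",
         paste(utils::head(test$id[is.na(test$species)], 5L),
               collapse = ", "))
  }
  by_species <- split(train$id, train$species)
  hit <- test$species %in% names(by_species)
  rows <- stats::setNames(by_species[test$species[hit]], test$id[hit])
  structure(list(rows = rows, absent_species_ids = test$id[!hit]),
            class = "exclusion_table")
}

#' @export
print.exclusion_table <- function(x, ...) {
  cat("exclusion_table:", length(x$rows), "test sequences with",
      "same-species training sequences;", length(x$absent_species_ids),
      "with absent species\n")
  invisible(x)
}

#' Cluster training sequences at 100% identity
#'
#' Identity counts every mismatch and gap as a difference, so clusters
#' are exact string-equality classes of the (region-trimmed) sequences.
#'
#' @param train A [training_set()] whose sequences are already trimmed to
#'   the evaluation region.
#' @return A `redundancy_clusters` object: list of character vectors of
#'   member IDs, in order of first appearance.
#' @export
cluster_identical <- function(train) {
  cl <- split(train$id, factor(train$sequence,
                               levels = unique(train$sequence)))
  structure(unname(cl), class = "redundancy_clusters")
}

#' Build a genus-preserving non-redundant training set
#'
#' Within each cluster of identical sequences, exactly one representative
#' is retained per genus (two identical sequences survive only if they
#' belong to different genera). The representative is the first member in
#' input order. Members absent from `train` (e.g. excluded same-species
#' sequences) are ignored, so another sequence of the same genus takes
#' the representative slot when the usual representative was excluded.
#'
#' @param train A [training_set()] (possibly with rows removed).
#' @param clusters A `redundancy_clusters` built on the full set.
#' @return The non-redundant [training_set()].
#' @export
build_nonredundant_set <- function(train, clusters) {
  keep_ids <- unlist(lapply(clusters, function(members) {
    idx <- match(members, train$id)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(character(0))
    g <- train$genus[idx]
    train$id[idx[!duplicated(g)]]
  }), use.names = FALSE)
  out <- train[train$id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "region_label") <- attr(train, "region_label")
  class(out) <- class(train)
  out
}

#' Leave-k-out configuration
#'
#' @param bootstrap Bootstrap iterations per classification.
#' @param repeats Number of repeats of the whole test (repeats differ
#'   only in bootstrap seeds).
#' @param seed Integer base seed.
#' @param word_size Classifier word length.
#' @return An `lko_config` list.
#' @export
lko_config <- function(bootstrap = 100L, repeats = 1L, seed = 1L,
                       word_size = 8L) {
  if (repeats < 1L) stop("repeats must be >= 1")
  list(bootstrap = as.integer(bootstrap), repeats = as.integer(repeats),
       seed = as.integer(seed), word_size = as.integer(word_size))
}

#' Run species-exclusion leave-k-out classification tests
#'
#' Test sequences whose species is absent from the training set are
#' classified against the original non-redundant training set. Every
#' other test sequence is classified against a non-redundant set rebuilt,
#' from the precomputed identity clusters, after removing all
#' same-species sequences from the full training set — so a genus's other
#' species re-enter the representative slot when an excluded sequence was
#' the cluster representative. Repeats rerun the classification with
#' fresh bootstrap seeds only.
#'
#' @param test A [training_set()] whose `sequence` column holds the read
#'   strings to classify; species annotations required.
#' @param train The full [training_set()] (sequences trimmed to the
#'   training region); species and genus required.
#' @param cfg An [lko_config()].
#' @param clusters Optional precomputed [cluster_identical()] result.
#' @return An `lko_run`: list with `results` (long data frame: `rep`,
#'   `test_id`, `ref_<rank>`, predicted `<rank>` and `conf_<rank>`
#'   columns, `failed`), `config`, `exclusion`, and `training_ids` (the
#'   training IDs used for each species batch, for auditing).
#' @export
run_lko <- function(test, train, cfg = lko_config(), clusters = NULL) {
  excl <- build_exclusion_table(test, train)
  if (is.null(clusters)) clusters <- cluster_identical(train)
  train_g <- trim_to_genus(train)
  words_list <- lapply(train_g$sequence, sequence_words,
                       word_size = cfg$word_size)
  names(words_list) <- train_g$id

  subset_model <- function(ids) {
    sub <- train_g[match(ids, train_g$id), , drop = FALSE]
    build_word_model(words_list[ids], sub, cfg$word_size)
  }

  orig_nr <- build_nonredundant_set(train_g, clusters)
  batches <- list()
  if (length(excl$absent_species_ids)) {
    batches[["..absent.."]] <- list(test_ids = excl$absent_species_ids,
                                    train_ids = orig_nr$id)
  }
  # exclusion sets are a species-level property: group test sequences by
  # species so each reduced training set is built and trained once
  sp_of_test <- test$species[match(names(excl$rows), test$id)]
  for (sp in unique(sp_of_test)) {
    tids <- names(excl$rows)[sp_of_test == sp]
    drop_ids <- unique(unlist(excl$rows[tids], use.names = FALSE))
    reduced <- train_g[!(train_g$id %in% drop_ids), , drop = FALSE]
    nr <- build_nonredundant_set(reduced, clusters)
    batches[[sp]] <- list(test_ids = tids, train_ids = nr$id)
  }

  ref_cols <- paste0("ref_", lineage_cols())
  res_list <- vector("list", length(batches) * cfg$repeats)
  k <- 0L
  for (b in names(batches)) {
    bt <- batches[[b]]
    model <- subset_model(bt$train_ids)
    reads <- data.frame(id = bt$test_ids,
                        sequence = test$sequence[match(bt$test_ids,
                                                       test$id)],
                        stringsAsFactors = FALSE)
    for (r in seq_len(cfg$repeats)) {
      rep_seed <- derive_seed(cfg$seed, paste0("repeat:", r))
      cls <- classify_batch(reads, model, bootstrap = cfg$bootstrap,
                            seed = rep_seed)
      ref <- as.data.frame(test)[match(bt$test_ids, test$id),
                                 lineage_cols(), drop = FALSE]
      names(ref) <- ref_cols
      k <- k + 1L
      res_list[[k]] <- cbind(
        data.frame(rep = r, test_id = bt$test_ids,
                   stringsAsFactors = FALSE),
        ref,
        as.data.frame(cls)[, c(rbind(lineage_cols(),
                                     paste0("conf_", lineage_cols()))),
                           drop = FALSE],
        data.frame(failed = cls$failed)
      )
    }
  }
  results <- do.call(rbind, res_list[seq_len(k)])
  results <- results[order(results$rep, match(results$test_id, test$id)), ,
                     drop = FALSE]
  rownames(results) <- NULL
  structure(
    list(results = results, config = cfg, exclusion = excl,
         training_ids = lapply(batches, `[[`, "train_ids")),
    class = "lko_run"
  )
}

#' @export
print.lko_run <- function(x, ...) {
  cat("lko_run:", length(unique(x$results$test_id)), "test sequences x",
      x$config$repeats, "repeats\n")
  invisible(x)
}

#' Write the long results table of a leave-k-out run as TSV
#'
#' @param run An `lko_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lko_results <- function(run, path) {
  utils::write.table(run$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
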