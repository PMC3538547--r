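# Merging classifications of two regions of the same molecule.

#' Combine classifications from two gene regions
#'
#' For every query classified in both regions, the comparison rank R is
#' the highest-resolution rank predicted by both classifications (in
#' well-sampled data this is usually genus). The entire taxonomic path
#' of the prediction with the higher confidence at R is copied to the
#' combined result; queries with equal confidence but different taxa at
#' R are discarded, as are pairs sharing no predicted rank. Queries
#' present in only one input (covering only one region) are skipped. An
#' equal-confidence tie on the same taxon keeps region A's path.
#'
#' @param resA,resB `classification_set`s for regions A and B.
#' @return A `combined_set` data frame: `query_id`, `status`
#'   (`combined` / `discarded` / `skipped`), `chosen_source` (`A`/`B`),
#'   `rank_used`, `reason`, and the merged per-rank taxon and
#'   `conf_<rank>` columns (the winner's full path, byte-identical).
#' @export
combine_predictions <- function(resA, resB) {
  all_ids <- union(resA$query_id, resB$query_id)
  out <- empty_classification_set(length(all_ids))
  out$query_id <- all_ids
  out$status <- "skipped"
  out$chosen_source <- NA_character_
  out$rank_used <- NA_character_
  out$reason <- "single_region"
  out$failed <- NULL
  ia <- match(all_ids, resA$query_id)
  ib <- match(all_ids, resB$query_id)
  for (k in seq_along(all_ids)) {
    if (is.na(ia[k]) || is.na(ib[k])) next
    a <- resA[ia[k], ]
    b <- resB[ib[k], ]
    both <- vapply(lineage_cols(), function(r) {
      !isTRUE(a$failed) && !isTRUE(b$failed) &&
        !is.na(a[[r]]) && !is.na(b[[r]])
    }, logical(1L))
    if (!any(both)) {
      out$status[k] <- "discarded"
      out$reason[k] <- "no_common_rank"
      next
    }
    R <- lineage_cols()[max(which(both))]
    ca <- a[[paste0("conf_", R)]]
    cb <- b[[paste0("conf_", R)]]
    if (ca == cb && a[[R]] != b[[R]]) {
      out$status[k] <- "discarded"
      out$reason[k] <- "equal_confidence_conflict"
      out$rank_used[k] <- R
      next
    }
    src <- if (cb > ca) "B" else "A"
    win <- if (src == "A") a else b
    for (r in lineage_cols()) {
      out[[r]][k] <- win[[r]]
      out[[paste0("conf_", r)]][k] <- win[[paste0("conf_", r)]]
    }
    out$status[k] <- "combined"
    out$chosen_source[k] <- src
    out$rank_used[k] <- R
    out$reason[k] <- ""
  }
  class(out) <- c("combined_set", "data.frame")
  out
}

#' Discard fraction of a combined classification set
#'
#' @param combined A [combine_predictions()] result.
#' @return Fraction of two-region queries that were discarded.
#' @export
combine_discard_fraction <- function(combined) {
  considered <- combined$status %in% c("combined", "discarded")
  if (!any(considered)) return(0)
  sum(combined$status == "discarded") / sum(considered)
}
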