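#' Taxonomic ranks used throughout the package
#'
#' The six primary ranks, ordered from coarsest to finest. Species is
#' deliberately not a rank here: it is metadata used only for building
#' leave-k-out exclusion tables.
#'
#' @return Character vector `c("domain", "phylum", "class", "order",
#'   "family", "genus")`.
#' @export
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}

#' Depth of a rank (domain = 0 ... genus = 5)
#'
#' @param rank Character vector of rank names.
#' @return Integer vector of depths.
#' @export
rank_depth <- function(rank) {
  d <- match(rank, tax_ranks()) - 1L
  if (anyNA(d)) {
    stop("unknown rank(s): ", paste(rank[is.na(d)], collapse = ", "))
  }
  d
}

# columns of a training-set data frame that hold the ranked lineage
lineage_cols <- function() tax_ranks()

rank_of_prefixed <- function(x) {
  sub("__.*$", "", x)
}

strip_rank_prefix <- function(x) {
  sub("^[a-z]+__", "", x)
}

#' Normalize a raw lineage into a ranked, prefixed lineage
#'
#' Drops path components that begin with `"unclassified"` (case-insensitive)
#' or end with `"incertae_sedis"`, then prefixes every surviving taxon name
#' with its rank (`"<rank>__"`). The operation is idempotent: already
#' prefixed names are not prefixed twice. Identical names at different
#' ranks (e.g. a phylum and a class sharing a name) remain distinguishable
#' through their prefixes.
#'
#' @param names Character vector of taxon names, ordered coarse to fine.
#' @param ranks Character vector of rank names, one per entry of `names`.
#'   If `NULL`, ranks are inferred from existing `"<rank>__"` prefixes.
#' @return Named character vector of prefixed taxon names; names of the
#'   vector are the ranks. Dropped components are absent.
#' @examples
#' normalize_lineage(c("Bacteria", "unclassified_Bacteria", "G1"),
#'                   c("domain", "phylum", "genus"))
#' @export
normalize_lineage <- function(names, ranks = NULL) {
  if (length(names) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  if (any(!nzchar(names))) stop("empty taxon name in lineage")
  if (is.null(ranks)) {
    ranks <- rank_of_prefixed(names)
    bad <- !(ranks %in% tax_ranks())
    if (any(bad)) {
      stop("cannot infer rank for component(s) without a rank prefix: ",
           paste(names[bad], collapse = ", "))
    }
  }
  if (length(ranks) != length(names)) {
    stop("`names` and `ranks` must have equal length")
  }
  bare <- strip_rank_prefix(names)
  drop <- grepl("^unclassified", bare, ignore.case = TRUE) |
    grepl("incertae_sedis$", bare)
  bare <- bare[!drop]
  ranks <- ranks[!drop]
  if (anyDuplicated(ranks)) {
    stop("two lineage components claim the same rank: ",
         paste(ranks[duplicated(ranks)], collapse = ", "))
  }
  depth <- rank_depth(ranks)
  if (is.unsorted(depth, strictly = TRUE)) {
    stop("lineage ranks must strictly increase in depth")
  }
  stats::setNames(paste0(ranks, "__", bare), ranks)
}

#' Construct an empty training set
#'
#' A training set is a data frame with one row per reference sequence:
#' columns `id`, `sequence` (possibly `NA` before sequences are attached),
#' one column per rank holding the prefixed taxon name (`NA` where the
#' hierarchy omits the rank), and `species` (unprefixed, `NA` if unknown).
#'
#' @param n Number of rows to allocate.
#' @param region_label Free-text label of the gene region the sequences
#'   cover.
#' @return A `training_set` data frame.
#' @export
training_set <- function(n = 0L, region_label = "") {
  df <- data.frame(
    id = character(n), sequence = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  for (r in lineage_cols()) df[[r]] <- rep(NA_character_, n)
  df$species <- rep(NA_character_, n)
  attr(df, "region_label") <- region_label
  class(df) <- c("training_set", "data.frame")
  df
}

as_training_set <- function(df, region_label = "") {
  stopifnot(all(c("id", lineage_cols()) %in% names(df)))
  if (is.null(df$sequence)) df$sequence <- NA_character_
  if (is.null(df$species)) df$species <- NA_character_
  df <- df[, c("id", "sequence", lineage_cols(), "species")]
  rownames(df) <- NULL
  attr(df, "region_label") <- region_label
  class(df) <- c("training_set", "data.frame")
  df
}

#' Configuration for reading a taxonomy table
#'
#' @param style `"prefixed"` if lineage components carry `"<rank>__"`
#'   prefixes (species as `"species__<name>"`), or `"positional"` if
#'   components map onto `ranks` by position.
#' @param ranks For the positional style, the rank of each component in
#'   order; may end with `"species"` to capture a species column.
#' @param subspecies_pattern Regular expression removed from the end of
#'   species names (subspecies designations); set `NULL` to keep them.
#' @return A dialect description list.
#' @export
taxonomy_dialect <- function(style = c("prefixed", "positional"),
                             ranks = c(tax_ranks(), "species"),
                             subspecies_pattern = "\\s+subsp\\..*$") {
  style <- match.arg(style)
  if (style == "positional") {
    known <- c(tax_ranks(), "species")
    if (!all(ranks %in% known) || anyDuplicated(ranks)) {
      stop("positional dialect ranks must be distinct rank names")
    }
  }
  list(style = style, ranks = ranks, subspecies_pattern = subspecies_pattern)
}

normalize_species <- function(species, pattern) {
  if (!is.null(pattern)) species <- sub(pattern, "", species)
  species
}

#' Parse a taxonomy table into a training set (lineages only)
#'
#' Reads the tab-separated `"seqID<TAB>taxon1;taxon2;...;"` dialect used
#' by amplicon classifiers (a trailing semicolon is allowed). Lineages are
#' normalized (see [normalize_lineage()]): unclassified / incertae sedis
#' components are dropped and names are rank-prefixed. Sequences are
#' attached separately with [attach_sequences()].
#'
#' @param path Path to the taxonomy file.
#' @param dialect A [taxonomy_dialect()].
#' @return A [training_set()] with `sequence` columns `NA`.
#' @export
parse_taxonomy_table <- function(path, dialect = taxonomy_dialect()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ts <- training_set(length(lines))
  if (length(lines) == 0L) return(ts)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stop("malformed taxonomy line ", which(nf != 2L)[1L],
         ": expected 'id<TAB>lineage'")
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ID in taxonomy table: ",
         ids[duplicated(ids)][1L])
  }
  ts$id <- ids
  for (i in seq_along(lines)) {
    comp <- strsplit(parts[[i]][2L], ";", fixed = TRUE)[[1L]]
    comp <- comp[nzchar(comp)]
    res <- tryCatch(
      parse_lineage_components(comp, dialect),
      error = function(e) {
        stop("malformed taxonomy line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    for (r in names(res$lineage)) ts[[r]][i] <- res$lineage[[r]]
    ts$species[i] <- res$species
  }
  ts
}

parse_lineage_components <- function(comp, dialect) {
  species <- NA_character_
  if (dialect$style == "prefixed") {
    ranks <- rank_of_prefixed(comp)
    is_sp <- ranks == "species"
    if (any(is_sp)) {
      species <- strip_rank_prefix(comp[is_sp][1L])
      comp <- comp[!is_sp]
      ranks <- ranks[!is_sp]
    }
    lin <- normalize_lineage(comp)
  } else {
    if (length(comp) > length(dialect$ranks)) {
      stop("more lineage components (", length(comp),
           ") than positional ranks (", length(dialect$ranks), ")")
    }
    ranks <- dialect$ranks[seq_along(comp)]
    is_sp <- ranks == "species"
    if (any(is_sp)) {
      species <- comp[is_sp][1L]
      comp <- comp[!is_sp]
      ranks <- ranks[!is_sp]
    }
    lin <- normalize_lineage(comp, ranks)
  }
  species <- normalize_species(species, dialect$subspecies_pattern)
  list(lineage = lin, species = species)
}

#' Write a training set's taxonomy in the canonical prefixed dialect
#'
#' Inverse of [parse_taxonomy_table()] for the prefixed dialect:
#' `id<TAB>domain__...;...;genus__...;species__...;` with a trailing
#' semicolon. Writing then re-parsing reproduces the file byte for byte.
#'
#' @param ts A [training_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(ts, path) {
  lin <- vapply(seq_len(nrow(ts)), function(i) {
    comp <- unlist(ts[i, lineage_cols()], use.names = FALSE)
    comp <- comp[!is.na(comp)]
    if (!is.na(ts$species[i])) {
      comp <- c(comp, paste0("species__", ts$species[i]))
    }
    paste0(paste0(comp, ";", collapse = ""), "")
  }, "")
  writeLines(paste0(ts$id, "\t", lin), path)
  invisible(path)
}

#' Attach sequences from a FASTA file or named vector to a training set
#'
#' @param ts A [training_set()].
#' @param sequences A named character vector of sequences, or a path to a
#'   plain FASTA file.
#' @return The training set with its `sequence` column filled.
#' @export
attach_sequences <- function(ts, sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    ss <- Biostrings::readBStringSet(sequences)
    sequences <- stats::setNames(as.character(ss), names(ss))
  }
  idx <- match(ts$id, names(sequences))
  if (anyNA(idx)) {
    stop("no sequence for ID(s): ",
         paste(utils::head(ts$id[is.na(idx)], 5L), collapse = ", "))
  }
  ts$sequence <- toupper(unname(sequences[idx]))
  ts
}

#' Trim a training set's taxonomy to the genus level
#'
#' Removes species information from the lineage (entries deeper than genus
#' do not exist in this representation, so this clears the `species`
#' field). Species annotations used for leave-k-out exclusion must be taken
#' from the untrimmed set.
#'
#' @param ts A [training_set()] (or a named lineage vector, returned
#'   unchanged since lineages never extend past genus).
#' @return The genus-trimmed object.
#' @export
trim_to_genus <- function(ts) {
  if (is.data.frame(ts)) {
    ts$species <- NA_character_
    return(ts)
  }
  ts[names(ts) %in% tax_ranks()]
}

#' Build a taxonomy tree from a set of lineages
#'
#' The tree is stored as the set of distinct root-to-terminal paths; gaps
#' (omitted ranks) are preserved as `NA` entries.
#'
#' @param ts A [training_set()] or a data frame with the rank columns.
#' @return A `taxonomy_tree` object.
#' @export
taxonomy_tree <- function(ts) {
  paths <- unique(as.data.frame(ts)[, lineage_cols(), drop = FALSE])
  rownames(paths) <- NULL
  structure(list(paths = paths), class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree with", nrow(x$paths), "distinct paths\n")
  invisible(x)
}

#' Ranks that can never be predicted under a taxon
#'
#' Given a node of the hierarchy, returns the set of ranks deeper than the
#' node that appear on no path passing through it — the ranks for which any
#' sequence classified at or under this node can receive no prediction.
#' A phylum with no child taxa omits class through genus; a class whose
#' children are genera omits order and family.
#'
#' @param tree A [taxonomy_tree()].
#' @param taxon A prefixed taxon name (e.g. `"phylum__Acidobacteria"`).
#' @return Character vector of omitted rank names (possibly empty).
#' @export
ranks_omitted_below <- function(tree, taxon) {
  rank <- rank_of_prefixed(taxon)
  if (!(rank %in% tax_ranks())) stop("taxon must carry a rank prefix")
  hit <- tree$paths[[rank]] == taxon & !is.na(tree$paths[[rank]])
  if (!any(hit)) stop("unknown taxon: ", taxon)
  deeper <- tax_ranks()[rank_depth(tax_ranks()) > rank_depth(rank)]
  omitted <- vapply(deeper, function(r) {
    all(is.na(tree$paths[[r]][hit]))
  }, logical(1L))
  deeper[omitted]
}
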