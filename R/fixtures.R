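# Synthetic taxonomy / alignment / query generator. Gives every stage of
# the framework a self-contained test surface with controlled
# between-genus divergence, designed confusable genus pairs, hierarchy
# gaps, and alignment indels. The substitution process is a per-site
# uniform random replacement (Jukes-Cantor-like) — adequate for
# exercising word-based classification, not a biological model.

#' Specification of a synthetic benchmark data set
#'
#' @param n_phyla,classes_per_phylum,orders_per_class,families_per_order,genera_per_family,species_per_genus,seqs_per_species
#'   Balanced-tree fan-outs (all >= 1).
#' @param seq_len Ungapped root sequence length in bases (default 250,
#'   the scale of a short hypervariable-region amplicon).
#' @param between_genus_divergence Per-site substitution probability on
#'   the branch leading to each genus (default 0.10).
#' @param between_species_divergence Per-site substitution probability
#'   from genus to species (default 0.03).
#' @param within_species_divergence Per-site substitution probability
#'   from species to individual sequence (default 0.005).
#' @param confusable_pairs Data frame with columns `g1`, `g2` (genus
#'   indices) and `q`: genus `g2` is generated from genus `g1`'s
#'   sequence at divergence `q` instead of from the family ancestor,
#'   creating a designed confusability.
#' @param gap_lineage_fraction Fraction of genera attached directly
#'   under their class, omitting the order and family ranks (hierarchy
#'   gaps; default 0.1).
#' @param indel_rate Expected insertion events per root position
#'   (default 0.01); each event adds an alignment column carried by one
#'   genus clade.
#' @param seed Integer seed; all generator output is deterministic
#'   given the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_phyla = 2L, classes_per_phylum = 2L,
                         orders_per_class = 1L, families_per_order = 2L,
                         genera_per_family = 3L, species_per_genus = 2L,
                         seqs_per_species = 2L, seq_len = 250L,
                         between_genus_divergence = 0.10,
                         between_species_divergence = 0.03,
                         within_species_divergence = 0.005,
                         confusable_pairs = NULL,
                         gap_lineage_fraction = 0.1,
                         indel_rate = 0.01, seed = 1L) {
  counts <- c(n_phyla, classes_per_phylum, orders_per_class,
              families_per_order, genera_per_family, species_per_genus,
              seqs_per_species)
  if (any(counts < 1L)) stop("all fan-out counts must be >= 1")
  probs <- c(between_genus_divergence, between_species_divergence,
             within_species_divergence, gap_lineage_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (seq_len < 1L) stop("seq_len must be >= 1")
  structure(
    list(n_phyla = as.integer(n_phyla),
         classes_per_phylum = as.integer(classes_per_phylum),
         orders_per_class = as.integer(orders_per_class),
         families_per_order = as.integer(families_per_order),
         genera_per_family = as.integer(genera_per_family),
         species_per_genus = as.integer(species_per_genus),
         seqs_per_species = as.integer(seqs_per_species),
         seq_len = as.integer(seq_len),
         between_genus_divergence = between_genus_divergence,
         between_species_divergence = between_species_divergence,
         within_species_divergence = within_species_divergence,
         confusable_pairs = confusable_pairs,
         gap_lineage_fraction = gap_lineage_fraction,
         indel_rate = indel_rate, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate the balanced taxonomy of a fixture spec
#'
#' Builds a balanced hierarchy with the spec's fan-outs; a
#' `gap_lineage_fraction` of genera (chosen under the spec seed) are
#' attached directly under their class, omitting order and family.
#'
#' @param spec A [fixture_spec()].
#' @return A `fixture_taxonomy`: data frame with one row per genus
#'   (prefixed rank columns, `genus_index`) plus attribute `"species"`,
#'   a data frame of species names per genus.
#' @export
gen_taxonomy <- function(spec) {
  rows <- list()
  g <- 0L
  for (p in seq_len(spec$n_phyla)) {
    for (cl in seq_len(spec$classes_per_phylum)) {
      for (o in seq_len(spec$orders_per_class)) {
        for (f in seq_len(spec$families_per_order)) {
          for (gn in seq_len(spec$genera_per_family)) {
            g <- g + 1L
            rows[[g]] <- data.frame(
              domain = "domain__Bacteria",
              phylum = sprintf("phylum__P%d", p),
              class = sprintf("class__C%d.%d", p, cl),
              order = sprintf("order__O%d.%d.%d", p, cl, o),
              family = sprintf("family__F%d.%d.%d.%d", p, cl, o, f),
              genus = sprintf("genus__G%03d", g),
              genus_index = g, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  tax <- do.call(rbind, rows)
  n_gap <- round(spec$gap_lineage_fraction * nrow(tax))
  gap_idx <- with_rng_seed(derive_seed(spec$seed, "gaps"),
                           sample.int(nrow(tax), n_gap))
  tax$order[gap_idx] <- NA_character_
  tax$family[gap_idx] <- NA_character_
  species <- do.call(rbind, lapply(seq_len(nrow(tax)), function(i) {
    data.frame(genus_index = i,
               species = sprintf("G%03d_sp%d", i,
                                 seq_len(spec$species_per_genus)),
               stringsAsFactors = FALSE)
  }))
  structure(tax, species = species,
            class = c("fixture_taxonomy", "data.frame"))
}

mutate_seq <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  n <- sum(hit)
  if (n) {
    # replace with one of the three other bases
    shift <- sample.int(3L, n, replace = TRUE)
    cur <- match(chars[hit], c("A", "C", "G", "T"))
    chars[hit] <- c("A", "C", "G", "T")[(cur - 1L + shift) %% 4L + 1L]
  }
  chars
}

#' Generate the aligned sequences of a fixture
#'
#' A random root sequence is mutated down the taxonomy: moderate
#' divergence accumulates at each rank above genus, each genus diverges
#' from its family ancestor at the spec's between-genus rate (confusable
#' pairs instead share the partner genus's sequence at divergence `q`),
#' species and individual sequences add the finer-scale rates. Insertion
#' events add alignment columns carried by one genus clade each; all
#' other sequences hold a gap there.
#'
#' @param spec A [fixture_spec()].
#' @param tax A [gen_taxonomy()] result for `spec`.
#' @return A list: `aligned` ([aligned_set()]), `training`
#'   ([training_set()] with ungapped sequences, lineages and species),
#'   and `species_seqs` (per-species aligned strings, used by
#'   [gen_queries()]). Attribute `"root_col_map"` maps root positions to
#'   alignment columns.
#' @export
gen_alignment <- function(spec, tax = gen_taxonomy(spec)) {
  with_rng_seed(derive_seed(spec$seed, "alignment"), {
    root <- sample(c("A", "C", "G", "T"), spec$seq_len, replace = TRUE)
    anc_rate <- 0.04  # per-rank divergence above genus
    anc_key <- function(row, upto) {
      paste(unlist(row[tax_ranks()[seq_len(upto)]]), collapse = ";")
    }
    anc_cache <- new.env(parent = emptyenv())
    ancestor_of <- function(row, upto) {
      if (upto == 0L) return(root)
      key <- anc_key(row, upto)
      if (!is.null(anc_cache[[key]])) return(anc_cache[[key]])
      anc_cache[[key]] <- mutate_seq(ancestor_of(row, upto - 1L), anc_rate)
      anc_cache[[key]]
    }
    conf <- spec$confusable_pairs
    genus_seqs <- vector("list", nrow(tax))
    for (i in seq_len(nrow(tax))) {
      ci <- if (!is.null(conf)) match(i, conf$g2) else NA_integer_
      if (!is.na(ci)) next  # confusable partner: filled in second pass
      fam_anc <- ancestor_of(tax[i, ], 5L)
      genus_seqs[[i]] <- mutate_seq(fam_anc, spec$between_genus_divergence)
    }
    if (!is.null(conf)) {
      for (k in seq_len(nrow(conf))) {
        genus_seqs[[conf$g2[k]]] <-
          mutate_seq(genus_seqs[[conf$g1[k]]], conf$q[k])
      }
    }
    sp_tab <- attr(tax, "species")
    species_seqs <- vector("list", nrow(sp_tab))
    names(species_seqs) <- sp_tab$species
    ids <- character(0); seq_rows <- list(); meta <- list()
    for (s in seq_len(nrow(sp_tab))) {
      gi <- sp_tab$genus_index[s]
      species_seqs[[s]] <- mutate_seq(genus_seqs[[gi]],
                                      spec$between_species_divergence)
      for (j in seq_len(spec$seqs_per_species)) {
        id <- sprintf("%s_seq%d", sp_tab$species[s], j)
        ids <- c(ids, id)
        seq_rows[[id]] <- mutate_seq(species_seqs[[s]],
                                     spec$within_species_divergence)
        meta[[id]] <- data.frame(id = id, genus_index = gi,
                                 species = sp_tab$species[s],
                                 stringsAsFactors = FALSE)
      }
    }
    mat <- do.call(rbind, seq_rows)
    sp_mat <- do.call(rbind, species_seqs)
    # insertion events: one extra alignment column each, carried by one
    # genus clade
    n_events <- stats::rpois(1L, spec$indel_rate * spec$seq_len)
    root_col_map <- seq_len(spec$seq_len)
    if (n_events > 0L) {
      md <- do.call(rbind, meta)
      for (ev in seq_len(n_events)) {
        pos <- sample.int(ncol(mat) - 1L, 1L)  # insert after this column
        carrier <- sample.int(nrow(tax), 1L)
        newcol <- rep("-", nrow(mat))
        rows_c <- which(md$genus_index == carrier)
        newcol[rows_c] <- sample(c("A", "C", "G", "T"), length(rows_c),
                                 replace = TRUE)
        mat <- cbind(mat[, seq_len(pos), drop = FALSE], newcol,
                     mat[, -seq_len(pos), drop = FALSE])
        sp_new <- rep("-", nrow(sp_mat))
        sp_carrier <- which(sp_tab$genus_index == carrier)
        # species consensus carries the clade's inserted state
        sp_new[sp_carrier] <- newcol[rows_c][1L]
        sp_mat <- cbind(sp_mat[, seq_len(pos), drop = FALSE], sp_new,
                        sp_mat[, -seq_len(pos), drop = FALSE])
        root_col_map <- ifelse(root_col_map > pos, root_col_map + 1L,
                               root_col_map)
      }
    }
    aligned_strings <- apply(mat, 1L, paste, collapse = "")
    md <- do.call(rbind, meta)
    ts <- training_set(nrow(md))
    ts$id <- md$id
    ts$sequence <- gsub("-", "", aligned_strings, fixed = TRUE)
    for (r in lineage_cols()) ts[[r]] <- tax[[r]][md$genus_index]
    ts$species <- md$species
    out <- list(
      aligned = aligned_set(md$id, unname(aligned_strings)),
      training = ts,
      species_seqs = apply(sp_mat, 1L, paste, collapse = ""),
      taxonomy = tax
    )
    attr(out, "root_col_map") <- root_col_map
    out
  })
}

#' Generate labeled query sequences from a fixture
#'
#' Emits new individual sequences for each requested species by mutating
#' the species consensus at the within-species rate. Passing held-out
#' species (and excluding them from training) creates the novel-species
#' scenario common in environmental surveys; trained species yield
#' queries with a recoverable truth label.
#'
#' @param spec A [fixture_spec()].
#' @param sim A [gen_alignment()] result.
#' @param species Character vector of species names to draw queries from
#'   (default: all).
#' @param n_per_species Queries per species (default 2).
#' @return A list: `aligned` ([aligned_set()] of query rows, same
#'   columns as the fixture alignment) and `truth` (a [training_set()]
#'   of reference lineages, no sequences).
#' @export
gen_queries <- function(spec, sim, species = names(sim$species_seqs),
                        n_per_species = 2L) {
  tax <- sim$taxonomy
  sp_tab <- attr(tax, "species")
  idx <- match(species, sp_tab$species)
  if (anyNA(idx)) stop("unknown species: ", species[is.na(idx)][1L])
  with_rng_seed(derive_seed(spec$seed, "queries"), {
    ids <- character(0); seqs <- character(0); gidx <- integer(0)
    for (k in seq_along(idx)) {
      base <- strsplit(sim$species_seqs[[species[k]]], "")[[1L]]
      nong <- base != "-"
      for (j in seq_len(n_per_species)) {
        q <- base
        q[nong] <- mutate_seq(base[nong],
                              spec$within_species_divergence)
        ids <- c(ids, sprintf("query_%s_%d", species[k], j))
        seqs <- c(seqs, paste(q, collapse = ""))
        gidx <- c(gidx, sp_tab$genus_index[idx[k]])
      }
    }
    truth <- training_set(length(ids))
    truth$id <- ids
    for (r in lineage_cols()) truth[[r]] <- tax[[r]][gidx]
    truth$species <- rep(species, each = n_per_species)
    list(aligned = aligned_set(ids, seqs), truth = truth)
  })
}
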