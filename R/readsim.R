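#' Read-simulation configuration
#'
#' @param read_length Read length X in bases (the study's configurations
#'   use 100 or 120).
#' @param mode `"single-forward"`, `"single-reverse"`, or `"paired"`.
#' @param spacer_len Length of the run of `N`s fused between the two
#'   halves of a paired read (default 10).
#' @param max_ambiguous Maximum number of ambiguous characters tolerated
#'   per read, not counting the inserted spacer (default 10; reads with
#'   more are filtered out).
#' @param revcomp Reverse-complement reverse reads. Off by default: the
#'   simulated reverse read is literally the last X bases of the amplicon,
#'   which is the appropriate input for a classifier trained on
#'   like-trimmed sequences.
#' @return A `read_config` list.
#' @export
read_config <- function(read_length = 100L,
                        mode = c("paired", "single-forward",
                                 "single-reverse"),
                        spacer_len = 10L, max_ambiguous = 10L,
                        revcomp = FALSE) {
  mode <- match.arg(mode)
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("read_length must be >= 1")
  if (spacer_len < 0L) stop("spacer_len must be >= 0")
  list(read_length = read_length, mode = mode,
       spacer_len = as.integer(spacer_len),
       max_ambiguous = as.integer(max_ambiguous), revcomp = revcomp)
}

amplicon_input <- function(x) {
  if (inherits(x, "amplicon_set")) {
    return(stats::setNames(x$amplicons$amplicon, x$amplicons$id))
  }
  if (is.data.frame(x)) {
    col <- intersect(c("amplicon", "sequence"), names(x))[1L]
    return(stats::setNames(x[[col]], x$id))
  }
  if (is.null(names(x))) stop("amplicons need names (IDs)")
  x
}

sim_reads_df <- function(id, sequence, spacer_start, spacer_len, mode) {
  structure(
    data.frame(id = id, sequence = sequence,
               spacer_start = as.integer(spacer_start),
               spacer_len = as.integer(spacer_len),
               stringsAsFactors = FALSE),
    mode = mode,
    class = c("sim_reads", "data.frame")
  )
}

#' Simulate single-end reads from amplicons
#'
#' A forward read is the first `X` bases of the amplicon, a reverse read
#' the last `X` bases; amplicons shorter than `X` yield the whole
#' amplicon.
#'
#' @param amps An `amplicon_set`, a data frame with `id` and
#'   `amplicon`/`sequence` columns, or a named character vector.
#' @param cfg A [read_config()] with a single-end mode.
#' @return A `sim_reads` data frame (`id`, `sequence`, `spacer_start` and
#'   `spacer_len` both `NA`/0 for single reads).
#' @export
make_single_read <- function(amps, cfg = read_config(mode = "single-forward")) {
  if (!startsWith(cfg$mode, "single")) {
    stop("cfg$mode must be single-forward or single-reverse")
  }
  a <- amplicon_input(amps)
  len <- nchar(a)
  if (any(len == 0L)) {
    stop("empty amplicon: ", names(a)[len == 0L][1L])
  }
  x <- pmin(cfg$read_length, len)
  seqs <- if (cfg$mode == "single-forward") {
    substr(a, 1L, x)
  } else {
    r <- substr(a, len - x + 1L, len)
    if (cfg$revcomp) as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(r))) else r
  }
  sim_reads_df(names(a), unname(seqs), NA_integer_, 0L, cfg$mode)
}

#' Simulate fused paired-end reads from amplicons
#'
#' For an amplicon longer than `2X`, the first and last `X` bases are
#' fused with a run of `spacer_len` `N`s in between (so the read has
#' length `2X + spacer_len`); an amplicon of length `<= 2X` is used
#' unchanged.
#'
#' @inheritParams make_single_read
#' @param cfg A [read_config()] with `mode = "paired"`.
#' @return A `sim_reads` data frame; `spacer_start` marks the first base
#'   of the inserted spacer (`NA` when the amplicon was used unchanged).
#' @export
make_paired_read <- function(amps, cfg = read_config(mode = "paired")) {
  if (cfg$mode != "paired") stop("cfg$mode must be paired")
  a <- amplicon_input(amps)
  len <- nchar(a)
  if (any(len == 0L)) {
    stop("empty amplicon: ", names(a)[len == 0L][1L])
  }
  x <- cfg$read_length
  fuse <- len > 2L * x
  seqs <- a
  seqs[fuse] <- paste0(substr(a[fuse], 1L, x),
                       strrep("N", cfg$spacer_len),
                       substr(a[fuse], len[fuse] - x + 1L, len[fuse]))
  sim_reads_df(names(a), unname(seqs),
               ifelse(fuse, x + 1L, NA_integer_),
               ifelse(fuse, cfg$spacer_len, 0L), cfg$mode)
}

count_ambiguous <- function(reads) {
  seqs <- reads$sequence
  # blank out the constructed spacer before counting: its Ns are not
  # evidence of sequence ambiguity
  has_sp <- !is.na(reads$spacer_start) & reads$spacer_len > 0L
  if (any(has_sp)) {
    seqs[has_sp] <- paste0(
      substr(seqs[has_sp], 1L, reads$spacer_start[has_sp] - 1L),
      substring(seqs[has_sp],
                reads$spacer_start[has_sp] + reads$spacer_len[has_sp])
    )
  }
  nchar(seqs) - nchar(gsub("[^ACGTUacgtu]", "", seqs))
}

#' Filter reads containing too many ambiguous characters
#'
#' Removes any read whose count of non-`ACGT(U)` characters — excluding
#' the constructed paired-read spacer — exceeds `cfg$max_ambiguous`.
#'
#' @param reads A `sim_reads` data frame.
#' @param cfg A [read_config()].
#' @return A list with the retained `reads` and a `report` data frame
#'   (`id`, `n_ambiguous`, `kept`).
#' @export
ambiguity_filter <- function(reads, cfg = read_config()) {
  namb <- count_ambiguous(reads)
  keep <- namb <= cfg$max_ambiguous
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- attr(reads, "mode")
  class(out) <- class(reads)
  list(reads = out,
       report = data.frame(id = reads$id, n_ambiguous = namb, kept = keep,
                           stringsAsFactors = FALSE))
}
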