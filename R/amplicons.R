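#' Construct an aligned sequence set
#'
#' @param ids Character vector of sequence IDs (unique).
#' @param seqs Character vector of aligned sequences, all the same length.
#'   Gap characters are `-` or `.`.
#' @return An `aligned_set` object with fields `ids`, `seqs` and
#'   `column_count`. Columns are 1-based and inclusive.
#' @export
aligned_set <- function(ids, seqs) {
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("duplicate sequence IDs in alignment")
  nc <- unique(nchar(seqs))
  if (length(nc) > 1L) stop("aligned sequences differ in length")
  structure(
    list(ids = as.character(ids), seqs = toupper(as.character(seqs)),
         column_count = if (length(nc)) nc else 0L),
    class = "aligned_set"
  )
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", length(x$ids), "sequences x",
      x$column_count, "columns\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned (gapped) FASTA file.
#' @return An [aligned_set()].
#' @export
read_aligned_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  aligned_set(names(ss), as.character(ss))
}

#' Write sequences to a plain FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Define a primer window on a reference sequence
#'
#' The window spans from the first alignment column covered by the forward
#' primer to the last column covered by the reverse primer, located once on
#' a named reference sequence; coordinates are 1-based inclusive alignment
#' columns.
#'
#' @param reference_id ID of the reference sequence the coordinates were
#'   read off.
#' @param first_col,last_col Alignment columns of the window.
#' @return A `primer_window` object.
#' @export
primer_window <- function(reference_id, first_col, last_col) {
  first_col <- as.integer(first_col)
  last_col <- as.integer(last_col)
  if (first_col < 1L || last_col < first_col) {
    stop("need 1 <= first_col <= last_col")
  }
  structure(list(reference_id = reference_id, first_col = first_col,
                 last_col = last_col),
            class = "primer_window")
}

first_nongap <- function(seqs) {
  nchar(sub("^([-.]*).*$", "\\1", seqs)) + 1L
}

last_nongap <- function(seqs) {
  nchar(sub("[-.]*$", "", seqs))
}

#' Excise in-silico amplicons for a primer window from an alignment
#'
#' One flanking column is added on each side of the window so that
#' insertions adjacent to the primers are not missed; only sequences that
#' begin before or at the first column of that widened sub-alignment and
#' end after or at its last column are kept; the flanking end columns are
#' then stripped and the remaining window degapped. If the widened window
#' would extend past the alignment edge it is clamped with a warning.
#'
#' @param msa An [aligned_set()].
#' @param window A [primer_window()]; its reference sequence must have
#'   non-gap characters at both window columns.
#' @return An `amplicon_set`: a list with `amplicons` (data frame `id`,
#'   `amplicon`), the `window`, and a `report` data frame recording every
#'   input ID with its keep/exclude status.
#' @export
extract_amplicons <- function(msa, window) {
  stopifnot(inherits(msa, "aligned_set"), inherits(window, "primer_window"))
  if (window$last_col > msa$column_count) {
    stop("window extends past alignment column count")
  }
  ri <- match(window$reference_id, msa$ids)
  if (is.na(ri)) stop("reference sequence not in alignment: ",
                      window$reference_id)
  ref <- msa$seqs[ri]
  refchars <- substring(ref, c(window$first_col, window$last_col),
                        c(window$first_col, window$last_col))
  if (any(refchars %in% c("-", "."))) {
    stop("reference sequence has a gap at a primer window column")
  }
  wf <- window$first_col - 1L
  wl <- window$last_col + 1L
  if (wf < 1L || wl > msa$column_count) {
    warning("widened window clamped to alignment boundary")
    wf <- max(wf, 1L)
    wl <- min(wl, msa$column_count)
  }
  fng <- first_nongap(msa$seqs)
  lng <- last_nongap(msa$seqs)
  keep <- fng <= wf & lng >= wl
  amp <- gsub("[-.]", "", substr(msa$seqs[keep], window$first_col,
                                 window$last_col))
  report <- data.frame(
    id = msa$ids,
    kept = keep,
    reason = ifelse(keep, "", ifelse(fng > wf, "starts_after_window",
                                     "ends_before_window")),
    stringsAsFactors = FALSE
  )
  structure(
    list(amplicons = data.frame(id = msa$ids[keep], amplicon = amp,
                                stringsAsFactors = FALSE),
         window = window, report = report),
    class = "amplicon_set"
  )
}

#' @export
print.amplicon_set <- function(x, ...) {
  cat("amplicon_set:", nrow(x$amplicons), "amplicons from window [",
      x$window$first_col, ",", x$window$last_col, "]\n")
  invisible(x)
}

#' Length-filter an amplicon set
#'
#' @param amps An `amplicon_set` from [extract_amplicons()].
#' @param policy Either `list(type = "median_frac", min_frac, max_frac)`
#'   (keep amplicons within the given fractions of the median length;
#'   default 0.5–1.5) or `list(type = "bounds", min, max)`.
#' @return The filtered `amplicon_set`; its `length_report` attribute
#'   records the removed count and fraction.
#' @export
filter_amplicon_lengths <- function(amps,
                                    policy = list(type = "median_frac",
                                                  min_frac = 0.5,
                                                  max_frac = 1.5)) {
  len <- nchar(amps$amplicons$amplicon)
  keep <- if (length(len) == 0L) {
    logical(0)
  } else if (policy$type == "median_frac") {
    med <- stats::median(len)
    len >= policy$min_frac * med & len <= policy$max_frac * med
  } else if (policy$type == "bounds") {
    len >= policy$min & len <= policy$max
  } else {
    stop("unknown length policy type: ", policy$type)
  }
  out <- amps
  out$amplicons <- amps$amplicons[keep, , drop = FALSE]
  rownames(out$amplicons) <- NULL
  out$length_report <- data.frame(
    removed = sum(!keep),
    total = length(keep),
    fraction = if (length(keep)) sum(!keep) / length(keep) else 0
  )
  out
}
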