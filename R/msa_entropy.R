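# Gap-weighted Shannon entropy over MSA columns, sliding-window profiles,
# and coordinate mapping between an ungapped reference row and MSA columns.
# All intervals are 1-based and closed, the native R/Bioconductor convention.

#' Construct an aligned sequence set
#'
#' @param records Sequence record data.frame (see [read_fasta()]); all
#'   sequences must have equal length and there must be at least two rows.
#' @param reference_row_id Id of the coordinate-reference row (the analog of
#'   the E. coli anchor sequence used to locate primer sites).
#' @return An `aligned_set`: character matrix of residues (rows = sequences),
#'   row ids, reference row id, and alignment width.
#' @export
aligned_set <- function(records, reference_row_id) {
  stopifnot(is.data.frame(records), nrow(records) >= 2L)
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1L) {
    stop("aligned rows must all have equal length; got lengths ",
         paste(unique(lens), collapse = ", "))
  }
  if (!reference_row_id %in% records$id) {
    stop("reference_row_id '", reference_row_id, "' not among row ids")
  }
  mat <- do.call(rbind, strsplit(records$sequence, ""))
  rownames(mat) <- records$id
  structure(list(ids = records$id, matrix = mat,
                 reference_row_id = reference_row_id, width = ncol(mat)),
            class = "aligned_set")
}

#' Read an aligned FASTA file as an aligned sequence set
#'
#' @inheritParams read_fasta
#' @inheritParams aligned_set
#' @return An `aligned_set`.
#' @export
read_aligned_fasta <- function(path, reference_row_id) {
  aligned_set(read_fasta(path, allow_gaps = TRUE), reference_row_id)
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("<aligned_set> ", length(x$ids), " rows x ", x$width, " columns; ",
      "reference row '", x$reference_row_id, "'\n", sep = "")
  invisible(x)
}

#' Residue counts in one alignment column
#'
#' @param msa An `aligned_set`.
#' @param col Column index (1-based).
#' @return Named integer vector over `A`, `C`, `G`, `T`, `gap`, `ambiguous`,
#'   summing to the number of rows. IUPAC degeneracy codes count as
#'   `ambiguous`.
#' @export
column_counts <- function(msa, col) {
  stopifnot(inherits(msa, "aligned_set"))
  if (col < 1L || col > msa$width) {
    stop("column ", col, " out of range [1, ", msa$width, "]")
  }
  chars <- msa$matrix[, col]
  c(A = sum(chars == "A"), C = sum(chars == "C"),
    G = sum(chars == "G"), T = sum(chars == "T"),
    gap = sum(chars == "-"),
    ambiguous = sum(!chars %in% c("A", "C", "G", "T", "-")))
}

#' Shannon entropy of a column (bits)
#'
#' Probabilities are taken over the four concrete nucleotides only: gaps and
#' ambiguous residues carry no positional information and are excluded, which
#' keeps the 2-bit upper bound exact. A column with no concrete residue has
#' entropy 0.
#'
#' @param counts Counts from [column_counts()].
#' @return Entropy in bits, in \[0, 2\].
#' @export
column_entropy <- function(counts) {
  res <- counts[c("A", "C", "G", "T")]
  n <- sum(res)
  if (n == 0L) return(0)
  p <- res[res > 0] / n
  -sum(p * log2(p))
}

#' Gap-weighted Shannon entropy of a column (bits)
#'
#' Alignments place indel-rich regions in heavily gapped columns, where plain
#' entropy would make them masquerade as conserved sequence. Down-weighting by
#' the fraction of rows with a concrete residue corrects for that:
#' `H_w = H * (A+C+G+T) / n_rows`.
#'
#' @inheritParams column_entropy
#' @return Weighted entropy in bits, never exceeding [column_entropy()].
#' @export
gap_weighted_entropy <- function(counts) {
  total <- sum(counts)
  if (total == 0L) return(0)
  column_entropy(counts) * sum(counts[c("A", "C", "G", "T")]) / total
}

#' Sliding-window entropy profile of an alignment
#'
#' Each window value is the mean gap-weighted entropy of the columns it
#' frames. Only fully contained windows are emitted: the last partial window
#' is dropped. High-entropy windows flag variable regions; low-entropy windows
#' flag conserved sequence where primers can bind.
#'
#' @param msa An `aligned_set`.
#' @param window_length Window width in columns (default 30).
#' @param step Step between window starts in columns (default 1).
#' @return An `entropy_profile` data.frame with columns `window_start`
#'   (1-based first column of the window) and `entropy_bits`.
#' @export
sliding_window_profile <- function(msa, window_length = 30L, step = 1L) {
  stopifnot(inherits(msa, "aligned_set"))
  if (window_length < 1L || step < 1L) {
    stop("window_length and step must be positive")
  }
  if (window_length > msa$width) {
    stop("window_length ", window_length, " exceeds alignment width ",
         msa$width)
  }
  hw <- vapply(seq_len(msa$width),
               function(j) gap_weighted_entropy(column_counts(msa, j)),
               numeric(1))
  starts <- seq.int(1L, msa$width - window_length + 1L, by = step)
  vals <- vapply(starts,
                 function(s) mean(hw[s:(s + window_length - 1L)]),
                 numeric(1))
  out <- data.frame(window_start = starts, entropy_bits = vals)
  attr(out, "window_length") <- as.integer(window_length)
  attr(out, "step") <- as.integer(step)
  class(out) <- c("entropy_profile", "data.frame")
  out
}

#' Map an ungapped reference interval to MSA columns
#'
#' Positions `start:end` (1-based, closed) on the ungapped reference row are
#' mapped to the alignment columns holding those residues. Inverse of
#' [map_msa_to_reference()].
#'
#' @param msa An `aligned_set`.
#' @param start,end Interval on the ungapped reference row, `1 <= start <=
#'   end <= ungapped length`.
#' @return Named vector `c(start=, end=)` of MSA columns.
#' @export
map_reference_to_msa <- function(msa, start, end) {
  stopifnot(inherits(msa, "aligned_set"))
  ref <- msa$matrix[msa$reference_row_id, ]
  pos <- which(ref != "-")
  if (start < 1L || end > length(pos) || start > end) {
    stop("interval [", start, ", ", end, "] outside ungapped reference ",
         "length ", length(pos))
  }
  c(start = pos[start], end = pos[end])
}

#' Map an MSA column back to the ungapped reference coordinate
#'
#' @param msa An `aligned_set`.
#' @param col MSA column (1-based); must hold a residue (not a gap) of the
#'   reference row.
#' @return The 1-based position on the ungapped reference row.
#' @export
map_msa_to_reference <- function(msa, col) {
  stopifnot(inherits(msa, "aligned_set"))
  if (col < 1L || col > msa$width) {
    stop("column ", col, " out of range [1, ", msa$width, "]")
  }
  ref <- msa$matrix[msa$reference_row_id, ]
  if (ref[col] == "-") {
    stop("column ", col, " is a gap in the reference row")
  }
  sum(ref[seq_len(col)] != "-")
}
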