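# IUPAC-aware in silico PCR. Primer sites are located on the ungapped
# coordinate-reference row only (the E. coli-anchored procedure); all other
# rows inherit the bracketed interval through the MSA columns. Matching is
# exact-length and zero-mismatch: this is computational coordinate-finding,
# not a thermodynamic model of primer annealing.

#' Does an IUPAC code match a concrete base?
#'
#' Lifted to equal-length strings: every position of `code` must admit the
#' corresponding position of `base`.
#'
#' @param code IUPAC nucleotide string (may be degenerate, e.g. `"M"` = A/C).
#' @param base String over `A`, `C`, `G`, `T` of the same length.
#' @return Logical scalar.
#' @export
iupac_match <- function(code, base) {
  stopifnot(nchar(code) == nchar(base))
  map <- Biostrings::IUPAC_CODE_MAP
  cs <- strsplit(code, "")[[1]]
  bs <- strsplit(base, "")[[1]]
  if (any(!cs %in% names(map))) {
    stop("invalid IUPAC code(s): ",
         paste(unique(cs[!cs %in% names(map)]), collapse = " "))
  }
  if (any(!bs %in% c("A", "C", "G", "T"))) {
    stop("invalid base(s): ",
         paste(unique(bs[!bs %in% c("A", "C", "G", "T")]), collapse = " "))
  }
  all(mapply(function(co, ba) grepl(ba, map[[co]], fixed = TRUE), cs, bs))
}

#' Reverse complement of an IUPAC string
#'
#' Degeneracy codes are complemented as sets (M <-> K, W <-> W, ...), so
#' `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param seq IUPAC nucleotide string.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Find exact-match primer sites on an ungapped sequence
#'
#' Forward primers are matched as given; reverse primers are given 5'->3' on
#' the reverse strand, so their reverse complement is searched on the plus
#' strand. Zero mismatches; degenerate positions match any base in their
#' IUPAC expansion.
#'
#' @param seq Ungapped subject sequence (A/C/G/T).
#' @param primer IUPAC primer string, 5'->3'.
#' @param orientation `"forward"` or `"reverse"`.
#' @return Data.frame of 1-based closed intervals (`start`, `end`); zero rows
#'   when there is no site.
#' @export
find_primer_sites <- function(seq, primer, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (grepl("-", seq, fixed = TRUE)) stop("subject sequence must be ungapped")
  pat <- if (orientation == "forward") primer else reverse_complement(primer)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                   Biostrings::DNAString(seq),
                                   fixed = c(pattern = FALSE, subject = TRUE))
  data.frame(start = Biostrings::start(hits), end = Biostrings::end(hits))
}

#' Construct a primer pair
#'
#' @param region Region label the pair amplifies (e.g. `"V4"`).
#' @param forward,reverse IUPAC primer strings, each 5'->3' (the reverse
#'   primer on the reverse strand), length >= 10.
#' @return A `primer_pair` object.
#' @export
primer_pair <- function(region, forward, reverse) {
  ok <- .iupac_letters()
  for (p in c(forward, reverse)) {
    if (nchar(p) < 10L) stop("primer shorter than 10 nt: ", p)
    ch <- unique(strsplit(p, "")[[1]])
    if (any(!ch %in% ok)) {
      stop("non-IUPAC character(s) in primer ", p, ": ",
           paste(setdiff(ch, ok), collapse = " "))
    }
  }
  structure(list(region = region, forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("<primer_pair ", x$region, "> F: ", x$forward, "  R: ", x$reverse,
      "\n", sep = "")
  invisible(x)
}

#' Load a primer set from TSV
#'
#' The packaged default (`inst/extdata/primers.tsv`) holds the seven
#' published/designed 16S primer pairs spanning V1-V3, V2-V3, V3, V3-V4, V4,
#' V4-V6, and V6.
#'
#' @param path TSV with columns `region`, `forward_name`, `forward`,
#'   `reverse_name`, `reverse`; defaults to the packaged set.
#' @return Named list of `primer_pair` objects (names = region labels).
#' @export
load_primer_pairs <- function(path = system.file("extdata", "primers.tsv",
                                                 package = "schemeval")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pairs <- lapply(seq_len(nrow(tab)), function(i) {
    primer_pair(tab$region[i], tab$forward[i], tab$reverse[i])
  })
  stats::setNames(pairs, tab$region)
}

#' Extract computational amplicons from an alignment
#'
#' Locates the unique forward and reverse primer sites on the ungapped
#' reference row, maps the bracketed interval to MSA columns via
#' [map_reference_to_msa()], and emits the degapped slice of those columns
#' for every row. Rows whose slice degaps to nothing are omitted; their count
#' is attached as attribute `n_empty_dropped` and reported in a warning.
#'
#' @param msa An `aligned_set`.
#' @param pair A `primer_pair`.
#' @param include_primers Include the primer footprints in the amplicon
#'   (default `FALSE`: the identifier is the between-primer region).
#' @param first_site On multiple reference sites for a primer, take the first
#'   instead of erroring (default `FALSE`; use deliberately).
#' @return Data.frame with columns `source_id`, `region`, `sequence`,
#'   `msa_start`, `msa_end`, `includes_primers`. All rows share one MSA
#'   interval.
#' @export
extract_amplicons <- function(msa, pair, include_primers = FALSE,
                              first_site = FALSE) {
  stopifnot(inherits(msa, "aligned_set"), inherits(pair, "primer_pair"))
  ref_chars <- msa$matrix[msa$reference_row_id, ]
  ref <- paste(ref_chars[ref_chars != "-"], collapse = "")
  pick <- function(primer, orientation) {
    sites <- find_primer_sites(ref, primer, orientation)
    if (nrow(sites) == 0L) {
      stop(orientation, " primer ", primer, " (", pair$region,
           ") not found on reference row")
    }
    if (nrow(sites) > 1L && !first_site) {
      stop(orientation, " primer ", primer, " (", pair$region,
           ") matches multiple reference sites: ",
           paste(sprintf("[%d,%d]", sites$start, sites$end), collapse = " "))
    }
    if (nrow(sites) > 1L) {
      message("multiple ", orientation, " sites for ", pair$region,
              "; taking the first")
    }
    sites[1L, ]
  }
  f <- pick(pair$forward, "forward")
  r <- pick(pair$reverse, "reverse")
  if (r$start <= f$end) {
    stop("reverse site [", r$start, ",", r$end, "] not downstream of forward ",
         "site [", f$start, ",", f$end, "] for ", pair$region)
  }
  iv <- if (include_primers) c(f$start, r$end) else c(f$end + 1L, r$start - 1L)
  cols <- map_reference_to_msa(msa, iv[1], iv[2])
  slice <- msa$matrix[, cols["start"]:cols["end"], drop = FALSE]
  seqs <- apply(slice, 1L, function(ch) paste(ch[ch != "-"], collapse = ""))
  keep <- nzchar(seqs)
  if (any(!keep)) {
    warning(sum(!keep), " row(s) degap to empty within ", pair$region,
            " interval and were omitted")
  }
  out <- data.frame(source_id = msa$ids[keep],
                    region = pair$region,
                    sequence = unname(seqs[keep]),
                    msa_start = unname(cols["start"]),
                    msa_end = unname(cols["end"]),
                    includes_primers = include_primers,
                    stringsAsFactors = FALSE)
  attr(out, "n_empty_dropped") <- sum(!keep)
  out
}
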