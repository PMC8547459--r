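# Species-synonym tables. Bacterial nomenclature changes over time, so label
# equality has to honor known synonym groups; groups are merged to their
# transitive closure so lookup is an equivalence relation by construction.

.new_synonym_table <- function(groups, n_skipped = 0L) {
  groups <- lapply(groups, function(g) sort(unique(g)))
  map <- integer(0)
  if (length(groups)) {
    map <- stats::setNames(rep(seq_along(groups), lengths(groups)),
                           unlist(groups))
  }
  structure(list(groups = groups, map = map, n_skipped = as.integer(n_skipped)),
            class = "synonym_table")
}

#' Build a synonym table from groups of species names
#'
#' @param groups List of character vectors; each vector is one set of
#'   synonymous species names (raw labels are normalized via
#'   [normalize_species_label()]). Groups sharing a member are merged
#'   (transitive closure), so the result partitions the names.
#' @param n_skipped Count of malformed input rows, carried for reporting.
#' @return A `synonym_table` object.
#' @export
synonym_table <- function(groups = list(), n_skipped = 0L) {
  groups <- lapply(groups, function(g) {
    g <- trimws(as.character(g))
    unique(as.character(normalize_species_label(g[nzchar(g)])))
  })
  groups <- groups[lengths(groups) > 0L]
  if (!length(groups)) return(.new_synonym_table(list(), n_skipped))
  # union-find over names for the transitive closure
  nms <- unique(unlist(groups))
  parent <- stats::setNames(seq_along(nms), nms)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  for (g in groups) {
    r <- find(match(g[1], nms))
    for (nm in g[-1]) {
      r2 <- find(match(nm, nms))
      if (r2 != r) parent[[r2]] <- r
    }
  }
  root <- vapply(seq_along(nms), find, integer(1))
  merged <- unname(split(nms, root))
  .new_synonym_table(merged, n_skipped)
}

#' Load a species-synonym table from TSV
#'
#' Each line holds one synonym group as tab-separated species names. Rows
#' with fewer than two non-empty fields are skipped (their count is available
#' as `$n_skipped` and reported in a warning). Names are normalized, and rows
#' sharing members are merged transitively, so e.g. strain-level entries that
#' collapse to one binomial yield a singleton group.
#'
#' @param path Path to the TSV file.
#' @return A `synonym_table` object.
#' @export
load_synonym_table <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.new_synonym_table(list(), 0L))
  rows <- lapply(strsplit(lines, "\t", fixed = TRUE),
                 function(f) trimws(f)[nzchar(trimws(f))])
  bad <- lengths(rows) < 2L
  if (any(bad)) {
    warning(sum(bad), " malformed synonym row(s) skipped")
  }
  synonym_table(rows[!bad], n_skipped = sum(bad))
}

#' @export
print.synonym_table <- function(x, ...) {
  cat("<synonym_table> ", length(x$groups), " group(s), ",
      length(x$map), " name(s)", sep = "")
  if (x$n_skipped > 0L) cat(" (", x$n_skipped, " row(s) skipped)", sep = "")
  cat("\n")
  invisible(x)
}

#' Are two species labels the same species?
#'
#' True when the (normalized) labels are identical or co-occur in one synonym
#' group. Names absent from the table are their own singletons, so the
#' predicate is an equivalence relation over all labels.
#'
#' @param a,b Normalized species binomials (scalars).
#' @param table A `synonym_table`, or `NULL` for exact equality only.
#' @return Logical scalar.
#' @export
same_species <- function(a, b, table = NULL) {
  if (is.na(a) || is.na(b)) return(FALSE)
  if (a == b) return(TRUE)
  if (is.null(table)) return(FALSE)
  ga <- table$map[a]
  gb <- table$map[b]
  !is.na(ga) && !is.na(gb) && ga == gb
}

# Canonical group representative used to compare label vectors in bulk: the
# lexicographically first member of a name's group, or the name itself.
.syn_canon <- function(x, table = NULL) {
  if (is.null(table) || !length(table$map)) return(x)
  out <- x
  hit <- !is.na(x) & x %in% names(table$map)
  out[hit] <- vapply(x[hit], function(nm) table$groups[[table$map[[nm]]]][1],
                     character(1))
  out
}
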