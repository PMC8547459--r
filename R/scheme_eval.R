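# Record-pair confusion framework. Per-query assignments are expanded onto
# the query x reference-species pair grid: an assignment of query q to
# species L marks pair (q, L) as an assigned match and every other pair of q
# as a nonmatch. Pairs are then scored as true match, false match, false
# nonmatch, or true nonmatch. TNM is tabulated for conservation checks but
# never enters precision/recall/F.

#' Construct confusion counts
#'
#' @param TM,FM,FNM,TNM Nonnegative counts of true matches, false matches,
#'   false nonmatches, and true nonmatches over the record-pair grid.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TM, FM, FNM, TNM) {
  v <- c(TM = TM, FM = FM, FNM = FNM, TNM = TNM)
  if (any(v < 0)) stop("confusion counts must be nonnegative")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TM=", x$TM, " FM=", x$FM, " FNM=", x$FNM,
      " TNM=", x$TNM, "\n", sep = "")
  invisible(x)
}

#' Is a species represented in a reference database?
#'
#' True when any record's species label is the same species (synonym-aware)
#' as the query. Records lacking a parsed species field fall back to
#' word-boundary, case-insensitive matching of the binomial (and its
#' synonyms) inside the free-text description — the grep-style presence
#' check used for databases without structured species annotations.
#'
#' @param db A `reference_db`.
#' @param species Normalized species binomial.
#' @param table Optional `synonym_table`.
#' @return Logical scalar.
#' @export
species_in_database <- function(db, species, table = NULL) {
  stopifnot(inherits(db, "reference_db"))
  labels <- names(db$species_index)
  target <- .syn_canon(species, table)
  if (length(labels) && target %in% .syn_canon(labels, table)) return(TRUE)
  nospec <- is.na(db$records$species_binomial)
  if (!any(nospec)) return(FALSE)
  group <- if (!is.null(table) && species %in% names(table$map)) {
    table$groups[[table$map[[species]]]]
  } else species
  any(vapply(group, function(nm) {
    any(grepl(paste0("\\b", nm, "\\b"), db$records$description[nospec],
              ignore.case = TRUE))
  }, logical(1)))
}

#' Apply a confidence-score threshold to assignments
#'
#' Assignments whose confidence is strictly less than `tau` become
#' `"unclassified"`; confidences exactly equal to the threshold are
#' retained. `tau = "ignore"` (and, vacuously, `tau = 0`) leaves every
#' assignment unchanged.
#'
#' @param assignments Data.frame from [classify_queries()].
#' @param tau `"ignore"` or a numeric threshold in `[0, 100]`.
#' @return The thresholded assignments (confidences kept for audit).
#' @export
apply_threshold <- function(assignments, tau) {
  if (identical(tau, "ignore")) return(assignments)
  if (!is.numeric(tau) || tau < 0 || tau > 100) {
    stop("tau must be \"ignore\" or within [0, 100]")
  }
  drop <- !is.na(assignments$confidence) & assignments$confidence < tau
  assignments$species[drop] <- "unclassified"
  assignments
}

#' Tabulate record-pair confusion counts
#'
#' The pair grid spans every query against every distinct species label in
#' the database (genus-only records contribute no label; their count is
#' attached as attribute `n_labels_excluded`). Per pair, with synonym-aware
#' label equality:
#' * assigned match with the query's true species: true match;
#' * assigned match with any other label: false match;
#' * the pair (q, truth(q)) left unassigned while truth(q) is present in the
#'   database: false nonmatch;
#' * every remaining pair: true nonmatch.
#'
#' @param assignments Thresholded assignments (see [apply_threshold()]).
#' @param truth Named character vector mapping every query id to its true
#'   species binomial.
#' @param db A `reference_db`.
#' @param table Optional `synonym_table` honored by all label comparisons.
#' @return A `confusion_counts` object.
#' @export
tabulate_confusion <- function(assignments, truth, db, table = NULL) {
  stopifnot(is.data.frame(assignments), inherits(db, "reference_db"))
  missing_truth <- setdiff(assignments$query_id, names(truth))
  if (length(missing_truth)) {
    stop("query without truth label: ", paste(missing_truth, collapse = ", "))
  }
  labels <- sort(unique(names(db$species_index)))
  n_excluded <- sum(is.na(db$records$species_binomial))
  canon_labels <- .syn_canon(labels, table)
  tm <- fm <- fnm <- 0L
  for (i in seq_len(nrow(assignments))) {
    q <- assignments$query_id[i]
    a <- assignments$species[i]
    t_canon <- .syn_canon(truth[[q]], table)
    assigned <- !is.na(a) && a != "unclassified"
    correct <- FALSE
    if (assigned) {
      if (!a %in% labels) {
        warning("assigned label '", a, "' not among database species; ",
                "treated as unassigned for query ", q)
        assigned <- FALSE
      } else if (.syn_canon(a, table) == t_canon) {
        tm <- tm + 1L
        correct <- TRUE
      } else {
        fm <- fm + 1L
      }
    }
    if (!correct && species_in_database(db, truth[[q]], table)) {
      fnm <- fnm + 1L
    }
  }
  total <- nrow(assignments) * length(labels)
  cc <- confusion_counts(tm, fm, fnm, total - tm - fm - fnm)
  attr(cc, "n_labels_excluded") <- n_excluded
  cc
}

#' Precision of a scheme
#'
#' Proportion of assigned matches that were correct: `TM / (TM + FM)`.
#' `NA` (undefined) when no match was assigned.
#'
#' @param cc A `confusion_counts` object.
#' @return Numeric in \[0, 1\], or `NA_real_`.
#' @export
precision <- function(cc) {
  d <- cc$TM + cc$FM
  if (d == 0) NA_real_ else cc$TM / d
}

#' Recall of a scheme
#'
#' Proportion of possible matches that were found: `TM / (TM + FNM)`.
#' `NA` (undefined) when there was no possible match.
#'
#' @param cc A `confusion_counts` object.
#' @return Numeric in \[0, 1\], or `NA_real_`.
#' @export
recall <- function(cc) {
  d <- cc$TM + cc$FNM
  if (d == 0) NA_real_ else cc$TM / d
}

#' F-measure
#'
#' Equally weighted harmonic mean of precision and recall,
#' `2PR / (P + R)`; 0 when both are 0; `NA` propagated from an undefined
#' input.
#'
#' @param P,R Precision and recall.
#' @return Numeric in \[0, 1\], or `NA_real_`.
#' @export
f_measure <- function(P, R) {
  if (is.na(P) || is.na(R)) return(NA_real_)
  if (P + R == 0) return(0)
  2 * P * R / (P + R)
}

#' Cohen's kappa for two binary score vectors
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e = sum_c p_c(x) p_c(y)` over classes `{0, 1}`. When
#' `p_e = 1` (both vectors constant and equal-margin), kappa is 1 if the
#' vectors agree perfectly and undefined (`NA`) otherwise.
#'
#' @param x,y Equal-length vectors with entries in `{0, 1}` (1 = species
#'   correctly identified).
#' @return Kappa in \[-1, 1\], or `NA_real_`.
#' @export
cohens_kappa <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ",
                                   length(y))
  if (length(x) < 1L) stop("need at least one observation")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("entries must be 0 or 1")
  }
  p_o <- mean(x == y)
  p_e <- mean(x == 1) * mean(y == 1) + mean(x == 0) * mean(y == 0)
  if (p_e == 1) {
    if (p_o == 1) return(1)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Summarize F-measures per database
#'
#' @param results A scheme-result data.frame (see [run_benchmark()]) with
#'   columns `database` and `f_measure`.
#' @return Data.frame with per-database `median_f`, `min_f`, `max_f`,
#'   `n_schemes`, and `n_undefined` (schemes with undefined F, excluded from
#'   the statistics).
#' @export
summarize_schemes <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("database", "f_measure") %in% names(results)))
  parts <- split(results$f_measure, results$database)
  out <- do.call(rbind, lapply(names(parts), function(d) {
    f <- parts[[d]]
    def <- f[!is.na(f)]
    data.frame(database = d,
               median_f = if (length(def)) stats::median(def) else NA_real_,
               min_f = if (length(def)) min(def) else NA_real_,
               max_f = if (length(def)) max(def) else NA_real_,
               n_schemes = length(f),
               n_undefined = sum(is.na(f)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
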