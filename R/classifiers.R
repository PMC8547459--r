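# Two desk-scale species-level classifiers. Both emit one assignment per
# query: a species binomial (or "unclassified") plus a bootstrap confidence
# on the 0-100 scale used for confidence-score thresholding downstream.
# These are deliberately small re-implementations of the two classifier
# families (k-mer naive Bayes; alignment-based Bayesian LCA); no numeric
# equivalence with any external tool is claimed.

#' Construct a reference database
#'
#' @param records A [taxon_records()] data.frame (ungapped sequences with
#'   parsed lineages).
#' @return A `reference_db` with a `species_index` mapping each species
#'   binomial to its record ids. Genus-only records (no species binomial)
#'   are retained but indexed under no species.
#' @export
reference_db <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            "species_binomial" %in% names(records))
  if (any(grepl("-", records$sequence, fixed = TRUE))) {
    stop("database sequences must be ungapped")
  }
  ok <- !is.na(records$species_binomial)
  species_index <- split(records$id[ok], records$species_binomial[ok])
  structure(list(records = records, species_index = species_index,
                 dialect = if ("dialect" %in% names(records))
                   records$dialect[1] else NA_character_),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db> ", nrow(x$records), " record(s), ",
      length(x$species_index), " species", sep = "")
  if (!is.na(x$dialect)) cat(" [", x$dialect, "]", sep = "")
  cat("\n")
  invisible(x)
}

.distinct_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- unique(substring(seq, 1:(n - k + 1L), k:n))
  w[grepl("^[ACGT]+$", w)]
}

#' Train the k-mer naive Bayes word model
#'
#' Word presence/absence per training sequence (not multiplicity) is
#' modelled, RDP-style. For species `s` and word `w`,
#' `P(w|s) = (m_ws + p_w) / (M_s + 1)` with word prior
#' `p_w = (n_w + 0.5) / (N + 1)`, where `m_ws` counts the species' training
#' sequences containing `w`, `M_s` is that species' sequence count, `n_w`
#' counts all training sequences containing `w`, and `N` is the total number
#' of training sequences. The smoothing keeps every probability strictly
#' inside (0, 1).
#'
#' @param db A `reference_db` with at least two species.
#' @param k Word length (default 8; must be >= 4).
#' @return A `kmer_model`.
#' @export
train_nb <- function(db, k = 8L) {
  stopifnot(inherits(db, "reference_db"))
  k <- as.integer(k)
  if (k < 4L) stop("k must be >= 4")
  rec <- db$records[!is.na(db$records$species_binomial), , drop = FALSE]
  if (nrow(rec) < nrow(db$records)) {
    message(nrow(db$records) - nrow(rec),
            " record(s) without species label excluded from training")
  }
  species <- sort(unique(rec$species_binomial))
  if (length(species) < 2L) stop("need >= 2 species to train")
  if (any(nchar(rec$sequence) < k)) {
    stop("k = ", k, " exceeds the shortest training sequence")
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(rec$sequence), width = k)
  presence <- counts > 0L
  n_w <- colSums(presence)
  vocab <- colnames(counts)[n_w > 0L]
  presence <- presence[, vocab, drop = FALSE]
  n_w <- n_w[vocab]
  N <- nrow(rec)
  m <- rowsum(presence + 0L, group = rec$species_binomial)[species, , drop = FALSE]
  M <- as.vector(table(rec$species_binomial)[species])
  p_w <- (n_w + 0.5) / (N + 1)
  log_p <- log(sweep(sweep(m, 2L, p_w, "+"), 1L, M + 1, "/"))
  p0 <- 0.5 / (N + 1)
  structure(list(k = k, species = species,
                 M = stats::setNames(M, species), N = N, vocab = vocab,
                 n_w = n_w, log_p = log_p,
                 log_p_unseen = stats::setNames(log(p0 / (M + 1)), species)),
            class = "kmer_model")
}

#' @export
print.kmer_model <- function(x, ...) {
  cat("<kmer_model> k=", x$k, "; ", length(x$species), " species; ",
      length(x$vocab), " words from ", x$N, " sequence(s)\n", sep = "")
  invisible(x)
}

.argmax_species <- function(scores, species, quiet = FALSE) {
  top <- which(scores == max(scores))
  if (length(top) > 1L && !quiet) {
    message("score tie between ", paste(species[top], collapse = ", "),
            "; broken lexicographically")
  }
  species[top[1L]] # species sorted, so first maximal = lexicographic winner
}

#' Classify a query with the naive Bayes word model
#'
#' The full-data label is the species maximizing the summed log word
#' probabilities over the query's distinct valid words. The confidence is
#' the percentage of `boot` bootstrap replicates whose label agrees with the
#' full-data label, each replicate scoring a uniform random subsample of
#' `ceiling(W/8)` of the query's `W` distinct words.
#'
#' @param model A `kmer_model` from [train_nb()].
#' @param query Query sequence (length >= `k`).
#' @param boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed; classification is deterministic under it.
#' @return List with `species` (binomial or `"unclassified"`), `confidence`
#'   (0-100, `NA` when unclassified), and `classifier = "nb"`.
#' @export
classify_nb <- function(model, query, boot = 100L, seed = 1L) {
  stopifnot(inherits(model, "kmer_model"))
  if (nchar(query) < model$k) stop("query shorter than k = ", model$k)
  words <- .distinct_kmers(toupper(query), model$k)
  W <- length(words)
  if (W == 0L) {
    return(list(species = "unclassified", confidence = NA_real_,
                classifier = "nb"))
  }
  idx <- match(words, model$vocab)
  S <- length(model$species)
  Q <- matrix(rep(model$log_p_unseen, each = W), nrow = W, ncol = S)
  seen <- !is.na(idx)
  if (any(seen)) Q[seen, ] <- t(model$log_p[, idx[seen], drop = FALSE])
  full <- .argmax_species(colSums(Q), model$species)
  set.seed(as.integer(seed))
  size <- ceiling(W / 8)
  agree <- vapply(seq_len(boot), function(b) {
    sub <- sample.int(W, size)
    model$species[which.max(colSums(Q[sub, , drop = FALSE]))] == full
  }, logical(1))
  list(species = full, confidence = 100 * mean(agree), classifier = "nb")
}

.nuc_submat <- function(match = 1, mismatch = -1) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE, type = "DNA")
}

#' Local pairwise alignment score and identity
#'
#' Smith-Waterman local alignment with affine gaps (defaults: match +1,
#' mismatch -1, gap open -2, gap extend -1, i.e. a length-L gap costs
#' `gap_open + (L-1) * gap_extend`). Identity is the fraction of matching
#' columns among all aligned columns (gap columns included in the
#' denominator).
#'
#' @param query,ref Ungapped nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters; gap
#'   penalties are positive costs.
#' @return List with `score`, `identity`, the gapped aligned strings
#'   (`query_aligned`, `ref_aligned`), and the 1-based start of the local
#'   alignment on each input (`query_start`, `ref_start`).
#' @export
align_score <- function(query, ref, match = 1, mismatch = -1,
                        gap_open = 2, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(ref)) stop("empty input sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = ref, type = "local",
    substitutionMatrix = .nuc_submat(match, mismatch),
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
  qa <- as.character(Biostrings::alignedPattern(aln))
  ra <- as.character(Biostrings::alignedSubject(aln))
  qc <- strsplit(qa, "")[[1]]
  rc <- strsplit(ra, "")[[1]]
  list(score = Biostrings::score(aln),
       identity = sum(qc == rc & qc != "-") / length(qc),
       query_aligned = qa, ref_aligned = ra,
       query_start = Biostrings::start(Biostrings::pattern(aln)),
       ref_start = Biostrings::start(Biostrings::subject(aln)))
}

# Decompose one local alignment into per-query-position score contributions
# (so that sum(contrib) == alignment score). Gap-run costs attach to the
# query position last consumed before/within the run (position 1 if none),
# which keeps column resampling well defined across hits.
.query_contributions <- function(q_aln, r_aln, q_start, q_len,
                                 match = 1, mismatch = -1,
                                 gap_open = 2, gap_extend = 1) {
  qc <- strsplit(q_aln, "")[[1]]
  rc <- strsplit(r_aln, "")[[1]]
  qgap <- qc == "-"
  rgap <- rc == "-"
  both <- !qgap & !rgap
  col_score <- numeric(length(qc))
  col_score[both] <- ifelse(qc[both] == rc[both], match, mismatch)
  run_start <- function(g) g & !c(FALSE, g[-length(g)])
  col_score[qgap] <- -gap_extend
  col_score[run_start(qgap)] <- -gap_open
  col_score[rgap] <- -gap_extend
  col_score[run_start(rgap)] <- -gap_open
  anchor <- pmax(cumsum(!qgap) + max(q_start - 1L, 0L), 1L)
  contrib <- numeric(q_len)
  agg <- rowsum(col_score, anchor)
  contrib[as.integer(rownames(agg))] <- agg[, 1L]
  contrib
}

#' Classify a query with the alignment-based Bayesian LCA-style classifier
#'
#' The query is locally aligned against every species-labelled database
#' record; hits whose identity — matched columns as a fraction of the query
#' length, so short spurious local alignments cannot pass — falls below
#' `identity_min` are discarded, and the `top_n` best by score are retained. The species posterior is proportional
#' to the sum over a species' retained hits of `exp(score / temp)`,
#' normalized over retained hits. The confidence is the percentage of `boot`
#' bootstrap replicates (query columns resampled with replacement, hits
#' rescored, posterior re-maximized) agreeing with the full-data label.
#'
#' @param query Ungapped query sequence.
#' @param db A `reference_db`.
#' @param top_n Number of best hits retained (default 10).
#' @param identity_min Query-coverage identity floor for a hit to be
#'   retained (default 0.80).
#' @param temp Softmax temperature on alignment scores (default 10).
#' @param boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @inheritParams align_score
#' @return List with `species`, `confidence`, `classifier = "blca"`, and the
#'   normalized `posterior` over retained species.
#' @export
classify_blca <- function(query, db, top_n = 10L, identity_min = 0.80,
                          temp = 10, boot = 100L, seed = 1L,
                          match = 1, mismatch = -1,
                          gap_open = 2, gap_extend = 1) {
  stopifnot(inherits(db, "reference_db"))
  rec <- db$records[!is.na(db$records$species_binomial), , drop = FALSE]
  if (nrow(rec) == 0L) stop("database has no species-labelled records")
  alns <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(rec$sequence), subject = query,
    type = "local", substitutionMatrix = .nuc_submat(match, mismatch),
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
  scores <- Biostrings::score(alns)
  qa <- as.character(Biostrings::alignedSubject(alns))  # query side
  ra <- as.character(Biostrings::alignedPattern(alns))  # reference side
  ident <- Biostrings::nmatch(alns) / nchar(query)
  retained <- which(ident >= identity_min)
  if (!length(retained)) {
    return(list(species = "unclassified", confidence = NA_real_,
                classifier = "blca", posterior = numeric(0)))
  }
  retained <- retained[order(scores[retained], decreasing = TRUE)]
  retained <- utils::head(retained, top_n)
  hit_species <- rec$species_binomial[retained]
  q_len <- nchar(query)
  q_starts <- Biostrings::start(Biostrings::subject(alns))[retained]
  contrib <- t(vapply(seq_along(retained), function(j) {
    i <- retained[j]
    .query_contributions(qa[i], ra[i], q_starts[j], q_len,
                         match, mismatch, gap_open, gap_extend)
  }, numeric(q_len)))
  hit_scores <- rowSums(contrib) # == scores[retained]
  posterior_of <- function(sc) {
    w <- exp((sc - max(sc)) / temp)
    p <- vapply(split(w, hit_species), sum, numeric(1))
    p / sum(p)
  }
  post <- posterior_of(hit_scores)
  sp <- sort(names(post))
  full <- .argmax_species(post[sp], sp)
  set.seed(as.integer(seed))
  agree <- vapply(seq_len(boot), function(b) {
    cols <- sample.int(q_len, q_len, replace = TRUE)
    p <- posterior_of(rowSums(contrib[, cols, drop = FALSE]))
    s2 <- sort(names(p))
    .argmax_species(p[s2], s2, quiet = TRUE) == full
  }, logical(1))
  list(species = full, confidence = 100 * mean(agree),
       classifier = "blca", posterior = post)
}

#' Classify a set of queries under one scheme
#'
#' Thin batch wrapper: trains the naive Bayes model once per call (for
#' `classifier = "nb"`) and derives a per-query seed from `seed` so results
#' are reproducible and order-independent.
#'
#' @param queries Query record data.frame (e.g. `make_queries()$records` or
#'   amplicons from [extract_amplicons()] renamed to `id`/`sequence`).
#' @param db A `reference_db`.
#' @param classifier `"nb"` or `"blca"`.
#' @param seed Integer base seed.
#' @param nb_k Word length for `"nb"`.
#' @param boot Bootstrap replicates per query.
#' @param blca_top_n,blca_identity_min,blca_temp BLCA-style parameters; see
#'   [classify_blca()].
#' @return Data.frame with columns `query_id`, `species`, `confidence`,
#'   `classifier` (one row per query).
#' @export
classify_queries <- function(queries, db, classifier = c("nb", "blca"),
                             seed = 1L, nb_k = 8L, boot = 100L,
                             blca_top_n = 10L, blca_identity_min = 0.80,
                             blca_temp = 10) {
  classifier <- match.arg(classifier)
  stopifnot(is.data.frame(queries), nrow(queries) >= 1L)
  model <- if (classifier == "nb") train_nb(db, k = nb_k) else NULL
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    res <- if (classifier == "nb") {
      classify_nb(model, queries$sequence[i], boot = boot,
                  seed = as.integer(seed) + i)
    } else {
      classify_blca(queries$sequence[i], db, top_n = blca_top_n,
                    identity_min = blca_identity_min, temp = blca_temp,
                    boot = boot, seed = as.integer(seed) + i)
    }
    data.frame(query_id = queries$id[i], species = res$species,
               confidence = res$confidence, classifier = res$classifier,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
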