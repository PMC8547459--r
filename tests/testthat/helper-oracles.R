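# Independent brute-force oracles. These never share code with the package
# internals they check.

# all concrete expansions of a degenerate IUPAC string
expand_degenerate <- function(s) {
  sets <- lapply(strsplit(s, "")[[1]], function(ch) {
    strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
  })
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  apply(grid, 1L, paste, collapse = "")
}

# primer-site starts by expanding the primer and substring-comparing at
# every offset
find_sites_bruteforce <- function(seq, primer) {
  exps <- expand_degenerate(primer)
  n <- nchar(seq)
  k <- nchar(primer)
  if (n < k) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - k + 1L)) {
    if (substr(seq, i, i + k - 1L) %in% exps) starts <- c(starts, i)
  }
  starts
}

# Gotoh-style local alignment score by direct dynamic programming (affine
# gaps; gap of length L costs gap_open + (L-1)*gap_extend)
local_align_score_oracle <- function(a, b, match = 1, mismatch = -1,
                                     gap_open = 2, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      M[i, j] <- max(0, max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                            Y[i - 1L, j - 1L]) + s)
      X[i, j] <- max(M[i - 1L, j] - gap_open, X[i - 1L, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1L] - gap_open, Y[i, j - 1L] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# naive Bayes log-posterior scores by direct enumeration over the stated
# word-probability formula, with containment tested via grepl
nb_scores_oracle <- function(train_seqs, train_species, query, k) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    w <- unique(substring(s, 1:(n - k + 1L), k:n))
    w[grepl("^[ACGT]+$", w)]
  }
  qw <- kmers(query)
  N <- length(train_seqs)
  species <- sort(unique(train_species))
  vapply(species, function(sp) {
    idx <- train_species == sp
    M <- sum(idx)
    sum(vapply(qw, function(w) {
      n_w <- sum(grepl(w, train_seqs, fixed = TRUE))
      m_ws <- sum(grepl(w, train_seqs[idx], fixed = TRUE))
      p_w <- (n_w + 0.5) / (N + 1)
      log((m_ws + p_w) / (M + 1))
    }, numeric(1)))
  }, numeric(1))
}

# sort-based median/range oracle
median_range_oracle <- function(x) {
  s <- sort(x)
  list(median = stats::median(s), min = s[1], max = s[length(s)])
}
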