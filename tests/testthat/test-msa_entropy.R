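toy_msa <- function(seqs, ref = names(seqs)[1]) {
  aligned_set(data.frame(id = names(seqs), description = "",
                         sequence = unname(seqs), stringsAsFactors = FALSE),
              ref)
}

test_that("column_counts partitions residues, gaps, and ambiguity codes", {
  msa <- toy_msa(c(a = "AAAR", b = "ACR-", c = "A-TA", d = "AGGA"))
  expect_equal(column_counts(msa, 1L),
               c(A = 4L, C = 0L, G = 0L, T = 0L, gap = 0L, ambiguous = 0L))
  expect_equal(sum(column_counts(msa, 3L)), 4L)
  expect_equal(column_counts(msa, 3L)[["ambiguous"]], 1L)
  expect_equal(column_counts(msa, 4L)[["gap"]], 1L)
  expect_error(column_counts(msa, 5L), "out of range")
})

test_that("column entropy hits its analytic extremes and hand values", {
  expect_equal(column_entropy(c(A = 4, C = 0, G = 0, T = 0, gap = 0,
                                ambiguous = 0)), 0)
  expect_equal(column_entropy(c(A = 1, C = 1, G = 1, T = 1, gap = 0,
                                ambiguous = 0)), 2)
  expect_equal(column_entropy(c(A = 2, C = 2, G = 0, T = 0, gap = 4,
                                ambiguous = 0)), 1)
})

test_that("gap weighting scales entropy by the concrete-residue fraction", {
  expect_equal(gap_weighted_entropy(c(A = 4, C = 0, G = 0, T = 0, gap = 0,
                                      ambiguous = 0)), 0)
  expect_equal(gap_weighted_entropy(c(A = 2, C = 2, G = 0, T = 0, gap = 0,
                                      ambiguous = 0)), 1)
  expect_equal(gap_weighted_entropy(c(A = 2, C = 2, G = 0, T = 0, gap = 4,
                                      ambiguous = 0)), 0.5)
})

test_that("entropy bounds and H_w <= H hold on random columns", {
  set.seed(5)
  for (rep in 1:50) {
    counts <- c(A = sample(0:5, 1), C = sample(0:5, 1), G = sample(0:5, 1),
                T = sample(0:5, 1), gap = sample(0:5, 1),
                ambiguous = sample(0:3, 1))
    h <- column_entropy(counts)
    hw <- gap_weighted_entropy(counts)
    expect_gte(h, 0)
    expect_lte(h, 2)
    expect_lte(hw, h + 1e-12)
  }
})

test_that("adding gap rows never increases weighted entropy", {
  base <- c(A = 3, C = 3, G = 2, T = 2, gap = 0, ambiguous = 0)
  hw <- vapply(0:8, function(g) {
    counts <- base
    counts["gap"] <- g
    gap_weighted_entropy(counts)
  }, numeric(1))
  expect_true(all(diff(hw) <= 1e-12))
})

test_that("sliding windows match a per-column brute-force recomputation", {
  msa <- toy_msa(c(a = "ACGTAC-G", b = "AGGTA--G"))
  prof <- sliding_window_profile(msa, window_length = 4L, step = 2L)
  # brute force: recompute per-column weighted entropies directly
  hw <- vapply(1:8, function(j) {
    ch <- c(substr("ACGTAC-G", j, j), substr("AGGTA--G", j, j))
    res <- ch[ch %in% c("A", "C", "G", "T")]
    h <- if (!length(res)) 0 else {
      p <- table(res) / length(res)
      -sum(p * log2(p))
    }
    h * length(res) / 2
  }, numeric(1))
  expect_equal(prof$window_start, c(1L, 3L, 5L))
  expect_equal(prof$entropy_bits,
               c(mean(hw[1:4]), mean(hw[3:6]), mean(hw[5:8])))
})

test_that("degenerate windows: identical rows give zeros, full-width gives mean", {
  msa <- toy_msa(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  prof <- sliding_window_profile(msa, window_length = 3L)
  expect_true(all(prof$entropy_bits == 0))

  msa2 <- toy_msa(c(a = "ACGT", b = "TGCA"))
  prof2 <- sliding_window_profile(msa2, window_length = 4L)
  expect_equal(nrow(prof2), 1L)
  hw <- vapply(1:4, function(j) gap_weighted_entropy(column_counts(msa2, j)),
               numeric(1))
  expect_equal(prof2$entropy_bits, mean(hw))
  expect_error(sliding_window_profile(msa2, window_length = 5L), "exceeds")
  expect_error(sliding_window_profile(msa2, window_length = 0L), "positive")
})

test_that("reference-row coordinate mapping matches hand counting", {
  msa <- toy_msa(c(ref = "A-CG", other = "ATCG"), ref = "ref")
  # ungapped reference is "ACG"; positions 2..3 are the C and G
  expect_equal(map_reference_to_msa(msa, 2L, 3L), c(start = 3L, end = 4L))
  expect_equal(map_msa_to_reference(msa, 3L), 2L)
  expect_error(map_reference_to_msa(msa, 1L, 4L), "outside")
  expect_error(map_msa_to_reference(msa, 2L), "gap")

  nogap <- toy_msa(c(ref = "ACGT", o = "AGGT"), ref = "ref")
  expect_equal(map_reference_to_msa(nogap, 2L, 4L), c(start = 2L, end = 4L))
})

test_that("msa->ref->msa mapping round-trips over random gapped rows", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 30L
    ch <- sample(c("A", "C", "G", "T", "-"), n, replace = TRUE,
                 prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
    if (all(ch == "-")) ch[1] <- "A"
    ref <- paste(ch, collapse = "")
    msa <- toy_msa(c(ref = ref, other = random_seq(n)), ref = "ref")
    ungapped_len <- sum(ch != "-")
    for (pos in sample(ungapped_len, min(5L, ungapped_len))) {
      col <- map_reference_to_msa(msa, pos, pos)[["start"]]
      expect_equal(map_msa_to_reference(msa, col), pos)
    }
  }
})

test_that("variable blocks of a synthetic world carry more entropy than conserved", {
  w <- default_world()
  prof_cols <- vapply(seq_len(w$msa$width),
                      function(j) gap_weighted_entropy(column_counts(w$msa, j)),
                      numeric(1))
  by_type <- split(prof_cols, w$blocks$type[findInterval(seq_len(w$msa$width),
                                                         w$blocks$start)])
  expect_gt(mean(by_type$variable), mean(by_type$conserved))
})
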