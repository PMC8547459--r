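# two-species toy database with disjoint 8-mer vocabularies
disjoint_db <- function() {
  recs <- data.frame(
    id = c("a1", "b1"),
    description = c("k__Bacteria; g__Aa; s__one", "k__Bacteria; g__Bb; s__two"),
    sequence = c(strrep("ACGT", 10L), strrep("GGTTCCAA", 5L)),
    stringsAsFactors = FALSE)
  reference_db(taxon_records(recs, "greengenes"))
}

test_that("train_nb reproduces the smoothed word-probability formula", {
  db <- disjoint_db()
  model <- train_nb(db, k = 8L)
  # word present in its own species' single sequence and nowhere else:
  # P = (1 + (1 + 0.5)/3) / 2 = 0.75
  w <- "ACGTACGT"
  expect_equal(exp(model$log_p["Aa one", w]), 0.75)
  # absent everywhere: P = (0.5/3)/2
  expect_equal(exp(model$log_p_unseen[["Bb two"]]), (0.5 / 3) / 2)
  # all stored probabilities strictly in (0, 1)
  p <- exp(model$log_p)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(exp(model$log_p_unseen) > 0 & exp(model$log_p_unseen) < 1))
})

test_that("train_nb enforces its preconditions", {
  db <- disjoint_db()
  expect_error(train_nb(db, k = 3L), ">= 4")
  expect_error(train_nb(db, k = 50L), "shortest")
  one_sp <- reference_db(taxon_records(data.frame(
    id = "a", description = "k__Bacteria; g__Aa; s__one",
    sequence = strrep("ACGT", 5L), stringsAsFactors = FALSE), "greengenes"))
  expect_error(train_nb(one_sp), ">= 2 species")
})

test_that("disjoint word sets classify with confidence 100", {
  model <- train_nb(disjoint_db(), k = 8L)
  res <- classify_nb(model, strrep("ACGT", 6L), seed = 3L)
  expect_equal(res$species, "Aa one")
  expect_equal(res$confidence, 100)
})

test_that("all-ambiguous queries are unclassified", {
  model <- train_nb(disjoint_db(), k = 8L)
  res <- classify_nb(model, strrep("N", 30L), seed = 3L)
  expect_equal(res$species, "unclassified")
  expect_true(is.na(res$confidence))
})

test_that("naive Bayes argmax matches the brute-force posterior oracle", {
  set.seed(47)
  for (rep in 1:3) {
    n_sp <- sample(3:5, 1L)
    seqs <- vapply(seq_len(n_sp), function(i) random_seq(150L), character(1))
    species <- sprintf("Genus%02d sp%d", seq_len(n_sp), seq_len(n_sp))
    recs <- data.frame(id = sprintf("r%d", seq_len(n_sp)),
                       description = sprintf("%s strain x 16S", species),
                       sequence = seqs, stringsAsFactors = FALSE)
    db <- reference_db(taxon_records(recs, "ncbi"))
    model <- train_nb(db, k = 8L)
    query <- paste0(substr(seqs[1], 20L, 90L), random_seq(30L))
    res <- classify_nb(model, query, seed = 5L)
    oracle <- nb_scores_oracle(seqs, species, query, k = 8L)
    expect_equal(res$species, names(which.max(oracle)))
  }
})

test_that("align_score handles identity, single-base overlap, and errors", {
  a <- align_score(strrep("ACGT", 5L), strrep("ACGT", 5L))
  expect_equal(a$score, 20)
  expect_equal(a$identity, 1.0)
  b <- align_score("ACGT", "TTTT")
  expect_equal(b$score, 1)
  expect_error(align_score("", "ACGT"), "empty")
})

test_that("align_score agrees with an exhaustive affine-gap oracle", {
  set.seed(53)
  for (rep in 1:25) {
    a <- random_seq(sample(4:8, 1L))
    b <- random_seq(sample(4:8, 1L))
    expect_equal(align_score(a, b)$score, local_align_score_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("blca retains only the exact hit when all others fall below the floor", {
  set.seed(59)
  target <- random_seq(120L)
  decoys <- vapply(1:3, function(i) random_seq(120L), character(1))
  recs <- data.frame(
    id = c("t", "d1", "d2", "d3"),
    description = sprintf("%s strain x 16S",
                          c("Aa tt", "Bb uu", "Cc vv", "Dd ww")),
    sequence = c(target, decoys), stringsAsFactors = FALSE)
  db <- reference_db(taxon_records(recs, "ncbi"))
  res <- classify_blca(substr(target, 10L, 90L), db, seed = 7L)
  expect_equal(res$species, "Aa tt")
  expect_equal(res$confidence, 100)
  expect_equal(sum(res$posterior), 1)
})

test_that("blca returns unclassified when no hit reaches the identity floor", {
  recs <- data.frame(
    id = c("a", "b"),
    description = c("Aa bb strain x", "Cc dd strain y"),
    sequence = c(strrep("AC", 50L), strrep("AG", 50L)),
    stringsAsFactors = FALSE)
  db <- reference_db(taxon_records(recs, "ncbi"))
  res <- classify_blca(strrep("GT", 50L), db, identity_min = 0.99, seed = 7L)
  expect_equal(res$species, "unclassified")
  expect_true(is.na(res$confidence))
})

test_that("classification is deterministic under a fixed seed", {
  w <- tiny_world()
  db <- make_database(w, 0, seed = 5L)
  q <- make_queries(w, "V1", 0.01, seed = 9L)
  for (clf in c("nb", "blca")) {
    a1 <- classify_queries(q$records, db, clf, seed = 13L)
    a2 <- classify_queries(q$records, db, clf, seed = 13L)
    expect_identical(a1, a2)
  }
})

test_that("both classifiers recover ground truth and agree on a clean world", {
  w <- tiny_world()
  db <- make_database(w, 0, seed = 5L)
  q <- make_queries(w, "full", 0, seed = 9L)
  nb <- classify_queries(q$records, db, "nb", seed = 13L)
  bl <- classify_queries(q$records, db, "blca", seed = 13L)
  expect_gte(mean(nb$species == q$truth[nb$query_id]), 0.95)
  expect_gte(mean(bl$species == q$truth[bl$query_id]), 0.95)
  expect_gte(mean(nb$species == bl$species), 0.90)
})

test_that("a species removed from the database is never assigned", {
  w <- tiny_world()
  db <- make_database(w, 0.25, seed = 21L)
  removed <- names(db$dropout_mask)[db$dropout_mask]
  expect_gt(length(removed), 0L)
  q <- make_queries(w, "full", 0, seed = 9L)
  for (clf in c("nb", "blca")) {
    a <- classify_queries(q$records, db, clf, seed = 13L)
    expect_false(any(a$species %in% removed))
  }
})
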