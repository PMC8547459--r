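test_that("the worked record-pair scenario tabulates 1/2/1/8 and its metrics", {
  sc <- worked_example()
  cc <- tabulate_confusion(sc$assignments, sc$truth, sc$db)
  expect_equal(cc$TM, 1L)
  expect_equal(cc$FM, 2L)
  expect_equal(cc$FNM, 1L)
  expect_equal(cc$TNM, 8L)
  P <- precision(cc)
  R <- recall(cc)
  expect_equal(round(P, 2), 0.33)
  expect_equal(R, 0.5)
  expect_equal(round(f_measure(round(P, 2), round(R, 1)), 2), 0.40)
})

test_that("perfect assignment yields no false matches or nonmatches", {
  sc <- worked_example()
  perfect <- sc$assignments
  perfect$species <- unname(sc$truth[perfect$query_id])
  perfect <- perfect[perfect$species %in% names(sc$db$species_index), ]
  cc <- tabulate_confusion(perfect, sc$truth, sc$db)
  expect_equal(cc$FM, 0L)
  expect_equal(cc$FNM, 0L)
})

test_that("absent truth species contribute no false nonmatch when unassigned", {
  sc <- worked_example()
  a <- sc$assignments
  a$species <- "unclassified" # nothing assigned at all
  cc <- tabulate_confusion(a, sc$truth, sc$db)
  expect_equal(cc$TM + cc$FM, 0L)
  # qE and qF truths are present in the db, qG's is not
  expect_equal(cc$FNM, 2L)
  expect_error(tabulate_confusion(sc$assignments, sc$truth[-1], sc$db),
               "qE")
})

test_that("synonym-aware equality upgrades false matches to true matches", {
  sc <- worked_example()
  tab <- synonym_table(list(c("Facklamia hominis", "Lactobacillus iners")))
  cc <- tabulate_confusion(sc$assignments, sc$truth, sc$db, tab)
  expect_equal(cc$TM, 2L) # qF's wrong label is now a synonym of its truth
  expect_equal(cc$FM, 1L)
  expect_equal(cc$FNM, 0L)
})

test_that("species_in_database honors synonyms and free-text fallback", {
  sc <- worked_example()
  expect_true(species_in_database(sc$db, "Escherichia coli"))
  expect_false(species_in_database(sc$db, "Gardnerella vaginalis"))
  tab <- synonym_table(list(c("Gardnerella vaginalis", "Moraxella osloensis")))
  expect_true(species_in_database(sc$db, "Gardnerella vaginalis", tab))
  # genus-only record found only through its description text
  recs <- data.frame(id = "g1",
                     description = "k__Bacteria; g__Lactobacillus; s__",
                     sequence = strrep("ACGT", 10L), stringsAsFactors = FALSE)
  db2 <- reference_db(taxon_records(recs, "greengenes"))
  expect_false(species_in_database(db2, "Lactobacillus iners"))
  recs$description <- "Lactobacillus iners cultured isolate"
  db3 <- reference_db(data.frame(recs, species_binomial = NA_character_,
                                 stringsAsFactors = FALSE))
  expect_true(species_in_database(db3, "Lactobacillus iners"))
})

test_that("thresholding drops strictly-below-threshold confidences only", {
  a <- data.frame(query_id = c("q1", "q2", "q3"),
                  species = c("Aa bb", "Cc dd", "Ee ff"),
                  confidence = c(45, 80, 95), classifier = "nb",
                  stringsAsFactors = FALSE)
  expect_identical(apply_threshold(a, "ignore"), a)
  expect_identical(apply_threshold(a, 0), a)
  thr <- apply_threshold(a, 80)
  expect_equal(thr$species, c("unclassified", "Cc dd", "Ee ff"))
  expect_error(apply_threshold(a, 101), "\\[0, 100\\]")
  expect_error(apply_threshold(a, -1), "\\[0, 100\\]")
})

test_that("precision, recall, and F handle boundary and undefined cases", {
  expect_equal(precision(confusion_counts(5, 0, 2, 1)), 1)
  expect_true(is.na(precision(confusion_counts(0, 0, 3, 1))))
  expect_equal(recall(confusion_counts(0, 2, 3, 1)), 0)
  expect_true(is.na(recall(confusion_counts(0, 2, 0, 1))))
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0, 0.7), 0)
  expect_equal(f_measure(0, 0), 0)
  expect_true(is.na(f_measure(NA_real_, 0.5)))
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("F lies between min and max of P and R, equality when P == R", {
  set.seed(61)
  for (rep in 1:50) {
    P <- runif(1)
    R <- runif(1)
    F <- f_measure(P, R)
    expect_lte(F, max(P, R) + 1e-12)
    expect_gte(F, 0)
    expect_lte(F, 1)
  }
  expect_equal(f_measure(0.37, 0.37), 0.37)
})

test_that("Cohen's kappa matches hand-computed values", {
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0, tolerance = 1e-12)
  expect_equal(cohens_kappa(c(1, 1, 1, 0), c(1, 1, 0, 0)), 0.5,
               tolerance = 1e-12)
  expect_equal(cohens_kappa(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_error(cohens_kappa(c(1, 0), c(1, 0, 1)), "mismatch")
  expect_error(cohens_kappa(c(1, 2), c(1, 0)), "0 or 1")
  # constant, perfectly agreeing vectors
  expect_equal(cohens_kappa(c(1, 1), c(1, 1)), 1)
  # one constant margin: chance agreement equals observed agreement
  expect_equal(cohens_kappa(c(1, 1, 1, 1), c(1, 1, 1, 0)), 0)
})

test_that("kappa stays in [-1, 1] and agrees with an independent implementation", {
  set.seed(67)
  for (rep in 1:30) {
    n <- sample(4:40, 1L)
    x <- sample(0:1, n, replace = TRUE)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) next
    k <- cohens_kappa(x, y)
    expect_gte(k, -1)
    expect_lte(k, 1)
    tab <- table(factor(x, 0:1), factor(y, 0:1))
    expect_equal(k, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
  x <- sample(0:1, 20, replace = TRUE)
  expect_equal(cohens_kappa(x, x), 1)
})

test_that("per-database F summaries match a sort-based oracle", {
  res <- data.frame(database = rep(c("d1", "d2"), c(3L, 4L)),
                    f_measure = c(0.2, 0.4, 0.6, 0.1, NA, 0.5, 0.3),
                    stringsAsFactors = FALSE)
  s <- summarize_schemes(res)
  expect_equal(s$median_f[s$database == "d1"], 0.4)
  expect_equal(s$min_f[s$database == "d1"], 0.2)
  expect_equal(s$max_f[s$database == "d1"], 0.6)
  expect_equal(s$n_undefined[s$database == "d2"], 1L)
  set.seed(71)
  for (rep in 1:10) {
    f <- runif(sample(1:9, 1L))
    s1 <- summarize_schemes(data.frame(database = "d", f_measure = f))
    o <- median_range_oracle(f)
    expect_equal(s1$median_f, o$median)
    expect_equal(s1$min_f, o$min)
    expect_equal(s1$max_f, o$max)
  }
})
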