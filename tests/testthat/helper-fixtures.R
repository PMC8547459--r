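# Shared fixtures. Worlds are generated once per session and cached; all
# randomness is seed-fixed so the suite is reproducible.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small world for unit tests: 8 species, 640 columns
tiny_world <- function() {
  cached("tiny_world", generate_world(
    world_spec(n_genera = 4L, species_per_genus = 2L,
               block_length = 80L, n_blocks = 8L),
    seed = 101L))
}

# the default study-scale world: 36 species / 12 genera, 960 columns
default_world <- function() {
  cached("default_world", generate_world(world_spec(), seed = 42L))
}

write_tmp_fasta <- function(records, wrap = 60L) {
  path <- tempfile(fileext = ".fasta")
  write_fasta(records, path, wrap = wrap)
  path
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_records <- function(n_rec, len_range = c(5L, 120L)) {
  data.frame(id = sprintf("seq%03d", seq_len(n_rec)),
             description = ifelse(seq_len(n_rec) %% 2L == 0L,
                                  sprintf("desc %d", seq_len(n_rec)), ""),
             sequence = vapply(seq_len(n_rec), function(i) {
               random_seq(sample(len_range[1]:len_range[2], 1L))
             }, character(1)),
             stringsAsFactors = FALSE)
}

# the worked-example scenario: 3 queries against 4 reference species labels,
# one correct match, one wrong-but-present match, one match for a query whose
# species is absent from the reference set
worked_example <- function() {
  refs <- data.frame(
    id = c("rE", "rF", "rL", "rM"),
    description = c("Escherichia coli strain K1 16S ribosomal RNA",
                    "Facklamia hominis strain H2 16S ribosomal RNA",
                    "Lactobacillus iners strain L3 16S ribosomal RNA",
                    "Moraxella osloensis strain M4 16S ribosomal RNA"),
    sequence = replicate(4L, strrep("ACGT", 10L)),
    stringsAsFactors = FALSE)
  db <- reference_db(taxon_records(refs, dialect = "ncbi"))
  truth <- c(qE = "Escherichia coli", qF = "Facklamia hominis",
             qG = "Gardnerella vaginalis")
  assignments <- data.frame(
    query_id = c("qE", "qF", "qG"),
    species = c("Escherichia coli", "Lactobacillus iners",
                "Moraxella osloensis"),
    confidence = c(95, 90, 85), classifier = "nb",
    stringsAsFactors = FALSE)
  list(db = db, truth = truth, assignments = assignments)
}
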