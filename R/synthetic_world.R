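# Ground-truth 16S-like worlds. Sequences evolve from one ancestor through
# genus ancestors to species, with substitution concentrated in variable
# blocks; primer footprints are mutation-protected so planted primer pairs
# match every species exactly. Generation is column-preserving (indels are
# deletions rendered as gaps), so the true MSA is exact by construction and
# no aligner is needed anywhere in the test loop.

#' Specify a synthetic 16S-like world
#'
#' Defaults give 36 species in 12 genera over eight alternating
#' conserved/variable blocks of 120 nt (960 nt total), with per-site
#' substitution rates of 0.01 in conserved and 0.15 in variable blocks and
#' two planted primer pairs: one amplifying a single variable block
#' (region `"V1"`) and one spanning two variable blocks plus the conserved
#' block between them (region `"V2-V3"`).
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus.
#' @param block_length Length of each block in nt.
#' @param n_blocks Number of alternating blocks, starting conserved; at least
#'   7 so both primer pairs can be planted.
#' @param mu_conserved,mu_variable Per-site substitution rates in conserved
#'   and variable blocks; `mu_conserved < mu_variable` is required.
#' @param genus_split Fraction of divergence spent on the genus ancestor
#'   (the rest separates species within a genus).
#' @param indel_rate Per-site deletion rate outside primer footprints
#'   (deletions appear as gaps in the true MSA).
#' @param primer_length Length of planted primer footprints.
#' @param n_degenerate Number of degenerate (two-fold) positions widened into
#'   each planted primer.
#' @return A validated `world_spec` list.
#' @export
world_spec <- function(n_genera = 12L, species_per_genus = 3L,
                       block_length = 120L, n_blocks = 8L,
                       mu_conserved = 0.01, mu_variable = 0.15,
                       genus_split = 0.5, indel_rate = 0.005,
                       primer_length = 18L, n_degenerate = 3L) {
  spec <- list(n_genera = as.integer(n_genera),
               species_per_genus = as.integer(species_per_genus),
               block_length = as.integer(block_length),
               n_blocks = as.integer(n_blocks),
               mu_conserved = mu_conserved, mu_variable = mu_variable,
               genus_split = genus_split, indel_rate = indel_rate,
               primer_length = as.integer(primer_length),
               n_degenerate = as.integer(n_degenerate))
  if (!(spec$mu_conserved < spec$mu_variable ||
        (spec$mu_conserved == 0 && spec$mu_variable == 0))) {
    stop("mu_conserved must be < mu_variable (or both zero)")
  }
  if (spec$n_blocks < 7L) stop("need at least 7 blocks to plant both primer pairs")
  if (spec$block_length * spec$n_blocks < 600L) {
    stop("total length must be >= 600 nt")
  }
  if (spec$block_length < 2L * spec$primer_length) {
    stop("blocks must fit two primer footprints (block_length >= 2 * primer_length)")
  }
  if (spec$n_genera * spec$species_per_genus < 2L) stop("need >= 2 species")
  if (spec$genus_split < 0 || spec$genus_split > 1) stop("genus_split in [0,1]")
  structure(spec, class = "world_spec")
}

.mutate_chars <- function(chars, rates) {
  hit <- which(stats::runif(length(chars)) < rates)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

# widen a concrete primer footprint at n positions into two-fold IUPAC codes
# that still admit the original base
.degenerate_widen <- function(chars, n) {
  two_fold <- list(A = c("M", "R", "W"), C = c("M", "S", "Y"),
                   G = c("R", "S", "K"), T = c("W", "Y", "K"))
  pos <- sample.int(length(chars), min(n, length(chars)))
  for (i in pos) chars[i] <- sample(two_fold[[chars[i]]], 1L)
  paste(chars, collapse = "")
}

#' Generate a synthetic world
#'
#' @param spec A [world_spec()].
#' @param seed Integer seed; generation is bit-reproducible under it.
#' @return A `synthetic_world`: taxonomy table, per-species full-length
#'   sequences, the exact true MSA (reference row `"ref_anchor"` is the
#'   ungapped ancestor, the E. coli analog), planted `primer_pair`s, true
#'   amplicon column intervals and per-species amplicon sequences, block
#'   layout, and provenance (`spec`, `seed`).
#' @export
generate_world <- function(spec = world_spec(), seed = 1L) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(as.integer(seed))
  bl <- spec$block_length
  nb <- spec$n_blocks
  L <- bl * nb
  block_of <- rep(seq_len(nb), each = bl)
  type_of_block <- rep(c("conserved", "variable"), length.out = nb)
  col_type <- type_of_block[block_of]
  b_start <- (seq_len(nb) - 1L) * bl + 1L
  b_end <- seq_len(nb) * bl
  plen <- spec$primer_length

  # footprints: pair 1 brackets block 2; pair 2 brackets blocks 4-6
  fp <- list(f1 = (b_end[1] - plen + 1L):b_end[1],
             r1 = b_start[3]:(b_start[3] + plen - 1L),
             f2 = (b_end[3] - plen + 1L):b_end[3],
             r2 = b_start[7]:(b_start[7] + plen - 1L))
  protected <- sort(unique(unlist(fp)))

  ancestor <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  rate <- ifelse(col_type == "variable", spec$mu_variable, spec$mu_conserved)
  rate[protected] <- 0

  primers <- list(
    "V1" = primer_pair("V1",
                       .degenerate_widen(ancestor[fp$f1], spec$n_degenerate),
                       reverse_complement(
                         .degenerate_widen(ancestor[fp$r1], spec$n_degenerate))),
    "V2-V3" = primer_pair("V2-V3",
                          .degenerate_widen(ancestor[fp$f2], spec$n_degenerate),
                          reverse_complement(
                            .degenerate_widen(ancestor[fp$r2], spec$n_degenerate))))
  amplicon_cols <- list(
    "V1" = c(start = b_end[1] + 1L, end = b_start[3] - 1L),
    "V2-V3" = c(start = b_end[3] + 1L, end = b_start[7] - 1L))

  n_sp <- spec$n_genera * spec$species_per_genus
  ids <- sprintf("TS%03d", seq_len(n_sp))
  genus <- character(n_sp)
  binomial <- character(n_sp)
  rows <- matrix("", nrow = n_sp, ncol = L)
  idx <- 0L
  for (g in seq_len(spec$n_genera)) {
    g_anc <- .mutate_chars(ancestor, rate * spec$genus_split)
    for (s in seq_len(spec$species_per_genus)) {
      idx <- idx + 1L
      chars <- .mutate_chars(g_anc, rate * (1 - spec$genus_split))
      del <- stats::runif(L) < spec$indel_rate
      del[protected] <- FALSE
      chars[del] <- "-"
      rows[idx, ] <- chars
      genus[idx] <- sprintf("Genus%02d", g)
      binomial[idx] <- sprintf("Genus%02d sp%d%s", g, g, letters[s])
    }
  }
  row_strings <- apply(rows, 1L, paste, collapse = "")
  msa_records <- .seq_records(c(ids, "ref_anchor"),
                              c(binomial, "ancestral reference row"),
                              c(row_strings, paste(ancestor, collapse = "")))
  msa <- aligned_set(msa_records, "ref_anchor")
  sequences <- stats::setNames(gsub("-", "", row_strings, fixed = TRUE), ids)

  amplicons <- lapply(amplicon_cols, function(cols) {
    slice <- rows[, cols["start"]:cols["end"], drop = FALSE]
    stats::setNames(apply(slice, 1L, function(ch) {
      paste(ch[ch != "-"], collapse = "")
    }), ids)
  })

  structure(list(
    spec = spec, seed = as.integer(seed),
    taxonomy = data.frame(id = ids, genus = genus, species = binomial,
                          stringsAsFactors = FALSE),
    sequences = sequences, msa = msa, primers = primers,
    amplicon_cols = amplicon_cols, amplicons = amplicons,
    blocks = data.frame(block = seq_len(nb), start = b_start, end = b_end,
                        type = type_of_block, stringsAsFactors = FALSE)),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", nrow(x$taxonomy), " species / ",
      length(unique(x$taxonomy$genus)), " genera; ", x$msa$width,
      " alignment columns; regions: ",
      paste(names(x$primers), collapse = ", "), "; seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

.emit_annotation <- function(genus_idx, epithet, id,
                             dialect = c("greengenes", "silva", "ncbi")) {
  dialect <- match.arg(dialect)
  g <- sprintf("Genus%02d", genus_idx)
  switch(dialect,
    greengenes = sprintf(
      "k__Bacteria; p__Phylum%02d; c__Class%02d; o__Order%02d; f__Family%02d; g__%s; s__%s",
      genus_idx, genus_idx, genus_idx, genus_idx, g, epithet),
    silva = sprintf("Bacteria;Phylum%02d;Class%02d;Order%02d;Family%02d;%s %s",
                    genus_idx, genus_idx, genus_idx, genus_idx, g, epithet),
    ncbi = sprintf("%s %s strain %s 16S ribosomal RNA", g, epithet, id))
}

#' Build a reference database from a world, with species dropout
#'
#' Emulates incomplete real-world reference databases by removing a uniform
#' random `round(dropout * S)` of the world's `S` species before emitting
#' taxonomy annotations in the requested dialect.
#'
#' @param world A `synthetic_world`.
#' @param dropout Fraction of species to remove, in `[0, 1)`.
#' @param seed Integer seed for the dropout draw.
#' @param dialect Annotation dialect to emit; see [parse_lineage()].
#' @return A `reference_db`; the logical dropout mask (TRUE = removed),
#'   keyed by species binomial, is stored as `$dropout_mask`.
#' @export
make_database <- function(world, dropout = 0, seed = 1L,
                          dialect = c("greengenes", "silva", "ncbi")) {
  stopifnot(inherits(world, "synthetic_world"))
  dialect <- match.arg(dialect)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  tax <- world$taxonomy
  S <- nrow(tax)
  n_drop <- round(dropout * S)
  if (n_drop >= S) stop("dropout would remove every species")
  set.seed(as.integer(seed))
  dropped <- sort(sample.int(S, n_drop))
  mask <- stats::setNames(seq_len(S) %in% dropped, tax$species)
  keep <- setdiff(seq_len(S), dropped)
  genus_idx <- as.integer(sub("^Genus", "", tax$genus))
  epithet <- sub("^\\S+\\s+", "", tax$species)
  ann <- vapply(keep, function(i) {
    .emit_annotation(genus_idx[i], epithet[i], tax$id[i], dialect)
  }, character(1))
  recs <- .seq_records(tax$id[keep], ann, unname(world$sequences[tax$id[keep]]))
  db <- reference_db(taxon_records(recs, dialect = dialect))
  db$dropout_mask <- mask
  db
}

#' Emit query reads from a world with substitution noise
#'
#' @param world A `synthetic_world`.
#' @param region A planted region label (see `names(world$primers)`) to use
#'   the true amplicons, or `"full"` for full-length sequences.
#' @param error_rate Per-site i.i.d. substitution rate on the queries, in
#'   `[0, 0.25)`; extends the purely computational amplicons with read noise.
#' @param seed Integer seed.
#' @return List with `records` (query sequence data.frame, ids `q_<id>`) and
#'   `truth` (named character vector query id -> true species binomial).
#' @export
make_queries <- function(world, region = "full", error_rate = 0, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  if (error_rate < 0 || error_rate >= 0.25) stop("error_rate must be in [0, 0.25)")
  if (identical(region, "full")) {
    seqs <- world$sequences
  } else if (region %in% names(world$amplicons)) {
    seqs <- world$amplicons[[region]]
  } else {
    stop("unknown region '", region, "'; available: full, ",
         paste(names(world$amplicons), collapse = ", "))
  }
  set.seed(as.integer(seed))
  noisy <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    paste(.mutate_chars(ch, rep(error_rate, length(ch))), collapse = "")
  }, character(1))
  ids <- paste0("q_", names(seqs))
  truth <- stats::setNames(
    world$taxonomy$species[match(names(seqs), world$taxonomy$id)], ids)
  list(records = .seq_records(ids, "", unname(noisy)), truth = truth)
}
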