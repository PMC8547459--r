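# Sequence records are plain data.frames (columns id, description, sequence)
# holding uppercase strings over the IUPAC nucleotide alphabet plus '-'.
# U is folded to T on ingest because rRNA databases distribute RNA alphabets.

.iupac_letters <- function() names(Biostrings::IUPAC_CODE_MAP)

.ambig_letters <- function() setdiff(.iupac_letters(), c("A", "C", "G", "T"))

.seq_records <- function(id, description, sequence) {
  data.frame(id = as.character(id),
             description = as.character(description),
             sequence = as.character(sequence),
             stringsAsFactors = FALSE)
}

#' Read a FASTA file into a sequence record table
#'
#' Parses plain or aligned FASTA. Sequences are uppercased and `U` is
#' normalized to `T`; `.` gap characters are normalized to `-`. Records with
#' more than 5% ambiguous bases are reported via a message but kept, since
#' reference databases legitimately contain degenerate positions.
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Permit `-` characters (needed for alignments). Set to
#'   `FALSE` for database ingestion, where gaps indicate a malformed input.
#' @return A data.frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path, allow_gaps = TRUE) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no sequence records in '", path, "'")
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(id))) stop("FASTA header with empty id in '", path, "'")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U.", "T-", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ", paste(id[!nzchar(seqs)], collapse = ", "))
  }
  ok <- c(.iupac_letters(), "-")
  seen <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(seen, ok)
  if (length(bad)) {
    stop("non-nucleotide character(s) in '", path, "': ",
         paste(bad, collapse = " "))
  }
  if (!allow_gaps && any(grepl("-", seqs, fixed = TRUE))) {
    stop("gap characters present but allow_gaps = FALSE: ",
         paste(id[grepl("-", seqs, fixed = TRUE)], collapse = ", "))
  }
  ambig <- .ambig_letters()
  frac <- vapply(strsplit(seqs, ""), function(ch) {
    res <- ch[ch != "-"]
    if (!length(res)) 0 else mean(res %in% ambig)
  }, numeric(1))
  if (any(frac > 0.05)) {
    message(sum(frac > 0.05), " record(s) with >5% ambiguous bases: ",
            paste(utils::head(id[frac > 0.05], 5L), collapse = ", "))
  }
  .seq_records(id, description, seqs)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, p))` reproduces `x`.
#'
#' @param records Data.frame with columns `id`, `description`, `sequence`.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (positive integer).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(is.data.frame(records), wrap >= 1L)
  if (nrow(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  headers <- ifelse(nzchar(records$description),
                    paste(records$id, records$description),
                    records$id)
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, headers))
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(wrap))
  invisible(path)
}

.rank_names <- c("kingdom", "phylum", "class", "order", "family",
                 "genus", "species")

.lineage <- function(ranks, species_binomial, dialect) {
  structure(list(ranks = ranks, species_binomial = species_binomial,
                 dialect = dialect),
            class = "lineage")
}

#' Parse a taxonomy annotation into a lineage
#'
#' Supports three annotation dialects found in 16S reference databases:
#' \describe{
#'   \item{greengenes}{semicolon-separated path with rank prefixes
#'     (`k__...;s__...`); the species binomial is genus + the `s__` epithet
#'     when both are non-empty.}
#'   \item{silva}{semicolon-separated rank path; the final element is read as
#'     `"Genus epithet"` when it has two tokens, otherwise as a genus-only
#'     entry (species fields are inconsistently populated in the wild).}
#'   \item{ncbi}{free-text description; the binomial is the first two
#'     whitespace tokens.}
#' }
#'
#' @param annotation Annotation string. Empty input yields an all-absent
#'   lineage, not an error.
#' @param dialect One of `"greengenes"`, `"silva"`, `"ncbi"`.
#' @return A `lineage` object: named rank vector (`NA` for absent ranks),
#'   `species_binomial` (or `NA`), and the dialect used.
#' @export
parse_lineage <- function(annotation, dialect = c("greengenes", "silva", "ncbi")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(annotation), length(annotation) == 1L)
  ranks <- stats::setNames(rep(NA_character_, 7L), .rank_names)
  binom <- NA_character_
  ann <- trimws(annotation)
  if (!nzchar(ann)) return(.lineage(ranks, binom, dialect))

  if (dialect == "greengenes") {
    parts <- trimws(strsplit(ann, ";", fixed = TRUE)[[1]])
    for (p in parts) {
      m <- regmatches(p, regexec("^([kpcofgs])__(.*)$", p))[[1]]
      if (length(m) == 3L && nzchar(m[3])) {
        slot <- match(m[2], c("k", "p", "c", "o", "f", "g", "s"))
        ranks[slot] <- m[3]
      }
    }
    if (!is.na(ranks["genus"]) && !is.na(ranks["species"])) {
      binom <- paste(ranks[["genus"]], ranks[["species"]])
    }
  } else if (dialect == "silva") {
    parts <- trimws(strsplit(ann, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    n <- length(parts)
    if (n > 0L) {
      last <- strsplit(parts[n], "\\s+")[[1]]
      if (length(last) >= 2L) {
        binom <- paste(last[1], last[2])
        ranks["genus"] <- last[1]
        ranks["species"] <- last[2]
        lead <- parts[-n]
      } else {
        ranks["genus"] <- parts[n]
        lead <- parts[-n]
      }
      k <- min(length(lead), 5L)
      if (k > 0L) ranks[seq_len(k)] <- lead[seq_len(k)]
    }
  } else { # ncbi
    tokens <- strsplit(ann, "\\s+")[[1]]
    ranks["genus"] <- tokens[1]
    if (length(tokens) >= 2L) {
      binom <- paste(tokens[1], tokens[2])
      ranks["species"] <- tokens[2]
    }
  }
  if (!is.na(binom) && !is.na(ranks["genus"]) &&
      strsplit(binom, " ", fixed = TRUE)[[1]][1] != ranks[["genus"]]) {
    stop("lineage invariant violated: binomial genus differs from genus rank")
  }
  .lineage(ranks, binom, dialect)
}

#' @export
print.lineage <- function(x, ...) {
  shown <- x$ranks[!is.na(x$ranks)]
  cat("<lineage [", x$dialect, "]> ",
      paste(names(shown), shown, sep = "=", collapse = "; "), "\n", sep = "")
  if (!is.na(x$species_binomial)) cat("  binomial:", x$species_binomial, "\n")
  invisible(x)
}

#' Normalize a species label to a canonical binomial
#'
#' Collapses whitespace (underscores count as spaces), drops everything from
#' the first strain/subspecies marker (`subsp.`, `subspecies`, `str.`,
#' `strain`, `var.`) onward, truncates to the binomial, capitalizes the genus
#' and lowercases the epithet. Idempotent. Single-token inputs are returned
#' unchanged with the `no_epithet` attribute flagged.
#'
#' @param raw Character vector of raw species labels.
#' @return Character vector of canonical binomials with a logical attribute
#'   `no_epithet` marking entries that had no species epithet.
#' @export
normalize_species_label <- function(raw) {
  stopifnot(is.character(raw), all(nzchar(trimws(raw))))
  markers <- c("subsp.", "subspecies", "str.", "strain", "var.")
  no_epithet <- logical(length(raw))
  out <- character(length(raw))
  for (i in seq_along(raw)) {
    x <- gsub("\\s+", " ", trimws(chartr("_", " ", raw[i])))
    tokens <- strsplit(x, " ", fixed = TRUE)[[1]]
    cut <- which(tolower(tokens) %in% markers)
    if (length(cut)) tokens <- tokens[seq_len(min(cut) - 1L)]
    if (length(tokens) < 2L) {
      out[i] <- x
      no_epithet[i] <- TRUE
    } else {
      genus <- tolower(tokens[1])
      substr(genus, 1L, 1L) <- toupper(substr(genus, 1L, 1L))
      out[i] <- paste(genus, tolower(tokens[2]))
    }
  }
  structure(out, no_epithet = no_epithet)
}

#' Attach parsed lineages to sequence records
#'
#' @param records Sequence record data.frame from [read_fasta()].
#' @param dialect Taxonomy dialect of the `description` column; see
#'   [parse_lineage()].
#' @return The records with rank columns, `species_binomial`, and `dialect`
#'   appended. Species-absent entries keep `NA` binomials (genus-only entries
#'   are a fact of real databases and are not an error).
#' @export
taxon_records <- function(records, dialect = c("greengenes", "silva", "ncbi")) {
  dialect <- match.arg(dialect)
  lins <- lapply(records$description, parse_lineage, dialect = dialect)
  rk <- do.call(rbind, lapply(lins, function(l) l$ranks))
  out <- cbind(records, as.data.frame(rk, stringsAsFactors = FALSE))
  out$species_binomial <- vapply(lins, function(l) l$species_binomial,
                                 character(1))
  ok <- !is.na(out$species_binomial)
  out$species_binomial[ok] <- as.character(
    normalize_species_label(out$species_binomial[ok]))
  out$dialect <- dialect
  out
}
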