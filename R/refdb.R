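# Reference barcode database: FASTA-backed labelled records, species label
# index, split sampling, and the ngsfilter-style tag manifest.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so library code does not disturb user-level randomness.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Construct a reference barcode database
#'
#' A `reference_db` holds labelled amplicon records (primer-free reference
#' sequences with species labels) together with a dense 0-based class index
#' over the distinct species labels, which fixes the output layer of a
#' classifier trained on the database. Identical (sequence, species) pairs
#' are collapsed into one record whose `multiplicity` counts the copies.
#'
#' @param sequences Character vector of IUPAC DNA sequences (non-empty).
#' @param species Character vector of species labels, same length.
#' @param record_id Optional record identifiers; defaults to `seq_1 ...`.
#' @param multiplicity Optional positive integer copy counts.
#' @return An object of class `reference_db`: a list with `records` (a
#'   data.frame with columns record_id, sequence, species, multiplicity)
#'   and `label_index` (named integer vector, species -> class in 0..C-1,
#'   alphabetical and therefore stable under serialization).
#' @export
reference_db <- function(sequences, species, record_id = NULL,
                         multiplicity = NULL) {
  stopifnot(length(sequences) == length(species))
  if (!length(sequences)) stop("reference database must contain >= 1 record")
  if (any(!nzchar(sequences))) {
    stop(sprintf("empty sequence in record %d", which(!nzchar(sequences))[1]))
  }
  if (any(is.na(species) | !nzchar(species))) {
    stop(sprintf("empty species label in record %d",
                 which(is.na(species) | !nzchar(species))[1]))
  }
  sequences <- vapply(sequences, function(s) paste(.normalize_seq(s), collapse = ""),
                      character(1), USE.NAMES = FALSE)
  if (is.null(record_id)) record_id <- paste0("seq_", seq_along(sequences))
  if (is.null(multiplicity)) multiplicity <- rep(1L, length(sequences))

  key <- paste(species, sequences, sep = "\r")
  first <- !duplicated(key)
  mult <- as.integer(rowsum(as.numeric(multiplicity), key,
                            reorder = FALSE)[, 1])
  records <- data.frame(
    record_id = record_id[first],
    sequence = sequences[first],
    species = species[first],
    multiplicity = mult,
    stringsAsFactors = FALSE
  )
  labels <- sort(unique(records$species))
  label_index <- stats::setNames(seq_along(labels) - 1L, labels)
  structure(list(records = records, label_index = label_index),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf(
    "reference_db: %d records (%d total copies), %d species\n",
    nrow(x$records), sum(x$records$multiplicity), length(x$label_index)))
  invisible(x)
}

#' Number of species classes in a reference database
#' @param db A `reference_db`.
#' @return Integer count of distinct species labels.
#' @export
n_classes <- function(db) length(db$label_index)

#' Read a reference database from FASTA
#'
#' One record per FASTA entry. The species label is extracted from the
#' header by `label_parser`; the default takes everything after the first
#' whitespace (falling back to the whole header when there is none).
#' Duplicate (sequence, species) pairs collapse with multiplicity retained.
#'
#' @param path FASTA file path.
#' @param label_parser Function mapping a header string to a species label.
#' @return A [reference_db()].
#' @export
read_reference_fasta <- function(path, label_parser = default_label_parser) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop(sprintf("empty FASTA file: %s", path))
  headers <- names(seqs)
  labels <- vapply(headers, label_parser, character(1), USE.NAMES = FALSE)
  bad <- which(is.na(labels) | !nzchar(labels))
  if (length(bad)) {
    stop(sprintf("unparsable species label in FASTA record %d ('%s')",
                 bad[1], headers[bad[1]]))
  }
  ids <- sub("\\s.*$", "", headers)
  reference_db(as.character(seqs), labels, record_id = ids)
}

#' Default FASTA header label parser
#' @param header A FASTA header (without the leading `>`).
#' @return The species label: text after the first whitespace, or the whole
#'   header when it contains none.
#' @export
default_label_parser <- function(header) {
  if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else header
}

#' Write a reference database to FASTA
#'
#' Headers are `record_id species`; multiplicities are expanded back into
#' repeated entries so that a write/read round trip is faithful.
#'
#' @param db A `reference_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, path) {
  rec <- db$records
  idx <- rep(seq_len(nrow(rec)), rec$multiplicity)
  copy <- sequence(rec$multiplicity)
  ids <- ifelse(copy == 1L, rec$record_id[idx],
                paste0(rec$record_id[idx], ".", copy))
  x <- Biostrings::DNAStringSet(rec$sequence[idx])
  names(x) <- paste(ids, rec$species[idx])
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Serialize / read a species label index as JSON
#'
#' The label index (species -> dense 0-based class integer) is written as a
#' JSON object so that model checkpoints are self-describing; reading it
#' back reproduces the index exactly.
#'
#' @param label_index Named integer vector as in `reference_db$label_index`.
#' @param path JSON file path.
#' @return `write_label_index`: `path` invisibly; `read_label_index`: the
#'   named integer vector.
#' @export
write_label_index <- function(label_index, path) {
  jsonlite::write_json(as.list(label_index), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_index
#' @export
read_label_index <- function(path) {
  x <- jsonlite::read_json(path)
  stats::setNames(as.integer(unlist(x)), names(x))
}

# unique sequence strings per species, as a named list
.unique_seqs_by_species <- function(db) {
  split(db$records$sequence, db$records$species) |> lapply(unique)
}

#' Species eligible for split sampling
#'
#' Split sampling needs species with enough distinct sequences to populate
#' both partitions; uniqueness is by exact sequence string.
#'
#' @param db A `reference_db`.
#' @param min_unique Minimum number of unique sequences (default 2).
#' @return Character vector of eligible species labels (sorted).
#' @export
eligible_species_for_split <- function(db, min_unique = 2L) {
  stopifnot(min_unique >= 1L)
  u <- .unique_seqs_by_species(db)
  sort(names(u)[vapply(u, length, integer(1)) >= min_unique])
}

#' Restrict a reference database to a set of species
#'
#' @param db A `reference_db`.
#' @param species Character vector of species labels to keep.
#' @return A new `reference_db` (label index rebuilt over the kept species).
#' @export
subset_species <- function(db, species) {
  keep <- db$records$species %in% species
  if (!any(keep)) stop("no records left after subsetting")
  r <- db$records[keep, , drop = FALSE]
  reference_db(r$sequence, r$species, r$record_id, r$multiplicity)
}

#' Random split sampling of a reference database
#'
#' Per species, `holdout_per_species` randomly chosen unique sequences go to
#' the hold-out partition and the remainder to the training partition, so
#' that both partitions cover every species and the hold-out sequences are
#' never seen in training. All species present must have at least
#' `holdout_per_species + 1` unique sequences (restrict first with
#' [subset_species()] and [eligible_species_for_split()]).
#'
#' @param db A `reference_db` containing only eligible species.
#' @param holdout_per_species Unique sequences held out per species
#'   (default 1, the smallest split that covers every species).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with elements `train` and `holdout`, both `reference_db`
#'   objects sharing the same label universe.
#' @export
split_train_holdout <- function(db, holdout_per_species = 1L, seed = 1L) {
  u <- .unique_seqs_by_species(db)
  nu <- vapply(u, length, integer(1))
  short <- names(u)[nu < holdout_per_species + 1L]
  if (length(short)) {
    stop(sprintf(
      "species with fewer than %d unique sequences present (e.g. '%s'); restrict to eligible species first",
      holdout_per_species + 1L, short[1]))
  }
  hold <- .with_seed(seed, lapply(u, function(s) {
    s[sample.int(length(s), holdout_per_species)]
  }))
  rec <- db$records
  is_hold <- mapply(function(sq, sp) sq %in% hold[[sp]],
                    rec$sequence, rec$species, USE.NAMES = FALSE)
  mk <- function(keep) reference_db(rec$sequence[keep], rec$species[keep],
                                    rec$record_id[keep], rec$multiplicity[keep])
  list(train = mk(!is_hold), holdout = mk(is_hold))
}

# ---------------------------------------------------------------------------
# Tag manifest (ngsfilter dialect)

#' Construct a tag manifest
#'
#' The manifest maps each PCR-replicate sample to its demultiplexing tags
#' and amplification primers, plus the nested sampling hierarchy (which
#' filtration capsule and river the replicate belongs to).
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param forward_tag,reverse_tag Fixed-length tag sequences (default
#'   length 8) ligated 5' of each primer.
#' @param forward_primer,reverse_primer IUPAC primer sequences.
#' @param filter_id,river_id Optional hierarchy metadata (default: one
#'   filter per sample, one river overall).
#' @param experiment Library name stored in the ngsfilter `experiment`
#'   column.
#' @param tag_len Expected tag length; all tags are validated against it.
#' @return A data.frame of class `tag_manifest` with attribute `tag_len`.
#' @export
tag_manifest <- function(sample_id, forward_tag, reverse_tag,
                         forward_primer, reverse_primer,
                         filter_id = sample_id,
                         river_id = rep("river1", length(sample_id)),
                         experiment = rep("lib1", length(sample_id)),
                         tag_len = 8L) {
  n <- length(sample_id)
  stopifnot(length(forward_tag) == n, length(reverse_tag) == n,
            length(forward_primer) == n, length(reverse_primer) == n,
            length(filter_id) == n, length(river_id) == n)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id in manifest")
  forward_tag <- toupper(forward_tag); reverse_tag <- toupper(reverse_tag)
  badlen <- nchar(forward_tag) != tag_len | nchar(reverse_tag) != tag_len
  if (any(badlen)) {
    stop(sprintf("tag length != %d for sample '%s'", tag_len,
                 sample_id[which(badlen)[1]]))
  }
  pair <- paste(forward_tag, reverse_tag, sep = ":")
  if (anyDuplicated(pair)) {
    stop(sprintf("duplicate tag pair '%s'", pair[duplicated(pair)][1]))
  }
  out <- data.frame(
    experiment = experiment, sample_id = sample_id,
    forward_tag = forward_tag, reverse_tag = reverse_tag,
    forward_primer = toupper(forward_primer),
    reverse_primer = toupper(reverse_primer),
    filter_id = filter_id, river_id = river_id,
    stringsAsFactors = FALSE
  )
  structure(out, tag_len = as.integer(tag_len),
            class = c("tag_manifest", "data.frame"))
}

#' Read a tag manifest from an ngsfilter-style TSV
#'
#' Expected tab-separated columns: experiment, sample, tags as `FWD:REV`,
#' forward primer, reverse primer, then optional `key=value` metadata
#' fields (`filter=...`, `river=...`). Lines starting with `#` are skipped.
#' Ragged rows, malformed tag fields, tags of the wrong length and
#' duplicate tag pairs are rejected.
#'
#' @param path TSV path.
#' @param tag_len Expected tag length (default 8).
#' @return A [tag_manifest()].
#' @export
read_tag_manifest <- function(path, tag_len = 8L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop(sprintf("empty manifest: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    stop(sprintf("ragged manifest row %d: expected >= 5 tab-separated fields, got %d",
                 which(nf < 5L)[1], nf[which(nf < 5L)[1]]))
  }
  tags <- vapply(fields, `[[`, character(1), 3L)
  tp <- strsplit(tags, ":", fixed = TRUE)
  if (any(lengths(tp) != 2L)) {
    stop(sprintf("malformed tags field '%s' in manifest row %d (expected FWD:REV)",
                 tags[which(lengths(tp) != 2L)[1]], which(lengths(tp) != 2L)[1]))
  }
  meta <- function(key, default) {
    vapply(seq_along(fields), function(i) {
      extra <- fields[[i]][-(1:5)]
      hit <- grep(paste0("^", key, "="), extra, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else default[i]
    }, character(1))
  }
  sample_id <- vapply(fields, `[[`, character(1), 2L)
  tag_manifest(
    sample_id = sample_id,
    forward_tag = vapply(tp, `[[`, character(1), 1L),
    reverse_tag = vapply(tp, `[[`, character(1), 2L),
    forward_primer = vapply(fields, `[[`, character(1), 4L),
    reverse_primer = vapply(fields, `[[`, character(1), 5L),
    filter_id = meta("filter", sample_id),
    river_id = meta("river", rep("river1", length(fields))),
    experiment = vapply(fields, `[[`, character(1), 1L),
    tag_len = tag_len
  )
}

#' Write a tag manifest as ngsfilter-style TSV
#' @param manifest A [tag_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_manifest <- function(manifest, path) {
  lines <- sprintf("%s\t%s\t%s:%s\t%s\t%s\tfilter=%s\triver=%s",
                   manifest$experiment, manifest$sample_id,
                   manifest$forward_tag, manifest$reverse_tag,
                   manifest$forward_primer, manifest$reverse_primer,
                   manifest$filter_id, manifest$river_id)
  writeLines(lines, path)
  invisible(path)
}
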