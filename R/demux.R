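# Exact-match tag demultiplexing: assign raw reads to samples by hashing
# the first few positions of each read, with no tag error correction.

#' Build the tag lookup table
#'
#' Maps every tag of every sample — forward tag, reverse tag, and their
#' reverse complements (reads occur on either strand) — to the sample id.
#' Keys shared *within* a sample collapse; a key claimed by two different
#' samples (including a tag colliding with another sample's tag reverse
#' complement) is rejected at build time.
#'
#' @param manifest A [tag_manifest()].
#' @return Named character vector: tag string -> sample_id, with attribute
#'   `tag_len`.
#' @export
build_tag_table <- function(manifest) {
  stopifnot(inherits(manifest, "tag_manifest"))
  keys <- character(0); vals <- character(0)
  for (i in seq_len(nrow(manifest))) {
    k <- unique(c(manifest$forward_tag[i], manifest$reverse_tag[i],
                  .revcomp_many(c(manifest$forward_tag[i],
                                  manifest$reverse_tag[i]))))
    keys <- c(keys, k)
    vals <- c(vals, rep(manifest$sample_id[i], length(k)))
  }
  dup <- duplicated(keys)
  if (any(dup)) {
    clash <- keys[dup][1]
    stop(sprintf(
      "tag collision: key '%s' maps to samples %s (tags and their reverse complements must be unique across samples)",
      clash, paste(unique(vals[keys == clash]), collapse = ", ")))
  }
  structure(stats::setNames(vals, keys), tag_len = attr(manifest, "tag_len"))
}

#' Assign a read to a sample by exact tag lookup
#'
#' Probes `max_offset` start offsets (0 .. `max_offset` − 1): at each, the
#' `tag_len`-mer starting there is looked up in the table; the first hit
#' wins. Offsets absorb the 0-2 plate-attachment bases that are often read
#' before the tag. There is no mismatch tolerance: a single substitution
#' inside the tag leaves the read unassigned (`NA`).
#'
#' @param read Read sequence string (vectorized).
#' @param table Lookup table from [build_tag_table()].
#' @param tag_len Tag length (default: the table's `tag_len`).
#' @param max_offset Number of offsets probed (default 5).
#' @return Character vector of sample ids, `NA` where unassigned.
#' @export
assign_read <- function(read, table, tag_len = attr(table, "tag_len"),
                        max_offset = 5L) {
  stopifnot(tag_len >= 1L, max_offset >= 1L)
  reads <- toupper(read)
  out <- rep(NA_character_, length(reads))
  keys <- names(table)
  for (o in 0:(max_offset - 1L)) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    sub <- substr(reads[todo], o + 1L, o + tag_len)
    hit <- match(sub, keys)
    found <- !is.na(hit) & nchar(sub) == tag_len
    out[todo[found]] <- unname(table[hit[found]])
  }
  out
}

#' Demultiplex a FASTQ file
#'
#' Reads a FASTQ(.gz) file, assigns every read to a sample with
#' [assign_read()], and returns per-sample read sets plus counts. Every
#' read lands in exactly one bucket (a sample or `UNASSIGNED`), so bucket
#' counts always sum to the input read count. Qualities are ignored.
#'
#' @param fastq_path FASTQ or gzipped FASTQ path.
#' @param manifest A [tag_manifest()].
#' @param max_offset Offsets probed per read (default 5).
#' @return List with `reads` (named list sample_id -> character vector of
#'   read sequences), `unassigned` (character vector), `counts` (named
#'   integer vector over all manifest samples plus `UNASSIGNED`), and
#'   `assignments` (per-read sample id or `NA`, in file order).
#' @export
demux_fastq <- function(fastq_path, manifest, max_offset = 5L) {
  seqs <- as.character(Biostrings::readDNAStringSet(fastq_path, format = "fastq"))
  demux_reads(seqs, manifest, max_offset = max_offset)
}

#' @rdname demux_fastq
#' @param reads Character vector of read sequences (alternative entry point
#'   when reads are already in memory).
#' @export
demux_reads <- function(reads, manifest, max_offset = 5L) {
  table <- build_tag_table(manifest)
  assignments <- if (length(reads)) assign_read(reads, table,
                                                max_offset = max_offset)
                 else character(0)
  samples <- manifest$sample_id
  counts <- stats::setNames(integer(length(samples) + 1L),
                            c(samples, "UNASSIGNED"))
  tab <- table(factor(ifelse(is.na(assignments), "UNASSIGNED", assignments),
                      levels = names(counts)))
  counts[] <- as.integer(tab)
  by_sample <- lapply(stats::setNames(samples, samples),
                      function(s) reads[!is.na(assignments) & assignments == s])
  list(reads = by_sample,
       unassigned = reads[is.na(assignments)],
       counts = counts,
       assignments = assignments)
}

#' Write demultiplexing counts as TSV
#' @param counts Named counts from [demux_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demux_counts <- function(counts, path) {
  utils::write.table(
    data.frame(sample_id = names(counts), reads = as.integer(counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
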