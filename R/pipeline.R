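# End-to-end application: FASTQ (raw or pre-demultiplexed) -> thresholded
# per-sample species read-count tables, with replicate/filter/river
# aggregation.

#' Per-sample species read-count table
#'
#' Long-format counts keyed by PCR-replicate sample, with the nested
#' sampling hierarchy (replicate -> filtration capsule -> river) and run
#' metadata attached.
#'
#' @param counts data.frame with columns `sample_id`, `species`, `reads`
#'   (non-negative integers); zero rows are dropped.
#' @param hierarchy data.frame with columns `sample_id`, `filter_id`,
#'   `river_id` covering every sample in `counts`.
#' @param meta Named list of run metadata (threshold, min_reads,
#'   rejected/unassigned read counts, ...).
#' @return An object of class `sample_table`.
#' @export
sample_table <- function(counts, hierarchy, meta = list()) {
  stopifnot(all(c("sample_id", "species", "reads") %in% names(counts)),
            all(c("sample_id", "filter_id", "river_id") %in% names(hierarchy)))
  counts <- counts[counts$reads > 0, c("sample_id", "species", "reads")]
  if (any(counts$reads < 0)) stop("negative read counts")
  counts$reads <- as.integer(counts$reads)
  missing <- setdiff(counts$sample_id, hierarchy$sample_id)
  if (length(missing))
    stop(sprintf("sample '%s' missing from hierarchy", missing[1]))
  hierarchy <- unique(hierarchy[, c("sample_id", "filter_id", "river_id")])
  if (anyDuplicated(hierarchy$sample_id))
    stop("conflicting hierarchy rows for a sample")
  rownames(counts) <- NULL
  rownames(hierarchy) <- NULL
  structure(list(counts = counts, hierarchy = hierarchy, meta = meta),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf(
    "sample_table: %d samples, %d species, %s reads (level: %s)\n",
    length(unique(x$counts$sample_id)), length(unique(x$counts$species)),
    format(sum(x$counts$reads), big.mark = ","),
    if (is.null(x$meta$level)) "replicate" else x$meta$level))
  invisible(x)
}

#' Classify a set of reads into per-species counts
#'
#' Applies the classifier with rejection at threshold `t` and tallies
#' accepted reads per species. Invalid reads (non-IUPAC characters) are
#' counted with the rejected. Counts plus rejected always sum to the
#' number of input reads.
#'
#' @param reads Character vector of read sequences.
#' @param classifier A trained `cnn_classifier`.
#' @param t Binarization threshold (default 0.9).
#' @param chunk_size Passed to [predict_proba()].
#' @return List with `counts` (named integer vector over detected species)
#'   and `rejected` (integer).
#' @export
classify_reads <- function(reads, classifier, t = 0.9, chunk_size = 4096L) {
  if (!length(reads)) return(list(counts = integer(0), rejected = 0L))
  probs <- predict_proba(classifier, reads, chunk_size = chunk_size)
  labels <- classify_with_threshold(probs, t)
  acc <- labels[!is.na(labels)]
  counts <- if (length(acc)) {
    tb <- table(acc)
    stats::setNames(as.integer(tb), names(tb))
  } else integer(0)
  list(counts = counts, rejected = sum(is.na(labels)))
}

#' Filter species by a minimum read count per PCR replicate
#'
#' A species is retained in a replicate only when its read count there
#' reaches `min_reads`; removed cells are zeroed (dropped). Applying a
#' stricter threshold after a weaker one equals applying the stricter one
#' directly.
#'
#' @param table A [sample_table()] at replicate level.
#' @param min_reads Non-negative detection threshold (`0` = identity).
#' @return The filtered `sample_table` (meta records `min_reads`).
#' @export
apply_min_reads <- function(table, min_reads) {
  stopifnot(inherits(table, "sample_table"), min_reads >= 0)
  counts <- table$counts[table$counts$reads >= min_reads, , drop = FALSE]
  rownames(counts) <- NULL
  meta <- table$meta
  meta$min_reads <- max(min_reads, if (is.null(meta$min_reads)) 0 else meta$min_reads)
  sample_table(counts, table$hierarchy, meta)
}

#' Aggregate a sample table to filter or river level
#'
#' Sums read counts within the requested grouping of the sampling
#' hierarchy; `level = "replicate"` is the identity. Aggregation preserves
#' total reads.
#'
#' @param table A [sample_table()] at replicate level.
#' @param level One of `"replicate"`, `"filter"`, `"river"`.
#' @return A `sample_table` whose `sample_id`s are the group ids.
#' @export
aggregate_table <- function(table, level = c("replicate", "filter", "river")) {
  level <- match.arg(level)
  if (level == "replicate") return(table)
  h <- table$hierarchy
  key <- if (level == "filter") h$filter_id else h$river_id
  group <- stats::setNames(key, h$sample_id)
  cnt <- table$counts
  cnt$sample_id <- unname(group[cnt$sample_id])
  agg <- stats::aggregate(reads ~ sample_id + species, data = cnt, FUN = sum)
  hier <- if (level == "filter") {
    unique(data.frame(sample_id = h$filter_id, filter_id = h$filter_id,
                      river_id = h$river_id))
  } else {
    unique(data.frame(sample_id = h$river_id, filter_id = h$river_id,
                      river_id = h$river_id))
  }
  meta <- table$meta
  meta$level <- level
  sample_table(agg, hier, meta)
}

#' Raw-FASTQ pipeline: demultiplex, classify, threshold
#'
#' The end-to-end application path: raw reads are demultiplexed by exact
#' tag lookup, every assigned read is classified with rejection at
#' threshold `t`, and the per-replicate species counts are filtered at
#' `min_reads`. Unassigned and rejected reads never contribute counts but
#' are reported in the metadata.
#'
#' @param fastq_path Raw FASTQ(.gz) path.
#' @param manifest A [tag_manifest()].
#' @param classifier A trained `cnn_classifier`.
#' @param t Binarization threshold (default 0.9).
#' @param min_reads Per-replicate detection threshold (default 50).
#' @param max_offset Demultiplexing offsets probed (default 5).
#' @return A [sample_table()] at replicate level; `meta` records all
#'   parameters plus unassigned/rejected read counts.
#' @export
run_raw <- function(fastq_path, manifest, classifier, t = 0.9,
                    min_reads = 50L, max_offset = 5L) {
  dm <- demux_fastq(fastq_path, manifest, max_offset = max_offset)
  .classify_demuxed(dm, manifest, classifier, t, min_reads,
                    mode = "raw", n_unassigned = length(dm$unassigned))
}

#' Clean-reads pipeline: classify pre-demultiplexed reads
#'
#' Consumes reads that were already merged, cleaned and demultiplexed by an
#' upstream pipeline (one read set per sample) and applies the same
#' classification and thresholding as [run_raw()].
#'
#' @param reads_by_sample Named list: sample_id -> character vector of
#'   reads.
#' @param manifest A [tag_manifest()] supplying the hierarchy.
#' @param classifier,t,min_reads As in [run_raw()].
#' @return A [sample_table()] at replicate level.
#' @export
run_clean <- function(reads_by_sample, manifest, classifier, t = 0.9,
                      min_reads = 50L) {
  stopifnot(!is.null(names(reads_by_sample)))
  missing <- setdiff(names(reads_by_sample), manifest$sample_id)
  if (length(missing))
    stop(sprintf("sample '%s' not in manifest", missing[1]))
  dm <- list(reads = reads_by_sample)
  .classify_demuxed(dm, manifest, classifier, t, min_reads,
                    mode = "clean", n_unassigned = 0L)
}

.classify_demuxed <- function(dm, manifest, classifier, t, min_reads,
                              mode, n_unassigned) {
  rows <- list()
  rejected <- 0L
  for (s in names(dm$reads)) {
    cl <- classify_reads(dm$reads[[s]], classifier, t = t)
    rejected <- rejected + cl$rejected
    if (length(cl$counts)) {
      rows[[s]] <- data.frame(sample_id = s, species = names(cl$counts),
                              reads = as.integer(cl$counts))
    }
  }
  counts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), species = character(0),
               reads = integer(0))
  hierarchy <- data.frame(sample_id = manifest$sample_id,
                          filter_id = manifest$filter_id,
                          river_id = manifest$river_id)
  tab <- sample_table(counts, hierarchy,
                      meta = list(mode = mode, threshold = t,
                                  min_reads = 0L,
                                  n_rejected = rejected,
                                  n_unassigned = n_unassigned))
  apply_min_reads(tab, min_reads)
}

#' Read / write a sample table as long-format TSV
#'
#' Columns: sample_id, filter_id, river_id, species, reads. Metadata can be
#' written alongside as JSON.
#'
#' @param table A [sample_table()].
#' @param path TSV path.
#' @param meta_path Optional JSON path for the metadata.
#' @return `write_sample_table`: `path` invisibly; `read_sample_table`: a
#'   `sample_table`.
#' @export
write_sample_table <- function(table, path, meta_path = NULL) {
  h <- table$hierarchy
  m <- match(table$counts$sample_id, h$sample_id)
  out <- data.frame(sample_id = table$counts$sample_id,
                    filter_id = h$filter_id[m], river_id = h$river_id[m],
                    species = table$counts$species,
                    reads = table$counts$reads)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    jsonlite::write_json(table$meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path, meta_path = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "character", "integer"))
  meta <- if (!is.null(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  sample_table(df[, c("sample_id", "species", "reads")],
               unique(df[, c("sample_id", "filter_id", "river_id")]),
               meta)
}
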