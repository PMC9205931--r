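# Training-time data augmentation: class balancing, substitution noise,
# random indels, raw-read-style decoration, reverse complements.
#
# All stochastic operators draw from R's global RNG; callers (train_classifier,
# the simulator, the tests) seed it once so whole runs are reproducible.

#' Augmentation configuration
#'
#' Bundles the stochastic transforms applied to every reference sequence at
#' each training epoch. Training defaults: 5% per-position substitution
#' rate, up to 2 insertions and 2 deletions. Evaluation-grade noise (see
#' [eval_augment_config()]) uses 2% and single indels, reflecting that PCR
#' and sequencing are expected to be cleaner than the noise injected during
#' training. Decoration emulates the structure of a raw Illumina read: a
#' 10-bp block of `N` (standing in for the 8-bp tag plus up to 2 attachment
#' bases), the forward primer, the amplicon, the reverse complement of the
#' reverse primer, and a trailing `N` block — shifting the amplicon to the
#' position where it occurs in raw reads.
#'
#' @param sub_rate Per-position substitution probability in `[0,1]`.
#' @param max_insertions,max_deletions Upper bounds of the uniform number of
#'   random insertions/deletions per sequence.
#' @param n_prefix_len Length of the `N` blocks added by decoration.
#' @param decorate Logical: decorate sequences with primers and `N` blocks
#'   (required when the classifier will be applied to raw reads).
#' @param add_reverse_complements Logical: also emit the reverse complement
#'   of every augmented sequence (reads occur on either strand).
#' @param target_width Model input width in positions (default 150, the
#'   Illumina read length).
#' @param prefix_jitter During epoch-batch construction the lengths of the
#'   leading and trailing `N` blocks are drawn independently and uniformly
#'   from `[n_prefix_len - prefix_jitter, n_prefix_len]` (default 2),
#'   covering the 0-2 attachment bases actually read before the tag, so
#'   the amplicon is seen at every position where raw reads place it.
#'   Set to 0 for fixed-length blocks. [decorate_read()] itself always
#'   uses fixed blocks.
#' @param forward_primer,reverse_primer Primer sequences used by decoration.
#' @param concrete_tags Logical: decorate with concrete random tags instead
#'   of `N` blocks (ablation option; the default `N` decoration keeps the
#'   classifier tag-agnostic).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(sub_rate = 0.05,
                           max_insertions = 2L, max_deletions = 2L,
                           n_prefix_len = 10L,
                           decorate = FALSE,
                           add_reverse_complements = FALSE,
                           target_width = 150L,
                           prefix_jitter = 2L,
                           forward_primer = "", reverse_primer = "",
                           concrete_tags = FALSE) {
  stopifnot(sub_rate >= 0, sub_rate <= 1,
            max_insertions >= 0, max_deletions >= 0,
            n_prefix_len >= 0, target_width >= 1,
            prefix_jitter >= 0, prefix_jitter <= n_prefix_len)
  structure(list(
    sub_rate = sub_rate,
    max_insertions = as.integer(max_insertions),
    max_deletions = as.integer(max_deletions),
    n_prefix_len = as.integer(n_prefix_len),
    decorate = isTRUE(decorate),
    add_reverse_complements = isTRUE(add_reverse_complements),
    target_width = as.integer(target_width),
    prefix_jitter = as.integer(prefix_jitter),
    forward_primer = toupper(forward_primer),
    reverse_primer = toupper(reverse_primer),
    concrete_tags = isTRUE(concrete_tags)
  ), class = "augment_config")
}

#' Evaluation-mode augmentation configuration
#'
#' 2% substitution noise with at most one insertion and one deletion,
#' used to emulate realistic read noise when evaluating a classifier.
#'
#' @param ... Overrides passed to [augment_config()].
#' @return An `augment_config`.
#' @export
eval_augment_config <- function(...) {
  defaults <- list(sub_rate = 0.02, max_insertions = 1L, max_deletions = 1L)
  do.call(augment_config, utils::modifyList(defaults, list(...)))
}

#' Serialize / read an augmentation configuration as JSON
#' @param config An [augment_config()].
#' @param path JSON file path.
#' @return `write_augment_config`: `path` invisibly; `read_augment_config`:
#'   the configuration.
#' @export
write_augment_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_augment_config
#' @export
read_augment_config <- function(path) {
  do.call(augment_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Random base substitutions
#'
#' Each position is independently mutated with probability `sub_rate`. A
#' mutated canonical base is replaced by one of the three *other* canonical
#' bases (uniformly), so the observed change rate equals `sub_rate`; a
#' mutated ambiguity code is replaced by a uniform draw over A/C/G/T.
#' Length is preserved.
#'
#' @param seq IUPAC DNA string.
#' @param sub_rate Per-position substitution probability.
#' @return Mutated sequence string.
#' @export
substitute_bases <- function(seq, sub_rate) {
  stopifnot(sub_rate >= 0, sub_rate <= 1)
  chars <- .normalize_seq(seq)
  n <- length(chars)
  hit <- which(stats::runif(n) < sub_rate)
  if (!length(hit)) return(paste(chars, collapse = ""))
  cur <- chars[hit]
  canon <- match(cur, .BASES)
  is_can <- !is.na(canon)
  new <- character(length(hit))
  if (any(is_can)) {
    # uniform over the 3 bases different from the original
    shift <- sample.int(3L, sum(is_can), replace = TRUE)
    new[is_can] <- .BASES[((canon[is_can] - 1L + shift) %% 4L) + 1L]
  }
  if (any(!is_can)) {
    new[!is_can] <- .BASES[sample.int(4L, sum(!is_can), replace = TRUE)]
  }
  chars[hit] <- new
  paste(chars, collapse = "")
}

#' Random insertions and deletions
#'
#' Draws `k_ins ~ Uniform{0..max_insertions}` random canonical bases and
#' inserts them at uniform positions, then deletes
#' `k_del ~ Uniform{0..max_deletions}` uniformly chosen positions (capped
#' at length − 1 so the sequence never vanishes). Output length is
#' `len + k_ins - k_del`.
#'
#' @param seq IUPAC DNA string.
#' @param max_insertions,max_deletions Bounds of the uniform indel counts.
#' @return Mutated sequence string.
#' @export
apply_indels <- function(seq, max_insertions = 2L, max_deletions = 2L) {
  chars <- .normalize_seq(seq)
  k_ins <- sample.int(max_insertions + 1L, 1L) - 1L
  if (k_ins > 0L) {
    for (i in seq_len(k_ins)) {
      pos <- sample.int(length(chars) + 1L, 1L) - 1L  # insert after `pos`
      chars <- append(chars, .BASES[sample.int(4L, 1L)], after = pos)
    }
  }
  k_del <- min(sample.int(max_deletions + 1L, 1L) - 1L, length(chars) - 1L)
  if (k_del > 0L) {
    chars <- chars[-sample.int(length(chars), k_del)]
  }
  paste(chars, collapse = "")
}

#' Decorate an amplicon like a raw Illumina read
#'
#' Returns `N^k + forward_primer + seq + revcomp(reverse_primer) + N^k`
#' with `k = n_prefix_len`. The `N` blocks stand in for the 8-bp tag plus
#' up to 2 attachment bases that precede the primer in raw reads (and the
#' tag complement downstream), so a classifier trained on decorated
#' sequences sees the amplicon at its raw-read position while remaining
#' tag-agnostic.
#'
#' @param seq Amplicon sequence.
#' @param forward_primer,reverse_primer Primer sequences; the reverse
#'   primer is appended as its reverse complement (its orientation in a
#'   forward read).
#' @param n_prefix_len Length of the `N` blocks (default 10).
#' @return Decorated sequence string.
#' @export
decorate_read <- function(seq, forward_primer = "", reverse_primer = "",
                          n_prefix_len = 10L) {
  nb <- strrep("N", n_prefix_len)
  rp <- if (nzchar(reverse_primer)) reverse_complement(reverse_primer) else ""
  paste0(nb, toupper(forward_primer), toupper(seq), rp, nb)
}

#' Balance a reference database by oversampling
#'
#' Every species is brought up to the same total record count — the maximum
#' per-species count in the input — by sampling its records with
#' replacement. Copy counts are tracked through record multiplicities.
#'
#' @param db A [reference_db()].
#' @param seed Integer seed (sampling is deterministic given it).
#' @return A balanced `reference_db` with `n_classes(db) * max_count` total
#'   copies.
#' @export
balance_oversample <- function(db, seed = 1L) {
  rec <- db$records
  tot <- tapply(rec$multiplicity, rec$species, sum)
  target <- max(tot)
  extra <- .with_seed(seed, {
    lapply(names(tot), function(sp) {
      need <- target - tot[[sp]]
      if (need == 0L) return(integer(0))
      rows <- which(rec$species == sp)
      rows[sample.int(length(rows), need, replace = TRUE,
                      prob = rec$multiplicity[rows])]
    })
  })
  add <- tabulate(unlist(extra), nbins = nrow(rec))
  reference_db(rec$sequence, rec$species, rec$record_id,
               rec$multiplicity + add)
}

# Expand a reference_db into per-copy vectors (sequence, class)
.expand_records <- function(db) {
  rec <- db$records
  idx <- rep(seq_len(nrow(rec)), rec$multiplicity)
  list(sequence = rec$sequence[idx],
       class = unname(db$label_index[rec$species[idx]]))
}

#' Build one augmented training epoch
#'
#' Applies, per record copy: optional decoration, indels, substitutions,
#' optional reverse-complement duplication; then encodes and shapes every
#' sequence to the target width. Randomness is drawn fresh from the global
#' RNG, so successive epochs essentially never repeat a training sample.
#'
#' @param db A [reference_db()] (balance beforehand with
#'   [balance_oversample()] if desired).
#' @param config An [augment_config()].
#' @return List with `inputs` (a `(4*target_width) x N` matrix, one encoded
#'   sequence per column in position-major layout), `labels` (0-based class
#'   integers), and `sequences` (the augmented strings).
#' @export
make_epoch_batch <- function(db, config = augment_config()) {
  ex <- .expand_records(db)
  seqs <- ex$sequence
  if (config$decorate) {
    lo <- config$n_prefix_len - config$prefix_jitter
    span <- config$prefix_jitter + 1L
    n_lead <- lo + sample.int(span, length(seqs), replace = TRUE) - 1L
    n_trail <- lo + sample.int(span, length(seqs), replace = TRUE) - 1L
    rp <- if (nzchar(config$reverse_primer))
      reverse_complement(config$reverse_primer) else ""
    if (config$concrete_tags) {
      seqs <- vapply(seq_along(seqs), function(i) {
        paste0(.random_bases(n_lead[i]), config$forward_primer, seqs[i],
               rp, .random_bases(n_trail[i]))
      }, character(1))
    } else {
      seqs <- paste0(strrep("N", n_lead), config$forward_primer, seqs,
                     rp, strrep("N", n_trail))
    }
  }
  if (config$max_insertions > 0L || config$max_deletions > 0L) {
    seqs <- vapply(seqs, apply_indels, character(1),
                   max_insertions = config$max_insertions,
                   max_deletions = config$max_deletions, USE.NAMES = FALSE)
  }
  if (config$sub_rate > 0) {
    seqs <- vapply(seqs, substitute_bases, character(1),
                   sub_rate = config$sub_rate, USE.NAMES = FALSE)
  }
  labels <- ex$class
  if (config$add_reverse_complements) {
    seqs <- c(seqs, .revcomp_many(seqs))
    labels <- c(labels, labels)
  }
  list(inputs = .encode_batch(seqs, config$target_width),
       labels = labels, sequences = seqs)
}
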