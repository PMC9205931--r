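# Synthetic data: reference databases, tag manifests and raw FASTQ read
# sets with known ground truth, emulating a short-amplicon (12S "teleo"
# style) metabarcoding experiment so that every pipeline stage is testable
# without restricted field data.

# default teleo-style 12S primer pair (forward 17 bp, reverse 20 bp)
.DEFAULT_FWD_PRIMER <- "ACACCGCCCGTCACTCT"
.DEFAULT_REV_PRIMER <- "CTTCCGGTACACTTACCATG"

.random_bases <- function(n) {
  paste(.BASES[sample.int(4L, n, replace = TRUE)], collapse = "")
}

# mutate exactly k distinct positions of a character vector, each to a
# different canonical base
.mutate_k <- function(chars, k) {
  pos <- sample.int(length(chars), k)
  cur <- match(chars[pos], .BASES)
  cur[is.na(cur)] <- 1L
  shift <- sample.int(3L, k, replace = TRUE)
  chars[pos] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  chars
}

#' Simulate a reference barcode database
#'
#' Generates species consensus amplicons whose pairwise Hamming divergence
#' is at least `min_divergence` (as a fraction of positions), then draws
#' per-species sequence variants differing from their consensus at no more
#' than `min_divergence / 2` of positions — so intraspecific variation
#' never exceeds half the interspecific gap. The per-species sequence
#' count is uniform over `seqs_per_species_range`, mimicking the skewed
#' coverage of real barcode databases. Deterministic given `seed`.
#'
#' @param n_species Number of species (>= 2).
#' @param amplicon_len Amplicon length in bp (default 60, a teleo-sized
#'   fragment).
#' @param min_divergence Minimum pairwise consensus divergence as a
#'   fraction of positions (default 0.05, a few percent as typical for
#'   congeneric 12S barcodes).
#' @param seqs_per_species_range Length-2 integer range of sequences per
#'   species (default 1 to 10).
#' @param seed Integer seed.
#' @return List with `db` (a [reference_db()]; species are named
#'   `species_001 ...`) and `consensus` (named character vector of
#'   consensus sequences).
#' @export
simulate_reference_db <- function(n_species, amplicon_len = 60L,
                                  min_divergence = 0.05,
                                  seqs_per_species_range = c(1L, 10L),
                                  seed = 1L) {
  stopifnot(n_species >= 2L, amplicon_len >= 1L,
            min_divergence >= 0, min_divergence <= 1,
            length(seqs_per_species_range) == 2L)
  d_min <- ceiling(min_divergence * amplicon_len)
  if (d_min > amplicon_len)
    stop("min_divergence infeasible for this amplicon length")
  .with_seed(seed, {
    cons <- matrix("", nrow = amplicon_len, ncol = 0L)
    tries <- 0L
    while (ncol(cons) < n_species) {
      cand <- .BASES[sample.int(4L, amplicon_len, replace = TRUE)]
      ok <- !ncol(cons) || all(colSums(cons != cand) >= d_min)
      if (ok) cons <- cbind(cons, cand)
      tries <- tries + 1L
      if (tries > 1000L * n_species)
        stop("could not place species consensus sequences at the requested divergence")
    }
    sp_names <- sprintf("species_%03d", seq_len(n_species))
    max_var <- floor(min_divergence * amplicon_len / 2)
    lo <- seqs_per_species_range[1]; hi <- seqs_per_species_range[2]
    seqs <- character(0); labels <- character(0)
    for (s in seq_len(n_species)) {
      n_seq <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      variants <- paste(cons[, s], collapse = "")
      while (length(variants) < n_seq) {
        if (max_var == 0L) {  # no room for distinct variants: repeat consensus
          variants <- c(variants, variants[1])
          next
        }
        v <- paste(.mutate_k(cons[, s], sample.int(max_var, 1L)),
                   collapse = "")
        if (!(v %in% variants)) variants <- c(variants, v)
      }
      seqs <- c(seqs, variants)
      labels <- c(labels, rep(sp_names[s], n_seq))
    }
    consensus <- stats::setNames(apply(cons, 2L, paste, collapse = ""),
                                 sp_names)
    list(db = reference_db(seqs, labels), consensus = consensus)
  })
}

#' Simulate a tag manifest
#'
#' Draws distinct random tags (one per PCR-replicate sample, used as both
#' forward and reverse tag, with reverse-complement collisions avoided so
#' the demultiplexing table always builds) and lays the samples out on a
#' nested hierarchy: `replicates_per_filter` PCR replicates per filtration
#' capsule and `filters_per_river` capsules per river.
#'
#' @param n_samples Number of PCR-replicate samples.
#' @param replicates_per_filter,filters_per_river Hierarchy layout
#'   (defaults 2 and 2).
#' @param tag_len Tag length (default 8).
#' @param forward_primer,reverse_primer Primer pair (teleo-style 12S
#'   defaults).
#' @param seed Integer seed.
#' @return A [tag_manifest()].
#' @export
simulate_tag_manifest <- function(n_samples, replicates_per_filter = 2L,
                                  filters_per_river = 2L, tag_len = 8L,
                                  forward_primer = .DEFAULT_FWD_PRIMER,
                                  reverse_primer = .DEFAULT_REV_PRIMER,
                                  seed = 1L) {
  stopifnot(n_samples >= 1L, tag_len >= 1L)
  .with_seed(seed, {
    tags <- character(0)
    while (length(tags) < n_samples) {
      cand <- .random_bases(tag_len)
      clash <- c(tags, .revcomp_many(tags))
      if (!(cand %in% clash) && !(reverse_complement(cand) %in% c(clash, cand)))
        tags <- c(tags, cand)
    }
    filt <- ceiling(seq_len(n_samples) / replicates_per_filter)
    river <- ceiling(filt / filters_per_river)
    tag_manifest(
      sample_id = sprintf("sample_%02d", seq_len(n_samples)),
      forward_tag = tags, reverse_tag = tags,
      forward_primer = rep(forward_primer, n_samples),
      reverse_primer = rep(reverse_primer, n_samples),
      filter_id = sprintf("filter_%02d", filt),
      river_id = sprintf("river_%02d", river),
      tag_len = tag_len)
  })
}

#' Simulate a raw Illumina FASTQ read set with ground truth
#'
#' Every read reproduces the structure of a raw single-end 150-bp
#' metabarcoding read: 0-2 random plate-attachment bases, the sample tag,
#' the forward primer, the species amplicon (with substitution errors at
#' `error_rate`), the reverse complement of the reverse primer, the
#' reverse complement of the tag, and random downstream filler, truncated
#' to 150 bp. A fraction `revcomp_fraction` of reads is emitted from the
#' opposite strand (tag and primers of the reverse side leading). Reads
#' are assigned to samples uniformly and to species according to the
#' per-sample composition weights. Qualities are a constant `I` (they are
#' not used by the classifier).
#'
#' @param db A [reference_db()] (e.g. from [simulate_reference_db()]).
#' @param manifest A [tag_manifest()].
#' @param composition Named list: sample_id -> named non-negative weight
#'   vector over species. Default: uniform over all species of `db` for
#'   every sample.
#' @param n_reads Total reads to emit.
#' @param error_rate Per-position substitution error probability applied to
#'   the amplicon (default 0.01; substitution-only, matching the
#'   augmentation error model).
#' @param indel_error_rate Optional per-read probability of one random
#'   indel in the amplicon (default 0: substitution-only model).
#' @param revcomp_fraction Fraction of reads emitted reverse-complemented
#'   (default 0.5: either strand equally likely).
#' @param read_len Read length (default 150).
#' @param path Output FASTQ path (`.gz` supported); default a tempfile.
#' @param seed Integer seed.
#' @return List with `fastq` (path), `truth` (data.frame read_id,
#'   sample_id, species), and `composition` (the weights used).
#' @export
simulate_raw_fastq <- function(db, manifest, composition = NULL,
                               n_reads = 1000L, error_rate = 0.01,
                               indel_error_rate = 0,
                               revcomp_fraction = 0.5, read_len = 150L,
                               path = tempfile(fileext = ".fastq"),
                               seed = 1L) {
  stopifnot(inherits(db, "reference_db"), inherits(manifest, "tag_manifest"),
            n_reads >= 1L, error_rate >= 0, error_rate <= 1,
            revcomp_fraction >= 0, revcomp_fraction <= 1)
  species_all <- names(db$label_index)
  if (is.null(composition)) {
    composition <- stats::setNames(rep(list(
      stats::setNames(rep(1, length(species_all)), species_all)),
      nrow(manifest)), manifest$sample_id)
  }
  if (!all(names(composition) %in% manifest$sample_id))
    stop("composition names must be manifest sample ids")
  .with_seed(seed, {
    samples <- names(composition)
    s_idx <- sample.int(length(samples), n_reads, replace = TRUE)
    species <- character(n_reads)
    for (i in seq_along(samples)) {
      take <- s_idx == i
      w <- composition[[i]]
      if (any(w < 0) || sum(w) == 0) stop("invalid composition weights")
      species[take] <- sample(names(w), sum(take), replace = TRUE,
                              prob = w / sum(w))
    }
    # pick a variant record per read, weighted by record multiplicity
    rec <- db$records
    amp <- character(n_reads)
    for (sp in unique(species)) {
      rows <- which(rec$species == sp)
      if (!length(rows)) stop(sprintf("species '%s' not in reference db", sp))
      take <- which(species == sp)
      pick <- if (length(rows) == 1L) rep(rows, length(take))
              else sample(rows, length(take), replace = TRUE,
                          prob = rec$multiplicity[rows])
      amp[take] <- rec$sequence[pick]
    }
    if (error_rate > 0) {
      amp <- vapply(amp, substitute_bases, character(1),
                    sub_rate = error_rate, USE.NAMES = FALSE)
    }
    if (indel_error_rate > 0) {
      hit <- stats::runif(n_reads) < indel_error_rate
      amp[hit] <- vapply(amp[hit], apply_indels, character(1),
                         max_insertions = 1L, max_deletions = 1L,
                         USE.NAMES = FALSE)
    }
    m <- match(samples[s_idx], manifest$sample_id)
    ftag <- manifest$forward_tag[m]; rtag <- manifest$reverse_tag[m]
    fpr <- manifest$forward_primer[m]; rpr <- manifest$reverse_primer[m]
    att_n <- sample(0:2, n_reads, replace = TRUE)
    att_pool <- .random_bases(4096L)
    att_start <- sample.int(4000L, n_reads, replace = TRUE)
    att <- substr(rep(att_pool, n_reads), att_start, att_start + att_n - 1L)
    rc <- .revcomp_many
    is_rc <- stats::runif(n_reads) < revcomp_fraction
    core <- character(n_reads)
    fwd <- !is_rc
    if (any(fwd)) {
      core[fwd] <- paste0(att[fwd], ftag[fwd], fpr[fwd], amp[fwd],
                          rc(rpr[fwd]), rc(rtag[fwd]))
    }
    if (any(is_rc)) {
      core[is_rc] <- paste0(att[is_rc], rtag[is_rc], rpr[is_rc],
                            rc(amp[is_rc]), rc(fpr[is_rc]), rc(ftag[is_rc]))
    }
    fill_pool <- .random_bases(65536L)
    fill_start <- sample.int(65536L - read_len, n_reads, replace = TRUE)
    reads <- paste0(core, substr(rep(fill_pool, n_reads), fill_start,
                                 fill_start + read_len - 1L))
    reads <- substr(reads, 1L, read_len)
    ids <- sprintf("read_%07d", seq_len(n_reads))
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- ids
    qual <- Biostrings::BStringSet(rep(strrep("I", read_len), n_reads))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                                compress = grepl("\\.gz$", path))
    list(fastq = path,
         truth = data.frame(read_id = ids, sample_id = samples[s_idx],
                            species = species, stringsAsFactors = FALSE),
         composition = composition)
  })
}

#' Ground-truth sample table from a simulation truth table
#'
#' Tallies the simulated reads per (sample, species) into a
#' [sample_table()], the reference against which pipeline output can be
#' compared (e.g. with [median_agreement()]).
#'
#' @param truth The `truth` data.frame from [simulate_raw_fastq()].
#' @param manifest The [tag_manifest()] used in the simulation.
#' @return A [sample_table()].
#' @export
truth_sample_table <- function(truth, manifest) {
  agg <- stats::aggregate(list(reads = rep(1L, nrow(truth))),
                          by = truth[, c("sample_id", "species")], FUN = sum)
  sample_table(agg,
               data.frame(sample_id = manifest$sample_id,
                          filter_id = manifest$filter_id,
                          river_id = manifest$river_id),
               meta = list(mode = "truth"))
}
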