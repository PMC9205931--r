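# ednacnn

Convolutional neural network annotation of eDNA metabarcoding reads.

## The problem

Environmental DNA (eDNA) metabarcoding amplifies a short taxonomically
informative marker — here the ~60 bp 12S rRNA "teleo" fragment targeting
fishes — from water samples and sequences it at depth. Turning the raw
Illumina output into per-sample species tables classically requires a
multi-step pipeline (read-pair merging, demultiplexing, dereplication,
denoising, alignment-based taxonomic assignment) that dominates the
analysis cost. `ednacnn` replaces those steps with a single trained
convolutional classifier applied directly to raw 150-bp reads, plus an
exact-match hash-table demultiplexer, and provides the community-agreement
statistics needed to validate the output against a baseline pipeline or
historical records.

It is aimed at metabarcoding bioinformaticians who have a reference
barcode database (FASTA with species labels) and raw FASTQ files with an
ngsfilter-style tag manifest, and want species × read-count tables per PCR
replicate, filtration capsule, or river.

## The method

**Encoding.** Each IUPAC base becomes a probability distribution over
(A, C, G, T): `A → [1,0,0,0]`, `W → [0.5,0,0,0.5]`, `N → [0.25 × 4]`.
Sequences are zero-padded or truncated to a fixed 150-position input.

**Training with augmentation.** The reference database is class-balanced
by oversampling; at every epoch each sequence is freshly perturbed with
0–2 random insertions and deletions and a 5 % per-position substitution
rate, optionally decorated into raw-read form (leading `N` block standing
in for tag + attachment bases, forward primer, amplicon, reverse
complement of the reverse primer, trailing `N` block) and duplicated as
its reverse complement. The network — 1–3 convolutional layers (4–16
filters, the first kernel spanning 7 positions × 4 bases), 1–3 dense
layers, leaky-ReLU, dropout, softmax over species — is fit with Adam on
categorical cross-entropy.

**Rejection thresholding.** A read is assigned to the argmax species only
when the softmax maximum reaches a binarization threshold (default 0.9);
otherwise it is rejected. The threshold can be selected on labelled data
by maximizing F-beta with beta = 0.3, weighting precision heavily so
false positives are suppressed at the cost of discarding some correct
assignments.

**Demultiplexing.** Raw reads are assigned to samples by exact lookup of
the 8-bp tag at the first 5 read offsets (absorbing the 0–2
plate-attachment bases read before the tag), with no error correction —
a handful of hash lookups per read.

**Validation statistics.** Per-sample Kendall tau-b on read counts,
Cohen's kappa on presence/absence, Bray–Curtis dissimilarity matrices,
species-richness correlation, and three-way species-overlap counts, each
at replicate / filter / river aggregation and across a ladder of
minimum-read detection thresholds (0–100 reads per PCR replicate).

A synthetic-data generator (`simulate_reference_db`,
`simulate_tag_manifest`, `simulate_raw_fastq`) emulates the whole study —
reference database, tag manifest, raw reads with known ground truth — so
every stage is testable end to end.

## Worked example

```r
library(ednacnn)

# 1. a synthetic study: 10 species, 3 PCR replicates, 20,000 raw reads;
#    each replicate contains a random 6-species community
sim <- simulate_reference_db(n_species = 10, amplicon_len = 60,
                             min_divergence = 0.10, seed = 1)
manifest <- simulate_tag_manifest(n_samples = 3, seed = 2)
set.seed(4)
composition <- lapply(setNames(manifest$sample_id, manifest$sample_id),
                      function(s) {
  community <- sample(names(sim$db$label_index), 6)
  setNames(runif(6, 0.5, 2), community)
})
reads <- simulate_raw_fastq(sim$db, manifest, composition,
                            n_reads = 20000, error_rate = 0, seed = 3)
sim$db
#> reference_db: 52 records (52 total copies), 10 species

# 2. train the classifier with raw-read augmentation
aug <- augment_config(decorate = TRUE, add_reverse_complements = TRUE,
                      forward_primer = manifest$forward_primer[1],
                      reverse_primer = manifest$reverse_primer[1])
clf <- build_classifier(model_config(n_classes = n_classes(sim$db)),
                        sim$db$label_index, seed = 1)
clf <- train_classifier(clf, sim$db, aug, epochs = 50, seed = 1)
clf
#> cnn_classifier: 1 conv layer(s) [4 filters], dense [128,128,128],
#>   10 classes, 108,286 parameters (trained)

# 3. raw FASTQ -> thresholded per-sample species table
tab <- run_raw(reads$fastq, manifest, clf, t = 0.9, min_reads = 0)
head(tab$counts)
#>   sample_id     species reads
#> 1 sample_01 species_003  1683
#> 2 sample_01 species_004   810
#> 3 sample_01 species_007  1446
#> 4 sample_01 species_008  1627
#> 5 sample_01 species_009   543
#> 6 sample_01 species_010   557

# 4. agreement with the simulated ground truth
truth <- truth_sample_table(reads$truth, manifest)
median_agreement(tab, truth, level = "replicate",
                 min_reads_grid = c(0, 50))[
  , c("min_reads", "median_tau_b", "median_kappa")]
#>   min_reads median_tau_b median_kappa
#> 1         0            1            1
#> 2        50            1            1
```

The table lists, for each PCR replicate, the number of reads confidently
assigned to each species; reads below the 0.9 softmax threshold, with
invalid characters, or with unmatched tags are excluded and tallied in
`tab$meta`. Here the error-free simulation is recovered exactly: rank
correlation (tau-b) and presence/absence agreement (kappa) with the
ground truth are both 1 at every detection threshold.

A command-line wrapper with `simulate`, `train`, `classify-raw`,
`classify-clean`, `demux` and `compare` subcommands is installed at
`inst/scripts/ednacnn-cli.R`.

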