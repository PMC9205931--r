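---
title: "Methods: CNN annotation of eDNA metabarcoding reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNN annotation of eDNA metabarcoding reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the augmentation scheme, the numerical
and design choices behind `ednacnn`, and what the synthetic-data tests do
and do not establish about real data.

## The classification model

The classifier maps a fixed-width encoded read to a probability
distribution over the species of a reference barcode database. Inputs are
150 positions wide — the Illumina single-end read length for short-marker
metabarcoding — with four channels per position.

**Sequence encoding.** Each IUPAC code becomes the uniform distribution
over the canonical bases it denotes, in fixed column order (A, C, G, T):
`A` is `[1,0,0,0]`, `W` (A or T) is `[0.5,0,0,0.5]`, `N` is uniform 0.25.
Any fixed column order is equivalent up to a permutation of the input
channels; (A, C, G, T) is used consistently and never changed, so trained
checkpoints are unambiguous. Positions beyond the end of a short sequence
are all-zero rows. Zero padding is deliberately distinct from `N`: absent
signal (row sum 0) and maximal base ambiguity (uniform row) carry
different information, and the network can use that distinction. Padding
is appended at the 3' end, because reads are anchored on their 5' tag
end. Lowercase input is accepted; `U` is read as `T`. Base-call quality
scores are ignored throughout.

**Architecture.** One to three convolutional layers with 4–16 filters
each; the first kernel spans 7 positions and the full 4-wide base axis,
collapsing the base dimension (stride 1, no padding along the position
axis), so subsequent layers are 1-D convolutions over positions with 7
positions × all input channels per kernel. The convolutional stack feeds
one to three dense layers, with leaky-ReLU activations (negative slope
0.01) and dropout (rate 0.2) on all hidden dense layers, and a softmax
output over the species classes. The configuration constructor enforces
these ranges. A `depthwise_separable` flag is accepted on conv layer
specifications for forward compatibility but standard dense convolutions
are computed; at 4–16 filters the parameter savings of separable kernels
are negligible. The default network — one conv layer of 4 filters,
three dense layers of 128 — is the smallest configuration that reliably
captures short-amplicon structure in our tests; `grid_search()` ranks
alternative configurations by hold-out accuracy, breaking ties toward
fewer parameters.

**Engine.** No deep-learning framework is used: the network is a compact,
purpose-built engine in vectorized base R (`R/nn.R`). Convolutions are
computed as one im2col gather plus a single matrix product per layer over
the whole minibatch, which keeps CPU training in the seconds-to-minutes
range for networks of this size. Backpropagated gradients are verified
against central finite differences in the test suite (tolerance 1e-4 on
randomly probed coordinates of every layer). Training minimizes
categorical cross-entropy with Adam (beta1 0.9, beta2 0.999, eps 1e-8).

## Augmentation

Reference databases for regional faunas are small and unbalanced (a few
hundred sequences, one to ten per species), far too little to fit a
network directly. Training therefore draws, at every epoch, a fresh
stochastic perturbation of every (class-balanced) reference record:

1. **Balancing** (`balance_oversample`): every species is oversampled
   with replacement to the maximum per-species count.
2. **Decoration** (optional; for classifiers applied to raw reads): the
   amplicon is embedded in raw-read context —
   `N^k + forward primer + amplicon + revcomp(reverse primer) + N^k`.
   The `N` blocks stand in for the 8-bp sample tag plus plate-attachment
   bases, keeping the classifier tag-agnostic; an ablation flag
   (`concrete_tags`) substitutes concrete random bases instead.
3. **Indels**: 0–2 random insertions and 0–2 random deletions, uniform
   counts and positions.
4. **Substitutions**: each position mutates independently with
   probability 5 % — to one of the three *other* canonical bases, so the
   observed change rate equals the nominal rate ("mutation" is read as
   "change"; the alternative convention, uniform over all four bases,
   would realize only ~3.75 %). Mutated ambiguity codes become a uniform
   canonical base.
5. **Reverse complements** (optional): every augmented sequence is also
   emitted reverse-complemented, because sequencing reads either strand.

Evaluation-grade noise (`eval_augment_config()`) uses 2 % substitutions
and at most one insertion and one deletion, reflecting that PCR and
sequencing are cleaner than the noise injected for training robustness.

**Noise order.** Indels are applied before substitutions; the two
operators nearly commute in distribution and a fixed order keeps batches
reproducible.

**Prefix jitter.** Raw reads carry 0–2 attachment bases before the tag,
so the amplicon starts 0–2 positions earlier than the fixed 10-bp `N`
block implies. During epoch-batch construction the leading and trailing
`N` block lengths are therefore drawn independently and uniformly from
8–10 (`prefix_jitter = 2`). Without the jitter, reads with fewer than two
attachment bases are systematically shifted relative to everything the
network saw in training, and in our end-to-end simulations the rare
confidently-wrong assignments were exclusively such shifted reads; with
it, the error-free fixture is recovered exactly. `decorate_read()`
itself always uses fixed-length blocks.

## Training defaults

| parameter | default | rationale |
|---|---|---|
| epochs | 50 | fresh augmentation each epoch; loss plateaus on desk-scale databases |
| learning rate | 1e-3 | standard Adam default, stable for all grid architectures |
| batch size | 32 | an epoch over a small split database is only ~100–200 records; 32 doubles the gradient steps per epoch relative to 64 at identical cost |
| dropout | 0.2 | light regularization; augmentation is the main overfitting control |
| leaky slope | 0.01 | conventional; avoids dead units in small nets |

A single integer seed drives balancing, augmentation, shuffling and
dropout; weight initialization is seeded separately at `build_classifier`.
All randomness flows through R's global RNG, saved and restored around
every seeded entry point so library calls do not disturb the caller's RNG
state. Training is bit-reproducible given the two seeds; inference is
deterministic, and checkpoints (weights serialized at full precision,
architecture and label index as JSON) reload to bit-identical
predictions. Exact argmax ties resolve to the lowest class index.

## Rejection thresholding

`classify_with_threshold` accepts the argmax species only when the
softmax maximum reaches the binarization threshold `t` (default 0.9).
`select_threshold` scans a grid (default 0, 0.05, …, 1) and maximizes
F-beta with beta = 0.3. Precision and recall are micro-averaged over
reads, with recall denominated by *all* reads, so every rejection costs
recall; this makes the trade-off explicit — a small beta heavily
discourages false positives at the price of discarding correct
assignments. F-beta ties resolve toward the stricter (larger) threshold.
Species-level read-count tables are additionally filtered by a minimum
read count per PCR replicate (ladder 0/5/10/25/50/75/100; pipeline
default 50), applied at replicate level before filter/river aggregation.

## Demultiplexing

Tags (8 bp) and their reverse complements are hashed to sample ids;
collisions — including a tag matching another sample's tag reverse
complement — abort table construction. Each read is probed at start
offsets 0–4 (five lookups, absorbing the 0–2 attachment bases read
before the tag, with margin); the first exact hit wins and there is no
mismatch tolerance, so a single tag error leaves a read unassigned.
Only the 5' tag of the single-end read is used; paired-tag verification
and tag-jump filtering are out of scope.

## The synthetic-data generator

`simulate_reference_db` emulates a regional short-amplicon reference
database: ~60 bp species consensus sequences with pairwise divergence at
least `min_divergence` (default 5 %, a realistic order for congeneric
12S barcodes), per-species variants within half that divergence of their
consensus, and 1–10 sequences per species. `simulate_raw_fastq` emits
150-bp single-end reads with the full raw-read anatomy (0–2 attachment
bases, tag, forward primer, amplicon with substitution errors, reverse
primer complement, tag complement, random downstream filler), from
either strand, with a per-read truth table.

What it does **not** emulate: PCR chimeras, tag jumps, abundance
amplification bias, quality-score structure, indel sequencing errors by
default (available behind `indel_error_rate`), and — most importantly —
the near-identical congeneric sequences of real faunas (e.g. Cichlidae
sharing a barcode). Synthetic species are separated by independent
random divergence, which is the *easy* regime. Passing the end-to-end
tests therefore establishes the mechanics of the pipeline (conservation,
determinism, exact recovery in the error-free limit), not field-data
accuracy for closely related taxa, where probability mass splits across
indistinguishable species and the 0.9 threshold rejects them.

## Problem sizes in the test suite

The suite exercises the full loop at sizes chosen to be decisive yet
desk-scale: species-recovery at 50 species (60 bp, ≥10 % divergence,
3 sequences per species, one hold-out sequence per species, 50 epochs),
demultiplexing at 10,000 reads, agreement statistics against a
brute-force pair-count oracle on 1,000 random vectors, and the raw
pipeline on a 10-species, 5-sample, 50,000-read error-free simulation,
which must be recovered with kappa exactly 1 in every sample. The
hold-out split holds out exactly one unique sequence per eligible
species (those with at least two unique sequences) — the smallest split
that still covers every species; the proportion is configurable.

## Known limitations

- Species-level softmax forces every read to a species; conflicts among
  identical barcodes are only handled by rejection, not by assignment to
  a higher taxonomic rank.
- The engine is CPU-bound R; it is fast enough for training and for
  classifying tens of thousands of reads per second-scale batch, but
  makes no attempt at GPU-class throughput.
- `read_sample_table` reconstructs the hierarchy only for samples with
  at least one detected species.
- The paired Wilcoxon helper (`paired_agreement_test`) is exploratory
  and not a calibrated test for correlated community data.
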