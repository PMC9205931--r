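# Shared in-code fixtures for the test suite.

# toy database: species A has 2 unique sequences (one duplicated), B has 1
# (duplicated), C has 3 — the split-eligibility worked example
toy_db <- function() {
  reference_db(
    sequences = c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTTT",
                  "GGGGCCCCAA", "GGGGCCCCAA",
                  "TTTTAAAACC", "TTTTAAAAGG", "TTTTAAAATT"),
    species = c("A", "A", "A", "B", "B", "C", "C", "C"))
}

# well-separated tiny database for fast training tests: n species whose
# consensus sequences differ at >= 30% of positions
tiny_sep_db <- function(n_species = 3L, len = 40L, seqs_per_species = 2L,
                        seed = 101L) {
  sim <- simulate_reference_db(n_species, amplicon_len = len,
                               min_divergence = 0.3,
                               seqs_per_species_range = rep(seqs_per_species, 2),
                               seed = seed)
  sim$db
}

# small manifest with known tags
toy_manifest <- function() {
  tag_manifest(
    sample_id = c("s1", "s2"),
    forward_tag = c("AAGGTTCC", "ACGGTCAA"),
    reverse_tag = c("AAGGTTCC", "ACGGTCAA"),
    forward_primer = rep("ACACCGCCCGTCACTCT", 2),
    reverse_primer = rep("CTTCCGGTACACTTACCATG", 2),
    filter_id = c("f1", "f1"), river_id = c("r1", "r1"))
}

# brute-force O(n^2) Kendall tau-b oracle (independent of stats::cor)
taub_bruteforce <- function(x, y) {
  n <- length(x)
  P <- Q <- Tx <- Ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    else if (dx == 0) Tx <- Tx + 1
    else if (dy == 0) Ty <- Ty + 1
    else if (dx == dy) P <- P + 1
    else Q <- Q + 1
  }
  den <- sqrt((P + Q + Tx) * (P + Q + Ty))
  if (den == 0) return(NA_real_)
  (P - Q) / den
}

# hand-rolled sample_table from a compact spec list(sample -> c(species=reads))
st_from_list <- function(lst, filters = NULL, rivers = NULL) {
  rows <- do.call(rbind, lapply(names(lst), function(s) {
    data.frame(sample_id = s, species = names(lst[[s]]),
               reads = as.integer(lst[[s]]))
  }))
  ids <- names(lst)
  if (is.null(filters)) filters <- ids
  if (is.null(rivers)) rivers <- rep("r1", length(ids))
  sample_table(rows, data.frame(sample_id = ids, filter_id = filters,
                                river_id = rivers))
}
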