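# Agreement statistics between two methods' per-sample species tables and
# against independent checklists: Kendall tau-b on read counts, Cohen's
# kappa on presence/absence, Bray-Curtis dissimilarity, species richness
# correlation, and three-way overlap counts.

#' Kendall rank correlation with tie correction (tau-b)
#'
#' `tau_b = (P - Q) / sqrt((P + Q + Tx)(P + Q + Ty))` over all pairs, with
#' concordant P, discordant Q and per-vector tie counts. Computed via
#' [stats::cor()]; vectors shorter than 2 or entirely tied give `NA`
#' (undefined), never a silent 0.
#'
#' @param x,y Equal-length numeric vectors (e.g. per-species read counts of
#'   two methods over the union of detected species, absences as 0).
#' @return tau-b in `[-1, 1]`, or `NA` when undefined.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L || length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(NA_real_)
  stats::cor(x, y, method = "kendall")
}

#' Cohen's kappa for presence/absence agreement
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` from the
#' 2x2 agreement table of two binary vectors, with expected agreement
#' `p_e` from the marginals. When `p_e = 1` (both raters constant) kappa is
#' undefined and `NA` is returned.
#'
#' @param pres_a,pres_b Equal-length logical/0-1 vectors.
#' @return kappa (<= 1), or `NA` when undefined.
#' @export
cohen_kappa <- function(pres_a, pres_b) {
  stopifnot(length(pres_a) == length(pres_b))
  if (!length(pres_a)) stop("empty vectors")
  a <- as.logical(pres_a); b <- as.logical(pres_b)
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - p_e) < .Machine$double.eps^0.5) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(a_i, b_i)) / (sum(a) + sum(b))`: 0 for identical
#' abundance vectors, 1 for disjoint supports. Undefined (`NA`) when both
#' vectors are all-zero.
#'
#' @param counts_a,counts_b Equal-length non-negative vectors.
#' @return Dissimilarity in `[0, 1]`, or `NA`.
#' @export
bray_curtis <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b),
            all(counts_a >= 0), all(counts_b >= 0))
  tot <- sum(counts_a) + sum(counts_b)
  if (tot == 0) return(NA_real_)
  1 - 2 * sum(pmin(counts_a, counts_b)) / tot
}

#' Bray-Curtis dissimilarity matrix between samples of a table
#'
#' @param table A [sample_table()] (aggregate first for filter/river-level
#'   matrices).
#' @return A symmetric dissimilarity matrix over the table's samples.
#' @export
bray_curtis_matrix <- function(table) {
  wide <- .counts_wide(table)
  n <- nrow(wide)
  out <- matrix(0, n, n, dimnames = list(rownames(wide), rownames(wide)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) out[i, j] <- out[j, i] <- bray_curtis(wide[i, ], wide[j, ])
  }
  out
}

# samples x species count matrix
.counts_wide <- function(table) {
  cnt <- table$counts
  samples <- sort(unique(table$hierarchy$sample_id))
  species <- sort(unique(cnt$species))
  out <- matrix(0L, length(samples), length(species),
                dimnames = list(samples, species))
  out[cbind(match(cnt$sample_id, samples), match(cnt$species, species))] <-
    cnt$reads
  out
}

#' Per-sample agreement between two tables across read-count thresholds
#'
#' For every value of `min_reads_grid`, both tables are filtered at that
#' per-replicate detection threshold, aggregated to the requested level,
#' and compared sample by sample: Kendall tau-b on read counts and Cohen's
#' kappa on presence/absence, each over the union of species detected by
#' either method in that sample (with the species universe of the whole
#' comparison supplying the shared absences for kappa). Medians and ranges
#' across samples are reported per threshold; samples where a statistic is
#' undefined (e.g. all-tied counts) are excluded from its median and
#' counted.
#'
#' @param table_a,table_b [sample_table()]s at replicate level with
#'   overlapping samples.
#' @param level Aggregation level for the comparison.
#' @param min_reads_grid Detection thresholds to scan (default the
#'   0/5/10/25/50/75/100 ladder).
#' @return data.frame with one row per threshold: median/min/max tau-b and
#'   kappa, and the number of samples where each was defined.
#' @export
median_agreement <- function(table_a, table_b,
                             level = c("replicate", "filter", "river"),
                             min_reads_grid = c(0, 5, 10, 25, 50, 75, 100)) {
  level <- match.arg(level)
  rows <- lapply(min_reads_grid, function(mr) {
    a <- aggregate_table(apply_min_reads(table_a, mr), level)
    b <- aggregate_table(apply_min_reads(table_b, mr), level)
    shared <- intersect(unique(a$hierarchy$sample_id),
                        unique(b$hierarchy$sample_id))
    if (!length(shared)) stop("no shared samples between the tables")
    universe <- sort(union(unique(a$counts$species), unique(b$counts$species)))
    taus <- kappas <- rep(NA_real_, length(shared))
    for (i in seq_along(shared)) {
      ca <- a$counts[a$counts$sample_id == shared[i], ]
      cb <- b$counts[b$counts$sample_id == shared[i], ]
      sp <- sort(union(ca$species, cb$species))
      va <- stats::setNames(numeric(length(sp)), sp)
      vb <- va
      va[ca$species] <- ca$reads
      vb[cb$species] <- cb$reads
      taus[i] <- if (length(sp) >= 2L) kendall_tau_b(va, vb) else NA_real_
      pa <- universe %in% ca$species
      pb <- universe %in% cb$species
      kappas[i] <- cohen_kappa(pa, pb)
    }
    data.frame(
      min_reads = mr, level = level, n_samples = length(shared),
      median_tau_b = stats::median(taus, na.rm = TRUE),
      tau_b_min = suppressWarnings(min(taus, na.rm = TRUE)),
      tau_b_max = suppressWarnings(max(taus, na.rm = TRUE)),
      n_tau_b_defined = sum(!is.na(taus)),
      median_kappa = stats::median(kappas, na.rm = TRUE),
      kappa_min = suppressWarnings(min(kappas, na.rm = TRUE)),
      kappa_max = suppressWarnings(max(kappas, na.rm = TRUE)),
      n_kappa_defined = sum(!is.na(kappas)))
  })
  do.call(rbind, rows)
}

#' Species richness correlation between two tables
#'
#' Correlates per-sample species richness (number of detected species)
#' between two methods at the requested aggregation level.
#'
#' @param table_a,table_b [sample_table()]s at replicate level.
#' @param level Aggregation level.
#' @param method Correlation method passed to [stats::cor()].
#' @return List with `correlation` and the per-sample richness data.frame.
#' @export
richness_correlation <- function(table_a, table_b,
                                 level = c("replicate", "filter", "river"),
                                 method = "pearson") {
  level <- match.arg(level)
  a <- aggregate_table(table_a, level)
  b <- aggregate_table(table_b, level)
  shared <- intersect(unique(a$hierarchy$sample_id),
                      unique(b$hierarchy$sample_id))
  if (!length(shared)) stop("no shared samples between the tables")
  rich <- function(tb, s) sum(tb$counts$sample_id == s)
  df <- data.frame(
    sample_id = shared,
    richness_a = vapply(shared, rich, numeric(1), tb = a),
    richness_b = vapply(shared, rich, numeric(1), tb = b))
  list(correlation = stats::cor(df$richness_a, df$richness_b, method = method),
       richness = df)
}

#' Three-way species overlap counts
#'
#' Counts the 7 regions of the Venn diagram of three species sets (e.g.
#' classifier detections, baseline-pipeline detections, historical
#' records). Region sums reproduce the set sizes.
#'
#' @param set_a,set_b,set_c Character vectors of species names.
#' @param names Labels for the three sets.
#' @return Named integer vector with entries `a_only`, `b_only`, `c_only`,
#'   `ab`, `ac`, `bc`, `abc` (prefixed by the set labels via names
#'   attribute `sets`).
#' @export
overlap_counts <- function(set_a, set_b, set_c,
                           names = c("a", "b", "c")) {
  a <- unique(set_a); b <- unique(set_b); c <- unique(set_c)
  u <- union(union(a, b), c)
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  out <- c(
    a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab = sum(ina & inb & !inc),
    ac = sum(ina & !inb & inc),
    bc = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
  structure(out, sets = stats::setNames(c(length(a), length(b), length(c)),
                                        names))
}

#' Paired Wilcoxon comparison of per-sample agreement values
#'
#' Convenience test for whether two vectors of per-sample statistics (e.g.
#' tau-b of method A vs raw reads and of method A vs clean reads) differ.
#' Offered for exploratory use; it is an ordinary paired Wilcoxon
#' signed-rank test, not a calibrated significance procedure for
#' correlated community data.
#'
#' @param values_a,values_b Paired per-sample statistics (`NA`s dropped
#'   pairwise).
#' @return The [stats::wilcox.test()] result.
#' @export
paired_agreement_test <- function(values_a, values_b) {
  keep <- !is.na(values_a) & !is.na(values_b)
  stats::wilcox.test(values_a[keep], values_b[keep], paired = TRUE,
                     exact = FALSE)
}
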