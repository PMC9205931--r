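test_that("Kendall tau-b matches hand fixtures and flags undefined cases", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(kendall_tau_b(x, x), 1)
  expect_equal(kendall_tau_b(x, -x), -1)
  expect_equal(kendall_tau_b(c(12, 2, 1, 12, 2), c(1, 4, 7, 1, 0)),
               -0.4714045, tolerance = 1e-6)
  expect_true(is.na(kendall_tau_b(1, 2)))
  expect_true(is.na(kendall_tau_b(c(5, 5, 5), c(1, 2, 3))))
})

test_that("Kendall tau-b equals the brute-force pair-count oracle on random count vectors", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(3:50, 1)
    x <- rpois(n, 3); y <- rpois(n, 3)
    expect_equal(kendall_tau_b(x, y), taub_bruteforce(x, y), tolerance = 1e-12)
  }
})

test_that("tau-b is symmetric and invariant under strictly monotone transforms", {
  set.seed(43)
  x <- rpois(30, 5); y <- rpois(30, 5)
  expect_equal(kendall_tau_b(x, y), kendall_tau_b(y, x))
  expect_equal(kendall_tau_b(exp(x), y^3 + 1), kendall_tau_b(x, y))
})

test_that("Cohen's kappa matches the 2x2 worked example and its boundary cases", {
  # agreement table a=20 (both present), b=5, c=10, d=15 -> kappa = 0.4
  a <- c(rep(TRUE, 20), rep(TRUE, 5), rep(FALSE, 10), rep(FALSE, 15))
  b <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 15))
  expect_equal(cohen_kappa(a, b), 0.4)
  expect_equal(cohen_kappa(a, a), 1)
  # marginal-matched independence fixture: p_o == p_e -> kappa = 0
  x <- c(TRUE, TRUE, FALSE, FALSE)
  y <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(cohen_kappa(x, y), 0)
  # both raters constant -> chance agreement 1, undefined
  expect_true(is.na(cohen_kappa(rep(TRUE, 4), rep(TRUE, 4))))
  expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
})

test_that("Cohen's kappa agrees with the e1071 implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(44)
  for (i in 1:20) {
    a <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    b <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
    ours <- cohen_kappa(a, b)
    theirs <- e1071::classAgreement(tab)$kappa
    if (!is.na(ours) && is.finite(theirs)) expect_equal(ours, theirs)
  }
})

test_that("Bray-Curtis matches hand fixtures and the vegan implementation", {
  expect_equal(bray_curtis(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(bray_curtis(c(5, 0, 0), c(0, 2, 3)), 1)
  expect_equal(bray_curtis(c(6, 2, 0), c(2, 2, 4)), 0.5)
  expect_true(is.na(bray_curtis(c(0, 0), c(0, 0))))
  skip_if_not_installed("vegan")
  set.seed(45)
  for (i in 1:20) {
    a <- rpois(10, 4); b <- rpois(10, 4)
    if (sum(a) + sum(b) == 0) next
    expect_equal(bray_curtis(a, b),
                 as.numeric(vegan::vegdist(rbind(a, b), method = "bray")))
  }
})

test_that("Bray-Curtis stays within [0,1] and a sample-table matrix is symmetric with zero diagonal", {
  set.seed(46)
  for (i in 1:50) {
    a <- rpois(8, 2); b <- rpois(8, 2)
    if (sum(a) + sum(b) == 0) next
    d <- bray_curtis(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
  }
  st <- st_from_list(list(s1 = c(A = 6, B = 2), s2 = c(A = 2, B = 2, C = 4)))
  m <- bray_curtis_matrix(st)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(s1 = 0, s2 = 0))
  expect_equal(m["s1", "s2"], 0.5)
})

test_that("three-way overlap counts cover all 7 Venn regions consistently", {
  same <- letters[1:5]
  oc <- overlap_counts(same, same, same)
  expect_equal(unname(oc["abc"]), 5)
  expect_equal(sum(oc), 5)
  disj <- overlap_counts(letters[1:3], letters[4:5], letters[6:9])
  expect_equal(unname(disj[c("a_only", "b_only", "c_only")]), c(3, 2, 4))
  expect_equal(sum(disj[c("ab", "ac", "bc", "abc")]), 0)
  set.seed(47)
  for (i in 1:20) {
    a <- sample(letters, 8); b <- sample(letters, 10); c <- sample(letters, 6)
    oc <- overlap_counts(a, b, c)
    # region sums reproduce the set sizes (inclusion-exclusion identity)
    expect_equal(unname(oc["a_only"] + oc["ab"] + oc["ac"] + oc["abc"]),
                 length(unique(a)))
    expect_equal(unname(oc["b_only"] + oc["ab"] + oc["bc"] + oc["abc"]),
                 length(unique(b)))
    expect_equal(unname(oc["c_only"] + oc["ac"] + oc["bc"] + oc["abc"]),
                 length(unique(c)))
    expect_equal(sum(oc), length(unique(c(a, b, c))))
  }
})

test_that("median agreement of a table with itself is perfect at every threshold", {
  st <- st_from_list(list(s1 = c(A = 60, B = 40, C = 10),
                          s2 = c(A = 5, C = 80, D = 12)),
                     filters = c("f1", "f1"))
  rep <- median_agreement(st, st, level = "replicate",
                          min_reads_grid = c(0, 5, 10))
  expect_equal(nrow(rep), 3)
  expect_equal(rep$median_tau_b, rep(1, 3))
  expect_equal(rep$median_kappa, rep(1, 3))
})

test_that("median agreement medians match direct medians on hand-built tables", {
  a <- st_from_list(list(s1 = c(A = 10, B = 5, C = 1),
                         s2 = c(A = 8, B = 2),
                         s3 = c(A = 1, B = 2, C = 3)))
  b <- st_from_list(list(s1 = c(A = 10, B = 5, C = 1),   # identical -> tau 1
                         s2 = c(A = 2, B = 8),           # reversed -> tau -1
                         s3 = c(A = 1, B = 2, C = 3)))   # identical -> tau 1
  rep <- median_agreement(a, b, level = "replicate", min_reads_grid = 0)
  taus <- c(1, -1, 1)
  expect_equal(rep$median_tau_b, median(taus))
  expect_equal(rep$tau_b_min, -1)
  expect_equal(rep$n_tau_b_defined, 3)
})

test_that("min-read filtering improves agreement as spurious rare species drop out", {
  # s1 carries low-count disagreements (B vs C); s2 anchors the species
  # universe with a high-count species E detected by both methods
  a <- st_from_list(list(s1 = c(A = 100, B = 3), s2 = c(E = 50)))
  b <- st_from_list(list(s1 = c(A = 90, C = 2), s2 = c(E = 60)))
  rep <- median_agreement(a, b, level = "replicate", min_reads_grid = c(0, 10))
  expect_equal(rep$median_kappa[2], 1)
  expect_gt(rep$median_kappa[2], rep$median_kappa[1])
})

test_that("richness correlation is 1 for identical tables and counts species per sample", {
  a <- st_from_list(list(s1 = c(A = 4, B = 2), s2 = c(A = 1),
                         s3 = c(A = 2, B = 2, C = 2)))
  rc <- richness_correlation(a, a, level = "replicate")
  expect_equal(rc$correlation, 1)
  expect_equal(sort(rc$richness$richness_a), c(1, 2, 3))
})
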