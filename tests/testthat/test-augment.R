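test_that("substitution operator is identity at rate 0 and always changes bases at rate 1", {
  s <- strrep("ACGT", 25)
  set.seed(1)
  expect_identical(substitute_bases(s, 0), s)
  mut <- substitute_bases(s, 1)
  expect_equal(nchar(mut), nchar(s))
  expect_true(all(strsplit(mut, "")[[1]] != strsplit(s, "")[[1]]))
})

test_that("empirical substitution frequency matches the configured rate within 3 binomial SE", {
  s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  orig <- strsplit(s, "")[[1]]
  for (rate in c(0.05, 0.02)) {
    set.seed(42)
    changed <- 0L
    n_draws <- 2000L
    for (i in seq_len(n_draws)) {
      changed <- changed + sum(strsplit(substitute_bases(s, rate), "")[[1]] != orig)
    }
    n_pos <- 100 * n_draws
    se <- sqrt(rate * (1 - rate) / n_pos)
    expect_lt(abs(changed / n_pos - rate), 3 * se)
  }
})

test_that("ambiguity codes mutate to canonical bases and sequences stay IUPAC-valid", {
  set.seed(3)
  s <- "NNRYWSKM"
  mut <- substitute_bases(s, 1)
  expect_true(all(strsplit(mut, "")[[1]] %in% c("A", "C", "G", "T")))
  for (i in 1:20) {
    m <- substitute_bases(apply_indels(s, 2, 2), 0.5)
    expect_true(ednacnn:::.valid_iupac(m))
  }
})

test_that("indel counts are bounded by and attain the configured maxima", {
  s <- strrep("ACGT", 15)
  set.seed(9)
  expect_identical(apply_indels(s, 0, 0), s)
  deltas <- replicate(2000, nchar(apply_indels(s, 2, 2)) - nchar(s))
  expect_true(all(deltas >= -2 & deltas <= 2))
  expect_true(any(deltas == 2))   # 2 insertions, 0 deletions attained
  expect_true(any(deltas == -2))  # 0 insertions, 2 deletions attained
  # deletions are capped so short sequences never vanish
  expect_gte(nchar(apply_indels("AC", 0, 5)), 1)
})

test_that("decoration adds N blocks and primers with the expected length arithmetic", {
  amp <- strrep("A", 60)
  fpr <- strrep("C", 21); rpr <- strrep("G", 20)
  dec <- decorate_read(amp, fpr, rpr, n_prefix_len = 10)
  expect_equal(nchar(dec), 60 + 21 + 20 + 20)
  expect_equal(substr(dec, 1, 10), strrep("N", 10))
  expect_equal(substr(dec, nchar(dec) - 9, nchar(dec)), strrep("N", 10))
  expect_equal(substr(dec, 11, 31), fpr)
  # reverse primer is appended reverse-complemented
  expect_equal(substr(dec, 92, 111), reverse_complement(rpr))
  expect_identical(decorate_read(amp, "", "", 0), amp)
})

test_that("oversampling balances every species to the maximum count", {
  db <- reference_db(c("ACGTACGTAC", "ACGTACGTTT", "ACGTACGTGG", "GGGGCCCCAA"),
                     c("A", "A", "A", "B"))
  bal <- balance_oversample(db, seed = 4)
  tot <- tapply(bal$records$multiplicity, bal$records$species, sum)
  expect_equal(as.numeric(tot), c(3, 3))
  expect_equal(sum(bal$records$multiplicity), n_classes(db) * 3)
  # already balanced input is unchanged in counts
  bal2 <- balance_oversample(bal, seed = 4)
  expect_equal(sum(bal2$records$multiplicity), sum(bal$records$multiplicity))
})

test_that("noise-free epoch batches equal the encoded references", {
  db <- toy_db()
  cfg <- augment_config(sub_rate = 0, max_insertions = 0, max_deletions = 0,
                        decorate = FALSE, add_reverse_complements = FALSE,
                        target_width = 20)
  set.seed(5)
  batch <- make_epoch_batch(db, cfg)
  ex <- ednacnn:::.expand_records(db)
  expect_identical(batch$sequences, ex$sequence)
  expect_identical(batch$labels, ex$class)
  expect_equal(batch$inputs, ednacnn:::.encode_batch(ex$sequence, 20))
})

test_that("reverse-complement duplication doubles the batch with matching labels", {
  db <- toy_db()
  cfg <- augment_config(sub_rate = 0, max_insertions = 0, max_deletions = 0,
                        add_reverse_complements = TRUE, target_width = 20)
  set.seed(6)
  batch <- make_epoch_batch(db, cfg)
  n <- length(batch$labels) / 2
  expect_equal(batch$labels[1:n], batch$labels[n + 1:n])
  expect_identical(batch$sequences[n + 1:n],
                   vapply(batch$sequences[1:n], reverse_complement,
                          character(1), USE.NAMES = FALSE))
})

test_that("epoch batches have uniform model shape and fresh randomness", {
  db <- toy_db()
  cfg <- augment_config(target_width = 30)
  set.seed(7)
  b1 <- make_epoch_batch(db, cfg)
  b2 <- make_epoch_batch(db, cfg)
  expect_equal(dim(b1$inputs), c(4 * 30, sum(db$records$multiplicity)))
  expect_false(identical(b1$sequences, b2$sequences))
})

test_that("decorated epoch batches jitter the leading N block over the attachment range", {
  db <- toy_db()
  cfg <- augment_config(sub_rate = 0, max_insertions = 0, max_deletions = 0,
                        decorate = TRUE, forward_primer = "ACGTACG",
                        reverse_primer = "TTGCA", target_width = 60)
  set.seed(8)
  lead <- integer(0)
  for (i in 1:10) {
    b <- make_epoch_batch(db, cfg)
    lead <- c(lead, nchar(sub("[^N].*$", "", b$sequences)))
  }
  expect_true(all(lead %in% 8:10))
  expect_setequal(unique(lead), 8:10)
  # jitter disabled -> exactly 10
  cfg0 <- augment_config(sub_rate = 0, max_insertions = 0, max_deletions = 0,
                         decorate = TRUE, prefix_jitter = 0,
                         forward_primer = "ACGTACG", reverse_primer = "TTGCA",
                         target_width = 60)
  b0 <- make_epoch_batch(db, cfg0)
  expect_true(all(startsWith(b0$sequences, strrep("N", 10))))
})

test_that("augment configuration round-trips through JSON", {
  cfg <- augment_config(sub_rate = 0.02, max_insertions = 1, decorate = TRUE,
                        forward_primer = "ACGT", reverse_primer = "TTAA")
  path <- withr::local_tempfile(fileext = ".json")
  write_augment_config(cfg, path)
  expect_equal(read_augment_config(path), cfg)
  # evaluation-mode defaults
  ev <- eval_augment_config()
  expect_equal(ev$sub_rate, 0.02)
  expect_equal(ev$max_insertions, 1L)
  expect_equal(ev$max_deletions, 1L)
})
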