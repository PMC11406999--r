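test_that("find_array_start matches the (T)x(M)(G)y(M) rule", {
  expect_equal(find_array_start("ACGTTTAGGGATTAGGG"), 3L)
  expect_equal(find_array_start("TTTAGGGA"), 0L)
  expect_error(find_array_start("ACGTACGT"), "no telomeric array")

  set.seed(13)
  for (i in 1:200) {
    s <- paste0(teloatlas:::random_dna(sample(10:80, 1)),
                sample(c("TAGGA", "TTTAGGGA", ""), 1),
                teloatlas:::random_dna(20))
    oracle <- array_start_oracle(s)
    if (is.na(oracle)) {
      expect_error(find_array_start(s), "no telomeric array")
    } else {
      expect_equal(find_array_start(s), oracle)
    }
  }
})

test_that("tokenize reproduces the worked unit decomposition", {
  expect_identical(tokenize("TGTTTAGGGTCTGATGGG")$units$seq,
                   c("TG", "TTTAGGG", "TCTGA", "TGGG"))
  # single-substitution variants are kept whole, not split internally
  expect_identical(tokenize("TATAGGGTATAGGG")$units$seq,
                   c("TATAGGG", "TATAGGG"))
  expect_identical(tokenize("TTTAGGGTTTAGGG")$units$seq, c(CANON, CANON))
  # the ambiguous decomposition resolves deterministically
  expect_identical(tokenize("TTTAGGATTAGGG")$units$seq,
                   c("TTTAGGA", "TTAGGG"))
  expect_error(tokenize("T"), "shorter")
})

test_that("tokenization is lossless and respects unit length bounds", {
  for (n in c(1, 2, 5, 50, 100)) {
    u <- tokenize(strrep(CANON, n))$units$seq
    expect_identical(u, rep(CANON, n))
  }
  set.seed(17)
  for (i in 1:200) {
    s <- random_unit_array(sample(10:60, 1))
    ua <- tokenize(s)
    expect_identical(paste(ua$units$seq, collapse = ""), s)
    expect_true(all(nchar(ua$units$seq) >= 2 & nchar(ua$units$seq) <= 17))
    expect_equal(ua$units$start, c(0L, head(ua$units$end, -1)))
  }
})

test_that("classify_units partitions units into the three classes", {
  expect_identical(classify_units(CANON), "canonical")
  expect_identical(classify_units("TTCAGGG"), "variant")
  # oracle: distance of TG to the canonical unit is 5 > 2
  expect_equal(c(utils::adist("TG", CANON)), 5)
  expect_identical(classify_units("TG"), "degenerate")

  set.seed(19)
  units <- tokenize(random_unit_array(80))$units$seq
  cls <- classify_units(units)
  expect_true(all(cls %in% c("canonical", "variant", "degenerate")))
  expect_length(cls, length(units))
  # class agrees with an independent distance oracle
  d <- c(utils::adist(CANON, units))
  expect_identical(cls == "canonical", units == CANON)
  expect_identical(cls == "variant",
                   units != CANON & d <= 2 & nchar(units) >= 5 & nchar(units) <= 9)
})

test_that("terminal boundary sits after the last conserved variant unit", {
  arr <- c("TG", "TTCAGGG", "TATAGGG", rep(CANON, 20))
  b <- terminal_canonical_boundary(list(arr, arr, arr))
  expect_equal(b$terminal_start, rep(3L, 3))
  expect_false(b$low_confidence)

  # an error-injected spurious variant in one read is not conserved
  arr2 <- c("TG", "TTCAGGG", "TATAGGG", rep(CANON, 10), "TTAGG",
            rep(CANON, 9))
  b2 <- terminal_canonical_boundary(list(arr, arr2, arr))
  expect_equal(b2$terminal_start[c(1, 3)], rep(3L, 2))
  expect_equal(b2$terminal_start[2], 3L)

  # zero variant units: the whole array is the terminal region
  pure <- rep(CANON, 15)
  b3 <- terminal_canonical_boundary(list(pure, pure))
  expect_equal(b3$terminal_start, c(0L, 0L))

  # single read: fall back to its own last non-canonical unit, flagged
  b4 <- terminal_canonical_boundary(list(arr))
  expect_equal(b4$terminal_start, 3L)
  expect_true(b4$low_confidence)
})

test_that("planted insertions are detected and labelled by source", {
  set.seed(23)
  lib_src <- teloatlas:::random_dna(1000)
  frag <- substr(lib_src, 301, 410)                      # 110 bp
  repeats1 <- random_unit_array(30)
  repeats2 <- random_unit_array(30)
  tract <- paste0(repeats1, frag, repeats2, strrep(CANON, 30))
  ins <- detect_insertions(tract, c(mito_like = lib_src))
  expect_equal(nrow(ins), 1L)
  expect_identical(ins$source, "mito_like")
  expect_gte(ins$identity, 0.9)
  # reported span covers the planted fragment
  expect_lte(ins$start, nchar(repeats1) + 5)
  expect_gte(ins$end, nchar(repeats1) + 110 - 5)

  # a pure repeat tract reports nothing
  expect_equal(nrow(detect_insertions(paste0(repeats1, strrep(CANON, 30)),
                                      c(mito_like = lib_src))), 0L)

  # a fragment shared by two ends: identical label, high mutual identity
  shared <- teloatlas:::random_dna(495)
  t1 <- paste0(random_unit_array(25), shared, strrep(CANON, 25))
  t2 <- paste0(random_unit_array(25), shared, strrep(CANON, 25))
  i1 <- detect_insertions(t1)
  i2 <- detect_insertions(t2)
  expect_equal(nrow(i1), 1L)
  expect_equal(nrow(i2), 1L)
  expect_identical(i1$source, i2$source)  # both unclassified
  expect_gte(teloatlas:::insertion_identity(i1$seq, i2$seq), 0.99)
})

test_that("simulated insertion fragments surface through the read pipeline", {
  cfg <- errorfree_config(
    n_accessions = 2L, depth = 3L, ends = c("chr1p", "chr3q", "chr5q"),
    insertion_specs = list(
      list(len = 110L, source = "mito_like", prob = 1, ends = "chr1p",
           shared = FALSE),
      list(len = 495L, source = "unclassified", prob = 1,
           ends = c("chr3q", "chr5q"), shared = TRUE)))
  truth <- simulate_truth(cfg)
  reads <- simulate_reads(truth, cfg)
  lib <- attr(truth, "source_library")
  m <- reads$meta[reads$meta$end == "chr1p", ][1, ]
  tract <- substring(m$molecule_seq, m$truth_array_start + 1L)
  ins <- detect_insertions(tract, lib)
  expect_true("mito_like" %in% ins$source)

  # the shared fragment is recovered from both ends with identical sequence
  m3 <- reads$meta[reads$meta$accession == "acc01" & reads$meta$end == "chr3q", ][1, ]
  m5 <- reads$meta[reads$meta$accession == "acc01" & reads$meta$end == "chr5q", ][1, ]
  i3 <- detect_insertions(substring(m3$molecule_seq, m3$truth_array_start + 1L), lib)
  i5 <- detect_insertions(substring(m5$molecule_seq, m5$truth_array_start + 1L), lib)
  expect_true(nrow(i3) >= 1 && nrow(i5) >= 1)
  best <- function(x) x$seq[which.max(x$end - x$start)]
  expect_gte(teloatlas:::insertion_identity(best(i3), best(i5)), 0.99)
})
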