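test_that("representative reads come from the median-length pool", {
  lens <- c(90, 100, 100, 100, 110)
  pick <- select_representative_reads(lens, seed = 1)
  expect_true(all(pick$idx %in% 2:4))
  expect_false(pick$duplicated)

  pick2 <- select_representative_reads(c(90, 120), seed = 1)
  expect_setequal(pick2$idx, 1:2)

  # deterministic under a fixed seed
  p1 <- select_representative_reads(rep(100, 6), seed = 9)
  p2 <- select_representative_reads(rep(100, 6), seed = 9)
  expect_identical(p1, p2)

  p3 <- select_representative_reads(100, seed = 1)
  expect_true(p3$duplicated)
  expect_equal(p3$idx, c(1L, 1L))
  expect_error(select_representative_reads(numeric(0)), "no reads")
})

test_that("consensus keeps conserved units and masks differences as N", {
  a <- c("TG", "TTCAGGG", CANON, "TATAGGG")
  expect_identical(build_consensus(a, a), a)

  b <- a; b[2] <- "TTAGGG"
  cons <- build_consensus(a, b)
  expect_identical(cons, c("TG", "N", CANON, "TATAGGG"))

  # one extra unit (indel): single N, other columns preserved
  d <- append(a, "TTTAGG", after = 2)
  cons2 <- build_consensus(a, d)
  expect_equal(sum(cons2 == "N"), 1L)
  expect_identical(cons2[cons2 != "N"], a)
})

test_that("unit-level alignment is optimal (exhaustive oracle, short arrays)", {
  set.seed(43)
  pool <- c("A", "B", "C", "D")
  for (i in 1:25) {
    a <- sample(pool, sample(2:6, 1), replace = TRUE)
    b <- sample(pool, sample(2:6, 1), replace = TRUE)
    codes <- unique(c(a, b))
    al <- teloatlas:::cpp_nw_units(match(a, codes), match(b, codes), 1, -1, -1)
    score <- sum(vapply(seq_len(ncol(al)), function(cc) {
      ia <- al[1, cc]; ib <- al[2, cc]
      if (ia == 0 || ib == 0) -1 else if (a[ia] == b[ib]) 1 else -1
    }, numeric(1)))
    expect_equal(score, nw_score_oracle(a, b))
  }
})

test_that("unit catalog counts, frequencies and singleton fraction", {
  cat <- unit_catalog(list(c("A", "A", "B"), c("B", "C")))
  expect_equal(cat$n_distinct, 3L)
  tab <- cat$table
  expect_equal(tab$count[match(c("A", "B", "C"), tab$unit)], c(2L, 2L, 1L))
  expect_equal(sum(tab$frequency), 1)
  expect_equal(cat$singleton_fraction, 1 / 3)

  empty <- unit_catalog(list(c("N", "N")))
  expect_equal(empty$n_distinct, 0L)
})

test_that("error-free simulated consensus recovers the planted alphabet", {
  cfg <- errorfree_config(n_accessions = 2L, depth = 4L,
                          ends = c("chr1q", "chr2q"))
  truth <- simulate_truth(cfg)
  planted <- unique(unlist(lapply(truth, function(te) te$units$seq)))
  # consensus per end from truth-linked reads
  reads <- simulate_reads(truth, cfg)
  seen <- character(0)
  for (key in names(truth)) {
    te <- truth[[key]]
    m <- reads$meta[reads$meta$accession == te$accession_id &
                      reads$meta$end == te$end_label, ]
    ulists <- lapply(seq_len(nrow(m)), function(i) {
      tr <- substring(m$molecule_seq[i], m$truth_array_start[i] + 1L)
      tokenize(tr)$units$seq
    })
    b <- terminal_canonical_boundary(ulists)
    trimmed <- lapply(seq_along(ulists), function(i)
      head(ulists[[i]], b$terminal_start[i]))
    cons <- build_consensus(trimmed[[1]], trimmed[[2]])
    expect_equal(sum(cons == "N"), 0L)
    seen <- union(seen, cons)
  }
  expect_true(all(seen %in% planted))
})

test_that("saturation curve is monotone and conserves the final count", {
  sets <- list(a1 = "A", a2 = "A", a3 = c("A", "B"))
  sc <- saturation_curve(sets)
  expect_equal(sc$cumulative_units, c(1L, 1L, 2L))

  set.seed(47)
  sets2 <- lapply(1:10, function(i) sample(LETTERS[1:8], 5, replace = TRUE))
  names(sets2) <- paste0("a", 1:10)
  total <- length(unique(unlist(sets2)))
  for (perm in 1:5) {
    sc2 <- saturation_curve(sets2, order = sample(names(sets2)))
    expect_true(all(diff(sc2$cumulative_units) >= 0))
    expect_equal(sc2$cumulative_units[10], total)
  }

  # shared-alphabet cohort plateaus at the alphabet size
  sets3 <- lapply(1:20, function(i) sample(LETTERS[1:10], 30, replace = TRUE))
  names(sets3) <- paste0("a", 1:20)
  sc3 <- saturation_curve(sets3)
  expect_equal(max(sc3$cumulative_units), 10L)
})
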