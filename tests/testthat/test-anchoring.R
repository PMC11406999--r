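test_that("orient_read follows the motif-count rule and is an involution", {
  expect_identical(orient_read("TTTAGGGTTTAGGG"),
                   list(seq = "TTTAGGGTTTAGGG", flipped = FALSE))
  expect_identical(orient_read("CCCTAAACCCTAAA"),
                   list(seq = "TTTAGGGTTTAGGG", flipped = TRUE))
  expect_identical(orient_read("ACGT"), list(seq = "ACGT", flipped = FALSE))
  expect_error(orient_read(""), "empty")

  set.seed(5)
  for (i in 1:20) {
    s <- paste0(teloatlas:::random_dna(50), strrep(CANON, 5))
    flip <- teloatlas:::revcomp(s)
    once <- orient_read(flip)$seq
    expect_identical(orient_read(once)$seq, once)
    expect_identical(once, s)
  }
})

test_that("assign_reads assigns by longest exact block with flags", {
  set.seed(7)
  a1 <- teloatlas:::random_dna(2000)
  a2 <- teloatlas:::random_dna(2000)
  anchors <- c(chr1q = a1, chr2q = a2)
  tail <- strrep(CANON, 60)
  reads <- c(
    full = paste0(substr(a1, 501, 2000), tail),              # 1500 bp anchor
    short = paste0(substr(a1, 1501, 2000), tail),            # 500 bp anchor
    chim = paste0(substr(a1, 1001, 2000), substr(a2, 1001, 2000), tail))
  res <- assign_reads(reads, anchors, min_anchor = 1000L)
  expect_identical(res$end, c("chr1q", "unassigned", "ambiguous"))
  expect_true(res$short_anchor[2])
  expect_true(res$ambiguous[3])
  # no read both assigned and ambiguous
  expect_false(any(res$ambiguous & !res$end %in% c("ambiguous", "unassigned")))
  # clipped tract of the assigned read is the telomeric tail
  expect_identical(res$tract_seq[1], tail)
})

test_that("assignment on error-free simulated reads is perfect", {
  cfg <- errorfree_config(n_accessions = 2L, depth = 3L)
  truth <- simulate_truth(cfg)
  reads <- simulate_reads(truth, cfg)
  acc <- "acc01"
  ids <- reads$meta$read_id[reads$meta$accession == acc]
  anchors <- vapply(cfg$ends, function(e)
    truth[[paste(acc, e, sep = "|")]]$anchor_seq, character(1))
  res <- assign_reads(reads$sequences[ids], anchors, min_anchor = 1000L)
  truth_end <- reads$meta$end[match(res$read_id, reads$meta$read_id)]
  expect_false(any(res$ambiguous))
  expect_identical(res$end, truth_end)
  # clipping recovers the truth array start
  m <- reads$meta[match(res$read_id, reads$meta$read_id), ]
  expect_equal(res$array_start, m$truth_array_start)
})

test_that("verify_consistency flags planted chimeras, keeps consistent reads", {
  set.seed(11)
  a1 <- teloatlas:::random_dna(2000)
  a2 <- teloatlas:::random_dna(2000)
  tail <- strrep(CANON, 40)
  mk <- function(flank) data.frame(oriented_seq = paste0(flank, tail),
                                   array_start = nchar(flank),
                                   stringsAsFactors = FALSE)
  good <- do.call(rbind, lapply(c(1200, 1400, 1600, 1800), function(n)
    mk(substr(a1, 2001 - n, 2000))))
  chim <- mk(paste0(substr(a2, 1001, 2000), substr(a1, 1701, 2000)))
  rep5 <- rbind(good, chim)
  v <- verify_consistency(rep5)
  expect_identical(v$chimeric, c(rep(FALSE, 4), TRUE))

  v2 <- verify_consistency(good)
  expect_false(any(v2$chimeric))
  expect_identical(v2$n_components, 1L)

  # single read: trivially consistent
  v1 <- verify_consistency(good[1, ])
  expect_false(any(v1$chimeric))

  # two reads without anchor overlap: no edge, none flagged as chimeric
  shorts <- rbind(mk(substr(a1, 1901, 2000)), mk(substr(a2, 1901, 2000)))
  v3 <- verify_consistency(shorts, min_overlap = 200L)
  expect_equal(v3$no_overlap_pairs, 1L)
  expect_false(any(v3$chimeric))
})

test_that("rDNA reads cluster into their two end groups", {
  cfg <- errorfree_config(n_accessions = 2L, depth = 6L,
                          ends = c("chr2p", "chr4p"),
                          rdna_ends = c("chr2p", "chr4p"))
  truth <- simulate_truth(cfg)
  reads <- simulate_reads(truth, cfg)
  ids <- reads$meta$read_id[reads$meta$accession == "acc01"]
  oriented <- vapply(reads$sequences[ids], function(s) orient_read(s)$seq,
                     character(1))
  m <- reads$meta[match(ids, reads$meta$read_id), ]
  # error-free: array starts are known from the truth link
  cl <- cluster_rdna_reads(oriented, m$truth_array_start, min_rdna = 500L)
  expect_true(all(cl$retained))
  expect_identical(length(unique(cl$group)), 2L)
  # groups match the truth end labels exactly (up to label swap)
  expect_identical(length(unique(paste(cl$group, m$end))), 2L)

  # all reads from one end: single cluster plus warning
  one <- m$end == "chr2p"
  cl1 <- cluster_rdna_reads(oriented[one], m$truth_array_start[one],
                            min_rdna = 500L)
  expect_match(cl1$warning, "one")
  expect_true(all(cl1$group[cl1$retained] == 1L))

  # a read with only two consecutive repeats is excluded by the retention rule
  fake <- paste0(substr(oriented[1], 1, m$truth_array_start[1]),
                 strrep(CANON, 2), "ACACAC")
  cl2 <- cluster_rdna_reads(c(oriented[1], fake),
                            c(m$truth_array_start[1], m$truth_array_start[1]),
                            min_rdna = 500L)
  expect_false(cl2$retained[2])
})
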