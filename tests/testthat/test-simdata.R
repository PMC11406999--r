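test_that("truth simulation is deterministic and honours switches", {
  cfg <- small_config()
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1[], t2[])

  cfg0 <- small_config(hor_plant_prob = 0, ends = "chr1q")
  t0 <- simulate_truth(cfg0)
  expect_length(t0, cfg0$n_accessions)
  expect_true(all(vapply(t0, function(te) length(te$planted_hors) == 0,
                         logical(1))))
})

test_that("zero group divergence makes within-group arrays identical", {
  cfg <- small_config(n_accessions = 4L, group_divergence = 0,
                      somatic_jitter = 0, hor_plant_prob = 0)
  truth <- simulate_truth(cfg)
  groups <- attr(truth, "groups")
  for (end in attr(truth, "ends")) {
    for (g in unique(groups)) {
      accs <- names(groups)[groups == g]
      arrays <- lapply(accs, function(a) truth[[paste(a, end, sep = "|")]]$units$seq)
      for (i in seq_along(arrays)[-1]) {
        expect_identical(arrays[[i]], arrays[[1]])
      }
    }
  }
})

test_that("error-free reads round-trip to their truth molecules", {
  cfg <- errorfree_config(n_accessions = 2L, depth = 3L,
                          ends = c("chr1p", "chr1q"))
  truth <- simulate_truth(cfg)
  reads <- simulate_reads(truth, cfg)
  expect_equal(nrow(reads$events), 0L)
  for (i in seq_len(nrow(reads$meta))) {
    m <- reads$meta[i, ]
    seq <- reads$sequences[[m$read_id]]
    if (m$strand == "-") seq <- teloatlas:::revcomp(seq)
    expect_identical(seq, m$molecule_seq)
  }
})

test_that("injected errors are undone exactly by the event log", {
  cfg <- small_config(n_accessions = 2L, depth = 5L,
                      ends = c("chr1q", "chr2q"),
                      error_rate_fn = function(rq) 0.05)
  truth <- simulate_truth(cfg)
  reads <- simulate_reads(truth, cfg)
  expect_gt(nrow(reads$events), 0)
  for (i in seq_len(nrow(reads$meta))) {
    m <- reads$meta[i, ]
    seq <- reads$sequences[[m$read_id]]
    if (m$strand == "-") seq <- teloatlas:::revcomp(seq)
    ev <- reads$events[reads$events$read_id == m$read_id, , drop = FALSE]
    expect_identical(teloatlas:::undo_errors(seq, ev), m$molecule_seq)
  }
})

test_that("injected error counts decrease with read quality", {
  tr <- tail_reads(1000, seed = 99)
  set.seed(99)  # regenerate to count events with the same draws
  np <- sample(3:20, 1000, replace = TRUE)
  rq <- pmin(0.9999, 1 - 0.1 * exp(-(np - 3) / 6) + rnorm(1000, 0, 0.005))
  nerr <- vapply(seq_along(rq), function(i) {
    s <- strrep(CANON, sample(60:120, 1))
    nrow(teloatlas:::inject_homopolymer_errors(s, 0.3 * (1 - rq[i]))$events)
  }, numeric(1))
  expect_lt(cor(nerr, rq), 0)
  bins <- cut(rq, breaks = quantile(rq, 0:4 / 4), include.lowest = TRUE)
  means <- tapply(nerr, bins, mean)
  expect_true(all(diff(means) <= 0))
})

test_that("writing a simulation twice gives identical bytes", {
  cfg <- small_config(n_accessions = 2L, depth = 2L,
                      ends = c("chr1q", "chr2q"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_truth(cfg), simulate_reads(simulate_truth(cfg), cfg), d1)
  write_simulation(simulate_truth(cfg), simulate_reads(simulate_truth(cfg), cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(anchor_len = 100L), "uniqueness floor")
  expect_error(sim_config(orientation_flip_prob = 1.5), "probabilities")
  expect_error(sim_config(rq_of_np = function(np) rep(0.99, length(np))),
               "strictly increasing")
  expect_error(sim_config(rq_of_np = function(np) np), "into \\(0, 1\\]")
})
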