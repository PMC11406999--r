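test_that("repeat compression collapses adjacent duplicates only", {
  expect_identical(compress_units(c("TTCAGGG", "TTCAGGG", "TTCAGGG")),
                   "TTCAGGG")
  expect_identical(compress_units(c("X", "Y", "X")), "XYX")
  expect_identical(compress_units(character(0)), "")
  # idempotence at unit level
  set.seed(67)
  for (i in 1:20) {
    u <- sample(c("A", "B", "C"), 15, replace = TRUE)
    once <- rle(u)$values
    expect_identical(compress_units(once), compress_units(u))
  }
  # N positions are dropped before compression
  expect_identical(compress_units(c("X", "N", "X")), "X")
})

test_that("relative L-distance normalizes by the longer sequence", {
  expect_equal(relative_ldistance("TTTAGGG", "TTTAGGG"), 0)
  expect_equal(relative_ldistance("TTTAGGG", ""), 1)
  expect_equal(relative_ldistance("", ""), 0)
  expect_equal(relative_ldistance("TTTAGGG", "TATAGGG"), 1 / 7,
               tolerance = 1e-12)
  set.seed(71)
  for (i in 1:50) {
    a <- teloatlas:::random_dna(sample(1:40, 1))
    b <- teloatlas:::random_dna(sample(1:40, 1))
    expect_equal(relative_ldistance(a, b),
                 c(utils::adist(a, b)) / max(nchar(a), nchar(b)))
  }
})

test_that("distance matrices are symmetric, zero-diagonal and bounded", {
  set.seed(73)
  seqs <- vapply(1:6, function(i) teloatlas:::random_dna(50), character(1))
  names(seqs) <- paste0("acc", 1:6)
  groups <- stats::setNames(rep(1:2, each = 3), names(seqs))
  dm <- distance_matrices(list(chr1q = seqs, chr2q = seqs), groups)
  for (m in dm$matrices) {
    expect_true(isSymmetric(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))
  }
  # two identical accessions give a zero matrix
  dup <- c(a = "TTTAGGGTG", b = "TTTAGGGTG")
  expect_true(all(distance_matrices(list(e = dup),
                                    c(a = 1, b = 1))$matrices$e == 0))
})

test_that("group structure separates within- from between-group distances", {
  cfg <- small_config(n_accessions = 8L, hor_plant_prob = 0)
  truth <- simulate_truth(cfg)
  groups <- attr(truth, "groups")
  compressed <- lapply(attr(truth, "ends"), function(e) {
    v <- vapply(attr(truth, "accessions"), function(a)
      compress_units(truth[[paste(a, e, sep = "|")]]$units$seq), character(1))
    v
  })
  names(compressed) <- attr(truth, "ends")
  dm <- distance_matrices(compressed, groups)
  expect_lt(median(dm$same_group), median(dm$cross_group))
})

test_that("F test matches var.test and its invariances", {
  st <- f_test_two_tailed(1:5, 1:5)
  expect_equal(st$statistic, 1)
  expect_equal(st$p_value, 1)

  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  st2 <- f_test_two_tailed(x, y)
  expect_equal(st2$statistic, 0.25)
  expect_equal(st2$df, c(4L, 4L))
  ref <- stats::var.test(x, y)
  expect_equal(st2$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(st2$p_value, 0.208, tolerance = 1e-3)

  set.seed(79)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    mine <- f_test_two_tailed(a, b)
    ref <- stats::var.test(a, b)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
    # reciprocal symmetry
    rev <- f_test_two_tailed(b, a)
    expect_equal(mine$statistic * rev$statistic, 1, tolerance = 1e-12)
    expect_equal(mine$p_value, rev$p_value, tolerance = 1e-12)
    # common scaling leaves the ratio unchanged
    sc <- f_test_two_tailed(3 * a, 3 * b)
    expect_equal(sc$statistic, mine$statistic, tolerance = 1e-12)
  }
  expect_error(f_test_two_tailed(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("Wilcoxon rank-sum matches exhaustive enumeration and wilcox.test", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(w$p_value, 0.1, tolerance = 1e-12)

  same <- wilcoxon_rank_sum(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_gte(same$p_value, 0.99)

  set.seed(83)
  for (i in 1:15) {
    a <- sample(1:50, sample(3:6, 1))
    b <- sample(51:99, sample(3:6, 1))  # untied
    mine <- wilcoxon_rank_sum(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
  # large-sample branch agrees with the corrected normal approximation
  set.seed(89)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  mine <- wilcoxon_rank_sum(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)

  # invariance under strictly monotone transforms
  tr <- function(v) exp(v)
  expect_equal(wilcoxon_rank_sum(tr(a), tr(b))$p_value, mine$p_value)
})

test_that("noncoding regions are extracted with half-open coordinates", {
  s <- paste0(strrep("A", 10), "CGCGT", strrep(CANON, 3))
  expect_identical(noncoding_region(s, 10L, 15L), "CGCGT")
  expect_identical(noncoding_region(s, 15L, 15L), "")
  expect_error(noncoding_region(s, 16L, 15L), "inconsistent")

  cfg <- errorfree_config(n_accessions = 2L, depth = 2L, ends = "chr1q")
  truth <- simulate_truth(cfg)
  te <- truth[["acc01|chr1q"]]
  full <- paste0(te$anchor_seq, paste(te$units$seq, collapse = ""))
  got <- noncoding_region(full, te$gene_span[2],
                          nchar(te$anchor_seq))
  expect_identical(got, te$noncoding_seq)
})

test_that("noncoding distance matrices match the DP oracle", {
  seqs <- c(a = "ACACACAC", b = "ACACACAC", c = "GTGTGTGT")
  m <- noncoding_distance_matrix(seqs)
  expect_equal(m["a", "b"], 0)
  expect_equal(m["a", "c"], 1)
  set.seed(97)
  seqs2 <- vapply(1:5, function(i) teloatlas:::random_dna(30), character(1))
  names(seqs2) <- letters[1:5]
  m2 <- noncoding_distance_matrix(seqs2)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(m2[i, j],
                 c(utils::adist(seqs2[i], seqs2[j])) / 30)
  }
  # all-empty set: zero matrix
  m0 <- noncoding_distance_matrix(c(a = "", b = ""))
  expect_true(all(m0 == 0))
})

test_that("neighbor joining recovers additive trees", {
  # 4-leaf additive matrix from the quartet ((a,b),(c,d))
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.2
  d["a", "c"] <- d["c", "a"] <- 0.7
  d["a", "d"] <- d["d", "a"] <- 0.8
  d["b", "c"] <- d["c", "b"] <- 0.7
  d["b", "d"] <- d["d", "b"] <- 0.8
  d["c", "d"] <- d["d", "c"] <- 0.3
  tree <- neighbor_joining(d)
  expect_true(ape::is.monophyletic(tree$phylo, c("a", "b")))
  expect_true(ape::is.monophyletic(tree$phylo, c("c", "d")))

  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    ref <- ape::rtree(n, rooted = FALSE)
    ref$edge.length <- runif(nrow(ref$edge), 0.05, 1)
    dd <- cophenetic(ref)
    got <- neighbor_joining(dd)
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(got$phylo)), 0,
                 ignore_attr = TRUE)
    expect_setequal(got$leaf_order, ref$tip.label)
  }

  # permuting labels preserves topology
  perm <- sample(4)
  tree2 <- neighbor_joining(d[perm, perm])
  expect_true(ape::is.monophyletic(tree2$phylo, c("a", "b")))

  # serialized Newick re-parses to the same topology
  reparsed <- ape::read.tree(text = tree$newick)
  expect_equal(ape::dist.topo(ape::unroot(reparsed),
                              ape::unroot(tree$phylo)), 0,
               ignore_attr = TRUE)
})

test_that("merged matrix combines triangles and measures association", {
  set.seed(103)
  seqs <- vapply(1:8, function(i) teloatlas:::random_dna(40), character(1))
  names(seqs) <- paste0("a", 1:8)
  m <- noncoding_distance_matrix(seqs)
  mm <- merged_matrix(m, m, n_perm = 99)
  expect_equal(mm$mantel_r, 1, tolerance = 1e-12)
  ut <- upper.tri(mm$matrix)
  expect_equal(mm$matrix[ut], t(mm$matrix)[ut])

  # independent random matrices: association should not look significant
  mk <- function(seed) {
    set.seed(seed)
    x <- matrix(runif(64), 8, 8); x <- (x + t(x)) / 2; diag(x) <- 0
    dimnames(x) <- list(names(seqs), names(seqs)); x
  }
  mm2 <- merged_matrix(mk(1), mk(2), n_perm = 499, seed = 4)
  expect_gt(mm2$mantel_p, 0.01)

  expect_error(merged_matrix(m, mk(1)[1:7, 1:7]), "label sets")
})
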