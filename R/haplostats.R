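#' Repeat compression of a unit array
#'
#' Collapses every maximal run of consecutive identical units to a single
#' copy and concatenates the surviving units' bases, mitigating the impact
#' of repeat number variation on pairwise distances. "N" positions are
#' dropped first. Idempotent at unit level.
#'
#' @param units character vector of unit strings (possibly containing "N").
#' @return compressed base string (empty input gives "").
#' @export
compress_units <- function(units) {
  units <- units[!is.na(units) & units != "N"]
  if (length(units) == 0) return("")
  paste(rle(units)$values, collapse = "")
}

#' Relative Levenshtein distance between two sequences
#'
#' Levenshtein distance divided by the length of the longer sequence;
#' two empty strings have distance 0.
#'
#' @param a,b strings.
#' @return value in \[0, 1\].
#' @export
relative_ldistance <- function(a, b) {
  m <- max(nchar(a), nchar(b))
  if (m == 0) return(0)
  cpp_levenshtein(a, b) / m
}

#' Per-end relative-distance matrices and pooled comparison samples
#'
#' For each chromosome end, the all-pairs relative Levenshtein distance
#' matrix over accessions' compressed repeat arrays, plus pooled distance
#' samples for the same-end versus cross-end and same-group versus
#' cross-group comparisons. Cross-end pairs are subsampled (seeded) when
#' their number exceeds `max_cross_pairs`.
#'
#' @param compressed named list: end label -> named character vector
#'   (accession -> compressed array string).
#' @param groups named vector mapping accession to genetic group.
#' @param max_cross_pairs cap on sampled cross-end pairs.
#' @param seed seed for cross-end subsampling.
#' @return list with `matrices` (per end), `same_end`, `cross_end`,
#'   `same_group`, `cross_group` (numeric distance samples).
#' @export
distance_matrices <- function(compressed, groups, max_cross_pairs = 2000L,
                              seed = 1L) {
  matrices <- lapply(compressed, function(seqs) {
    d <- cpp_lev_matrix(seqs)
    len <- nchar(seqs)
    norm <- outer(len, len, pmax)
    norm[norm == 0] <- 1
    m <- d / norm
    dimnames(m) <- list(names(seqs), names(seqs))
    m
  })

  same_end <- numeric(0)
  same_group <- numeric(0)
  cross_group <- numeric(0)
  for (e in names(matrices)) {
    m <- matrices[[e]]
    if (nrow(m) < 2) next
    acc <- rownames(m)
    ut <- upper.tri(m)
    same_end <- c(same_end, m[ut])
    g <- groups[acc]
    same_g <- outer(g, g, "==")
    same_group <- c(same_group, m[ut & same_g])
    cross_group <- c(cross_group, m[ut & !same_g])
  }

  # cross-end sample: distances between arrays of different ends
  flat <- unlist(lapply(names(compressed), function(e) {
    stats::setNames(compressed[[e]], paste(e, names(compressed[[e]]), sep = "|"))
  }))
  ends_of <- sub("\\|.*", "", names(flat))
  pairs <- which(outer(ends_of, ends_of, "!=") & upper.tri(diag(length(flat))),
                 arr.ind = TRUE)
  if (nrow(pairs) > max_cross_pairs) {
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), max_cross_pairs), , drop = FALSE]
  }
  cross_end <- vapply(seq_len(nrow(pairs)), function(i) {
    relative_ldistance(flat[[pairs[i, 1]]], flat[[pairs[i, 2]]])
  }, numeric(1))

  list(matrices = matrices, same_end = same_end, cross_end = cross_end,
       same_group = same_group, cross_group = cross_group)
}

#' Two-tailed F test for equality of variances
#'
#' F = var(x)/var(y) with sample variances (n-1 denominators), degrees of
#' freedom (|x|-1, |y|-1) and p = 2 min(P(F <= f), P(F >= f)) capped at 1 —
#' the variance-ratio test as performed by `var.test`.
#'
#' @param x,y numeric samples of length >= 2.
#' @return list of class `telo_stat`: test, statistic, df, p_value.
#' @export
f_test_two_tailed <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per sample")
  vx <- var(x); vy <- var(y)
  if (vx == 0 || vy == 0) stop("zero variance: F statistic undefined")
  f <- vx / vy
  df <- c(length(x) - 1L, length(y) - 1L)
  p <- min(1, 2 * min(pf(f, df[1], df[2]), pf(f, df[1], df[2], lower.tail = FALSE)))
  structure(list(test = "two-tailed F", statistic = f, df = df, p_value = p),
            class = "telo_stat")
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties. For pooled sizes of at most
#' `exact_max` the two-sided p-value is computed by exhaustive enumeration
#' of all group assignments (valid under ties); above that, the normal
#' approximation with tie correction and continuity correction is used (as
#' in `wilcox.test`).
#'
#' @param x,y numeric samples (length >= 1 each).
#' @param exact_max enumeration threshold on |x| + |y| (default 12).
#' @return list of class `telo_stat`: test, statistic (W, number of (x, y)
#'   pairs with x > y counting ties as 1/2), df (NA), p_value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("need >= 1 observation per sample")
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2

  if (nx + ny <= exact_max) {
    combs <- utils::combn(nx + ny, nx)
    ws <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
    mu <- nx * ny / 2
    p <- mean(abs(ws - mu) >= abs(W - mu) - 1e-9)
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sigma2 <- (nx * ny / 12) *
      ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  structure(list(test = "Wilcoxon rank-sum", statistic = W, df = NA_real_,
                 p_value = p), class = "telo_stat")
}

#' @export
print.telo_stat <- function(x, ...) {
  cat(x$test, ": statistic =", signif(x$statistic, 5),
      if (!all(is.na(x$df))) paste0("df = (", paste(x$df, collapse = ", "), ")"),
      "p =", signif(x$p_value, 5), "\n")
  invisible(x)
}

#' Extract the non-coding region of a chromosome end
#'
#' The sequence between the most distal gene and the first telomeric
#' repeat; may be empty when the gene abuts the array.
#'
#' @param truth_seq chromosome-end sequence (flank plus array).
#' @param gene_end 0-based end of the most distal gene on `truth_seq`.
#' @param array_start 0-based start of the repeat array on `truth_seq`.
#' @return the non-coding sequence (possibly "").
#' @export
noncoding_region <- function(truth_seq, gene_end, array_start) {
  if (gene_end > array_start) {
    stop("inconsistent annotation: gene ends beyond the array start")
  }
  substr(truth_seq, gene_end + 1L, array_start)
}

#' Pairwise relative-distance matrix for non-coding regions
#'
#' Alignment-free pairwise relative Levenshtein distances (distance divided
#' by the longer sequence), a stated simplification of MSA-based distances.
#'
#' @param seqs named character vector of non-coding sequences.
#' @return symmetric matrix with zero diagonal, entries in \[0, 1\].
#' @export
noncoding_distance_matrix <- function(seqs) {
  n <- length(seqs)
  if (n < 2) stop("need >= 2 sequences")
  len <- nchar(seqs)
  if (all(len == 0)) {
    m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    return(m)
  }
  d <- cpp_lev_matrix(seqs)
  norm <- outer(len, len, pmax)
  norm[norm == 0] <- 1
  m <- d / norm
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ (Saitou-Nei Q criterion) with a deterministic leaf order
#' from a fixed (cladewise) traversal; labels are sorted before
#' construction so equal-distance ties resolve by label order.
#'
#' @param d symmetric distance matrix with labels.
#' @return list of class `telo_tree`: `phylo` ([ape::nj()] tree), `newick`
#'   string, `leaf_order`.
#' @export
neighbor_joining <- function(d) {
  labs <- rownames(d)
  if (is.null(labs)) stop("distance matrix must carry labels")
  if (nrow(d) < 3) {
    ord <- sort(labs)
    return(structure(list(phylo = NULL, newick = paste0(
      "(", paste(ord, collapse = ","), ");"), leaf_order = ord),
      class = "telo_tree"))
  }
  ord <- order(labs)
  tr <- ape::nj(as.dist(d[ord, ord]))
  leaf_order <- tr$tip.label[tr$edge[tr$edge[, 2] <= length(tr$tip.label), 2]]
  structure(list(phylo = tr, newick = ape::write.tree(tr),
                 leaf_order = leaf_order), class = "telo_tree")
}

#' @export
print.telo_tree <- function(x, ...) {
  cat("telo_tree:", length(x$leaf_order), "leaves\n")
  invisible(x)
}

#' Merge repeat and non-coding distance matrices and test their association
#'
#' Builds the combined matrix shown per chromosome end — upper triangle:
#' relative distances of compressed repeat arrays; lower triangle:
#' non-coding-region distances — with rows and columns in NJ leaf order,
#' and quantifies the association of the two distance structures with a
#' Mantel-style permutation test (Pearson correlation of off-diagonal
#' entries; permutation p-value). The association statistic is an addition
#' that turns the visual comparison into a number.
#'
#' @param repeat_d,noncoding_d symmetric labelled distance matrices over the
#'   same label set.
#' @param leaf_order row/column order (default: NJ leaf order of
#'   `noncoding_d`).
#' @param n_perm Mantel permutations.
#' @param seed permutation seed.
#' @return list with `matrix`, `leaf_order`, `mantel_r`, `mantel_p`.
#' @export
merged_matrix <- function(repeat_d, noncoding_d, leaf_order = NULL,
                          n_perm = 999L, seed = 1L) {
  if (!setequal(rownames(repeat_d), rownames(noncoding_d))) {
    stop("label sets of the two matrices differ")
  }
  if (is.null(leaf_order)) {
    leaf_order <- neighbor_joining(noncoding_d)$leaf_order
  }
  r <- repeat_d[leaf_order, leaf_order]
  nc <- noncoding_d[leaf_order, leaf_order]
  m <- r
  m[lower.tri(m)] <- nc[lower.tri(nc)]
  diag(m) <- 0

  set.seed(seed)
  mt <- vegan::mantel(as.dist(r), as.dist(nc), method = "pearson",
                      permutations = n_perm)
  list(matrix = m, leaf_order = leaf_order,
       mantel_r = unname(mt$statistic), mantel_p = mt$signif)
}
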