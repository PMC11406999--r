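#' Select two representative reads for a chromosome end
#'
#' Consensus arrays are built from two random reads whose degenerate+variant
#' array length equals the median over the end's reads (ties resolved to the
#' nearest-to-median lengths); the pair is drawn uniformly with the given
#' seed. A single available read is duplicated and flagged.
#'
#' @param array_lens integer vector: degenerate+variant array length (bp)
#'   per read.
#' @param seed integer seed for the draw.
#' @return list with `idx` (two indices into the input), `duplicated` flag.
#' @export
select_representative_reads <- function(array_lens, seed = 1L) {
  n <- length(array_lens)
  if (n == 0) stop("no reads for this end")
  if (n == 1) return(list(idx = c(1L, 1L), duplicated = TRUE))
  med <- median(array_lens)
  dev <- abs(array_lens - med)
  pool <- which(dev == min(dev))
  if (length(pool) == 1) {
    pool <- order(dev, seq_along(dev))[1:2]  # nearest to median next
  }
  set.seed(seed)
  idx <- if (length(pool) == 2) sample(pool) else sample(pool, 2L)
  list(idx = idx, duplicated = FALSE)
}

#' Build a consensus unit array from two reads
#'
#' The two unit sequences are globally aligned at unit level (match =
#' identical unit string); conserved units are retained and mismatch or gap
#' columns are marked "N".
#'
#' @param a,b character vectors of unit strings.
#' @param match,mismatch,gap alignment scores.
#' @return character vector over unit strings and "N", one entry per
#'   alignment column.
#' @export
build_consensus <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  if (length(a) == 0 && length(b) == 0) return(character(0))
  if (length(a) == 0) return(rep("N", length(b)))
  if (length(b) == 0) return(rep("N", length(a)))
  codes <- unique(c(a, b))
  al <- cpp_nw_units(base::match(a, codes), base::match(b, codes),
                     match, mismatch, gap)
  vapply(seq_len(ncol(al)), function(c) {
    ia <- al[1, c]; ib <- al[2, c]
    if (ia > 0 && ib > 0 && a[ia] == b[ib]) a[ia] else "N"
  }, character(1))
}

#' Catalog repeat unit types across consensus arrays
#'
#' Counts every distinct unit string over the given consensus arrays ("N"
#' positions excluded) and reports counts, relative frequencies, the
#' singleton fraction and the top-K most frequent units.
#'
#' @param consensus_list list of consensus unit vectors.
#' @param top_k size of the top list (default 20).
#' @return list of class `unit_catalog`: `table` (data frame unit, count,
#'   frequency), `n_distinct`, `singleton_fraction`, `top` (head of table).
#' @export
unit_catalog <- function(consensus_list, top_k = 20L) {
  units <- unlist(consensus_list, use.names = FALSE)
  units <- units[!is.na(units) & units != "N"]
  if (length(units) == 0) {
    tab <- data.frame(unit = character(0), count = integer(0),
                      frequency = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(table = tab, n_distinct = 0L,
                          singleton_fraction = NA_real_, top = tab),
                     class = "unit_catalog"))
  }
  counts <- sort(table(units), decreasing = TRUE)
  tab <- data.frame(unit = names(counts), count = as.integer(counts),
                    frequency = as.numeric(counts) / sum(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    table = tab,
    n_distinct = nrow(tab),
    singleton_fraction = mean(tab$count == 1L),
    top = head(tab, top_k)), class = "unit_catalog")
}

#' @export
print.unit_catalog <- function(x, ...) {
  cat("unit_catalog:", x$n_distinct, "distinct units;",
      sprintf("%.1f%%", 100 * x$singleton_fraction), "singletons\n")
  print(head(x$table, 5))
  invisible(x)
}

#' Saturation curve of distinct repeat units over accessions
#'
#' Cumulative count of distinct units ("N" excluded) as accessions are added
#' in the given order; optionally averaged over random permutations.
#'
#' @param units_by_accession named list: accession -> character vector of
#'   unit strings observed in that accession's consensus arrays.
#' @param order accession order (default input order).
#' @param n_perm if > 0, also return the curve averaged over `n_perm`
#'   random permutations (seeded).
#' @param seed seed for the permutations.
#' @return data frame with accession index, accession id, cumulative
#'   distinct-unit count (and `mean_permuted` when requested).
#' @export
saturation_curve <- function(units_by_accession,
                             order = names(units_by_accession),
                             n_perm = 0L, seed = 1L) {
  sets <- lapply(units_by_accession, function(u) unique(u[u != "N" & !is.na(u)]))
  cum_curve <- function(ord) {
    seen <- character(0)
    vapply(ord, function(a) {
      seen <<- union(seen, sets[[a]])
      length(seen)
    }, integer(1))
  }
  out <- data.frame(index = seq_along(order), accession = order,
                    cumulative_units = cum_curve(order),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (n_perm > 0) {
    set.seed(seed)
    perms <- replicate(n_perm, cum_curve(sample(order)))
    out$mean_permuted <- rowMeans(perms)
  }
  out
}
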