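#' Detect monomer homogenization runs
#'
#' Maximal runs of at least `min_run` consecutive identical units; pure
#' canonical runs are excluded by default (the terminal canonical tract is
#' homogeneous by definition).
#'
#' @param units character vector of unit strings in array order.
#' @param min_run minimal run length (default 3).
#' @param exclude_canonical drop runs of the canonical unit.
#' @return data frame: class, k, copies, start, end (unit indices, 0-based
#'   half-open), block (unit string), n_mutated.
#' @export
detect_runs <- function(units, min_run = 3L, exclude_canonical = TRUE) {
  empty <- hor_empty()
  if (length(units) == 0) return(empty)
  r <- rle(units)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_run
  if (exclude_canonical) keep <- keep & r$values != CANONICAL_UNIT
  if (!any(keep)) return(empty)
  data.frame(class = "homogenization", k = 1L,
             copies = r$lengths[keep],
             start = starts[keep], end = ends[keep],
             block = r$values[keep], n_mutated = 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}

hor_empty <- function() {
  data.frame(class = character(0), k = integer(0), copies = integer(0),
             start = integer(0), end = integer(0), block = character(0),
             n_mutated = integer(0), stringsAsFactors = FALSE)
}

#' Detect higher-order repeats (HORs) on a unit sequence
#'
#' Scans all block sizes k = 2..`k_max` and all phases for tandem tilings of
#' a k-unit block with at least `min_copies` copies, allowing up to
#' `max_mut` unit substitutions per copy relative to the position-wise
#' majority consensus of the accepted copies. Candidate annotations are
#' reduced to a non-overlapping set chosen greedily by longest total span,
#' then fewest mutated units, then smallest k, then leftmost start; blocks
#' whose consensus has a
#' smaller internal period are discarded, as are mutated tilings with fewer
#' than two exact copies (too little evidence that the consensus block is
#' real). Copies carrying substitutions set
#' the class to `mutated_hor`; otherwise blocks of 2-4 units are
#' `simple_hor` and blocks of 5 or more are `multi_monomer_hor`.
#'
#' @param units character vector of unit strings.
#' @param k_max maximal block size in units (default 8).
#' @param min_copies minimal tandem copies (default 2).
#' @param max_mut maximal unit substitutions per copy (default 1).
#' @return data frame as in [detect_runs()], plus attribute
#'   `mutated_copies`: list (per row) of (copy, position) pairs.
#' @export
detect_hors <- function(units, k_max = 8L, min_copies = 2L, max_mut = 1L) {
  n <- length(units)
  cands <- list()
  for (k in 2:max(2L, k_max)) {
    if (n < k * min_copies) break
    s <- 1L
    while (s + k * min_copies - 1L <= n) {
      fit <- grow_hor(units, s, k, max_mut)
      # mutated candidates need at least two exact copies as evidence that
      # the consensus block is real
      n_mut_copies <- length(unique(vapply(fit$mutated, `[[`, numeric(1),
                                           "copy")))
      ok <- fit$copies >= min_copies && min_period(fit$consensus) == k &&
        (n_mut_copies == 0L || fit$copies - n_mut_copies >= 2L)
      if (ok) cands[[length(cands) + 1L]] <- fit
      s <- s + 1L
    }
  }
  if (length(cands) == 0) return(hor_empty())
  select_annotations(cands)
}

# Greedy extension of a k-block tiling from unit index s (1-based); the
# consensus is the position-wise majority over accepted copies.
grow_hor <- function(units, s, k, max_mut) {
  n <- length(units)
  copies <- list(units[s:(s + k - 1L)])
  consensus <- copies[[1]]
  p <- s + k
  while (p + k - 1L <= n) {
    cand <- units[p:(p + k - 1L)]
    if (sum(cand != consensus) > max_mut) break
    copies[[length(copies) + 1L]] <- cand
    mat <- do.call(rbind, copies)
    consensus <- apply(mat, 2, function(col) names(which.max(table(col))))
    p <- p + k
  }
  # recount mutations against the final consensus
  mut <- list()
  for (i in seq_along(copies)) {
    diffpos <- which(copies[[i]] != consensus)
    if (length(diffpos) > 0) {
      for (d in diffpos) mut[[length(mut) + 1L]] <- c(copy = i, position = d)
    }
  }
  list(k = k, copies = length(copies), start = s - 1L,
       end = s - 1L + k * length(copies), consensus = consensus,
       mutated = mut)
}

# Smallest period of a unit vector (a block tileable by a smaller divisor
# period is not a genuine k-block).
min_period <- function(block) {
  k <- length(block)
  for (p in seq_len(k)) {
    if (k %% p == 0 && all(block == rep(block[seq_len(p)], k / p))) return(p)
  }
  k
}

# Greedy non-overlapping selection: longest span, then fewest mutated
# units, then smallest k, then leftmost.
select_annotations <- function(cands) {
  span <- vapply(cands, function(c) c$end - c$start, integer(1))
  k <- vapply(cands, `[[`, integer(1), "k")
  start <- vapply(cands, `[[`, integer(1), "start")
  nmut <- vapply(cands, function(c) length(c$mutated), integer(1))
  ord <- order(-span, nmut, k, start)
  chosen <- list()
  covered <- integer(0)
  for (i in ord) {
    c <- cands[[i]]
    idx <- seq(c$start + 1L, c$end)
    if (any(idx %in% covered)) next
    chosen[[length(chosen) + 1L]] <- c
    covered <- c(covered, idx)
  }
  rows <- lapply(chosen, function(c) {
    n_mut <- length(c$mutated)
    cls <- if (n_mut > 0) "mutated_hor"
           else if (c$k <= 4) "simple_hor" else "multi_monomer_hor"
    data.frame(class = cls, k = c$k, copies = c$copies,
               start = c$start, end = c$end,
               block = paste(c$consensus, collapse = ","),
               n_mutated = n_mut, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "mutated_copies") <- lapply(chosen, `[[`, "mutated")[order(
    vapply(chosen, `[[`, integer(1), "start"))]
  out
}

#' Classify the sequence-organization patterns of a unit array
#'
#' Combines homogenization runs and HOR annotations into the array's pattern
#' label set: `singleton_array` (every unit occurs exactly once),
#' `homogenization`, `simple_hor` (2-4-unit blocks), `multi_monomer_hor`
#' (blocks of 5 or more units) and `mutated_hor` (HORs with mutated copies).
#' An array may carry several labels. Overlaps between run and HOR
#' annotations resolve to the larger span (then smaller k, then leftmost).
#'
#' @param units character vector of unit strings.
#' @param min_run,k_max,min_copies,max_mut detection parameters, see
#'   [detect_runs()] and [detect_hors()].
#' @return list with `labels` (character vector) and `annotations` (merged
#'   non-overlapping annotation table).
#' @export
classify_array <- function(units, min_run = 3L, k_max = 8L,
                           min_copies = 2L, max_mut = 1L) {
  runs <- detect_runs(units, min_run = min_run)
  hors <- detect_hors(units, k_max = k_max, min_copies = min_copies,
                      max_mut = max_mut)
  merged <- merge_annotations(runs, hors)
  labels <- unique(merged$class)
  if (length(units) > 0 && !anyDuplicated(units)) {
    labels <- c("singleton_array", labels)
  }
  list(labels = labels, annotations = merged)
}

# Non-overlapping union of run and HOR annotations (longest span first,
# then smallest k, then leftmost).
merge_annotations <- function(...) {
  all <- do.call(rbind, list(...))
  if (is.null(all) || nrow(all) == 0) return(hor_empty())
  ord <- order(-(all$end - all$start), all$n_mutated, all$k, all$start)
  covered <- integer(0)
  keep <- logical(nrow(all))
  for (i in ord) {
    idx <- seq(all$start[i] + 1L, all$end[i])
    if (any(idx %in% covered)) next
    keep[i] <- TRUE
    covered <- c(covered, idx)
  }
  out <- all[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  row.names(out) <- NULL
  out
}
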