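#' Orient a read to the 5'-TTTAGGG-3' convention
#'
#' Reads whose telomeric repeats run in the 3'-CCCTAAA-5' orientation are
#' reverse-complemented: if the count of CCCTAAA exceeds the count of
#' TTTAGGG the reverse complement is returned. Ties (including zero counts
#' of both motifs) leave the input unchanged.
#'
#' @param seq sequence over \{A,C,G,T,N\}.
#' @return list with `seq` (oriented sequence) and `flipped` flag.
#' @export
orient_read <- function(seq) {
  if (is.na(seq) || nchar(seq) == 0) stop("empty sequence")
  fwd <- count_motif(seq, "TTTAGGG")
  rev <- count_motif(seq, "CCCTAAA")
  if (rev > fwd) list(seq = revcomp(seq), flipped = TRUE)
  else list(seq = seq, flipped = FALSE)
}

#' Assign reads to chromosome ends by unique flank anchors
#'
#' A read is assigned to the end whose anchor shares its longest exact-match
#' block (k-mer seeding then ungapped extension) of at least `min_anchor` bp
#' with the oriented read; reads reaching `min_anchor` on two or more
#' anchors are flagged ambiguous and excluded from assignment. Orientation
#' is applied first. The repeat-array start on each assigned read is located
#' with the `(T)x(M)(G)y(M)` rule downstream of the anchor block.
#'
#' @param reads named character vector of read sequences.
#' @param anchors named character vector: end label -> repeat-adjacent
#'   anchor sequence (for this accession).
#' @param min_anchor minimal exact-match block length (bp).
#' @param k seed k-mer length.
#' @return data frame of class `anchored_reads`: read_id, end, anchor_len,
#'   anchor_start, anchor_end (0-based half-open on the oriented read),
#'   array_start, flipped, ambiguous, short_anchor, oriented_seq, tract_seq.
#' @export
assign_reads <- function(reads, anchors, min_anchor = 1000L, k = 31L) {
  if (anyDuplicated(anchors)) stop("anchors must be pairwise distinct")
  n <- length(reads)
  oriented <- character(n)
  flipped <- logical(n)
  for (i in seq_len(n)) {
    o <- orient_read(reads[[i]])
    oriented[i] <- o$seq
    flipped[i] <- o$flipped
  }

  # longest exact block of every read against every anchor
  best_len <- matrix(0L, n, length(anchors))
  best_start <- matrix(-1L, n, length(anchors))
  best_astart <- matrix(-1L, n, length(anchors))
  for (a in seq_along(anchors)) {
    blk <- cpp_anchor_blocks(anchors[[a]], oriented, as.integer(k))
    best_len[, a] <- blk[, 1]
    best_start[, a] <- blk[, 2]
    best_astart[, a] <- blk[, 3]
  }

  hits <- best_len >= min_anchor
  n_hits <- rowSums(hits)
  end <- rep("unassigned", n)
  ambiguous <- n_hits >= 2L
  end[ambiguous] <- "ambiguous"
  assigned <- n_hits == 1L
  which_a <- apply(best_len, 1, which.max)
  end[assigned] <- names(anchors)[which_a[assigned]]
  short_anchor <- !assigned & !ambiguous & rowSums(best_len > 0) > 0

  anchor_start <- ifelse(assigned, best_start[cbind(seq_len(n), which_a)], NA_integer_)
  anchor_len_hit <- ifelse(assigned, best_len[cbind(seq_len(n), which_a)], NA_integer_)
  anchor_end <- anchor_start + anchor_len_hit

  array_start <- rep(NA_integer_, n)
  tract <- rep(NA_character_, n)
  for (i in which(assigned)) {
    # residual anchor not covered by the exact block (read errors can end
    # the block early); skip it via anchor coordinates before applying the
    # array-start rule
    a <- which_a[i]
    residual <- nchar(anchors[[a]]) - (best_astart[i, a] + best_len[i, a])
    rest_start <- min(anchor_end[i] + residual, nchar(oriented[i]))
    rest <- substr(oriented[i], rest_start + 1L, nchar(oriented[i]))
    off <- tryCatch(find_array_start(rest), error = function(e) NA_integer_)
    if (is.na(off)) {
      # pure canonical tracts have no (T)x(M)(G)y(M) instance; fall back to
      # the first canonical unit
      cp <- regexpr(CANONICAL_UNIT, rest, fixed = TRUE)
      if (cp != -1L) off <- as.integer(cp) - 1L
    }
    if (!is.na(off)) {
      array_start[i] <- rest_start + off
      tract[i] <- substr(oriented[i], array_start[i] + 1L, nchar(oriented[i]))
    }
  }

  out <- data.frame(
    read_id = names(reads), end = end,
    anchor_len = anchor_len_hit, anchor_start = anchor_start,
    anchor_end = anchor_end, array_start = array_start,
    flipped = flipped, ambiguous = ambiguous, short_anchor = short_anchor,
    oriented_seq = oriented, tract_seq = tract,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("anchored_reads", "data.frame")
  out
}

#' Verify mutual consistency of the reads assigned to one end
#'
#' Builds a read graph with an edge whenever two reads' anchor-overlapping
#' segments (the shared suffix of their pre-array portions) agree at
#' `min_identity` or better over at least `min_overlap` bp. Reads outside
#' the largest connected component are flagged as putative chimeras or
#' error-rich reads; reads whose anchor segments do not overlap stay
#' unflagged but are reported.
#'
#' @param anchored data frame for the reads of one end (rows of
#'   [assign_reads()] output with `array_start` set).
#' @param min_identity identity threshold for an edge (default 0.99).
#' @param min_overlap minimal overlap span in bp.
#' @return list with `component` (integer per read), `chimeric` (logical per
#'   read), `n_components`, and `no_overlap_pairs` count.
#' @export
verify_consistency <- function(anchored, min_identity = 0.99,
                               min_overlap = 200L) {
  n <- nrow(anchored)
  if (n < 2) {
    return(list(component = rep(1L, n), chimeric = rep(FALSE, n),
                n_components = as.integer(n > 0), no_overlap_pairs = 0L))
  }
  pre <- substr(anchored$oriented_seq, 1L, anchored$array_start)
  edges <- list()
  no_overlap <- 0L
  compared <- logical(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      span <- min(nchar(pre[i]), nchar(pre[j]))
      if (span < min_overlap) { no_overlap <- no_overlap + 1L; next }
      compared[i] <- compared[j] <- TRUE
      if (suffix_identity(pre[i], pre[j], span) >= min_identity) {
        edges[[length(edges) + 1L]] <- c(i, j)
      }
    }
  }
  comp <- graph_components(n, edges)
  sizes <- table(comp)
  main <- as.integer(names(sizes)[which.max(sizes)])
  list(component = match(comp, unique(comp)),
       # only reads that overlapped something can be called inconsistent
       chimeric = comp != main & compared,
       n_components = length(sizes),
       no_overlap_pairs = no_overlap)
}

#' Cluster rDNA-adjacent reads into their two chromosome-end groups
#'
#' Reads whose telomere abuts the shared rDNA-like array cannot be anchored
#' uniquely; those carrying at least three consecutive canonical repeats and
#' at least `min_rdna` bp of rDNA-like flank are clustered by greedy
#' single-linkage on pairwise flank identity (shared suffix of the
#' pre-array portion). The two largest clusters are returned; reads in
#' smaller clusters are flagged.
#'
#' @param oriented_seqs named character vector of oriented read sequences.
#' @param array_starts integer vector, 0-based array start per read.
#' @param min_rdna minimal rDNA-like flank length (bp).
#' @param min_identity single-linkage join threshold (default 0.98).
#' @return list with `group` (1, 2 or NA per retained read), `retained`
#'   (logical over input reads), `warning` (character or NULL).
#' @export
cluster_rdna_reads <- function(oriented_seqs, array_starts,
                               min_rdna = 1000L, min_identity = 0.98) {
  tracts <- substring(oriented_seqs, array_starts + 1L)
  has_repeats <- vapply(tracts, function(t)
    grepl("(TTTAGGG){3}", t, fixed = FALSE), logical(1))
  flank_len <- array_starts
  retained <- has_repeats & flank_len >= min_rdna
  idx <- which(retained)
  group <- rep(NA_integer_, length(oriented_seqs))
  if (length(idx) == 0) {
    return(list(group = group, retained = retained,
                warning = "no reads pass the rDNA retention rules"))
  }
  pre <- substr(oriented_seqs[idx], 1L, array_starts[idx])
  m <- length(idx)
  edges <- list()
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        if (suffix_identity(pre[i], pre[j]) >= min_identity) {
          edges[[length(edges) + 1L]] <- c(i, j)
        }
      }
    }
  }
  comp <- graph_components(m, edges)
  sizes <- sort(table(comp), decreasing = TRUE)
  warn <- NULL
  if (length(sizes) < 2) {
    warn <- "only one rDNA read cluster found"
    group[idx] <- 1L
  } else {
    top2 <- as.integer(names(sizes)[1:2])
    group[idx[comp == top2[1]]] <- 1L
    group[idx[comp == top2[2]]] <- 2L
    if (length(sizes) > 2) {
      warn <- sprintf("%d reads outside the two main rDNA clusters flagged",
                      sum(!comp %in% top2))
    }
  }
  list(group = group, retained = retained, warning = warn)
}
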