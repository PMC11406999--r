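#' Locate the start of the telomeric repeat array
#'
#' The irregular degenerate repeats make the boundary between non-repeat and
#' repeat sequence ambiguous, so the array start is defined operationally as
#' the first instance of the pattern `(T)x(M)(G)y(M)` with M = A or C. The
#' trailing M base is context only and is not consumed: the array starts at
#' the leading T of the match.
#'
#' @param tract oriented sequence (5'-TTTAGGG-3' convention).
#' @return 0-based index of the array start.
#' @export
find_array_start <- function(tract) {
  if (is.na(tract) || nchar(tract) == 0) stop("empty sequence")
  m <- regexpr("T+[AC]G+[AC]", tract)
  if (m == -1L) stop("no telomeric array: pattern (T)x(M)(G)y(M) not found")
  as.integer(m) - 1L
}

#' Tokenize a repeat tract into telomeric units
#'
#' Partitions an oriented repeat-array sequence into contiguous units,
#' following the unit convention that a unit begins at a T and ends with the
#' last non-T base before the next unit, with the canonical-like
#' `(T)x(A)y(G)z` shape. A dynamic program minimizes the total edit distance
#' of segments to the canonical unit TTTAGGG under that convention (segment
#' boundaries preferentially at non-T-to-T transitions; segments spanning
#' more than one maximal G-run penalized; segment lengths 2-17 bp), with
#' deterministic tie-breaks: more boundaries at G-to-T or A-to-T transitions,
#' then fewer segments, then leftmost-longest. Concatenating the units always
#' reproduces the input (lossless).
#'
#' @param arrayseq sequence starting at the array start.
#' @param min_len,max_len allowed unit lengths in bp.
#' @return An object of class `unit_array`: list with `units` (data frame
#'   seq/start/end, 0-based half-open bp coordinates) and `seq`.
#' @export
tokenize <- function(arrayseq, min_len = 2L, max_len = 17L) {
  if (is.na(arrayseq) || nchar(arrayseq) < 2L) {
    stop("array sequence shorter than 2 bp")
  }
  bounds <- cpp_tokenize_bounds(arrayseq, CANONICAL_UNIT, min_len, max_len)
  n <- length(bounds) - 1L
  units <- data.frame(
    seq = substring(arrayseq, bounds[-length(bounds)] + 1L, bounds[-1]),
    start = bounds[-length(bounds)], end = bounds[-1],
    stringsAsFactors = FALSE)
  structure(list(units = units, seq = arrayseq), class = "unit_array")
}

#' @export
print.unit_array <- function(x, ...) {
  cat("unit_array:", nrow(x$units), "units over", nchar(x$seq), "bp\n")
  cat(" ", paste(head(x$units$seq, 12), collapse = " "),
      if (nrow(x$units) > 12) "..." else "", "\n")
  invisible(x)
}

#' Classify repeat units as canonical, variant or degenerate
#'
#' Canonical units are exactly TTTAGGG; variant units differ from the
#' canonical by at most `max_dist` edits and have lengths within
#' `variant_len`; everything else is degenerate.
#'
#' @param units character vector of unit strings.
#' @param max_dist maximal edit distance to TTTAGGG for a variant call.
#' @param variant_len allowed variant unit length range (bp).
#' @return character vector of class labels, one per unit.
#' @export
classify_units <- function(units, max_dist = 2L, variant_len = c(5L, 9L)) {
  if (length(units) == 0) return(character(0))
  d <- cpp_lev_vec(CANONICAL_UNIT, units)
  len <- nchar(units)
  ifelse(units == CANONICAL_UNIT, "canonical",
         ifelse(d <= max_dist & len >= variant_len[1] & len <= variant_len[2],
                "variant", "degenerate"))
}

#' Locate the homogeneous canonical terminal region across reads of one end
#'
#' The terminal region runs from just after the most distal *conserved*
#' non-canonical unit to the read end; it is treated as pure TTTAGGG with
#' residual sequencing artifacts and excluded from repeat-content analyses.
#' Reads' unit sequences are star-aligned at unit level (match = identical
#' unit string) to the read with the median unit count; a non-canonical unit
#' is conserved iff it occupies the same homologous column in at least half
#' (ceiling) of the reads.
#'
#' @param unit_lists list of character vectors, one per read (units in array
#'   order).
#' @return list with `terminal_start` (integer vector, per read: 0-based unit
#'   index at which the terminal canonical region starts) and `low_confidence`
#'   flag (single read fallback).
#' @export
terminal_canonical_boundary <- function(unit_lists) {
  n <- length(unit_lists)
  if (n == 0) stop("no reads")
  if (n == 1) {
    u <- unit_lists[[1]]
    noncan <- which(u != CANONICAL_UNIT)
    ts <- if (length(noncan) == 0) 0L else max(noncan)
    return(list(terminal_start = ts, low_confidence = TRUE))
  }
  lens <- lengths(unit_lists)
  ref_i <- order(abs(lens - median(lens)), seq_along(lens))[1]
  ref <- unit_lists[[ref_i]]
  codes <- unique(unlist(unit_lists))
  enc <- function(u) match(u, codes)

  # columns: reference positions; per read, the unit aligned to each column
  colmat <- matrix(NA_character_, nrow = n, ncol = length(ref))
  for (i in seq_len(n)) {
    u <- unit_lists[[i]]
    if (length(u) == 0) next
    al <- cpp_nw_units(enc(u), enc(ref), 1, -1, -1)
    hit <- al[2, ] > 0 & al[1, ] > 0
    colmat[i, al[2, hit]] <- u[al[1, hit]]
  }

  quorum <- ceiling(n / 2)
  conserved_noncan <- vapply(seq_along(ref), function(j) {
    col <- colmat[, j]
    tab <- table(col[!is.na(col)])
    if (length(tab) == 0) return(FALSE)
    top <- names(tab)[which.max(tab)]
    top != CANONICAL_UNIT && max(tab) >= quorum
  }, logical(1))

  last_col <- if (any(conserved_noncan)) max(which(conserved_noncan)) else 0L

  terminal_start <- integer(n)
  for (i in seq_len(n)) {
    u <- unit_lists[[i]]
    if (length(u) == 0) { terminal_start[i] <- 0L; next }
    if (last_col == 0L) { terminal_start[i] <- 0L; next }
    al <- cpp_nw_units(enc(u), enc(ref), 1, -1, -1)
    # read position aligned to (or last before) the boundary column
    upto <- al[1, al[2, ] > 0 & al[2, ] <= last_col]
    upto <- upto[upto > 0]
    terminal_start[i] <- if (length(upto) == 0) 0L else max(upto)
  }
  list(terminal_start = terminal_start, low_confidence = FALSE)
}

#' Detect non-telomeric insertions within a repeat tract
#'
#' Tokenizes the tract and reports maximal spans of degenerate-class units
#' (runs interrupted by at most one short non-degenerate unit are merged)
#' of at least `min_len` bp, then labels each span by its best match in a
#' user-supplied source library (>= `min_identity` over the span, either
#' strand) or "unclassified".
#'
#' @param tract oriented repeat tract (sequence after the array start; pass
#'   the portion after any leading degenerate segment to avoid reporting it).
#' @param source_library named character vector of candidate source
#'   sequences; may be empty.
#' @param min_len minimal insertion span (bp). Default 40.
#' @param min_identity identity threshold for a source label.
#' @return data frame with columns start, end (0-based half-open bp on
#'   `tract`), seq, source, identity.
#' @export
detect_insertions <- function(tract, source_library = character(0),
                              min_len = 40L, min_identity = 0.9) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      seq = character(0), source = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  if (nchar(tract) < min_len) return(empty)
  ua <- tokenize(tract)
  cls <- classify_units(ua$units$seq)
  is_deg <- cls == "degenerate"
  if (!any(is_deg)) return(empty)

  # merge degenerate runs separated by a single short non-degenerate unit
  r <- rle(is_deg)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  keep <- r$values
  for (i in which(!r$values)) {
    if (i > 1 && i < length(r$values) && r$lengths[i] == 1L &&
        nchar(ua$units$seq[idx_start[i]]) <= 9L) {
      keep[i] <- TRUE
    }
  }
  merged <- rle(keep)
  spans <- list()
  pos <- 1L
  for (i in seq_along(merged$lengths)) {
    blocks <- seq(pos, pos + merged$lengths[i] - 1L)
    if (merged$values[i]) {
      u0 <- idx_start[blocks[1]]
      u1 <- idx_end[blocks[length(blocks)]]
      # trim merged edges back to true degenerate units
      while (u0 <= u1 && !is_deg[u0]) u0 <- u0 + 1L
      while (u1 >= u0 && !is_deg[u1]) u1 <- u1 - 1L
      if (u1 >= u0) {
        bp0 <- ua$units$start[u0]
        bp1 <- ua$units$end[u1]
        if (bp1 - bp0 >= min_len) spans[[length(spans) + 1L]] <- c(bp0, bp1)
      }
    }
    pos <- pos + merged$lengths[i]
  }
  if (length(spans) == 0) return(empty)

  out <- lapply(spans, function(sp) {
    frag <- substr(tract, sp[1] + 1L, sp[2])
    src <- "unclassified"
    best_id <- NA_real_
    if (length(source_library) > 0) {
      ids <- vapply(source_library, function(lib) {
        max(insertion_identity(frag, lib),
            insertion_identity(frag, revcomp(lib)))
      }, numeric(1))
      if (max(ids) >= min_identity) {
        src <- names(source_library)[which.max(ids)]
        best_id <- max(ids)
      }
    }
    data.frame(start = sp[1], end = sp[2], seq = frag, source = src,
               identity = best_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Identity of a detected fragment against a library sequence via local
# alignment: detected spans can carry a few repeat-derived units at their
# edges, so only the aligned core is scored. The local alignment must cover
# at least `min_cover` of the shorter sequence to count at all.
insertion_identity <- function(frag, lib, min_cover = 0.6) {
  lf <- nchar(frag); ll <- nchar(lib)
  if (lf == 0 || ll == 0) return(0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(frag), Biostrings::DNAString(lib),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 1, gapExtension = 1)
  width <- Biostrings::nchar(Biostrings::pattern(aln))
  if (width < min_cover * min(lf, ll)) return(0)
  Biostrings::pid(aln) / 100
}
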