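#' Levenshtein distance
#'
#' Standard unit-cost edit distance (substitution, insertion and deletion
#' each cost 1). `N` mismatches every base, including another `N`.
#'
#' @param a,b strings over \{A,C,G,T,N\}; empty strings allowed.
#' @return integer distance.
#' @export
levenshtein <- function(a, b) {
  cpp_levenshtein(a, b)
}

#' Convert a sequence length in bp to an approximate canonical repeat count
#'
#' Telomeric lengths are routinely expressed in units of the 7-bp canonical
#' repeat: the length is divided by seven and rounded to the nearest
#' integer. Used both to seed the ideal-sequence search and to express
#' repeat-number ranges in units.
#'
#' @param bp length (or length range width) in bp.
#' @return integer repeat count.
#' @export
approx_repeat_units <- function(bp) {
  as.integer(round(bp / 7))
}

#' Best ideal canonical array for an observed terminal sequence
#'
#' Finds the canonical repeat count `n_star` whose ideal sequence
#' TTTAGGG^n minimizes the Levenshtein distance to the observed terminal
#' sequence. The search starts at `round(len/7)` (minimum 1) and
#' hill-climbs in steps of one repeat until neither neighbour improves; a
#' tie between n and n+1 resolves to the smaller n. As a safeguard the
#' local optimum is probed at n±2, and on any disagreement the search falls
#' back to exhaustive minimisation, so the result always equals the
#' exhaustive argmin. The minimized distance divided by the observed length
#' is the relative distance, an indication of indel density.
#'
#' @param terminal_seq observed terminal canonical region (non-empty).
#' @return list with `n_star`, `L_star`, `rel_dist`, `terminal_seq_len`.
#' @export
ideal_distance <- function(terminal_seq) {
  len <- nchar(terminal_seq)
  if (is.na(terminal_seq) || len == 0) stop("terminal sequence is empty")
  L <- function(n) cpp_levenshtein(terminal_seq, strrep(CANONICAL_UNIT, n))
  n <- max(1L, approx_repeat_units(len))
  cur <- L(n)
  repeat {
    lo <- if (n > 1L) L(n - 1L) else Inf
    hi <- L(n + 1L)
    if (lo <= cur && lo <= hi) {          # ties prefer smaller n
      n <- n - 1L; cur <- lo
    } else if (hi < cur) {
      n <- n + 1L; cur <- hi
    } else break
  }
  # unimodality guard: probe two steps out; fall back to exhaustive search
  probe_ns <- c(n - 2L, n + 2L)
  probe_ns <- probe_ns[probe_ns >= 1L]
  if (any(vapply(probe_ns, L, integer(1)) < cur) ||
      any(vapply(probe_ns, L, integer(1)) == cur & probe_ns < n)) {
    all_n <- seq_len(max(1L, len))
    all_L <- vapply(all_n, L, integer(1))
    n <- all_n[which.min(all_L)]
    cur <- min(all_L)
  }
  list(n_star = n, L_star = cur, rel_dist = cur / len,
       terminal_seq_len = len)
}

#' Per-read error profiles for the terminal canonical region
#'
#' @param terminal_seqs named character vector of terminal canonical
#'   sequences (one per read).
#' @param meta data frame with columns read_id, np, rq.
#' @return data frame of class `error_profiles`: read_id, terminal_seq_len,
#'   n_star, L_star, rel_dist, np, rq.
#' @export
error_profiles <- function(terminal_seqs, meta) {
  keep <- nchar(terminal_seqs) > 0
  ids <- names(terminal_seqs)[keep]
  prof <- lapply(terminal_seqs[keep], ideal_distance)
  out <- data.frame(
    read_id = ids,
    terminal_seq_len = vapply(prof, `[[`, integer(1), "terminal_seq_len"),
    n_star = vapply(prof, `[[`, integer(1), "n_star"),
    L_star = vapply(prof, `[[`, integer(1), "L_star"),
    rel_dist = vapply(prof, `[[`, numeric(1), "rel_dist"),
    stringsAsFactors = FALSE)
  m <- meta[match(out$read_id, meta$read_id), c("np", "rq")]
  out$np <- m$np
  out$rq <- m$rq
  class(out) <- c("error_profiles", "data.frame")
  out
}

#' Correlate per-read indel density with read quality
#'
#' Pearson correlation of the relative distance with read accuracy (rq) and
#' with subread count (np); two-sided p-values from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param profiles data frame with columns rel_dist, rq, np (see
#'   [error_profiles()]).
#' @return data frame with one row per covariate: variable, r, p, n.
#' @export
error_quality_correlation <- function(profiles) {
  if (nrow(profiles) < 3) stop("need at least 3 profiles")
  one <- function(x, y, nm) {
    if (var(x) == 0 || var(y) == 0) {
      stop("undefined correlation: zero variance in ", nm, " or rel_dist")
    }
    r <- cor(x, y)
    n <- length(x)
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
    data.frame(variable = nm, r = r, p = p, n = n, stringsAsFactors = FALSE)
  }
  rbind(one(profiles$rel_dist, profiles$rq, "rq"),
        one(profiles$rel_dist, profiles$np, "np"))
}
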