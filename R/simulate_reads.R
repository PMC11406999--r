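#' Simulate HiFi-like reads from a truth set
#'
#' Emits `depth` reads per truth end. Each read is a suffix of the
#' repeat-adjacent flank, followed by the full repeat array (with
#' per-molecule somatic jitter of tandem unit runs and any planted
#' non-telomeric insertions) and a per-molecule canonical TTTAGGG tail.
#' Homopolymer 1-bp indels are then injected into runs of two or more
#' identical T or G bases, one potential event per run, at rate
#' `error_rate_fn(rq)`; the read is finally reverse-complemented with
#' probability `orientation_flip_prob`. Every injected event is logged so
#' reads can be round-tripped back to their error-free molecules.
#'
#' @param truth a `telo_truth` object from [simulate_truth()].
#' @param config the [sim_config()] used to build `truth`.
#' @param seed integer seed for read-level randomness.
#' @return An object of class `telo_reads`: list with elements
#'   `sequences` (named character vector), `meta` (data frame with read_id,
#'   np, rq, accession, end, molecule, strand, truth_array_start, n_errors)
#'   and `events` (injected error log: read_id, pos on the un-oriented
#'   error-free read, 0-based; op "ins"/"del"; base).
#' @export
simulate_reads <- function(truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(truth, "telo_truth"))
  if (length(truth) == 0) stop("truth set is empty")
  cfg <- config
  set.seed(seed)

  seqs <- character(0)
  meta <- list()
  events <- list()
  np_pool <- seq(cfg$np_range[1], cfg$np_range[2])

  for (te in truth) {
    flank <- te$anchor_seq
    core_len <- te$anchor_core_len
    nc_len <- nchar(te$noncoding_seq)
    for (r in seq_len(cfg$depth)) {
      mol_units <- jitter_runs(te$units$seq, cfg$somatic_jitter)
      array_bases <- apply_insertions(mol_units, te$insertions)
      tail_units <- sample.int(
        max(1L, floor(cfg$canonical_tail_len[2] / 7)) -
          max(1L, floor(cfg$canonical_tail_len[1] / 7)) + 1L, 1L) +
        max(1L, floor(cfg$canonical_tail_len[1] / 7)) - 1L
      tail <- strrep(CANONICAL_UNIT, tail_units)

      keep_core <- sample(seq(round(0.55 * core_len), core_len), 1L)
      flank_suffix <- substr(flank, nchar(flank) - nc_len - keep_core + 1L,
                             nchar(flank))
      molecule <- paste0(flank_suffix, array_bases, tail)
      array_start <- nchar(flank_suffix)  # 0-based on the un-oriented read

      np <- sample(np_pool, 1L)
      rq <- min(1, max(1e-6, cfg$rq_of_np(np) + stats::rnorm(1, 0, cfg$rq_noise_sd)))
      rate <- cfg$error_rate_fn(rq)
      err <- inject_homopolymer_errors(molecule, rate)

      flipped <- runif(1) < cfg$orientation_flip_prob
      out_seq <- if (flipped) revcomp(err$seq) else err$seq

      read_id <- sprintf("%s_%s_r%03d", te$accession_id, te$end_label, r)
      seqs[[read_id]] <- out_seq
      meta[[length(meta) + 1L]] <- data.frame(
        read_id = read_id, np = np, rq = rq,
        accession = te$accession_id, end = te$end_label,
        molecule = r, strand = if (flipped) "-" else "+",
        truth_array_start = array_start,
        molecule_seq = molecule,
        n_errors = nrow(err$events), stringsAsFactors = FALSE)
      if (nrow(err$events) > 0) {
        err$events$read_id <- read_id
        events[[length(events) + 1L]] <- err$events
      }
    }
  }

  meta <- do.call(rbind, meta)
  events <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(pos = integer(0), op = character(0), base = character(0),
               read_id = character(0))
  structure(list(sequences = seqs, meta = meta,
                 events = events[, c("read_id", "pos", "op", "base")]),
            class = "telo_reads")
}

# Expand/contract maximal runs of identical units by one copy, each with
# probability `rate` (runs of length >= 2 only).
jitter_runs <- function(units, rate) {
  if (rate <= 0 || length(units) < 2) return(units)
  r <- rle(units)
  for (i in which(r$lengths >= 2)) {
    if (runif(1) < rate) {
      r$lengths[i] <- r$lengths[i] + sample(c(-1L, 1L), 1L)
    }
  }
  inverse.rle(r)
}

# Concatenate units, splicing insertion fragments after their unit offsets.
apply_insertions <- function(units, insertions) {
  if (length(insertions) == 0) return(paste(units, collapse = ""))
  offs <- vapply(insertions, function(x) x$unit_offset, integer(1))
  frags <- vapply(insertions, function(x) x$seq, character(1))
  ord <- order(offs)
  pieces <- character(0)
  prev <- 0L
  for (i in ord) {
    o <- min(offs[i], length(units))
    pieces <- c(pieces, paste(units[seq_len(o)][-seq_len(prev)], collapse = ""),
                frags[i])
    prev <- o
  }
  pieces <- c(pieces, paste(units[-seq_len(prev)], collapse = ""))
  paste(pieces, collapse = "")
}

# Inject 1-bp indels into homopolymer runs (>= 2 identical T or G bases), one
# candidate event per run at probability `rate`; insertions and deletions are
# equiprobable. Event positions are 0-based run starts on the input sequence.
inject_homopolymer_errors <- function(seq, rate) {
  empty <- data.frame(pos = integer(0), op = character(0), base = character(0),
                      stringsAsFactors = FALSE)
  if (rate <= 0 || nchar(seq) < 2) return(list(seq = seq, events = empty))
  m <- gregexpr("T{2,}|G{2,}", seq)[[1]]
  if (m[1] == -1L) return(list(seq = seq, events = empty))
  starts <- as.integer(m)
  hit <- which(runif(length(starts)) < rate)
  if (length(hit) == 0) return(list(seq = seq, events = empty))
  ops <- sample(c("ins", "del"), length(hit), replace = TRUE)
  bases <- substring(seq, starts[hit], starts[hit])
  # apply right-to-left so earlier positions stay valid
  out <- seq
  for (i in rev(seq_along(hit))) {
    p <- starts[hit[i]]
    if (ops[i] == "ins") {
      out <- paste0(substr(out, 1, p), bases[i], substr(out, p + 1, nchar(out)))
    } else {
      out <- paste0(substr(out, 1, p - 1), substr(out, p + 1, nchar(out)))
    }
  }
  list(seq = out,
       events = data.frame(pos = starts[hit] - 1L, op = ops, base = bases,
                           stringsAsFactors = FALSE))
}

# Undo logged events on an un-oriented errored read, recovering the
# error-free molecule (round-trip check for the simulator).
undo_errors <- function(err_seq, events) {
  if (nrow(events) == 0) return(err_seq)
  ev <- events[order(events$pos), , drop = FALSE]
  shift <- cumsum(c(0L, ifelse(ev$op == "ins", 1L, -1L)))[seq_len(nrow(ev))]
  actual <- ev$pos + 1L + shift  # 1-based position in err_seq
  out <- err_seq
  for (i in rev(seq_len(nrow(ev)))) {
    p <- actual[i]
    if (ev$op[i] == "ins") {
      out <- paste0(substr(out, 1, p - 1), substr(out, p + 1, nchar(out)))
    } else {
      out <- paste0(substr(out, 1, p - 1), ev$base[i],
                    substr(out, p, nchar(out)))
    }
  }
  out
}

#' @export
print.telo_reads <- function(x, ...) {
  cat("telo_reads:", length(x$sequences), "reads;",
      nrow(x$events), "injected homopolymer indels\n")
  invisible(x)
}
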