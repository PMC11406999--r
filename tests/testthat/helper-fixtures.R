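# Shared fixtures: small simulation configs and hand-built arrays.

CANON <- "TTTAGGG"

small_config <- function(seed = 42L, n_accessions = 3L, depth = 4L,
                         ends = c("chr1p", "chr1q", "chr2q", "chr3q"),
                         rdna_ends = character(0), ...) {
  sim_config(seed = seed, n_accessions = n_accessions, depth = depth,
             ends = ends, rdna_ends = rdna_ends,
             variant_len = c(80L, 250L), canonical_tail_len = c(150L, 300L),
             ...)
}

errorfree_config <- function(..., insertion_specs = list()) {
  small_config(error_rate_fn = function(rq) 0, somatic_jitter = 0,
               insertion_specs = insertion_specs, ...)
}

# Random unit array drawn from realistic variant/degenerate alphabets.
random_unit_array <- function(n_units = 40L) {
  pool <- c("TTTAGGG", "TTCAGGG", "TATAGGG", "TTAGGG", "TTTAGG", "TTTTAGGG",
            "TG", "TAG", "TCTGA", "TAGGA", "TTAGGA", "TTGG")
  paste(sample(pool, n_units, replace = TRUE), collapse = "")
}

# Pure-R reference scan for the array-start rule (oracle for regexpr).
array_start_oracle <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  for (i in seq_len(n)) {
    if (chars[i] != "T") next
    j <- i
    while (j <= n && chars[j] == "T") j <- j + 1
    if (j > n || !chars[j] %in% c("A", "C")) next
    g <- j + 1
    if (g > n || chars[g] != "G") next
    while (g <= n && chars[g] == "G") g <- g + 1
    if (g <= n && chars[g] %in% c("A", "C")) return(i - 1L)
  }
  NA_integer_
}

# Exhaustive best-score global alignment of two short unit vectors (oracle
# for the Needleman-Wunsch unit aligner), returning the best score.
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  if (length(a) == 0) return(gap * length(b))
  if (length(b) == 0) return(gap * length(a))
  max(
    nw_score_oracle(a[-1], b[-1], match, mismatch, gap) +
      if (a[1] == b[1]) match else mismatch,
    nw_score_oracle(a[-1], b, match, mismatch, gap) + gap,
    nw_score_oracle(a, b[-1], match, mismatch, gap) + gap)
}

# HiFi-like canonical-tail reads with quality-dependent homopolymer errors.
tail_reads <- function(n, seed, rate_fn = function(rq) 0.3 * (1 - rq)) {
  set.seed(seed)
  np <- sample(3:20, n, replace = TRUE)
  rq <- pmin(0.9999, 1 - 0.1 * exp(-(np - 3) / 6) + rnorm(n, 0, 0.005))
  seqs <- vapply(seq_len(n), function(i) {
    s <- strrep(CANON, sample(60:120, 1))
    teloatlas:::inject_homopolymer_errors(s, rate_fn(rq[i]))$seq
  }, character(1))
  names(seqs) <- sprintf("r%04d", seq_len(n))
  list(seqs = seqs,
       meta = data.frame(read_id = names(seqs), np = np, rq = rq,
                         stringsAsFactors = FALSE))
}
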