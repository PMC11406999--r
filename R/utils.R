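# Internal helpers shared across modules.

# Reverse complement for plain character sequences (keeps N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Count occurrences of a fixed motif in a single sequence.
count_motif <- function(seq, motif) {
  m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# Random DNA sequence of length n under the current RNG state.
random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  if (n <= 0) return("")
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Substitute bases at rate `rate`; each hit becomes a different random base.
mutate_bases <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# Identity of two equal-role sequences over their shared suffix span:
# 1 - L(a, b) / span. Used for flank agreement checks.
suffix_identity <- function(a, b, span = min(nchar(a), nchar(b))) {
  if (span == 0) return(NA_real_)
  sa <- substr(a, nchar(a) - span + 1L, nchar(a))
  sb <- substr(b, nchar(b) - span + 1L, nchar(b))
  1 - cpp_levenshtein(sa, sb) / span
}

# Write a TSV with a leading comment line declaring the coordinate convention.
write_tsv_conv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_conv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

write_fasta <- function(seqs, names, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

# Connected components of an undirected graph given as an edge list over
# integer vertex ids 1..n.
graph_components <- function(n, edges) {
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  if (length(edges) > 0) {
    for (e in edges) {
      a <- find(e[1]); b <- find(e[2])
      if (a != b) comp[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}
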