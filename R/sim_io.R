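# Simulation outputs: FASTA/TSV/BED serialization of a truth set and reads.

#' Write a simulated truth set and reads to a run directory
#'
#' Emits `reads.fasta`, `reads_meta.tsv`, `anchors.fasta` (per
#' accession x end repeat-adjacent flanks; shared rDNA-like flanks under
#' `rdna|<end>`), `truth_units.tsv`, `truth_regions.bed`,
#' `source_library.fasta`, `template_locus.fasta`, `groups.tsv`,
#' `config.txt` and `run_params.json`. All coordinates are 0-based
#' half-open.
#'
#' @param truth `telo_truth` object.
#' @param reads `telo_reads` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(truth, "config")

  write_fasta(unname(reads$sequences), names(reads$sequences),
              file.path(dir, "reads.fasta"))
  meta_cols <- c("read_id", "np", "rq", "accession", "end", "molecule",
                 "strand", "truth_array_start", "n_errors")
  write_tsv_conv(reads$meta[, meta_cols], file.path(dir, "reads_meta.tsv"),
                 "truth_array_start is 0-based on the un-oriented read")
  write_tsv_conv(reads$events, file.path(dir, "error_events.tsv"),
                 "pos is 0-based on the un-oriented error-free molecule")

  anchor_names <- character(0)
  anchor_seqs <- character(0)
  for (key in names(truth)) {
    te <- truth[[key]]
    if (!te$is_rdna) {
      anchor_names <- c(anchor_names, key)
      anchor_seqs <- c(anchor_seqs, te$anchor_seq)
    }
  }
  for (end in names(attr(truth, "rdna_flanks"))) {
    anchor_names <- c(anchor_names, paste0("rdna|", end))
    anchor_seqs <- c(anchor_seqs, attr(truth, "rdna_flanks")[[end]])
  }
  write_fasta(anchor_seqs, anchor_names, file.path(dir, "anchors.fasta"))

  units_rows <- lapply(names(truth), function(key) {
    te <- truth[[key]]
    if (nrow(te$units) == 0) return(NULL)
    data.frame(accession = te$accession_id, end = te$end_label,
               index = seq_len(nrow(te$units)) - 1L,
               start = te$units$start, stop = te$units$end,
               seq = te$units$seq, class = te$units$class,
               stringsAsFactors = FALSE)
  })
  write_tsv_conv(do.call(rbind, units_rows), file.path(dir, "truth_units.tsv"),
                 "start/stop are 0-based half-open bp within the repeat array")

  bed <- lapply(names(truth), function(key) {
    te <- truth[[key]]
    flank_len <- nchar(te$anchor_seq)
    array_len <- if (nrow(te$units) > 0) max(te$units$end) else 0L
    rows <- data.frame(chrom = key,
                       start = c(0L, flank_len),
                       end = c(flank_len, flank_len + array_len),
                       name = c("flank", "repeat_array"),
                       stringsAsFactors = FALSE)
    if (!te$is_rdna && !is.na(te$gene_span[1])) {
      rows <- rbind(rows, data.frame(
        chrom = key,
        start = c(te$gene_span[1], te$gene_span[2]),
        end = c(te$gene_span[2], flank_len),
        name = c("distal_gene", "noncoding"), stringsAsFactors = FALSE))
    }
    rows
  })
  bed <- do.call(rbind, bed)
  write_tsv_conv(bed, file.path(dir, "truth_regions.bed"),
                 "BED-like, 0-based half-open")

  src <- attr(truth, "source_library")
  if (length(src) > 0) {
    write_fasta(unname(src), names(src), file.path(dir, "source_library.fasta"))
  }
  acc <- attr(truth, "accessions")
  tmpl <- vapply(acc, function(a) {
    truth[[paste(a, attr(truth, "ends")[1], sep = "|")]]$template_locus
  }, character(1))
  write_fasta(unname(tmpl), acc, file.path(dir, "template_locus.fasta"))

  groups <- attr(truth, "groups")
  write_tsv_conv(data.frame(accession = names(groups), group = unname(groups),
                            stringsAsFactors = FALSE),
                 file.path(dir, "groups.tsv"))

  writeLines(config_as_text(cfg), file.path(dir, "config.txt"))
  jsonlite::write_json(list(
    seed = cfg$seed, n_accessions = cfg$n_accessions,
    n_groups = cfg$n_groups, ends = cfg$ends, rdna_ends = cfg$rdna_ends,
    anchor_len = cfg$anchor_len, depth = cfg$depth),
    file.path(dir, "run_params.json"), auto_unbox = TRUE)
  invisible(dir)
}
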