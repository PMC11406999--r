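#' Check the telomerase RNA template locus against the canonical motif
#'
#' Locates a template locus (flank + 9-base template + flank) in a subject
#' sequence by approximate search on either strand and reports whether the
#' 9-base template — 3'-TCCCAAATC-5' in genomic sense — matches the
#' canonical motif exactly.
#'
#' @param subject assembly or truth sequence to search.
#' @param locus_query template locus sequence containing the canonical
#'   motif.
#' @param motif the canonical 9-base template in genomic sense.
#' @param max_mismatch mismatches tolerated in the flanks when locating the
#'   locus.
#' @return list: `found`, `strand`, `position` (0-based on `subject`),
#'   `observed`, `identical`, `mismatch_offsets` (0-based within the
#'   template).
#' @export
check_template <- function(subject, locus_query, motif = TEMPLATE_MOTIF,
                           max_mismatch = 2L) {
  off <- regexpr(motif, locus_query, fixed = TRUE)
  if (off == -1L) stop("locus_query does not contain the canonical template")
  not_found <- list(found = FALSE, strand = NA_character_,
                    position = NA_integer_, observed = NA_character_,
                    identical = NA, mismatch_offsets = integer(0))
  allow <- max_mismatch + nchar(motif)  # flank tolerance + mutated template
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") subject else revcomp(subject)
    hits <- Biostrings::matchPattern(locus_query, Biostrings::DNAString(subj),
                                     max.mismatch = allow, with.indels = FALSE)
    if (length(hits) == 0) next
    # best hit = fewest mismatches
    mm <- vapply(seq_along(hits), function(i) {
      sum(strsplit(as.character(hits[[i]]), "")[[1]] !=
            strsplit(locus_query, "")[[1]])
    }, numeric(1))
    best <- which.min(mm)
    start <- Biostrings::start(hits)[best]
    observed <- substr(subj, start + off - 1L, start + off + nchar(motif) - 2L)
    mismatches <- which(strsplit(observed, "")[[1]] !=
                          strsplit(motif, "")[[1]]) - 1L
    return(list(found = TRUE, strand = strand,
                position = start - 1L, observed = observed,
                identical = length(mismatches) == 0,
                mismatch_offsets = mismatches))
  }
  not_found
}

# ---------------------------------------------------------------------------
# Pipeline stages. Each stage reads its inputs from, and writes its outputs
# to, the run directory, so the corresponding CLI subcommands can be run
# independently. All emitted coordinates are 0-based half-open.
# ---------------------------------------------------------------------------

#' @rdname run_pipeline
#' @param config a [sim_config()] object (simulate stage only).
#' @export
stage_simulate <- function(config, dir) {
  truth <- simulate_truth(config)
  reads <- simulate_reads(truth, config)
  write_simulation(truth, reads, dir)
  invisible(dir)
}

#' @rdname run_pipeline
#' @param min_anchor minimal exact-match block (default: half the simulated
#'   anchor length).
#' @param k seed k-mer length.
#' @export
stage_anchor <- function(dir, min_anchor = NULL, k = 31L) {
  params <- jsonlite::read_json(file.path(dir, "run_params.json"),
                                simplifyVector = TRUE)
  if (is.null(min_anchor)) min_anchor <- params$anchor_len %/% 2L
  reads <- read_fasta(file.path(dir, "reads.fasta"))
  meta <- read_tsv_conv(file.path(dir, "reads_meta.tsv"))
  anchors <- read_fasta(file.path(dir, "anchors.fasta"))

  rdna_flanks <- anchors[startsWith(names(anchors), "rdna|")]
  out <- list()
  for (a in unique(meta$accession)) {
    acc_reads <- reads[meta$read_id[meta$accession == a]]
    acc_anchor_names <- names(anchors)[startsWith(names(anchors),
                                                  paste0(a, "|"))]
    acc_anchors <- anchors[acc_anchor_names]
    names(acc_anchors) <- sub(".*\\|", "", acc_anchor_names)
    res <- assign_reads(acc_reads, acc_anchors, min_anchor = min_anchor, k = k)
    res$accession <- a

    # unassigned reads: try the shared rDNA-like flanks (best of the two);
    # rDNA arrays are mostly pure canonical, so the array start falls back
    # to the first canonical unit when the degenerate-start rule finds
    # nothing
    una <- which(res$end == "unassigned")
    if (length(una) > 0 && length(rdna_flanks) > 0) {
      blks <- lapply(rdna_flanks, function(fl)
        cpp_anchor_blocks(fl, res$oriented_seq[una], 16L))
      lens <- vapply(blks, function(b) b[, 1], numeric(length(una)))
      lens <- matrix(lens, nrow = length(una))
      bestf <- max.col(lens, ties.method = "first")
      bestlen <- lens[cbind(seq_along(una), bestf)]
      cand <- which(bestlen >= min_anchor %/% 2L)
      if (length(cand) > 0) {
        ii <- una[cand]
        arr_start <- vapply(seq_along(ii), function(j) {
          b <- blks[[bestf[cand[j]]]]
          fl <- rdna_flanks[[bestf[cand[j]]]]
          pe <- b[cand[j], 2] + b[cand[j], 1] +
            (nchar(fl) - (b[cand[j], 3] + b[cand[j], 1]))
          rest <- substr(res$oriented_seq[ii[j]], pe + 1L,
                         nchar(res$oriented_seq[ii[j]]))
          strict <- tryCatch(find_array_start(rest),
                             error = function(e) NA_integer_)
          canon <- regexpr(CANONICAL_UNIT, rest, fixed = TRUE)
          canon <- if (canon == -1L) NA_integer_ else as.integer(canon) - 1L
          o <- suppressWarnings(min(strict, canon, na.rm = TRUE))
          if (is.infinite(o)) NA_integer_ else pe + o
        }, integer(1))
        ok <- !is.na(arr_start)
        if (any(ok)) {
          cl <- cluster_rdna_reads(res$oriented_seq[ii[ok]], arr_start[ok],
                                   min_rdna = min_anchor %/% 2L)
          grp <- cl$group
          sel <- ii[ok]
          res$end[sel][!is.na(grp)] <- paste0("rdna_g", grp[!is.na(grp)])
          res$array_start[sel] <- arr_start[ok]
          res$tract_seq[sel] <- substring(res$oriented_seq[sel],
                                          arr_start[ok] + 1L)
        }
      }
    }
    out[[a]] <- res
  }
  res <- do.call(rbind, out)

  keep <- !is.na(res$tract_seq) & !res$end %in% c("unassigned", "ambiguous")
  write_fasta(res$tract_seq[keep], res$read_id[keep],
              file.path(dir, "tracts.fasta"))
  tab <- res[, c("read_id", "accession", "end", "anchor_len", "anchor_start",
                 "anchor_end", "array_start", "flipped", "ambiguous",
                 "short_anchor")]
  write_tsv_conv(tab, file.path(dir, "anchored_reads.tsv"),
                 "anchor/array coordinates 0-based half-open on oriented read")
  invisible(dir)
}

#' @rdname run_pipeline
#' @export
stage_tokenize <- function(dir) {
  tracts <- read_fasta(file.path(dir, "tracts.fasta"))
  rows <- lapply(names(tracts), function(id) {
    ua <- tryCatch(tokenize(tracts[[id]]), error = function(e) NULL)
    if (is.null(ua)) return(NULL)
    data.frame(source_id = id, index = seq_len(nrow(ua$units)) - 1L,
               start = ua$units$start, stop = ua$units$end,
               seq = ua$units$seq, class = classify_units(ua$units$seq),
               stringsAsFactors = FALSE)
  })
  write_tsv_conv(do.call(rbind, rows), file.path(dir, "units.tsv"),
                 "start/stop 0-based half-open bp on the read tract")
  invisible(dir)
}

#' @rdname run_pipeline
#' @export
stage_boundaries <- function(dir) {
  units <- read_tsv_conv(file.path(dir, "units.tsv"))
  anch <- read_tsv_conv(file.path(dir, "anchored_reads.tsv"))
  key <- paste(anch$accession, anch$end, sep = "|")
  rows <- list()
  for (grp in unique(key)) {
    ids <- anch$read_id[key == grp]
    ids <- ids[ids %in% units$source_id]
    if (length(ids) == 0) next
    ulists <- lapply(ids, function(id) units$seq[units$source_id == id])
    b <- terminal_canonical_boundary(ulists)
    rows[[grp]] <- data.frame(
      read_id = ids, accession = sub("\\|.*", "", grp),
      end = sub(".*\\|", "", grp),
      terminal_start_unit = b$terminal_start,
      low_confidence = b$low_confidence, stringsAsFactors = FALSE)
  }
  write_tsv_conv(do.call(rbind, rows), file.path(dir, "boundaries.tsv"),
                 "terminal_start_unit is a 0-based unit index on the tract")
  invisible(dir)
}

#' @rdname run_pipeline
#' @export
stage_errormodel <- function(dir) {
  units <- read_tsv_conv(file.path(dir, "units.tsv"))
  bounds <- read_tsv_conv(file.path(dir, "boundaries.tsv"))
  tracts <- read_fasta(file.path(dir, "tracts.fasta"))
  meta <- read_tsv_conv(file.path(dir, "reads_meta.tsv"))

  term <- vapply(seq_len(nrow(bounds)), function(i) {
    id <- bounds$read_id[i]
    u <- units[units$source_id == id, ]
    ts <- bounds$terminal_start_unit[i]
    bp <- if (ts == 0) 0L else u$stop[u$index == ts - 1L]
    substr(tracts[[id]], bp + 1L, nchar(tracts[[id]]))
  }, character(1))
  names(term) <- bounds$read_id

  prof <- error_profiles(term, meta)
  write_tsv_conv(as.data.frame(prof), file.path(dir, "error_profiles.tsv"))
  corr <- tryCatch(error_quality_correlation(prof), error = function(e) {
    data.frame(variable = c("rq", "np"), r = NA_real_, p = NA_real_,
               n = nrow(prof), stringsAsFactors = FALSE)
  })
  write_tsv_conv(corr, file.path(dir, "correlation_report.tsv"))
  invisible(dir)
}

#' @rdname run_pipeline
#' @param seed seed for representative-read selection and permutations.
#' @export
stage_consensus <- function(dir, seed = 1L) {
  units <- read_tsv_conv(file.path(dir, "units.tsv"))
  bounds <- read_tsv_conv(file.path(dir, "boundaries.tsv"))
  key <- paste(bounds$accession, bounds$end, sep = "|")
  cons_rows <- list()
  for (grp in unique(key)) {
    sel <- bounds[key == grp, ]
    ulists <- lapply(seq_len(nrow(sel)), function(i) {
      u <- units[units$source_id == sel$read_id[i], ]
      head(u$seq, sel$terminal_start_unit[i])
    })
    lens <- vapply(seq_len(nrow(sel)), function(i) {
      u <- units[units$source_id == sel$read_id[i], ]
      ts <- sel$terminal_start_unit[i]
      if (ts == 0) 0L else u$stop[u$index == ts - 1L]
    }, integer(1))
    pick <- select_representative_reads(lens, seed = seed)
    cons <- build_consensus(ulists[[pick$idx[1]]], ulists[[pick$idx[2]]])
    if (length(cons) == 0) next
    cons_rows[[grp]] <- data.frame(
      accession = sel$accession[1], end = sel$end[1],
      position = seq_along(cons) - 1L, unit = cons,
      read_a = sel$read_id[pick$idx[1]], read_b = sel$read_id[pick$idx[2]],
      stringsAsFactors = FALSE)
  }
  cons <- do.call(rbind, cons_rows)
  write_tsv_conv(cons, file.path(dir, "consensus.tsv"),
                 "position is a 0-based unit index in the consensus array")

  cat_list <- split(cons$unit, paste(cons$accession, cons$end, sep = "|"))
  cat <- unit_catalog(cat_list)
  write_tsv_conv(cat$table, file.path(dir, "catalog.tsv"))
  by_acc <- split(cons$unit, cons$accession)
  sat <- saturation_curve(by_acc)
  write_tsv_conv(sat, file.path(dir, "saturation.tsv"))
  invisible(dir)
}

#' @rdname run_pipeline
#' @export
stage_hor <- function(dir) {
  cons <- read_tsv_conv(file.path(dir, "consensus.tsv"))
  key <- paste(cons$accession, cons$end, sep = "|")
  rows <- lapply(unique(key), function(grp) {
    u <- cons$unit[key == grp]
    u <- u[u != "N"]
    if (length(u) == 0) return(NULL)
    cl <- classify_array(u)
    ann <- cl$annotations
    if (nrow(ann) == 0) {
      return(data.frame(source = grp, class = paste(cl$labels, collapse = ","),
                        k = NA_integer_, copies = NA_integer_,
                        start = NA_integer_, end = NA_integer_,
                        block = "", n_mutated = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    data.frame(source = grp, class = ann$class, k = ann$k,
               copies = ann$copies, start = ann$start, end = ann$end,
               block = ann$block, n_mutated = ann$n_mutated,
               stringsAsFactors = FALSE)
  })
  write_tsv_conv(do.call(rbind, rows), file.path(dir, "hors.tsv"),
                 "start/end are 0-based half-open unit indices")
  invisible(dir)
}

#' @rdname run_pipeline
#' @param n_perm Mantel permutations for the merged-matrix association.
#' @export
stage_haplotype <- function(dir, seed = 1L, n_perm = 199L) {
  cons <- read_tsv_conv(file.path(dir, "consensus.tsv"))
  groups_df <- read_tsv_conv(file.path(dir, "groups.tsv"))
  groups <- stats::setNames(groups_df$group, groups_df$accession)
  params <- jsonlite::read_json(file.path(dir, "run_params.json"),
                                simplifyVector = TRUE)

  key <- paste(cons$accession, cons$end, sep = "|")
  compressed_all <- vapply(unique(key), function(grp) {
    compress_units(cons$unit[key == grp])
  }, character(1))
  acc_of <- sub("\\|.*", "", unique(key))
  end_of <- sub(".*\\|", "", unique(key))

  non_rdna <- setdiff(params$ends, params$rdna_ends)
  compressed <- list()
  for (e in non_rdna) {
    sel <- end_of == e & nchar(compressed_all) > 0
    if (sum(sel) >= 2) {
      compressed[[e]] <- stats::setNames(compressed_all[sel], acc_of[sel])
    }
  }
  dm <- distance_matrices(compressed, groups, seed = seed)
  for (e in names(dm$matrices)) {
    m <- dm$matrices[[e]]
    write_tsv_conv(data.frame(accession = rownames(m), m,
                              check.names = FALSE, stringsAsFactors = FALSE),
                   file.path(dir, sprintf("repeat_dist_%s.tsv", e)))
  }

  stats_rows <- list()
  add_stat <- function(name, st) {
    stats_rows[[length(stats_rows) + 1L]] <<- data.frame(
      comparison = name, test = st$test, statistic = st$statistic,
      df1 = st$df[1], df2 = if (length(st$df) > 1) st$df[2] else NA_real_,
      p_value = st$p_value, stringsAsFactors = FALSE)
  }
  if (length(dm$same_end) >= 2 && length(dm$cross_end) >= 2) {
    add_stat("same_end_vs_cross_end",
             wilcoxon_rank_sum(dm$same_end, dm$cross_end))
    st <- tryCatch(f_test_two_tailed(dm$same_end, dm$cross_end),
                   error = function(e) NULL)
    if (!is.null(st)) add_stat("same_end_vs_cross_end", st)
  }
  if (length(dm$same_group) >= 2 && length(dm$cross_group) >= 2) {
    add_stat("same_group_vs_cross_group",
             wilcoxon_rank_sum(dm$same_group, dm$cross_group))
    st <- tryCatch(f_test_two_tailed(dm$same_group, dm$cross_group),
                   error = function(e) NULL)
    if (!is.null(st)) add_stat("same_group_vs_cross_group", st)
  }

  # non-coding regions (truth annotation: flank minus gene+core)
  anchors <- read_fasta(file.path(dir, "anchors.fasta"))
  bed <- read_tsv_conv(file.path(dir, "truth_regions.bed"))
  nc_by_end <- list()
  nc_rows <- bed[bed$name == "noncoding", ]
  if (nrow(nc_rows) > 0) {
    for (e in non_rdna) {
      sel <- nc_rows[endsWith(nc_rows$chrom, paste0("|", e)), ]
      if (nrow(sel) < 2) next
      seqs <- vapply(seq_len(nrow(sel)), function(i) {
        substr(anchors[[sel$chrom[i]]], sel$start[i] + 1L, sel$end[i])
      }, character(1))
      names(seqs) <- sub("\\|.*", "", sel$chrom)
      nc_by_end[[e]] <- seqs
    }
  }

  trees <- character(0)
  mantel_rows <- list()
  for (e in names(nc_by_end)) {
    ncm <- noncoding_distance_matrix(nc_by_end[[e]])
    write_tsv_conv(data.frame(accession = rownames(ncm), ncm,
                              check.names = FALSE, stringsAsFactors = FALSE),
                   file.path(dir, sprintf("noncoding_dist_%s.tsv", e)))
    tree <- neighbor_joining(ncm)
    trees[e] <- paste0(e, "\t", tree$newick)
    if (e %in% names(dm$matrices) &&
        setequal(rownames(dm$matrices[[e]]), rownames(ncm))) {
      mm <- merged_matrix(dm$matrices[[e]], ncm, n_perm = n_perm, seed = seed)
      write_tsv_conv(data.frame(accession = mm$leaf_order, mm$matrix,
                                check.names = FALSE, stringsAsFactors = FALSE),
                     file.path(dir, sprintf("merged_matrix_%s.tsv", e)))
      mantel_rows[[e]] <- data.frame(
        comparison = sprintf("mantel_repeat_vs_noncoding_%s", e),
        test = "Mantel permutation (Pearson)", statistic = mm$mantel_r,
        df1 = NA_real_, df2 = NA_real_, p_value = mm$mantel_p,
        stringsAsFactors = FALSE)
    }
  }
  writeLines(trees, file.path(dir, "noncoding_nj.nwk"))
  stats_tab <- do.call(rbind, c(stats_rows, unname(mantel_rows)))
  write_tsv_conv(stats_tab, file.path(dir, "stats_report.tsv"))
  invisible(dir)
}

#' @rdname run_pipeline
#' @export
stage_report <- function(dir) {
  tmpl <- read_fasta(file.path(dir, "template_locus.fasta"))
  tmpl_rows <- lapply(names(tmpl), function(a) {
    r <- check_template(tmpl[[a]], tmpl[[1]])
    data.frame(accession = a, found = r$found, strand = r$strand,
               identical = r$identical,
               observed = r$observed, stringsAsFactors = FALSE)
  })
  write_tsv_conv(do.call(rbind, tmpl_rows),
                 file.path(dir, "template_report.tsv"))

  catalog <- read_tsv_conv(file.path(dir, "catalog.tsv"))
  cons <- read_tsv_conv(file.path(dir, "consensus.tsv"))
  hors <- read_tsv_conv(file.path(dir, "hors.tsv"))
  corr <- read_tsv_conv(file.path(dir, "correlation_report.tsv"))
  sat <- read_tsv_conv(file.path(dir, "saturation.tsv"))
  anch <- read_tsv_conv(file.path(dir, "anchored_reads.tsv"))

  key <- paste(cons$accession, cons$end, sep = "|")
  arr_len <- tapply(cons$unit, key, length)
  hor_counts <- table(unlist(strsplit(hors$class, ",")))

  summary <- list(
    n_reads = nrow(anch),
    n_assigned = sum(!anch$end %in% c("unassigned", "ambiguous")),
    n_ambiguous = sum(anch$end == "ambiguous"),
    catalog_size = nrow(catalog),
    canonical_frequency = if (CANONICAL_UNIT %in% catalog$unit)
      catalog$frequency[catalog$unit == CANONICAL_UNIT] else 0,
    top20 = head(catalog, 20),
    singleton_fraction = mean(catalog$count == 1L),
    saturation_final = if (nrow(sat) > 0) sat$cumulative_units[nrow(sat)] else 0L,
    hor_counts = as.list(hor_counts),
    consensus_length_units = list(mean = mean(arr_len), min = min(arr_len),
                                  max = max(arr_len)),
    error_correlation = corr)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full telomeric-repeat analysis pipeline
#'
#' Executes all stages in order — simulate, anchor, tokenize, boundaries,
#' errormodel, consensus, hor, haplotype, report — writing every
#' intermediate file into `dir`. Rerunning with the same configuration is
#' byte-identical except for the run log's timestamps. A stage failure
#' aborts with the failing stage named; partial outputs are retained.
#'
#' @param dir run directory.
#' @return `dir`, invisibly.
#' @export
run_pipeline <- function(config, dir) {
  validate_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(dir, "run.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n",
        file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  log_line("teloatlas", as.character(utils::packageVersion("teloatlas")),
           "| R", as.character(getRversion()), "| seed", config$seed)
  stages <- list(
    simulate = function() stage_simulate(config, dir),
    anchor = function() stage_anchor(dir),
    tokenize = function() stage_tokenize(dir),
    boundaries = function() stage_boundaries(dir),
    errormodel = function() stage_errormodel(dir),
    consensus = function() stage_consensus(dir, seed = config$seed),
    hor = function() stage_hor(dir),
    haplotype = function() stage_haplotype(dir, seed = config$seed),
    report = function() stage_report(dir))
  for (nm in names(stages)) {
    log_line("stage:", nm)
    tryCatch(stages[[nm]](), error = function(e) {
      log_line("stage", nm, "FAILED:", conditionMessage(e))
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_line("done")
  invisible(dir)
}
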