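#' Simulate ground-truth chromosome ends for a cohort of accessions
#'
#' Builds one `TruthEnd` record per accession and chromosome end. Each
#' non-rDNA end carries a unique anchor core (screened so that no two cores
#' share an exact block of 200 bp or more) ending in the most distal gene,
#' followed by a per-accession non-coding region and a repeat array of
#' degenerate then variant units; rDNA-like ends share a long common flank
#' (each diverged independently from the same base) and only rarely carry a
#' variant array. Variant and degenerate arrays descend from per-end global
#' ancestors through group ancestors, so accessions of the same genetic group
#' are more similar than accessions of different groups; planted higher-order
#' repeats (HORs) are introduced at the group-ancestor level. Truth unit
#' lists are normalized through the package's own unit definition
#' ([tokenize()] from the detected array start), so they are well defined
#' under the first-T/last-non-T unit convention.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `telo_truth`: a list of truth-end records with
#'   the cohort tables attached as attributes.
#' @export
simulate_truth <- function(config) {
  validate_config(config)
  cfg <- config
  set.seed(cfg$seed)

  acc_ids <- sprintf("acc%02d", seq_len(cfg$n_accessions))
  groups <- rep(seq_len(cfg$n_groups), length.out = cfg$n_accessions)
  names(groups) <- acc_ids

  is_rdna <- cfg$ends %in% cfg$rdna_ends
  anchors <- generate_anchor_cores(cfg, is_rdna)

  # Insertion source library; fragments with source "unclassified" are
  # deliberately absent so the labelling fallback is exercised.
  source_library <- c(mito_like = random_dna(1000L))
  tmpl_flank_l <- random_dna(150L)
  tmpl_flank_r <- random_dna(150L)
  template_locus <- paste0(tmpl_flank_l, TEMPLATE_MOTIF, tmpl_flank_r)

  # shared insertion fragments (one sequence per accession, reused across the
  # listed ends); fixed fragments are one substring of the library source
  frag_pool <- lapply(cfg$insertion_specs, function(spec) {
    if (isTRUE(spec$shared)) {
      frags <- vapply(acc_ids, function(a) random_dna(spec$len), character(1))
      stats::setNames(frags, acc_ids)
    } else if (spec$source %in% names(source_library)) {
      src <- source_library[[spec$source]]
      start <- sample.int(nchar(src) - spec$len + 1L, 1L)
      rep(substr(src, start, start + spec$len - 1L), cfg$n_accessions) |>
        stats::setNames(acc_ids)
    } else {
      stats::setNames(rep(random_dna(spec$len), cfg$n_accessions), acc_ids)
    }
  })
  frag_present <- lapply(cfg$insertion_specs, function(spec) {
    stats::setNames(runif(cfg$n_accessions) < spec$prob, acc_ids)
  })

  truth <- list()
  for (e in seq_along(cfg$ends)) {
    end <- cfg$ends[e]
    rdna <- is_rdna[e]

    # per-end global ancestors
    var_target <- sample.int(cfg$variant_len[2] - cfg$variant_len[1] + 1L, 1L) +
      cfg$variant_len[1] - 1L
    deg_target <- sample.int(cfg$degenerate_len[2] - cfg$degenerate_len[1] + 1L, 1L) +
      cfg$degenerate_len[1] - 1L
    global_var <- sample_alphabet(cfg$unit_alphabet, var_target)
    global_deg <- sample_alphabet(cfg$degenerate_alphabet, deg_target,
                                  pattern_start = TRUE)
    nc_len <- sample.int(cfg$noncoding_range[2] - cfg$noncoding_range[1] + 1L, 1L) +
      cfg$noncoding_range[1] - 1L
    global_nc <- random_dna(nc_len)

    group_state <- lapply(seq_len(cfg$n_groups), function(g) {
      gv <- mutate_units(global_var, cfg$group_ancestor_divergence, cfg$unit_alphabet)
      gd <- mutate_units(global_deg, cfg$group_ancestor_divergence,
                         cfg$degenerate_alphabet, protect = 1L)
      gnc <- mutate_bases(global_nc, cfg$group_ancestor_divergence)
      hor <- NULL
      if (!rdna && runif(1) < cfg$hor_plant_prob && length(gv) >= 2L) {
        planted <- plant_hor(gv, cfg)
        gv <- planted$units
        hor <- planted$hor
      }
      list(var = gv, deg = gd, nc = gnc, hor = hor)
    })

    for (a in acc_ids) {
      g <- groups[[a]]
      st <- group_state[[g]]
      hor <- st$hor
      protected <- if (!is.null(hor)) {
        seq(hor$start_unit + 1L, hor$start_unit + hor$k * hor$copies)
      } else integer(0)

      if (rdna) {
        has_var <- runif(1) < cfg$rdna_variant_prob
        var_units <- if (has_var) {
          mutate_units(st$var[seq_len(min(length(st$var), 12L))],
                       cfg$group_divergence, cfg$unit_alphabet)
        } else character(0)
        deg_units <- character(0)
        nc_seq <- ""
        flank <- anchors$rdna_flanks[[end]]
        gene_span <- c(NA_integer_, NA_integer_)
        hor <- NULL
      } else {
        var_units <- mutate_units(st$var, cfg$group_divergence,
                                  cfg$unit_alphabet, protect = protected)
        deg_units <- mutate_units(st$deg, cfg$group_divergence,
                                  cfg$degenerate_alphabet, protect = 1L)
        nc_seq <- mutate_bases(st$nc, cfg$group_divergence)
        flank <- paste0(anchors$cores[[end]], nc_seq)
        gene_span <- c(cfg$anchor_len - cfg$gene_len, cfg$anchor_len)
      }

      # normalize through the unit definition so truth units are exactly what
      # the tokenizer calls units; bases before the array-start rule's first
      # match are trimmed away
      norm <- normalize_truth_units(deg_units, var_units)
      units_df <- norm$units
      if (!is.null(hor)) {
        # re-locate the planted block on the normalized unit list
        hor$start_unit <- locate_block(units_df$seq, hor$block, 1L)
        if (is.na(hor$start_unit)) hor <- NULL
      }

      insertions <- list()
      for (s in seq_along(cfg$insertion_specs)) {
        spec <- cfg$insertion_specs[[s]]
        if (!(end %in% spec$ends) || rdna) next
        if (!frag_present[[s]][[a]]) next
        n_units <- nrow(units_df)
        lo <- norm$n_deg + 1L
        if (n_units < lo + 1L) next
        offset <- sample(seq(lo, n_units - 1L), 1L)
        insertions[[length(insertions) + 1L]] <-
          list(unit_offset = offset, seq = frag_pool[[s]][[a]],
               source = spec$source)
      }

      truth[[paste(a, end, sep = "|")]] <- structure(list(
        accession_id = a, group_id = g, end_label = end, is_rdna = rdna,
        anchor_seq = flank, anchor_core_len = if (rdna) nchar(flank) else cfg$anchor_len,
        gene_span = gene_span, noncoding_seq = nc_seq,
        units = units_df, n_degenerate = norm$n_deg,
        planted_hors = if (is.null(hor)) list() else list(hor),
        insertions = insertions,
        canonical_tail_len = cfg$canonical_tail_len,
        template_locus = template_locus), class = "telo_truth_end")
    }
  }

  structure(truth, class = "telo_truth",
            accessions = acc_ids, groups = groups, ends = cfg$ends,
            rdna_ends = cfg$rdna_ends,
            anchor_cores = anchors$cores, rdna_flanks = anchors$rdna_flanks,
            source_library = source_library, config = cfg)
}

# Draw alphabet units until the target bp length is reached. With
# `pattern_start`, the first unit is drawn from the subset matching the
# array-start rule (T)x(M)(G)y(M), so the array by construction begins where
# that rule says an array begins.
ARRAY_START_UNITS <- c(TAGGA = 0.5, TTAGGA = 0.3, TCGA = 0.2)

sample_alphabet <- function(alphabet, target_bp, pattern_start = FALSE) {
  units <- character(0)
  total <- 0L
  if (pattern_start) {
    u <- sample(names(ARRAY_START_UNITS), 1L, prob = ARRAY_START_UNITS)
    units <- u
    total <- nchar(u)
  }
  while (total < target_bp) {
    u <- sample(names(alphabet), 1L, prob = alphabet)
    units <- c(units, u)
    total <- total + nchar(u)
  }
  units
}

# Substitute units at `rate` with a different alphabet draw; `protect` gives
# 1-based indices exempt from substitution (planted HOR spans).
mutate_units <- function(units, rate, alphabet, protect = integer(0)) {
  if (rate <= 0 || length(units) == 0) return(units)
  hit <- setdiff(which(runif(length(units)) < rate), protect)
  for (i in hit) {
    pool <- setdiff(names(alphabet), units[i])
    if (length(pool) > 0) {
      w <- alphabet[pool]
      units[i] <- sample(pool, 1L, prob = w)
    }
  }
  units
}

# Plant one HOR into a unit vector: pick block size, copy number and anchor
# position, tandem-duplicate the block, optionally mutating single units of
# individual copies.
plant_hor <- function(units, cfg) {
  k <- sample(cfg$hor_block_sizes, 1L)
  k <- min(k, length(units))
  copies <- sample(cfg$hor_copies, 1L)
  if (k == 1L) copies <- max(copies, 3L)  # monomer homogenization needs a run
  p <- sample.int(length(units) - k + 1L, 1L)
  block <- units[p:(p + k - 1L)]
  mutated <- list()
  expansion <- character(0)
  for (cpy in seq_len(copies)) {
    cp <- block
    if (k > 1L && runif(1) < cfg$hor_mutation_prob) {
      pos <- sample.int(k, 1L)
      pool <- setdiff(names(cfg$unit_alphabet), cp[pos])
      cp[pos] <- sample(pool, 1L, prob = cfg$unit_alphabet[pool])
      mutated[[length(mutated) + 1L]] <- c(copy = cpy, position = pos)
    }
    expansion <- c(expansion, cp)
  }
  out <- append(units[-(p:(p + k - 1L))], expansion, after = p - 1L)
  list(units = out,
       hor = list(block = block, k = k, copies = copies,
                  mutated_copies = mutated, start_unit = p - 1L))
}

# Tokenize the concatenated degenerate+variant bases from the array start and
# return the truth unit table (0-based bp coordinates within the array).
normalize_truth_units <- function(deg_units, var_units) {
  deg_bases <- paste(deg_units, collapse = "")
  var_bases <- paste(var_units, collapse = "")
  full <- paste0(deg_bases, var_bases)
  if (nchar(full) < 2L) {
    return(list(units = data.frame(seq = character(0), class = character(0),
                                   start = integer(0), end = integer(0)),
                n_deg = 0L, n_deg_dropped = 0L))
  }
  astart <- tryCatch(find_array_start(full), error = function(e) NA_integer_)
  if (is.na(astart)) astart <- 0L
  ua <- tokenize(substr(full, astart + 1L, nchar(full)))
  cls <- classify_units(ua$units$seq)
  units <- data.frame(seq = ua$units$seq, class = cls,
                      start = ua$units$start, end = ua$units$end,
                      stringsAsFactors = FALSE)
  deg_end_bp <- nchar(deg_bases) - astart
  n_deg <- sum(units$end <= deg_end_bp)
  list(units = units, n_deg = n_deg, n_deg_dropped = 0L)
}

# First occurrence of `block` at or after unit index `from` (1-based window
# start); returns 0-based start or NA.
locate_block <- function(units, block, from) {
  k <- length(block)
  n <- length(units)
  if (n < k) return(NA_integer_)
  for (p in seq(max(1L, from), n - k + 1L)) {
    if (all(units[p:(p + k - 1L)] == block)) return(p - 1L)
  }
  NA_integer_
}

# Generate pairwise-distinguishable anchor cores for non-rDNA ends and the
# shared rDNA-like flanks (each diverged from a common base).
generate_anchor_cores <- function(cfg, is_rdna) {
  cores <- list()
  for (e in which(!is_rdna)) {
    repeat {
      cand <- random_dna(cfg$anchor_len)
      ok <- TRUE
      for (prev in cores) {
        blk <- cpp_anchor_blocks(prev, cand, 16L)
        if (blk[1, 1] >= ANCHOR_UNIQUENESS_FLOOR) { ok <- FALSE; break }
      }
      if (ok) { cores[[cfg$ends[e]]] <- cand; break }
    }
  }
  rdna_flanks <- list()
  if (any(is_rdna)) {
    base <- random_dna(cfg$anchor_len)
    for (e in which(is_rdna)) {
      rdna_flanks[[cfg$ends[e]]] <- mutate_bases(base, cfg$rdna_flank_divergence)
    }
  }
  list(cores = cores, rdna_flanks = rdna_flanks)
}

#' @export
print.telo_truth <- function(x, ...) {
  cat("telo_truth:", length(attr(x, "accessions")), "accessions x",
      length(attr(x, "ends")), "ends =", length(x), "truth ends\n")
  invisible(x)
}
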