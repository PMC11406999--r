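#' Simulation configuration for chromosome-end truth sets and HiFi-like reads
#'
#' Bundles every tunable of the synthetic-data generator: cohort structure,
#' chromosome-end layout, repeat-unit alphabets, higher-order repeat (HOR)
#' planting, non-telomeric insertions, read depth and the quality-dependent
#' homopolymer indel error model. Defaults describe a desk-scale cohort with
#' the organisation observed at *A. thaliana* chromosome ends: a unique
#' repeat-adjacent flank per end (two rDNA-like ends share a long common
#' flank instead), a distal gene followed by a non-coding region, then
#' degenerate, variant and finally canonical repeats in head-to-tail
#' arrangement.
#'
#' @param seed integer seed controlling truth-set generation.
#' @param n_accessions number of accessions in the cohort.
#' @param n_groups number of genetic groups; accessions are assigned
#'   round-robin.
#' @param ends chromosome-end labels. `rdna_ends` must be a subset.
#' @param rdna_ends ends whose telomere abuts a shared rDNA-like array and
#'   therefore has no unique anchor.
#' @param anchor_len length (bp) of the unique repeat-adjacent anchor core.
#' @param gene_len length (bp) of the most distal gene, placed at the end of
#'   the anchor core.
#' @param noncoding_range range (bp) of the non-coding region between the
#'   distal gene and the first telomeric repeat.
#' @param degenerate_len,variant_len target length ranges (bp) of the
#'   degenerate and variant repeat segments.
#' @param unit_alphabet named numeric vector: variant-unit strings with
#'   sampling weights (canonical TTTAGGG interspersed among them).
#' @param degenerate_alphabet named numeric vector of degenerate unit draws.
#' @param hor_plant_prob probability that a group ancestor array at one end
#'   receives a planted HOR.
#' @param hor_block_sizes,hor_copies integer ranges for HOR block size (units)
#'   and tandem copy number.
#' @param hor_mutation_prob per-copy probability of a single-unit mutation in
#'   a planted HOR.
#' @param insertion_specs list of non-telomeric insertion specifications; each
#'   element is `list(len =, source =, prob =, ends =, shared = )`. Fragments
#'   with `shared = TRUE` use one sequence per accession across all listed
#'   ends; `source` names an entry of the emitted source library (or
#'   "unclassified" for fragments deliberately absent from it).
#' @param canonical_tail_len range (bp) of the terminal pure-canonical tail,
#'   drawn per molecule.
#' @param depth simulated reads per chromosome end.
#' @param np_range integer range of HiFi subread counts (np).
#' @param rq_of_np monotone increasing function mapping np to read accuracy
#'   rq in (0, 1].
#' @param rq_noise_sd small Gaussian jitter added to `rq_of_np(np)`.
#' @param error_rate_fn per-homopolymer-run 1-bp indel probability as a
#'   decreasing function of rq.
#' @param orientation_flip_prob probability a read is emitted as the reverse
#'   complement.
#' @param somatic_jitter per-molecule probability that a run of identical
#'   units expands or contracts by one copy.
#' @param group_divergence per-accession unit substitution rate applied to
#'   the group-ancestor arrays (repeats and non-coding alike).
#' @param group_ancestor_divergence substitution rate from the global to the
#'   group ancestor; the default keeps between-group divergence at three
#'   times the within-group rate.
#' @param rdna_flank_divergence substitution rate applied independently to
#'   each rDNA-like end flank from their common base sequence.
#' @param rdna_variant_prob probability an rDNA-like end carries a (short)
#'   variant array at all.
#'
#' @return A validated list of class `telo_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_accessions = 10L,
                       n_groups = 2L,
                       ends = c("chr1p", "chr1q", "chr2p", "chr2q", "chr3p",
                                "chr3q", "chr4p", "chr4q", "chr5p", "chr5q"),
                       rdna_ends = c("chr2p", "chr4p"),
                       anchor_len = 2000L,
                       gene_len = 400L,
                       noncoding_range = c(0L, 1200L),
                       degenerate_len = c(30L, 150L),
                       variant_len = c(100L, 700L),
                       unit_alphabet = c(TTTAGGG = 0.25, TTCAGGG = 0.18,
                                         TATAGGG = 0.13, TTAGGG = 0.11,
                                         TTTAGG = 0.10, TTTTAGGG = 0.08,
                                         TTTCAGGG = 0.06, TTTAGGGG = 0.05,
                                         TTCAGGGG = 0.04),
                       degenerate_alphabet = c(TG = 0.15, TAG = 0.13,
                                               TTG = 0.10, TTAG = 0.10,
                                               TCTGA = 0.09, TGG = 0.09,
                                               TTTAG = 0.08, TAAG = 0.07,
                                               TCG = 0.05, TAGGA = 0.08,
                                               TTAGGA = 0.06),
                       hor_plant_prob = 0.35,
                       hor_block_sizes = 1:8,
                       hor_copies = 2:15,
                       hor_mutation_prob = 0.2,
                       insertion_specs = list(
                         list(len = 110L, source = "mito_like", prob = 0.06,
                              ends = "chr1p", shared = FALSE),
                         list(len = 495L, source = "unclassified", prob = 0.04,
                              ends = c("chr3q", "chr5q"), shared = TRUE)),
                       canonical_tail_len = c(300L, 800L),
                       depth = 10L,
                       np_range = c(3L, 20L),
                       rq_of_np = function(np) 1 - 0.02 * exp(-(np - 3) / 6),
                       rq_noise_sd = 0.002,
                       error_rate_fn = function(rq) 0.3 * (1 - rq),
                       orientation_flip_prob = 0.5,
                       somatic_jitter = 0.02,
                       group_divergence = 0.05,
                       group_ancestor_divergence = 3 * group_divergence,
                       rdna_flank_divergence = 0.02,
                       rdna_variant_prob = 12 / 148) {
  cfg <- list(seed = as.integer(seed), n_accessions = as.integer(n_accessions),
              n_groups = as.integer(n_groups), ends = ends,
              rdna_ends = rdna_ends, anchor_len = as.integer(anchor_len),
              gene_len = as.integer(gene_len),
              noncoding_range = as.integer(noncoding_range),
              degenerate_len = as.integer(degenerate_len),
              variant_len = as.integer(variant_len),
              unit_alphabet = unit_alphabet,
              degenerate_alphabet = degenerate_alphabet,
              hor_plant_prob = hor_plant_prob,
              hor_block_sizes = as.integer(hor_block_sizes),
              hor_copies = as.integer(hor_copies),
              hor_mutation_prob = hor_mutation_prob,
              insertion_specs = insertion_specs,
              canonical_tail_len = as.integer(canonical_tail_len),
              depth = as.integer(depth), np_range = as.integer(np_range),
              rq_of_np = rq_of_np, rq_noise_sd = rq_noise_sd,
              error_rate_fn = error_rate_fn,
              orientation_flip_prob = orientation_flip_prob,
              somatic_jitter = somatic_jitter,
              group_divergence = group_divergence,
              group_ancestor_divergence = group_ancestor_divergence,
              rdna_flank_divergence = rdna_flank_divergence,
              rdna_variant_prob = rdna_variant_prob)
  class(cfg) <- "telo_config"
  validate_config(cfg)
  cfg
}

# Anchors must be long enough to remain pairwise distinguishable after the
# shared-substring screen; 200 bp is the screen's ceiling.
ANCHOR_UNIQUENESS_FLOOR <- 200L

validate_config <- function(cfg) {
  probs <- c(cfg$hor_plant_prob, cfg$hor_mutation_prob,
             cfg$orientation_flip_prob, cfg$somatic_jitter,
             cfg$group_divergence, cfg$group_ancestor_divergence,
             cfg$rdna_flank_divergence, cfg$rdna_variant_prob,
             vapply(cfg$insertion_specs, function(s) s$prob, numeric(1)))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$n_accessions < 1L || cfg$n_groups < 1L) {
    stop("n_accessions and n_groups must be positive")
  }
  if (cfg$anchor_len < ANCHOR_UNIQUENESS_FLOOR) {
    stop("anchor_len below the k-mer uniqueness floor (",
         ANCHOR_UNIQUENESS_FLOOR, " bp): anchors would not be pairwise ",
         "distinguishable")
  }
  if (!all(cfg$rdna_ends %in% cfg$ends)) stop("rdna_ends must be a subset of ends")
  np <- seq(cfg$np_range[1], cfg$np_range[2])
  rq <- cfg$rq_of_np(np)
  if (any(diff(rq) <= 0)) stop("rq_of_np must be strictly increasing in np")
  if (any(rq <= 0 | rq > 1)) stop("rq_of_np must map into (0, 1]")
  if (any(!grepl("^[ACGT]+$", names(cfg$unit_alphabet))) ||
      any(!grepl("^[ACGT]+$", names(cfg$degenerate_alphabet)))) {
    stop("alphabet units must be over {A,C,G,T}")
  }
  invisible(cfg)
}

#' @export
print.telo_config <- function(x, ...) {
  cat("telo_config:", x$n_accessions, "accessions in", x$n_groups,
      "groups;", length(x$ends), "ends (", length(x$rdna_ends),
      "rDNA-like); depth", x$depth, "\n")
  cat("  anchor", x$anchor_len, "bp; variant segment",
      paste(x$variant_len, collapse = "-"), "bp; tail",
      paste(x$canonical_tail_len, collapse = "-"), "bp\n")
  invisible(x)
}

# Echo the configuration as structured text (for the run directory).
config_as_text <- function(cfg) {
  flat <- lapply(cfg, function(v) {
    if (is.function(v)) paste(deparse(v), collapse = " ")
    else if (is.list(v)) paste(vapply(v, function(s)
      paste(names(s), vapply(s, paste, character(1), collapse = ","),
            sep = "=", collapse = ";"), character(1)), collapse = " | ")
    else paste(if (!is.null(names(v))) paste(names(v), v, sep = ":") else v,
               collapse = ",")
  })
  paste(names(flat), unlist(flat), sep = "\t")
}
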