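# teloatlas

Telomeric repeat variant analysis from HiFi-like long reads, with a
built-in truth-known simulator.

Plant telomeres end in arrays of the canonical repeat 5'-TTTAGGG-3'.
Between the unique chromosome-end flank and that pure canonical tract lie
*degenerate* and *variant* repeats (for example TTCAGGG, TATAGGG) whose
composition is hypervariable between individuals, yet heritable enough to
act as a haplotype marker for each chromosome end. Profiling this region
from accurate long reads requires a chain of small, well-defined
algorithms, and `teloatlas` implements each of them as a tested R
function:

* **Simulation** — chromosome-end truth structures (unique anchors, distal
  gene + non-coding region, degenerate → variant → canonical arrays,
  planted higher-order repeats, non-telomeric insertions, shared rDNA-like
  flanks) and HiFi-like reads with per-read subread count (np), read
  quality (rq) and quality-dependent 1-bp homopolymer indels.
* **Anchoring** — orientation to 5'-TTTAGGG-3', read-to-end assignment by
  exact k-mer-seeded flank blocks, consistency graphs with chimera
  flagging, and similarity clustering of rDNA-adjacent reads.
* **Tokenization** — array-start detection at the first
  (T)x(M)(G)y(M) instance (M = A or C) and a deterministic
  dynamic-programming decomposition of the tract into 2–17 bp units that
  begin at a T and end with the last non-T base, minimizing edit distance
  to the canonical unit under that convention.
* **Error model** — per-read minimized Levenshtein distance L(obs,
  TTTAGGG^n) over the terminal canonical region via hill-climbing with an
  exhaustive-search guard; the *relative distance* L\*/len(obs) is an
  indel-density measure correlated against rq and np.
* **Consensus & catalog** — two-read consensus unit arrays per end
  (non-conserved positions masked "N"), unit frequency catalogs, top-20
  lists and saturation curves.
* **HOR annotation** — monomer homogenization runs, simple (2–4-unit) and
  multi-monomer (≥5-unit) higher-order repeats, and HORs with mutated
  copies, selected greedily into a deterministic non-overlapping set.
* **Haplotype statistics** — repeat-compressed arrays (runs of identical
  units collapsed), relative L-distance matrices (L/max length), F and
  Wilcoxon tests on same/cross end and same/cross genetic-group distance
  pools, neighbor-joining trees of non-coding flanks, and merged
  repeat/non-coding matrices with a Mantel-style association test.

## A worked example

```r
library(teloatlas)

ua <- tokenize("TGTTTAGGGTCTGATGGG")
ua
#> unit_array: 4 units over 18 bp
#>   TG TTTAGGG TCTGA TGGG
classify_units(ua$units$seq)
#> [1] "degenerate" "canonical"  "degenerate" "degenerate"
```

The tract decomposes into four units under the first-T/last-non-T
convention; only the exact TTTAGGG is canonical, and short or distant
units are degenerate.

```r
ideal_distance("TTAGGGTTTAGG")
#> $n_star
#> [1] 2
#> $L_star
#> [1] 2
#> $rel_dist
#> [1] 0.1666667
```

A 12-bp terminal sequence is best explained by a 2-unit ideal canonical
array at edit distance 2 (two 1-bp deletions — the classic homopolymer
artifact), giving a relative distance of 2/12.

A full synthetic cohort runs through every stage with one call and writes
all intermediates (FASTA/TSV/BED/Newick/JSON, coordinates 0-based
half-open) into a run directory:

```r
cfg <- sim_config(seed = 7, n_accessions = 4, depth = 5)
cfg
#> telo_config: 4 accessions in 2 groups; 10 ends ( 2 rDNA-like); depth 5
#>   anchor 2000 bp; variant segment 100-700 bp; tail 300-800 bp
run_pipeline(cfg, "my_run")
```

`my_run/summary.json` then reports the assignment counts, catalog size,
canonical-unit frequency, top-20 units, HOR class counts and the
rq/np-versus-indel-density correlations for that cohort. A thin CLI over
the same stages is provided at `inst/cli/teloatlas.R`
(`Rscript teloatlas.R all --dir my_run --seed 7`); every subcommand can be
re-run independently from the run directory.

See `vignettes/teloatlas-methods.Rmd` for the model, the tokenizer's
tie-break rules, the error model, all tunable thresholds, and what the
simulator does and does not emulate.

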