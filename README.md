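# genebirth

Reconstructing how *de novo* protein-coding genes originate in the
*Saccharomyces cerevisiae* lineage.

Most genes arise from other genes; *de novo* genes arise from non-genic DNA
that accumulates mutations until it is transcribed, carries an open reading
frame (ORF) and is translated. `genebirth` is for molecular evolution
researchers who want to observe that transition directly rather than infer
it from cross-species snapshots. Given per-species genome FASTA files, a
catalogue of young genes with conservation classes, and a rooted species
tree, it:

1. assigns each gene's **birth edge** on the tree by parsimony
   (cerevisiae-specific classes S0+/S1: edge A1 → cerevisiae; class S2,
   shared with paradoxus: edge A2 → A1, where A1/A2 are the
   cerevisiae+paradoxus and +mikatae ancestors);
2. maps each locus (with 500 nt flanks) onto the related genomes by
   **glocal alignment** — global in the query, local in the target — and
   builds a progressive multiple alignment of the orthologue set;
3. reconstructs **marginal maximum-likelihood ancestral sequences** at both
   ends of the birth edge under an HKY model (pruning algorithm; per-site
   posteriors p_ij; sequences with mean max posterior
   (1/L) Σ_i max_j p_ij < 0.80 are discarded);
4. quantifies the evolution from the non-genic parent to the genic child —
   GC content (third codon positions for genic, whole region for
   non-genic), the seven mutation classes (transition, transversion,
   AT>GC, GC>AT, AT>AT, GC>GC, indel), ORF length changes under three
   start-codon rules (most upstream `ATG`, `A..ATG`, `A..ATG.C`), and
   Kozak-signature turnover (No/Retain/Disappear/Appear) — with intergenic
   ORFs as the neutral background;
5. tests the four-stage origination scenario: (1) GC-rich origin →
   (2) neutral mutation accumulation → (3) ORF extension/combination →
   (4) Kozak recruitment, using Welch's *t*-tests against the intergene
   background and exact one-sided binomial trend tests with
   intergene-derived background probabilities
   p0 = (bg_extend + ½)/(bg_extend + bg_shrink + 1).

A sequence-evolution simulator (`simulate_catalogue()`) generates genomes,
catalogues and a complete ground-truth event log under the same model
assumptions, so every stage is testable without external genome downloads.

## Worked example

Simulate a small study — 30 cerevisiae-specific (S1-like) loci that gained
a stop-removing mutation on their birth edge, plus 50 intergenic background
loci — and run the full pipeline:

```r
library(genebirth)

cfg <- sim_config(tree_spec = yeast_tree(bayanus = FALSE),
                  n_loci_per_class = c(S1 = 30, intergene = 50),
                  locus_length = 240, seed = 2024)
sim  <- simulate_catalogue(cfg)
scen <- denovo_scenario(sim$genomes, sim$catalogue, sim$tree, flank = 50)
print(scen)
```

```
De novo gene-birth scenario analysis
  catalogue: 80 loci, 80 after length filter, 130 feature rows
De novo gene origination scenario (alpha = 0.01)
  (1) GC-rich origin                   supported  [min p = 3.51e-09]
  (2) neutral mutation accumulation    supported  [min p = 0.233]
  (3) ORF extension/combination        supported  [min p = 0.00165]
  (4) Kozak signature recruitment      not supported  [min p = 0.944]
```

Stage 1: the reconstructed ancestors of the S1 loci average 38.6% GC versus
32.7% for intergenic ancestors (Welch p = 3.5e-09) — the birth regions were
GC-rich *before* the genes existed. Stage 2: none of the seven
mutation-class frequencies on the birth edge differs from the intergenic
background (all p ≥ 0.23) — the mutations that made these genes look
neutral. Stage 3: 17 of 21 changed loci extended their most-upstream-ATG
ORF against a background probability of 0.47 (exact binomial p = 0.0016) —
the injected stop removals are recovered. Stage 4: Kozak appearances show
no trend (p = 0.94) because the simulation injected none — the package
reports translation-signature recruitment as a later, separate step, which
is exactly the ordering the scenario predicts:

```r
print(scen$tests$orf_changes[["S1 ATG"]])
#> binomial trend: 17/21 successes vs p0 = 0.4722, p = 0.001649 (one-sided)
print(scen$tests$kozak[["S1 A..ATG"]])
#> binomial trend: 1/5 successes vs p0 = 0.4375, p = 0.9437 (one-sided)
```

Per-locus features are in `scen$features`, the pooled per-class tables in
`scen$summaries`, and `plot(scen)` draws the ancestral-GC box plot.
`run_pipeline()` runs the same analysis from files on disk and writes the
feature table, the four summary tables and `scenario_report.json`;
`inst/scripts/denovo-scenario.R` wraps it for the shell.

## Package layout

- `R/simulate.R` — HKY + indel simulator with replayable event logs
- `R/glocal.R`, `src/align.cpp` — glocal scan/traceback and profile aligner
- `R/ortholog.R` — catalogue filtering, locus extraction, orthologue search
- `R/msa.R` — progressive profile alignment on the guide tree
- `R/reconstruct.R` — pruning-based marginal ancestors, confidence filter
- `R/features.R` — mutation classes, GC, ORF scanning, Kozak transitions
- `R/stats.R` — Welch tests, exact binomial trends, scenario report
- `R/pipeline.R` — `denovo_scenario()` / `run_pipeline()`
- `R/validate.R` — brute-force oracles and seeded recovery evaluations
- `vignettes/gene-birth-methods.Rmd` — models, parameters, design choices
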