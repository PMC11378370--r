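---
title: "Methods: reconstructing the birth of de novo protein-coding genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing the birth of de novo protein-coding genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(genebirth)
```

## The question and the approach

Most protein-coding genes arise by duplication or rearrangement of existing
genes, but a substantial minority are born *de novo*: a stretch of non-genic
DNA accumulates mutations until it is transcribed, carries an open reading
frame (ORF), and is translated. `genebirth` implements an analysis that makes
this transition directly observable for the *Saccharomyces cerevisiae*
lineage. The idea is to exploit a catalogue of young genes whose conservation
level across the *sensu stricto* clade is known:

* classes `S0+` (unannotated, translation evidence only) and `S1`
  (annotated) are specific to cerevisiae — by parsimony they were born on
  the tree edge from **A1** (the cerevisiae+paradoxus ancestor) to the
  cerevisiae tip;
* class `S2` is shared with paradoxus — born on the edge from **A2** (the
  cerevisiae+paradoxus+mikatae ancestor) to A1.

For each catalogued locus the pipeline reconstructs the sequence at both
ends of its birth edge and asks what changed between the non-genic parent
and the genic child, using intergenic ORFs — loci sampled from
transcription-free regions — as the neutral background. Four feature sets
are computed: GC content, the spectrum of accumulated mutations, ORF length
changes, and turnover of the Kozak translation-initiation context.

## Pipeline stages

1. **Catalogue filtering.** Loci shorter than 60 nt are discarded
   (statistics from very short ORFs are unreliable); the per-class tally of
   discards is logged.
2. **Locus extraction.** Each locus is cut from the focal genome with up to
   500 nt of flank on both sides (truncated at contig ends); minus-strand
   loci are reverse-complemented so the ORF reads 5'→3'. The flanks usually
   contain pieces of neighbouring conserved sequence, which makes the next
   step effectively synteny-aware without an explicit synteny model.
3. **Orthologue mapping.** The locus is aligned to both strands of every
   chromosome of each related genome with a *glocal* aligner — global in
   the query, local in the target — under affine gap scores
   (match +5, mismatch −4, gap open −12, gap extend −4 per position; a gap
   run of length $k$ costs $-12 - 4k$). The single best hit per genome is
   kept; hits scoring below `0.3 * match * query length` are treated as
   missing. The implementation scans chromosomes with a linear-memory
   score-only pass, locates the alignment start with a reversed pass, and
   runs the traceback only inside that window, so whole-genome scans stay
   exact.
4. **Multiple alignment.** Orthologue sets are aligned progressively along
   the species-tree topology; each merge is an affine-gap global
   profile–profile alignment ("once a gap, always a gap").
5. **Ancestral reconstruction.** Marginal maximum-likelihood ancestors at
   A1 and A2 are computed per column with the pruning algorithm under an
   HKY model. Gap/base status at internal nodes is decided first by Fitch
   parsimony on the binary gap character (ties resolved toward "base
   present" so sites remain available to the likelihood); gapped or
   ambiguous leaves are missing data. The reconstruction confidence is the
   mean over base-bearing columns of the maximum posterior; sequences
   below 0.80 are discarded.
6. **Features and statistics.** Features are computed on the induced
   pairwise alignment of the two edge ends, restricted to the columns
   spanned by the catalogued ORF. Group contrasts use Welch's *t*-test
   (unequal variances, Welch–Satterthwaite degrees of freedom);
   directional ORF-extension and Kozak-appearance trends use exact
   one-sided binomial tests whose background probability comes from the
   intergene tallies.

## Models and parameters

**Substitution model (HKY).** The mutation classes the analysis reports —
transition vs transversion, and the GC-pressure classes AT>GC / GC>AT /
AT>AT / GC>GC — are exactly the degrees of freedom of HKY (a
transition/transversion ratio $\kappa$ plus stationary base frequencies),
so nothing richer than HKY is needed to represent or emulate them. The rate
matrix is scaled to one expected substitution per site per unit branch
length. For reconstruction, $\kappa = 2$ by default and base frequencies
are estimated from each alignment (pooled counts, one pseudo-count per
base); branch lengths are taken from the input tree rather than
re-estimated, because individual loci (≥ 60 nt) are far too short for
stable per-locus estimates.

**Species tree.** `yeast_tree()` provides a rooted tree with branch lengths
in expected substitutions/site (cerevisiae 0.06, paradoxus 0.06, A1 0.05,
mikatae 0.12, A2 0.08, bayanus 0.20), emulating the published *sensu
stricto* phylogeny. The bayanus branch is much longer than the rest, which
is why no ancestor above A2 is ever reported: bayanus data, when present,
only adds likelihood signal.

**Start-codon rules.** An ORF is a stop-to-stop segment in one frame
containing a start under the active rule: the most upstream `ATG`, the most
upstream `A..ATG` (A at −3) or `A..ATG.C` (A at −3 and C at +4), '.' being
any base. Context bases may fall in the flank beyond the ORF: an ATG at a
segment's 5' edge still has a −3 base in the genome. ORF length runs from
the start through the stop codon inclusive; the convention is applied to
both nodes, so Extend/Shrink calls are convention-invariant. A segment
truncated by the sequence end yields an ORF without a stop, ending at its
last complete codon.

**GC content.** Genic sequences are measured at third codon positions only
(the positions least constrained by coding, hence the best proxy for
regional composition); non-genic sequences — including the ancestral,
pre-birth state of a locus — over the whole region. A descendant region
whose length is not a multiple of three (possible after indels in
simulation) falls back to whole-region GC.

**Mutation counting.** On the induced pair, aligned mismatching bases are
substitutions and each maximal run of one-sided gaps is one indel event; a
run that switches the gapped row mid-way counts once per side.
Substitution frequencies are percentages of aligned-base columns, the
indel frequency a percentage of all retained columns; columns containing N
are removed before counting. These denominators are a package choice — the
source tables print percentages without defining them — and are documented
here rather than inferred.

**Ancestral ORF mapping.** A recent ORF is mapped to the ancestral ORF that
overlaps it in alignment columns, is frame-consistent (codon phase agrees
at ≥ 50% of jointly aligned base columns, tolerating indel-induced frame
shifts), and has maximal overlap, ties to the most upstream candidate.
Loci with no mappable ancestral ORF are tallied separately, not as length
changes. Kozak transitions compare pattern presence within the ORF segment
at both nodes (`No`/`Retain`/`Disappear`/`Appear`); "No" means the pattern
is absent at both nodes, whether or not a bare ATG exists.

**Trend tests.** "No change" loci are not binomial trials. The background
probability uses half pseudo-counts,
$p_0 = (b_\mathrm{extend} + \tfrac12)/(b_\mathrm{extend} + b_\mathrm{shrink} + 1)$,
so it can never reach 0 or 1 even with sparse intergene tallies. Tests are
one-sided (the hypotheses — extension, appearance — are directional), with
a two-sided flag. Welch p-values use the *t* distribution by default; a
normal-approximation flag exists because one published ancestral-genome
bound is reproduced by a normal tail but not by a *t* tail, a discrepancy
we flag rather than resolve. Raw p-values are reported; multiplicity
correction is left to the caller (`p.adjust`) since the published analysis
reports raw bounds.

## The simulator and what it does (not) emulate

`simulate_catalogue()` generates per-species genomes, a catalogue and a
complete ground-truth log. Loci evolve independently down the tree under
HKY (exact stochastic simulation, every event logged) plus a Poisson indel
process (geometric lengths, mean 2, insertions and deletions equally
likely, inserted bases at the stationary composition). Defaults are the
study conditions the analysis assumes:

* root GC 0.38 for the de novo classes vs 0.31 for intergene loci
  (emulating the observed 37–40% vs 30–33% contrast);
* $\kappa = 3$ and stationary GC 0.40, giving a transition excess of
  ~1.6× and an AT>GC : GC>AT flux ratio of ~1.5 at 31% GC, matching the
  observed per-branch spectra; per-branch substitution loads fall in the
  observed 0.1–7% range for the default branch lengths;
* indel rate 0.1 events/site/unit branch — observed per-branch indel
  frequencies span roughly 0.1–3%, and this default sits inside that
  range for the default tree;
* gene birth as explicit targeted edits at a configurable time point on
  the class's birth edge: `stop_removal` mutates the first base of the
  most upstream ORF's stop codon (always T→C, never creating a new stop),
  extending or fusing ORFs; `kozak_creation` writes the −3 A (or +4 C)
  of the most upstream start. The source analysis gives no effect sizes
  for birth events; injecting exactly one stop-removal per locus
  reproduces the qualitative extend ≫ shrink asymmetry, which is all the
  downstream tests assert.

Loci are separated by fixed 200-nt spacers built from a `TAATTAATTAA`
repeat: stop codons in all three frames on both strands, no ATG, zero GC.
This keeps glocal mapping unambiguous at desk scale and terminates ORFs
cleanly at locus boundaries. All randomness flows from one seed through
R's generator in documented call order, so a fixed seed reproduces every
output byte for byte.

The simulator does **not** emulate selection on codons, recombination,
transcription (there is no RNA-seq/ribosome-profiling layer), repeat
content, or mosaic local GC structure. Passing the recovery tests
therefore shows that the pipeline is correct under its own model
assumptions — not that real genomes satisfy those assumptions.

## Validation design and problem sizes

Every load-bearing computation has an independent check:

* the glocal and global aligners against exhaustive enumeration of
  monotone matchings (all pairs up to 8 nt);
* the pruning posteriors against explicit summation over all internal
  state assignments, with transition matrices from `Matrix::expm` rather
  than the package's own eigendecomposition;
* Welch's test against a 50-digit `mpmath` reference, and the binomial
  tails against exact rational summation (Python `fractions`), for every
  trial count up to 200;
* the whole pipeline against the simulator's truth log: with 500
  indel-free intergenic loci of 300 nt on a tree with all branches ≤ 0.1,
  pooled transition/transversion frequencies on the reconstructed
  A1→cerevisiae edge recover the logged values within a few percent
  relative, and argmax ancestors match truth at ~99% of sites;
* scenario-order recovery: S1-like loci given a stop-removal but no Kozak
  creation show a strong extension trend and no Kozak-appearance trend —
  the "extension before Kozak recruitment" ordering.

Simulated scenarios are run as independent batches of 25–40 loci per
genome (pooled to 500 intergenic / ~280 mixed loci): the orthologue scan
is quadratic in genome size, and batching keeps it at desk scale without
changing any statistical condition. The multi-replicate check (20 seeds,
100 injected + 100 no-edit + 400 intergenic loci per replicate) runs on
truth-log-derived features rather than through the full mapping stage —
the same statistical computation at a tractable size. Its neutrality
assertion uses the no-edit class against a background simulated at the
same root composition: mutation-class frequencies are
composition-sensitive, so comparing GC-rich birth loci directly with
AT-richer intergene loci would confound the GC-rich-origin effect
(stage 1) with the neutrality of the accumulation process (stage 2).
The injected class is only required to show the extension trend; its
spectrum legitimately carries the targeted T→C edit, and the idealized
simulator has enough power to see it — the same phenomenon the noisy
real data showed as a single significant transition contrast.

## Numerical choices and degenerate inputs

* Alignment tie-breaks: highest score, then smallest chromosome name,
  then leftmost interval, then plus strand.
* The glocal windowed traceback asserts that it reproduces the scan
  score; a mismatch is an internal error, not a silent degradation.
* `hky_prob_matrix()` clips tiny negative eigen-reconstruction residues
  and renormalises rows; it is tested against matrix exponentials to
  1e-9.
* Posterior rows are renormalised per column; confidence is only defined
  over base-bearing columns (gap columns are excluded from $L$ — whether
  the source analysis included them is unknowable from the text; we
  exclude and say so).
* Empty catalogues, empty segments, loci without ATG, loci whose
  ancestral ORF cannot be mapped, and absent orthologues all produce
  recorded drops or NA fields, never errors; replaying a corrupted truth
  log fails loudly.

## Known limitations

* The orthologue scan has no heuristic seeding; real whole-genome use at
  megabase scale would want a seeded pre-filter in front of the exact
  glocal stage.
* Marginal (per-node) reconstruction only; no joint reconstruction, no
  rate heterogeneity across sites, no model selection.
* The published mutation-frequency and ORF/Kozak count tables derive from
  the original genome assemblies and catalogue, which are not
  redistributable inputs; the package reproduces the published
  summary-statistic contrasts exactly and everything else on simulated
  data with known truth.
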