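---
title: "Lineage-specific regulatory evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage-specific regulatory evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilineage)
```

## The problem

Open-chromatin peaks from single-nucleus ATAC-seq are treated as putative
gene regulatory elements (GREs). The package asks, for each GRE, *when* its
DNA sequence changed on the way to modern humans: on the human branch
itself, on the hominin branch (human+chimp ancestor), or deeper — African
great ape, great ape, or the ape stem branch. Downstream, it aggregates
those per-branch substitutions into element-level divergence calls, links
divergent elements to the genes they plausibly regulate, and asks which
transcription-factor binding sites (TFBS) were gained or lost on each
branch.

## The lineage chain

All event assignment runs over an ordered path of six states: the
catarrhine ancestor (apes + Old World monkeys), the ape ancestor, the great
ape ancestor, the African great ape ancestor, the hominin ancestor, and the
human tip. Consecutive pairs define the five lineages (Ape, GreatApe,
AfricanGreatApe, Hominin, Human). The catarrhine ancestor is included even
though it is not itself a lineage of interest: without a state one node
deeper than the ape ancestor, a change on the ape stem branch cannot be
assigned. Old and New World monkey sequences exist in the analysis solely
to polarise that deepest state; a five-sequence chain (dropping the
catarrhine node) would support only four lineages.

Branch times in million years — Human 6, Hominin 2, African Great Ape 8,
Great Ape 4, Ape 13 (`default_branch_my()`) — are lower-bound divergence
estimates and are used only to normalise counts into rates per MY.

## Ancestral reconstruction

Reconstruction is marginal maximum likelihood under F81: equal
exchangeabilities, arbitrary equilibrium frequencies `pi`, transition
probability `P(j|i,t) = e^(-bt) [i=j] + (1 - e^(-bt)) pi_j` with
`b = 1/(1 - sum(pi^2))` so `t` is in expected substitutions per site.
Per-site posteriors at every internal node come from Felsenstein pruning
combined with an upward pass; identical site patterns are collapsed before
computation. Equilibrium frequencies are set empirically per GRE;
branch-length re-optimisation (`fit_f81()`, cyclic bounded univariate
ascent, convergence at a log-likelihood gain below 1e-6 or 20 cycles) is
optional and off by default because a few hundred bp of sequence carries
little length signal — the guide tree's lengths are reused instead.

Three conventions matter downstream:

* an ancestral state is called only when its posterior strictly exceeds
  0.75, otherwise `N`; ties at exactly 0.75 are `N` (conservative);
* alignment columns deleted in human are removed before anything else
  (`strip_human_gaps()`), so coordinates are human coordinates and
  human-specific deletions are out of scope;
* non-human gaps and `N`s are missing data (all-ones partials), not a fifth
  state.

## Substitution calling

A site yields a substitution record if and only if every chain state is
confidently reconstructed (no `N`) and exactly one state transition occurs
along the six states. This single rule unifies the published discard
criteria: multiple changes and reversals both produce two or more
transitions. The record carries the lineage of the transition, ancestral
and derived base, and 0-based human-genome and in-GRE coordinates.
Counts are normalised as `count / branch_MY / GRE_length_bp * 1000` — the
substitution rate per MY per kb. The weak-to-strong (GC) conversion ratio
is the fraction of records with ancestral A/T and derived G/C; an empty
record set reports a missing value, not zero, so sparse elements do not
fake perfect conservation.

## Divergence classification

Per GRE, the five lineage substitution proportions (count / GRE total) are
compared to a resampling background: 1,000 draws of 10,000 GREs, each
pooled into one background proportion per lineage. A GRE is divergent in a
lineage when all of the following hold: empirical p (`#{background >
observed}/1000`, BH-adjusted per lineage) below 0.05; fold change (observed
/ background median) above 1.5; z-scored proportion (standardised across
all GREs with substitutions) above 1; and at least 2 substitutions in that
lineage. Conserved GREs lie strictly below the per-lineage median
normalised rate in *all five* lineages and are not divergent anywhere. The
conservation score is `1 / mean(fold change)` per GRE.

Two properties of this procedure are worth knowing. First, the pooled
background proportions are extremely concentrated (they average ~10,000
GREs), so the empirical p is nearly binary and the operative filters are
the fold-change, z and minimum-count cutoffs. Second, at realistic per-GRE
counts (a ~1 kb element accumulates roughly 33 substitutions across the
33 MY of the chain at ~0.001 substitutions/site/MY), Poisson noise alone
pushes roughly 5–7% of null GREs past those cutoffs in the longer-branch
lineages, and more in the short-branch lineages (Hominin, Great Ape) where
expected counts are 2–4. Users should read per-lineage divergent sets as
enriched, not pure, and lean on the downstream permutation tests (RDGs)
which are calibrated against this noise.

## GRE–gene linkage and RDGs

Accessibility–expression Pearson correlations are computed for every
GRE–gene pair within 500 kb of the gene body across pseudobulk units. Each
correlation is standardised against a matched background: the correlations
of 200 background GREs — nearest neighbours of the focal GRE in
standardised (mean accessibility, GC) space — with the same gene; a
two-sided normal p on the resulting z is BH-adjusted, and links need
FDR < 0.05 *and* correlation above 0.01 (negative links never qualify).
Regulation-divergent genes (RDGs) are genes whose significant links hit a
lineage's divergent GREs more often than in 1,000 same-size random GRE
draws from the full universe (empirical p with ties counting against
significance, BH over genes), additionally requiring at least 2 divergent
and 5 total links. The overlap of RDGs with an external gene list (e.g.
human-specific differentially expressed genes) is tested by the same
permutation logic over genes.

## TFBS gains and losses

Motifs are scanned as log-odds PWMs (pseudocount 0.8 per column before
log-odds) on both strands at every offset of each chain-node sequence;
windows containing `N` never match. The match threshold is computed
exactly: the integer-scaled null score distribution under the background
model is built by dynamic programming and the threshold is the smallest
achievable score with exceedance probability at most 5e-5. Presence is
element-level (any match anywhere). Per (GRE, motif), the six presence
bits are reduced exactly like substitutions: a single 0→1 transition is a
gain, a single 1→0 a loss, anything else no event. Expansion/depletion of
a motif in a lineage requires both a deviation from the global gain/loss
split (1-df goodness of fit) and from the same motif's other lineages
(2×2 chi-square, 0.5 continuity on zero cells), each at BH FDR < 0.01, in
the same direction; motifs with fewer than 5 events, or whose TF is
detected in under 25% of cells in every cell type, are not tested.
Family-level events are unions over member motifs, deduplicated per GRE,
lineage and direction.

## The synthetic-data generator

Every pipeline input can be generated with planted ground truth
(`simulate_study()`), so all stages are testable without external data.
Defaults were fixed once as study-like conditions:

| parameter | default | why |
|---|---|---|
| background rate | 0.001 subs/site/MY | catarrhine phylogenetic rate (~1e-9/site/yr) |
| GRE length | 600–1400 bp | typical snATAC peak widths |
| equilibrium frequencies | uniform 0.25 | matches the inference model, so reconstruction error is attributable to data, not model mismatch |
| tree | 5 apes, 2+ OWM, 2+ NWM | minimal topology that polarises the catarrhine ancestor |
| pseudobulk units | 200 | enough for stable Pearson correlations |

Sequences evolve gapless root-to-tips under F81 (optional gap injection
into non-human tips exercises the missing-data path). Planted
substitutions overwrite the whole alignment column (ancestral base
everywhere, derived base in the named branch's clade), which makes them
homoplasy-free by construction; planted motif gains embed the consensus in
the gaining clade and a verified non-matching shuffle elsewhere (losses
inverted). Planted GRE–gene links share a latent Gaussian factor tuned to
the target correlation. A faster rate-table-level generator
(`simulate_substitution_counts()`) draws Poisson counts directly under the
same planted-divergence spec; it is used for classifier-scale experiments
(thousands of GREs) where per-site simulation adds only runtime.

What the generator does *not* emulate: indels and alignment error, CpG
hypermutability and rate heterogeneity along the sequence, GC-biased gene
conversion, count overdispersion and sparsity of real pseudobulk matrices,
batch effects, and correlated motif content. Passing tests therefore
demonstrate the pipeline's correctness and calibration under its own model
assumptions, not robustness to real-data pathologies.

## Numerical choices and degenerate inputs

* Stage-specific RNG streams are derived from one run seed by stage name,
  so stages rerun independently and every output is byte-reproducible.
* Empirical p-values use the literal `k/n` convention (zeros allowed),
  matching the resampling design; permutation ties count against
  significance.
* BH is the multiple-testing adjustment wherever FDR appears.
* Zero-variance accessibility or expression rows are skipped (with a
  message), not scored zero. Fisher odds ratios use 0.5 continuity only
  for display when a table cell is zero. Perfect separation in the
  logistic enrichment is flagged and left unlabelled.
* GREs whose human record is entirely gaps are skipped and counted.
* Motif thresholds are integer-scaled at 1000 units per log2-odds; a
  match p below the probability of the best achievable window yields an
  infinite threshold (the motif can never match), which is reported rather
  than silently clamped.

## Test problem sizes

The end-to-end recovery experiment runs 1,000 GREs of 500 bp with 250
planted substitutions; divergence recovery plants 100 five-fold
human-divergent GREs among 5,000 (three seeds); linkage plants 20 links at
correlation targets 0.6–0.8 across 200 pseudobulk units; TFBS recovery
plants 40 gain/loss events over four motifs. These sizes give the planted
effects unambiguous signal while keeping a full suite run inside a few
minutes on one CPU.

## Known limitations

* **Spurious ape-stem calls from outgroup conspiracies.** When parallel
  background changes in the monkey taxa make all (or most) outgroup tips
  agree on a non-ancestral base, marginal ML prefers the single-change
  explanation — a substitution on the ape stem branch — over the true
  multi-change monkey-side history. On simulated data this affects roughly
  2 in 10,000 sites; the affected calls are genuine background
  substitutions, just attributed one node too deep. Real analyses inherit
  the same bias.
* **Divergence false-positive rate at realistic counts.** As described
  above, the three-cutoff classification passes ~5–7% of null GREs per
  long-branch lineage at ~33 substitutions per element; short-branch
  lineages are noisier. The classifier reproduces the published rules
  exactly rather than recalibrating them.
* The linkage null assumes approximate normality of the matched background
  correlations; with fewer than ~50 pseudobulk units the normal p is
  optimistic.
* The five-sequence (no catarrhine) sensitivity mode is intentionally not
  offered as a flag; restricting the chain removes the Ape lineage
  entirely, which changes every downstream table shape. Users wanting it
  can simply drop `Catarrhine` rows before `call_substitutions()`, which
  reduces the caller to the four shallower lineages.
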