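# epilineage

Lineage-specific substitution and regulatory evolution analysis for
open-chromatin elements.

## What this package is for

Single-nucleus ATAC-seq gives catalogues of gene regulatory elements
(GREs) in human tissue; comparative genomics gives multi-species
alignments over them. `epilineage` connects the two: for every GRE it
reconstructs the ancestral sequences along the catarrhine-to-human node
path and assigns each single-event DNA substitution to one of five
lineages — Human, Hominin, African Great Ape, Great Ape, Ape. On top of
the per-site calls it provides the element- and gene-level machinery of a
regulatory-evolution study:

* **Ancestral reconstruction** (`reconstruct_gres()`): marginal maximum
  likelihood under F81 via Felsenstein pruning, with empirical base
  frequencies, optional per-element branch-length optimisation, and a
  strict posterior > 0.75 confidence rule (`N` otherwise).
* **Substitution calling** (`call_substitutions()`): a site is retained
  iff all six chain states are confident and exactly one transition
  occurs along the chain; counts are normalised to substitutions per MY
  per kb using branch times (Human 6, Hominin 2, A.G. Ape 8, G. Ape 4,
  Ape 13 MY); weak-to-strong conversion ratios via
  `gc_conversion_ratio()`.
* **Divergence classification** (`classify_divergent()`,
  `classify_conserved()`): the three-cutoff resampling test (empirical
  FDR < 0.05, fold change > 1.5 against 1,000 draws of 10,000 GREs,
  z > 1, at least 2 substitutions) plus the below-median-in-all-lineages
  conserved set and `conservation_score()` (1 / mean fold change).
* **Enrichment statistics** (`marker_substitution_deviation()`,
  `fisher_marker_enrichment()`, `logistic_enrichment()`,
  `interval_overlap()`): cell-type deviation chi-squares,
  marker-by-class Fisher tests, length-adjusted logistic (Wald) tests,
  and BED-style interval overlap.
* **GRE–gene linkage and RDGs** (`link_gres_to_genes()`,
  `identify_rdgs()`, `hsdeg_overlap_test()`): accessibility–expression
  correlations against a matched background null, and the
  regulation-divergent-gene permutation test (>= 2 divergent and >= 5
  total links, FDR < 0.05 over 1,000 permutations).
* **TFBS evolution** (`build_pwm()`, `scan_motifs()`,
  `call_tfbs_events()`, `gain_loss_ratios()`,
  `test_expansion_depletion()`, `tfbs_celltype_enrichment()`): exact-DP
  PWM match thresholds at p = 5e-5, single-transition gain/loss calling
  along the chain, and the double chi-square expansion/depletion rule
  (both FDRs < 0.01).
* **LDSC annotation prep** (`ldsc_annotation_prep()`): ±25 kb flank
  expansion of top-ranked GREs and the −100..+100 kb / 5 kb sliding
  50 kb windows (41 BED files).
* **A synthetic-data generator** (`sim_config()`, `simulate_study()`)
  that produces every input with planted ground truth — substitutions on
  known branches, rate-multiplied divergent elements, GRE–gene links at
  target correlations, motif gains/losses — so the whole pipeline is
  testable offline.

The model and its conventions are described in
`vignettes/epilineage-methods.Rmd`.

## Worked example

Simulate a small study with one planted human-branch substitution, then
recover it:

```r
library(epilineage)

cfg <- sim_config(
  seed = 7, n_gres = 20, gre_length_range = c(300, 500),
  planted_events = tibble::tibble(
    gre_id = "gre_1", branch = "Human", position = 42,
    ancestral_base = "A", derived_base = "T"))
tr  <- build_guide_tree(cfg)
sim <- simulate_alignments(tr, cfg)
rec <- reconstruct_gres(sim$alignments, tr)
subs <- call_substitutions(rec, sim$bed)
dplyr::filter(subs, gre_id == "gre_1", offset == 42)
#> # A tibble: 1 × 7
#>   lineage chrom position gre_id offset ancestral_base derived_base
#>   <chr>   <chr>    <int> <chr>   <int> <chr>          <chr>
#> 1 Human   chrS1       42 gre_1      42 A              T
```

The planted A→T at offset 42 comes back on the Human lineage with the
right bases; `position` is the 0-based coordinate on the pseudo-chromosome
(`gre_1` starts at 0). The remaining rows of `subs` are background
substitutions the simulator evolved along the tree. Rates and
classification then chain in the usual tidyverse style:

```r
rates <- substitution_rate_table(subs, sim$bed)
null  <- build_resampling_null(rates, n_draw = 20, n_iter = 1000, seed = 1)
fit   <- classify_divergent(rates, null)
as.data.frame(glance(fit))
#>   n_gres n_iter n_draw divergent_AfricanGreatApe divergent_Ape
#> 1     20   1000     20                         4             2
#>   divergent_GreatApe divergent_Hominin divergent_Human
#> 1                  2                 2               2
```

At this toy scale the resampling background is drawn from only 20 GREs,
so a few background elements clear the fold-change and z cutoffs by
chance — a useful reminder that the classifier is meant for thousands of
elements (see the calibration notes in the vignette). `tidy(fit)` returns
the per-GRE, per-lineage table; `autoplot(fit)` plots proportion against
fold change.

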