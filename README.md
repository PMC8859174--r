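# clonotrack

Longitudinal analysis of TCRβ clonal repertoires from sorted T-cell
subsets, with generation- and selection-probability modelling.

## The problem

After immunoablative therapy (for example autologous haematopoietic stem
cell transplantation in multiple sclerosis), the T-cell compartment is
rebuilt from a mixture of surviving clones and new thymic output. Tracking
that process from TCRβ repertoire sequencing of sorted naïve (CD45RA+) and
memory (CD45RO+) CD4+/CD8+ subsets raises a connected set of computational
questions that this package answers in one place:

- **UMI-based quantification** — from structured reads
  (adapter + 10 bp UMI + spacer + CDR3 insert) to clonotype tables with
  molecule-level abundances, via error-tolerant directional UMI collapsing.
- **Clonotype tracking** — persistence of the dominant ("top 100 by read
  size") clones across timepoints, and the split of each follow-up
  repertoire into persistent versus new mass.
- **Diversity kinetics** — Shannon entropy `H = −Σ p log p` per sample and
  its least-squares trend over months.
- **Public clonotypes** — amino-acid clonotypes (V gene, J gene, CDR3)
  detected with ≥ 2 reads in ≥ 2 subjects, their sharing structure,
  convergent-recombination counts (distinct nucleotide encodings per
  clonotype), and HLA-stratified views (e.g. DRB1\*15:01 carriers).
- **Antigen annotation** — exact V/J/CDR3 matching against a VDJdb-style
  specificity table, restricted to the subject's HLA haplotype.
- **CDR3 motif enrichment** — interior k-mers (k = 3..7, minimum CDR3
  length 7) tested sample-vs-reference with a one-sided Fisher exact test
  (retention at p < 10⁻³) and a Bonferroni-corrected binomial V-bias score.
- **Generation and selection probabilities** — an explicit V(D)J
  recombination model gives `P_GEN`, the probability that a CDR3 is
  produced by recombination (computed exactly by dynamic programming at the
  nucleotide level and by codon-level marginalization at the amino-acid
  level). A log-linear selection model over CDR3 length, anchored
  amino-acid positions and V/J usage maps it to
  `P_POST = Q · P_GEN`, the probability of reaching the periphery after
  thymic selection. Clones are binned by `r = P_POST/P_GEN`
  (`r ≥ 0.1` not rare; `10⁻⁴ ≤ r < 0.1` intermediate; `r < 10⁻⁴` rare) and
  rare-bin clones — easily generated yet unlikely to survive selection —
  are flagged as putative escapees of negative selection, with
  `log10(P_POST) < −10` reported alongside.
- **Cohort statistics** — exact Wilcoxon matched-pairs signed-rank test
  (valid with ties) and Bonferroni correction.

Everything is driven by a synthetic cohort generator with complete ground
truth (clone frequencies, survival indicators, public-clone registry with
nucleotide encodings, per-clone generation probabilities), so every stage
of the pipeline is verifiable without any external data.

## Worked example

```r
library(clonotrack)

cfg <- simulation_config(n_subjects = 6, subsets = c("CD4_RO", "CD4_RA"),
                         clones_per_sample = 200, umis_per_sample = 2000,
                         n_public = 10, seed = 42)
sim <- simulate_cohort(cfg)
sim$cohort
#> TCR repertoire cohort
#>   subjects:   6
#>   samples:    60
#>   records:    12091  (nucleotide clonotypes)
#>   timepoints: 0, 6, 12, 24, 36 months
#>   subsets:    CD4_RA, CD4_RO

kin <- persistence_kinetics(sim$cohort, "CD4_RO")
aggregate(persistence ~ timepoint_months, kin, mean)
#>   timepoint_months persistence
#> 1                6   0.6216667
#> 2               12   0.3716667
#> 3               24   0.2550000
#> 4               36   0.1850000
```

The mean persistence of the baseline top-100 memory clones decays roughly
as `s^k` with the configured per-interval survival `s = 0.66` — by 36
months only ~19% of the dominant pre-treatment clones are still detected.
Memory diversity declines in parallel:

```r
mem <- subset(cohort_entropy(sim$cohort), cell_subset == "CD4_RO")
unlist(entropy_trend(data.frame(timepoint_months = mem$timepoint_months,
                                entropy = mem$entropy)))
#>         slope     intercept        adj_r2       p_value             n
#> -4.867659e-02  4.121449e+00  9.465740e-01  1.446715e-19  3.000000e+01
```

Public clonotypes and probability annotation:

```r
pub <- identify_public(sim$cohort, "CD4_RO", 0)   # >=2 reads in >=2 subjects
nrow(pub)
#> [1] 18
head(pub, 3)
#>   v_call  j_call  junction_aa n_subjects             subjects
#> 1  TRBV7 TRBJ1-2   CASRDRGYTF          3 HSCT01,HSCT05,HSCT06
#> 2  TRBV7 TRBJ2-2 CASSDRGPGELF          3 HSCT02,HSCT04,HSCT06
#> 3  TRBV7 TRBJ1-1 CASSEDRDTEAF          3 HSCT02,HSCT04,HSCT05

gen <- default_vdj_model()
sel <- selection_model(c("l:5:V" = -10))  # a planted depletion for illustration
ann <- ppost_annotate(sel, gen, head(aggregate_to_aa(
  get_sample(sim$cohort, "HSCT01", 0, "CD4_RO")), 5))
ann[c("v_gene", "cdr3_aa", "pgen", "ppost", "q_ratio", "bin")]
#>   v_gene        cdr3_aa         pgen        ppost      q_ratio      bin
#> 1  TRBV9  CASSVGQGAGYTF 2.402168e-05 1.090583e-09 4.539993e-05     rare
#> 2  TRBV2    CASRQGATQYF 1.066950e-06 1.066950e-06 1.000000e+00 not_rare
#> 3 TRBV19 CASSIIRRGRTQYF 6.605066e-10 6.605066e-10 1.000000e+00 not_rare
#> 4 TRBV20   CSARGTSNTEAF 3.737359e-06 3.737359e-06 1.000000e+00 not_rare
#> 5 TRBV19   CASSITGITQYF 4.480361e-08 4.480361e-08 1.000000e+00 not_rare
```

The first clone carries the penalized feature (V at the fifth CDR3
position), so its selection factor is `e^{-10}`, its `P_POST/P_GEN` ratio
falls below 10⁻⁴, and it lands in the rare bin — the escapee candidate
population.

A complete multi-stage analysis (simulation, tracking, diversity, public
clones, annotation, motifs, selection) can also be driven from a YAML
configuration with `run_pipeline()`; each run writes tidy TSV/JSON outputs
plus `run_info.json` with the seed and config hash, and is byte-identical
across repeat runs with the same seed.

Fitting a selection model from data uses the classic modelling interface:
`fit_selection()` returns a classed object with `print()`, `summary()`,
`coef()` and `predict()` methods.

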