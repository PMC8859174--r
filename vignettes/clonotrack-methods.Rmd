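---
title: "Models and methods behind clonotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrack)
```

clonotrack analyses longitudinal TCRβ repertoires from sorted T-cell
subsets: clonotype tracking, diversity, public-clone and motif analysis,
and probabilistic modelling of receptor generation and thymic selection.
This vignette explains the models, the assumptions behind them, the
parameters that matter, and the choices made where the design was open.

## Clonotypes and the interchange format

The unit of tracking is the amino-acid clonotype key: the triple
(V gene, J gene, CDR3 amino-acid sequence), where the CDR3/junction spans
the conserved cysteine through the conserved phenylalanine. One key may be
carried by several nucleotide sequences — convergent recombination — so
tables store one row per nucleotide variant and `aggregate_to_aa()`
collapses them, counting the distinct encodings. Tables use AIRR
Rearrangement column names (`v_call`, `j_call`, `junction`, `junction_aa`,
`duplicate_count`) extended with `subject_id`, `timepoint_months`,
`cell_subset` and `umi_count`; construction validates that every junction
translates to its `junction_aa` and aggregates duplicate rows, which makes
the write/read round trip an exact identity.

Clone abundance defaults to the UMI count when UMIs are present and the
read count otherwise: UMIs count molecules rather than PCR-amplified
reads, so they are the less biased size measure wherever available. Both
weightings are exposed (`weight = "reads"` / `"umis"`) because which one a
given study used for "read size" ranking is often unstated.

## The generative V(D)J model and P\_GEN

`vdj_model()` describes a simplified recombination process: a V 3′-flank
(starting at the conserved-C codon) truncated by 0..maxDel exonuclease
deletions, non-templated VD insertions with i.i.d. nucleotides, a D
segment truncated from both ends, DJ insertions, and a truncated J
5′-flank ending at the conserved-F codon. Three simplifications relative
to full published recombination models are deliberate:

- D usage is independent of J (full models condition P(D | J));
- there are no palindromic (negative) deletions;
- insertion nucleotides are i.i.d. rather than a Markov chain.

These keep the scenario space of a small model exactly enumerable, so
every probability the package computes can be checked against brute
force, while preserving the phenomenon that matters downstream: some
amino-acid CDR3s are realizable by many scenarios and codings (high
generation probability, hence frequently shared between individuals).
Model validation additionally requires max(del5) + max(del3) ≤ |D| so
every deletion combination is a valid scenario and the total scenario
probability is exactly 1 — the anchor for the conservation tests.

`pgen_nt()` sums the probability of every scenario realizing a nucleotide
string, organised as a dynamic program over (V-prefix match length) ×
(J-suffix match length) × (D placement in the remaining middle), never by
enumeration; `enumerate_scenarios()` is the independent brute-force oracle
and agrees to < 10⁻¹². `pgen_aa()` marginalizes all synonymous codings by
codon-level dynamic programming: for each scenario shape, each codon
contributes a weight summing insertion-nucleotide probabilities over the
codings compatible with its fixed (segment-derived) bases, so the sum over
up to 6^L explicit codings is never formed. Both kernels are implemented
in C++ (as is usual for recombination-probability software) and admit a
variant restricted to a fixed (V, J) attribution, used when annotating
clonotype keys; the restricted values over all (V, J) pairs partition the
marginal.

Two models ship with the package. `toy_vdj_model()` (6 V / 2 D / 4 J,
deletions and insertions ≤ 1; 19 200 scenarios, 4 307 realizable strings)
exists for exact verification. `default_vdj_model()` (8 V / 2 D / 8 J,
15 nt flanks, deletions to 4–6, insertions to 8, G/C-biased insertion
nucleotides as expected from TdT) produces CDR3s of realistic length
(mostly 11–15 amino acids, conserved C...F frame, ~27% of raw
rearrangements productive) and is the cohort-scale default. Segment
sequences are hand-set plausible flanks, not copies of reference alleles;
inference of model parameters from data is out of scope — the model is an
input.

**V/J attribution.** A sequencing pipeline assigns V and J by sequence
match, not by knowledge of the latent recombination event; when deletions
erase the distinguishing bases the attribution can legitimately differ
from the generating segment. The simulator therefore labels every emitted
clonotype with the same flank-matching attribution the CDR3 caller uses
(longest prefix/suffix match, ≥ 6 nt, ≤ 1 mismatch, ties to the first
segment), which makes simulation and calling exactly consistent.

## The selection model and P\_POST

Selection is modelled log-linearly over interpretable features of the
key: one CDR3-length indicator, one V and one J indicator, and one
(amino acid, position) indicator per residue anchored from the left and
from the right (truncated at 12 positions from each end to bound the
feature space). A key's selection factor is
`Q = exp(Σ λ_f − logZ)` and `P_POST = Q · P_GEN`; with all λ = 0 and
logZ = 0 selection is the identity.

`fit_selection()` maximizes the mean observed log selection factor under
the constraint that Q averages to 1 over a baseline sample generated from
the recombination model, equivalently the concave penalized objective

```
mean_obs(λ·f) − log mean_base exp(λ·f) − l2·‖λ‖².
```

Ascent uses BFGS with the analytic gradient and stops when the gradient
max-norm is below 10⁻⁴ (restarting up to 10⁴ iterations; non-convergence
warns with the final norm). The fitted `logZ` additionally absorbs the
baseline's productive fraction, so that P\_POST integrates to 1 over the
space of generatable *keys* (in-frame, stop-free sequences) rather than
over all nucleotide strings. For enumerable models,
`renormalize_selection()` replaces the Monte-Carlo `logZ` with its exact
enumerated value; this is what makes the "ΣP\_POST = 1 ± 10⁻⁶" check
meaningful, since a sampled normalizer carries O(n^−1/2) error by nature.

The default penalty `l2 = 0.02` is a variance-based choice: with ~500
features and 10⁴ observed sequences, the sampling noise of a feature with
frequency p perturbs its weight by ≈ √(p/n)/(p(1−p)+2·l2), which is
maximized near p ≈ 0.04 and bounded around 0.07 at this penalty — small
enough that a no-selection repertoire fits to approximately zero weights,
while planted weights of magnitude 0.4–1 on features of 5–45% frequency
are still recovered with correlation above 0.9. The feature basis is
overcomplete (a residue is seen by both its left- and right-anchored
feature, and V/J/length indicators each sum to one), so fitted weights are
the minimum-norm representative of the selection pressure; comparisons to
planted values are made on the planted coordinates.

**Ratio bins and escapees.** Each annotated clone is binned by
`r = P_POST/P_GEN`: `r ≥ 0.1` not rare, `10⁻⁴ ≤ r < 0.1` intermediate,
`r < 10⁻⁴` rare to survive thymic negative selection. The "1:x" ratio
notation is read with x = P\_POST/P\_GEN — the orientation in which a
printed range from 1.38 down to 7.4×10⁻⁷ spans mild enrichment to strong
depletion and small x means rare survival. Bins are half-open with the
boundary belonging to the upper class. `flag_escapees()` returns the rare
bin; whether `log10(P_POST) < −10` — observed to accompany the rare bin in
practice — is *reported* as a separate column rather than conjoined into
the definition, since the two criteria are logically independent.
Ungeneratable keys (P\_GEN = 0) are annotated with both probabilities 0,
assigned to `not_rare` (no evidence of depletion), and flagged
`ungeneratable`.

## UMI clonotyping

Reads follow a template-switch design: constant adapter, 10 bp UMI,
7 nt spacer, then the insert (the CDR3 from the conserved-C codon to the
conserved-F codon). `extract_umi()` tolerates one mismatch in adapter and
spacer and classifies failures (`no_adapter`, `no_spacer`, `too_short`)
as data rather than errors. `call_cdr3()` attributes V and J by the
flank-matching rule above and rejects off-frame or stop-containing
inserts (`frame`). Quality scores are ignored throughout: the synthetic
error model is positional substitution only.

UMI collapsing is directional: UMI b merges into a when their Hamming
distance is ≤ 1 and `count(a) ≥ 2·count(b) − 1`, iterated to a fixpoint
processing groups in descending read count with lexicographic
tie-breaks — a deterministic, order-independent variant of the standard
adjacency rule built for the "errors are rare copies of an abundant
parent" regime.

Two physical limits of 10 bp UMIs are worth stating because the synthetic
ground truth makes them visible. First, tags collide: with m molecules in
a clone, ≈ C(m,2)/4¹⁰ molecule pairs draw the same tag, so the *distinct
tag count* — which `simulate_reads()` reports as the `umi_truth`
attribute — is the quantity a pipeline can recover, and it falls below the
molecule count for clones with thousands of molecules. Second, a read with
two errors inside the UMI lands at Hamming distance 2 from its parent and
cannot be merged under the ≤ 1 rule (≈ 4.5 per 10⁵ reads at 0.1%/base).
Fidelity checks therefore run on samples whose per-clone molecule counts
stay in the regime the method is designed for (up to a few hundred
molecules per clone); at that scale the pipeline reproduces the distinct
tag counts exactly at zero error and for ≥ 99% of clones at 0.1% per-base
error.

## The synthetic cohort generator

`simulation_config()` encodes the emulated study design, and its defaults
are the package's reference conditions:

- 13 subjects, timepoints 0/6/12/24/36 months, four sorted subsets
  (CD4/CD8 × RA/RO), 300 clones and 3 000 molecules per sample (a
  desk-scale stand-in for ~10⁵ cells sequenced to ~0.5M reads), mean 3
  reads per molecule.
- Memory clone sizes are Zipf with exponent α = 1 at baseline, increasing
  by 0.2 per interval (`alpha_step`): post-ablation repertoires grow more
  clonal over time, which is what drives the declining memory entropy.
  Naïve subsets use a near-flat α = 0.3 and no skew increase.
- Survival per interval: dominant memory clones 0.66 (chosen so that
  four-interval persistence lands near the ~19% reported for dominant
  CD4 memory clones at 36 months; the 6-month value then overestimates
  the reported 40.8% because real attrition is front-loaded — a
  single-rate model cannot capture both, and matching the endpoint was
  preferred), background memory clones 0.5, naïve clones 0.2 (naïve
  repertoires show little replicate-to-replicate overlap, so their
  persistence is dominated by sampling turnover).
- **Dominance is defined on the emitted baseline counts**, using exactly
  the ranking and tie-break of `top_n_clones()`. The alternative —
  defining dominance on latent true frequencies — would contaminate the
  measured top-100 with background clones wherever the Zipf tail is flat,
  and the persistence estimator would no longer be the clean binomial the
  recovery checks rely on. Observed dominance is also what the tracked
  statistic means in real data.
- **Public clonotypes are drawn from convergent recombination**: the
  generator samples a large rearrangement pool and selects injected
  public keys among amino-acid keys that occurred at least twice in
  independent draws (weighted by recurrence). Publicity thereby correlates
  with generation probability mechanically — the same mechanism proposed
  for real public clones — and the "public clones have higher mean
  P\_GEN than private clones" pattern is a consequence, not an assertion.
  Each public clone receives 1–5 distinct nucleotide encodings
  (default distribution 0.75/0.15/0.05/0.03/0.02, putting roughly a
  quarter of public clones on ≥ 2 encodings), drawn from the pool's real
  variants first and synonymous recodings (with unchanged V/J attribution)
  after.
- Injected publics get at least 2 molecules per designated subject, so a
  clone injected as public satisfies the ≥ 2 reads detection rule it is
  meant to be found by; every present clone gets ≥ 1 molecule so that
  survival, not resampling noise, determines detection.
- Roughly 40% of subjects carry the MS-risk allele DRB1\*15:01
  (`risk_allele_carriers`, default ⌈0.4·n⌉), enabling the HLA-stratified
  public-clone analyses; the remaining subjects receive other class II
  alleles, and everyone gets two plausible class I alleles.

What the generator does **not** emulate: front-loaded attrition kinetics
(survival is a single per-interval rate), antigen-driven clonal expansion
dynamics, shared clones between subsets of one subject, PCR chimeras and
index hopping, quality-score structure, and paired-end read layout.
Passing tests therefore demonstrate that the estimators recover the
parameters of this generative process, not that real repertoires satisfy
its assumptions.

## Tracking, diversity, public clones, annotation, motifs

**Tracking.** `top_n_clones()` ranks by UMI-weighted abundance with the
deterministic tie-break (abundance, CDR3, V, J). "Still detected" at
follow-up means abundance ≥ 1 by default (`min_count` exposed, since no
detection threshold is standard); per-subject persistence fractions are
averaged for cohort summaries. When a repertoire holds fewer than n
clones, all are used and the denominator reported.

**Diversity.** Shannon entropy uses the natural log by default with
base-2 and normalized (H/log K) variants exposed; it is computed on
UMI-weighted amino-acid frequencies for consistency with tracking.
`entropy_trend()` is ordinary least squares of entropy on months (slope,
adjusted R², two-sided slope p) via `lm()`.

**Public clones.** The detection rule — at least two reads, in two or
more individuals — is applied per subject (each detection must reach two
reads), the stricter of the two possible readings; the pooled
`threshold = "total"` mode implements the other. Detection defaults to a
single timepoint, with pooling across timepoints available, because
baseline and follow-up sharing are analysed separately. `identify_public`
is verified against a brute-force double loop on random cohorts.

**Annotation** requires an exact (V, J, CDR3) match and an HLA restriction
carried by the subject; alleles match by field prefix across typing
resolutions (class I typing is often low-resolution). No fuzzy CDR3
matching is offered. Per-species fractions assign each clonotype to the
majority species among its matches (ties alphabetically) so fractions sum
to ≤ 1. The shipped `inst/extdata/synthetic_antigen_db.tsv` is a
synthetic table in VDJdb column layout for format tests and examples; it
is not derived from any real specificity database.

**Motifs.** Interior k-mers (k = 3..7) after trimming 3 residues from the
left and 2 from the right of CDR3s of length ≥ 7, each distinct k-mer
counted once per clonotype. Enrichment is a one-sided Fisher exact test
(hypergeometric tail via `phyper`, verified against an explicit tail sum),
retained at p < 10⁻³ — one-sided because the question is
over-representation in the sample. The V-bias score is the
Bonferroni-corrected binomial tail of the most over-represented V gene
against reference usage (flag at 0.05): deterministic and oracle-checkable
where the original tool simulates. The pooled-baseline reference mode
(all subjects' baseline clonotypes as the reference for post-treatment
samples) is how `run_pipeline()` wires the stage. Because the retention
test is discrete and conservative, null calibration is asserted as the
retained-motif count falling inside the 95% Poisson band of α × (motifs
tested), with the sample sized so the band includes small counts.

**Statistics.** `wilcoxon_paired()` drops zero differences (reporting the
count), uses average ranks for ties, and computes the exact two-sided
null distribution by convolution over sign assignments for n ≤ 15 —
unlike textbook tables, this remains exact under ties — switching to the
normal approximation with continuity and tie corrections above.
`bonferroni_adjust()` multiplies by the number of tests and caps at 1.

## Numerical conventions

- Deterministic orderings everywhere a ranking or set is emitted
  (abundance desc, then CDR3/V/J lexicographic), so repeated runs are
  byte-identical.
- Bin boundaries half-open with the boundary in the upper class;
  equality comparisons on ratios are therefore exact at 0.1 and 10⁻⁴.
- Probability-vector validation at 10⁻¹²; frequency sums at 10⁻¹²;
  enumeration-vs-DP agreement at 10⁻¹²; total-probability conservation at
  10⁻⁹ (accumulated float error over ~10⁴ summands); exact P\_POST
  normalization at 10⁻⁶.
- Seeds control every stochastic step; `run_pipeline()` stamps outputs
  with the seed and the config file's MD5 hash.

## Problem sizes in the shipped checks

The test suite exercises the oracles at full exactness on the toy model
(all 4 307 sequences), selection fitting at 2×10⁴ observed / 1.2×10⁵
baseline sequences for planted recovery and 10⁴/10⁵ for the null, cohort
recovery on 20 subjects × 250 clones, the UMI pipeline at ~10⁵ reads over
2 000 clones, and motif power over 50 replicates of 200 sample / 2 000
reference clonotypes — sizes at which the binomial and Monte-Carlo error
bars quoted above are decisive. `scripts/acceptance.R` re-runs the same
computations from scratch under a caller-supplied seed.

## Known limitations

- The recombination model is intentionally reduced; its probabilities are
  internally exact but not comparable to values from full published
  models conditioned on real gene references.
- The selection model is identifiable only up to the gauge of its
  overcomplete basis; weights should be compared as patterns (or through
  Q) rather than coordinate-by-coordinate against other tools.
- UMI quantification inherits the physical limits of short tags described
  above; molecule counts for very large clones are lower bounds.
- The exact Wilcoxon path is quadratic in the rank sum and capped at
  n = 15 by default; beyond that the corrected normal approximation is
  used, as is standard.
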