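---
title: "Methods: detecting clonal selection in paired tumor RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting clonal selection in paired tumor RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonsel)
```

# The model

`clonsel` compares one drug-sensitive tumor sample with its
treatment-derived resistant counterpart. The observable at each variant
site is the alternative allele ratio (AAR), `alt / (ref + alt)`. Under a
simple clonal mixture, a variant carried on `m` of a region's `k` parental
alleles by a clone at cell fraction `f` has expected AAR `f · m/k`.
Treatment changes `f` for selected subclones and leaves it unchanged for
the ancestral clone, so selection is detectable as an AAR shift between
the paired samples.

The pipeline has four statistical components, each deliberately simple and
auditable:

1. a **Fisher exact test** on the per-variant 2×2 table
   `[[ref_s, alt_s], [ref_r, alt_r]]`, two-sided;
2. an **annotation decision tree** that restricts testing to credible
   somatic, protein-altering variants;
3. a **mirrored binomial likelihood** over candidate allelic
   configurations for regional ploidy / allelic imbalance;
4. an **exact conditional binomial test** for differential expression
   between two libraries without replicates.

## Assumptions

* Allele counts are pre-filtered upstream to bases with phred ≥ 20 and
  reads with alignment score ≥ 20, with PCR duplicates removed; `clonsel`
  consumes counts, it does not touch alignments.
* Expression-derived allele ratios are unbiased for the underlying allelic
  copy ratio. This ignores allele-specific expression and mapping bias,
  which in real data add dispersion (see *Limitations*).
* Sites are independent given the clonal structure.

# Classification rules and their thresholds

All cutoffs live in one validated object, `clonsel_thresholds()`:

| parameter | default | role |
|---|---|---|
| `depth_min_strict` | 10 | testing requires strictly more than this many reads in *both* samples |
| `ceu_af_max` | 0.05 | population-frequency ceiling for the COSMIC branch |
| `fisher_alpha` | 1e-3 | per-variant significance level (a fixed alpha, not an FDR) |
| `delta_aar_min` | 0.1 | minimum AAR shift for a selection call |
| `ancestral_aar_min` | 0.30 | both AARs must exceed this for an ancestral assignment |
| `fc_min`, `adj_p_max` | 2.5, 0.01 | DE gates (fold change, BH-adjusted p) |
| `het_min_depth`, `het_aar_window` | 20, (0.10, 0.90) | site selection for ploidy estimation |

A variant is `selected_up` (or `_down`) when the Fisher p is at most
`fisher_alpha` **and** the AAR shift is at least `delta_aar_min` in
magnitude: significance alone would flag biologically negligible shifts at
high depth, and effect size alone would flag noise at low depth. Variants
failing the selection call with AAR above `ancestral_aar_min` in both
samples are assigned to the ancestral clone; the remainder —
low-abundance, underpowered, or noise — stay `unclassified`. The ancestral
rule is applied only after the selection call fails, so the categories are
mutually exclusive and exhaustive.

Three points in the decision tree were genuinely open and are this
package's documented choices:

* **Genotype scope.** Requiring a non-reference genotype in *both* samples
  would exclude every de-novo-appearing variant (sensitive AF 0), which
  are exactly the interesting ones; the filter therefore requires
  non-homozygous-reference in *at least one* sample. The genotype
  estimator itself (`alt ≥ 2` and AAR ≥ 0.05) is a definition, chosen so a
  single sequencing-error read never creates a genotype.
* **Predictor gates.** "Deleterious" is taken literally: PolyPhen-2
  "possibly_damaging" does not qualify. Novel variants need one
  deleterious call, dbSNP-known variants need both — known polymorphisms
  carry a higher germline prior and face a stricter bar.
* **No path for CEU-present non-COSMIC variants.** Only the three evidence
  branches admit variants; a variant present in the CEU panel but absent
  from COSMIC has no branch and is excluded, whatever its frequency.

Missing data are never coerced: a sample with no record at a site is
*missing*, fails the depth rule, and is distinguished from an observed
zero throughout (an observed zero is evidence of absence; a missing record
is absence of evidence).

# The Fisher exact test

`fisher_exact_two_sided()` sums hypergeometric probabilities over all
tables with the observed margins whose probability does not exceed the
observed table's, with a relative tie tolerance of 1e-7 (the convention of
`stats::fisher.test`, which serves as an independent cross-check in the
tests — never as the implementation). Degenerate margins give p = 1. The
test suite verifies exact agreement (< 1e-9) with a `choose()`-based
enumeration oracle for **every** 2×2 table with total at most 60 — 635,376
tables.

Because the test conditions on margins and the alpha is per-variant, no
multiple-testing correction is applied to selection calls (by design: the
analysis screens a conservative, pre-filtered variant list at a strict
fixed alpha).

# Regional ploidy from heterozygous-site AARs

"Ploidy" here means the total number of parental alleles in a large
genomic region. Expression AARs identify only the *ratio* `m:(k−m)` of the
two parental copy numbers — a 2:2 region looks exactly like 1:1 — so the
reported `k` is the smallest ploidy consistent with the estimated ratio
(lowest terms). This is the only identifiable representative and is
flagged prominently: "tetra-ploidy" means "allelic ratio 3:1", not an
absolute copy-number measurement.

For each candidate coprime configuration `r = m/k`, `2 ≤ k ≤ k_max` (10 by
default), the log-likelihood is the phase-agnostic mirror mixture

```
sum_i log( 0.5 · Binom(alt_i | depth_i, r) + 0.5 · Binom(alt_i | depth_i, 1 − r) )
```

because either parental haplotype may carry the alternative allele. The
selected configuration maximizes a penalized score with two terms:

* a BIC term `0.5 · df · log(n)` where the balanced configuration (1/2)
  has `df = 0` and unbalanced candidates `df = 1` — imbalance must be
  demanded by the data;
* a description-length term `log(k) + log(n_m(k))`, where `n_m(k)` is the
  number of canonical coprime numerators for denominator `k`. Large
  denominators contribute more, and more finely spaced, candidate ratios
  (4/7, 5/8, 7/9 ...), so an unpenalized maximum likelihood is biased
  toward large `k`; the penalty is the prefix-code cost of specifying the
  configuration and removes that multiplicity bias without any fitted
  constant.

Ties (within 1e-9) go to the smaller `k`, then to the ratio closer to 1/2.
Fewer than `min_sites` usable sites (20 by default) yields an explicit
no-call rather than a weak call. Site selection requires depth ≥ 20 and
AAR strictly inside (0.10, 0.90), discarding near-homozygous sites that
carry no imbalance signal. A beta-binomial variant (`overdispersion`
parameter, 0 = binomial) is available for overdispersed data. Calls use
the conventional labels `-` (balanced, i.e. absence of allelic imbalance)
through `deca-ploidy`; segments are a fixed, configurable grid
(cytoband-scale BED), not change-point segmentation, which is out of
scope.

# Differential expression without replicates

The per-gene statistic is the exact conditional binomial test: given a
gene's total count `n = count_s + count_r`, under the null of equal
relative expression `count_s ~ Binomial(n, lib_s / (lib_s + lib_r))`;
two-sided p by the same minimum-likelihood tie rule as the Fisher test.
This is the canonical exact test for comparing two sequencing libraries
without replicates, chosen for auditability; it is a *stand-in*, not a
reconstruction of any particular published statistic, and — like every
no-replicate method — its p-values describe sampling noise only, not
biological variability. Fold changes use a 0.5 pseudocount on the
normalized scale, are reported symmetrically (`fold_change ≥ 1` with a
separate `direction`), and genes with zero counts in both samples are
excluded from testing and from the BH denominator. Library sizes default
to column sums and can be supplied externally.

# What the synthetic data emulate — and what they do not

`simulate_pair()` draws per-site depths from a negative binomial
(`mean_depth` 100, `size` 10 by default — overdispersed site coverage with
two parameters), then alternative counts binomially at the variant's true
AAR. The clonal structure is an ancestral clone (fraction 1 by default), a
resistant subclone absent before treatment and at fraction 0.7 after
(stand-in values: the study design reports no subclone fractions or
depths), and a depleted clone mirroring the expanding one. Somatic
variants are placed only on segments whose allelic configuration is shared
by the two samples, so that planted categories are consistent with planted
AARs (on a ploidy-changing segment an ancestral variant's AAR shifts with
no clonal selection — real data contain such variants; the generator's
truth labels deliberately do not conflate the two mechanisms).
Sequencing error (0.1% per base) applies at homozygous-reference sites,
exercising the ≥ 1-alt-read table-inclusion rule; 10% of neutral variants
are flagged as segmental duplications to exercise the exclusion branch.
Annotations give planted selected variants the COSMIC profile and spread
germline/noise sites over dbSNP identifiers, common CEU frequencies,
tolerated/benign predictor calls and non-coding classes.

The generator does **not** simulate spliced alignment, mapping bias,
allele-specific expression, base-quality miscalibration, or the
intermediate passages between the endpoint pair. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to alignment artifacts.

`simulate_expression()` is Poisson by default (`dispersion = 0`): two
libraries from the same RNA differing only by planted fold changes, the
regime in which the exact binomial test is calibrated. With biological
overdispersion (`dispersion > 0`) any no-replicate exact test is
anticonservative — that is a property of the design, not of the
implementation, and is why the null-calibration checks run at the default.
The default DE plan plants 15 up- and 15 down-regulated genes including
one 17-fold repression with a high planted baseline (the magnitude of the
strongest apoptosis-regulator repression the analysis is meant to
resolve). `simulate_read_pairs()` draws fragment lengths from
Normal(175, 70) — the library geometry of a typical TruSeq RNA prep — and
reads them in FR orientation at 2×101 bp; fragments shorter than one read
are rejected with a logged skip.

All generator randomness derives from one explicit seed via
`withr::with_seed`; the global RNG stream is untouched and identical seeds
give identical output.

# Read-overlap merging

Fragments shorter than twice the read length produce mates that overlap by
`2·read_length − fragment_length` bases; counting both mates there doubles
coverage. `detect_overlap()` returns the longest suffix of R1 matching a
prefix of the reverse-complemented R2 with mismatch fraction ≤
`max_mismatch_rate` (0.1) and length ≥ `min_overlap` (10); `N` never
matches and always counts as a mismatch. Merged bases take the mate with
the higher phred score, ties to R1; the merged fragment is split at
`floor(len/2)` — the split point is a choice (balanced downstream
coverage), as is the SeqPrep-like parameter pair. Non-overlapping pairs
pass through byte-identically.

`min_overlap` is an identifiability floor, not a tuning knob: on a
four-letter alphabet a chance suffix/prefix match of length `L` has
probability ≈ 4^−L, so overlaps of a few bases cannot be distinguished
from coincidence by any detector honoring the longest-match contract. The
geometry checks in the test suite therefore assert exact recovery for all
fragments whose true overlap is at least `min_overlap` (lengths 101–192 at
2×101 bp) and exact pass-through below it.

# Numerical and procedural details

* Tie handling in both exact tests uses a relative tolerance of 1e-7 when
  comparing outcome probabilities; mixture log-likelihoods use the
  log-sum-exp form; score ties in the ploidy grid use 1e-9.
* Coordinates are 1-based fully closed internally; BED input/output
  converts at the boundary.
* Degenerate inputs are defined, not errors: empty variant tables flow
  through to an all-zero report; empty regions give empty site lists;
  zero-depth sites have undefined (NA) AAR and are flagged, never treated
  as AAR 0.
* The pipeline logs `records in / passed / failed` per stage to standard
  error and asserts count conservation; reruns on identical inputs are
  byte-identical.

# Problem sizes used in the test suite

The acceptance-level checks run at: 10⁵ null sites for size calibration of
the selection caller; all 635,376 tables with total ≤ 60 for the Fisher
oracle; 20 × 1000 random p-vectors for the BH oracle; 600 planted somatic
variants (200 per category) for recovery; 100 seeded replicates of 50
sites at depth 100 for each coprime configuration with k ≤ 5; 5000 genes
with 30 planted fold changes for DE; and 184 error-free read pairs
spanning every fragment length in the identifiable overlap range. The
whole suite runs in a few minutes on one CPU.

# Limitations

* The ploidy module is a re-design built only on the definition of
  regional ploidy as a parental-allele count; exact agreement with any
  particular published segment table is not claimed, and lowest-terms
  reporting understates true copy number whenever the configuration is
  reducible.
* The DE statistic ignores biological variability (no replicates); its DE
  lists should be read as "inconsistent with sampling noise", not as
  population-level claims.
* COSMIC/dbSNP/CEU/SIFT/PolyPhen fields are consumed as given; the package
  does not compute annotations.
* Real tumor data violate the clean clonal mixture (subclonal copy number,
  allele-specific expression, purity < 1); the synthetic recovery rates
  are upper bounds on real-data performance.
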