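---
title: "Methods: primary-metastasis concordance across mutations, miRNAs and proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: primary-metastasis concordance across mutations, miRNAs and proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metconcord)
```

`metconcord` asks one question three ways: are the molecular profiles of a
primary tumour and its matched metastasis the same? It answers it at the
level of somatic mutations (presence and clonality background), miRNA
expression (qPCR relative quantification) and protein expression
(reverse-phase protein arrays), each with its own calibrated decision
rule, and ties the three together with a small shared statistical core.
This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where the method left room.

## Heterogeneity scoring of somatic mutations

A mutant allele fraction (MAF) by itself confounds biology with specimen
quality: stromal admixture dilutes tumour DNA. The heterogeneity score
removes the dilution,

$$\mathrm{HS} = \frac{\mathrm{MAF} \times 2}{\mathrm{TC}/100},$$

where TC is the tumour cellularity in percent. Under the assumption of a
diploid locus with one mutant copy, HS is approximately the fraction of
tumour cells carrying the mutation: HS near 1 means the mutation is
clonal. Scores partition into four backgrounds:

* `WT` — HS = 0 (wild type; takes precedence over the subclonal band at 0);
* `STC` — 0 < HS < 0.95 (mutation in a subpopulation of tumour cells);
* `ATC` — 0.95 ≤ HS ≤ 1.05 (all tumour cells);
* `CNV` — HS > 1.05 (copy-number-variation background).

The clonal band is closed on both sides so the three positive intervals
form a partition with no gaps; this is a deliberate reading of the
interval wording and is property-tested over a grid of the whole
(MAF, TC) domain. Scores above 2 are legal (amplification) and flagged in
reports rather than capped.

Between the members of a pair, a locus shows an **inter-status** change
when its background label differs, and an **intra-status** change when
the label is retained but |ΔHS| ≥ 0.5 — the shift expected when the
entire tumour-cell population gains or loses one mutant allele copy. The
discordant fraction (inter + intra) is tested with the one-proportion
z-test described below. The denominator defaults to loci detected in the
primary tumour; an alternative reading — all loci from pairs with known
cellularity — gives the same count on the study data, and a `union_loci`
policy is selectable.

MAF ratios (`mafr_table()`) divide each mutation's MAF by the MAF of the
sample's reference driver, cancelling cellularity entirely. The original
description of the driver choice is external to this package, so the
policy is explicit and configurable: the highest-MAF mutant gene among
the trunk drivers (APC, KRAS, NRAS, BRAF), falling back to the branch
driver TP53, and dropping (with a warning) samples with neither.

## The statistical core

**One-proportion z-test, complement null.** The study's proportion tests
never state their null value. Reverse-engineering from the six printed
miRNA z-scores shows that every one of them reproduces at full precision
under $p_0 = 1 - \hat p$, i.e. the altered fraction tested against the
unaltered fraction; that convention is the default
(`one_proportion_z()`), and a conventional fixed null is available. The
somatic-mutation z-score additionally requires both proportions to be
rounded to three decimals before the formula — the signature of a desk
calculation on pre-rounded percentages — exposed as
`rounding = "three_decimals"` and off by default. At $p_0 \in \{0, 1\}$
the statistic is undefined and the function raises an error; the
cohort-level wrappers report the limiting ±Inf instead, because an
all-concordant or all-discordant cohort is a legitimate boundary, not a
user mistake.

**Cohen's kappa.** Paired categorical agreement uses unweighted kappa
with the Fleiss–Cohen–Everitt large-sample standard error. Kappa is
reported *undefined* when chance agreement is 1 or when either margin has
fewer than two occupied categories — in that case observed and chance
agreement coincide and the statistic carries no information. This rule
reproduces the study's behaviour, where agreement could not be computed
for the miRNA with 20 of 21 pairs in a single cell. The printed standard
errors of the study could not all be reproduced by any single SE formula,
so only the kappa point estimates that recompute exactly from the printed
table are asserted.

**Benjamini–Hochberg.** Multiple testing across a miRNA family uses the
step-up FDR adjustment via `stats::p.adjust(method = "BH")`, validated in
the tests against a brute-force step-up evaluation on short lists.
Pearson correlations delegate to `stats::cor.test`.

## miRNA quantification

Relative expression follows the comparative Ct method with RNU6B as the
small-RNA reference and a pooled normal colon baseline:
ΔCt = Ct(target) − Ct(RNU6B), ΔΔCt = ΔCt(tumour) − ΔCt(normal),
RR = 2^−ΔΔCt (efficiency 2.0 per cycle is assumed; primer-specific
efficiencies are not modelled). Replicates enter as means; a replicate SD
above 0.5 cycles triggers an advisory warning, mirroring the assay
quality bar.

The cellularity correction rests on two assumptions: only the
tumour-cell fraction of the specimen contributes differential signal,
and all tumour cells express the miRNA equally. Under them the measured
fold change is the true fold change diluted by TC/100, so the corrected
value is measured × (100/TC), i.e. ΔΔCt_tc = ΔΔCt − log2(100/TC). The
original sentence describing the correction is ambiguous about sign;
this package fixes the direction by the dilution argument above, applies
it per tissue (not to the final ratio), and exposes the opposite sign as
`tc_direction = "scale_down"` for sensitivity analysis.

Categories use inclusive cutoffs: RR ≥ 2 high, RR ≤ 0.5 low, otherwise
normal. (A 0.5/1.5 preset, matching the pooled-normal calibration range,
can be selected through `analysis_config()`.) Concordance between the
paired categories is summarised per miRNA by kappa on the 3×3 table.

The paired expression change PM-RE = RR(primary)/RR(metastasis) is
*altered* when ≥ 2-fold in either direction (inclusive), counted per
miRNA, tested with the complement-null z-test and BH-adjusted across the
panel. The overall verdict is a 50%-of-50% rule, inclusive at both
levels: discordant when at least half the miRNAs are altered in at least
half the pairs. The packaged category and ratio tables are independent
fixtures: the categories cannot be re-derived from the ratios (they come
from per-tissue relative ratios that are not printed), so the package
never attempts that reconstruction.

## RPPA pathway cascade

Each spot is normalised to its lysate's total protein. The metastatic
member of a pair is then adjusted for the cellularity difference,
$E^m_{adj} = E^m(1 + \Delta TC/100)$ with ΔTC = TC(primary) −
TC(metastasis) — an upward correction when the metastasis is the less
cellular specimen, and the identity at equal cellularities.

The alteration cutoff is deliberately simple: a marker is altered in a
pair when |E^p − E^m_adj| strictly exceeds the marker's sample standard
deviation over the entire tumour population (both roles pooled, n−1
denominator, computed after the cellularity adjustment; both choices are
configurable because the original description fixes neither). Ties at
exactly one SD are *not* altered ("greater than" is read strictly).
Direction is reported relative to the metastasis.

The approach is validated internally by agreement (kappa on the 3-level
up/none/down status) between isoforms, modified forms and functionally
related markers — eight default pairs, e.g. PTEN/phosphoPTEN and
RAS/RASA1. For pathway analysis, modified forms collapse onto parents
(P85, P110 → PI3K; PTEN forms → PTEN; the two phospho-AKT epitopes →
AKT) by an idempotent, monotone union. The pathway map groups the
collapsed markers into six pathways (CAM-EMT, RAS-RAF-MEK,
PI3K-AKT-PTEN, TGFB-SMAD4, apoptosis, transcriptional mis-regulation).
The source text announces "seven" pathways but enumerates six, and its
results are reported out of six; six is used here, and the map is
overridable. The TGFB/TGFBRII naming inconsistency is resolved by
storing the marker once under `TGFBRII`.

The cascade is three inclusive ≥ 50% rules: pathway altered when ≥ half
its markers are altered; pair profile altered when ≥ half its pathways
are; population different when ≥ half the pairs are.

## The synthetic cohort generator

`simulation_design()` + the three `generate_*_cohort()` functions build
paired cohorts with known truth, inverting each pipeline stage:

* **Mutations** — a background status is drawn per locus (defaults
  approximate the study's observed status mix and ~70% discordance), a
  score is drawn inside the status band, and the MAF is realised as
  HS × (TC/100)/2, truncated to [0.01, 0.99] for present mutations.
  Discordant loci redraw the metastatic status in a *different* band;
  concordant loci keep the primary score exactly. Score noise is
  truncated to ±0.04 and clamped inside the band so that concordant loci
  can never trip either change rule by accident.
* **Ct values** — Ct(target) = Ct(ref) + baseline ΔCt − log2(fold) +
  log2(100/TC) + noise, three replicates per assay plus a pooled-normal
  sample; the dilution term is the exact inverse of the pipeline's
  correction, so at zero noise the pipeline recovers designed fold
  changes exactly. Altered pairs receive a ±2 log2 primary-vs-metastasis
  effect with per-miRNA probabilities defaulting to the study's observed
  altered fractions.
* **RPPA** — log-normal baseline expressions; an altered pathway shifts
  *all* its markers by 3 theoretical marker SDs (direction random,
  flipped upward if a downward shift would go non-positive), which
  always clears the empirical population-SD cutoff, so pathway calls
  equal the design truth and recovered rates are binomially distributed
  around the design probabilities. The raw metastatic value is
  pre-divided by the pair's cellularity factor so the pipeline's
  adjustment lands on the designed target. The generator draws at the
  collapsed-marker level; the isoform-collapsing logic is exercised
  separately on constructed call tables.

Each generator derives its own RNG stream from the master seed by a
fixed offset, so enabling one data type never shifts another's draws,
and identical (design, seed) input yields byte-identical files.

What the generator does *not* emulate: sequencing reads and their error
model, primer-efficiency differences between assays, spatial RPPA
artefacts, and any correlation structure between the three molecular
levels. Passing recovery tests therefore demonstrate that the pipeline
inverts its own model faithfully — not that the model captures every
feature of real FFPE-derived data.

## Numerical choices and test scale

Category and cutoff boundaries are inclusive exactly where the decision
rules above say so; the only strict inequality is the RPPA SD cutoff.
Proportion-test rounding is off by default. Kappa tables are padded with
zero rows/columns to a common category set before computation. Report
files are written atomically (temp file + rename) with a fixed column
order and dialect (UTF-8, tab-separated mutations and reports,
comma-separated Ct/RPPA, `.` decimal point).

The packaged analyses are desk-scale (21–22 pairs) and run in well under
a second. Simulation-based checks use 100–200 pairs (≈ 500 loci, 600
miRNA assays, 3 800 marker measurements) with fixed seeds, sized so the
whole test suite completes in well under a minute; recovered rates are
compared with exact binomial intervals, widened to simultaneous coverage
where a loop performs many interval checks at once.

## Known limitations

* The clinicopathological covariates of the cohort are not modelled; no
  clinical interpretation is attempted.
* Allele-level scores of the original cohort exist only in its
  supplementary files, so heterogeneity statistics on the packaged
  mutation table are limited to presence/absence summaries, and the
  printed discordance counts enter the proportion test as direct inputs.
* CNV here is a label derived from the score, not a copy-number call
  from sequencing depth; no variant calling or image quantification is
  performed.
* The published per-gene narrative counts disagree internally with the
  published mutation table (they sum to one more than the stated locus
  total); this package treats the table as authoritative, and the
  affected narrative values are the documented exceptions in the
  acceptance tests.
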