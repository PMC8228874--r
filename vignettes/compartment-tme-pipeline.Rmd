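---
title: "Compartment-resolved TME profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-resolved TME profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclcTME)
library(data.table)
```

This vignette is the package's own account of the science it implements:
the models and rules, the tunable parameters with their defaults and
units, the synthetic-data generator and its limits, and the design
decisions taken where the methodology was genuinely open.

## 1. Morphometry

Cell counts are collected per TMA core section, separately for the stroma
and tumor-nest compartments, together with the manually annotated
compartment area in µm². `cell_density()` converts to cells/mm². Primary
tumors contribute two cores (A, B) with two sections each; lymph-node (LN)
metastases one core with two sections. `average_replicates()` averages
section densities within a core and then core means per sample,
unweighted. Weighting cores by area would be an alternative; unweighted
averaging is used because replicate cores are deliberately taken from
different tumor regions and should count equally. A compartment absent
from every section of a sample produces *no* record — treating it as zero
would drag the cohort medians (and hence every MAD cutoff) down.

CD33+ myeloid cells are too sparse for stable densities and are scored
ordinally per core compartment: 0 (0 cells), 1 (1–10), 2 (11–20), 3 (≥21).
A count of exactly 21 maps to 3 so that the bins partition the integers.
`cd33_scores()` averages section counts within cores, core means per
sample, and bins the rounded mean.

`composition()` expresses marker densities as fractions of the CD45+
(pan-leukocyte) density per group and compartment. Markers overlap (CD163+
M2 macrophages are a subset of CD68+ macrophages), so fractions need not
sum to 1. Two aggregation modes exist because group percentages can be
formed either way and the choice matters for skewed densities: the default
`ratio_of_sums` (group-summed marker density over group-summed CD45
density) is robust to samples with near-zero CD45; `mean_of_ratios`
averages per-sample fractions.

## 2. Dichotomization and phenotype rules

Each (marker, compartment) parameter — written `CD68s`, `CD68t`, … — is
dichotomized at

$$t = \mathrm{median}(x) + c \cdot \mathrm{MAD}(x), \qquad
\mathrm{MAD}(x) = \mathrm{median}\left(|x_i - \mathrm{median}(x)|\right),$$

with the *raw* (unscaled) MAD and default $c = 0$, i.e. a median split.
The multiplier is exposed because published cutoff tables rarely state it;
so is the sample set on which cutoffs are computed (all samples pooled by
default, primaries-only via `cutoff_samples`). Values strictly above the
threshold are HIGH; ties are LOW, a deterministic rule consistent with the
ordinal convention (scores 2–3 are HIGH, 0–1 LOW). Missing stays missing.

The immune phenotype of a sample follows a fixed Boolean rule over four
calls:

* **oasis**: (CD45s HIGH **or** CD45t HIGH) **and** (CD3s HIGH **or** CD3t HIGH);
* **desert**: (CD3s LOW **and** CD3t LOW) **and** (CD45s LOW **or** CD45t LOW);
* **ambiguous** otherwise, including any missing required call (with a
  reason code).

The two rules are mutually exclusive by construction (oasis needs a HIGH
CD3 call, desert forbids one) but not exhaustive — e.g. CD45 fully HIGH
with CD3 fully LOW matches neither — so a third label is emitted rather
than forcing a call. The test suite checks the classifier against an
independently written truth-table oracle on all 16 combinations.

The macrophage-high/low grouping has no canonical definition; the default
rule calls a sample macrophage-high when at least half of its available
macrophage-related calls (CD68s/t, CD163s/t, CD33s, tumor-cell MHCII where
present) are HIGH, and both the parameter list and the fraction are
configurable.

## 3. Association statistics

Rank statistics are used throughout because TMA densities are heavily
right-skewed. Spearman coefficients use midranks; Kendall coefficients are
tau-b (tie-corrected); both come from `stats::cor.test` with asymptotic
two-sided p-values, and missing values are removed pairwise because tissue
dropout is compartment-specific. Verbal strength labels (weak < 0.4 ≤
moderate ≤ 0.7 < strong) are a configurable reporting convention, not
inference.

`two_group_test()` (Mann–Whitney U) reports the U statistic of each group
(they sum to $n_a n_b$). For groups of at most 8 the two-sided p is exact
by full enumeration of all $\binom{n_a+n_b}{n_a}$ group assignments of the
observed values — this stays valid under ties, where the textbook exact
null does not apply and `stats::wilcox.test` falls back to an
approximation. Larger groups use the normal approximation with tie
correction and continuity correction (verified to match `wilcox.test` to
10 digits). `paired_replicate_test()` is the Wilcoxon signed-rank test
used to confirm that replicate cores A and B are exchangeable before
averaging; zero differences are dropped and an all-zero comparison returns
p = 1 with a warning rather than an error.

## 4. Preranked gene-set enrichment

Genes are ranked for a two-group contrast by signal-to-noise
$(m_1 - m_2)/(s_1 + s_2)$ with the conventional floor
$s_i \leftarrow \max(s_i, 0.2\,|m_i|)$ (and 0.2 when both are zero), or by
Welch t or plain log2FC; the metric is a configuration switch recorded in
the output metadata because published analyses rarely state it. Ties are
broken by gene identifier so the ranking is strictly deterministic.

The enrichment score walks the ranked list of $N$ genes: a position in the
set increments the running sum by $|s_i|^p / \sum_{hits} |s_j|^p$, one
outside decrements by $1/(N - N_h)$; ES is the running-sum value of
maximal absolute deviation (an exact positive/negative tie resolves to the
positive extremum — a documented convention; such ties essentially only
arise with $p = 0$). The sum provably returns to zero, which the tests
assert to $10^{-9}$, and the implementation evaluates only the $2N_h$
candidate extrema so permutation nulls are cheap. The unweighted form
equals the classical Kolmogorov–Smirnov statistic and is checked against a
brute-force oracle; the weighted form is checked against
`fgsea::calcGseaStat` on random instances.

Normalization uses a *gene-label* permutation null (matching the preranked
tool family): `n_perm` draws of $|set|$ genes without replacement,
$NES = ES / \mathrm{mean}(|ES_{null}|\ \text{of the same sign})$, and the
nominal p is the same-sign exceedance fraction with a +1 pseudocount. If
no null draw shares the sign, p is $1/(n_{perm}+1)$ and the NES is flagged
unstable. Phenotype-label permutation would be the alternative null; the
gene-label null was chosen to match the cited tool family and to stay
valid at small group sizes. Under a null cohort the nominal p of random
decoy sets is uniform (Kolmogorov–Smirnov check across 1000 sets in the
test suite).

For display, `nes_heatmap_matrix()` keeps pathways with max |NES| > 1
across groups and z-scores each pathway across groups with the
*population* (n) standard deviation — a display scaling, not inference;
pathways constant across groups get a zero row and a flag.

## 5. Differential expression, volcano categories, networks

Per-gene tests are Welch t on log2 expression with an optional
empirical-Bayes-style shrinkage of group variances toward their mean
(`shrink`, default 0) and a variance floor (`var_floor = 0.05` log2 units)
so degenerate zero-variance genes remain finite; a fully moderated fit is
deliberately not re-implemented because downstream consumers only use
thresholded calls, and at these effect sizes Welch and moderated t select
the same genes (checked against limma in the tests). Multiplicity is
handled by Bonferroni over the panel (2560 tests: a raw p of $10^{-5}$
becomes 0.0256), the conservative choice matching how the volcano
thresholds are stated. Volcano categories apply to |log2FC| at
significance p < 0.05: strictly above 2 red, strictly between 1.5 and 2
dark blue, otherwise light blue; boundaries are read literally (exactly 2
is dark blue, exactly 1.5 light blue). Whether the categorizing p is raw
or adjusted is a switch (`p_for_category`), default adjusted.

Network nodes are genes with p < 0.05 and log2FC > 1.5 (strict,
directional — only upregulation in the focal group selects a node); the
same p-type switch applies, default adjusted for consistency with the
volcano. The induced subgraph keeps supplied interaction edges with score
≥ 0.4 between selected nodes; isolated selected nodes are retained because
they belong in the edges-per-node denominator. "Edges/node" is reported as
the literal ratio E/N, with mean degree 2E/N available as an alternative
convention flag; the total connection score is the sum of retained edge
scores. Edges always come from a user-supplied table — no live database
calls, for reproducibility.

## 6. The synthetic cohort generator

The generator exists so that every stage is testable offline, with known
ground truth. It emulates:

* **Cohort structure**: 32 patients, each with a primary tumor (2 cores ×
  2 sections) and a matched LN metastasis (1 core × 2 sections); the
  NE-high fraction defaults to 20/31 as realized among typed primaries;
  the LN sample inherits the patient's NE label with flip probability 0.1
  (primary/LN phenotypes are concordant but not identical).
* **Density means** (cells/mm²) per marker, compartment, site and NE
  subtype, fixed from published group means. CD45/CD3 means are not
  published as densities and were chosen once so tumor-nest composition
  reproduces the published percentages (CD68+ ≈ 64%/71% and CD3+ ≈
  38%/18% of CD45+ cells in NE-low/NE-high nests). The published CD33
  figures (2.05 vs 0.8) are mean *ordinal scores*, not densities — 2
  cells/mm² could never reach the 11–20-cell score bin on a ~0.3 mm²
  compartment — so the CD33 density means (65 vs 9 cells/mm² in primary
  stroma) are back-converted to reproduce those score means under the
  score bins.
* **Correlation structure**: one latent "infiltration" factor per sample
  (correlated within a patient), with per-parameter loadings. Pooled
  Spearman targets (CD68~CD163: 0.76 tumor nest, 0.455 stroma;
  CD33~CD163 stroma: 0.651) are honored by (i) converting Spearman to a
  normal-scale correlation, (ii) *de-attenuating* for the counting noise
  of a replicate-averaged density estimate, (iii) subtracting the
  between-NE-group mean component, and (iv) solving the loadings by
  minimum-norm log least squares with clamping at 1. Targets that survive
  none of this — a required within-group correlation or loading outside
  [−1, 1], an inconsistent sign cycle — are rejected with a diagnostic;
  this is the one-factor analogue of a non-positive-semidefinite
  correlation matrix. A single factor was chosen over a full copula
  because it matches the narrative that macrophage and T-cell densities
  co-vary along one infiltration axis, and it is always internally
  consistent. The full published correlation grid is *not* one-factor
  representable (the tumor-nest CD68/CD163/CD3 triangle alone implies a
  loading above 1 after group-mean adjustment), so the defaults carry the
  consistent subset above.
* **Counts**: negative-binomial with mean density × area (size 20) over
  log-normal areas (0.30/0.35 mm² stroma/nest, sdlog 0.25), so density
  estimates carry realistic integer sampling noise; this is also why
  correlations need the attenuation step above.
* **Expression**: 2560 genes partitioned into immune (120), proliferation
  (100), neuroendocrine (40) modules plus background; per-gene baselines
  N(6, 1.2²) log2 units; module genes shifted by `effect_size` (default
  1.5) in their favored phenotype (immune up in NE-low, proliferation and
  neuroendocrine up in NE-high); a patient random effect (sd 0.6) shared
  by a patient's primary and LN sample; residual noise sd 1.0. Four
  immune genes (CSF1, VEGFC, IL4R, CXCR2) have their group means pinned
  to published values so that pipeline group-mean summaries are directly
  comparable. Immune genes are additionally coupled to the sample's
  infiltration factor at 0.8 log2 units per factor sd: bulk immune-gene
  expression in tissue largely *is* a readout of the infiltrate, and at a
  weak coupling the oasis-vs-desert contrast would contain no targets at
  the Bonferroni + log2FC > 1.5 filter, contrary to the phenomenon being
  modeled. With it, the oasis target network is non-empty but much
  sparser than the NE-low network, matching the reported pattern.
* **Gene sets and interactions**: one gene set per module plus random
  decoys; interaction edges with within-module probability 8× the
  baseline (default baseline 0.006, chosen once so a module-driven target
  selection has an edge-to-node ratio near 2, the order reported for
  string maps of co-functional genes) and scores uniform on (0.4, 1].

### What the generator does not emulate

Spatial structure (necrosis, compartment geometry), staining artifacts,
inter-observer counting variability, dropout patterns, any real gene-gene
covariance beyond the module/infiltration structure, and the real panel's
gene identities outside a few named markers. Passing tests therefore
establish that the *pipeline* is correct and recovers known structure at
realistic noise levels — not that the biological conclusions would
replicate on new tissue.

### A note on the phenotype-recovery property

The recovery test ("the classifier agrees with the generating infiltration
factor") is run on a cohort where infiltration is the *sole* group driver:
NE-neutral density means and CD45/CD3 pooled correlation targets of 0.93
(0.95 is unreachable once counting noise is accounted for). Under the
default NE-stratified means no classifier could pass it — the NE mean gaps
dominate the calls while the factor is independent of the NE label.
Agreement is judged against the factor's sign relative to the cohort
median, because a median-split classifier centers there, not at the
population zero.

## 7. Numerical choices and degenerate inputs

* Ties at a dichotomization threshold → LOW; ES extremum ties → positive;
  ranking ties → lexicographic by gene.
* All-identical cutoff inputs warn (degenerate dichotomization); constant
  correlation inputs are flagged with NA coefficients; empty networks
  return all-zero statistics with a flag; an all-zero CD45 aggregate
  flags the composition fraction as undefined rather than returning 0.
* All randomness flows from explicit seeds; permutation streams are local
  (the caller's RNG state is saved and restored), so pipeline stages do
  not perturb each other and reruns are byte-identical.
* Problem sizes used by the test-suite simulations were chosen to make
  Monte-Carlo noise small relative to the asserted tolerances: 5000
  patients for correlation-target realization, 1000 decoy sets × 200
  permutations for p-uniformity, 20 replicate cohorts for enrichment
  recovery, 4000 replicates for the Mann–Whitney size check.

## 8. Known limitations

* The MAD multiplier and the cutoff cohort (primary-only vs pooled) for
  the published annotations are unknown; both are configuration, and the
  default median split need not reproduce any particular published
  per-sample call table.
* Bonferroni over 2560 genes at n ≈ 60 samples is severe; target counts
  (and hence network statistics) swing strongly between seeds at the
  default effect sizes. This is the honest behavior of the thresholded
  method at this design size, not a bug.
* The Mann–Whitney exact path enumerates all assignments and is meant for
  the n ≤ 8 regime it defaults to; forcing `exact = TRUE` on large groups
  is combinatorially expensive.
* `run_gsea` adjusts p across pathways within one contrast
  (Benjamini–Hochberg); no adjustment is applied across contrasts or
  across the correlation grid (coefficients there are reported
  unadjusted, as is conventional for descriptive grids).
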