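---
title: "Methods: tractwise connectome statistics and persistent homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tractwise connectome statistics and persistent homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`tractopo` analyses structural brain connectomes in which each undirected
connection ("tract") between two parcellation regions carries the mean
generalized fractional anisotropy (GFA) of the streamlines linking them.
The pipeline addresses a comparison of cognitively normal (CN)
participants with amnestic and non-amnestic Alzheimer's disease
phenotypes (amnestic MCI/AD; logopenic-variant primary progressive
aphasia, posterior cortical atrophy, behavioural-variant AD, and
corticobasal syndrome), and runs in a fixed order:

1. **Quality control** of sparse per-participant connectivity matrices;
2. **Normative w-scoring** of tract GFA and regional grey-matter volumes
   against the CN group;
3. **Mass-univariate tractwise contrasts** with FDR control and Tukey
   post-hoc tests, plus the same engine for global white-matter
   microstructure (FA, MD, isotropic diffusion);
4. **Grey-matter/white-matter coupling** via linear mixed-effects models;
5. **Persistent homology** of each participant's weighted brain graph
   (Betti-0/Betti-1 curves over a graph filtration) with **exact
   topological inference** for group differences; and
6. **Clinical regressions** of topological metrics on cognition and
   disease duration.

Because no patient data ship with the package, a synthetic-cohort
generator is a first-class module: it produces data with the statistical
structure each stage assumes, together with the generating ground truth,
so every stage is tested by parameter recovery rather than by fixture
files.

# Quality control

A region is an *island* in a scan when it has no defined connection to
any other region. Regions that are islands in **more than** 25% of scans
are excluded (the comparison is strict, so a region at exactly the
threshold is retained). Tracts are then kept only if present in **at
least** 50% of the participants of *every* phenotype in the rule's
phenotype set (inclusive comparison); the default set is
{CN, lvPPA, PCA, bvAD, CBS}. The set deliberately omits the amnestic
group, matching the rule as published for this cohort; because that
omission may be unintended in the original, `coverage_filter()` emits a
message unless the caller passes the set explicitly. Finally, tracts
whose value in a population-average template matrix is zero or undefined
are dropped. Cases missing a retained tract are excluded tract-by-tract
downstream, never listwise.

# Normative w-scores

For each tract (covariates: age at MRI, sex) and each region's
grey-matter volume (covariates: intracranial volume, age, sex), an
ordinary least-squares model is fitted **in the CN group only**, and all
participants are scored as

$$ w = \frac{\mathrm{observed} - \mathrm{predicted}}{\hat\sigma_{\mathrm{resid}}}, $$

with the residual SD computed on $n_{\mathrm{train}} - p$ degrees of
freedom. Positive w means more GFA or volume than expected for a CN
individual with the same covariates; negative w means degeneration. By
OLS orthogonality the CN training mean of w is zero per target (asserted
to $10^{-10}$ in the tests). Sex enters as a single indicator (reference
F); a two-level factor is fit-equivalent either way.

W-scores are truncated at the 0.1 and 99.9 percentiles of the pooled
per-modality distribution (all participants x all targets, linear
interpolation between order statistics). Pooling is deliberate: at a
cohort of ~153 participants a per-target 0.1 percentile would sit outside
the observed sample. Truncation is applied before any downstream use,
including the grey-matter means entering the mixed models; this ordering
follows the data-preparation description preceding the models.

For topological analysis only, w-scores are min/max normalized so the
global minimum maps to 0 and the global maximum to 1, and **missing
tracts are then encoded as 0**. Together with the strict edge rule below
this guarantees an absent tract never appears in any filtration
subgraph. Statistical contrasts always use the unnormalized table with
tract-by-tract exclusion instead.

# Tractwise contrasts

Per tract, w is regressed on the factor of interest (group or phenotype)
plus covariates (default: MMSE), and the factor is tested with a Type II
F (factor adjusted for covariates and vice versa); with a single
covariate this is order-invariant and matches the stated model intent.
Benjamini–Hochberg adjustment runs across all tested tracts; tracts with
an entirely missing factor level are skipped, not imputed. For
FDR-significant tracts, all pairwise level contrasts of estimated
marginal means (evaluated at the grand covariate mean) are reported with
studentized-range (Tukey) adjustment, with one family per tract — the
standard reading of post-hoc testing after a per-tract omnibus. The same
engine serves the three global microstructure metrics (covariates age,
sex, MMSE; BH across the three metrics) and generic neuropsychological
contrasts.

One estimand subtlety is worth stating. When a covariate is strongly
collinear with the factor — as MMSE is with diagnostic group in this
population — the adjusted contrast estimates the group effect
*orthogonal to the covariate*, which is a different quantity from an
unconditional group shift. The package's parameter-recovery checks of
injected group effects therefore use the unadjusted contrast, because
the generator injects unconditional shifts; the adjusted engine remains
the default for data analysis.

# Grey-matter/white-matter coupling

For each participant and region, the mean w over all retained,
non-missing tracts incident to the region (each tract counts toward both
endpoint regions) is the outcome of

```
mean_wm_w ~ moderator * gm_w + (1 | participant)
```

fitted by REML with Satterthwaite denominator degrees of freedom
(`lmerTest`), the machinery that reproduces observation-level
denominator df in the tens of thousands for ~150 participants x ~148
regions. The moderator is group, phenotype, or APOE e4 copy number; for
APOE, two companion models separate genotype from diagnostic group (an
additive model and a full-factorial model). Random slopes and crossed
random effects are intentionally out of scope — the design is
intercept-only. Fixed-effects variance explained is reported as the
squared correlation between fixed-effect fitted values and observations;
the source analysis does not name its formula, and this definition
coincides with the fitted-variance ratio for least-squares-centered
fits.

Two generators feed this module. The full cohort generator couples
volumes to white matter in the *generative* direction (volume = baseline
+ slope x mean incident-tract GFA deviation + noise), which is the
structure stated for the emulation; regressing WM on GM on such data
attenuates the slope (reverse regression), so it cannot be used to test
slope recovery. `simulate_gmwm_data()` instead draws directly from the
fitted model's own data-generating process with known intercepts,
slopes, random-intercept SD and noise SD, and the recovery tests (slopes
CN 0.03 vs patients 0.08; zero random variance collapsing to OLS within
$10^{-6}$) run on it.

# Persistent homology and exact inference

Each participant's graph has the retained regions as its fixed node set
and edge weights from either normalized w-scores or raw GFA (missing =
0). At threshold $\lambda$ the filtration subgraph keeps edges with
weight **strictly greater** than $\lambda$; Betti-0 is the number of
connected components (isolated nodes count) via union-find, and Betti-1
follows exactly from the Euler characteristic,
$\beta_1 = \beta_0 - V + E(\lambda) \ge 0$. Curves are evaluated on 100
linearly spaced thresholds spanning the pooled weight range; optionally
the union of every participant's spanning-tree weights is merged in.
Because components merge as the threshold *decreases*, the relevant tree
for a similarity (GFA) graph is the **maximum-weight** spanning tree —
the wording "minimum spanning tree" in the single-linkage literature
refers to the distance representation of the same tree — and a
configuration switch (`mst_direction = "min"`) preserves the literal
reading. $\beta_0$ is non-decreasing and $\beta_1$ non-increasing along
the grid; both are asserted exactly, as is the Euler identity, and
component counts are cross-checked against an independent BFS oracle.

Group curves are compared by the Kolmogorov–Smirnov distance
$D = \max_\lambda |\bar\beta_A(\lambda) - \bar\beta_B(\lambda)|$, ties
broken at the smallest threshold. The exact p-value treats the two
curves as a pair of exchangeable monotone walks from $(0,0)$ to $(q,q)$
on a Cartesian grid ($q$ = node count for $\beta_0$; $q = E_{\max} - V +
1$, the maximal cycle count of the densest retained graph, for
$\beta_1$) and counts, by dynamic programming with exact
arbitrary-precision integer limbs, the walks staying strictly within the
band $|x - y| < b$ with $b = \lceil D \rceil$:

$$ p = 1 - A_{q,b} / \binom{2q}{q}. $$

$\binom{296}{148} \approx 10^{87}$ overflows double precision, hence the
exact limb arithmetic; the complement $\binom{2q}{q} - A$ is formed by
exact subtraction *before* the final floating division, avoiding
catastrophic cancellation when $A$ is close to the total. The dynamic
program is validated against exhaustive enumeration of all paths for
$q \le 8$ and against Monte-Carlo sampling of uniform monotone walks.

The ceiling rule for the band is a documented discretization choice: the
walks live in integer component/cycle counts while the mean-curve
distance is real-valued, and no finer mapping is specified by the
construction this reproduces.

A label-permutation test over participant curves is provided as a
companion (`permutation_pvalue()`), but it answers a different question:
its null is exchangeability of *participants*, under which the group
mean curves differ by $O(1/\sqrt{n})$, whereas the combinatorial null
treats the two mean curves as individual uniform walks. The exact
p-value is therefore conservative relative to the permutation test
except at very large effects, and the two should not be expected to
agree numerically at moderate effect sizes. A further caveat specific to
w-score-based graphs: normative scores are defined relative to the CN
training sample, so even under a zero injected effect, patient w-scores
have slightly inflated out-of-sample variance and participant labels are
not exactly exchangeable; permutation validation is best performed on
raw-GFA graphs.

At the threshold $\lambda^*$ attaining the CN vs non-amnestic $\beta_0$
distance, per-participant $(\beta_0, \beta_1, \beta_1/\beta_0)$ are
extracted and regressed on MMSE (all participants) and disease duration
(patients only), adjusting for age and sex, at $\alpha = 0.05$
uncorrected — mirroring the source analysis, which applies no
multiplicity correction here. Pearson correlations with global FA, MD
and isotropic diffusion are reported alongside. When $\lambda^*$ falls
where $\beta_1$ is constant (often 0), the singular fits are flagged
rather than silently dropped.

# The synthetic cohort

Defaults emulate the study conditions: phenotype sizes 45/41/32/17/10/8;
a 152-region parcellation in two hemispheric blocks; a sparse tract
universe (within-block pair probability 0.10, between-block 0.008, with
a minimum degree of 4 so only designated regions recur as islands); four
low-coverage regions emulating the excluded island regions; per-tract
presence probabilities drawn from a Beta distribution with mean 0.805
and SD 0.119, then Bernoulli per participant, independent of group by
default (a configuration switch couples missingness to group for stress
tests); control tract means uniform on [0.3, 0.7]; residual GFA SD 0.05,
which is also the unit of injected effect shifts; linear age
(-0.0012/yr) and sex (+0.008 M) effects so the w-score stage has real
covariate signal to remove; phenotype-specific degeneration on
presence-ranked tract sets; grey-matter volumes coupled to incident
tract GFA with group-dependent slopes plus ICV/age/sex effects; global
FA/MD/ISO shifted by group; MMSE, ages, sex ratios and APOE
distributions per phenotype following the published cohort table, with
configurable missingness counts and biomarker-confirmation flags for the
subset re-analysis. Each patient additionally carries a latent disease
severity (standard normal) that scales their injected tract shifts
(mean shift preserved; `severity_effect`, default 0.35) and lowers
their MMSE (`mmse_severity_slope`, default 2 points/SD). This coupling
is what justifies MMSE as a covariate "adjusting for within-group
variation in disease progression": without it, a group-collinear MMSE
carries no within-group signal and covariate adjustment over-corrects
the group contrast, to the point of reversing its sign on affected
tracts. The GFA marginal distribution is an emulation
choice, not a claim about the data.

What the generator does **not** emulate: streamline-level tractography
artifacts, spatially structured (autocorrelated) noise, non-linear age
effects, and missingness mechanisms tied to atrophy. Passing tests
therefore demonstrate correctness of the statistical machinery under the
assumed model, not robustness to those real-data features.

Problem sizes in the test-suite and acceptance runs are the package's
standard verification sizes: the full 153-participant cohort for
calibration, monotonicity and determinism checks; 40-node two-group
cohorts for exact-vs-permutation comparisons; 200 replicates of a
497-tract global null for FDR calibration; 500 random graphs (up to 20
nodes) for the component and cycle-rank oracles; exhaustive path
enumeration up to q = 8.

# Numerical and design choices

* Strict (`>`) edge retention in filtrations; strict island threshold;
  inclusive coverage threshold — each following the stated rule text.
* Canonical tract identifiers sort the two region labels
  lexicographically and join with `--`; all tables are sorted for
  reproducible diffs, and repeated pipeline runs are byte-identical
  (provenance headers carry a configuration hash and seed, no
  timestamps).
* Percentiles: type-7 linear interpolation, stated for reproducibility.
* BH ties resolved by stable sort; deterministic output ordering.
* Degenerate fits (zero residual variance, singular designs, constant
  metrics) are flagged and excluded from inference, never silently
  patched.
* The tractwise engine uses QR-based residual sums of squares per tract
  (shared design reuse) rather than repeated `lm()` calls, which keeps
  the 497-tract x 200-replicate null calibration within minutes on one
  CPU.

# Limitations

* The exact topological test is conservative for group-mean curves (see
  above); it is reported alongside, not instead of, the permutation
  test.
* Observation-level degrees-of-freedom bookkeeping in the mixed models
  cannot be verified against the original tables without the original
  data; property tests (OLS degeneracy, affine invariance, slope
  recovery) substitute.
* The w-score stage assumes linear covariate effects; no GAM or
  quantile-regression normative models are provided.
* Betti numbers above dimension 1 and persistence diagrams/barcodes are
  out of scope.
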