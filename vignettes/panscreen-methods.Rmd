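---
title: "PanScreen: models and methods of the production-screen pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PanScreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PanScreen)
```

PanScreen analyses high-throughput screens of secreted heterologous
enzyme production across yeast strain libraries. This vignette explains
the statistical models behind each stage, the tunable parameters and
their defaults, what the synthetic-data generators emulate (and what they
do not), and the numerical choices made where the procedure was genuinely
open.

## Enzyme kinetics: from absorbance traces to Units

A microplate enzymatic assay reads absorbance of the chromogenic product
(oxidized ABTS at 420 nm for a laccase) once per minute for an hour. The
informative quantity is the initial rate: the slope of the linear part of
the progress curve. Curves are non-linear at both ends — a lag while the
reaction mixture equilibrates, and saturation as substrate is consumed —
so the conventional manual practice is to discard points from both ends
until the straight-line fit is excellent.

`trimToLinear()` makes that deterministic: it searches *all* contiguous
windows of at least `minPoints` readings and returns the longest one
whose ordinary-least-squares fit has $R^2 \ge$ `r2Min`, ties broken by
the earliest start. Manual or greedy end-trimming is order-dependent and
can stop in a local optimum; the exhaustive search is $O(n^2)$ with
prefix sums, negligible for traces of tens to hundreds of points, and is
at least as good as any end-trimming schedule by construction. The
package tests this operation against an independently coded brute-force
search on a thousand simulated traces.

Three conventions matter for degenerate traces:

* $R^2 = 1 - SS_{res}/SS_{tot}$; a window with **zero response variance**
  ($SS_{tot}=0$, a well with no signal) gets $R^2 = 1$ by convention,
  slope 0, and the `flat` quality flag — a valid zero-activity
  measurement, not a failure.
* When **no window qualifies**, the best-$R^2$ window of length
  `minPoints` is reported with flag `no_linear_window`; downstream stages
  treat its activity as missing.
* Window indices are 1-based and inclusive, following R convention, in
  memory and in output files.

`activityFromFit()` converts the slope with the Beer–Lambert law:

$$U \;=\; \frac{\text{slope}}{\varepsilon\, l}\; V_{rxn}\,(\mathrm{L})
 \times 10^6 \times \text{dilution},$$

1 U being 1 µmol of substrate converted per minute. Defaults:
$\varepsilon = 36\,000\ \mathrm{M^{-1}cm^{-1}}$ (oxidized ABTS),
$V_{rxn} = 200$ µL, dilution 1. The optical **path length has no
default**: in a microplate it depends on fill volume and instrument, the
assay description does not determine it, and results scale as $1/l$ — so
it is a required configuration value. Negative slopes are clamped to
zero with a flag: secreted-enzyme activity is physically non-negative and
the screen treats such wells as non-producers. `minPoints = 10` (ten
minutes of signal at one reading per minute) is a floor we chose;
nothing in the assay prescribes one, and it is configurable.

Whether a blank (no-enzyme) slope is subtracted is exposed as
`blankSubtract` (default off), and OD600 is carried through
`quantifyPlate()` without being applied — the screen's activity values
are raw Units unless the analyst decides otherwise.

## Hit calling

The primary screen measures each strain once, so hit calling must be
robust to the heavy right tail the producers themselves create.
`callPrimaryHits()` uses the scaled median absolute deviation,
$\mathrm{MAD} = 1.4826 \cdot \mathrm{median}_i\,
|x_i - \mathrm{median}(x)|$ (1.4826 makes it estimate $\sigma$ under
normality), and flags strains strictly above
$\mathrm{median} + k\cdot\mathrm{MAD}$ with $k = 3$. The median/MAD pool
includes the reference strain — the threshold is defined over all
screened strains — and the rule is equivariant under affine rescaling of
the activity axis, so units do not matter. Strict `>` means ties can
never be hits, which only matters in degenerate zero-spread data.

The secondary screen re-assays candidates with replicates (four
biological replicates is the study design the generator mirrors).
`secondaryScreen()` runs a Welch unequal-variance $t$-test of each strain
against the reference, one-sided ("greater") by default because the
screening question is directional; `alternative = "two.sided"` and a
Benjamini–Hochberg flag are available. No multiplicity correction is
applied by default: each strain is its own confirmatory comparison
against the control, the per-strain framing used when such screens are
reported; the BH option surfaces how sensitive the confirmed-hit count
is to that choice. With two enzymes screened in parallel,
`combineDualScreen()` categorizes strains (`a_only`, `b_only`, `both`,
`neither`) and reports the Pearson correlation of mean activities with
its exact $t$-transform p-value.

## Pan-genome presence/absence enrichment

Hit strains may share gene content differences that explain production.
The matrix of presence/absence calls over the species pan-genome is first
reduced by `retainVariableOrfs()`: only ORFs whose state in at least one
hit strain differs from the reference strain are informative.
`fisherEnrichment()` then tests each retained ORF's 2×2 table (presence
in hits vs in the remainder of the library) with the two-sided Fisher
exact test; direction (enriched/depleted) comes from the presence
proportions, significance from $p < \alpha$ (default 0.05, raw p;
BH optional and reported alongside). Two-sided is the deliberate default
— the standard exact-test function's default — with direction assigned
afterwards, rather than two one-sided tests.

Some ORFs absent from the reference genome are near-identical homologs
of reference genes: a depleted gene whose homolog is enriched among the
hits is functionally *compensated*, not lost. `classifyCompensation()`
relabels any depleted ORF linked by a homology pair with amino-acid
identity ≥ `minIdentity` (default 0.73 — the bottom of the identity
range such homolog sets span; the exact criterion is a declared proxy,
not an established convention) to an ORF classified enriched. Pairs are
treated symmetrically, and when several enriched homologs qualify the
highest-identity link is recorded.

Because the exact test is discrete and hundreds of background ORFs are
tested, a handful of chance discoveries at $\alpha = 0.05$ is expected
even under BH adjustment; recovery tests therefore assert perfect recall
of planted classes plus a bounded false-discovery fraction rather than
exact count equality.

## Neighbour-joining phylogeny

`njTree()` wraps the standard Saitou–Nei agglomeration with the
Studier–Keppler update (via ape), after validating symmetry,
non-negativity and a zero diagonal. On additive (tree-metric) distances
NJ recovers the generating tree exactly — topology and branch lengths —
which the test suite verifies on 200 random additive matrices of 4–16
taxa. Negative branch-length estimates (possible on non-additive data)
are clamped to zero and counted in the `clampedEdges` attribute;
transferring the deficit to the sibling edge was considered and rejected
for opacity. `rootAtOutgroup()` places the root at the **midpoint of the
outgroup's pendant edge**: an outgroup choice alone does not determine
the position along that edge, and the midpoint conserves total tree
length. Newick serialization (branch lengths with `:`, trailing
semicolon) is a write–read–write fixpoint.

## Comparative Ct

`relativeExpression()` implements the textbook ΔΔCt method: technical
replicates are averaged on the Ct scale (standard practice; averaging
after exponentiation would weight cycles asymmetrically), then
$\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{ref}$ per strain,
$\Delta\Delta Ct$ against the calibrator strain, and relative level
$E^{-\Delta\Delta Ct}$. The amplification efficiency defaults to the
classic $E = 2$ and is adjustable since no efficiency calibration is
assumed. The calibrator's level is exactly 1 by construction, and levels
are invariant to any constant added to both genes' Ct values of one
strain. `activityPerMrna()` divides activity by relative transcript
level and rescales so the calibrator is 1: ratios above 1 indicate
post-transcriptional advantages (folding, modification, secretion)
rather than more transcript.

## Proteome post-processing

The proteomics module starts downstream of spectral search, at a
proteins × samples intensity matrix (a `ProteomeExperiment`, a
`SummarizedExperiment` with sample metadata distinguishing technical
from biological replicates). The pipeline order is enforced — QC,
normalize, impute, test — and testing a matrix that still has missing
cells is an error.

**Replicate QC.** A biological replicate is excluded only when its
pairwise $R^2$ of log2 intensities (over mutually observed proteins) is
below `r2Exclude` (default 0.85) against *every* other replicate of its
strain. With exactly two mutually discordant replicates that rule would
delete the whole strain; instead only the sample with the lower median
$R^2$ against all other samples in the dataset is dropped (tie: the
later column), a deliberate tie-break recorded here.

**Normalization.** `medianNormalize()` divides each sample by its
observed median and multiplies by the mean of all per-sample medians, so
every sample's median equals that common target; the operation is
idempotent. Rescaling one sample beforehand changes the common target —
so outputs are identical only up to one global factor; every
within-/between-sample ratio, and hence every fold change, is exactly
invariant, which is the property that matters downstream.

**Imputation.** Missing DIA intensities concentrate at low abundance
(left-censoring), which is the premise of bottom-quantile imputation.
`imputeMinProb()` draws each sample's missing cells from
$\mathcal N(\mu_j, \sigma_j)$ with $\mu_j$ the sample's
`imputeQuantile` quantile (default 0.05) and $\sigma_j$ initialized to
the spread of the sample's bottom decile and **halved until all draws
are positive** — our concrete reading of "tuning sigma so nothing
negative is imputed"; the rule and final sigmas are recorded in the
object metadata, and the draws are seeded. Samples with under 20
observed values fall back to global quantities with a warning. Observed
cells are never altered.

**Differential abundance.** Per protein, a two-sided Welch $t$-test on
log2 intensities of the strain's biological replicates versus the
reference's; $\log_2$FC is the difference of group means. Tests are run
on the log scale and CVs are computed on the linear scale — the
field-standard pairing; neither scale is dictated by the assay itself.
`up`/`down` calls require $|\log_2\mathrm{FC}| \ge \log_2(\texttt{fcMin})$
(default two-fold) and raw $p \le \alpha$ (default 0.05); BH q-values
are always reported, and a strict-BH filter is a flag. A protein with
zero variance in both groups is $p = 1$ when the means agree and a
certain call when they differ.

**Recurrence.** `recurrenceFilter()` keeps proteins called in the same
direction in at least `ceil(recurrenceFraction × nStrains)` strains
(default half, so 10 of 20 qualifies and 9 does not). A protein reaching
the cut-off in both directions is excluded from both sets and flagged.

**Reporting.** `cvProfile()` gives per-protein sd/mean within technical
or biological replicate groups with the median across proteins as
summary; `pcaSamples()` is plain PCA of log2, per-protein-centred,
complete-case intensities.

## What the synthetic generators emulate

Each generator is seeded (one global seed fans out into per-module
substreams, so stages can be regenerated independently) and returns its
planted truth.

* `simulateScreen()` emulates a ~600-strain screen: 61 readings at
  1-minute spacing, progress curves
  $A(t) = A_{base} + A_{max}(1 - e^{-r (t-t_{lag})_+}) + \epsilon$ with
  a 3-minute lag and $A_{max} = 36$ AU — full conversion of the 1 mM
  substrate at $\varepsilon = 36\,000$ and 1 cm, so the hour consumes
  only ~6% of substrate and the curve is gently saturating, as in the
  real assay. The rate $r$ is scaled so the initial slope encodes the
  strain's true activity (baseline $2\times10^{-4}$ U, tied to the
  worked Beer–Lambert example) through the same conversion the analysis
  inverts. Reading noise is 0.002 AU, a level at which the
  $R^2 \ge 0.999$ criterion is attainable on 10-point windows, as it was
  in the assay being emulated. By default all non-hit strains share the
  baseline activity, so planted effects are the only biological signal;
  `strainSdLog` adds log-normal strain-to-strain spread when a diffuse
  library is wanted. Planted hits multiply the baseline by `effectSize`
  (default 2). Every 96-well plate carries one reference-strain control
  well. At these defaults the 3-MAD rule recovers all 30 planted hits
  with specificity ≥ 0.996 across seeds.
* `simulatePangenome()` plants study-scale classes by default — 23
  enriched ORFs of which 10 are `-like` homologs compensating 10 of 48
  depleted ORFs — on an i.i.d. background (presence rate 0.35). The
  reference strain carries the laboratory genome: every planted depleted
  ORF present, every planted enriched (pan-genome) ORF absent. Homolog
  identities are uniform on [0.73, 0.99], the range such homolog sets
  span, plus decoy pairs among background ORFs.
* `simulateDistances()` draws a random unrooted binary tree with uniform
  branch lengths and returns exact path-length distances — additive by
  construction, so NJ must recover the tree exactly.
* `simulateProteomes()` draws log-normal base abundances (log2 mean 20,
  sd 2, a typical DIA intensity range), plants log2 fold changes, and
  injects technical (target CV 8%) and biological (target total CV 22%,
  of which the technical component is part) replicate noise. Because the
  plain sd/mean estimator is biased low at small $n$ (its median is that
  of a scaled chi distribution — ~13% low at $n=4$), the injected spread
  is inflated by the inverse of that median factor at the design's
  replicate counts so the *measured* median CVs land on the targets, as
  they should for data emulating reported CV scales. Censoring is
  logistic in log2 intensity (midpoint 16, scale 1, ~7% missing
  overall), strictly left-censored; setting the amplitude to 0 disables
  it.
* `simulateQpcr()` encodes planted relative expression in the target
  gene's Ct (`ct = base − log(level)/log(E) + noise`), three technical
  replicates per strain and gene.

What the generators do **not** emulate: plate-position and batch
effects, growth differences (OD600 is carried but constant), non-Gaussian
read noise, correlated proteins or pathway structure, presence/absence
linkage between ORFs, qPCR efficiency drift, and biological replicate
variation in the primary screen (each strain is read once, as in the
screening design). Passing recovery tests on synthetic data therefore
demonstrates the correctness of the computations and their behaviour at
realistic noise scales, not robustness to every artefact of real plates
and instruments.

## Problem sizes and determinism

The default pipeline (`pipelineConfig()`) simulates the study at full
scale — 600 strains, 500 ORFs, 4 000 proteins over 21 strains with 4
biological replicates plus 14 technical replicates of the reference, 24
taxa — and completes in well under a minute on a single core; the
acceptance machinery runs whole-pipeline replicates and 200-tree NJ
sweeps in a few minutes. All randomness derives from the configuration
seed; reruns with the same configuration are byte-identical, and every
output table carries a header comment with package version,
configuration hash and seed.

## Known limitations

* Pipeline orchestration is by exported functions over plain text files;
  there is no shell entry point, in keeping with an analysis package
  whose interface is R.
* The homolog "compensation" call is a declared identity-threshold proxy
  for functional substitution; it does not model function.
* `replicateQC` compares biological replicates only; technical
  replicates are assumed pre-vetted run controls.
* Exact-test discoveries among hundreds of null features are expected at
  raw $\alpha$; interpreting enrichment lists without the BH column is
  the analyst's responsibility.
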