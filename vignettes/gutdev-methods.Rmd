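---
title: "Methods: community typing, maturation and stability in the developing infant gut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community typing, maturation and stability in the developing infant gut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

gutdev analyses longitudinal infant gut microbiome cohorts sampled monthly
from early infancy into the fourth year of life. This vignette documents the
statistical machinery, the choices behind its defaults, and what the
package's synthetic-cohort tests do and do not demonstrate.

## Data model

Count tables are wide tibbles: a `sample_id` column followed by one integer
column per taxon. Metadata splits into per-sample records (`subject_id`,
`age_days`, and the derived `age_months`), per-subject static covariates
(delivery mode, sex, site, HLA group, ...), and a long table of dynamic
covariate event windows (`covariate`, `start_day`, `stop_day`, with `NA`
for open-ended windows). Month labels use `floor(age_days / 30.44)`; study
reports typically give only month labels, and flooring makes "month 3" mean
"has completed 3 months", which is the interpretation we adopt (the divisor
is configurable in `age_to_month()`).

Rarefaction subsamples reads without replacement (multivariate
hypergeometric), the convention of the QIIME era; samples under the target
depth are excluded rather than carried unrarefied, since downstream
diversity and community-typing analyses assume equal effort. The
conventional depths are 3,000 reads for 16S amplicon tables and 100,000 for
shotgun metagenomic tables (`rarefaction_depths()`).

## Dirichlet-multinomial mixture community typing

Samples are binned into community types with a finite mixture of
Dirichlet-multinomial (DM) components. The DM log pmf includes the
multinomial coefficient, making it a proper pmf (the coefficient cancels in
responsibilities, but keeping it makes the per-sample log-likelihoods and
evidence comparable across K). All likelihood terms are evaluated in
log-gamma space, and every term involving a zero count vanishes, so the
implementation touches only the positive cells of the count matrix.

`fit_dmm()` runs EM: log-sum-exp responsibilities in the E-step; in the
M-step, mixture weights are responsibility means and each component's
Dirichlet vector is updated by the weighted fixed-point iteration
(a Minka-style minorise-maximise step, three inner iterations per M-step by
default). Components are initialised from a k-means partition of
square-root proportions. If a component loses all responsibility
(max responsibility < 1e-6) it is reseeded from the worst-fit sample; the
NLL trace records only genuine EM steps, which are monotone.

`laplace_score()` evaluates the negative Laplace-approximate log evidence in
the log parameterisation `lambda = log(alpha)`, with an independent Gaussian
prior on each `lambda` (mean 0, variance 10 — broad, so it penalises only
degenerate `alpha -> 0` directions; configurable). The Hessian of the
negative log posterior is taken block-diagonal per component with expected
responsibilities; each block is diagonal-plus-rank-one, so its log
determinant costs O(S) via the matrix determinant lemma, with a regularised
eigendecomposition fallback for non-positive blocks. The free parameter
count is K x S.

`select_k()` fits a ladder of K values and returns the K with the lowest
score. Mixture EM at one K is prone to local optima, and uneven optimisation
across K is the dominant source of selection noise; `select_k()` therefore
warm-starts each K from the previous K's solution by splitting a candidate
component (worst weighted per-sample fit first, then largest) along its
internal 2-means partition, in addition to fresh k-means restarts. On the
synthetic cohort this reduced the spread of neighbouring-K scores by an
order of magnitude and made the planted K the reproducible minimiser.

## Developmental phases

`phase_slope_test()` regresses each response (top-five phylum relative
abundances and Shannon diversity) on age in months within fixed phase
windows — developmental (months 3-14), transitional (15-30), stable
(>= 31) — and tests the slope with subject-clustered standard errors
(`sandwich::vcovCL`, t reference with subjects-minus-one degrees of
freedom). This is a deliberate simplification of subject-level
random-intercept mixed models: for testing a population-average slope the
cluster-robust estimator has the same null behaviour, which the suite
verifies by type-I calibration. No multiplicity correction is applied across
the six responses by default (per-response significance is reported, as is
conventional for this display); a BH option exists. Phases are labelled
developmental-like (all responses change), stable-like (none), or
transitional-like (some). When the *label* is the quantity of interest — a
joint claim over six correlated tests in each of three windows — the
package's own analyses run the slope tests with the BH option at a 1%
family level: under per-response testing at 5%, a truly static phase would
fail to earn the stable label roughly a quarter of the time purely by
multiplicity, and even BH at 5% mislabels one stable cohort in twenty. The
strict level costs nothing in the developmental window, where slope
p-values sit many orders of magnitude below any reasonable threshold.

Transitions between community states are counted between consecutive samples
of a subject, not calendar-adjacent months, because monthly sampling has
~10% missed visits; an edge's frequency is its count over its origin node's
count, and edges under 4% frequency are flagged hidden (not dropped) to
mirror the conventional display rule.

## Microbiota age and MAZ

A regression forest predicts chronological age from relative abundances,
trained on a healthy reference: full-term (> 37 weeks), vaginally delivered,
breastfed children with at least 10 samples, capped at 150 randomly drawn
subjects. The full-scale configuration is 10,000 trees with n/3 features per
split; the package defaults are 500 final trees and 150 per
cross-validation fit, which on the synthetic cohort leaves the selection
curve and held-out accuracy unchanged while keeping a desk-scale runtime
(the acceptance run uses 400/100 on a 90-subject cohort). Feature selection
is recursive halving on cross-validated MSE with folds split by subject —
never within a subject, a leakage guard the tests assert — and ties resolve
toward fewer features; "minimise the CV error curve" operationalises the
percentage-increase-in-MSE criterion whose exact cut-point is ambiguous in
the source literature.

Microbiota age is the forest prediction; MAZ standardises it against the
reference per integer month bin: `(microbiota age - reference median) /
reference SD`. Reference statistics use the model's predictions on the
reference samples themselves, so reference per-bin median MAZ is exactly
zero by construction; months missing from the reference fall back to the
nearest bin with a warning. Model features absent from new data are imputed
as zero (absence in a rarefied profile), with a warning.

## Covariate screening and per-taxon associations

Dynamic covariates are classified per sample as before / during / after an
event window, or never when the subject has no event. Samples are stratified
into the eight closed month windows 3-6 through 27-30 plus 31-40, keeping
each child's first sample per window so that fixed-effect models apply.

`envfit_factor()` fits a factor onto an NMDS ordination:
`r2 = 1 - SS_within / SS_total` over the coordinates, with a permutation
p-value `(#{r2_perm >= r2_obs} + 1) / (B + 1)` from seeded label shuffles
(B = 10,000 in final screens; tests use smaller B). The implementation is
in-package for full control of seeding and is verified against
`vegan::envfit` to 1e-10. BH adjustment is applied across the covariate set
within each window (matching the per-window display convention; a global
family is a configuration choice away), and `q < 0.05` is flagged.

`fit_feature_models()` is the per-taxon screen: arcsine-square-root
transformed relative abundance regressed on a target covariate plus the full
adjustment set, BH across features, `q < 0.25` reported; features under
0.01% mean relative abundance and covariates with more than 10% missingness
are excluded. Boosting-based covariate pre-selection from the original
multivariate framework is intentionally omitted — all declared covariates
enter every model — and mixed effects reduce to fixed effects because the
windowed first-sample design has no repeated measures. "Minimum percentage
relative abundance" is read as a mean-abundance filter (a prevalence variant
is configurable).

## Matched case-control stability

Pairs are 1:1 matched on site and sex. For sample-level analyses, each case
sample greedily claims the unused control sample nearest in day of life
(chronological order; the source convention does not specify conflict
resolution, and greedy matching makes the result independent of input
order), retained only when the day gap is within 20% of the case sample's
day of life — the denominator choice is configurable since "±20%" is
ambiguous.

`clr_fit()` maximises the exact 1:1 conditional likelihood — logistic
regression without intercept on within-pair differences — by Newton-Raphson
with an observed-information covariance; complete separation triggers a
coefficient cap at |beta| = 15 and a non-converged flag. The genus screen
enters the top 50 genera as `log2(count + 0.01)` with BH across genera;
stability screens compute per-subject unique-state and transition counts in
windows anchored at the case's diagnosis day for both pair members (window
edges closed on the early side, open on the late side).

## The synthetic cohort

`generate_cohort()` emulates the structure of a monthly-sampled infant
cohort: 10 planted community types over a 60-genus panel spanning the five
dominant phyla; a sticky latent chain whose month-indexed target mix drifts
from Bifidobacterium/Proteobacteria-dominated types through mixed
transitional types to diverse Firmicutes types, linearly between anchors at
months 3, 14 and 24 and constant afterwards — planting a developmental
phase (3-14), a transitional phase (15-30 with drift through month 24) and
a genuinely stationary stable phase (>= 31); covariate effects as
multiplicative Dirichlet-mass shifts (while active, breastfeeding boosts
Bifidobacterium x1.7 and carries a background signature — milk-adapted
Actinobacteria up, solid-food clostridia down — that displaces whole
compositions without touching cluster-defining taxa; vaginal birth x1.7 on
Bacteroides-type genera for the first year; weaning x1.4 on a Firmicutes
set); and a monotone maturation tilt
(amplitude 0.8 on the log scale, plateauing at month 24) on
"chronometer" genera that are deliberately not cluster-defining dominants.
That last separation matters: effect sizes large enough to dominate a
cluster's own signature would genuinely split the planted mixture
components, making the planted K unrecoverable by any correct model-selection
procedure. Sequencing depth is exactly 3,000 reads per emitted sample;
visits are missed independently with probability 0.10. Breastfeeding stops
at a lognormal median of ~9 months (sdlog 0.4), caesarean probability is
0.25, and 22 covariates (9 dynamic, 13 static) are emitted to mirror a
realistic screening set. KO profiles assign each detected species a
repertoire of synthetic KEGG-module orthologues — an HMO-utilisation-like
module only in Bifidobacterium, butyrate production in late-phase
Firmicutes, deliberately partial carriers for incomplete calls — with
Poisson counts proportional to taxon reads.

`generate_paired()` adds 1:1 case-control structure: shared matching
factors, a diagnosis day after the case's first sample, and optional planted
effects (a binary-exposure log odds ratio, a pre-diagnosis genus abundance
shift, or a transition-rate increase implemented as reduced stickiness).

What passing tests on this generator show: the estimators recover planted
truth of realistic magnitude at realistic sample sizes, and calibrate
correctly under planted nulls. What they do not show: robustness to real
cohorts' visit-compliance patterns, sequencing batch structure,
strain-level variation, or compositional effects not representable as
Dirichlet-mass shifts — the generator makes no claim of biological realism
beyond its planted structure.

## Numerical choices and limitations

- EM convergence: relative NLL change under 1e-6 (500 iteration cap);
  model-selection ladders use 1e-5/200-250 since the Laplace score is flat
  at that resolution. Dirichlet parameters are floored at 1e-8.
- Problem sizes: the model-selection acceptance run uses ~600 samples at
  depth 3,000 over K = 1..15; phase and maturation runs use 60-90 subjects.
  These sizes were chosen as the smallest at which the planted structure is
  comfortably identifiable.
- NMDS uses `vegan::metaMDS` on a precomputed Bray-Curtis matrix (k = 2
  default; ties in the monotone regression take vegan's primary treatment).
  Stress near zero triggers vegan's degenerate-solution warnings on toy
  inputs; they are benign.
- Assignment ties (equal responsibilities) resolve to the lowest cluster
  index; cluster labels are ordered by decreasing mixture weight.
- `arcsin_sqrt()` clamps inputs within 1e-12 of [0, 1] and errors beyond.
- The Laplace score's Gaussian prior variance (10) is a package default;
  the behaviour contract is correct-K recovery on separated data, not score
  equality with any particular legacy implementation.
- Full KEGG boolean module grammar (complexes, optional steps) is out of
  scope; module definitions are flat step lists with alternatives.
- UniFrac, OTU calling, read mapping and minimum-pathway reconstruction are
  upstream of this package's inputs and intentionally absent.
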