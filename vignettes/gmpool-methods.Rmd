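---
title: "Multi-site gray-matter classification: models, resampling and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site gray-matter classification: models, resampling and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmpool)
```

`gmpool` studies a pooled multi-center design: voxel-based-morphometry
gray-matter probability maps from several scanners, one linear
maximum-margin classifier, and the question of whether pooling
heterogeneous sites helps or hurts the prediction of a subject
characteristic — sex as a strong biological benchmark, or the
continuous-versus-remitting illness course after a first psychotic
episode as the clinically interesting, much weaker target. This vignette
explains the models, every tunable parameter that matters, the synthetic
generator the tests run on, and the design decisions taken where the
design was genuinely open.

## Outcome labelling from episode histories

Follow-up information enters as interval histories: psychotic episodes and
remission periods, each a `(start_day, duration_days)` pair inside the
follow-up window. The course rule, with "six months" pinned at 183 days
(`threshold_days`, a visible parameter):

* **continuous** — no remission of more than six months anywhere in
  follow-up;
* **remitting** — at least one remission of at least six months and no
  episode longer than six months; a history consisting of a single episode
  of at most six months is also remitting, even when no remission interval
  was recorded;
* **excluded** — both a long remission and a long episode are present, so
  the patient fits neither extreme group and is dropped from outcome
  analyses (but not from sex analyses).

The two clauses quote the boundary differently (">" versus "at least"),
which would make a remission of exactly 183 days both "not long" for the
continuous clause and "long" for the remitting clause. We pin one
convention — a remission ≥ 183 days is long in both clauses — so that the
three labels are exhaustive and mutually exclusive. The test suite checks
this against an independently coded truth table on every history with up
to two episodes and two remissions on a 30-day grid (about 111,000
histories), and checks monotonicity: lengthening the longest remission can
never turn a remitting patient into a continuous one. Histories in which
short episodes and short remissions alternate for years are labelled
continuous by the truth table above; that case is a convention of this
package, since no clinical definition covers it explicitly.

## From volumes to features

Maps are per-voxel gray-matter probabilities on a common grid (default
16×16×16 at 2 mm — a desk-scale grid with the resolution of typical
2 mm resampled analyses; real 91×109×91 volumes work unchanged).
Processing order is smooth, then mask, then flatten:

1. **Smoothing** (`gm_smooth`): separable Gaussian convolution,
   per-axis `sigma = fwhm / (voxel_size · 2√(2 ln 2))`; default 4-mm FWHM,
   the conventional noise-reduction kernel for these analyses. Boundary
   handling is mirror padding, which conserves mass for interior sources
   (the standard choice in neuroimaging smoothers); `fwhm = 0` is the
   identity, and outputs are clipped to [0, 1] after convolution so maps
   remain probabilities. The unclipped operator is exactly linear and is
   tested against a brute-force direct convolution to 1e-10.
2. **Masking** (`build_mask`): a voxel enters the feature space when the
   cohort-mean probability is at least `threshold` (default 0.03). A
   group-level rule is used so every subject shares one feature space,
   which the SVM requires; a stricter per-subject variant
   (`rule = "all"`) is available because the choice between the two is not
   dictated by anything beyond the shared-space requirement.
3. **Flattening** (`extract_features`): masked voxels in R's native array
   order (first index fastest) — any fixed order works, but it must be
   pinned so weight vectors can be folded back onto the grid
   reproducibly.

## The classifier

`linsvm` fits the usual soft-margin hinge-loss problem with a linear
kernel. The quadratic program is solved by libsvm (via `e1071`) — the
appropriate delegation, since the contribution here is the surrounding
design, not a new solver — but the package owns the contract: explicit
weight vector and bias, decision values `w·x + b`, a pinned orientation
(second factor level is the positive class; `sign(0)` predicts positive so
confusion counts are reproducible), and determinism. The tests hold this
contract against an independent interior-point QP solver on small toys to
1e-6. Features are not rescaled by default because gray-matter
probabilities already share the [0, 1] scale; optional per-feature
standardization is fit on training data only.

Inside cross-validation the same solver runs in Gram space: for a linear
kernel the dual depends on the data only through `XXᵀ`, so each fold
trains on a Cholesky factor of the training-rows Gram submatrix. This is
algebraically the same optimization (the suite asserts equality against
the explicit-feature path) and makes the permutation experiments feasible
at high voxel counts.

The penalty `C` is chosen by nested cross-validation: an inner stratified
5-fold loop evaluates each candidate on mean balanced accuracy, with ties
broken toward the smallest `C` (larger margin). The default grid is
`10^(-3..3)`; neither a published grid nor fold count exists for this
design, so both are declared defaults, not inferences.

## Resampling and inference

**Balanced subsampling** (`balanced_subsample`): within each site, all
minority-class subjects are kept and an equal number of majority-class
subjects is drawn uniformly; a site short of majority subjects borrows its
deficit from other sites' unused majority members, so overall class counts
are exactly equal. This mirrors building a balanced sex model from all 133
females plus 133 site-matched males.

**Site-matched leave-two-out CV** (`leave_two_out_cv`): within each site
the two classes are randomly matched into disjoint pairs; each fold holds
out one pair, selects `C` on the remaining subjects, trains, and records
the pair's decision values. Whether all cross-class same-site pairs should
be enumerated or a single matching drawn is not determined by the design;
we draw one random matching per run and let the bootstrap ensemble average
over matchings, which keeps every subject tested exactly once per run.
Unpaired remainders (class imbalance at a site, or a single-class site)
stay in every training set but are never tested — training-set retention
maximizes data use — and are counted in `n_unpaired`. Per-site pairing
seeds derive from the site label alone, so removing one site never changes
the folds of the others.

**The ensemble** (`bootstrap_ensemble`) repeats balanced subsample +
leave-two-out `n_bootstraps` times (default 100) with independently
derived seeds and averages the metrics, overall and per site, over runs
where they are defined.

**Metrics** (`compute_metrics`): PPA = TP/(TP+FP), NPA = TN/(TN+FN) for
outcome models (positive class = continuous); per-class accuracies
(sensitivity/specificity form, positive class = male) for sex models.
Zero denominators yield `NA` — undefined, not zero — and drop out of
averages.

**Permutation test** (`permutation_test`): class labels are shuffled
within site (preserving the site structure the matched CV assumes), the
full pipeline re-runs, and `p` is the fraction of null metrics ≥ the
observed one. Permutations reuse the observed run's seed stream so only
the labels differ. The plain estimator (no +1 smoothing) is the default so
`p = 0` is representable; `smoothed = TRUE` gives the add-one variant.
Default 1000 permutations.

## The synthetic generator

`generate_subject_map` produces, in order: baseline template, plus
`effect_size × noise_sd` inside each applicable effect region, plus site
intensity offset, times site gain, plus per-voxel Gaussian noise, blurred
by the site point-spread FWHM, clipped to [0, 1] last. Scaling effects by
the site noise SD makes `effect_size` read as a per-voxel Cohen's d, which
is what makes parameter-recovery statements well defined. The baseline is
a deterministic "pseudo-brain": six fixed Gaussian blobs inside an
ellipsoid, values in [0.05, 0.95] inside and 0 outside, giving the mask a
realistic in/out structure without external atlases.

Site profiles default to mild differences (offsets ±0.02, gains
0.95–1.05, noise SD 0.05, blur 2–4 mm FWHM). No quantitative description
of real inter-site intensity differences exists for this design, so these
magnitudes are chosen once for test sensitivity rather than fitted to
anything. The default planted sex effect is strong (d = 2 — sex is the reliably
separable benchmark here) and the course effect weak (d = 0.5).

What the generator does **not** emulate: anatomy, tissue-class
correlations, registration error, nonstationary noise, or any
site-by-effect interaction. Passing tests therefore show the *machinery*
is correct and calibrated — they say nothing about whether real illness
course is predictable from real maps.

All randomness flows from one master seed through a counter/key hash
(`derive_seed`), so cohorts are pure functions of their configuration and
any single fold can be replayed in isolation.

## Experiment scales used by the test suite

The suite runs everything at desk scale, chosen as the smallest sizes at
which the statistical statements are meaningful: null calibration uses 50
effect-free cohorts (16³ grid, 2 sites, 20 subjects/class) with 200
permutations each, checking the rejection rate at α = 0.05 against the
exact binomial band; planted-effect recovery uses d ∈ {0, 1, 3} in a
50-voxel region with n = 40; the pooling experiment uses three sites
(10/30/30 subjects) sharing a d = 0.5 sex effect, comparing the small
site's accuracy under the pooled model versus its single-site model,
averaged over 20 replicate cohorts because a 10-subject site's single-site
accuracy fluctuates strongly between cohorts. Headline-scale settings
(100 bootstraps, 1000 permutations) remain the defaults of
`experiment_config()`.

## Known limitations

* The generator's additive, spatially homogeneous site model is far
  simpler than real scanner effects; conclusions about pooling transfer
  only qualitatively.
* Single-matching leave-two-out means per-run metrics depend on the drawn
  matching; use the ensemble average, not single runs.
* The permutation test re-runs the pipeline with the same subsampling seed
  stream; this isolates the label association but does not propagate
  subsampling variability into the null.
* `p = 0` from the plain estimator should be read as `p < 1/n_permutations`.
* No multiple-comparison correction across sites or models is applied, by
  design.
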