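---
title: "FaceTrust methods: facial dimorphism morphometrics and Trust-Game statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FaceTrust methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`FaceTrust` couples two halves: geometric morphometrics of 2-D facial
landmark configurations, and behavioral statistics for a five-game
binary-choice Trust-Game design (one anonymous game, then four
personalized games — two same-sex, two opposite-sex — played after seeing
a short video of the partner). This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
cohort generator does and does not emulate.

## Landmark scheme and superimposition

Configurations carry 70 points: 36 fixed anatomical landmarks and 34
sliding semi-landmarks on three curves (facial outline, 20 points; each
eyebrow, 7 points). The curve membership is an editable YAML file
(`inst/extdata/face70_scheme.yaml`); each curve's endpoints are fixed
anchors that never slide. The packaged scheme reproduces the point counts
and topology of the classical frontal-face protocol, not its anatomical
definitions, which live in specialized atlases.

Generalized Procrustes superimposition removes position, scale and
orientation: each configuration is centered, scaled to unit centroid size
(`size = sqrt(sum((x - centroid)^2))`), and rotated onto the consensus,
which is recomputed as the arithmetic mean of the aligned shapes until its
root-mean-square change falls below `tol` (default `1e-8`, cap 100
iterations; hitting the cap flags `converged = FALSE` rather than
erroring). Only proper rotations (determinant +1) are used: faces must
never be mirrored by the alignment. TPS digitizers store image
coordinates with a down-positive y-axis; `readTPS()` flips to the
mathematical up-positive convention so grids and morphs render upright.

### Sliding semi-landmarks

Semi-landmark positions along a curve are arbitrary, so they are treated
as nuisance directions: each specimen's semi-landmarks are moved along
their local tangents (central differences of the curve neighbors;
undefined tangents hold the point fixed with a warning) to minimize the
thin-plate-spline bending energy of the specimen's displacement from the
consensus. The bending-energy matrix comes from the 2-D radial basis
`U(r) = r^2 log r`; it is symmetric positive semi-definite and vanishes
exactly on affine fields. Two deliberate choices:

* **Joint rather than per-point minimization.** All sliding amounts of a
  specimen are solved in one small linear system (the exact minimizer of
  the quadratic energy restricted to tangent movements, with a `1e-10`
  relative ridge for well-posedness). Independent per-point 1-D
  minimizations applied simultaneously can overshoot and are not
  guaranteed to decrease the energy; the joint solve is, and the
  non-increase is asserted in the test suite.
* **A finite number of sliding passes.** Sliding is interleaved with the
  superimposition for the first `slideIters` iterations (default 5), with
  the kernel rebuilt on the updated consensus each pass, after which the
  semi-landmarks freeze and the superimposition converges tightly. A
  fresh full relaxation at every iteration re-excites a small tangential
  smoothing drift on noisy data (the consensus keeps sliding along its own
  outline at an RMS change around `5e-4`, far above `tol`), so "slide
  until 1e-8" is not a fixed point; after five passes the per-pass
  movements are far below digitization noise.

## Shape statistics

**Permutation MANOVA.** Total sum of squared Euclidean distances among the
flattened Procrustes coordinates is partitioned by predictors entered
sequentially (entry order = column order), via the Gower-centered
distance decomposition `G`; the SS of a term is `tr(H G) - tr(H' G)` for
its and the previous hat matrices. Significance permutes the raw
observation labels (not residuals), recomputing the full decomposition;
`p = (exceedances + 1) / (nPerm + 1)`, with the seed recorded in the
result. An explicit permutation matrix can be supplied for exhaustive
enumeration (then `p` is the plain exceedance fraction, identity
included). Constant responses flag the result instead of dividing by
zero. Ties and duplicate configurations are left as they are — no jitter.

**Repeatability.** The same SS machinery decomposes replicate
digitizations by individual: with `r` replicates,
`sigma2_among = (MS_among - MS_within)/r` and the repeatability is
`sigma2_among / (sigma2_among + MS_within)`, clamped to [0, 1].

**Femininity scores.** With ~145 samples and 140 coordinate dimensions
the within-group scatter is singular, so the two-group Fisher
discriminant (female vs male) is computed after projecting onto principal
components — components up to 95% cumulative variance by default, hard
cap `n - 3` — and the axis is mapped back to coordinate space for
display. Scores are oriented female-high; an explicit sign check makes
the orientation deterministic. Within-sex z-scores are provided in two
contexts: over the full sample (`z_full`) and, because a small stimulus
subsample need not be symmetric around the full-sample means, over a
designated subsample with its own per-sex means and SDs (`z_partner`).
Zero within-group SD is an error, not a silent NaN.

## Trust-Game statistics

Payoffs follow the game rules (keep: 50/0; entrust: return and
150 − return; totals conserve 150 or 50 — a property test). Decisions are
settled post hoc against each partner's *anonymous* decision; anonymous
games match a seeded uniformly random partner. Behavioral measures:

* **Switches and shifts.** Per personalized interaction, the trust switch
  (+1 distrust→trust, −1 trust→distrust, 0 unchanged) and the **signed**
  return shift (personalized − anonymous points). The sign is deliberate:
  direction sensitivity is what the per-video summaries and the linear
  shift model need; an unsigned difference would fold increases onto
  decreases.
* **Fleiss' kappa** treats a subject's five decisions as interchangeable
  ratings of one disposition (items = subjects, ratings = settings);
  returns are binarized fair (= 100) vs non-fair. Complete cases only;
  `Pe = 1` (a single observed category) flags the result as undefined
  rather than reporting 1. Significance uses the large-sample null SE.
* **GEE.** Marginal regression with robust sandwich covariance and Wald
  X² = (B / robust SE)² per coefficient. The working correlation is
  exchangeable by default with the moment estimator capped at 0.95;
  the switch-direction models use the *independence* structure because a
  subject's switch direction is constant across their games (it is fixed
  by the anonymous baseline), which drives the exchangeable correlation to
  1 and makes that working model singular. With robust SEs the choice is
  second-order for inference. Binomial fits abort with a separation
  message (naming the worst predictor) once linear predictors exceed ±30.
* **Major-axis regression** (both variables carry error) takes the slope
  from the leading eigenvector of the 2×2 covariance; association
  strength and significance are the squared Pearson correlation and its
  t-test.

## The synthetic cohort generator

The generator exists so every stage is testable with known ground truth.
Its defaults are the study conditions of the motivating design and were
fixed once, against published marginal rates, before being frozen:

* **Faces** (`faceSimConfig`): 72 males + 73 females; coordinates =
  template + (±delta/2) × dimorphism field + individual variation
  (`sigmaIndividual = 0.03` template units per coordinate) + per-observer
  digitization error (`sigmaDigitization = 0.004`, which puts two-observer
  repeatability near 0.96) + a random similarity transform per sample so
  superimposition is genuinely exercised. The hand-authored unit-norm
  dimorphism field encodes the qualitative European-face contrast: males
  with longer/wider/more robust jaws, thinner lips, lower and more medial
  brows, smaller visible eye areas, and a left-side bilateral-asymmetry
  component. `delta = 0.275` was set by `calibrateDimorphism(0.07)`
  (bisection, 20 replicate simulations per probe, tolerance 0.005) so sex
  explains ≈7% of shape variance at n = 145.
* **Behavior** (`behaviorSimConfig`): 89 + 87 subjects, 10 videos per
  sex. Trust is Bernoulli with log-odds `alpha + theta_i` (anonymous)
  plus `betaPersonal + betaPartnerSex·male(partner) + betaFem·z +
  betaFemByDmSex·male(subject)·z` (personalized). Defaults
  `alpha = 1.85`, `thetaSd = 3.0` give ≈70% trust with κ ≈ 0.45
  consistency; `betaPersonal = 0.95` with `betaPartnerSex = -1.5` centers
  the partner-sex contrast on the anonymous baseline (female partners
  raise trust, male partners lower it, matching the per-video shift
  pattern); `betaFem = -1.0` and `betaFemByDmSex = +0.8` make high
  femininity reduce elicited trust with the reduction attenuated in male
  deciders. Returns follow a cumulative-logit model: a latent subject
  fairness propensity (`fairSd = 10`) plus a personalization location
  drift (`returnDrift = -1.2`) plus logistic noise, cut at
  `(-12.5, -4.6, -0.4)` into 0/50/75/100 — yielding ≈46–50% fair returns,
  ≈80% within-subject return consistency (κ ≈ 0.83) and the observed
  preponderance of downward return shifts.

What the generator does **not** emulate: age effects on shape (age is a
null covariate, so the sequential age+sex decomposition demonstrates the
machinery at its null level); any coupling between a subject's trust
shifts and trustworthiness shifts (the major-axis stage therefore sees
null-level associations on synthetic data); attractiveness, sexual
orientation, photographic artifacts, or realistic landmark covariance
structure (individual variation is isotropic). Passing tests on synthetic
data therefore validate the estimators and their calibration, not any
empirical claim about real faces.

Note one estimand subtlety exploited by the parameter-recovery tests: GEE
estimates population-averaged effects, so with a subject random intercept
(`thetaSd > 0`) the marginal coefficient is attenuated relative to the
conditional one. Recovery/coverage studies of a −1.5 partner-sex effect
generate with `thetaSd = 0` (a marginal generating model); pipeline-level
checks on the full model assert effect *directions*, which survive
attenuation.

## Problem sizes and numerical conventions

The test suite runs the studies at desk scale, chosen to keep the whole
suite near a minute while leaving comfortable Monte-Carlo margins: 500
null simulations (n = 40, 199 permutations) for the type-I error of the
permutation MANOVA; 200 replicates × 500 subjects for GEE coverage;
20 replicate simulations per calibration probe and 20 out-of-sample seeds
for the dimorphism calibration; 20 pipeline replicates for end-to-end
sign recovery. Exhaustive permutation enumeration is used at n = 6.
`scripts/acceptance.R` runs the full-size synthetic study (145 faces,
176 subjects, 10,000 MANOVA permutations) from one master seed.

Other conventions: two-sided tests everywhere; no multiple-testing
correction is applied anywhere in the pipeline (matching common practice
for these designs — readers should treat marginal p-values accordingly);
Mann–Whitney U is reported as the smaller of the two group statistics,
with exact enumeration when `n_x · n_y ≤ 400` and no ties; the
chi-squared test applies no continuity correction; degenerate inputs
(coincident points, duplicate TPS source points, single-category
ratings, zero variance) raise errors or flagged results rather than
silent numbers.

## Known limitations

Two-dimensional shapes only; no curve resampling from pixel outlines; no
image processing or automatic landmarking; two-group discriminants only;
the schematic template face and dimorphism field are qualitative
emulations. The GEE implementation covers the binomial-logit and
gaussian-identity families with exchangeable/independence working
correlations — the set these analyses need — not the full GLM family zoo.
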