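---
title: "Models and methods in predinf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in predinf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predinf)
```

# The task and its statistics

The helicopter predictive-inference task asks for a prediction of a hidden
Gaussian mean that occasionally jumps. All positions live on a screen scale
of 0–300 "screen units". Per trial, with hazard `H` (default 0.1) the
helicopter relocates to a uniform draw over the screen; a bag is dropped at
`χ_t ~ N(μ_t, σ²_N)` with `σ_N` constant within a block (defaults 10 and
25, one block of 200 trials each); with probability 0.1 the helicopter is
visible ("catch trial"); bag contents are gold or worthless rocks with
probability one half. Bags that would fall off screen are redrawn by
default (`bag_edge = "redraw"`); truncation to the edge is available, and
the choice matters only in the rare case of a helicopter within ~2σ of an
edge. Catch trials and change points are sampled independently. Gold
payouts fall off linearly with bucket–bag distance over a configurable
width (`coin_falloff = 100` units; the payout function is a convenience for
simulation scoring, not part of any inference).

# The normative model

The model tracks two latent quantities per trial: the **change-point
probability** `Ω_t` (how likely the newest outcome followed a relocation)
and the **relative uncertainty** `τ_t` (how much of the total predictive
variance is uncertainty about the helicopter rather than bag noise).

With `U = 1/300` the uniform outcome density after a change,

```
Ω = U·H / ( U·H + N(δ; 0, σ²_N / (1 − τ)) · (1 − H) )
```

Uncertainty propagates by moment-matching the two-branch posterior (change
vs no change), whose means differ by `δ(1 − τ)`:

```
σ²_μ' = Ω σ²_N + (1 − Ω) τ σ²_N + Ω (1 − Ω) (δ (1 − τ))²
τ'    = σ²_μ' / (σ²_μ' + σ²_N)
```

and the belief moves by `α δ` with `α = Ω + (1 − Ω) τ`.

On catch trials the visible helicopter is treated as a Gaussian cue centred
on the true mean with s.d. `σ_H` (default 10 units, reflecting perceptual
ambiguity about the image centre); belief and cue combine by relative
precision, `w = σ²_H / (σ²_H + σ²_μ)` being the weight on the current
belief, and the posterior variance is the harmonic combination. The
combination is applied after the bag-driven update of the same trial, i.e.
at the end of each visible trial.

**Initialization.** Internal state starts each block from a flat prior:
`τ = 1` with the belief at the screen centre. The first outcome is then
absorbed with `α = 1`, which is identical to initializing the belief at the
first bag with `τ = 0.5`. Two useful consequences: with `H = 0` the model
is exactly the running mean of the observed bags with `α_t = 1/t` (asserted
to 1e-10 in the tests), and duplicating a session as additional blocks
exactly doubles the fit likelihood. `τ = 1` appears only on the recorded
first trial of a block, which every downstream analysis excludes.

**Conditioned mode.** For regressors and fitting, the recursions for
`Ω`/`τ` are evaluated on the subject's own prediction errors rather than
the outcomes that generated them — an unsurprising outcome for the model
may be a large surprise for a subject whose prediction differed. Only `δ`
enters the recursions; the subject's actual bucket positions anchor the
predicted updates on catch trials.

A deliberate non-feature: the full run-length-distribution Bayesian model
is not implemented; the reduced two-branch recursion above is the model
under study, and exact closed forms (running mean, conjugate posteriors)
serve as test oracles instead.

# Flexible deviations

`flexible_params()` nests the normative model at neutral values (asserted
bit-identical in the tests) and exposes:

- **Hazard `H`**: the assumed relocation rate, free in fitting
  (logit-scale prior centred on 0.1).
- **Surprise sensitivity `SS ∈ (0, 1]`**: the change-point likelihood
  ratio is raised to the power `SS` and renormalized,
  `odds' = odds^SS · (H/(1−H))^(1−SS)` — a tempering that compresses the
  posterior log-odds towards the hazard prior. It preserves the endpoints
  0 and 1, is the identity at `SS = 1`, and discounts large surprises the
  most. The alternative of exponentiating only the uniform change-point
  density was rejected: since `U < 1`, that *raises* baseline surprise and
  cannot blunt responses to large errors, which is the phenomenon the
  parameter exists to express.
- **Uncertainty underestimation `UU ≥ 1`** (stored and fitted in log
  units): divides `σ²_μ` once per trial, after propagation and before
  `τ'`, so underestimated uncertainty also sharpens subsequent surprise via
  the reduced total variance — the behavioural signature is learning driven
  by surprise alone (`α → Ω` as `UU → ∞`).
- **Perceived noise**: `σ̃_N = s_mult·σ_N + s_add`, floored at 0.5 units,
  substituted for `σ_N` everywhere inside the model and nowhere in the
  generative task. With only two noise conditions this is equivalent to
  fitting the two perceived noise levels freely.
- **Noise dispersion `ν`**: uncertainty about the noise level itself,
  represented as a weighted mixture over scale factors on the total
  predictive s.d. — scales on a uniform grid over [0.1, 100] (200 points by
  default, so the region around 1 is resolved) with weights from an
  inverse-gamma density with shape `ν` and scale `ν + 1`, putting the mode
  at scale 1 (unbiased perception at the mode; smaller `ν` = more
  dispersion). The mixture enters both the outcome-predictive density
  inside the `Ω` computation and the update-residual likelihood, where
  component s.d.s combine in quadrature with the response s.d. The same
  construction generates data (a scale drawn per trial), keeping model
  recovery well posed.
- **Response variability `UV`, `LRV`**: realized updates are Gaussian
  around the deterministic model update with s.d. `UV + LRV·|δ|` (units:
  screen units, and units per unit error), interpreted as motor/update
  noise and learning-rate selection noise.

# Fitting

`fit_subject()` maximizes the log posterior of observed updates given
prediction errors: per-trial Gaussian (or mixture) response likelihoods
summed over included trials, plus weak independent priors favouring
normative learning parameters — `logit H ~ N(logit 0.1, 2²)`,
`SS ~ N(1, 0.5²)` (bounded to (0, 1]), `log UU ~ N(0, 2²)`; response and
noise-perception parameters carry bounds only. Optimization is L-BFGS-B on
a bounded, partially log/logit-transformed parameter vector from
`n_restarts` starts (the first at the normative point with a data-driven
`UV` guess, the rest jittered), `maxit = 200`, `factr = 1e8`; the model
recursion runs over *all* trials (state must evolve through excluded ones)
while the likelihood sums over included trials only. `σ_H` is fixed at 10
by default — the minimal model has five free parameters (`H`, `SS`,
`log UU`, `UV`, `LRV`) — and can be freed with `fit_heli_sd = TRUE`. Model
comparison uses BIC by default (AIC available), ties broken by fewest
parameters.

Recovery behaviour computed by the test suite at its chosen problem sizes
(two 200-trial blocks per subject, 3 restarts): the rank correlation
between true and recovered `log UU` across 20 subjects spanning
`log UU ∈ {0, 1, 2, 3}` exceeds 0.8, and a simulated old/young cohort with
a 1.2 offset in mean `log UU` (n = 20 per group) yields a significant
two-sample difference. One caveat established during development: the
noise-dispersion mixture is identified by the *tails* of the update
distribution, which the 15-unit exclusion rule (below) truncates; the
model-recovery test therefore preprocesses with `max_dev = Inf`. On
tail-truncated data the simpler Gaussian response model wins by
construction.

# The descriptive regression

`preprocess_trials()` computes `δ_t = χ_t − B_t`, `u_t = B_{t+1} − B_t` and
excludes (1) first and last trials of each block, (2) zero-error trials,
and (3) trials whose next bucket lands more than 15 units (configurable
`max_dev`) from every possible delta-rule update — the segment between
bucket and bag, unioned on catch trials with the segment between bucket and
helicopter. On near-deterministic normative agents the rule removes < 5% of
eligible trials; on the default synthetic cohort ~3%.

The design matrix contains the prediction error, its interactions with five
factors mean-centred within subject — surprise (`Ω`) and uncertainty (`τ`)
from the conditioned normative model, noise condition, trial value,
helicopter visibility — a helicopter term, and a centre-bias nuisance term
`(150 − B_t)`. The helicopter term is `visible · (μ_t − B_t)`, the pull
toward the visible helicopter: a raw `μ × visibility` product would omit
the matching `B` term and confound cue use with screen position. Weights
are inverse residual variances estimated from an unpenalized initialization
fit per subject, residuals pooled across subjects and variance computed in
sliding 10% windows of `|δ|` (nearest-window lookup; variances floored at a
configurable epsilon). The penalized weighted solve is
`β = (AᵀPA + R)⁻¹AᵀPy` with `R = λI` over all columns except the intercept
(shrink slopes, not the grand mean), `λ = 0.1`.

**Sliding bins.** Trials are ranked by `|δ|/σ_N`; 90 windows each hold 10%
of trials, with starts stepped evenly over the ranks so the full range is
covered and every bin holds 10% ± 1 trials. Within each window the five
interaction factors are **re-centred within the window** and the
interaction columns are residualized against the `δ` column (weighted
projection). This matters: inside a narrow window of relative error,
globally centred surprise/uncertainty/noise factors are nearly
deterministic functions of `|δ|`, leaving the `δ` coefficient confounded
with its interactions (in development, a fixed-learning-rate-0.5 agent came
out with per-bin `δ` coefficients anywhere between 0.24 and 1.0). With
window-local centring and orthogonalization the per-bin `δ` coefficient
*is* the bin's learning rate — a fixed-rate agent is recovered flat at
0.5 ± 0.05 across all 90 bins, and a normative agent shows the
characteristic rise of learning with relative error magnitude — while the
full-dataset fit keeps the global centring for interpretable interaction
coefficients. Regressors stay in natural units, so `δ`-type coefficients
read directly as learning rates.

# Group inference

Coefficient-by-bin matrices are smoothed per subject by a centred moving
average (default width 5 bins, edge-truncated) before testing. The
cluster-mass permutation test forms clusters as maximal runs of bins with
two-sided `p < 0.05` (per-bin one-sample t, or two-sample pooled-variance
t with constant degrees of freedom — chosen so the label-flip null is fully
vectorizable), scores them by `length × mean |t|`, and compares each
observed mass against the permutation distribution of the *maximum*
cluster mass (sign-flips of whole subjects for one-group tests, label
flips for group comparisons), which is the standard familywise-controlling
summary. Cluster p-values are `(1 + #{null ≥ obs})/(1 + n_perm)`; the
smallest achievable p is therefore `1/(1 + n_perm)`. Zero-variance bins
are excluded from cluster formation with a warning. The test suite checks
the familywise false-positive rate on null data (500 simulations × 200
permutations, 20 subjects × 90 bins) against the [0.025, 0.075] band.

**LOSO extraction** reads each subject's coefficient from the bin with the
maximum absolute between-group t-statistic computed over all *other*
subjects (lowest bin on ties). This removes the subject's own data from the
bin choice, which is what makes the per-subject values usable as predictors
in the age regressions. It does not make a *group mean* test on the
extracted values exact: the bin is still selected for extremeness by the
remaining subjects, and on null data such a test stays anticonservative
(though far less than extracting at the full-sample argmax, which is wrong
essentially always — both behaviours are asserted in the tests). Group
differences should be established by the cluster permutation test; LOSO
values feed individual-difference models.

Age models regress age on (1) an intercept, (2) the task-derived predictor,
(3) predictor plus Raven and OSPAN scores, compared by nested F-tests
`F = ((RSS_r − RSS_f)/(df_r − df_f))/(RSS_f/df_f)`; the key comparison adds
the predictor to the covariates-only model.

# The synthetic cohort

`generate_cohort()` draws per-subject parameters: young `log UU ~ N(1.5,
0.7)` (floored at 0), `LRV ~ |N(0.1, 0.05)|`, `UV ~ logN(log 4, 0.3)`;
the older group's `log UU` and `LRV` means are shifted by `cohort_effects()`
(defaults +1.2 and +0.15, the direction and rough magnitude of the
age-deficit pattern the package is designed to analyse). The
between-subject s.d. of 0.7 for `log UU` is chosen below the spread seen in
fitted human estimates, since those include estimation noise that the
generator should not duplicate. Ages are uniform on 20–30 and 60–80;
covariate scores are Gaussian with group offsets. Hazard and surprise
sensitivity are held at normative values across the cohort.

What the generator emulates: the task statistics above, agents whose
*latent state is driven by their own realized prediction errors* (exactly
matching the fitting model's assumption), response noise linear in `|δ|`,
bucket clamping to the screen. What it does not emulate: sequential
human artifacts (autocorrelated motor noise, lapses, drift, learning of the
hazard within a session), perceptual error on bag positions, and any
pupil-linked or neural quantity. Passing tests therefore demonstrate
internal consistency of model, fitting and inference machinery — parameter
and signature recovery when the generating process is in the model family —
not that human data satisfy these assumptions.

# Numerical choices and degenerate inputs

- `τ = 1` (flat prior) makes the Gaussian outcome density 0 and `Ω = 1`
  (or 0 when `H = 0`) without special-casing, since
  `exp(−δ²/∞)/√(2π·∞) = 0` in IEEE arithmetic.
- Perceived noise s.d. is floored at 0.5 units so `s_add` cannot drive the
  model degenerate.
- The response s.d. `UV + LRV·|δ|` must be positive for the Gaussian
  likelihood; the mixture likelihood tolerates `UV = LRV = 0` because
  component variances include the scaled total uncertainty, and underflow
  of all components raises an explicit error.
- Heteroscedasticity windows are floored at 10 trials and collapse to a
  single window (equal weights) when fewer than two windows fit; window
  variances are floored at 1e-6. The initialization regression uses a
  vanishing ridge (1e-8) so rank-deficient small datasets stay defined.
- Ridge solves report singularity explicitly at `λ = 0`; ties in model
  comparison go to the fewest parameters; ties in LOSO argmax go to the
  lowest bin.
- All stochastic stages take explicit integer seeds; `run_pipeline()` fans
  one global seed out to named per-stage streams so each stage is
  independently reproducible, and fixtures regenerate byte-identically.

Problem sizes in the test suite (10-block signature simulations, 20–40
fitted subjects, 500 × 200 permutation calibration) are chosen as the
smallest sizes at which the respective statistical assertions are stable
across seeds.

# Known limitations

- The exact published forms of the antecedent model's equations were fixed
  from the cited model family; the surprise-sensitivity transform in
  particular follows the tempering construction described above rather than
  any single canonical reference.
- The per-bin interaction coefficients from the windowed fit are noisy
  wherever a factor barely varies within a window; inference on
  interactions should use the full-design coefficients or the smoothed
  binned curves, not single bins.
- Subjects are fit independently; no hierarchical pooling.
- Fits use finite-difference gradients; with ~400 trials and 5–8 parameters
  a fit takes on the order of a second, and the mixture family several
  seconds, per restart.
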