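# predinf

Learning models and group analyses for change-point ("helicopter")
predictive-inference tasks.

In this paradigm a participant places a bucket where they believe a hidden
helicopter hovers on a 0–300 screen; on each trial the helicopter drops a
bag whose position is Gaussian around the helicopter (s.d. 10 or 25,
blockwise), the helicopter relocates with hazard `H = 0.1`, and on 10% of
trials ("catch trials") it becomes visible. The behavioural measure is the
trial-by-trial update `u_t = B_{t+1} − B_t` in response to the prediction
error `δ_t = χ_t − B_t` (bag minus bucket).

`predinf` implements, end to end and on purely synthetic data:

- **A reduced-Bayesian normative model.** Each trial it computes the
  change-point probability
  `Ω = U·H / (U·H + N(δ; 0, σ²_N/(1−τ))·(1−H))` (uniform post-change vs
  Gaussian no-change outcome density), propagates uncertainty by the
  mixture-variance recursion
  `σ²_μ' = Ω σ²_N + (1−Ω) τ σ²_N + Ω(1−Ω)(δ(1−τ))²`,
  `τ' = σ²_μ'/(σ²_μ' + σ²_N)`, and updates with learning rate
  `α = Ω + (1−Ω)τ`. Visible helicopters are combined as a Gaussian cue by
  relative precision. Run it generatively or conditioned on a subject's own
  prediction errors (`run_model()`).
- **A flexible model family** nesting the normative model: hazard
  mis-estimation, surprise insensitivity (tempering of the change-point
  likelihood ratio), uncertainty underestimation (`UU` divides `σ²_μ` each
  trial; log units), subjective noise perception, and response variability
  with s.d. `UV + LRV·|δ|` (`run_flexible()`, `flexible_params()`).
- **MAP fitting** of that family to (error, update) pairs with weak priors
  favouring normative parameters, bound-constrained quasi-Newton restarts,
  and penalized comparison of noise-perception variants including a
  mixture-over-noise-scales likelihood (`fit_subject()`,
  `compare_noise_models()`).
- **The descriptive regression**: trial exclusions, model-derived surprise
  and uncertainty regressors, heteroscedasticity weights from pooled
  initialization residuals, and a penalized weighted solve
  `β = (AᵀPA + R)⁻¹AᵀPy` in 90 sliding bins of relative error magnitude
  (`make_regression_dataset()`, `sliding_window_fit()`).
- **Group inference**: cluster-mass permutation tests (sign- or
  label-flipping, max-cluster-mass null), leave-one-subject-out coefficient
  extraction, and nested F-tests relating task measures to age
  (`cluster_mass_permutation_test()`, `loso_extract()`,
  `age_explanatory_model()`).
- **A synthetic task/agent/cohort generator** standing in for human data
  (`generate_task_session()`, `simulate_agent()`, `generate_cohort()`), and
  `run_pipeline()` to orchestrate everything reproducibly.

## Worked example

An agent that underestimates its uncertainty tenfold (`UU = 10`) performs a
session; we fit the flexible model to its behaviour and profile its
learning across error magnitudes:

```r
library(predinf)

session   <- generate_task_session(task_config(), seed = 11)
agent     <- agent_spec("uncertainty_underestimation",
                        update_variability = 3, lr_variability = 0.1)
behaviour <- simulate_agent(session, agent, seed = 12)

fit <- fit_subject(subject_data(session, behaviour), n_restarts = 3, seed = 13)
fit
#> Flexible-model fit (base): log posterior -1149.38 over 392 trials
#>   H = 0.1358, SS = 0.859, log-UU = 2.77, UV = 2.89, LRV = 0.0834
#>   penalty score 2319.68 (5 parameters)

ds <- make_regression_dataset(session, behaviour)
wf <- sliding_window_fit(ds, estimate_heteroscedastic_weights(ds))
lr <- wf$estimate[wf$term == "delta"]
c(small_errors = mean(lr[1:10]), large_errors = mean(lr[81:90]))
#> small_errors large_errors
#>  -0.046        0.564
```

The fit recovers a large log uncertainty underestimation (2.77, truth
`log 10 ≈ 2.30`; `H` and `SS` stay near their normative values), and the
binned regression shows the model's signature deficit: essentially no
learning after small prediction errors (−0.05) with intact updating after
large, surprising ones (0.56). A normative agent instead learns at ≈ 0.25
in the smallest-error bins.

## Vignette

`vignettes/predinf-methods.Rmd` describes the model equations and their
assumptions, the fitting and regression design choices, what the synthetic
generator does and does not emulate, and known limitations.
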