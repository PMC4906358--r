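# Shared simulation helpers: sessions of alternating-noise blocks and
# agents of the named model kinds performing them.

mk_session <- function(seed, n_blocks = 2, n_trials = 200,
                       cfg = task_config(n_trials = n_trials)) {
  set.seed(seed)
  out <- vector("list", n_blocks)
  for (b in seq_len(n_blocks))
    out[[b]] <- generate_task_block(
      cfg, noise_sd = cfg$noise_sds[(b - 1) %% length(cfg$noise_sds) + 1],
      block = b)
  do.call(rbind, out)
}

mk_agent_run <- function(kind, seed, n_blocks = 2, uv = 1, lrv = 0,
                         params = NULL, n_trials = 200) {
  ses <- mk_session(seed, n_blocks, n_trials)
  ag <- agent_spec(kind, params = params, update_variability = uv,
                   lr_variability = lrv)
  beh <- simulate_agent(ses, ag, seed = seed + 1)
  list(session = ses, beh = beh)
}

# one subject's windowed coefficients for a given model kind
mk_window_fit <- function(kind, seed, n_blocks = 10, uv = 1, lrv = 0) {
  r <- mk_agent_run(kind, seed, n_blocks, uv, lrv)
  ds <- make_regression_dataset(r$session, r$beh)
  w <- estimate_heteroscedastic_weights(ds)
  sliding_window_fit(ds, w)
}

term_vec <- function(fit, term) fit$estimate[fit$term == term]

# subject_data for an agent with given flexible parameters
mk_subject_data <- function(seed, log_uu = 0, uv = 3, lrv = 0.1,
                            noise_shape = NA, n_trials = 200,
                            max_dev = 15) {
  ses <- mk_session(seed, n_blocks = 2, n_trials = n_trials)
  ag <- agent_spec("flexible",
                   params = flexible_params(log_uu = log_uu,
                                            update_variability = uv,
                                            lr_variability = lrv,
                                            noise_shape = noise_shape),
                   seed = seed + 1)
  subject_data(ses, simulate_agent(ses, ag), max_dev = max_dev)
}
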