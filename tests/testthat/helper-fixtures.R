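# shared fixtures: one reference truth/world used across module tests
ref_truth <- function(background_mu = 0.4) {
  truth_spec(delta = log(3), k = 0.6, omega = 0.01, sigma_log = 0.8,
             n_in = 70, background_mu = background_mu)
}

ref_params <- function() as_temporal_params(ref_truth())

fast_config <- function(seed = 1, n_iter = 3000, n_burnin = 1000, ...) {
  mcmc_config(n_iter = n_iter, n_burnin = n_burnin, seed = seed, ...)
}

eb_chamber <- function() chamber_geometry(diameter = 0.38, height = 0.22)

# random valid temporal parameter sets for property-style tests
random_params <- function(n, seed = 7) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    temporal_params(delta = runif(1, log(0.5), log(15)),
                    k = runif(1, 0.1, 2),
                    omega = runif(1, 1e-4, 0.05),
                    sigma_log = runif(1, 0, 2),
                    n_in = runif(1, 40, 120))
  })
}

# a tiny two-treatment event table for pipeline tests
tiny_event <- function(seed = 11, treatments = "AN") {
  simulate_event(ref_truth(), schedule_daily_then_alternate(),
                 campaign_layout(treatments = treatments), seed = seed,
                 site = "EB", event = 1L)
}
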