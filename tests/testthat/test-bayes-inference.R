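test_that("configuration and prior constructors validate", {
  expect_error(mcmc_config(n_chains = 1), "n_chains")
  expect_error(mcmc_config(n_iter = 100, n_burnin = 100), "n_iter > n_burnin")
  expect_error(prior_spec(omega_sdlog = -1), "scales")
  expect_error(sample_posterior(NULL, n_in = 0), "n_in")
})

test_that("sampler is deterministic under a fixed seed", {
  obs <- tiny_event(seed = 4)
  an <- obs[obs$treatment == "AN", ]
  cfg <- fast_config(seed = 42, n_iter = 800, n_burnin = 300)
  a <- sample_posterior(an, 70, config = cfg)
  b <- sample_posterior(an, 70, config = cfg)
  expect_identical(a$chains, b$chains)
  c <- sample_posterior(an, 70, config = fast_config(seed = 43, n_iter = 800,
                                                     n_burnin = 300))
  expect_false(identical(a$chains, c$chains))
})

test_that("sampler kernel matches the exported likelihood", {
  obs <- tiny_event(seed = 8)
  an <- obs[obs$treatment == "AN", ]
  ll <- n2oflux:::make_loglik(an, n_in = 70, background_rate = 0.009,
                              floor_nmol = 1e-4)
  for (pp in random_params(10, seed = 3)) {
    theta <- c(pp$delta, log(pp$k), log(pp$omega), log(max(pp$sigma_log, 0.05)))
    pars <- temporal_params(theta[1], exp(theta[2]), exp(theta[3]),
                            exp(theta[4]), 70)
    expect_equal(ll(theta), log_likelihood(an, pars, background_rate = 0.009),
                 tolerance = 1e-10)
  }
})

test_that("flat likelihood returns the prior (prior recovery)", {
  pr <- prior_spec()
  # thinned long run so the KS comparison sees near-independent draws
  cfg <- mcmc_config(n_iter = 26000, n_burnin = 1000, thin = 10, seed = 99)
  ch <- sample_posterior(NULL, n_in = 70, priors = pr, config = cfg)
  m <- do.call(rbind, ch$chains)
  set.seed(1); n_ref <- 1e4
  refs <- list(
    omega = rlnorm(n_ref, log(pr$omega_median), pr$omega_sdlog),
    delta = rnorm(n_ref, pr$delta_mean, pr$delta_sd),
    k = rlnorm(n_ref, log(pr$k_median), pr$k_sdlog),
    sigma_log = rlnorm(n_ref, log(pr$sigma_log_median), pr$sigma_log_sdlog))
  for (nm in names(refs)) {
    d <- suppressWarnings(ks.test(m[, nm], refs[[nm]]))$statistic
    expect_lt(unname(d), 0.05)
  }
})

test_that("gelman_rubin matches an independently coded formula", {
  # identical chains: R-hat ~ 1 (exactly sqrt((n-1)/n))
  set.seed(6)
  m1 <- matrix(rnorm(500), 250, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(gelman_rubin(list(m1, m1))), rep(sqrt(249 / 250), 2),
               tolerance = 1e-12)

  # chains from distinct distributions diverge
  m2 <- m1 + 5
  expect_true(all(gelman_rubin(list(m1, m2)) > 1.1))

  # cross-check on random matrices against a from-scratch implementation
  chains <- lapply(1:3, function(i) {
    matrix(rnorm(400, mean = i * 0.1), 200, 2,
           dimnames = list(NULL, c("a", "b")))
  })
  oracle <- sapply(1:2, function(j) {
    draws <- sapply(chains, function(m) m[, j])
    n <- nrow(draws); m <- ncol(draws)
    chain_means <- colMeans(draws)
    B <- n / (m - 1) * sum((chain_means - mean(chain_means))^2)
    W <- mean(apply(draws, 2, function(x) sum((x - mean(x))^2) / (n - 1)))
    sqrt(((n - 1) / n * W + B / n) / W)
  })
  expect_equal(unname(gelman_rubin(chains)), oracle, tolerance = 1e-12)

  expect_error(gelman_rubin(list(m1)), "at least 2 chains")
})

test_that("posterior_cumulative summarises per-draw closed-form values", {
  obs <- tiny_event(seed = 5)
  an <- obs[obs$treatment == "AN", ]
  ch <- sample_posterior(an, 70, config = fast_config(seed = 2, n_iter = 1500,
                                                      n_burnin = 500))
  ps <- posterior_cumulative(ch, 30)
  draws <- cumulative_draws(ch, 30)
  expect_equal(ps$mean, mean(draws), tolerance = 1e-12)
  expect_equal(ps$median, median(draws), tolerance = 1e-12)
  expect_equal(c(ps$ci_low, ps$ci_high),
               unname(quantile(draws, c(0.025, 0.975))), tolerance = 1e-12)
  expect_true(ps$ci_low <= ps$median && ps$median <= ps$ci_high)

  # all draws identical -> zero-width interval
  degenerate <- ch
  one <- ch$chains[[1]][1, , drop = FALSE]
  degenerate$chains <- list(one[rep(1, 50), ], one[rep(1, 50), ])
  degenerate$rhat <- gelman_rubin(degenerate)
  psd <- posterior_cumulative(degenerate, 30)
  expect_equal(psd$ci_low, psd$ci_high)
})

test_that("credible interval widens as sampling is thinned to weekly", {
  tr <- ref_truth()
  lay <- campaign_layout(treatments = "AN")
  widths <- vapply(list(schedule_daily_then_alternate(),
                        sampling_schedule(seq(7, 28, by = 7))), function(sch) {
    obs <- simulate_event(tr, sch, lay, seed = 55)
    an <- obs[obs$treatment == "AN", ]
    ct <- obs[obs$treatment == "control", ]
    ch <- sample_posterior(an, 70, background_rate = background_rate(ct),
                           config = fast_config(seed = 7))
    ps <- posterior_cumulative(ch, 30)
    ps$ci_high - ps$ci_low
  }, numeric(1))
  expect_gt(widths[2], widths[1])
})

test_that("dense plot replication shrinks the omega posterior SD >= 2x", {
  tr <- ref_truth()
  sch <- schedule_daily_then_alternate()
  sds <- vapply(c(4, 40), function(np) {
    obs <- simulate_event(tr, sch,
                          campaign_layout(n_treatment_plots = np,
                                          treatments = "AN"), seed = 66)
    an <- obs[obs$treatment == "AN", ]
    ct <- obs[obs$treatment == "control", ]
    ch <- sample_posterior(an, 70, background_rate = background_rate(ct),
                           config = fast_config(seed = 8, n_iter = 4000,
                                                n_burnin = 1000))
    sd(do.call(rbind, ch$chains)[, "omega"])
  }, numeric(1))
  expect_gte(sds[1] / sds[2], 2)
})

test_that("omega posterior is invariant to consistent rescaling", {
  obs <- tiny_event(seed = 12)
  an <- obs[obs$treatment == "AN", ]
  ct <- obs[obs$treatment == "control", ]
  bgr <- background_rate(ct)
  cfg <- fast_config(seed = 3, n_iter = 1200, n_burnin = 400)
  a <- sample_posterior(an, 70, background_rate = bgr, config = cfg)
  an10 <- transform(an, flux_nmol_m2_s = 10 * flux_nmol_m2_s)
  b <- sample_posterior(an10, 700, background_rate = 10 * bgr, config = cfg)
  expect_equal(do.call(rbind, a$chains)[, "omega"],
               do.call(rbind, b$chains)[, "omega"], tolerance = 1e-10)
  # EF draws are invariant too (cumulative and background both scale)
  expect_equal(ef_draws(a), ef_draws(b), tolerance = 1e-8)
})

test_that("divergence guard trips on frozen absurd proposal scales", {
  obs <- tiny_event(seed = 14)
  an <- obs[obs$treatment == "AN", ]
  cfg <- mcmc_config(n_iter = 600, n_burnin = 0, seed = 4,
                     proposal_scales = c(delta = 2000, log_k = 2000,
                                         log_omega = 2000,
                                         log_sigma_log = 2000))
  expect_error(sample_posterior(an, 70, config = cfg), "divergence")
})
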