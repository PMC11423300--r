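# Likelihood identities, prior handling, sampler correctness on
# constructed posteriors, MAP extraction and posterior summaries.

# analytic stand-in surrogate: "curve" of two points equal to the
# parameters themselves, so the chi-square likelihood becomes a product
# of two independent Gaussians centered on the data values
analytic_surrogate <- function() {
  structure(list(q = c(0.1, 0.2), net = NULL), class = "analytic_surrogate")
}

gaussian_data <- function(center = c(35, 5), sd = c(0.8, 0.12)) {
  saxs_curve(c(0.1, 0.2), center, sigma = sd)
}

test_that("chi-square log likelihood satisfies its exact identities", {
  sm <- smoke_surrogate()
  q <- sm$q
  f <- predict_curve(sm, c(30, 5))[1, ]
  # perfect fit scores zero
  data0 <- saxs_curve(q, f, sigma = 0.02 * f)
  expect_equal(chi2_log_likelihood(c(30, 5), data0, sm), 0,
               tolerance = 1e-10)
  # doubling every sigma divides the log likelihood by four (pure
  # chi-square kernel, no model-error augmentation)
  data1 <- saxs_curve(q, f * 1.03, sigma = 0.02 * f * 1.03)
  data2 <- saxs_curve(q, f * 1.03, sigma = 0.04 * f * 1.03)
  l1 <- chi2_log_likelihood(c(30, 5), data1, sm, model_error = FALSE)
  l2 <- chi2_log_likelihood(c(30, 5), data2, sm, model_error = FALSE)
  expect_lt(l1, 0)
  expect_equal(l2, l1 / 4, tolerance = 1e-10)
  # curves without a sigma column fall back to the fractional default
  data3 <- saxs_curve(q, f * 1.03)
  expect_equal(chi2_log_likelihood(c(30, 5), data3, sm, sigma_frac = 0.02,
                                   model_error = FALSE),
               l1, tolerance = 1e-10)
  # the model-error augmentation only widens the uncertainty budget
  expect_gt(chi2_log_likelihood(c(30, 5), data1, sm, model_error = TRUE),
            l1)
  # grid mismatch is rejected
  bad <- saxs_curve(q[1:100], f[1:100], sigma = f[1:100])
  expect_error(chi2_log_likelihood(c(30, 5), bad, sm), "grid")
})

test_that("log posterior is -Inf outside and finite on the closed boundary", {
  registerS3method("predict_curve", "analytic_surrogate",
                   function(model, params) {
                     m <- if (is.matrix(params)) params else matrix(params, 1)
                     m
                   },
                   envir = asNamespace("saxsdlvo"))
  sm <- analytic_surrogate()
  data <- gaussian_data()
  expect_identical(log_posterior(c(5, 5), data, sm), -Inf)
  expect_identical(log_posterior(c(35, 8), data, sm), -Inf)
  expect_true(is.finite(log_posterior(c(70, 7), data, sm)))
  expect_true(is.finite(log_posterior(c(10, 3), data, sm)))
  # interior ranking equals the likelihood ranking (flat prior)
  g <- as.matrix(expand.grid(seq(10, 70, by = 1), seq(3, 7, by = 0.1)))
  lp <- log_posterior(g, data, sm)
  ll <- chi2_log_likelihood(g, data, sm)
  expect_equal(g[which.max(lp), ], g[which.max(ll), ])
})

test_that("a flat likelihood returns the uniform prior", {
  sm <- analytic_surrogate()
  # enormous uncertainties flatten the likelihood
  data <- saxs_curve(c(0.1, 0.2), c(35, 5), sigma = c(1e9, 1e9))
  post <- run_mcmc(data, sm, config = mcmc_config(
    n_walkers = 16, n_steps = 3000, thin = 10, init = "uniform",
    seed = 51))
  s <- post$samples
  expect_true(all(s[, 1] >= 10 & s[, 1] <= 70))
  expect_true(all(s[, 2] >= 3 & s[, 2] <= 7))
  # occasional exact ties from rejected walker moves are benign here
  expect_gt(suppressWarnings(stats::ks.test(s[, 1], "punif", 10, 70))$p.value,
            0.01)
  expect_gt(suppressWarnings(stats::ks.test(s[, 2], "punif", 3, 7))$p.value,
            0.01)
})

test_that("a sharply peaked likelihood is recovered with correct width", {
  sm <- analytic_surrogate()
  data <- gaussian_data(center = c(35, 5), sd = c(0.8, 0.12))
  post <- run_mcmc(data, sm, config = mcmc_config(
    n_walkers = 16, n_steps = 3000, seed = 52))
  expect_true(post$converged)
  m <- colMeans(post$samples)
  sds <- apply(post$samples, 2, sd)
  expect_lt(abs(m[1] - 35), 3 * sds[1])
  expect_lt(abs(m[2] - 5), 3 * sds[2])
  # marginal widths match the constructed Gaussian within sampling error
  expect_equal(unname(sds[1]), 0.8, tolerance = 0.15)
  expect_equal(unname(sds[2]), 0.12, tolerance = 0.15)
  # independent components: correlation near zero
  expect_lt(abs(posterior_summary(post)$correlation), 0.15)
  # chains with different seeds agree within Monte Carlo error
  post2 <- run_mcmc(data, sm, config = mcmc_config(
    n_walkers = 16, n_steps = 3000, seed = 53))
  expect_lt(abs(mean(post2$samples[, 1]) - m[1]), 0.2)
})

test_that("MAP estimate maximizes the retained samples and sits inside the CI", {
  sm <- analytic_surrogate()
  data <- gaussian_data()
  post <- run_mcmc(data, sm, config = mcmc_config(
    n_walkers = 16, n_steps = 2000, seed = 54))
  map <- map_estimate(post, refine = FALSE)
  expect_gte(map$log_posterior, max(post$log_posterior))
  ci68 <- map$credible_intervals$z_eff$ci68
  expect_true(map$z_eff >= ci68[1] && map$z_eff <= ci68[2])
  # refinement can only improve the posterior value
  map_r <- map_estimate(post, refine = TRUE)
  expect_gte(map_r$log_posterior, map$log_posterior)
  expect_equal(map_r$z_eff, 35, tolerance = 0.01)
  expect_equal(map_r$kappa_inv, 5, tolerance = 0.01)
  # empty chain errors
  empty <- post; empty$samples <- post$samples[0, , drop = FALSE]
  empty$log_posterior <- numeric(0)
  expect_error(map_estimate(empty), "empty")
})

test_that("posterior summaries normalize histograms and detect independence", {
  set.seed(55)
  fake <- structure(list(samples = cbind(runif(5000, 10, 70),
                                         runif(5000, 3, 7)),
                         log_posterior = rep(0, 5000)),
                    class = "posterior_samples")
  s <- posterior_summary(fake)
  expect_lt(abs(s$correlation), 0.05)
  dz <- diff(s$z_eff_hist$breaks[1:2])
  expect_equal(sum(s$z_eff_hist$density) * dz, 1, tolerance = 1e-10)
  dk <- diff(s$kappa_inv_hist$breaks[1:2])
  expect_equal(sum(s$kappa_inv_hist$density) * dk, 1, tolerance = 1e-10)
})

test_that("sampler bookkeeping matches the retained sample count", {
  sm <- analytic_surrogate()
  data <- gaussian_data()
  post <- run_mcmc(data, sm, config = mcmc_config(
    n_walkers = 16, n_steps = 1000, thin = 4, seed = 56))
  kept <- length(seq(1, 1000 - post$burn_in, by = post$thin))
  expect_equal(nrow(post$samples), post$n_walkers * kept)
  expect_length(post$log_posterior, nrow(post$samples))
})
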