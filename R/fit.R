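# Top-level modelling interface: fit a measured SAXS curve with the
# surrogate-accelerated Bayesian workflow and return a classed model
# object in the classic R idiom.

#' Fit DLVO interaction parameters to a SAXS curve
#'
#' Runs the full inverse workflow on a measured (or synthetic) curve:
#' ensemble MCMC over the uniform prior box with the chi-square surrogate
#' likelihood, followed by MAP extraction, credible intervals and the
#' corner-plot posterior summary.
#'
#' @param curve a [saxs_curve()] on the surrogate grid; if it has no
#'   `sigma` column, `sigma_frac * intensity` is used.
#' @param surrogate a [train_surrogate_model()] result.
#' @param prior a [prior_box()].
#' @param config an [mcmc_config()].
#' @param sigma_frac fallback fractional uncertainty.
#' @param model_error include the surrogate's validation-residual scale
#'   in the likelihood uncertainty (see [chi2_log_likelihood()]).
#' @return object of class `saxs_dlvo_fit` with components `map`,
#'   `posterior`, `summary`, `curve` and `surrogate`. Supports `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `simulate` and `plot`.
#' @export
#' @seealso [run_mcmc()], [map_estimate()], [posterior_summary()]
fit_saxs_dlvo <- function(curve, surrogate, prior = prior_box(),
                          config = mcmc_config(), sigma_frac = 0.02,
                          model_error = TRUE) {
  posterior <- run_mcmc(curve, surrogate, prior, config, sigma_frac,
                        model_error)
  map <- map_estimate(posterior)
  structure(list(map = map,
                 posterior = posterior,
                 summary = posterior_summary(posterior, prior),
                 curve = curve,
                 surrogate = surrogate,
                 prior = prior,
                 sigma_frac = sigma_frac),
            class = "saxs_dlvo_fit")
}

#' @export
print.saxs_dlvo_fit <- function(x, ...) {
  cat("DLVO parameter fit to a SAXS curve (surrogate + ensemble MCMC)\n")
  print(x$map)
  cat(sprintf("  Z_eff/kappa^-1 correlation: %.3f\n", x$summary$correlation))
  invisible(x)
}

#' @export
coef.saxs_dlvo_fit <- function(object, ...) {
  c(z_eff = object$map$z_eff, kappa_inv = object$map$kappa_inv)
}

#' @export
summary.saxs_dlvo_fit <- function(object, ...) {
  s <- object$posterior$samples
  out <- list(map = coef(object),
              posterior_mean = colMeans(s),
              posterior_sd = apply(s, 2, stats::sd),
              credible_intervals = object$map$credible_intervals,
              correlation = object$summary$correlation,
              n_samples = nrow(s),
              rhat = object$posterior$rhat,
              converged = object$posterior$converged)
  class(out) <- "summary.saxs_dlvo_fit"
  out
}

#' @export
print.summary.saxs_dlvo_fit <- function(x, ...) {
  cat("Posterior over (Z_eff, kappa^-1)\n")
  cat(sprintf("  MAP      : Z_eff = %.4g, kappa^-1 = %.4g nm\n",
              x$map[1], x$map[2]))
  cat(sprintf("  mean(sd) : Z_eff = %.4g (%.3g), kappa^-1 = %.4g (%.3g)\n",
              x$posterior_mean[1], x$posterior_sd[1],
              x$posterior_mean[2], x$posterior_sd[2]))
  ci <- x$credible_intervals
  cat(sprintf("  95%% CI   : Z_eff [%.4g, %.4g], kappa^-1 [%.4g, %.4g]\n",
              ci$z_eff$ci95[1], ci$z_eff$ci95[2],
              ci$kappa_inv$ci95[1], ci$kappa_inv$ci95[2]))
  cat(sprintf("  correlation %.3f; %d samples; R-hat %.3f\n",
              x$correlation, x$n_samples, x$rhat))
  invisible(x)
}

#' Predicted curve at the MAP (or given) parameters
#'
#' @param object a `saxs_dlvo_fit`.
#' @param params optional parameter pair; defaults to the MAP.
#' @param ... unused.
#' @return a [saxs_curve()] of surrogate intensities.
#' @export
predict.saxs_dlvo_fit <- function(object, params = coef(object), ...) {
  i <- predict_curve(object$surrogate, as.numeric(params))[1, ]
  saxs_curve(object$surrogate$q, i,
             metadata = list(params = as.numeric(params)))
}

#' @export
residuals.saxs_dlvo_fit <- function(object, ...) {
  f <- predict(object)$intensity
  sig <- .curve_sigma(object$curve, object$sigma_frac)
  (object$curve$intensity - f) / sig
}

#' Posterior-predictive curves
#'
#' Draws parameter pairs from the posterior, evaluates the surrogate and
#' adds Gaussian noise at the curve's uncertainty.
#'
#' @param object a `saxs_dlvo_fit`.
#' @param nsim number of simulated curves.
#' @param seed optional seed.
#' @param ... unused.
#' @return `nsim` x n_q intensity matrix.
#' @export
simulate.saxs_dlvo_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- object$posterior$samples
  rows <- sample.int(nrow(s), nsim, replace = TRUE)
  f <- predict_curve(object$surrogate, s[rows, , drop = FALSE])
  sig <- .curve_sigma(object$curve, object$sigma_frac)
  f + matrix(stats::rnorm(length(f), sd = rep(sig, each = nsim)),
             nrow = nsim)
}

#' Corner plot of a fit
#'
#' Marginal posterior histograms on the diagonal and the joint kernel
#' density off-diagonal, with the MAP marked; plus the data/model curve
#' overlay.
#'
#' @param x a `saxs_dlvo_fit`.
#' @param ... unused.
#' @export
plot.saxs_dlvo_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  s <- x$summary
  graphics::plot(s$z_eff_hist, freq = FALSE, col = "grey80", border = NA,
                 main = "", xlab = expression(Z[eff]), ylab = "density")
  graphics::abline(v = x$map$z_eff, col = "red3", lwd = 2)
  graphics::plot(x$curve$q, x$curve$intensity, log = "y", type = "p",
                 pch = 16, cex = 0.4, col = "grey40",
                 xlab = expression(q ~ (ring(A)^-1)), ylab = "I(q)")
  graphics::lines(x$surrogate$q, predict(x)$intensity, col = "red3",
                  lwd = 1.5)
  graphics::image(s$joint_density, col = grDevices::hcl.colors(30, "YlOrRd",
                                                               rev = TRUE),
                  xlab = expression(Z[eff]),
                  ylab = expression(kappa^-1 ~ (nm)))
  graphics::points(x$map$z_eff, x$map$kappa_inv, pch = 8, col = "black")
  graphics::plot(s$kappa_inv_hist, freq = FALSE, col = "grey80",
                 border = NA, main = "",
                 xlab = expression(kappa^-1 ~ (nm)), ylab = "density")
  graphics::abline(v = x$map$kappa_inv, col = "red3", lwd = 2)
  invisible(x)
}
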