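# Forward (curve -> parameters) and surrogate (parameters -> curve)
# models over a saxs_dataset, plus the q-cutoff model-selection sweep.

.standardize_cols <- function(m) {
  mu <- colMeans(m)
  sd_ <- apply(m, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1e-12
  list(z = sweep(sweep(m, 2, mu), 2, sd_, "/"), mean = mu, sd = sd_)
}

.split_rows <- function(dataset) {
  list(train = which(dataset$split == "train"),
       val = which(dataset$split == "val"),
       test = which(dataset$split == "test"))
}

#' Train the forward model
#'
#' Fits the curve -> `(z_eff, kappa_inv)` network: intensities are log10
#' transformed and standardized per q point, targets standardized, both
#' using training-split statistics only; training follows
#' [training_config()] with early stopping on the validation split and
#' best-validation weights restored.
#'
#' @param dataset a `saxs_dataset`, optionally already truncated with
#'   [apply_q_cutoff()].
#' @param q_cutoff optional cutoff applied before training.
#' @param spec architecture; defaults to [forward_model_spec()] at the
#'   retained grid width.
#' @param config a [training_config()].
#' @return object of class `saxs_forward_model`.
#' @export
train_forward_model <- function(dataset, q_cutoff = NULL, spec = NULL,
                                config = training_config()) {
  stopifnot(inherits(dataset, "saxs_dataset"))
  if (!is.null(q_cutoff)) dataset <- apply_q_cutoff(dataset, q_cutoff)
  rows <- .split_rows(dataset)
  if (any(lengths(rows) == 0)) stop("dataset must have non-empty splits")
  norm <- normalize_features(dataset)
  tstat <- .standardize_cols(dataset$labels[rows$train, , drop = FALSE])
  ystd <- sweep(sweep(dataset$labels, 2, tstat$mean), 2, tstat$sd, "/")
  if (is.null(spec)) spec <- forward_model_spec(ncol(norm$features))
  net <- mlp_train(norm$features[rows$train, , drop = FALSE],
                   ystd[rows$train, , drop = FALSE],
                   spec, config,
                   X_val = norm$features[rows$val, , drop = FALSE],
                   Y_val = ystd[rows$val, , drop = FALSE])
  structure(list(net = net, q = dataset$q,
                 q_cutoff = dataset$q_cutoff,
                 feature_stats = norm$stats,
                 target_stats = list(mean = tstat$mean, sd = tstat$sd)),
            class = "saxs_forward_model")
}

#' @export
print.saxs_forward_model <- function(x, ...) {
  cat("Forward SAXS model (curve -> Z_eff, kappa^-1)\n")
  cat(sprintf("  grid: %d points up to q = %.4g A^-1\n",
              length(x$q), max(x$q)))
  print(x$net)
  invisible(x)
}

# Accepts a saxs_curve (truncated to the model grid) or an intensity
# matrix already on the model grid.
.curve_features <- function(model, curve) {
  if (inherits(curve, "saxs_curve")) {
    keep <- curve$q <= max(model$q) + 1e-12
    q <- curve$q[keep]
    if (length(q) != length(model$q) ||
        max(abs(q - model$q)) > 1e-8)
      stop("curve grid does not match the model's training grid")
    m <- matrix(curve$intensity[keep], 1)
  } else {
    m <- if (is.matrix(curve)) curve else matrix(curve, 1)
    if (ncol(m) != length(model$q))
      stop("intensity width does not match the model's training grid")
  }
  forward_transform(m, model$feature_stats)
}

#' Predict interaction parameters from a curve
#'
#' De-standardized forward-model predictions in physical units; values are
#' not clipped, so predictions outside the training box surface as such.
#'
#' @param model a [train_forward_model()] result.
#' @param curve a [saxs_curve()] on the training grid (longer grids are
#'   truncated to the model's cutoff), or an intensity matrix with one row
#'   per curve.
#' @return matrix with columns `z_eff`, `kappa_inv`.
#' @export
predict_params <- function(model, curve) {
  stopifnot(inherits(model, "saxs_forward_model"))
  z <- predict(model$net, .curve_features(model, curve))
  out <- sweep(sweep(z, 2, model$target_stats$sd, "*"), 2,
               model$target_stats$mean, "+")
  colnames(out) <- c("z_eff", "kappa_inv")
  out
}

#' Train the surrogate model
#'
#' Fits the `(z_eff, kappa_inv)` -> curve network used inside the MCMC
#' sampler. Inputs are standardized parameters; outputs are log10
#' intensities centered per q point but scaled by a single global
#' standard deviation (training split only). The global scale -- unlike
#' the per-point standardization used for forward-model inputs -- keeps
#' the loss weighted by each point's natural signal variance, so the
#' network spends its capacity on the structure-carrying low-q region
#' instead of on high-q points whose column variance is almost entirely
#' simulation noise. The stored statistics de-normalize predictions back
#' to physical intensity.
#'
#' @inheritParams train_forward_model
#' @param mc_noise optional per-q relative simulation noise of the
#'   dataset's curves (from [estimate_mc_noise()]). When supplied it is
#'   subtracted in quadrature from the validation residual scale, so the
#'   stored model-error estimate reflects genuine surrogate error rather
#'   than the validation curves' own noise.
#' @return object of class `saxs_surrogate_model`.
#' @export
train_surrogate_model <- function(dataset, spec = NULL,
                                  config = training_config(),
                                  mc_noise = NULL) {
  stopifnot(inherits(dataset, "saxs_dataset"))
  rows <- .split_rows(dataset)
  if (any(lengths(rows) == 0)) stop("dataset must have non-empty splits")
  if (any(dataset$curves <= 0)) stop("intensities must be positive")
  lg <- log10(dataset$curves)
  mu <- colMeans(lg[rows$train, , drop = FALSE])
  ctr <- sweep(lg, 2, mu)
  gsd <- stats::sd(as.numeric(ctr[rows$train, , drop = FALSE]))
  stats_ <- list(mean = mu, sd = rep(gsd, ncol(lg)))
  feats <- ctr / gsd
  tstat <- .standardize_cols(dataset$labels[rows$train, , drop = FALSE])
  xstd <- sweep(sweep(dataset$labels, 2, tstat$mean), 2, tstat$sd, "/")
  if (is.null(spec)) spec <- surrogate_model_spec(ncol(feats))
  net <- mlp_train(xstd[rows$train, , drop = FALSE],
                   feats[rows$train, , drop = FALSE],
                   spec, config,
                   X_val = xstd[rows$val, , drop = FALSE],
                   Y_val = feats[rows$val, , drop = FALSE])
  model <- structure(list(net = net, q = dataset$q,
                          feature_stats = stats_,
                          param_stats = list(mean = tstat$mean,
                                             sd = tstat$sd)),
                     class = "saxs_surrogate_model")
  # per-q relative residual scale on the validation split: the
  # surrogate's own model-error estimate, used by the inference module to
  # avoid overconfident posteriors conditional on a perfect emulator.
  # The robust (median-based) scale keeps extreme corner-of-the-box
  # curves, whose structure factor grazes zero, from dominating.
  pred <- predict_curve(model, dataset$labels[rows$val, , drop = FALSE])
  truth <- dataset$curves[rows$val, , drop = FALSE]
  resid <- 1.4826 * apply(abs((pred - truth) / truth), 2, stats::median)
  if (!is.null(mc_noise)) {
    stopifnot(length(mc_noise) == length(resid))
    resid <- sqrt(pmax(resid^2 - mc_noise^2, 0))
  }
  model$val_residual_frac <- resid
  model
}

#' @export
print.saxs_surrogate_model <- function(x, ...) {
  cat("Surrogate SAXS model (Z_eff, kappa^-1 -> curve)\n")
  cat(sprintf("  grid: %d points, q in [%.4g, %.4g] A^-1\n",
              length(x$q), min(x$q), max(x$q)))
  print(x$net)
  invisible(x)
}

#' Predict a SAXS curve from parameters
#'
#' Evaluates the surrogate at one or many parameter pairs and returns
#' physical intensities (the stored normalization is inverted
#' internally). Batched evaluation is a single matrix pass, which is what
#' makes the surrogate fast enough to sit inside the MCMC loop.
#'
#' @param model a [train_surrogate_model()] result (method dispatch allows
#'   other curve predictors carrying a compatible `q` field).
#' @param params numeric vector `c(z_eff, kappa_inv)` or an n x 2 matrix.
#' @return intensity matrix (n x n_q).
#' @export
predict_curve <- function(model, params) UseMethod("predict_curve")

#' @rdname predict_curve
#' @export
predict_curve.saxs_surrogate_model <- function(model, params) {
  m <- if (is.matrix(params)) params else matrix(params, 1)
  if (ncol(m) != 2) stop("params must have two columns")
  x <- sweep(sweep(m, 2, model$param_stats$mean), 2,
             model$param_stats$sd, "/")
  inverse_transform(predict(model$net, x), model$feature_stats)
}

#' Validation sweep over q cutoffs
#'
#' Trains one forward model per candidate cutoff (shared seed and recipe)
#' and returns the cutoff minimizing the best validation loss, with the
#' full table. High-q points carry almost no structure-factor signal, so
#' an intermediate cutoff typically wins over the full grid.
#'
#' @param dataset a `saxs_dataset`.
#' @param candidate_cutoffs numeric vector (>= 2 values), all within the
#'   grid.
#' @param spec_fn function `input_width -> mlp_spec`; defaults to
#'   [forward_model_spec()].
#' @param config a [training_config()].
#' @return list with `best_cutoff`, `table` (cutoff, retained points,
#'   validation loss) and the fitted `models`.
#' @export
select_q_cutoff <- function(dataset, candidate_cutoffs,
                            spec_fn = forward_model_spec,
                            config = training_config()) {
  stopifnot(inherits(dataset, "saxs_dataset"),
            length(candidate_cutoffs) >= 2)
  for (qc in candidate_cutoffs)
    if (!any(dataset$q <= qc))
      stop(sprintf("candidate cutoff %.4g retains no grid points", qc))
  models <- vector("list", length(candidate_cutoffs))
  val_loss <- numeric(length(candidate_cutoffs))
  n_points <- integer(length(candidate_cutoffs))
  for (i in seq_along(candidate_cutoffs)) {
    ds <- apply_q_cutoff(dataset, candidate_cutoffs[i])
    n_points[i] <- ncol(ds$curves)
    models[[i]] <- train_forward_model(ds, spec = spec_fn(n_points[i]),
                                       config = config)
    val_loss[i] <- models[[i]]$net$best_val_loss
  }
  best <- which.min(val_loss)
  list(best_cutoff = candidate_cutoffs[best],
       table = data.frame(q_cutoff = candidate_cutoffs,
                          n_points = n_points,
                          val_loss = val_loss),
       models = models)
}
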