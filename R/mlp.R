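# Dense feed-forward networks (ReLU + MSE + Adam + early stopping) in base
# R matrix algebra. Small by deep-learning standards, but the matrix sizes
# here (hundreds of samples, <= 512-wide layers) run comfortably on BLAS.

#' Dense network specification
#'
#' @param input_width number of input features.
#' @param hidden integer vector of hidden-layer widths.
#' @param output_width number of outputs.
#' @param activation hidden activation; only the rectifier is supported.
#' @return object of class `mlp_spec`.
#' @export
mlp_spec <- function(input_width, hidden, output_width,
                     activation = "relu") {
  stopifnot(input_width >= 1, output_width >= 1, length(hidden) >= 1,
            all(hidden >= 1), identical(activation, "relu"))
  structure(list(input_width = as.integer(input_width),
                 hidden = as.integer(hidden),
                 output_width = as.integer(output_width),
                 activation = activation),
            class = "mlp_spec")
}

#' Forward-model architecture
#'
#' Curve -> parameters: 8 hidden layers starting at 512 nodes and halving
#' every layer (512, 256, 128, 64, 32, 16, 8, 4), two outputs.
#'
#' @param input_width number of retained q points.
#' @return an [mlp_spec()].
#' @export
forward_model_spec <- function(input_width) {
  mlp_spec(input_width, hidden = 512L %/% 2L^(0:7), output_width = 2L)
}

#' Surrogate-model architecture
#'
#' Parameters -> curve: 4 hidden layers (128, 512, 512, 512), one output
#' node per grid point (225 on the default grid).
#'
#' @param output_width number of q points the surrogate emits.
#' @return an [mlp_spec()].
#' @export
surrogate_model_spec <- function(output_width = 225L) {
  mlp_spec(2L, hidden = c(128L, 512L, 512L, 512L),
           output_width = as.integer(output_width))
}

#' Training configuration
#'
#' Learning rate 0.001, mean-squared-error loss and early stopping after
#' 10 epochs without validation improvement; batch size, epoch cap and
#' optimizer details are implementation defaults (small batches suit the
#' few-hundred-sample corpora these models are typically fitted on here).
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param early_stop_patience consecutive epochs without validation-loss
#'   decrease before stopping; `Inf` disables early stopping.
#' @param seed initialization/shuffling seed.
#' @return object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, batch_size = 16L,
                            max_epochs = 500L, early_stop_patience = 10L,
                            seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            early_stop_patience >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 seed = as.integer(seed)),
            class = "training_config")
}

# He-scaled initialization; biases start at a small positive value so no
# rectifier unit is born dead.
.mlp_init <- function(spec, seed) {
  set.seed(seed)
  widths <- c(spec$input_width, spec$hidden, spec$output_width)
  n_layers <- length(widths) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    W[[l]] <- matrix(stats::rnorm(widths[l] * widths[l + 1L],
                                  sd = sqrt(2 / widths[l])),
                     widths[l], widths[l + 1L])
    b[[l]] <- rep(0.01, widths[l + 1L])
  }
  list(W = W, b = b)
}

# Forward pass; returns output and, if keep = TRUE, layer activations for
# backpropagation.
.mlp_forward <- function(wts, X, keep = FALSE) {
  L <- length(wts$W)
  acts <- if (keep) vector("list", L) else NULL
  Z <- X
  for (l in seq_len(L)) {
    if (keep) acts[[l]] <- Z
    A <- Z %*% wts$W[[l]]
    A <- sweep(A, 2, wts$b[[l]], "+")
    Z <- if (l < L) pmax(A, 0) else A
  }
  list(out = Z, acts = acts)
}

# Gradient of mean-squared error (averaged over samples and outputs).
.mlp_gradient <- function(wts, X, Y) {
  L <- length(wts$W)
  fw <- .mlp_forward(wts, X, keep = TRUE)
  n <- nrow(X)
  delta <- 2 * (fw$out - Y) / (n * ncol(Y))
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- tcrossprod(delta, wts$W[[l]])
      delta <- delta * (fw$acts[[l]] > 0)   # ReLU mask of layer input
    }
  }
  list(W = gW, b = gb, loss = mean((fw$out - Y)^2))
}

.mse <- function(pred, Y) mean((pred - Y)^2)

#' Train a dense network
#'
#' Minibatch Adam on mean-squared error with early stopping on the
#' validation loss; the weights of the best validation epoch are restored.
#'
#' @param X,Y training inputs/targets (matrices, rows are samples).
#' @param spec an [mlp_spec()].
#' @param config a [training_config()].
#' @param X_val,Y_val validation arrays; when `NULL`, early stopping is
#'   disabled and training runs for `max_epochs`.
#' @param val_metric optional function `(wts, epoch) -> loss` replacing the
#'   validation MSE (used by tests to probe the stopping rule).
#' @return object of class `mlp` with weights, spec, and per-epoch
#'   `history` (train/val loss).
#' @export
mlp_train <- function(X, Y, spec, config = training_config(),
                      X_val = NULL, Y_val = NULL, val_metric = NULL) {
  stopifnot(inherits(spec, "mlp_spec"), inherits(config, "training_config"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != spec$input_width) stop("X width does not match spec")
  if (ncol(Y) != spec$output_width) stop("Y width does not match spec")
  if (nrow(X) == 0) stop("empty training split")
  has_val <- !is.null(val_metric) ||
    (!is.null(X_val) && !is.null(Y_val) && nrow(as.matrix(X_val)) > 0)
  if (!is.null(X_val)) { X_val <- as.matrix(X_val); Y_val <- as.matrix(Y_val) }

  wts <- .mlp_init(spec, config$seed)
  L <- length(wts$W)
  mW <- lapply(wts$W, function(w) w * 0); vW <- mW
  mb <- lapply(wts$b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  n <- nrow(X)
  best <- list(loss = Inf, wts = wts, epoch = 0L)
  stall <- 0L
  hist_train <- numeric(0); hist_val <- numeric(0)

  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      rows <- idx[s:min(s + config$batch_size - 1L, n)]
      g <- .mlp_gradient(wts, X[rows, , drop = FALSE],
                         Y[rows, , drop = FALSE])
      ep_loss <- ep_loss + g$loss * length(rows)
      t <- t + 1L
      corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$W[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$W[[l]]^2
        wts$W[[l]] <- wts$W[[l]] - config$learning_rate *
          (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$b[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$b[[l]]^2
        wts$b[[l]] <- wts$b[[l]] - config$learning_rate *
          (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    hist_train <- c(hist_train, ep_loss / n)
    if (has_val) {
      vl <- if (!is.null(val_metric)) val_metric(wts, epoch)
            else .mse(.mlp_forward(wts, X_val)$out, Y_val)
      hist_val <- c(hist_val, vl)
      if (vl < best$loss) {
        best <- list(loss = vl, wts = wts, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) break
      }
    }
  }
  final <- if (has_val) best$wts else wts
  structure(list(weights = final, spec = spec, config = config,
                 history = list(train = hist_train, val = hist_val),
                 best_epoch = if (has_val) best$epoch else length(hist_train),
                 best_val_loss = if (has_val) best$loss else NA_real_),
            class = "mlp")
}

#' @export
print.mlp <- function(x, ...) {
  widths <- c(x$spec$input_width, x$spec$hidden, x$spec$output_width)
  cat(sprintf("Dense network %s, %d epochs (best %d)%s\n",
              paste(widths, collapse = "-"),
              length(x$history$train), x$best_epoch,
              if (is.na(x$best_val_loss)) ""
              else sprintf(", val MSE %.3g", x$best_val_loss)))
  invisible(x)
}

#' Predict with a trained dense network
#'
#' @param object an [mlp_train()] result.
#' @param newdata matrix (rows are samples) or a single numeric vector.
#' @param ... unused.
#' @return prediction matrix.
#' @export
predict.mlp <- function(object, newdata, ...) {
  m <- if (is.matrix(newdata)) newdata else matrix(newdata, 1)
  if (ncol(m) != object$spec$input_width)
    stop("newdata width does not match the network input")
  .mlp_forward(object$weights, m)$out
}

# layer widths, for architecture introspection in tests
#' Layer widths of a network or spec
#'
#' @param x an `mlp` or `mlp_spec`.
#' @return integer vector input, hidden..., output.
#' @export
mlp_widths <- function(x) {
  spec <- if (inherits(x, "mlp")) x$spec else x
  c(spec$input_width, spec$hidden, spec$output_width)
}
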