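# Labelled (curve, parameter) corpora over the sampled parameter box.

.param_box <- list(z_eff = c(10, 70), kappa_inv = c(3, 7))

#' Sample interaction parameters from the training box
#'
#' Independent uniform draws of `(z_eff, kappa_inv)` over
#' \[10, 70\] x \[3, 7\] nm -- the same box the MCMC prior uses.
#'
#' @param n number of pairs.
#' @param seed integer seed.
#' @return `n` x 2 matrix with columns `z_eff`, `kappa_inv`.
#' @export
sample_parameters <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  cbind(z_eff = runif(n, .param_box$z_eff[1], .param_box$z_eff[2]),
        kappa_inv = runif(n, .param_box$kappa_inv[1], .param_box$kappa_inv[2]))
}

#' Simulate one labelled SAXS curve
#'
#' Composes the Monte Carlo stage (initialize, equilibrate, snapshot,
#' RDF) with the scattering stage (structure factor, sphere form factor,
#' intensity) into a single labelled curve on the default grid.
#'
#' @param params a [dlvo_params()].
#' @param config a [sim_config()]; its `seed` makes the curve reproducible.
#' @param q scattering grid in Angstrom^-1.
#' @param n_bins RDF bins.
#' @return a [saxs_curve()] with `labels` set and the seed recorded in
#'   `metadata`.
#' @export
generate_curve <- function(params, config, q = make_q_grid(),
                           n_bins = 200L) {
  mc <- run_mc_rdf(params, config, n_bins = n_bins)
  s <- structure_factor(mc$rdf, q)
  # finite-size S(q) estimates can graze zero at the strongest couplings;
  # a small positive floor keeps intensities valid on the log scale
  s <- pmax(s, 1e-3)
  p <- sphere_form_factor(q, diameter = 2 * params$radius)
  intensity_curve(q, p, s,
                  labels = list(z_eff = params$z_eff,
                                kappa_inv = params$kappa_inv),
                  metadata = list(seed = config$seed,
                                  n_particles = config$n_particles,
                                  number_density = config$number_density,
                                  equil_steps = mc$steps))
}

#' Build a labelled training dataset
#'
#' Simulates `n` curves at uniformly sampled parameters and assigns a
#' deterministic, seeded 8:1:1 train/validation/test split. Per-curve seeds
#' are derived from the master seed, so any single curve can be rebuilt in
#' isolation.
#'
#' @param n number of curves (>= 10).
#' @param config a [sim_config()] used for every curve (its seed field is
#'   replaced per curve).
#' @param seed master seed controlling parameters, per-curve seeds and the
#'   split shuffle.
#' @param q scattering grid.
#' @param progress print a line every 25 curves.
#' @return object of class `saxs_dataset` with fields `curves`
#'   (n x length(q) intensity matrix), `labels` (n x 2), `q`, `split`
#'   (factor train/val/test), `curve_seeds`, `config`.
#' @export
build_dataset <- function(n, config, seed = 1L, q = make_q_grid(),
                          progress = FALSE) {
  stopifnot(n >= 10)
  pars <- sample_parameters(n, seed = seed)
  set.seed(seed + 1L)
  curve_seeds <- sample.int(2^30, n)
  curves <- matrix(NA_real_, n, length(q))
  for (i in seq_len(n)) {
    ci <- config
    ci$seed <- curve_seeds[i]
    p <- dlvo_params(z_eff = pars[i, 1], kappa_inv = pars[i, 2])
    curves[i, ] <- generate_curve(p, ci, q = q)$intensity
    if (progress && i %% 25 == 0)
      message(sprintf("  %d / %d curves", i, n))
  }
  split <- assign_split(n, seed = seed + 2L)
  structure(list(curves = curves, labels = pars, q = q, split = split,
                 curve_seeds = curve_seeds, config = config,
                 seed = as.integer(seed)),
            class = "saxs_dataset")
}

#' Deterministic 8:1:1 split assignment
#'
#' @param n number of samples.
#' @param seed shuffle seed.
#' @return factor with levels train/val/test in proportions 8:1:1 within
#'   rounding; disjoint and exhaustive by construction.
#' @export
assign_split <- function(n, seed = 1L) {
  n_test <- floor(n / 10)
  n_val <- floor(n / 10)
  n_train <- n - n_val - n_test
  set.seed(seed)
  lab <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  factor(sample(lab), levels = c("train", "val", "test"))
}

#' @export
print.saxs_dataset <- function(x, ...) {
  cat(sprintf("SAXS dataset: %d curves x %d q points\n",
              nrow(x$curves), ncol(x$curves)))
  print(table(x$split))
  invisible(x)
}

#' Truncate a dataset at a q cutoff
#'
#' Retains only grid points with `q <= q_cutoff` -- the low-q region that
#' carries the structure-factor signal.
#'
#' @param dataset a `saxs_dataset`.
#' @param q_cutoff cutoff in Angstrom^-1; must retain at least one point.
#' @return the truncated dataset; the cutoff is recorded in `$q_cutoff`.
#' @export
apply_q_cutoff <- function(dataset, q_cutoff) {
  stopifnot(inherits(dataset, "saxs_dataset"))
  keep <- dataset$q <= q_cutoff
  if (!any(keep))
    stop(sprintf("q_cutoff %.4g lies below the first grid point %.4g",
                 q_cutoff, dataset$q[1]))
  dataset$curves <- dataset$curves[, keep, drop = FALSE]
  dataset$q <- dataset$q[keep]
  dataset$q_cutoff <- q_cutoff
  dataset
}

#' Normalize intensity features
#'
#' log10-transforms intensities, then standardizes each q column using
#' mean and standard deviation computed from the training split only (no
#' leakage into validation/test). The returned `stats` invert the
#' transform exactly.
#'
#' @param dataset a `saxs_dataset`.
#' @return list with `features` (n x n_q standardized matrix), `stats`
#'   (`mean`, `sd` per column) and the dataset's `split`.
#' @export
normalize_features <- function(dataset) {
  stopifnot(inherits(dataset, "saxs_dataset"))
  if (any(dataset$curves <= 0)) stop("intensities must be positive")
  lg <- log10(dataset$curves)
  tr <- dataset$split == "train"
  mu <- colMeans(lg[tr, , drop = FALSE])
  sd_ <- apply(lg[tr, , drop = FALSE], 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1e-12
  feats <- sweep(sweep(lg, 2, mu), 2, sd_, "/")
  list(features = feats, stats = list(mean = mu, sd = sd_),
       split = dataset$split)
}

#' Apply stored feature normalization to new intensities
#'
#' @param intensity matrix or vector of positive intensities on the stored
#'   grid.
#' @param stats the `stats` element of [normalize_features()].
#' @return standardized log10 features.
#' @export
forward_transform <- function(intensity, stats) {
  m <- if (is.matrix(intensity)) intensity else matrix(intensity, 1)
  if (any(m <= 0)) stop("intensities must be positive")
  if (ncol(m) != length(stats$mean)) stop("grid width mismatch")
  sweep(sweep(log10(m), 2, stats$mean), 2, stats$sd, "/")
}

#' Invert stored feature normalization
#'
#' @param features standardized log10 features.
#' @inheritParams forward_transform
#' @return intensity matrix on the original scale; exact round trip with
#'   [forward_transform()].
#' @export
inverse_transform <- function(features, stats) {
  m <- if (is.matrix(features)) features else matrix(features, 1)
  if (ncol(m) != length(stats$mean)) stop("grid width mismatch")
  10^(sweep(sweep(m, 2, stats$sd, "*"), 2, stats$mean, "+"))
}

#' Estimate the simulation noise of a curve configuration
#'
#' Generates replicate curves at fixed parameters with different seeds
#' and returns the per-q relative standard deviation. Synthetic
#' "measurements" produced by [generate_curve()] carry this noise in
#' addition to any injected measurement noise; their uncertainty columns
#' should state the full budget.
#'
#' @param params a [dlvo_params()]; box-center values are representative.
#' @param config a [sim_config()]; its seed field seeds the replicates.
#' @param n_rep number of replicate simulations.
#' @param q scattering grid.
#' @return numeric vector of per-q relative standard deviations.
#' @export
estimate_mc_noise <- function(params, config, n_rep = 6,
                              q = make_q_grid()) {
  stopifnot(n_rep >= 2)
  m <- vapply(seq_len(n_rep), function(i) {
    ci <- config
    ci$seed <- config$seed + i
    generate_curve(params, ci, q = q)$intensity
  }, numeric(length(q)))
  apply(m, 1, stats::sd) / rowMeans(m)
}

#' Write a dataset as plain text
#'
#' Persists curves, labels, grid, split and seeds as TSV files plus a JSON
#' manifest in `dir`.
#'
#' @param dataset a `saxs_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "saxs_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$curves, file.path(dir, "curves.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", row.names = FALSE)
  writeLines(format(dataset$q, digits = 17), file.path(dir, "q.txt"))
  writeLines(as.character(dataset$split), file.path(dir, "split.txt"))
  writeLines(as.character(dataset$curve_seeds), file.path(dir, "seeds.txt"))
  manifest <- list(n = nrow(dataset$curves), n_q = ncol(dataset$curves),
                   seed = dataset$seed,
                   q_cutoff = dataset$q_cutoff,
                   config = unclass(dataset$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Export dataset curves as individual .dat files
#'
#' Writes one labelled curve file per sample (the common SAS dialect of
#' [write_saxs_curve()]) for interoperability with other fitting tools.
#'
#' @param dataset a `saxs_dataset`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return character vector of paths, invisibly.
#' @export
export_curves <- function(dataset, dir, prefix = "curve") {
  stopifnot(inherits(dataset, "saxs_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(dataset$curves)
  paths <- file.path(dir, sprintf("%s_%04d.dat", prefix, seq_len(n)))
  for (i in seq_len(n)) {
    cur <- saxs_curve(dataset$q, dataset$curves[i, ],
                      labels = list(z_eff = dataset$labels[i, 1],
                                    kappa_inv = dataset$labels[i, 2]),
                      metadata = list(seed = dataset$curve_seeds[i],
                                      split = as.character(dataset$split[i])))
    write_saxs_curve(cur, paths[i])
  }
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a `saxs_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  curves <- as.matrix(utils::read.table(file.path(dir, "curves.tsv"),
                                        sep = "\t"))
  dimnames(curves) <- NULL
  labels <- as.matrix(utils::read.table(file.path(dir, "labels.tsv"),
                                        sep = "\t", header = TRUE))
  q <- as.numeric(readLines(file.path(dir, "q.txt")))
  split <- factor(readLines(file.path(dir, "split.txt")),
                  levels = c("train", "val", "test"))
  seeds <- as.integer(readLines(file.path(dir, "seeds.txt")))
  cfg <- manifest$config
  cfg$cutoff <- if (is.null(cfg$cutoff)) NULL else cfg$cutoff
  config <- do.call(sim_config, cfg[setdiff(names(cfg), "cutoff")])
  config$cutoff <- cfg$cutoff
  structure(list(curves = curves, labels = labels, q = q, split = split,
                 curve_seeds = seeds, config = config,
                 seed = as.integer(manifest$seed),
                 q_cutoff = manifest$q_cutoff),
            class = "saxs_dataset")
}
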