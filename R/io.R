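# File I/O, run configuration and the synthetic fixture generator.
# Curve files use the common SAS .dat dialect: whitespace-delimited
# columns q, I [, sigma], with '#' comment lines carrying metadata.
# q in files is Angstrom^-1 (a flag converts nm^-1 on read); lengths in
# configs are nm. That dual-unit convention mirrors standard SAS practice
# and is the likeliest place for unit bugs, so it is centralized here and
# in the scattering module.

#' Write a SAXS curve to a .dat file
#'
#' @param curve a [saxs_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_saxs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  hdr <- c("# saxsdlvo curve", "# columns: q[A^-1] I [sigma]")
  if (!is.null(curve$labels))
    hdr <- c(hdr, sprintf("# labels: z_eff=%.10g kappa_inv=%.10g",
                          curve$labels$z_eff, curve$labels$kappa_inv))
  md <- curve$metadata
  for (k in names(md))
    if (is.atomic(md[[k]]) && length(md[[k]]) == 1)
      hdr <- c(hdr, sprintf("# meta: %s=%s", k, format(md[[k]])))
  tab <- cbind(curve$q, curve$intensity)
  if (!is.null(curve$sigma)) tab <- cbind(tab, curve$sigma)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(tab, digits = 12, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a SAXS curve from a .dat file
#'
#' Parses whitespace-delimited 2- or 3-column data with `#` comments.
#' Label and metadata header lines written by [write_saxs_curve()] are
#' recovered. q is assumed to be in Angstrom^-1 unless `q_unit = "nm^-1"`.
#'
#' @param path input file.
#' @param q_unit `"A^-1"` (default) or `"nm^-1"` (converted on read).
#' @return a [saxs_curve()].
#' @export
read_saxs_curve <- function(path, q_unit = c("A^-1", "nm^-1")) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  data_lines <- which(!is_comment)
  if (length(data_lines) == 0) stop("no data lines in ", path)
  fields <- strsplit(trimws(lines[data_lines]), "\\s+")
  ncols <- lengths(fields)
  if (any(ncols < 2))
    stop("line ", data_lines[which(ncols < 2)[1]],
         ": fewer than 2 columns")
  nc <- min(ncols)
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[1:nc]), numeric(nc)))
  if (any(!is.finite(vals)))
    stop("line ", data_lines[which(colSums(!is.finite(vals)) > 0)[1]],
         ": non-numeric field")
  vals <- t(vals)
  q <- vals[, 1]
  if (q_unit == "nm^-1") q <- q / 10
  if (any(diff(q) <= 0))
    stop("line ", data_lines[which(diff(q) <= 0)[1] + 1],
         ": q is not strictly increasing")
  if (any(vals[, 2] <= 0))
    stop("line ", data_lines[which(vals[, 2] <= 0)[1]],
         ": nonpositive intensity")
  labels <- NULL
  lab_line <- grep("^# labels:", lines, value = TRUE)
  if (length(lab_line) == 1) {
    m <- regmatches(lab_line,
                    gregexpr("[a-z_]+=[-0-9.eE+]+", lab_line))[[1]]
    kv <- strsplit(m, "=")
    labels <- stats::setNames(lapply(kv, function(x) as.numeric(x[2])),
                              vapply(kv, `[`, "", 1))
  }
  meta <- list()
  for (ml in grep("^# meta: ", lines, value = TRUE)) {
    kv <- strsplit(sub("^# meta: ", "", ml), "=")[[1]]
    meta[[kv[1]]] <- utils::type.convert(kv[2], as.is = TRUE)
  }
  saxs_curve(q, vals[, 2],
             sigma = if (nc >= 3) vals[, 3] else NULL,
             labels = labels, metadata = meta)
}

#' Serialize a run configuration
#'
#' Writes nested configuration sections (simulation, training, sampler,
#' seeds, output paths) as YAML; [read_run_config()] restores it
#' identically. A short hash of the canonical YAML text identifies every
#' artifact produced under the config.
#'
#' @param config a named list of sections.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname write_run_config
#' @export
config_hash <- function(config) {
  txt <- yaml::as.yaml(config)
  # polynomial rolling hash over the canonical YAML text; stable across
  # sessions and platforms (kept within exact double-precision integers)
  h <- 0
  for (byte in utf8ToInt(txt)) h <- (h * 131 + byte) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Generate the synthetic fixture bundle
#'
#' Writes, in well under a minute: (a) a tiny labelled Monte Carlo dataset
#' spanning the parameter-box corners and center; (b) one
#' pseudo-experimental curve -- a fresh, higher-fidelity MC curve at a
#' held-out parameter pair with 2% multiplicative Gaussian noise and a
#' sigma column, standing in for a measured curve (synthetic, and labelled
#' as such); (c) analytic-limit fixtures: an ideal-gas curve and a dilute
#' hard-sphere curve. Everything is plain text.
#'
#' @param out_dir writable directory.
#' @param seed master seed.
#' @param n_dataset dataset size (default 60).
#' @return invisible list of paths.
#' @export
make_fixtures <- function(out_dir, seed = 1L, n_dataset = 60L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- desk_sim_config(n_particles = 128, post_equil_steps = 15000,
                         n_snapshots = 150, max_equil_blocks = 80)
  q <- make_q_grid()

  # (a) tiny dataset: corners + center + uniform fill
  ds <- build_dataset(n_dataset, cfg, seed = seed, q = q)
  corners <- rbind(c(10, 3), c(10, 7), c(70, 3), c(70, 7), c(40, 5))
  set.seed(seed + 10L)
  corner_seeds <- sample.int(2^30, nrow(corners))
  for (i in seq_len(nrow(corners))) {
    ci <- cfg; ci$seed <- corner_seeds[i]
    ds$curves[i, ] <- generate_curve(
      dlvo_params(corners[i, 1], corners[i, 2]), ci, q = q)$intensity
    ds$labels[i, ] <- corners[i, ]
    ds$curve_seeds[i] <- corner_seeds[i]
  }
  ds_dir <- file.path(out_dir, "dataset")
  write_dataset(ds, ds_dir)

  # (b) pseudo-experimental curve at a held-out pair, 2% noise + sigma.
  # Same particle count (hence box and finite-size signature) as the
  # dataset curves -- a simulated "measurement" in a different box would
  # carry a different low-q truncation imprint than the models trained on
  # this bundle. Fidelity comes from a longer production run, and the
  # sigma column states the full budget: injected noise plus the curve's
  # own estimated simulation noise.
  truth <- c(z_eff = 35, kappa_inv = 5)
  exp_cfg <- desk_sim_config(n_particles = cfg$n_particles,
                             post_equil_steps = 90000,
                             n_snapshots = 900, seed = seed + 20L)
  clean <- generate_curve(dlvo_params(truth[1], truth[2]), exp_cfg, q = q)
  noise_cfg <- exp_cfg
  noise_cfg$seed <- seed + 40L
  mc_sd <- estimate_mc_noise(dlvo_params(truth[1], truth[2]), noise_cfg,
                             n_rep = 4, q = q)
  set.seed(seed + 21L)
  noisy_i <- clean$intensity * (1 + 0.02 * stats::rnorm(length(q)))
  noisy_i <- pmax(noisy_i, 1e-12)
  sigma_full <- clean$intensity * sqrt(0.02^2 + mc_sd^2)
  pseudo <- saxs_curve(q, noisy_i, sigma = sigma_full,
                       labels = as.list(truth),
                       metadata = list(kind = "synthetic_pseudo_experiment",
                                       noise_frac = 0.02,
                                       seed = exp_cfg$seed))
  pseudo_path <- file.path(out_dir, "pseudo_experiment_synthetic.dat")
  write_saxs_curve(pseudo, pseudo_path)

  # (c) analytic limits; the ideal-gas curve runs with long, widely
  # spaced sampling so its structure factor is flat to about 1%
  ig_params <- dlvo_params(z_eff = 0, kappa_inv = 5, hamaker = 0)
  ig_cfg <- desk_sim_config(seed = seed + 30L, number_density = 3e-5,
                            n_particles = 128, equil_block = 2000,
                            post_equil_steps = 100000, n_snapshots = 1000,
                            max_displacement = 40,
                            adapt_displacement = FALSE)
  ig <- generate_curve(ig_params, ig_cfg, q = q)
  ig_path <- file.path(out_dir, "ideal_gas.dat")
  write_saxs_curve(ig, ig_path)

  hs_params <- dlvo_params(z_eff = 0, kappa_inv = 5, hamaker = 0)
  hs_cfg <- desk_sim_config(seed = seed + 31L,
                            number_density = 0.05 /
                              ((4 / 3) * pi * hs_params$radius^3))
  hs <- generate_curve(hs_params, hs_cfg, q = q)
  hs_path <- file.path(out_dir, "hard_sphere_phi05.dat")
  write_saxs_curve(hs, hs_path)

  invisible(list(dataset = ds_dir, pseudo_experiment = pseudo_path,
                 ideal_gas = ig_path, hard_sphere = hs_path))
}
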