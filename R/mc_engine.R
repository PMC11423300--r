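# Metropolis Monte Carlo of DLVO spheres in a periodic cubic box.
# Positions are nm; energies kBT; minimum-image convention throughout.

#' Simulation configuration
#'
#' Defaults correspond to the full production protocol: 5000 particles,
#' energy checkpoints every 1e5 single-particle steps with a 1% relative
#' equilibration threshold, then 5e4 production steps from which 1000
#' configurations are kept for the radial distribution function. The
#' default number density corresponds to a 40 mg/mL aqueous suspension of
#' 3.97 nm gold cores (packing fraction about 2e-3). [desk_sim_config()]
#' gives a reduced preset for interactive work and tests.
#'
#' @param n_particles number of spheres.
#' @param number_density particles per nm^3; sets the box edge via
#'   `box_length = (n_particles / number_density)^(1/3)`.
#' @param max_displacement initial trial-move amplitude per axis (nm); when
#'   `adapt_displacement` is `TRUE` it is tuned during equilibration toward
#'   30--50% acceptance and then frozen for production.
#' @param temperature kelvin.
#' @param seed integer seed making every stage reproducible.
#' @param equil_block steps between total-energy checkpoints.
#' @param equil_rel_tol relative energy-change threshold declaring
#'   equilibrium.
#' @param max_equil_blocks hard budget on equilibration checkpoints.
#' @param post_equil_steps production steps after equilibration.
#' @param n_snapshots configurations sampled (uniformly, without
#'   replacement) from the production window.
#' @param adapt_displacement logical; adapt `max_displacement` during
#'   equilibration only (adaptation during production would break detailed
#'   balance).
#' @param equil_block_average logical; compare block-averaged instead of
#'   instantaneous energies at equilibration checkpoints. Off by default
#'   (the literal rule); recommended at reduced particle counts, where
#'   instantaneous energies fluctuate more than the 1% band.
#' @param cutoff pair-potential truncation radius (nm); `NULL` selects
#'   `min(box_length/2, 2*radius + 8*kappa_inv)` at run time.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_particles = 5000,
                       number_density = 6.1e-5,
                       max_displacement = 2,
                       temperature = 297,
                       seed = 1L,
                       equil_block = 100000,
                       equil_rel_tol = 0.01,
                       max_equil_blocks = 100,
                       post_equil_steps = 50000,
                       n_snapshots = 1000,
                       adapt_displacement = TRUE,
                       equil_block_average = FALSE,
                       cutoff = NULL) {
  stopifnot(n_particles >= 2, number_density > 0, max_displacement > 0,
            temperature > 0, equil_block >= 1, equil_rel_tol > 0,
            max_equil_blocks >= 1, post_equil_steps >= 1, n_snapshots >= 1)
  if (n_snapshots > post_equil_steps)
    stop("n_snapshots cannot exceed post_equil_steps")
  structure(list(n_particles = as.integer(n_particles),
                 number_density = number_density,
                 max_displacement = max_displacement,
                 temperature = temperature,
                 seed = as.integer(seed),
                 equil_block = as.integer(equil_block),
                 equil_rel_tol = equil_rel_tol,
                 max_equil_blocks = as.integer(max_equil_blocks),
                 post_equil_steps = as.integer(post_equil_steps),
                 n_snapshots = as.integer(n_snapshots),
                 adapt_displacement = isTRUE(adapt_displacement),
                 equil_block_average = isTRUE(equil_block_average),
                 cutoff = cutoff),
            class = "sim_config")
}

#' Reduced-scale simulation preset
#'
#' Same physics as [sim_config()] at a size suited to interactive runs:
#' 200 particles, 1e4-step checkpoints, 3e4 production steps, 300
#' snapshots. One curve takes on the order of a second.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
desk_sim_config <- function(...) {
  args <- list(n_particles = 200, equil_block = 10000,
               max_equil_blocks = 60, post_equil_steps = 30000,
               n_snapshots = 300, equil_block_average = TRUE)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

.box_length <- function(config) {
  (config$n_particles / config$number_density)^(1 / 3)
}

.packing_fraction <- function(config, params) {
  config$number_density * (4 / 3) * pi * params$radius^3
}

.resolve_cutoff <- function(config, params, box) {
  cutoff <- config$cutoff
  if (is.null(cutoff))
    cutoff <- min(box / 2, 2 * params$radius + 8 * params$kappa_inv)
  if (cutoff > box / 2)
    stop("cutoff exceeds box_length/2; minimum image would be violated")
  if (cutoff <= 2 * params$radius)
    stop("cutoff must exceed the contact distance")
  cutoff
}

#' Random initial configuration
#'
#' Places `n_particles` spheres by sequential random insertion with
#' hard-core rejection. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param params a [dlvo_params()].
#' @param max_attempts insertion attempts per particle before giving up.
#' @return An object of class `particle_configuration` with fields
#'   `positions` (N x 3 matrix, nm), `box_length` and `radius`.
#' @export
initialize_configuration <- function(config, params, max_attempts = 10000L) {
  phi <- .packing_fraction(config, params)
  if (phi >= 0.3)
    stop(sprintf("packing fraction %.3f too high for random insertion", phi))
  box <- .box_length(config)
  set.seed(config$seed)
  pos <- cpp_insert_random(config$n_particles, box, params$radius,
                           as.integer(max_attempts))
  structure(list(positions = pos, box_length = box, radius = params$radius),
            class = "particle_configuration")
}

.check_conf <- function(conf) {
  stopifnot(inherits(conf, "particle_configuration"))
  stopifnot(is.matrix(conf$positions), ncol(conf$positions) == 3)
}

#' Total configurational energy
#'
#' Pairwise sum of [u_dlvo()] over unique minimum-image pairs; pairs beyond
#' `cutoff` contribute zero. Returns `+Inf` if any pair overlaps.
#'
#' @param conf a `particle_configuration`.
#' @param params a [dlvo_params()].
#' @param cutoff truncation radius in nm (must not exceed half the box).
#' @return energy in kBT.
#' @export
total_energy <- function(conf, params, cutoff) {
  .check_conf(conf)
  if (cutoff > conf$box_length / 2)
    stop("cutoff exceeds box_length/2; minimum image would be violated")
  cpp_total_energy(conf$positions, conf$box_length, params$radius,
                   .vdw_prefactor(params), .yukawa_prefactor(params),
                   1 / params$kappa_inv, cutoff)
}

# Low-level chain driver shared by the public stages. Advances n_steps
# single-particle Metropolis moves; returns updated conf, running energy,
# acceptance rate and any requested snapshots.
.mc_run <- function(conf, params, config, n_steps, max_disp,
                    energy = NULL, snapshot_steps = integer(0)) {
  box <- conf$box_length
  cutoff <- .resolve_cutoff(config, params, box)
  if (is.null(energy)) energy <- total_energy(conf, params, cutoff)
  out <- cpp_mc_chain(conf$positions, box, params$radius,
                      .vdw_prefactor(params), .yukawa_prefactor(params),
                      1 / params$kappa_inv, cutoff,
                      as.integer(n_steps), max_disp, energy,
                      as.integer(sort(snapshot_steps)))
  conf$positions <- out$positions
  list(conf = conf, energy = out$energy, mean_energy = out$mean_energy,
       acceptance_rate = out$accepted / out$n_steps,
       snapshots = out$snapshots)
}

#' Advance the chain by Metropolis moves
#'
#' Each step picks one particle uniformly at random, proposes a uniform
#' displacement within +/- `max_displacement` per axis (with periodic
#' wrapping) and accepts with the Metropolis probability
#' `min(1, exp(-dE/kBT))`; moves creating hard-core overlap are always
#' rejected. Energy bookkeeping is incremental.
#'
#' @param conf a `particle_configuration`.
#' @param params a [dlvo_params()].
#' @param config a [sim_config()].
#' @param n_steps number of attempted moves.
#' @return list with the updated `conf`, running `energy` (kBT) and
#'   `acceptance_rate` diagnostics.
#' @export
mc_sweep <- function(conf, params, config, n_steps = 1L) {
  .check_conf(conf)
  res <- .mc_run(conf, params, config, n_steps, config$max_displacement)
  res$snapshots <- NULL
  res
}

#' Equilibrate by the checkpoint-energy rule
#'
#' Runs blocks of `equil_block` steps; after each block the instantaneous
#' total energy `E_i` is compared with the previous checkpoint `E_{i-1}`
#' and equilibrium is declared when `|E_i - E_{i-1}| / max(|E_{i-1}|, eps)`
#' falls below `equil_rel_tol`. The guard `eps = n_particles` (kBT) is the
#' system's thermal energy scale: it makes the relative rule well-posed
#' for weakly interacting systems whose total energy is near zero (for
#' which random initial configurations are already near equilibrium).
#' While equilibrating, the trial-move amplitude is adapted toward 30--50%
#' acceptance (unless disabled) and then frozen.
#'
#' @inheritParams mc_sweep
#' @return list with `conf`, `steps` run, the frozen `max_displacement`,
#'   the checkpoint `energy_trace` and final `energy`.
#' @export
run_to_equilibrium <- function(conf, params, config) {
  .check_conf(conf)
  set.seed(config$seed + 1L)
  box <- conf$box_length
  cutoff <- .resolve_cutoff(config, params, box)
  energy <- total_energy(conf, params, cutoff)
  disp <- config$max_displacement
  disp_lo <- 0.02 * params$radius
  disp_hi <- 2.5 * params$radius
  eps <- config$n_particles   # thermal floor, kBT
  trace <- energy
  steps <- 0L
  for (blk in seq_len(config$max_equil_blocks)) {
    res <- .mc_run(conf, params, config, config$equil_block, disp,
                   energy = energy)
    conf <- res$conf
    e_prev <- trace[length(trace)]
    energy <- res$energy
    trace <- c(trace, if (config$equil_block_average) res$mean_energy
                      else energy)
    steps <- steps + config$equil_block
    if (config$adapt_displacement) {
      if (res$acceptance_rate > 0.5) disp <- min(disp * 1.3, disp_hi)
      else if (res$acceptance_rate < 0.3) disp <- max(disp * 0.75, disp_lo)
    }
    e_chk <- trace[length(trace)]
    if (abs(e_chk - e_prev) / max(abs(e_prev), eps) < config$equil_rel_tol) {
      return(list(conf = conf, steps = steps, max_displacement = disp,
                  energy_trace = trace, energy = energy))
    }
  }
  cond <- simpleError(
    sprintf("equilibration budget of %d blocks exhausted",
            config$max_equil_blocks))
  cond$energy_trace <- trace
  stop(cond)
}

#' Sample production snapshots
#'
#' Runs `post_equil_steps` further moves and records the configuration at
#' `n_snapshots` step indices drawn uniformly without replacement from the
#' production window (deterministic given `config$seed`).
#'
#' @inheritParams mc_sweep
#' @param max_displacement trial-move amplitude frozen at the value
#'   returned by [run_to_equilibrium()]; defaults to the config value.
#' @return list of `particle_configuration` snapshots (the chain state is
#'   attached as attribute `final`).
#' @export
sample_snapshots <- function(conf, params, config,
                             max_displacement = config$max_displacement) {
  .check_conf(conf)
  if (config$n_snapshots > config$post_equil_steps)
    stop("n_snapshots cannot exceed post_equil_steps")
  set.seed(config$seed + 2L)
  idx <- sort(sample.int(config$post_equil_steps, config$n_snapshots))
  res <- .mc_run(conf, params, config, config$post_equil_steps,
                 max_displacement, snapshot_steps = idx)
  snaps <- lapply(res$snapshots, function(p)
    structure(list(positions = p, box_length = conf$box_length,
                   radius = conf$radius), class = "particle_configuration"))
  attr(snaps, "final") <- res$conf
  attr(snaps, "snapshot_steps") <- idx
  snaps
}

#' Radial distribution function from snapshots
#'
#' Histograms unique minimum-image pair distances over all snapshots and
#' normalizes each bin by the ideal-gas expectation
#' `(N/2) * ((N-1)/V) * (4/3) pi (r_{k+1}^3 - r_k^3)` per snapshot. The
#' `(N-1)/V` pair density makes g exactly 1 on average for an ideal gas at
#' finite N; the particle density `N/V` is stored as `n_p` for the
#' structure-factor prefactor.
#'
#' @param snapshots list of `particle_configuration` objects sharing one
#'   box.
#' @param n_bins number of equal-width bins on (0, r_max].
#' @param r_max histogram range in nm; must not exceed half the box edge.
#' @return An object of class `rdf` with `r_centers`, `g_values`, `n_p`,
#'   `breaks` and bookkeeping fields.
#' @export
compute_rdf <- function(snapshots, n_bins = 200L, r_max = NULL) {
  if (length(snapshots) < 1) stop("at least one snapshot is required")
  box <- snapshots[[1]]$box_length
  n <- nrow(snapshots[[1]]$positions)
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-9)
    stop("r_max exceeds box_length/2; minimum image would be violated")
  breaks <- seq(0, r_max, length.out = n_bins + 1L)
  counts <- cpp_pair_histogram(lapply(snapshots, `[[`, "positions"),
                               box, breaks)
  vol <- box^3
  shell <- (4 / 3) * pi * diff(breaks^3)
  ideal <- length(snapshots) * (n / 2) * ((n - 1) / vol) * shell
  structure(list(r_centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 g_values = counts / ideal,
                 n_p = n / vol,
                 breaks = breaks,
                 n_snapshots = length(snapshots),
                 n_particles = n,
                 box_length = box),
            class = "rdf")
}

#' Run the full Monte Carlo stage for one parameter set
#'
#' Convenience composition: initialize, equilibrate, sample snapshots and
#' bin the radial distribution function.
#'
#' @inheritParams mc_sweep
#' @param n_bins,r_max forwarded to [compute_rdf()].
#' @return list with `rdf`, the final `conf`, equilibration `steps` and the
#'   checkpoint `energy_trace`.
#' @export
run_mc_rdf <- function(params, config, n_bins = 200L, r_max = NULL) {
  conf <- initialize_configuration(config, params)
  eq <- run_to_equilibrium(conf, params, config)
  snaps <- sample_snapshots(eq$conf, params, config,
                            max_displacement = eq$max_displacement)
  list(rdf = compute_rdf(snaps, n_bins = n_bins, r_max = r_max),
       conf = attr(snaps, "final"),
       steps = eq$steps,
       energy_trace = eq$energy_trace)
}

#' Write configurations as a plain-text XYZ trajectory
#'
#' One frame per configuration in the standard XYZ layout; the comment
#' line carries the box edge and, when available, the production step
#' index of each snapshot.
#'
#' @param snapshots a `particle_configuration` or a list of them (as
#'   returned by [sample_snapshots()]).
#' @param path output file.
#' @param element atom label written for every sphere.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(snapshots, path, element = "Au") {
  if (inherits(snapshots, "particle_configuration"))
    snapshots <- list(snapshots)
  steps <- attr(snapshots, "snapshot_steps")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(snapshots)) {
    pos <- snapshots[[i]]$positions
    writeLines(as.character(nrow(pos)), con)
    writeLines(sprintf("box_length=%.10g nm step=%s",
                       snapshots[[i]]$box_length,
                       if (is.null(steps)) i else steps[i]), con)
    writeLines(sprintf("%s %.8f %.8f %.8f", element,
                       pos[, 1], pos[, 2], pos[, 3]), con)
  }
  invisible(path)
}

#' Minimum pair distance of a configuration
#'
#' Minimum-image nearest-pair distance; used to assert the hard-core
#' invariant.
#'
#' @param conf a `particle_configuration`.
#' @return distance in nm.
#' @export
min_pair_distance <- function(conf) {
  .check_conf(conf)
  cpp_min_pair_distance(conf$positions, conf$box_length)
}
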