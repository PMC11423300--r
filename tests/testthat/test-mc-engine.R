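# Metropolis engine: initialization, energies vs brute force, move
# acceptance, equilibration rule, snapshot sampling, RDF normalization.

brute_force_energy <- function(conf, params, cutoff) {
  # independent O(N^2) double loop in R with minimum image
  pos <- conf$positions; box <- conf$box_length
  n <- nrow(pos); e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dv <- pos[i, ] - pos[j, ]
      dv <- dv - box * round(dv / box)
      d <- sqrt(sum(dv^2))
      if (d <= 2 * params$radius) return(Inf)
      if (d < cutoff) e <- e + u_dlvo(d, params)
    }
  }
  e
}

test_that("random insertion yields valid, reproducible configurations", {
  p <- dlvo_params(20, 4)
  cfg <- desk_sim_config(n_particles = 500,
                         number_density = 0.05 /
                           ((4 / 3) * pi * p$radius^3), seed = 3)
  conf <- initialize_configuration(cfg, p)
  expect_equal(dim(conf$positions), c(500, 3))
  expect_true(all(conf$positions >= 0 & conf$positions < conf$box_length))
  # brute-force overlap oracle
  dmat <- as.matrix(dist(conf$positions))
  # minimum-image check via the package helper plus raw non-periodic scan
  expect_gt(min_pair_distance(conf), 2 * p$radius)
  expect_gt(min(dmat[upper.tri(dmat)]), 0)
  # determinism
  conf2 <- initialize_configuration(cfg, p)
  expect_identical(conf$positions, conf2$positions)
  # two particles at very low density
  cfg2 <- desk_sim_config(n_particles = 2, number_density = 1e-6, seed = 1)
  c2 <- initialize_configuration(cfg2, p)
  expect_gt(min_pair_distance(c2), 2 * p$radius)
  # impossible density errors out with advice
  cfg3 <- desk_sim_config(n_particles = 100, number_density = 0.02)
  expect_error(initialize_configuration(cfg3, p), "packing fraction")
})

test_that("total energy equals the brute-force double loop", {
  p <- dlvo_params(25, 5)
  cfg <- desk_sim_config(n_particles = 50, seed = 11)
  conf <- initialize_configuration(cfg, p)
  cutoff <- conf$box_length / 3
  expect_equal(total_energy(conf, p, cutoff),
               brute_force_energy(conf, p, cutoff),
               tolerance = 1e-10)
  # N = 2 reduces to the pair potential
  cfg2 <- desk_sim_config(n_particles = 2, number_density = 2e-5, seed = 5)
  c2 <- initialize_configuration(cfg2, p)
  d <- min_pair_distance(c2)
  cut2 <- c2$box_length / 2
  e2 <- total_energy(c2, p, cut2)
  expect_equal(e2, if (d < cut2) u_dlvo(d, p) else 0, tolerance = 1e-12)
  # zero-coupling configuration has exactly zero energy
  pid <- dlvo_params(0, 5, hamaker = 0)
  expect_identical(total_energy(conf, pid, cutoff), 0)
  expect_error(total_energy(conf, p, conf$box_length), "minimum image")
})

test_that("ideal-gas moves are always accepted and overlaps always rejected", {
  pid <- dlvo_params(0, 5, hamaker = 0)
  # point-like spheres at low density: no overlap proposals
  cfg <- desk_sim_config(n_particles = 40, number_density = 1e-6,
                         seed = 2, max_displacement = 0.5)
  pid_small <- dlvo_params(0, 5, radius = 1e-3, hamaker = 0)
  conf <- initialize_configuration(cfg, pid_small)
  set.seed(10)
  res <- mc_sweep(conf, pid_small, cfg, n_steps = 10000)
  expect_equal(res$acceptance_rate, 1)
  expect_equal(res$energy, 0)
  # dense hard spheres: some proposals overlap and are rejected
  cfg2 <- desk_sim_config(n_particles = 60,
                          number_density = 0.2 /
                            ((4 / 3) * pi * pid$radius^3),
                          seed = 4, max_displacement = 3)
  conf2 <- initialize_configuration(cfg2, pid)
  set.seed(11)
  res2 <- mc_sweep(conf2, pid, cfg2, n_steps = 5000)
  expect_lt(res2$acceptance_rate, 1)
  expect_gt(min_pair_distance(res2$conf), 2 * pid$radius)
})

test_that("incremental energy bookkeeping stays consistent with recomputation", {
  p <- dlvo_params(30, 5)
  cfg <- desk_sim_config(seed = 21)
  conf <- initialize_configuration(cfg, p)
  cutoff <- min(conf$box_length / 2, 2 * p$radius + 8 * p$kappa_inv)
  set.seed(22)
  res <- mc_sweep(conf, p, cfg, n_steps = 100000)
  expect_lt(abs(res$energy - total_energy(res$conf, p, cutoff)), 1e-6)
  # hard core never violated after many accepted moves
  expect_gt(min_pair_distance(res$conf), 2 * p$radius)
})

test_that("equilibration declares immediately for an ideal gas and is reproducible", {
  pid <- dlvo_params(0, 5, hamaker = 0)
  cfg <- desk_sim_config(n_particles = 80, equil_block = 1000, seed = 9)
  conf <- initialize_configuration(cfg, pid)
  eq <- run_to_equilibrium(conf, pid, cfg)
  expect_equal(eq$steps, 1000)   # first checkpoint passes (E identically 0)
  expect_equal(eq$energy, 0)
  # determinism of the full stage
  eq2 <- run_to_equilibrium(initialize_configuration(cfg, pid), pid, cfg)
  expect_identical(eq$steps, eq2$steps)
  expect_identical(eq$conf$positions, eq2$conf$positions)
})

test_that("declared equilibrium sits in the stationary band of a longer run", {
  p <- dlvo_params(30, 4)
  cfg <- desk_sim_config(n_particles = 100, equil_block = 5000, seed = 31)
  conf <- initialize_configuration(cfg, p)
  eq <- run_to_equilibrium(conf, p, cfg)
  # reference: run 10x the declared budget further, collect checkpoint
  # energies of the stationary regime
  long <- mc_sweep(eq$conf, p, cfg, n_steps = 10 * eq$steps)
  ref <- replicate(10, {
    r <- mc_sweep(long$conf, p, cfg, n_steps = 2000)
    long$conf <<- r$conf
    r$energy
  })
  band <- range(ref)
  slack <- diff(band)
  expect_gt(eq$energy, band[1] - 2 * slack)
  expect_lt(eq$energy, band[2] + 2 * slack)
})

test_that("equilibration budget exhaustion carries the energy trace", {
  p <- dlvo_params(70, 7)   # strong coupling, tight tolerance, tiny budget
  cfg <- desk_sim_config(n_particles = 150, equil_block = 200,
                         max_equil_blocks = 2, equil_rel_tol = 1e-9,
                         equil_block_average = FALSE, seed = 12)
  conf <- initialize_configuration(cfg, p)
  err <- tryCatch(run_to_equilibrium(conf, p, cfg), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "budget")
  expect_length(err$energy_trace, 3)   # initial + 2 checkpoints
})

test_that("snapshot sampling honors count, determinism and the uniform window", {
  pid <- dlvo_params(0, 5, radius = 0.5, hamaker = 0)
  cfg <- desk_sim_config(n_particles = 60, number_density = 1e-5,
                         post_equil_steps = 500, n_snapshots = 500,
                         seed = 77)
  conf <- initialize_configuration(cfg, pid)
  snaps <- sample_snapshots(conf, pid, cfg)
  # n_snapshots = post_equil_steps returns every production configuration
  expect_length(snaps, 500)
  expect_identical(attr(snaps, "snapshot_steps"), 1:500)
  # determinism
  snaps2 <- sample_snapshots(conf, pid, cfg)
  expect_identical(snaps[[500]]$positions, snaps2[[500]]$positions)
  expect_error(sample_snapshots(conf, pid,
                                desk_sim_config(n_particles = 60,
                                                number_density = 1e-5,
                                                post_equil_steps = 10,
                                                n_snapshots = 20)),
               "n_snapshots")
})

test_that("ideal-gas snapshots are uniform across box octants", {
  # small box and near-teleport moves so widely spaced snapshots are
  # essentially independent and the multinomial oracle applies
  pid <- dlvo_params(0, 5, radius = 0.2, hamaker = 0)
  cfg <- desk_sim_config(n_particles = 100, number_density = 1e-4,
                         post_equil_steps = 20000, n_snapshots = 50,
                         seed = 55, max_displacement = 50,
                         adapt_displacement = FALSE)
  conf <- initialize_configuration(cfg, pid)
  eq <- run_to_equilibrium(conf, pid, cfg)
  snaps <- sample_snapshots(eq$conf, pid, cfg)
  half <- snaps[[1]]$box_length / 2
  counts <- integer(8)
  for (s in snaps) {
    oct <- 1 + (s$positions[, 1] >= half) + 2 * (s$positions[, 2] >= half) +
      4 * (s$positions[, 3] >= half)
    counts <- counts + tabulate(oct, 8)
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
  expect_equal(sum(counts), 50 * 100)
})

test_that("RDF is flat for an ideal gas and counts pairs exactly", {
  pid <- dlvo_params(0, 5, radius = 0.3, hamaker = 0)
  cfg <- desk_sim_config(n_particles = 150, number_density = 3e-5,
                         post_equil_steps = 30000, n_snapshots = 300,
                         seed = 8, max_displacement = 30,
                         adapt_displacement = FALSE)
  conf <- initialize_configuration(cfg, pid)
  eq <- run_to_equilibrium(conf, pid, cfg)
  snaps <- sample_snapshots(eq$conf, pid, cfg)
  rdf <- compute_rdf(snaps, n_bins = 60)
  sel <- rdf$r_centers > 2   # beyond contact
  counts_per_bin <- rdf$n_snapshots * (rdf$n_particles / 2) *
    ((rdf$n_particles - 1) / rdf$box_length^3) *
    (4 / 3) * pi * diff(rdf$breaks^3)[sel]
  three_sigma <- 3 / sqrt(counts_per_bin)
  expect_true(all(abs(rdf$g_values[sel] - 1) < pmax(3 * three_sigma, 0.2)))
  # outer quarter within 5% of 1 on average
  outer <- rdf$g_values[rdf$r_centers > 0.75 * max(rdf$r_centers)]
  expect_lt(abs(mean(outer) - 1), 0.05)
  # two particles, one snapshot: exactly one count in the right bin
  cfg2 <- desk_sim_config(n_particles = 2, number_density = 1e-5, seed = 2)
  c2 <- initialize_configuration(cfg2, pid)
  rdf2 <- compute_rdf(list(c2), n_bins = 50)
  d <- min_pair_distance(c2)
  hit <- findInterval(d, rdf2$breaks)
  raw_counts <- rdf2$g_values * (2 / 2) * (1 / c2$box_length^3) *
    (4 / 3) * pi * diff(rdf2$breaks^3)
  expect_equal(sum(raw_counts > 0), 1)
  expect_gt(raw_counts[hit], 0)
  expect_error(compute_rdf(list(c2), r_max = c2$box_length),
               "minimum image")
})

test_that("simulated curves are bitwise reproducible from their seed", {
  p <- dlvo_params(28, 4.4)
  cfg <- desk_sim_config(n_particles = 64, equil_block = 2000,
                        post_equil_steps = 3000, n_snapshots = 50,
                        seed = 1234)
  c1 <- generate_curve(p, cfg)
  c2 <- generate_curve(p, cfg)
  expect_identical(c1$intensity, c2$intensity)
  expect_equal(c1$labels$z_eff, 28)
})
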