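# Shared fixtures, built once per test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 200-curve corpus at the reduced simulation scale; the workhorse for the
# learning and inference tests.
smoke_dataset <- function() {
  cached("smoke_dataset",
         build_dataset(200, desk_sim_config(), seed = 101))
}

smoke_forward_model <- function() {
  cached("smoke_forward_model",
         train_forward_model(apply_q_cutoff(smoke_dataset(), 0.0677),
                             config = training_config(seed = 5,
                                                      max_epochs = 1000)))
}

smoke_surrogate <- function() {
  cached("smoke_surrogate",
         train_surrogate_model(smoke_dataset(),
                               config = training_config(seed = 7,
                                                        max_epochs = 400)))
}

# a fast, tiny corpus for structural dataset tests (seconds, not minutes)
tiny_dataset <- function() {
  cached("tiny_dataset", {
    cfg <- desk_sim_config(n_particles = 64, equil_block = 2000,
                           post_equil_steps = 4000, n_snapshots = 40,
                           max_equil_blocks = 40)
    build_dataset(10, cfg, seed = 7)
  })
}

# deterministic high-fidelity pseudo-measurement at known parameters
pseudo_experiment <- function(z_eff = 35, kappa_inv = 5, seed = 2024,
                              noise_frac = 0.02) {
  cfg <- desk_sim_config(n_particles = 300, post_equil_steps = 60000,
                         n_snapshots = 600, seed = seed)
  clean <- generate_curve(dlvo_params(z_eff, kappa_inv), cfg)
  set.seed(seed + 1L)
  noisy <- clean$intensity * (1 + noise_frac * stats::rnorm(length(clean$q)))
  saxs_curve(clean$q, pmax(noisy, 1e-12),
             sigma = noise_frac * clean$intensity,
             labels = list(z_eff = z_eff, kappa_inv = kappa_inv))
}

r_squared <- function(pred, truth) {
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}
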