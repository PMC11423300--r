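# q grids, sphere form factor, structure-factor transform, intensity
# composition and the nm/Angstrom unit conversion.

make_fake_rdf <- function(r, g, n_p) {
  structure(list(r_centers = r, g_values = g, n_p = n_p,
                 breaks = NULL, n_snapshots = 1L,
                 n_particles = NA_integer_, box_length = NA_real_),
            class = "rdf")
}

test_that("q grid hits the documented endpoints and spacing rules", {
  q <- make_q_grid()
  expect_length(q, 225)
  expect_equal(q[1], 0.012)
  expect_equal(q[225], 0.501)
  expect_true(all(diff(q) > 0))
  expect_equal(make_q_grid(n = 2), c(0.012, 0.501))
  qlog <- make_q_grid(n = 50, spacing = "log")
  expect_equal(diff(log(qlog)), rep(diff(log(qlog))[1], 49),
               tolerance = 1e-12)
  expect_error(make_q_grid(q_min = 0.5, q_max = 0.1), "q_min")
})

test_that("uncorrelated fluid gives S(q) identically 1", {
  rdf <- make_fake_rdf(seq(0.05, 60, by = 0.1), rep(1, 600), 6e-5)
  s <- structure_factor(rdf, make_q_grid())
  expect_equal(s, rep(1, 225), tolerance = 1e-14)
  # q = 0 takes the analytic sinc limit without error
  expect_equal(structure_factor(rdf, 0), 1, tolerance = 1e-14)
})

test_that("exponential correlation transforms to its analytic Fourier form", {
  # g(r) = 1 + A exp(-r/xi): S(q) = 1 + 4 pi n_p A * 2 a / (a^2+q^2)^2,
  # a = 1/xi (q in nm^-1); quadrature on a fine grid must match closely
  xi <- 4; A <- 0.35; n_p <- 2e-4
  r <- seq(0.005, 80, by = 0.01)
  rdf <- make_fake_rdf(r, 1 + A * exp(-r / xi), n_p)
  q_a <- make_q_grid(0.02, 0.4, n = 40)   # A^-1
  q_nm <- q_a * 10
  a <- 1 / xi
  expected <- 1 + 4 * pi * n_p * A * 2 * a / (a^2 + q_nm^2)^2
  expect_equal(structure_factor(rdf, q_a), expected, tolerance = 1e-4)
})

test_that("structure-factor transform is linear in g - 1", {
  set.seed(9)
  r <- seq(0.1, 30, by = 0.05)
  g1 <- 1 + 0.3 * exp(-r / 3) * cos(r)
  g2 <- 1 + runif(length(r), -0.1, 0.1)
  n_p <- 1e-4
  q <- make_q_grid(n = 30)
  s1 <- structure_factor(make_fake_rdf(r, g1, n_p), q)
  s2 <- structure_factor(make_fake_rdf(r, g2, n_p), q)
  s12 <- structure_factor(make_fake_rdf(r, g1 + g2 - 1, n_p), q)
  expect_equal(s12 - 1, (s1 - 1) + (s2 - 1), tolerance = 1e-12)
})

test_that("sphere form factor is normalized, bounded and has the known first zero", {
  q <- make_q_grid()
  p <- sphere_form_factor(q, diameter = 3.97)
  expect_true(all(p <= 1 + 1e-12))
  expect_true(all(p >= 0))
  expect_equal(sphere_form_factor(1e-9, 3.97), 1, tolerance = 1e-8)
  # first zero of 3(sin x - x cos x)/x^3 at x = 4.4934094579090642
  # (root of tan x = x, frozen from mpmath root finding)
  R_nm <- 3.97 / 2
  q_zero <- 4.4934094579090642 / (10 * R_nm)   # A^-1
  eps <- 1e-6
  expect_lt(sphere_form_factor(q_zero, 3.97), 1e-12)
  # a sign change of (sin x - x cos x) brackets the root
  f <- function(qa) {
    x <- qa * 10 * R_nm
    sin(x) - x * cos(x)
  }
  expect_lt(f(q_zero - eps) * f(q_zero + eps), 0)
  expect_error(sphere_form_factor(q, diameter = -1), "diameter")
})

test_that("intensity composes P and S with scale and background", {
  q <- make_q_grid(n = 50)
  p <- sphere_form_factor(q)
  s <- rep(0.8, 50)
  cur <- intensity_curve(q, p, s)
  expect_s3_class(cur, "saxs_curve")
  expect_equal(cur$intensity, p * s, tolerance = 1e-14)
  cur2 <- intensity_curve(q, p, s, scale = 2)
  expect_equal(cur2$intensity, 2 * cur$intensity, tolerance = 1e-14)
  cur3 <- intensity_curve(q, p, s, scale = 2, background = 0.5)
  expect_equal(cur3$intensity, 2 * p * s + 0.5, tolerance = 1e-14)
  expect_error(intensity_curve(q, p[-1], s), "grid")
  # dilute limit: S = 1 reduces intensity to the form factor
  expect_equal(intensity_curve(q, p, rep(1, 50))$intensity, p)
})

test_that("real-space nm and reciprocal Angstrom units are reconciled", {
  # a delta-like correlation shell at r0 nm modulates S with period
  # 2*pi/r0 in q_nm = 10*q_A; verify the first minimum location
  r0 <- 25; width <- 0.05
  r <- seq(0.1, 60, by = 0.01)
  g <- 1 + ifelse(abs(r - r0) < width, 5, 0)
  rdf <- make_fake_rdf(r, g, 1e-4)
  q_a <- seq(0.001, 0.05, by = 1e-4)
  s <- structure_factor(rdf, q_a)
  # sinc(q_nm * r0) has its minimum at q_nm * r0 = 4.4934
  q_min_expected_a <- 4.4934094579090642 / r0 / 10
  expect_equal(q_a[which.min(s)], q_min_expected_a, tolerance = 2e-3)
})

test_that("curve container validates its invariants", {
  q <- make_q_grid(n = 10)
  expect_error(saxs_curve(rev(q), rep(1, 10)), "increasing")
  expect_error(saxs_curve(q, c(rep(1, 9), -1)), "intensity")
  expect_error(saxs_curve(q, rep(1, 10), sigma = rep(0, 10)), "sigma")
  expect_error(saxs_curve(q, rep(1, 10), labels = list(z_eff = 1)),
               "kappa_inv")
  cur <- saxs_curve(q, rep(2, 10), sigma = rep(0.1, 10),
                    labels = list(z_eff = 30, kappa_inv = 4))
  expect_equal(cur$labels$kappa_inv, 4)
})
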