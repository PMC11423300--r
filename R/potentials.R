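# DLVO pair potentials for charged spheres, in thermal-energy (kBT) units.
# Lengths are nm throughout; scattering vectors elsewhere are Angstrom^-1.

.kB <- 1.380649e-23        # J/K
.e_charge <- 1.602176634e-19  # C
.eps0 <- 8.8541878128e-12  # F/m
.eps_water <- 78.5         # relative permittivity used for the aqueous default

#' Bjerrum length in water
#'
#' Distance at which two unit charges interact with thermal energy kB*T,
#' `L_B = e^2 / (4 pi eps0 eps_r kB T)`. A fixed relative permittivity of
#' 78.5 is used by default, giving approximately 0.71 nm at 297 K.
#'
#' @param temperature temperature in kelvin, inside (273, 373).
#' @param eps_r relative permittivity of the solvent.
#' @return Bjerrum length in nm.
#' @export
#' @examples
#' bjerrum_length_water(297)
bjerrum_length_water <- function(temperature, eps_r = .eps_water) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (!is.finite(temperature) || temperature <= 273 || temperature >= 373)
    stop("temperature must be in (273, 373) K")
  lb_m <- .e_charge^2 / (4 * pi * .eps0 * eps_r * .kB * temperature)
  lb_m * 1e9
}

#' Interaction parameters of a DLVO system
#'
#' Bundles the pair of parameters the method estimates -- the effective
#' macroion valency `z_eff` and the Debye length `kappa_inv` -- with the
#' fixed physical constants of the suspension: sphere radius, Hamaker
#' constant, temperature and Bjerrum length.
#'
#' @param z_eff effective macroion valency (dimensionless, >= 0).
#' @param kappa_inv Debye screening length in nm (> 0).
#' @param radius sphere radius in nm; default is half the 3.97 nm core
#'   diameter of the reference gold nanoparticles.
#' @param hamaker Hamaker constant in joules. The default 1e-20 J is an
#'   effective value for ligand-capped gold cores across water: the
#'   bare-gold constant (about 2.5e-19 J) gives a contact adhesion of
#'   hundreds of kBT that collapses weakly charged suspensions into
#'   aggregates, which the organic ligand shell suppresses in the real
#'   system. Set it explicitly to study other chemistries.
#' @param temperature temperature in kelvin.
#' @param bjerrum_length Bjerrum length in nm; computed from `temperature`
#'   for water when `NULL`.
#' @return An object of class `dlvo_params`.
#' @export
#' @examples
#' p <- dlvo_params(z_eff = 35, kappa_inv = 5)
#' u_dlvo(3 * p$radius, p)
dlvo_params <- function(z_eff, kappa_inv, radius = 3.97 / 2,
                        hamaker = 1e-20, temperature = 297,
                        bjerrum_length = NULL) {
  stopifnot(length(z_eff) == 1L, length(kappa_inv) == 1L)
  if (!is.finite(z_eff) || z_eff < 0) stop("z_eff must be >= 0")
  if (!is.finite(kappa_inv) || kappa_inv <= 0) stop("kappa_inv must be > 0")
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  if (is.null(bjerrum_length))
    bjerrum_length <- bjerrum_length_water(temperature)
  if (!is.finite(bjerrum_length) || bjerrum_length <= 0)
    stop("bjerrum_length must be positive and finite")
  structure(list(z_eff = as.numeric(z_eff),
                 kappa_inv = as.numeric(kappa_inv),
                 radius = as.numeric(radius),
                 hamaker = as.numeric(hamaker),
                 temperature = as.numeric(temperature),
                 bjerrum_length = as.numeric(bjerrum_length)),
            class = "dlvo_params")
}

#' @export
print.dlvo_params <- function(x, ...) {
  cat("DLVO interaction parameters\n")
  cat(sprintf("  Z_eff       : %.4g\n", x$z_eff))
  cat(sprintf("  kappa^-1    : %.4g nm\n", x$kappa_inv))
  cat(sprintf("  radius      : %.4g nm\n", x$radius))
  cat(sprintf("  Hamaker     : %.3g J (%.3g kBT)\n", x$hamaker,
              x$hamaker / (.kB * x$temperature)))
  cat(sprintf("  temperature : %.4g K\n", x$temperature))
  cat(sprintf("  Bjerrum L_B : %.4g nm\n", x$bjerrum_length))
  invisible(x)
}

.check_separation <- function(d, params) {
  if (any(!is.finite(d)))
    stop("center distance must be finite")
  if (any(d <= 2 * params$radius))
    stop("center distance must exceed the contact distance 2*radius ",
         "(hard-core overlap)")
}

# dimensionless vdW prefactor H_A / (6 kB T)
.vdw_prefactor <- function(params) {
  params$hamaker / (6 * .kB * params$temperature)
}

# Yukawa prefactor Z^2 L_B (e^{kr}/(1+kr))^2, in nm
.yukawa_prefactor <- function(params) {
  kr <- params$radius / params$kappa_inv
  params$z_eff^2 * params$bjerrum_length * (exp(kr) / (1 + kr))^2
}

#' Van der Waals attraction between two spheres
#'
#' Nonretarded Hamaker sphere-sphere attraction,
#' `U_vdW/kBT = -H_A/(6 kBT) * (2r^2/(d^2-4r^2) + 2r^2/d^2 +
#' log(1 - 4r^2/d^2))`. Always attractive (<= 0), increasing towards zero
#' with distance.
#'
#' @param d center-to-center distance in nm, strictly greater than
#'   `2 * params$radius`. Vectorized.
#' @param params a [dlvo_params()] object.
#' @return energy in kBT units.
#' @export
u_vdw <- function(d, params) {
  .check_separation(d, params)
  r2 <- params$radius^2
  x <- 4 * r2 / d^2
  -.vdw_prefactor(params) * (2 * r2 / (d^2 - 4 * r2) + 2 * r2 / d^2 +
                               log1p(-x))
}

#' Screened-Coulomb repulsion between two charged spheres
#'
#' Yukawa repulsion with the surface-charge geometry correction,
#' `U_el/kBT = Z_eff^2 L_B (e^{kr}/(1+kr))^2 e^{-kd}/d`, where
#' `k = 1/kappa_inv`. Always repulsive (>= 0), decreasing with distance.
#'
#' @inheritParams u_vdw
#' @return energy in kBT units.
#' @export
u_el <- function(d, params) {
  .check_separation(d, params)
  .yukawa_prefactor(params) * exp(-d / params$kappa_inv) / d
}

#' DLVO pair potential
#'
#' Sum of [u_vdw()] and [u_el()]. Distances at or below contact are a
#' hard-core overlap: the Monte Carlo engine treats such pair energies as
#' +Inf and this function signals an error.
#'
#' @inheritParams u_vdw
#' @return energy in kBT units.
#' @export
u_dlvo <- function(d, params) {
  u_vdw(d, params) + u_el(d, params)
}
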