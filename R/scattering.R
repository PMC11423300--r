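# RDF -> structure factor -> SAXS intensity.
# Real-space lengths are nm; scattering vectors are Angstrom^-1.
# The single nm <-> Angstrom conversion lives in .q_to_nm_inv().

# q [A^-1] -> q [nm^-1]; 1 nm = 10 A.
.q_to_nm_inv <- function(q) q * 10

#' Scattering-vector grid
#'
#' The default grid is the 225-point range 0.012--0.501 Angstrom^-1 on
#' which all curves, network inputs and outputs live.
#'
#' @param q_min,q_max grid bounds in Angstrom^-1.
#' @param n number of points (>= 2).
#' @param spacing `"linear"` or `"log"`.
#' @return strictly increasing numeric vector of length `n`.
#' @export
#' @examples
#' q <- make_q_grid()
#' length(q); range(q)
make_q_grid <- function(q_min = 0.012, q_max = 0.501, n = 225L,
                        spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  if (!(q_min > 0 && q_min < q_max)) stop("require 0 < q_min < q_max")
  if (n < 2) stop("n must be >= 2")
  if (spacing == "linear") seq(q_min, q_max, length.out = n)
  else exp(seq(log(q_min), log(q_max), length.out = n))
}

#' Structure factor from a radial distribution function
#'
#' Evaluates
#' `S(q) = 1 + 4 pi n_p \int_0^{r_max} (g(r) - 1) sinc(qr) r^2 dr`
#' by trapezoidal quadrature over the RDF bin centers. The `q = 0` point
#' uses the analytic `sinc` limit of 1. Real-space units (nm) and the
#' Angstrom^-1 q grid are reconciled internally.
#'
#' @param rdf an [compute_rdf()] result.
#' @param q scattering-vector grid in Angstrom^-1 (may include 0).
#' @return numeric vector `S(q)`.
#' @export
structure_factor <- function(rdf, q) {
  stopifnot(inherits(rdf, "rdf"))
  r <- rdf$r_centers              # nm
  h <- rdf$g_values - 1
  qn <- .q_to_nm_inv(q)           # nm^-1
  # trapezoid weights on the r grid
  w <- numeric(length(r))
  dr <- diff(r)
  w[1] <- dr[1] / 2
  w[length(r)] <- dr[length(dr)] / 2
  if (length(r) > 2)
    w[2:(length(r) - 1)] <- (dr[-length(dr)] + dr[-1]) / 2
  base <- 4 * pi * rdf$n_p * w * h * r^2
  vapply(qn, function(qk) {
    if (qk == 0) return(1 + sum(base))
    x <- qk * r
    1 + sum(base * sin(x) / x)
  }, numeric(1))
}

#' Sphere form factor
#'
#' Normalized intra-particle scattering of a homogeneous sphere,
#' `P(q) = (3 (sin(qR) - qR cos(qR)) / (qR)^3)^2`, with `P(0) = 1` by the
#' series limit. The default diameter is the 3.97 nm best-fit core of the
#' reference gold nanoparticles.
#'
#' @param q grid in Angstrom^-1.
#' @param diameter sphere diameter in nm.
#' @return numeric vector with values in (0, 1].
#' @export
sphere_form_factor <- function(q, diameter = 3.97) {
  if (diameter <= 0) stop("diameter must be > 0")
  x <- .q_to_nm_inv(q) * diameter / 2
  p <- ifelse(x < 1e-4,
              1 - x^2 / 5,                      # series, avoids 0/0
              3 * (sin(x) - x * cos(x)) / x^3)
  p^2
}

#' SAXS curve container
#'
#' A table of intensity versus scattering vector, optionally with
#' per-point uncertainty and, for synthetic curves, the generating
#' `(z_eff, kappa_inv)` ground truth.
#'
#' @param q strictly increasing grid in Angstrom^-1.
#' @param intensity positive finite intensities (arbitrary units).
#' @param sigma optional positive per-point uncertainties.
#' @param labels optional named vector/list with `z_eff` and `kappa_inv`.
#' @param metadata optional named list carried along (seed, config, ...).
#' @return object of class `saxs_curve`.
#' @export
saxs_curve <- function(q, intensity, sigma = NULL, labels = NULL,
                       metadata = list()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensity must be finite and > 0")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length differs from q")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be finite and > 0")
  }
  if (!is.null(labels)) {
    labels <- as.list(labels)
    stopifnot(all(c("z_eff", "kappa_inv") %in% names(labels)))
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 labels = labels, metadata = metadata),
            class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("SAXS curve: %d points, q in [%.4g, %.4g] A^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with sigma"))
  if (!is.null(x$labels))
    cat(sprintf("  labels: Z_eff = %.4g, kappa^-1 = %.4g nm\n",
                x$labels$z_eff, x$labels$kappa_inv))
  invisible(x)
}

#' Compose a SAXS intensity curve
#'
#' `I(q) = scale * P(q) * S(q) + background`; the defaults give the pure
#' product of form and structure factor.
#'
#' @param q grid in Angstrom^-1.
#' @param p_of_q form-factor values on `q`.
#' @param s_of_q structure-factor values on `q`.
#' @param scale,background affine calibration constants.
#' @param labels,metadata forwarded to [saxs_curve()].
#' @return a `saxs_curve`.
#' @export
intensity_curve <- function(q, p_of_q, s_of_q, scale = 1, background = 0,
                            labels = NULL, metadata = list()) {
  if (length(p_of_q) != length(q) || length(s_of_q) != length(q))
    stop("p_of_q, s_of_q and q must share one grid")
  saxs_curve(q, scale * p_of_q * s_of_q + background,
             labels = labels, metadata = metadata)
}
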