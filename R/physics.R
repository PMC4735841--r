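#' Electron rest energy in keV
#'
#' Single source of truth for \eqn{m_e c^2} used by every Compton-kinematic
#' formula in the package. Fixed at 511.0 keV so that the annihilation line
#' and the kinematic constant coincide in worked examples.
#' @export
electron_rest_kev <- 511.0

#' Energy of a Compton-scattered photon
#'
#' Compton formula \eqn{E' = E_0 / (1 + (E_0/m_e c^2)(1 - \cos\theta))}.
#'
#' @param e0 Incident photon energy in keV (> 0). Vectorized.
#' @param cos_theta Cosine of the scattering angle, in \[-1, 1\]. Vectorized.
#' @return Scattered photon energy in keV, between `backscatter_limit(e0)`
#'   and `e0`.
#' @examples
#' scattered_energy(511, 0)    # 255.5 keV at 90 degrees
#' scattered_energy(1275, -1)  # backscatter, 212.85 keV
#' @export
scattered_energy <- function(e0, cos_theta) {
  if (any(e0 <= 0)) stop("e0 must be > 0", call. = FALSE)
  if (any(cos_theta < -1 | cos_theta > 1)) {
    stop("cos_theta outside [-1, 1] is non-physical", call. = FALSE)
  }
  e0 / (1 + (e0 / electron_rest_kev) * (1 - cos_theta))
}

#' Cosine of the Compton scattering angle from deposited energy
#'
#' Inverse Compton relation
#' \eqn{\cos\theta = 1 - m_e c^2 (1/(E_0 - E_{dep}) - 1/E_0)}.
#'
#' @param e0 Incident photon energy in keV.
#' @param e_dep Energy deposited on the scattering electron, 0 < e_dep < e0.
#' @param on_invalid What to do when the energy pair is kinematically
#'   impossible (|cos| > 1): `"error"` (default) or `"na"` to return `NA`
#'   for the offending elements (used for bulk event screening).
#' @param tol Numerical slack on the \[-1, 1\] clip before an inconsistency
#'   is declared.
#' @return Cosine of the scattering angle.
#' @export
cos_scatter_angle <- function(e0, e_dep, on_invalid = c("error", "na"),
                              tol = 1e-9) {
  on_invalid <- match.arg(on_invalid)
  if (any(e0 <= 0)) stop("e0 must be > 0", call. = FALSE)
  if (any(e_dep <= 0 | e_dep >= e0)) {
    stop("e_dep must satisfy 0 < e_dep < e0", call. = FALSE)
  }
  ct <- 1 - electron_rest_kev * (1 / (e0 - e_dep) - 1 / e0)
  bad <- ct < -1 - tol | ct > 1 + tol
  if (any(bad)) {
    if (on_invalid == "error") {
      stop("kinematically inconsistent (e0, e_dep) pair: deposit exceeds ",
           "the backscatter limit", call. = FALSE)
    }
    ct[bad] <- NA_real_
  }
  pmin(pmax(ct, -1), 1)
}

#' Minimum energy of a Compton-scattered photon (backscatter, theta = pi)
#'
#' @param e0 Incident photon energy in keV.
#' @return `e0 / (1 + 2 e0 / 511)` in keV.
#' @export
backscatter_limit <- function(e0) {
  if (any(e0 <= 0)) stop("e0 must be > 0", call. = FALSE)
  e0 / (1 + 2 * e0 / electron_rest_kev)
}

#' Klein-Nishina angular density in cos(theta)
#'
#' Relative probability density of the Compton scattering angle, proportional
#' to \eqn{d\sigma/d\Omega \cdot 2\pi} marginalized to \eqn{\cos\theta}.
#' Normalized so the value at `cos_theta = 1` is 1 for every energy, which is
#' also its maximum (used as the rejection-sampling envelope).
#'
#' @param e0 Incident photon energy in keV.
#' @param cos_theta Cosine of the scattering angle.
#' @param normalize If `TRUE`, rescale numerically so the density integrates
#'   to 1 over \[-1, 1\].
#' @return Non-negative relative density values.
#' @export
klein_nishina_pdf <- function(e0, cos_theta, normalize = FALSE) {
  if (any(e0 <= 0)) stop("e0 must be > 0", call. = FALSE)
  if (any(cos_theta < -1 | cos_theta > 1)) {
    stop("cos_theta outside [-1, 1]", call. = FALSE)
  }
  ratio <- 1 / (1 + (e0 / electron_rest_kev) * (1 - cos_theta)) # E'/E0
  sin2 <- 1 - cos_theta^2
  val <- 0.5 * ratio^2 * (ratio + 1 / ratio - sin2)
  if (normalize) {
    stopifnot(length(e0) == 1)
    z <- stats::integrate(function(ct) klein_nishina_pdf(e0, ct),
                          -1, 1, rel.tol = 1e-10)$value
    val <- val / z
  }
  val
}

#' Sample Compton scattering angles from the Klein-Nishina law
#'
#' Rejection sampling with a uniform envelope (the density is bounded by its
#' forward value, which `klein_nishina_pdf()` scales to 1). Uses the R global
#' random-number stream; fix it with [set.seed()] for reproducibility.
#'
#' @param e0 Incident photon energies in keV; one sample is drawn per element.
#' @return Vector of sampled `cos_theta`, same length as `e0`.
#' @export
sample_scatter_angle <- function(e0) {
  if (any(e0 <= 0)) stop("e0 must be > 0", call. = FALSE)
  n <- length(e0)
  out <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    m <- length(todo)
    ct <- stats::runif(m, -1, 1)
    u <- stats::runif(m)
    ok <- u < klein_nishina_pdf(e0[todo], ct)
    out[todo[ok]] <- ct[ok]
    todo <- todo[!ok]
  }
  out
}

#' Total Klein-Nishina cross-section per electron
#'
#' Closed-form integral of the Klein-Nishina differential cross-section over
#' the full solid angle, in cm^2 per electron. Used to build the embedded
#' LaBr3 attenuation table so that free-path sampling and angular sampling
#' share one cross-section model.
#'
#' @param e0 Photon energy in keV.
#' @return Cross-section in cm^2.
#' @export
kn_total_cross_section <- function(e0) {
  if (any(e0 <= 0)) stop("e0 must be > 0", call. = FALSE)
  re2 <- 7.94080e-26 # classical electron radius squared, cm^2
  k <- e0 / electron_rest_kev
  2 * pi * re2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) -
                                     log(1 + 2 * k) / k) +
                    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}
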