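#' Saturating light response of photosynthesis
#'
#' Photosynthetic rate at irradiance `I`, a Monod (saturating) function of
#' light with half-saturation `h` and maximum `rho_max`.
#'
#' @param I irradiance, umol quanta m^-2 s^-1 (vectorized).
#' @param params a [mixo_params()] object.
#' @return Rate in d^-1, bounded above by `rho_max`.
#' @examples
#' p <- mixo_params(z = 0)
#' light_response(c(0, 250, 1e6), p)
#' @export
light_response <- function(I, params) {
  if (any(!is.finite(I)) || any(I < 0)) stop("irradiance 'I' must be >= 0")
  params$rho_max * I / (params$h + I)
}

#' Photosynthesis-phagotrophy trade-off curve
#'
#' Maximum photosynthetic capacity remaining after investing a fraction
#' `theta` in phagotrophy:
#' `rho0(theta, z) = rho_max (1 - theta^(2^z))^(2^-z)`.
#' The curve runs from `rho_max` at `theta = 0` to 0 at `theta = 1`; `z`
#' sets its curvature (convex for `z > 0`, the chord for `z = 0`, concave
#' for `z < 0`).
#'
#' @param theta phagotrophic investment in `[0, 1]` (vectorized).
#' @param params a [mixo_params()] object (supplies `z` and `rho_max`).
#' @param z optional trade-off shape override; defaults to `params$z`.
#' @return Maximum photosynthetic rate, d^-1.
#' @examples
#' p <- mixo_params(z = 1)
#' tradeoff_rho0(0.6, p)        # 0.8 * rho_max
#' tradeoff_rho0(0.25, p, z = -1)  # 0.25 * rho_max
#' @export
tradeoff_rho0 <- function(theta, params, z = params$z) {
  check_theta(theta)
  params$rho_max * (1 - theta^(2^z))^(2^(-z))
}

# Dimensionless thermal multiplier shared by both metabolisms. The linear
# form is floored at zero below T0; the exponential sensitivity variant is
# anchored to equal 1 at 13 degC (as the linear form does with the default
# coefficients) and ignores T0.
thermal_multiplier <- function(T, m, T0, type) {
  if (type == "linear") pmax(0, m * (T - T0)) else exp(m * (T - 13))
}

#' Temperature-dependent attack rate
#'
#' Per-mixotroph attack rate on bacteria,
#' `alpha(theta, T) = alpha_max * theta * max(0, m_alpha (T - T0_alpha))`
#' (linear thermal response; see [mixo_params()] for the exponential
#' variant). Zero below `T0_alpha` and at `theta = 0`.
#'
#' @param theta phagotrophic investment in `[0, 1]`.
#' @param T temperature, degC.
#' @param params a [mixo_params()] object.
#' @return Attack rate, cm^2 d^-1 cell_M^-1.
#' @examples
#' p <- mixo_params(z = 0)
#' thermal_attack_rate(1, 13, p)  # alpha_max exactly at 13 degC
#' @export
thermal_attack_rate <- function(theta, T, params) {
  check_theta(theta)
  params$alpha_max * theta *
    thermal_multiplier(T, params$m_alpha, params$T0_alpha,
                       params$thermal_response)
}

#' Temperature-dependent photosynthetic capacity
#'
#' `rho(theta, z, T) = rho0(theta, z) * max(0, m_rho (T - T0_rho))`:
#' the trade-off-constrained maximum photosynthetic rate scaled by the
#' (linear, floored) thermal multiplier. Zero at or below `T0_rho`.
#'
#' @inheritParams thermal_attack_rate
#' @param z optional trade-off shape override; defaults to `params$z`.
#' @return Photosynthetic rate, d^-1.
#' @export
thermal_photo_rate <- function(theta, T, params, z = params$z) {
  tradeoff_rho0(theta, params, z = z) *
    thermal_multiplier(T, params$m_rho, params$T0_rho,
                       params$thermal_response)
}

# Depth-averaged light factor ln((h + I_in) / (h + I_in e^{-kM})) / (kM),
# the mean of the Monod light response over an exponentially attenuating
# light profile. The singularity at M = 0 is removable; below kM = 1e-8
# the analytic limit I_in / (h + I_in) is used.
depth_light_factor <- function(M, params) {
  x <- params$k * M
  lim <- params$I_in / (params$h + params$I_in)
  out <- rep(lim, length(x))
  big <- x >= 1e-8
  if (any(big)) {
    xb <- x[big]
    out[big] <- log((params$h + params$I_in) /
                      (params$h + params$I_in * exp(-xb))) / xb
  }
  out
}

#' Depth-averaged per-capita photosynthetic growth
#'
#' Per-capita photosynthetic growth of a mixotroph population of density
#' `M` in a well-mixed water column with self-shading:
#' `P = rho(theta, z, T) / (k M) * ln((h + I_in) / (h + I_in e^{-kM}))`.
#' Strictly decreasing in `M`; continuous at `M = 0` with limit
#' `rho(theta, z, T) * I_in / (h + I_in)`.
#'
#' @inheritParams thermal_photo_rate
#' @param M mixotroph density, cell_M cm^-2 (vectorized, `>= 0`).
#' @return Per-capita growth rate, d^-1.
#' @examples
#' p <- mixo_params(z = 1)
#' depth_avg_photo_growth(0, 0, 13, p)  # = 1.0 * 100/350
#' @export
depth_avg_photo_growth <- function(theta, M, T, params, z = params$z) {
  if (any(!is.finite(M)) || any(M < 0)) stop("density 'M' must be >= 0")
  thermal_photo_rate(theta, T, params, z = z) * depth_light_factor(M, params)
}

#' Per-capita grazing growth
#'
#' Type-I (linear) functional response: growth gained from grazing at prey
#' density `B` is `G = b * alpha(theta, T) * B`.
#'
#' @inheritParams thermal_attack_rate
#' @param B bacterial prey density, cell_B cm^-2 (vectorized, `>= 0`).
#' @return Per-capita growth rate, d^-1.
#' @export
grazing_growth <- function(theta, B, T, params) {
  if (any(!is.finite(B)) || any(B < 0)) stop("prey density 'B' must be >= 0")
  params$b * thermal_attack_rate(theta, T, params) * B
}

#' Population dynamics right-hand sides
#'
#' `mixotroph_rhs` gives dM/dt = (P + G - l) M and `bacteria_rhs` gives
#' dB/dt = (r (1 - B/K_B) - alpha M) B for the coupled
#' mixotroph-bacteria system.
#'
#' @param M,B mixotroph and bacterial densities, cells cm^-2.
#' @param theta phagotrophic investment in `[0, 1]`.
#' @param T temperature, degC.
#' @param params a [mixo_params()] object.
#' @return Time derivative, cells cm^-2 d^-1.
#' @examples
#' p <- mixo_params(z = 1)
#' mixotroph_rhs(M = 1e6, B = 1e8, theta = 0.3, T = 18, params = p)
#' @export
mixotroph_rhs <- function(M, B, theta, T, params) {
  (depth_avg_photo_growth(theta, M, T, params) +
     grazing_growth(theta, B, T, params) - params$l) * M
}

#' @rdname mixotroph_rhs
#' @export
bacteria_rhs <- function(M, B, theta, T, params) {
  (params$r * (1 - B / params$K_B) -
     thermal_attack_rate(theta, T, params) * M) * B
}
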