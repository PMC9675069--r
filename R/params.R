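#' Model parameters for the mixotroph-bacteria system
#'
#' Constructs and validates the full parameter set of the
#' mixotroph-bacteria model. Defaults are the baseline simulation values
#' used throughout the package's canonical scenarios (prey carrying
#' capacity at its lower bound, incident light 100 umol quanta m^-2 s^-1).
#' The trade-off shape `z` has no default: it selects the scenario
#' (specialist `z = -1`, linear `z = 0`, generalist `z = 1`) and must be
#' chosen deliberately.
#'
#' @param z trade-off shape parameter (dimensionless). `z > 0` gives a
#'   convex ("generalist") photosynthesis-phagotrophy trade-off, `z = 0`
#'   a linear one, `z < 0` a concave ("specialist") one.
#' @param rho_max maximum carbon-uptake (photosynthesis) rate, d^-1.
#' @param alpha_max maximum attack rate on bacteria, cm^2 d^-1 cell_M^-1.
#' @param b conversion of captured bacteria into mixotroph cells,
#'   cell_M cell_B^-1.
#' @param K_B bacterial carrying capacity, cell_B cm^-2.
#' @param r bacterial growth rate, d^-1.
#' @param h half-saturation light level for photosynthesis,
#'   umol quanta m^-2 s^-1.
#' @param I_in incident surface light, same units as `h`.
#' @param k per-cell light absorbance, cm^2 cell_M^-1.
#' @param l mixotroph mortality rate, d^-1.
#' @param m_rho photosynthetic temperature sensitivity, degC^-1.
#' @param m_alpha heterotrophic temperature sensitivity, degC^-1.
#' @param T0_rho temperature at which photosynthesis shuts off, degC.
#' @param T0_alpha temperature at which phagotrophy shuts off, degC.
#' @param thermal_response `"linear"` (default) for rate multipliers
#'   `max(0, m (T - T0))`, or `"exponential"` for the sensitivity variant
#'   `exp(m (T - 13))`, normalized so both variants equal 1 at 13 degC
#'   with the default coefficients.
#'
#' @details Densities are depth-integrated (cells per cm^2 of surface) for
#'   a well-mixed water column, so light units (per m^2) and absorbance
#'   units (cm^2 per cell) are used exactly as given, with no area
#'   conversion: the parameter set is internally consistent only when
#'   taken at face value.
#'
#' @return An object of class `mixo_params` (a named list).
#' @examples
#' p <- mixo_params(z = 1)
#' p$K_B
#' @export
mixo_params <- function(z,
                        rho_max = 1,
                        alpha_max = 0.15e-8,
                        b = 0.15,
                        K_B = 1e8,
                        r = 0.693,
                        h = 250,
                        I_in = 100,
                        k = 5e-7,
                        l = 0.05,
                        m_rho = 0.1,
                        m_alpha = 0.25,
                        T0_rho = 3,
                        T0_alpha = 9,
                        thermal_response = c("linear", "exponential")) {
  if (missing(z)) {
    stop("'z' (trade-off shape) must be given explicitly; there is no default shape")
  }
  thermal_response <- match.arg(thermal_response)
  p <- list(
    rho_max = rho_max, alpha_max = alpha_max, b = b, K_B = K_B, r = r,
    h = h, I_in = I_in, k = k, l = l, m_rho = m_rho, m_alpha = m_alpha,
    T0_rho = T0_rho, T0_alpha = T0_alpha, z = z,
    thermal_response = thermal_response
  )
  num <- setdiff(names(p), "thermal_response")
  p[num] <- lapply(p[num], function(v) {
    if (is.numeric(v)) as.numeric(v) else v
  })
  validate_mixo_params(p)
  class(p) <- "mixo_params"
  p
}

# Parameter names admissible in a scenario file, in canonical order.
PARAM_KEYS <- c(
  "rho_max", "alpha_max", "b", "K_B", "r", "h", "I_in", "k", "l",
  "m_rho", "m_alpha", "T0_rho", "T0_alpha", "z", "thermal_response"
)

validate_mixo_params <- function(p) {
  num <- PARAM_KEYS[PARAM_KEYS != "thermal_response"]
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter '%s' must be a single finite number", nm))
    }
  }
  strict_pos <- c("rho_max", "alpha_max", "b", "K_B", "r", "h", "I_in",
                  "k", "m_rho", "m_alpha")
  bad <- strict_pos[vapply(strict_pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad)) {
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "))
  }
  if (p$l < 0) stop("mortality 'l' must be >= 0")
  if (!p$thermal_response %in% c("linear", "exponential")) {
    stop("'thermal_response' must be \"linear\" or \"exponential\"")
  }
  invisible(p)
}

#' @export
print.mixo_params <- function(x, ...) {
  shape <- if (x$z > 0) "generalist (convex)" else if (x$z < 0) {
    "specialist (concave)"
  } else "linear"
  cat("Mixotroph-bacteria model parameters\n")
  cat(sprintf("  trade-off: z = %g [%s], thermal response: %s\n",
              x$z, shape, x$thermal_response))
  cat(sprintf("  rho_max = %g /d, alpha_max = %g cm^2/d/cell, b = %g\n",
              x$rho_max, x$alpha_max, x$b))
  cat(sprintf("  prey: K_B = %g cells/cm^2, r = %g /d\n", x$K_B, x$r))
  cat(sprintf("  light: I_in = %g, h = %g umol quanta/m^2/s, k = %g cm^2/cell\n",
              x$I_in, x$h, x$k))
  cat(sprintf("  l = %g /d, m_rho = %g /degC (T0 = %g), m_alpha = %g /degC (T0 = %g)\n",
              x$l, x$m_rho, x$T0_rho, x$m_alpha, x$T0_alpha))
  invisible(x)
}

#' Canonical scenario parameter sets
#'
#' The three trade-off scenarios analyzed throughout: specialist
#' (`z = -1`), linear (`z = 0`) and generalist (`z = 1`), all with
#' `K_B = 1e8` cells/cm^2 and `I_in = 100` umol quanta m^-2 s^-1.
#'
#' @param shape one of `"specialist"`, `"linear"`, `"generalist"`.
#' @param ... overrides passed on to [mixo_params()].
#' @return A `mixo_params` object.
#' @examples
#' canonical_params("generalist")
#' @export
canonical_params <- function(shape = c("specialist", "linear", "generalist"),
                             ...) {
  shape <- match.arg(shape)
  z <- c(specialist = -1, linear = 0, generalist = 1)[[shape]]
  mixo_params(z = z, ...)
}

check_theta <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 1)) {
    stop("phagotrophic investment 'theta' must lie in [0, 1]")
  }
  invisible(theta)
}
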