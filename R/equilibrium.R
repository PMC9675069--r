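#' Prey nullcline
#'
#' The nonnegative bacterial density at which prey growth balances grazing
#' for a fixed mixotroph density: `B = max(0, K_B (1 - alpha(theta,T) M / r))`.
#' Substituting this into the mixotroph per-capita growth reduces the
#' two-dimensional steady-state problem to one dimension in `M`.
#'
#' @param M mixotroph density, cell_M cm^-2 (vectorized).
#' @param theta phagotrophic investment in `[0, 1]`.
#' @param T temperature, degC.
#' @param params a [mixo_params()] object.
#' @return Bacterial density, cell_B cm^-2.
#' @export
prey_nullcline <- function(M, theta, T, params) {
  a <- thermal_attack_rate(theta, T, params)
  pmax(0, params$K_B * (1 - a * M / params$r))
}

#' Per-capita growth of a rare mixotroph in an empty environment
#'
#' Growth rate of a mixotroph with investment `theta` invading an
#' environment with no resident (`M -> 0`, prey at carrying capacity):
#' `rho(theta,z,T) I_in/(h + I_in) + b alpha(theta,T) K_B - l`. Its sign
#' decides viability of a strategy from scratch, and drives the gray-region
#' (nonviable-resident) semantics of pairwise invasibility plots.
#'
#' @inheritParams prey_nullcline
#' @return Per-capita growth rate, d^-1 (vectorized over `theta`).
#' @examples
#' p <- mixo_params(z = 1)
#' empty_environment_growth(0, 13, p)  # positive: phototroph viable
#' empty_environment_growth(1, 13, p)  # negative: pure phagotroph not
#' @export
empty_environment_growth <- function(theta, T, params) {
  depth_avg_photo_growth(theta, rep(0, length(theta)), T, params) +
    grazing_growth(theta, params$K_B, T, params) - params$l
}

# Per-capita growth of the resident along the prey nullcline (the reduced
# 1-D steady-state condition): zero at any interior equilibrium.
resident_percap <- function(M, theta, T, params) {
  depth_avg_photo_growth(theta, M, T, params) +
    grazing_growth(theta, prey_nullcline(M, theta, T, params), T, params) -
    params$l
}

#' Local stability of an interior equilibrium
#'
#' Evaluates the 2x2 Jacobian of the mixotroph-bacteria system by central
#' finite differences at a point and tests whether both eigenvalues have
#' negative real part.
#'
#' @param M,B densities at the point to test, cells cm^-2.
#' @inheritParams prey_nullcline
#' @return Logical flag.
#' @export
local_stability <- function(M, B, theta, T, params) {
  f <- function(s) c(mixotroph_rhs(s[1], s[2], theta, T, params),
                     bacteria_rhs(s[1], s[2], theta, T, params))
  s0 <- c(M, B)
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    d <- max(abs(s0[j]), 1) * 1e-6
    up <- s0; up[j] <- up[j] + d
    dn <- s0; dn[j] <- max(0, dn[j] - d)
    J[, j] <- (f(up) - f(dn)) / (up[j] - dn[j])
  }
  all(Re(eigen(J, only.values = TRUE)$values) < 0)
}

#' Resident ecological equilibrium
#'
#' Solves for the steady state `(M*, B*)` of a resident mixotroph with
#' investment `theta` at temperature `T`. The prey nullcline is substituted
#' into the mixotroph per-capita growth, and the resulting one-dimensional
#' condition is solved for `M > 0` by a logarithmic-grid sign scan followed
#' by Brent refinement (the steady states have no closed form). If no
#' positive root exists -- equivalently, if
#' [empty_environment_growth()] is non-positive -- the population is
#' clipped to the empty boundary state `M* = 0`, `B* = K_B` and flagged
#' nonviable.
#'
#' When several interior roots exist all are reported, and the largest
#' locally stable one is designated the resident equilibrium (the state
#' reached by forward dynamics from high density). A `prey_extinct`
#' boundary (`B* = 0`) is reported with a warning: it lies outside the
#' analyzed regime.
#'
#' @inheritParams prey_nullcline
#' @param M_range search range for `M` (cells cm^-2); the sign scan uses a
#'   logarithmic grid over this interval and expands it if growth has not
#'   changed sign by the upper end.
#' @param n_scan number of scan points.
#' @return An object of class `mixo_equilibrium`: a list with elements
#'   `theta`, `T`, `M_star`, `B_star`, `viable`, `boundary` (one of
#'   `"interior"`, `"empty"`, `"prey_extinct"`), `residual` (max absolute
#'   right-hand side at the reported state), `locally_stable`, and `roots`
#'   (a data.frame of all positive roots found, with per-root stability).
#' @examples
#' p <- mixo_params(z = 1)
#' find_resident_equilibrium(0, 13, p)
#' @export
find_resident_equilibrium <- function(theta, T, params,
                                      M_range = c(1e-2, 1e12),
                                      n_scan = 240) {
  check_theta(theta)
  empty_g <- empty_environment_growth(theta, T, params)
  res <- list(theta = theta, T = T, M_star = 0, B_star = params$K_B,
              viable = FALSE, boundary = "empty", residual = 0,
              locally_stable = empty_g <= 0,
              roots = data.frame(M = numeric(0), B = numeric(0),
                                 stable = logical(0)))
  class(res) <- "mixo_equilibrium"
  if (empty_g <= 0) return(res)

  f <- function(M) resident_percap(M, theta, T, params)
  lo <- M_range[1]; hi <- M_range[2]
  roots <- numeric(0)
  for (attempt in 1:3) {
    grid <- exp(seq(log(lo), log(hi), length.out = n_scan))
    fg <- f(grid)
    flip <- which(fg[-n_scan] > 0 & fg[-1] <= 0 |
                    fg[-n_scan] <= 0 & fg[-1] > 0)
    roots <- vapply(flip, function(i) {
      stats::uniroot(f, lower = grid[i], upper = grid[i + 1],
                     f.lower = fg[i], f.upper = fg[i + 1],
                     tol = 1e-10 * grid[i + 1])$root
    }, numeric(1))
    if (length(roots) > 0 && fg[n_scan] <= 0) break
    hi <- hi * 1e3  # adaptive bracket expansion
    if (attempt == 3) {
      stop(sprintf(paste0("no sign change of resident growth found for M in ",
                          "[%g, %g] although a rare invader grows ",
                          "(theta = %g, T = %g)"), lo, hi, theta, T))
    }
  }

  B_at <- function(M) prey_nullcline(M, theta, T, params)
  stable <- vapply(roots, function(M) {
    local_stability(M, B_at(M), theta, T, params)
  }, logical(1))
  res$roots <- data.frame(M = roots, B = B_at(roots), stable = stable)
  pick <- if (any(stable)) max(roots[stable]) else max(roots)
  res$M_star <- pick
  res$B_star <- B_at(pick)
  res$viable <- TRUE
  res$boundary <- if (res$B_star <= 0) "prey_extinct" else "interior"
  if (res$boundary == "prey_extinct") {
    warning(sprintf(paste0("prey driven extinct at equilibrium ",
                           "(theta = %g, T = %g): outside the analyzed ",
                           "regime"), theta, T))
  }
  res$locally_stable <- local_stability(res$M_star, res$B_star, theta, T,
                                        params)
  res$residual <- max(abs(c(
    mixotroph_rhs(res$M_star, res$B_star, theta, T, params) /
      max(res$M_star, 1),
    bacteria_rhs(res$M_star, res$B_star, theta, T, params) /
      max(res$B_star, 1)
  )))
  res
}

#' @export
print.mixo_equilibrium <- function(x, ...) {
  cat(sprintf("Resident equilibrium (theta = %g, T = %g degC)\n", x$theta, x$T))
  cat(sprintf("  M* = %.6g cells/cm^2, B* = %.6g cells/cm^2 [%s]\n",
              x$M_star, x$B_star, x$boundary))
  cat(sprintf("  viable: %s, locally stable: %s, per-capita residual = %.3g\n",
              x$viable, x$locally_stable, x$residual))
  if (nrow(x$roots) > 1) {
    cat(sprintf("  note: %d positive roots found; largest stable root reported\n",
                nrow(x$roots)))
  }
  invisible(x)
}

# Internal: equilibrium reduced to the (M*, B*) pair adaptive dynamics
# needs, with the empty-environment fallback for nonviable residents.
resident_state <- function(theta, T, params) {
  eq <- find_resident_equilibrium(theta, T, params)
  list(M = eq$M_star, B = eq$B_star, viable = eq$viable)
}
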