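#' Invasion fitness of a rare mutant
#'
#' Per-capita growth rate of a rare mutant with investment `theta_mut`
#' appearing in a resident population with investment `theta_res` at its
#' ecological equilibrium:
#' `lambda = rho(theta_mut, z, T) Lbar(M*) + b alpha(theta_mut, T) B* - l`,
#' where `Lbar(M*)` is the depth-averaged light factor set by the
#' resident's density. A viable resident at its own equilibrium always has
#' `lambda(theta, theta) = 0`. If the resident is nonviable the mutant
#' invades an empty environment (`M* = 0`, `B* = K_B`) and the fitness
#' reduces to [empty_environment_growth()].
#'
#' @param theta_mut mutant investment in `[0, 1]` (vectorized).
#' @param theta_res resident investment in `[0, 1]`.
#' @param T temperature, degC.
#' @param params a [mixo_params()] object.
#' @param state optional precomputed resident state (as returned by the
#'   equilibrium solver), to avoid re-solving when scanning many mutants.
#' @return Invasion fitness, d^-1.
#' @examples
#' p <- mixo_params(z = 1)
#' invasion_fitness(0.5, 0.2, 18, p)
#' @export
invasion_fitness <- function(theta_mut, theta_res, T, params, state = NULL) {
  check_theta(theta_mut)
  if (is.null(state)) {
    check_theta(theta_res)
    state <- resident_state(theta_res, T, params)
  }
  mutant_growth(theta_mut, T, params, state)
}

# Mutant per-capita growth in a fixed environment (M, B).
mutant_growth <- function(theta_mut, T, params, state) {
  depth_avg_photo_growth(theta_mut, rep(state$M, length(theta_mut)), T,
                         params) +
    grazing_growth(theta_mut, state$B, T, params) - params$l
}

# Selection gradient in a fixed environment: central finite difference in
# the mutant direction, one-sided at the trait boundaries.
gradient_in_state <- function(theta, T, params, state, step = 1e-5) {
  lo <- max(0, theta - step)
  hi <- min(1, theta + step)
  (mutant_growth(hi, T, params, state) -
     mutant_growth(lo, T, params, state)) / (hi - lo)
}

#' Selection gradient at a resident strategy
#'
#' Derivative of invasion fitness with respect to the mutant trait,
#' evaluated at `theta_mut = theta_res` (central finite difference with
#' step `1e-5`; one-sided at the boundaries). Its sign gives the direction
#' of gradual trait substitution.
#'
#' @inheritParams invasion_fitness
#' @param theta_res resident investment in `[0, 1]`.
#' @param step finite-difference step in trait units.
#' @param require_viable if `TRUE` (default), a nonviable resident is an
#'   error: the gradient of invasion into an environment the resident does
#'   not set is reported through [find_singular_points()] and
#'   [ess_curve()] instead.
#' @return Gradient, d^-1 per unit trait.
#' @export
selection_gradient <- function(theta_res, T, params, step = 1e-5,
                               require_viable = TRUE) {
  check_theta(theta_res)
  state <- resident_state(theta_res, T, params)
  if (require_viable && !state$viable) {
    stop(sprintf(paste0("resident theta = %g is not viable at T = %g; ",
                        "no resident-set environment exists"), theta_res, T))
  }
  gradient_in_state(theta_res, T, params, state, step = step)
}

#' Pairwise invasibility plot (PIP) grid
#'
#' Categorizes the sign structure of invasion fitness over all
#' (resident, mutant) trait pairs on a regular grid:
#' \describe{
#'   \item{`mutant_invades`}{resident viable and `lambda > 0`.}
#'   \item{`mutant_excluded`}{resident viable and `lambda <= 0`.}
#'   \item{`resident_nonviable_mutant_viable`}{resident nonviable but the
#'     mutant can invade the empty environment.}
#'   \item{`mutant_nonviable`}{neither can grow.}
#' }
#' The last two categories make up the "gray" region of the plots, where
#' no resident-set environment exists.
#'
#' @inheritParams invasion_fitness
#' @param grid_n number of grid points per axis (`>= 3`).
#' @param tol numerical tolerance: fitness within `tol` of zero (e.g. on
#'   the diagonal, where it vanishes identically) is not counted as
#'   invasion.
#' @return An object of class `mixo_pip`: list with `theta_res_grid`,
#'   `theta_mut_grid`, `category` (a `grid_n x grid_n` factor matrix,
#'   mutants in rows), `lambda` (fitness matrix), `resident_viable`, `T`.
#' @examples
#' p <- mixo_params(z = -1)
#' pip <- compute_pip(13, p, grid_n = 21)
#' table(pip$category)
#' @export
compute_pip <- function(T, params, grid_n = 101, tol = 1e-8) {
  if (grid_n < 3) stop("'grid_n' must be at least 3")
  th <- seq(0, 1, length.out = grid_n)
  lambda <- matrix(NA_real_, grid_n, grid_n)
  viable <- logical(grid_n)
  for (j in seq_len(grid_n)) {
    st <- resident_state(th[j], T, params)
    viable[j] <- st$viable
    lambda[, j] <- mutant_growth(th, T, params, st)
  }
  empty_ok <- empty_environment_growth(th, T, params) > 0
  cat_lv <- c("mutant_invades", "mutant_excluded",
              "resident_nonviable_mutant_viable", "mutant_nonviable")
  category <- matrix(cat_lv[2], grid_n, grid_n)
  for (j in seq_len(grid_n)) {
    category[, j] <- if (viable[j]) {
      ifelse(lambda[, j] > tol, cat_lv[1], cat_lv[2])
    } else {
      ifelse(empty_ok, cat_lv[3], cat_lv[4])
    }
  }
  structure(list(theta_res_grid = th, theta_mut_grid = th,
                 category = matrix(factor(category, levels = cat_lv),
                                   grid_n, grid_n),
                 lambda = lambda, resident_viable = viable, T = T),
            class = "mixo_pip")
}

#' @export
print.mixo_pip <- function(x, ...) {
  cat(sprintf("Pairwise invasibility plot at T = %g degC (%d x %d grid)\n",
              x$T, length(x$theta_mut_grid), length(x$theta_res_grid)))
  print(table(x$category))
  invisible(x)
}

#' @describeIn compute_pip long-format conversion (columns `theta_res`,
#'   `theta_mut`, `category`, `lambda`), suitable for CSV export.
#' @param x a `mixo_pip` object.
#' @param ... unused.
#' @export
as.data.frame.mixo_pip <- function(x, ...) {
  data.frame(
    theta_res = rep(x$theta_res_grid, each = length(x$theta_mut_grid)),
    theta_mut = rep(x$theta_mut_grid, times = length(x$theta_res_grid)),
    category = as.character(x$category[cbind(
      rep(seq_along(x$theta_mut_grid), times = length(x$theta_res_grid)),
      rep(seq_along(x$theta_res_grid), each = length(x$theta_mut_grid)))]),
    lambda = as.vector(x$lambda)
  )
}

#' Locate and classify evolutionarily singular strategies
#'
#' Scans the selection gradient over a trait grid, refines each
#' zero-crossing by Brent bisection, and classifies the singular points by
#' the standard second-order conditions: evolutionary stability from the
#' curvature of invasion fitness in the mutant direction (step
#' `curv_step`), convergence stability from the slope of the gradient
#' through the crossing. In the nonviable-resident ("gray") region the
#' gradient of invasion into the empty environment is used, matching the
#' PIP semantics; such points carry `resident_viable = FALSE`.
#'
#' Classification: a convergence-unstable point is a `repeller`; a
#' convergence-stable point is an `ESS` if fitness curvature is below
#' `-tol_curv`, a `branching_point` if above `+tol_curv`, and `neutral`
#' when the curvature magnitude is within `tol_curv` (the flat fitness
#' landscape of the linear trade-off). Trait boundaries toward which the
#' one-sided gradient points are appended as `boundary_attractor` rows.
#'
#' @inheritParams invasion_fitness
#' @param grid_n number of scan points over `[0, 1]`.
#' @param curv_step finite-difference step for the fitness curvature.
#' @param tol_curv classification tolerance on the curvature; below this
#'   magnitude fitness evaluations are dominated by solver noise.
#' @return A data.frame with columns `theta_star`, `T`, `classification`,
#'   `evolutionarily_stable`, `convergence_stable`, `lambda_curv`,
#'   `grad_slope`, `resident_viable`.
#' @examples
#' p <- mixo_params(z = -1)
#' find_singular_points(23, p, grid_n = 51)
#' @export
find_singular_points <- function(T, params, grid_n = 201, curv_step = 1e-3,
                                 tol_curv = 1e-6) {
  th <- seq(0, 1, length.out = grid_n)
  states <- lapply(th, resident_state, T = T, params = params)
  g <- vapply(seq_along(th), function(i) {
    gradient_in_state(th[i], T, params, states[[i]])
  }, numeric(1))

  grad_at <- function(theta) {
    gradient_in_state(theta, T, params, resident_state(theta, T, params))
  }
  rows <- list()
  flips <- which(sign(g[-grid_n]) * sign(g[-1]) < 0)
  for (i in flips) {
    theta_star <- stats::uniroot(grad_at, lower = th[i], upper = th[i + 1],
                                 f.lower = g[i], f.upper = g[i + 1],
                                 tol = 1e-9)$root
    st <- resident_state(theta_star, T, params)
    d <- curv_step
    curv <- (mutant_growth(min(1, theta_star + d), T, params, st) -
               2 * mutant_growth(theta_star, T, params, st) +
               mutant_growth(max(0, theta_star - d), T, params, st)) / d^2
    dd <- max(curv_step, 2 * (th[2] - th[1]))
    slope <- (grad_at(min(1, theta_star + dd)) -
                grad_at(max(0, theta_star - dd))) /
      (min(1, theta_star + dd) - max(0, theta_star - dd))
    conv <- slope < 0
    evst <- curv < -tol_curv
    classification <- if (!conv) {
      "repeller"
    } else if (evst) {
      "ESS"
    } else if (curv > tol_curv) {
      "branching_point"
    } else {
      "neutral"
    }
    rows[[length(rows) + 1]] <- data.frame(
      theta_star = theta_star, T = T, classification = classification,
      evolutionarily_stable = evst, convergence_stable = conv,
      lambda_curv = curv, grad_slope = slope,
      resident_viable = st$viable
    )
  }
  # boundaries attract when the one-sided gradient points into them
  if (g[1] < 0) {
    rows[[length(rows) + 1]] <- data.frame(
      theta_star = 0, T = T, classification = "boundary_attractor",
      evolutionarily_stable = NA, convergence_stable = TRUE,
      lambda_curv = NA_real_, grad_slope = NA_real_,
      resident_viable = states[[1]]$viable
    )
  }
  if (g[grid_n] > 0) {
    rows[[length(rows) + 1]] <- data.frame(
      theta_star = 1, T = T, classification = "boundary_attractor",
      evolutionarily_stable = NA, convergence_stable = TRUE,
      lambda_curv = NA_real_, grad_slope = NA_real_,
      resident_viable = states[[grid_n]]$viable
    )
  }
  if (!length(rows)) {
    return(data.frame(theta_star = numeric(0), T = numeric(0),
                      classification = character(0),
                      evolutionarily_stable = logical(0),
                      convergence_stable = logical(0),
                      lambda_curv = numeric(0), grad_slope = numeric(0),
                      resident_viable = logical(0)))
  }
  do.call(rbind, rows)
}

#' Trait-substitution ascent to an evolutionary attractor
#'
#' Simulates gradual evolution as a sequence of invasion-replacement
#' events: from the current resident, a mutant one step (`step`, default
#' `1e-3`) along the selection gradient replaces the resident whenever its
#' invasion fitness is positive. When no step of at least `min_step`
#' (default `1e-4`) in the gradient direction succeeds, a local scan at
#' `min_step` resolution checks for any remaining improving mutant; the
#' ascent stops when none improves fitness by more than `tol_improve`.
#' Nonviable residents evolve under invasion-of-empty-environment fitness,
#' so a lineage can cross (or end in) the nonviable region; viability of
#' the final attractor is reported.
#'
#' @inheritParams invasion_fitness
#' @param theta_init starting resident investment in `[0, 1]`.
#' @param step mutational step size in trait units.
#' @param min_step resolution of the terminal local scan; steps are halved
#'   down to this size when larger ones are rejected.
#' @param max_steps substitution budget; exceeding it is a diagnostic
#'   error.
#' @param tol_improve fitness improvement below which a mutant is treated
#'   as neutral and the ascent as converged.
#' @return A list with `theta` (the attractor), `viable`, `M_star`,
#'   `B_star`, `steps`.
#' @examples
#' p <- mixo_params(z = 1)
#' trait_substitution(0.5, 13, p)$theta
#' @export
trait_substitution <- function(theta_init, T, params, step = 1e-3,
                               min_step = 1e-4, max_steps = 1e5,
                               tol_improve = 1e-10) {
  check_theta(theta_init)
  theta <- theta_init
  last_theta <- NA_real_
  for (it in seq_len(max_steps)) {
    st <- resident_state(theta, T, params)
    g <- gradient_in_state(theta, T, params, st)
    # A viable resident sits at lambda = 0 in its own environment, so a
    # replacing mutant needs positive invasion fitness. In the
    # nonviable-resident (extinct) region the lineage instead climbs the
    # empty-environment growth surface itself.
    thr <- if (st$viable) tol_improve else {
      mutant_growth(theta, T, params, st) + tol_improve
    }
    dir <- sign(g)
    moved <- FALSE
    if (dir != 0) {
      s <- step
      while (s >= min_step) {
        cand <- min(1, max(0, theta + dir * s))
        if (cand != theta &&
            mutant_growth(cand, T, params, st) > thr) {
          if (identical(cand, last_theta)) break  # 2-cycle around attractor
          last_theta <- theta
          theta <- cand
          moved <- TRUE
          break
        }
        s <- s / 2
      }
    }
    if (!moved) {
      off <- min_step * (1:10)
      cand <- unique(pmin(1, pmax(0, c(theta + off, theta - off))))
      cand <- cand[cand != theta]
      lam <- mutant_growth(cand, T, params, st)
      if (!length(cand) || max(lam) <= thr) {
        return(list(theta = theta, viable = st$viable, M_star = st$M,
                    B_star = if (st$viable) st$B else params$K_B,
                    steps = it))
      }
      best <- cand[which.max(lam)]
      if (identical(best, last_theta)) {
        # bouncing across the attractor at scan resolution: settled
        return(list(theta = theta, viable = st$viable, M_star = st$M,
                    B_star = if (st$viable) st$B else params$K_B,
                    steps = it))
      }
      last_theta <- theta
      theta <- best
    }
  }
  stop(sprintf(paste0("trait substitution did not converge within %d ",
                      "steps (T = %g, start = %g)"), max_steps, T,
               theta_init))
}

#' Evolutionarily stable investment across a temperature grid
#'
#' Runs the trait-substitution ascent at each temperature, warm-starting
#' from the previous temperature's attractor so branch identity is kept
#' across the grid. Specialist trade-offs (`z < 0`) are bistable, so two
#' branches are tracked, started from `theta = 0.05` and `theta = 0.95`;
#' other shapes use a single branch started from `theta_init`.
#'
#' @inheritParams invasion_fitness
#' @param T_grid ascending temperatures, degC.
#' @param theta_init starting investment for the first temperature.
#' @param ... passed on to [trait_substitution()].
#' @return A data.frame with columns `T`, `branch` (`"low"`/`"high"` for
#'   bistable shapes, `"main"` otherwise), `theta_ess`, `viable`,
#'   `M_star`, `B_star`.
#' @examples
#' p <- mixo_params(z = 0)
#' ess_curve(p, T_grid = c(13, 18), theta_init = 0)
#' @export
ess_curve <- function(params, T_grid = 13:33, theta_init = 0.5, ...) {
  if (is.unsorted(T_grid)) stop("'T_grid' must be ascending")
  check_theta(theta_init)
  starts <- if (params$z < 0) c(low = 0.05, high = 0.95) else {
    c(main = theta_init)
  }
  out <- list()
  for (br in names(starts)) {
    theta <- starts[[br]]
    for (T in T_grid) {
      fix <- trait_substitution(theta, T, params, ...)
      theta <- fix$theta
      out[[length(out) + 1]] <- data.frame(
        T = T, branch = br, theta_ess = fix$theta, viable = fix$viable,
        M_star = fix$M_star, B_star = fix$B_star
      )
    }
  }
  do.call(rbind, out)
}
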