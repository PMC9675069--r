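#' Carbon-cycling comparison: evolving versus genetically static mixotrophs
#'
#' For each temperature on a grid, contrasts an evolving lineage (resident
#' investment at the temperature-specific attractor `theta_ESS(T)`) with a
#' genetically static lineage (investment frozen at its attractor from the
#' reference temperature). At each equilibrium the population growth-rate
#' components `P * M*` (photosynthesis; carbon-fixation proxy) and
#' `G * M*` (grazing; remineralization proxy) are recorded. For `z < 0`
#' the system is evolutionarily bistable, so the photosynthetic
#' (`theta = 0`) and phagotrophic (`theta = 1`) specialist branches are
#' both emitted; on each, evolution does not move the trait, so evolving
#' and static records coincide.
#'
#' At an interior equilibrium `P + G = l`, so `photo_flux + graze_flux =
#' l * M*` holds for every viable record.
#'
#' @param params a [mixo_params()] object.
#' @param T_grid ascending temperatures, degC.
#' @param reference_T temperature whose attractor defines the static
#'   lineage (must lie within the span of `T_grid`).
#' @param theta_init starting investment for the continuation (non-bistable
#'   shapes only).
#' @param ... passed on to [trait_substitution()] via [ess_curve()].
#' @return A data.frame with one row per (temperature, scenario, branch):
#'   columns `T`, `scenario` (`"evolving"`/`"static"`), `z`, `branch`,
#'   `theta_used`, `M_star`, `B_star`, `photo_flux`, `graze_flux`
#'   (fluxes in cell_M cm^-2 d^-1).
#' @examples
#' p <- mixo_params(z = 0)
#' cc <- carbon_cycling_comparison(p, T_grid = c(13, 18))
#' @export
carbon_cycling_comparison <- function(params, T_grid = 13:33,
                                      reference_T = 13, theta_init = 0.5,
                                      ...) {
  if (reference_T < min(T_grid) || reference_T > max(T_grid)) {
    stop("'reference_T' must lie within the range of 'T_grid'")
  }
  ess <- ess_curve(params, T_grid = T_grid, theta_init = theta_init, ...)
  ref <- ess[ess$T == reference_T, ]
  if (!nrow(ref)) stop("'reference_T' must be a point of 'T_grid'")

  record <- function(T, scenario, branch, theta) {
    eq <- find_resident_equilibrium(theta, T, params)
    Pf <- if (eq$M_star > 0) {
      depth_avg_photo_growth(theta, eq$M_star, T, params) * eq$M_star
    } else 0
    Gf <- if (eq$M_star > 0) {
      grazing_growth(theta, eq$B_star, T, params) * eq$M_star
    } else 0
    data.frame(T = T, scenario = scenario, z = params$z, branch = branch,
               theta_used = theta, M_star = eq$M_star, B_star = eq$B_star,
               photo_flux = Pf, graze_flux = Gf)
  }

  out <- list()
  for (br in unique(ess$branch)) {
    theta_ref <- ref$theta_ess[ref$branch == br]
    evo <- ess[ess$branch == br, ]
    for (i in seq_len(nrow(evo))) {
      out[[length(out) + 1]] <-
        record(evo$T[i], "evolving", br, evo$theta_ess[i])
      out[[length(out) + 1]] <-
        record(evo$T[i], "static", br, theta_ref)
    }
  }
  do.call(rbind, out)
}

#' Sweep the evolutionary attractor over resource landscapes
#'
#' Cross-product sweep of [ess_curve()] over prey carrying capacities and
#' incident light levels, to map how the evolutionarily stable investment
#' responds to prey availability and light at each temperature. Failures
#' in a sweep cell are caught and logged as a warning; the sweep continues.
#'
#' @inheritParams carbon_cycling_comparison
#' @param K_B_values prey carrying capacities to sweep, cell_B cm^-2.
#' @param I_in_values incident light levels to sweep,
#'   umol quanta m^-2 s^-1.
#' @return A tidy data.frame: one row per
#'   (temperature, K_B, I_in, z, branch), with columns of [ess_curve()]
#'   plus `K_B` and `I_in`.
#' @examples
#' p <- mixo_params(z = 1)
#' landscape_sweep(p, T_grid = c(18, 23), K_B_values = c(1e8, 3e8),
#'                 I_in_values = 100)
#' @export
landscape_sweep <- function(params, T_grid = 13:33,
                            K_B_values = c(1e8, 3e8),
                            I_in_values = c(100, 150),
                            theta_init = 0.5, ...) {
  if (!length(K_B_values) || !length(I_in_values)) {
    stop("'K_B_values' and 'I_in_values' must be nonempty")
  }
  out <- list()
  for (K_B in K_B_values) {
    for (I_in in I_in_values) {
      p <- params
      p$K_B <- K_B
      p$I_in <- I_in
      validate_mixo_params(p)
      cell <- tryCatch(
        ess_curve(p, T_grid = T_grid, theta_init = theta_init, ...),
        error = function(e) {
          warning(sprintf("sweep cell K_B = %g, I_in = %g failed: %s",
                          K_B, I_in, conditionMessage(e)))
          NULL
        })
      if (!is.null(cell)) {
        cell$K_B <- K_B
        cell$I_in <- I_in
        cell$z <- params$z
        out[[length(out) + 1]] <- cell
      }
    }
  }
  if (!length(out)) stop("all sweep cells failed")
  do.call(rbind, out)
}
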