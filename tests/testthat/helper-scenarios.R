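# Canonical scenario fixtures used across the suite.
p_spec <- canonical_params("specialist")   # z = -1
p_lin  <- canonical_params("linear")       # z =  0
p_gen  <- canonical_params("generalist")   # z =  1

# Independent oracle: integrate the coupled mixotroph-bacteria system to
# (near) steady state with lsoda, from moderate initial densities. Used to
# cross-check the nullcline-substitution root solver; it never replaces it.
integrate_to_steady <- function(theta, T, params, M0 = 1e4, B0 = NULL,
                                chunk = 2e4, max_chunks = 20) {
  if (is.null(B0)) B0 <- params$K_B
  rhs <- function(t, y, parms) {
    M <- max(y[1], 0)
    B <- max(y[2], 0)
    list(c(mixotroph_rhs(M, B, theta, T, params),
           bacteria_rhs(M, B, theta, T, params)))
  }
  y <- c(M = M0, B = B0)
  for (i in seq_len(max_chunks)) {
    out <- deSolve::lsoda(y, c(0, chunk), rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-6)
    y <- out[nrow(out), c("M", "B")]
    percap <- abs(unlist(rhs(0, y, NULL))) / pmax(y, 1)
    if (all(percap < 1e-9)) break  # settled (interior or boundary)
  }
  list(M = unname(y["M"]), B = unname(y["B"]))
}

# Equilibrium grazing and photosynthesis population fluxes for a strategy.
eq_fluxes <- function(theta, T, params) {
  eq <- find_resident_equilibrium(theta, T, params)
  if (eq$M_star <= 0) {
    return(list(photo = 0, graze = 0, M = eq$M_star, B = eq$B_star))
  }
  list(photo = depth_avg_photo_growth(theta, eq$M_star, T, params) * eq$M_star,
       graze = grazing_growth(theta, eq$B_star, T, params) * eq$M_star,
       M = eq$M_star, B = eq$B_star)
}
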