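test_that("invasion fitness vanishes on the diagonal for viable residents", {
  th <- seq(0, 1, length.out = 21)
  for (p in list(p_spec, p_lin, p_gen)) {
    for (T in c(13, 23)) {
      for (theta in th) {
        st <- mixoevolve:::resident_state(theta, T, p)
        if (!st$viable) next
        expect_lt(abs(invasion_fitness(theta, theta, T, p, state = st)),
                  1e-8)
      }
    }
  }
})

test_that("fitness against a nonviable resident is empty-environment growth", {
  # theta_res = 1 is nonviable at 13 degC in every scenario
  th <- seq(0, 1, by = 0.25)
  expect_equal(invasion_fitness(th, 1, 13, p_spec),
               empty_environment_growth(th, 13, p_spec))
})

test_that("selection gradient matches a brute-force two-point oracle", {
  for (case in list(list(p_gen, 0.3, 18), list(p_lin, 0.05, 20),
                    list(p_spec, 0.2, 25))) {
    p <- case[[1]]; theta <- case[[2]]; T <- case[[3]]
    g <- selection_gradient(theta, T, p)
    st <- mixoevolve:::resident_state(theta, T, p)
    d <- 1e-5
    oracle <- (invasion_fitness(theta + d, theta, T, p, state = st) -
                 invasion_fitness(theta - d, theta, T, p, state = st)) /
      (2 * d)
    expect_equal(g, oracle, tolerance = 1e-6)
  }
  # generalist gradient at theta = 0 is strictly positive (theta = 0 never
  # an attractor for the convex trade-off: grazing gain is first order,
  # photosynthetic loss second order)
  expect_gt(selection_gradient(0, 13, p_gen), 0)
  expect_error(selection_gradient(1, 13, p_gen), "not viable")
})

test_that("PIP categories are exclusive, diagonal-excluded, with gray columns", {
  for (p in list(p_spec, p_lin, p_gen)) {
    pip <- compute_pip(13, p, grid_n = 41)
    expect_false(any(is.na(pip$category)))
    diag_cat <- as.character(diag(pip$category))
    expect_false(any(diag_cat == "mutant_invades"))
    # nonviable resident columns carry only the two gray categories
    gray <- c("resident_nonviable_mutant_viable", "mutant_nonviable")
    for (j in which(!pip$resident_viable)) {
      expect_true(all(as.character(pip$category[, j]) %in% gray))
    }
    # theta_res = 1 is nonviable at 13 degC: last column is gray
    expect_false(pip$resident_viable[41])
  }
  df <- as.data.frame(compute_pip(13, p_gen, grid_n = 5))
  expect_identical(nrow(df), 25L)
  expect_identical(names(df), c("theta_res", "theta_mut", "category", "lambda"))
})

test_that("PIP region topology matches the three trade-off regimes", {
  th_at <- function(pip, x) which.min(abs(pip$theta_res_grid - x))
  # specialist at 13 degC: selection points away from mixotrophy for
  # viable residents (theta <~ 0.37; beyond that the concave trade-off
  # makes intermediate residents nonviable -> gray columns)
  pip <- compute_pip(13, p_spec, grid_n = 41)
  j <- th_at(pip, 0.2)
  expect_identical(as.character(pip$category[th_at(pip, 0.1), j]),
                   "mutant_invades")
  expect_identical(as.character(pip$category[th_at(pip, 0.3), j]),
                   "mutant_excluded")
  expect_false(pip$resident_viable[th_at(pip, 0.5)])
  # linear trade-off at 23 degC: selection pushes investment up everywhere
  pip <- compute_pip(23, p_lin, grid_n = 41)
  for (x in c(0.2, 0.5, 0.8)) {
    j <- th_at(pip, x)
    expect_identical(as.character(pip$category[th_at(pip, x + 0.1), j]),
                     "mutant_invades")
    expect_identical(as.character(pip$category[th_at(pip, x - 0.1), j]),
                     "mutant_excluded")
  }
  # generalist at 18 degC: convergence toward the interior ESS (~0.85)
  pip <- compute_pip(18, p_gen, grid_n = 41)
  j <- th_at(pip, 0.5)
  expect_identical(as.character(pip$category[th_at(pip, 0.6), j]),
                   "mutant_invades")
  j <- th_at(pip, 0.95)
  expect_identical(as.character(pip$category[th_at(pip, 0.85), j]),
                   "mutant_invades")
})

test_that("pairwise invasibility signs agree with the substitution direction", {
  # lambda(a, b) > 0 with lambda(b, a) < 0 means a replaces b: the ascent
  # from b must move toward a
  for (case in list(c(0.3, 0.4), c(0.7, 0.6))) {
    a <- case[1]; b <- case[2]
    la <- invasion_fitness(a, b, 18, p_gen)
    lb <- invasion_fitness(b, a, 18, p_gen)
    fix <- trait_substitution(b, 18, p_gen)
    if (la > 0 && lb < 0) {
      expect_gt(abs(b - fix$theta), 0)
      expect_identical(sign(fix$theta - b), sign(a - b))
    }
  }
})

test_that("singular strategies are located and classified by scenario", {
  # generalist, 18 degC: one interior convergence-stable ESS
  sg <- find_singular_points(18, p_gen, grid_n = 101)
  ess <- sg[sg$classification == "ESS", ]
  expect_identical(nrow(ess), 1L)
  expect_gt(ess$theta_star, 0)
  expect_lt(ess$theta_star, 1)
  expect_true(ess$convergence_stable && ess$evolutionarily_stable)
  # no mutant invades the ESS anywhere in trait space (global for z = 1)
  st <- mixoevolve:::resident_state(ess$theta_star, 18, p_gen)
  lam <- invasion_fitness(seq(0, 1, length.out = 101), ess$theta_star, 18,
                          p_gen, state = st)
  expect_lt(max(lam), 1e-8)

  # specialist, 18 degC: interior repeller, both boundaries attracting
  sg <- find_singular_points(18, p_spec, grid_n = 101)
  expect_identical(sum(sg$classification == "repeller"), 1L)
  expect_setequal(sg$theta_star[sg$classification == "boundary_attractor"],
                  c(0, 1))
  rep_pt <- sg[sg$classification == "repeller", ]
  expect_false(rep_pt$convergence_stable)
  # gradient diverges through the repeller: - below, + above
  expect_lt(selection_gradient(max(0, rep_pt$theta_star - 0.05), 18, p_spec,
                               require_viable = FALSE), 0)
  expect_gt(rep_pt$grad_slope, 0)

  # linear trade-off, 18 degC: flat landscape at the neutral interior point
  sg <- find_singular_points(18, p_lin, grid_n = 101)
  neu <- sg[sg$classification == "neutral", ]
  expect_identical(nrow(neu), 1L)
  expect_equal(neu$theta_star, 0.1256, tolerance = 1e-2)
  st <- mixoevolve:::resident_state(neu$theta_star, 18, p_lin)
  lam <- invasion_fitness(seq(0, 1, length.out = 101), neu$theta_star, 18,
                          p_lin, state = st)
  expect_lt(max(abs(lam)), 1e-6)
})

test_that("specialist branching point emerges only at extreme temperature", {
  # within the simulated 13-33 degC range the sole interior singular point
  # is a repeller; a convergence-stable branching point appears when the
  # thermal extrapolation is pushed far beyond it
  sg33 <- find_singular_points(33, p_spec, grid_n = 101)
  expect_false(any(sg33$classification == "branching_point"))
  sg <- find_singular_points(100, p_spec, grid_n = 201)
  br <- sg[sg$classification == "branching_point", ]
  expect_gte(nrow(br), 1L)
  expect_true(all(br$convergence_stable & !br$evolutionarily_stable))
  expect_gt(br$lambda_curv[1], 0)  # fitness minimum: disruptive selection
})

test_that("trait substitution reaches the known attractors", {
  fix <- trait_substitution(0.5, 13, p_gen)
  expect_equal(fix$theta, 0.4435, tolerance = 5e-3)
  expect_true(fix$viable)
  expect_equal(trait_substitution(0.5, 13, p_lin)$theta, 0)
  expect_equal(trait_substitution(0.05, 13, p_spec)$theta, 0)
  high <- trait_substitution(0.95, 13, p_spec)
  expect_equal(high$theta, 1)
  expect_false(high$viable)
  expect_error(trait_substitution(0.5, 13, p_gen, max_steps = 2),
               "did not converge")
})

test_that("generalist attractor rises then falls with temperature", {
  e <- ess_curve(p_gen, T_grid = seq(13, 33, by = 2), theta_init = 0.5)
  expect_identical(unique(e$branch), "main")
  peak <- which.max(e$theta_ess)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(e))
  expect_gt(e$theta_ess[peak], e$theta_ess[1])
  expect_gt(e$theta_ess[peak], e$theta_ess[nrow(e)])
  expect_true(all(e$theta_ess > 0 & e$theta_ess < 1))
})

test_that("specialist curve is bistable with only boundary attractors", {
  e <- ess_curve(p_spec, T_grid = seq(13, 33, by = 4))
  expect_setequal(unique(e$branch), c("low", "high"))
  expect_true(all(e$theta_ess %in% c(0, 1)))
  expect_true(all(e$viable[e$branch == "low"]))
  high <- e[e$branch == "high", ]
  expect_false(any(high$viable[high$T < 18]))
  expect_true(all(high$viable[high$T >= 18]))
  expect_error(ess_curve(p_spec, T_grid = c(20, 15)), "ascending")
})
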