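test_that("colonization and infection success probabilities follow the branching formulas", {
  expect_equal(p_col(0.1, 0.7), 1 - 0.1 / 0.7)
  expect_equal(p_col(0, 0.7), 1)
  expect_equal(p_col(0.7, 0.7), 0)
  expect_warning(out <- p_col(0.9, 0.7), "impossible")
  expect_equal(out, 0)
  expect_error(p_col(0.1, 0), "positive")

  expect_equal(p_inf(85.714, 0.5, 0.5), 1 - 0.5 / (85.714 * 0.5))
  expect_equal(p_inf(1, 0.5, 0.5), 0)          # w * beta = a: threshold
  expect_equal(p_inf(1e12, 0.5, 0.5), 1, tolerance = 1e-10)
  expect_error(p_inf(10, 0.5, 0), "positive")
  expect_true(all(p_inf(c(0.5, 2, 100), 0.5, 0.5) >= 0 &
                  p_inf(c(0.5, 2, 100), 0.5, 0.5) <= 1))
})

test_that("extinction-recolonization selection vanishes for symmetric genotypes", {
  expect_equal(s_ext_rec(85, 85, 0.857, 0.857, 0.988, 0.988), 0)
  expect_equal(s_ext_rec(100, 102, 0.8, 0.8, 0.9, 0.9), 0.02)
  expect_error(s_ext_rec(0, 85, 0.857, 0.857, 0.988, 0.988), "positive")
})

test_that("extinction-recolonization selection is much weaker than cell-level selection", {
  # hand-evaluated chain for the deme parameter set with a 2% division
  # advantage: loads from the logistic closed form, then p_col and p_inf
  r <- 0.7; d <- 0.1; beta <- 0.5; a <- 0.5; K <- 100; s_cell <- 0.02
  w_x <- logistic_equilibrium(r, d, K)
  w_y <- logistic_equilibrium(r * (1 + s_cell), d, K)
  oracle <- (w_y * (1 - d / (r * (1 + s_cell))) * (1 - a / (w_x * beta))) /
            (w_x * (1 - d / r) * (1 - a / (w_y * beta))) - 1
  got <- s_ext_rec(w_x, w_y,
                   p_col(d, r), p_col(d, r * (1 + s_cell)),
                   p_inf(w_x, beta, a), p_inf(w_y, beta, a))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_lt(abs(got), 0.02)
})

test_that("the combined patch selection coefficient is a rate-weighted mean", {
  expect_equal(s_patch(0.02, 0.001, R_conv = 0, R_extrec = 3), 0.001)
  expect_equal(s_patch(0.02, 0.001, R_conv = 3, R_extrec = 0), 0.02)
  expect_equal(s_patch(0.02, 0, R_conv = 1, R_extrec = 1), 0.01)
  # always between its two inputs
  for (k in 1:20) {
    sc <- runif(1, -0.1, 0.1); se <- runif(1, -0.1, 0.1)
    rc <- runif(1); re <- runif(1)
    sp <- s_patch(sc, se, rc, re)
    expect_gte(sp, min(sc, se) - 1e-12)
    expect_lte(sp, max(sc, se) + 1e-12)
  }
  expect_error(s_patch(0.02, 0.001, 0, 0), "positive")
})

test_that("patch-level Moran prediction matches the chain oracle and is monotone", {
  expect_equal(patch_moran_fixation(1e-16, 1, 100), 0.01)
  expect_equal(patch_moran_fixation(0.3, 12, 12), 1)
  expect_equal(patch_moran_fixation(0.1, 1, 4), chain_fixation(0.1, 1, 4),
               tolerance = 1e-10)
  p_i <- patch_moran_fixation(0.05, 1:10, 10)
  expect_true(all(diff(p_i) > 0))
  sp <- seq(-0.3, 0.3, by = 0.05)
  expect_true(all(diff(patch_moran_fixation(sp, 2, 30)) > 0))
  expect_error(patch_moran_fixation(0.1, 5, 4), "i <= X_eq")
  # identical formula as the cell-level reference
  expect_equal(patch_moran_fixation(0.07, 3, 40), moran_fixation(0.07, 3, 40))
})

sym_params <- function(N = 120) {
  coarse_params(N_patches = N, mu = 0.02, w_x = 85.7, w_y = 85.7, w_z = 30,
                P_col_x = 6 / 7, P_col_y = 6 / 7, P_inf_x = 0.988,
                P_inf_y = 0.988, P_xy = 0.01, P_yx = 0.01, T_ext = 20)
}

test_that("the coarse ODE reduces to logistic patch colonization without mutants or infection", {
  prm <- sym_params()
  tr <- integrate_coarse(coarse_state(X = 2), prm, horizon = 200)
  X <- tr$trajectory$X
  expect_true(all(diff(X) > -1e-8))
  expect_equal(tail(X, 1), prm$N_patches, tolerance = 1e-3)
  expect_equal(tail(tr$trajectory$Y, 1), 0)
  expect_equal(tail(tr$trajectory$Z, 1), 0)

  # the empty state is a fixed point
  tr0 <- integrate_coarse(coarse_state(0, 0, 0), prm, horizon = 10)
  expect_true(all(abs(as.matrix(tr0$trajectory[, c("X", "Y", "Z")])) < 1e-12))
})

test_that("coarse trajectories stay in the simplex and respect the genotype symmetry", {
  prm <- sym_params()
  tr <- integrate_coarse(coarse_state(X = 40, Y = 40, Z = 10), prm,
                         horizon = 400)
  occ <- tr$trajectory$X + tr$trajectory$Y + tr$trajectory$Z
  expect_true(all(occ <= prm$N_patches * (1 + 1e-6)))
  expect_true(all(as.matrix(tr$trajectory[, c("X", "Y", "Z")]) >= 0))
  # symmetric parameters and X0 = Y0 force X(t) = Y(t)
  expect_equal(tr$trajectory$X, tr$trajectory$Y, tolerance = 1e-7)

  # label swap: swapping the x/y parameter roles mirrors the trajectory
  asym <- coarse_params(N_patches = 120, mu = 0.02, w_x = 80, w_y = 90,
                        w_z = 30, P_col_x = 0.8, P_col_y = 0.9,
                        P_inf_x = 0.99, P_inf_y = 0.98, P_xy = 0.012,
                        P_yx = 0.01, T_ext = 20)
  swapped <- coarse_params(N_patches = 120, mu = 0.02, w_x = 90, w_y = 80,
                           w_z = 30, P_col_x = 0.9, P_col_y = 0.8,
                           P_inf_x = 0.98, P_inf_y = 0.99, P_xy = 0.01,
                           P_yx = 0.012, T_ext = 20)
  t1 <- integrate_coarse(coarse_state(X = 30, Y = 50, Z = 10), asym, 100)
  t2 <- integrate_coarse(coarse_state(X = 50, Y = 30, Z = 10), swapped, 100)
  expect_equal(t1$trajectory$X, t2$trajectory$Y, tolerance = 1e-6)
  expect_equal(t1$trajectory$Y, t2$trajectory$X, tolerance = 1e-6)
})

test_that("event-rate estimation reads the fluxes off the ODE terms", {
  prm <- sym_params()
  # no infected patches -> no extinction-recolonization flux
  st <- coarse_state(X = 60, Y = 20, Z = 0)
  expect_warning(r0 <- estimate_event_rates(st, prm), "equilibrium")
  expect_equal(r0$R_extrec, 0)
  expect_gt(r0$R_conv, 0)
  # single genotype -> no conversion flux
  st1 <- coarse_state(X = 60, Y = 0, Z = 10)
  r1 <- suppressWarnings(estimate_event_rates(st1, prm))
  expect_equal(r1$R_conv, 0)
  # overrides pass through untouched
  ro <- estimate_event_rates(st, prm, override = c(0.3, 0.7))
  expect_equal(ro, list(R_conv = 0.3, R_extrec = 0.7))
})
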