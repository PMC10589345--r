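test_that("parameter invariants are enforced, not clamped", {
  expect_error(abm_params(R = 0.9, D = 0.2, n1 = 10, n2 = 10), "budget")
  expect_error(abm_params(R = 0.5, D = 0.05, s = 0.95, n1 = 10, n2 = 10),
               "budget")
  expect_error(abm_params(R = 0.5, D = 0.05, A = 0.6, B = 0.5,
                          n1 = 10, n2 = 10), "budget")
  expect_error(abm_params(R = 0.5, D = 0.05, s = -1.5, n1 = 10, n2 = 10),
               "non-negative")
  expect_error(abm_params(R = 0.5, D = 0.05, n1 = 2, n2 = 10), ">= 3")
  expect_silent(abm_params(R = 0.5, D = 0.5, n1 = 3, n2 = 3))
})

test_that("block initial condition has the right arithmetic", {
  p <- abm_params(R = 0.5, D = 0.05, A = 0.1, B = 0.2, n1 = 100, n2 = 100)
  st <- abm_init_block(p, outer_side = 50, inner_side = 10)
  expect_equal(unname(st$counts["uninf_wt"]), 50^2 - 10^2)
  expect_equal(unname(st$counts["inf_wt"]), 100)
  expect_equal(sum(st$lattice == 0), 100^2 - 50^2)
  expect_equal(st$N1, 50^2)

  # degenerate: no infected block
  st0 <- abm_init_block(p, outer_side = 20, inner_side = 0)
  expect_equal(unname(st0$counts["inf_wt"]), 0)
  expect_equal(unname(st0$counts["uninf_wt"]), 400)

  # boundary: the whole grid infected
  pf <- abm_params(R = 0.5, D = 0.05, A = 0.1, B = 0.2, n1 = 10, n2 = 10)
  stf <- abm_init_block(pf, outer_side = 10, inner_side = 10)
  expect_equal(unname(stf$counts["inf_wt"]), 100)
  expect_equal(unname(stf$counts["uninf_wt"]), 0)

  expect_error(abm_init_block(pf, outer_side = 11), "<=")
})

test_that("elementary rules do what the rule table says (forced draws)", {
  p <- abm_params(R = 0.5, D = 0.05, A = 0.1, B = 0.3, s = 0, n1 = 5, n2 = 5)
  lat <- matrix(0L, 5, 5)
  lat[3, 3] <- 1L
  st <- grid_state(lat)

  # division into an empty Moore neighbor duplicates the genotype
  div <- abm_elementary_update(st, p, site = c(3, 3), u = 0.49, neighbor = 5)
  expect_equal(div$event, "division")
  expect_equal(unname(div$state$counts["uninf_wt"]), 2)
  expect_equal(div$state$lattice[3, 4], 1L)  # neighbor 5 = E

  # death empties the site
  dth <- abm_elementary_update(st, p, site = c(3, 3), u = 0.5 + 0.04)
  expect_equal(dth$event, "death")
  expect_equal(dth$state$N1, 0)

  # no event above R + D
  non <- abm_elementary_update(st, p, site = c(3, 3), u = 0.99)
  expect_equal(non$event, "none")
  expect_identical(non$state$lattice, st$lattice)

  # division into an occupied site silently fails
  lat2 <- lat; lat2[3, 4] <- 1L
  blk <- abm_elementary_update(grid_state(lat2), p, site = c(3, 3),
                               u = 0.1, neighbor = 5)
  expect_equal(blk$event, "division_blocked")
  expect_identical(blk$state$lattice, lat2)

  # infection converts an uninfected mutant neighbor, keeping its genotype
  lat3 <- matrix(0L, 5, 5); lat3[3, 3] <- 2L; lat3[3, 4] <- 3L
  st3 <- grid_state(lat3)
  inf <- abm_elementary_update(st3, p, site = c(3, 3), u = 0.1, neighbor = 5)
  expect_equal(inf$event, "infection")
  expect_equal(inf$state$lattice[3, 4], 4L)
  expect_equal(unname(inf$state$counts["uninf_mut"]), 0)
  expect_equal(unname(inf$state$counts["inf_mut"]), 1)

  # infection attempt onto empty space fails
  fail <- abm_elementary_update(grid_state(lat3), p, site = c(3, 3),
                                u = 0.1, neighbor = 4)
  expect_equal(fail$event, "infection_failed")

  # infected death in [B, B + A)
  idth <- abm_elementary_update(st3, p, site = c(3, 3), u = 0.35)
  expect_equal(idth$event, "infected_death")
  expect_equal(unname(idth$state$counts["inf_wt"]), 0)
})

test_that("the Moore neighborhood wraps periodically on both axes", {
  p <- abm_params(R = 0.5, D = 0.05, n1 = 4, n2 = 6)
  lat <- matrix(0L, 4, 6)
  lat[1, 1] <- 1L
  # neighbor 1 = NW of the corner wraps to the opposite corner
  res <- abm_elementary_update(grid_state(lat), p, site = c(1, 1),
                               u = 0.1, neighbor = 1)
  expect_equal(res$event, "division")
  expect_equal(res$state$lattice[4, 6], 1L)
})

test_that("mutant division uses the (1+s)-scaled probability", {
  p <- abm_params(R = 0.5, D = 0.05, s = 0.5, n1 = 5, n2 = 5)
  lat <- matrix(0L, 5, 5); lat[3, 3] <- 3L
  st <- grid_state(lat)
  # u = 0.6 < 0.75 = R(1+s): a mutant divides where a wild-type would not
  mut <- abm_elementary_update(st, p, site = c(3, 3), u = 0.6, neighbor = 5)
  expect_equal(mut$event, "division")
  lat_wt <- lat; lat_wt[3, 3] <- 1L
  wt <- abm_elementary_update(grid_state(lat_wt), p, site = c(3, 3),
                              u = 0.6, neighbor = 5)
  # 0.6 >= R + D = 0.55 for the wild-type: no event
  expect_equal(wt$event, "none")
})

test_that("same seed and config give bit-identical trajectories", {
  p <- abm_params(R = 0.5, D = 0.05, A = 0.1, B = 0.3, n1 = 12, n2 = 12)
  st <- abm_init_block(p)
  r1 <- abm_run(st, p, steps = 100, seed = 99)
  r2 <- abm_run(st, p, steps = 100, seed = 99)
  expect_identical(r1$state$lattice, r2$state$lattice)
  expect_identical(r1$series, r2$series)
  r3 <- abm_run(st, p, steps = 100, seed = 100)
  expect_false(identical(r1$state$lattice, r3$state$lattice))
})

test_that("forced-death limit strictly shrinks occupancy; saturating limit fills the grid", {
  # D = 1: every picked uninfected cell dies
  p <- abm_params(R = 0, D = 1, A = 1, B = 0, n1 = 8, n2 = 8)
  st <- abm_init_block(p, outer_side = 6, inner_side = 2)
  r <- abm_run(st, p, steps = 1, seed = 3)
  expect_lt(r$state$N1, st$N1)

  # D = 0, B = 0: absorbing full lattice of uninfected cells
  p2 <- abm_params(R = 0.5, D = 0, n1 = 8, n2 = 8)
  st2 <- abm_init_block(p2, outer_side = 4, inner_side = 0)
  r2 <- abm_run(st2, p2, steps = 200, seed = 3)
  expect_equal(unname(r2$state$counts["uninf_wt"]), 64)
})

test_that("occupancy changes by at most one per elementary update", {
  # a 3x3 grid with one cell performs exactly one update per time-step
  p <- abm_params(R = 0.5, D = 0.25, n1 = 3, n2 = 3)
  lat <- matrix(0L, 3, 3); lat[2, 2] <- 1L
  for (seed in 1:40) {
    r <- abm_run(grid_state(lat), p, steps = 1, seed = seed, record = FALSE)
    expect_true(abs(r$state$N1 - 1L) <= 1L)
  }
})

test_that("count statistics are invariant under translating the initial block", {
  p <- abm_params(R = 0.5, D = 0.05, n1 = 12, n2 = 12)
  mk_shifted <- function(dr, dc) {
    lat <- matrix(0L, 12, 12)
    rows <- ((3:8 + dr - 1) %% 12) + 1
    cols <- ((3:8 + dc - 1) %% 12) + 1
    lat[rows, cols] <- 1L
    grid_state(lat)
  }
  mean_occ <- function(st, seed) {
    r <- abm_run(st, p, steps = 400, seed = seed)
    mean(r$series$uninf_wt[201:400])
  }
  m0 <- mean(vapply(1:6, function(s) mean_occ(mk_shifted(0, 0), s), numeric(1)))
  m1 <- mean(vapply(1:6, function(s) mean_occ(mk_shifted(5, 9), s), numeric(1)))
  expect_equal(m1, m0, tolerance = 0.05)
})

test_that("equilibrium measurement reports persistence failures", {
  p <- abm_params(R = 0.05, D = 0.5, n1 = 10, n2 = 10)  # death-dominated
  expect_error(abm_equilibrium(p, burn_in = 200, window = 100, seed = 1),
               "extinct")
})

test_that("grid calibration finds the no-infection grid and rejects unreachable targets", {
  p <- abm_params(R = 0.5, D = 0.05, n1 = 20, n2 = 20)
  cal <- abm_calibrate(p, target_nu = 360, sides = c(12L, 20L, 28L),
                       burn_in = 200, window = 600, seed = 5)
  expect_equal(c(cal$n1, cal$n2), c(20, 20))
  expect_equal(cal$N_u, 360, tolerance = 0.05)
  # a fully occupied grid is unreachable while D > 0
  expect_error(
    abm_calibrate(p, target_nu = 400, sides = c(12L, 20L),
                  burn_in = 100, window = 200, seed = 5, tol = 0.02),
    "calibration failure")
})
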