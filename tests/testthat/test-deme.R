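test_that("the per-patch rate table follows the patch ODE terms", {
  p <- deme_params(r = 0.7, d = 0.1, K = 100, n1 = 1, n2 = 1)
  s <- deme_system(p, x = 85L)
  tab <- deme_event_rates(s, p)
  expect_equal(tab$div_wt, 0.7 * 85 * (1 - 85 / 100))  # 8.925
  expect_equal(tab$death_wt, 0.1 * 85)
  expect_equal(tab$inf_wt, 0)

  # logistic ceiling: division clamps to zero at or beyond K
  s2 <- deme_system(p, x = 60L, y = 30L, z = 20L)
  tab2 <- deme_event_rates(s2, p)
  expect_equal(tab2$div_wt, 0)
  expect_equal(tab2$div_mut, 0)
  expect_equal(tab2$migration, 0)    # mu = 0 here

  # no infecteds anywhere -> zero total infection rate
  p3 <- deme_params(r = 0.7, d = 0.1, beta = 0.5, a = 0.5, K = 100,
                    mu = 0.02, n1 = 2, n2 = 2)
  s3 <- deme_system(p3, x = rep(40L, 4), init_infected = 0)
  tab3 <- deme_event_rates(s3, p3)
  expect_equal(sum(tab3$inf_wt) + sum(tab3$inf_mut), 0)
  expect_equal(tab3$migration, rep(0.02 * 40, 4))
})

test_that("the R rate table matches the engine's internal rates", {
  p <- deme_params(r = 0.7, d = 0.1, beta = 0.5, a = 0.5, K = 100,
                   mu = 0.02, s = 0.03, n1 = 2, n2 = 3)
  set.seed(4)
  s <- deme_system(p, x = as.integer(sample(0:90, 6)),
                   y = as.integer(sample(0:20, 6)),
                   z = as.integer(sample(0:30, 6)))
  r_tab <- as.matrix(deme_event_rates(s, p))
  c_tab <- enemyfix:::cpp_deme_rates(s$x, s$y, s$z, p$r, p$d, p$beta, p$a,
                                     p$K, p$mu, p$s)
  expect_equal(unname(r_tab), unname(c_tab), tolerance = 1e-12)
})

test_that("mutant introduction is proportional and conserving", {
  p <- deme_params(r = 0.7, d = 0.1, K = 100, mu = 0.02, n1 = 2, n2 = 2)
  s <- deme_system(p, x = c(50L, 30L, 20L, 0L))

  # exhaustion: every uninfected individual becomes mutant
  all_mut <- introduce_mutants_deme(s, k = 100, seed = 1)
  expect_equal(sum(all_mut$x), 0)
  expect_equal(all_mut$y, c(50L, 30L, 20L, 0L))

  # single occupied patch is chosen with probability 1
  s1 <- deme_system(p, x = c(0L, 0L, 7L, 0L))
  one <- introduce_mutants_deme(s1, k = 1, seed = 1)
  expect_equal(one$y, c(0L, 0L, 1L, 0L))

  # total uninfected count is unchanged; placement tracks x_i proportions
  k <- 40L
  res <- introduce_mutants_deme(s, k = k, seed = 42)
  expect_equal(sum(res$x) + sum(res$y), 100)
  expect_equal(sum(res$y), 40)
  draws <- t(vapply(1:300, function(sd)
    introduce_mutants_deme(s, k = 1, seed = sd)$y, integer(4)))
  freq <- colMeans(draws)
  expect_equal(freq, c(0.5, 0.3, 0.2, 0), tolerance = 0.25)

  expect_error(introduce_mutants_deme(s, k = 101, seed = 1), "fewer")
})

test_that("migration-only dynamics conserve class totals exactly", {
  p <- deme_params(r = 0, d = 0, beta = 0, a = 0, K = 100, mu = 1,
                   n1 = 3, n2 = 3)
  s <- deme_system(p, x = rep(20L, 9), y = rep(5L, 9), z = rep(3L, 9))
  for (mode in c("nonspatial", "spatial")) {
    pm <- deme_params(r = 0, d = 0, beta = 0, a = 0, K = 100, mu = 1,
                      n1 = 3, n2 = 3, migration_mode = mode)
    r <- deme_run(s, pm, duration = 20, seed = 8)
    expect_equal(sum(r$sys$x), 180)
    expect_equal(sum(r$sys$y), 45)
    expect_equal(sum(r$sys$z), 27)
    expect_true(all(r$sys$x >= 0))
  }
})

test_that("a single isolated patch fluctuates around the logistic equilibrium", {
  p <- deme_params(r = 0.7, d = 0.1, K = 100, mu = 0, n1 = 1, n2 = 1)
  eq <- deme_equilibrium(p, burn_in = 200, window = 3000, seed = 21)
  expect_equal(eq$N_u_raw, logistic_equilibrium(0.7, 0.1, 100),
               tolerance = 0.04)
})

test_that("same seed reproduces the identical event sequence", {
  p <- deme_params(r = 0.7, d = 0.1, beta = 0.5, a = 0.5, K = 100,
                   mu = 0.02, n1 = 3, n2 = 3)
  s <- deme_system(p)
  r1 <- deme_run(s, p, duration = 50, seed = 17)
  r2 <- deme_run(s, p, duration = 50, seed = 17)
  expect_identical(r1$sys, r2$sys)
  expect_identical(r1$series, r2$series)
  r3 <- deme_run(s, p, duration = 50, seed = 18)
  expect_false(identical(r1$sys, r3$sys))
})

test_that("large-K stochastic means track the deterministic patch ODEs", {
  # one isolated patch, SI dynamics, scaled so mass action matches at K=4000
  K <- 4000
  p <- deme_params(r = 0.7, d = 0.1, beta = 0.5 * 100 / K, a = 0.5, K = K,
                   mu = 0, n1 = 1, n2 = 1)
  x0 <- 2000L; z0 <- 100L
  rhs <- function(t, st, pp) {
    x <- st[1]; z <- st[2]
    dx <- pp$r * x * (1 - (x + z) / pp$K) - pp$d * x - pp$beta * x * z
    dz <- pp$beta * x * z - pp$a * z
    list(c(dx, dz))
  }
  ode <- deSolve::ode(c(x = x0, z = z0), seq(0, 5, by = 1), rhs, p)
  sims <- vapply(1:20, function(sd) {
    s <- deme_system(p, x = x0, z = z0)
    r <- deme_run(s, p, duration = 5, sample_dt = 5, seed = 300 + sd)
    c(r$sys$x, r$sys$z)
  }, numeric(2))
  expect_equal(mean(sims[1, ]), unname(ode[6, "x"]), tolerance = 0.05)
  expect_equal(mean(sims[2, ]), unname(ode[6, "z"]), tolerance = 0.05)
})

test_that("infection invasion follows the threshold beta*K*(1-d/r)/a", {
  # single well-mixed patch.  Subcritical (ratio 0.34): the introduced
  # infecteds dwindle without an outbreak.  Supercritical (ratio 86): a
  # large outbreak occurs before the pathogen burns through its hosts
  # (long-term coexistence in one well-mixed patch is not expected; that is
  # what the spatial structure is for).
  max_z <- function(beta, seeds) {
    p <- deme_params(r = 0.7, d = 0.1, beta = beta, a = 0.5, K = 100,
                     mu = 0, n1 = 1, n2 = 1)
    vapply(seeds, function(sd) {
      s <- deme_system(p, x = 86L, z = 10L)
      r <- deme_run(s, p, duration = 60, sample_dt = 0.5, seed = sd)
      max(r$series$total_z)
    }, numeric(1))
  }
  sub <- max_z(0.002, 501:520)
  sup <- max_z(0.5, 701:720)
  expect_gte(mean(sub <= 15), 0.9)   # no outbreak beyond small fluctuations
  expect_gte(mean(sup >= 40), 0.9)   # outbreak infects a large host fraction
})

test_that("deme equilibrium with infection shows local extinctions under global persistence", {
  p <- deme_params(r = 0.7, d = 0.1, beta = 0.5, a = 0.5, K = 100, mu = 0.02,
                   n1 = 19, n2 = 19, migration_mode = "spatial")
  s <- deme_system(p)
  r <- deme_run(s, p, duration = 150, sample_dt = 1, seed = 12)
  expect_false(r$extinct)
  expect_gt(sum(r$sys$x), 0)
  expect_gt(sum(r$sys$z), 0)               # infection persists globally
  expect_gt(sum(r$sys$x + r$sys$z == 0), 0)  # some patches currently empty
})
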