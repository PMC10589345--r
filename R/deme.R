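# Stochastic deme (metapopulation) model.
#
# N = n1*n2 patches, each a well-mixed SI-logistic system: susceptible
# wild-type x_i, susceptible mutant y_i (division rate r(1+s)), infected z_i.
# Per-patch event rates follow the patch ODEs: logistic division
# r x_i (1 - (x_i+y_i+z_i)/K) (clamped at 0 beyond K), death d x_i,
# mass-action infection beta x_i z_i, infected death a z_i, and per-capita
# migration mu, either to a uniformly chosen patch (non-spatial; self allowed,
# which reproduces the ODE migration term exactly in mean) or to one of the
# 8 Moore-neighbor patches on the torus (spatial).  Realized by an exact
# Gillespie algorithm.

#' Parameters of the stochastic deme model
#'
#' @param r basic division rate of uninfected cells (1/time).
#' @param d death rate of uninfected cells (1/time).
#' @param beta infection rate (1/(individual x time)).
#' @param a death rate of infected cells (1/time).
#' @param K patch carrying capacity (individuals).
#' @param mu per-capita migration rate (1/time).
#' @param s mutant selection coefficient; mutant division rate `r * (1 + s)`.
#' @param n1,n2 patch-grid dimensions.
#' @param migration_mode `"nonspatial"` (destination uniform over all
#'   patches) or `"spatial"` (destination uniform over the 8 periodic
#'   nearest-neighbor patches).
#' @return An object of class `deme_params`.
#' @export
#' @examples
#' deme_params(r = 0.7, d = 0.1, beta = 0.5, a = 0.5, K = 100, mu = 0.02,
#'             n1 = 19, n2 = 19)
deme_params <- function(r, d, beta = 0, a = 0, K, mu = 0, s = 0,
                        n1, n2, migration_mode = c("nonspatial", "spatial")) {
  migration_mode <- match.arg(migration_mode)
  vals <- c(r = r, d = d, beta = beta, a = a, K = K, mu = mu)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rates and K must be finite and non-negative", call. = FALSE)
  if (K < 1) stop("carrying capacity K must be >= 1", call. = FALSE)
  if (r * (1 + s) < 0)
    stop("mutant division rate r*(1+s) must be non-negative", call. = FALSE)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 1L || n2 < 1L) stop("need at least one patch", call. = FALSE)
  if (migration_mode == "spatial" && (n1 < 3L || n2 < 3L))
    stop("spatial migration needs n1 >= 3 and n2 >= 3", call. = FALSE)
  structure(list(r = r, d = d, beta = beta, a = a, K = K, mu = mu, s = s,
                 n1 = n1, n2 = n2, migration_mode = migration_mode),
            class = "deme_params")
}

#' @export
print.deme_params <- function(x, ...) {
  cat("<deme_params> ", x$n1, "x", x$n2, " patches, ",
      x$migration_mode, " migration\n", sep = "")
  cat(sprintf("  r = %g  d = %g  beta = %g  a = %g  K = %g  mu = %g  s = %g\n",
              x$r, x$d, x$beta, x$a, x$K, x$mu, x$s))
  invisible(x)
}

new_deme_system <- function(x, y, z, t = 0, event_count = 0) {
  structure(list(x = as.integer(x), y = as.integer(y), z = as.integer(z),
                 t = t, event_count = event_count),
            class = "deme_system")
}

#' Construct the per-patch state of the deme model
#'
#' Builds a `deme_system` either from explicit per-patch counts or from the
#' standard starting configuration: every patch at its infection-free
#' quasi-equilibrium `round(K * (1 - d/r))` wild-type individuals, with
#' `init_infected` infected individuals seeded into one central patch.
#'
#' @param params a [deme_params()].
#' @param x,y,z optional integer vectors of per-patch counts (length
#'   `n1 * n2`): wild-type uninfected, mutant uninfected, infected.
#' @param init_infected number of infected individuals seeded into the
#'   central patch when `x` is not given (default: 10 if `beta > 0`, else 0).
#' @return An object of class `deme_system` with fields `x`, `y`, `z`,
#'   `t` and `event_count`.
#' @export
deme_system <- function(params, x = NULL, y = NULL, z = NULL,
                        init_infected = NULL) {
  stopifnot(inherits(params, "deme_params"))
  np <- params$n1 * params$n2
  if (is.null(x)) {
    if (params$r <= params$d)
      stop("default initialization needs r > d", call. = FALSE)
    x <- rep(round(params$K * (1 - params$d / params$r)), np)
    y <- rep(0L, np)
    z <- rep(0L, np)
    if (is.null(init_infected))
      init_infected <- if (params$beta > 0) 10L else 0L
    if (init_infected > 0) {
      center <- (params$n1 %/% 2) * params$n2 + params$n2 %/% 2 + 1L
      take <- min(init_infected, x[center])
      x[center] <- x[center] - take
      z[center] <- take
    }
  } else {
    if (is.null(y)) y <- rep(0L, np)
    if (is.null(z)) z <- rep(0L, np)
  }
  if (length(x) != np || length(y) != np || length(z) != np)
    stop("x, y, z must each have one entry per patch", call. = FALSE)
  if (any(x < 0) || any(y < 0) || any(z < 0))
    stop("patch counts must be non-negative", call. = FALSE)
  new_deme_system(x, y, z)
}

#' @export
print.deme_system <- function(x, ...) {
  cat("<deme_system> ", length(x$x), " patches at t = ",
      format(x$t, digits = 6), "\n", sep = "")
  cat("  totals: x =", sum(x$x), " y =", sum(x$y), " z =", sum(x$z), "\n")
  invisible(x)
}

#' Per-patch event rate table
#'
#' Evaluates the Gillespie event rates of every patch: clamped logistic
#' division of each genotype, deaths, mass-action infections, infected
#' death, and the per-capita migration rate `mu * (x + y + z)`.
#'
#' @param sys a [deme_system()].
#' @param params a [deme_params()].
#' @return A data frame with one row per patch and columns `div_wt`,
#'   `div_mut`, `death_wt`, `death_mut`, `inf_wt`, `inf_mut`, `death_inf`,
#'   `migration`; the total rate is attached as attribute `"total"`.
#' @export
#' @examples
#' p <- deme_params(r = 0.7, d = 0.1, K = 100, n1 = 1, n2 = 1)
#' s <- deme_system(p, x = 85L)
#' deme_event_rates(s, p)  # division rate 0.7 * 85 * 0.15 = 8.925
deme_event_rates <- function(sys, params) {
  stopifnot(inherits(sys, "deme_system"), inherits(params, "deme_params"))
  n <- sys$x + sys$y + sys$z
  room <- pmax(0, 1 - n / params$K)
  tab <- data.frame(
    div_wt    = params$r * sys$x * room,
    div_mut   = params$r * (1 + params$s) * sys$y * room,
    death_wt  = params$d * sys$x,
    death_mut = params$d * sys$y,
    inf_wt    = params$beta * sys$x * sys$z,
    inf_mut   = params$beta * sys$y * sys$z,
    death_inf = params$a * sys$z,
    migration = params$mu * n)
  attr(tab, "total") <- sum(unlist(tab))
  tab
}

#' Advance the deme model by Gillespie simulation
#'
#' Runs the exact stochastic simulation for `duration` time units from the
#' system's current time.  Between events the state is piecewise constant;
#' class totals are recorded every `sample_dt` time units.
#'
#' @param sys a [deme_system()].
#' @param params a [deme_params()].
#' @param duration simulated time span.
#' @param sample_dt sampling interval for the totals series; 0 disables
#'   recording.
#' @param seed integer seed; with `stream`, fully determines the event
#'   sequence.
#' @param stream stream selector (default 1).
#' @return A list with `sys` (advanced system), `series` (data frame
#'   `t, total_x, total_y, total_z`), `frozen` (total rate hit 0) and
#'   `extinct` (no individuals left).
#' @export
deme_run <- function(sys, params, duration, sample_dt = 1, seed, stream = 1L) {
  stopifnot(inherits(sys, "deme_system"), inherits(params, "deme_params"),
            duration > 0)
  res <- cpp_deme_run(sys$x, sys$y, sys$z, params$n1, params$n2,
                      params$r, params$d, params$beta, params$a, params$K,
                      params$mu, params$s,
                      params$migration_mode == "spatial",
                      sys$t, duration, sample_dt, 0, -1,
                      as.double(seed), as.double(stream))
  list(sys = new_deme_system(res$x, res$y, res$z, res$t,
                             sys$event_count + res$n_events),
       series = res$series, frozen = isTRUE(res$frozen),
       extinct = isTRUE(res$extinct))
}

#' Introduce mutants into the deme system
#'
#' Repeats `k` times: select a patch with probability proportional to its
#' current number of uninfected wild-type individuals and replace one
#' wild-type individual there by a mutant.  The total uninfected count is
#' unchanged.
#'
#' @param sys a [deme_system()].
#' @param k number of mutants to introduce; at most the wild-type total.
#' @param seed integer seed.
#' @param stream stream selector (default 3).
#' @return The modified [deme_system()].
#' @export
introduce_mutants_deme <- function(sys, k, seed, stream = 3L) {
  stopifnot(inherits(sys, "deme_system"), k >= 1)
  if (sum(sys$x) < k)
    stop("fewer uninfected wild-type individuals (", sum(sys$x),
         ") than mutants to introduce (", k, ")", call. = FALSE)
  res <- cpp_deme_introduce(sys$x, sys$y, as.integer(k),
                            as.double(seed), as.double(stream))
  new_deme_system(res$x, res$y, sys$z, sys$t, sys$event_count)
}

#' Measure the deme model's quasi-equilibrium uninfected population
#'
#' Runs the Gillespie simulation from the standard initial configuration,
#' discards `burn_in` time units and returns the rounded time-weighted mean
#' of the total uninfected population over the following `window` time
#' units.
#'
#' @param params a [deme_params()].
#' @param burn_in burn-in time (default 100).
#' @param window averaging window (default 500).
#' @param seed integer seed.
#' @param init optional starting [deme_system()].
#' @param sample_dt sampling interval of the returned series (default 1).
#' @return A list with `N_u` (rounded temporal mean), `N_u_raw`, `series`,
#'   and `sys` (final state).
#' @export
#' @examples
#' \donttest{
#' p <- deme_params(r = 0.7, d = 0.1, K = 100, mu = 0.02, n1 = 4, n2 = 3)
#' deme_equilibrium(p, burn_in = 50, window = 200, seed = 1)$N_u
#' }
deme_equilibrium <- function(params, burn_in = 100, window = 500, seed,
                             init = NULL, sample_dt = 1) {
  stopifnot(window > 0)
  sys <- if (is.null(init)) deme_system(params) else init
  res <- cpp_deme_run(sys$x, sys$y, sys$z, params$n1, params$n2,
                      params$r, params$d, params$beta, params$a, params$K,
                      params$mu, params$s,
                      params$migration_mode == "spatial",
                      sys$t, burn_in + window, sample_dt,
                      sys$t + burn_in, sys$t + burn_in + window,
                      as.double(seed), 1)
  if (isTRUE(res$extinct) || sum(res$x) + sum(res$y) == 0)
    stop("population went globally extinct before the averaging window ",
         "completed", call. = FALSE)
  list(N_u = round(res$avg_uninf), N_u_raw = res$avg_uninf,
       series = res$series,
       sys = new_deme_system(res$x, res$y, res$z, res$t,
                             sys$event_count + res$n_events))
}
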