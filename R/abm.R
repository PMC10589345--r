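# Lattice agent-based host-pathogen model.
#
# Each site of an n1 x n2 toroidal grid is empty or holds one cell:
# uninfected/infected x wild-type/mutant.  A time-step consists of N1
# elementary updates (N1 = occupied sites at the step boundary).  Per pick,
# one uniform variate is partitioned into [0, p_div), [p_div, p_div + D) for
# uninfected cells (p_div = R or R(1+s)) and [0, B), [B, B + A) for infected
# cells; the remainder is "no event".  Division and infection target a
# uniformly chosen Moore neighbor and silently fail if the target is
# unsuitable (occupied / not uninfected, respectively).

#' Site state codes used by the lattice model
#'
#' Integer codes shared by lattice matrices, snapshot files and the C++
#' engine: 0 = empty, 1 = uninfected wild-type, 2 = infected wild-type,
#' 3 = uninfected mutant, 4 = infected mutant.
#'
#' @return A named integer vector of the five codes.
#' @export
#' @examples
#' abm_site_codes()
abm_site_codes <- function() {
  c(empty = 0L, uninf_wt = 1L, inf_wt = 2L, uninf_mut = 3L, inf_mut = 4L)
}

#' Parameters of the lattice agent-based model
#'
#' Per-pick event probabilities of the agent-based model.  An uninfected cell
#' attempts division with probability `R` (mutants: `R * (1 + s)`) into a
#' random Moore neighbor, and dies with probability `D`.  An infected cell
#' attempts to infect a random Moore neighbor with probability `B` and dies
#' with probability `A`.  Infected cells never divide or recover.
#'
#' The per-genotype outcome probabilities must form a sub-distribution:
#' `R * (1 + s) + D <= 1` and `A + B <= 1`.  Violations are rejected here,
#' never clamped.
#'
#' @param R division probability per elementary pick (wild-type).
#' @param D death probability of an uninfected cell per pick.
#' @param A death probability of an infected cell per pick.
#' @param B infection-attempt probability of an infected cell per pick.
#' @param s selection coefficient of the mutant; the mutant division
#'   probability is `R * (1 + s)`.
#' @param n1,n2 grid dimensions (rows, columns); both at least 3 so the
#'   Moore neighborhood is well defined under periodic wrap.
#' @return An object of class `abm_params`.
#' @export
#' @examples
#' abm_params(R = 0.5, D = 0.05, A = 0.1, B = 0.2, n1 = 42, n2 = 42)
abm_params <- function(R, D, A = 0, B = 0, s = 0, n1, n2) {
  stopifnot(is.numeric(R), is.numeric(D), is.numeric(A), is.numeric(B),
            is.numeric(s), length(R) == 1, length(D) == 1, length(A) == 1,
            length(B) == 1, length(s) == 1)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (is.na(n1) || is.na(n2) || n1 < 3L || n2 < 3L)
    stop("grid dimensions n1 and n2 must both be >= 3", call. = FALSE)
  if (R < 0 || D < 0)
    stop("R and D must be non-negative", call. = FALSE)
  if (R * (1 + s) < 0)
    stop("mutant division probability R*(1+s) must be non-negative", call. = FALSE)
  if (R * (1 + s) + D > 1 || R + D > 1)
    stop("probability budget violated: R*(1+s) + D must be <= 1 for both genotypes",
         call. = FALSE)
  if (A < 0 || B < 0 || A + B > 1)
    stop("probability budget violated: need 0 <= A, 0 <= B, A + B <= 1",
         call. = FALSE)
  structure(list(R = R, D = D, A = A, B = B, s = s, n1 = n1, n2 = n2),
            class = "abm_params")
}

#' @export
print.abm_params <- function(x, ...) {
  cat("<abm_params> ", x$n1, "x", x$n2, " toroidal grid\n", sep = "")
  cat(sprintf("  R = %g  D = %g  A = %g  B = %g  s = %g\n",
              x$R, x$D, x$A, x$B, x$s))
  invisible(x)
}

new_grid_state <- function(lattice, step = 0L) {
  codes <- abm_site_codes()
  tab <- tabulate(as.vector(lattice) + 1L, nbins = 5L)
  counts <- c(uninf_wt = tab[2], uninf_mut = tab[4],
              inf_wt = tab[3], inf_mut = tab[5])
  structure(list(lattice = lattice, counts = counts, step = as.integer(step),
                 N1 = sum(counts)),
            class = "grid_state")
}

#' Lattice state of the agent-based model
#'
#' Constructs a `grid_state` from an integer matrix of site codes (see
#' [abm_site_codes()]).  Counts are tallied from the lattice; `N1` is the
#' number of occupied sites at the current step boundary.
#'
#' @param lattice integer matrix of site codes.
#' @param step time-step counter.
#' @return An object of class `grid_state` with elements `lattice`, `counts`
#'   (uninf_wt, uninf_mut, inf_wt, inf_mut), `step` and `N1`.
#' @export
grid_state <- function(lattice, step = 0L) {
  if (!is.matrix(lattice) || !all(lattice %in% 0:4))
    stop("lattice must be an integer matrix with values in 0..4", call. = FALSE)
  storage.mode(lattice) <- "integer"
  new_grid_state(lattice, step)
}

#' @export
print.grid_state <- function(x, ...) {
  cat("<grid_state> ", nrow(x$lattice), "x", ncol(x$lattice),
      " step ", x$step, "\n", sep = "")
  cat("  occupied:", x$N1, " (",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Block initial condition
#'
#' Places a centered square block of uninfected wild-type cells on an
#' otherwise empty grid, with a smaller centered square block of infected
#' wild-type cells overwriting its middle.  This is the standard starting
#' configuration for reaching quasi-equilibrium; its exact dimensions do not
#' matter for the long-run state.
#'
#' @param params an [abm_params()] object.
#' @param outer_side side of the uninfected block; default
#'   `floor(min(n1, n2) / 2)`.
#' @param inner_side side of the infected block; default
#'   `max(2, floor(outer_side / 5))` when infection is present (`B > 0`),
#'   otherwise 0.
#' @return A [grid_state()].
#' @export
#' @examples
#' p <- abm_params(R = 0.5, D = 0.05, A = 0.1, B = 0.2, n1 = 100, n2 = 100)
#' st <- abm_init_block(p, outer_side = 50, inner_side = 10)
#' st$counts
abm_init_block <- function(params, outer_side = NULL, inner_side = NULL) {
  stopifnot(inherits(params, "abm_params"))
  n1 <- params$n1; n2 <- params$n2
  if (is.null(outer_side)) outer_side <- floor(min(n1, n2) / 2)
  if (is.null(inner_side))
    inner_side <- if (params$B > 0) max(2L, floor(outer_side / 5)) else 0L
  outer_side <- as.integer(outer_side); inner_side <- as.integer(inner_side)
  if (inner_side < 0L || inner_side > outer_side || outer_side > min(n1, n2))
    stop("need 0 <= inner_side <= outer_side <= min(n1, n2)", call. = FALSE)
  lat <- matrix(0L, n1, n2)
  block_idx <- function(n, side) {
    if (side == 0L) return(integer(0))
    lo <- floor((n - side) / 2) + 1L
    seq.int(lo, lo + side - 1L)
  }
  lat[block_idx(n1, outer_side), block_idx(n2, outer_side)] <- 1L
  if (inner_side > 0L)
    lat[block_idx(n1, inner_side), block_idx(n2, inner_side)] <- 2L
  new_grid_state(lat)
}

as_series_df <- function(series, first_step) {
  df <- as.data.frame(series)
  names(df) <- c("uninf_wt", "uninf_mut", "inf_wt", "inf_mut")
  cbind(step = seq.int(first_step, length.out = nrow(df)), df)
}

#' Run the agent-based model for a number of time-steps
#'
#' Advances a [grid_state()] by `steps` time-steps.  Each time-step performs
#' `N1` elementary updates, where `N1` is frozen at the step boundary as the
#' number of occupied sites; within a step, picks are uniform (with
#' replacement) over the sites occupied at the moment of the pick.  The run
#' stops early if the grid goes globally extinct.
#'
#' @param state a [grid_state()].
#' @param params an [abm_params()] matching the lattice dimensions.
#' @param steps number of time-steps.
#' @param seed integer seed of the trajectory's own random stream; the same
#'   `(seed, stream)` pair reproduces the trajectory bit-exactly.
#' @param stream stream selector (default 1).
#' @param record if `TRUE`, return the per-step count series.
#' @return A list with `state` (the advanced [grid_state()]), `series` (a
#'   data frame `step, uninf_wt, uninf_mut, inf_wt, inf_mut`, or `NULL`),
#'   and `extinct`.
#' @export
abm_run <- function(state, params, steps, seed, stream = 1L, record = TRUE) {
  stopifnot(inherits(state, "grid_state"), inherits(params, "abm_params"))
  if (!identical(dim(state$lattice), c(params$n1, params$n2)))
    stop("lattice dimensions do not match params", call. = FALSE)
  if (state$N1 < 1L) stop("cannot advance an extinct (empty) grid", call. = FALSE)
  steps <- as.integer(steps)
  res <- cpp_abm_run(state$lattice, params$R, params$D, params$A, params$B,
                     params$s, steps, as.double(seed), as.double(stream),
                     isTRUE(record))
  out_state <- new_grid_state(res$lattice, state$step + res$steps_done)
  series <- if (isTRUE(record))
    as_series_df(res$series[seq_len(res$steps_done), , drop = FALSE],
                 state$step + 1L) else NULL
  list(state = out_state, series = series, extinct = isTRUE(res$extinct))
}

#' Apply one elementary rule with forced draws
#'
#' Executes exactly one elementary update on the engine's rule code path,
#' with the picked site, the event variate and the neighbor draw supplied by
#' the caller.  Intended for rule-level verification; stochastic runs use
#' [abm_run()].
#'
#' The event variate `u` is interpreted against the documented partition:
#' for an uninfected cell `[0, p_div)` division attempt, `[p_div, p_div + D)`
#' death; for an infected cell `[0, B)` infection attempt, `[B, B + A)`
#' death; remainder no event.  Neighbors 1..8 index the Moore neighborhood
#' in row-major order (NW, N, NE, W, E, SW, S, SE) with periodic wrap.
#'
#' @param state a [grid_state()].
#' @param params an [abm_params()].
#' @param site length-2 integer vector, 1-based (row, col) of the picked cell.
#' @param u event variate in `[0, 1)`.
#' @param neighbor Moore neighbor index in 1..8 (used only if the event
#'   needs a target).
#' @return A list with the updated `state` and `event`, one of `"none"`,
#'   `"division"`, `"death"`, `"infection"`, `"infected_death"`,
#'   `"division_blocked"`, `"infection_failed"`.
#' @export
abm_elementary_update <- function(state, params, site, u, neighbor = 1L) {
  stopifnot(inherits(state, "grid_state"), inherits(params, "abm_params"),
            length(site) == 2, u >= 0, u < 1, neighbor %in% 1:8)
  res <- cpp_abm_forced_update(state$lattice, params$R, params$D, params$A,
                               params$B, params$s,
                               as.integer(site[1]) - 1L,
                               as.integer(site[2]) - 1L,
                               as.double(u), as.integer(neighbor) - 1L)
  events <- c("none", "division", "death", "infection", "infected_death",
              "division_blocked", "infection_failed")
  list(state = new_grid_state(res$lattice, state$step),
       event = events[res$event + 1L])
}

#' Measure the quasi-equilibrium uninfected population size
#'
#' Runs the model from a block initial condition, discards `burn_in`
#' time-steps and returns the temporal mean of the uninfected count (both
#' genotypes) over the following `window` time-steps, together with the
#' per-step series for diagnostics.
#'
#' @param params an [abm_params()].
#' @param burn_in burn-in time-steps (default 500).
#' @param window averaging window in time-steps (default 5000).
#' @param seed integer seed.
#' @param init optional starting [grid_state()]; default [abm_init_block()].
#' @return A list with `N_u` (the temporal mean), `series` (data frame over
#'   the window) and `state` (final [grid_state()]).
#' @export
#' @examples
#' \donttest{
#' p <- abm_params(R = 0.5, D = 0.05, n1 = 32, n2 = 33)
#' eq <- abm_equilibrium(p, burn_in = 200, window = 500, seed = 1)
#' eq$N_u
#' }
abm_equilibrium <- function(params, burn_in = 500L, window = 5000L, seed,
                            init = NULL) {
  stopifnot(window >= 1L)
  state <- if (is.null(init)) abm_init_block(params) else init
  burn <- abm_run(state, params, burn_in, seed = seed, stream = 1L,
                  record = FALSE)
  if (burn$extinct)
    stop("population went extinct during burn-in (step ",
         burn$state$step, ")", call. = FALSE)
  win <- abm_run(burn$state, params, window, seed = seed, stream = 2L,
                 record = TRUE)
  if (win$extinct)
    stop("population went extinct during the averaging window (step ",
         win$state$step, ")", call. = FALSE)
  uninf <- win$series$uninf_wt + win$series$uninf_mut
  list(N_u = mean(uninf), series = win$series, state = win$state)
}

#' Calibrate the grid size to a target equilibrium population
#'
#' When the infection probability is varied, the equilibrium uninfected
#' population changes; to compare fixation probabilities across infection
#' rates at a common population size, the grid is enlarged or shrunk until
#' the measured long-run mean \eqn{N_u} is close to `target_nu`.  Candidate
#' (near-)square grids are measured with [abm_equilibrium()] and the closest
#' one is returned.
#'
#' @param params an [abm_params()]; its `n1`, `n2` are ignored.
#' @param target_nu target mean uninfected population.
#' @param sides integer vector of candidate square side lengths, or a
#'   two-column matrix of candidate `(n1, n2)` pairs.
#' @param tol maximal acceptable relative deviation of the best candidate's
#'   measured `N_u` from `target_nu` (default 0.1).
#' @param burn_in,window measurement settings passed to [abm_equilibrium()].
#' @param seed integer seed; candidate `k` is measured with seed `seed + k`.
#' @return A list with `n1`, `n2`, `N_u` (measured) and `table` (all
#'   candidates with their measurements).  If no candidate is within `tol`,
#'   an error lists the best candidate found.
#' @export
abm_calibrate <- function(params, target_nu, sides, tol = 0.1,
                          burn_in = 300L, window = 1500L, seed) {
  stopifnot(inherits(params, "abm_params"), target_nu > 0)
  cand <- if (is.matrix(sides)) sides else cbind(sides, sides)
  if (any(cand < 3L)) stop("candidate grid sides must be >= 3", call. = FALSE)
  meas <- rep(NA_real_, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    pk <- abm_params(params$R, params$D, params$A, params$B, params$s,
                     n1 = cand[k, 1], n2 = cand[k, 2])
    if (target_nu >= pk$n1 * pk$n2 && params$D > 0) next  # unreachable
    meas[k] <- tryCatch(
      abm_equilibrium(pk, burn_in, window, seed = seed + k)$N_u,
      error = function(e) NA_real_)
  }
  tab <- data.frame(n1 = cand[, 1], n2 = cand[, 2], N_u = meas)
  err <- abs(meas - target_nu) / target_nu
  if (all(is.na(err)))
    stop("calibration failure: no candidate grid persisted or could reach ",
         "target N_u = ", target_nu, call. = FALSE)
  best <- which.min(err)
  if (err[best] > tol)
    stop(sprintf(paste0("calibration failure: best candidate %dx%d has ",
                        "N_u = %.1f, %.1f%% from target %.1f"),
                 tab$n1[best], tab$n2[best], meas[best], 100 * err[best],
                 target_nu), call. = FALSE)
  list(n1 = tab$n1[best], n2 = tab$n2[best], N_u = meas[best], table = tab)
}
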