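# Coarse-grained patch-competition model.
#
# When infection is fast, patches rarely contain both genotypes, and whole
# patches become the competing agents.  X, Y, Z count uninfected wild-type
# patches, uninfected mutant patches and infected patches; w_x, w_y, w_z are
# the mean per-deme populations of those patch types.  Patch-level processes:
# colonization of empty patches (rate prop. to mu * X * w_x * free fraction,
# discounted by the single-cell colonization success P_col), patch infection
# (a migrating infected cell establishing, success P_inf), patch conversion
# (a migrant of the other genotype taking over an uninfected patch, success
# P_xy / P_yx), and infected-patch extinction (timescale T_ext).

#' Coarse patch-model parameters
#'
#' @param N_patches total number of patches.
#' @param mu migration rate (as in the deme model).
#' @param w_x,w_y,w_z mean per-deme populations of wild-type, mutant and
#'   infected patches.
#' @param P_col_x,P_col_y probability that a single wild-type (mutant) cell
#'   successfully colonizes an empty patch; see [p_col()].
#' @param P_inf_x,P_inf_y probability that a single infected cell starts a
#'   successful infection in a wild-type (mutant) patch; see [p_inf()].
#' @param P_xy,P_yx conversion probabilities: a mutant migrant taking over a
#'   wild-type patch (`P_xy`) and vice versa (`P_yx`).
#' @param T_ext mean time to extinction of an infected patch.
#' @return An object of class `coarse_params`.
#' @export
coarse_params <- function(N_patches, mu, w_x, w_y, w_z,
                          P_col_x, P_col_y, P_inf_x, P_inf_y,
                          P_xy, P_yx, T_ext) {
  probs <- c(P_col_x = P_col_x, P_col_y = P_col_y, P_inf_x = P_inf_x,
             P_inf_y = P_inf_y, P_xy = P_xy, P_yx = P_yx)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (any(c(w_x, w_y, w_z) < 0)) stop("mean loads w_* must be >= 0", call. = FALSE)
  if (T_ext <= 0) stop("T_ext must be positive", call. = FALSE)
  if (N_patches < 1) stop("need at least one patch", call. = FALSE)
  structure(list(N_patches = N_patches, mu = mu, w_x = w_x, w_y = w_y,
                 w_z = w_z, P_col_x = P_col_x, P_col_y = P_col_y,
                 P_inf_x = P_inf_x, P_inf_y = P_inf_y, P_xy = P_xy,
                 P_yx = P_yx, T_ext = T_ext),
            class = "coarse_params")
}

#' Coarse patch-model state
#'
#' @param X,Y,Z counts (or densities) of uninfected wild-type, uninfected
#'   mutant and infected patches.
#' @param t time.
#' @return An object of class `coarse_state`.
#' @export
coarse_state <- function(X, Y = 0, Z = 0, t = 0) {
  if (any(c(X, Y, Z) < 0)) stop("patch counts must be >= 0", call. = FALSE)
  structure(list(X = X, Y = Y, Z = Z, t = t), class = "coarse_state")
}

#' Single-cell colonization success probability
#'
#' The probability that a single cell with division rate `r_rate` and death
#' rate `d_rate` founds a surviving patch population: `1 - d/r` (the survival
#' probability of the corresponding branching process).  When `d > r`
#' colonization is impossible and 0 is returned with a warning.
#'
#' @param d_rate death rate.
#' @param r_rate division rate (> 0).
#' @return A probability in `[0, 1]`.
#' @export
#' @examples
#' p_col(0.1, 0.7)  # 6/7
p_col <- function(d_rate, r_rate) {
  if (any(r_rate <= 0)) stop("division rate must be positive", call. = FALSE)
  out <- 1 - d_rate / r_rate
  if (any(out < 0)) {
    warning("death rate exceeds division rate; colonization impossible",
            call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}

#' Single-infected-cell patch-infection success probability
#'
#' The probability that a single infected cell arriving in an uninfected
#' patch with mean load `w` starts a successful infection:
#' `1 - (w * beta / a)^(-1)`, clamped to 0 below the invasion threshold
#' `w * beta <= a`.
#'
#' @param w mean per-deme uninfected population of the target patch type.
#' @param beta infection rate.
#' @param a death rate of infected cells (> 0).
#' @return A probability in `[0, 1]`.
#' @export
#' @examples
#' p_inf(85.714, 0.5, 0.5)
p_inf <- function(w, beta, a) {
  if (any(a <= 0)) stop("infected death rate a must be positive", call. = FALSE)
  pmax(0, 1 - a / (w * beta))
}

#' Patch-level selection coefficient of extinction-recolonization
#'
#' The selection coefficient experienced by mutant patches through the
#' extinction-recolonization loop: mutant patches seed colonists at rate
#' proportional to `w_y * P_col_y` and survive infection attempts in
#' proportion to `P_inf_x / P_inf_y` relative to wild-type patches, giving
#' \deqn{s_p^{ext-rec} = \frac{w_y P_{col}^y P_{inf}^x}{w_x P_{col}^x P_{inf}^y} - 1.}
#' Because the pathogen compresses the between-genotype differences at the
#' patch level, this coefficient is typically much smaller in magnitude than
#' the cell-level selection coefficient.
#'
#' @param w_x,w_y mean per-deme loads of wild-type and mutant patches.
#' @param P_col_x,P_col_y colonization success probabilities, [p_col()].
#' @param P_inf_x,P_inf_y infection success probabilities, [p_inf()].
#' @return The selection coefficient (0 for fully symmetric inputs).
#' @export
s_ext_rec <- function(w_x, w_y, P_col_x, P_col_y, P_inf_x, P_inf_y) {
  den <- w_x * P_col_x * P_inf_y
  if (any(den <= 0))
    stop("s_ext_rec undefined: w_x * P_col_x * P_inf_y must be positive",
         call. = FALSE)
  (w_y * P_col_y * P_inf_x) / den - 1
}

#' Patch-level selection coefficient of conversion
#'
#' Bias of the patch-conversion process, read off the ratio of the
#' conversion fluxes: a wild-type patch is converted by a mutant migrant at
#' rate proportional to `w_y * P_xy`, and a mutant patch by a wild-type
#' migrant at rate proportional to `w_x * P_yx`, giving
#' `s_p_conv = (w_y * P_xy) / (w_x * P_yx) - 1`.  Conversion through
#' death-birth events is the process that reduces to ordinary Moran dynamics
#' when patches are well mixed; this default definition is pluggable — any
#' externally derived value can be passed to [s_patch()] directly.
#'
#' @param w_x,w_y mean per-deme loads.
#' @param P_xy probability that a mutant migrant converts a wild-type patch.
#' @param P_yx probability that a wild-type migrant converts a mutant patch.
#' @return The conversion selection coefficient.
#' @export
s_conv <- function(w_x, w_y, P_xy, P_yx) {
  den <- w_x * P_yx
  if (any(den <= 0))
    stop("s_conv undefined: w_x * P_yx must be positive", call. = FALSE)
  (w_y * P_xy) / den - 1
}

#' Overall patch-level selection coefficient
#'
#' The rate-weighted mean of the conversion and extinction-recolonization
#' selection coefficients,
#' \deqn{s_p = \frac{R_{ext-rec}\, s_p^{ext-rec} + R_{conv}\, s_p^{conv}}{R_{ext-rec} + R_{conv}}.}
#' In a conversion-dominated system (`R_extrec = 0`) this is `s_conv` and
#' patch dynamics reduce to ordinary Moran competition; in a sparse,
#' extinction-driven system (`R_conv = 0`) it is `s_extrec`.
#'
#' @param s_conv conversion selection coefficient.
#' @param s_extrec extinction-recolonization selection coefficient.
#' @param R_conv,R_extrec the rates of the two processes (non-negative, not
#'   both zero).
#' @return The combined selection coefficient.
#' @export
s_patch <- function(s_conv, s_extrec, R_conv, R_extrec) {
  if (any(R_conv < 0) || any(R_extrec < 0))
    stop("process rates must be non-negative", call. = FALSE)
  if (any(R_conv + R_extrec == 0))
    stop("at least one of R_conv, R_extrec must be positive", call. = FALSE)
  (R_extrec * s_extrec + R_conv * s_conv) / (R_extrec + R_conv)
}

#' Moran fixation probability at the level of patches
#'
#' Applies the Moran fixation formula with the patch-level selection
#' coefficient: the probability that `i` initial mutant patches take over a
#' system whose mutant-free equilibrium holds `X_eq` uninfected patches.
#'
#' @param s_p patch-level selection coefficient (e.g. from [s_patch()]).
#' @param i initial number of mutant patches, `i <= X_eq`.
#' @param X_eq equilibrium number of uninfected patches without mutants.
#' @return The fixation probability; `i / X_eq` in the neutral limit.
#' @export
#' @examples
#' patch_moran_fixation(0.001, 1, 120)
patch_moran_fixation <- function(s_p, i, X_eq) {
  if (any(i > X_eq)) stop("need i <= X_eq", call. = FALSE)
  moran_fixation(s_p, i, X_eq)
}

# right-hand side of the patch ODEs; state = c(X, Y, Z)
coarse_rhs <- function(t, state, p) {
  X <- state[1]; Y <- state[2]; Z <- state[3]
  Np <- p$N_patches
  free <- 1 - (X + Y + Z) / Np
  col_x <- p$mu * X * p$w_x * free * p$P_col_x
  col_y <- p$mu * Y * p$w_y * free * p$P_col_y
  inf_x <- p$mu * Z * p$w_z * (X / Np) * p$P_inf_x
  inf_y <- p$mu * Z * p$w_z * (Y / Np) * p$P_inf_y
  conv_xy <- p$mu * Y * p$w_y * (X / Np) * p$P_xy   # X -> Y
  conv_yx <- p$mu * X * p$w_x * (Y / Np) * p$P_yx   # Y -> X
  dX <- col_x - inf_x - conv_xy + conv_yx
  dY <- col_y - inf_y + conv_xy - conv_yx
  dZ <- inf_x + inf_y - Z / p$T_ext
  list(c(dX, dY, dZ))
}

#' Integrate the coarse patch-competition ODEs
#'
#' Numerically integrates the three patch-type equations (colonization,
#' infection, conversion and extinction terms) with an adaptive embedded
#' Runge-Kutta 4(5) scheme, projecting the sampled trajectory onto
#' non-negative values.  An equilibrium flag is set when the final
#' derivatives are small relative to the patch number.
#'
#' @param state0 a [coarse_state()] initial condition.
#' @param params a [coarse_params()].
#' @param horizon integration time span.
#' @param solver_tol relative tolerance of the solver (default 1e-8).
#' @param n_out number of output samples (default 201).
#' @return A list with `trajectory` (data frame `t, X, Y, Z`),
#'   `equilibrium` (final state) and `converged`.
#' @export
integrate_coarse <- function(state0, params, horizon, solver_tol = 1e-8,
                             n_out = 201L) {
  stopifnot(inherits(state0, "coarse_state"), inherits(params, "coarse_params"),
            horizon > 0)
  y0 <- c(X = state0$X, Y = state0$Y, Z = state0$Z)
  times <- seq(state0$t, state0$t + horizon, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times, func = coarse_rhs,
                      parms = params, method = "ode45",
                      rtol = solver_tol, atol = solver_tol * params$N_patches)
  traj <- as.data.frame(sol)
  names(traj)[1] <- "t"
  occ <- traj$X + traj$Y + traj$Z
  if (any(occ > params$N_patches * (1 + 1e-6)) ||
      any(traj[, c("X", "Y", "Z")] < -1e-6 * params$N_patches))
    warning("trajectory left the [0, N] simplex beyond solver tolerance",
            call. = FALSE)
  traj$X <- pmax(traj$X, 0); traj$Y <- pmax(traj$Y, 0); traj$Z <- pmax(traj$Z, 0)
  nf <- nrow(traj)
  final <- coarse_state(traj$X[nf], traj$Y[nf], traj$Z[nf], traj$t[nf])
  d_end <- coarse_rhs(traj$t[nf], c(final$X, final$Y, final$Z), params)[[1]]
  list(trajectory = traj, equilibrium = final,
       converged = all(abs(d_end) < 1e-6 * params$N_patches))
}

#' Patch-process rates at equilibrium
#'
#' Reads the per-uninfected-patch rates of the two competing processes off
#' the coarse ODE terms at a (near-)equilibrium state: `R_conv` from the
#' conversion fluxes and `R_extrec` from the infection fluxes (each divided
#' by the number of uninfected patches).  User-supplied overrides are passed
#' through unchanged, so externally derived rates can be plugged in.
#'
#' @param eq_state a [coarse_state()] near equilibrium.
#' @param params a [coarse_params()].
#' @param override optional numeric vector `c(R_conv, R_extrec)` returned
#'   as-is.
#' @return A list with `R_conv` and `R_extrec`.
#' @export
estimate_event_rates <- function(eq_state, params, override = NULL) {
  if (!is.null(override)) {
    stopifnot(length(override) == 2, all(override >= 0))
    return(list(R_conv = override[1], R_extrec = override[2]))
  }
  stopifnot(inherits(eq_state, "coarse_state"), inherits(params, "coarse_params"))
  X <- eq_state$X; Y <- eq_state$Y; Z <- eq_state$Z
  d0 <- coarse_rhs(eq_state$t, c(X, Y, Z), params)[[1]]
  if (any(abs(d0) > 1e-3 * params$N_patches))
    warning("state does not look like an equilibrium of the coarse model",
            call. = FALSE)
  Np <- params$N_patches
  n_uninf <- X + Y
  if (n_uninf <= 0) stop("no uninfected patches in eq_state", call. = FALSE)
  conv <- params$mu * Y * params$w_y * (X / Np) * params$P_xy +
          params$mu * X * params$w_x * (Y / Np) * params$P_yx
  infc <- params$mu * Z * params$w_z *
          (X * params$P_inf_x + Y * params$P_inf_y) / Np
  list(R_conv = conv / n_uninf, R_extrec = infc / n_uninf)
}
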