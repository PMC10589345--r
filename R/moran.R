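# Moran-process reference formula and estimation statistics.

#' Fixation probability of the Moran process
#'
#' Evaluates the classical fixation probability of `i` mutants with
#' selection coefficient `s` in a constant population of `n` individuals,
#' \deqn{P_{fix}(i) = \frac{1 - 1/(1+s)^i}{1 - 1/(1+s)^n},}
#' numerically stably: via `expm1` throughout, switching to log-space for
#' strongly deleterious mutants in large populations (where numerator and
#' denominator overflow), and returning the neutral limit `i / n` as
#' `s -> 0`.
#'
#' @param s selection coefficient, `s > -1`.
#' @param i initial number of mutants, `0 <= i <= n`.
#' @param n total population size.
#' @return The fixation probability (vectorized over `s`, `i`, `n`).
#' @seealso [patch_moran_fixation()] for the same formula applied at the
#'   level of patches.
#' @export
#' @examples
#' moran_fixation(0, 1, 944)       # neutral: 1/944
#' moran_fixation(0.02, 1, 944)    # advantageous single mutant
#' moran_fixation(-0.001, 9000, 11288)
moran_fixation <- function(s, i, n) {
  k <- max(length(s), length(i), length(n))
  s <- rep_len(s, k); i <- rep_len(i, k); n <- rep_len(n, k)
  if (any(s <= -1)) stop("selection coefficient must satisfy s > -1", call. = FALSE)
  if (any(n < 1)) stop("population size n must be >= 1", call. = FALSE)
  if (any(i < 0 | i > n)) stop("need 0 <= i <= n", call. = FALSE)
  t <- log1p(s)
  out <- numeric(k)
  for (j in seq_len(k)) {
    if (abs(t[j]) < 1e-14) {               # neutral limit
      out[j] <- i[j] / n[j]
    } else if (-n[j] * t[j] > 700) {       # deleterious, overflow regime
      # log(expm1(a)) for large a is a + log1p(-exp(-a)) ~= a
      lnum <- -i[j] * t[j] + log1p(-exp(-abs(-i[j] * t[j])))
      lden <- -n[j] * t[j] + log1p(-exp(-abs(-n[j] * t[j])))
      out[j] <- exp(lnum - lden)
    } else {
      out[j] <- expm1(-i[j] * t[j]) / expm1(-n[j] * t[j])
    }
  }
  out
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' wilson_ci(3, 100)
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Clopper-Pearson (exact) confidence interval for a binomial proportion
#'
#' @inheritParams wilson_ci
#' @return Numeric vector `c(lower, upper)`.
#' @export
clopper_pearson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  alpha <- 1 - conf
  lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo, hi)
}

#' A single fixation-trial outcome
#'
#' @param kind one of `"fixation"`, `"extinction"`, `"global_extinction"`,
#'   `"censored"`.
#' @param t_conditional time from mutant introduction to fixation; present
#'   if and only if `kind == "fixation"` (time-steps for the ABM, model time
#'   for the deme model).
#' @param seed the trial's seed (reproduces the trial bit-exactly).
#' @param introduction_step step/time at which mutants were introduced
#'   (absent when the population died before introduction).
#' @return An object of class `trial_outcome`.
#' @export
trial_outcome <- function(kind, t_conditional = NA_real_, seed = NA_integer_,
                          introduction_step = NA_real_) {
  kinds <- c("fixation", "extinction", "global_extinction", "censored")
  if (!kind %in% kinds)
    stop("unknown outcome kind: ", kind, call. = FALSE)
  if (kind == "fixation" && !is.finite(t_conditional))
    stop("fixation outcomes must carry t_conditional", call. = FALSE)
  if (kind != "fixation" && is.finite(t_conditional))
    stop("t_conditional is only defined for fixation outcomes", call. = FALSE)
  structure(list(kind = kind, t_conditional = t_conditional, seed = seed,
                 introduction_step = introduction_step),
            class = "trial_outcome")
}

#' Estimate fixation probability and conditional fixation time
#'
#' Aggregates replicated [trial_outcome()]s into a point estimate of the
#' fixation probability with 95% confidence limits and the conditional
#' fixation-time mean with its standard error (over fixation runs only).
#'
#' Runs that ended in global extinction count in the denominator as
#' non-fixations but are reported separately.  Censored runs are excluded
#' from the denominator when they exceed 0.1% of all runs; a smaller number
#' of censored runs is counted as non-fixation with a warning.
#'
#' @param outcomes a list of [trial_outcome()]s, or a data frame with
#'   columns `kind` and `t_conditional`.
#' @param method confidence-interval method, `"wilson"` (default) or
#'   `"clopper-pearson"`.
#' @param conf confidence level (default 0.95).
#' @return An object of class `fixation_estimate`: `n_runs`, `n_fix`,
#'   `n_ext`, `n_global_ext`, `n_censored`, `p_hat`, `ci95_low`, `ci95_high`,
#'   `t_fix_mean`, `t_fix_se` (the time fields are `NA` when no run fixed).
#' @export
#' @examples
#' est <- estimate_fixation(list(
#'   trial_outcome("fixation", t_conditional = 7, seed = 1),
#'   trial_outcome("extinction", seed = 2),
#'   trial_outcome("extinction", seed = 3)))
#' est$p_hat
estimate_fixation <- function(outcomes, method = c("wilson", "clopper-pearson"),
                              conf = 0.95) {
  method <- match.arg(method)
  if (is.data.frame(outcomes)) {
    kind <- outcomes$kind
    t_fix <- outcomes$t_conditional
  } else {
    if (length(outcomes) == 0) stop("no outcomes supplied", call. = FALSE)
    kind <- vapply(outcomes, function(o) o$kind, character(1))
    t_fix <- vapply(outcomes, function(o) o$t_conditional, numeric(1))
  }
  if (length(kind) == 0) stop("no outcomes supplied", call. = FALSE)

  n_total <- length(kind)
  n_cens <- sum(kind == "censored")
  if (n_cens > 0 && n_cens / n_total > 0.001) {
    keep <- kind != "censored"
    kind <- kind[keep]; t_fix <- t_fix[keep]
  } else if (n_cens > 0) {
    warning(n_cens, " censored run(s) counted as non-fixation", call. = FALSE)
  }
  n_runs <- length(kind)
  if (n_runs == 0) stop("all runs were censored", call. = FALSE)
  n_fix <- sum(kind == "fixation")
  n_glob <- sum(kind == "global_extinction")
  n_ext <- n_runs - n_fix - n_glob
  p_hat <- n_fix / n_runs
  ci <- if (method == "wilson") wilson_ci(n_fix, n_runs, conf)
        else clopper_pearson_ci(n_fix, n_runs, conf)

  tf <- t_fix[kind == "fixation"]
  t_mean <- if (n_fix > 0) mean(tf) else NA_real_
  t_se <- if (n_fix > 1) stats::sd(tf) / sqrt(n_fix)
          else if (n_fix == 1) NA_real_ else NA_real_

  structure(list(n_runs = n_runs, n_fix = n_fix, n_ext = n_ext,
                 n_global_ext = n_glob, n_censored = n_cens,
                 p_hat = p_hat, ci95_low = ci[1], ci95_high = ci[2],
                 t_fix_mean = t_mean, t_fix_se = t_se,
                 method = method, conf = conf),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat("<fixation_estimate> ", x$n_runs, " runs: ", x$n_fix, " fixed, ",
      x$n_ext, " lost, ", x$n_global_ext, " globally extinct",
      if (x$n_censored > 0) paste0(", ", x$n_censored, " censored"), "\n",
      sep = "")
  cat(sprintf("  p_fix = %.5g  [%.5g, %.5g] (%s %g%%)\n",
              x$p_hat, x$ci95_low, x$ci95_high, x$method, 100 * x$conf))
  if (is.finite(x$t_fix_mean))
    cat(sprintf("  conditional fixation time: %.5g (se %.3g)\n",
                x$t_fix_mean, x$t_fix_se))
  invisible(x)
}
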