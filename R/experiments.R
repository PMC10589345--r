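# Fixation-trial protocol, shared by both engines:
# burn in to quasi-equilibrium, introduce mutants when the uninfected count
# first equals round(N_u) after burn-in (nearest-approach fallback if exact
# equality is not hit within a waiting window), run to absorption, classify.

#' Fixation-trial protocol
#'
#' Bundles an engine, its parameters and the trial settings for
#' [run_trial()] / [run_trials()] / [run_sweep()].
#'
#' @param engine `"abm"` or `"deme"`.
#' @param params an [abm_params()] or [deme_params()] matching the engine.
#' @param n_mutants number of mutants introduced at quasi-equilibrium.
#' @param N_u the equilibrium uninfected population used as introduction
#'   trigger; if `NULL` it is measured once with [abm_equilibrium()] /
#'   [deme_equilibrium()] at trial time.
#' @param burn_in burn-in before the trigger is armed (time-steps for the
#'   ABM, time units for the deme model).
#' @param max_wait trigger waiting window before the nearest-approach
#'   fallback engages.
#' @param horizon censoring horizon measured from mutant introduction
#'   (default 1e6).
#' @param n_replicates number of replicate trials.
#' @param seed_base root seed; trial `k` runs with seed `seed_base + k`.
#' @return An object of class `trial_protocol`.
#' @export
trial_protocol <- function(engine = c("abm", "deme"), params, n_mutants,
                           N_u = NULL, burn_in = NULL, max_wait = NULL,
                           horizon = 1e6, n_replicates = 1L, seed_base = 1L) {
  engine <- match.arg(engine)
  expected <- if (engine == "abm") "abm_params" else "deme_params"
  if (!inherits(params, expected))
    stop("engine '", engine, "' needs ", expected, " parameters", call. = FALSE)
  if (n_mutants < 1) stop("n_mutants must be >= 1", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (!is.null(N_u) && N_u < n_mutants)
    stop("N_u must be at least n_mutants", call. = FALSE)
  if (is.null(burn_in)) burn_in <- if (engine == "abm") 500 else 100
  if (is.null(max_wait)) max_wait <- if (engine == "abm") 5000 else 2000
  structure(list(engine = engine, params = params,
                 n_mutants = as.integer(n_mutants), N_u = N_u,
                 burn_in = burn_in, max_wait = max_wait, horizon = horizon,
                 n_replicates = as.integer(n_replicates),
                 seed_base = as.integer(seed_base)),
            class = "trial_protocol")
}

#' @export
print.trial_protocol <- function(x, ...) {
  cat("<trial_protocol> engine ", x$engine, ", ", x$n_mutants,
      " mutant(s), ", x$n_replicates, " replicate(s)\n", sep = "")
  if (!is.null(x$N_u)) cat("  trigger N_u =", x$N_u, "\n")
  invisible(x)
}

#' Classify the absorption state from class counts
#'
#' Operationalizes the stopping rule on uninfected-class counts only:
#' infected cells neither divide nor recover, so they cannot re-found a
#' lineage and the uninfected counts decide the outcome.
#'
#' @param counts named numeric vector with at least `uninf_wt` and
#'   `uninf_mut` (infected counts may be present and are ignored).
#' @return One of `"fixation"` (no uninfected WT left, mutants remain),
#'   `"extinction"` (no uninfected mutants left), `"global_extinction"`
#'   (no uninfected cells of either genotype), or `"ongoing"`.
#' @export
#' @examples
#' classify_absorption(c(uninf_wt = 0, uninf_mut = 5, inf_wt = 3))
classify_absorption <- function(counts) {
  cw <- counts[["uninf_wt"]]
  cm <- counts[["uninf_mut"]]
  if (cw == 0 && cm == 0) "global_extinction"
  else if (cm == 0) "extinction"
  else if (cw == 0) "fixation"
  else "ongoing"
}

measure_protocol_nu <- function(protocol, seed) {
  if (!is.null(protocol$N_u)) return(protocol$N_u)
  if (protocol$engine == "abm")
    abm_equilibrium(protocol$params, burn_in = protocol$burn_in,
                    window = 2000L, seed = seed)$N_u
  else
    deme_equilibrium(protocol$params, burn_in = protocol$burn_in,
                     window = 500, seed = seed)$N_u
}

#' Run a single fixation trial
#'
#' Executes one complete trial: burn the mutant-free system in, wait for the
#' uninfected population to equal `round(N_u)`, convert `n_mutants`
#' uninfected wild-type individuals to mutants (ABM: uniformly chosen sites,
#' simultaneous conversion; deme: patches chosen proportionally to their
#' wild-type load), run until the mutant lineage is fixed or lost, and
#' classify the outcome.  Conditional times are measured from introduction.
#'
#' @param protocol a [trial_protocol()].
#' @param seed the trial's seed; the same seed reproduces the trial
#'   bit-exactly.
#' @return A [trial_outcome()].
#' @export
run_trial <- function(protocol, seed) {
  stopifnot(inherits(protocol, "trial_protocol"))
  Nu <- measure_protocol_nu(protocol, seed)
  if (Nu < protocol$n_mutants)
    stop("equilibrium N_u (", Nu, ") smaller than n_mutants", call. = FALSE)
  p <- protocol$params
  if (protocol$engine == "abm") {
    init <- abm_init_block(p)
    res <- cpp_abm_trial(init$lattice, p$R, p$D, p$A, p$B, p$s,
                         Nu, protocol$n_mutants,
                         as.integer(protocol$burn_in),
                         as.integer(protocol$max_wait),
                         protocol$horizon, as.double(seed), 7)
  } else {
    sys <- deme_system(p)
    res <- cpp_deme_trial(sys$x, sys$y, sys$z, p$n1, p$n2,
                          p$r, p$d, p$beta, p$a, p$K, p$mu, p$s,
                          p$migration_mode == "spatial",
                          Nu, protocol$n_mutants, protocol$burn_in,
                          protocol$max_wait, protocol$horizon,
                          as.double(seed), 7)
  }
  kinds <- c("fixation", "extinction", "global_extinction", "censored")
  intro <- res[[3]]  # introduction step/time (NA when never introduced)
  trial_outcome(kinds[res$kind], t_conditional = res$t_conditional,
                seed = seed, introduction_step = intro)
}

#' Run replicated fixation trials
#'
#' Runs `protocol$n_replicates` independent trials with seeds
#' `seed_base + 1, ..., seed_base + n_replicates` and collects the outcomes.
#' `N_u` is measured once (if not supplied) and shared by all replicates.
#'
#' @param protocol a [trial_protocol()].
#' @return A list with `outcomes` (data frame `kind, t_conditional, seed,
#'   introduction_step`), `estimate` (a [estimate_fixation()] result),
#'   and `N_u` (the trigger value used).
#' @export
run_trials <- function(protocol) {
  stopifnot(inherits(protocol, "trial_protocol"))
  Nu <- measure_protocol_nu(protocol, protocol$seed_base)
  proto <- protocol
  proto$N_u <- Nu
  outs <- vector("list", protocol$n_replicates)
  for (k in seq_len(protocol$n_replicates))
    outs[[k]] <- run_trial(proto, seed = protocol$seed_base + k)
  df <- data.frame(
    kind = vapply(outs, `[[`, character(1), "kind"),
    t_conditional = vapply(outs, `[[`, numeric(1), "t_conditional"),
    seed = vapply(outs, `[[`, numeric(1), "seed"),
    introduction_step = vapply(outs, `[[`, numeric(1), "introduction_step"))
  fail <- mean(df$kind == "global_extinction")
  if (fail > 0.5)
    stop("persistence failure: ", round(100 * fail), "% of trials went ",
         "globally extinct; the system does not persist at these parameters",
         call. = FALSE)
  list(outcomes = df, estimate = estimate_fixation(df), N_u = Nu)
}

#' Sweep fixation trials over a list of protocols
#'
#' Runs [run_trials()] for each protocol (typically one per infection rate,
#' each calibrated to approximately the same equilibrium population) and
#' tabulates the per-protocol fixation estimates.
#'
#' @param protocols a list of [trial_protocol()]s.
#' @param labels optional character labels for the rows (default: the
#'   infection rate `B` or `beta` of each protocol).
#' @return A list with `table` (one row per protocol: label, engine, N_u,
#'   n_runs, n_fix, p_hat, ci95_low, ci95_high, t_fix_mean, t_fix_se) and
#'   `runs` (the per-protocol [run_trials()] results).
#' @export
run_sweep <- function(protocols, labels = NULL) {
  if (length(protocols) == 0) stop("no protocols supplied", call. = FALSE)
  for (p in protocols) stopifnot(inherits(p, "trial_protocol"))
  if (is.null(labels))
    labels <- vapply(protocols, function(p)
      as.character(if (p$engine == "abm") p$params$B else p$params$beta),
      character(1))
  runs <- lapply(protocols, run_trials)
  rows <- Map(function(lab, p, r) {
    e <- r$estimate
    data.frame(label = lab, engine = p$engine, N_u = r$N_u,
               n_runs = e$n_runs, n_fix = e$n_fix, p_hat = e$p_hat,
               ci95_low = e$ci95_low, ci95_high = e$ci95_high,
               t_fix_mean = e$t_fix_mean, t_fix_se = e$t_fix_se)
  }, labels, protocols, runs)
  list(table = do.call(rbind, rows), runs = runs)
}
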