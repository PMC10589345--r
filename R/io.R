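# Configuration parsing/validation, content digests, and readers/writers
# for the CSV/JSON artifacts and lattice snapshot dumps.

djb2_hex <- function(raw) {
  # 32-bit djb2 hash over a raw vector (exact in double arithmetic:
  # h*33 + b < 2^53); configs and reports are tiny, speed is irrelevant
  h <- 5381
  for (b in as.integer(raw)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Content digest of a configuration (or any R object)
#'
#' A stable content hash (djb2 over the canonical serialization) embedded
#' in every artifact the package writes, so that outputs can be matched to
#' the exact configuration that produced them.
#'
#' @param x any R object.
#' @return An 8-hex-digit character scalar.
#' @export
config_digest <- function(x) {
  djb2_hex(serialize(x, NULL, version = 2))
}

abm_config_keys <- c("R", "D", "A", "B", "s", "n1", "n2")
deme_config_keys <- c("r", "d", "beta", "a", "K", "mu", "s", "n1", "n2",
                      "migration_mode")
exp_config_keys <- c("n_mutants", "N_u", "n_replicates", "burn_in",
                     "max_wait", "horizon")

#' Load and validate a run configuration
#'
#' Reads a JSON (or YAML) configuration with top-level keys `engine`
#' (`"abm"` or `"deme"`), `params` (the engine's parameter block), optional
#' `experiment` (trial settings: `n_mutants`, `N_u`, `n_replicates`,
#' `burn_in`, `max_wait`, `horizon`), `seed`, and optional `burn_in`,
#' `window` (equilibrium-measurement settings).  Unknown keys anywhere are
#' an error, and the engine constructors reject probability-budget
#' violations (`R*(1+s) + D > 1`, `A + B > 1`) rather than clamping them.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return An object of class `run_config`: the validated blocks plus
#'   `params` (a constructed [abm_params()]/[deme_params()]) and `digest`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format '.", ext, "' (use JSON or YAML)",
         call. = FALSE))
  top_keys <- c("engine", "params", "experiment", "seed", "burn_in", "window",
                "out_dir", "log_level")
  problems <- character(0)
  unknown <- setdiff(names(cfg), top_keys)
  if (length(unknown))
    problems <- c(problems, paste0("unknown top-level key(s): ",
                                   paste(unknown, collapse = ", ")))
  if (is.null(cfg$engine) || !cfg$engine %in% c("abm", "deme"))
    problems <- c(problems, "engine must be \"abm\" or \"deme\"")
  if (is.null(cfg$params)) problems <- c(problems, "missing params block")
  if (length(problems)) stop(paste(problems, collapse = "; "), call. = FALSE)

  allowed <- if (cfg$engine == "abm") abm_config_keys else deme_config_keys
  unknown <- setdiff(names(cfg$params), allowed)
  if (length(unknown))
    stop("unknown params key(s) for engine '", cfg$engine, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  params <- do.call(if (cfg$engine == "abm") abm_params else deme_params,
                    cfg$params)

  if (!is.null(cfg$experiment)) {
    unknown <- setdiff(names(cfg$experiment), exp_config_keys)
    if (length(unknown))
      stop("unknown experiment key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  out <- structure(list(engine = cfg$engine, params = params,
                        experiment = cfg$experiment, seed = cfg$seed,
                        burn_in = cfg$burn_in, window = cfg$window,
                        out_dir = cfg$out_dir, log_level = cfg$log_level),
                   class = "run_config")
  out$digest <- config_digest(out[setdiff(names(out), "digest")])
  out
}

#' Write a run configuration back to disk
#'
#' Inverse of [load_config()]; a load-dump-load round trip is idempotent.
#'
#' @param config a `run_config` from [load_config()].
#' @param path output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- list(engine = config$engine, params = unclass(config$params),
              experiment = config$experiment, seed = config$seed,
              burn_in = config$burn_in, window = config$window,
              out_dir = config$out_dir, log_level = config$log_level)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else if (ext %in% c("yaml", "yml"))
    yaml::write_yaml(lst, path)
  else stop("unsupported config format '.", ext, "'", call. = FALSE)
  invisible(path)
}

#' Write / read a fixation-estimate JSON report
#'
#' The report schema is `{n_runs, n_fix, n_ext, n_global_ext, p_hat,
#' ci95: [lo, hi], t_fix: {mean, se}, config_digest, seeds}`.  A report
#' without a `seeds` field is rejected on read (every artifact must be
#' reproducible from its seed ledger).  An undefined `t_fix` standard error
#' (single fixation) is serialized as `null` and read back as `NA`.
#'
#' @param estimate a [estimate_fixation()] result.
#' @param path output path.
#' @param config_digest digest of the configuration that produced the runs
#'   (see [config_digest()]).
#' @param seeds integer vector of the trial seeds.
#' @return `path` invisibly (write) or a `fixation_estimate` with
#'   attributes `config_digest` and `seeds` (read).
#' @export
write_report <- function(estimate, path, config_digest, seeds) {
  stopifnot(inherits(estimate, "fixation_estimate"))
  if (missing(seeds) || length(seeds) == 0)
    stop("a report needs the seed ledger", call. = FALSE)
  rep <- list(
    n_runs = estimate$n_runs, n_fix = estimate$n_fix, n_ext = estimate$n_ext,
    n_global_ext = estimate$n_global_ext, n_censored = estimate$n_censored,
    p_hat = estimate$p_hat,
    ci95 = c(estimate$ci95_low, estimate$ci95_high),
    t_fix = list(
      mean = if (is.finite(estimate$t_fix_mean)) estimate$t_fix_mean,
      se = if (is.finite(estimate$t_fix_se)) estimate$t_fix_se),
    config_digest = config_digest, seeds = as.integer(seeds))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  required <- c("n_runs", "n_fix", "n_ext", "n_global_ext", "p_hat", "ci95",
                "config_digest", "seeds")
  missing_keys <- setdiff(required, names(rep))
  if (length(missing_keys))
    stop("malformed report, missing field(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  est <- structure(list(
    n_runs = rep$n_runs, n_fix = rep$n_fix, n_ext = rep$n_ext,
    n_global_ext = rep$n_global_ext,
    n_censored = if (is.null(rep$n_censored)) 0L else rep$n_censored,
    p_hat = rep$p_hat, ci95_low = rep$ci95[1], ci95_high = rep$ci95[2],
    t_fix_mean = num_or_na(rep$t_fix$mean), t_fix_se = num_or_na(rep$t_fix$se),
    method = "wilson", conf = 0.95), class = "fixation_estimate")
  attr(est, "config_digest") <- rep$config_digest
  attr(est, "seeds") <- rep$seeds
  est
}

abm_series_cols <- c("step", "uninf_wt", "uninf_mut", "inf_wt", "inf_mut")
deme_series_cols <- c("t", "total_x", "total_y", "total_z")

#' Write / read a count time series as CSV
#'
#' ABM series use the schema `step, uninf_wt, uninf_mut, inf_wt, inf_mut`;
#' deme series use `t, total_x, total_y, total_z`.  The configuration digest
#' is embedded as a `# digest:` comment line so every artifact can be traced
#' to its configuration; schema mismatches on read are an explicit error.
#'
#' @param series a data frame conforming to one of the two schemas.
#' @param path output path.
#' @param digest optional [config_digest()] string to embed.
#' @return `path` invisibly (write) or the data frame (read).
#' @export
write_series_csv <- function(series, path, digest = NULL) {
  if (!identical(names(series), abm_series_cols) &&
      !identical(names(series), deme_series_cols))
    stop("series does not conform to the ABM or deme schema", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(digest)) writeLines(paste0("# digest: ", digest), con)
  write.csv(series, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!identical(names(df), abm_series_cols) &&
      !identical(names(df), deme_series_cols))
    stop("file does not conform to the ABM or deme series schema: ",
         paste(names(df), collapse = ","), call. = FALSE)
  df
}

#' Write / read a lattice snapshot as a plain-text matrix
#'
#' One row of space-separated site codes per grid row (see
#' [abm_site_codes()]: 0 empty, 1 uninfected WT, 2 infected WT, 3 uninfected
#' MUT, 4 infected MUT).
#'
#' @param state a [grid_state()].
#' @param path output path.
#' @return `path` invisibly (write) or a [grid_state()] (read).
#' @export
write_snapshot <- function(state, path) {
  stopifnot(inherits(state, "grid_state"))
  write.table(state$lattice, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  grid_state(m)
}
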