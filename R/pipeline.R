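# Pipeline configuration schema (YAML or list):
#   mode: run | simulate | analyze      (default run)
#   seed: integer                       (required for simulate/run)
#   n_trials: integer                   (default 200)
#   session_dir: path                   (analyze: input; simulate: output)
#   out_dir: path                       (analysis outputs)
#   session: named overrides of session_config()
#   model:   named overrides of feedback_model() (no functions)
#   analysis: lags (ms), n_boot, conf
# Function arguments override config values; unknown keys are rejected
# before any computation.

rc_log_threshold <- function(level) {
  match(level, c("quiet", "info", "debug"))
}

rc_log <- function(level, msg, threshold) {
  if (match(level, c("quiet", "info", "debug")) <= threshold) {
    message(format(Sys.time(), "%H:%M:%OS1"), " [", level, "] ", msg)
  }
}

validate_pipeline_config <- function(config) {
  known <- c(
    "mode", "seed", "n_trials", "session_dir", "out_dir",
    "session", "model", "analysis"
  )
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop("run_pipeline: unknown config key(s): ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  config[["mode"]] <- config[["mode"]] %||% "run"
  if (!config[["mode"]] %in% c("run", "simulate", "analyze")) {
    stop("run_pipeline: mode must be one of run/simulate/analyze",
      call. = FALSE
    )
  }
  check_sub <- function(sub, fn, what) {
    extra <- setdiff(names(sub), names(formals(fn)))
    if (length(extra)) {
      stop("run_pipeline: unknown ", what, " key(s): ",
        paste(extra, collapse = ", "),
        call. = FALSE
      )
    }
  }
  check_sub(config[["session"]], session_config, "session")
  check_sub(config[["model"]], feedback_model, "model")
  extra <- setdiff(names(config[["analysis"]]), c("lags", "n_boot", "conf"))
  if (length(extra)) {
    stop("run_pipeline: unknown analysis key(s): ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  if (config[["mode"]] == "analyze" && is.null(config[["session_dir"]])) {
    stop("run_pipeline: analyze mode requires `session_dir`", call. = FALSE)
  }
  config
}

#' Run the simulate/analyze pipeline end to end
#'
#' Drives the whole package from one declarative configuration: simulate a
#' session (or read one from disk), annotate movement ends, estimate all
#' response kernels, reduce them to the lag-slice vigour comparison, and
#' write tidy result tables plus a human-readable report. Every path is
#' deterministic given the seed; the run record echoes the configuration,
#' its hash, the seed, and exclusion counts.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list (see the schema at the top of the pipeline source; all keys
#'   optional except `session_dir` in analyze mode).
#' @param out_dir Output directory; overrides the config value. `NULL`
#'   (and absent from config) skips writing and returns results only.
#' @param seed Seed; overrides the config value.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return Invisibly, a list with `session`, `kernels`, `vigour`,
#'   `summary`, and `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL,
                         log_level = "info") {
  thr <- rc_log_threshold(match.arg(log_level, c("quiet", "info", "debug")))
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("run_pipeline: `config` must be a YAML path or a list", call. = FALSE)
  }
  config <- validate_pipeline_config(config)
  seed <- seed %||% config[["seed"]]
  out_dir <- out_dir %||% config[["out_dir"]]

  cfg <- do.call(session_config, config[["session"]] %||% list())
  if (config[["mode"]] %in% c("run", "simulate")) {
    if (is.null(seed)) {
      stop("run_pipeline: simulation requires a seed", call. = FALSE)
    }
    model <- do.call(feedback_model, config[["model"]] %||% list())
    n_trials <- config[["n_trials"]] %||% 200L
    rc_log("info", paste0(
      "simulating ", n_trials, " trials (seed ", seed, ")"
    ), thr)
    session <- simulate_session(cfg, model, n_trials, seed = seed)
    if (!is.null(config[["session_dir"]])) {
      write_session(session, config[["session_dir"]])
      rc_log("info", paste0("session written to ", config[["session_dir"]]), thr)
    }
    if (config[["mode"]] == "simulate") {
      return(invisible(list(
        session = session, kernels = NULL, vigour = NULL,
        summary = NULL, out_dir = config[["session_dir"]]
      )))
    }
  } else {
    rc_log("info", paste0("reading session from ", config[["session_dir"]]), thr)
    session <- read_session(config[["session_dir"]], cfg)
  }

  session <- annotate_session(session, cfg)
  n_exc <- sum(vapply(session$trials, function(tr) isTRUE(tr$excluded), TRUE))
  rc_log("info", paste0(
    length(session$trials), " trials annotated, ", n_exc, " excluded"
  ), thr)

  kernels <- kernel_matrix(session, cfg)
  ana <- config[["analysis"]] %||% list()
  vig <- vigour_summary(kernels,
    lags = ana$lags %||% c(160, 170, 180),
    n_boot = ana$n_boot %||% 2000,
    conf = ana$conf %||% 0.95,
    seed = seed
  )
  summ <- session_summary(session)
  rc_log("debug", paste0(nrow(kernels), " kernel rows"), thr)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(kernels, file.path(out_dir, "kernels.csv"))
    readr::write_csv(vig$pairs, file.path(out_dir, "vigour_pairs.csv"))
    readr::write_csv(vig$fits, file.path(out_dir, "vigour_fits.csv"))
    readr::write_csv(summ, file.path(out_dir, "session_summary.csv"))
    writeLines(pipeline_report(session, kernels, vig, summ),
      file.path(out_dir, "report.txt")
    )
    echo <- config
    echo$session <- config[["session"]] %||% list()
    yaml::write_yaml(
      list(
        config = echo, seed = seed, config_hash = rlang::hash(config),
        n_trials = length(session$trials), n_excluded = n_exc
      ),
      file.path(out_dir, "run_info.yml")
    )
    rc_log("info", paste0("results written to ", out_dir), thr)
  }
  invisible(list(
    session = session, kernels = kernels, vigour = vig,
    summary = summ, out_dir = out_dir
  ))
}

#' Human-readable pipeline report
#'
#' @param session,kernels,vigour,summary Pipeline products as returned by
#'   [run_pipeline()].
#' @return Character vector of report lines.
#' @export
pipeline_report <- function(session, kernels, vigour, summary) {
  lines <- c(
    sprintf("Session %s: %d trials", session$session_id, length(session$trials)),
    "",
    "Per perturbation type:"
  )
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    lines <- c(lines, sprintf(
      "  %-6s n = %d (%d excluded), hit fraction %.2f, end of movement %.0f +/- %.0f ms",
      r$perturb_type, r$n_trials, r$n_excluded, r$hit_fraction,
      r$end_time_mean_ms, r$end_time_sd_ms
    ))
  }
  lines <- c(lines, "", sprintf(
    "Kernels: %d curves (%d target, %d cursor), k = %d..%d",
    length(unique(paste(kernels$perturb_type, kernels$k))),
    length(unique(kernels$k[kernels$perturb_type == "target"])),
    length(unique(kernels$k[kernels$perturb_type == "cursor"])),
    min(kernels$k), max(kernels$k)
  ), "", "Cursor vs target vigour (through-origin fits):")
  for (i in seq_len(nrow(vigour$fits))) {
    r <- vigour$fits[i, ]
    lines <- c(lines, sprintf(
      "  lag %3.0f ms: slope %.3f, curvature %+.2e [%.2e, %.2e], %d pairs",
      r$lag_ms, r$origin_slope, r$curvature_index, r$curvature_lo,
      r$curvature_hi, r$n_pairs
    ))
  }
  lines
}
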