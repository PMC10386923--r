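# On-disk session dialect: three UTF-8 comma-separated files with header
# rows — samples.csv (trial_id, t_s, finger_x_mm, finger_y_mm), frames.csv
# (trial_id, frame_idx, t_s, step_dir, jitter_mm, target_x_mm, target_y_mm,
# cursor_offset_mm) and trials.csv (trial_id, perturb_type, hit,
# session_id) — ordered by trial_id then time. Externally produced tables
# (e.g. coerced from other motion-capture layouts) are accepted as long as
# they carry these columns.

SAMPLES_COLS <- c("trial_id", "t_s", "finger_x_mm", "finger_y_mm")
FRAMES_COLS <- c(
  "trial_id", "frame_idx", "t_s", "step_dir", "jitter_mm",
  "target_x_mm", "target_y_mm", "cursor_offset_mm"
)
TRIALS_COLS <- c("trial_id", "perturb_type", "hit", "session_id")

#' Write a session to a directory
#'
#' Writes the three files of the trial-table dialect (`samples.csv`,
#' `frames.csv`, `trials.csv`), deterministically ordered by trial id and
#' time. Excluded trials are written like any other: exclusion is an
#' analysis-time annotation, not a property of the data.
#'
#' @param session An `rc_session`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "rc_session"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop("write_session: cannot write to directory '", dir, "'", call. = FALSE)
  }
  trials <- session$trials[order(vapply(session$trials, function(tr) tr$trial_id, numeric(1)))]
  samples <- purrr::map_dfr(trials, function(tr) {
    tibble::tibble(
      trial_id = tr$trial_id, t_s = tr$samples$t,
      finger_x_mm = tr$samples$x, finger_y_mm = tr$samples$y
    )
  })
  frames <- purrr::map_dfr(trials, function(tr) {
    tibble::tibble(
      trial_id = tr$trial_id, frame_idx = tr$frames$frame,
      t_s = tr$frames$t, step_dir = tr$frames$step_dir,
      jitter_mm = tr$frames$jitter, target_x_mm = tr$frames$target_x,
      target_y_mm = tr$frames$target_y,
      cursor_offset_mm = tr$frames$cursor_offset
    )
  })
  meta <- purrr::map_dfr(trials, function(tr) {
    tibble::tibble(
      trial_id = tr$trial_id, perturb_type = tr$perturb_type,
      hit = isTRUE(tr$hit), session_id = session$session_id
    )
  })
  readr::write_csv(fmt17(samples), file.path(dir, "samples.csv"))
  readr::write_csv(fmt17(frames), file.path(dir, "frames.csv"))
  readr::write_csv(meta, file.path(dir, "trials.csv"))
  invisible(dir)
}

# Doubles are serialised with 17 significant digits so that
# write -> read -> write round-trips are bit-faithful and byte-identical.
fmt17 <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

stop_io <- function(...) stop(..., call. = FALSE)

check_cols <- function(df, needed, file) {
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_io(
      "read_session: ", file, " is missing column(s): ",
      paste(missing, collapse = ", ")
    )
  }
}

#' Read a session from a directory
#'
#' Reads and validates the three-file trial-table dialect written by
#' [write_session()]. Validation is total: non-monotone times, unknown
#' perturbation types, orphan trial ids, or jitter on the wrong channel
#' are rejected with the offending trial id and row.
#'
#' @param dir Directory containing `samples.csv`, `frames.csv`,
#'   `trials.csv`.
#' @param cfg The [session_config()] the session was recorded under
#'   (defaults to the standard configuration); used to validate the
#'   unperturbed target path on cursor trials.
#' @param session_id Optional override of the stored session id.
#' @return An `rc_session` (unannotated; run [annotate_session()] before
#'   analysis).
#' @export
read_session <- function(dir, cfg = session_config(), session_id = NULL) {
  paths <- file.path(dir, c("samples.csv", "frames.csv", "trials.csv"))
  for (p in paths) {
    if (!file.exists(p)) stop_io("read_session: missing file '", p, "'")
  }
  # base read.csv: exact (correctly rounded) double parsing, so that
  # write -> read -> write round-trips are bit-faithful
  samples <- tibble::as_tibble(utils::read.csv(paths[1L]))
  frames <- tibble::as_tibble(utils::read.csv(paths[2L]))
  meta <- tibble::as_tibble(utils::read.csv(paths[3L]))
  check_cols(samples, SAMPLES_COLS, "samples.csv")
  check_cols(frames, FRAMES_COLS, "frames.csv")
  check_cols(meta, TRIALS_COLS, "trials.csv")

  bad_type <- !meta$perturb_type %in% c("target", "cursor")
  if (any(bad_type)) {
    stop_io(
      "read_session: unknown perturb_type '",
      meta$perturb_type[bad_type][1L], "' for trial ",
      meta$trial_id[bad_type][1L], " (trials.csv row ",
      which(bad_type)[1L], ")"
    )
  }
  if (anyDuplicated(meta$trial_id)) {
    stop_io(
      "read_session: duplicated trial_id ",
      meta$trial_id[duplicated(meta$trial_id)][1L], " in trials.csv"
    )
  }
  for (nm in c("samples", "frames")) {
    df <- get(nm)
    orphan <- !df$trial_id %in% meta$trial_id
    if (any(orphan)) {
      stop_io(
        "read_session: trial_id ", df$trial_id[orphan][1L], " in ", nm,
        ".csv (row ", which(orphan)[1L], ") does not appear in trials.csv"
      )
    }
  }

  trials <- purrr::map(seq_len(nrow(meta)), function(i) {
    id <- meta$trial_id[i]
    ptype <- meta$perturb_type[i]
    s_rows <- which(samples$trial_id == id)
    f_rows <- which(frames$trial_id == id)
    if (!length(s_rows) || !length(f_rows)) {
      stop_io("read_session: trial ", id, " has no samples or no frames")
    }
    st <- samples$t_s[s_rows]
    if (any(diff(st) <= 0)) {
      bad <- s_rows[which(diff(st) <= 0)[1L] + 1L]
      stop_io(
        "read_session: sample times not strictly increasing for trial ",
        id, " (samples.csv row ", bad, ")"
      )
    }
    ft <- frames$t_s[f_rows]
    if (any(diff(ft) <= 0)) {
      bad <- f_rows[which(diff(ft) <= 0)[1L] + 1L]
      stop_io(
        "read_session: frame times not strictly increasing for trial ",
        id, " (frames.csv row ", bad, ")"
      )
    }
    sd_ok <- frames$step_dir[f_rows] %in% c(-1, 1)
    if (!all(sd_ok)) {
      stop_io(
        "read_session: step_dir must be -1 or +1 for trial ", id,
        " (frames.csv row ", f_rows[!sd_ok][1L], ")"
      )
    }
    if (ptype == "target" && any(frames$cursor_offset_mm[f_rows] != 0)) {
      bad <- f_rows[which(frames$cursor_offset_mm[f_rows] != 0)[1L]]
      stop_io(
        "read_session: target-jitter trial ", id,
        " has nonzero cursor_offset_mm (frames.csv row ", bad, ")"
      )
    }
    if (ptype == "cursor") {
      path_x <- cfg$target_start[1] + cfg$target_speed * ft
      off <- abs(frames$target_x_mm[f_rows] - path_x)
      if (any(off > 1e-6)) {
        bad <- f_rows[which(off > 1e-6)[1L]]
        stop_io(
          "read_session: cursor-jitter trial ", id,
          " deviates from the unperturbed target path (frames.csv row ",
          bad, ")"
        )
      }
    }
    structure(
      list(
        trial_id = id, perturb_type = ptype,
        samples = tibble::tibble(
          t = st, x = samples$finger_x_mm[s_rows],
          y = samples$finger_y_mm[s_rows]
        ),
        frames = tibble::tibble(
          frame = frames$frame_idx[f_rows], t = ft,
          step_dir = frames$step_dir[f_rows],
          jitter = frames$jitter_mm[f_rows],
          target_x = frames$target_x_mm[f_rows],
          target_y = frames$target_y_mm[f_rows],
          cursor_offset = frames$cursor_offset_mm[f_rows]
        ),
        hit = meta$hit[i], hit_position = NULL,
        movement_end = NULL, excluded = FALSE
      ),
      class = "rc_trial"
    )
  })
  structure(
    list(
      session_id = session_id %||% meta$session_id[1L],
      config = cfg, model = NULL, trials = trials
    ),
    class = "rc_session"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
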