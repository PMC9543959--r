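#' Trial-structured motion dataset
#'
#' Container for a joint-angle time series organised as an
#' `I x J x K` array: `I` joints, `J` time frames per trial, `K` trials.
#' All trials share the same joints and window length; missing values are
#' not allowed.
#'
#' @param angles Numeric array of dimension `c(I, J, K)` (joint, frame, trial).
#'   A matrix is interpreted as a single trial.
#' @param joints Character vector of `I` joint labels. Defaults to
#'   `"joint1" ... "jointI"`; a four-joint dataset defaults to the lower-limb
#'   labels toe, ankle, knee, hip.
#' @param sample_rate Sampling rate in Hz (default 120).
#' @param units Angle units, `"deg"` or `"rad"`.
#' @param subject_id,experiment_id Identifiers carried through to file output.
#'
#' @return An object of class `motion_data`: a list with elements `angles`,
#'   `joints`, `sample_rate`, `window_ms`, `units`, `subject_id`,
#'   `experiment_id`.
#' @examples
#' md <- motion_data(array(rnorm(4 * 60 * 10), c(4, 60, 10)))
#' dim(md)
#' @export
motion_data <- function(angles, joints = NULL, sample_rate = 120,
                        units = c("deg", "rad"),
                        subject_id = "S01", experiment_id = "E1") {
  units <- match.arg(units)
  if (is.matrix(angles)) angles <- array(angles, c(dim(angles), 1L))
  if (!is.array(angles) || length(dim(angles)) != 3L) {
    abort("`angles` must be an I x J x K array (joint, frame, trial).")
  }
  if (anyNA(angles) || !all(is.finite(angles))) {
    bad <- which(!is.finite(angles), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "missing/non-finite angle at joint %d, frame %d, trial %d",
      bad[1L], bad[2L], bad[3L]
    ))
  }
  d <- dim(angles)
  if (d[2L] < 2L) abort("at least 2 frames per trial are required")
  if (d[3L] < 2L) abort("at least 2 trials are required")
  if (is.null(joints)) {
    joints <- if (d[1L] == 4L) {
      c("toe", "ankle", "knee", "hip")
    } else {
      paste0("joint", seq_len(d[1L]))
    }
  }
  if (length(joints) != d[1L]) abort("`joints` must have one label per joint")
  dimnames(angles) <- list(joints, NULL, NULL)
  structure(
    list(
      angles = angles, joints = joints, sample_rate = sample_rate,
      window_ms = 1000 * d[2L] / sample_rate, units = units,
      subject_id = subject_id, experiment_id = experiment_id
    ),
    class = "motion_data"
  )
}

#' @export
dim.motion_data <- function(x) dim(x$angles)

#' @export
print.motion_data <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<motion_data> %d joints x %d frames x %d trials (%g Hz, %.0f ms window)\n",
    d[1L], d[2L], d[3L], x$sample_rate, x$window_ms
  ))
  cat("joints:", paste(x$joints, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn motion_data Number of trials.
#' @param x A `motion_data` object.
#' @export
n_trials <- function(x) dim(x$angles)[3L]

#' Per-trial performance table
#'
#' Builds the per-trial companion table of a [motion_data] dataset: one row
#' per trial with the scalar performance (e.g. jump height in %Max), the
#' target value and the feedback perturbation applied on that trial.
#'
#' @param performance Numeric vector, one value per trial.
#' @param target Numeric target per trial (default `NA`).
#' @param perturbation Per-trial feedback perturbation; 0 when absent.
#' @param trial Integer trial indices, strictly increasing.
#' @param subject_id Subject identifier.
#'
#' @return A tibble with columns `subject`, `trial`, `performance`, `target`,
#'   `perturbation`.
#' @export
trial_data <- function(performance, target = NA_real_, perturbation = 0,
                       trial = seq_along(performance), subject_id = "S01") {
  if (anyNA(performance)) abort("`performance` must not contain NA")
  trial <- as.integer(trial)
  if (length(trial) != length(performance) || any(diff(trial) <= 0)) {
    abort("`trial` must be strictly increasing, one index per trial")
  }
  tibble::tibble(
    subject = subject_id,
    trial = trial,
    performance = as.numeric(performance),
    target = rep_len(as.numeric(target), length(performance)),
    perturbation = rep_len(as.numeric(perturbation), length(performance))
  )
}

#' Convert a long table of joint angles to a motion dataset
#'
#' @param df Data frame with columns `trial`, `frame`, `joint`, `angle`
#'   (and optionally `subject`). Frame indices are 0-based.
#' @param sample_rate,units Passed to [motion_data()].
#' @return A [motion_data] object.
#' @export
as_motion_data <- function(df, sample_rate = 120, units = "deg") {
  need <- c("trial", "frame", "joint", "angle")
  if (!all(need %in% names(df))) {
    abort(paste("long motion table needs columns:", paste(need, collapse = ", ")))
  }
  subject <- if ("subject" %in% names(df)) as.character(df$subject[1L]) else "S01"
  joints <- unique(as.character(df$joint))
  trials <- sort(unique(df$trial))
  frames <- sort(unique(df$frame))
  I <- length(joints); J <- length(frames); K <- length(trials)
  if (!identical(frames, as.numeric(seq_len(J) - 1)) &&
      !identical(as.integer(frames), seq_len(J) - 1L)) {
    abort("frame indices must be the consecutive 0-based sequence 0..J-1")
  }
  arr <- array(NA_real_, c(I, J, K))
  ii <- match(as.character(df$joint), joints)
  jj <- match(df$frame, frames)
  kk <- match(df$trial, trials)
  if (anyDuplicated(cbind(ii, jj, kk))) abort("duplicate (joint, frame, trial) cells")
  arr[cbind(ii, jj, kk)] <- df$angle
  if (anyNA(arr)) {
    bad <- which(is.na(arr), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "missing angle cell: trial %s, frame %s, joint %s",
      trials[bad[3L]], frames[bad[2L]], joints[bad[1L]]
    ))
  }
  motion_data(arr, joints = joints, sample_rate = sample_rate, units = units,
              subject_id = subject)
}

#' @export
tidy.motion_data <- function(x, ...) {
  d <- dim(x)
  tibble::tibble(
    subject = x$subject_id,
    trial = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    frame = rep(rep(seq_len(d[2L]) - 1L, each = d[1L]), times = d[3L]),
    joint = rep(x$joints, times = d[2L] * d[3L]),
    angle = as.numeric(x$angles)
  )
}

delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

fmt9 <- function(x) {
  ifelse(is.na(x), NA_character_, trimws(formatC(x, digits = 9, format = "g")))
}

#' Read a trial-structured dataset from delimited text
#'
#' Reads the long-format pair of files produced by [write_trials()]: a motion
#' file with columns `subject, trial, frame, joint, angle` (frames 0-based)
#' and a trial file with columns `subject, trial, performance, target,
#' perturbation`. The delimiter is chosen from the extension (`.csv` comma,
#' `.tsv`/`.txt` tab). Trials must be present in both files; they are matched
#' by trial index.
#'
#' @param motion_path,trials_path Paths to the two files.
#' @param sample_rate,units Metadata not carried by the files.
#' @return A list with elements `motion` (a [motion_data]) and `trials`
#'   (a tibble as from [trial_data()]).
#' @export
read_trials <- function(motion_path, trials_path, sample_rate = 120,
                        units = "deg") {
  mo <- readr::read_delim(motion_path, delim = delim_for(motion_path),
                          show_col_types = FALSE, progress = FALSE,
                          trim_ws = TRUE)
  tr <- readr::read_delim(trials_path, delim = delim_for(trials_path),
                          show_col_types = FALSE, progress = FALSE,
                          trim_ws = TRUE)
  need <- c("subject", "trial", "performance", "target", "perturbation")
  if (!all(need %in% names(tr))) {
    abort(paste("trial table needs columns:", paste(need, collapse = ", ")))
  }
  common <- intersect(unique(mo$trial), tr$trial)
  if (length(common) == 0L) abort("no trial indices shared by the two files")
  mo <- dplyr::filter(mo, .data$trial %in% common)
  tr <- dplyr::filter(tr, .data$trial %in% common)
  # ragged check: every trial must carry the same (joint, frame) grid
  counts <- dplyr::count(mo, .data$trial)
  if (length(unique(counts$n)) != 1L) {
    bad <- counts$trial[counts$n != max(counts$n)]
    abort(sprintf("ragged trials (unequal frame counts): trial %s",
                  paste(bad, collapse = ", ")))
  }
  motion <- as_motion_data(mo, sample_rate = sample_rate, units = units)
  tr <- dplyr::arrange(tr, .data$trial)
  trials <- trial_data(tr$performance, target = tr$target,
                       perturbation = tr$perturbation, trial = tr$trial,
                       subject_id = as.character(tr$subject[1L]))
  list(motion = motion, trials = trials)
}

#' Write a trial-structured dataset as delimited text
#'
#' Writes the long-format motion and trial files read back by
#' [read_trials()]. Floating-point values are written with 9 significant
#' digits.
#'
#' @param motion A [motion_data] object.
#' @param trials A tibble as from [trial_data()].
#' @param motion_path,trials_path Output paths (`.csv` comma, `.tsv` tab).
#' @return Invisibly, the two paths.
#' @export
write_trials <- function(motion, trials, motion_path, trials_path) {
  stopifnot(inherits(motion, "motion_data"))
  long <- tidy(motion)
  long$angle <- fmt9(long$angle)
  tr <- trials[, c("subject", "trial", "performance", "target", "perturbation")]
  tr$performance <- fmt9(tr$performance)
  tr$target <- fmt9(tr$target)
  tr$perturbation <- fmt9(tr$perturbation)
  readr::write_delim(long, motion_path, delim = delim_for(motion_path),
                     na = "NA", progress = FALSE)
  readr::write_delim(tr, trials_path, delim = delim_for(trials_path),
                     na = "NA", progress = FALSE)
  invisible(c(motion_path, trials_path))
}

#' Extract the pre-release analysis window
#'
#' Keeps the `J` frames strictly before the release event of each trial:
#' with 0-based frame indexing and release at frame `release_frame`, the
#' window is frames `release_frame - J` to `release_frame - 1`. This is the
#' analysis window of the jump paradigm (e.g. 60 frames = 500 ms at 120 Hz
#' before take-off).
#'
#' @param motion A [motion_data] object, a frames-by-trials matrix, or a
#'   single numeric series.
#' @param release_frame 0-based release frame per trial (scalar recycled).
#'   See [detect_release()].
#' @param J Window length in frames.
#' @return The same type as `motion`, restricted to the window.
#' @export
extract_prerelease_window <- function(motion, release_frame, J) {
  take <- function(series, rf) {
    n <- length(series)
    if (rf < J) {
      abort(sprintf("release_frame %d is smaller than window length %d", rf, J))
    }
    if (rf > n) abort(sprintf("release_frame %d beyond series length %d", rf, n))
    series[(rf - J + 1L):rf]   # 1-based positions of 0-based frames rf-J .. rf-1
  }
  if (inherits(motion, "motion_data")) {
    K <- n_trials(motion)
    rf <- rep_len(as.integer(release_frame), K)
    out <- array(0, c(dim(motion)[1L], J, K))
    for (k in seq_len(K)) {
      if (rf[k] < J) {
        abort(sprintf("release_frame %d is smaller than window length %d",
                      rf[k], J))
      }
      if (rf[k] > dim(motion)[2L]) {
        abort(sprintf("release_frame %d beyond series length %d",
                      rf[k], dim(motion)[2L]))
      }
      out[, , k] <- motion$angles[, (rf[k] - J + 1L):rf[k], k]
    }
    return(motion_data(out, joints = motion$joints,
                       sample_rate = motion$sample_rate, units = motion$units,
                       subject_id = motion$subject_id,
                       experiment_id = motion$experiment_id))
  }
  if (is.matrix(motion)) {
    rf <- rep_len(as.integer(release_frame), ncol(motion))
    cols <- lapply(seq_len(ncol(motion)), function(k) take(motion[, k], rf[k]))
    return(do.call(cbind, cols))
  }
  take(motion, as.integer(release_frame))
}
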