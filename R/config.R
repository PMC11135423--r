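#' Acquisition configuration
#'
#' Describes the imaging acquisition that sampled (or will sample) the
#' trajectories: a fixed frame interval, a total duration, and the standard
#' deviation of the Gaussian localization error added to each coordinate.
#' Defaults match a live-imaging protocol of one frame every 0.6 s for 90 s.
#'
#' The number of frames implied by a configuration is
#' \code{floor(duration / frame_interval) + 1} (a frame at t = 0 plus one per
#' full interval).
#'
#' @param frame_interval Time between consecutive frames, seconds. Must be > 0.
#' @param duration Total acquisition time, seconds. Must be >= frame_interval.
#' @param localization_sigma Standard deviation of the localization error per
#'   coordinate, micrometres. Must be >= 0. Default 0.02 um (sub-pixel).
#' @param seed Integer seed for the run. Per-track random streams are derived
#'   deterministically from this seed and the track id, so results do not
#'   depend on track order.
#' @return An object of class \code{acq_config}.
#' @examples
#' acq <- acq_config()
#' n_frames(acq)  # 151
#' @export
acq_config <- function(frame_interval = 0.6, duration = 90,
                       localization_sigma = 0.02, seed = 1L) {
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be a single positive number (seconds)")
  if (!is.numeric(duration) || length(duration) != 1L ||
      !is.finite(duration) || duration < frame_interval)
    stop("'duration' must be a single number >= frame_interval (seconds)")
  if (!is.numeric(localization_sigma) || length(localization_sigma) != 1L ||
      !is.finite(localization_sigma) || localization_sigma < 0)
    stop("'localization_sigma' must be a single number >= 0 (micrometres)")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  structure(list(frame_interval = frame_interval,
                 duration = duration,
                 localization_sigma = localization_sigma,
                 seed = as.integer(seed)),
            class = "acq_config")
}

#' @rdname acq_config
#' @param acq An \code{acq_config} object.
#' @export
n_frames <- function(acq) {
  stopifnot(inherits(acq, "acq_config"))
  as.integer(floor(acq$duration / acq$frame_interval + 1e-9)) + 1L
}

#' @export
print.acq_config <- function(x, ...) {
  cat("Acquisition: dt =", x$frame_interval, "s, duration =", x$duration,
      "s (", n_frames(x), "frames ), localization sigma =",
      x$localization_sigma, "um, seed =", x$seed, "\n")
  invisible(x)
}

#' Motion-classification thresholds
#'
#' All tunable constants of the two classifiers and the track filter, with
#' defaults equal to the published analysis: tracks are actively driven if
#' the fitted exponent alpha > 1.5, diffusive if 0.9 < alpha < 1.1, confined
#' if alpha < 0.5 (all strict); directed if net displacement ND > 5 um,
#' stationary if ND < 5 um and lateral maximal displacement LMD < 1 um,
#' otherwise oscillatory; only tracks with more than 20 frames are analysed;
#' MSD lags run up to 25% of the trajectory duration.
#'
#' @param alpha_active Lower bound (exclusive) of the actively driven class.
#' @param alpha_diff_lo,alpha_diff_hi Open interval of the diffusive class.
#' @param alpha_confined Upper bound (exclusive) of the confined class.
#' @param nd_directed_um ND threshold (exclusive) for the directed class, um.
#' @param lmd_stationary_um LMD threshold (exclusive) for stationary, um.
#' @param min_frames_exclusive Tracks must have strictly more frames than this.
#' @param max_lag_fraction Largest MSD lag as a fraction of trajectory duration.
#' @return An object of class \code{motion_thresholds}.
#' @export
motion_thresholds <- function(alpha_active = 1.5,
                              alpha_diff_lo = 0.9,
                              alpha_diff_hi = 1.1,
                              alpha_confined = 0.5,
                              nd_directed_um = 5,
                              lmd_stationary_um = 1,
                              min_frames_exclusive = 20L,
                              max_lag_fraction = 0.25) {
  if (!(alpha_confined < alpha_diff_lo && alpha_diff_lo < alpha_diff_hi &&
        alpha_diff_hi < alpha_active))
    stop("alpha thresholds must satisfy confined < diff_lo < diff_hi < active")
  if (nd_directed_um <= 0 || lmd_stationary_um <= 0)
    stop("displacement thresholds must be positive")
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("'max_lag_fraction' must be in (0, 1]")
  if (min_frames_exclusive < 1)
    stop("'min_frames_exclusive' must be >= 1")
  structure(list(alpha_active = alpha_active,
                 alpha_diff_lo = alpha_diff_lo,
                 alpha_diff_hi = alpha_diff_hi,
                 alpha_confined = alpha_confined,
                 nd_directed_um = nd_directed_um,
                 lmd_stationary_um = lmd_stationary_um,
                 min_frames_exclusive = as.integer(min_frames_exclusive),
                 max_lag_fraction = max_lag_fraction),
            class = "motion_thresholds")
}

#' @export
print.motion_thresholds <- function(x, ...) {
  cat("Motion thresholds:\n")
  cat("  alpha: active >", x$alpha_active,
      "| diffusive (", x$alpha_diff_lo, ",", x$alpha_diff_hi,
      ") | confined <", x$alpha_confined, "\n")
  cat("  displacement: directed ND >", x$nd_directed_um,
      "um | stationary LMD <", x$lmd_stationary_um, "um\n")
  cat("  filter: > ", x$min_frames_exclusive, " frames; MSD lags <= ",
      x$max_lag_fraction * 100, "% of duration\n", sep = "")
  invisible(x)
}

#' Read an acquisition / threshold configuration from a key-value file
#'
#' Parses a flat YAML-style `key: value` (or `key = value`) text file whose
#' keys are any of the arguments of [acq_config()] and [motion_thresholds()].
#' Unknown keys raise an error. Missing keys keep their defaults.
#'
#' @param path Path to the configuration file.
#' @return A list with elements \code{acq} and \code{thresholds}.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad))
    stop("malformed configuration line(s): ", paste(sQuote(bad), collapse = ", "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- as.numeric(vapply(kv, `[`, "", 3L))
  if (anyNA(vals))
    stop("non-numeric configuration value for key(s): ",
         paste(keys[is.na(vals)], collapse = ", "))
  acq_keys <- c("frame_interval", "duration", "localization_sigma", "seed")
  thr_keys <- names(formals(motion_thresholds))
  unknown <- setdiff(keys, c(acq_keys, thr_keys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  acq_args <- as.list(vals[keys %in% acq_keys])
  names(acq_args) <- keys[keys %in% acq_keys]
  thr_args <- as.list(vals[keys %in% thr_keys])
  names(thr_args) <- keys[keys %in% thr_keys]
  list(acq = do.call(acq_config, acq_args),
       thresholds = do.call(motion_thresholds, thr_args))
}
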