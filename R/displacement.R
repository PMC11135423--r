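#' Net and lateral maximal displacement along the neurite axis
#'
#' Both features use only the axial (x) coordinate. The net displacement (ND)
#' is the magnitude of the difference between the first and last x positions;
#' the lateral maximal displacement (LMD) is the largest excursion
#' \eqn{|x(t) - x(0)|} over all frames. By construction ND <= LMD. Magnitudes
#' are used because a 6-um retrograde run is as directed as an anterograde
#' one.
#'
#' @param traj A [trajectory()] with >= 2 frames.
#' @return Displacement in micrometres.
#' @examples
#' tr <- trajectory("t", t = c(0, 0.6, 1.2), x = c(0, 3, 0), y = c(0, 0, 0))
#' compute_nd(tr)   # 0
#' compute_lmd(tr)  # 3
#' @export
compute_nd <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$x) < 2L) stop("trajectory must have >= 2 frames")
  abs(traj$x[length(traj$x)] - traj$x[1])
}

#' @rdname compute_nd
#' @export
compute_lmd <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$x) < 2L) stop("trajectory must have >= 2 frames")
  max(abs(traj$x - traj$x[1]))
}

#' Classify track directionality from ND and LMD
#'
#' Published rules, strict inequalities: directed if ND > 5 um; stationary if
#' ND < 5 um and LMD < 1 um; oscillatory if ND < 5 um and LMD > 1 um.
#' Boundary values (ND exactly at the directed threshold, LMD exactly at the
#' stationary threshold) fall through to \code{"oscillatory"} by the
#' evaluation order, since the published inequalities leave them undefined.
#'
#' @param nd Net displacement, micrometres (>= 0).
#' @param lmd Lateral maximal displacement, micrometres (>= 0).
#' @param thr A [motion_thresholds()].
#' @return One of \code{"directed"}, \code{"stationary"},
#'   \code{"oscillatory"}.
#' @export
classify_directionality <- function(nd, lmd, thr = motion_thresholds()) {
  stopifnot(inherits(thr, "motion_thresholds"))
  if (!is.finite(nd) || !is.finite(lmd) || nd < 0 || lmd < 0)
    stop("nd and lmd must be finite and >= 0")
  if (nd > thr$nd_directed_um) return("directed")
  if (lmd < thr$lmd_stationary_um) return("stationary")
  "oscillatory"
}

#' Displacement features and directionality for one trajectory
#'
#' @inheritParams compute_nd
#' @param thr A [motion_thresholds()].
#' @return A list with \code{nd}, \code{lmd} (micrometres) and
#'   \code{directionality}.
#' @export
displacement_features <- function(traj, thr = motion_thresholds()) {
  nd <- compute_nd(traj)
  lmd <- compute_lmd(traj)
  list(nd = nd, lmd = lmd,
       directionality = classify_directionality(nd, lmd, thr))
}
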