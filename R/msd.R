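#' Time-averaged mean squared displacement
#'
#' Computes the time-averaged MSD of a single trajectory:
#' \deqn{MSD(\tau) = \langle [x(t+\tau) - x(t)]^2 + [y(t+\tau) - y(t)]^2 \rangle}
#' where the brackets average over all overlapping origin times t along the
#' track. Lags are \eqn{\tau = k \Delta t} for
#' \code{k = 1 ... floor(max_lag_fraction * (N - 1))}; the 25% default keeps
#' the averages well-populated on ~150-frame tracks. At least the first lag is
#' always returned, even when the fraction rounds to zero on short tracks.
#'
#' @param traj A [trajectory()] (>= 2 frames, uniformly sampled).
#' @param max_lag_fraction Largest lag as a fraction of trajectory duration,
#'   in (0, 1]. Default 0.25.
#' @return An object of class \code{msd_curve}: a data frame with columns
#'   \code{lag_s} (seconds), \code{msd_um2} (micrometres^2), and
#'   \code{n_pairs} (origins averaged at that lag).
#' @examples
#' tr <- trajectory("t1", t = c(0, 0.6, 1.2), x = c(0, 1, 2), y = c(0, 0, 0))
#' compute_msd(tr, max_lag_fraction = 1)
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25) {
  stopifnot(inherits(traj, "trajectory"))
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("'max_lag_fraction' must be in (0, 1]")
  n <- length(traj$t)
  if (n < 2L) stop("trajectory must have >= 2 frames")
  dt <- traj$t[2] - traj$t[1]
  k_max <- max(1L, as.integer(floor(max_lag_fraction * (n - 1L) + 1e-9)))
  msd <- numeric(k_max)
  npairs <- integer(k_max)
  x <- traj$x; y <- traj$y
  for (k in seq_len(k_max)) {
    i <- seq_len(n - k)
    ddx <- x[i + k] - x[i]
    ddy <- y[i + k] - y[i]
    msd[k] <- mean(ddx * ddx + ddy * ddy)
    npairs[k] <- n - k
  }
  structure(data.frame(lag_s = seq_len(k_max) * dt,
                       msd_um2 = msd, n_pairs = npairs),
            class = c("msd_curve", "data.frame"),
            track_id = traj$track_id)
}

#' Fit the anomalous diffusion model to an MSD curve
#'
#' Fits \eqn{MSD(\tau) = A \tau^\alpha + B} by bounded nonlinear least squares
#' in linear space, unweighted, with bounds \eqn{A \ge 0},
#' \eqn{0 \le \alpha \le 3}, \eqn{B \ge 0} and starting values \eqn{\alpha =
#' 1}, \eqn{A = MSD(\tau_1)/\tau_1}, \eqn{B = 0}. \eqn{A} reflects the
#' mobility of the particle, \eqn{B} is the residual MSD (offset from, e.g.,
#' localization error), and \eqn{\alpha} indicates the motion type:
#' \eqn{\alpha \approx 2} ballistic transport, \eqn{\alpha \approx 1} free
#' diffusion, \eqn{\alpha \ll 1} confinement.
#'
#' Curves with fewer than three lags, non-finite values, an essentially flat
#' profile (non-identifiable \eqn{\alpha} because \eqn{A \approx 0}), or an
#' optimizer failure return \code{converged = FALSE}; such tracks are later
#' classified as ambiguous rather than dropped.
#'
#' @param curve An \code{msd_curve} from [compute_msd()].
#' @return An object of class \code{anomalous_fit} with elements \code{A},
#'   \code{alpha}, \code{B}, \code{residual_norm}, \code{converged},
#'   \code{n_lags_used}, and the data used for the fit.
#' @examples
#' tau <- seq(0.6, 9, by = 0.6)
#' curve <- structure(data.frame(lag_s = tau, msd_um2 = tau^2,
#'                               n_pairs = rep(10L, length(tau))),
#'                    class = c("msd_curve", "data.frame"))
#' coef(fit_anomalous(curve))  # A = 1, alpha = 2, B = 0
#' @export
fit_anomalous <- function(curve) {
  stopifnot(inherits(curve, "msd_curve"))
  lag <- curve$lag_s
  msd <- curve$msd_um2
  if (!all(is.finite(msd)) || !all(is.finite(lag)))
    stop("MSD curve contains non-finite values")
  out <- list(A = NA_real_, alpha = NA_real_, B = NA_real_,
              residual_norm = NA_real_, converged = FALSE,
              n_lags_used = length(lag), data = curve)
  class(out) <- "anomalous_fit"
  if (length(lag) < 3L) return(out)
  # flat curve: A and alpha jointly non-identifiable; report non-converged
  if (diff(range(msd)) <= 1e-12 * max(abs(msd), 1e-300)) {
    out$A <- 0; out$B <- mean(msd); out$alpha <- NA_real_
    out$residual_norm <- sqrt(sum((msd - mean(msd))^2))
    return(out)
  }
  # Two starts: the canonical (alpha = 1, A = msd(tau_1)/tau_1, B = 0), and a
  # log-log regression start that rescues strongly super/sub-diffusive curves
  # from the local minimum at the alpha bound. Best residual wins.
  starts <- list(list(A = max(msd[1] / lag[1], 1e-12), alpha = 1, B = 0))
  pos <- msd > 0
  if (sum(pos) >= 3L) {
    ll <- stats::lm(log(msd[pos]) ~ log(lag[pos]))
    a0 <- min(max(unname(stats::coef(ll)[2]), 0), 3)
    starts <- c(starts, list(list(A = exp(unname(stats::coef(ll)[1])),
                                  alpha = a0, B = 0)))
  }
  resid_fn <- function(p) msd - (p[1] * lag^p[2] + p[3])
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = unlist(st), fn = resid_fn,
                         lower = c(0, 0, 0), upper = c(Inf, 3, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(par = fit$par, rn = rn)
  }
  if (is.null(best)) return(out)
  p <- stats::setNames(best$par, c("A", "alpha", "B"))
  out$A <- unname(p["A"]); out$alpha <- unname(p["alpha"])
  out$B <- unname(p["B"])
  out$residual_norm <- best$rn
  out$converged <- is.finite(out$residual_norm) &&
    all(is.finite(p)) && out$alpha >= 0 && out$alpha <= 3
  out
}

#' @export
print.anomalous_fit <- function(x, ...) {
  cat("Anomalous diffusion fit: MSD(tau) = A * tau^alpha + B\n")
  if (x$converged) {
    cat(sprintf("  A = %.4g um^2 s^-alpha, alpha = %.4f, B = %.4g um^2\n",
                x$A, x$alpha, x$B))
    cat(sprintf("  residual norm %.4g um^2 over %d lags\n",
                x$residual_norm, x$n_lags_used))
  } else {
    cat("  did not converge (", x$n_lags_used, "lags ); track is ambiguous\n")
  }
  invisible(x)
}

#' @export
coef.anomalous_fit <- function(object, ...) {
  c(A = object$A, alpha = object$alpha, B = object$B)
}

#' @export
predict.anomalous_fit <- function(object, lag_s = object$data$lag_s, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  object$A * lag_s^object$alpha + object$B
}

#' @export
residuals.anomalous_fit <- function(object, ...) {
  if (!object$converged) return(rep(NA_real_, object$n_lags_used))
  object$data$msd_um2 - predict(object)
}

#' @export
summary.anomalous_fit <- function(object, ...) {
  lab <- classify_alpha(object, motion_thresholds())
  structure(list(fit = object, motion_class = lab), class = "summary.anomalous_fit")
}

#' @export
print.summary.anomalous_fit <- function(x, ...) {
  print(x$fit)
  cat("  motion class (default thresholds):", x$motion_class, "\n")
  invisible(x)
}

#' @export
plot.anomalous_fit <- function(x, ...) {
  graphics::plot(x$data$lag_s, x$data$msd_um2, xlab = "lag (s)",
                 ylab = expression(MSD ~ (mu * m^2)),
                 main = "Time-averaged MSD", ...)
  if (x$converged) {
    tau <- seq(min(x$data$lag_s), max(x$data$lag_s), length.out = 200)
    graphics::lines(tau, predict(x, tau), col = "firebrick")
    graphics::legend("topleft", bty = "n", legend = sprintf(
      "A = %.3g, alpha = %.2f, B = %.3g", x$A, x$alpha, x$B))
  }
  invisible(x)
}

#' Classify motion type from the fitted exponent
#'
#' Applies the published strict-inequality rules: actively driven if
#' \eqn{\alpha > 1.5}, diffusive if \eqn{0.9 < \alpha < 1.1}, confined if
#' \eqn{\alpha < 0.5}. Exponents falling in the gaps [0.5, 0.9] or
#' [1.1, 1.5], sitting exactly on a boundary, or coming from a non-converged
#' fit are labelled \code{"ambiguous"}.
#'
#' @param fit An [fit_anomalous()] result (or a bare numeric alpha).
#' @param thr A [motion_thresholds()].
#' @return One of \code{"active"}, \code{"diffusive"}, \code{"confined"},
#'   \code{"ambiguous"}.
#' @export
classify_alpha <- function(fit, thr = motion_thresholds()) {
  stopifnot(inherits(thr, "motion_thresholds"))
  if (inherits(fit, "anomalous_fit")) {
    if (!isTRUE(fit$converged)) return("ambiguous")
    a <- fit$alpha
  } else {
    a <- as.numeric(fit)
  }
  if (!is.finite(a)) return("ambiguous")
  if (a > thr$alpha_active) return("active")
  if (a > thr$alpha_diff_lo && a < thr$alpha_diff_hi) return("diffusive")
  if (a < thr$alpha_confined) return("confined")
  "ambiguous"
}
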