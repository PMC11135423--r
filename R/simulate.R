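#' Motion specification for the trajectory simulator
#'
#' Parameterizes the ground-truth motion regime of a simulated particle.
#' Three modes are supported: \code{ballistic} (constant velocity along the
#' neurite axis x), \code{brownian} (free 2-D diffusion with coefficient D),
#' and \code{confined} (diffusion inside a reflecting circular corral).
#' Fields irrelevant to the chosen mode are ignored.
#'
#' @param mode One of \code{"ballistic"}, \code{"brownian"}, \code{"confined"}.
#' @param velocity Speed along x, micrometres/second (ballistic). >= 0.
#' @param D Diffusion coefficient, micrometres^2/second (brownian, confined).
#'   >= 0.
#' @param corral_radius Radius of the reflecting corral, micrometres
#'   (confined). Must be > 0 for confined mode.
#' @param start_position Numeric length-2 vector (x0, y0), micrometres.
#' @return An object of class \code{motion_spec}.
#' @export
motion_spec <- function(mode = c("ballistic", "brownian", "confined"),
                        velocity = 0, D = 0, corral_radius = 0,
                        start_position = c(0, 0)) {
  mode <- match.arg(mode)
  if (velocity < 0 || D < 0 || corral_radius < 0)
    stop("velocity, D and corral_radius must be >= 0")
  if (mode == "confined" && corral_radius <= 0)
    stop("confined mode requires corral_radius > 0")
  if (length(start_position) != 2L || !all(is.finite(start_position)))
    stop("'start_position' must be a finite (x, y) pair")
  structure(list(mode = mode, velocity = velocity, D = D,
                 corral_radius = corral_radius,
                 start_position = as.numeric(start_position)),
            class = "motion_spec")
}

#' @export
print.motion_spec <- function(x, ...) {
  cat("Motion spec:", x$mode)
  if (x$mode == "ballistic") cat(", v =", x$velocity, "um/s")
  if (x$mode %in% c("brownian", "confined")) cat(", D =", x$D, "um^2/s")
  if (x$mode == "confined") cat(", corral radius =", x$corral_radius, "um")
  cat(", start = (", x$start_position[1], ",", x$start_position[2], ") um\n")
  invisible(x)
}

# Deterministic per-track seed from (run seed, track id): polynomial string
# hash mod 2^31 - 1, so results are independent of track order.
track_seed <- function(seed, track_id) {
  h <- 0
  for (cp in utf8ToInt(as.character(track_id)))
    h <- (h * 31 + cp) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647)) %% 2147483647)
}

# Run expr with a local RNG state seeded from (seed, track_id); the caller's
# RNG stream is untouched.
with_track_rng <- function(seed, track_id, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(track_seed(seed, track_id))
  expr
}

# Shared across modes: draw the per-frame diffusive increments first (dx then
# dy), then the localization noise, in a fixed order, so a confined track with
# an effectively infinite corral reproduces the Brownian track bit for bit.
sim_draws <- function(n, acq, D) {
  sd_step <- sqrt(2 * D * acq$frame_interval)
  list(dx = rnorm(n - 1L, sd = sd_step),
       dy = rnorm(n - 1L, sd = sd_step),
       ex = if (acq$localization_sigma > 0)
         rnorm(n, sd = acq$localization_sigma) else numeric(n),
       ey = if (acq$localization_sigma > 0)
         rnorm(n, sd = acq$localization_sigma) else numeric(n))
}

#' Simulate a single trajectory
#'
#' Generates one particle track under the motion model in \code{spec}, sampled
#' on the uniform time grid of \code{acq}, with i.i.d. Gaussian localization
#' noise (sd \code{acq$localization_sigma}) added to each coordinate after the
#' physical path. The random stream is derived from \code{(acq$seed,
#' track_id)}, so the same arguments always give a bit-identical track.
#'
#' Mode details: \emph{ballistic} moves at constant velocity along +x;
#' \emph{brownian} takes independent Gaussian increments of variance
#' \eqn{2 D \Delta t} per coordinate per frame; \emph{confined} takes the same
#' increments but reflects the position back inside a disc of radius
#' \code{corral_radius} centred on the start position (radial folding of the
#' overshoot).
#'
#' @param spec A [motion_spec()].
#' @param acq An [acq_config()].
#' @param track_id Identifier for the track (also seeds its random stream).
#' @return A [trajectory()] with \code{true_mode} set to the simulated mode.
#' @examples
#' acq <- acq_config(localization_sigma = 0, seed = 7)
#' tr <- simulate_track(motion_spec("ballistic", velocity = 0.5), acq, "b1")
#' tail(tr$x, 1) - tr$x[1]  # 45 um = v * T
#' @export
simulate_track <- function(spec, acq, track_id = "track_1") {
  stopifnot(inherits(spec, "motion_spec"), inherits(acq, "acq_config"))
  n <- n_frames(acq)
  t <- (seq_len(n) - 1L) * acq$frame_interval
  with_track_rng(acq$seed, track_id, {
    if (spec$mode == "ballistic") {
      draws <- sim_draws(n, acq, D = 0)
      x <- spec$start_position[1] + spec$velocity * t
      y <- rep(spec$start_position[2], n)
    } else {
      draws <- sim_draws(n, acq, D = spec$D)
      # both diffusive modes accumulate through the same walker so that an
      # unbounded corral reproduces free Brownian motion bit for bit
      R <- if (spec$mode == "confined") spec$corral_radius else Inf
      pos <- reflect_in_disc(draws$dx, draws$dy, spec$start_position, R)
      x <- pos$x
      y <- pos$y
    }
    trajectory(track_id, t, x + draws$ex, y + draws$ey,
               true_mode = spec$mode)
  })
}

# Reflecting disc: walk the increments; whenever the position leaves the disc,
# fold the radius back (r -> 2R - r, repeated until inside). Preserves the
# angular coordinate; adequate for steps not much larger than the corral.
reflect_in_disc <- function(dx, dy, centre, R) {
  n <- length(dx) + 1L
  x <- numeric(n); y <- numeric(n)
  x[1] <- centre[1]; y[1] <- centre[2]
  for (i in seq_along(dx)) {
    px <- x[i] + dx[i] - centre[1]
    py <- y[i] + dy[i] - centre[2]
    r <- sqrt(px^2 + py^2)
    while (r > R) {
      r2 <- abs(2 * R - r)
      if (r > 0) { px <- px * r2 / r; py <- py * r2 / r }
      r <- r2
    }
    x[i + 1L] <- centre[1] + px
    y[i + 1L] <- centre[2] + py
  }
  list(x = x, y = y)
}

#' Simulate a set of trajectories
#'
#' Convenience wrapper generating \code{n_tracks} independent tracks from one
#' motion specification. Track ids are \code{<prefix>_1 ... <prefix>_n}; each
#' id seeds its own random stream, so subsets are reproducible.
#'
#' @inheritParams simulate_track
#' @param n_tracks Number of tracks to generate.
#' @param id_prefix Prefix for track ids (default the motion mode).
#' @return A named list of [trajectory()] objects.
#' @export
simulate_tracks <- function(spec, acq, n_tracks, id_prefix = spec$mode) {
  stopifnot(n_tracks >= 1)
  ids <- paste0(id_prefix, "_", seq_len(n_tracks))
  out <- lapply(ids, function(id) simulate_track(spec, acq, id))
  names(out) <- ids
  out
}
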