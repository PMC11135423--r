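#' Single-particle trajectory
#'
#' A uniformly sampled time series of particle positions. \code{x} is the
#' coordinate along the neurite axis, \code{y} perpendicular to it, both in
#' micrometres; \code{t} in seconds with the first frame at t = 0.
#'
#' @param track_id Identifier (coerced to character).
#' @param t Numeric vector of times, seconds; strictly increasing, uniformly
#'   spaced to within 1e-9 s.
#' @param x,y Numeric position vectors, micrometres; same length as \code{t}.
#' @param true_mode Optional ground-truth motion mode label (simulated tracks).
#' @return An object of class \code{trajectory}.
#' @export
trajectory <- function(track_id, t, x, y, true_mode = NA_character_) {
  if (length(t) < 2L || length(x) != length(t) || length(y) != length(t))
    stop("trajectory needs >= 2 frames with matching t, x, y lengths")
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("trajectory values must be finite")
  dt <- diff(t)
  if (any(dt <= 0))
    stop("times must be strictly increasing")
  if (diff(range(dt)) > 1e-9)
    stop("times must be uniformly spaced (tolerance 1e-9 s)")
  structure(list(track_id = as.character(track_id)[1L],
                 t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 true_mode = as.character(true_mode)[1L]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory", sQuote(x$track_id), "-", length(x$t), "frames, dt =",
      signif(x$t[2] - x$t[1], 6), "s")
  if (!is.na(x$true_mode)) cat(", true mode:", x$true_mode)
  cat("\n  x range [um]:", signif(range(x$x), 4),
      " y range [um]:", signif(range(x$y), 4), "\n")
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$t)

#' @export
as.data.frame.trajectory <- function(x, ...) {
  d <- data.frame(track_id = x$track_id,
                  frame = seq_along(x$t) - 1L,
                  t_s = x$t, x_um = x$x, y_um = x$y,
                  stringsAsFactors = FALSE)
  if (!is.na(x$true_mode)) d$true_mode <- x$true_mode
  d
}

#' Convert between trajectory lists and track tables
#'
#' A track table is a data frame with columns
#' \code{track_id, frame, t_s, x_um, y_um} and optionally \code{true_mode}
#' (plus any extra per-track metadata columns, which are carried along by the
#' pipeline but ignored here). \code{tracks_to_table()} stacks a list of
#' [trajectory()] objects into one table; \code{table_to_tracks()} splits a
#' table back into trajectories, preserving first-appearance order of ids.
#'
#' @param tracks List of \code{trajectory} objects.
#' @param table A track table data frame.
#' @return A data frame, or a named list of \code{trajectory} objects.
#' @export
tracks_to_table <- function(tracks) {
  stopifnot(is.list(tracks))
  if (!length(tracks))
    return(data.frame(track_id = character(), frame = integer(),
                      t_s = numeric(), x_um = numeric(), y_um = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(tracks, function(tr) {
    d <- as.data.frame(tr)
    if (is.null(d$true_mode)) d$true_mode <- NA_character_
    d
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$true_mode))) out$true_mode <- NULL
  rownames(out) <- NULL
  out
}

#' @rdname tracks_to_table
#' @export
table_to_tracks <- function(table) {
  req <- c("track_id", "t_s", "x_um", "y_um")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("track table is missing column(s): ", paste(miss, collapse = ", "))
  ids <- unique(as.character(table$track_id))
  out <- lapply(ids, function(id) {
    d <- table[as.character(table$track_id) == id, , drop = FALSE]
    d <- d[order(d$t_s), , drop = FALSE]
    mode <- if ("true_mode" %in% names(d)) d$true_mode[1L] else NA_character_
    trajectory(id, d$t_s, d$x_um, d$y_um, true_mode = mode)
  })
  names(out) <- ids
  out
}
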