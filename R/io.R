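#' Write and read track tables
#'
#' Track tables are plain CSV with header
#' \code{track_id,frame,t_s,x_um,y_um[,true_mode]} and 0-based frame indices.
#' Positions round-trip at full double precision.
#'
#' On read, each track must be uniformly sampled; where a track has a time gap
#' (a missing frame), it is split at every gap into uniformly sampled segments
#' whose ids get suffixes \code{_s1, _s2, ...}, with a warning reporting how
#' many tracks were split. Malformed rows (non-numeric or missing fields)
#' raise an error naming the offending line. Segments left with fewer than two
#' frames are dropped.
#'
#' @param tracks List of [trajectory()] objects (or a track table data frame).
#' @param path File path.
#' @return \code{read_tracks()} returns a named list of [trajectory()]
#'   objects; \code{write_tracks()} returns \code{path} invisibly.
#' @export
write_tracks <- function(tracks, path) {
  tab <- if (is.data.frame(tracks)) tracks else tracks_to_table(tracks)
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("track_id", "t_s", "x_um", "y_um")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("track file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(raw)) return(structure(list(), names = character()))
  num <- c("t_s", "x_um", "y_um")
  for (col in num) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("malformed row in ", path, ": line ", bad[1] + 1L,
           " has non-numeric ", col, " (", sQuote(raw[[col]][bad[1]]), ")")
    raw[[col]] <- v
  }
  ids <- unique(raw$track_id)
  n_split <- 0L
  out <- list()
  for (id in ids) {
    d <- raw[raw$track_id == id, , drop = FALSE]
    d <- d[order(d$t_s), , drop = FALSE]
    mode <- if ("true_mode" %in% names(d) && nzchar(d$true_mode[1]))
      d$true_mode[1] else NA_character_
    segs <- split_uniform_segments(d$t_s)
    if (length(segs) > 1L) n_split <- n_split + 1L
    for (k in seq_along(segs)) {
      idx <- segs[[k]]
      if (length(idx) < 2L) next
      seg_id <- if (length(segs) == 1L) id else paste0(id, "_s", k)
      out[[seg_id]] <- trajectory(seg_id, d$t_s[idx], d$x_um[idx],
                                  d$y_um[idx], true_mode = mode)
    }
  }
  if (n_split > 0L)
    warning(n_split, " track(s) had non-uniform time spacing and were split ",
            "at each gap into uniformly sampled segments")
  out
}

# Partition indices 1..n into maximal runs of uniform spacing, where the
# reference interval is the smallest observed positive interval.
split_uniform_segments <- function(t) {
  n <- length(t)
  if (n < 2L) return(list(seq_len(n)))
  dt <- diff(t)
  ref <- min(dt)
  breaks <- which(abs(dt - ref) > 1e-9)
  if (!length(breaks)) return(list(seq_len(n)))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
}
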