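#' Filter tracks by minimum frame count
#'
#' Retains exactly the tracks with strictly more than
#' \code{thr$min_frames_exclusive} frames (default: more than 20, the
#' published inclusion rule) and reports the excluded ids.
#'
#' @param tracks Named list of [trajectory()] objects.
#' @param thr A [motion_thresholds()].
#' @return A list with \code{retained} (list of trajectories) and
#'   \code{excluded_ids} (character).
#' @export
filter_tracks <- function(tracks, thr = motion_thresholds()) {
  stopifnot(is.list(tracks), inherits(thr, "motion_thresholds"))
  nfr <- vapply(tracks, length, 1L)
  keep <- nfr > thr$min_frames_exclusive
  excluded <- vapply(tracks[!keep], function(tr) tr$track_id, "")
  list(retained = tracks[keep], excluded_ids = unname(excluded))
}

#' Project a trajectory onto its principal axis
#'
#' Optional preprocessing for raw tracks whose coordinate frame is not
#' aligned with the neurite: rotates (x, y) so that x lies along the track's
#' principal axis of variation (first principal component of the positions)
#' and y perpendicular to it. Simulated tracks are already emitted in the
#' axial frame and do not need this.
#'
#' @param traj A [trajectory()].
#' @return A [trajectory()] in the rotated frame (same times and id).
#' @export
project_axial <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  xy <- cbind(traj$x - mean(traj$x), traj$y - mean(traj$y))
  v <- eigen(crossprod(xy), symmetric = TRUE)$vectors[, 1L]
  rot <- xy %*% cbind(v, c(-v[2], v[1]))
  trajectory(traj$track_id, traj$t, rot[, 1L], rot[, 2L],
             true_mode = traj$true_mode)
}

#' Per-track motion analysis
#'
#' Runs the full single-track analysis on every trajectory: time-averaged MSD
#' over the first \code{max_lag_fraction} of lags, anomalous-diffusion fit,
#' exponent-based motion class, and displacement-based directionality class.
#' No filtering is applied here; see [filter_tracks()] / [run_pipeline()].
#'
#' @param tracks Named list of [trajectory()] objects.
#' @param thr A [motion_thresholds()].
#' @return A data frame with one row per track: \code{track_id},
#'   \code{n_frames}, \code{A}, \code{alpha}, \code{B}, \code{converged},
#'   \code{motion_class}, \code{nd_um}, \code{lmd_um}, \code{directionality},
#'   and \code{true_mode} where available.
#' @export
classify_tracks <- function(tracks, thr = motion_thresholds()) {
  stopifnot(is.list(tracks))
  rows <- lapply(tracks, function(tr) {
    fit <- fit_anomalous(compute_msd(tr, thr$max_lag_fraction))
    dsp <- displacement_features(tr, thr)
    data.frame(track_id = tr$track_id,
               n_frames = length(tr),
               A = fit$A, alpha = fit$alpha, B = fit$B,
               converged = fit$converged,
               motion_class = classify_alpha(fit, thr),
               nd_um = dsp$nd, lmd_um = dsp$lmd,
               directionality = dsp$directionality,
               true_mode = tr$true_mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

MOTION_CLASSES <- c("active", "diffusive", "confined", "ambiguous")
DIRECTION_CLASSES <- c("directed", "stationary", "oscillatory")

# fractions of `labels` falling in each of `classes`; sums to 1 when n > 0
class_fractions <- function(labels, classes) {
  n <- length(labels)
  vapply(classes, function(cl) sum(labels == cl) / n, 1.0)
}

#' Aggregate class fractions per replicate and group
#'
#' The statistical unit is the replicate (an independent culture): fractions
#' of each motion class and each directionality class are computed within
#' every (group, replicate) cell, then summarised per group as mean and SD
#' across replicates. Tracks are never pooled across replicates.
#'
#' @param records A per-track data frame from [classify_tracks()] with added
#'   \code{group} and \code{replicate_id} columns.
#' @return A list with \code{replicate_fractions} (long data frame:
#'   \code{group, replicate_id, family, class, fraction, n_tracks}) and
#'   \code{group_stats} (mean and SD of each fraction across replicates).
#' @export
summarize_groups <- function(records) {
  need <- c("group", "replicate_id", "motion_class", "directionality")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  cells <- unique(records[, c("group", "replicate_id")])
  frac_rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- records$group == cells$group[i] &
      records$replicate_id == cells$replicate_id[i]
    sub <- records[sel, , drop = FALSE]
    if (!nrow(sub)) next
    for (fam in c("motion", "directionality")) {
      classes <- if (fam == "motion") MOTION_CLASSES else DIRECTION_CLASSES
      labels <- if (fam == "motion") sub$motion_class else sub$directionality
      fr <- class_fractions(labels, classes)
      frac_rows[[length(frac_rows) + 1L]] <- data.frame(
        group = cells$group[i], replicate_id = cells$replicate_id[i],
        family = fam, class = classes, fraction = unname(fr),
        n_tracks = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  rep_frac <- do.call(rbind, frac_rows)
  rownames(rep_frac) <- NULL
  agg_mean <- stats::aggregate(fraction ~ group + family + class,
                               data = rep_frac, FUN = mean)
  agg_sd <- stats::aggregate(fraction ~ group + family + class,
                             data = rep_frac,
                             FUN = function(v) if (length(v) > 1) stats::sd(v) else 0)
  names(agg_mean)[names(agg_mean) == "fraction"] <- "mean_fraction"
  agg_mean$sd_fraction <- agg_sd$fraction[match(
    paste(agg_mean$group, agg_mean$family, agg_mean$class),
    paste(agg_sd$group, agg_sd$family, agg_sd$class))]
  list(replicate_fractions = rep_frac, group_stats = agg_mean)
}

#' Compare class fractions between two groups with Welch's t test
#'
#' For every (family, class) fraction, applies Welch's unequal-variance
#' two-sided t test to the per-replicate fractions of the two groups. A class
#' whose fractions are identical in every replicate of both groups is
#' reported with t = 0 and p = 1 (the test statistic is degenerate there).
#' With fewer than two replicates in either group the comparison is skipped
#' with a warning.
#'
#' @param replicate_fractions Long data frame from
#'   [summarize_groups()]\code{$replicate_fractions} containing exactly two
#'   groups (or use \code{group_a} / \code{group_b} to pick two).
#' @param group_a,group_b Group labels to compare; default the first two
#'   levels found.
#' @param holm If TRUE, Holm-adjust the p-values within each classifier
#'   family. Default FALSE (per-class tests, as commonly reported per panel).
#' @return A data frame \code{family, class, t, df, p_value} (plus
#'   \code{p_holm} if requested), or NULL if skipped.
#' @export
compare_groups <- function(replicate_fractions, group_a = NULL, group_b = NULL,
                           holm = FALSE) {
  groups <- unique(replicate_fractions$group)
  if (is.null(group_a)) group_a <- groups[1]
  if (is.null(group_b)) group_b <- setdiff(groups, group_a)[1]
  if (is.na(group_b)) stop("need two groups to compare")
  combos <- unique(replicate_fractions[, c("family", "class")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- replicate_fractions$family == combos$family[i] &
      replicate_fractions$class == combos$class[i]
    a <- replicate_fractions$fraction[sel & replicate_fractions$group == group_a]
    b <- replicate_fractions$fraction[sel & replicate_fractions$group == group_b]
    if (length(a) < 2L || length(b) < 2L) {
      warning("fewer than 2 replicates in a group; comparison skipped for ",
              combos$family[i], "/", combos$class[i])
      next
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
                 p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      family = combos$family[i], class = combos$class[i],
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  if (holm) {
    out$p_holm <- NA_real_
    for (fam in unique(out$family)) {
      sel <- out$family == fam
      out$p_holm[sel] <- stats::p.adjust(out$p_value[sel], method = "holm")
    }
  }
  rownames(out) <- NULL
  out
}

#' End-to-end trajectory analysis pipeline
#'
#' Filters tracks (strictly more frames than the threshold), runs the MSD /
#' anomalous-fit / exponent classifier and the displacement classifier on
#' every retained track, aggregates class fractions per replicate, and — when
#' exactly two groups are present with >= 2 replicates each — compares the
#' groups with Welch's t test per class. Deterministic given its inputs.
#'
#' @param track_table A track table data frame (columns \code{track_id, frame,
#'   t_s, x_um, y_um}, optional \code{true_mode}); alternatively a named list
#'   of [trajectory()] objects. Per-track metadata columns \code{replicate_id}
#'   and \code{group} are read from the table when present, or supplied via
#'   \code{metadata}.
#' @param thr A [motion_thresholds()].
#' @param metadata Optional data frame \code{track_id, replicate_id, group}
#'   assigning each track to a culture replicate and genotype group. Tracks
#'   without metadata are placed in replicate "r1", group "all".
#' @param holm Passed to [compare_groups()].
#' @return An object of class \code{motrack_run}: a list with \code{records}
#'   (per-track table), \code{summary} (from [summarize_groups()]),
#'   \code{comparison} (Welch tests or NULL), and \code{log} (counts of
#'   exclusions and non-converged fits).
#' @export
run_pipeline <- function(track_table, thr = motion_thresholds(),
                         metadata = NULL, holm = FALSE) {
  tracks <- if (is.data.frame(track_table)) {
    extra <- intersect(c("replicate_id", "group"), names(track_table))
    if (length(extra) && is.null(metadata)) {
      metadata <- unique(track_table[, c("track_id", extra), drop = FALSE])
      metadata$track_id <- as.character(metadata$track_id)
    }
    table_to_tracks(track_table)
  } else track_table
  flt <- filter_tracks(tracks, thr)
  if (!length(flt$retained))
    stop("no tracks retained after the frame-count filter")
  records <- classify_tracks(flt$retained, thr)
  if (!is.null(metadata)) {
    if (!all(c("track_id") %in% names(metadata)))
      stop("metadata must contain a track_id column")
    idx <- match(records$track_id, as.character(metadata$track_id))
    base_ids <- sub("_s[0-9]+$", "", records$track_id)
    idx[is.na(idx)] <- match(base_ids[is.na(idx)],
                             as.character(metadata$track_id))
    if (anyNA(idx))
      stop("metadata is missing track id(s): ",
           paste(utils::head(records$track_id[is.na(idx)], 5), collapse = ", "))
    records$replicate_id <- if ("replicate_id" %in% names(metadata))
      as.character(metadata$replicate_id[idx]) else "r1"
    records$group <- if ("group" %in% names(metadata))
      as.character(metadata$group[idx]) else "all"
  } else {
    records$replicate_id <- "r1"
    records$group <- "all"
  }
  summ <- summarize_groups(records)
  groups <- unique(records$group)
  comparison <- NULL
  if (length(groups) == 2L) {
    reps_per_group <- tapply(records$replicate_id, records$group,
                             function(v) length(unique(v)))
    if (all(reps_per_group >= 2L)) {
      comparison <- compare_groups(summ$replicate_fractions,
                                   groups[1], groups[2], holm = holm)
    } else {
      warning("fewer than 2 replicates in a group; group comparison skipped")
    }
  }
  structure(list(records = records, summary = summ, comparison = comparison,
                 log = list(n_excluded = length(flt$excluded_ids),
                            excluded_ids = flt$excluded_ids,
                            n_nonconverged = sum(!records$converged))),
            class = "motrack_run")
}

#' @export
print.motrack_run <- function(x, ...) {
  cat("motrack pipeline run\n")
  cat("  tracks analysed:", nrow(x$records),
      "| excluded by frame filter:", x$log$n_excluded,
      "| non-converged fits:", x$log$n_nonconverged, "\n")
  gs <- x$summary$group_stats
  for (g in unique(gs$group)) {
    cat("  group", sQuote(g), "mean fractions:\n")
    for (fam in c("motion", "directionality")) {
      sub <- gs[gs$group == g & gs$family == fam, ]
      cat("   ", fam, ": ",
          paste(sprintf("%s %.2f", sub$class, sub$mean_fraction),
                collapse = ", "), "\n", sep = "")
    }
  }
  if (!is.null(x$comparison)) {
    cat("  Welch's t tests (two-sided):\n")
    print(x$comparison, row.names = FALSE)
  }
  invisible(x)
}
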