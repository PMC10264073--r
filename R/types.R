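#' Acquisition parameters
#'
#' Bundles the camera frame interval and (optionally) the static localization
#' precision of the instrument. All displacement-based quantities in the
#' package are expressed per frame interval.
#'
#' @param frame_interval Seconds per frame. Default 0.03 (30 ms exposure).
#' @param localization_precision Per-axis localization error, um. Default 0.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(frame_interval = 0.03,
                               localization_precision = 0) {
  stopifnot(is.numeric(frame_interval), frame_interval > 0,
            is.numeric(localization_precision), localization_precision >= 0)
  structure(list(frame_interval = frame_interval,
                 localization_precision = localization_precision),
            class = "acquisition_params")
}

#' Construct a localization table
#'
#' A localization table is the pipeline's raw input: frame-indexed 2D point
#' detections in micrometres. Rows are sorted by frame; an optional `id`
#' column carries ground-truth track identity for simulated data.
#'
#' @param frame Non-negative integer frame indices (0-based).
#' @param x,y Coordinates in um.
#' @param id Optional ground-truth track ids.
#' @param acquisition An [acquisition_params()] object.
#' @return A `data.frame` of class `loc_table` with attributes `acquisition`
#'   and `extent` (bounding box `c(xmin, xmax, ymin, ymax)`, `NA` when empty).
#' @export
loc_table <- function(frame, x, y, id = NULL,
                      acquisition = acquisition_params()) {
  stopifnot(length(frame) == length(x), length(x) == length(y))
  if (length(frame) > 0) {
    if (any(!is.finite(x)) || any(!is.finite(y)))
      stop("non-finite coordinates at rows: ",
           paste(which(!is.finite(x) | !is.finite(y)), collapse = ", "))
    if (any(frame < 0)) stop("negative frame indices")
  }
  df <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                   y = as.numeric(y))
  if (!is.null(id)) df$id <- id
  ord <- order(df$frame)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  extent <- if (nrow(df)) c(xmin = min(df$x), xmax = max(df$x),
                            ymin = min(df$y), ymax = max(df$y))
            else c(xmin = NA_real_, xmax = NA_real_,
                   ymin = NA_real_, ymax = NA_real_)
  attr(df, "acquisition") <- acquisition
  attr(df, "extent") <- extent
  class(df) <- c("loc_table", "data.frame")
  df
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, frames %s-%s, dt = %g s\n",
              nrow(x),
              if (nrow(x)) min(x$frame) else "-",
              if (nrow(x)) max(x$frame) else "-",
              attr(x, "acquisition")$frame_interval))
  if (nrow(x)) print(head(as.data.frame(x)))
  invisible(x)
}

#' Construct a track set
#'
#' Linked trajectories in long format: one row per localization with its
#' track id and (when assigned) per-point phase label. Per-step labels
#' (phase of a step, motion state of a step) are derived with
#' [track_steps()].
#'
#' @param df `data.frame` with columns `track_id`, `frame`, `x`, `y` and
#'   optionally `row` (index into the source localization table), `phase`,
#'   `state`.
#' @param acquisition An [acquisition_params()] object.
#' @param provenance Named list of linking parameters used.
#' @return A `data.frame` of class `track_set`.
#' @export
track_set <- function(df, acquisition = acquisition_params(),
                      provenance = list()) {
  stopifnot(all(c("track_id", "frame", "x", "y") %in% names(df)))
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  fr_ok <- tapply(df$frame, df$track_id, function(f) all(diff(f) > 0))
  if (length(fr_ok) && !all(unlist(fr_ok)))
    stop("frames must be strictly increasing within each track")
  attr(df, "acquisition") <- acquisition
  attr(df, "provenance") <- provenance
  class(df) <- c("track_set", "data.frame")
  df
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d localizations, dt = %g s\n",
              length(unique(x$track_id)), nrow(x),
              attr(x, "acquisition")$frame_interval))
  invisible(x)
}

#' Number of tracks in a track set
#' @param tracks A [track_set()].
#' @return Integer count.
#' @export
n_tracks <- function(tracks) length(unique(tracks$track_id))

#' Per-step view of a track set
#'
#' Converts the long per-localization representation into one row per
#' consecutive-frame step, with the step displacement and endpoint phases.
#' Steps spanning a frame gap (non-consecutive frames) are excluded.
#'
#' @param tracks A [track_set()].
#' @param map Optional [phase_map()] or region geometry; when given, endpoint
#'   phases are (re)computed and each step is labelled `condensed`, `dilute`
#'   or `crossing`.
#' @return `data.frame` with columns `track_id`, `frame`, `x0`, `y0`, `x1`,
#'   `y1`, `d` (um) and, when phases are available, `phase0`, `phase1`,
#'   `step_phase`.
#' @export
track_steps <- function(tracks, map = NULL) {
  df <- as.data.frame(tracks)
  n <- nrow(df)
  if (n < 2) return(data.frame())
  same <- df$track_id[-n] == df$track_id[-1] &
    df$frame[-1] - df$frame[-n] == 1L
  i0 <- which(same)
  out <- data.frame(track_id = df$track_id[i0], frame = df$frame[i0],
                    x0 = df$x[i0], y0 = df$y[i0],
                    x1 = df$x[i0 + 1L], y1 = df$y[i0 + 1L])
  out$d <- sqrt((out$x1 - out$x0)^2 + (out$y1 - out$y0)^2)
  geom <- if (inherits(map, "phase_map")) map$geometry else map
  if (!is.null(geom)) {
    p0 <- region_contains(geom, cbind(out$x0, out$y0))
    p1 <- region_contains(geom, cbind(out$x1, out$y1))
    out$phase0 <- p0
    out$phase1 <- p1
    out$step_phase <- ifelse(p0 == p1, p0, "crossing")
  } else if ("phase" %in% names(df)) {
    p0 <- df$phase[i0]
    p1 <- df$phase[i0 + 1L]
    out$phase0 <- p0
    out$phase1 <- p1
    out$step_phase <- ifelse(p0 == p1, p0, "crossing")
  }
  out
}
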