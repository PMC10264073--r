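#' Read a localization CSV
#'
#' Expects a header naming at least `frame`, `x` and `y` columns (an optional
#' `id` column is kept); coordinates are micrometres unless `units = "nm"`,
#' in which case they are divided by 1000.
#'
#' @param path CSV file path.
#' @param acquisition An [acquisition_params()] object.
#' @param units `"um"` (default) or `"nm"`.
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, acquisition = acquisition_params(),
                               units = c("um", "nm")) {
  units <- match.arg(units)
  df <- read.csv(path, check.names = FALSE)
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("localization CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df)) {
    bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$frame))
    if (length(bad))
      stop("non-finite values at row(s): ", paste(bad, collapse = ", "))
  }
  s <- if (units == "nm") 1e-3 else 1
  loc_table(df$frame, df$x * s, df$y * s,
            id = if ("id" %in% names(df)) df$id else NULL,
            acquisition = acquisition)
}

#' Write a localization table to CSV
#' @param table A [loc_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write track CSV
#'
#' Track CSV columns: `track_id,frame,x,y[,phase,state]`.
#'
#' @param path CSV file path.
#' @param acquisition An [acquisition_params()] object.
#' @return A [track_set()].
#' @export
read_tracks <- function(path, acquisition = acquisition_params()) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track CSV is missing column(s): ", paste(miss, collapse = ", "))
  track_set(df, acquisition = acquisition)
}

#' @rdname read_tracks
#' @param tracks A [track_set()].
#' @export
write_tracks <- function(tracks, path) {
  write.csv(as.data.frame(tracks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write region geometry JSON
#'
#' Geometry JSON is `{"disks": [[cx, cy, r], ...]}` or
#' `{"polygons": [[[x, y], ...], ...]}`; raster masks round-trip as
#' `{"mask": {"origin": [x, y], "cell_size": s, "nrow": n, "grid": [...]}}`
#' with the grid in column-major 0/1.
#'
#' @param path JSON file path.
#' @return A `region_geometry`.
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$disks)) {
    d <- matrix(unlist(obj$disks), ncol = 3, byrow = !is.matrix(obj$disks))
    if (is.matrix(obj$disks)) d <- obj$disks
    disk_geometry(d[, 1], d[, 2], d[, 3])
  } else if (!is.null(obj$polygons)) {
    rings <- obj$polygons
    if (is.matrix(rings)) rings <- list(rings)
    polygon_geometry(lapply(rings, function(r) {
      m <- if (is.matrix(r)) r else matrix(unlist(r), ncol = 2, byrow = TRUE)
      m
    }))
  } else if (!is.null(obj$mask)) {
    g <- obj$mask
    mask_geometry(matrix(as.logical(g$grid), nrow = g$nrow),
                  origin = g$origin, cell_size = g$cell_size)
  } else stop("unrecognized geometry JSON")
}

#' @rdname read_geometry
#' @param geometry A `region_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  obj <- switch(geometry$type,
    disks = list(disks = unname(geometry$disks)),
    polygons = list(polygons = lapply(geometry$rings, unname)),
    mask = list(mask = list(origin = geometry$origin,
                            cell_size = geometry$cell_size,
                            nrow = nrow(geometry$mask),
                            grid = as.integer(geometry$mask))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
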