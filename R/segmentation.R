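#' Local localization densities and density field
#'
#' Per-localization density is the neighbour count within `radius`
#' (self-inclusive) divided by the disk area. The field is a grid of binned
#' counts (cell `cell_size`) smoothed with a normalized disk kernel of the
#' same radius; the raw counts conserve the total localization number.
#'
#' @param table A [loc_table()] (all frames pooled: the stacked
#'   super-resolution image is treated as a static molecular distribution).
#' @param radius Neighbourhood radius, um. Default 0.1 (100 nm).
#' @param cell_size Grid cell edge, um. Default 0.05 (50 nm).
#' @return List with `point_density` (per localization, /um^2) and `field`
#'   (class `density_field`: `counts`, smoothed `density` (/um^2),
#'   `origin`, `cell_size`, `radius`).
#' @export
local_density <- function(table, radius = 0.1, cell_size = 0.05) {
  stopifnot(radius > 0, cell_size > 0)
  if (!nrow(table)) stop("empty localization table")
  cnt <- count_neighbors_cpp(table$x, table$y, radius)
  point_density <- cnt / (pi * radius^2)
  ext <- attr(table, "extent")
  origin <- c(ext["xmin"], ext["ymin"]) - radius
  rad_c <- ceiling(radius / cell_size)
  nx <- max(2 * rad_c + 1,
            ceiling((ext["xmax"] + radius - origin[1]) / cell_size))
  ny <- max(2 * rad_c + 1,
            ceiling((ext["ymax"] + radius - origin[2]) / cell_size))
  ix <- pmin(nx, floor((table$x - origin[1]) / cell_size) + 1)
  iy <- pmin(ny, floor((table$y - origin[2]) / cell_size) + 1)
  counts <- matrix(0L, nx, ny)
  tab <- table(factor(ix, levels = seq_len(nx)),
               factor(iy, levels = seq_len(ny)))
  counts[] <- as.integer(tab)
  # normalized disk kernel with the same radius as the point neighbourhood
  off <- seq(-rad_c, rad_c)
  kern <- outer(off, off, function(i, j) (i^2 + j^2) * cell_size^2 <= radius^2)
  kern <- kern / sum(kern)
  sm <- EBImage::filter2(EBImage::Image(counts / cell_size^2), kern,
                         boundary = 0)
  field <- structure(list(counts = counts,
                          density = EBImage::imageData(sm),
                          origin = unname(origin), cell_size = cell_size,
                          radius = radius,
                          pad = as.integer(ceiling(radius / cell_size))),
                     class = "density_field")
  list(point_density = point_density, field = field)
}

#' Segment condensed-phase regions from a density field
#'
#' Default (`"otsu"`) strategy: an Otsu split of the per-localization
#' log-density histogram (the operative signal is its bimodality) gives a
#' provisional condensed/dilute separation; the final threshold is the
#' half-height level `(sigma_c + sigma_d) / 2` of the provisional phase
#' densities, which places the boundary contour of the kernel-smoothed
#' field at the true density step. A morphological closing and a minimum
#' condensed-area filter clean the mask, and per-phase densities are
#' recomputed from the raw (unsmoothed) counts over the final masks. When
#' the provisional split shows less than `min_contrast`-fold density
#' contrast the field is treated as single-phase (no condensed regions).
#'
#' @param density Output of [local_density()] (a list with `point_density`
#'   and `field`); a bare `density_field` is accepted for the `"kmedian"`
#'   and `"absolute"` strategies.
#' @param strategy `"otsu"` (default), `"kmedian"` (threshold = `k` times
#'   the median cell density) or `"absolute"`.
#' @param k Multiplier for `"kmedian"`. Default 5.
#' @param absolute Absolute density threshold (/um^2) for `"absolute"`.
#' @param min_area Minimum condensed-region area, um^2. Default 0.05 — just
#'   above the smoothing-kernel footprint (`pi * radius^2` = 0.031 for the
#'   100 nm default), so an isolated blinking localization cannot survive
#'   as a region.
#' @param min_contrast Minimum provisional density contrast for a
#'   two-phase call. Default 5 (condensates enrich tens-fold; a smaller
#'   ratio indicates shot noise on a single-phase field).
#' @return A `phase_map`: `geometry` (raster `region_geometry`), `contours`
#'   (boundary rings, um), `sigma_c`, `sigma_d` (/um^2), `areas`
#'   (condensed/dilute, um^2), `ef`, `threshold`, `degenerate` flag.
#' @export
segment_phases <- function(density, strategy = c("otsu", "kmedian",
                                                 "absolute"),
                           k = 5, absolute = NULL, min_area = 0.05,
                           min_contrast = 5) {
  strategy <- match.arg(strategy)
  field <- if (inherits(density, "density_field")) density else density$field
  dens <- field$density
  eps <- 0.5 / (pi * field$radius^2)  # half a neighbour-count unit
  thr <- switch(strategy,
    otsu = {
      if (inherits(density, "density_field"))
        stop("the otsu strategy needs the full local_density() output")
      # per-point density without the self count, matching the field scale
      zp <- log10(pmax(density$point_density - 1 / (pi * field$radius^2), 0)
                  + eps)
      zr <- range(zp)
      t0 <- if (diff(zr) == 0) zr[1] else {
        img <- EBImage::Image(matrix((zp - zr[1]) / diff(zr)))
        zr[1] + EBImage::otsu(img, range = c(0, 1)) * diff(zr)
      }
      t0_lin <- 10^t0 - eps
      hi <- dens > t0_lin
      s_c0 <- if (any(hi)) mean(dens[hi]) else 0
      s_d0 <- mean(dens[!hi])
      # significance floor: the threshold must exceed the largest kernel
      # count a uniform Poisson field of the same mean would produce
      a_k <- pi * field$radius^2
      t_null <- stats::qpois(1 - 1 / length(dens), mean(dens) * a_k) / a_k
      t_half <- (s_c0 + s_d0) / 2  # half-height refinement
      if (!any(hi) || s_c0 < min_contrast * max(s_d0, eps / 10) ||
          t_half < t_null) Inf
      else t_half
    },
    kmedian = k * pmax(median(dens), eps),
    absolute = absolute)
  mask <- dens > thr
  brush_sz <- 2 * ceiling(field$radius / field$cell_size) + 1
  mimg <- EBImage::Image(mask * 1)
  mimg <- EBImage::closing(mimg, EBImage::makeBrush(brush_sz, "disc"))
  lab <- EBImage::bwlabel(mimg)
  sizes <- table(lab[lab > 0])
  min_cells <- min_area / field$cell_size^2
  keep <- as.integer(names(sizes)[sizes >= min_cells])
  mask <- matrix(EBImage::imageData(lab) %in% keep, nrow(dens), ncol(dens))
  degenerate <- all(mask) || !any(mask)
  cell_area <- field$cell_size^2
  # the kernel-padding ring around the field of view holds no data and is
  # excluded from the phase areas and densities
  pad <- if (is.null(field$pad)) 0L else field$pad
  interior <- matrix(FALSE, nrow(dens), ncol(dens))
  interior[(pad + 1):(nrow(dens) - pad), (pad + 1):(ncol(dens) - pad)] <- TRUE
  a_c <- sum(mask & interior) * cell_area
  a_d <- sum(!mask & interior) * cell_area
  n_c <- sum(field$counts[mask & interior])
  n_d <- sum(field$counts[!mask & interior])
  sigma_c <- if (a_c > 0) n_c / a_c else NA_real_
  sigma_d <- if (a_d > 0) n_d / a_d else NA_real_
  contours <- list()
  if (any(mask)) {
    oc <- EBImage::ocontour(EBImage::bwlabel(EBImage::Image(mask * 1)))
    contours <- lapply(oc, function(m)
      cbind(field$origin[1] + (m[, 1] - 0.5) * field$cell_size,
            field$origin[2] + (m[, 2] - 0.5) * field$cell_size))
  }
  if (degenerate)
    warning("degenerate segmentation: all or no cells condensed")
  structure(list(geometry = mask_geometry(mask, origin = field$origin,
                                          cell_size = field$cell_size),
                 contours = contours, sigma_c = sigma_c, sigma_d = sigma_d,
                 areas = c(condensed = a_c, dilute = a_d),
                 ef = sigma_c / sigma_d, threshold = thr,
                 degenerate = degenerate),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf(paste0("<phase_map> %d condensed region(s), area %.3g um^2;",
                     " sigma_c = %.3g, sigma_d = %.3g /um^2, EF = %.3g\n"),
              length(x$contours), x$areas["condensed"], x$sigma_c,
              x$sigma_d, x$ef))
  invisible(x)
}

#' Phase map from a known region geometry
#'
#' Builds a `phase_map` directly from given condensed-region geometry and a
#' localization table (e.g. for simulated scenes with known boundaries).
#'
#' @param geometry A `region_geometry`.
#' @param table A [loc_table()].
#' @param total_area Analyzed area, um^2; default the table's bounding box.
#' @return A `phase_map`.
#' @export
phase_map_from_geometry <- function(geometry, table, total_area = NULL) {
  ext <- attr(table, "extent")
  if (is.null(total_area))
    total_area <- (ext["xmax"] - ext["xmin"]) * (ext["ymax"] - ext["ymin"])
  a_c <- region_area(geometry)
  a_d <- unname(total_area) - a_c
  lab <- region_contains(geometry, cbind(table$x, table$y))
  n_c <- sum(lab == "condensed")
  n_d <- sum(lab == "dilute")
  structure(list(geometry = geometry, contours = list(),
                 sigma_c = n_c / a_c, sigma_d = n_d / a_d,
                 areas = c(condensed = a_c, dilute = a_d),
                 ef = (n_c / a_c) / (n_d / a_d), threshold = NA_real_,
                 degenerate = FALSE),
            class = "phase_map")
}

#' Enrichment fold from localizations with bootstrap uncertainty
#'
#' `EF = (n_c / A_c) / (n_d / A_d)` with the condensed/dilute split taken
#' from the phase map; uncertainty by resampling localizations.
#'
#' @param table A [loc_table()].
#' @param map A `phase_map`.
#' @param n_boot Bootstrap replicates. Default 200.
#' @return List with `ef`, `se`, `n_condensed`, `n_dilute`.
#' @export
enrichment_from_localizations <- function(table, map, n_boot = 200) {
  lab <- region_contains(map$geometry, cbind(table$x, table$y))
  a_c <- unname(map$areas["condensed"])
  a_d <- unname(map$areas["dilute"])
  is_c <- lab == "condensed"
  n_c <- sum(is_c); n_d <- sum(!is_c)
  if (n_d == 0) stop("empty dilute region")
  ef <- (n_c / a_c) / (n_d / a_d)
  boots <- vapply(seq_len(n_boot), function(i) {
    s <- sample(is_c, replace = TRUE)
    nc <- sum(s)
    (nc / a_c) / ((length(s) - nc) / a_d)
  }, numeric(1))
  list(ef = ef, se = sd(boots), n_condensed = n_c, n_dilute = n_d)
}
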