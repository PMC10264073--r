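# static two-phase point pattern at a given density contrast
two_phase_points <- function(geom, box, lambda_d, contrast) {
  a_c <- region_area(geom)
  n_c <- rpois(1, contrast * lambda_d * a_c)
  n_d <- rpois(1, lambda_d * (box[1] * box[2] - a_c))
  pc <- adaptrack:::sample_in_geometry(geom, n_c)
  pd <- adaptrack:::sample_outside_geometry(geom, box, n_d)
  loc_table(rep(0L, n_c + n_d), c(pc[, 1], pd[, 1]), c(pc[, 2], pd[, 2]))
}

test_that("local densities match the point geometry and conserve counts", {
  one <- loc_table(0L, 5, 5)
  ld <- local_density(one, radius = 0.1)
  expect_equal(ld$point_density, 1 / (pi * 0.1^2))
  expect_equal(sum(ld$field$counts), 1)
  # uniform Poisson field: mean point density -> lambda + self-count
  set.seed(501)
  n <- 20000
  u <- loc_table(rep(0L, n), runif(n, 0, 10), runif(n, 0, 10))
  ldu <- local_density(u, radius = 0.1)
  lambda <- n / 100
  expect_equal(mean(ldu$point_density), lambda + 1 / (pi * 0.1^2),
               tolerance = 0.02)
  expect_equal(sum(ldu$field$counts), n)
  # 60:1 two-density field has a bimodal (wide-spread) density histogram
  set.seed(502)
  g <- disk_geometry(c(3, 7), c(3, 7), c(0.8, 0.6))
  tp <- two_phase_points(g, c(10, 10), 15, 60)
  ldt <- local_density(tp)
  # dilute points (lower quartile) sit far below the condensed majority
  q <- quantile(ldt$point_density, c(0.1, 0.5))
  expect_gt(q[2] / q[1], 5)
})

test_that("segmentation recovers disk regions at 60-fold contrast with high
           overlap and EF within 10%", {
  set.seed(503)
  g <- disk_geometry(c(3, 7), c(3, 7), c(0.8, 0.6))
  tab <- two_phase_points(g, c(10, 10), 15, 60)
  map <- segment_phases(local_density(tab))
  expect_false(map$degenerate)
  expect_equal(length(map$contours), 2L)
  # Jaccard of the recovered mask against the true disks at cell centers
  gm <- map$geometry
  nx <- nrow(gm$mask); ny <- ncol(gm$mask)
  pts <- cbind(rep(gm$origin[1] + (seq_len(nx) - 0.5) * gm$cell_size, ny),
               rep(gm$origin[2] + (seq_len(ny) - 0.5) * gm$cell_size,
                   each = nx))
  truth <- region_contains(g, pts) == "condensed"
  jac <- sum(truth & gm$mask) / sum(truth | gm$mask)
  expect_gte(jac, 0.9)
  expect_equal(map$ef, 60, tolerance = 0.1)
  e <- enrichment_from_localizations(tab, map)
  expect_equal(e$ef, 60, tolerance = 0.1)
  expect_gt(e$se, 0)
})

test_that("a uniform field yields no condensed regions", {
  set.seed(504)
  n <- 3000
  u <- loc_table(rep(0L, n), runif(n, 0, 10), runif(n, 0, 10))
  map <- suppressWarnings(segment_phases(local_density(u)))
  expect_equal(length(map$contours), 0L)
  expect_true(map$degenerate)
})

test_that("segmentation is invariant to translation and frame relabeling", {
  set.seed(505)
  g <- disk_geometry(c(3, 7), c(3, 7), c(0.8, 0.6))
  tab <- two_phase_points(g, c(10, 10), 15, 60)
  m1 <- segment_phases(local_density(tab))
  shift <- loc_table(rev(seq_len(nrow(tab))) %% 7, tab$x + 3.2, tab$y - 1.7)
  m2 <- segment_phases(local_density(shift))
  expect_equal(m2$ef, m1$ef, tolerance = 0.02)
  expect_equal(unname(m2$areas), unname(m1$areas), tolerance = 0.02)
})

test_that("enrichment estimate is invariant in expectation to uniform
           thinning and exact on constructed counts", {
  # constructed: 6000 points in 1 um^2 condensed, 100 in 1 um^2 dilute
  g <- disk_geometry(0.5, 0.5, sqrt(1 / pi))
  set.seed(506)
  pc <- adaptrack:::sample_in_geometry(g, 6000)
  box_pts <- adaptrack:::sample_outside_geometry(g, c(2, 1), 100)
  tab <- loc_table(rep(0L, 6100), c(pc[, 1], box_pts[, 1]),
                   c(pc[, 2], box_pts[, 2]))
  map <- phase_map_from_geometry(g, tab, total_area = 2)
  e <- enrichment_from_localizations(tab, map)
  expect_equal(e$ef, 60, tolerance = 1e-12)
  # 50% thinning preserves the estimate in expectation
  keep <- runif(6100) < 0.5
  thin <- loc_table(tab$frame[keep], tab$x[keep], tab$y[keep])
  et <- enrichment_from_localizations(thin, map)
  expect_equal(et$ef, 60, tolerance = 3 * et$se / 60 + 0.05)
})

test_that("condensate-scene round trip: segmentation EF lands near the
           configured enrichment", {
  set.seed(507)
  sc <- simulate_condensate_scene(box = c(14, 14), n_frames = 1500,
                                  geometry = disk_geometry(
                                    c(3.5, 10, 4, 10.5), c(3.5, 4, 10.5, 10),
                                    c(0.7, 0.6, 0.55, 0.7)))
  map <- segment_phases(local_density(sc$table))
  expect_equal(map$ef, 60, tolerance = 0.15)
})
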