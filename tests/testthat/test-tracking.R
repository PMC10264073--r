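test_that("assignment-error model reproduces its limits and stationarity
           condition", {
  expect_lt(assignment_error(10, 0)$E_TN, 1e-40)
  # c = 0: pure exp(-X^2), monotone decreasing
  X <- seq(0.5, 4, 0.25)
  e0 <- assignment_error(X, 0)$E_total
  expect_equal(e0, exp(-X^2))
  expect_true(all(diff(e0) < 0))
  # the minimum of E(X) satisfies X exp(-X^2) = c (numerical derivative)
  c0 <- 2e-3
  f <- function(X) assignment_error(X, c0)$E_total
  xs <- optimize(f, c(1, 5), tol = 1e-10)$minimum
  expect_equal(xs * exp(-xs^2), c0, tolerance = 1e-5)
})

test_that("optimal_X solves the stationarity equation on the admissible
           branch", {
  # oracle values frozen from bisection on X exp(-X^2) - c over [1, 6]
  expect_equal(optimal_X(4.3e-3), 2.524948, tolerance = 1e-5)
  expect_equal(optimal_X(2.7e-4), 3.055146, tolerance = 1e-5)
  for (c0 in c(1e-4, 1e-3, 4e-3, 0.05)) {
    x <- optimal_X(c0)
    expect_lt(abs(x * exp(-x^2) - c0), 1e-10)
    expect_gt(x, 1 / sqrt(2))
  }
  # strictly decreasing in c
  cs <- 10^seq(-4, -1.5, length.out = 8)
  expect_true(all(diff(vapply(cs, optimal_X, numeric(1))) < 0))
  expect_error(optimal_X(1), "admissible")
})

test_that("search_range follows R = X sqrt(4 D t)", {
  expect_equal(search_range(0.22, 0.03, 2.5), 2.5 * sqrt(4 * 0.22 * 0.03))
  expect_equal(search_range(0.57, 0.03, 2.5), 0.6538, tolerance = 1e-4)
  expect_equal(search_range(0.1, 0.03, 5), 2 * search_range(0.1, 0.03, 2.5))
})

test_that("rough_D is the consistent moment estimator", {
  expect_equal(rough_D(rep(0, 60), 0.03), 0)
  set.seed(201)
  d <- r_disp(1e4, D = 0.46, t = 0.03)
  expect_equal(rough_D(d, 0.03), 0.46, tolerance = 0.03)
  expect_equal(rough_D(d, 0.06), rough_D(d, 0.03) / 2)
  expect_error(rough_D(d[1:10], 0.03), "too few")
})

test_that("gated linking forms and splits tracks as prescribed", {
  for (strat in c("bipartite", "greedy")) {
    near <- loc_table(c(0L, 1L), c(0, 0.1), c(0, 0))
    ts <- link_localizations(near, 0.5, strat)
    expect_equal(n_tracks(ts), 1L)
    far <- loc_table(c(0L, 1L), c(0, 0.6), c(0, 0))
    ts2 <- link_localizations(far, 0.5, strat)
    expect_equal(n_tracks(ts2), 2L)
  }
})

test_that("linking is invariant to input row order", {
  set.seed(202)
  sim <- simulate_homogeneous(0.2, 0.1, 60, box = c(8, 8))
  tab <- sim$table
  perm <- sample(nrow(tab))
  tab2 <- loc_table(tab$frame[perm], tab$x[perm], tab$y[perm],
                    id = tab$id[perm])
  l1 <- link_localizations(tab, 0.3, "bipartite")
  l2 <- link_localizations(tab2, 0.3, "bipartite")
  # same multiset of linked coordinate pairs
  key <- function(ts, tb) {
    lk <- attr(ts, "links")
    sort(paste(round(tb$x[lk[, 1]], 9), round(tb$y[lk[, 1]], 9),
               round(tb$x[lk[, 2]], 9), round(tb$y[lk[, 2]], 9)))
  }
  expect_identical(key(l1, tab), key(l2, tab2))
})

test_that("every localization lands in exactly one track and the link-count
           identity holds", {
  set.seed(203)
  sim <- simulate_homogeneous(0.25, 0.15, 80, box = c(10, 10))
  ts <- link_localizations(sim$table, 0.35, "bipartite")
  expect_equal(nrow(ts), nrow(sim$table))
  expect_equal(length(unique(ts$row)), nrow(sim$table))
  n_links <- nrow(attr(ts, "links"))
  expect_equal(n_tracks(ts) + n_links, nrow(sim$table))
})

test_that("adaptive two-pass tracking shrinks the slow-phase gate and beats
           pass 1 on ground-truth link recovery", {
  set.seed(204)
  sc <- simulate_condensate_scene(box = c(12, 12), n_frames = 1200,
                                  geometry = disk_geometry(
                                    c(3, 8.5, 3.5, 9), c(3, 3.5, 8.5, 9),
                                    c(0.7, 0.6, 0.5, 0.7)))
  cfg <- link_config()
  tk <- adaptive_track(sc$table, sc$geometry, cfg)
  prov <- attr(tk, "provenance")
  # slow condensed phase gets a smaller gate than the fast dilute phase
  expect_lt(prov$R_phase[["condensed"]], prov$R_phase[["dilute"]])
  # pass-2 recovery of true links is at least as good as the global default
  p1 <- link_localizations(sc$table, cfg$default_R, cfg$strategy)
  e1 <- evaluate_tracking(p1, sc$table)
  e2 <- evaluate_tracking(tk, sc$table)
  expect_lte(e2$total_error, e1$total_error)
})

test_that("single-phase adaptation with a single-state scene reduces to the
           moment-gate identity", {
  set.seed(205)
  sim <- simulate_homogeneous(0.1, 0.2, 150, box = c(12, 12))
  tk <- adaptive_track(sim$table, map = NULL, link_config())
  prov <- attr(tk, "provenance")
  expect_equal(prov$R_phase[["all"]],
               search_range(prov$D_rough[["all"]], 0.03, 2.5),
               tolerance = 1e-9)
})

test_that("crossing events count directed boundary passages", {
  g <- disk_geometry(0, 0, 1)
  inside <- track_set(data.frame(track_id = 1L, frame = 0:2,
                                 x = c(0, 0.1, 0.2), y = 0))
  ev <- crossing_events(inside, g)
  expect_equal(ev$n_go_in, 0L)
  expect_equal(ev$n_go_out, 0L)
  inout <- track_set(data.frame(track_id = 1L, frame = 0:2,
                                x = c(1.5, 0.5, 1.5), y = 0))
  ev2 <- crossing_events(inout, g)
  expect_equal(ev2$n_go_in, 1L)
  expect_equal(ev2$n_go_out, 1L)
})

test_that("total link error is U-shaped in X with its floor in [2.0, 3.5]
           across density/diffusivity conditions", {
  set.seed(206)
  conds <- list(c(sigma = 0.3, D = 0.1), c(sigma = 0.05, D = 0.5),
                c(sigma = 0.02, D = 2))
  for (cd in conds) {
    bench <- optimal_x_benchmark(sigma = cd["sigma"], D = cd["D"],
                                 n_frames = 120, box = c(18, 18))
    best <- attr(bench, "best_X")
    expect_gte(best, 2.0)
    expect_lte(best, 3.5)
    # U-shape: errors at the grid ends exceed the minimum
    expect_gt(bench$total_error[1], min(bench$total_error))
    expect_gt(bench$total_error[nrow(bench)], min(bench$total_error))
  }
})
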