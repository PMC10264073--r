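test_that("displacement magnitudes and histograms follow the step
           geometry", {
  tr <- track_set(data.frame(track_id = 1L, frame = 0:1,
                             x = c(0, 0.003), y = c(0, 0.004)))
  dm <- displacement_magnitudes(tr)
  expect_equal(dm$d, 0.005)
  expect_equal(dm$binwidth, 0.005)
  # phase filter on a dilute-only track yields an error (empty selection)
  g <- disk_geometry(10, 10, 0.5)
  expect_error(displacement_magnitudes(tr, phase = "condensed", map = g),
               "no displacements")
})

test_that("single-population Brownian fit recovers D from exact samples and
           flags two-state mixtures", {
  set.seed(301)
  d <- r_disp(1e4, 0.46, 0.03)
  fit <- fit_rayleigh(d, 0.03)
  expect_equal(fit$D, 0.46, tolerance = 0.03)
  expect_equal(fit$D_moment, 0.46, tolerance = 0.03)
  expect_gt(fit$r2, 0.95)
  expect_equal(fit_rayleigh(rep(0, 100), 0.03)$D, 0)
  # 95/5 confined/mobile mixture: single-population fit hugs the confined
  # peak and misses the high-displacement tail
  dmix <- c(r_disp(9500, 0.006, 0.03), r_disp(500, 0.17, 0.03))
  fmix <- fit_rayleigh(dmix, 0.03)
  expect_lt(fmix$D, 0.05)  # stays on the dominant confined peak
  # the fitted model predicts essentially no steps beyond 0.1 um, while the
  # mobile tail holds hundreds
  pred_tail <- length(dmix) * exp(-0.1^2 / (4 * fmix$D * 0.03))
  expect_gt(sum(dmix > 0.1), 10 * pred_tail)
})

test_that("MSD is exact for ballistic and stationary tracks and linear for
           Brownian tracks", {
  bal <- ballistic_track(12, step = 0.05)
  cv <- msd(bal, max_lag = 5)
  expect_equal(cv$msd, (0.05 * cv$lag)^2, tolerance = 1e-12)
  stat <- track_set(data.frame(track_id = 1L, frame = 0:10, x = 1, y = 2))
  expect_true(all(msd(stat, max_lag = 3)$msd == 0))
  set.seed(302)
  sim <- simulate_homogeneous(0.08, 0.61, 150, box = c(20, 20),
                              mean_lifetime = 12)
  cv2 <- msd(sim$truth, max_lag = 5)
  fit <- fit_msd(cv2, "linear", n_lags = 5)
  expect_equal(fit$D, 0.61, tolerance = 0.05)
})

test_that("MSD model fits invert exact curves to machine precision", {
  t <- (1:10) * 0.03
  sub <- data.frame(t = t, msd = 4 * 0.014 * t^0.74)
  fa <- fit_msd(sub, "anomalous")
  expect_equal(fa$D_alpha, 0.014, tolerance = 1e-10)
  expect_equal(fa$alpha, 0.74, tolerance = 1e-10)
  lin <- data.frame(t = t, msd = 4 * 0.5 * t)
  fl <- fit_msd(lin, "linear")
  expect_equal(fl$D, 0.5, tolerance = 1e-12)
  expect_equal(fit_msd(lin, "anomalous")$alpha, 1, tolerance = 1e-10)
})

test_that("condensed-phase two-state tracks are subdiffusive by the
           anomalous fit", {
  set.seed(303)
  sim <- simulate_two_state(400, n_steps = 30, D_m = 0.17,
                            P_cm = 0.038, P_mc = 0.828, confined = "psf")
  cv <- msd(sim$truth, max_lag = 10)
  fa <- fit_msd(cv, "anomalous")
  expect_lt(fa$alpha, 1)
})

test_that("kinetic enrichment relation and confinement ratios match their
           closed forms", {
  # printed-value identities
  expect_equal(round(ef_from_kinetics(0.47, 0.17, 0.044), 1), 62.8)
  expect_equal(round(ef_from_kinetics(0.47, 0.044, 0.135)), 79)
  expect_equal(ef_from_kinetics(0.3, 0.3, 1), 1)
  expect_error(ef_from_kinetics(0.3, 0.3, 0), "zero mobile ratio")
  cr <- confinement_ratios(P_mc = 0.828, P_cm = 0.038)
  expect_equal(round(100 * cr$P_c, 1), 95.6)
  expect_equal(cr$P_c + cr$P_m, 1)
  expect_equal(confinement_ratios(0.5, 0.5)$P_c, 0.5)
  expect_equal(confinement_ratios(0, 0.2)$P_c, 0)
  expect_error(confinement_ratios(0, 0), "undefined")
})

test_that("localization-error scale converts confined D as s = sqrt(D t)", {
  expect_equal(loc_error_scale(0.0127, 0.03), 19.5, tolerance = 0.01)
  expect_equal(loc_error_scale(0.006149, 0.03), 13.6, tolerance = 0.01)
  expect_equal(loc_error_scale(0, 0.03), 0)
})

test_that("multi-state flux balance detects Eq.-consistent equilibria", {
  same <- list(list(sigma = 2, D = 0.3), list(sigma = 2, D = 0.3))
  expect_equal(flux_balance_check(same)$imbalance, 0)
  # condensed two-state vs dilute single state built from the kinetic
  # relation: sigma_c * (P_m * D_m) = sigma_d * D_d exactly
  ef <- 0.47 / (0.044 * 0.17)
  phases <- list(
    list(sigma = c(ef * 0.956, ef * 0.044), D = c(0, 0.17)),
    list(sigma = 1, D = 0.47))
  expect_lt(flux_balance_check(phases)$imbalance, 1e-12)
})

test_that("Baum-Welch recovers two-state parameters with a monotone
           likelihood", {
  set.seed(304)
  sim <- simulate_two_state(2000, n_steps = 10, D_m = 0.167,
                            P_cm = 0.038, P_mc = 0.828,
                            confined = "brownian", D_c = 0.0127)
  m <- hmm_fit(sim$truth)
  expect_equal(m$D_c, 0.0127, tolerance = 0.15)
  expect_equal(m$D_m, 0.167, tolerance = 0.15)
  expect_equal(m$P_cm, 0.038, tolerance = 0.15)
  expect_equal(m$P_mc, 0.828, tolerance = 0.15)
  tr <- attr(m, "loglik_trace")
  expect_false(is.unsorted(tr))
  # likelihood at the fitted optimum beats perturbed parameter sets
  pert <- two_state_model(0.0127 * 1.6, 0.167 * 0.6, 0.07, 0.6)
  expect_gt(m$loglik, hmm_loglik(sim$truth, pert))
})

test_that("single-state data yields a flagged degenerate two-state fit", {
  set.seed(305)
  sim <- simulate_homogeneous(0.02, 0.2, 150, box = c(15, 15),
                              mean_lifetime = 8)
  m <- hmm_fit(sim$truth)
  expect_true(any(grepl("second state|weakly separated", m$flags)))
})

test_that("parameter recovery holds across a two-state grid with
           well-separated states", {
  set.seed(306)
  grid <- list(c(D_c = 0.01, D_m = 0.1, P_cm = 0.05, P_mc = 0.4),
               c(D_c = 0.02, D_m = 0.3, P_cm = 0.1, P_mc = 0.2))
  for (g in grid) {
    sim <- simulate_two_state(1200, n_steps = 10, D_m = g["D_m"],
                              P_cm = g["P_cm"], P_mc = g["P_mc"],
                              confined = "brownian", D_c = g["D_c"])
    m <- hmm_fit(sim$truth)
    err <- abs(c(m$D_c, m$D_m, m$P_cm, m$P_mc) - g) / g
    expect_lt(median(err), 0.15)
  }
})
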