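test_that("overlap coefficient obeys its defining properties and the
           Gaussian closed form", {
  grid <- seq(-12, 12, by = 0.01)
  p <- gauss_hist(0, 1, grid)
  q <- gauss_hist(2, 1, grid)
  # OVL of two unit-variance Gaussians 2 sd apart = 2 * pnorm(-1)
  expect_equal(ovl(p, q, 0.01), 2 * pnorm(-1), tolerance = 1e-3)
  expect_equal(ovl(p, p, 0.01), 1, tolerance = 1e-6)
  expect_equal(ovl(p, q, 0.01), ovl(q, p, 0.01))
  disj <- gauss_hist(30, 1, grid)  # support outside the grid: all ~0
  expect_lt(ovl(p, disj, 0.01), 1e-10)
  expect_error(ovl(p, q[-1], 0.01), "common grid")
  # invariance under grid refinement (within discretization error)
  grid2 <- seq(-12, 12, by = 0.002)
  expect_equal(ovl(gauss_hist(0, 1, grid2), gauss_hist(2, 1, grid2), 0.002),
               ovl(p, q, 0.01), tolerance = 1e-4)
})

test_that("conditional distributions separate two-state motion and
           coincide for simple diffusion", {
  set.seed(401)
  two <- sim_classified_tracks(250, 25, P_cm = 0.09, P_mc = 0.59)
  cd <- conditional_dists(two, 60)
  expect_lt(ovl(cd), 0.9)
  expect_equal(cd$n_low + cd$n_high, 250 * (25 - 1))
  # i.i.d. Rayleigh steps: conditionals converge (OVL near 1)
  iid <- sim_classified_tracks(400, 25, P_cm = 1, P_mc = 0,
                               D_m = 0.05, d_b_nm = 1e-9)
  cd2 <- conditional_dists(iid, 60)
  expect_gt(ovl(cd2), 0.93)
  # a single 10-step track gives exactly 9 conditional pairs
  one <- sim_classified_tracks(1, 10, P_cm = 0.2, P_mc = 0.5)
  cd3 <- conditional_dists(one, 60)
  expect_equal(cd3$n_low + cd3$n_high, 9)
  expect_true(cd3$low_power)
})

test_that("demarcation scan localizes the state boundary and returns null
           for simple diffusion", {
  set.seed(402)
  # well-separated construction: confined scale 14 nm vs mobile D = 0.17
  sim <- simulate_two_state(400, n_steps = 25, D_m = 0.17,
                            P_cm = 0.15, P_mc = 0.55, confined = "psf",
                            psf_scatter = 0.014)
  sc <- scan_demarcation(sim$truth)
  expect_false(is.na(sc$d_b_star))
  # between the confined displacement mode (~20 nm) and twice the mobile
  # step mode (~101 nm per-axis RMS)
  expect_gte(sc$d_b_star, 20)
  expect_lte(sc$d_b_star, 200)
  expect_equal(max(sc$curve$separation[!sc$curve$low_power]),
               sc$curve$separation[sc$curve$d_b == sc$d_b_star],
               tolerance = 1e-12)
  # simple diffusion: flat curve, null demarcation
  set.seed(403)
  iid <- sim_classified_tracks(500, 25, P_cm = 1, P_mc = 0,
                               D_m = 0.05, d_b_nm = 1e-9)
  sc2 <- scan_demarcation(iid)
  expect_true(is.na(sc2$d_b_star))
})

test_that("threshold classification recovers ratios and switching
           frequencies on demarcation-consistent data", {
  set.seed(404)
  sim <- sim_classified_tracks(400, 25, P_cm = 0.09, P_mc = 0.59)
  cl <- classify_steps(sim, 60)
  expect_equal(cl$P_c + cl$P_m, 1)
  expect_equal(cl$P_m, 0.09 / (0.09 + 0.59), tolerance = 0.1)
  expect_equal(cl$P_cm, 0.09, tolerance = 0.1)
  expect_equal(cl$P_mc, 0.59, tolerance = 0.1)
  # degenerate label patterns
  slow <- sim_classified_tracks(30, 12, P_cm = 0, P_mc = 1)
  cls <- classify_steps(slow, 60)
  expect_equal(cls$P_c, 1)
  expect_equal(cls$P_cm, 0)
})

test_that("component fits recover the confined scale and mobile D", {
  set.seed(405)
  # un-truncated samples: plain ML fit
  dl <- 0.0136 * sqrt(-4 * log(runif(4000)))
  sL <- adaptrack:::fit_rayleigh_scale_ml(dl)
  expect_equal(1000 * sL, 13.6, tolerance = 0.1)
  dh <- r_disp(4000, 0.044, 0.03)
  sH <- adaptrack:::fit_rayleigh_scale_ml(dh)
  expect_equal(sH^2 / 0.03, 0.044, tolerance = 0.1)
  # truncation-aware ML on classified (cut at d_b) components
  sim <- sim_classified_tracks(600, 25, P_cm = 0.09, P_mc = 0.59,
                               s_conf = 0.0136, D_m = 0.044)
  cl <- classify_steps(sim, 60)
  fc <- fit_components(cl, 0.03)
  expect_equal(fc$s_L, 13.6, tolerance = 0.1)
  expect_equal(fc$D_H, 0.044, tolerance = 0.1)
  # Brownian-generated H samples: the heavy-tail alternative does not beat
  # the Brownian fit by AIC
  clb <- cl
  fcb <- fit_components(clb, 0.03, heavy_tail = TRUE)
  expect_gt(fcb$levy$dAIC_vs_brownian, 0)
})

test_that("classification-based ratios agree with the HMM on well-separated
           two-state data", {
  set.seed(406)
  sim <- simulate_two_state(900, n_steps = 20, D_m = 0.17,
                            P_cm = 0.1, P_mc = 0.6, confined = "psf",
                            psf_scatter = 0.014)
  m <- hmm_fit(sim$truth)
  # demarcate at the geometric mean of the two step scales (~60 nm)
  cl <- classify_steps(sim$truth, 60)
  expect_lt(abs(cl$P_m - m$P_m), 0.10)
})
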