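test_that("Brownian increments have the prescribed variance and MSD", {
  set.seed(101)
  st <- brownian_step(0.5, 0.03, n = 1e5)
  # per-axis variance 2 D dt within 2%
  expect_equal(var(st[, 1]), 2 * 0.5 * 0.03, tolerance = 0.02)
  expect_equal(var(st[, 2]), 2 * 0.5 * 0.03, tolerance = 0.02)
  # mean square step 4 D dt
  expect_equal(mean(rowSums(st^2)), 4 * 0.5 * 0.03, tolerance = 0.02)
  expect_true(all(brownian_step(0, 0.03, n = 10) == 0))
})

test_that("homogeneous generator honors track count, lifetimes and D = 0", {
  set.seed(102)
  sim <- simulate_homogeneous(sigma = 0.3, D = 0.1, n_frames = 400,
                              box = c(10, 10))
  nt <- n_tracks(sim$truth)
  expect_equal(nt, round(0.3 * 100 * 400 / 3.5), tolerance = 0.001)
  # realized mean lifetime ~ 3.5 frames (Poisson mean, min 1) within 3%
  lens <- table(sim$truth$track_id)
  expect_equal(mean(lens), 3.5, tolerance = 0.03)
  # frozen molecules: every localization of a track identical
  frz <- simulate_homogeneous(sigma = 0.05, D = 0, n_frames = 50)
  spread <- tapply(frz$truth$x, frz$truth$track_id, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("two-state generator reaches the stationary mobile fraction and
           the PSF-scattered confined scale", {
  set.seed(103)
  sim <- simulate_two_state(500, n_steps = 200, D_m = 0.17,
                            P_cm = 0.1, P_mc = 0.9, confined = "psf",
                            psf_scatter = 0.0136)
  st <- sim$truth$state
  expect_equal(mean(st == "mobile"), 0.1 / (0.1 + 0.9), tolerance = 0.02)
  # confined-to-confined displacements follow the s-scale law:
  # moment estimate of s from d^2 (E[d^2] = 4 s^2)
  steps <- track_steps(sim$truth)
  conf_pair <- sim$truth$state[-1] == "confined" &
    sim$truth$state[-nrow(sim$truth)] == "confined" &
    sim$truth$track_id[-1] == sim$truth$track_id[-nrow(sim$truth)]
  dx <- diff(sim$truth$x)[conf_pair]
  dy <- diff(sim$truth$y)[conf_pair]
  s_hat <- sqrt(mean(dx^2 + dy^2) / 4)
  expect_equal(s_hat, 0.0136, tolerance = 0.05)
  # frozen chain: no escape when P_cm = 0
  frz <- simulate_two_state(50, n_steps = 30, D_m = 0.1, P_cm = 0,
                            P_mc = 1, confined = "psf")
  expect_true(all(frz$truth$state == "confined"))
})

test_that("equilibrium simulator conserves molecules, stays in the box and
           is seed-reproducible", {
  w <- sim_world(D_d = 0.6, D_m = 0.2, mobile_ratio = 0.05,
                 mobile_lifetime = 0.1, dt = 1e-3, n_molecules = 500,
                 T_total = 2)
  set.seed(104)
  r1 <- simulate_equilibrium(w)
  expect_length(r1$final$x, 500)
  expect_true(all(r1$final$x >= 0 & r1$final$x < 15))
  expect_true(all(r1$final$y >= 0 & r1$final$y < 30))
  set.seed(104)
  r2 <- simulate_equilibrium(w)
  expect_identical(r1$trace$ef, r2$trace$ef)
  expect_identical(r1$final$x, r2$final$x)
  # confined molecules are stationary when D_c = 0: run with no switching
  # out and all confined
  w0 <- sim_world(D_d = 0, D_m = 0, mobile_ratio = 0.5,
                  mobile_lifetime = 1, dt = 1e-3, n_molecules = 200,
                  T_total = 0.5)
  set.seed(105)
  st <- adaptrack:::init_molecules(w0, 60)
  res <- adaptrack:::particle_sim_cpp(st$x, st$y, st$state, 15, 30,
                                      w0$geometry$disks, 0, 0, 0,
                                      0, 0, 1e-3, 100, 100,
                                      matrix(numeric(0), 0, 3),
                                      matrix(logical(0), 0, 0))
  expect_identical(res$x, st$x)
})

test_that("no-contrast world equilibrates to EF = 1 and the detailed
           balance of switching holds", {
  set.seed(106)
  w <- sim_world(D_d = 0.3, D_m = 0.3, mobile_ratio = 1,
                 mobile_lifetime = NULL, dt = 1e-3, n_molecules = 4000,
                 T_total = 8)
  r <- simulate_equilibrium(w, init = "uniform")
  ss <- steady_state_ef(r, window = 4)
  expect_equal(ss$mean, 1, tolerance = 0.15)
  # long-run mobile fraction of condensed molecules matches eta within 3 sd
  set.seed(107)
  w2 <- sim_world(D_d = 0.6, D_m = 0.1, mobile_ratio = 0.1,
                  mobile_lifetime = 0.1, dt = 5e-4, n_molecules = 3000,
                  T_total = 6)
  r2 <- simulate_equilibrium(w2)
  cond <- region_contains(w2$geometry,
                          cbind(r2$final$x, r2$final$y)) == "condensed"
  n_c <- sum(cond)
  p_hat <- mean(r2$final$state[cond] == 1L)
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / n_c))
})

test_that("steady_state_ef averages the final window and needs a long
           enough trace", {
  const <- data.frame(t = seq(0, 20, 0.1), ef = 60)
  ss <- steady_state_ef(const)
  expect_equal(ss$mean, 60)
  expect_equal(ss$sd, 0)
  ramp <- data.frame(t = seq(0, 100, 0.5), ef = seq(0, 100, 0.5))
  expect_equal(steady_state_ef(ramp, window = 10)$mean, 95, tolerance = 0.01)
  expect_error(steady_state_ef(data.frame(t = 0:5, ef = 1), window = 10),
               "shorter")
})

test_that("sim_world rejects inconsistent configurations", {
  expect_error(sim_world(mobile_ratio = 1, mobile_lifetime = 0.1),
               "no confined state")
  expect_error(sim_world(mobile_ratio = 0.5, mobile_lifetime = 1e-5,
                         dt = 1e-4), "smaller")
})

test_that("switch-walk apparent D scales with the mobile ratio", {
  set.seed(108)
  res <- simulate_switch_walk(D_m = 0.61, P_cm = 0.1,
                              mobile_ratios = c(0.25, 0.5, 0.75, 1),
                              n_particles = 300, T_total = 12)
  # P_m = 1: apparent D equals the mobile-state input
  expect_equal(res$D_apparent[res$mobile_ratio == 1], 0.61,
               tolerance = 0.05)
  # P_m = 0.5: apparent D is about half the mobile-state D
  expect_equal(res$D_apparent[res$mobile_ratio == 0.5], 0.61 / 2,
               tolerance = 0.1)
  # monotone increase across the grid
  expect_true(all(diff(res$D_apparent) > 0))
})

test_that("FRAP with full mobility recovers completely and a fully bleached
           small droplet recovers slowest", {
  set.seed(109)
  cfg <- frap_config(ef = 100, D_d = 1, D_m = 0.01, mobile_ratio = 1,
                     confined_lifetime = Inf, dt = 2e-3,
                     n_molecules = 8000, T_total = 40)
  s <- simulate_frap(cfg, record_every = 0.5)
  pl <- frap_plateau(s, window = 10)
  # ROI 3 bleaches its entire droplet: early recovery is the slowest
  early <- colMeans(s$curve[s$curve$t > 1 & s$curve$t < 5, -1])
  expect_lt(early["roi_3"], early["roi_1"])
  expect_lt(early["roi_3"], early["roi_2"])
  # all-mobile system heads towards full exchange
  expect_gt(pl["roi_1"], 60)
})
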