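# shared fixture builders for the test suite

# displacement magnitudes drawn from the 2D Brownian form
# p(d) = d/(2 D t) exp(-d^2/(4 D t)) (Rayleigh with sigma = sqrt(2 D t))
r_disp <- function(n, D, t) sqrt(2 * D * t) * sqrt(-2 * log(runif(n)))

# two-state Markov label chain with stationary start
r_state_chain <- function(n, P_cm, P_mc) {
  s <- integer(n)
  s[1] <- as.integer(runif(1) < P_cm / (P_cm + P_mc))  # 1 = mobile
  for (t in 2:n) {
    u <- runif(1)
    s[t] <- if (s[t - 1] == 1L) as.integer(u >= P_mc) else as.integer(u < P_cm)
  }
  s
}

# demarcation-consistent two-state track set: L steps drawn below d_b from
# the confined scale, H steps above d_b from the mobile scale, so threshold
# classification recovers the generating chain exactly
sim_classified_tracks <- function(n_tracks, n_steps, P_cm, P_mc,
                                  s_conf = 0.0136, D_m = 0.044,
                                  d_b_nm = 60, t = 0.03) {
  db <- d_b_nm / 1000
  r_trunc <- function(n, scale2, lower, upper) {
    # inverse-cdf sampling of the Rayleigh-form law truncated to (lower, upper)
    Fl <- 1 - exp(-lower^2 / (4 * scale2))
    Fu <- 1 - exp(-upper^2 / (4 * scale2))
    u <- runif(n, Fl, Fu)
    sqrt(-4 * scale2 * log(1 - u))
  }
  rows <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    st <- r_state_chain(n_steps, P_cm, P_mc)
    d <- numeric(n_steps)
    nm <- sum(st == 1L)
    if (nm) d[st == 1L] <- r_trunc(nm, D_m * t, db, Inf)
    if (nm < n_steps) d[st == 0L] <- r_trunc(n_steps - nm, s_conf^2, 0, db)
    th <- runif(n_steps, 0, 2 * pi)
    x <- cumsum(c(0, d * cos(th)))
    y <- cumsum(c(0, d * sin(th)))
    rows[[i]] <- data.frame(track_id = i, frame = 0:n_steps, x = x, y = y)
  }
  track_set(do.call(rbind, rows),
            acquisition = acquisition_params(frame_interval = t))
}

# straight-line constant-speed track (ballistic reference for MSD)
ballistic_track <- function(n_points, step, t = 0.03) {
  track_set(data.frame(track_id = 1L, frame = seq_len(n_points) - 1L,
                       x = step * (seq_len(n_points) - 1L), y = 0),
            acquisition = acquisition_params(frame_interval = t))
}

# discretized standard-normal density histogram on a fine grid
gauss_hist <- function(mean, sd, grid) dnorm(grid, mean, sd)
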