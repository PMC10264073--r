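#' Single Brownian increment
#'
#' Draws 2D Brownian displacement(s): each axis is an independent Gaussian
#' with standard deviation `sqrt(2 * D * dt)`, so the mean square step is
#' `4 * D * dt`.
#'
#' @param D Diffusion coefficient, um^2/s (`>= 0`).
#' @param dt Time step, s (`> 0`).
#' @param n Number of draws.
#' @return `n x 2` matrix of displacements (um).
#' @export
brownian_step <- function(D, dt, n = 1) {
  stopifnot(D >= 0, dt > 0)
  s <- sqrt(2 * D * dt)
  matrix(rnorm(2 * n, sd = s), ncol = 2,
         dimnames = list(NULL, c("dx", "dy")))
}

#' Simulate a homogeneous Brownian localization scene
#'
#' Ground-truth generator for tracker evaluation: molecules appear at uniform
#' random positions and start frames, live for Poisson-distributed lifetimes
#' (mean `mean_lifetime` frames, minimum 1), and diffuse with coefficient
#' `D`. The expected number of tracks is `sigma * area * n_frames /
#' mean_lifetime` so the per-frame localization density is `sigma`.
#'
#' Per-frame displacements are Gaussian with variance `2 * D * t` per axis —
#' identical in distribution to accumulating sub-steps, since the scene has
#' no boundaries (set `n_substeps` to draw the sub-steps explicitly).
#'
#' @param sigma Per-frame localization density, molecules/um^2.
#' @param D Diffusion coefficient, um^2/s.
#' @param n_frames Number of frames over which tracks are born.
#' @param mean_lifetime Mean track lifetime in frames (localizations per
#'   track). Default 3.5.
#' @param box `c(width, height)` of the field of view, um.
#' @param acquisition An [acquisition_params()]; its localization precision
#'   (if nonzero) is added to emitted localizations as Gaussian noise.
#' @param n_substeps Sub-steps per frame interval (default 1; see above).
#' @return List with `truth` (a [track_set()] of true positions, with per
#'   point `id`) and `table` (a [loc_table()] carrying the same `id` column
#'   as ground truth; linking algorithms ignore it).
#' @export
simulate_homogeneous <- function(sigma, D, n_frames, mean_lifetime = 3.5,
                                 box = c(10, 10),
                                 acquisition = acquisition_params(),
                                 n_substeps = 1) {
  stopifnot(sigma > 0, n_frames >= 2, D >= 0)
  area <- box[1] * box[2]
  ntr <- max(1L, round(sigma * area * n_frames / mean_lifetime))
  lens <- pmax(1L, rpois(ntr, mean_lifetime))
  start <- sample.int(n_frames, ntr, replace = TRUE) - 1L
  x0 <- runif(ntr, 0, box[1])
  y0 <- runif(ntr, 0, box[2])
  tfr <- acquisition$frame_interval
  npts <- sum(lens)
  idx <- rep.int(seq_len(ntr), lens)
  within <- sequence(lens)
  sd_fr <- sqrt(2 * D * tfr)
  draw_axis <- function() {
    if (n_substeps > 1) {
      st <- matrix(rnorm(npts * n_substeps, sd = sd_fr / sqrt(n_substeps)),
                   nrow = npts)
      rowSums(st)
    } else rnorm(npts, sd = sd_fr)
  }
  sx <- draw_axis(); sy <- draw_axis()
  sx[within == 1L] <- 0
  sy[within == 1L] <- 0
  cx <- cumsum(sx); cy <- cumsum(sy)
  first <- which(within == 1L)
  x <- x0[idx] + cx - rep.int(cx[first], lens)
  y <- y0[idx] + cy - rep.int(cy[first], lens)
  frame <- start[idx] + within - 1L
  truth <- track_set(data.frame(track_id = idx, frame = frame, x = x, y = y),
                     acquisition = acquisition,
                     provenance = list(generator = "homogeneous", sigma = sigma,
                                       D = D, mean_lifetime = mean_lifetime))
  prec <- acquisition$localization_precision
  if (prec > 0) {
    x <- x + rnorm(npts, sd = prec)
    y <- y + rnorm(npts, sd = prec)
  }
  table <- loc_table(frame, x, y, id = idx, acquisition = acquisition)
  list(truth = truth, table = table)
}

#' Simulate two-state (confined/mobile) tracks
#'
#' Per-frame Markov switching between a confined and a mobile state. Mobile
#' frames advance by Brownian steps with `D_m`. Confined frames either
#' scatter localizations around a fixed anchor with per-axis Gaussian scale
#' `psf_scatter` (emulating point-spread-function jitter of a stationary
#' emitter), or diffuse slowly with `D_c` when `confined` is `"brownian"`.
#' Initial states are drawn from the stationary distribution
#' `P_m = P_cm / (P_cm + P_mc)`.
#'
#' @param n_tracks Number of tracks.
#' @param n_steps Steps per track (scalar, or vector per track); lifetimes
#'   can also be drawn as `pmax(1, rpois(n, lambda))` by the caller.
#' @param D_m Mobile-state diffusion coefficient, um^2/s.
#' @param P_cm,P_mc Per-frame switching probabilities (confined-to-mobile,
#'   mobile-to-confined).
#' @param confined `"psf"` (anchored, PSF-scattered) or `"brownian"`.
#' @param psf_scatter Per-axis confined scatter, um (used for `"psf"`).
#' @param D_c Confined-state diffusion coefficient, um^2/s (for
#'   `"brownian"`).
#' @param box Field of view for uniform start positions, um.
#' @param acquisition An [acquisition_params()].
#' @return List with `truth` (track_set with per-point `state`,
#'   `"confined"`/`"mobile"`: the state that produced the step into each
#'   point) and `table` (loc_table with `id`).
#' @export
simulate_two_state <- function(n_tracks, n_steps, D_m, P_cm, P_mc,
                               confined = c("psf", "brownian"),
                               psf_scatter = 0.0136, D_c = 0.0127,
                               box = c(20, 20),
                               acquisition = acquisition_params()) {
  confined <- match.arg(confined)
  stopifnot(P_cm >= 0, P_cm <= 1, P_mc >= 0, P_mc <= 1)
  tfr <- acquisition$frame_interval
  lens <- rep_len(as.integer(n_steps) + 1L, n_tracks)  # points per track
  tmax <- max(lens)
  pm0 <- if (P_cm + P_mc > 0) P_cm / (P_cm + P_mc) else 0
  # state matrices: TRUE = mobile; column t is the state during frame t
  st <- matrix(FALSE, n_tracks, tmax)
  st[, 1] <- runif(n_tracks) < pm0
  for (t in 2:tmax) {
    u <- runif(n_tracks)
    st[, t] <- ifelse(st[, t - 1], u >= P_mc, u < P_cm)
  }
  sd_m <- sqrt(2 * D_m * tfr)
  sd_c <- sqrt(2 * D_c * tfr)
  x <- matrix(NA_real_, n_tracks, tmax)
  y <- matrix(NA_real_, n_tracks, tmax)
  x[, 1] <- runif(n_tracks, 0, box[1])
  y[, 1] <- runif(n_tracks, 0, box[2])
  if (confined == "brownian") {
    for (t in 2:tmax) {
      s <- ifelse(st[, t], sd_m, sd_c)
      x[, t] <- x[, t - 1] + rnorm(n_tracks, sd = s)
      y[, t] <- y[, t - 1] + rnorm(n_tracks, sd = s)
    }
    lx <- x; ly <- y
  } else {
    # anchor-based: position only advances during mobile frames;
    # confined localizations scatter about the anchor
    ax <- x[, 1]; ay <- y[, 1]
    lx <- x; ly <- y
    lx[, 1] <- ax + rnorm(n_tracks, sd = psf_scatter) * !st[, 1]
    ly[, 1] <- ay + rnorm(n_tracks, sd = psf_scatter) * !st[, 1]
    for (t in 2:tmax) {
      mob <- st[, t]
      ax <- ax + ifelse(mob, rnorm(n_tracks, sd = sd_m), 0)
      ay <- ay + ifelse(mob, rnorm(n_tracks, sd = sd_m), 0)
      lx[, t] <- ax + ifelse(mob, 0, rnorm(n_tracks, sd = psf_scatter))
      ly[, t] <- ay + ifelse(mob, 0, rnorm(n_tracks, sd = psf_scatter))
      x[, t] <- ax; y[, t] <- ay
    }
  }
  keep <- sequence(lens)
  idx <- rep.int(seq_len(n_tracks), lens)
  sel <- cbind(idx, keep)
  frame <- keep - 1L
  state <- ifelse(st[sel], "mobile", "confined")
  truth <- track_set(data.frame(track_id = idx, frame = frame,
                                x = lx[sel], y = ly[sel], state = state),
                     acquisition = acquisition,
                     provenance = list(generator = "two_state", D_m = D_m,
                                       P_cm = P_cm, P_mc = P_mc,
                                       confined = confined))
  table <- loc_table(frame, lx[sel], ly[sel], id = idx,
                     acquisition = acquisition)
  list(truth = truth, table = table)
}

#' Motion-switch random walk: apparent D versus mobile ratio
#'
#' Particles switch between an immobile confined state and a mobile Brownian
#' state once per frame; for each requested mobile ratio `P_m` the
#' mobile-to-confined probability is set by detailed balance
#' `P_mc = P_cm * (1 - P_m) / P_m`. The apparent diffusion coefficient is
#' obtained from a linear (alpha = 1) MSD fit.
#'
#' @param D_m Mobile-state diffusion coefficient, um^2/s (default 0.61).
#' @param P_cm Per-frame confined-to-mobile probability (default 0.1).
#' @param mobile_ratios Grid of mobile ratios in (0, 1].
#' @param n_particles Particles per condition (default 500).
#' @param T_total Duration, s (default 100).
#' @param acquisition An [acquisition_params()].
#' @param max_lag Number of MSD lags fitted (default 10).
#' @return `data.frame` with `mobile_ratio`, `D_apparent`, plus the MSD
#'   curves as attribute `"msd"`.
#' @export
simulate_switch_walk <- function(D_m = 0.61, P_cm = 0.1,
                                 mobile_ratios = seq(0.1, 0.9, by = 0.1),
                                 n_particles = 500, T_total = 100,
                                 acquisition = acquisition_params(),
                                 max_lag = 10) {
  stopifnot(all(mobile_ratios > 0), all(mobile_ratios <= 1))
  tfr <- acquisition$frame_interval
  nfr <- max(2L, floor(T_total / tfr))
  res <- lapply(mobile_ratios, function(pm) {
    p_mc <- if (pm < 1) P_cm * (1 - pm) / pm else 0
    sim <- simulate_two_state(n_particles, nfr - 1L, D_m = D_m,
                              P_cm = P_cm, P_mc = min(1, p_mc),
                              confined = "brownian", D_c = 0,
                              acquisition = acquisition)
    curve <- msd(sim$truth, max_lag = max_lag)
    fit <- fit_msd(curve, model = "linear")
    list(D = fit$D, msd = curve)
  })
  out <- data.frame(mobile_ratio = mobile_ratios,
                    D_apparent = vapply(res, `[[`, numeric(1), "D"))
  attr(out, "msd") <- lapply(res, `[[`, "msd")
  out
}

#' Simulate a two-phase condensate localization scene
#'
#' End-to-end synthetic scene: condensed regions (geometry) hold a two-state
#' population (confined/mobile) at per-frame localization density
#' `sigma_d * ef`; the dilute background diffuses freely with `D_d` at
#' density `sigma_d`. Track births are placed according to the phase
#' densities; per-frame motion uses the region at the step's start to select
#' the diffusion rule, and molecules entering the condensed phase become
#' eligible for confinement at the next frame. Defaults follow the kinetic
#' consistency `ef = D_d / (P_m * D_m)` so the configured densities are
#' stationary.
#'
#' @param geometry Condensed-region `region_geometry` (disks recommended).
#' @param box `c(width, height)` um.
#' @param sigma_d Dilute per-frame localization density, /um^2.
#' @param ef Enrichment fold (condensed density = `ef * sigma_d`).
#' @param D_d Dilute diffusion coefficient, um^2/s.
#' @param D_m,D_c Condensed mobile / apparent confined diffusion
#'   coefficients.
#' @param P_cm,P_mc Per-frame switching probabilities in the condensed phase.
#' @param confined `"psf"` (default): confined molecules are anchored and
#'   their localizations scatter with per-axis scale `sqrt(D_c * t)`
#'   (equivalent in displacement distribution to Brownian motion at `D_c`,
#'   but anchored molecules cannot drift across the phase boundary — the
#'   flux balance behind `ef = D_d / (P_m * D_m)` counts only mobile-state
#'   exchange). `"brownian"`: confined molecules truly diffuse at `D_c`.
#' @param n_frames Number of frames.
#' @param mean_lifetime Mean Poisson track lifetime, frames.
#' @param acquisition An [acquisition_params()].
#' @return List with `truth` ([track_set()] with per-point `phase` and
#'   `state`) and `table` ([loc_table()] with `id`).
#' @export
simulate_condensate_scene <- function(geometry = NULL, box = c(24, 24),
                                      sigma_d = 0.005, ef = 62.8,
                                      D_d = 0.47, D_m = 0.17, D_c = 0.0127,
                                      P_cm = 0.038, P_mc = 0.828,
                                      confined = c("psf", "brownian"),
                                      n_frames = 4000, mean_lifetime = 3.5,
                                      acquisition = acquisition_params()) {
  confined <- match.arg(confined)
  if (is.null(geometry))
    geometry <- disk_geometry(
      cx = c(4, 12, 20, 4, 11.5, 19, 5, 12, 20, 16, 8, 16.5),
      cy = c(4, 3.5, 4, 12, 11, 12, 19, 20, 19.5, 7, 7.5, 16),
      r = c(0.7, 0.55, 0.6, 0.5, 0.75, 0.45, 0.6, 0.5, 0.65, 0.4,
            0.45, 0.5))
  tfr <- acquisition$frame_interval
  a_c <- region_area(geometry)
  a_d <- box[1] * box[2] - a_c
  sigma_c <- sigma_d * ef
  ntr <- max(1L, round((sigma_c * a_c + sigma_d * a_d) * n_frames /
                         mean_lifetime))
  p_cond <- sigma_c * a_c / (sigma_c * a_c + sigma_d * a_d)
  lens <- pmax(1L, rpois(ntr, mean_lifetime))
  start <- sample.int(n_frames, ntr, replace = TRUE) - 1L
  born_cond <- runif(ntr) < p_cond
  pm0 <- if (P_cm + P_mc > 0) P_cm / (P_cm + P_mc) else 1
  n_c0 <- sum(born_cond)
  xy <- matrix(NA_real_, ntr, 2)
  if (n_c0 > 0) xy[born_cond, ] <- sample_in_geometry(geometry, n_c0)
  if (n_c0 < ntr)
    xy[!born_cond, ] <- sample_outside_geometry(geometry, box, ntr - n_c0)
  state0 <- ifelse(born_cond, as.integer(runif(ntr) < pm0), 1L)
  n_sub <- max(1L, round(tfr / 1e-4))  # motion integrated at ~0.1 ms
  pr <- propagate_scene_cpp(xy[, 1], xy[, 2], state0, lens,
                            geometry$disks, D_d, D_m, D_c, P_cm, P_mc,
                            tfr, n_sub, confined == "psf",
                            sqrt(D_c * tfr))
  idx <- rep.int(seq_len(ntr), lens)
  df <- data.frame(track_id = idx,
                   frame = start[idx] + sequence(lens) - 1L,
                   x = pr$x, y = pr$y,
                   phase = ifelse(pr$condensed == 1, "condensed", "dilute"),
                   state = ifelse(pr$state == 1, "mobile", "confined"))
  truth <- track_set(df, acquisition = acquisition,
                     provenance = list(generator = "condensate_scene",
                                       ef = ef, D_d = D_d, D_m = D_m,
                                       D_c = D_c, P_cm = P_cm, P_mc = P_mc))
  # only localizations inside the field of view are detected
  fov <- df$x >= 0 & df$x <= box[1] & df$y >= 0 & df$y <= box[2]
  table <- loc_table(df$frame[fov], df$x[fov], df$y[fov],
                     id = df$track_id[fov], acquisition = acquisition)
  list(truth = truth, table = table, geometry = geometry, box = box)
}

# uniform sample inside disk/mask geometry
sample_in_geometry <- function(geometry, n) {
  if (geometry$type == "disks") {
    d <- geometry$disks
    w <- d[, "r"]^2
    k <- sample.int(nrow(d), n, replace = TRUE, prob = w)
    rr <- d[k, "r"] * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cbind(d[k, "cx"] + rr * cos(th), d[k, "cy"] + rr * sin(th))
  } else stop("sampling implemented for disk geometry")
}

sample_outside_geometry <- function(geometry, box, n) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(16L, 2L * (n - nrow(out)))
    p <- cbind(runif(m, 0, box[1]), runif(m, 0, box[2]))
    keep <- region_contains(geometry, p) == "dilute"
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
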