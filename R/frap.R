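#' Default droplet geometry for the FRAP simulation
#'
#' Seven circular condensed droplets in a 20 x 8 um periodic box: radii
#' 0.5/1/1/2/1/1/0.5 um at x = 1/3/5/10/15/17/19 um, centred at mid-height.
#'
#' @return A disk `region_geometry`.
#' @export
default_frap_droplets <- function() {
  disk_geometry(cx = c(1, 3, 5, 10, 15, 17, 19), cy = rep(4, 7),
                r = c(0.5, 1, 1, 2, 1, 1, 0.5))
}

#' FRAP simulation configuration
#'
#' @param droplets Condensed-region disk geometry.
#' @param box `c(width, height)` um (periodic).
#' @param rois `n x 3` matrix (cx, cy, r) of bleach regions, um. Default:
#'   0.5-um-radius ROIs centred in the 2, 1 and 0.5 um radius droplets.
#' @param ef Enrichment fold the system is pre-equilibrated to.
#' @param D_d,D_m,D_c Diffusion coefficients, um^2/s.
#' @param mobile_ratio Condensed-phase mobile fraction.
#' @param confined_lifetime Mean confined dwell time, s; `Inf` means
#'   permanently immobilized (both switching probabilities zero).
#' @param dt Integration step, s.
#' @param n_molecules Number of molecules.
#' @param T_total Post-bleach duration, s.
#' @return Object of class `frap_config`.
#' @export
frap_config <- function(droplets = default_frap_droplets(), box = c(20, 8),
                        rois = NULL, ef = 100, D_d = 1, D_m = 0.1, D_c = 0,
                        mobile_ratio = 0.1, confined_lifetime = Inf,
                        dt = 1e-4, n_molecules = 50000, T_total = 100) {
  if (is.null(rois))
    rois <- cbind(cx = c(10, 3, 1), cy = c(4, 4, 4), r = 0.5)
  stopifnot(all(rois[, 3] > 0), mobile_ratio > 0, mobile_ratio <= 1)
  if (any(rois[, 1] < 0 | rois[, 1] > box[1] |
          rois[, 2] < 0 | rois[, 2] > box[2]))
    stop("bleach ROI centre outside the simulation box")
  if (is.infinite(confined_lifetime)) {
    P_cm <- 0; P_mc <- 0
  } else {
    P_cm <- dt / confined_lifetime
    P_mc <- P_cm * (1 - mobile_ratio) / mobile_ratio
  }
  structure(list(droplets = droplets, box = box, rois = rois, ef = ef,
                 D_d = D_d, D_m = D_m, D_c = D_c,
                 mobile_ratio = mobile_ratio,
                 confined_lifetime = confined_lifetime, dt = dt,
                 n_molecules = as.integer(n_molecules), T_total = T_total,
                 P_cm = P_cm, P_mc = P_mc),
            class = "frap_config")
}

#' Simulate fluorescence recovery after photo-bleaching
#'
#' Molecules are placed at the configured enrichment with condensed-phase
#' states drawn at the stationary mobile ratio, every molecule inside a
#' bleach ROI at time zero is flagged bleached with respect to that ROI, and
#' the ensemble then evolves under the two-phase/two-state dynamics. The
#' recovery of ROI `j` is the unbleached count inside it, normalized to the
#' pre-bleach occupancy (100%) — it starts at 0% by construction. Bleaching
#' does not alter the dynamics, so all ROIs are evaluated on the same
#' trajectory ensemble.
#'
#' @param config A [frap_config()].
#' @param record_every Curve sampling interval, s.
#' @return List of class `frap_sim` with `curve` (`data.frame` `t` plus one
#'   `roi_k` column per ROI, percent recovery), `pre_counts`, `config`.
#' @export
simulate_frap <- function(config, record_every = 0.1) {
  stopifnot(inherits(config, "frap_config"))
  world <- structure(list(box = config$box, geometry = config$droplets,
                          mobile_ratio = config$mobile_ratio,
                          n_molecules = config$n_molecules),
                     class = "sim_world")
  st <- init_molecules(world, config$ef)
  rois <- config$rois
  nroi <- nrow(rois)
  bleached <- matrix(FALSE, config$n_molecules, nroi)
  for (j in seq_len(nroi)) {
    dx <- st$x - rois[j, 1]; dy <- st$y - rois[j, 2]
    bleached[, j] <- dx * dx + dy * dy <= rois[j, 3]^2
  }
  pre <- colSums(bleached)
  if (any(pre == 0)) stop("a bleach ROI contains no molecules")
  n_steps <- round(config$T_total / config$dt)
  rec <- max(1L, round(record_every / config$dt))
  res <- particle_sim_cpp(st$x, st$y, st$state, config$box[1], config$box[2],
                          config$droplets$disks, config$D_d, config$D_m,
                          config$D_c, config$P_cm, config$P_mc, config$dt,
                          n_steps, rec, rois, bleached)
  curve <- data.frame(t = res$t)
  for (j in seq_len(nroi))
    curve[[paste0("roi_", j)]] <- 100 * res$roi_unbleached[, j] / pre[j]
  structure(list(curve = curve, pre_counts = pre, config = config),
            class = "frap_sim")
}

#' Plateau recovery level of simulated FRAP curves
#'
#' @param sim A `frap_sim`.
#' @param window Averaging window over the end of the curve, s.
#' @return Named numeric vector, percent recovery per ROI.
#' @export
frap_plateau <- function(sim, window = 10) {
  cv <- sim$curve
  sel <- cv$t > max(cv$t) - window
  vapply(cv[sel, -1, drop = FALSE], mean, numeric(1))
}
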