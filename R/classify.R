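#' Condensed-phase tracks eligible for step classification
#'
#' Keeps tracks that lie entirely within the condensed phase and have at
#' least `min_steps` consecutive-frame steps.
#'
#' @param tracks A [track_set()].
#' @param map Optional [phase_map()]/geometry to (re)label phases.
#' @param min_steps Minimum steps per track. Default 10 (11 positions).
#' @return A filtered [track_set()].
#' @export
eligible_tracks <- function(tracks, map = NULL, min_steps = 10) {
  tracks_in_phase(tracks, "condensed", map, min_steps)
}

#' Tracks lying entirely within one phase
#'
#' @param tracks A [track_set()].
#' @param phase `"condensed"` or `"dilute"`.
#' @param map Optional [phase_map()]/geometry to (re)label phases.
#' @param min_steps Minimum consecutive-frame steps per track.
#' @return A filtered [track_set()].
#' @export
tracks_in_phase <- function(tracks, phase, map = NULL, min_steps = 1) {
  steps <- track_steps(tracks, map)
  empty <- {
    out <- tracks[0, , drop = FALSE]
    attr(out, "acquisition") <- attr(tracks, "acquisition")
    class(out) <- class(tracks)
    out
  }
  if (!nrow(steps)) return(empty)
  if (is.null(steps$step_phase))
    steps$step_phase <- phase  # single-phase input: all eligible
  by_tr <- split(steps$step_phase, steps$track_id)
  keep <- names(by_tr)[vapply(by_tr, function(p)
    length(p) >= min_steps && all(p == phase), logical(1))]
  out <- tracks[as.character(tracks$track_id) %in% keep, , drop = FALSE]
  attr(out, "acquisition") <- attr(tracks, "acquisition")
  class(out) <- class(tracks)
  out
}

# consecutive displacement pairs (d_i, d_{i+1}) within tracks
displacement_pairs <- function(tracks) {
  segs <- track_displacement_sequences(tracks, min_steps = 2)
  if (!length(segs)) stop("no track with >= 2 consecutive steps")
  di <- unlist(lapply(segs, function(d) d[-length(d)]))
  dj <- unlist(lapply(segs, function(d) d[-1]))
  cbind(d_i = di, d_next = dj)
}

#' Conditional next-step displacement distributions
#'
#' Splits consecutive step pairs `(d_i, d_{i+1})` by whether `d_i` falls
#' below or above the demarcation `d_b`, and histograms `d_{i+1}` for each
#' condition on a common 5 nm grid. Under simple Brownian diffusion the two
#' conditionals coincide; a two-state process separates them.
#'
#' @param tracks A [track_set()] of condensed-phase tracks (see
#'   [eligible_tracks()]).
#' @param d_b Demarcation, nm. If it collides with an observed displacement
#'   it is perturbed by half a bin.
#' @param binwidth Histogram bin, nm. Default 5.
#' @return Object of class `conditional_dists`: `d_b` (nm), `mids` (nm),
#'   densities `P_low`, `P_high` (per nm), counts `n_low`, `n_high`, and a
#'   `low_power` flag when either condition has fewer than 100 pairs.
#' @export
conditional_dists <- function(tracks, d_b, binwidth = 5) {
  pr <- displacement_pairs(tracks) * 1000  # nm
  if (any(pr[, "d_i"] == d_b)) d_b <- d_b + binwidth / 2
  lo <- pr[, "d_i"] < d_b
  dmax <- max(pr[, "d_next"])
  breaks <- seq(0, dmax + binwidth, by = binwidth)
  h_lo <- hist(pr[lo, "d_next"], breaks = breaks, plot = FALSE)
  h_hi <- hist(pr[!lo, "d_next"], breaks = breaks, plot = FALSE)
  structure(list(d_b = d_b, mids = h_lo$mids,
                 P_low = h_lo$density, P_high = h_hi$density,
                 n_low = sum(lo), n_high = sum(!lo), binwidth = binwidth,
                 low_power = min(sum(lo), sum(!lo)) < 100),
            class = "conditional_dists")
}

#' Overlap coefficient of two distributions
#'
#' `OVL = integral of min(P, Q)`, computed on a common histogram grid as
#' `sum(pmin(P, Q)) * binwidth`. Symmetric, 1 for identical distributions,
#' 0 for disjoint supports.
#'
#' @param P,Q Density vectors on a common grid (or a `conditional_dists`,
#'   in which case `Q` is ignored).
#' @param binwidth Grid bin width (matching the densities' unit).
#' @return Overlap in `[0, 1]`.
#' @export
ovl <- function(P, Q = NULL, binwidth = NULL) {
  if (inherits(P, "conditional_dists")) {
    binwidth <- P$binwidth
    Q <- P$P_high
    P <- P$P_low
  }
  if (length(P) != length(Q)) stop("distributions must share a common grid")
  stopifnot(!is.null(binwidth))
  sum(pmin(P, Q)) * binwidth
}

#' Scan demarcation values for maximal state separation
#'
#' Computes the overlap coefficient between the low- and high-condition
#' next-step distributions across a grid of demarcations. Because the
#' empirical OVL of finite histograms is biased below 1 by an amount that
#' grows as a condition's pair count shrinks, the observed OVL at each
#' demarcation is calibrated against a permutation null (the conditioning
#' displacements shuffled across pairs, destroying the step-to-step
#' correlation while preserving both counts): the separation signal is
#' `ovl_null - ovl`, and the selected demarcation maximizes it. A signal
#' below `flat_tol` everywhere indicates no two-state structure (as for
#' simple Brownian motion, whose consecutive steps are independent) and
#' yields a null demarcation. Demarcations leaving a condition with fewer
#' than 100 pairs are excluded.
#'
#' @param tracks Condensed-phase [track_set()].
#' @param grid Demarcation grid, nm. Default 10-200 nm in 10 nm steps.
#' @param binwidth Histogram bin, nm.
#' @param z_threshold Structure is declared when the separation exceeds
#'   `z_threshold` permutation-null standard deviations somewhere on the
#'   grid. Default 4.
#' @param n_perm Permutations per demarcation (null mean and sd).
#'   Default 8.
#' @return List with `d_b_star` (nm or `NA`), `curve`
#'   (`data.frame(d_b, ovl, ovl_null, separation, z, low_power)`), `flat`.
#' @export
scan_demarcation <- function(tracks, grid = seq(10, 200, by = 10),
                             binwidth = 5, z_threshold = 4, n_perm = 8) {
  pr <- displacement_pairs(tracks) * 1000  # nm
  cond_ovl <- function(d_i, d_next, db) {
    if (any(d_i == db)) db <- db + binwidth / 2
    lo <- d_i < db
    n_lo <- sum(lo)
    if (min(n_lo, length(d_i) - n_lo) < 100) return(NA_real_)
    breaks <- seq(0, max(d_next) + binwidth, by = binwidth)
    h_lo <- hist(d_next[lo], breaks = breaks, plot = FALSE)$density
    h_hi <- hist(d_next[!lo], breaks = breaks, plot = FALSE)$density
    sum(pmin(h_lo, h_hi)) * binwidth
  }
  ovls <- vapply(grid, function(db)
    cond_ovl(pr[, "d_i"], pr[, "d_next"], db), numeric(1))
  perms <- vapply(seq_len(n_perm), function(k) {
    di <- sample(pr[, "d_i"])
    vapply(grid, function(db) cond_ovl(di, pr[, "d_next"], db), numeric(1))
  }, numeric(length(grid)))
  perms <- matrix(perms, nrow = length(grid))
  nulls <- rowMeans(perms)
  null_sd <- apply(perms, 1, sd)
  sep <- nulls - ovls
  z <- sep / pmax(null_sd, 1e-6)
  curve <- data.frame(d_b = grid, ovl = ovls, ovl_null = nulls,
                      separation = sep, z = z, low_power = is.na(ovls))
  ok <- !is.na(sep)
  if (!any(ok))
    return(list(d_b_star = NA_real_, curve = curve, flat = NA))
  flat <- max(z[ok]) < z_threshold
  list(d_b_star = if (flat) NA_real_ else grid[ok][which.max(sep[ok])],
       curve = curve, flat = flat)
}

#' Classify displacement steps into low/high mobility states
#'
#' Step `i` is labelled `L` (low mobility, confined-like) if `d_i < d_b`,
#' else `H`. The confinement and mobile ratios are the label fractions;
#' switching frequencies come from transition counts within tracks:
#' `P_mc = #(H followed by L) / #(H followed by anything)` and vice versa.
#'
#' @param tracks Condensed-phase [track_set()].
#' @param d_b Demarcation, nm.
#' @return Object of class `classification_result`: `d_b`, per-step
#'   `labels` (per track), `P_c`, `P_m`, `P_cm`, `P_mc`, counts, and the
#'   step magnitudes per label (`d_L`, `d_H`, um).
#' @export
classify_steps <- function(tracks, d_b) {
  stopifnot(d_b > 0)
  segs <- track_displacement_sequences(tracks, min_steps = 1)
  if (!length(segs)) stop("no consecutive-frame steps to classify")
  db_um <- d_b / 1000
  labs <- lapply(segs, function(d) ifelse(d < db_um, "L", "H"))
  all_lab <- unlist(labs)
  n_L <- sum(all_lab == "L")
  n_H <- sum(all_lab == "H")
  trans <- table(factor(unlist(lapply(labs, function(l) l[-length(l)])),
                        levels = c("L", "H")),
                 factor(unlist(lapply(labs, function(l) l[-1])),
                        levels = c("L", "H")))
  P_cm <- if (sum(trans["L", ]) > 0) trans["L", "H"] / sum(trans["L", ]) else 0
  P_mc <- if (sum(trans["H", ]) > 0) trans["H", "L"] / sum(trans["H", ]) else 0
  d_all <- unlist(segs)
  structure(list(d_b = d_b, labels = labs,
                 P_c = n_L / (n_L + n_H), P_m = n_H / (n_L + n_H),
                 P_cm = unname(P_cm), P_mc = unname(P_mc),
                 n_L = n_L, n_H = n_H, transitions = trans,
                 d_L = d_all[all_lab == "L"], d_H = d_all[all_lab == "H"]),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(paste0("<classification> d_b = %g nm: P_c = %.1f%%,",
                     " P_m = %.1f%% (%d L / %d H steps)\n",
                     "  P_cm = %.3g, P_mc = %.3g per frame\n"),
              x$d_b, 100 * x$P_c, 100 * x$P_m, x$n_L, x$n_H,
              x$P_cm, x$P_mc))
  invisible(x)
}

# ML scale fit for p(d) = d/(2 s^2) exp(-d^2/(4 s^2)), optionally truncated
# to d < ub or d > lb (classification cuts the support at d_b).
fit_rayleigh_scale_ml <- function(d, lb = 0, ub = Inf) {
  s0 <- sqrt(sum(d^2) / (4 * length(d)))
  if (lb <= 0 && is.infinite(ub)) return(s0)
  nll <- function(ls) {
    s2 <- exp(2 * ls)
    ll <- sum(log(d) - log(2 * s2) - d^2 / (4 * s2))
    mass <- exp(-lb^2 / (4 * s2)) - if (is.finite(ub))
      exp(-ub^2 / (4 * s2)) else 0
    ll - length(d) * log(max(mass, 1e-300))
  }
  opt <- optimize(function(ls) -nll(ls),
                  interval = log(s0) + c(-4, 4), tol = 1e-10)
  exp(opt$minimum)
}

#' Fit the classified L and H displacement components
#'
#' The L component is fitted by the detection-error form with per-axis
#' scale `s` (`s^2 = D_L * t`); the H component by a 2D Brownian
#' distribution giving `D_H`. Fits are maximum likelihood and account for
#' the truncation of each component's support at the demarcation
#' (`truncated = FALSE` fits the plain distributions, appropriate for
#' un-truncated samples). Optionally, a one-sided heavy-tailed (Levy-type,
#' stability 1/2) alternative is fitted to the H component and compared by
#' AIC as a diagnostic.
#'
#' @param result A [classify_steps()] result.
#' @param t Frame interval, s.
#' @param truncated Account for the `d_b` cut. Default `TRUE`.
#' @param heavy_tail Also fit the Levy-type alternative. Default `FALSE`.
#' @return List with `s_L` (nm), `D_L` (um^2/s), `D_H` (um^2/s), component
#'   sizes, and (optionally) `levy` with scale and delta-AIC versus
#'   Brownian.
#' @export
fit_components <- function(result, t, truncated = TRUE, heavy_tail = FALSE) {
  stopifnot(inherits(result, "classification_result"))
  if (!length(result$d_L) || !length(result$d_H))
    stop("both components must be non-empty")
  db_um <- result$d_b / 1000
  s_L <- fit_rayleigh_scale_ml(result$d_L,
                               ub = if (truncated) db_um else Inf)
  s_H <- fit_rayleigh_scale_ml(result$d_H,
                               lb = if (truncated) db_um else 0)
  out <- list(s_L = 1000 * s_L, D_L = s_L^2 / t, D_H = s_H^2 / t,
              n_L = length(result$d_L), n_H = length(result$d_H))
  if (heavy_tail) {
    d <- result$d_H
    c_hat <- length(d) / sum(1 / d)  # ML scale of the alpha = 1/2 Levy law
    ll_levy <- sum(0.5 * log(c_hat / (2 * pi)) - 1.5 * log(d) -
                     c_hat / (2 * d))
    ll_ray <- sum(log(d) - log(2 * s_H^2) - d^2 / (4 * s_H^2))
    out$levy <- list(scale = c_hat, dAIC_vs_brownian = 2 * (ll_ray - ll_levy))
  }
  out
}
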