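#' Step displacement magnitudes of a track set
#'
#' One displacement per consecutive-frame step, optionally filtered by step
#' phase, with a histogram at 5 nm bins.
#'
#' @param tracks A [track_set()].
#' @param phase Optional filter: `"condensed"`, `"dilute"` or `"crossing"`.
#' @param map Optional [phase_map()]/geometry used to (re)label phases.
#' @param binwidth Histogram bin width, um. Default 0.005 (5 nm).
#' @return List with sorted `d` (um), `mids`, `counts`, `density` and
#'   `binwidth`.
#' @export
displacement_magnitudes <- function(tracks, phase = NULL, map = NULL,
                                    binwidth = 0.005) {
  steps <- track_steps(tracks, map)
  d <- if (is.null(phase)) steps$d
       else steps$d[!is.null(steps$step_phase) & steps$step_phase == phase]
  if (!length(d)) stop("no displacements in the selected phase")
  d <- sort(d)
  breaks <- seq(0, max(d) + binwidth, by = binwidth)
  h <- hist(d, breaks = breaks, plot = FALSE)
  list(d = d, mids = h$mids, counts = h$counts, density = h$density,
       binwidth = binwidth)
}

#' Fit a single-population 2D Brownian displacement distribution
#'
#' Nonlinear least-squares fit of the binned displacement histogram to
#' `n * binwidth * d/(2 D t) * exp(-d^2 / (4 D t))`, plus the closed-form
#' moment estimator `sum(d^2) / (4 n t)`. Falls back (flagged) to the
#' moment estimator when the fit does not converge.
#'
#' @param displacements Step magnitudes, um (`>= 50`).
#' @param t Frame interval, s.
#' @param binwidth Histogram bin width, um.
#' @return List with `D`, `se`, `r2`, `rmse`, `D_moment`, `converged`.
#' @export
fit_rayleigh <- function(displacements, t, binwidth = 0.005) {
  if (length(displacements) < 50) stop("too few displacements (need >= 50)")
  n <- length(displacements)
  D_mom <- sum(displacements^2) / (4 * n * t)
  if (D_mom == 0)
    return(list(D = 0, se = 0, r2 = NA_real_, rmse = 0, D_moment = 0,
                converged = TRUE))
  breaks <- seq(0, max(displacements) + binwidth, by = binwidth)
  h <- hist(displacements, breaks = breaks, plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)
  model <- count ~ n * binwidth * mid / (2 * D * t) * exp(-mid^2 / (4 * D * t))
  fit <- tryCatch(
    minpack.lm::nlsLM(model, data = df, start = list(D = D_mom),
                      lower = 1e-12,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- n * binwidth * df$mid / (2 * D_mom * t) *
      exp(-df$mid^2 / (4 * D_mom * t))
    return(list(D = D_mom, se = NA_real_,
                r2 = 1 - sum((df$count - pred)^2) /
                  sum((df$count - mean(df$count))^2),
                rmse = sqrt(mean((df$count - pred)^2)),
                D_moment = D_mom, converged = FALSE))
  }
  pred <- predict(fit)
  list(D = coef(fit)[["D"]], se = summary(fit)$coefficients["D", "Std. Error"],
       r2 = 1 - sum((df$count - pred)^2) / sum((df$count - mean(df$count))^2),
       rmse = sqrt(mean((df$count - pred)^2)),
       D_moment = D_mom, converged = TRUE)
}

#' Time-averaged mean square displacement
#'
#' `MSD(l * t)` is the mean over all eligible (track, start) pairs of the
#' squared displacement at lag `l` frames. Overlapping windows are used by
#' default; pairs spanning frame gaps are excluded.
#'
#' @param tracks A [track_set()].
#' @param max_lag Maximum lag, frames.
#' @param overlapping Use overlapping time-average windows (default) or
#'   stride-`l` non-overlapping windows.
#' @return `data.frame(lag, t, msd, n)`.
#' @export
msd <- function(tracks, max_lag = 10, overlapping = TRUE) {
  tfr <- attr(tracks, "acquisition")$frame_interval
  df <- as.data.frame(tracks)
  by_tr <- split(df[c("frame", "x", "y")], df$track_id)
  acc_s <- numeric(max_lag)
  acc_n <- integer(max_lag)
  for (tr in by_tr) {
    np <- nrow(tr)
    if (np < 2) next
    for (l in seq_len(min(max_lag, np - 1))) {
      i <- if (overlapping) seq_len(np - l) else seq(1, np - l, by = l)
      ok <- tr$frame[i + l] - tr$frame[i] == l
      if (!any(ok)) next
      sq <- (tr$x[i + l] - tr$x[i])^2 + (tr$y[i + l] - tr$y[i])^2
      acc_s[l] <- acc_s[l] + sum(sq[ok])
      acc_n[l] <- acc_n[l] + sum(ok)
    }
  }
  if (!any(acc_n > 0)) stop("no track long enough for the requested lags")
  keep <- acc_n > 0
  data.frame(lag = seq_len(max_lag)[keep], t = seq_len(max_lag)[keep] * tfr,
             msd = acc_s[keep] / acc_n[keep], n = acc_n[keep])
}

#' Fit an MSD curve
#'
#' Linear model `MSD = 4 D t` (least squares through the origin) or the
#' subdiffusive model `MSD = 4 D_alpha t^alpha` via log-log linear
#' regression (`alpha` = slope). Nonpositive MSD values are excluded
#' (flagged) from the log-log fit.
#'
#' @param curve Output of [msd()] (or `data.frame(t, msd)`).
#' @param model `"linear"` or `"anomalous"`.
#' @param n_lags Number of initial lag points fitted. Default 10.
#' @return Object of class `msd_fit`: for linear, `D`; for anomalous,
#'   `D_alpha` and `alpha`; plus `r2` and the points used.
#' @export
fit_msd <- function(curve, model = c("linear", "anomalous"), n_lags = 10) {
  model <- match.arg(model)
  cv <- head(curve[order(curve$t), ], n_lags)
  if (nrow(cv) < 4) stop("need at least 4 lag points")
  if (model == "linear") {
    fit <- lm(msd ~ t + 0, data = cv)
    out <- list(model = "linear", D = unname(coef(fit)[1]) / 4,
                r2 = suppressWarnings(summary(fit)$r.squared), points = cv)
  } else {
    ok <- cv$msd > 0
    fit <- lm(log(msd) ~ log(t), data = cv[ok, ])
    out <- list(model = "anomalous",
                alpha = unname(coef(fit)[2]),
                D_alpha = exp(unname(coef(fit)[1])) / 4,
                r2 = suppressWarnings(summary(fit)$r.squared),
                excluded = sum(!ok), points = cv)
  }
  structure(out, class = "msd_fit")
}

#' Kinetic prediction of the equilibrium enrichment fold
#'
#' `EF = D_d / (P_m * D_m)`: flux balance across the phase boundary between
#' the dilute phase (density sigma_d, diffusivity D_d) and the mobile
#' fraction of the condensed phase (fraction P_m at diffusivity D_m)
#' requires `sigma_c * P_m * D_m = sigma_d * D_d`.
#'
#' @param D_d Dilute-phase diffusion coefficient, um^2/s.
#' @param D_m Condensed-phase mobile-state diffusion coefficient, um^2/s.
#' @param P_m Mobile ratio, in (0, 1].
#' @return Enrichment fold.
#' @export
ef_from_kinetics <- function(D_d, D_m, P_m) {
  stopifnot(D_d > 0, D_m > 0)
  if (P_m <= 0) stop("EF is undefined for a zero mobile ratio")
  D_d / (P_m * D_m)
}

#' Multi-state flux balance across coexisting phases
#'
#' For each phase the exchange flux is `sum_i sigma_i * D_i` over its
#' diffusion states; at equilibrium all phases carry equal flux. Reports
#' the per-phase fluxes and the maximum pairwise relative imbalance.
#'
#' @param phases List of phases; each is a list/data.frame with `sigma`
#'   (densities) and `D` (diffusivities) of its states.
#' @return List with `flux` (per phase) and `imbalance` (max pairwise
#'   relative difference).
#' @export
flux_balance_check <- function(phases) {
  stopifnot(length(phases) >= 2)
  flux <- vapply(phases, function(ph) sum(ph$sigma * ph$D), numeric(1))
  imbalance <- (max(flux) - min(flux)) / mean(flux)
  list(flux = flux, imbalance = imbalance)
}

#' Localization-error scale equivalent to a confined-state diffusivity
#'
#' A stationary emitter localized with per-axis error `s` in consecutive
#' frames produces the same displacement distribution as Brownian motion
#' with `D_L = s^2 / t`; hence `s = sqrt(D_L * t)`.
#'
#' @param D_L Apparent confined-state diffusion coefficient, um^2/s.
#' @param t Frame interval, s.
#' @return Scale `s` in nm.
#' @export
loc_error_scale <- function(D_L, t) {
  stopifnot(D_L >= 0, t > 0)
  1000 * sqrt(D_L * t)
}
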