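#' Track-assignment error model
#'
#' Total linking error as a function of the dimensionless search range
#' `X = R / sqrt(4 D t)`: missed true links (true negatives) follow
#' `E_TN = exp(-X^2)` from the 2D Brownian step distribution, while
#' spurious links (false positives) grow linearly with the search range,
#' `E_FP = 2 c X`, where `c` is a composite collision coefficient
#' proportional to `sigma * D * t` (see [fp_coefficient()]). The minimum of
#' `E_TN + E_FP` satisfies `X exp(-X^2) = c`.
#'
#' @param X Dimensionless search range (`> 0`).
#' @param c Composite false-positive coefficient (`>= 0`).
#' @return List with `E_TN`, `E_FP`, `E_total`.
#' @export
assignment_error <- function(X, c) {
  stopifnot(all(X > 0), all(c >= 0))
  e_tn <- exp(-X^2)
  e_fp <- 2 * c * X
  list(E_TN = e_tn, E_FP = e_fp, E_total = e_tn + e_fp)
}

#' @rdname assignment_error
#' @param sigma Molecule density, /um^2.
#' @param D Diffusion coefficient, um^2/s.
#' @param t Frame interval, s.
#' @export
fp_coefficient <- function(sigma, D, t) pi * sigma * D * t

#' Error-optimal dimensionless search range
#'
#' Solves the stationarity condition `X exp(-X^2) = c` on the decreasing
#' branch `X > 1/sqrt(2)` (where the second derivative of the error is
#' positive, i.e. the minimum). For the experimentally relevant range of
#' `c` (~3e-4 to 4e-3) the solution lies between ~2.5 and ~3.1, which is why
#' a fixed default `X = 2.5` is used operationally.
#'
#' @param c Composite false-positive coefficient, `0 < c <
#'   exp(-1/2)/sqrt(2)`.
#' @return `X*` with residual `|X* exp(-X*^2) - c| < 1e-10`.
#' @export
optimal_X <- function(c) {
  cmax <- exp(-0.5) / sqrt(2)
  if (c <= 0 || c >= cmax)
    stop("no admissible root: need 0 < c < ", signif(cmax, 4),
         "; consider the default X = 2.5")
  f <- function(X) X * exp(-X^2) - c
  x <- uniroot(f, c(1 / sqrt(2) + 1e-9, 15),
               tol = .Machine$double.eps^0.75)$root
  for (i in 1:5) {  # Newton polish to drive the residual below 1e-10
    fx <- x * exp(-x^2) - c
    dfx <- (1 - 2 * x^2) * exp(-x^2)
    x <- x - fx / dfx
  }
  x
}

#' Search range from diffusion coefficient
#'
#' `R = X * sqrt(4 D t)` — the gate in units of the per-frame root mean
#' square displacement.
#'
#' @param D Diffusion coefficient, um^2/s.
#' @param t Frame interval, s.
#' @param X Dimensionless search range, default 2.5.
#' @return Search range, um.
#' @export
search_range <- function(D, t, X = 2.5) {
  stopifnot(D >= 0, t > 0, X > 0)
  X * sqrt(4 * D * t)
}

#' Rough diffusion-coefficient estimate from displacements
#'
#' Maximum-likelihood (moment) estimator for the 2D Brownian displacement
#' magnitude distribution `p(d) = d/(2 D t) exp(-d^2 / (4 D t))`:
#' `D = sum(d^2) / (4 n t)`.
#'
#' @param displacements Step magnitudes, um (`>= 50` values).
#' @param t Frame interval, s.
#' @return Estimated D, um^2/s.
#' @export
rough_D <- function(displacements, t) {
  if (length(displacements) < 50)
    stop("too few displacements (need >= 50)")
  sum(displacements^2) / (4 * length(displacements) * t)
}

#' Linking configuration
#'
#' @param default_R Pass-1 global search range, um. Default 0.5.
#' @param X_target Dimensionless search range for the adapted pass.
#'   Default 2.5 (must exceed `1/sqrt(2)` for the error model's minimum
#'   condition).
#' @param strategy `"bipartite"` (minimum summed distance over gated pairs,
#'   via maximum-weight bipartite matching) or `"greedy"` (nearest first).
#' @param max_gap Maximum frame gap closed when extending track ends.
#'   Default 0 (no gap closing).
#' @param n_adapt Number of adaptation passes. Default 1.
#' @param gate `"mixture"` (default) or `"moment"`: how the per-phase
#'   gating diffusion coefficient is estimated from pass-1 displacements.
#'   A phase whose molecules switch between confined and mobile states has
#'   a two-component displacement distribution; gating on the pooled moment
#'   estimator would censor the mobile state's steps, so the mixture gate
#'   fits a two-component model to the squared displacements and gates on
#'   the fast component. For a single-state phase (components
#'   indistinguishable) it falls back to the moment estimator.
#' @return Object of class `link_config`.
#' @export
link_config <- function(default_R = 0.5, X_target = 2.5,
                        strategy = c("bipartite", "greedy"), max_gap = 0,
                        n_adapt = 1, gate = c("mixture", "moment")) {
  strategy <- match.arg(strategy)
  gate <- match.arg(gate)
  stopifnot(default_R > 0, X_target > 1 / sqrt(2), max_gap >= 0, n_adapt >= 1)
  structure(list(default_R = default_R, X_target = X_target,
                 strategy = strategy, max_gap = as.integer(max_gap),
                 n_adapt = as.integer(n_adapt), gate = gate),
            class = "link_config")
}

# Mixture EM on squared displacements: a slow and a fast exponential
# component (the 2D Brownian d^2 is exponential with mean 4 D t) plus a
# fixed-shape spurious-link component. False-positive links pair unrelated
# molecules uniformly over the gate disk, so their d^2 is uniform on
# (0, gate^2); modelling them explicitly keeps the fast component on
# genuine motion.
fit_d2_mixture <- function(d2, gate = NULL, max_iter = 500, tol = 1e-10) {
  m1 <- mean(d2[d2 <= median(d2)])
  m2 <- mean(d2[d2 >= quantile(d2, 0.9)])
  if (m1 <= 0) m1 <- mean(d2) / 10 + 1e-12
  g2 <- if (is.null(gate)) Inf else gate^2
  w <- if (is.finite(g2)) c(0.9, 0.05, 0.05) else c(0.9, 0.1, 0)
  ll_prev <- -Inf
  for (i in seq_len(max_iter)) {
    f <- cbind(w[1] * exp(-d2 / m1) / m1,
               w[2] * exp(-d2 / m2) / m2,
               if (is.finite(g2)) w[3] * (d2 <= g2) / g2 else 0)
    tot <- pmax(rowSums(f), 1e-300)
    ll <- sum(log(tot))
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- ll
    r <- f / tot
    w <- colMeans(r)
    m1 <- sum(r[, 1] * d2) / max(sum(r[, 1]), 1e-300)
    m2 <- sum(r[, 2] * d2) / max(sum(r[, 2]), 1e-300)
  }
  if (m1 > m2) {  # order slow, fast
    tmp <- m1; m1 <- m2; m2 <- tmp
    w[1:2] <- w[2:1]
  }
  list(m_slow = m1, m_fast = m2, w_slow = w[1], w_fast = w[2],
       w_spurious = w[3])
}

# per-phase gating D: fast mixture component when a clearly separated,
# sufficiently populated fast state is present, else the pooled moment
gate_D <- function(d, t, method = "mixture", gate = NULL, min_fast = 50,
                   min_sep = 3) {
  D_mom <- rough_D(d, t)
  if (method == "moment") return(D_mom)
  mx <- fit_d2_mixture(d^2, gate = gate)
  if (mx$m_fast / max(mx$m_slow, 1e-300) >= min_sep &&
      mx$w_fast * length(d) >= min_fast)
    mx$m_fast / (4 * t)
  else D_mom
}

# Match points in frame f to frame f+1. a, b: data.frames with x, y, R and
# optionally phase. Pair gate = min of the two point gates for same-phase
# pairs, max for cross-phase pairs (so genuine exchange events are not
# truncated by the tighter gate). Returns 2-column matrix of (ia, ib).
match_frame_pair <- function(a, b, strategy) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(integer(0), 0, 2))
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dist <- sqrt(dx * dx + dy * dy)
  gate <- outer(a$R, b$R, pmin)
  if (!is.null(a$phase)) {
    cross <- outer(a$phase, b$phase, "!=")
    gate[cross] <- outer(a$R, b$R, pmax)[cross]
  }
  ok <- which(dist <= gate, arr.ind = TRUE)
  if (nrow(ok) == 0) return(matrix(integer(0), 0, 2))
  d <- dist[ok]
  if (strategy == "greedy") {
    ord <- order(d, ok[, 1], ok[, 2])  # deterministic lexicographic ties
    used_a <- logical(na); used_b <- logical(nb)
    out <- matrix(integer(0), 0, 2)
    for (k in ord) {
      i <- ok[k, 1]; j <- ok[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        out <- rbind(out, c(i, j))
      }
    }
    out
  } else {
    # max-weight bipartite matching with weight C - d, C large enough that
    # cardinality dominates: yields max links, then minimum summed distance
    C <- sum(d) + 1
    g <- igraph::make_bipartite_graph(c(rep(0, na), rep(1, nb)),
                                      as.vector(rbind(ok[, 1], na + ok[, 2])))
    m <- igraph::max_bipartite_match(g, weights = C - d)$matching
    ia <- which(!is.na(m[seq_len(na)]))
    if (!length(ia)) return(matrix(integer(0), 0, 2))
    cbind(ia, m[ia] - na)
  }
}

#' Link localizations into tracks
#'
#' Frame-to-frame gated assignment: localizations in frame `f` may link to
#' localizations in frame `f + 1` within the pair gate (the smaller of the
#' two per-point search ranges; the larger for cross-phase pairs).
#' `"greedy"` resolves by ascending distance with deterministic
#' lexicographic tie-breaking; `"bipartite"` maximizes the number of links
#' and minimizes the summed distance. Unmatched localizations start or
#' terminate tracks.
#'
#' @param table A [loc_table()].
#' @param R Per-localization search range, um (scalar recycled).
#' @param strategy `"bipartite"` or `"greedy"`.
#' @param phase Optional per-localization phase labels (used for the
#'   cross-phase gate rule).
#' @param max_gap Frame gaps closed by joining a track end at frame `f` to a
#'   track start at frame `f + 1 + g`, `g <= max_gap`. Default 0.
#' @return A [track_set()] with a `row` column indexing into `table`; the
#'   linked pairs are stored in the attribute `"links"`.
#' @export
link_localizations <- function(table, R, strategy = c("bipartite", "greedy"),
                               phase = NULL, max_gap = 0) {
  strategy <- match.arg(strategy)
  n <- nrow(table)
  R <- rep_len(R, n)
  stopifnot(all(R > 0))
  nxt <- rep(NA_integer_, n)
  frames <- sort(unique(table$frame))
  by_frame <- split(seq_len(n), factor(table$frame, levels = frames))
  for (fi in seq_len(length(frames) - 1)) {
    if (frames[fi + 1] - frames[fi] != 1L) next
    ia <- by_frame[[fi]]; ib <- by_frame[[fi + 1]]
    a <- data.frame(x = table$x[ia], y = table$y[ia], R = R[ia])
    b <- data.frame(x = table$x[ib], y = table$y[ib], R = R[ib])
    if (!is.null(phase)) { a$phase <- phase[ia]; b$phase <- phase[ib] }
    m <- match_frame_pair(a, b, strategy)
    if (nrow(m)) nxt[ia[m[, 1]]] <- ib[m[, 2]]
  }
  if (max_gap > 0) {
    prev <- rep(NA_integer_, n)
    prev[nxt[!is.na(nxt)]] <- which(!is.na(nxt))
    for (g in seq_len(max_gap)) {
      ends <- which(is.na(nxt))
      starts <- which(is.na(prev))
      for (fi in seq_along(frames)) {
        f2 <- frames[fi] + 1L + g
        ia <- intersect(by_frame[[fi]], ends)
        ib <- intersect(unlist(by_frame[which(frames == f2)]), starts)
        if (!length(ia) || !length(ib)) next
        a <- data.frame(x = table$x[ia], y = table$y[ia], R = R[ia])
        b <- data.frame(x = table$x[ib], y = table$y[ib], R = R[ib])
        if (!is.null(phase)) { a$phase <- phase[ia]; b$phase <- phase[ib] }
        m <- match_frame_pair(a, b, strategy)
        if (nrow(m)) {
          nxt[ia[m[, 1]]] <- ib[m[, 2]]
          prev[ib[m[, 2]]] <- ia[m[, 1]]
        }
      }
    }
  }
  # assign track ids by following links in frame order
  tid <- rep(NA_integer_, n)
  ord <- order(table$frame)
  counter <- 0L
  for (i in ord) {
    if (is.na(tid[i])) {
      counter <- counter + 1L
      tid[i] <- counter
    }
    if (!is.na(nxt[i])) tid[nxt[i]] <- tid[i]
  }
  links <- cbind(from = which(!is.na(nxt)), to = nxt[!is.na(nxt)])
  df <- data.frame(track_id = tid, frame = table$frame, x = table$x,
                   y = table$y, row = seq_len(n))
  if (!is.null(phase)) df$phase <- phase
  ts <- track_set(df, acquisition = attr(table, "acquisition"),
                  provenance = list(strategy = strategy, max_gap = max_gap))
  attr(ts, "links") <- links
  ts
}

#' Adaptive two-pass tracking
#'
#' Pass 1 links all localizations with a global default search range. The
#' pass-1 displacements, split by the phase of the step's start, give rough
#' per-phase diffusion coefficients, from which phase-specific optimized
#' search ranges `R = X * sqrt(4 D t)` are derived. Pass 2 relinks every
#' localization with its per-phase gate (cross-phase pairs use the larger
#' gate). Each localization and each step is labelled by phase.
#'
#' @param table A [loc_table()].
#' @param map A [phase_map()] or `region_geometry`; `NULL` for a
#'   single-phase scene.
#' @param config A [link_config()].
#' @return A [track_set()] with `phase` column; the provenance records the
#'   per-phase rough D and adapted R.
#' @export
adaptive_track <- function(table, map = NULL, config = link_config()) {
  tfr <- attr(table, "acquisition")$frame_interval
  geom <- if (inherits(map, "phase_map")) map$geometry else map
  phase <- if (is.null(geom)) rep("all", nrow(table))
           else region_contains(geom, cbind(table$x, table$y))
  pass <- link_localizations(table, config$default_R, config$strategy,
                             phase = phase, max_gap = config$max_gap)
  D_rough <- list(); R_phase <- list(); fallback <- character(0)
  R_prev <- setNames(rep(config$default_R, length(unique(phase))),
                     unique(phase))
  for (it in seq_len(config$n_adapt)) {
    steps <- track_steps(pass)
    sphase <- steps$phase0  # phase of the step's start point
    R_pt <- rep(config$default_R, nrow(table))
    for (ph in unique(phase)) {
      dns <- steps$d[sphase == ph]
      if (length(dns) >= 50) {
        D_rough[[ph]] <- rough_D(dns, tfr)
        Dp <- gate_D(dns, tfr, method = config$gate, gate = R_prev[[ph]])
        R_phase[[ph]] <- search_range(Dp, tfr, config$X_target)
      } else {
        fallback <- union(fallback, ph)
        D_rough[ph] <- list(NULL)
        R_phase[[ph]] <- config$default_R
      }
      R_pt[phase == ph] <- R_phase[[ph]]
    }
    R_prev[names(R_phase)] <- unlist(R_phase)
    pass <- link_localizations(table, R_pt, config$strategy,
                               phase = phase, max_gap = config$max_gap)
  }
  attr(pass, "provenance") <- list(config = config, D_rough = D_rough,
                                   R_phase = R_phase,
                                   fallback_phases = fallback)
  pass
}

#' Phase-boundary crossing statistics
#'
#' Counts steps whose endpoints lie in different phases: `go_in` (dilute to
#' condensed) and `go_out` (condensed to dilute). Percentages are relative
#' to all boundary-crossing steps.
#'
#' @param tracks A [track_set()] (with `phase` labels, or supply `map`).
#' @param map Optional [phase_map()]/geometry to (re)label phases.
#' @return List with `n_go_in`, `n_go_out`, `pct_go_in`, `pct_go_out`,
#'   `n_crossing`.
#' @export
crossing_events <- function(tracks, map = NULL) {
  steps <- track_steps(tracks, map)
  if (!nrow(steps) || is.null(steps$phase0))
    return(list(n_go_in = 0L, n_go_out = 0L, pct_go_in = NA_real_,
                pct_go_out = NA_real_, n_crossing = 0L))
  go_in <- sum(steps$phase0 == "dilute" & steps$phase1 == "condensed")
  go_out <- sum(steps$phase0 == "condensed" & steps$phase1 == "dilute")
  nc <- go_in + go_out
  list(n_go_in = go_in, n_go_out = go_out,
       pct_go_in = if (nc) 100 * go_in / nc else NA_real_,
       pct_go_out = if (nc) 100 * go_out / nc else NA_real_,
       n_crossing = nc)
}

#' Compare linked tracks against ground truth
#'
#' True links are consecutive-frame pairs of localizations sharing a
#' ground-truth id; found links come from [link_localizations()]. The true
#' negative rate is the fraction of true links missed; the false positive
#' rate is the number of found links absent from the truth, relative to the
#' number of true links.
#'
#' @param tracks A [track_set()] from [link_localizations()] (carrying the
#'   `"links"` attribute).
#' @param table The source [loc_table()] with ground-truth `id`.
#' @return List with `tn_rate`, `fp_rate`, `total_error`, `n_true_links`.
#' @export
evaluate_tracking <- function(tracks, table) {
  stopifnot("id" %in% names(table))
  n <- nrow(table)
  ord <- order(table$id, table$frame)
  ids <- table$id[ord]
  frs <- table$frame[ord]
  consec <- ids[-length(ids)] == ids[-1] & frs[-1] - frs[-length(frs)] == 1L
  true_from <- ord[-length(ord)][consec]
  true_to <- ord[-1][consec]
  true_keys <- true_from * (n + 1) + true_to
  found <- attr(tracks, "links")
  found_keys <- found[, 1] * (n + 1) + found[, 2]
  n_true <- length(true_keys)
  tn <- sum(!(true_keys %in% found_keys))
  fp <- sum(!(found_keys %in% true_keys))
  list(tn_rate = tn / n_true, fp_rate = fp / n_true,
       total_error = (tn + fp) / n_true, n_true_links = n_true)
}

#' Spurious-link flux from a frame-shift control
#'
#' Even at the error-optimal gate, a localization whose molecule blinks off
#' can be linked to an unrelated molecule appearing nearby in the next
#' frame; in a dense condensed phase those spurious links carry large
#' displacements and inflate the apparent mobile-state flux `P_m * D_m`.
#' Their rate is estimated without ground truth by relinking frame `f`
#' against frame `f + offset` (far beyond the track survival time, so every
#' match is between unrelated co-occupants) under the same gates and
#' assignment strategy. Scaling the co-occupant match rate by the observed
#' per-localization track-end and track-start probabilities predicts the
#' expected number of spurious links and their squared-displacement flux.
#'
#' @param table A [loc_table()].
#' @param tracks The linked [track_set()] (for gates and birth/death rates).
#' @param map A [phase_map()]/geometry.
#' @param phase Phase to evaluate. Default `"condensed"`.
#' @param offsets Frame shifts for the null control (all must exceed the
#'   track survival time); results pool over them.
#' @return List with `flux` (expected spurious contribution to
#'   `P_m * D_m`, um^2/s per step), `n_expected` spurious links,
#'   `n_control` control matches, `p_end`, `p_start`.
#' @export
spurious_link_flux <- function(table, tracks, map, phase = "condensed",
                               offsets = c(11, 15, 19, 23)) {
  tfr <- attr(table, "acquisition")$frame_interval
  geom <- if (inherits(map, "phase_map")) map$geometry else map
  pt_phase <- region_contains(geom, cbind(table$x, table$y))
  prov <- attr(tracks, "provenance")
  R_pt <- rep(if (!is.null(prov$config)) prov$config$default_R else 0.5,
              nrow(table))
  if (!is.null(prov$R_phase))
    for (ph in names(prov$R_phase))
      R_pt[pt_phase == ph] <- prov$R_phase[[ph]]
  # observed birth/death rates per phase
  df <- as.data.frame(tracks)
  df <- df[order(df$track_id, df$frame), ]
  first <- !duplicated(df$track_id)
  last <- !duplicated(df$track_id, fromLast = TRUE)
  in_ph <- pt_phase[df$row] == phase
  p_start <- sum(first & in_ph) / max(sum(in_ph), 1)
  p_end <- sum(last & in_ph) / max(sum(in_ph), 1)
  # control matching at the frame offset
  frames <- sort(unique(table$frame))
  by_frame <- split(seq_len(nrow(table)), factor(table$frame,
                                                 levels = frames))
  strategy <- if (!is.null(prov$config)) prov$config$strategy else "bipartite"
  n_pairs_real <- sum(diff(frames) == 1L)
  d2_ctrl <- numeric(0)
  n_ctrl_pairs <- 0L
  cases <- expand.grid(fi = seq_along(frames), off = offsets)
  for (ci in seq_len(nrow(cases))) {
    fi <- cases$fi[ci]
    fj <- match(frames[fi] + cases$off[ci], frames)
    if (is.na(fj)) next
    n_ctrl_pairs <- n_ctrl_pairs + 1L
    ia <- by_frame[[fi]]; ib <- by_frame[[fj]]
    a <- data.frame(x = table$x[ia], y = table$y[ia], R = R_pt[ia],
                    phase = pt_phase[ia])
    b <- data.frame(x = table$x[ib], y = table$y[ib], R = R_pt[ib],
                    phase = pt_phase[ib])
    m <- match_frame_pair(a, b, strategy)
    if (nrow(m)) {
      keep <- a$phase[m[, 1]] == phase
      if (any(keep)) {
        dd <- (a$x[m[keep, 1]] - b$x[m[keep, 2]])^2 +
          (a$y[m[keep, 1]] - b$y[m[keep, 2]])^2
        d2_ctrl <- c(d2_ctrl, dd)
      }
    }
  }
  if (n_ctrl_pairs == 0 || !length(d2_ctrl))
    return(list(flux = 0, n_expected = 0, n_control = 0,
                p_end = p_end, p_start = p_start))
  n_exp <- length(d2_ctrl) / n_ctrl_pairs * n_pairs_real * p_end * p_start
  steps <- track_steps(tracks, geom)
  n_steps <- sum(steps$step_phase == phase)
  list(flux = n_exp * mean(d2_ctrl) / (4 * tfr * max(n_steps, 1)),
       n_expected = n_exp, n_control = length(d2_ctrl),
       p_end = p_end, p_start = p_start)
}

#' Benchmark the error-optimal search range on synthetic scenes
#'
#' Generates a homogeneous ground-truth Brownian scene, links it with
#' search ranges `R = X * sqrt(4 D t)` across a grid of `X`, and reports
#' the combined missed-link plus spurious-link error rate at each `X`.
#'
#' @param sigma Per-frame molecule density, /um^2.
#' @param D Diffusion coefficient, um^2/s.
#' @param n_frames Frames to simulate.
#' @param box Field of view, um.
#' @param X_grid Grid of dimensionless search ranges.
#' @param strategy Assignment strategy.
#' @param acquisition An [acquisition_params()].
#' @return `data.frame(X, tn_rate, fp_rate, total_error)` with the
#'   error-minimizing X as attribute `"best_X"`.
#' @export
optimal_x_benchmark <- function(sigma = 0.3, D = 0.1, n_frames = 300,
                                box = c(20, 20), X_grid = seq(1, 5, by = 0.5),
                                strategy = "bipartite",
                                acquisition = acquisition_params()) {
  sim <- simulate_homogeneous(sigma, D, n_frames, box = box,
                              acquisition = acquisition)
  tfr <- acquisition$frame_interval
  rows <- lapply(X_grid, function(X) {
    ts <- link_localizations(sim$table, search_range(D, tfr, X), strategy)
    ev <- evaluate_tracking(ts, sim$table)
    data.frame(X = X, tn_rate = ev$tn_rate, fp_rate = ev$fp_rate,
               total_error = ev$total_error)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_X") <- out$X[which.min(out$total_error)]
  out
}
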