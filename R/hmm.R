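#' Two-state diffusion model
#'
#' Container for the condensed-phase two-state model: confined and mobile
#' diffusion coefficients, per-frame switching probabilities, and the
#' derived confinement/mobile ratios and state lifetimes. States are
#' relabelled so that `D_c <= D_m`.
#'
#' @param D_c,D_m State diffusion coefficients, um^2/s.
#' @param P_cm,P_mc Per-frame switching probabilities (confined-to-mobile,
#'   mobile-to-confined).
#' @param frame_interval Seconds per frame.
#' @param loglik,n_iter Optional fit diagnostics.
#' @param flags Character vector of fit warnings.
#' @return Object of class `two_state_model` with derived `P_c`, `P_m`,
#'   `t_c`, `t_m` (s).
#' @export
two_state_model <- function(D_c, D_m, P_cm, P_mc, frame_interval = 0.03,
                            loglik = NA_real_, n_iter = NA_integer_,
                            flags = character(0)) {
  stopifnot(P_cm >= 0, P_cm <= 1, P_mc >= 0, P_mc <= 1)
  if (D_c > D_m) {  # relabel so the confined state is the slower one
    tmp <- D_c; D_c <- D_m; D_m <- tmp
    tmp <- P_cm; P_cm <- P_mc; P_mc <- tmp
  }
  cr <- confinement_ratios(P_mc, P_cm, frame_interval)
  structure(list(D_c = D_c, D_m = D_m, P_cm = P_cm, P_mc = P_mc,
                 P_c = cr$P_c, P_m = cr$P_m, t_c = cr$t_c, t_m = cr$t_m,
                 frame_interval = frame_interval, loglik = loglik,
                 n_iter = n_iter, flags = flags),
            class = "two_state_model")
}

#' @export
print.two_state_model <- function(x, ...) {
  cat(sprintf(paste0("<two_state_model> D_c = %.4g, D_m = %.4g um^2/s\n",
                     "  P_cm = %.3g, P_mc = %.3g per frame;",
                     " P_c = %.1f%%, P_m = %.1f%%\n"),
              x$D_c, x$D_m, x$P_cm, x$P_mc, 100 * x$P_c, 100 * x$P_m))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Confinement and mobile ratios from switching probabilities
#'
#' `P_c = P_mc / (P_mc + P_cm)` is the stationary fraction of time spent
#' confined; `P_m = 1 - P_c`. Mean state lifetimes are the inverse
#' switching probabilities in frames, converted to seconds.
#'
#' @param P_mc,P_cm Per-frame switching probabilities.
#' @param frame_interval Seconds per frame.
#' @return List with `P_c`, `P_m`, `t_c`, `t_m` (s).
#' @export
confinement_ratios <- function(P_mc, P_cm, frame_interval = 0.03) {
  if (P_mc == 0 && P_cm == 0)
    stop("both switching probabilities are zero; ratios undefined")
  P_c <- P_mc / (P_mc + P_cm)
  list(P_c = P_c, P_m = 1 - P_c,
       t_c = if (P_cm > 0) frame_interval / P_cm else Inf,
       t_m = if (P_mc > 0) frame_interval / P_mc else Inf)
}

# displacement sequences per track (consecutive-frame steps only; tracks
# are split at frame gaps), for tracks contributing >= min_steps steps
track_displacement_sequences <- function(tracks, min_steps = 2) {
  df <- as.data.frame(tracks)
  segs <- list()
  for (tr in split(df[c("frame", "x", "y")], df$track_id)) {
    np <- nrow(tr)
    if (np < 2) next
    gap <- c(0, diff(tr$frame)) != 1
    gap[1] <- TRUE
    seg_id <- cumsum(gap)
    for (s in split(tr, seg_id)) {
      if (nrow(s) < min_steps + 1) next
      d <- sqrt(diff(s$x)^2 + diff(s$y)^2)
      segs[[length(segs) + 1]] <- d
    }
  }
  segs
}

#' Fit the two-state hidden Markov diffusion model
#'
#' Baum-Welch expectation-maximization over all tracks jointly: per-track
#' scaled forward-backward passes (starting from a shared initial-state
#' distribution) with a pooled M-step. The emission model for state `k` is
#' the 2D Brownian displacement-magnitude density
#' `p(d) = d/(2 D_k t) exp(-d^2 / (4 D_k t))`. The log-likelihood is
#' non-decreasing across iterations; a decrease beyond numerical tolerance
#' aborts with diagnostics. States are relabelled so `D_c <= D_m`.
#'
#' @param tracks A [track_set()] (typically condensed-phase tracks), or a
#'   list of per-track displacement vectors.
#' @param init Optional `two_state_model` initial values; by default `D`
#'   initials come from the lower/upper tails of the squared-displacement
#'   distribution and switching starts at 0.1/0.1.
#' @param tol Relative log-likelihood convergence tolerance. Default 1e-8.
#' @param max_iter Maximum EM iterations. Default 10000.
#' @param frame_interval Seconds per frame (taken from `tracks` when it is
#'   a track set).
#' @return A [two_state_model()] with `loglik`, `n_iter` and the iteration
#'   trace in attribute `"loglik_trace"`.
#' @export
hmm_fit <- function(tracks, init = NULL, tol = 1e-8, max_iter = 10000,
                    frame_interval = NULL) {
  if (inherits(tracks, "track_set")) {
    frame_interval <- attr(tracks, "acquisition")$frame_interval
    segs <- track_displacement_sequences(tracks, min_steps = 2)
  } else {
    segs <- tracks[vapply(tracks, length, integer(1)) >= 2]
    if (is.null(frame_interval)) frame_interval <- 0.03
  }
  if (!length(segs)) stop("no track with >= 2 consecutive steps")
  d <- pmax(unlist(segs), 1e-9)
  lens <- vapply(segs, length, integer(1))
  tfr <- frame_interval
  if (is.null(init)) {
    d2 <- d^2
    D1 <- mean(d2[d2 <= quantile(d2, 0.5)]) / (4 * tfr)
    D2 <- mean(d2[d2 >= quantile(d2, 0.9)]) / (4 * tfr)
    if (D2 <= D1 * 1.5) D2 <- D1 * 3
    D <- c(max(D1, 1e-8), D2)
    A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  } else {
    D <- c(max(init$D_c, 1e-8), init$D_m)
    A <- matrix(c(1 - init$P_cm, init$P_cm, init$P_mc, 1 - init$P_mc),
                2, 2, byrow = TRUE)
  }
  pi0 <- stationary_dist(A)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  flags <- character(0)
  for (it in seq_len(max_iter)) {
    es <- hmm_estep_cpp(d, lens, D, A, pi0, tfr)
    ll <- es$loglik
    ll_trace <- c(ll_trace, ll)
    if (ll < ll_prev - 1e-6 * abs(ll_prev))
      stop(sprintf("EM log-likelihood decreased at iteration %d (%.6g -> %.6g)",
                   it, ll_prev, ll))
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- ll
    D <- pmax(es$gamma_d2 / (4 * tfr * es$gamma_sum), 1e-10)
    A <- es$xi / rowSums(es$xi)
    pi0 <- es$gamma1 / es$n_tracks
    pi0 <- pi0 / sum(pi0)
  }
  if (it == max_iter) flags <- c(flags, "max_iter reached")
  # degenerate-data check: does the two-state model beat a single Brownian
  # population by more than its three extra parameters cost (BIC)?
  D1 <- sum(d^2) / (4 * tfr * length(d))
  ll1 <- sum(log(d / (2 * D1 * tfr)) - d^2 / (4 * D1 * tfr))
  if (2 * (ll - ll1) < 3 * log(length(d)))
    flags <- c(flags,
               "no support for a second state; ratios unidentifiable")
  if (max(D) < 3 * min(D))
    flags <- c(flags,
               "states weakly separated; two-state ratios unreliable")
  if (min(A[1, 2], A[2, 1]) < 1e-5)
    flags <- c(flags, "a switching probability is pinned near zero")
  m <- two_state_model(D_c = D[1], D_m = D[2], P_cm = A[1, 2], P_mc = A[2, 1],
                       frame_interval = tfr, loglik = ll, n_iter = it,
                       flags = flags)
  attr(m, "loglik_trace") <- ll_trace
  m
}

stationary_dist <- function(A) {
  p <- c(A[2, 1], A[1, 2])
  if (sum(p) == 0) c(0.5, 0.5) else p / sum(p)
}

#' Log-likelihood of pooled tracks under a two-state model
#'
#' Scores displacement sequences under a [two_state_model()] without
#' refitting (one forward pass). Useful for comparing parameter sets.
#'
#' @param tracks A [track_set()] or list of displacement vectors.
#' @param model A [two_state_model()].
#' @param frame_interval Seconds per frame (for displacement lists).
#' @return Total log-likelihood.
#' @export
hmm_loglik <- function(tracks, model, frame_interval = NULL) {
  if (inherits(tracks, "track_set")) {
    frame_interval <- attr(tracks, "acquisition")$frame_interval
    segs <- track_displacement_sequences(tracks, min_steps = 2)
  } else {
    segs <- tracks
    if (is.null(frame_interval)) frame_interval <- model$frame_interval
  }
  d <- pmax(unlist(segs), 1e-9)
  lens <- vapply(segs, length, integer(1))
  A <- matrix(c(1 - model$P_cm, model$P_cm, model$P_mc, 1 - model$P_mc),
              2, 2, byrow = TRUE)
  hmm_estep_cpp(d, lens, c(max(model$D_c, 1e-10), model$D_m), A,
                stationary_dist(A), frame_interval)$loglik
}

#' Per-step state decoding under a fitted two-state model
#'
#' Viterbi decoding of each track's most likely state sequence.
#'
#' @param tracks A [track_set()] or list of displacement vectors.
#' @param model A [two_state_model()].
#' @param frame_interval Seconds per frame (for displacement lists).
#' @return List of per-track character vectors (`"confined"`/`"mobile"`).
#' @export
hmm_states <- function(tracks, model, frame_interval = NULL) {
  if (inherits(tracks, "track_set")) {
    frame_interval <- attr(tracks, "acquisition")$frame_interval
    segs <- track_displacement_sequences(tracks, min_steps = 2)
  } else {
    segs <- tracks
    if (is.null(frame_interval)) frame_interval <- model$frame_interval
  }
  d <- pmax(unlist(segs), 1e-9)
  lens <- vapply(segs, length, integer(1))
  A <- matrix(c(1 - model$P_cm, model$P_cm, model$P_mc, 1 - model$P_mc),
              2, 2, byrow = TRUE)
  path <- hmm_viterbi_cpp(d, lens, c(max(model$D_c, 1e-10), model$D_m), A,
                          stationary_dist(A), frame_interval)
  split(ifelse(path == 0, "confined", "mobile"),
        rep.int(seq_along(lens), lens))
}
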