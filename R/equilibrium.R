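#' Default synthetic droplet geometry for the equilibrium simulator
#'
#' Eight well-separated circular condensed regions (radii 0.4-0.8 um,
#' total area ~8.9 um^2, ~2% of the default 15 x 30 um box), emulating the
#' micron-scale condensed patches seen on supported bilayers.
#'
#' @return A disk `region_geometry`.
#' @export
default_condensate_geometry <- function() {
  disk_geometry(cx = c(3, 11, 7, 3, 11, 7, 3, 11),
                cy = c(5, 5, 10, 15, 15, 20, 25, 25),
                r = c(0.8, 0.6, 0.5, 0.6, 0.8, 0.4, 0.5, 0.4))
}

#' Simulation world for the two-phase Monte Carlo
#'
#' Parameters of the equilibrium two-phase/two-state diffusion simulation:
#' a periodic box with stationary condensed regions, dilute diffusivity
#' `D_d`, condensed mobile diffusivity `D_m`, confined diffusivity `D_c`
#' (default 0, stationary), mobile ratio `eta` and mobile-state lifetime
#' `t_m`. Per-step switching probabilities are `P_mc = dt / t_m` and, from
#' the steady-state balance `P_mc * eta = P_cm * (1 - eta)`,
#' `P_cm = P_mc * eta / (1 - eta)`.
#'
#' @param box `c(width, height)` um. Default `c(15, 30)`.
#' @param geometry Condensed regions (disk `region_geometry`).
#' @param D_d,D_m,D_c Diffusion coefficients, um^2/s.
#' @param mobile_ratio Mobile fraction eta in (0, 1].
#' @param mobile_lifetime Mean mobile-state dwell time t_m, s (`NULL` only
#'   when `mobile_ratio = 1`).
#' @param dt Integration step, s. Default 1e-4.
#' @param n_molecules Number of molecules. Default 50000.
#' @param T_total Total simulated time, s. Default 100.
#' @return Object of class `sim_world`.
#' @export
sim_world <- function(box = c(15, 30), geometry = default_condensate_geometry(),
                      D_d = 0.6, D_m = 0.1, D_c = 0, mobile_ratio = 0.1,
                      mobile_lifetime = 0.1, dt = 1e-4, n_molecules = 50000,
                      T_total = 100) {
  stopifnot(all(box > 0), D_d >= 0, D_m >= 0, D_c >= 0,
            mobile_ratio > 0, mobile_ratio <= 1, dt > 0, n_molecules > 0)
  if (mobile_ratio >= 1) {
    if (!is.null(mobile_lifetime))
      stop("mobile_ratio = 1 leaves no confined state; set mobile_lifetime = NULL")
    P_mc <- 0; P_cm <- 0
  } else {
    stopifnot(!is.null(mobile_lifetime), mobile_lifetime > 0)
    if (dt >= mobile_lifetime)
      stop("dt must be smaller than the mobile-state lifetime")
    P_mc <- dt / mobile_lifetime
    P_cm <- P_mc * mobile_ratio / (1 - mobile_ratio)
  }
  structure(list(box = box, geometry = geometry, D_d = D_d, D_m = D_m,
                 D_c = D_c, mobile_ratio = mobile_ratio,
                 mobile_lifetime = mobile_lifetime, dt = dt,
                 n_molecules = as.integer(n_molecules), T_total = T_total,
                 P_mc = P_mc, P_cm = P_cm),
            class = "sim_world")
}

#' Theoretical enrichment fold of a simulation world
#'
#' The kinetic flux-balance prediction `EF = D_d / (eta * D_m)`.
#'
#' @param world A [sim_world()].
#' @return Enrichment fold.
#' @export
theory_ef <- function(world) {
  world$D_d / (world$mobile_ratio * world$D_m)
}

# Draw initial positions/states; init_ef = NULL -> homogeneous.
init_molecules <- function(world, init_ef = NULL) {
  n <- world$n_molecules
  geom <- world$geometry
  a_c <- region_area(geom)
  a_d <- world$box[1] * world$box[2] - a_c
  if (is.null(init_ef)) {
    xy <- cbind(runif(n, 0, world$box[1]), runif(n, 0, world$box[2]))
  } else {
    p_c <- init_ef * a_c / (init_ef * a_c + a_d)
    n_c <- round(n * p_c)
    xy <- rbind(sample_in_geometry(geom, n_c),
                sample_outside_geometry(geom, world$box, n - n_c))
  }
  cond <- region_contains(geom, xy) == "condensed"
  state <- ifelse(cond, as.integer(runif(n) < world$mobile_ratio), 1L)
  list(x = xy[, 1], y = xy[, 2], state = as.integer(state))
}

#' Run the equilibrium two-phase Monte Carlo simulation
#'
#' Molecules diffuse in a periodic box with stationary condensed regions.
#' At every step `dt`, condensed-phase molecules switch between the confined
#' and mobile state with the world's per-step probabilities; dilute-phase
#' molecules are always mobile. The diffusion coefficient for a whole step
#' is that of the region at the step's start, even when the step crosses a
#' phase boundary. The enrichment fold
#' `EF(t) = (N_c / A_c) / (N_d / A_d)` is recorded along the trajectory.
#'
#' @param world A [sim_world()].
#' @param init `"ef"` (random placement at enrichment `init_ef`, states at
#'   the stationary mobile ratio — the equilibrated-start protocol) or
#'   `"uniform"` (homogeneous start).
#' @param init_ef Initial enrichment for `init = "ef"`; default the
#'   theoretical EF of the world.
#' @param record_every Trace recording interval, s.
#' @return List of class `eq_sim` with `trace` (`data.frame(t, ef,
#'   n_condensed)`), `final` (positions and states), `world`, `theory_ef`.
#' @export
simulate_equilibrium <- function(world, init = c("ef", "uniform"),
                                 init_ef = NULL, record_every = 0.1) {
  init <- match.arg(init)
  stopifnot(inherits(world, "sim_world"))
  if (world$geometry$type != "disks")
    stop("the equilibrium engine requires disk geometry")
  if (is.null(init_ef)) init_ef <- theory_ef(world)
  st <- init_molecules(world, if (init == "ef") init_ef else NULL)
  n_steps <- round(world$T_total / world$dt)
  rec <- max(1L, round(record_every / world$dt))
  res <- particle_sim_cpp(st$x, st$y, st$state, world$box[1], world$box[2],
                          world$geometry$disks, world$D_d, world$D_m,
                          world$D_c, world$P_cm, world$P_mc, world$dt,
                          n_steps, rec,
                          matrix(numeric(0), 0, 3),
                          matrix(logical(0), 0, 0))
  a_c <- res$area_condensed
  a_d <- world$box[1] * world$box[2] - a_c
  n <- world$n_molecules
  ef <- (res$n_condensed / a_c) / ((n - res$n_condensed) / a_d)
  structure(list(trace = data.frame(t = res$t, ef = ef,
                                    n_condensed = res$n_condensed),
                 final = list(x = res$x, y = res$y, state = res$state),
                 world = world, theory_ef = theory_ef(world)),
            class = "eq_sim")
}

#' Steady-state enrichment fold of simulation traces
#'
#' Averages EF over the final `window` seconds of each trace; with several
#' replicate runs the spread across runs is reported as the standard
#' deviation.
#'
#' @param x An `eq_sim`, a trace `data.frame(t, ef)`, or a list of either
#'   (replicate seeds).
#' @param window Averaging window, s. Default 10.
#' @return List with `mean`, `sd` (0 for a single run) and `per_run` values.
#' @export
steady_state_ef <- function(x, window = 10) {
  traces <- if (inherits(x, "eq_sim")) list(x$trace)
    else if (is.data.frame(x)) list(x)
    else lapply(x, function(e) if (inherits(e, "eq_sim")) e$trace else e)
  per <- vapply(traces, function(tr) {
    span <- max(tr$t) - min(tr$t)
    if (span < window) stop("trace shorter than the averaging window")
    mean(tr$ef[tr$t > max(tr$t) - window])
  }, numeric(1))
  list(mean = mean(per), sd = if (length(per) > 1) sd(per) else 0,
       per_run = per)
}

#' The printed parameter rows of the equilibrium-simulation benchmark
#'
#' Six configurations spanning theoretical enrichment folds 30, 60 and 120.
#'
#' @return `data.frame` with columns `D_m`, `D_d`, `mobile_ratio`,
#'   `mobile_lifetime` (`NA` for the all-mobile row) and `ef_theory`.
#' @export
table1_rows <- function() {
  data.frame(
    D_m = c(0.2, 0.1, 0.01, 0.1, 0.1, 0.2),
    D_d = rep(0.6, 6),
    mobile_ratio = c(0.05, 0.1, 1, 0.1, 0.05, 0.1),
    mobile_lifetime = c(0.1, 0.1, NA, 0.5, 0.1, 0.1),
    ef_theory = c(60, 60, 60, 60, 120, 30))
}
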