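#' Fully occupied initial landscape
#'
#' Every site occupied, as in the long-term phase-diagram protocol. In mixed
#' mode each site is independently NC with probability `fraction_nc`, otherwise
#' exploiter (the symmetric default for competition runs is 0.5).
#'
#' @param L Lattice side length (>= 4).
#' @param fraction_nc Probability that a site starts as NC (default 1: single
#'   strategy, all NC).
#' @param seed Optional RNG seed for the mixed assignment.
#' @return A `landscape` matrix.
#' @export
init_full <- function(L, fraction_nc = 1, seed = NULL) {
  L <- .check_L(L)
  stopifnot(
    "'fraction_nc' must be in [0, 1]" =
      length(fraction_nc) == 1 && is.finite(fraction_nc) &&
        fraction_nc >= 0 && fraction_nc <= 1
  )
  if (!is.null(seed)) set.seed(seed)
  g <- landscape(L, "nc")
  if (fraction_nc < 1) {
    ex <- runif(L * L) >= fraction_nc
    g[ex] <- .S_EX
  }
  g
}

#' Single-seed initial landscape
#'
#' One central NC site, by default on an otherwise fully destroyed lattice.
#' The range-expansion protocol instead uses `background = "vacant"`: a still
#' habitable landscape that decays into the destroyed "vacuum" at rate `e`
#' wherever no population is nearby to renew it — the setting in which a
#' lone founder can establish for any construction range (on an all-destroyed
#' background, establishment requires the seed to construct one of its few
#' colonizable neighbors before dying, which is vanishingly rare once the
#' construction effort is spread over a large neighborhood).
#'
#' @param L Lattice side length (>= 3).
#' @param background State of all non-seed sites: `"destroyed"` (default) or
#'   `"vacant"`.
#' @return A `landscape` matrix with one NC site at
#'   `(floor(L/2) + 1, floor(L/2) + 1)`.
#' @export
init_single_seed <- function(L, background = c("destroyed", "vacant")) {
  L <- .check_L(L)
  g <- landscape(L, match.arg(background))
  ctr <- floor(L / 2) + 1L
  g[ctr, ctr] <- .S_NC
  g
}

#' Seed site of the single-seed initial condition
#' @param L Lattice side length.
#' @return `c(row, col)` of the central seed (1-based).
#' @export
seed_site <- function(L) rep(floor(.check_L(L) / 2) + 1L, 2L)

#' Per-site transition rates
#'
#' The admissible transitions at one site and their rates, given the current
#' configuration. This is the model's defining rate table, evaluated directly
#' from neighbor counts; the fast simulator ([run_ips()]) realizes exactly
#' these rates through source-driven event thinning and is cross-checked
#' against them in the test suite.
#'
#' @param grid A landscape matrix.
#' @param site `c(row, col)`, 1-based.
#' @param params A [model_params()] object.
#' @return Named numeric vector of rates; the names encode the transition
#'   (`extinction` to vacant, `destruction` to destroyed, `colonization_nc` /
#'   `colonization_ex` to occupied, `construction` to vacant).
#' @examples
#' g <- landscape(8, "nc")
#' g[3, 3] <- 0L
#' site_rates(g, c(3, 3), model_params(delta = 0.1, c = 0.4))
#' @export
site_rates <- function(grid, site, params) {
  st <- grid[site[1], site[2]]
  if (st == .S_NC || st == .S_EX) {
    return(c(extinction = params$delta, destruction = params$e))
  }
  zcol <- neighborhood_offsets(params$r_col)
  if (st == .S_VAC) {
    n_nc <- count_neighbors(grid, site, zcol, "nc")
    n_ex <- count_neighbors(grid, site, zcol, "exploiter")
    k <- nrow(zcol$offsets)
    return(c(
      destruction = params$e,
      colonization_nc = .beta_col(params) * n_nc / k,
      colonization_ex = n_ex / k
    ))
  }
  # destroyed: only NC constructs
  if (is.infinite(params$r_con)) {
    n_nc <- sum(grid == .S_NC) - (st == .S_NC)
    k <- length(grid) - 1
  } else {
    zcon <- neighborhood_offsets(params$r_con)
    n_nc <- count_neighbors(grid, site, zcon, "nc")
    k <- nrow(zcon$offsets)
  }
  c(construction = params$c * n_nc / k)
}

#' Simulation state for the reference stepper
#'
#' Wraps a landscape, the model time and event tallies into a state object for
#' the exact single-event reference simulator [step_ips()]. The fast path for
#' production runs is [run_ips()]; `sim_state`/`step_ips` exist as the
#' transparent, direct-Gillespie implementation used for validation on small
#' lattices.
#'
#' @param grid A landscape matrix.
#' @param params A [model_params()] object.
#' @param t Initial model time.
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(grid, params, t = 0) {
  structure(
    list(
      grid = .as_landscape(grid), params = params, t = t,
      absorbed = !any(grid == .S_NC | grid == .S_EX),
      event_counts = c(
        extinction = 0, destruction = 0, colonization_nc = 0,
        colonization_ex = 0, construction = 0
      )
    ),
    class = "sim_state"
  )
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf(
    "<sim_state> t=%.4f  L=%d%s\n", x$t, nrow(x$grid),
    if (x$absorbed) "  [absorbed]" else ""
  ))
  invisible(x)
}

# All site rates of the configuration as a (L*L x 5) matrix, columns
# extinction / destruction / colonization_nc / colonization_ex / construction.
# Vectorized over sites via toroidal shifts of the indicator matrices.
.rate_matrix <- function(grid, params) {
  L <- nrow(grid)
  n <- L * L
  shift_sum <- function(ind, offsets) {
    out <- matrix(0, L, L)
    for (i in seq_len(nrow(offsets))) {
      rr <- ((seq_len(L) - 1 + offsets[i, 1]) %% L) + 1
      cc <- ((seq_len(L) - 1 + offsets[i, 2]) %% L) + 1
      out <- out + ind[rr, cc, drop = FALSE]
    }
    out
  }
  is_nc <- (unclass(grid) == .S_NC) + 0
  is_ex <- (unclass(grid) == .S_EX) + 0
  occ <- grid == .S_NC | grid == .S_EX
  vac <- grid == .S_VAC
  des <- grid == .S_DES

  zcol <- neighborhood_offsets(params$r_col)$offsets
  n_nc_col <- shift_sum(is_nc, zcol)
  n_ex_col <- shift_sum(is_ex, zcol)
  if (is.infinite(params$r_con)) {
    n_nc_con <- matrix(sum(is_nc), L, L) - is_nc
    k_con <- n - 1
  } else {
    zcon <- neighborhood_offsets(params$r_con)$offsets
    n_nc_con <- shift_sum(is_nc, zcon)
    k_con <- nrow(zcon)
  }

  rates <- matrix(0, n, 5,
    dimnames = list(NULL, c(
      "extinction", "destruction", "colonization_nc",
      "colonization_ex", "construction"
    ))
  )
  rates[occ, "extinction"] <- params$delta
  rates[occ | vac, "destruction"] <- params$e
  rates[vac, "colonization_nc"] <-
    .beta_col(params) * n_nc_col[vac] / nrow(zcol)
  rates[vac, "colonization_ex"] <- n_ex_col[vac] / nrow(zcol)
  rates[des, "construction"] <- params$c * n_nc_con[des] / k_con
  rates
}

#' Advance the reference simulator by one event
#'
#' Exact direct Gillespie step: computes every admissible per-site rate,
#' draws an exponential waiting time with mean `1 / (total rate)`, picks one
#' transition with probability proportional to its rate and applies it. With
#' no occupied site and `e = 0` (or a fully destroyed lattice) the state is
#' frozen and returned unchanged with `absorbed = TRUE`.
#'
#' Intended for small lattices (cost is `O(L^2)` per event); production runs
#' use [run_ips()].
#'
#' @param state A [sim_state()] object.
#' @return The updated `sim_state`.
#' @export
step_ips <- function(state) {
  rates <- .rate_matrix(state$grid, state$params)
  total <- sum(rates)
  if (total <= 0) {
    state$absorbed <- TRUE
    return(state)
  }
  state$t <- state$t + stats::rexp(1, total)
  pick <- sample.int(length(rates), 1, prob = as.vector(rates))
  site <- (pick - 1) %% nrow(rates) + 1
  channel <- colnames(rates)[(pick - 1) %/% nrow(rates) + 1]
  new_state <- switch(channel,
    extinction = .S_VAC,
    destruction = .S_DES,
    colonization_nc = .S_NC,
    colonization_ex = .S_EX,
    construction = .S_VAC
  )
  state$grid[site] <- new_state
  nm <- if (channel %in% c("extinction")) "extinction" else channel
  state$event_counts[nm] <- state$event_counts[nm] + 1
  state$absorbed <- !any(state$grid == .S_NC | state$grid == .S_EX) &&
    (state$params$e == 0 || all(state$grid == .S_DES))
  state
}

#' Run the stochastic particle system
#'
#' Continuous-time Monte Carlo run of the niche-construction model (and, with
#' `params$competition`, the two-strategy scramble-competition model) using the
#' exact compiled Gillespie sampler. State fractions are sampled every
#' `sample_dt` units of model time; once the configuration is frozen (no event
#' can ever fire) remaining samples repeat the frozen state.
#'
#' @param params A [model_params()] object.
#' @param init Initial `landscape` (e.g. [init_full()], [init_single_seed()]).
#' @param t_max Run length in model time units (> 0). One "time step" of the
#'   long-run protocols equals one unit of model time.
#' @param sample_dt Sampling interval (default 1).
#' @param seed Optional RNG seed; fixed seed implies an identical trajectory.
#' @param record_row Optional 1-based row index whose states are snapshotted at
#'   every sample time (for space-time transects).
#' @param track_extent If `TRUE`, records at each sample the maximum Chebyshev
#'   radius of occupied sites from the lattice center (minimum-image), the
#'   mosaic-extent measure of the range-expansion protocol.
#' @return An object of class `ips_run`: list with `trajectory` (data frame
#'   `t`, `p_minus`, `p_vacant`, `p_nc`, `p_ex`, `occupied`, plus `extent`
#'   and/or row snapshots when requested), `final_grid`, `params`, `absorbed`,
#'   `t_absorbed`, `event_counts` and `seed`.
#' @examples
#' run <- run_ips(model_params(delta = 0.3), init_full(16), t_max = 20, seed = 1)
#' tail(run$trajectory$p_nc, 1)
#' @export
run_ips <- function(params, init, t_max, sample_dt = 1, seed = NULL,
                    record_row = NULL, track_extent = FALSE) {
  stopifnot(
    "'t_max' must be > 0" = length(t_max) == 1 && is.finite(t_max) && t_max > 0,
    "'sample_dt' must be > 0" = sample_dt > 0
  )
  init <- .as_landscape(init)
  L <- nrow(init)
  if (!is.infinite(params$r_con) && params$r_con >= L) {
    stop("construction range must be smaller than the lattice size (use r_con = Inf for global)")
  }
  if (params$r_col >= L) stop("colonization range must be smaller than the lattice size")
  if (!is.null(seed)) set.seed(seed)
  ctr <- seed_site(L)
  res <- run_ips_cpp(
    as.integer(init), L, params$delta, params$e, params$c, params$alpha,
    params$r_col, if (is.infinite(params$r_con)) -1L else params$r_con,
    is.infinite(params$r_con), t_max, sample_dt,
    if (is.null(record_row)) -1L else as.integer(record_row) - 1L,
    ctr[1] - 1L, ctr[2] - 1L, isTRUE(track_extent)
  )
  traj <- data.frame(
    t = res$times, p_minus = res$p_minus, p_vacant = res$p_vacant,
    p_nc = res$p_nc, p_ex = res$p_ex, occupied = res$occupied
  )
  if (isTRUE(track_extent)) traj$extent <- res$extent
  out <- list(
    trajectory = traj,
    final_grid = .as_landscape(matrix(res$final_grid, L, L)),
    params = params,
    t_final = res$t_final,
    absorbed = res$absorbed,
    t_absorbed = res$t_absorbed,
    event_counts = res$event_counts,
    seed = seed
  )
  if (!is.null(record_row)) {
    out$row_snapshots <- res$row_snapshots
    out$record_row <- as.integer(record_row)
  }
  structure(out, class = "ips_run")
}

#' @export
print.ips_run <- function(x, ...) {
  fr <- state_fractions(x$final_grid)
  cat(sprintf(
    "<ips_run> %s  t_max=%g  final p+: %.4f  p++: %.4f  p-: %.4f%s\n",
    format(x$params), x$t_final, fr["p_nc"], fr["p_ex"], fr["p_minus"],
    if (x$absorbed) sprintf("  [absorbed at t=%.1f]", x$t_absorbed) else ""
  ))
  invisible(x)
}

#' @export
format.model_params <- function(x, ...) {
  sprintf(
    "{a=%g, d=%g, c=%g, e=%g}", x$alpha, x$delta, x$c, x$e
  )
}

#' Reference (pure R) run of the particle system
#'
#' Drives [step_ips()] event by event and samples state fractions on a fixed
#' grid of times. Exact but `O(L^2)` per event; used to validate the compiled
#' sampler on small lattices.
#'
#' @inheritParams run_ips
#' @return A data frame with columns `t`, `p_minus`, `p_vacant`, `p_nc`,
#'   `p_ex`.
#' @export
run_reference <- function(params, init, t_max, sample_dt = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- sim_state(.as_landscape(init), params)
  times <- seq(0, t_max, by = sample_dt)
  out <- matrix(NA_real_, length(times), 4)
  i <- 1
  repeat {
    t_prev <- st$t
    fr <- state_fractions(st$grid)
    st2 <- if (st$absorbed) st else step_ips(st)
    t_next <- if (st2$absorbed && st2$t == t_prev) Inf else st2$t
    while (i <= length(times) && times[i] < t_next) {
      out[i, ] <- fr
      i <- i + 1
    }
    st <- st2
    if (i > length(times)) break
  }
  data.frame(
    t = times, p_minus = out[, 1], p_vacant = out[, 2],
    p_nc = out[, 3], p_ex = out[, 4]
  )
}

#' Time-averaged occupancy of a run
#'
#' Mean state fractions over a time window of a trajectory, the measurement
#' used by the phase-diagram protocol (discard the transient, average the
#' following window).
#'
#' @param run An `ips_run` (or its trajectory data frame).
#' @param t_from,t_to Averaging window (inclusive).
#' @return Named vector of mean `p_minus`, `p_vacant`, `p_nc`, `p_ex`.
#' @export
mean_occupancy <- function(run, t_from, t_to = Inf) {
  traj <- if (inherits(run, "ips_run")) run$trajectory else run
  sel <- traj$t >= t_from & traj$t <= t_to
  if (!any(sel)) stop("empty averaging window")
  colMeans(traj[sel, c("p_minus", "p_vacant", "p_nc", "p_ex")])
}

#' Write a trajectory to CSV
#'
#' @param run An `ips_run` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(run, path) {
  utils::write.csv(run$trajectory, path, row.names = FALSE)
  invisible(path)
}
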