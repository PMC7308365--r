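# Derived per-task seeds, kept below 2^31 so set.seed() accepts them.
.derive_seed <- function(base, ...) {
  k <- as.numeric(base)
  for (x in list(...)) k <- (k * 7919 + as.numeric(x)) %% 2147483629
  as.integer(k) + 1L
}

#' Phase-diagram sweep over (c, e)
#'
#' Runs the particle system once per grid cell from a fully occupied lattice,
#' discards the transient and reports the time-averaged occupancy over the
#' following window (runs that went extinct report 0). With
#' `base_params$competition` the initial lattice is an i.i.d. NC/exploiter
#' mixture and per-strategy means plus the relative occupancy
#' `p+ / (p+ + p++)` are returned.
#'
#' @param c_values,e_values Grid of construction allocations and destruction
#'   rates.
#' @param base_params A [model_params()] whose `c` and `e` are overridden
#'   cell by cell.
#' @param protocol List overriding any of `L` (256), `t_transient` (5000),
#'   `t_avg` (250), `sample_dt` (1), `fraction_nc` (0.5, competition only).
#'   The defaults are the full long-run protocol; scaled-down sweeps pass a
#'   smaller `L` and shorter times.
#' @param seed Base seed; each cell derives its own seed from it, so a fixed
#'   seed gives a bitwise-reproducible matrix.
#' @return A `phase_diagram` object: axis grids plus matrices
#'   (`length(e_values)` rows by `length(c_values)` columns) `mean_occupancy`
#'   (NC), and for competition `mean_exploiter` and `relative_occupancy`
#'   (`NaN` where both strategies are extinct).
#' @export
sweep_phase_diagram <- function(c_values, e_values, base_params = model_params(),
                                protocol = list(), seed = 1) {
  stopifnot(length(c_values) > 0, length(e_values) > 0)
  pr <- modifyList(
    list(L = 256, t_transient = 5000, t_avg = 250, sample_dt = 1, fraction_nc = 0.5),
    protocol
  )
  t_max <- pr$t_transient + pr$t_avg
  dn <- list(signif(e_values, 6), signif(c_values, 6))
  occ <- matrix(NA_real_, length(e_values), length(c_values), dimnames = dn)
  occ_ex <- if (base_params$competition) occ else NULL
  for (j in seq_along(c_values)) {
    for (i in seq_along(e_values)) {
      p <- base_params
      p$c <- c_values[j]
      p$e <- e_values[i]
      cell_seed <- .derive_seed(seed, i, j)
      init <- if (base_params$competition) {
        init_full(pr$L, fraction_nc = pr$fraction_nc, seed = cell_seed)
      } else {
        init_full(pr$L)
      }
      run <- run_ips(p, init, t_max,
        sample_dt = pr$sample_dt,
        seed = .derive_seed(cell_seed, 1)
      )
      if (sum(run$trajectory$occupied[nrow(run$trajectory)]) == 0) {
        occ[i, j] <- 0
        if (base_params$competition) occ_ex[i, j] <- 0
      } else {
        m <- mean_occupancy(run, pr$t_transient, t_max)
        occ[i, j] <- m[["p_nc"]]
        if (base_params$competition) occ_ex[i, j] <- m[["p_ex"]]
      }
    }
  }
  out <- list(
    c_values = c_values, e_values = e_values, mean_occupancy = occ,
    params = base_params, protocol = pr, seed = seed
  )
  if (base_params$competition) {
    out$mean_exploiter <- occ_ex
    out$relative_occupancy <- occ / (occ + occ_ex) # NaN where both are 0
  }
  structure(out, class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf(
    "<phase_diagram> %d x %d cells (e x c), L=%d, persistent fraction %.2f\n",
    length(x$e_values), length(x$c_values), x$protocol$L,
    mean(x$mean_occupancy > 0)
  ))
  invisible(x)
}

#' Summary of the persistence region of a phase diagram
#'
#' Thresholds the mean-occupancy matrix into a persistence mask and reports
#' its connected-component count (4-connectivity in the parameter plane, no
#' wrap) and the vertex of the extinction-threshold curve: the `c` column
#' sustaining the largest `e` with persistence.
#'
#' @param pd A [sweep_phase_diagram()] result (single-strategy matrix).
#' @param threshold Occupancy above which a cell counts as persistent.
#' @return List with `n_regions`, `vertex_c`, `vertex_e`, `interior_vertex`
#'   (is the vertex away from both `c` grid edges?), and the logical `mask`.
#' @export
persistence_region <- function(pd, threshold = 0.01) {
  mask <- pd$mean_occupancy > threshold
  cl <- clusters_cpp(
    as.integer(ifelse(mask, 1L, 0L)), nrow(mask), ncol(mask),
    1L, FALSE
  )
  emax <- apply(mask, 2, function(col) {
    if (any(col)) max(pd$e_values[col]) else -Inf
  })
  v <- which.max(emax)
  list(
    n_regions = length(cl$sizes),
    vertex_c = pd$c_values[v],
    vertex_e = emax[v],
    interior_vertex = v > 1 && v < length(pd$c_values),
    mask = mask
  )
}

# Survival probability of the process at t_max over seeded replicates.
.survival_prob <- function(params, L, t_max, replicates, seed, fraction_nc = 1) {
  surv <- logical(replicates)
  for (r in seq_len(replicates)) {
    init <- if (params$competition) {
      init_full(L, fraction_nc, seed = .derive_seed(seed, r, 2))
    } else {
      init_full(L)
    }
    run <- run_ips(params, init, t_max,
      sample_dt = t_max,
      seed = .derive_seed(seed, r, 1)
    )
    surv[r] <- !run$absorbed
  }
  mean(surv)
}

#' Locate a critical point by survival-probability bisection
#'
#' Estimates the critical value of a control parameter (`delta` or `e`) of the
#' absorbing-state transition: a probe value is called subcritical
#' (persistent) when at least half of the seeded replicate runs from full
#' occupancy still have occupied sites at `t_max`. Requires a valid bracket
#' (persistent at `bracket[1]`, extinct at `bracket[2]`) and bisects to the
#' requested width.
#'
#' @param control `"delta"` or `"e"`.
#' @param params A [model_params()]; the control entry is overridden.
#' @param bracket `c(lo, hi)` control values bracketing the transition.
#' @param L Lattice side (the protocol default for the contact-process
#'   benchmark is 128).
#' @param t_max Run length per probe (default 2000).
#' @param replicates Replicates per probe (>= 10 for the benchmark protocol).
#' @param tol Final bracket width (default 0.005).
#' @param seed Base seed.
#' @return A `critical_fit` object: `k_name`, `k_crit` (bracket midpoint),
#'   `bracket`, `probes` (data frame of probe values and survival), `tol`.
#' @examples
#' \donttest{
#' # contact-process benchmark: recovers delta_c about 0.6065
#' estimate_critical_point("delta", model_params(e = 0, c = 0),
#'   bracket = c(0.5, 0.7), L = 64, t_max = 500, replicates = 5, seed = 1
#' )
#' }
#' @export
estimate_critical_point <- function(control = c("delta", "e"), params = model_params(),
                                    bracket, L = 128, t_max = 2000,
                                    replicates = 10, tol = 0.005, seed = 1) {
  control <- match.arg(control)
  stopifnot(
    "'bracket' must be c(lo, hi) with lo < hi" =
      length(bracket) == 2 && bracket[1] < bracket[2]
  )
  probe <- function(k, pseed) {
    p <- params
    p[[control]] <- k
    .survival_prob(p, L, t_max, replicates, pseed)
  }
  probes <- data.frame(k = numeric(0), survival = numeric(0))
  note <- function(k, s) probes[nrow(probes) + 1, ] <<- c(k, s)

  s_lo <- probe(bracket[1], .derive_seed(seed, 1))
  note(bracket[1], s_lo)
  s_hi <- probe(bracket[2], .derive_seed(seed, 2))
  note(bracket[2], s_hi)
  if (s_lo < 0.5 || s_hi >= 0.5) {
    stop(sprintf(
      "invalid bracket: survival %.2f at %s=%g, %.2f at %s=%g (need >= 0.5 then < 0.5)",
      s_lo, control, bracket[1], s_hi, control, bracket[2]
    ))
  }
  lo <- bracket[1]
  hi <- bracket[2]
  i <- 2
  while (hi - lo > tol) {
    i <- i + 1
    mid <- (lo + hi) / 2
    s <- probe(mid, .derive_seed(seed, i))
    note(mid, s)
    if (s >= 0.5) lo <- mid else hi <- mid
  }
  structure(
    list(
      k_name = control, k_crit = (lo + hi) / 2, bracket = c(lo, hi),
      probes = probes, tol = tol, L = L, t_max = t_max,
      replicates = replicates
    ),
    class = "critical_fit"
  )
}

#' @export
print.critical_fit <- function(x, ...) {
  if (!is.null(x$exponent)) {
    cat(sprintf(
      "<critical_fit> exponent %.4f (se %.4f) from %d points below %s_crit=%.4f\n",
      x$exponent, x$stderr, x$n_points, x$k_name, x$k_crit
    ))
  } else {
    cat(sprintf(
      "<critical_fit> %s_crit = %.4f (bracket [%.4f, %.4f], %d probes)\n",
      x$k_name, x$k_crit, x$bracket[1], x$bracket[2], nrow(x$probes)
    ))
  }
  invisible(x)
}

#' Refine a critical point from the survival curve
#'
#' Second-stage refinement of a bisection estimate: measures the survival
#' probability (occupied sites remaining at `t_max`, from full occupancy) on
#' a grid of control values spanning the coarse estimate, fits a binomial
#' GLM (logistic dose-response) and returns its 50% crossing. Pooling all
#' probes into one smooth fit makes the estimate far less sensitive to a
#' single borderline probe than a bisection path, which matters when a
#' downstream quantity (the order-parameter exponent) amplifies errors in
#' the critical point. Longer horizons sharpen the curve: the crossing
#' approaches the true critical point as `t_max^(-1/nu_parallel)`.
#'
#' @param control `"delta"` or `"e"`.
#' @param params Base [model_params()]; the control entry is overridden.
#' @param k_values Probe grid (should straddle the transition).
#' @param L Lattice side.
#' @param t_max Survival horizon (long: default 10000).
#' @param replicates Replicates per probe.
#' @param seed Base seed.
#' @return A `critical_fit` with `k_crit` (the 50% crossing), `probes` and
#'   the fitted `glm`. Falls back to the midpoint between the last mostly
#'   surviving and first mostly extinct probe if the fit cannot be computed.
#' @export
critical_point_survival_curve <- function(control = c("delta", "e"),
                                          params = model_params(), k_values,
                                          L = 128, t_max = 10000,
                                          replicates = 12, seed = 1) {
  control <- match.arg(control)
  surv <- vapply(seq_along(k_values), function(i) {
    p <- params
    p[[control]] <- k_values[i]
    .survival_prob(p, L, t_max, replicates, .derive_seed(seed, i))
  }, numeric(1))
  probes <- data.frame(k = k_values, survival = surv)
  k50 <- NA_real_
  if (length(unique(surv)) > 1) {
    fit <- suppressWarnings(stats::glm(
      cbind(
        round(surv * replicates),
        replicates - round(surv * replicates)
      ) ~ k_values,
      family = stats::binomial()
    ))
    b <- coef(fit)
    if (is.finite(b[2]) && b[2] < 0) k50 <- unname(-b[1] / b[2])
  }
  if (!is.finite(k50) || k50 < min(k_values) || k50 > max(k_values)) {
    alive <- which(surv >= 0.5)
    dead <- which(surv < 0.5)
    if (!length(alive) || !length(dead)) {
      stop("probe grid does not straddle the transition")
    }
    k50 <- (max(k_values[alive]) + min(k_values[dead])) / 2
  }
  structure(
    list(
      k_name = control, k_crit = k50, bracket = range(k_values),
      probes = probes, tol = NA_real_, L = L, t_max = t_max,
      replicates = replicates
    ),
    class = "critical_fit"
  )
}

#' Long-run occupancy at a set of control-parameter values
#'
#' Measures the order parameter (time-averaged occupied fraction after a
#' transient) at each control value, averaging over replicates; the input for
#' the power-law exponent fit.
#'
#' @param control `"delta"` or `"e"`.
#' @param k_values Control values.
#' @param params Base [model_params()].
#' @param L Lattice side.
#' @param t_transient,t_avg Discarded transient and averaging window.
#' @param replicates Replicates averaged per value (extinct runs enter as 0).
#' @param seed Base seed.
#' @return Data frame `k`, `occupancy`.
#' @export
order_parameter_samples <- function(control = c("delta", "e"), k_values,
                                    params = model_params(), L = 128,
                                    t_transient = 1500, t_avg = 500,
                                    replicates = 2, seed = 1) {
  control <- match.arg(control)
  occ <- vapply(seq_along(k_values), function(i) {
    p <- params
    p[[control]] <- k_values[i]
    mean(vapply(seq_len(replicates), function(r) {
      run <- run_ips(p, init_full(L), t_transient + t_avg,
        sample_dt = 1, seed = .derive_seed(seed, i, r)
      )
      if (run$absorbed) 0 else mean_occupancy(run, t_transient)[["p_nc"]]
    }, numeric(1)))
  }, numeric(1))
  data.frame(k = k_values, occupancy = occ)
}

#' Fit the order-parameter exponent near criticality
#'
#' Least-squares slope of `log(occupancy)` against `log(k_crit - k)` for
#' control values below the critical point: the power-law exponent `beta`
#' of the continuous absorbing-state transition.
#'
#' @param k_values Control values, all strictly below `k_crit`.
#' @param occupancies Long-run mean occupancies at `k_values`.
#' @param k_crit The critical point estimate.
#' @return A `critical_fit` object with `exponent`, `stderr`, `n_points`,
#'   `fit_window` (range of `k_crit - k` used) and the underlying `lm` fit.
#' @examples
#' k <- 0.6 - c(0.005, 0.01, 0.02, 0.04)
#' fit_order_parameter_exponent(k, 0.8 * (0.6 - k)^0.58, 0.6)$exponent
#' @export
fit_order_parameter_exponent <- function(k_values, occupancies, k_crit) {
  stopifnot(
    "all control values must lie strictly below k_crit" = all(k_values < k_crit),
    length(k_values) == length(occupancies)
  )
  keep <- occupancies > 0
  if (sum(keep) < 3) stop("need at least 3 positive-occupancy points to fit")
  dk <- k_crit - k_values[keep]
  fit <- lm(log(occupancies[keep]) ~ log(dk))
  x <- log(dk)
  dof <- length(x) - 2
  se <- sqrt(sum(fit$residuals^2) / dof / sum((x - mean(x))^2))
  structure(
    list(
      k_name = "k", k_crit = k_crit,
      exponent = unname(coef(fit)[2]), stderr = se,
      n_points = sum(keep), fit_window = range(dk), fit = fit
    ),
    class = "critical_fit"
  )
}

#' Relaxation profiles around the critical point
#'
#' Mean occupancy decay curves for control values below, at and above the
#' critical point, started from full occupancy. Each curve is classified:
#' `"subcritical"` when the occupancy plateaus at a positive quasi-stationary
#' level, otherwise `"critical"` when the decay is closer to a power law
#' (better linear fit of log p vs log t) and `"supercritical"` when it is
#' closer to exponential (log p vs t).
#'
#' @param control `"delta"` or `"e"`.
#' @param k_values Control values (e.g. `c(sub = , at = , super = )`).
#' @param params Base [model_params()].
#' @param L Lattice side.
#' @param t_max Run length.
#' @param replicates Replicates averaged per value.
#' @param seed Base seed.
#' @param fit_window Time window `c(lo, hi)` used for the decay-shape fits.
#' @return List with `profiles` (data frame `k`, `t`, `p_occ`) and
#'   `classification` (character vector along `k_values`).
#' @export
relaxation_profile <- function(control = c("delta", "e"), k_values,
                               params = model_params(), L = 128, t_max = 1000,
                               replicates = 3, seed = 1,
                               fit_window = c(10, t_max)) {
  control <- match.arg(control)
  profiles <- list()
  classification <- character(length(k_values))
  for (i in seq_along(k_values)) {
    p <- params
    p[[control]] <- k_values[i]
    acc <- NULL
    for (r in seq_len(replicates)) {
      run <- run_ips(p, init_full(L), t_max,
        sample_dt = 1,
        seed = .derive_seed(seed, i, r)
      )
      occ <- run$trajectory$p_nc + run$trajectory$p_ex
      acc <- if (is.null(acc)) occ else acc + occ
    }
    occ <- acc / replicates
    tt <- seq(0, t_max, by = 1)
    profiles[[i]] <- data.frame(k = unname(k_values[i]), t = tt, p_occ = occ)
    classification[i] <- .classify_decay(tt, occ, fit_window)
  }
  list(
    profiles = do.call(rbind, profiles),
    classification = setNames(classification, names(k_values))
  )
}

.classify_decay <- function(tt, occ, fit_window) {
  sel <- tt >= fit_window[1] & tt <= fit_window[2] & occ > 0
  if (sum(sel) < 5) {
    return("supercritical") # died almost immediately
  }
  late <- occ[tt >= 0.8 * max(tt[sel])]
  mid <- occ[tt >= 0.4 * max(tt[sel]) & tt < 0.6 * max(tt[sel])]
  if (length(late) && length(mid) && mean(mid) > 0 &&
    mean(late) > 0.8 * mean(mid) && mean(late) > 1e-3) {
    return("subcritical")
  }
  r2 <- function(f) summary(f)$r.squared
  exp_fit <- lm(log(occ[sel]) ~ tt[sel])
  pow_fit <- lm(log(occ[sel]) ~ log(tt[sel]))
  if (r2(pow_fit) > r2(exp_fit)) "critical" else "supercritical"
}

#' Range expansion from a single seed
#'
#' Grows the metapopulation from one central NC site on an initially
#' habitable (vacant) lattice for each construction range in `r_values`: away
#' from the population the landscape decays into the destroyed vacuum at rate
#' `e`, while the expanding mosaic renews it. Tracks the occupied
#' count and the mosaic extent (maximum Chebyshev radius of occupied sites
#' from the seed). Saturation time is the first time the occupancy reaches
#' `plateau_frac` of its long-run plateau (mean occupancy over the final fifth
#' of the run). Replicates are conditioned on establishment: a seed whose
#' lineage dies or fails to reach `min_plateau` is redrawn (up to `max_tries`
#' attempts), because saturation time is undefined for a failed establishment.
#'
#' @param params Base [model_params()] (use destruction `e` well below the
#'   critical rate); `r_con` is overridden by `r_values`.
#' @param r_values Construction ranges to compare.
#' @param L Lattice side.
#' @param t_max Run length.
#' @param replicates Established replicates per range.
#' @param seed Base seed; replicate `i` shares its seed stream across ranges
#'   (paired comparison).
#' @param plateau_frac Fraction of the plateau defining saturation.
#' @param min_plateau Minimum plateau occupancy accepted as established.
#' @param max_tries Attempt cap per replicate.
#' @return An `expansion_result`: `summary` data frame (`r`, `replicate`,
#'   `t_saturation`, `plateau`, `tries`) and `curves`, one data frame per `r`
#'   with per-time mean `occupied` and `extent` across replicates.
#' @export
range_expansion <- function(params, r_values, L = 128, t_max = 1500,
                            replicates = 10, seed = 1, plateau_frac = 0.9,
                            min_plateau = 0.02, max_tries = 20) {
  summary_rows <- list()
  curves <- list()
  for (r in r_values) {
    p <- params
    p$r_con <- r
    acc_occ <- acc_ext <- NULL
    for (rep in seq_len(replicates)) {
      run <- NULL
      tries <- 0
      plateau <- 0
      while (tries < max_tries) {
        tries <- tries + 1
        cand <- run_ips(p, init_single_seed(L, background = "vacant"), t_max,
          sample_dt = 1,
          seed = .derive_seed(seed, rep, tries), track_extent = TRUE
        )
        occ <- cand$trajectory$p_nc + cand$trajectory$p_ex
        plateau <- mean(occ[cand$trajectory$t >= 0.8 * t_max])
        if (!cand$absorbed && plateau >= min_plateau) {
          run <- cand
          break
        }
      }
      if (is.null(run)) {
        stop(sprintf(
          "no established expansion in %d tries at r=%s (e too close to e_crit?)",
          max_tries, format(r)
        ))
      }
      occ <- run$trajectory$p_nc + run$trajectory$p_ex
      t_sat <- run$trajectory$t[which(occ >= plateau_frac * plateau)[1]]
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        r = r, replicate = rep, t_saturation = t_sat, plateau = plateau,
        tries = tries
      )
      acc_occ <- if (is.null(acc_occ)) run$trajectory$occupied else acc_occ + run$trajectory$occupied
      acc_ext <- if (is.null(acc_ext)) run$trajectory$extent else acc_ext + run$trajectory$extent
    }
    curves[[as.character(r)]] <- data.frame(
      t = seq(0, t_max, by = 1),
      occupied = acc_occ / replicates,
      extent = acc_ext / replicates
    )
  }
  structure(
    list(summary = do.call(rbind, summary_rows), curves = curves, params = params),
    class = "expansion_result"
  )
}

#' @export
print.expansion_result <- function(x, ...) {
  agg <- stats::aggregate(t_saturation ~ r, data = x$summary, FUN = mean)
  cat("<expansion_result> mean saturation time by construction range:\n")
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  r=%-3s t_sat=%.1f\n", format(agg$r[i]), agg$t_saturation[i]))
  }
  invisible(x)
}

#' Classify the outcome of a competition run
#'
#' Labels a two-strategy trajectory with the disturbance-regime outcome:
#' \itemize{
#'   \item `NC_monopoly`: the exploiter went extinct and the constructor
#'     plateaus above `theta` (high-disturbance regime);
#'   \item `coexistence`: both strategies average above `theta` over the final
#'     window (intermediate disturbance);
#'   \item `ecological_suicide`: the constructor was driven extinct first
#'     (while the exploiter was still above `theta`), after which the
#'     exploiter collapsed with the landscape (low disturbance, `e > 0`);
#'   \item `competitive_exclusion`: `e = 0` only; the constructor went extinct
#'     and the exploiter persists;
#'   \item `trivial_extinction`: both strategies died under `e > 0` without an
#'     exclusion event (the exploiter was already below `theta` when the
#'     constructor died, or died first);
#'   \item `ambiguous`: still transient at the end of the run (e.g. the
#'     constructor is extinct but the doomed exploiter has not yet collapsed).
#' }
#'
#' @param run An `ips_run` from a competition simulation (or its trajectory
#'   data frame, in which case `e` must be supplied).
#' @param window Fraction of the run forming the final averaging window.
#' @param theta Occupancy threshold separating persistence from lingering
#'   transients (default 0.01).
#' @param e Destruction rate (taken from `run$params` when available).
#' @return A `regime_label` object: `label` plus the extinction times and
#'   window means behind the decision.
#' @export
classify_regime <- function(run, window = 0.25, theta = 0.01, e = NULL) {
  traj <- if (inherits(run, "ips_run")) run$trajectory else run
  if (is.null(e)) {
    if (!inherits(run, "ips_run")) stop("'e' must be given with a bare trajectory")
    e <- run$params$e
  }
  t_end <- max(traj$t)
  win <- traj$t >= (1 - window) * t_end
  mean_nc <- mean(traj$p_nc[win])
  mean_ex <- mean(traj$p_ex[win])
  t0 <- function(p) {
    i <- which(p == 0)[1]
    if (is.na(i)) NA_real_ else traj$t[i]
  }
  t_nc <- t0(traj$p_nc)
  t_ex <- t0(traj$p_ex)
  ex_at_nc_death <- if (!is.na(t_nc)) traj$p_ex[match(t_nc, traj$t)] else NA_real_

  label <- if (is.na(t_nc) && is.na(t_ex)) {
    if (mean_nc > theta && mean_ex > theta) "coexistence" else "ambiguous"
  } else if (is.na(t_nc)) { # exploiter extinct, constructor alive
    if (mean_nc > theta) "NC_monopoly" else "ambiguous"
  } else if (is.na(t_ex)) { # constructor extinct, exploiter alive
    if (e == 0 && mean_ex > theta) "competitive_exclusion" else "ambiguous"
  } else { # both extinct
    if (e > 0 && t_nc < t_ex && !is.na(ex_at_nc_death) && ex_at_nc_death > theta) {
      "ecological_suicide"
    } else if (e > 0) {
      "trivial_extinction"
    } else {
      "ambiguous"
    }
  }
  structure(
    list(
      label = label, t_extinct_nc = t_nc, t_extinct_ex = t_ex,
      mean_nc = mean_nc, mean_ex = mean_ex, theta = theta, e = e
    ),
    class = "regime_label"
  )
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf(
    "<regime_label> %s  (final means: NC %.4f, EX %.4f)\n",
    x$label, x$mean_nc, x$mean_ex
  ))
  invisible(x)
}

#' Space-time transect of a run
#'
#' Extracts the recorded 1D spatial transect (one lattice row through time)
#' from a run made with `record_row`.
#'
#' @param run An `ips_run` created with `record_row = row`.
#' @param row The recorded row (defaults to the one recorded; any other value
#'   is an error).
#' @return A `transect` object: integer matrix of state codes, one row per
#'   sample time (attribute `times`), one column per lattice column.
#' @export
transect <- function(run, row = run$record_row) {
  if (is.null(run$row_snapshots)) {
    stop("run was not recorded with 'record_row'")
  }
  if (is.null(row) || length(row) != 1 || row != run$record_row) {
    stop(sprintf("row %s was not recorded (recorded row: %d)", format(row), run$record_row))
  }
  structure(run$row_snapshots,
    times = run$trajectory$t, row = run$record_row,
    class = c("transect", "matrix", "array")
  )
}

#' @export
print.transect <- function(x, ...) {
  cat(sprintf(
    "<transect> row %d, %d time samples x %d sites\n",
    attr(x, "row"), nrow(x), ncol(x)
  ))
  invisible(x)
}

#' Write a PNG of a space-time transect
#'
#' @param tr A [transect()] object.
#' @param path Output PNG path.
#' @param pixel_size Pixels per cell.
#' @return `path`, invisibly.
#' @export
write_transect_png <- function(tr, path, pixel_size = 2) {
  pal <- c("black", "white", "forestgreen", "red3")
  grDevices::png(path, width = ncol(tr) * pixel_size, height = nrow(tr) * pixel_size)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({
    graphics::par(op)
    grDevices::dev.off()
  })
  z <- t(unclass(tr))[, nrow(tr):1, drop = FALSE] # time flows downward
  graphics::image(z,
    col = pal, breaks = c(-1.5, -0.5, 0.5, 1.5, 2.5),
    axes = FALSE, useRaster = TRUE
  )
  invisible(path)
}

#' Occupancy against destruction rate
#'
#' Long-run occupancy curve over a grid of destruction rates at fixed
#' strategy, the raw material of the transition-sharpness comparison between
#' construction ranges.
#'
#' @param params Base [model_params()].
#' @param e_values Destruction rates.
#' @param L Lattice side.
#' @param t_transient,t_avg Protocol windows.
#' @param replicates Replicates averaged per rate (extinct runs enter as 0).
#' @param seed Base seed.
#' @return Data frame `e`, `occupancy`.
#' @export
occupancy_vs_e <- function(params, e_values, L = 64, t_transient = 600,
                           t_avg = 100, replicates = 3, seed = 1) {
  df <- order_parameter_samples(
    "e", e_values,
    params = params, L = L,
    t_transient = t_transient, t_avg = t_avg, replicates = replicates,
    seed = seed
  )
  names(df) <- c("e", "occupancy")
  df
}

#' Width of the occupancy drop across the extinction transition
#'
#' Measures how sharply the order parameter falls with the destruction rate:
#' the distance in `e` between the (interpolated) last crossing of
#' `hi * max(occupancy)` and the subsequent crossing of `lo * max(occupancy)`.
#' Sharper (more discontinuous) transitions give smaller widths.
#'
#' @param e_values Increasing destruction rates.
#' @param occupancy Matching long-run occupancies.
#' @param hi,lo Fractions of the maximum occupancy defining the drop.
#' @return The width in `e` (possibly 0 for a one-step drop); `NA` if the
#'   curve never falls below `lo * max`.
#' @export
transition_width <- function(e_values, occupancy, hi = 0.75, lo = 0.05) {
  stopifnot(length(e_values) == length(occupancy), !is.unsorted(e_values))
  pmax_ref <- max(occupancy)
  cross <- function(level) {
    above <- which(occupancy >= level)
    if (!length(above)) {
      return(e_values[1])
    }
    i <- max(above) # last point at or above the level
    if (i == length(e_values)) {
      return(NA_real_)
    }
    # linear interpolation between the bracketing grid points
    e0 <- e_values[i]
    e1 <- e_values[i + 1]
    p0 <- occupancy[i]
    p1 <- occupancy[i + 1]
    if (p0 == p1) e0 else e0 + (p0 - level) / (p0 - p1) * (e1 - e0)
  }
  e_hi <- cross(hi * pmax_ref)
  e_lo <- cross(lo * pmax_ref)
  if (is.na(e_hi) || is.na(e_lo)) {
    return(NA_real_)
  }
  max(0, e_lo - e_hi)
}
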