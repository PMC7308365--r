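#' Mean-field vector field
#'
#' Right-hand side of the well-mixed (mean-field) reduction of the model, in
#' the destroyed/occupied fractions `(p_minus, p_plus)` with
#' `p_vacant = 1 - p_plus - p_minus`:
#' \deqn{\dot p_- = e (1 - p_-) - c\, p_+ p_-}
#' \deqn{\dot p_+ = (1-c)^\alpha p_+ (1 - p_+ - p_-) - p_+ (\delta + e)}
#' With `c = 0`, `e = 0`, `p_minus = 0` this is the Levins metapopulation
#' equation `dp/dt = p(1 - p) - delta p`.
#'
#' @param state Numeric `c(p_minus, p_plus)`.
#' @param params A [model_params()] object.
#' @return Numeric `c(dp_minus, dp_plus)`.
#' @export
mf_rhs <- function(state, params) {
  pm <- state[[1]]
  pp <- state[[2]]
  c(
    params$e * (1 - pm) - params$c * pp * pm,
    .beta_col(params) * pp * (1 - pp - pm) - pp * (params$delta + params$e)
  )
}

# Jacobian of mf_rhs at (pm, pp).
.mf_jacobian <- function(pm, pp, params) {
  beta <- .beta_col(params)
  matrix(
    c(
      -params$e - params$c * pp, -params$c * pm,
      -beta * pp, beta * (1 - 2 * pp - pm) - (params$delta + params$e)
    ),
    2, 2,
    byrow = TRUE
  )
}

.mf_equilibrium <- function(pm, pp, kind, params, tol = 1e-10) {
  ev <- eigen(.mf_jacobian(pm, pp, params), only.values = TRUE)$values
  re <- Re(ev)
  if (params$e == 0 && params$c == 0) {
    # degenerate Levins limit: p_minus is frozen, so its neutral direction
    # carries a structural zero eigenvalue; judge stability on the occupied
    # direction alone
    re <- .mf_jacobian(pm, pp, params)[2, 2]
  }
  stable <- if (all(re < -tol)) TRUE else if (any(re > tol)) FALSE else NA
  structure(
    list(
      p_minus = pm, p_plus = pp, p_vacant = 1 - pm - pp,
      kind = kind, stable = stable, eigenvalues = ev,
      s_bar = 1 - pm,
      Lambda = params$c * pp,
      delta_tilde = params$delta + params$e,
      R0 = if (params$delta > 0) 1 / params$delta else Inf,
      tau = if (params$e > 0) 1 / params$e else Inf
    ),
    class = "mf_equilibrium"
  )
}

#' @export
print.mf_equilibrium <- function(x, ...) {
  cat(sprintf(
    "<mf_equilibrium %s> p-=%.6f  p+=%.6f  %s\n", x$kind, x$p_minus, x$p_plus,
    if (isTRUE(x$stable)) "stable" else if (isFALSE(x$stable)) "unstable" else "marginal"
  ))
  invisible(x)
}

#' Mean-field equilibria and their stability
#'
#' All equilibria of the mean-field system in the simplex. Besides the
#' absorbing state (`p_minus = 1` when `e > 0`; the extinct axis `p_plus = 0`
#' when `e = 0`), interior equilibria solve
#' `p_minus = e / (e + c p_plus)` together with
#' `p_vacant = (delta + e) / (1 - c)^alpha`, which reduces to a quadratic in
#' `p_plus`:
#' `c p+^2 + (e - c (1 - K)) p+ + e K = 0` with `K = (delta+e)/(1-c)^alpha`.
#' Both real roots in the simplex are returned with stability labels (the
#' bistable window below the saddle-node has an upper stable and a lower
#' unstable root). At every interior root the suitable-habitat identity
#' `s_bar = Lambda / (Lambda + e)` with `Lambda = c p_plus` holds.
#'
#' @param params A [model_params()] object.
#' @param tol Stability tolerance on eigenvalue real parts.
#' @return List of `mf_equilibrium` objects (absorbing first).
#' @examples
#' eq <- mf_equilibria(model_params(delta = 0.1, e = 0, c = 0))
#' eq[[2]]$p_plus # Levins equilibrium 1 - delta = 0.9
#' @export
mf_equilibria <- function(params, tol = 1e-10) {
  beta <- .beta_col(params)
  out <- list()
  if (params$e > 0) {
    out[[1]] <- .mf_equilibrium(1, 0, "absorbing", params, tol)
  } else {
    out[[1]] <- .mf_equilibrium(0, 0, "absorbing", params, tol)
  }
  if (beta <= 0) {
    return(out) # c = 1 with alpha > 0: no colonization, only extinction
  }
  K <- (params$delta + params$e) / beta
  if (K >= 1) {
    return(out)
  }
  if (params$e == 0) {
    # clean landscape: p_minus stays 0, Levins-type interior root
    out[[length(out) + 1]] <-
      .mf_equilibrium(0, 1 - K, "interior", params, tol)
    return(out)
  }
  if (params$c == 0) {
    return(out) # destruction without construction: landscape decays
  }
  a <- params$c
  b <- params$e - params$c * (1 - K)
  cc <- params$e * K
  disc <- b^2 - 4 * a * cc
  if (disc < 0 || b >= 0) {
    return(out)
  }
  sq <- sqrt(disc)
  roots <- sort((-b + c(-1, 1) * sq) / (2 * a))
  for (pp in roots) {
    if (pp <= 0 || pp > 1) next
    pm <- params$e / (params$e + params$c * pp)
    out[[length(out) + 1]] <- .mf_equilibrium(pm, pp, "interior", params, tol)
    if (disc == 0) break # double root: report once
  }
  out
}

# TRUE if an interior equilibrium exists at destruction rate e.
.mf_interior_exists <- function(e, c, delta, alpha) {
  beta <- (1 - c)^alpha
  if (beta <= 0) {
    return(FALSE)
  }
  K <- (delta + e) / beta
  if (K >= 1) {
    return(FALSE)
  }
  if (e == 0) {
    return(TRUE)
  }
  if (c == 0) {
    return(FALSE)
  }
  b <- e - c * (1 - K)
  b < 0 && b^2 - 4 * c * e * K >= 0
}

#' Critical destruction rate of the mean field
#'
#' The largest destruction rate `e` for which the mean field admits an
#' interior equilibrium, i.e. the saddle-node locus where the discriminant of
#' the interior quadratic vanishes. Just below this threshold the stable
#' occupancy is still finite, so the mean-field extinction transition is
#' discontinuous. Computed by bisection on the existence predicate over
#' `e` in `[0, 1]`.
#'
#' @param c Construction allocation in `(0, 1)` (boundaries give 0).
#' @param delta Extinction rate.
#' @param alpha Trade-off exponent.
#' @param tol Bisection tolerance (default `1e-8`).
#' @return The critical rate `e_crit >= 0`; 0 when no interior equilibrium
#'   exists for any `e > 0` (e.g. `delta >= (1-c)^alpha`).
#' @examples
#' mf_ecrit(0.4, delta = 0.1, alpha = 1)
#' @export
mf_ecrit <- function(c, delta, alpha, tol = 1e-8) {
  stopifnot(
    "'c' must be in [0, 1]" = length(c) == 1 && c >= 0 && c <= 1,
    "'delta' must be >= 0" = delta >= 0, "'alpha' must be >= 0" = alpha >= 0
  )
  if (!.mf_interior_exists(tol * 1e-3, c, delta, alpha)) {
    return(0)
  }
  lo <- 0
  hi <- 1 # K(e = 1) = (delta + 1)/(1-c)^alpha >= 1: never interior
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.mf_interior_exists(mid, c, delta, alpha)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Optimal construction allocation of the mean field
#'
#' The allocation `c**` that maximizes the critical destruction rate
#' [mf_ecrit()], i.e. the strategy persisting in the broadest range of
#' ephemeral landscapes (the vertex of the extinction-threshold curve
#' `e_crit(c)`).
#'
#' @param delta Extinction rate (`delta < 1` for a nondegenerate problem).
#' @param alpha Trade-off exponent.
#' @param tol Optimization tolerance on `c` (default `1e-4`).
#' @return List with `c_star` (argmax) and `e_crit` (its threshold).
#' @examples
#' mf_cstar(delta = 0.1, alpha = 1)$c_star # about 0.4
#' @export
mf_cstar <- function(delta, alpha, tol = 1e-4) {
  grid <- seq(0.005, 0.995, by = 0.005)
  vals <- vapply(grid, mf_ecrit, numeric(1), delta = delta, alpha = alpha)
  if (max(vals) <= 0) {
    stop("degenerate problem: e_crit(c) is identically 0 (is delta >= 1?)")
  }
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(
    function(x) mf_ecrit(x, delta, alpha),
    interval = c(lo, hi), maximum = TRUE, tol = tol
  )
  list(c_star = opt$maximum, e_crit = opt$objective)
}

# --- adaptive Cash-Karp RK45 with cubic-Hermite dense output ----------------
# (no ODE-solver package in the dependency stack; the 2-state system is
# non-stiff away from the saddle-node, where tight tolerances keep steps small)

.rk45 <- function(f, y0, t_max, rtol = 1e-9, atol = 1e-12, h0 = 1e-3) {
  a <- list(
    c2 = 1 / 5, c3 = 3 / 10, c4 = 3 / 5, c5 = 1, c6 = 7 / 8,
    b21 = 1 / 5,
    b31 = 3 / 40, b32 = 9 / 40,
    b41 = 3 / 10, b42 = -9 / 10, b43 = 6 / 5,
    b51 = -11 / 54, b52 = 5 / 2, b53 = -70 / 27, b54 = 35 / 27,
    b61 = 1631 / 55296, b62 = 175 / 512, b63 = 575 / 13824,
    b64 = 44275 / 110592, b65 = 253 / 4096
  )
  c5th <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  c4th <- c(
    2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4
  )
  ts <- numeric(512)
  ys <- matrix(NA_real_, 512, length(y0))
  fs <- matrix(NA_real_, 512, length(y0))
  n <- 1
  t <- 0
  y <- y0
  k1 <- f(y)
  ts[1] <- 0
  ys[1, ] <- y
  fs[1, ] <- k1
  h <- h0
  while (t < t_max) {
    h <- min(h, t_max - t)
    k2 <- f(y + h * a$b21 * k1)
    k3 <- f(y + h * (a$b31 * k1 + a$b32 * k2))
    k4 <- f(y + h * (a$b41 * k1 + a$b42 * k2 + a$b43 * k3))
    k5 <- f(y + h * (a$b51 * k1 + a$b52 * k2 + a$b53 * k3 + a$b54 * k4))
    k6 <- f(y + h * (a$b61 * k1 + a$b62 * k2 + a$b63 * k3 + a$b64 * k4 + a$b65 * k5))
    y5 <- y + h * (c5th[1] * k1 + c5th[3] * k3 + c5th[4] * k4 + c5th[6] * k6)
    y4 <- y + h * (c4th[1] * k1 + c4th[3] * k3 + c4th[4] * k4 + c4th[5] * k5 + c4th[6] * k6)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1 || h <= 1e-14) {
      t <- t + h
      y <- y5
      k1 <- f(y)
      n <- n + 1
      if (n > nrow(ys)) {
        ts <- c(ts, numeric(nrow(ys)))
        ys <- rbind(ys, matrix(NA_real_, nrow(ys), ncol(ys)))
        fs <- rbind(fs, matrix(NA_real_, nrow(fs), ncol(fs)))
      }
      ts[n] <- t
      ys[n, ] <- y
      fs[n, ] <- k1
    }
    fac <- if (err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
  }
  list(ts = ts[seq_len(n)], ys = ys[seq_len(n), , drop = FALSE], fs = fs[seq_len(n), , drop = FALSE])
}

# Cubic Hermite interpolation of an .rk45 solution onto arbitrary times.
.hermite_eval <- function(sol, times) {
  idx <- findInterval(times, sol$ts, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx >= length(sol$ts)] <- length(sol$ts) - 1
  if (length(sol$ts) == 1) {
    return(matrix(sol$ys[1, ], length(times), ncol(sol$ys), byrow = TRUE))
  }
  t0 <- sol$ts[idx]
  t1 <- sol$ts[idx + 1]
  hh <- t1 - t0
  s <- ifelse(hh > 0, (times - t0) / hh, 0)
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  out <- matrix(NA_real_, length(times), ncol(sol$ys))
  for (j in seq_len(ncol(sol$ys))) {
    out[, j] <- h00 * sol$ys[idx, j] + h10 * hh * sol$fs[idx, j] +
      h01 * sol$ys[idx + 1, j] + h11 * hh * sol$fs[idx + 1, j]
  }
  out
}

#' Integrate the mean-field dynamics
#'
#' Adaptive Runge-Kutta (Cash-Karp 4/5) integration of the mean-field system
#' from an initial state, with dense output on a fixed time grid. Trajectories
#' started in the simplex stay in it (up to the integration tolerance; output
#' is clamped to `[0, 1]`).
#'
#' @param params A [model_params()] object.
#' @param init Numeric `c(p_minus, p_plus)` in the simplex.
#' @param t_max Integration horizon.
#' @param sample_dt Output sampling interval (default `t_max / 500`).
#' @param rtol,atol Integration tolerances.
#' @return Data frame `t`, `p_minus`, `p_vacant`, `p_plus`.
#' @examples
#' tr <- mf_integrate(model_params(delta = 0.1), c(0, 0.5), t_max = 100)
#' tail(tr$p_plus, 1) # approaches the Levins equilibrium 0.9
#' @export
mf_integrate <- function(params, init, t_max, sample_dt = NULL,
                         rtol = 1e-9, atol = 1e-12) {
  stopifnot(
    "'init' must be c(p_minus, p_plus) in the simplex" =
      length(init) == 2 && all(init >= 0) && sum(init) <= 1 + 1e-12
  )
  if (is.null(sample_dt)) sample_dt <- t_max / 500
  times <- seq(0, t_max, by = sample_dt)
  sol <- .rk45(function(y) mf_rhs(y, params), as.numeric(init), t_max,
    rtol = rtol, atol = atol
  )
  y <- .hermite_eval(sol, times)
  y <- pmin(pmax(y, 0), 1)
  data.frame(
    t = times, p_minus = y[, 1], p_vacant = pmax(0, 1 - y[, 1] - y[, 2]),
    p_plus = y[, 2]
  )
}

#' Mean-field phase matrix over a (c, e) grid
#'
#' Long-term occupancy of the mean field over a grid of construction
#' allocations and destruction rates, mirroring the stochastic phase-diagram
#' protocol. `method = "integrate"` (default) integrates from full occupancy
#' `(p_minus, p_plus) = (0, 1)` for `t_max` time units and reports the final
#' occupancy; `method = "equilibrium"` reports the stable interior root when
#' one exists and 0 otherwise.
#'
#' @param c_values,e_values Axis grids.
#' @param delta,alpha Fixed life-history parameters.
#' @param method `"integrate"` or `"equilibrium"`.
#' @param t_max Integration horizon for `method = "integrate"`.
#' @param rtol Integration tolerance (the default is looser than
#'   [mf_integrate()]'s because thousands of cells are integrated).
#' @return Matrix of `p_plus` values, `length(e_values)` rows (increasing `e`)
#'   by `length(c_values)` columns.
#' @export
mf_phase_matrix <- function(c_values, e_values, delta = 0.1, alpha = 1,
                            method = c("integrate", "equilibrium"),
                            t_max = 5000, rtol = 1e-7) {
  method <- match.arg(method)
  out <- matrix(
    NA_real_, length(e_values), length(c_values),
    dimnames = list(signif(e_values, 6), signif(c_values, 6))
  )
  for (j in seq_along(c_values)) {
    for (i in seq_along(e_values)) {
      p <- model_params(delta = delta, e = e_values[i], c = c_values[j], alpha = alpha)
      if (method == "equilibrium") {
        eq <- mf_equilibria(p)
        interior <- Filter(function(x) x$kind == "interior" && isTRUE(x$stable), eq)
        out[i, j] <- if (length(interior)) {
          max(vapply(interior, `[[`, numeric(1), "p_plus"))
        } else {
          0
        }
      } else {
        tr <- mf_integrate(p, c(0, 1), t_max,
          sample_dt = t_max, rtol = rtol, atol = 1e-10
        )
        out[i, j] <- tr$p_plus[nrow(tr)]
      }
    }
  }
  out
}
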