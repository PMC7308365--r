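test_that("the vector field reduces to its known limits", {
  p <- model_params(delta = 0.2, e = 0.05, c = 0.3, alpha = 1)
  # extinct axis: no occupied dynamics, landscape decays toward p- = 1
  d <- mf_rhs(c(0.4, 0), p)
  expect_equal(d[2], 0)
  expect_equal(d[1], 0.05 * 0.6)
  # Levins limit: c = 0, e = 0, p- = 0 gives p(1-p) - delta p
  p <- model_params(delta = 0.3, e = 0, c = 0)
  for (pp in c(0.1, 0.5, 0.9)) {
    expect_equal(mf_rhs(c(0, pp), p)[2], pp * (1 - pp) - 0.3 * pp)
  }
})

test_that("equilibria solve the fixed-point system with correct stability", {
  # Levins equilibrium 1 - delta
  eq <- mf_equilibria(model_params(delta = 0.1, e = 0, c = 0))
  expect_length(eq, 2)
  expect_equal(eq[[2]]$p_plus, 0.9)
  expect_true(eq[[2]]$stable)
  # R0 <= 1: only the absorbing state
  for (delta in c(1, 1.5)) {
    eq <- mf_equilibria(model_params(delta = delta, e = 0, c = 0))
    expect_length(eq, 1)
    expect_identical(eq[[1]]$kind, "absorbing")
  }
  # c = 1 with alpha > 0: no colonization at all
  eq <- mf_equilibria(model_params(delta = 0.1, e = 0.01, c = 1, alpha = 1))
  expect_length(eq, 1)

  # bistable window: two interior roots, upper stable / lower unstable,
  # verified against a dense sign-change scan of the scalar fixed-point map
  p <- model_params(delta = 0.1, e = 0.06, c = 0.4, alpha = 1)
  eq <- mf_equilibria(p)
  interior <- Filter(function(x) x$kind == "interior", eq)
  expect_length(interior, 2)
  pp <- sort(vapply(interior, `[[`, numeric(1), "p_plus"))
  grid <- seq(1e-6, 1, by = 1e-6)
  g <- function(x) {
    pm <- p$e / (p$e + p$c * x)
    (1 - p$c)^p$alpha * (1 - x - pm) - (p$delta + p$e)
  }
  sgn <- sign(g(grid))
  roots <- grid[which(diff(sgn) != 0)]
  expect_length(roots, 2)
  expect_equal(pp, sort(roots), tolerance = 1e-5)
  stab <- vapply(interior, `[[`, logical(1), "stable")
  names(stab) <- vapply(interior, function(x) if (x$p_plus == max(pp)) "hi" else "lo", "")
  expect_true(stab[["hi"]])
  expect_false(stab[["lo"]])

  # every reported equilibrium annihilates the vector field
  for (e in eq) {
    expect_equal(mf_rhs(c(e$p_minus, e$p_plus), p), c(0, 0), tolerance = 1e-12)
  }
})

test_that("the suitable-habitat identity holds at interior equilibria", {
  for (pars in list(
    model_params(delta = 0.1, e = 0.03, c = 0.25, alpha = 1),
    model_params(delta = 0.05, e = 0.06, c = 0.5, alpha = 2),
    model_params(delta = 0.2, e = 0.01, c = 0.6, alpha = 0.5)
  )) {
    interior <- Filter(
      function(x) x$kind == "interior",
      mf_equilibria(pars)
    )
    for (e in interior) {
      # s_bar = Lambda / (Lambda + e), and occupancy = s_bar - delta~/(1-c)^a
      expect_equal(e$s_bar, e$Lambda / (e$Lambda + pars$e), tolerance = 1e-12)
      expect_equal(
        e$p_plus,
        e$s_bar - e$delta_tilde / (1 - pars$c)^pars$alpha,
        tolerance = 1e-12
      )
    }
  }
})

test_that("the critical destruction rate is a saddle-node threshold", {
  # independent closed-form oracle at delta = 0: the saddle-node condition
  # reduces to e = c (1 - sqrt(e / (1-c)))^2, solvable by uniroot
  oracle <- uniroot(
    function(e) e - 0.4 * (1 - sqrt(e / 0.6))^2,
    c(1e-6, 0.2),
    tol = 1e-12
  )$root
  expect_equal(mf_ecrit(0.4, 0, 1), oracle, tolerance = 1e-6)

  ec <- mf_ecrit(0.4, 0.1, 1)
  # forward integration from full occupancy: persistent just below, extinct
  # just above the threshold
  below <- mf_integrate(
    model_params(delta = 0.1, e = ec - 0.005, c = 0.4, alpha = 1),
    c(0, 1), 4000
  )
  above <- mf_integrate(
    model_params(delta = 0.1, e = ec + 0.005, c = 0.4, alpha = 1),
    c(0, 1), 4000
  )
  expect_gt(tail(below$p_plus, 1), 0.1)
  expect_lt(tail(above$p_plus, 1), 1e-3)

  # the transition is discontinuous: finite occupancy right at the threshold
  eq <- mf_equilibria(model_params(delta = 0.1, e = ec - 1e-6, c = 0.4, alpha = 1))
  interior <- Filter(function(x) x$kind == "interior", eq)
  expect_gt(max(vapply(interior, `[[`, numeric(1), "p_plus")), 0.1)

  # vanishes toward both allocation extremes, positive in between
  expect_lt(mf_ecrit(0.001, 0.1, 1), 0.002)
  expect_lt(mf_ecrit(0.999, 0.1, 1), 0.002)
  expect_gt(ec, 0.05)
  # continuity on a coarse allocation grid
  cs <- seq(0.05, 0.95, by = 0.05)
  es <- vapply(cs, mf_ecrit, numeric(1), delta = 0.1, alpha = 1)
  expect_true(all(abs(diff(es)) < 0.03))
  # no interior solution when colonization cannot beat extinction
  expect_identical(mf_ecrit(0.4, 0.7, 1), 0)
})

test_that("the optimal allocation maximizes the threshold curve", {
  cs <- mf_cstar(0.1, 1)
  expect_true(cs$c_star > 0.35 && cs$c_star < 0.45)
  # invariant to the optimizer: a fine grid scan lands at the same argmax
  grid <- seq(0.3, 0.55, by = 1e-3)
  vals <- vapply(grid, mf_ecrit, numeric(1), delta = 0.1, alpha = 1)
  expect_lt(abs(grid[which.max(vals)] - cs$c_star), 2e-3)
  expect_error(mf_cstar(1.5, 1), "degenerate")
})

test_that("integration matches the logistic closed form and stays in the simplex", {
  # e = 0, c = 0: the occupied fraction follows the logistic solution exactly
  p <- model_params(delta = 0.1, e = 0, c = 0)
  tr <- mf_integrate(p, c(0, 0.5), 40, sample_dt = 1)
  r <- 0.9
  K <- 0.9
  logistic <- K * 0.5 * exp(r * tr$t) / (K + 0.5 * (exp(r * tr$t) - 1))
  expect_equal(tr$p_plus, logistic, tolerance = 1e-7)

  # generic parameter draws: trajectories remain in the simplex and approach
  # a stable equilibrium of the analytic list
  set.seed(31)
  for (i in 1:6) {
    pars <- model_params(
      delta = runif(1, 0, 0.3), e = runif(1, 0, 0.08),
      c = runif(1, 0.1, 0.9), alpha = 1
    )
    tr <- mf_integrate(pars, c(0, 1), 3000)
    expect_true(all(tr$p_minus >= 0 & tr$p_plus >= 0 &
      tr$p_minus + tr$p_plus <= 1 + 1e-9))
    eq <- mf_equilibria(pars)
    stable <- Filter(function(x) isTRUE(x$stable), eq)
    final <- c(tail(tr$p_minus, 1), tail(tr$p_plus, 1))
    d <- vapply(stable, function(x) {
      sqrt((x$p_minus - final[1])^2 + (x$p_plus - final[2])^2)
    }, numeric(1))
    expect_lt(min(d), 1e-3)
  }

  # bistability: starting below the unstable root collapses the landscape
  p <- model_params(delta = 0.1, e = 0.06, c = 0.4, alpha = 1)
  interior <- Filter(function(x) x$kind == "interior", mf_equilibria(p))
  p_lo <- min(vapply(interior, `[[`, numeric(1), "p_plus"))
  tr <- mf_integrate(p, c(p$e / (p$e + p$c * p_lo), p_lo * 0.5), 4000)
  expect_gt(tail(tr$p_minus, 1), 0.99)
})

test_that("the mean-field phase matrix reproduces the threshold geometry", {
  cs <- c(0.2, 0.4, 0.6)
  es <- c(0.02, 0.08, 0.2)
  m_eq <- mf_phase_matrix(cs, es, delta = 0.1, alpha = 1, method = "equilibrium")
  m_int <- mf_phase_matrix(cs, es, delta = 0.1, alpha = 1, method = "integrate", t_max = 3000)
  # both protocols agree on which cells persist, and e = 0.2 kills everything
  expect_identical(m_eq > 0.01, m_int > 0.01)
  expect_true(all(m_eq[3, ] == 0))
  # occupancy decreases with destruction within a column
  expect_true(all(diff(m_eq[, 2]) <= 0))
})
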