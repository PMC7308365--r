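test_that("the exponent fit recovers exact power laws", {
  k_crit <- 0.6
  k <- k_crit - exp(seq(log(0.004), log(0.06), length.out = 9))
  occ <- 0.83 * (k_crit - k)^0.58
  fit <- fit_order_parameter_exponent(k, occ, k_crit)
  expect_equal(fit$exponent, 0.58, tolerance = 1e-6)
  expect_lt(fit$stderr, 1e-8)
  # slope is invariant under rescaling the occupancies
  fit2 <- fit_order_parameter_exponent(k, 17 * occ, k_crit)
  expect_equal(fit2$exponent, fit$exponent, tolerance = 1e-10)
  # contract errors
  expect_error(fit_order_parameter_exponent(c(0.5, 0.7), c(0.1, 0.1), 0.6), "below")
  expect_error(fit_order_parameter_exponent(c(0.5, 0.55, 0.59), c(0.1, 0, 0), 0.6), "positive")
})

test_that("phase-diagram sweeps are reproducible and absorb where they must", {
  cs <- c(0.2, 0.4, 0.6)
  es <- c(0.01, 0.05, 3)
  prot <- list(L = 32, t_transient = 60, t_avg = 20)
  pd1 <- sweep_phase_diagram(cs, es, model_params(delta = 0.1, alpha = 1), prot, seed = 7)
  pd2 <- sweep_phase_diagram(cs, es, model_params(delta = 0.1, alpha = 1), prot, seed = 7)
  expect_identical(pd1$mean_occupancy, pd2$mean_occupancy)
  expect_true(all(pd1$mean_occupancy >= 0 & pd1$mean_occupancy <= 1))
  # destruction far beyond any threshold: everything extinct, reported as 0
  expect_true(all(pd1$mean_occupancy[3, ] == 0))
})

test_that("persistence-region geometry is summarized correctly", {
  pd <- list(
    c_values = seq(0.1, 0.5, by = 0.1),
    e_values = seq(0.01, 0.04, by = 0.01),
    mean_occupancy = rbind(
      c(0.2, 0.3, 0.4, 0.3, 0.0),
      c(0.0, 0.2, 0.3, 0.2, 0.0),
      c(0.0, 0.0, 0.2, 0.0, 0.0),
      c(0.0, 0.0, 0.0, 0.0, 0.0)
    )
  )
  pr <- persistence_region(pd, threshold = 0.01)
  expect_identical(pr$n_regions, 1L)
  expect_equal(pr$vertex_c, 0.3)
  expect_equal(pr$vertex_e, 0.03)
  expect_true(pr$interior_vertex)
  # two disjoint blobs
  pd$mean_occupancy[4, 5] <- 0.5
  expect_identical(persistence_region(pd)$n_regions, 2L)
})

test_that("critical-point bisection rejects an invalid bracket", {
  expect_error(
    estimate_critical_point("delta", model_params(e = 0, c = 0),
      bracket = c(0.9, 1.2), L = 16, t_max = 100, replicates = 3, seed = 1
    ),
    "invalid bracket"
  )
})

test_that("the regime classifier separates the disturbance regimes", {
  mk <- function(p_nc, p_ex) {
    n <- length(p_nc)
    data.frame(
      t = seq_len(n) - 1, p_nc = p_nc, p_ex = p_ex,
      p_minus = pmax(0, 1 - p_nc - p_ex - 0.2), p_vacant = 0.2,
      occupied = round(1000 * (p_nc + p_ex))
    )
  }
  n <- 200
  # both strategies settle at positive occupancy
  tr <- mk(rep(0.3, n), rep(0.2, n))
  expect_identical(classify_regime(tr, e = 0.01)$label, "coexistence")
  # exploiter dies, constructor persists
  tr <- mk(rep(0.4, n), c(seq(0.3, 0, length.out = 50), rep(0, n - 50)))
  expect_identical(classify_regime(tr, e = 0.02)$label, "NC_monopoly")
  # constructor collapses first while the exploiter is thriving, then the
  # exploiter follows: ecological suicide
  tr <- mk(
    c(seq(0.3, 0, length.out = 40), rep(0, n - 40)),
    c(rep(0.4, 60), seq(0.4, 0, length.out = 60), rep(0, n - 120))
  )
  expect_identical(classify_regime(tr, e = 0.01)$label, "ecological_suicide")
  # static landscape: exclusion of the weaker colonizer
  tr <- mk(c(seq(0.3, 0, length.out = 80), rep(0, n - 80)), rep(0.5, n))
  expect_identical(classify_regime(tr, e = 0)$label, "competitive_exclusion")
  # both die almost together under destruction, no exclusion event
  tr <- mk(
    c(seq(0.2, 0, length.out = 50), rep(0, n - 50)),
    c(seq(0.005, 0, length.out = 48), rep(0, n - 48))
  )
  expect_identical(classify_regime(tr, e = 0.5)$label, "trivial_extinction")
  # still transient: constructor extinct but the doomed exploiter lingers
  tr <- mk(c(seq(0.3, 0, length.out = 40), rep(0, n - 40)), rep(0.2, n))
  expect_identical(classify_regime(tr, e = 0.01)$label, "ambiguous")
})

test_that("transects extract the recorded row exactly", {
  p <- model_params(delta = 0.4, e = 0.05, c = 0.3, alpha = 1)
  run <- run_ips(p, init_full(12), 30, seed = 17, record_row = 5)
  tr <- transect(run)
  expect_identical(dim(tr), c(31L, 12L))
  expect_identical(attr(tr, "times"), run$trajectory$t)
  # the last recorded sample is the final configuration's row
  expect_identical(unname(tr[31, ]), unname(unclass(run$final_grid)[5, ]))
  expect_error(transect(run, row = 3), "not recorded")
  run2 <- run_ips(p, init_full(12), 10, seed = 17)
  expect_error(transect(run2), "record_row")

  # an all-destroyed run stays constant at the destroyed code
  frozen <- run_ips(p, landscape(8, "destroyed"), 5, seed = 1, record_row = 2)
  expect_true(all(transect(frozen) == -1L))
})

test_that("transition width ranks sharp drops below broad ones", {
  e <- seq(0.01, 0.1, by = 0.01)
  broad <- c(0.9, 0.85, 0.75, 0.6, 0.45, 0.3, 0.18, 0.08, 0.02, 0)
  sharp <- c(0.9, 0.89, 0.88, 0.87, 0.86, 0.85, 0.84, 0, 0, 0)
  expect_lt(
    transition_width(e, sharp),
    transition_width(e, broad)
  )
  # exact crossings of a linear ramp: occupancy 1 -> 0 over [0.01, 0.1],
  # width = (hi - lo) * range
  ramp <- seq(1, 0, length.out = 10)
  expect_equal(transition_width(e, ramp, hi = 0.75, lo = 0.05), 0.7 * 0.09,
    tolerance = 1e-12
  )
  expect_true(is.na(transition_width(e, rep(0.5, 10))))
})

test_that("relaxation profiles classify clear sub- and supercritical decays", {
  prof <- relaxation_profile("delta", c(sub = 0.3, super = 1.2),
    params = model_params(e = 0, c = 0), L = 32, t_max = 150,
    replicates = 2, seed = 9
  )
  expect_identical(unname(prof$classification["sub"]), "subcritical")
  expect_identical(unname(prof$classification["super"]), "supercritical")
  expect_identical(nrow(prof$profiles), 2L * 151L)
})

test_that("range expansion establishes and saturates at small scale", {
  ex <- range_expansion(model_params(delta = 0.1, e = 0.01, c = 0.4, alpha = 1),
    r_values = 1, L = 32, t_max = 400, replicates = 2, seed = 19
  )
  expect_true(all(is.finite(ex$summary$t_saturation)))
  expect_true(all(ex$summary$plateau > 0.02))
  cv <- ex$curves[["1"]]
  expect_identical(nrow(cv), 401L)
  # the mosaic extent never exceeds the torus radius and grows on average
  expect_true(all(cv$extent <= 16))
  expect_gt(mean(cv$extent[300:401]), mean(cv$extent[1:50]))
})
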