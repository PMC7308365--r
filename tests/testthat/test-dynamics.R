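test_that("initial conditions match their contracts", {
  expect_equal(state_fractions(init_full(16))[["p_nc"]], 1)
  expect_identical(init_full(16, fraction_nc = 1), init_full(16))

  set.seed(1)
  g <- init_full(64, fraction_nc = 0.5, seed = 5)
  fr <- state_fractions(g)
  expect_equal(fr[["p_nc"]] + fr[["p_ex"]], 1)
  # binomial standard error at n = 4096: 4 s.e. band around 0.5
  expect_lt(abs(fr[["p_nc"]] - 0.5), 4 * sqrt(0.25 / 4096))

  g <- init_single_seed(9)
  fr <- state_fractions(g)
  expect_equal(fr[["p_nc"]], 1 / 81)
  expect_equal(fr[["p_minus"]], 80 / 81)
  expect_identical(g[5, 5], 1L) # center (floor(9/2)+1, floor(9/2)+1)
  for (L in c(3, 8, 21)) {
    expect_identical(sum(init_single_seed(L) == 1L), 1L)
  }
  gv <- init_single_seed(8, background = "vacant")
  expect_equal(state_fractions(gv)[["p_vacant"]], 63 / 64)
})

test_that("site rates follow the reaction scheme", {
  p <- model_params(delta = 0.25, e = 0.05, c = 0, alpha = 1)
  full <- landscape(8, "nc")
  full[4, 4] <- 0L
  # vacant with all 4 nearest neighbors NC, c = 0: colonization rate 1
  r <- site_rates(full, c(4, 4), p)
  expect_equal(r[["colonization_nc"]], 1)
  expect_equal(r[["destruction"]], 0.05)
  # occupied site: extinction delta, destruction e
  r <- site_rates(full, c(1, 1), p)
  expect_equal(unname(r[c("extinction", "destruction")]), c(0.25, 0.05))

  # 2 of 4 neighbors NC at c = 0.4, alpha = 1: 0.6 * 2/4 = 0.3
  g <- landscape(8, "vacant")
  g[3, 4] <- g[5, 4] <- 1L
  p <- model_params(delta = 0.1, c = 0.4, alpha = 1)
  expect_equal(site_rates(g, c(4, 4), p)[["colonization_nc"]], 0.3)

  # destroyed with 1 NC construction neighbor (r = 1), c = 0.25: 0.25/4
  g <- landscape(8, "destroyed")
  g[4, 5] <- 1L
  p <- model_params(delta = 0.1, c = 0.25, alpha = 1)
  expect_equal(site_rates(g, c(4, 4), p)[["construction"]], 0.25 / 4)

  # global construction: all NC sites weighted over the L^2 - 1 other sites
  g <- landscape(8, "destroyed")
  g[1, 1] <- g[8, 8] <- 1L
  p <- model_params(delta = 0.1, c = 0.4, r_con = Inf)
  expect_equal(site_rates(g, c(4, 4), p)[["construction"]], 0.4 * 2 / 63)

  # exploiter colonization is undiscounted
  g <- landscape(8, "vacant")
  g[3, 4] <- 2L
  p <- model_params(delta = 0.1, c = 0.4, competition = TRUE)
  r <- site_rates(g, c(4, 4), p)
  expect_equal(r[["colonization_ex"]], 1 / 4)
  expect_equal(r[["colonization_nc"]], 0)
})

test_that("the reference stepper is exact on a lone constructor", {
  # lone NC on an all-destroyed lattice with e = 0: the only events are its
  # extinction (delta) and construction of its 4 neighbors (total rate c),
  # so the first-event time is Exp(delta + c)
  delta <- 0.2
  cons <- 0.4
  p <- model_params(delta = delta, e = 0, c = cons, alpha = 1)
  set.seed(99)
  n <- 2000
  waits <- vapply(seq_len(n), function(i) {
    st <- step_ips(sim_state(init_single_seed(5), p))
    st$t
  }, numeric(1))
  mu <- 1 / (delta + cons)
  expect_lt(abs(mean(waits) - mu), 3 * mu / sqrt(n)) # Exp: sd = mean

  # frozen configurations are returned unchanged and flagged
  st <- sim_state(landscape(5, "destroyed"), p)
  st2 <- step_ips(st)
  expect_true(st2$absorbed)
  expect_identical(st2$t, 0)
  expect_identical(unclass(st2$grid), unclass(st$grid))
})

test_that("runs are reproducible and conserve state fractions", {
  p <- model_params(delta = 0.4, e = 0.02, c = 0.3, alpha = 1)
  r1 <- run_ips(p, init_full(16), 50, seed = 123)
  r2 <- run_ips(p, init_full(16), 50, seed = 123)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(unclass(r1$final_grid), unclass(r2$final_grid))

  tr <- r1$trajectory
  expect_true(all(abs(tr$p_minus + tr$p_vacant + tr$p_nc + tr$p_ex - 1) < 1e-12))
  expect_true(all(tr$p_nc >= 0 & tr$p_nc <= 1))
})

test_that("degenerate parameter sets behave as contracted", {
  # contact process with no removal: full occupancy is frozen
  r <- run_ips(model_params(delta = 0, e = 0, c = 0), init_full(12), 100, seed = 1)
  expect_true(all(r$trajectory$p_nc == 1))
  # far supercritical extinction
  r <- run_ips(model_params(delta = 5, e = 0, c = 0), init_full(32), 200, seed = 2)
  expect_true(r$absorbed)
  expect_identical(r$trajectory$p_nc[nrow(r$trajectory)], 0)
  # c = 1 with alpha > 0: colonization impossible, population must vanish
  r <- run_ips(model_params(delta = 0.5, e = 0, c = 1), init_full(12), 200, seed = 3)
  expect_true(r$absorbed)
})

test_that("a destruction-free start with e = 0 never produces destroyed sites", {
  p <- model_params(delta = 0.1, e = 0, c = 0.4, alpha = 1)
  r <- run_ips(p, init_full(24), 100, seed = 8)
  expect_true(all(r$trajectory$p_minus == 0))
  expect_false(any(r$final_grid == -1L))
})

test_that("extinction events occur at rate delta per occupied site", {
  delta <- 0.3
  r <- run_ips(model_params(delta = delta, e = 0, c = 0), init_full(32), 300, seed = 13)
  occ_integral <- sum(r$trajectory$occupied) * 1 # dt = 1
  expected <- delta * occ_integral
  observed <- r$event_counts[["extinction_nc"]]
  expect_lt(abs(observed - expected), 4 * sqrt(expected))
})

test_that("compiled and reference samplers agree in distribution", {
  # mean occupied fraction at t = 2 on a 3x3 lattice, both code paths
  p <- model_params(delta = 0.4, e = 0.1, c = 0.3, alpha = 1)
  n <- 400
  set.seed(21)
  occ_fast <- vapply(seq_len(n), function(i) {
    run_ips(p, init_full(3), 2, sample_dt = 2)$trajectory$p_nc[2]
  }, numeric(1))
  occ_ref <- vapply(seq_len(n), function(i) {
    tail(run_reference(p, init_full(3), 2, sample_dt = 2)$p_nc, 1)
  }, numeric(1))
  se <- sqrt(var(occ_fast) / n + var(occ_ref) / n)
  expect_lt(abs(mean(occ_fast) - mean(occ_ref)), 3 * se)
})

test_that("long-run occupancy responds monotonically to extinction rate", {
  # stochastic monotonicity check with replicated paired seeds
  qs_occ <- function(delta, seed) {
    r <- run_ips(model_params(delta = delta, e = 0, c = 0), init_full(32), 300,
      seed = seed
    )
    mean_occupancy(r, 150)[["p_nc"]]
  }
  lo <- vapply(1:3, function(s) qs_occ(0.2, 100 + s), numeric(1))
  hi <- vapply(1:3, function(s) qs_occ(0.45, 100 + s), numeric(1))
  expect_gt(mean(lo), mean(hi))
})

test_that("competition runs track both strategies", {
  p <- model_params(delta = 0.3, e = 0.01, c = 0.3, alpha = 1, competition = TRUE)
  r <- run_ips(p, init_full(16, fraction_nc = 0.5, seed = 4), 30, seed = 5)
  expect_gt(max(r$trajectory$p_ex), 0)
  tr <- r$trajectory
  expect_true(all(abs(tr$p_minus + tr$p_vacant + tr$p_nc + tr$p_ex - 1) < 1e-12))
})
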