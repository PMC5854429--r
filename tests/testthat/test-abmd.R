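# Adaptive-bias (flooding) machinery: deposit-rate contract, interpolation,
# walls, multi-walker runs and the dropped-energy convergence diagnostic.

test_that("bias grid and flooding schedule enforce their invariants", {
  g <- bias_grid(20, 200, 1.0)
  expect_length(g$U, floor((200 - 20) / 1) + 1)
  expect_true(all(g$U == 0))
  expect_error(flooding_schedule(tau = 0), "tau")
  expect_error(bias_grid(10, 5), "hi > lo")
})

test_that("deposits honor the kB*T*dt/tau normalization contract", {
  sch <- flooding_schedule(tau = 100)
  g <- bias_grid(0, 50, 1.0)
  # a walker parked at one position for total time tau deposits exactly kBT
  for (i in 1:40) g <- deposit_bias(g, 25, dt = 100 / 40, sch)
  expect_equal(sum(g$U) * g$dd, kBT(300), tolerance = 1e-9)
  # dt = 0 leaves the bias unchanged
  g2 <- deposit_bias(g, 25, dt = 0, sch)
  expect_identical(g2$U, g$U)
  # two walkers depositing for time t each integrate to 2 kBT t / tau
  g3 <- bias_grid(0, 50, 1.0)
  g3 <- deposit_bias(g3, c(10, 30), dt = 7, sch)
  expect_equal(sum(g3$U) * g3$dd, 2 * kBT(300) * 7 / 100, tolerance = 1e-9)
  # monotone: node values never decrease under further deposits
  g4 <- deposit_bias(g3, c(10.5, 29), dt = 1, sch)
  expect_true(all(g4$U >= g3$U))
  # out-of-range deposit skipped with a warning
  expect_warning(deposit_bias(g3, 60, dt = 1, sch), "outside")
})

test_that("bias interpolation is exact on nodes with analytic derivative", {
  g <- bias_grid(0, 30, 1.0)
  g <- deposit_bias(g, c(8.2, 15.7, 15.9, 22.4), dt = 5,
                    flooding_schedule(tau = 10))
  expect_equal(evaluate_bias(g, g$nodes)$E, g$U)
  # empty bias evaluates to zero everywhere
  g0 <- bias_grid(0, 30, 1.0)
  expect_equal(evaluate_bias(g0, c(-5, 3.3, 35))$E, c(0, 0, 0))
  expect_equal(evaluate_bias(g0, c(-5, 3.3, 35))$dEdd, c(0, 0, 0))
  # outside the range the bias vanishes
  expect_equal(evaluate_bias(g, c(-1, 31))$E, c(0, 0))
  # derivative of the interpolant matches central differences
  x <- seq(0.4, 29.6, by = 0.111)
  h <- 1e-6
  num <- (evaluate_bias(g, x + h)$E - evaluate_bias(g, x - h)$E) / (2 * h)
  ev <- evaluate_bias(g, x)$dEdd
  expect_lt(max(abs(num - ev) / pmax(abs(num), 1e-6)), 1e-5)
})

test_that("walls are one-sided quadratics without a 1/2 factor", {
  expect_equal(wall_energy(c(30, 100, 190), 25, 195, 10), c(0, 0, 0))
  expect_equal(wall_energy(24, 25, 195, 10), 10)    # 10 * 1^2
  expect_equal(wall_energy(25 - 2.5, 25, 195, 10),
               wall_energy(195 + 2.5, 25, 195, 10))
  expect_equal(wall_force_dd(24, 25, 195, 10), -20)
  expect_error(wall_energy(1, 10, 5), "lo_wall < hi_wall")
})

test_that("multi-walker flooding conserves deposits and records coverage", {
  dw <- dw_spec(barrier = 2)
  sys <- potential_system(dw, init_at = c(45, 55))
  res <- run_multiwalker(sys, flooding_schedule(tau = 10),
                         range = c(40, 60), walls = c(41, 59),
                         n_walkers = 4L, total_time = 100, dt = 0.05,
                         record_interval = 20L, snapshot_every = 25,
                         seed = 11,
                         init = matrix(c(45, 55, 45, 55), nrow = 1L))
  # conservation: integrated bias == kBT/tau * total in-range residence time
  expect_equal(res$deposited_total,
               kBT(300) * res$residence_time / 10, tolerance = 1e-6)
  # bias nodes never decrease across snapshots
  dU <- res$snapshots[, -1] - res$snapshots[, -ncol(res$snapshots)]
  expect_true(all(dU > -1e-12))
  # determinism
  res2 <- run_multiwalker(sys, flooding_schedule(tau = 10),
                          range = c(40, 60), walls = c(41, 59),
                          n_walkers = 4L, total_time = 100, dt = 0.05,
                          record_interval = 20L, snapshot_every = 25,
                          seed = 11,
                          init = matrix(c(45, 55, 45, 55), nrow = 1L))
  expect_identical(res$traces$d_A, res2$traces$d_A)
  expect_identical(res$bias$U, res2$bias$U)
})

test_that("with tau -> infinity flooding reduces to unbiased sampling", {
  dw <- dw_spec()
  sys <- potential_system(dw, init_at = 45)
  res <- run_multiwalker(sys, flooding_schedule(tau = 1e12),
                         range = c(40, 60), n_walkers = 1L,
                         total_time = 50, dt = 0.05, record_interval = 10L,
                         snapshot_every = 25, seed = 2)
  expect_lt(max(res$bias$U), 1e-9)
})

test_that("flooding flattens a low barrier and the deposit rate uniformizes", {
  # barrier 2 kcal/mol ~ 3.4 kBT; after sustained flooding the effective
  # landscape range shrinks well below the original barrier
  dw <- dw_spec(barrier = 2)
  sys <- potential_system(dw, init_at = c(45, 55))
  res <- run_multiwalker(sys, flooding_schedule(tau = 20),
                         range = c(40, 60), walls = c(42, 58),
                         n_walkers = 8L, total_time = 4000, dt = 0.05,
                         record_interval = 50L, snapshot_every = 250,
                         seed = 31,
                         init = matrix(rep(c(45, 55), 4L), nrow = 1L))
  sel <- res$bias$nodes >= 44 & res$bias$nodes <= 56
  est <- abmd_free_energy(res$snapshots, res$bias$nodes)
  eff <- potential_energy(dw, res$bias$nodes[sel]) - est$F[sel]
  expect_lt(diff(range(eff)), 0.2 * 2)
  # every bin in the explored band was visited (walkers swept the range)
  expect_true(all(res$bias$U[sel] > 0))
  dep <- dropped_energy_profile(res$snapshots, res$snapshot_times,
                                region = range(which(sel)))
  nu <- length(dep$uniformity)
  expect_lt(dep$uniformity[nu], dep$uniformity[1L])
})

test_that("dropped-energy accounting conserves single deposits", {
  g0 <- bias_grid(0, 20, 1)
  sch <- flooding_schedule(tau = 50)
  g1 <- deposit_bias(g0, 10, dt = 3, sch)
  snaps <- cbind(g0$U, g1$U, g1$U)
  dep <- dropped_energy_profile(snaps, times = c(0, 1, 2))
  expect_equal(sum(dep$deposits[, 1L]) * 1.0, kBT(300) * 3 / 50,
               tolerance = 1e-9)
  expect_equal(dep$deposits[, 2L], rep(0, nrow(snaps)))
  expect_true(is.na(dep$uniformity[2L]))
})
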