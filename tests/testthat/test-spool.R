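# The bead-on-spool mimic: geometry, mirror symmetry, exact forces, the
# quadrature + enumeration oracle, and its agreement with sampling.

test_that("spec validation and wrapped-state energy bookkeeping", {
  expect_error(spool_spec(sites = c(1, 3)), "sites >= 2")
  expect_error(spool_spec(capture = c(5, 4)), "capture")
  sp <- spool_spec(epsilon = c(0.5, 1, 1.5, 2))
  expect_equal(sp$epsilon[, 1], c(0.5, 1, 1.5, 2))
  # fully wrapped reference: total binding energy is -sum(eps) over both arms
  sys <- spool_system(sp)
  expect_equal(sys$force(sys$init(1L))$E, -2 * sum(c(0.5, 1, 1.5, 2)),
               tolerance = 1e-9)
})

test_that("arm swap by mirror symmetry preserves d and energy", {
  sp <- spool_spec()
  sys <- spool_system(sp)
  set.seed(14)
  x <- sys$init(1L) + matrix(stats::rnorm(sys$n_dof, sd = 0.4), ncol = 1L)
  fr <- spool_frame(x[, 1L], sp)
  mir <- fr
  mir[, 2] <- -mir[, 2]; mir[, 3] <- -mir[, 3]
  B <- sp$n_beads
  swapped <- rbind(mir[(B + 1):(2 * B), ], mir[1:B, ])
  x_sw <- matrix(as.vector(t(swapped)), ncol = 1L)
  expect_equal(sys$rc(x_sw)$d, sys$rc(x)$d, tolerance = 1e-12)
  expect_equal(sys$force(x_sw)$E, sys$force(x)$E, tolerance = 1e-9)
  a <- sys$aux(x); a_sw <- sys$aux(x_sw)
  expect_equal(unname(a_sw[1, ]), unname(a[2, ]))
  expect_equal(unname(a_sw[2, ]), unname(a[1, ]))
})

test_that("forces and the d-gradient match finite differences", {
  sp <- small_spool()
  sys <- spool_system(sp)
  set.seed(8)
  x <- sys$init(1L) + matrix(stats::rnorm(sys$n_dof, sd = 0.6), ncol = 1L)
  f <- sys$force(x)
  g <- sys$rc(x)
  for (i in seq_len(sys$n_dof)) {
    e <- matrix(0, sys$n_dof, 1L); e[i] <- 1e-6
    expect_equal(f$F[i, 1],
                 -(sys$force(x + e)$E - sys$force(x - e)$E) / 2e-6,
                 tolerance = 1e-4)
    expect_equal(g$grad[i, 1],
                 (sys$rc(x + e)$d - sys$rc(x - e)$d) / 2e-6,
                 tolerance = 1e-4)
  }
})

test_that("quadrature site statistics agree with direct Metropolis MC", {
  sp <- spool_spec()
  st <- spool_site_stats(sp)
  ref <- spool_reference(sp)
  b_ref <- ref$bond_ref1[, sp$sites[1]]
  ax <- ref$pull_axis1
  beta <- 1 / kBT(300)
  V <- function(b) {
    u <- sqrt(sum((b - b_ref)^2)); r <- sqrt(sum(b^2))
    S <- unspool:::.switch_S(u, sp$capture[1], sp$capture[2])
    S * (sp$bound_k * u^2 - sp$epsilon[1, 1]) +
      (1 - S) * (sp$free_k * (r - sp$free_length)^2 +
                   sp$tension * (1 - sum(b * ax) / sp$free_length))
  }
  set.seed(3)
  b <- b_ref; n <- 150000L
  bound <- logical(n)
  for (i in seq_len(n)) {
    bp <- b + stats::rnorm(3L, sd = 1.0)
    if (stats::runif(1L) < exp(-beta * (V(bp) - V(b)))) b <- bp
    bound[i] <- sqrt(sum((b - b_ref)^2)) < sp$r_mid
  }
  keep <- bound[-seq_len(10000L)]
  se <- block_se(as.numeric(keep))
  expect_lt(abs(mean(keep) - st$p_bound[1]), 3 * se)
})

test_that("occupancy enumeration equals the independent-site convolution", {
  sp <- spool_spec(epsilon = c(0.5, 1.0, 1.5, 2.0))
  st <- spool_site_stats(sp)
  prof <- spool_occupancy_profile(sp)
  # brute force over all 2^8 occupancy states
  n <- nrow(st)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  wts <- apply(states, 1L, function(s) {
    prod(ifelse(s == 1L, st$Z_free, st$Z_bound))
  })
  P_brute <- vapply(0:n, function(r) sum(wts[rowSums(states) == r]),
                    numeric(1L))
  P_brute <- P_brute / sum(P_brute)
  expect_equal(prof$P, P_brute, tolerance = 1e-12)
  expect_equal(min(prof$F), 0)
})

test_that("long-run occupancy sampling matches the enumeration oracle", {
  sp <- spool_spec()
  r <- spool_occupancy_mc(sp, n_sweeps = 6000L, seed = 21L)
  prof <- spool_occupancy_profile(sp)
  mean_oracle <- sum(prof$centers * prof$P)
  se <- block_se(r[-seq_len(500L)])
  expect_lt(abs(mean(r[-seq_len(500L)]) - mean_oracle), 3 * se)
})

test_that("released fraction grows with temperature", {
  sp <- spool_spec()
  p_cold <- spool_occupancy_profile(sp, temperature = 250)
  p_hot <- spool_occupancy_profile(sp, temperature = 450)
  expect_gt(sum(p_hot$centers * p_hot$P), sum(p_cold$centers * p_cold$P))
  # with eps = 0 the sites detach much more readily at any temperature
  sp0 <- spool_spec(epsilon = 0)
  p0 <- spool_occupancy_profile(sp0)
  p1 <- spool_occupancy_profile(sp)
  expect_gt(sum(p0$centers * p0$P), sum(p1$centers * p1$P))
})

test_that("unbiased dynamics reproduces the occupancy marginal", {
  # short ensemble run against the exact per-site free fraction; the spool
  # exchanges sites on ~100 ps timescales, so use many walkers + block SE
  sp <- spool_spec()
  sys <- spool_system(sp)
  set.seed(27)
  run <- unspool:::.run_dynamics(sys, sys$init(24L), n_steps = 60000L,
                                 dt = 0.02, gamma = 2, temperature = 300,
                                 record_interval = 50L)
  n_rec <- dim(run$aux)[1]
  r2 <- run$aux[(n_rec %/% 2):n_rec, 1L, ] + run$aux[(n_rec %/% 2):n_rec, 2L, ]
  prof <- spool_occupancy_profile(sp)
  mean_oracle <- sum(prof$centers * prof$P)
  se_w <- stats::sd(colMeans(r2)) / sqrt(ncol(r2))
  # walker means are still relaxing from the all-bound start; allow the
  # relaxation direction but require closeness at the 3 SE + bias level
  expect_lt(abs(mean(r2) - mean_oracle), 3 * se_w + 0.5)
})

test_that("pinned arms stay wrapped and shortening drops outer sites", {
  spp <- spool_spec(pinned_arm = 2L)
  sys <- spool_system(spp)
  set.seed(10)
  run <- unspool:::.run_dynamics(sys, sys$init(4L), n_steps = 5000L,
                                 dt = 0.02, gamma = 2, temperature = 300,
                                 record_interval = 100L)
  expect_true(all(run$aux[, "unwrapped_end2", ] == 0))
  expect_gt(max(run$aux[, "unwrapped_end1", ]), 0)

  sp <- spool_spec()
  sh <- spool_shorten(sp, 2L)
  expect_equal(sh$n_beads, 8L)
  expect_equal(sh$sites, c(3L, 5L, 7L))   # site at bond 9 removed
  x <- spool_system(sp)$init(3L)
  xs <- spool_drop_beads(x, sp, 2L)
  expect_equal(nrow(xs), spool_system(sh)$n_dof)
  expect_equal(ncol(xs), 3L)
  # retained beads carry identical coordinates
  expect_equal(spool_frame(xs[, 1L], sh),
               spool_frame(x[, 1L], sp)[c(1:8, 11:18), ])
})
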