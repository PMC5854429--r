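# Umbrella machinery: window grids, seed selection, the combined bias form,
# restrained sampling statistics, and the discard filter.

test_that("window grids use inclusive endpoints and reject bad ranges", {
  g1 <- build_window_grid(40, 180, 2)
  expect_equal(g1$n_windows, 71L)
  expect_equal(g1$centers[1], 40)
  expect_equal(g1$centers[71], 180)
  expect_equal(build_window_grid(125, 175, 2)$n_windows, 26L)
  g0 <- build_window_grid(50, 50, 2)
  expect_equal(g0$n_windows, 1L)
  expect_equal(g0$centers, 50)
  expect_error(build_window_grid(40, 181, 2), "not a multiple")
  # purity / reproducibility
  expect_identical(build_window_grid(40, 180, 2), build_window_grid(40, 180, 2))
})

test_that("seed selection picks nearest walkers with low-id tie-breaks", {
  g <- build_window_grid(40, 44, 2)
  expect_equal(select_seeds(c(41, 44), g), c(1L, 1L, 2L))
  # equidistant walkers: lower id wins
  expect_equal(select_seeds(c(39, 41), build_window_grid(40, 40, 2)), 1L)
  # one walker seeds every window
  expect_equal(select_seeds(100, build_window_grid(40, 48, 2)),
               rep(1L, 5L))
  expect_error(select_seeds(numeric(0), g), "no walkers")
})

test_that("combined bias is k (d - c)^2 + U_abmd with no 1/2 factor", {
  w <- umbrella_window(center = 50, k = 0.2)
  expect_equal(combined_bias(50, w), 0)
  expect_equal(combined_bias(51, w), 0.2)
  expect_equal(combined_bias(47, w), 0.2 * 9)
  g <- bias_grid(30, 70, 1)
  g <- deposit_bias(g, c(48, 52), dt = 10, flooding_schedule(tau = 10))
  wb <- umbrella_window(center = 50, k = 0.2, bias = g)
  d <- seq(31, 69, by = 0.7)
  expect_equal(combined_bias(d, wb),
               0.2 * (d - 50)^2 + evaluate_bias(g, d)$E)
  # additivity: shifting U_abmd by c shifts the combined bias by c
  g2 <- g; g2$U <- g$U + 1.3
  wb2 <- umbrella_window(center = 50, k = 0.2, bias = g2)
  inside <- d >= 30 & d <= 70
  expect_equal(combined_bias(d[inside], wb2),
               combined_bias(d[inside], wb) + 1.3)
})

test_that("restrained sampling on a flat potential is Gaussian kBT/(2k)", {
  flat <- potential_spec("tabulated", d = seq(0, 120, 2), V = rep(0, 61))
  sys <- potential_system(flat, init_at = 30)
  grid <- build_window_grid(30, 90, 30)   # far-apart windows
  ws <- run_windows(sys, grid, k = 0.2, duration = 4000, dt = 0.05,
                    record_interval = 10L, seed = 17,
                    inits = matrix(grid$centers, nrow = 1L))
  expect_length(ws, 3L)
  for (w in ws) {
    ctr <- attr(w, "center")
    se_m <- block_se(w$d_A)
    expect_lt(abs(mean(w$d_A) - ctr), 3 * se_m)
    v <- (w$d_A - ctr)^2
    expect_lt(abs(mean(v) - kBT(300) / (2 * 0.2)), 3 * block_se(v))
  }
})

test_that("stiff restraint pulls the mean between center and potential minimum", {
  # V = k0 (d - m)^2 with restraint k (d - c)^2: stationary mean is the
  # precision-weighted combination (k0 m + k c) / (k0 + k)
  k0 <- 0.1; m <- 50
  hs <- potential_spec("harmonic", stiffness = k0, center = m)
  sys <- potential_system(hs)
  grid <- build_window_grid(56, 56, 2)
  ws <- run_windows(sys, grid, k = 0.4, duration = 4000, dt = 0.05,
                    record_interval = 10L, seed = 23,
                    inits = matrix(56, 1L, 1L))
  expected <- (k0 * m + 0.4 * 56) / (k0 + 0.4)
  expect_lt(abs(mean(ws[[1]]$d_A) - expected), 3 * block_se(ws[[1]]$d_A))
  expect_gt(expected, m); expect_lt(expected, 56)
})

test_that("window sample counts follow duration / record cadence", {
  flat <- potential_spec("tabulated", d = seq(0, 100, 2), V = rep(0, 51))
  sys <- potential_system(flat, init_at = 50)
  grid <- build_window_grid(48, 52, 2)
  ws <- run_windows(sys, grid, k = 0.2, duration = 150, dt = 0.05,
                    record_interval = 10L, seed = 1,
                    inits = matrix(grid$centers, nrow = 1L))
  expect_true(all(vapply(ws, nrow, integer(1L)) == 300L))
  # frozen bias is shared bit-identically across windows of a stage
  g <- bias_grid(0, 100, 1)
  g <- deposit_bias(g, 50, dt = 5, flooding_schedule(tau = 10))
  ws2 <- run_windows(sys, grid, k = 0.2, frozen_bias = g, duration = 50,
                     dt = 0.05, record_interval = 10L, seed = 1,
                     inits = matrix(grid$centers, nrow = 1L))
  expect_identical(attr(ws2, "frozen_bias")$U, g$U)
})

test_that("discard filter keeps the closed interval and logs removals", {
  df <- as_window_df(c(39, 40, 100, 180, 181))
  kept <- filter_discard_regions(df, c(40, 180))
  expect_equal(kept$d_A, c(40, 100, 180))
  expect_equal(attr(kept, "removed"), 2L)
  expect_equal(attr(kept, "window_id"), attr(df, "window_id"))
  # all inside -> unchanged; empty -> empty
  all_in <- filter_discard_regions(df, c(0, 200))
  expect_equal(all_in$d_A, df$d_A)
  none <- filter_discard_regions(df[0, ], c(40, 180))
  expect_equal(nrow(none), 0L)
})
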