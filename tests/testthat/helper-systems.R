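# Shared fixtures: oracle systems and exact samplers used across the suite.

# Canonical double-well benchmark: wells at 45/55 A, 3 kcal/mol barrier.
dw_spec <- function(barrier = 3, center = 50, sep = 10, domain = c(30, 70)) {
  potential_spec("double_well", center = center, well_separation = sep,
                 barrier = barrier, domain = domain)
}

# Exact rejection sampling from the biased density of an umbrella window:
# proposal ~ N(center, kBT/(2k)) from the harmonic restraint (no 1/2 in the
# quadratic), acceptance exp(-(V(d) - Vmin)/kBT) from the potential, with
# out-of-domain proposals rejected.  Exact up to floating point.
sample_window_exact <- function(spec, center, k, n, temperature = 300,
                                v_min = 0) {
  sd <- sqrt(kBT(temperature) / (2 * k))
  out <- numeric(0L)
  while (length(out) < n) {
    d <- stats::rnorm(2L * n, mean = center, sd = sd)
    d <- d[d >= spec$domain[1] & d <= spec$domain[2]]
    acc <- stats::runif(length(d)) <
      exp(-(potential_energy(spec, d) - v_min) / kBT(temperature))
    out <- c(out, d[acc])
  }
  out[seq_len(n)]
}

# Wrap plain coordinate draws in the window-samples schema.
as_window_df <- function(d, window_id = 1L, center = NA_real_, k = 0.2) {
  df <- data.frame(time_ps = seq_along(d), d_A = d,
                   unwrapped_end1 = 0, unwrapped_end2 = 0,
                   energy_kcal_mol = 0)
  attr(df, "window_id") <- window_id
  attr(df, "center") <- center
  attr(df, "k") <- k
  df
}

# Independent second-path WHAM: direct self-consistent iteration of the
# histogram equations written without log-space tricks or shared code with
# solve_wham().  Serves as the cross-check oracle on small benchmarks.
wham_direct <- function(counts, Bmat, N, temperature = 300, tol = 1e-10,
                        max_iter = 50000L) {
  kT <- kBT(temperature)
  nw <- length(N)
  f <- numeric(nw)
  for (it in seq_len(max_iter)) {
    denom <- sapply(seq_along(counts), function(b) {
      sum(N * exp((f - Bmat[b, ]) / kT))
    })
    p <- ifelse(counts > 0, counts / denom, 0)
    p <- p / sum(p)
    fn <- -kT * log(sapply(seq_len(nw), function(j) {
      sum(p * exp(-Bmat[, j] / kT))
    }))
    fn <- fn - fn[1L]
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  denom <- sapply(seq_along(counts), function(b) {
    sum(N * exp((f - Bmat[b, ]) / kT))
  })
  p <- ifelse(counts > 0, counts / denom, 0)
  list(F = f, p_mass = p / sum(p))
}

# Block (batch-mean) standard error for correlated series.
block_se <- function(x, n_blocks = 20L) {
  n <- length(x)
  cut <- (n %/% n_blocks) * n_blocks
  bm <- colMeans(matrix(x[seq_len(cut)], ncol = n_blocks))
  stats::sd(bm) / sqrt(n_blocks)
}

# A toy reference structure for the unwrapping metrics: 6 units per end on
# a circle of radius 10 around the origin, per-end lists outermost first.
toy_reference <- function() {
  ang <- seq(0, 150, by = 30) * pi / 180
  c1 <- cbind(10 * cos(ang), 10 * sin(ang), 0)
  c2 <- c1; c2[, 2] <- -c2[, 2]
  coords <- rbind(c1, c2)
  rownames(coords) <- c(paste0("u", 1:6), paste0("v", 1:6))
  reference_structure(coords, c(0, 0, 0),
                      end1 = paste0("u", 6:1), end2 = paste0("v", 6:1))
}

# Tiny spool used where dynamics cost matters more than realism.
small_spool <- function(...) {
  spool_spec(n_beads = 5L, sites = c(3L, 5L), ...)
}
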