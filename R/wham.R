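#' Uniform histogram grid for WHAM output
#'
#' Half-open bins \code{[edge_k, edge_{k+1})}; the last edge is closed so
#' samples exactly at \code{hi} are kept.
#'
#' @param lo,hi Range, A.
#' @param width Bin width, A (default 1.0, matching the adaptive-bias grid
#'   resolution).
#' @return An object of class \code{histogram_grid} with \code{edges} and
#'   \code{centers}.
#' @export
histogram_grid <- function(lo, hi, width = 1.0) {
  stopifnot(hi > lo, width > 0)
  n <- ceiling((hi - lo) / width - 1e-9)
  edges <- lo + width * (0:n)
  structure(list(lo = lo, hi = edges[n + 1L], width = width, edges = edges,
                 centers = edges[-(n + 1L)] + width / 2),
            class = "histogram_grid")
}

.bin_index <- function(grid, d) {
  i <- floor((d - grid$lo) / grid$width) + 1L
  n <- length(grid$centers)
  i[d == grid$hi] <- n   # closed top edge
  if (any(i < 1L | i > n, na.rm = TRUE)) {
    stop("samples fall outside the histogram grid [", grid$lo, ", ",
         grid$hi, "]")
  }
  as.integer(i)
}

.logsumexp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  ok <- is.finite(mx)
  out <- rep(-Inf, nrow(M))
  out[ok] <- mx[ok] + log(rowSums(exp(M[ok, , drop = FALSE] - mx[ok])))
  out
}

#' Self-consistent WHAM on umbrella-window samples
#'
#' Solves the weighted-histogram equations for the unbiased probability
#' distribution P(d) and the per-window free-energy shifts F_j under the
#' combined harmonic + frozen adaptive bias of each window:
#' \deqn{P(d) \propto \sum_i h_i(d) \Big/ \sum_j N_j
#'   e^{[F_j - V_j(d)]/k_B T},\qquad
#'   F_j = -k_B T \ln \sum_d P(d) e^{-V_j(d)/k_B T},}
#' iterated to self-consistency on \code{max |dF_j|} (tolerance interpreted
#' in kcal/mol).  All sums are accumulated in log space so biases of
#' hundreds of kcal/mol cannot overflow.  F is anchored to the first window
#' during iteration; bins with zero counts get zero probability and are
#' reported as unsupported, never imputed.
#'
#' @param windows List of per-window sample data.frames (a \code{d_A}
#'   column), as from [run_windows()].
#' @param biases List of [umbrella_window()] definitions aligned with
#'   \code{windows}.
#' @param temperature Temperature, K.
#' @param tol Convergence tolerance on \code{max |F_j^{new} - F_j|},
#'   kcal/mol (default 1e-8).
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @param grid Output [histogram_grid()]; defaults to 1 A bins spanning the
#'   samples.
#' @return An object of class \code{wham_solution}: fields \code{F}
#'   (per-window shifts, first window 0), \code{P} (probability density on
#'   the grid, integrates to 1), \code{p_mass} (per-bin masses, sum 1),
#'   \code{counts}, \code{grid}, \code{log_denom} (per-bin log of the WHAM
#'   denominator, from which per-sample weights follow), \code{iterations},
#'   \code{residual}, \code{residual_history}, \code{temperature},
#'   \code{n_samples} (per window).
#' @export
solve_wham <- function(windows, biases, temperature = 300, tol = 1e-8,
                       max_iter = 100000L, grid = NULL) {
  stopifnot(length(windows) >= 1L, length(biases) == length(windows))
  d_all <- lapply(windows, function(w) w$d_A)
  N <- vapply(d_all, length, integer(1L))
  if (any(N == 0L)) stop("window(s) ", paste(which(N == 0L), collapse = ", "),
                         " contain no samples")
  if (is.null(grid)) {
    rng <- range(unlist(d_all))
    grid <- histogram_grid(floor(rng[1]), ceiling(rng[2] + 1e-9), 1.0)
  }
  nb <- length(grid$centers)
  nw <- length(windows)
  counts <- numeric(nb)
  occ <- matrix(FALSE, nb, nw)
  for (j in seq_len(nw)) {
    tb <- tabulate(.bin_index(grid, d_all[[j]]), nbins = nb)
    counts <- counts + tb
    occ[, j] <- tb > 0
  }
  # windows sharing no occupied bin with any other have unconstrained shifts
  if (nw > 1L) {
    lonely <- vapply(seq_len(nw), function(j) {
      shared <- occ[, j] & (rowSums(occ[, -j, drop = FALSE]) > 0)
      !any(shared)
    }, logical(1L))
    if (any(lonely)) {
      warning("window(s) ", paste(which(lonely), collapse = ", "),
              " do not overlap any other window")
    }
  }
  kT <- kBT(temperature)
  Bmat <- vapply(biases, function(b) combined_bias(grid$centers, b),
                 numeric(nb))                     # nb x nw
  lN <- log(N)
  lH <- ifelse(counts > 0, log(counts), -Inf)
  Fj <- numeric(nw)
  res_hist <- numeric(0L)
  for (it in seq_len(max_iter)) {
    log_denom <- .logsumexp_rows(sweep(-Bmat / kT, 2L, lN + Fj / kT, `+`))
    lp <- lH - log_denom
    lp <- lp - .logsumexp_rows(matrix(lp, nrow = 1L))[1L]   # normalize mass
    lz <- vapply(seq_len(nw), function(j) {
      .logsumexp_rows(matrix(lp - Bmat[, j] / kT, nrow = 1L))[1L]
    }, numeric(1L))
    Fnew <- -kT * lz
    Fnew <- Fnew - Fnew[1L]
    res <- max(abs(Fnew - Fj))
    res_hist <- c(res_hist, res)
    Fj <- Fnew
    if (res < tol) break
  }
  if (res >= tol) {
    stop("WHAM did not reach tol = ", tol, " in ", max_iter,
         " iterations (residual ", signif(res, 3), ")")
  }
  log_denom <- .logsumexp_rows(sweep(-Bmat / kT, 2L, lN + Fj / kT, `+`))
  lp <- lH - log_denom
  lp <- lp - .logsumexp_rows(matrix(lp, nrow = 1L))[1L]
  p_mass <- exp(lp)
  structure(list(F = Fj, P = p_mass / grid$width, p_mass = p_mass,
                 counts = counts, grid = grid, log_denom = log_denom,
                 iterations = it, residual = res,
                 residual_history = res_hist, temperature = temperature,
                 n_samples = N),
            class = "wham_solution")
}

#' @export
print.wham_solution <- function(x, ...) {
  cat("<wham_solution>", length(x$F), "windows,",
      length(x$grid$centers), "bins;", x$iterations,
      "iterations, residual", signif(x$residual, 3), "kcal/mol\n")
  invisible(x)
}

#' Free-energy profile from an unbiased distribution
#'
#' \eqn{F = -k_B T \ln P}, shifted so the minimum over supported bins is
#' zero; bins with zero probability are reported as \code{NA} (undefined),
#' never as zero or silently infinite.
#'
#' @param P A [solve_wham()] solution, a \code{fe_profile}, or a numeric
#'   vector of probability masses.
#' @param centers Bin centers (required when \code{P} is a bare vector).
#' @param temperature Temperature, K (taken from the solution object when
#'   available).
#' @return A \code{fe_profile} over the coordinate \code{d_A}.
#' @export
free_energy_1d <- function(P, centers = NULL, temperature = 300) {
  if (inherits(P, "wham_solution")) {
    centers <- P$grid$centers
    temperature <- P$temperature
    n <- P$counts
    P <- P$p_mass
  } else if (inherits(P, "fe_profile")) {
    centers <- P$centers
    temperature <- P$temperature
    n <- P$n
    P <- P$P
  } else {
    stopifnot(!is.null(centers), length(centers) == length(P))
    n <- NULL
  }
  if (all(P <= 0)) stop("distribution has no support")
  p <- P / sum(P)
  F <- ifelse(p > 0, -kBT(temperature) * log(p), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  fe_profile("d_A", centers, F = F, P = p, n = n, temperature = temperature)
}

#' Unbiased per-sample weights from a WHAM solution
#'
#' The weight of a sample in window j is the WHAM denominator factor
#' \eqn{w \propto [\sum_j N_j e^{[F_j - V_j]/k_B T}]^{-1}} evaluated at the
#' sample's histogram bin, normalized so all weights sum to 1.  The weighted
#' histogram of the reaction coordinate then reproduces the solution's P
#' bin-for-bin.
#'
#' @param solution A [solve_wham()] result.
#' @param samples A window sample data.frame, or the list of all windows.
#' @return Numeric vector of strictly positive weights summing to 1 (over
#'   the concatenation of all windows when a list is given).
#' @export
sample_weights <- function(solution, samples) {
  stopifnot(inherits(solution, "wham_solution"))
  if (is.data.frame(samples)) samples <- list(samples)
  d <- unlist(lapply(samples, function(s) s$d_A))
  w <- exp(-solution$log_denom[.bin_index(solution$grid, d)])
  w / sum(w)
}
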