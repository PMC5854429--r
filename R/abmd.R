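#' Adaptive biasing potential on a reaction-coordinate grid
#'
#' The shared, history-dependent biasing potential U(d) is tabulated on a
#' uniform grid over \code{[lo, hi]}.  Deposits only ever add, so node values
#' are non-negative and non-decreasing in time; the bias evaluates to zero
#' outside the range.
#'
#' @param lo,hi Range of the reaction coordinate, A.
#' @param dd Grid resolution, A (default 1.0).
#' @return An object of class \code{bias_grid} with fields \code{lo},
#'   \code{hi}, \code{dd}, \code{nodes} (node coordinates) and \code{U}
#'   (node values, kcal/mol).
#' @export
bias_grid <- function(lo, hi, dd = 1.0) {
  stopifnot(hi > lo, dd > 0)
  n <- floor((hi - lo) / dd) + 1L
  stopifnot(n >= 4L)
  nodes <- lo + (seq_len(n) - 1L) * dd
  structure(list(lo = lo, hi = nodes[n], dd = dd, nodes = nodes,
                 U = numeric(n)),
            class = "bias_grid")
}

#' @export
print.bias_grid <- function(x, ...) {
  cat("<bias_grid> [", x$lo, ",", x$hi, "] A, dd =", x$dd, "A,",
      length(x$U), "nodes; max U =", sprintf("%.4f", max(x$U)),
      "kcal/mol\n")
  invisible(x)
}

#' Flooding schedule for the adaptive bias
#'
#' @param tau Flooding time constant, ps: each walker deposits integrated
#'   bias kB*T*dt/tau per elapsed time dt, so smaller tau floods faster.
#' @param deposit_interval Deposit every this many integration steps
#'   (default 1: updated every step).
#' @param kernel_width Gaussian kernel sigma in units of the grid resolution
#'   (default 1); the kernel is truncated at 4 sigma and renormalized so the
#'   deposit-rate contract is exact.
#' @return An object of class \code{flooding_schedule}.
#' @export
flooding_schedule <- function(tau = 100, deposit_interval = 1L,
                              kernel_width = 1) {
  stopifnot(tau > 0, deposit_interval >= 1, kernel_width > 0)
  structure(list(tau = tau, deposit_interval = as.integer(deposit_interval),
                 kernel_width = kernel_width),
            class = "flooding_schedule")
}

# Cubic (Catmull-Rom) interpolation of node values with analytic derivative.
# Returns list(E, dEdd); zero outside [lo, hi].  Internal workhorse shared by
# evaluate_bias() and the in-run bias closures.
.bias_eval_core <- function(U, lo, dd, d) {
  n <- length(U)
  hi <- lo + (n - 1L) * dd
  E <- numeric(length(d))
  g <- numeric(length(d))
  ins <- which(d >= lo & d <= hi)
  if (length(ins)) {
    # one-sided slopes at the boundary nodes, central elsewhere (per dt unit)
    m <- c(U[2L] - U[1L],
           (U[seq(3L, n)] - U[seq(1L, n - 2L)]) / 2,
           U[n] - U[n - 1L])
    di <- d[ins]
    i <- pmin(pmax(floor((di - lo) / dd) + 1L, 1L), n - 1L)
    t <- (di - (lo + (i - 1L) * dd)) / dd
    t2 <- t * t; t3 <- t2 * t
    h00 <- 2 * t3 - 3 * t2 + 1; h10 <- t3 - 2 * t2 + t
    h01 <- -2 * t3 + 3 * t2;    h11 <- t3 - t2
    E[ins] <- h00 * U[i] + h10 * m[i] + h01 * U[i + 1L] + h11 * m[i + 1L]
    g00 <- 6 * t2 - 6 * t; g10 <- 3 * t2 - 4 * t + 1
    g01 <- -g00;           g11 <- 3 * t2 - 2 * t
    g[ins] <- (g00 * U[i] + g10 * m[i] + g01 * U[i + 1L] +
               g11 * m[i + 1L]) / dd
  }
  list(E = E, dEdd = g)
}

#' Evaluate the adaptive bias (energy and force)
#'
#' Cubic interpolation of the tabulated node values; the returned derivative
#' is the exact derivative of the interpolant.  On a node the interpolant
#' equals the node value; outside the grid range the bias (and force) is
#' zero.
#'
#' @param bias A [bias_grid()].
#' @param d Coordinate value(s), A.
#' @return \code{list(E, dEdd)}: bias energy (kcal/mol) and its derivative
#'   dU/dd (kcal/mol/A), each vectorized over \code{d}.  The force on the
#'   coordinate is \code{-dEdd}.
#' @export
evaluate_bias <- function(bias, d) {
  stopifnot(inherits(bias, "bias_grid"))
  .bias_eval_core(bias$U, bias$lo, bias$dd, d)
}

# Kernel accumulation used by deposit_bias and the multiwalker driver.
# Adds, for each in-range d, a truncated Gaussian whose in-grid integral
# (sum over nodes * dd) equals `weight`.  Returns the updated node vector.
.deposit_core <- function(U, lo, dd, n, d, weight, sigma) {
  K <- ceiling(4 * sigma / dd)
  j0 <- round((d - lo) / dd) + 1L
  cols <- outer(j0, seq(-K, K), `+`)
  xnode <- lo + (cols - 1L) * dd
  w <- exp(-(xnode - d)^2 / (2 * sigma^2))
  w[cols < 1L | cols > n | abs(xnode - d) > 4 * sigma] <- 0
  w <- w * (weight / (dd * rowSums(w)))
  acc <- rowsum(as.vector(w), as.vector(pmin(pmax(cols, 1L), n)))
  idx <- as.integer(rownames(acc))
  U[idx] <- U[idx] + acc[, 1L]
  U
}

#' Deposit flooding bias at the current coordinate
#'
#' Adds a smooth Gaussian kernel centered at \code{d} whose integrated weight
#' over the grid (sum over nodes times the resolution) equals
#' \code{kB*T*dt/tau} — the deposit-rate contract that makes the total
#' deposited energy proportional to walker count over flooding time.
#' Deposits at coordinates outside the grid range are skipped with a warning
#' (walkers there should be held by the walls).
#'
#' @param bias A [bias_grid()].
#' @param d Walker coordinate(s), A; one deposit per element.
#' @param dt Elapsed simulation time represented by this deposit, ps.
#' @param schedule A [flooding_schedule()].
#' @param temperature Temperature, K.
#' @return The updated [bias_grid()].
#' @export
deposit_bias <- function(bias, d, dt, schedule, temperature = 300) {
  stopifnot(inherits(bias, "bias_grid"), inherits(schedule, "flooding_schedule"),
            dt >= 0)
  if (dt == 0) return(bias)
  ins <- d >= bias$lo & d <= bias$hi
  if (any(!ins)) {
    warning(sum(!ins), " deposit(s) outside bias range [", bias$lo, ", ",
            bias$hi, "] skipped")
  }
  if (any(ins)) {
    w <- kBT(temperature) * dt / schedule$tau
    bias$U <- .deposit_core(bias$U, bias$lo, bias$dd, length(bias$U),
                            d[ins], w, schedule$kernel_width * bias$dd)
  }
  bias
}

#' One-sided harmonic wall energy
#'
#' Zero between the walls; \code{k_wall * (d - wall)^2} beyond either wall
#' (no 1/2 factor, the same quadratic convention as the umbrella restraint).
#'
#' @param d Coordinate value(s), A.
#' @param lo_wall,hi_wall Wall positions, A (\code{lo_wall < hi_wall}).
#' @param k_wall Wall force constant, kcal/mol/A^2 (default 10.0).
#' @return Wall energy, kcal/mol, vectorized over \code{d}.
#' @export
wall_energy <- function(d, lo_wall, hi_wall, k_wall = 10.0) {
  stopifnot(lo_wall < hi_wall)
  lo_ex <- pmin(d - lo_wall, 0)
  hi_ex <- pmax(d - hi_wall, 0)
  k_wall * (lo_ex^2 + hi_ex^2)
}

#' Derivative dE/dd of the wall energy
#'
#' @inheritParams wall_energy
#' @return dE/dd, kcal/mol/A (the force on d is its negative).
#' @export
wall_force_dd <- function(d, lo_wall, hi_wall, k_wall = 10.0) {
  stopifnot(lo_wall < hi_wall)
  2 * k_wall * (pmin(d - lo_wall, 0) + pmax(d - hi_wall, 0))
}

#' Multi-walker adaptively biased sampling
#'
#' Runs \code{n_walkers} concurrent Langevin walkers that share one adaptive
#' biasing potential: every \code{deposit_interval} steps each in-range
#' walker deposits a kernel of integrated weight \code{kB*T*dt/tau} at its
#' current coordinate, flooding visited regions so the ensemble diffuses over
#' barriers.  At long times the negative of the accumulated bias approaches
#' the free-energy profile (up to an additive constant) over the explored
#' range.  One-sided harmonic walls confine walkers to the biased range.
#'
#' @param system An [md_system()].
#' @param schedule A [flooding_schedule()].
#' @param range Bias range \code{c(lo, hi)}, A.
#' @param walls Wall positions \code{c(lo, hi)}, A (defaults to the bias
#'   range endpoints).
#' @param k_wall Wall force constant, kcal/mol/A^2.
#' @param n_walkers Number of walkers sharing the bias.
#' @param total_time Simulated time per walker, ps.
#' @param dt Timestep, ps.
#' @param dd Bias grid resolution, A.
#' @param gamma Friction, 1/ps.
#' @param temperature Temperature, K.
#' @param record_interval Record walker samples every this many steps.
#' @param snapshot_every Save a bias snapshot every this many ps (the
#'   dropped-energy convergence diagnostic interval).
#' @param seed Integer seed.
#' @param init Optional initial coordinate matrix (\code{n_dof x n_walkers}).
#' @return A list with elements \code{traces} (long data.frame in the trace
#'   schema with a \code{walker} column), \code{bias} (final
#'   [bias_grid()]), \code{snapshots} (nodes x snapshots matrix including the
#'   initial zero bias), \code{snapshot_times} (ps), \code{final}
#'   (coordinate matrix), \code{residence_time} (total in-range walker time
#'   at deposit events, ps), \code{skipped_deposits}, and
#'   \code{deposited_total} (kcal/mol, integrated over the grid).
#' @export
run_multiwalker <- function(system, schedule, range, walls = NULL,
                            k_wall = 10.0, n_walkers = 100L, total_time,
                            dt = 0.02, dd = 1.0, gamma = 2, temperature = 300,
                            record_interval = 50L, snapshot_every = 100,
                            seed = 1L, init = NULL) {
  stopifnot(inherits(system, "md_system"), inherits(schedule, "flooding_schedule"))
  if (is.null(walls)) walls <- c(range[1], range[2])
  set.seed(seed)
  n_steps <- round(total_time / dt)
  n_steps <- (n_steps %/% record_interval) * record_interval
  grid <- bias_grid(range[1], range[2], dd)
  env <- new.env(parent = emptyenv())
  env$U <- grid$U
  env$residence <- 0
  env$skipped <- 0L
  n_nodes <- length(grid$U)
  sigma <- schedule$kernel_width * dd
  dt_dep <- dt * schedule$deposit_interval
  w_dep <- kBT(temperature) * dt_dep / schedule$tau
  snap_steps <- max(1L, round(snapshot_every / dt))
  snaps <- list(env$U)
  snap_t <- 0
  hook <- function(d, step) {
    if (step %% schedule$deposit_interval == 0L) {
      ins <- d >= grid$lo & d <= grid$hi
      env$residence <- env$residence + dt_dep * sum(ins)
      env$skipped <- env$skipped + sum(!ins)
      if (any(ins)) {
        env$U <- .deposit_core(env$U, grid$lo, grid$dd, n_nodes, d[ins],
                               w_dep, sigma)
      }
    }
    if (step %% snap_steps == 0L) {
      snaps[[length(snaps) + 1L]] <<- env$U
      snap_t <<- c(snap_t, step * dt)
    }
  }
  bias_dEdd <- function(d) .bias_eval_core(env$U, grid$lo, grid$dd, d)$dEdd
  X <- if (is.null(init)) system$init(n_walkers) else init
  run <- .run_dynamics(system, X, n_steps, dt, gamma, temperature,
                       record_interval,
                       bias_dEdd = bias_dEdd,
                       wall = list(lo = walls[1], hi = walls[2], k = k_wall),
                       hook = hook)
  grid$U <- env$U
  list(traces = .traces_df(run),
       bias = grid,
       snapshots = do.call(cbind, snaps),
       snapshot_times = snap_t,
       final = run$X,
       residence_time = env$residence,
       skipped_deposits = env$skipped,
       deposited_total = sum(env$U) * grid$dd)
}

#' Free-energy estimate from late-stage bias snapshots
#'
#' Once flooding has converged, further deposits grow the bias uniformly
#' while its shape fluctuates around the negative free energy.  Averaging
#' the bias over the late snapshots suppresses those fluctuations, giving a
#' substantially steadier estimate than the single final snapshot.
#'
#' @param snapshots Nodes x snapshots bias matrix from [run_multiwalker()].
#' @param nodes Node coordinates (A).
#' @param last_frac Fraction of trailing snapshots averaged (default 0.5).
#' @param temperature Temperature, K.
#' @return A \code{fe_profile}: \eqn{F = -\langle U\rangle_{late}},
#'   min-anchored, with the corresponding Boltzmann masses.
#' @export
abmd_free_energy <- function(snapshots, nodes, last_frac = 0.5,
                             temperature = 300) {
  stopifnot(is.matrix(snapshots), nrow(snapshots) == length(nodes),
            last_frac > 0, last_frac <= 1)
  ns <- ncol(snapshots)
  first <- max(1L, ns - ceiling(last_frac * ns) + 1L)
  F <- -rowMeans(snapshots[, first:ns, drop = FALSE])
  F <- F - min(F)
  P <- exp(-F / kBT(temperature))
  fe_profile("d_A", nodes, F = F, P = P / sum(P), temperature = temperature)
}

#' Deposited-energy-per-interval convergence diagnostic
#'
#' Differences consecutive bias snapshots into the energy deposited per grid
#' node per interval (the "dropped energy" diagnostic: flooding has converged
#' when late-interval deposits are spatially uniform over the considered
#' region, since walkers then diffuse freely over the flattened landscape).
#'
#' @param snapshots Nodes x snapshots matrix of bias values (needs >= 2
#'   columns), e.g. from [run_multiwalker()].
#' @param times Snapshot times, ps.
#' @param region Optional node index range \code{c(first, last)} over which
#'   the uniformity metric is computed (defaults to all nodes).
#' @return A list with \code{deposits} (nodes x intervals, non-negative),
#'   \code{interval_times} (end time of each interval), and
#'   \code{uniformity}: per interval, the maximum over-bins deviation from
#'   the spatial mean deposit divided by that mean (NA where the mean is 0).
#' @export
dropped_energy_profile <- function(snapshots, times = NULL,
                                   region = NULL) {
  stopifnot(is.matrix(snapshots), ncol(snapshots) >= 2L)
  dep <- snapshots[, -1L, drop = FALSE] - snapshots[, -ncol(snapshots), drop = FALSE]
  dep[dep < 0 & dep > -1e-12] <- 0   # guard float round-off
  idx <- if (is.null(region)) seq_len(nrow(dep)) else seq(region[1], region[2])
  unif <- apply(dep[idx, , drop = FALSE], 2L, function(col) {
    m <- mean(col)
    if (m <= 0) NA_real_ else max(abs(col - m)) / m
  })
  list(deposits = dep,
       interval_times = if (is.null(times)) seq_len(ncol(dep)) else times[-1L],
       uniformity = unif)
}
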