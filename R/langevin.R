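# Langevin (BAOAB splitting) integration.  The same kernel drives single
# trajectories, the multi-walker adaptive-bias runs and the umbrella windows:
# coordinates live in an n_dof x W matrix and all walkers advance in
# lockstep.  One Gaussian matrix is drawn per step from the master stream;
# walker w always consumes column w, giving fixed per-walker substreams.

# Assemble total forces: system force plus the chain-rule contribution of all
# scalar biases acting on the reaction coordinate d.
# extra_dEdd: function(d) -> derivative dU/dd of the extra bias (per walker).
.total_force <- function(system, X, extra_dEdd = NULL) {
  sys <- system$force(X)
  if (!all(is.finite(sys$F))) {
    bad <- which(!is.finite(sys$F), arr.ind = TRUE)[1, ]
    stop("non-finite force on degree of freedom ", bad[1],
         " (walker ", bad[2], ")")
  }
  Ftot <- sys$F
  d <- NULL
  if (!is.null(extra_dEdd)) {
    rc <- system$rc(X)
    d <- rc$d
    dEdd <- extra_dEdd(d)
    Ftot <- Ftot - sweep(rc$grad, 2L, dEdd, `*`)
  }
  list(E = sys$E, F = Ftot, d = d)
}

# One BAOAB step for the whole ensemble.  Fcur is the force at X (from the
# previous step's trailing evaluation); returns the updated (X, V, Fnew, E, d).
.baoab_step <- function(system, X, V, Fcur, dt, gamma, temperature,
                        extra_dEdd = NULL) {
  m <- system$mass
  free <- system$free
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(kBT(temperature) * (1 - c1^2) / m)
  V <- V + (dt / 2) * Fcur / m                 # B
  V[!free, ] <- 0
  X <- X + (dt / 2) * V                        # A
  if (gamma > 0) {
    xi <- matrix(stats::rnorm(length(V)), nrow = nrow(V))
    V <- c1 * V + c2 * xi                      # O
    V[!free, ] <- 0
  }
  X <- X + (dt / 2) * V                        # A
  fb <- .total_force(system, X, extra_dEdd)
  V <- V + (dt / 2) * fb$F / m                 # B
  V[!free, ] <- 0
  list(X = X, V = V, Fcur = fb$F, E = fb$E, d = fb$d)
}

#' Single Langevin (BAOAB) integration step
#'
#' Advances one [system_state()] by one timestep of BAOAB-splitting Langevin
#' dynamics.  With \code{gamma = 0} the scheme reduces to velocity Verlet
#' (ballistic, energy-conserving to integrator order); with \code{gamma = 0}
#' and zero force the velocity is unchanged exactly.
#'
#' @param state A [system_state()].
#' @param system An [md_system()] providing the force evaluator.
#' @param dt Timestep, ps (> 0).
#' @param gamma Friction, 1/ps (>= 0).
#' @param temperature Temperature, K (> 0).
#' @return The updated [system_state()].
#' @export
langevin_step <- function(state, system, dt, gamma = 2, temperature = 300) {
  stopifnot(inherits(state, "system_state"), inherits(system, "md_system"),
            dt > 0, gamma >= 0, temperature > 0)
  X <- matrix(state$x, ncol = 1L)
  V <- matrix(state$v, ncol = 1L)
  f0 <- .total_force(system, X)
  st <- .baoab_step(system, X, V, f0$F, dt, gamma, temperature)
  system_state(st$X[, 1L], st$V[, 1L], state$time + dt)
}

# Shared dynamics driver.
#   restraint: list(k, centers) harmonic per-column restraints (no 1/2), or NULL
#   bias_dEdd/bias_E: functions of d (evaluated fresh each step so an adaptive
#     bias closure may mutate its grid), or NULL
#   wall: list(lo, hi, k) one-sided harmonic walls, or NULL
#   hook: function(d, step) called after each full step (e.g. bias deposits)
# Records every record_interval steps: time, d, aux rows, potential energy.
.run_dynamics <- function(system, X, n_steps, dt, gamma, temperature,
                          record_interval, restraint = NULL, bias_E = NULL,
                          bias_dEdd = NULL, wall = NULL, hook = NULL,
                          V0 = NULL, frame_every_rec = NULL) {
  W <- ncol(X)
  extra_dEdd <- NULL
  has_extra <- !is.null(restraint) || !is.null(bias_dEdd) || !is.null(wall)
  if (has_extra) {
    extra_dEdd <- function(d) {
      g <- numeric(length(d))
      if (!is.null(bias_dEdd)) g <- g + bias_dEdd(d)
      if (!is.null(restraint)) g <- g + 2 * restraint$k * (d - restraint$centers)
      if (!is.null(wall)) g <- g + wall_force_dd(d, wall$lo, wall$hi, wall$k)
      g
    }
  }
  if (is.null(V0)) {
    # Maxwell-Boltzmann start (drawn from the same master stream)
    V <- matrix(stats::rnorm(length(X), sd = sqrt(kBT(temperature) / system$mass)),
                nrow = nrow(X))
    V[!system$free, ] <- 0
  } else V <- V0
  f0 <- .total_force(system, X, extra_dEdd)
  Fcur <- f0$F
  n_rec <- n_steps %/% record_interval
  rec_t <- numeric(n_rec)
  rec_d <- matrix(NA_real_, n_rec, W)
  rec_E <- matrix(NA_real_, n_rec, W)
  aux0 <- if (is.null(system$aux)) NULL else system$aux(X)
  rec_aux <- if (is.null(aux0)) NULL else
    array(NA_real_, c(n_rec, nrow(aux0), W), dimnames = list(NULL, rownames(aux0), NULL))
  frames <- list()
  frame_rec <- integer(0L)
  k_rec <- 0L
  for (step in seq_len(n_steps)) {
    st <- .baoab_step(system, X, V, Fcur, dt, gamma, temperature, extra_dEdd)
    X <- st$X; V <- st$V; Fcur <- st$Fcur
    d <- if (is.null(st$d)) system$rc(X)$d else st$d
    if (!is.null(hook)) hook(d, step)
    if (step %% record_interval == 0L) {
      k_rec <- k_rec + 1L
      rec_t[k_rec] <- step * dt
      rec_d[k_rec, ] <- d
      rec_E[k_rec, ] <- st$E
      if (!is.null(rec_aux)) rec_aux[k_rec, , ] <- system$aux(X)
      if (!is.null(frame_every_rec) && k_rec %% frame_every_rec == 0L) {
        frames[[length(frames) + 1L]] <- X
        frame_rec <- c(frame_rec, k_rec)
      }
    }
  }
  list(X = X, V = V, time = rec_t, d = rec_d, E = rec_E, aux = rec_aux,
       frames = frames, frame_rec = frame_rec)
}

# Long-format trajectory data.frame in the package's trace schema.
.traces_df <- function(run, walker_ids = seq_len(ncol(run$d))) {
  W <- ncol(run$d)
  n <- length(run$time)
  u1 <- u2 <- matrix(0, n, W)
  if (!is.null(run$aux)) {
    nm <- dimnames(run$aux)[[2]]
    if ("unwrapped_end1" %in% nm) u1 <- run$aux[, "unwrapped_end1", , drop = TRUE]
    if ("unwrapped_end2" %in% nm) u2 <- run$aux[, "unwrapped_end2", , drop = TRUE]
    if (n == 1L) { u1 <- matrix(u1, 1L); u2 <- matrix(u2, 1L) }
  }
  data.frame(
    walker = rep(walker_ids, each = n),
    time_ps = rep(run$time, W),
    d_A = as.vector(run$d),
    unwrapped_end1 = as.vector(u1),
    unwrapped_end2 = as.vector(u2),
    energy_kcal_mol = as.vector(run$E)
  )
}

#' Simulate an unbiased (or statically biased) trajectory
#'
#' Runs Langevin dynamics for one walker and records the reaction coordinate,
#' auxiliary observables (per-end unwrapped counts where the system defines
#' them) and the potential energy at a fixed cadence.
#'
#' @param system An [md_system()].
#' @param bias Optional static bias: a [bias_grid()] evaluated along d.
#' @param n_steps Number of integration steps.
#' @param dt Timestep, ps.
#' @param record_interval Record every this many steps; must divide
#'   \code{n_steps}.
#' @param seed Integer seed (all randomness flows from it).
#' @param gamma Friction, 1/ps.
#' @param temperature Temperature, K.
#' @param init Optional initial coordinates (vector of length \code{n_dof}).
#' @return A data.frame with columns \code{time_ps}, \code{d_A},
#'   \code{unwrapped_end1}, \code{unwrapped_end2}, \code{energy_kcal_mol}
#'   (\code{n_steps / record_interval} rows), with the final state attached
#'   as attribute \code{"final_state"}.
#' @export
simulate_trajectory <- function(system, bias = NULL, n_steps, dt = 0.02,
                                record_interval = 10L, seed = 1L, gamma = 2,
                                temperature = 300, init = NULL) {
  stopifnot(inherits(system, "md_system"), n_steps >= 1,
            n_steps %% record_interval == 0L)
  set.seed(seed)
  X <- if (is.null(init)) system$init(1L) else matrix(init, ncol = 1L)
  bias_dEdd <- if (is.null(bias)) NULL else function(d) evaluate_bias(bias, d)$dEdd
  run <- .run_dynamics(system, X, n_steps, dt, gamma, temperature,
                       record_interval, bias_dEdd = bias_dEdd)
  out <- .traces_df(run, walker_ids = 1L)[, -1L]
  attr(out, "final_state") <- system_state(run$X[, 1L], run$V[, 1L],
                                           n_steps * dt)
  out
}
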