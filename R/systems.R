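#' Simulation system interface
#'
#' A \code{md_system} bundles everything the integrator and the sampling
#' drivers need to know about a model: its degrees of freedom, a vectorized
#' force evaluator, the scalar reaction coordinate d (the end-to-end distance
#' analog) with its gradient, auxiliary per-frame observables (per-end
#' unwrapped counts for the spool mimic), and an initializer.
#'
#' All evaluators are vectorized over an ensemble: coordinates are stored as
#' an \code{n_dof x n_walkers} matrix \code{X}, one column per walker (or per
#' umbrella window), so that walkers advance in lockstep with whole-ensemble
#' matrix operations.
#'
#' @param kind Short label ("potential1d", "spool", ...).
#' @param n_dof Number of degrees of freedom per walker.
#' @param force \code{function(X)} returning \code{list(E, F)}: potential
#'   energy per walker (length W) and forces (\code{n_dof x W}).
#' @param rc \code{function(X)} returning \code{list(d, grad)}: reaction
#'   coordinate per walker and its gradient (\code{n_dof x W}).
#' @param aux \code{function(X)} returning a matrix (rows = observables,
#'   columns = walkers) or \code{NULL}; row names label the observables.
#' @param init \code{function(n)} returning an initial \code{n_dof x n}
#'   coordinate matrix.
#' @param mass Mass per degree of freedom (kcal/mol ps^2/A^2 units).
#' @param free Logical vector of length \code{n_dof}: FALSE marks frozen
#'   (pinned) degrees of freedom.
#' @param spec The originating specification object, kept for provenance.
#' @return An object of class \code{md_system}.
#' @export
md_system <- function(kind, n_dof, force, rc, aux = NULL, init, mass = 1,
                      free = rep(TRUE, n_dof), spec = NULL) {
  stopifnot(is.function(force), is.function(rc), is.function(init),
            length(free) == n_dof)
  structure(list(kind = kind, n_dof = n_dof, force = force, rc = rc,
                 aux = aux, init = init, mass = mass, free = free,
                 spec = spec),
            class = "md_system")
}

#' Build a single-particle system from an analytic potential
#'
#' The coordinate itself is the reaction coordinate, so these systems have
#' exactly known free energies and serve as oracles for the samplers.
#'
#' @param spec A [potential_spec()].
#' @param init_at Starting coordinate(s); recycled over walkers.
#' @param mass Particle mass (internal units, default 1).
#' @return An [md_system()].
#' @export
potential_system <- function(spec, init_at = NULL, mass = 1) {
  stopifnot(inherits(spec, "potential_spec"))
  if (is.null(init_at)) {
    init_at <- switch(spec$kind,
      harmonic = spec$center,
      double_well = spec$center - spec$a,
      tabulated = mean(spec$domain))
  }
  force <- function(X) {
    x <- X[1L, ]
    list(E = potential_energy(spec, x),
         F = matrix(potential_force(spec, x), nrow = 1L))
  }
  rc <- function(X) {
    list(d = X[1L, ], grad = matrix(1, nrow = 1L, ncol = ncol(X)))
  }
  init <- function(n) matrix(rep_len(init_at, n), nrow = 1L)
  md_system("potential1d", 1L, force, rc, aux = NULL, init = init,
            mass = mass, spec = spec)
}

#' Instantaneous system state
#'
#' @param x Coordinates (numeric vector of length \code{n_dof}).
#' @param v Velocities (same length; default zero).
#' @param time Time in ps.
#' @return An object of class \code{system_state}.
#' @export
system_state <- function(x, v = NULL, time = 0) {
  x <- as.numeric(x)
  if (is.null(v)) v <- numeric(length(x))
  stopifnot(length(v) == length(x), all(is.finite(x)))
  structure(list(x = x, v = v, time = time), class = "system_state")
}
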