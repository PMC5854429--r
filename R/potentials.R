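#' One-dimensional analytic potential specifications
#'
#' Defines the analytic one-dimensional model potentials used as oracle
#' systems: their free energy along the coordinate is known in closed form
#' (for a one-dimensional system it equals the potential itself), so sampling
#' and estimator machinery can be validated against exact answers.
#'
#' Functional forms (no 1/2 factor in the harmonic, consistent with the
#' harmonic-restraint convention used throughout the package):
#' \itemize{
#'   \item \code{harmonic}: \eqn{V(d) = k (d - c)^2}
#'   \item \code{double_well}: \eqn{V(d) = h ((d-c)^2 - a^2)^2 / a^4} with
#'     minima at \eqn{c \pm a} (well separation \eqn{2a}) and barrier
#'     height \eqn{h} at \eqn{d = c}.
#'   \item \code{tabulated}: natural cubic spline through \code{(d, V)} pairs.
#' }
#'
#' @param kind One of \code{"harmonic"}, \code{"double_well"},
#'   \code{"tabulated"}.
#' @param stiffness Harmonic stiffness k in kcal/mol/A^2.
#' @param center Location of the harmonic minimum / double-well midpoint (A).
#' @param well_separation Distance between the two minima of the double well
#'   (A).
#' @param barrier Barrier height of the double well (kcal/mol).
#' @param domain Coordinate domain \code{c(lo, hi)} on which the potential is
#'   defined (A).
#' @param d,V Node coordinates and energies for \code{kind = "tabulated"}.
#' @return An object of class \code{potential_spec}.
#' @examples
#' dw <- potential_spec("double_well", center = 50, well_separation = 10,
#'                      barrier = 3, domain = c(35, 65))
#' potential_energy(dw, c(45, 50, 55))
#' @export
potential_spec <- function(kind = c("harmonic", "double_well", "tabulated"),
                           stiffness = 1.0, center = 0.0,
                           well_separation = 10.0, barrier = 3.0,
                           domain = c(-Inf, Inf), d = NULL, V = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(domain) == 2, domain[1] < domain[2])
  spec <- list(kind = kind, domain = as.numeric(domain))
  if (kind == "harmonic") {
    stopifnot(stiffness > 0)
    spec$stiffness <- stiffness
    spec$center <- center
  } else if (kind == "double_well") {
    stopifnot(well_separation > 0, barrier > 0)
    spec$center <- center
    spec$a <- well_separation / 2
    spec$barrier <- barrier
  } else {
    stopifnot(is.numeric(d), is.numeric(V), length(d) == length(V),
              length(d) >= 4, !is.unsorted(d, strictly = TRUE))
    spec$spline <- stats::splinefun(d, V, method = "natural")
    spec$domain <- c(max(domain[1], min(d)), min(domain[2], max(d)))
  }
  class(spec) <- "potential_spec"
  spec
}

#' Potential energy of an analytic 1-D potential
#'
#' @param spec A [potential_spec()].
#' @param x Coordinate value(s), A.
#' @return Energy in kcal/mol, vectorized over \code{x}.
#' @export
potential_energy <- function(spec, x) {
  stopifnot(inherits(spec, "potential_spec"))
  switch(spec$kind,
    harmonic = spec$stiffness * (x - spec$center)^2,
    double_well = {
      u <- (x - spec$center)^2 - spec$a^2
      spec$barrier * u^2 / spec$a^4
    },
    tabulated = spec$spline(x)
  )
}

#' Force (-dV/dx) of an analytic 1-D potential
#'
#' @inheritParams potential_energy
#' @return Force in kcal/mol/A, vectorized over \code{x}.
#' @export
potential_force <- function(spec, x) {
  stopifnot(inherits(spec, "potential_spec"))
  switch(spec$kind,
    harmonic = -2 * spec$stiffness * (x - spec$center),
    double_well = {
      u <- (x - spec$center)^2 - spec$a^2
      -spec$barrier * 4 * u * (x - spec$center) / spec$a^4
    },
    tabulated = -spec$spline(x, deriv = 1)
  )
}

#' Exact free-energy profile of an analytic potential
#'
#' For a one-dimensional system the free energy along the coordinate equals
#' the potential itself; this returns it on a grid of bin centers, anchored so
#' that its minimum is zero, together with the corresponding Boltzmann
#' probability masses.  Used as the exact oracle against which sampled and
#' WHAM-refined profiles are compared.
#'
#' @param spec A [potential_spec()].
#' @param grid Numeric vector of coordinate bin centers (A), strictly
#'   increasing, inside the spec's domain.
#' @param temperature Temperature in K (only sets the Boltzmann weights).
#' @return A \code{fe_profile} object (see [fe_profile()]).
#' @export
analytic_free_energy <- function(spec, grid, temperature = 300) {
  stopifnot(inherits(spec, "potential_spec"), is.numeric(grid),
            !is.unsorted(grid, strictly = TRUE))
  if (min(grid) < spec$domain[1] || max(grid) > spec$domain[2]) {
    stop("grid extends outside the potential's domain [",
         spec$domain[1], ", ", spec$domain[2], "]")
  }
  F <- potential_energy(spec, grid)
  F <- F - min(F)
  P <- exp(-F / kBT(temperature))
  P <- P / sum(P)
  fe_profile(coord = "d_A", centers = grid, F = F, P = P,
             temperature = temperature)
}

#' Free-energy profile container
#'
#' A light container for a free energy F and probability mass P over bins of
#' one coordinate (or pairs of coordinates for two-dimensional landscapes).
#' F is anchored to zero at its minimum over the supported bins; bins with no
#' support carry \code{NA} in F and zero mass in P.
#'
#' @param coord Coordinate name (1-D) or character vector of two names (2-D).
#' @param centers Bin centers: numeric vector (1-D) or a two-column matrix of
#'   center pairs (2-D).
#' @param F Free energies, kcal/mol (NA on unsupported bins).
#' @param P Probability masses (sum to 1 over support).
#' @param n Optional per-bin sample counts.
#' @param temperature Temperature in K.
#' @return An object of class \code{fe_profile}.
#' @export
fe_profile <- function(coord, centers, F, P, n = NULL, temperature = 300) {
  stopifnot(length(F) == length(P))
  structure(list(coord = coord, centers = centers, F = F, P = P, n = n,
                 temperature = temperature),
            class = "fe_profile")
}

#' @export
print.fe_profile <- function(x, ...) {
  dim2 <- is.matrix(x$centers)
  cat("<fe_profile> over", paste(x$coord, collapse = " x "),
      "-", if (dim2) nrow(x$centers) else length(x$centers), "bins,",
      sum(!is.na(x$F)), "supported; T =", x$temperature, "K\n")
  rng <- range(x$F, na.rm = TRUE)
  cat("  F range:", sprintf("%.4f .. %.4f kcal/mol", rng[1], rng[2]), "\n")
  invisible(x)
}
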