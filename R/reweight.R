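# Sum x over the integer codes of factor f, reported in level order with
# zeros for empty levels (rowsum() alone does not guarantee level order).
.tally_by <- function(x, f, nlev) {
  out <- numeric(nlev)
  acc <- rowsum(x, as.integer(f))
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out
}

#' Free-energy profile along an alternative coordinate
#'
#' Projects the WHAM-unbiased ensemble onto a per-sample coordinate (e.g.
#' the total number of unwrapped base pairs): the probability of each
#' coordinate value is the sum of the unbiased weights of the samples
#' carrying it, and \eqn{F = -k_B T \ln P}, min-anchored.  Integer-valued
#' coordinates are tallied at unit width; continuous ones may be pre-binned
#' by the caller.
#'
#' @param coordinate Per-sample coordinate values (numeric or integer).
#' @param weights Normalized per-sample unbiased weights (sum 1), e.g. from
#'   [sample_weights()].
#' @param temperature Temperature, K.
#' @param levels Optional vector of bin values to report (defaults to the
#'   sorted unique coordinate values); values with no samples get zero mass
#'   and undefined F.
#' @return A \code{fe_profile} over the coordinate.
#' @export
pmf_along <- function(coordinate, weights, temperature = 300,
                      levels = NULL) {
  stopifnot(length(coordinate) == length(weights), length(weights) > 0,
            all(is.finite(weights)))
  if (is.null(levels)) levels <- sort(unique(coordinate))
  f <- factor(coordinate, levels = levels)
  if (anyNA(f)) stop("coordinate values outside the requested levels")
  P <- .tally_by(weights, f, length(levels))
  P <- P / sum(P)
  if (all(P <= 0)) stop("empty support")
  F <- ifelse(P > 0, -kBT(temperature) * log(P), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  fe_profile(deparse(substitute(coordinate))[1L], as.numeric(levels),
             F = F, P = P,
             n = .tally_by(rep(1, length(weights)), f, length(levels)),
             temperature = temperature)
}

#' Weighted mean of an observable along a coordinate
#'
#' \eqn{\bar A(R) = \sum_s w_s A_s \delta_{R_s,R} / \sum_s w_s
#' \delta_{R_s,R}}: the unbiased-ensemble average of A within each
#' coordinate bin; undefined (NA) on empty bins.
#'
#' @param A Per-sample observable values.
#' @param coordinate Per-sample coordinate values.
#' @param weights Normalized per-sample weights.
#' @param levels Optional bin values to report.
#' @return A data.frame with columns \code{value} (bin), \code{mean},
#'   \code{weight} (bin mass).
#' @export
weighted_mean_by <- function(A, coordinate, weights, levels = NULL) {
  stopifnot(length(A) == length(coordinate),
            length(A) == length(weights), all(is.finite(A)))
  if (is.null(levels)) levels <- sort(unique(coordinate))
  f <- factor(coordinate, levels = levels)
  wsum <- .tally_by(weights, f, length(levels))
  wa <- .tally_by(weights * A, f, length(levels))
  data.frame(value = as.numeric(levels),
             mean = ifelse(wsum > 0, wa / wsum, NA_real_),
             weight = wsum)
}

#' Weighted spread (rms deviation) of an observable along a coordinate
#'
#' \eqn{\sigma^2(R) = \overline{A^2}(R) - \bar A(R)^2}; the max-with-zero
#' guards floating-point rounding for (near-)constant observables.
#'
#' @inheritParams weighted_mean_by
#' @return A data.frame with columns \code{value}, \code{mean}, \code{sd},
#'   \code{weight}.
#' @export
weighted_spread_by <- function(A, coordinate, weights, levels = NULL) {
  m1 <- weighted_mean_by(A, coordinate, weights, levels)
  m2 <- weighted_mean_by(A^2, coordinate, weights, levels)
  m1$sd <- sqrt(pmax(m2$mean - m1$mean^2, 0))
  m1[, c("value", "mean", "sd", "weight")]
}

#' Two-dimensional free-energy landscape
#'
#' Joint weighted histogram of two per-sample coordinates and the landscape
#' \eqn{F(R_1, R_2) = -k_B T \ln P(R_1, R_2)}, anchored so the global
#' minimum over the supported cells is zero.  Marginalizing the joint mass
#' over either axis reproduces the corresponding one-dimensional
#' projection.
#'
#' @param coord1,coord2 Per-sample coordinate values (binned by the caller
#'   where continuous; \code{coord1} is typically the end-to-end distance
#'   bin, \code{coord2} the unwrapped-bp count).
#' @param weights Normalized per-sample weights.
#' @param temperature Temperature, K.
#' @param levels1,levels2 Optional bin values per axis.
#' @return A \code{fe_profile} whose \code{centers} is a two-column matrix
#'   of (R1, R2) cell pairs (all cells, unsupported ones with NA free
#'   energy), plus attributes \code{P_matrix} and \code{F_matrix}
#'   (levels1 x levels2 matrices).
#' @export
fes_2d <- function(coord1, coord2, weights, temperature = 300,
                   levels1 = NULL, levels2 = NULL) {
  stopifnot(length(coord1) == length(coord2),
            length(coord1) == length(weights))
  if (is.null(levels1)) levels1 <- sort(unique(coord1))
  if (is.null(levels2)) levels2 <- sort(unique(coord2))
  f1 <- factor(coord1, levels = levels1)
  f2 <- factor(coord2, levels = levels2)
  idx <- (as.integer(f2) - 1L) * length(levels1) + as.integer(f1)
  P <- numeric(length(levels1) * length(levels2))
  acc <- rowsum(weights, idx)
  P[as.integer(rownames(acc))] <- acc[, 1L]
  P <- P / sum(P)
  F <- ifelse(P > 0, -kBT(temperature) * log(P), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  centers <- cbind(R1 = rep(as.numeric(levels1), length(levels2)),
                   R2 = rep(as.numeric(levels2), each = length(levels1)))
  out <- fe_profile(c("R1", "R2"), centers, F = F, P = P,
                    temperature = temperature)
  attr(out, "P_matrix") <- matrix(P, length(levels1),
                                  dimnames = list(levels1, levels2))
  attr(out, "F_matrix") <- matrix(F, length(levels1),
                                  dimnames = list(levels1, levels2))
  out
}
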