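#' Reference (fully wrapped) structure for unwrapping metrics
#'
#' @param coords Units x 3 coordinate matrix (A) with unique rownames as
#'   unit ids (base pairs, or beads for the mimic).
#' @param core_center Coordinate of the core center (length 3).
#' @param end1,end2 Character vectors of unit ids for the two ends, ordered
#'   outermost first; the two lists must be disjoint.
#' @return An object of class \code{reference_structure}.
#' @export
reference_structure <- function(coords, core_center, end1, end2) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L,
            !is.null(rownames(coords)), !anyDuplicated(rownames(coords)),
            length(core_center) == 3L,
            all(c(end1, end2) %in% rownames(coords)),
            !any(end1 %in% end2))
  structure(list(coords = coords, core_center = as.numeric(core_center),
                 end1 = end1, end2 = end2),
            class = "reference_structure")
}

#' Count unwrapped units in a frame
#'
#' A unit counts as unwrapped when its center has moved strictly more than
#' \code{threshold} from its reference position \emph{and} the displacement
#' points outward (positive component along the core-to-reference-position
#' direction) — a definition satisfying both the
#' "shifted outward by more than 4 A" and the "deviated from the core"
#' readings.  Alternative raw variants are exposed through \code{mode}.
#' Per-end counts are contiguous from the outermost unit inward (counting
#' stops at the first still-wrapped unit), matching progressive end
#' unwrapping; the non-contiguous tally is attached as attribute
#' \code{"any_count"}.
#'
#' @param frame Units x 3 coordinate matrix with rownames matching the
#'   reference.
#' @param reference A [reference_structure()].
#' @param threshold Displacement threshold, A (strict inequality;
#'   default 4.0).
#' @param mode \code{"radial_outward"} (default), \code{"displacement"}
#'   (magnitude only), or \code{"radial_distance"} (increase of the
#'   distance from the core center by more than the threshold).
#' @param contiguous Count per-end units contiguously from the end
#'   (default TRUE).
#' @return \code{list(n_end1, n_end2, total)} with \code{total = n_end1 +
#'   n_end2}; attribute \code{"any_count"} holds the number of unwrapped
#'   units anywhere.
#' @export
count_unwrapped <- function(frame, reference, threshold = 4.0,
                            mode = c("radial_outward", "displacement",
                                     "radial_distance"),
                            contiguous = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "reference_structure"))
  ids <- rownames(reference$coords)
  missing <- setdiff(ids, rownames(frame))
  if (length(missing)) {
    stop("frame is missing unit(s): ", paste(missing, collapse = ", "))
  }
  X <- frame[ids, , drop = FALSE]
  R <- reference$coords
  delta <- X - R
  dmag <- sqrt(rowSums(delta^2))
  unwrapped <- switch(mode,
    radial_outward = {
      rad <- sweep(R, 2L, reference$core_center)   # core -> reference unit
      rhat <- rad / sqrt(rowSums(rad^2))
      dmag > threshold & rowSums(delta * rhat) > 0
    },
    displacement = dmag > threshold,
    radial_distance = {
      rf <- sqrt(rowSums(sweep(X, 2L, reference$core_center)^2))
      rr <- sqrt(rowSums(sweep(R, 2L, reference$core_center)^2))
      rf - rr > threshold
    })
  names(unwrapped) <- ids
  end_count <- function(end_ids) {
    u <- unwrapped[end_ids]
    if (contiguous) {
      first_wrapped <- match(FALSE, u, nomatch = length(u) + 1L)
      first_wrapped - 1L
    } else sum(u)
  }
  n1 <- end_count(reference$end1)
  n2 <- end_count(reference$end2)
  out <- list(n_end1 = n1, n_end2 = n2, total = n1 + n2)
  attr(out, "any_count") <- sum(unwrapped)
  out
}

#' Residue contact probabilities stratified by unwrapping progress
#'
#' A frame is in contact (for a given residue/group) when at least one pair
#' of atoms between the two groups is within the cutoff (inclusive, "within
#' 4 A").  Probabilities are weighted frame fractions with the weights
#' renormalized inside each stratum of the stratifying variable (typically
#' the per-frame unwrapped count); with \code{weights = NULL} raw frame
#' frequencies are reported instead.
#'
#' @param frames List of coordinate matrices (rows named by atom/bead id).
#' @param groups_A Named list of id vectors, one per residue (or a single
#'   id vector for one group).
#' @param group_B Id vector of the partner group (e.g. DNA beads).
#' @param cutoff Contact cutoff, A (inclusive; default 4.0).
#' @param weights Per-frame unbiased weights, or NULL for raw frequencies.
#' @param stratify_by Per-frame stratum labels (e.g. total unwrapped
#'   count); NULL pools all frames into one stratum.
#' @return A data.frame of class \code{contact_table} with columns
#'   \code{residue}, \code{stratum}, \code{probability} (in [0, 1];
#'   strata with no frames are absent).
#' @export
contact_ratio <- function(frames, groups_A, group_B, cutoff = 4.0,
                          weights = NULL, stratify_by = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L, length(group_B) >= 1L)
  if (!is.list(groups_A)) groups_A <- list(group = groups_A)
  stopifnot(all(lengths(groups_A) >= 1L))
  if (is.null(names(groups_A))) names(groups_A) <- seq_along(groups_A)
  nf <- length(frames)
  if (is.null(weights)) weights <- rep(1 / nf, nf)
  if (is.null(stratify_by)) stratify_by <- rep(0L, nf)
  stopifnot(length(weights) == nf, length(stratify_by) == nf)
  # per-frame, per-residue contact indicators (all-pairs minimum distance)
  ind <- vapply(frames, function(fr) {
    B <- fr[group_B, , drop = FALSE]
    vapply(groups_A, function(ga) {
      A <- fr[ga, , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
      sqrt(max(min(d2), 0)) <= cutoff
    }, logical(1L))
  }, logical(length(groups_A)))
  ind <- matrix(ind, nrow = length(groups_A))   # residues x frames
  strata <- sort(unique(stratify_by))
  out <- do.call(rbind, lapply(strata, function(s) {
    sel <- stratify_by == s
    w <- weights[sel]
    p <- vapply(seq_along(groups_A), function(g) {
      sum(w[ind[g, sel]]) / sum(w)
    }, numeric(1L))
    data.frame(residue = names(groups_A), stratum = s, probability = p)
  }))
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_table", class(out))
  out
}

#' End-asymmetry distribution of unwrapping
#'
#' Tallies the weighted joint distribution of (total unwrapped count,
#' end difference n1 - n2) and normalizes each total-count column to 1 over
#' the differences, so each column answers "given this much total
#' unwrapping, how is it split between the two ends?".
#'
#' @param counts Two-column matrix or data.frame of per-frame
#'   (n_end1, n_end2) non-negative integer counts.
#' @param weights Per-frame weights (default uniform).
#' @return A data.frame of class \code{asymmetry_matrix} with columns
#'   \code{total}, \code{difference}, \code{probability}; within each
#'   populated total, probabilities sum to 1.
#' @export
asymmetry_distribution <- function(counts, weights = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2L, all(counts >= 0),
            all(counts == round(counts)))
  n <- nrow(counts)
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n)
  total <- counts[, 1L] + counts[, 2L]
  diff <- counts[, 1L] - counts[, 2L]
  key <- paste(total, diff, sep = ":")
  agg <- rowsum(weights, key)
  parts <- do.call(rbind, strsplit(rownames(agg), ":", fixed = TRUE))
  out <- data.frame(total = as.integer(parts[, 1L]),
                    difference = as.integer(parts[, 2L]),
                    probability = agg[, 1L])
  out <- out[order(out$total, out$difference), ]
  colsum <- rowsum(out$probability, out$total)
  out$probability <- out$probability / colsum[match(out$total,
                                                   as.integer(rownames(colsum)))]
  rownames(out) <- NULL
  class(out) <- c("asymmetry_matrix", class(out))
  out
}

#' Stitch per-stage free-energy changes into a total
#'
#' Stages of a staged unwrapping protocol are joined at matched end states;
#' the total free-energy change is the sum of the per-stage changes (e.g.
#' 5.5 + 6.0 = 11.5 kcal/mol for the two outer-turn stages).
#'
#' @param stage_deltas Numeric vector of per-stage free-energy changes,
#'   kcal/mol.
#' @param stage_names Optional stage labels.
#' @return A list with \code{total} (kcal/mol) and \code{stages} (a
#'   data.frame of stage, delta_F, and the running cumulative value).
#' @export
stitch_stage_profiles <- function(stage_deltas, stage_names = NULL) {
  stopifnot(is.numeric(stage_deltas), length(stage_deltas) >= 1L,
            all(is.finite(stage_deltas)))
  if (is.null(stage_names)) {
    stage_names <- paste0("stage", seq_along(stage_deltas))
  }
  list(total = sum(stage_deltas),
       stages = data.frame(stage = stage_names,
                           delta_F_kcal_mol = stage_deltas,
                           cumulative_kcal_mol = cumsum(stage_deltas)))
}
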