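#' Umbrella window grid
#'
#' Builds the inclusive-endpoint grid of window centers
#' \code{d_i = lo + spacing * i}, \code{i = 0 .. (hi-lo)/spacing}; the
#' canonical stage grids are 40..180 A (71 windows) and 125..175 A
#' (26 windows) at 2 A spacing.
#'
#' @param lo,hi Range of window centers, A (\code{hi >= lo}).
#' @param spacing Window spacing, A; \code{hi - lo} must be an integer
#'   multiple of it (no silent truncation).
#' @return An object of class \code{window_grid} with fields \code{lo},
#'   \code{spacing}, \code{n_windows} and \code{centers}.
#' @examples
#' build_window_grid(40, 180, 2)$n_windows   # 71
#' build_window_grid(125, 175, 2)$n_windows  # 26
#' @export
build_window_grid <- function(lo, hi, spacing = 2.0) {
  stopifnot(hi >= lo, spacing > 0)
  n_int <- (hi - lo) / spacing
  if (abs(n_int - round(n_int)) > 1e-9) {
    stop("window range [", lo, ", ", hi, "] is not a multiple of spacing ",
         spacing)
  }
  n <- as.integer(round(n_int)) + 1L
  structure(list(lo = lo, spacing = spacing, n_windows = n,
                 centers = lo + spacing * (seq_len(n) - 1L)),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat("<window_grid>", x$n_windows, "windows,", x$centers[1], "..",
      x$centers[x$n_windows], "A, spacing", x$spacing, "A\n")
  invisible(x)
}

#' Select umbrella seeds from walker end states
#'
#' For each window center, picks the walker whose reaction-coordinate value
#' is closest to it (ties broken toward the lower walker id); a walker may
#' seed several windows.
#'
#' @param walker_d Named or plain numeric vector of final walker coordinates
#'   (A); names (or positions) are the walker ids.
#' @param grid A [window_grid()].
#' @return Integer vector of walker indices, one per window.
#' @export
select_seeds <- function(walker_d, grid) {
  stopifnot(inherits(grid, "window_grid"))
  if (length(walker_d) == 0L) stop("no walkers to select seeds from")
  vapply(grid$centers, function(ctr) {
    dist <- abs(walker_d - ctr)
    which(dist == min(dist))[1L]    # lowest id on ties
  }, integer(1L))
}

#' One umbrella window definition
#'
#' @param center Restraint center d_i, A.
#' @param k Harmonic force constant, kcal/mol/A^2 (default 0.2).
#' @param bias Frozen adaptive [bias_grid()] shared by all windows of a
#'   stage, or NULL for a plain harmonic window.
#' @param seed_id Optional id of the walker that seeded the window.
#' @return An object of class \code{umbrella_window}.
#' @export
umbrella_window <- function(center, k = 0.2, bias = NULL, seed_id = NA) {
  stopifnot(k > 0)
  structure(list(center = center, k = k, bias = bias, seed_id = seed_id),
            class = "umbrella_window")
}

#' Combined umbrella + adaptive bias energy
#'
#' The biasing potential of a window is the harmonic restraint plus the
#' frozen adaptive bias: \eqn{V_i(d) = k_i (d - d_i)^2 + U_{abmd}(d)}
#' (note: no 1/2 factor in the harmonic term).
#'
#' @param d Coordinate value(s), A.
#' @param window An [umbrella_window()].
#' @return Bias energy, kcal/mol, vectorized over \code{d}.
#' @export
combined_bias <- function(d, window) {
  stopifnot(inherits(window, "umbrella_window"))
  e <- window$k * (d - window$center)^2
  if (!is.null(window$bias)) e <- e + evaluate_bias(window$bias, d)$E
  e
}

#' Run restrained sampling in all umbrella windows
#'
#' Each window samples Langevin dynamics under the combined bias of its
#' harmonic restraint and the frozen adaptive bias; all windows advance in
#' lockstep as one vectorized ensemble.  For a flat underlying potential the
#' stationary density in a window is Gaussian with variance
#' \code{kB*T/(2k)} (quadratic restraint without the 1/2 factor).
#'
#' @param system An [md_system()].
#' @param grid A [window_grid()].
#' @param k Restraint force constant, kcal/mol/A^2.
#' @param frozen_bias Frozen [bias_grid()] (identical across windows), or
#'   NULL.
#' @param duration Sampled time per window, ps.
#' @param dt Timestep, ps.
#' @param record_interval Record every this many steps.
#' @param gamma Friction, 1/ps.
#' @param temperature Temperature, K.
#' @param seed Integer seed.
#' @param inits Optional initial coordinates, \code{n_dof x n_windows}
#'   (e.g. seeded from walker end states); defaults to the system
#'   initializer.
#' @param burn_in Equilibration time discarded from the front of each
#'   window, ps (default 0; none is assumed silently).
#' @param frame_interval Optionally keep full coordinate frames every this
#'   many recorded samples (for structural metrics); NULL keeps none.
#' @return A list of per-window sample data.frames (columns
#'   \code{time_ps}, \code{d_A}, \code{unwrapped_end1},
#'   \code{unwrapped_end2}, \code{energy_kcal_mol}), each carrying
#'   attributes \code{window_id}, \code{center}, \code{k}; the shared frozen
#'   bias is attached to the list as attribute \code{"frozen_bias"}.
#' @export
run_windows <- function(system, grid, k = 0.2, frozen_bias = NULL, duration,
                        dt = 0.02, record_interval = 10L, gamma = 2,
                        temperature = 300, seed = 1L, inits = NULL,
                        burn_in = 0, frame_interval = NULL) {
  stopifnot(inherits(system, "md_system"), inherits(grid, "window_grid"))
  set.seed(seed)
  n_steps <- round(duration / dt)
  n_steps <- (n_steps %/% record_interval) * record_interval
  W <- grid$n_windows
  X <- if (is.null(inits)) system$init(W) else inits
  stopifnot(ncol(X) == W)
  bias_dEdd <- if (is.null(frozen_bias)) NULL else
    function(d) evaluate_bias(frozen_bias, d)$dEdd
  run <- .run_dynamics(system, X, n_steps, dt, gamma, temperature,
                       record_interval,
                       restraint = list(k = k, centers = grid$centers),
                       bias_dEdd = bias_dEdd,
                       frame_every_rec = frame_interval)
  keep <- run$time > burn_in
  out <- lapply(seq_len(W), function(w) {
    u1 <- u2 <- numeric(sum(keep))
    if (!is.null(run$aux)) {
      u1 <- run$aux[keep, "unwrapped_end1", w]
      u2 <- run$aux[keep, "unwrapped_end2", w]
    }
    df <- data.frame(time_ps = run$time[keep], d_A = run$d[keep, w],
                     unwrapped_end1 = u1, unwrapped_end2 = u2,
                     energy_kcal_mol = run$E[keep, w])
    attr(df, "window_id") <- w
    attr(df, "center") <- grid$centers[w]
    attr(df, "k") <- k
    df
  })
  attr(out, "frozen_bias") <- frozen_bias
  attr(out, "final") <- run$X
  if (!is.null(frame_interval)) {
    attr(out, "frames") <- run$frames
    attr(out, "frame_d") <- run$d[run$frame_rec, , drop = FALSE]
    attr(out, "frame_aux") <- if (is.null(run$aux)) NULL else
      run$aux[run$frame_rec, , , drop = FALSE]
  }
  out
}

#' Discard samples outside a coordinate range
#'
#' Removes samples whose reaction coordinate lies outside the closed
#' interval \code{keep_range} (the boundary values are retained, matching
#' window centers that sit exactly on the range limits) and records how many
#' were removed.
#'
#' @param samples A window sample data.frame (with a \code{d_A} column) or a
#'   list of them.
#' @param keep_range \code{c(lo, hi)}, A.
#' @return The filtered object, with attribute \code{"removed"} holding the
#'   number of samples discarded (total across windows for a list).
#' @export
filter_discard_regions <- function(samples, keep_range) {
  stopifnot(length(keep_range) == 2L, keep_range[1] <= keep_range[2])
  if (is.data.frame(samples)) {
    keep <- samples$d_A >= keep_range[1] & samples$d_A <= keep_range[2]
    out <- samples[keep, , drop = FALSE]
    for (a in c("window_id", "center", "k")) attr(out, a) <- attr(samples, a)
    attr(out, "removed") <- sum(!keep)
    return(out)
  }
  fb <- attr(samples, "frozen_bias")
  out <- lapply(samples, filter_discard_regions, keep_range = keep_range)
  attr(out, "removed") <- sum(vapply(out, attr, numeric(1L), "removed"))
  attr(out, "frozen_bias") <- fb
  out
}
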