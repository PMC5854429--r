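# Plain-text serialization of the pipeline artifacts: CSV payloads with JSON
# sidecars for provenance (spec, seed, parameters).

#' Write a trajectory trace CSV with a JSON provenance sidecar
#'
#' @param traces Trace data.frame (the \code{time_ps}, \code{d_A},
#'   \code{unwrapped_end1}, \code{unwrapped_end2}, \code{energy_kcal_mol}
#'   schema, optionally with a \code{walker} column).
#' @param path Output CSV path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @param meta Named list of provenance fields (spec, seed, ...).
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(traces, path, meta = list()) {
  utils::write.csv(traces, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a bias grid as CSV (+ JSON metadata)
#'
#' @param bias A [bias_grid()].
#' @param path Output CSV path (columns \code{d_A}, \code{U_kcal_mol}).
#' @param meta Extra metadata merged into the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_bias_csv <- function(bias, path, meta = list()) {
  utils::write.csv(data.frame(d_A = bias$nodes, U_kcal_mol = bias$U),
                   path, row.names = FALSE)
  meta <- c(list(lo = bias$lo, hi = bias$hi, dd = bias$dd), meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a bias grid written by [write_bias_csv()]
#'
#' @param path CSV path.
#' @return A [bias_grid()].
#' @export
read_bias_csv <- function(path) {
  df <- utils::read.csv(path)
  dd <- df$d_A[2] - df$d_A[1]
  g <- bias_grid(df$d_A[1], df$d_A[nrow(df)] + 1e-9, dd)
  g$U <- df$U_kcal_mol
  g
}

#' Write umbrella-window samples as one long CSV
#'
#' @param windows List of window sample data.frames from [run_windows()].
#' @param path Output CSV path (columns \code{window_id}, \code{center_A},
#'   \code{k}, then the trace schema).
#' @return \code{path}, invisibly.
#' @export
write_windows_csv <- function(windows, path) {
  long <- do.call(rbind, lapply(windows, function(w) {
    cbind(data.frame(window_id = attr(w, "window_id"),
                     center_A = attr(w, "center"),
                     k = attr(w, "k")), w)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read umbrella-window samples written by [write_windows_csv()]
#'
#' @param path CSV path.
#' @return A list of per-window data.frames with \code{window_id},
#'   \code{center} and \code{k} attributes restored.
#' @export
read_windows_csv <- function(path) {
  long <- utils::read.csv(path)
  lapply(split(long, long$window_id), function(df) {
    out <- df[, setdiff(names(df), c("window_id", "center_A", "k")),
              drop = FALSE]
    rownames(out) <- NULL
    attr(out, "window_id") <- df$window_id[1]
    attr(out, "center") <- df$center_A[1]
    attr(out, "k") <- df$k[1]
    out
  })
}

#' Write a free-energy profile as CSV
#'
#' One-dimensional profiles use columns (coordinate, \code{F_kcal_mol},
#' \code{P}, \code{n}); two-dimensional landscapes use the long format
#' (\code{R1_A}, \code{R2_bp}, \code{F_kcal_mol}, \code{P}).
#'
#' @param profile A \code{fe_profile}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "fe_profile"))
  if (is.matrix(profile$centers)) {
    df <- data.frame(R1_A = profile$centers[, 1L],
                     R2_bp = profile$centers[, 2L],
                     F_kcal_mol = profile$F, P = profile$P)
  } else {
    df <- data.frame(coord = profile$centers, F_kcal_mol = profile$F,
                     P = profile$P)
    names(df)[1L] <- if (is.character(profile$coord)) profile$coord[1L] else "coord"
    if (!is.null(profile$n)) df$n <- profile$n
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
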