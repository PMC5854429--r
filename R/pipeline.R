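#' Stage configuration for the two-stage unwrapping protocol
#'
#' Collects every tunable of one protocol stage (adaptive-bias flooding,
#' window seeding, umbrella refinement, WHAM, metrics) plus the system
#' definition and the single master seed from which all phase seeds are
#' derived.  Configurations serialize to JSON and round-trip exactly.
#'
#' @param stage_id Stage label (e.g. \code{"stage1"}).
#' @param system Named list describing the system: \code{type}
#'   (\code{"spool"} or \code{"potential"}) plus the constructor arguments
#'   of [spool_spec()] / [potential_spec()].
#' @param abmd Named list: \code{range} (c(lo, hi), A), \code{walls}
#'   (c(lo, hi), A), \code{k_wall}, \code{tau} (ps), \code{dd} (A),
#'   \code{n_walkers}, \code{duration} (ps per walker), \code{dt} (ps),
#'   \code{record_interval} (steps), \code{snapshot_every} (ps).
#' @param umbrella Named list: \code{lo}, \code{hi}, \code{spacing} (A),
#'   \code{k} (kcal/mol/A^2), \code{duration} (ps), \code{dt},
#'   \code{record_interval}, \code{discard} (keep range c(lo, hi), A),
#'   \code{frame_interval} (records between stored frames).
#' @param wham Named list: \code{temperature} (K), \code{tol},
#'   \code{max_iter}, \code{bin_width} (A).
#' @param metrics Named list: \code{unwrap_threshold} (A),
#'   \code{contact_cutoff} (A).
#' @param gamma Friction, 1/ps.
#' @param temperature Temperature, K.
#' @param seed Master seed (integer); phase seeds are fixed offsets of it.
#' @param shorten_arms Beads dropped per arm from the incoming state before
#'   this stage runs (the toy analog of deleting bps from each DNA end
#'   between stages); 0 for the first stage.
#' @return An object of class \code{stage_config}.
#' @export
stage_config <- function(stage_id = "stage1",
                         system = list(type = "spool"),
                         abmd = list(), umbrella = list(), wham = list(),
                         metrics = list(), gamma = 2, temperature = 300,
                         seed = 1L, shorten_arms = 0L) {
  abmd <- utils::modifyList(list(range = c(10, 90), walls = NULL,
                                 k_wall = 10.0, tau = 100, dd = 1.0,
                                 n_walkers = 100L, duration = 15000,
                                 dt = 0.02, record_interval = 50L,
                                 snapshot_every = 1000), abmd)
  if (is.null(abmd$walls)) abmd$walls <- abmd$range
  umbrella <- utils::modifyList(list(lo = 40, hi = 180, spacing = 2.0,
                                     k = 0.2, duration = 15000, dt = 0.02,
                                     record_interval = 10L, discard = NULL,
                                     frame_interval = 50L, burn_in = 0,
                                     replicates = 1L), umbrella)
  if (is.null(umbrella$discard)) umbrella$discard <- c(umbrella$lo, umbrella$hi)
  wham <- utils::modifyList(list(temperature = temperature, tol = 1e-8,
                                 max_iter = 100000L, bin_width = 1.0), wham)
  metrics <- utils::modifyList(list(unwrap_threshold = 4.0,
                                    contact_cutoff = 4.0), metrics)
  # store all numerics as doubles so JSON round-trips are exact
  norm <- function(l) rapply(l, function(z) {
    if (is.numeric(z)) as.numeric(z) else z
  }, how = "replace")
  structure(list(stage_id = as.character(stage_id), system = norm(system),
                 abmd = norm(abmd), umbrella = norm(umbrella),
                 wham = norm(wham), metrics = norm(metrics),
                 gamma = as.numeric(gamma),
                 temperature = as.numeric(temperature),
                 seed = as.integer(seed),
                 shorten_arms = as.integer(shorten_arms)),
            class = "stage_config")
}

#' Serialize / parse stage configurations (JSON)
#'
#' @param config A [stage_config()].
#' @param path Optional file path; when NULL the JSON string is returned.
#' @return [config_to_json()]: the JSON string (or path, invisibly);
#'   [config_from_json()]: the parsed [stage_config()], identical to the
#'   one serialized.
#' @export
config_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "stage_config"))
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @param json JSON string or path to a JSON file.
#' @rdname config_to_json
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  do.call(stage_config, x)
}

#' Aggregate sampling budget of a stage configuration
#'
#' Accounts the adaptive-bias sampling budget (walkers x per-walker
#' duration) and the umbrella budget (windows x duration) from the
#' configuration alone; the canonical full-scale protocol (100 walkers x
#' 15 ns) gives 1.5 us of flooding per stage.
#'
#' @param config A [stage_config()].
#' @return A list with \code{n_walkers}, \code{abmd_per_walker_ps},
#'   \code{abmd_total_ps}, \code{n_windows}, \code{umbrella_total_ps}.
#' @export
abmd_budget <- function(config) {
  stopifnot(inherits(config, "stage_config"))
  nwin <- build_window_grid(config$umbrella$lo, config$umbrella$hi,
                            config$umbrella$spacing)$n_windows
  list(n_walkers = config$abmd$n_walkers,
       abmd_per_walker_ps = config$abmd$duration,
       abmd_total_ps = config$abmd$n_walkers * config$abmd$duration,
       n_windows = nwin,
       umbrella_total_ps = nwin * config$umbrella$duration)
}

.build_system <- function(config) {
  args <- config$system
  type <- args$type
  args$type <- NULL
  if (identical(type, "spool")) {
    spec <- do.call(spool_spec, args)
    list(system = spool_system(spec), spec = spec, is_spool = TRUE)
  } else {
    spec <- do.call(potential_spec, args)
    list(system = potential_system(spec), spec = spec, is_spool = FALSE)
  }
}

# File inventory with checksums for the run manifest.
.inventory <- function(paths) {
  paths <- paths[file.exists(paths)]
  data.frame(file = basename(paths), md5 = unname(tools::md5sum(paths)),
             bytes = file.size(paths))
}

#' Run one full protocol stage
#'
#' Executes the chain flooding -> walker-sorted window seeding -> umbrella
#' refinement (with out-of-range discards) -> WHAM -> reweighting onto the
#' unwrapped-count coordinate and the 2-D landscape -> asymmetry/contact
#' metrics.  Each phase's outputs are persisted (CSV + JSON) as soon as it
#' completes when \code{out_dir} is given, and the expensive sampling
#' phases are reloaded from those files on \code{resume = TRUE}.
#'
#' @param config A [stage_config()].
#' @param out_dir Output directory (created if needed), or NULL to keep
#'   everything in memory.
#' @param init Optional initial walker coordinates (\code{n_dof x
#'   n_walkers}), e.g. the previous stage's end state after arm
#'   shortening.
#' @param resume Reload persisted flooding/umbrella outputs if present.
#' @return A list with elements \code{abmd}, \code{seeds}, \code{windows},
#'   \code{wham}, \code{profile_d}, \code{profile_r2}, \code{profile_2d},
#'   \code{asymmetry}, \code{contacts} (spool systems only),
#'   \code{delta_F} (stage free-energy change along the unwrapped count),
#'   \code{budget} and \code{manifest}.
#' @export
run_stage <- function(config, out_dir = NULL, init = NULL, resume = FALSE) {
  stopifnot(inherits(config, "stage_config"))
  sysdef <- .build_system(config)
  system <- sysdef$system
  if (!is.null(init) && nrow(init) != system$n_dof) {
    stop("init has ", nrow(init), " degrees of freedom but the configured ",
         "system has ", system$n_dof,
         " (does the system spec match the shortened arms?)")
  }
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  t0 <- Sys.time()
  timings <- list()
  files <- character(0L)

  # -- phase 1: multi-walker flooding -----------------------------------
  phase_t <- Sys.time()
  ab_files <- c(pth("abmd_traces.csv"), pth("abmd_bias.csv"))
  if (resume && persist && all(file.exists(ab_files))) {
    abmd <- list(traces = utils::read.csv(ab_files[1]),
                 bias = read_bias_csv(ab_files[2]),
                 final = NULL, snapshots = NULL)
    final_d <- utils::read.csv(pth("abmd_final.csv"))
    abmd$final <- as.matrix(final_d[, -1L, drop = FALSE])
    dimnames(abmd$final) <- NULL
  } else {
    a <- config$abmd
    abmd <- run_multiwalker(system, flooding_schedule(tau = a$tau),
                            range = a$range, walls = a$walls,
                            k_wall = a$k_wall, n_walkers = a$n_walkers,
                            total_time = a$duration, dt = a$dt, dd = a$dd,
                            gamma = config$gamma,
                            temperature = config$temperature,
                            record_interval = a$record_interval,
                            snapshot_every = a$snapshot_every,
                            seed = config$seed + 101L, init = init)
    if (persist) {
      write_trace_csv(abmd$traces, ab_files[1],
                      meta = list(stage = config$stage_id,
                                  seed = config$seed, phase = "abmd",
                                  config = unclass(config)))
      write_bias_csv(abmd$bias, ab_files[2],
                     meta = list(tau = a$tau, n_walkers = a$n_walkers,
                                 seed = config$seed))
      utils::write.csv(data.frame(dof = seq_len(nrow(abmd$final)),
                                  abmd$final),
                       pth("abmd_final.csv"), row.names = FALSE)
    }
  }
  files <- c(files, ab_files, pth("abmd_final.csv"))
  timings$abmd <- as.numeric(Sys.time() - phase_t, units = "secs")

  # -- phase 2: seed selection ------------------------------------------
  grid <- build_window_grid(config$umbrella$lo, config$umbrella$hi,
                            config$umbrella$spacing)
  final_d <- system$rc(abmd$final)$d
  seeds <- select_seeds(final_d, grid)
  # independent replicate runs per window, seeded from the next-nearest
  # walkers, pooled in WHAM: diversifies window starting branches
  reps <- max(1L, as.integer(config$umbrella$replicates))
  if (reps > 1L) {
    seed_rank <- lapply(grid$centers, function(ctr) {
      order(abs(final_d - ctr))
    })
    seeds <- unlist(lapply(seq_len(reps), function(k) {
      vapply(seed_rank, function(o) o[min(k, length(o))], integer(1L))
    }))
    grid <- structure(list(lo = grid$lo, spacing = grid$spacing,
                           n_windows = grid$n_windows * reps,
                           centers = rep(grid$centers, reps)),
                      class = "window_grid")
  }

  # -- phase 3: umbrella sampling ---------------------------------------
  phase_t <- Sys.time()
  win_file <- pth("umbrella_windows.csv")
  u <- config$umbrella
  if (resume && persist && file.exists(win_file)) {
    windows <- read_windows_csv(win_file)
    frames_info <- NULL
  } else {
    windows <- run_windows(system, grid, k = u$k,
                           frozen_bias = abmd$bias, duration = u$duration,
                           dt = u$dt, record_interval = u$record_interval,
                           gamma = config$gamma,
                           temperature = config$temperature,
                           seed = config$seed + 202L,
                           inits = abmd$final[, seeds, drop = FALSE],
                           burn_in = u$burn_in,
                           frame_interval = u$frame_interval)
    frames_info <- list(frames = attr(windows, "frames"),
                        d = attr(windows, "frame_d"),
                        aux = attr(windows, "frame_aux"))
    windows <- filter_discard_regions(windows, u$discard)
    keep <- vapply(windows, nrow, integer(1L)) > 0L
    if (!all(keep)) {
      message(sum(!keep), " window(s) empty after the discard filter; dropped")
      fb <- attr(windows, "frozen_bias")
      windows <- windows[keep]
      attr(windows, "frozen_bias") <- fb
    }
    if (persist) write_windows_csv(windows, win_file)
  }
  files <- c(files, win_file)
  timings$umbrella <- as.numeric(Sys.time() - phase_t, units = "secs")

  # -- phase 4: WHAM -----------------------------------------------------
  phase_t <- Sys.time()
  biases <- lapply(windows, function(w) {
    umbrella_window(attr(w, "center"), k = attr(w, "k"), bias = abmd$bias,
                    seed_id = seeds[attr(w, "window_id")])
  })
  wh <- solve_wham(windows, biases, temperature = config$wham$temperature,
                   tol = config$wham$tol, max_iter = config$wham$max_iter,
                   grid = histogram_grid(u$discard[1], u$discard[2],
                                         config$wham$bin_width))
  profile_d <- free_energy_1d(wh)
  if (persist) {
    write_profile_csv(profile_d, pth("profile_d.csv"))
    utils::write.csv(data.frame(window_id = seq_along(wh$F), F_j = wh$F,
                                n_i = wh$n_samples),
                     pth("wham_windows.csv"), row.names = FALSE)
    jsonlite::write_json(list(iterations = wh$iterations,
                              residual = wh$residual,
                              tol = config$wham$tol),
                         pth("wham_convergence.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  files <- c(files, pth("profile_d.csv"), pth("wham_windows.csv"),
             pth("wham_convergence.json"))
  timings$wham <- as.numeric(Sys.time() - phase_t, units = "secs")

  # -- phase 5: reweighting ---------------------------------------------
  phase_t <- Sys.time()
  w <- sample_weights(wh, windows)
  all_s <- do.call(rbind, lapply(windows, function(x) {
    x[, c("d_A", "unwrapped_end1", "unwrapped_end2")]
  }))
  r2 <- all_s$unwrapped_end1 + all_s$unwrapped_end2
  profile_r2 <- pmf_along(r2, w, temperature = config$temperature,
                          levels = seq(0L, max(r2)))
  profile_r2$coord <- "unwrapped_total"
  d_bin <- wh$grid$centers[.bin_index(wh$grid, all_s$d_A)]
  profile_2d <- fes_2d(d_bin, r2, w, temperature = config$temperature)
  if (persist) {
    write_profile_csv(profile_r2, pth("profile_r2.csv"))
    write_profile_csv(profile_2d, pth("profile_2d.csv"))
  }
  files <- c(files, pth("profile_r2.csv"), pth("profile_2d.csv"))
  timings$reweight <- as.numeric(Sys.time() - phase_t, units = "secs")

  # -- phase 6: structural metrics --------------------------------------
  phase_t <- Sys.time()
  asym <- asymmetry_distribution(
    cbind(all_s$unwrapped_end1, all_s$unwrapped_end2), weights = w)
  contacts <- NULL
  if (sysdef$is_spool && !is.null(frames_info) &&
      length(frames_info$frames)) {
    contacts <- .spool_contacts(frames_info, sysdef$spec, wh,
                                cutoff = config$metrics$contact_cutoff)
  }
  if (persist) {
    utils::write.csv(asym, pth("asymmetry.csv"), row.names = FALSE)
    if (!is.null(contacts)) {
      utils::write.csv(contacts, pth("contacts.csv"), row.names = FALSE)
    }
  }
  files <- c(files, pth("asymmetry.csv"), pth("contacts.csv"))
  timings$metrics <- as.numeric(Sys.time() - phase_t, units = "secs")

  # stage free-energy change along the unwrapped count
  sup <- which(!is.na(profile_r2$F))
  delta_F <- profile_r2$F[sup[length(sup)]] - profile_r2$F[sup[1L]]

  manifest <- list(stage = config$stage_id,
                   config_hash = .config_hash(config),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config$seed,
                   budget = abmd_budget(config),
                   timings = timings,
                   total_seconds = as.numeric(Sys.time() - t0, units = "secs"),
                   files = if (persist) .inventory(files) else NULL)
  if (persist) {
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
  }
  list(abmd = abmd, seeds = seeds, windows = windows, wham = wh,
       profile_d = profile_d, profile_r2 = profile_r2,
       profile_2d = profile_2d, asymmetry = asym, contacts = contacts,
       delta_F = delta_F, budget = abmd_budget(config), manifest = manifest,
       system = system, spec = sysdef$spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(config_to_json(config), tmp)
  unname(tools::md5sum(tmp))
}

# Contact table of the mimic's site beads against the core anchor points,
# stratified by the frame's total unwrapped count and weighted by the WHAM
# unbiased weights of the frames' coordinate bins.
.spool_contacts <- function(frames_info, spec, wham_solution, cutoff = 4.0) {
  ref <- spool_reference(spec)
  core <- rbind(ref$arm1[spec$sites, , drop = FALSE],
                ref$arm2[spec$sites, , drop = FALSE])
  rownames(core) <- c(paste0("core_a1_s", spec$sites),
                      paste0("core_a2_s", spec$sites))
  frames <- list(); wts <- numeric(0L); strat <- integer(0L)
  grid <- wham_solution$grid
  for (i in seq_along(frames_info$frames)) {
    X <- frames_info$frames[[i]]
    for (wcol in seq_len(ncol(X))) {
      dval <- frames_info$d[i, wcol]
      if (dval < grid$lo || dval > grid$hi) next
      fr <- rbind(spool_frame(X[, wcol], spec), core)
      frames[[length(frames) + 1L]] <- fr
      wts <- c(wts, exp(-wham_solution$log_denom[.bin_index(grid, dval)]))
      strat <- c(strat,
                 as.integer(sum(frames_info$aux[i, , wcol])))
    }
  }
  if (!length(frames)) return(NULL)
  beads <- c(paste0("a1_b", spec$sites), paste0("a2_b", spec$sites))
  groups_A <- as.list(beads)
  names(groups_A) <- beads
  contact_ratio(frames, groups_A, rownames(core), cutoff = cutoff,
                weights = wts / sum(wts), stratify_by = strat)
}

#' Run the staged protocol and stitch the stages
#'
#' Runs the configured stages in order; after each stage the walker end
#' states are carried into the next stage, with the configured number of
#' outermost beads removed per arm first (arm shortening between stages).
#' The per-stage free-energy changes along the unwrapped-count coordinate
#' are stitched into the total.
#'
#' @param configs List of [stage_config()]s in protocol order.
#' @param out_dir Output directory (one subdirectory per stage), or NULL.
#' @param resume Passed to [run_stage()].
#' @return A list with \code{stages} (per-stage results), \code{stitched}
#'   (from [stitch_stage_profiles()]), and \code{report} (summary list,
#'   also written as \code{report.json} when persisting).
#' @export
run_full <- function(configs, out_dir = NULL, resume = FALSE) {
  stopifnot(length(configs) >= 1L)
  stages <- list()
  init <- NULL
  prev_spec <- NULL
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    if (i > 1L && cfg$shorten_arms > 0L) {
      stopifnot(!is.null(prev_spec))
      init <- spool_drop_beads(init, prev_spec, cfg$shorten_arms)
      # walker count must match: recycle columns if needed
      nw <- cfg$abmd$n_walkers
      init <- init[, rep_len(seq_len(ncol(init)), nw), drop = FALSE]
    }
    res <- run_stage(cfg,
                     out_dir = if (is.null(out_dir)) NULL else
                       file.path(out_dir, cfg$stage_id),
                     init = init, resume = resume)
    stages[[cfg$stage_id]] <- res
    init <- res$abmd$final
    prev_spec <- res$spec
  }
  deltas <- vapply(stages, function(s) s$delta_F, numeric(1L))
  stitched <- stitch_stage_profiles(deltas, names(stages))
  report <- list(stages = names(stages),
                 delta_F_kcal_mol = as.list(deltas),
                 total_delta_F_kcal_mol = stitched$total,
                 budgets = lapply(stages, function(s) s$budget))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(stages = stages, stitched = stitched, report = report)
}
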