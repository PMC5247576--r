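#' Run a reproducible analysis pipeline from a configuration
#'
#' Executes a sequence of named stages described by a configuration list (or
#' a YAML file), validating every stage's parameters against the type
#' invariants before any computation starts, and writes a JSON manifest
#' recording parameters, the seed, package version and MD5 checksums of
#' every output, so identical config + seed gives identical checksums.
#'
#' Each stage draws its own deterministic seed from the global seed and the
#' stage name, so stages can be re-run independently.
#'
#' Supported stages and their parameter blocks:
#' \describe{
#'   \item{gen-current}{`schedule` (list of potential/duration), electro
#'     params, `noise_sd`; writes `trace` and `truth`}
#'   \item{gen-expression}{`s_rates`, `s_durations`, `k_deg`, noise, writes
#'     `trace` and `truth`}
#'   \item{gen-video}{motility scenario; writes `video` (TIFF + sidecar),
#'     `truth` and `speeds` CSVs}
#'   \item{gen-events}{`n_events`, `populations`; writes `events`, `labels`}
#'   \item{simulate-circuit}{`schedule`, circuit params; writes equal-length
#'     `fluorescence`, `current` and `frac_ox` CSVs}
#'   \item{deconvolve}{input `trace`, `k_deg`; writes cumulative `synthesis`}
#'   \item{cycle-sweep}{`cycle_times`; writes the half/end-cycle table}
#'   \item{track}{input `video`; writes `trajectories` and `speeds`}
#'   \item{velocity-stats}{inputs `speeds` (named paths); writes `summary`
#'     and `comparisons`}
#'   \item{rose}{input `trajectories`; writes origin-translated `rose` paths}
#'   \item{gate}{input `events`, `fsc_bounds`, `ssc_bounds`; writes `gated`}
#'   \item{cyto-summary}{input `events`; writes a JSON `summary`}
#' }
#'
#' @param config a list, or path to a YAML file, with elements `seed`
#'   (integer), `out_dir`, and `stages` (list of `list(stage =, params =,
#'   inputs =, outputs =)`); output paths are relative to `out_dir`
#' @return invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg_err <- function(path, msg) stop_invalid("config error at %s: %s", path, msg)
  if (is.null(config$out_dir)) cfg_err("out_dir", "missing")
  if (is.null(config$seed)) cfg_err("seed", "missing")
  if (!is.list(config$stages) || !length(config$stages))
    cfg_err("stages", "must be a non-empty list")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  known <- c("gen-current", "gen-expression", "gen-video", "gen-events",
             "simulate-circuit", "deconvolve", "cycle-sweep", "track",
             "velocity-stats", "rose", "gate", "cyto-summary")
  # -- validation pass: reject bad stages/params before computing anything
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    where <- sprintf("stages[%d]", i)
    if (is.null(st$stage) || !st$stage %in% known)
      cfg_err(paste0(where, ".stage"),
              sprintf("unknown stage '%s'", st$stage %||% "<missing>"))
    .validate_stage(st, where, cfg_err)
  }

  manifest <- list(package = "electrogenetics",
                   version = as.character(utils::packageVersion("electrogenetics")),
                   seed = config$seed, stages = list())
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    st_seed <- derive_seed(config$seed, paste0(st$stage, i))
    outs <- .run_stage(st, config$out_dir, st_seed)
    manifest$stages[[i]] <- list(
      stage = st$stage, params = st$params, inputs = st$inputs,
      seed = st_seed,
      outputs = lapply(outs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))))
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.schedule_from_params <- function(p) {
  if (is.character(p$schedule)) return(read_signal_schedule(p$schedule))
  segs <- p$schedule
  signal_schedule(
    vapply(segs, function(s)
      if (is.null(s$potential_V)) NA_real_ else as.numeric(s$potential_V),
      numeric(1)),
    vapply(segs, function(s) as.numeric(s$duration_s), numeric(1)))
}

.circuit_from_params <- function(p) {
  args <- p[intersect(names(p), c("s0", "s_max", "K_fcn", "pyo", "K_pyo",
                                  "k_deg", "maturation_lag"))]
  do.call(circuit_params, args)
}

.validate_stage <- function(st, where, cfg_err) {
  p <- st$params %||% list()
  tryCatch({
    switch(st$stage,
      "gen-current" = , "simulate-circuit" = {
        .schedule_from_params(p)
        if (st$stage == "simulate-circuit") .circuit_from_params(p)
      },
      "gen-expression" = {
        if (any(unlist(p[c("s_rates")]) < 0)) stop("negative synthesis rate")
        if (any(unlist(p[c("s_durations")]) <= 0)) stop("nonpositive duration")
        if ((p$k_deg %||% 0) < 0) stop("negative k_deg")
      },
      "gen-video" = {
        if ((p$stuck_fraction %||% 0) < 0 || (p$stuck_fraction %||% 0) > 1)
          stop("stuck_fraction outside [0, 1]")
        if ((p$tumble_rate %||% 0) < 0) stop("negative tumble_rate")
      },
      "gen-events" = {
        if (!is.null(p$populations)) {
          fr <- vapply(p$populations, function(q) as.numeric(q$fraction),
                       numeric(1))
          if (abs(sum(fr) - 1) > 1e-8) stop("population fractions must sum to 1")
        }
      },
      "deconvolve" = if ((p$k_deg %||% 0) < 0) stop("negative k_deg"),
      "cycle-sweep" = if (any(unlist(p$cycle_times) <= 0))
        stop("cycle times must be > 0"),
      "gate" = {
        b <- c(p$fsc_bounds, p$ssc_bounds)
        if (length(b) != 4 || p$fsc_bounds[1] >= p$fsc_bounds[2] ||
            p$ssc_bounds[1] >= p$ssc_bounds[2])
          stop("gate bounds must be ordered (lo, hi) pairs")
      },
      invisible(NULL))
    # input files are not checked here: they may be produced by an earlier
    # stage of this same run
  }, error = function(e) cfg_err(paste0(where, ".params"), conditionMessage(e)))
  invisible(TRUE)
}

.run_stage <- function(st, out_dir, st_seed) {
  p <- st$params %||% list()
  o <- lapply(st$outputs, function(f) file.path(out_dir, f))
  inp <- rapply(st$inputs %||% list(), how = "replace", function(f)
    if (file.exists(f)) f else file.path(out_dir, f))
  switch(st$stage,
    "gen-current" = {
      g <- gen_current_trace(.schedule_from_params(p),
                             k_e = p$k_e %||% (log(100) / 900),
                             noise_sd = p$noise_sd %||% 0, seed = st_seed)
      write_current_trace(g$trace, o$trace)
      jsonlite::write_json(list(true_charge_C = g$true_charge), o$truth,
                           auto_unbox = TRUE, digits = NA)
    },
    "gen-expression" = {
      g <- gen_expression_trace(unlist(p$s_rates), unlist(p$s_durations),
                                p$k_deg %||% (log(2) / 1500),
                                noise_cv = p$noise_cv %||% 0,
                                sampling_interval = p$sampling_interval %||% 60,
                                seed = st_seed)
      write_expression_trace(g$trace, o$trace)
      .write_csv(g$truth, o$truth)
    },
    "gen-video" = {
      g <- do.call(gen_motility_video,
                   c(p[intersect(names(p),
                                 names(formals(gen_motility_video)))],
                     list(seed = st_seed)))
      write_video_stack(g$video, o$video)
      .write_csv(g$truth, o$truth)
      .write_csv(g$speeds, o$speeds)
    },
    "gen-events" = {
      args <- list(seed = st_seed)
      if (!is.null(p$n_events)) args$n_events <- p$n_events
      if (!is.null(p$populations)) args$populations <- p$populations
      g <- do.call(gen_cytometry_events, args)
      write_event_table(g$events, o$events)
      .write_csv(data.frame(label = g$labels), o$labels)
    },
    "simulate-circuit" = {
      sim <- simulate_expression(.schedule_from_params(p),
                                 .circuit_from_params(p),
                                 k_e = p$k_e %||% (log(100) / 900),
                                 dt = p$dt %||% 1)
      write_expression_trace(sim$trace, o$fluorescence)
      write_current_trace(sim$current, o$current)
      .write_csv(data.frame(time_s = sim$times, value = sim$frac_ox),
                 o$frac_ox)
    },
    "deconvolve" = {
      tr <- read_expression_trace(inp$trace)
      S <- integrated_synthesis(tr, p$k_deg %||% (log(2) / 1500))
      .write_csv(data.frame(time_s = tr$time_s, synthesis_au = S),
                 o$synthesis)
    },
    "cycle-sweep" = {
      res <- cycle_experiment(unlist(p$cycle_times),
                              .circuit_from_params(p),
                              dt = p$dt %||% 1)
      .write_csv(res, o$cycles)
    },
    "track" = {
      video <- read_video_stack(inp$video, fps = p$fps,
                                pixel_size = p$pixel_size)
      args <- p[intersect(names(p), c("gate_radius", "min_area", "max_gap",
                                      "min_length"))]
      res <- do.call(track_video, c(list(video), args))
      write_trajectories(res$trajectories, o$trajectories)
      .write_csv(res$speeds, o$speeds)
    },
    "velocity-stats" = {
      groups <- lapply(inp$speeds, function(f) {
        df <- .read_csv_strict(f, "mean_speed_um_s")
        df$mean_speed_um_s[!is.na(df$mean_speed_um_s)]
      })
      vs <- velocity_statistics(groups)
      .write_csv(vs$summary, o$summary)
      if (!is.null(vs$comparisons)) .write_csv(vs$comparisons, o$comparisons)
    },
    "rose" = {
      trajs <- read_trajectories(inp$trajectories)
      rose <- trajectory_rose(trajs, fps = p$fps, pixel_size = p$pixel_size,
                              duration = p$duration %||% 3)
      .write_csv(rose, o$rose)
    },
    "gate" = {
      ev <- read_event_table(inp$events)
      gated <- gate_events(ev, unlist(p$fsc_bounds), unlist(p$ssc_bounds))
      write_event_table(gated, o$gated)
    },
    "cyto-summary" = {
      ev <- read_event_table(inp$events)
      spl <- population_split(ev)
      jsonlite::write_json(
        c(list(n_events = nrow(ev), mean_green = mean_fluorescence(ev)),
          spl),
        o$summary, auto_unbox = TRUE, digits = NA)
    })
  o
}
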