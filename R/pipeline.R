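#' Build a pipeline configuration
#'
#' A single nested list drives an end-to-end run: either a `simulate` block
#' (a [scene_config()], whose ROI and polyps also provide the analysis ROIs)
#' or an `input_dir` with ROI file paths; plus per-stage parameter blocks.
#' Every analysis default is an explicit config key: correction method
#' `gray_world` refitted per frame, k = 3 clusters, recurrence threshold
#' `epsilon = 0.02`, green channel, 64 histogram bins, 2-minute cadence.
#'
#' @param simulate optional `scene_config`
#' @param input_dir optional directory with frames + manifest (used when no
#'   `simulate` block)
#' @param roi list with `colony` (ROI file path) and `polyps` (named list of
#'   ROI file paths); ignored when simulating
#' @param correction list: `method`, `per_frame`
#' @param colors list: `k`, `smooth_window` (odd, analyzed frames),
#'   `decimate`, `n_boundaries`
#' @param correlation list: `channel`, `bins`, `reference_index`
#' @param recurrence list: `epsilon`, `l_min`, `v_min`, `theiler`, `window`,
#'   `stride` (window/stride `NULL` = one day of frames / half window)
#' @param out_dir output directory
#' @param seed global seed; per-stage seeds are derived from it
#' @return class `pipeline_config`
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL, roi = NULL,
                            correction = list(), colors = list(),
                            correlation = list(), recurrence = list(),
                            out_dir = tempfile("coraldyn_run_"), seed = 1L) {
  defaults <- list(
    correction = list(method = "gray_world", per_frame = TRUE),
    colors = list(k = 3L, smooth_window = NULL, decimate = 30L,
                  n_boundaries = 4L),
    correlation = list(channel = "G", bins = 64L, reference_index = 1L),
    recurrence = list(epsilon = 0.02, l_min = 2L, v_min = 2L, theiler = 1L,
                      window = NULL, stride = NULL))
  merge1 <- function(d, u) { d[names(u)] <- u; d }
  cfg <- list(simulate = simulate, input_dir = input_dir, roi = roi,
              correction = merge1(defaults$correction, correction),
              colors = merge1(defaults$colors, colors),
              correlation = merge1(defaults$correlation, correlation),
              recurrence = merge1(defaults$recurrence, recurrence),
              out_dir = out_dir, seed = as.integer(seed))
  if (is.null(cfg$simulate) && is.null(cfg$input_dir))
    .fail_field("simulate/input_dir", "need one of the two")
  if (!is.null(cfg$simulate)) stopifnot(inherits(cfg$simulate, "scene_config"))
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$roi$colony) || !file.exists(cfg$roi$colony))
      .fail_field("roi$colony", "ROI file missing or unreadable")
    for (p in cfg$roi$polyps) if (!file.exists(p))
      .fail_field("roi$polyps", paste("ROI file missing:", p))
  }
  structure(cfg, class = "pipeline_config")
}

# deterministic per-stage seed from global seed + stage name (kept < 2^31)
.stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((seed * 1009 + h) %% .Machine$integer.max)
}

.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(.config_payload(cfg), auto_unbox = TRUE, digits = 12)
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 131 + ch) %% 2147483629
  sprintf("%08x", as.integer(h))
}

# plain-list view of a config for hashing / embedding in the report
.config_payload <- function(cfg) {
  sim <- cfg$simulate
  if (!is.null(sim)) {
    sim <- list(width = sim$width, height = sim$height,
                n_frames = sim$n_frames,
                minutes_per_frame = sim$minutes_per_frame,
                base_colors = sim$base_colors,
                boundaries = sim$schedule$boundaries,
                shade_fractions = sim$schedule$shade_fractions,
                transition_width = sim$schedule$transition_width,
                blue_cast_gain = sim$blue_cast_gain,
                brightness_drift = sim$brightness_drift,
                noise_sd = sim$noise_sd,
                polyps = lapply(sim$polyps, function(p)
                  p[c("center", "radius", "oscillation_period",
                      "oscillation_amplitude", "change_day",
                      "post_change_drift")]),
                seed = sim$seed)
  }
  list(simulate = sim, input_dir = cfg$input_dir,
       roi = cfg$roi, correction = cfg$correction, colors = cfg$colors,
       correlation = cfg$correlation, recurrence = cfg$recurrence,
       seed = cfg$seed)
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: simulate (or load) the series; white-balance
#' correction; dominant-color analysis (extraction, smoothing, stage
#' boundaries, ternary trajectory); per-polyp correlation series and
#' change-point detection; per-polyp segmented RQA. All tabular outputs are
#' written under `config$out_dir` and summarized in a self-contained JSON
#' report. A rerun with an identical config and seed reproduces the report
#' payload byte-for-byte (timestamps excluded); if a report with the same
#' config hash already exists it is reused unless `resume = FALSE`.
#'
#' @param config a `pipeline_config`
#' @param resume reuse an existing report with a matching config hash
#' @param verbose log stage progress to stderr
#' @return class `run_report` (also written to `out_dir/report.json`)
#' @export
run_pipeline <- function(config, resume = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  report_path <- file.path(out, "report.json")
  if (resume && file.exists(report_path)) {
    old <- jsonlite::read_json(report_path, simplifyVector = TRUE)
    if (identical(old$config_hash, hash)) {
      if (verbose) message("[pipeline] reusing existing report ", report_path)
      return(structure(old, class = "run_report"))
    }
  }
  log <- function(stage, ...) if (verbose)
    message(sprintf("[%s] %s", stage, paste0(...)))

  # --- acquire series -----------------------------------------------------
  if (!is.null(config$simulate)) {
    log("simulate", "generating ", config$simulate$n_frames, " frames")
    gen <- generate_series(config$simulate)
    series <- gen$series
    gt <- gen$ground_truth
    # compositional analysis runs on the colony minus the polyp crops, which
    # are analyzed separately by the correlation stage
    colony_mask <- gt$color_mask
    if (!any(colony_mask)) {
      warning("polyp boxes cover the whole colony ROI; ",
              "color analysis falls back to the full ROI", call. = FALSE)
      colony_mask <- gt$roi_mask
    }
    # polyp crop inscribed in the disk at its smallest extent: the crop is
    # all tissue, so r tracks morphology rather than static surroundings
    polyp_rois <- lapply(config$simulate$polyps, function(p) {
      half <- max(3, floor(p$radius * 0.45))
      roi_rect(paste0("polyp_", p$center[1], "_", p$center[2]),
               max(0, p$center[1] - half), max(0, p$center[2] - half),
               min(config$simulate$height, p$center[1] + half),
               min(config$simulate$width, p$center[2] + half))
    })
    if (length(polyp_rois))
      names(polyp_rois) <- paste0("polyp_", seq_along(polyp_rois))
    write_ground_truth(gt, file.path(out, "ground_truth.json"))
  } else {
    log("load", "reading series from ", config$input_dir)
    series <- load_series(config$input_dir)
    colony_mask <- rasterize_roi(read_roi(config$roi$colony),
                                 dim(series$pixels[[1]])[1:2])
    polyp_rois <- lapply(config$roi$polyps, read_roi)
  }
  shape <- dim(series$pixels[[1]])[1:2]
  frames_per_day <- 1440 / series$minutes_per_frame

  # --- correction ---------------------------------------------------------
  log("correct", config$correction$method,
      if (isTRUE(config$correction$per_frame)) " (per frame)" else " (first frame)")
  series <- correct_series(series, method = config$correction$method,
                           per_frame = isTRUE(config$correction$per_frame))

  # --- color analysis -----------------------------------------------------
  log("colors", "k-means, decimate ", config$colors$decimate)
  dcs <- dominant_color_series(series, colony_mask, k = config$colors$k,
                               seed = .stage_seed(config$seed, "colors"),
                               decimate = config$colors$decimate)
  win <- config$colors$smooth_window
  if (is.null(win)) {
    # default: ~24 h of analyzed frames, forced odd, capped by series length
    per_day <- max(1, round(frames_per_day / config$colors$decimate))
    win <- min(per_day + (per_day + 1) %% 2, length(dcs$days) -
                 (1 - length(dcs$days) %% 2))
    win <- max(1L, win)
  }
  smoothed <- smooth_percentages(dcs, win)
  seg <- detect_stage_boundaries(smoothed, n_boundaries = config$colors$n_boundaries)
  tern <- ternary_trajectory(smoothed, seg)
  utils::write.csv(
    data.frame(day = smoothed$days,
               dark_pct = smoothed$percentages[, 1],
               medium_pct = smoothed$percentages[, 2],
               light_pct = smoothed$percentages[, 3],
               dark_rgb = apply(round(dcs$colors[, 1, , drop = FALSE]), 1,
                                paste, collapse = ";"),
               medium_rgb = apply(round(dcs$colors[, 2, , drop = FALSE]), 1,
                                  paste, collapse = ";"),
               light_rgb = apply(round(dcs$colors[, 3, , drop = FALSE]), 1,
                                 paste, collapse = ";")),
    file.path(out, "dominant_colors.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(boundaries_days = seg$boundaries,
                            stages = seg$stages,
                            improvement = seg$improvement,
                            no_strong_inflections = seg$no_strong_inflections,
                            convergence_center = tern$convergence_center,
                            smoothing = smoothed$smoothing),
                       file.path(out, "stages.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  # --- per-polyp correlation + change point + RQA -------------------------
  rq_win <- config$recurrence$window
  if (is.null(rq_win)) rq_win <- max(4L, as.integer(round(frames_per_day)))
  polyp_results <- list()
  for (nm in names(polyp_rois)) {
    log("correlate", nm)
    cs <- correlation_series(series, polyp_rois[[nm]],
                             reference_index = config$correlation$reference_index,
                             channel = config$correlation$channel,
                             roi_name = nm)
    utils::write.csv(data.frame(day = cs$days, r = cs$r),
                     file.path(out, paste0("correlation_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    cp <- detect_change_point(cs)
    srq <- segmented_rqa(cs, cp, window = min(rq_win, max(4L, cp$index - 1L),
                                              max(4L, length(cs$r) - cp$index)),
                         epsilon = config$recurrence$epsilon,
                         l_min = config$recurrence$l_min,
                         v_min = config$recurrence$v_min,
                         theiler = config$recurrence$theiler)
    polyp_results[[nm]] <- list(
      change_day = cp$day, change_magnitude = cp$magnitude,
      no_change = cp$no_change,
      before = list(mean = as.list(srq$before$mean), sd = as.list(srq$before$sd),
                    n_windows = srq$before$n_windows),
      after = list(mean = as.list(srq$after$mean), sd = as.list(srq$after$sd),
                   n_windows = srq$after$n_windows))
    jsonlite::write_json(polyp_results[[nm]],
                         file.path(out, paste0("rqa_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }

  report <- list(
    package = "coraldyn",
    version = as.character(utils::packageVersion("coraldyn")),
    config_hash = hash,
    config = .config_payload(config),
    n_frames = length(series),
    frame_shape = shape,
    stage_boundaries_days = seg$boundaries,
    convergence_center = tern$convergence_center,
    polyps = polyp_results,
    outputs = list(dominant_colors = "dominant_colors.csv",
                   stages = "stages.json",
                   report = "report.json"))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  structure(report, class = "run_report")
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `correct`, `colors`, `correlate`, `rqa`, `run`.
#' Typical usage from a shell (via the installed `coral-dyn` script or
#' `Rscript -e 'coraldyn::coraldyn_main()'`):
#' ```
#' coral-dyn run --config config.json --out results --seed 1
#' coral-dyn simulate --config scene.json --out frames --seed 1
#' coral-dyn rqa --series correlation_polyp_1.csv --epsilon 0.02 --out rqa.json
#' ```
#' Configs are JSON. Errors exit nonzero with the failing stage named.
#'
#' @param args character vector of CLI arguments (default: command line)
#' @return exit status, invisibly (0 on success)
#' @export
coraldyn_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: coral-dyn <simulate|correct|colors|correlate|rqa|run> [options]")
    cmd <- args[1]
    opt <- .parse_cli(args[-1])
    switch(cmd,
      run = .cli_run(opt),
      simulate = .cli_simulate(opt),
      correct = .cli_correct(opt),
      colors = .cli_colors(opt),
      correlate = .cli_correlate(opt),
      rqa = .cli_rqa(opt),
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("coral-dyn: error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_cli <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opt[[key]] <- TRUE
      i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opt
}

.opt_num <- function(opt, key, default = NULL) {
  if (is.null(opt[[key]])) default else as.numeric(opt[[key]])
}

# read a scene config from JSON
.scene_from_json <- function(path, seed = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sch <- if (!is.null(x$schedule))
    stage_schedule(x$schedule$boundaries,
                   matrix(unlist(x$schedule$shade_fractions), ncol = 3,
                          byrow = is.null(dim(x$schedule$shade_fractions))),
                   x$schedule$transition_width %||% 0)
  else stage_schedule(c(9, 46, 56, 70), default_shade_fractions(), 2)
  polyps <- lapply(x$polyps %||% list(), function(p)
    polyp_config(unlist(p$center), p$radius, p$oscillation_period,
                 p$oscillation_amplitude %||% 0.3,
                 p$change_day %||% Inf, p$post_change_drift %||% 3))
  scene_config(width = x$width, height = x$height, n_frames = x$n_frames,
               minutes_per_frame = x$minutes_per_frame %||% 2,
               base_colors = if (!is.null(x$base_colors))
                 matrix(unlist(x$base_colors), ncol = 3, byrow = TRUE)
                 else default_base_colors(),
               schedule = sch,
               blue_cast_gain = unlist(x$blue_cast_gain %||% c(0.85, 1, 1.35)),
               brightness_drift = x$brightness_drift %||% 0.1,
               noise_sd = x$noise_sd %||% 4,
               polyps = polyps,
               seed = seed %||% (x$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cli_simulate <- function(opt) {
  if (is.null(opt$config) || is.null(opt$out)) stop("simulate needs --config and --out")
  sc <- .scene_from_json(opt$config, seed = .opt_num(opt, "seed"))
  gen <- generate_series(sc)
  write_series(gen$series, opt$out)
  write_ground_truth(gen$ground_truth, file.path(opt$out, "ground_truth.json"))
  message("wrote ", length(gen$series), " frames to ", opt$out)
}

.cli_correct <- function(opt) {
  if (is.null(opt$`in`) || is.null(opt$out)) stop("correct needs --in and --out")
  s <- load_series(opt$`in`)
  gains <- if (!is.null(opt$gains)) as.numeric(strsplit(opt$gains, ",")[[1]])
  s2 <- correct_series(s, method = opt$method %||% "gray_world",
                       per_frame = is.null(opt$first_frame), gains = gains)
  write_series(s2, opt$out)
  message("corrected ", length(s2), " frames")
}

.cli_colors <- function(opt) {
  if (is.null(opt$`in`) || is.null(opt$roi)) stop("colors needs --in and --roi")
  s <- load_series(opt$`in`)
  dcs <- dominant_color_series(s, read_roi(opt$roi),
                               k = .opt_num(opt, "k", 3),
                               seed = .opt_num(opt, "seed", 1),
                               decimate = .opt_num(opt, "decimate", 1))
  win <- .opt_num(opt, "smooth_window", 1)
  sm <- smooth_percentages(dcs, win)
  out <- opt$out %||% "dominant_colors.csv"
  utils::write.csv(data.frame(day = sm$days, dark_pct = sm$percentages[, 1],
                              medium_pct = sm$percentages[, 2],
                              light_pct = sm$percentages[, 3]),
                   out, row.names = FALSE, quote = FALSE)
  message("wrote ", out)
}

.cli_correlate <- function(opt) {
  if (is.null(opt$`in`) || is.null(opt$roi)) stop("correlate needs --in and --roi")
  s <- load_series(opt$`in`)
  cs <- correlation_series(s, read_roi(opt$roi),
                           reference_index = .opt_num(opt, "ref_index", 1),
                           channel = opt$channel %||% "G")
  out <- opt$out %||% "correlation.csv"
  utils::write.csv(data.frame(day = cs$days, r = cs$r), out,
                   row.names = FALSE, quote = FALSE)
  message("wrote ", out)
}

.cli_rqa <- function(opt) {
  if (is.null(opt$series)) stop("rqa needs --series (CSV with day,r)")
  df <- utils::read.csv(opt$series)
  cs <- structure(list(r = df$r, days = df$day, reference_index = 1L,
                       roi_name = NULL, channel = "G",
                       normalization = "zscore_roi"),
                  class = "correlation_series")
  eps <- .opt_num(opt, "epsilon", 0.02)
  cp <- if (!is.null(opt$change_day)) {
    idx <- which.min(abs(df$day - as.numeric(opt$change_day)))
    structure(list(day = df$day[idx], index = idx, magnitude = NA,
                   window = NA, no_change = FALSE), class = "change_point")
  } else detect_change_point(cs)
  win <- .opt_num(opt, "window",
                  max(4, round(1 / stats::median(diff(df$day)))))
  res <- segmented_rqa(cs, cp, window = win, epsilon = eps,
                       l_min = .opt_num(opt, "lmin", 2),
                       v_min = .opt_num(opt, "vmin", 2),
                       theiler = .opt_num(opt, "theiler", 1))
  out <- opt$out %||% "rqa.json"
  jsonlite::write_json(list(change_day = cp$day,
                            before = list(mean = as.list(res$before$mean),
                                          sd = as.list(res$before$sd)),
                            after = list(mean = as.list(res$after$mean),
                                         sd = as.list(res$after$sd))),
                       out, auto_unbox = TRUE, digits = NA)
  message("wrote ", out)
}

.cli_run <- function(opt) {
  if (is.null(opt$config)) stop("run needs --config")
  x <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
  sim <- if (!is.null(x$simulate_config))
    .scene_from_json(x$simulate_config, seed = .opt_num(opt, "seed"))
  cfg <- pipeline_config(simulate = sim, input_dir = x$input_dir,
                         roi = x$roi,
                         correction = x$correction %||% list(),
                         colors = x$colors %||% list(),
                         correlation = x$correlation %||% list(),
                         recurrence = x$recurrence %||% list(),
                         out_dir = opt$out %||% (x$out_dir %||% "coraldyn_out"),
                         seed = .opt_num(opt, "seed", x$seed %||% 1))
  rep <- run_pipeline(cfg, verbose = isTRUE(opt$verbose))
  message("report: ", file.path(cfg$out_dir, "report.json"))
  invisible(rep)
}
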