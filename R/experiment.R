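#' Experiment configuration
#'
#' All tunables of the 2D AF mapping/ablation workflow with their reference
#' defaults: DF area threshold 9 Hz, ShEn/CFAE percentile areas 2.5%,
#' parameter-to-parameter overlap areas 10%, ablation fraction 5%, PS lesion
#' radius 1 mm, 6-s analysis windows, 600-ms pacing before cross-field
#' reentry initiation.  The full-scale grid is 600 x 600 at 250 um; the
#' default here is the package's scaled-down desk configuration (100 x 100
#' at 500 um, ~5 x 5 cm).
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    preset = "peaf",            # control | peaf
    nx = 100L, ny = 100L, dx_um = 500, Deff = 0.15,
    dt_ms = 0.05, sampling_ms = 1,
    pace_cl_ms = 600, pace_beats = 1L, pace_amp = -30,
    reset_time_ms = 240,        # cross-field reset; NA = auto trigger
    af_duration_ms = 6400,      # simulated time after the paced segment
    map_window_ms = 6000,
    egm_spacing_mm = 2,
    df_threshold_hz = 9, df_area_pct = 0.025,
    shen_area_pct = 0.025, cfae_area_pct = 0.025,
    table3_area_pct = 0.10,
    strategy = "none",          # none | ps | df | shen | cfae, "+"-combinable
    ablation_fraction = 0.05, ps_lesion_radius_mm = 1,
    post_duration_ms = 4000,
    fig4_df_hz = 7, fig4_shen = 7, fig4_cfae_ms = 100,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config fields: %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "experiment_config")
}

#' Write / read a configuration as plain text (key: value)
#' @param cfg `experiment_config`.
#' @param path file path.
#' @return `read_config` returns an `experiment_config`.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    sprintf("%s: %s", k, format(cfg[[k]], digits = 15)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":\\s*")
  vals <- lapply(kv, function(p) {
    v <- paste(p[-1], collapse = ": ")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  for (k in c("nx", "ny", "pace_beats", "seed"))
    if (!is.null(vals[[k]])) vals[[k]] <- as.integer(vals[[k]])
  do.call(experiment_config, vals)
}

#' Paced-strip wavelength measurement
#'
#' Measures conduction velocity and wavelength for a planar wave paced at
#' the reference cycle length on a long thin strip of the same tissue
#' (long enough to contain the excited band).
#'
#' @param params `ionic_params`.
#' @param dx_um,Deff grid properties.
#' @param pacing_cl cycle length (ms), default 600.
#' @param strip_mm strip length (mm).
#' @return list with `cv` (mm/ms) and `wavelength` (mm).
#' @export
measure_wavelength_paced <- function(params, dx_um = 500, Deff = 0.15,
                                     pacing_cl = 600, strip_mm = 180) {
  ny <- max(64L, round(strip_mm * 1000 / dx_um))
  grid <- tissue_grid(nx = 16, ny = ny, dx = dx_um, Deff = Deff)
  # two beats; measure on the second
  run <- simulate_tissue(grid, params,
                         stimulus_protocol("line-pace", cycle_length = pacing_cl,
                                           count = 2,
                                           pace_rows = max(2, round(1000 / dx_um))),
                         duration = 2 * pacing_cl + 200,
                         record_from = pacing_cl)
  m <- measure_cv_wavelength(run$movie, pacing_cl)
  list(cv = m$cv, wavelength = m$wavelength)
}

#' Run the 2D AF experiment
#'
#' End-to-end driver: paced planar wave, cross-field reentry initiation,
#' AF simulation, parameter mapping (DF/ShEn/CFAE), rotor tracking and
#' mother-rotor classification, overlap tables, and optionally one
#' virtual-ablation strategy with outcome classification.  With `out_dir`
#' set, writes a deterministic run directory (config, manifest, CSV tables).
#'
#' @param cfg `experiment_config`.
#' @param out_dir output directory (created); `NULL` returns results only.
#' @param keep_movie include the voltage movie in the returned object.
#' @param verbose print progress.
#' @return list of class `experiment_result` with elements `wavelength`,
#'   `trajectories`, `mother`, `maps`, `masks`, `overlaps` (Table-2-style),
#'   `pairwise` (Table-3-style), `plan`, `outcome`, `config`.
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = NULL,
                           keep_movie = FALSE, verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  params <- ionic_params(cfg$preset)
  grid <- tissue_grid(cfg$nx, cfg$ny, cfg$dx_um, cfg$Deff)
  say("measuring paced wavelength ...")
  wl <- measure_wavelength_paced(params, cfg$dx_um, cfg$Deff, cfg$pace_cl_ms)
  say("wavelength %.1f mm (CV %.2f mm/ms)", wl$wavelength, wl$cv)

  say("simulating %s episode (%d x %d, %.0f ms after initiation) ...",
      cfg$preset, cfg$nx, cfg$ny, cfg$af_duration_ms)
  prot <- stimulus_protocol("cross-field", cycle_length = cfg$pace_cl_ms,
                            count = cfg$pace_beats, amplitude = cfg$pace_amp,
                            reset_time = cfg$reset_time_ms)
  warm <- simulate_tissue(grid, params, prot,
                          duration = cfg$pace_beats * cfg$pace_cl_ms,
                          sampling = cfg$sampling_ms, record = FALSE)
  if (is.na(warm$reset_time))
    stopf("cross-field reset did not fire during the paced segment")
  main <- simulate_tissue(grid, params, stimulus_protocol("none"),
                          duration = cfg$af_duration_ms,
                          sampling = cfg$sampling_ms, state0 = warm$state,
                          t0 = cfg$pace_beats * cfg$pace_cl_ms)
  movie <- main$movie
  t_end <- max(movie$t)

  say("phase mapping and rotor tracking ...")
  mw <- movie_window(movie, t_end - cfg$map_window_ms, t_end)
  ph <- phase_movie(mw)
  ps <- detect_ps_all(ph)
  rm(ph); gc(FALSE)
  trajs <- if (nrow(ps)) track_ps(ps, movie$dx_mm) else NULL
  mother <- NULL
  if (!is.null(trajs) && nrow(trajs$trajectories)) {
    main_id <- trajs$trajectories$traj[which.max(trajs$trajectories$duration)]
    tp <- trajs$points[trajs$points$traj == main_id, ]
    mother <- classify_mother_rotor(tp, wl$wavelength, all_ps = trajs,
                                    dx_mm = movie$dx_mm)
  }

  say("parameter maps ...")
  dfm <- dominant_frequency_map(movie, window = cfg$map_window_ms)
  eg <- egm_grid(mw, spacing_mm = cfg$egm_spacing_mm)
  shm <- shannon_entropy_map(eg)
  cfm <- cfae_map(eg, window = cfg$map_window_ms)
  rm(mw); gc(FALSE)
  # the high-DF area is kept in both conventions: the reference 9-Hz
  # threshold, and the percentile form used for ShEn/CFAE (the threshold
  # mask can be empty on scaled-down domains whose rotors rotate below 9 Hz)
  masks <- list(
    df = area_mask(dfm, "threshold-above", cfg$df_threshold_hz),
    df_pct = area_mask(dfm, "upper-percentile", cfg$df_area_pct),
    shen = area_mask(shm, "upper-percentile", cfg$shen_area_pct),
    cfae = area_mask(cfm, "lower-percentile", cfg$cfae_area_pct))
  rotor_mask <- NULL
  overlaps <- NULL
  if (!is.null(mother)) {
    rotor_mask <- disk_mask(c(mother$center[2], mother$center[1]),
                            mother$radius_mm / movie$dx_mm,
                            movie$nx, movie$ny, movie$dx_mm, "rotor")
    # percent of each parameter area covered by the rotor area
    overlaps <- list(df = overlap(masks$df, rotor_mask),
                     df_pct = overlap(masks$df_pct, rotor_mask),
                     shen = overlap(masks$shen, rotor_mask),
                     cfae = overlap(masks$cfae, rotor_mask))
  }
  p10 <- cfg$table3_area_pct
  m10 <- list(df = area_mask(dfm, "upper-percentile", p10),
              shen = area_mask(shm, "upper-percentile", p10),
              cfae = area_mask(cfm, "lower-percentile", p10))
  pairwise <- list(df_by_shen = overlap(m10$df, m10$shen),
                   shen_by_cfae = overlap(m10$shen, m10$cfae),
                   cfae_by_df = overlap(m10$cfae, m10$df))

  # one or several strategies ("df+shen+cfae") compared against the same
  # pre-ablation state
  strategies <- setdiff(strsplit(cfg$strategy, "\\+")[[1]], "none")
  plan <- NULL; outcome <- NULL
  if (length(strategies)) {
    plan <- list(); outcome <- list()
    for (strat in strategies) {
      say("ablation strategy %s ...", strat)
      pl <- switch(strat,
        df = plan_map_ablation(dfm, "DF", cfg$ablation_fraction),
        shen = plan_map_ablation(shm, "ShEn", cfg$ablation_fraction),
        cfae = plan_map_ablation(cfm, "CFAE", cfg$ablation_fraction),
        ps = plan_ps_ablation(ps, movie$nx, movie$ny, movie$dx_mm,
                              cfg$ablation_fraction, cfg$ps_lesion_radius_mm),
        stopf("unknown strategy '%s'", strat))
      grid2 <- apply_ablation(grid, pl)
      post <- simulate_tissue(grid2, params, stimulus_protocol("none"),
                              duration = cfg$post_duration_ms,
                              sampling = cfg$sampling_ms, state0 = main$state,
                              t0 = t_end, stop_quiescent = TRUE)
      oc <- classify_outcome(post$movie, ablation_time = t_end,
                             lesion = grid2$lesion)
      say("outcome[%s]: %s", strat, oc$outcome)
      plan[[strat]] <- pl
      outcome[[strat]] <- oc
    }
    if (length(strategies) == 1) {
      plan <- plan[[1]]; outcome <- outcome[[1]]
    }
  }

  res <- structure(list(
    wavelength = wl, reset_time = warm$reset_time, ps = ps,
    trajectories = trajs, mother = mother,
    maps = list(df = dfm, shen = shm, cfae = cfm),
    masks = masks, rotor_mask = rotor_mask, overlaps = overlaps,
    pairwise = pairwise, plan = plan, outcome = outcome, config = cfg,
    movie = if (keep_movie) movie else NULL),
    class = "experiment_result")
  if (!is.null(out_dir)) write_run_dir(res, out_dir)
  res
}

# run-length encode a logical mask (row-major) as a CSV-able data.frame
mask_rle <- function(mask) {
  r <- rle(as.vector(t(mask)))
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1, length = r$lengths,
             value = as.integer(r$values))
}

write_run_dir <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfgfile <- file.path(out_dir, "config.txt")
  write_config(res$config, cfgfile)
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(data.frame(cv_mm_ms = res$wavelength$cv,
                  wavelength_mm = res$wavelength$wavelength), "wavelength.csv")
  if (!is.null(res$trajectories)) {
    wcsv(res$trajectories$points, "ps_points.csv")
    wcsv(res$trajectories$trajectories, "ps_trajectories.csv")
  }
  if (!is.null(res$mother)) {
    m <- res$mother
    wcsv(data.frame(duration_ms = m$duration,
                    confinement_diameter_mm = 2 * m$confinement_radius_mm,
                    rotor_radius_mm = m$radius_mm,
                    center_x_mm = m$center_mm[1], center_y_mm = m$center_mm[2],
                    wavelength_mm = m$wavelength, confined = m$confined,
                    breakup_observed = m$breakup_observed,
                    qualifies = m$qualifies), "mother_rotor.csv")
  }
  for (k in names(res$maps)) {
    v <- res$maps[[k]]$values
    utils::write.csv(as.data.frame(v), file.path(out_dir, paste0("map_", k, ".csv")),
                     row.names = FALSE)
  }
  for (k in names(res$masks))
    wcsv(mask_rle(res$masks[[k]]$mask), paste0("mask_", k, "_rle.csv"))
  if (!is.null(res$overlaps)) {
    ov <- res$overlaps
    wcsv(data.frame(
      area = c("DF", "DF", "ShEn", "CFAE"),
      rule = c(sprintf(">%g Hz", res$config$df_threshold_hz),
               sprintf("upper %g%%", 100 * res$config$df_area_pct),
               sprintf("upper %g%%", 100 * res$config$shen_area_pct),
               sprintf("lower %g%%", 100 * res$config$cfae_area_pct)),
      pct_overlapped_by_rotor = c(ov$df$percent, ov$df_pct$percent,
                                  ov$shen$percent, ov$cfae$percent),
      p_value = c(ov$df$p_value, ov$df_pct$p_value, ov$shen$p_value,
                  ov$cfae$p_value)),
      "overlap_rotor.csv")
  }
  pw <- res$pairwise
  wcsv(data.frame(pair = c("DF by ShEn", "ShEn by CFAE", "CFAE by DF"),
                  percent = c(pw$df_by_shen$percent, pw$shen_by_cfae$percent,
                              pw$cfae_by_df$percent),
                  p_value = c(pw$df_by_shen$p_value, pw$shen_by_cfae$p_value,
                              pw$cfae_by_df$p_value)),
       "overlap_pairwise.csv")
  plans <- res$plan
  if (inherits(plans, "ablation_plan")) plans <- list(plans)
  for (pl in plans)
    wcsv(mask_rle(pl$mask), sprintf("lesion_%s_rle.csv", tolower(pl$strategy)))
  ocs <- res$outcome
  if (inherits(ocs, "outcome_report")) ocs <- list(ocs)
  if (!is.null(ocs) && length(ocs))
    wcsv(do.call(rbind, lapply(seq_along(ocs), function(i) {
      data.frame(strategy = if (!is.null(names(ocs))) names(ocs)[i]
                 else res$config$strategy,
                 outcome = ocs[[i]]$outcome,
                 event_time_ms = ocs[[i]]$event_time,
                 post_cl_ms = ocs[[i]]$post_cl)
    })), "outcome.csv")
  manifest <- c(
    sprintf("package: rotormap %s", as.character(utils::packageVersion("rotormap"))),
    sprintf("config_md5: %s", unname(tools::md5sum(cfgfile))),
    sprintf("grid: %dx%d dx=%gum Deff=%g", res$config$nx, res$config$ny,
            res$config$dx_um, res$config$Deff),
    sprintf("wavelength_mm: %.6g", res$wavelength$wavelength),
    sprintf("mother_rotor_qualifies: %s",
            if (is.null(res$mother)) "none" else res$mother$qualifies))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result (%s, %dx%d)\n", x$config$preset,
              x$config$nx, x$config$ny))
  cat(sprintf("  wavelength %.1f mm; %d PS points; %d trajectories\n",
              x$wavelength$wavelength,
              if (is.null(x$ps)) 0 else nrow(x$ps),
              if (is.null(x$trajectories)) 0 else nrow(x$trajectories$trajectories)))
  if (!is.null(x$mother)) print(x$mother)
  if (!is.null(x$overlaps))
    cat(sprintf("  rotor covers: DF>thr %.1f%%, DF-pct %.1f%%, ShEn %.1f%%, CFAE %.1f%%\n",
                x$overlaps$df$percent, x$overlaps$df_pct$percent,
                x$overlaps$shen$percent, x$overlaps$cfae$percent))
  if (!is.null(x$outcome)) {
    ocs <- if (inherits(x$outcome, "outcome_report")) list(x$outcome) else x$outcome
    for (i in seq_along(ocs)) {
      if (!is.null(names(ocs))) cat(sprintf("  [%s] ", names(ocs)[i]))
      print(ocs[[i]])
    }
  }
  invisible(x)
}
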