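#' 2D tissue grid
#'
#' Regular isotropic monodomain grid.  The full-scale configuration is
#' 600 x 600 nodes at 250 um spacing (15 x 15 cm); scaled-down grids are used
#' for desk experiments.
#'
#' @param nx,ny node counts (>= 16).
#' @param dx node spacing in micrometres (default 250).
#' @param Deff effective diffusivity D/(beta*Cm) in mm^2/ms.  The default 0.15
#'   yields a planar conduction velocity of ~0.46 mm/ms under control kinetics
#'   (physiological atrial range 0.4-0.6); see [calibrate_deff()].
#' @param lesion optional ny x nx logical lesion mask (ablated nodes).
#' @return list of class `tissue_grid`.
#' @export
tissue_grid <- function(nx = 600, ny = 600, dx = 250, Deff = 0.15,
                        lesion = NULL) {
  if (nx < 16 || ny < 16) stopf("grid must be at least 16 x 16 nodes")
  if (dx <= 0 || Deff <= 0) stopf("dx and Deff must be positive")
  if (is.null(lesion)) lesion <- matrix(FALSE, ny, nx)
  if (!is.logical(lesion) || !all(dim(lesion) == c(ny, nx)))
    stopf("lesion must be an ny x nx logical matrix")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, dx_mm = dx / 1000, Deff = Deff, lesion = lesion),
            class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf("tissue_grid: %d x %d nodes, dx = %g um (%.1f x %.1f mm), Deff = %g mm^2/ms\n",
              x$nx, x$ny, x$dx, x$nx * x$dx_mm, x$ny * x$dx_mm, x$Deff))
  nl <- sum(x$lesion)
  if (nl > 0) cat(sprintf("  lesion: %d nodes (%.2f%%)\n", nl,
                          100 * nl / (x$nx * x$ny)))
  invisible(x)
}

#' Stimulation protocol
#'
#' Line pacing applies a current pulse to `pace_rows` rows at the row-1 edge
#' of the sheet.  Cross-field reentry initiation resets the membrane potential
#' to `reset_value` (0 mV) on the half-sheet of columns > nx/2, i.e. across a
#' boundary perpendicular to the paced planar wavefront, either at a fixed
#' `reset_time` or automatically when the paced planar wave is repolarizing:
#' the paced-edge node has depolarized and then recovered below -70 mV (plus
#' `reset_delay`, default 30 ms, to let sodium-channel inactivation recover),
#' so the reset boundary cuts across an excitability gradient and the broken
#' re-excitation wave curls into a spiral.
#'
#' @param kind "line-pace", "cross-field" (line pacing plus reset) or "none".
#' @param cycle_length pacing cycle length (ms).
#' @param count number of paced beats.
#' @param amplitude pulse amplitude (pA/pF, inward negative).
#' @param pulse_ms pulse width (ms).
#' @param pace_rows rows covered by the line electrode.
#' @param first_at time of the first pulse (ms).
#' @param reset_time cross-field reset time (ms); `NA` = automatic trigger.
#' @param reset_value reset potential (mV).
#' @param reset_delay delay after the automatic trigger (ms).
#' @return list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(kind = c("line-pace", "cross-field", "none"),
                              cycle_length = 600, count = 1, amplitude = -30,
                              pulse_ms = 2, pace_rows = 2, first_at = 5,
                              reset_time = NA, reset_value = 0,
                              reset_delay = 30) {
  kind <- match.arg(kind)
  if (kind != "none" && cycle_length <= 0) stopf("cycle_length must be > 0")
  structure(list(kind = kind, cycle_length = cycle_length,
                 count = as.integer(count), amplitude = amplitude,
                 pulse_ms = pulse_ms, pace_rows = as.integer(pace_rows),
                 first_at = first_at, reset_time = reset_time,
                 reset_value = reset_value, reset_delay = reset_delay),
            class = "stimulus_protocol")
}

protocol_to_cpp <- function(protocol) {
  if (protocol$kind == "none")
    return(list(pace_times = numeric(0), cross_field = FALSE))
  list(pace_times = protocol$first_at +
         (seq_len(protocol$count) - 1) * protocol$cycle_length,
       pace_dur = protocol$pulse_ms, pace_amp = protocol$amplitude,
       pace_rows = protocol$pace_rows,
       cross_field = protocol$kind == "cross-field",
       reset_time = if (is.na(protocol$reset_time)) -1 else protocol$reset_time,
       reset_value = protocol$reset_value,
       reset_delay = protocol$reset_delay)
}

new_voltage_movie <- function(v, t, nx, ny, dx_mm, preset = NA_character_) {
  structure(list(v = v, t = t, nx = as.integer(nx), ny = as.integer(ny),
                 dx_mm = dx_mm,
                 dt = if (length(t) > 1) t[2] - t[1] else NA_real_,
                 t0 = if (length(t)) t[1] else NA_real_, preset = preset),
            class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  cat(sprintf("voltage_movie: %d x %d nodes, %d frames at %g ms (%.0f-%.0f ms)\n",
              x$ny, x$nx, length(x$t), x$dt, min(x$t), max(x$t)))
  invisible(x)
}

#' Extract one frame of a movie as an ny x nx matrix
#' @param movie `voltage_movie` (or `phase_movie`).
#' @param k frame index.
#' @return ny x nx matrix indexed `[row, col]`.
#' @export
movie_frame <- function(movie, k) {
  src <- if (!is.null(movie$v)) movie$v else movie$phase
  as_frame(src[, k], movie$nx, movie$ny)
}

#' Time window of a movie
#' @param movie `voltage_movie`.
#' @param from,to absolute time bounds (ms).
#' @return `voltage_movie` restricted to `[from, to]`.
#' @export
movie_window <- function(movie, from = -Inf, to = Inf) {
  i <- movie$t >= from & movie$t <= to
  new_voltage_movie(movie$v[, i, drop = FALSE], movie$t[i], movie$nx, movie$ny,
                    movie$dx_mm, movie$preset)
}

#' Simulate 2D atrial tissue
#'
#' Integrates the monodomain reaction-diffusion equation dVm/dt =
#' Deff * Laplacian(Vm) - (Iion + Is) on the grid with no-flux boundaries,
#' explicit 5-point finite differences for diffusion and Rush-Larsen/Euler
#' operator splitting for the ionic ODEs.  Lesion nodes are clamped to the
#' resting potential (they continue to act as resting-value tissue in the
#' diffusion operator, producing conduction block).
#'
#' @param grid `tissue_grid`.
#' @param params `ionic_params`.
#' @param protocol `stimulus_protocol`.
#' @param duration simulated time (ms).
#' @param sampling movie sampling interval (ms); default 1 ms (1 kHz).
#' @param state0 initial state: `NULL` (resting), a 21-vector replicated to
#'   all nodes, or a 21 x (nx*ny) matrix (e.g. `$state` of a previous run).
#' @param dt ODE/PDE step (ms); must satisfy dt <= 0.8 dx^2/(4 Deff).
#' @param record record the movie (set `FALSE` for warm-up segments).
#' @param record_from start recording at this time (ms).
#' @param stop_quiescent stop early once no node exceeds -40 mV for 500 ms.
#' @param t0 absolute time assigned to simulation time 0 (bookkeeping for
#'   multi-segment runs).
#' @param pure_diffusion disable the ionic term (diffusion test mode).
#' @return list of class `tissue_run`: `movie` (`voltage_movie` or `NULL`),
#'   final `state` matrix, `reset_time`, `stop_time` (NA unless stopped
#'   quiescent), `grid`, `params`.
#' @export
simulate_tissue <- function(grid, params = ionic_params(),
                            protocol = stimulus_protocol(), duration = 1000,
                            sampling = 1, state0 = NULL, dt = 0.05,
                            record = TRUE, record_from = 0,
                            stop_quiescent = FALSE, t0 = 0,
                            pure_diffusion = FALSE) {
  nn <- grid$nx * grid$ny
  if (is.null(state0)) state0 <- resting_state(params, settle_ms = 20000)
  if (is.null(dim(state0))) state0 <- matrix(rep(as.numeric(state0), nn), nrow = 21)
  if (duration <= 0) stopf("duration must be positive")
  lr <- if (any(grid$lesion)) resting_state(params, 10000)[["V"]] else -81.18
  res <- crn_tissue_sim_cpp(state0, params, grid$nx, grid$ny, grid$dx_mm,
                            grid$Deff, as.vector(t(grid$lesion)),
                            protocol_to_cpp(protocol), duration, dt, sampling,
                            record, record_from, stop_quiescent,
                            pure_diffusion, lr)
  movie <- if (record)
    new_voltage_movie(res$v, res$t + t0, grid$nx, grid$ny, grid$dx_mm,
                      params$preset)
  else NULL
  structure(list(movie = movie, state = res$state,
                 reset_time = if (is.na(res$reset_time)) NA else res$reset_time + t0,
                 stop_time = if (is.na(res$stop_time)) NA else res$stop_time + t0,
                 grid = grid, params = params),
            class = "tissue_run")
}

#' Cross-field reentry initiation applied to a state snapshot
#'
#' Sets the membrane potential to `reset_value` (0 mV) on the half-sheet of
#' columns > nx/2 - the boundary is perpendicular to a planar wave travelling
#' along rows - leaving all other state variables untouched.  Used when
#' driving the protocol manually; `stimulus_protocol("cross-field")` performs
#' the same reset inside the solver.
#'
#' @param state 21 x (nx*ny) state matrix.
#' @param grid `tissue_grid`.
#' @param reset_value reset potential (mV).
#' @return modified state matrix.
#' @export
initiate_reentry <- function(state, grid, reset_value = 0) {
  if (max(state[1, ]) <= -40)
    stopf("no planar wave present (no nodes above -40 mV)")
  cols <- rep(seq_len(grid$nx), times = grid$ny)
  state[1, cols > grid$nx / 2] <- reset_value
  state
}

#' Conduction velocity and wavelength of a paced planar wave
#'
#' CV is the inverse slope of a linear regression of per-row activation times
#' (first crossing of -40 mV) on distance along the propagation axis.
#' Wavelength is the spatial extent of the excited band (V >= -60 mV) at
#' single time instants, averaged over instants where the band lies inside
#' the sheet mid-portion.
#'
#' @param movie `voltage_movie` of a line-paced sheet (wave along rows).
#' @param pacing_cl pacing cycle length (ms), reference 600.
#' @param act_thresh activation threshold (mV).
#' @param exc_thresh excited-state threshold (mV) for the wavelength band.
#' @return list with `cv` (mm/ms), `wavelength` (mm), `act_times` (ms per row).
#' @export
measure_cv_wavelength <- function(movie, pacing_cl = 600, act_thresh = -40,
                                  exc_thresh = -60) {
  nx <- movie$nx; ny <- movie$ny
  col <- max(1L, nx %/% 2L)
  idx <- node_index(seq_len(ny), col, nx)
  tr <- movie$v[idx, , drop = FALSE]     # ny x nt, one column of the sheet
  act <- apply(tr, 1, function(v) {
    i <- which(v > act_thresh)[1]
    if (is.na(i)) NA_real_ else movie$t[i]
  })
  rows <- which(!is.na(act))
  rows <- rows[rows > ny * 0.1 & rows < ny * 0.9]
  if (length(rows) < 10) stopf("no propagation detected")
  fit <- stats::lm(act[rows] ~ rows)
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope <= 0) stopf("no propagation detected")
  cv <- movie$dx_mm / slope
  # wavelength: excited-band extent while fully inside the sheet
  wl <- c()
  for (k in seq_along(movie$t)) {
    exc <- tr[, k] >= exc_thresh
    if (!any(exc)) next
    r <- range(which(exc))
    if (r[1] > 1 && r[2] < ny)  # band detached from both edges
      wl <- c(wl, (r[2] - r[1] + 1) * movie$dx_mm)
  }
  wavelength <- if (length(wl) >= 3) mean(wl) else {
    # band never fully inside (wavelength exceeds sheet): CV * time above
    # threshold at a mid-sheet node as the kinematic equivalent
    vmid <- tr[ny %/% 2, ]
    cv * sum(vmid >= exc_thresh) * movie$dt
  }
  list(cv = cv, wavelength = wavelength, act_times = act)
}

#' Calibrate the effective diffusivity against conduction velocity
#'
#' Measures planar CV on a thin strip at candidate diffusivities and
#' interpolates (CV ~ sqrt(Deff)) to the target velocity.
#'
#' @param target_cv desired CV (mm/ms).
#' @param params `ionic_params`.
#' @param dx node spacing (um).
#' @param Deff_probe initial probe diffusivity (mm^2/ms).
#' @param strip_len strip length in nodes.
#' @return list with `Deff`, `cv_probe`, `cv_check`.
#' @export
calibrate_deff <- function(target_cv = 0.46, params = ionic_params(),
                           dx = 500, Deff_probe = 0.15, strip_len = 240) {
  cv_at <- function(D) {
    g <- tissue_grid(nx = 16, ny = strip_len, dx = dx, Deff = D)
    run <- simulate_tissue(g, params,
                           stimulus_protocol("line-pace", count = 1),
                           duration = strip_len * dx / 1000 / 0.3 + 100)
    measure_cv_wavelength(run$movie)$cv
  }
  cv0 <- cv_at(Deff_probe)
  D1 <- Deff_probe * (target_cv / cv0)^2
  cv1 <- cv_at(D1)
  list(Deff = D1, cv_probe = cv0, cv_check = cv1)
}
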