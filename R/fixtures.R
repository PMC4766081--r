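# Synthetic fixtures: analytic spirals, deflection-train electrograms and
# PS point streams with known ground truth, so every analysis stage can be
# tested without running the PDE solver.

#' Spiral fixture specification
#'
#' Prescribes an Archimedean spiral phase field phi(x, t) =
#' theta(x - core(t)) - k*r + omega*t with a chosen tip path.
#'
#' @param nx,ny grid size (nodes).
#' @param dx_mm node spacing (mm).
#' @param core_path "stationary", "circle" (meander) or "drift".
#' @param core_center c(row, col) of the core (node units); default sheet
#'   center.
#' @param meander_radius_mm radius of the circular meander (mm).
#' @param meander_period_ms period of the meander (ms).
#' @param drift_mm_per_s linear drift speed (mm/s), along +x.
#' @param frequency_hz rotation frequency (Hz); omega = 2*pi*f.
#' @param wavelength_mm spatial wavelength (mm); must exceed 4*dx.
#' @param duration_ms,dt_ms movie duration and sampling.
#' @param chirality +1 (counter-clockwise) or -1.
#' @return list of class `spiral_fixture`.
#' @export
spiral_fixture <- function(nx = 60, ny = 60, dx_mm = 0.5,
                           core_path = c("stationary", "circle", "drift"),
                           core_center = NULL, meander_radius_mm = 2,
                           meander_period_ms = 500, drift_mm_per_s = 1,
                           frequency_hz = 8, wavelength_mm = 20,
                           duration_ms = 2000, dt_ms = 5, chirality = 1L) {
  core_path <- match.arg(core_path)
  if (wavelength_mm < 4 * dx_mm)
    stopf("wavelength below 4*dx would alias on the grid")
  if (is.null(core_center)) core_center <- c((ny + 1) / 2, (nx + 1) / 2)
  structure(list(nx = nx, ny = ny, dx_mm = dx_mm, core_path = core_path,
                 core_center = core_center,
                 meander_radius_mm = meander_radius_mm,
                 meander_period_ms = meander_period_ms,
                 drift_mm_per_s = drift_mm_per_s, frequency_hz = frequency_hz,
                 wavelength_mm = wavelength_mm, duration_ms = duration_ms,
                 dt_ms = dt_ms, chirality = as.integer(chirality)),
            class = "spiral_fixture")
}

# tip position (row, col; node units) at time t for a fixture
spiral_core_at <- function(f, t) {
  switch(f$core_path,
    stationary = cbind(row = rep(f$core_center[1], length(t)),
                       col = rep(f$core_center[2], length(t))),
    circle = {
      a <- 2 * pi * t / f$meander_period_ms
      r <- f$meander_radius_mm / f$dx_mm
      cbind(row = f$core_center[1] + r * sin(a),
            col = f$core_center[2] + r * cos(a))
    },
    drift = {
      v <- f$drift_mm_per_s / 1000 / f$dx_mm   # nodes per ms
      cbind(row = rep(f$core_center[1], length(t)),
            col = f$core_center[2] + v * t)
    })
}

# AP-like periodic waveform on phase in (-pi, pi]: fast upstroke, plateau,
# repolarization to a resting level, mapped to mV
ap_waveform <- function(phi) {
  u <- (phi + pi) / (2 * pi)            # 0..1 through the cycle
  v <- numeric(length(u))
  up <- u < 0.05
  plat <- u >= 0.05 & u < 0.35
  rep_ <- u >= 0.35 & u < 0.7
  v[up] <- u[up] / 0.05
  v[plat] <- 1 - 0.15 * (u[plat] - 0.05) / 0.3
  v[rep_] <- 0.85 * (1 - (u[rep_] - 0.35) / 0.35)^1.5
  v[u >= 0.7] <- 0
  -85 + 110 * v
}

#' Build a spiral voltage movie with ground truth
#'
#' Generates a `voltage_movie` whose phase field is an Archimedean spiral
#' around the prescribed tip path, mapped through an AP-like waveform, and
#' returns the analytic phase movie and core track as ground truth.
#'
#' @param f `spiral_fixture`.
#' @return list with `movie` (`voltage_movie`), `phase` (`phase_movie` with
#'   the constructed phase), `core` (data.frame t, row, col).
#' @export
make_spiral_movie <- function(f) {
  t <- seq(0, f$duration_ms, by = f$dt_ms)
  core <- spiral_core_at(f, t)
  omega <- 2 * pi * f$frequency_hz / 1000          # rad/ms
  k <- 2 * pi / (f$wavelength_mm / f$dx_mm)        # rad/node
  rows <- matrix(seq_len(f$ny), f$ny, f$nx)
  cols <- matrix(seq_len(f$nx), f$ny, f$nx, byrow = TRUE)
  nn <- f$nx * f$ny
  v <- matrix(0, nn, length(t))
  ph <- matrix(0, nn, length(t))
  for (i in seq_along(t)) {
    dyr <- rows - core[i, "row"]
    dxc <- cols - core[i, "col"]
    theta <- atan2(dyr, dxc)
    r <- sqrt(dyr^2 + dxc^2)
    phi <- wrap_phase(f$chirality * theta - k * r + omega * t[i])
    ph[, i] <- frame_to_col(phi)
    v[, i] <- frame_to_col(matrix(ap_waveform(phi), f$ny, f$nx))
  }
  movie <- new_voltage_movie(v, t, f$nx, f$ny, f$dx_mm, "fixture")
  phase <- structure(list(phase = ph, t = t, dt = f$dt_ms, nx = f$nx,
                          ny = f$ny, dx_mm = f$dx_mm,
                          defined = rep(TRUE, nn)),
                     class = "phase_movie")
  list(movie = movie, phase = phase,
       core = data.frame(t = t, row = core[, "row"], col = core[, "col"]))
}

#' Electrogram fixture: deflection train with prescribed intervals
#'
#' Superposes a biphasic deflection template at cumulative interval times,
#' optionally jittering timing and amplitude with a seeded RNG.
#'
#' @param intervals inter-deflection intervals (ms).
#' @param dt_ms sampling interval.
#' @param deflection_width_ms width of the biphasic template (ms).
#' @param amplitude template amplitude (mV).
#' @param amplitude_jitter,timing_jitter jitter SDs (fraction, ms).
#' @param seed RNG seed for the jitter.
#' @param pad_ms quiet padding before the first and after the last
#'   deflection.
#' @return `electrogram` with attribute `deflection_times`.
#' @export
make_egm <- function(intervals, dt_ms = 1, deflection_width_ms = 12,
                     amplitude = 1, amplitude_jitter = 0, timing_jitter = 0,
                     seed = 1, pad_ms = 50) {
  if (any(intervals <= 0)) stopf("intervals must be positive")
  if (any(intervals < deflection_width_ms))
    stopf("interval shorter than the deflection template would overlap")
  times <- pad_ms + cumsum(c(0, intervals))
  n_def <- length(times)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  jt <- stats::rnorm(n_def, 0, timing_jitter)
  ja <- 1 + stats::rnorm(n_def, 0, amplitude_jitter)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  times_j <- times + jt
  total <- max(times_j) + pad_ms
  t <- seq(0, total, by = dt_ms)
  sig <- numeric(length(t))
  # biphasic template: one sine period over the deflection width
  for (i in seq_len(n_def)) {
    idx <- which(t >= times_j[i] & t < times_j[i] + deflection_width_ms)
    u <- (t[idx] - times_j[i]) / deflection_width_ms
    sig[idx] <- sig[idx] + amplitude * ja[i] * sin(2 * pi * u)
  }
  structure(list(signal = sig, t = t, dt = dt_ms, spec = NULL),
            class = "electrogram", deflection_times = times_j)
}

#' PS point stream with known trajectory segmentation
#'
#' Builds the per-frame PS point stream of one or more prescribed paths for
#' testing the tracker: each path is a list with `t0`, `t1` (ms), start
#' position `x`, `y` (node units), velocity `vx`, `vy` (nodes per ms) and
#' `charge`.
#'
#' @param paths list of path descriptors.
#' @param dt_ms frame interval.
#' @return data.frame (t, x, y, charge) plus attribute `truth` (path id per
#'   row).
#' @export
make_ps_stream <- function(paths, dt_ms = 1) {
  out <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    t <- seq(p$t0, p$t1, by = dt_ms)
    data.frame(t = t, x = p$x + p$vx * (t - p$t0), y = p$y + p$vy * (t - p$t0),
               charge = as.integer(p$charge), path = i)
  })
  d <- do.call(rbind, out)
  d <- d[order(d$t, d$path), ]
  structure(d[, c("t", "x", "y", "charge")], truth = d$path)
}
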