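# shared fixtures and brute-force oracles built in code at test time

ctrl_params <- ionic_params("control")
peaf_params <- ionic_params("peaf")

# a relaxed resting state, computed once per test run
rest_ctrl <- resting_state(ctrl_params, settle_ms = 20000)

# kinematic movie: an excited band of width `band_nodes` travelling along
# +x (columns) at `speed` nodes per frame; AP-like plateau at +15 mV over
# -80 mV rest.  Ground truth for CV/wavelength and electrogram tests.
kinematic_band_movie <- function(nx = 80, ny = 20, band_nodes = 10,
                                 speed = 1, nframes = 60, dx_mm = 0.5,
                                 dt = 1, along = c("x", "y"), reverse = FALSE) {
  along <- match.arg(along)
  v <- matrix(-80, nx * ny, nframes)
  for (k in seq_len(nframes)) {
    front <- k * speed
    band <- (front - band_nodes + 1):front
    band <- band[band >= 1 & band <= (if (along == "x") nx else ny)]
    if (reverse) band <- (if (along == "x") nx else ny) + 1 - band
    fr <- matrix(-80, ny, nx)
    if (along == "x") fr[, band] <- 15 else fr[band, ] <- 15
    v[, k] <- as.vector(t(fr))
  }
  rotormap:::new_voltage_movie(v, seq(0, by = dt, length.out = nframes),
                               nx, ny, dx_mm)
}

# brute-force minimal enclosing circle for <= 12 points: try all pair and
# triple circles, keep the smallest that covers every point
mec_brute <- function(x, y) {
  n <- length(x)
  best <- list(radius = Inf)
  covers <- function(cx, cy, r) all((x - cx)^2 + (y - cy)^2 <= r^2 + 1e-9)
  for (i in 1:n) for (j in i:n) {
    cx <- (x[i] + x[j]) / 2; cy <- (y[i] + y[j]) / 2
    r <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) / 2
    if (r < best$radius && covers(cx, cy, r))
      best <- list(center = c(cx, cy), radius = r)
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r <- sqrt((ax - ux)^2 + (ay - uy)^2)
    if (r < best$radius && covers(ux, uy, r))
      best <- list(center = c(ux, uy), radius = r)
  }
  best
}

# brute-force histogram entropy oracle
entropy_brute <- function(x, bins, lo, hi) {
  br <- seq(lo, hi, length.out = bins + 1)
  cnt <- hist(pmin(pmax(x, lo), hi), breaks = br, plot = FALSE)$counts
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log2(p))
}

# small uniform-rest movie helper
uniform_movie <- function(value = -80, nx = 12, ny = 12, nframes = 30,
                          dx_mm = 0.25, dt = 1) {
  rotormap:::new_voltage_movie(matrix(value, nx * ny, nframes),
                               seq(0, by = dt, length.out = nframes),
                               nx, ny, dx_mm)
}
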