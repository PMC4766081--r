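#' Per-node dominant frequency map
#'
#' For every node the de-meaned, Hann-windowed action potential over the
#' analysis window is Fourier transformed (zero-padded to 0.05-Hz bin
#' spacing) and the DF is the frequency of maximal power inside the
#' physiological band.
#'
#' @param movie `voltage_movie` (sampled at >= 100 Hz).
#' @param window analysis duration (ms), default 6000; must be >= 2000.
#' @param band search band in Hz, default c(0.5, 20).
#' @param min_range nodes whose AP dynamic range over the window falls below
#'   this (mV) are flagged undefined (NA).
#' @param df_resolution zero-padding target bin spacing (Hz).
#' @return `scalar_map` of kind "DF" (Hz).
#' @export
dominant_frequency_map <- function(movie, window = 6000, band = c(0.5, 20),
                                   min_range = 5, df_resolution = 0.05) {
  if (window < 2000) stopf("DF window shorter than 2 s gives too little resolution")
  tmax <- max(movie$t)
  sel_t <- movie$t >= tmax - window + movie$dt / 2
  nt <- sum(sel_t)
  nn <- nrow(movie$v)
  fs <- 1000 / movie$dt
  nfft <- max(nt, ceiling(fs / df_resolution))
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  sel <- which(freqs >= band[1] & freqs <= band[2])
  w <- hann_window(nt)
  df <- rep(NA_real_, nn)
  chunk <- 256L
  i <- 1L
  while (i <= nn) {
    j <- min(i + chunk - 1L, nn)
    x <- t(movie$v[i:j, sel_t, drop = FALSE])   # nt x chunk
    rng <- apply(x, 2, function(v) diff(range(v)))
    xm <- (x - rep(colMeans(x), each = nt)) * w
    xp <- rbind(xm, matrix(0, nfft - nt, j - i + 1L))
    pw <- Mod(stats::mvfft(xp))^2
    df[i:j] <- freqs[sel[max.col(t(pw[sel, , drop = FALSE]),
                                 ties.method = "first")]]
    df[i:j][rng < min_range] <- NA_real_
    i <- j + 1L
  }
  new_scalar_map(as_frame(df, movie$nx, movie$ny), "DF", window, movie$dx_mm)
}

new_scalar_map <- function(values, kind, window, dx_mm) {
  structure(list(values = values, kind = kind, window = window,
                 ny = nrow(values), nx = ncol(values), dx_mm = dx_mm),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("scalar_map[%s]: %d x %d, window %g ms, range [%.3g, %.3g], %d undefined\n",
              x$kind, x$ny, x$nx, x$window, min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' Shannon entropy of an electrogram
#'
#' Amplitude-histogram entropy: samples are clipped to mean +/- 3 SD, binned
#' into `bins` uniform bins, and ShEn = -sum p_i log2 p_i over occupied bins.
#' A zero-variance signal has entropy 0.
#'
#' @param egm `electrogram` or numeric signal vector.
#' @param bins histogram bin count (default 50).
#' @param clip_sd clip range in standard deviations (default 3).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(egm, bins = 50, clip_sd = 3) {
  x <- if (inherits(egm, "electrogram")) egm$signal else as.numeric(egm)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  m <- mean(x)
  lo <- max(m - clip_sd * s, min(x))
  hi <- min(m + clip_sd * s, max(x))
  x <- pmin(pmax(x, lo), hi)
  b <- findInterval(x, seq(lo, hi, length.out = bins + 1),
                    rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(b, nbins = bins)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' CFAE mean cycle length of a bipolar electrogram
#'
#' Detects local minima of the signal's time derivative deeper than
#' `depth_frac` of the window's most negative derivative, enforces a
#' refractory gap, and returns the mean inter-deflection interval over the
#' analysis window (default 6 s).
#'
#' @param egm `electrogram`.
#' @param window analysis duration (ms); tail of the signal is used.
#' @param depth_frac detection threshold as a fraction of the most negative
#'   derivative (default 0.2).
#' @param refractory minimum interval between detections (ms, default 30).
#' @return mean cycle length (ms), or NA (undefined) with attribute
#'   `n_deflections` when fewer than 2 deflections are found.
#' @export
cfae_cycle_length <- function(egm, window = 6000, depth_frac = 0.2,
                              refractory = 30) {
  i <- egm$t >= max(egm$t) - window + egm$dt / 2
  x <- egm$signal[i]
  tt <- egm$t[i]
  d <- diff(x) / egm$dt
  if (!length(d) || min(d) >= 0 || diff(range(x)) < 1e-9)
    return(structure(NA_real_, n_deflections = 0L))
  thr <- depth_frac * min(d)
  n <- length(d)
  locmin <- which(d < thr &
                    d <= c(Inf, d[-n]) &
                    d <= c(d[-1], Inf))
  if (length(locmin) < 2) return(structure(NA_real_, n_deflections = length(locmin)))
  tmins <- tt[locmin]
  keep <- tmins[1]
  for (tm in tmins[-1]) if (tm - keep[length(keep)] >= refractory) keep <- c(keep, tm)
  if (length(keep) < 2) return(structure(NA_real_, n_deflections = length(keep)))
  structure(mean(diff(keep)), n_deflections = length(keep))
}

#' ShEn map over an electrogram grid
#' @param eg `egm_grid`.
#' @param ... passed to [shannon_entropy()].
#' @return `scalar_map` of kind "ShEn" (bits), painted to nodes.
#' @export
shannon_entropy_map <- function(eg, ...) {
  vals <- vapply(eg$egms, function(e)
    if (is.null(e)) NA_real_ else shannon_entropy(e, ...), numeric(1))
  new_scalar_map(paint_tiles(eg, vals), "ShEn", eg$window, eg$dx_mm)
}

#' CFAE-CL map over an electrogram grid
#' @param eg `egm_grid`.
#' @param ... passed to [cfae_cycle_length()].
#' @return `scalar_map` of kind "CFAE" (ms), painted to nodes; undefined
#'   tiles are NA.
#' @export
cfae_map <- function(eg, ...) {
  vals <- vapply(eg$egms, function(e)
    if (is.null(e)) NA_real_ else as.numeric(cfae_cycle_length(e, ...)), numeric(1))
  new_scalar_map(paint_tiles(eg, vals), "CFAE", eg$window, eg$dx_mm)
}

#' Binary area mask from a scalar map
#'
#' Threshold rules select nodes by inequality (e.g. DF > 9 Hz); percentile
#' rules select the highest- or lowest-valued fraction of defined nodes with
#' deterministic tie-breaking (value, then row-major node order).  Undefined
#' (NA) nodes are never selected.
#'
#' @param map `scalar_map`.
#' @param rule one of "threshold-above", "threshold-below",
#'   "upper-percentile", "lower-percentile".
#' @param value threshold (map units) or percentile fraction in (0, 1)
#'   (e.g. 0.025 for the upper 2.5%).
#' @return `area_mask` with logical `mask` and the rule recorded.
#' @export
area_mask <- function(map, rule = c("threshold-above", "threshold-below",
                                    "upper-percentile", "lower-percentile"),
                      value) {
  rule <- match.arg(rule)
  v <- map$values
  mask <- matrix(FALSE, map$ny, map$nx)
  if (rule %in% c("upper-percentile", "lower-percentile")) {
    if (value <= 0 || value >= 1) stopf("percentile fraction must be in (0,1)")
    n_target <- round(value * length(v))
    def <- which(!is.na(v))
    ord <- if (rule == "upper-percentile")
      def[order(-v[def], def)] else def[order(v[def], def)]
    mask[ord[seq_len(min(n_target, length(ord)))]] <- TRUE
  } else {
    mask[!is.na(v) & (if (rule == "threshold-above") v > value else v < value)] <- TRUE
  }
  structure(list(mask = mask, rule = rule, value = value,
                 source_kind = map$kind, ny = map$ny, nx = map$nx,
                 dx_mm = map$dx_mm),
            class = "area_mask")
}

#' Circular area mask (e.g. the rotor area)
#' @param center c(row, col) in node units.
#' @param radius_nodes radius in node units.
#' @param nx,ny,dx_mm grid geometry.
#' @param kind label recorded on the mask.
#' @return `area_mask`.
#' @export
disk_mask <- function(center, radius_nodes, nx, ny, dx_mm = NA, kind = "disk") {
  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  mask <- (rows - center[1])^2 + (cols - center[2])^2 <= radius_nodes^2
  structure(list(mask = mask, rule = "disk", value = radius_nodes,
                 source_kind = kind, ny = ny, nx = nx, dx_mm = dx_mm),
            class = "area_mask")
}

#' Spatial overlap between two area masks
#'
#' Percent of mask `a` covered by mask `b`, the 2x2 node contingency table,
#' and a chi-square association p-value.
#'
#' @param a,b `area_mask` objects on the same grid.
#' @return list of class `overlap_result`: `percent`, `counts`, `p_value`.
#' @export
overlap <- function(a, b) {
  if (!all(dim(a$mask) == dim(b$mask))) stopf("masks are on different grids")
  n11 <- sum(a$mask & b$mask)
  n10 <- sum(a$mask & !b$mask)
  n01 <- sum(!a$mask & b$mask)
  n00 <- sum(!a$mask & !b$mask)
  counts <- matrix(c(n11, n10, n01, n00), 2, 2, byrow = TRUE,
                   dimnames = list(c("inA", "outA"), c("inB", "outB")))
  pct <- if (sum(a$mask) == 0) NA_real_ else 100 * n11 / sum(a$mask)
  pv <- tryCatch(
    suppressWarnings(stats::chisq.test(counts, correct = FALSE)$p.value),
    error = function(e) NA_real_)
  structure(list(percent = pct, counts = counts, p_value = pv,
                 a_kind = a$source_kind, b_kind = b$source_kind),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %.1f%% of %s area covered by %s area (p = %.3g)\n",
              x$percent, x$a_kind, x$b_kind, x$p_value))
  invisible(x)
}
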