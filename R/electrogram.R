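#' Virtual bipolar electrode specification
#'
#' Geometry of the simulated ablation-catheter electrode pair: rectangular
#' distal (3.5 x 2.0 mm) and proximal (1.5 x 2.0 mm) electrodes 1.0 mm apart
#' edge-to-edge, laid along `orientation` and centered (as a pair) on the
#' given node.
#'
#' @param center_row,center_col grid node at the center of the pair.
#' @param orientation "x" (along columns) or "y" (along rows).
#' @param distal_mm,proximal_mm electrode length x width (mm).
#' @param gap_mm edge-to-edge gap (mm).
#' @return list of class `electrode_spec`.
#' @export
electrode_spec <- function(center_row, center_col, orientation = c("x", "y"),
                           distal_mm = c(3.5, 2.0), proximal_mm = c(1.5, 2.0),
                           gap_mm = 1.0) {
  orientation <- match.arg(orientation)
  structure(list(center_row = center_row, center_col = center_col,
                 orientation = orientation, distal_mm = distal_mm,
                 proximal_mm = proximal_mm, gap_mm = gap_mm),
            class = "electrode_spec")
}

# node-index footprints of the two electrodes; NULL if off-grid.
# Nodes whose centers fall inside each rectangle (half-open coverage).
electrode_footprints <- function(spec, nx, ny, dx_mm) {
  span_nodes <- function(mm) max(1L, floor(mm / dx_mm + 1e-9))
  dl <- span_nodes(spec$distal_mm[1]); dw <- span_nodes(spec$distal_mm[2])
  pl <- span_nodes(spec$proximal_mm[1]); pw <- span_nodes(spec$proximal_mm[2])
  gp <- max(1L, round(spec$gap_mm / dx_mm))
  total <- dl + gp + pl
  # pair laid along the axis; distal first
  a0 <- round(spec[[if (spec$orientation == "x") "center_col" else "center_row"]] - total / 2)
  c0 <- spec[[if (spec$orientation == "x") "center_row" else "center_col"]]
  axis_d <- a0 + seq_len(dl) - 1L
  axis_p <- a0 + dl + gp + seq_len(pl) - 1L
  perp_d <- c0 - floor(dw / 2) + seq_len(dw) - 1L
  perp_p <- c0 - floor(pw / 2) + seq_len(pw) - 1L
  if (spec$orientation == "x") {
    if (min(axis_d) < 1 || max(axis_p) > nx ||
        min(perp_d) < 1 || max(perp_d) > ny) return(NULL)
    distal <- as.vector(outer(perp_d, axis_d, function(r, cc) node_index(r, cc, nx)))
    proximal <- as.vector(outer(perp_p, axis_p, function(r, cc) node_index(r, cc, nx)))
  } else {
    if (min(axis_d) < 1 || max(axis_p) > ny ||
        min(perp_d) < 1 || max(perp_d) > nx) return(NULL)
    distal <- as.vector(outer(axis_d, perp_d, function(r, cc) node_index(r, cc, nx)))
    proximal <- as.vector(outer(axis_p, perp_p, function(r, cc) node_index(r, cc, nx)))
  }
  list(distal = distal, proximal = proximal)
}

#' Virtual bipolar electrogram
#'
#' The bipolar signal is the mean membrane potential over the distal
#' footprint minus the mean over the proximal footprint (action-potential
#' averaging; no extracellular forward model).
#'
#' @param movie `voltage_movie`.
#' @param spec `electrode_spec`.
#' @return list of class `electrogram` with `signal` (mV), `t`, `dt`, `spec`.
#' @export
bipolar_egm <- function(movie, spec) {
  fp <- electrode_footprints(spec, movie$nx, movie$ny, movie$dx_mm)
  if (is.null(fp)) stopf("electrode footprint falls outside the grid")
  sig <- colMeans(movie$v[fp$distal, , drop = FALSE]) -
    colMeans(movie$v[fp$proximal, , drop = FALSE])
  structure(list(signal = sig, t = movie$t, dt = movie$dt, spec = spec),
            class = "electrogram")
}

#' @export
print.electrogram <- function(x, ...) {
  cat(sprintf("electrogram: %d samples at %g ms, range [%.2f, %.2f] mV\n",
              length(x$signal), x$dt, min(x$signal), max(x$signal)))
  invisible(x)
}

#' Grid of bipolar electrograms tiling the sheet
#'
#' One virtual bipolar electrogram per tile of `spacing_mm` pitch, with the
#' electrode pair centered on the tile.  Tiles whose electrode footprint
#' would leave the grid are flagged undefined.  Tile-to-node bookkeeping is
#' retained so per-tile statistics can be painted back onto the node grid.
#'
#' @param movie `voltage_movie`.
#' @param spacing_mm tile pitch (mm), default 2.
#' @param orientation electrode axis.
#' @return list of class `egm_grid`: `egms` (list, NULL where undefined),
#'   `tile_rows`, `tile_cols` (tile center nodes), `nrow`, `ncol`, and
#'   `assign_tile` (ny x nx matrix of tile ids).
#' @export
egm_grid <- function(movie, spacing_mm = 2, orientation = "x") {
  step <- round(spacing_mm / movie$dx_mm)
  if (step < 2) stopf("tile spacing smaller than the node footprint")
  crows <- seq(floor(step / 2) + 1L, movie$ny, by = step)
  ccols <- seq(floor(step / 2) + 1L, movie$nx, by = step)
  egms <- vector("list", length(crows) * length(ccols))
  k <- 0L
  for (r in crows) for (cc in ccols) {
    k <- k + 1L
    spec <- electrode_spec(r, cc, orientation)
    fp <- electrode_footprints(spec, movie$nx, movie$ny, movie$dx_mm)
    if (!is.null(fp)) egms[[k]] <- bipolar_egm(movie, spec)
  }
  # nearest-tile assignment of every node
  rowtile <- pmin(length(crows), pmax(1L, round((seq_len(movie$ny) - crows[1]) / step) + 1L))
  coltile <- pmin(length(ccols), pmax(1L, round((seq_len(movie$nx) - ccols[1]) / step) + 1L))
  assign_tile <- outer(rowtile, coltile,
                       function(i, j) (i - 1L) * length(ccols) + j)
  structure(list(egms = egms, tile_rows = crows, tile_cols = ccols,
                 nrow = length(crows), ncol = length(ccols),
                 assign_tile = assign_tile, nx = movie$nx, ny = movie$ny,
                 dx_mm = movie$dx_mm, window = diff(range(movie$t))),
            class = "egm_grid")
}

# paint per-tile values back to the node grid (NA where tile undefined)
paint_tiles <- function(eg, tile_values) {
  m <- matrix(tile_values[eg$assign_tile], eg$ny, eg$nx)
  m
}
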