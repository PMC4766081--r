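#' Map-guided ablation plan
#'
#' Selects the target fraction (default 5%) of the domain by map value:
#' highest values for DF- and ShEn-guided strategies, lowest for
#' CFAE-guided.  Undefined map nodes are never selected.
#'
#' @param map `scalar_map`.
#' @param strategy "DF", "ShEn" or "CFAE".
#' @param fraction target lesion fraction of the domain, in (0, 0.5].
#' @return list of class `ablation_plan` with logical `mask` (ny x nx),
#'   `strategy`, `area_fraction` (target) and `achieved_fraction`.
#' @export
plan_map_ablation <- function(map, strategy = c("DF", "ShEn", "CFAE"),
                              fraction = 0.05) {
  strategy <- match.arg(strategy)
  if (fraction <= 0 || fraction > 0.5) stopf("fraction must be in (0, 0.5]")
  rule <- if (strategy == "CFAE") "lower-percentile" else "upper-percentile"
  am <- area_mask(map, rule, fraction)
  new_ablation_plan(am$mask, strategy, fraction, map$dx_mm)
}

new_ablation_plan <- function(mask, strategy, fraction, dx_mm,
                              flagged = FALSE) {
  structure(list(mask = mask, strategy = strategy, area_fraction = fraction,
                 achieved_fraction = sum(mask) / length(mask),
                 flagged = flagged, ny = nrow(mask), nx = ncol(mask),
                 dx_mm = dx_mm),
            class = "ablation_plan")
}

#' @export
print.ablation_plan <- function(x, ...) {
  cat(sprintf("ablation_plan[%s]: %d nodes (%.2f%% of domain; target %.2f%%)%s\n",
              x$strategy, sum(x$mask), 100 * x$achieved_fraction,
              100 * x$area_fraction,
              if (x$flagged) " [flagged: target not met exactly]" else ""))
  invisible(x)
}

#' PS-guided ablation plan
#'
#' Iterates PS points in time order; for each point not already inside the
#' lesion, all nodes within `lesion_radius_mm` (1 mm, the catheter tip size)
#' are added, until the cumulative lesion reaches the target fraction of the
#' domain.
#'
#' @param ps data.frame of PS points (t, x, y in node units), or a
#'   `ps_trajectories` object.
#' @param nx,ny grid dimensions.
#' @param dx_mm node spacing (mm).
#' @param fraction target lesion fraction (default 0.05).
#' @param lesion_radius_mm per-point lesion radius (default 1).
#' @return `ablation_plan`; `flagged` is TRUE when the PS stream was
#'   exhausted before the target (achieved < target) or when a single disk
#'   overshot the target.
#' @export
plan_ps_ablation <- function(ps, nx, ny, dx_mm, fraction = 0.05,
                             lesion_radius_mm = 1) {
  if (inherits(ps, "ps_trajectories")) ps <- ps$points
  if (!nrow(ps)) stopf("no PS points to ablate")
  ps <- ps[order(ps$t), , drop = FALSE]
  r_nodes <- lesion_radius_mm / dx_mm
  target <- fraction * nx * ny
  mask <- matrix(FALSE, ny, nx)
  # precompute disk offsets
  ir <- ceiling(r_nodes)
  off <- expand.grid(dr = -ir:ir, dc = -ir:ir)
  off <- off[off$dr^2 + off$dc^2 <= r_nodes^2, ]
  for (i in seq_len(nrow(ps))) {
    pr <- round(ps$y[i]); pc <- round(ps$x[i])
    if (pr >= 1 && pr <= ny && pc >= 1 && pc <= nx && mask[pr, pc]) next
    rr <- pmin(ny, pmax(1, pr + off$dr))
    cc <- pmin(nx, pmax(1, pc + off$dc))
    mask[cbind(rr, cc)] <- TRUE
    if (sum(mask) >= target) break
  }
  new_ablation_plan(mask, "PS", fraction, dx_mm,
                    flagged = sum(mask) < target ||
                      (nrow(ps) >= 1 && sum(mask) > target &&
                         sum(mask) <= nrow(off)))
}

#' Apply an ablation plan to a tissue grid
#'
#' Adds the plan's lesion to the grid mask.  During simulation lesion nodes
#' are permanently held at the resting potential (conduction block by
#' resting-value clamp); lesions are monotone - applying several plans takes
#' their union.
#'
#' @param grid `tissue_grid`.
#' @param plan `ablation_plan`.
#' @return updated `tissue_grid`.
#' @export
apply_ablation <- function(grid, plan) {
  if (!all(dim(plan$mask) == dim(grid$lesion))) stopf("plan is on a different grid")
  grid$lesion <- grid$lesion | plan$mask
  grid
}

#' Classify the post-ablation outcome
#'
#' Over the post-ablation movie: AF is *terminated* when no node exceeds
#' -40 mV for 500 ms (event time = start of the quiescent interval); the
#' rhythm is *AT-converted* when activity persists but global activation is
#' periodic - coefficient of variation of the activation cycle length below
#' 5% over the last 10 beats at sentinel nodes; otherwise AF is *sustained*.
#' Optionally computes the time courses of the four wave-dynamics areas
#' (PS count, DF > 7 Hz, ShEn > 7, CFAE-CL < 100 ms) in sliding windows.
#'
#' @param movie post-ablation `voltage_movie` (absolute time axis).
#' @param ablation_time time ablation was applied (ms).
#' @param lesion optional ny x nx lesion mask excluded from the activity test.
#' @param activity_thresh activation threshold (mV).
#' @param quiet_ms quiescence needed to call termination (ms).
#' @param cl_cv_max maximal CV of cycle length for AT (fraction).
#' @param time_courses compute windowed area time courses (costly).
#' @param window_ms,hop_ms sliding-window geometry for the time courses.
#' @return list of class `outcome_report`: `outcome` ("AF-terminated",
#'   "AT-converted", "AF-sustained" or "indeterminate"), `event_time`,
#'   `post_cl` (mean cycle length, AT only), optional `time_courses`.
#' @export
classify_outcome <- function(movie, ablation_time, lesion = NULL,
                             activity_thresh = -40, quiet_ms = 500,
                             cl_cv_max = 0.05, time_courses = FALSE,
                             window_ms = 6000, hop_ms = 1000) {
  post <- movie_window(movie, ablation_time, Inf)
  keep <- if (is.null(lesion)) seq_len(post$nx * post$ny) else which(!t(lesion))
  vmax <- apply(post$v[keep, , drop = FALSE], 2, max)
  active <- vmax > activity_thresh
  outcome <- NULL; event_time <- NA_real_; post_cl <- NA_real_
  # termination: sustained quiescence to the end of the movie
  rle_q <- rle(!active)
  if (length(rle_q$lengths)) {
    ends <- cumsum(rle_q$lengths)
    starts <- ends - rle_q$lengths + 1
    qi <- which(rle_q$values & rle_q$lengths * post$dt >= quiet_ms &
                  ends == length(active))
    if (length(qi)) {
      outcome <- "AF-terminated"
      event_time <- post$t[starts[qi[1]]]
    }
  }
  if (is.null(outcome)) {
    if (diff(range(post$t)) < 2000) {
      outcome <- "indeterminate"
    } else {
      # sentinel-node activation cycle lengths
      sent <- sentinel_nodes(post, lesion)
      cls <- lapply(sent, function(j) {
        v <- post$v[j, ]
        up <- which(diff(v > activity_thresh) == 1)
        tt <- post$t[up]
        if (length(tt) > 1) diff(tt) else numeric(0)
      })
      cls <- lapply(cls, function(d) d[d > 50])   # refractory guard
      enough <- vapply(cls, length, integer(1)) >= 10
      if (any(enough)) {
        cv <- vapply(cls[enough], function(d) {
          d <- tail(d, 10); stats::sd(d) / mean(d)
        }, numeric(1))
        if (all(cv < cl_cv_max)) {
          outcome <- "AT-converted"
          post_cl <- mean(unlist(lapply(cls[enough], tail, 10)))
          event_time <- ablation_time
        }
      }
      if (is.null(outcome)) outcome <- "AF-sustained"
    }
  }
  tc <- NULL
  if (time_courses) tc <- area_time_courses(movie, lesion, window_ms, hop_ms)
  structure(list(outcome = outcome, event_time = event_time,
                 post_cl = post_cl, ablation_time = ablation_time,
                 time_courses = tc),
            class = "outcome_report")
}

# a few activity sentinel nodes spread over non-lesion tissue
sentinel_nodes <- function(movie, lesion = NULL) {
  rows <- round(movie$ny * c(0.25, 0.25, 0.5, 0.75, 0.75))
  cols <- round(movie$nx * c(0.25, 0.75, 0.5, 0.25, 0.75))
  idx <- node_index(pmax(1, rows), pmax(1, cols), movie$nx)
  if (!is.null(lesion)) {
    les <- frame_to_col(lesion)
    idx <- idx[!les[idx]]
  }
  as.list(unique(idx))
}

#' Windowed time courses of the wave-dynamics areas
#'
#' For each sliding window: number of detected PS points per frame
#' (averaged), and the node fractions with DF > 7 Hz, ShEn > 7 and
#' CFAE-CL < 100 ms.
#'
#' @param movie `voltage_movie`.
#' @param lesion optional lesion mask (excluded nodes).
#' @param window_ms,hop_ms window length and hop.
#' @param egm_spacing_mm tile pitch for the ShEn/CFAE grids.
#' @return data.frame with window start time and the four measures.
#' @export
area_time_courses <- function(movie, lesion = NULL, window_ms = 6000,
                              hop_ms = 1000, egm_spacing_mm = 5) {
  t0s <- seq(min(movie$t), max(movie$t) - window_ms, by = hop_ms)
  if (!length(t0s)) return(NULL)
  les <- if (is.null(lesion)) NULL else frame_to_col(lesion)
  out <- lapply(t0s, function(t0) {
    mw <- movie_window(movie, t0, t0 + window_ms)
    ph <- phase_movie(mw)
    ps <- detect_ps_all(ph)
    dfm <- dominant_frequency_map(mw, window = window_ms)
    eg <- egm_grid(mw, spacing_mm = egm_spacing_mm)
    shm <- shannon_entropy_map(eg)
    cfm <- cfae_map(eg, window = window_ms)
    denom <- if (is.null(les)) movie$nx * movie$ny else sum(!les)
    frac <- function(m, f) {
      v <- frame_to_col(m$values)
      if (!is.null(les)) v <- v[!les]
      sum(f(v), na.rm = TRUE) / denom
    }
    data.frame(t = t0,
               ps_per_frame = nrow(ps) / length(ph$t),
               df_gt7 = frac(dfm, function(v) v > 7),
               shen_gt7 = frac(shm, function(v) v > 7),
               cfae_lt100 = frac(cfm, function(v) v < 100))
  })
  do.call(rbind, out)
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("outcome: %s", x$outcome))
  if (!is.na(x$event_time)) cat(sprintf(" (event at %.0f ms)", x$event_time))
  if (!is.na(x$post_cl)) cat(sprintf(", post-ablation CL %.0f ms", x$post_cl))
  cat("\n")
  invisible(x)
}
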