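#' Phase movie from a voltage movie
#'
#' Analytic-signal (quadrature) phase of the de-meaned action potential at
#' every node: the Hilbert transform supplies the quadrature component and
#' the phase is atan2(H(V - Vbar), V - Vbar).  Nodes whose AP dynamic range
#' over the window is below `min_range` are flagged undefined.
#'
#' @param movie `voltage_movie` (>= 2 s recommended).
#' @param min_range minimum peak-to-peak range (mV) for a defined phase.
#' @return list of class `phase_movie`: `phase` (nnode x nt, radians in
#'   (-pi, pi], NA rows where undefined), `defined`, grid fields.
#' @export
phase_movie <- function(movie, min_range = 5) {
  nt <- length(movie$t)
  nn <- nrow(movie$v)
  # analytic signal via FFT: zero negative frequencies, double positives;
  # nodes are processed in chunks to bound memory on large grids
  h <- numeric(nt)
  if (nt %% 2 == 0) {
    h[1] <- 1; h[nt / 2 + 1] <- 1; h[2:(nt / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((nt + 1) / 2)] <- 2
  }
  ph <- matrix(NA_real_, nn, nt)
  defined <- logical(nn)
  chunk <- 256L
  i <- 1L
  while (i <= nn) {
    j <- min(i + chunk - 1L, nn)
    x <- t(movie$v[i:j, , drop = FALSE])          # nt x chunk
    rng <- apply(x, 2, function(v) diff(range(v)))
    xm <- x - rep(colMeans(x), each = nt)
    X <- stats::mvfft(xm) * h
    an <- stats::mvfft(X, inverse = TRUE) / nt
    pc <- atan2(Im(an), Re(an))
    ok <- rng >= min_range
    pc[, !ok] <- NA_real_
    ph[i:j, ] <- t(pc)
    defined[i:j] <- ok
    i <- j + 1L
  }
  structure(list(phase = ph, t = movie$t, dt = movie$dt, nx = movie$nx,
                 ny = movie$ny, dx_mm = movie$dx_mm, defined = defined),
            class = "phase_movie")
}

#' @export
print.phase_movie <- function(x, ...) {
  cat(sprintf("phase_movie: %d x %d nodes, %d frames, %d undefined nodes\n",
              x$ny, x$nx, length(x$t), sum(!x$defined)))
  invisible(x)
}

# topological-charge detection on one phase frame (ny x nx matrix).
# Returns data.frame(x, y, charge) with plaquette-center coordinates
# (x = col + 0.5, y = row + 0.5 in node units).
detect_ps_frame <- function(pf) {
  ny <- nrow(pf); nx <- ncol(pf)
  p00 <- pf[-ny, -nx]; p01 <- pf[-ny, -1]; p11 <- pf[-1, -1]; p10 <- pf[-1, -nx]
  w <- wrap_phase(p01 - p00) + wrap_phase(p11 - p01) +
       wrap_phase(p10 - p11) + wrap_phase(p00 - p10)
  hit <- which(!is.na(w) & abs(w) > pi)    # winding is 0 or +/- 2pi
  if (!length(hit)) return(data.frame(x = numeric(0), y = numeric(0),
                                      charge = integer(0)))
  rr <- ((hit - 1) %% (ny - 1)) + 1
  cc <- ((hit - 1) %/% (ny - 1)) + 1
  data.frame(x = cc + 0.5, y = rr + 0.5,
             charge = as.integer(sign(w[hit])))
}

#' Phase singularities in one frame
#'
#' Iyer-Gray topological-charge detection: the wrapped phase differences are
#' summed around every 2x2 node plaquette; a winding of +/- 2pi marks a
#' phase singularity at the plaquette center with that chirality.
#'
#' @param phase `phase_movie`.
#' @param t time (ms) of the frame to analyze (nearest frame used).
#' @return data.frame with `t`, `x`, `y` (node units), `charge` (+/- 1).
#' @export
detect_ps <- function(phase, t) {
  k <- which.min(abs(phase$t - t))
  d <- detect_ps_frame(as_frame(phase$phase[, k], phase$nx, phase$ny))
  if (nrow(d)) cbind(t = phase$t[k], d)
  else data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                  charge = integer(0))
}

#' Phase singularities in every frame
#' @param phase `phase_movie`.
#' @return data.frame with `t`, `x`, `y`, `charge` over all frames.
#' @export
detect_ps_all <- function(phase) {
  out <- vector("list", length(phase$t))
  for (k in seq_along(phase$t)) {
    d <- detect_ps_frame(as_frame(phase$phase[, k], phase$nx, phase$ny))
    if (nrow(d)) out[[k]] <- cbind(t = phase$t[k], d)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                               charge = integer(0))
  else res
}

#' Track phase singularities into trajectories
#'
#' Greedy nearest-neighbour linkage of same-charge PS points across
#' consecutive frames within a gate distance; unmatched points start or end
#' trajectories.  A singularity missing for one frame (or reappearing beyond
#' the gate) starts a new trajectory.
#'
#' @param ps data.frame from [detect_ps_all()] (columns t, x, y, charge; x, y
#'   in node units).
#' @param dx_mm node spacing (mm), used to express the gate.
#' @param gate_mm maximum tip displacement per frame (mm), default 2.
#' @return list of class `ps_trajectories`: `points` (t, x, y, charge, traj),
#'   `trajectories` (traj, charge, birth, death, duration, n).
#' @export
track_ps <- function(ps, dx_mm, gate_mm = 2) {
  gate <- gate_mm / dx_mm
  ps <- ps[order(ps$t), , drop = FALSE]
  ps$traj <- NA_integer_
  frames <- unique(ps$t)
  next_id <- 1L
  # active trajectories from the previous frame: id, x, y, charge
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    charge = integer(0))
  for (ft in frames) {
    idx <- which(ps$t == ft)
    cur <- ps[idx, ]
    assigned <- rep(FALSE, nrow(cur))
    used <- rep(FALSE, nrow(act))
    if (nrow(act) && nrow(cur)) {
      dmat <- outer(act$x, cur$x, "-")^2 + outer(act$y, cur$y, "-")^2
      dmat[outer(act$charge, cur$charge, "!=")] <- Inf
      dmat[dmat > gate^2] <- Inf
      repeat {
        m <- which.min(dmat)
        if (!length(m) || !is.finite(dmat[m])) break
        ai <- (m - 1) %% nrow(act) + 1
        ci <- (m - 1) %/% nrow(act) + 1
        ps$traj[idx[ci]] <- act$id[ai]
        assigned[ci] <- TRUE; used[ai] <- TRUE
        dmat[ai, ] <- Inf; dmat[, ci] <- Inf
      }
    }
    for (ci in which(!assigned)) {
      ps$traj[idx[ci]] <- next_id
      next_id <- next_id + 1L
    }
    act <- data.frame(id = ps$traj[idx], x = cur$x, y = cur$y,
                      charge = cur$charge)
  }
  tr <- do.call(rbind, lapply(split(ps, ps$traj), function(d) {
    data.frame(traj = d$traj[1], charge = d$charge[1], birth = min(d$t),
               death = max(d$t), duration = max(d$t) - min(d$t), n = nrow(d))
  }))
  tr <- tr[order(tr$traj), , drop = FALSE]
  rownames(tr) <- NULL
  structure(list(points = ps, trajectories = tr, dx_mm = dx_mm,
                 gate_mm = gate_mm),
            class = "ps_trajectories")
}

#' @export
print.ps_trajectories <- function(x, ...) {
  cat(sprintf("ps_trajectories: %d points in %d trajectories; longest %.0f ms\n",
              nrow(x$points), nrow(x$trajectories),
              if (nrow(x$trajectories)) max(x$trajectories$duration) else 0))
  invisible(x)
}

#' Smallest enclosing circle of a 2D point set
#'
#' Exact minimal enclosing circle (Welzl-type randomized incremental
#' construction).
#'
#' @param x,y point coordinates.
#' @return list with `center` (c(x, y)) and `radius`.
#' @export
min_enclosing_circle <- function(x, y) {
  n <- length(x)
  if (n == 0) stopf("no points")
  if (n == 1) return(list(center = c(x, y), radius = 0))
  # deterministic low-discrepancy scramble (keeps expected-linear behaviour
  # without touching the global RNG state)
  perm <- order((seq_len(n) * 0.6180339887498949) %% 1)
  pts <- cbind(x, y)[perm, , drop = FALSE]
  inside <- function(c, r, p) sum((p - c)^2) <= r^2 * (1 + 1e-12) + 1e-12
  circ2 <- function(p, q) list(center = (p + q) / 2,
                               radius = sqrt(sum((p - q)^2)) / 2)
  circ3 <- function(p, q, r) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {
      # collinear: use the two farthest points
      cc <- list(circ2(p, q), circ2(p, r), circ2(q, r))
      cc[[which.max(vapply(cc, `[[`, numeric(1), "radius"))]]
    } else {
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
    }
  }
  dimnames(pts) <- NULL
  cc <- circ2(pts[1, ], pts[2, ])
  for (i in 3:n) {
    p <- pts[i, ]
    if (inside(cc$center, cc$radius, p)) next
    cc <- circ2(pts[1, ], p)
    for (j in 2:(i - 1)) {
      q <- pts[j, ]
      if (inside(cc$center, cc$radius, q)) next
      cc <- circ2(p, q)
      for (k in seq_len(j - 1)) {
        r <- pts[k, ]
        if (inside(cc$center, cc$radius, r)) next
        cc <- circ3(p, q, r)
      }
    }
  }
  list(center = unname(cc$center), radius = unname(cc$radius))
}

#' Classify a tracked rotor against the mother-rotor definition
#'
#' A trajectory qualifies as a mother rotor when (i) its tip remains within a
#' circle of diameter half the paced wavelength (smallest enclosing circle of
#' the tip points), (ii) it lasts longer than 5 s, and (iii) peripheral wave
#' breakup is observed, operationalized as at least one PS trajectory birth
#' outside the rotor area during the rotor's lifetime.  The rotor area is the
#' circle centered on the mean of the tip points with radius the distance to
#' the farthest tip point.
#'
#' @param traj one trajectory: data.frame with t, x, y (node units) - e.g.
#'   the points of one `traj` id from [track_ps()].
#' @param wavelength paced wavelength (mm) from [measure_cv_wavelength()].
#' @param all_ps optional `ps_trajectories` (or its `points`/`trajectories`)
#'   used to find PS births outside the rotor area; `NULL` leaves
#'   `breakup_observed` NA unless supplied via `births`.
#' @param births optional data.frame (t, x, y) of PS birth events.
#' @param dx_mm node spacing (mm).
#' @param min_duration duration threshold (ms), default 5000 (exclusive).
#' @return list of class `mother_rotor`.
#' @export
classify_mother_rotor <- function(traj, wavelength, all_ps = NULL,
                                  births = NULL, dx_mm, min_duration = 5000) {
  if (wavelength <= 0) stopf("wavelength must be positive")
  dur <- max(traj$t) - min(traj$t)
  mec <- min_enclosing_circle(traj$x, traj$y)
  confinement_radius_mm <- mec$radius * dx_mm
  center <- c(mean(traj$x), mean(traj$y))
  radius_mm <- sqrt(max((traj$x - center[1])^2 + (traj$y - center[2])^2)) * dx_mm
  if (is.null(births) && !is.null(all_ps)) {
    pts <- all_ps$points
    tr <- all_ps$trajectories
    own <- unique(traj$traj)
    bt <- tr[!(tr$traj %in% own), , drop = FALSE]
    births <- do.call(rbind, lapply(seq_len(nrow(bt)), function(i) {
      d <- pts[pts$traj == bt$traj[i], , drop = FALSE]
      d <- d[which.min(d$t), c("t", "x", "y")]
      d
    }))
    if (is.null(births)) births <- data.frame(t = numeric(0), x = numeric(0),
                                              y = numeric(0))
  }
  breakup <- NA
  if (!is.null(births)) {
    inlife <- births$t >= min(traj$t) & births$t <= max(traj$t)
    dist_mm <- sqrt((births$x - center[1])^2 + (births$y - center[2])^2) * dx_mm
    breakup <- any(inlife & dist_mm > radius_mm)
  }
  confined <- 2 * confinement_radius_mm <= wavelength / 2
  qualifies <- confined && dur > min_duration && isTRUE(breakup)
  structure(list(trajectory = traj, center = center,
                 center_mm = center * dx_mm, radius_mm = radius_mm,
                 confinement_radius_mm = confinement_radius_mm,
                 duration = dur, wavelength = wavelength,
                 confined = confined, breakup_observed = breakup,
                 qualifies = qualifies, dx_mm = dx_mm),
            class = "mother_rotor")
}

#' @export
print.mother_rotor <- function(x, ...) {
  cat(sprintf(paste0("mother_rotor candidate: duration %.0f ms, confinement ",
                     "diameter %.1f mm (lambda/2 = %.1f mm), breakup %s -> %s\n"),
              x$duration, 2 * x$confinement_radius_mm, x$wavelength / 2,
              ifelse(is.na(x$breakup_observed), "unknown",
                     ifelse(x$breakup_observed, "yes", "no")),
              ifelse(x$qualifies, "QUALIFIES", "does not qualify")))
  invisible(x)
}
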