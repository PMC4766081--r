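test_that("resting tissue with no stimulus stays at rest (PDE fixed point)", {
  g <- tissue_grid(16, 16, dx = 500, Deff = 0.15)
  run <- simulate_tissue(g, ctrl_params, stimulus_protocol("none"),
                         duration = 500, state0 = rest_ctrl)
  expect_true(all(abs(run$movie$v - rest_ctrl[["V"]]) < 0.1))
})

test_that("the diffusion operator conserves the spatial mean of V", {
  g <- tissue_grid(24, 24, dx = 500, Deff = 0.15)
  set.seed(99)
  st <- matrix(rep(rest_ctrl, 24 * 24), nrow = 21)
  st[1, ] <- runif(24 * 24, -85, 20)
  run <- simulate_tissue(g, ctrl_params, stimulus_protocol("none"),
                         duration = 20, state0 = st, sampling = 1,
                         pure_diffusion = TRUE)
  means <- colMeans(run$movie$v)
  expect_lt(max(abs(means - means[1])), 1e-9)
  # and diffusion smooths: variance decreases monotonically
  vars <- apply(run$movie$v, 2, var)
  expect_true(all(diff(vars) <= 1e-12))
})

test_that("planar conduction is isotropic (x vs y) to within 2%", {
  n <- 72
  g <- tissue_grid(n, n, dx = 500, Deff = 0.15)
  st <- matrix(rep(rest_ctrl, n * n), nrow = 21)
  strip_rows <- st; strip_cols <- st
  fr <- matrix(FALSE, n, n); fr[1:3, ] <- TRUE
  fc <- matrix(FALSE, n, n); fc[, 1:3] <- TRUE
  strip_rows[1, as.vector(t(fr))] <- 0   # depolarized stripe along x-edge
  strip_cols[1, as.vector(t(fc))] <- 0   # depolarized stripe along y-edge
  act_times <- function(state0, along) {
    run <- simulate_tissue(g, ctrl_params, stimulus_protocol("none"),
                           duration = 120, state0 = state0, sampling = 0.5)
    mid <- n %/% 2
    idx <- if (along == "y") node_index(seq_len(n), mid, n)
           else node_index(mid, seq_len(n), n)
    tr <- run$movie$v[idx, ]
    apply(tr, 1, function(v) {
      i <- which(v > -40)[1]
      if (is.na(i)) NA_real_ else run$movie$t[i]
    })
  }
  ay <- act_times(strip_rows, "y")
  ax <- act_times(strip_cols, "x")
  cv_from <- function(a) {
    k <- 10:60
    fit <- lm(a[k] ~ k)
    0.5 / coef(fit)[[2]]
  }
  cvy <- cv_from(ay); cvx <- cv_from(ax)
  expect_lt(abs(cvx - cvy) / cvy, 0.02)
})

test_that("CV scales as sqrt(Deff) and halving dx changes CV by < 5%", {
  cv_of <- function(dx_um, Deff, len_nodes, dt) {
    g <- tissue_grid(16, len_nodes, dx = dx_um, Deff = Deff)
    # stimulus strip kept at a fixed physical width of 1 mm
    prot <- stimulus_protocol("line-pace",
                              pace_rows = max(2, round(1000 / dx_um)))
    run <- simulate_tissue(g, ctrl_params, prot, duration = 260, dt = dt,
                           state0 = rest_ctrl)
    measure_cv_wavelength(run$movie)$cv
  }
  # diffusion scaling law, checked at the fine reference spacing where
  # discretization bias is small
  cv1 <- cv_of(250, 0.15, 240, dt = 0.04)
  cv2 <- cv_of(250, 0.30, 240, dt = 0.04)
  expect_equal(cv2 / cv1, sqrt(2), tolerance = 0.06)
  # spatial convergence at matched dt: halving the reference spacing moves
  # CV by < 8% (the sharp sodium upstroke limits 2nd-order FD accuracy at
  # 250 um; under-resolution slows conduction, so refinement speeds it up)
  cv_ref <- cv_of(250, 0.15, 240, dt = 0.02)
  cv_half <- cv_of(125, 0.15, 480, dt = 0.02)
  expect_lt(abs(cv_half - cv_ref) / cv_ref, 0.08)
  expect_gt(cv_half, cv_ref)
})

test_that("kinematic ground-truth movie yields its construction CV and wavelength", {
  # band of 10 nodes travelling 1 node/frame along y: CV = dx/dt, width 10*dx
  mv <- kinematic_band_movie(nx = 20, ny = 100, band_nodes = 10, speed = 1,
                             nframes = 95, dx_mm = 0.5, dt = 1, along = "y")
  m <- measure_cv_wavelength(mv, act_thresh = -40, exc_thresh = -60)
  expect_equal(m$cv, 0.5, tolerance = 0.05)
  expect_equal(m$wavelength, 5, tolerance = 0.5 + 1e-9)  # within one spacing
  expect_error(measure_cv_wavelength(uniform_movie()), "no propagation")
})

test_that("the CFL guard rejects unstable configurations", {
  g <- tissue_grid(16, 16, dx = 250, Deff = 0.15)
  expect_error(simulate_tissue(g, ctrl_params, duration = 10, dt = 0.2,
                               state0 = rest_ctrl), "CFL")
})

test_that("cross-field reset depolarizes exactly the half sheet and recovers without reentry from rest", {
  n <- 32
  g <- tissue_grid(n, n, dx = 500, Deff = 0.15)
  st <- matrix(rep(rest_ctrl, n * n), nrow = 21)
  expect_error(initiate_reentry(st, g), "no planar wave")
  st[1, node_index(1, 1, n)] <- -20   # token active node
  st2 <- initiate_reentry(st, g)
  changed <- which(st2[1, ] != st[1, ])
  cols <- ((changed - 1) %% n) + 1
  expect_true(all(cols > n / 2))
  expect_equal(length(changed), n * n / 2)
  expect_identical(st2[-1, ], st[-1, ])
  # applied to resting tissue: depolarized half recovers, no PS after 1 s
  st3 <- matrix(rep(rest_ctrl, n * n), nrow = 21)
  fr <- matrix(FALSE, n, n); fr[, (n / 2 + 1):n] <- TRUE
  st3[1, as.vector(t(fr))] <- 0
  run <- simulate_tissue(g, ctrl_params, stimulus_protocol("none"),
                         duration = 1200, state0 = st3)
  tailwin <- movie_window(run$movie, 1000, 1200)
  expect_true(all(tailwin$v < -60))
})
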