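test_that("analytic-signal phase advances uniformly for a sinusoidal node", {
  t <- seq(0, 1999, by = 1)
  v <- matrix(rep(-70 + 20 * cos(2 * pi * 5 * t / 1000), 4), nrow = 4,
              byrow = TRUE)
  # 2x2 grid, all four nodes sinusoidal; one node constant
  v[4, ] <- -70
  mv <- rotormap:::new_voltage_movie(v, t, 2, 2, 0.5)
  ph <- phase_movie(mv)
  expect_false(ph$defined[4])
  expect_true(all(is.na(ph$phase[4, ])))
  p1 <- ph$phase[1, ]
  dp <- wrap_phase(diff(p1))
  mid <- 200:1800
  expect_equal(mean(dp[mid]), 2 * pi * 5 / 1000, tolerance = 0.02)
  expect_lt(sd(dp[mid]), 0.02)
  # wraps once per 200-ms period
  wraps <- sum(abs(diff(p1[mid])) > pi)
  expect_equal(wraps, 8)
})

test_that("phase reconstruction matches a cosine spiral away from the core", {
  f <- spiral_fixture(nx = 40, ny = 40, frequency_hz = 8, duration_ms = 2000,
                      dt_ms = 2)
  sp <- make_spiral_movie(f)
  # cosine waveform so the analytic phase is the constructed phase itself
  vcos <- -70 + 20 * cos(sp$phase$phase)
  mv <- rotormap:::new_voltage_movie(vcos, sp$movie$t, f$nx, f$ny, f$dx_mm)
  ph <- phase_movie(mv)
  rows <- matrix(seq_len(f$ny), f$ny, f$nx)
  cols <- matrix(seq_len(f$nx), f$ny, f$nx, byrow = TRUE)
  far <- sqrt((rows - f$core_center[1])^2 + (cols - f$core_center[2])^2) > 8
  faridx <- which(as.vector(t(far)))
  mid <- which(mv$t > 300 & mv$t < 1700)
  dphi <- wrap_phase(ph$phase[faridx, mid] - sp$phase$phase[faridx, mid])
  # constant global offset allowed; spread about it must be small
  expect_lt(sqrt(mean((dphi - mean(dphi))^2)), 0.2)
})

test_that("Iyer-Gray detection finds analytic vortices exactly", {
  nx <- 31; ny <- 31
  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  vort <- atan2(rows - 15.2, cols - 16.7)
  d <- detect_ps_frame(vort)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 16.7), 1)
  expect_lt(abs(d$y - 15.2), 1)
  expect_equal(d$charge, 1L)
  dm <- detect_ps_frame(-vort)        # mirrored vortex
  expect_equal(dm$charge, -1L)
  expect_equal(nrow(detect_ps_frame(matrix(0.3, ny, nx))), 0)
})

test_that("net topological charge is conserved frame to frame on fixtures", {
  f <- spiral_fixture(nx = 40, ny = 40, core_path = "circle",
                      meander_radius_mm = 2, duration_ms = 1000, dt_ms = 5)
  sp <- make_spiral_movie(f)
  charges <- vapply(seq_along(sp$phase$t), function(k)
    sum(detect_ps_frame(as_frame(sp$phase$phase[, k], f$nx, f$ny))$charge),
    numeric(1))
  expect_true(all(charges == 1))
})

test_that("tracking links, gates and segments PS streams correctly", {
  # single stationary PS across 100 frames
  st <- make_ps_stream(list(list(t0 = 0, t1 = 99, x = 20, y = 20, vx = 0,
                                 vy = 0, charge = 1)))
  tr <- track_ps(st, dx_mm = 0.5)
  expect_equal(nrow(tr$trajectories), 1)
  expect_equal(tr$trajectories$duration, 99)

  # two parallel same-charge paths farther apart than the gate stay unbroken
  st2 <- make_ps_stream(list(
    list(t0 = 0, t1 = 80, x = 10, y = 10, vx = 0.5, vy = 0, charge = 1),
    list(t0 = 0, t1 = 80, x = 10, y = 30, vx = 0.5, vy = 0, charge = 1)))
  tr2 <- track_ps(st2, dx_mm = 0.5, gate_mm = 2)
  expect_equal(nrow(tr2$trajectories), 2)
  expect_true(all(tr2$trajectories$duration == 80))

  # disappearance and reappearance beyond the gate starts a new trajectory
  st3 <- rbind(data.frame(t = 0:10, x = 5, y = 5, charge = 1L),
               data.frame(t = 12:20, x = 25, y = 5, charge = 1L))
  tr3 <- track_ps(st3, dx_mm = 0.5, gate_mm = 2)
  expect_equal(nrow(tr3$trajectories), 2)

  # opposite charges never link
  st4 <- rbind(data.frame(t = 0:10, x = 5, y = 5, charge = 1L),
               data.frame(t = 11:20, x = 5, y = 5, charge = -1L))
  tr4 <- track_ps(st4, dx_mm = 0.5, gate_mm = 2)
  expect_equal(nrow(tr4$trajectories), 2)
})

test_that("smallest enclosing circle agrees with brute force on random sets", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    x <- runif(n, 0, 40); y <- runif(n, 0, 40)
    a <- min_enclosing_circle(x, y)
    b <- mec_brute(x, y)
    expect_equal(a$radius, b$radius, tolerance = 1e-6)
    expect_true(all((x - a$center[1])^2 + (y - a$center[2])^2 <=
                      a$radius^2 + 1e-6))
  }
  p1 <- min_enclosing_circle(3, 7)
  expect_equal(p1$radius, 0)
})

test_that("mother-rotor classification applies the confinement, duration and breakup rules", {
  dx_mm <- 0.5
  # stationary tip for 6 s with an external PS birth: qualifies at lambda/2 = 20 mm
  tip <- data.frame(t = seq(0, 6000, by = 10), x = 50, y = 50, traj = 1L)
  births_out <- data.frame(t = 3000, x = 90, y = 90)
  m <- classify_mother_rotor(tip, wavelength = 40, births = births_out,
                             dx_mm = dx_mm)
  expect_true(m$confined)
  expect_true(m$breakup_observed)
  expect_true(m$qualifies)

  # identical but 4.9 s: fails the "longer than 5 s" rule
  tip2 <- tip[tip$t <= 4900, ]
  m2 <- classify_mother_rotor(tip2, 40, births = births_out, dx_mm = dx_mm)
  expect_false(m2$qualifies)

  # meander across a circle of diameter 0.6*lambda: fails confinement
  th <- seq(0, 6 * pi, length.out = 601)
  r_nodes <- (0.6 * 40 / 2) / dx_mm      # meander diameter 0.6*lambda
  tip3 <- data.frame(t = seq(0, 6000, by = 10),
                     x = 50 + r_nodes * cos(th), y = 50 + r_nodes * sin(th),
                     traj = 1L)
  m3 <- classify_mother_rotor(tip3, 40, births = births_out, dx_mm = dx_mm)
  expect_false(m3$confined)
  expect_false(m3$qualifies)

  # no external birth (all births inside rotor area): no breakup, no rotor
  m4 <- classify_mother_rotor(tip, 40, births = data.frame(t = 3000, x = 50,
                                                           y = 50),
                              dx_mm = dx_mm)
  expect_false(isTRUE(m4$breakup_observed))
  expect_false(m4$qualifies)

  expect_error(classify_mother_rotor(tip, wavelength = 0, births = births_out,
                                     dx_mm = dx_mm), "wavelength")
})

test_that("classification is monotone in confinement and duration", {
  dx_mm <- 0.5
  births <- data.frame(t = 2500, x = 90, y = 90)
  base <- data.frame(t = seq(0, 5200, by = 10), traj = 1L)
  for (scale in c(1, 0.5, 0.25)) {
    th <- seq(0, 4 * pi, length.out = nrow(base))
    tip <- transform(base, x = 50 + scale * 25 * cos(th),
                     y = 50 + scale * 25 * sin(th))
    m_small <- classify_mother_rotor(tip, 40, births = births, dx_mm = dx_mm)
    # shrinking the meander can only help qualification
    if (scale == 1) expect_false(m_small$qualifies)
    if (scale == 0.25) expect_true(m_small$confined)
  }
  # lengthening duration with fixed confinement never disqualifies
  tipA <- data.frame(t = seq(0, 5100, by = 10), x = 50, y = 50, traj = 1L)
  tipB <- data.frame(t = seq(0, 8000, by = 10), x = 50, y = 50, traj = 1L)
  births2 <- data.frame(t = 2500, x = 90, y = 90)
  mA <- classify_mother_rotor(tipA, 40, births = births2, dx_mm = dx_mm)
  mB <- classify_mother_rotor(tipB, 40, births = births2, dx_mm = dx_mm)
  expect_true(mA$qualifies)
  expect_true(mB$qualifies)
})

test_that("20 randomized spiral fixtures are classified in full agreement with construction", {
  set.seed(1234)
  dx_mm <- 0.5
  wavelength <- 30                     # lambda/2 circle = 15 mm diameter
  for (i in 1:20) {
    stationary <- runif(1) < 0.5
    dur <- sample(c(4200, 5600, 7000), 1)
    meander_mm <- if (stationary) runif(1, 0, 1.5) else runif(1, 8.5, 14)
    f <- spiral_fixture(nx = 60, ny = 60, core_path = "circle",
                        meander_radius_mm = meander_mm,
                        meander_period_ms = 900,
                        duration_ms = dur, dt_ms = 20)
    sp <- make_spiral_movie(f)
    ps <- detect_ps_all(sp$phase)
    tr <- track_ps(ps, dx_mm, gate_mm = 3)
    id <- tr$trajectories$traj[which.max(tr$trajectories$duration)]
    tip <- tr$points[tr$points$traj == id, ]
    births <- data.frame(t = mean(range(tip$t)), x = 58, y = 58)
    m <- classify_mother_rotor(tip, wavelength, births = births, dx_mm = dx_mm)
    # construction truth: tip circle diameter 2*meander vs lambda/2, duration
    truth <- (2 * meander_mm <= wavelength / 2 - 1) && (dur > 5000)
    ambiguous <- abs(2 * meander_mm - wavelength / 2) < 2
    if (!ambiguous) expect_equal(m$qualifies, truth, info = sprintf(
      "fixture %d: meander %.1f mm, dur %d", i, meander_mm, dur))
  }
})
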