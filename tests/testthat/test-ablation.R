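test_that("map-guided plans take the right tail of the right map", {
  set.seed(8)
  v <- matrix(runif(600 * 600, 4, 12), 600, 600)
  dfm <- new_scalar_map(v, "DF", 6000, 0.25)
  plan <- plan_map_ablation(dfm, "DF", 0.05)
  expect_equal(sum(plan$mask), 18000)           # 5% of 360,000
  expect_gte(min(v[plan$mask]), max(v[!plan$mask]))
  # CFAE targets the lowest values and never selects undefined nodes
  v2 <- v; v2[1:50, ] <- NA
  cfm <- new_scalar_map(v2, "CFAE", 6000, 0.25)
  planc <- plan_map_ablation(cfm, "CFAE", 0.05)
  expect_false(any(planc$mask & is.na(v2)))
  expect_lte(max(v2[planc$mask], na.rm = TRUE),
             min(v2[!planc$mask & !is.na(v2)]))
  expect_error(plan_map_ablation(dfm, "DF", 0.9), "fraction")
})

test_that("PS-guided ablation grows 1-mm disks sequentially to the area budget", {
  # single stationary PS: exactly one disk; node count equals the disk oracle
  ps1 <- data.frame(t = 0:100, x = 300, y = 300, charge = 1L)
  plan1 <- plan_ps_ablation(ps1, 600, 600, 0.25, fraction = 0.05)
  disk_oracle <- sum(outer((-4):4, (-4):4,
                           function(a, b) a^2 + b^2) <= 16)
  expect_equal(sum(plan1$mask), disk_oracle)
  expect_equal(plan1$achieved_fraction, disk_oracle / 360000)
  expect_true(plan1$flagged)                     # stream exhausted early
  expect_equal(plan1$achieved_fraction * 100, 0.0136, tolerance = 0.01)

  # PS points on a line 2.5 mm apart: disjoint disks accumulate
  psl <- data.frame(t = 1:20, x = 50 + 10 * (1:20), y = 100, charge = 1L)
  plan2 <- plan_ps_ablation(psl, 300, 200, 0.25, fraction = 0.01)
  expect_equal(sum(plan2$mask) %% disk_oracle, 0)
  expect_gte(sum(plan2$mask), 0.01 * 300 * 200)

  # target smaller than one disk: exactly one disk, flagged overrun
  plan3 <- plan_ps_ablation(ps1, 600, 600, 0.25, fraction = 49 / 360000 / 2)
  expect_equal(sum(plan3$mask), disk_oracle)
  expect_true(plan3$flagged)

  # points already inside the lesion are skipped
  ps_rep <- data.frame(t = 1:50, x = 300, y = 300, charge = 1L)
  plan4 <- plan_ps_ablation(ps_rep, 600, 600, 0.25, fraction = 0.05)
  expect_equal(sum(plan4$mask), disk_oracle)
})

test_that("applying a plan is idempotent and lesions grow monotonically", {
  g <- tissue_grid(32, 32, dx = 500)
  v <- matrix(seq(0, 1, length.out = 32 * 32), 32, 32)
  m <- new_scalar_map(v, "DF", 6000, 0.5)
  p1 <- plan_map_ablation(m, "DF", 0.05)
  p2 <- plan_map_ablation(m, "ShEn", 0.10)
  g1 <- apply_ablation(g, p1)
  g11 <- apply_ablation(g1, p1)
  expect_identical(g1$lesion, g11$lesion)
  g12 <- apply_ablation(g1, p2)
  expect_true(all(g1$lesion | !g1$lesion & TRUE))
  expect_true(all(!(g1$lesion & !g12$lesion)))   # monotone union
  expect_error(apply_ablation(tissue_grid(16, 16), p1), "different grid")
})

test_that("lesions are clamped to rest forever and block conduction", {
  n <- 48
  lesion <- matrix(FALSE, n, n)
  lesion[22:26, ] <- TRUE                       # strip spanning the sheet
  g <- tissue_grid(n, n, dx = 500, Deff = 0.15, lesion = lesion)
  run <- simulate_tissue(g, ctrl_params, stimulus_protocol("line-pace"),
                         duration = 400, state0 = rest_ctrl)
  les_idx <- which(as.vector(t(lesion)))
  expect_true(all(abs(run$movie$v[les_idx, ] -
                        run$movie$v[les_idx[1], 1]) < 1e-9))
  # nothing beyond the strip ever activates (conduction block oracle)
  beyond <- which(as.vector(t(row(lesion) > 26)))
  expect_true(all(run$movie$v[beyond, ] < -40))
  # while the proximal side does activate
  before <- which(as.vector(t(row(lesion) < 20)))
  expect_true(any(run$movie$v[before, ] > 0))
})

test_that("outcome classification separates termination, AT and sustained AF", {
  nx <- 24; ny <- 24; nn <- nx * ny
  t <- 0:7999
  # terminated: activity for 1.2 s then rest
  v1 <- matrix(-80, nn, length(t))
  v1[, t < 1200] <- ifelse(matrix(rep((t[t < 1200] %% 150) < 50, each = nn),
                                  nn), 10, -80)
  mv1 <- rotormap:::new_voltage_movie(v1, t, nx, ny, 0.5)
  o1 <- classify_outcome(mv1, ablation_time = 0)
  expect_equal(o1$outcome, "AF-terminated")
  # last activation window is t in [1050, 1100); quiescence starts at 1100
  expect_lt(abs(o1$event_time - 1100), 10)

  # AT: strictly periodic global activation, CL 250 ms
  phase_lag <- outer(seq_len(nn), rep(1, length(t))) * 0
  v2 <- matrix(rep(ifelse((t %% 250) < 80, 5, -80), each = nn), nn)
  mv2 <- rotormap:::new_voltage_movie(v2, t, nx, ny, 0.5)
  o2 <- classify_outcome(mv2, ablation_time = 0)
  expect_equal(o2$outcome, "AT-converted")
  expect_equal(o2$post_cl, 250, tolerance = 2)

  # sustained: irregular aperiodic activity throughout
  set.seed(21)
  cl_seq <- cumsum(sample(c(80, 130, 190, 260), 60, TRUE))
  act <- findInterval(t, cl_seq) %% 2 == 0
  v3 <- matrix(rep(ifelse(act, 0, -80), each = nn), nn)
  mv3 <- rotormap:::new_voltage_movie(v3, t, nx, ny, 0.5)
  o3 <- classify_outcome(mv3, ablation_time = 0)
  expect_equal(o3$outcome, "AF-sustained")

  # too-short movie flagged indeterminate
  o4 <- classify_outcome(movie_window(mv3, 0, 1500), ablation_time = 0)
  expect_equal(o4$outcome, "indeterminate")
})
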