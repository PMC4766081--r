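make_signal_movie <- function(fun, nx = 8, ny = 8, dur = 6000, dt = 1) {
  t <- seq(0, dur - dt, by = dt)
  v <- t(matrix(fun(t), length(t), nx * ny))
  rotormap:::new_voltage_movie(v, t, nx, ny, 0.5)
}

test_that("DF finds pure tones, pacing rates and argmax of two-tone spectra", {
  mv <- make_signal_movie(function(t) -70 + 15 * sin(2 * pi * 7 * t / 1000))
  dfm <- dominant_frequency_map(mv, window = 6000)
  expect_true(all(abs(dfm$values - 7) < 0.06))

  # periodic AP train at CL 600 ms -> 1.67 Hz fundamental
  ap <- function(t) ifelse((t %% 600) < 180, 0, -80)
  dfm2 <- dominant_frequency_map(make_signal_movie(ap), window = 6000)
  expect_true(all(abs(dfm2$values - 1000 / 600) < 0.06))

  two <- function(t) -70 + 5 * sin(2 * pi * 5 * t / 1000) +
    9 * sin(2 * pi * 9 * t / 1000)
  dfm3 <- dominant_frequency_map(make_signal_movie(two), window = 6000)
  expect_true(all(abs(dfm3$values - 9) < 0.06))

  expect_error(dominant_frequency_map(mv, window = 1000), "resolution")
  # constant nodes are flagged undefined, never silently zero
  mvc <- uniform_movie(value = -70, nframes = 6000)
  dfc <- dominant_frequency_map(mvc, window = 6000)
  expect_true(all(is.na(dfc$values)))
})

test_that("Shannon entropy has its degenerate and maximal limits and matches brute force", {
  expect_equal(shannon_entropy(rep(3.3, 1000)), 0)
  # samples uniformly filling all N bins -> log2 N
  x <- rep(seq(0.5, 49.5, by = 1), times = 40)
  expect_equal(shannon_entropy(x, bins = 50), log2(50), tolerance = 1e-6)
  # brute-force oracle on a synthetic electrogram
  e <- make_egm(rep(c(100, 180), 20), amplitude_jitter = 0.3, seed = 11)
  s <- e$signal
  lo <- max(mean(s) - 3 * sd(s), min(s)); hi <- min(mean(s) + 3 * sd(s), max(s))
  expect_equal(shannon_entropy(e, bins = 50),
               entropy_brute(s, 50, lo, hi), tolerance = 1e-9)
  # invariance under constant offset and sign flip (generic continuous
  # signal: no probability mass exactly on histogram bin boundaries)
  set.seed(17)
  g <- rnorm(4000)^3
  expect_equal(shannon_entropy(g + 5, bins = 50),
               shannon_entropy(g, bins = 50), tolerance = 1e-9)
  expect_equal(shannon_entropy(-g, bins = 50),
               shannon_entropy(g, bins = 50), tolerance = 1e-9)
})

test_that("CFAE cycle length equals the constructed deflection intervals", {
  e <- make_egm(rep(150, 39))
  expect_equal(as.numeric(cfae_cycle_length(e, window = 6000)), 150,
               tolerance = 1)
  # one deflection per paced beat at CL 600
  e2 <- make_egm(rep(600, 10))
  expect_equal(as.numeric(cfae_cycle_length(e2, window = 6100)), 600,
               tolerance = 1)
  # alternating 100/200-ms intervals: mean interval = 150 (brute-force list mean)
  iv <- rep(c(100, 200), 20)
  e3 <- make_egm(iv)
  expect_equal(as.numeric(cfae_cycle_length(e3, window = 6050)),
               mean(iv), tolerance = 2)
  # flat signal is flagged undefined, not an error
  flat <- structure(list(signal = rep(0, 6000), t = 0:5999, dt = 1),
                    class = "electrogram")
  expect_true(is.na(cfae_cycle_length(flat)))
  # strict periodicity recovered within one sample
  e4 <- make_egm(rep(123, 45))
  expect_lt(abs(as.numeric(cfae_cycle_length(e4, window = max(e4$t))) - 123), 1)
})

test_that("area masks follow threshold and percentile rules with deterministic ties", {
  vals <- matrix(5, 20, 20)
  vals[1:2, ] <- 10                       # 10% of nodes above 9
  m <- new_scalar_map(vals, "DF", 6000, 0.5)
  am <- area_mask(m, "threshold-above", 9)
  expect_equal(sum(am$mask), 40)
  expect_true(all(which(am$mask) %in% which(vals > 9)))

  big <- new_scalar_map(matrix(runif(600 * 600), 600, 600), "DF", 6000, 0.25)
  am5 <- area_mask(big, "upper-percentile", 0.05)
  expect_equal(sum(am5$mask), 18000)
  # selected minimum exceeds every unselected value (order statistic)
  expect_gte(min(big$values[am5$mask]), max(big$values[!am5$mask]))

  # all-equal map: exactly the requested fraction chosen by row-major order
  eq <- new_scalar_map(matrix(1, 40, 40), "ShEn", 6000, 0.5)
  am_eq <- area_mask(eq, "upper-percentile", 0.025)
  expect_equal(sum(am_eq$mask), 40)
  first <- head(order(as.vector(t(!am_eq$mask))), 1)
  expect_true(am_eq$mask[1, 1])           # ties resolved from node 1 onward
  expect_error(area_mask(eq, "upper-percentile", 1.5), "percentile")

  # undefined nodes are never selected
  vna <- matrix(rnorm(400), 20, 20)
  vna[1:5, ] <- NA
  mna <- new_scalar_map(vna, "CFAE", 6000, 0.5)
  am_lo <- area_mask(mna, "lower-percentile", 0.1)
  expect_false(any(am_lo$mask & is.na(vna)))
})

test_that("overlap satisfies its identities and symmetry relation", {
  m <- new_scalar_map(matrix(runif(400), 20, 20), "DF", 6000, 0.5)
  a <- area_mask(m, "upper-percentile", 0.2)
  expect_equal(overlap(a, a)$percent, 100)
  b <- a; b$mask <- !a$mask
  expect_equal(overlap(a, b)$percent, 0)
  # b covers exactly half of a
  h <- a
  ia <- which(a$mask)
  h$mask[] <- FALSE
  h$mask[ia[seq_len(length(ia) / 2)]] <- TRUE
  expect_equal(overlap(a, h)$percent, 50)
  # |a| P(a covered by b) == |b| P(b covered by a) == 100 |a ^ b|
  set.seed(5)
  b2 <- a
  b2$mask <- matrix(runif(400) < 0.3, 20, 20)
  lhs <- sum(a$mask) * overlap(a, b2)$percent
  rhs <- sum(b2$mask) * overlap(b2, a)$percent
  expect_equal(lhs, rhs)
  expect_equal(lhs / 100, sum(a$mask & b2$mask))
  # contingency sums to the node count; empty source flagged undefined
  ov <- overlap(a, b2)
  expect_equal(sum(ov$counts), 400)
  empty <- a; empty$mask[] <- FALSE
  expect_true(is.na(overlap(empty, b2)$percent))
})

test_that("DF of a periodically paced movie returns the pacing rate at excited nodes", {
  # property over several pacing rates
  for (cl in c(400, 250, 125)) {
    ap <- function(t) ifelse((t %% cl) < 0.3 * cl, 10, -80)
    dfm <- dominant_frequency_map(make_signal_movie(ap), window = 6000)
    expect_true(all(abs(dfm$values - 1000 / cl) < 0.1),
                info = sprintf("CL %d", cl))
  }
})
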