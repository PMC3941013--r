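# Hexagon eccentricity and angles against a brute-force oracle, their
# invariances, and the Mann-Whitney comparison.

stretched_hexagon <- function(a = 1.2, r = 1) {
  th <- (0:5) * pi / 3
  cbind(a * r * cos(th), r * sin(th))
}

test_that("regular hexagons give E = 1 and 120-degree angles everywhere", {
  v <- stretched_hexagon(a = 1, r = 2.5)
  m <- hexagon_metrics(v)
  expect_equal(m$E, 1)
  expect_equal(m$angles, rep(120, 6))
  expect_true(m$convex)
})

test_that("the stretched hexagon matches the brute-force oracle", {
  v <- stretched_hexagon(1.2)
  m <- hexagon_metrics(v)
  o <- oracle_hexagon(v)
  expect_equal(m$E, o$E)
  expect_equal(m$D_max, 2.4)
  expect_equal(m$d_min, o$d_min)
  expect_equal(round(m$E, 3), 1.139)
  expect_equal(round(m$angles, 2),
               c(110.57, 124.72, 124.72, 110.57, 124.72, 124.72))
  expect_equal(sum(m$angles), 720)
})

test_that("random noisy hexagons agree with the oracle and sum to 720 deg", {
  set.seed(31)
  for (i in 1:25) {
    v <- stretched_hexagon(a = 1 + runif(1, 0, 0.3)) +
      matrix(rnorm(12, 0, 0.05), 6, 2)
    m <- hexagon_metrics(v)
    o <- oracle_hexagon(v)
    expect_equal(m$E, o$E)
    expect_equal(m$angles, o$angles)
    if (m$convex) expect_equal(sum(m$angles), 720, tolerance = 1e-6)
  }
})

test_that("E and angles are invariant to rigid motion and uniform scale", {
  v <- stretched_hexagon(1.15)
  m0 <- hexagon_metrics(v)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  v2 <- 3.2 * v %*% R + matrix(c(5, -2), 6, 2, byrow = TRUE)
  m2 <- hexagon_metrics(v2)
  expect_equal(m2$E, m0$E)
  expect_equal(m2$angles, m0$angles)
  # and to an arbitrary 3-D embedding (rotation out of the xy plane)
  v3 <- cbind(v, 0) %*% t(cbind(c(1, 0, 0), c(0, cos(1), sin(1)),
                                c(0, -sin(1), cos(1)))) + 7
  expect_equal(hexagon_metrics(v3)$E, m0$E)
})

test_that("degenerate hexagons are rejected", {
  v <- stretched_hexagon(1)
  v[2, ] <- v[1, ]
  expect_error(hexagon_metrics(v), "coincident")
})

test_that("eccentricity series aggregates per frame or pooled", {
  tr <- gen_hex_traj(hex_synth_spec(n_frames = 50, residues = 2:14, a = 1.2,
                                    noise_sd = 0, seed = 1))
  es <- eccentricity_series(tr)
  expect_equal(dim(es$E), c(50, 13))
  expect_equal(es$mean, hex_eccentricity_aniso(1.2))
  expect_equal(es$sem, 0)
  expect_equal(es$n, 50)
  pooled <- eccentricity_series(tr, aggregate = "pooled")
  expect_equal(pooled$n, 650)
  expect_equal(pooled$mean, es$mean)
  expect_error(eccentricity_series(tr, residues = 99), "not present")
  expect_error(eccentricity_series(tr, frames = integer(0)), "empty")
})

test_that("frame selection takes n equally spaced frames from the last t ns", {
  tr <- gen_hex_traj(hex_synth_spec(n_frames = 200, residues = 5,
                                    dt_frame = 0.18, seed = 1))
  idx <- frames_last(tr, last_ns = 18, n = 100)
  expect_length(idx, 100)
  expect_true(all(tr$time[idx] >= max(tr$time) - 18))
  expect_error(frames_last(tr, last_ns = 1, n = 100), "only")
})

test_that("anisotropy is recovered from noisy trajectories across seeds", {
  # 20 seeds at a = 1.05, noise 0.03 nm; reference = one long run at the
  # same settings. Noise biases E upward, so the reference shares it.
  seed_means <- sapply(1:20, function(s)
    eccentricity_series(gen_hex_traj(hex_synth_spec(
      n_frames = 100, residues = 2:14, a = 1.05, noise_sd = 0.03,
      seed = s)))$mean)
  ref <- eccentricity_series(gen_hex_traj(hex_synth_spec(
    n_frames = 2000, residues = 2:14, a = 1.05, noise_sd = 0.03,
    seed = 999)))
  se <- sqrt(var(seed_means) / 20 + ref$sem^2)
  expect_lt(abs(mean(seed_means) - ref$mean), 2 * se)
  # and the noiseless trajectory hits the analytic value exactly
  e0 <- eccentricity_series(gen_hex_traj(hex_synth_spec(
    n_frames = 5, residues = 2:14, a = 1.05, noise_sd = 0, seed = 1)))$mean
  expect_equal(e0, hex_eccentricity_aniso(1.05))
})

test_that("angle series are constant for rigid frames", {
  tr <- gen_hex_traj(hex_synth_spec(n_frames = 10, residues = 5, a = 1.2,
                                    noise_sd = 0, seed = 1))
  ang <- angle_series(tr, 5)
  expect_equal(dim(ang), c(10, 6))
  expect_equal(ang[3, ], oracle_hexagon(stretched_hexagon(1.2))$angles)
  expect_true(all(abs(rowSums(ang) - 720) < 1e-6))
})

test_that("Mann-Whitney: exact enumeration, symmetry, and the normal limit", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  o <- oracle_mwu_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$U, o$U)
  expect_equal(r$p, o$p)
  expect_identical(r$method, "exact")
  # swapping samples maps U -> n1 n2 - U and keeps the two-sided p
  r2 <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$U, 9)
  expect_equal(r2$p, r$p)
  # random small samples match the enumeration oracle
  set.seed(17)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5)
    r3 <- mann_whitney_u(a, b)
    o3 <- oracle_mwu_exact(a, b)
    expect_equal(r3$U, o3$U)
    expect_equal(r3$p, o3$p)
  }
  # identical samples: p at the top of the method's granularity
  expect_gt(mann_whitney_u(c(1, 2), c(1, 2), mode = "normal")$p, 0.9)
  # exact vs normal approximation within 0.02 at n = 20 + 20
  set.seed(23)
  a <- runif(20); b <- runif(20, 0.2, 1.2)
  pe <- mann_whitney_u(a, b, mode = "exact")$p
  pn <- mann_whitney_u(a, b, mode = "normal")$p
  expect_lt(abs(pe - pn), 0.02)
})
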