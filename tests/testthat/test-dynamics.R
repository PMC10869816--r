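fake_trace <- function(x, dt = 1) {
  tr <- data.frame(t = (seq_along(x) - 1) * dt, X = x, Y = 0, Z = 0)
  class(tr) <- c("hr_trace", "data.frame")
  tr
}

test_that("spike detection finds upward threshold crossings", {
  expect_length(detect_spikes(fake_trace(rep(-1.5, 100))), 0)
  saw <- rep(c(seq(-1, 2, length.out = 20), seq(2, -1, length.out = 20)), 5)
  expect_length(detect_spikes(fake_trace(saw, dt = 0.1), min_separation = 0.5), 5)
  # refractory separation drops closely spaced crossings
  xx <- rep(c(-1, 2), 10)
  expect_length(detect_spikes(fake_trace(xx, dt = 0.1), min_separation = 1), 2)
})

test_that("ISI extraction requires increasing times", {
  expect_equal(isi(structure(c(1, 3, 6), class = "spike_train")), c(2, 3))
  expect_error(isi(structure(c(1, 1), class = "spike_train")), "increasing")
})

test_that("period classification counts ISI clusters", {
  expect_equal(classify_period(rep(10, 30))$period, 1L)
  lab2 <- classify_period(rep(c(10, 14), 20))
  expect_equal(lab2$kind, "periodic")
  expect_equal(lab2$period, 2L)
  expect_error(classify_period(rep(10, 5)), "insufficient")
  # aperiodic ISIs spread over a wide range are chaotic
  set.seed(9)
  expect_equal(classify_period(exp(runif(60, 2, 4)))$kind, "chaotic")
})

test_that("classification is invariant to cyclic rotation and time rescaling", {
  base <- rep(c(8, 11, 25), 15)
  expect_equal(classify_period(base)$period, 3L)
  for (k in c(1, 2)) {
    rot <- c(base[-seq_len(k)], base[seq_len(k)])
    expect_equal(classify_period(rot)$period, 3L)
    expect_equal(classify_period(rot * 37.5)$period, 3L)
  }
})

test_that("error metrics satisfy their definitions and inequalities", {
  m <- error_metrics(1:10, 1:10 + 0.5)
  expect_equal(m$mae, 0.5)
  expect_equal(m$rmse, 0.5)
  expect_equal(m$corr, 1)
  expect_error(error_metrics(rep(1, 10), 1:10), "zero-variance")
  expect_error(error_metrics(1:5, 1:6), "equal length")
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    m <- error_metrics(a, b)
    expect_gte(m$rmse, m$mae)
    expect_true(m$corr >= -1 && m$corr <= 1)
  }
})

test_that("nullclines evaluate the clamped-plane curves", {
  xy <- hr_nullclines("XY", I = 0.5, clamp = 1, xlim = c(-1, 1), n = 3)
  # at X = 0: X-nullcline Y = Z - I = 0.5, Y-nullcline Y = 1
  expect_equal(xy$x_null[xy$X == 0], 0.5)
  expect_equal(xy$other_null[xy$X == 0], 1)
  xz <- hr_nullclines("XZ", I = 1, clamp = 1, xlim = c(-1, 1), n = 3)
  expect_equal(xz$other_null[xz$X == 0], 6.4)
  expect_equal(xz$x_null[xz$X == 0], 2)   # Y + I at X = 0
})

test_that("CORDIC nullclines track the reference curves within block tolerance", {
  for (plane in c("XY", "XZ")) {
    a <- hr_nullclines(plane, I = 1, model = "reference")
    b <- hr_nullclines(plane, I = 1, model = "cordic")
    expect_lt(max(abs(a$x_null - b$x_null)), 0.06)
    expect_lt(max(abs(a$other_null - b$other_null)), 0.06)
  }
})

test_that("equilibria are the nullcline intersections", {
  # I = 0: X^3 + 2X^2 = 0 has real roots 0 (double) and -2
  eq0 <- find_equilibria("XY", I = 0)
  expect_equal(sort(eq0$X), c(-2, 0))
  # I = 16: single real root X = 2
  eq16 <- find_equilibria("XY", I = 16)
  expect_equal(eq16$X, 2)
  expect_equal(eq16$Y, 1 - 5 * 4)
})

test_that("CORDIC and reference models share equilibrium structure", {
  for (plane in c("XY", "XZ")) {
    a <- find_equilibria(plane, I = 1, model = "reference")
    b <- find_equilibria(plane, I = 1, model = "cordic")
    expect_equal(nrow(a), nrow(b))
    expect_equal(b$X, a$X, tolerance = 0.02)
    expect_equal(b[[2]], a[[2]], tolerance = 0.05)
  }
})

test_that("phase trajectories preserve the trace and recur on periodic orbits", {
  p <- hr_params(I = 3, r = 0.04)
  tr <- simulate_hr(p, 400, "cordic")
  path <- phase_trajectory(tr)
  expect_equal(dim(path), c(nrow(tr), 3L))
  # steady-state orbit closes: a later state returns near the window start
  steady <- path[tr$t >= 200, ]
  start <- steady[1, ]
  d <- sqrt(colSums((t(steady[-(1:500), ]) - start)^2))
  expect_lt(min(d), 0.05)
})

test_that("the fixed-point phase portrait shadows the reference attractor", {
  p <- hr_params(I = 0.5, r = 0.0021)
  a <- simulate_hr(p, 1200, "reference")
  b <- simulate_hr(p, 1200, "cordic")
  keep <- a$t >= 200
  A <- phase_trajectory(a)[keep, ][seq(1, sum(keep), by = 50), ]
  B <- phase_trajectory(b)[keep, ][seq(1, sum(keep), by = 50), ]
  hd <- function(P, Q) max(apply(P, 1, function(pt) min(sqrt(colSums((t(Q) - pt)^2)))))
  expect_lt(max(hd(A, B), hd(B, A)), 0.1)
})

test_that("bifurcation sweeps are deterministic and label both models alike", {
  b1 <- bifurcation_sweep("r", c(0.02, 0.04), hr_params(I = 3), T = 600,
                          model = "cordic")
  b2 <- bifurcation_sweep("r", c(0.02, 0.04), hr_params(I = 3), T = 600,
                          model = "cordic")
  expect_identical(b1$labels, b2$labels)
  expect_identical(b1$isi_sets, b2$isi_sets)
  # the fixed-point and float models agree at the r values of the study
  rv <- c(0.006, 0.007, 0.018, 0.04)
  bc <- bifurcation_sweep("r", rv, hr_params(I = 3), model = "cordic", T = 2000)
  br <- bifurcation_sweep("r", rv, hr_params(I = 3), model = "reference", T = 2000)
  expect_identical(bc$labels$kind, br$labels$kind)
  expect_identical(bc$labels$period, br$labels$period)
})
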