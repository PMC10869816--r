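test_that("the reference Euler step evaluates the vector field", {
  p <- hr_params(I = 0, r = 0, dt = 1 / 256)
  s1 <- hr_reference_step(c(X = 0, Y = 0, Z = 0), p)
  # derivatives at the origin are (0, 1, 0)
  expect_equal(unname(s1), c(0, p$dt, 0))
  # dX/dt at (1,1,1) with I=1: 1 + 1*(3-1) - 1 + 1 = 3
  p2 <- hr_params(I = 1, r = 0.0021)
  s2 <- hr_reference_step(c(X = 1, Y = 1, Z = 1), p2)
  expect_equal(unname(s2["X"]), 1 + p2$dt * 3)
})

test_that("equilibria of the full system are fixed points of the step", {
  I <- 0.7
  # X* solves X^3 + 2X^2 + 4X + 6.4 - 1 - I = 0 with Y* = 1 - 5X*^2,
  # Z* = 4(X* + 1.6)
  rt <- polyroot(c(5.4 - I, 4, 2, 1))
  xs <- Re(rt[abs(Im(rt)) < 1e-9])
  p <- hr_params(I = I, r = 0.0021)
  for (x in xs) {
    s <- c(X = x, Y = 1 - 5 * x^2, Z = 4 * (x + 1.6))
    expect_equal(unname(hr_reference_step(s, p)), unname(s), tolerance = 1e-12)
  }
})

test_that("the fixed-point step vanishes at the origin except for the constants", {
  p <- hr_params(I = 0, r = 0.0021)
  s <- cordic_hr_step(c(X = 0, Y = 0, Z = 0), p)
  expect_equal(unname(s["X"]), 0)
  expect_equal(unname(s["Y"]), p$dt)   # dt = 2^-8 is exactly representable
  # Z' = (6.4 r quantized at 26 fractional bits) >> 8
  z_exp <- floor(round(6.4 * p$r * 2^26) / 2^8) / 2^26
  expect_equal(unname(s["Z"]), z_exp)
})

test_that("one fixed-point step matches the float evaluation of the same update", {
  p <- hr_params(I = 0.5, r = 0.0021)
  s0 <- c(X = 0.1, Y = 1, Z = 0.2)
  got <- cordic_hr_step(s0, p)
  xq <- fp_value(quantize(s0["X"]))    # the POW blocks see the quantized X
  x2 <- xq^2; x3 <- xq^3
  oracle <- c(X = s0[["X"]] + p$dt * (s0[["Y"]] + 3 * x2 - x3 - s0[["Z"]] + p$I),
              Y = s0[["Y"]] + p$dt * (1 - 5 * x2 - s0[["Y"]]),
              Z = s0[["Z"]] + p$dt * p$r * (4 * s0[["X"]] + 6.4 - s0[["Z"]]))
  expect_equal(unname(got), unname(oracle), tolerance = 3 * 2^-10)
})

test_that("simulate returns a uniform trace of the requested length", {
  p <- hr_params()
  tr <- simulate_hr(p, p$dt, "reference")
  expect_equal(nrow(tr), 2L)
  tr2 <- simulate_hr(p, 10, "cordic")
  expect_equal(nrow(tr2), floor(10 / p$dt) + 1)
  expect_equal(diff(tr2$t), rep(p$dt, nrow(tr2) - 1))
  expect_identical(attr(tr2, "model_tag"), "cordic")
  expect_error(simulate_hr(p, -1), "positive")
})

test_that("simulation is deterministic", {
  p <- hr_params(I = 1.5, r = 0.0021)
  a <- simulate_hr(p, 50, "cordic")
  b <- simulate_hr(p, 50, "cordic")
  expect_identical(a$X, b$X)
  expect_identical(a$Z, b$Z)
})

test_that("the fixed-point model converges to the reference as precision grows", {
  hi <- cordic_control(fmt = q_format(25L, 1L, 20L), n_iter = 24L,
                       state_frac_bits = 30L)
  p <- hr_params(I = 0.5, r = 0.0021)
  T <- 1000 * p$dt
  a <- simulate_hr(p, T, "reference")
  b <- simulate_hr(p, T, "cordic", control = hi)
  expect_lt(max(abs(a$X - b$X)), 1e-4)
  expect_lt(max(abs(a$Z - b$Z)), 1e-4)
})

test_that("trajectories stay bounded over long runs", {
  for (I in c(0.5, 2)) {
    tr <- simulate_hr(hr_params(I = I, r = 0.0021), 1e5 / 256, "cordic")
    expect_lt(max(abs(as.matrix(tr[, c("X", "Y", "Z")]))), 16)
  }
})

test_that("spiking regimes match the stimulation current", {
  n_low <- length(detect_spikes(simulate_hr(hr_params(I = 0.5, r = 0.0021),
                                            1000, "cordic")))
  n_high <- length(detect_spikes(simulate_hr(hr_params(I = 2, r = 0.0021),
                                             1000, "cordic")))
  expect_gt(n_low, 0)
  expect_gt(n_high, n_low)
})

test_that("a power-of-two Euler step is required by the fixed-point datapath", {
  expect_error(simulate_hr(hr_params(dt = 0.005), 1, "cordic"), "power of two")
  expect_silent(simulate_hr(hr_params(dt = 0.005), 1, "reference"))
})
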