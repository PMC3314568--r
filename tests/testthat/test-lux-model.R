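test_that("steady-state LuxR follows n * alphaTet / gammaX", {
  expect_equal(steadyStateLuxR(luxModelParameters(n = 1)), 2.3 / 0.06,
               tolerance = 1e-12)
  expect_equal(steadyStateLuxR(luxModelParameters(n = 0)), 0)
  expect_equal(steadyStateLuxR(luxModelParameters(n = 2)),
               2 * steadyStateLuxR(luxModelParameters(n = 1)))
  expect_error(luxModelParameters(gammaX = 0), "gammaX")
  expect_error(luxModelParameters(gammaX = -0.1), "gammaX")
})

test_that("activated complex has the right limits and monotonicity", {
  p <- luxModelParameters()
  Xss <- steadyStateLuxR(p)
  expect_equal(activatedComplex(553, Xss, p), Xss / 2, tolerance = 1e-12)
  expect_identical(activatedComplex(0, Xss, p), 0)
  expect_equal(activatedComplex(Inf, Xss, p), Xss)
  expect_error(activatedComplex(-1, Xss, p), "invalid input")
  H <- c(0, 10^seq(-2, 4, length.out = 40))
  A <- activatedComplex(H, Xss, p)
  expect_true(all(diff(A) > 0))
  expect_true(all(A <= Xss))
})

test_that("predicted S_cell saturates at n * alphaLux and is monotone in A", {
  p <- luxModelParameters(n = 1, alphaLux = 6.07, KA = 5.13e-4, nA = 0.747)
  expect_equal(predictedScell(p@KA, p), 6.07 / 2, tolerance = 1e-12)
  expect_identical(predictedScell(0, p), 0)
  expect_equal(predictedScell(Inf, p), 6.07)
  expect_error(predictedScell(-1, p), "invalid input")
  A <- 10^seq(-6, 3, length.out = 30)
  expect_true(all(diff(predictedScell(A, p)) > 0))
  # saturating output is exactly linear in n
  for (n in c(0.5, 2, 118.75)) {
    pn <- p; pn@n <- n
    expect_equal(predictedScell(Inf, pn), n * predictedScell(Inf, p),
                 tolerance = 1e-12)
  }
})

test_that("predicted RPU at saturation reproduces the published Vmax", {
  pSC <- luxModelParameters(n = 1, alphaLux = 6.07, KA = 5.13e-4, nA = 0.747)
  expect_equal(predictedRpu(Inf, pSC, scellRef = 0.69), 8.797, tolerance = 1e-3)
  pHC <- luxModelParameters(n = 118.75, alphaLux = 2.11, KA = 3.24e-2,
                            nA = 0.504)
  expect_equal(predictedRpu(Inf, pHC, scellRef = 88.36), 2.835,
               tolerance = 1e-3)
  expect_identical(predictedRpu(0, pSC, scellRef = 0.69), 0)
  expect_error(predictedRpu(1, pSC, scellRef = 0), "invalid reference")
})

test_that("simulated dynamics converge to the closed-form steady state", {
  p <- luxModelParameters(n = 1, alphaLux = 6.07, KA = 5.13e-4, nA = 0.747,
                          mu = log(2) / 86)
  traj <- simulateDynamics(p, H = 1000, horizon = 1500, dt = 0.1)
  Xbar <- steadyStateLuxR(p)
  expect_lt(relErr(tail(traj$X, 1), Xbar), 1e-3)
  Abar <- activatedComplex(1000, Xbar, p)
  Sbar <- predictedScell(Abar, p)
  expect_lt(relErr(tail(traj$R, 1), Sbar / p@mu), 1e-3)
  expect_true(all(traj$A <= traj$X + 1e-12))
})

test_that("steady state matches closed form across random parameter sets", {
  set.seed(42)
  for (i in 1:5) {
    p <- luxModelParameters(
      n = runif(1, 0.5, 50), alphaTet = runif(1, 0.5, 5),
      gammaX = runif(1, 0.02, 0.2), KH = runif(1, 100, 1000),
      nH = runif(1, 1, 3), alphaLux = runif(1, 1, 10),
      KA = 10^runif(1, -4, -1), nA = runif(1, 0.4, 1.5),
      mu = runif(1, 0.005, 0.02))
    H <- 10^runif(1, 0, 3)
    horizon <- 20 / min(p@gammaX, p@mu)
    traj <- simulateDynamics(p, H = H, horizon = horizon, dt = 0.5)
    Xbar <- steadyStateLuxR(p)
    Sbar <- predictedScell(activatedComplex(H, Xbar, p), p)
    expect_lt(relErr(tail(traj$X, 1), Xbar), 1e-3)
    expect_lt(relErr(tail(traj$R, 1), Sbar / p@mu), 1e-3)
  }
})

test_that("no-basal convention and growth-free accumulation hold", {
  p <- luxModelParameters(n = 1, alphaLux = 6.07, KA = 5.13e-4, nA = 0.747,
                          mu = 0.01)
  traj0 <- simulateDynamics(p, H = 0, horizon = 100, dt = 0.1)
  expect_true(all(traj0$R == 0))
  expect_true(all(traj0$A == 0))
  p0 <- p; p0@mu <- 0
  traj <- simulateDynamics(p0, H = 1e6, horizon = 2000, dt = 0.1)
  lateSlope <- diff(tail(traj$R, 2)) / diff(tail(traj$time, 2))
  # saturation is asymptotic: A -> Xss leaves a ~2e-4 shortfall from alphaLux
  expect_equal(lateSlope, p0@n * p0@alphaLux, tolerance = 1e-3)
})
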