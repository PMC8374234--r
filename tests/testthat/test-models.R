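test_that("the biphasic UR has its trough and peak at the nominal parameters", {
  ur <- published_human_ur()
  g <- time_grid(-0.7, 1.3, 1e-4)
  w <- eval_ur(ur, g)
  expect_equal(min(w$amplitude_uV), -0.155, tolerance = 1e-6)
  expect_equal(w$time_ms[which.min(w$amplitude_uV)], -0.166,
               tolerance = 2e-4)
  expect_equal(max(w$amplitude_uV), 0.022, tolerance = 1e-6)
  expect_equal(w$time_ms[which.max(w$amplitude_uV)], -0.128 + 0.155,
               tolerance = 2e-4)
  # exactly zero at the phase transition
  at_t0 <- eval_ur(ur, time_grid(ur$t0 - 0.01, ur$t0 + 0.01, 0.01))
  expect_equal(at_t0$amplitude_uV[2], 0)
})

test_that("UR parameter validation rejects non-physical values", {
  expect_error(ur_params(0, 0.04, 0.02, 0.1, -0.1), "u_n")
  expect_error(ur_params(0.1, -0.1, 0.02, 0.1, -0.1), "widths")
  expect_error(ur_params(0.1, 0.04, -0.01, 0.1, -0.1), "u_p")
})

test_that("a vanishing negative phase leaves the waveform near zero past t0", {
  ur <- ur_params(u_n = 1e-12, sigma_n = 0.04, u_p = 0, sigma_p = 0.1,
                  t0 = 0)
  w <- eval_ur(ur, time_grid(-0.5, 0.5, 0.005))
  expect_true(all(abs(w$amplitude_uV[w$time_ms >= 0]) == 0))
  expect_true(all(abs(w$amplitude_uV) <= 1e-12))
})

test_that("the CDLD mixture evaluates to a non-negative sum of Gaussians", {
  # single unit-peak component at the step-one starting values
  one <- cdld_params(alpha = 0.08, mu = 0.38, sigma = 0.06)
  w <- eval_cdld(one, time_grid(0, 1, 0.005))
  expect_equal(max(w$amplitude_uV), 0.08, tolerance = 1e-10)
  expect_equal(w$time_ms[which.max(w$amplitude_uV)], 0.38)

  zero <- cdld_params(alpha = c(0, 0), mu = c(0.3, 0.6),
                      sigma = c(0.05, 0.05))
  expect_true(all(eval_cdld(zero, time_grid(0, 1, 0.01))$amplitude_uV == 0))

  # non-negativity over random parameter draws
  set.seed(42)
  for (i in 1:25) {
    k <- sample(1:4, 1)
    p <- cdld_params(alpha = runif(k, 0, 0.35), mu = runif(k, 0.1, 1.3),
                     sigma = runif(k, 0.01, 0.45))
    expect_true(all(eval_cdld(p, time_grid(-1, 3, 0.01))$amplitude_uV >= 0))
  }
})

test_that("the CDLD integral matches the closed-form Gaussian area", {
  p <- cdld_params(alpha = c(0.12, 0.3), mu = c(0.4, 0.9),
                   sigma = c(0.05, 0.11))
  g <- time_grid(-2, 3.5, 0.001)
  w <- eval_cdld(p, g)
  trapz <- sum((w$amplitude_uV[-1] + w$amplitude_uV[-nrow(w)]) / 2) * 0.001
  closed <- sqrt(2 * pi) * sum(p$components$alpha * p$components$sigma)
  expect_equal(trapz, closed, tolerance = 1e-6)
})

test_that("components are reported sorted by latency, ties by width", {
  p <- cdld_params(alpha = c(0.1, 0.2, 0.3), mu = c(0.9, 0.3, 0.9),
                   sigma = c(0.2, 0.05, 0.1))
  expect_equal(p$components$mu, c(0.3, 0.9, 0.9))
  expect_equal(p$components$sigma, c(0.05, 0.1, 0.2))
})

test_that("the forward model reduces to a shifted UR for a narrow component", {
  # sigma = dt makes the unit-area component a discrete near-delta; the
  # dominant bias is Gaussian smoothing of the UR's slope discontinuity at
  # t0, which scales linearly in dt, so dt must be small for the 2% tolerance
  dt <- 0.001
  ur <- published_human_ur()
  mu <- 0.5
  # unit-area component with sigma = dt approximates a delta at mu
  cdld <- cdld_params(alpha = 1 / (dt * sqrt(2 * pi)), mu = mu, sigma = dt)
  g <- time_grid(-0.5, 2, dt)
  got <- forward_ecap(cdld, ur, g)
  want <- eval_ur(ur, time_grid(-0.5 - mu, 2 - mu, dt))
  peak <- max(abs(want$amplitude_uV))
  expect_lt(max(abs(got$amplitude_uV - want$amplitude_uV)) / peak, 0.02)
})

test_that("sampled convolution matches the closed-form Gaussian convolution", {
  dt <- 0.005
  gauss_wf <- function(mu, sg, id) {
    g <- time_grid(mu - 6 * sg, mu + 6 * sg, dt)
    t <- g$start + (seq_len(g$n) - 1) * dt
    tibble::tibble(waveform_id = id, time_ms = t,
                   amplitude_uV = stats::dnorm(t, mu, sg))
  }
  a <- gauss_wf(0.3, 0.05, "a")
  b <- gauss_wf(0.2, 0.04, "b")
  got <- convolve_sampled(a, b, scale = "dt")
  want <- stats::dnorm(got$time_ms, 0.5, sqrt(0.05^2 + 0.04^2))
  expect_lt(max(abs(got$amplitude_uV - want)), 1e-3)
})

test_that("the forward model is linear in the CDLD", {
  ur <- published_human_ur()
  g <- time_grid(0, 2.2, 0.01)
  c1 <- cdld_params(alpha = 0.1, mu = 0.4, sigma = 0.06)
  c2 <- cdld_params(alpha = 0.2, mu = 0.8, sigma = 0.1)
  mix <- cdld_params(alpha = c(3 * 0.1, 0.5 * 0.2), mu = c(0.4, 0.8),
                     sigma = c(0.06, 0.1))
  lhs <- forward_ecap(mix, ur, g)$amplitude_uV
  rhs <- 3 * forward_ecap(c1, ur, g)$amplitude_uV +
    0.5 * forward_ecap(c2, ur, g)$amplitude_uV
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("amplitude can trade between CDLD and UR without changing the eCAP", {
  # the scale degeneracy that motivates fixing the UR in step two
  g <- time_grid(0, 2.2, 0.01)
  cdld <- cdld_params(alpha = c(0.1, 0.05), mu = c(0.4, 0.8),
                      sigma = c(0.06, 0.1))
  ur <- published_human_ur()
  cc <- 4
  cdld_scaled <- cdld_params(alpha = cc * cdld$components$alpha,
                             mu = cdld$components$mu,
                             sigma = cdld$components$sigma)
  ur_scaled <- ur_params(ur$u_n / cc, ur$sigma_n, ur$u_p / cc, ur$sigma_p,
                         ur$t0)
  a <- forward_ecap(cdld, ur, g)$amplitude_uV
  b <- forward_ecap(cdld_scaled, ur_scaled, g)$amplitude_uV
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("the dt-scaled forward model converges as the grid is refined", {
  ur <- published_human_ur()
  cdld <- cdld_params(alpha = c(0.1, 0.05), mu = c(0.45, 0.8),
                      sigma = c(0.05, 0.1))
  coarse <- forward_ecap(cdld, ur, time_grid(0, 2.2, 0.01))
  fine <- forward_ecap(cdld, ur, time_grid(0, 2.2, 0.005))
  fine_on_coarse <- fine$amplitude_uV[seq(1, nrow(fine), by = 2)]
  peak <- max(abs(fine$amplitude_uV))
  expect_lt(max(abs(coarse$amplitude_uV - fine_on_coarse)) / peak, 0.005)
})

test_that("an all-zero CDLD produces an all-zero eCAP", {
  cdld <- cdld_params(alpha = c(0, 0), mu = c(0.4, 0.8),
                      sigma = c(0.06, 0.1))
  out <- forward_ecap(cdld, published_human_ur(), time_grid(0, 2, 0.01))
  expect_true(all(out$amplitude_uV == 0))
})
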