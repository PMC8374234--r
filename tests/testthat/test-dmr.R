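test_that("default bounds are internally consistent", {
  for (b in list(dmr_bounds_step1(), dmr_bounds_step2(1), dmr_bounds_step2(2),
                 dmr_bounds_step2(6))) {
    expect_true(all(b$lower <= b$start & b$start <= b$upper))
    expect_equal(names(b$lower), names(b$start))
  }
  expect_length(dmr_bounds_step1()$start, 11)
  expect_length(dmr_bounds_step2(3)$start, 9)
})

test_that("step two recovers known parameters from a clean eCAP", {
  ur <- published_human_ur()
  truth <- tibble::tibble(alpha = c(0.12, 0.3), mu = c(0.45, 0.85),
                          sigma = c(0.05, 0.08))
  ecap <- clean_ecap(cdld_params(truth), ur)
  fit <- fit_step_two(ecap, ur)
  expect_true(all(recovery_errors(fit, truth) < 0.01))
  expect_gt(fit$fit_index, 0.999)
  expect_true(fit$converged)
})

test_that("a joint step-one fit reproduces a self-generated eCAP", {
  ur <- step1_start_ur()
  cdld <- cdld_params(alpha = c(0.12, 0.08), mu = c(0.45, 0.75),
                      sigma = c(0.06, 0.1))
  ecap <- clean_ecap(cdld, ur)
  fit <- fit_step_one(ecap)
  expect_gte(fit$fit_index, 0.999)
  # every fitted parameter respects its printed domain
  pars <- tidy(fit)
  expect_true(all(pars$value >= pars$lower & pars$value <= pars$upper))
})

test_that("constant input is refused before any fit is attempted", {
  flat <- toy_waveform("f", dt = 0.005, n = 200, f = function(t) 0)
  expect_error(fit_step_two(flat, published_human_ur()), "degenerate eCAP")
  expect_error(fit_step_one(flat), "degenerate eCAP")
})

test_that("UR averaging is the parameterwise arithmetic mean", {
  u1 <- ur_params(0.10, 0.03, 0.02, 0.10, -0.10)
  u2 <- ur_params(0.20, 0.05, 0.04, 0.20, -0.16)
  expect_equal(average_urs(list(u1)), u1)
  avg <- average_urs(list(u1, u2))
  expect_equal(avg$u_n, 0.15)
  expect_equal(avg$sigma_n, 0.04)
  expect_equal(avg$t0, -0.13)
  expect_error(average_urs(list()), "empty")
})

test_that("the DMR optimum agrees with an exhaustive grid search", {
  # coarse 3-parameter subproblem: one component, fixed UR
  ur <- published_human_ur()
  truth <- cdld_params(alpha = 0.16, mu = 0.62, sigma = 0.09)
  ecap <- clean_ecap(truth, ur)
  fit <- fit_step_two(ecap, ur, k = 1)

  grid_a <- seq(0.05, 0.3, by = 0.025)
  grid_m <- seq(0.3, 0.9, by = 0.05)
  grid_s <- seq(0.02, 0.2, by = 0.02)
  obs <- ecap$amplitude_uV
  g <- time_grid(min(ecap$time_ms), max(ecap$time_ms), 0.005)
  sse <- function(a, m, s) {
    sum((obs - forward_ecap(cdld_params(a, m, s), ur, g)$amplitude_uV)^2)
  }
  combos <- expand.grid(a = grid_a, m = grid_m, s = grid_s)
  vals <- mapply(sse, combos$a, combos$m, combos$s)
  best <- combos[which.min(vals), ]
  comp <- fit$cdld$components
  expect_lte(abs(comp$alpha - best$a), 0.025)
  expect_lte(abs(comp$mu - best$m), 0.05)
  expect_lte(abs(comp$sigma - best$s), 0.02)
})

test_that("the residual norm never increases along a nested model-order sweep", {
  spec <- synthetic_spec(n_waveforms = 2, seed = 5)
  b <- simulate_batch(spec)
  pre <- preprocess_waveforms(b$waveforms)
  for (id in unique(pre$waveform_id)) {
    sw <- model_order_sweep(pre[pre$waveform_id == id, ], spec$ur,
                            k_range = 1:4)
    expect_true(all(diff(sw$residual_norm) <= 1e-8 * sw$residual_norm[-4]))
  }
  w <- pre[pre$waveform_id == "wf001", ]
  expect_error(model_order_sweep(w, spec$ur, k_range = integer(0)), "empty")
  expect_error(model_order_sweep(w, spec$ur, k_range = c(3, 2)),
               "increasing")
})

test_that("one to two components collapses the residual on bimodal data", {
  ur <- published_human_ur()
  cdld <- cdld_params(alpha = c(0.2, 0.15), mu = c(0.45, 0.95),
                      sigma = c(0.05, 0.06))
  ecap <- clean_ecap(cdld, ur)
  sw <- model_order_sweep(ecap, ur, k_range = 1:2)
  reduction <- (sw$residual_norm[1] - sw$residual_norm[2]) /
    sw$residual_norm[1]
  expect_gt(reduction, 0.5)
})

test_that("fitted parameters stay inside their bounds on noisy inputs", {
  spec <- synthetic_spec(n_waveforms = 5, seed = 21, noise_sd_rel = 0.05)
  b <- simulate_batch(spec)
  fits <- fit_batch(b$waveforms, ur = spec$ur)
  for (f in fits$fit) {
    pars <- tidy(f)
    free <- pars[!pars$fixed, ]
    expect_true(all(free$value >= free$lower & free$value <= free$upper))
    expect_true(all(f$cdld$components$alpha >= 0))
    expect_true(all(diff(f$cdld$components$mu) >= 0))
  }
})

test_that("fit quality degrades monotonically with noise level", {
  med_idx <- vapply(c(0.005, 0.05, 0.2), function(lvl) {
    spec <- synthetic_spec(n_waveforms = 6, seed = 11, noise_sd_rel = lvl)
    b <- simulate_batch(spec)
    fits <- fit_batch(b$waveforms, ur = spec$ur)
    median(fits$fit_index)
  }, numeric(1))
  expect_true(all(diff(med_idx) < 0))
})

test_that("tidy and glance expose the documented batch tables", {
  spec <- synthetic_spec(n_waveforms = 2, seed = 3)
  b <- simulate_batch(spec)
  fits <- fit_batch(b$waveforms, ur = spec$ur)
  long <- tidy(fits)
  expect_named(long, c("waveform_id", "step", "k", "parameter", "value",
                       "residual_norm", "fit_index", "converged"))
  expect_equal(nrow(long), 2 * 6)  # 3 parameters per component, K = 2
  gl <- glance(fits)
  expect_equal(gl$waveform_id, c("wf001", "wf002"))
  one <- glance(fits$fit[[1]])
  expect_equal(one$step, "two")
  expect_s3_class(autoplot(fits$fit[[1]]), "ggplot")
})
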