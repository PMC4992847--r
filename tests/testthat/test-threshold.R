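test_that("instantaneous threshold matches analytic values", {
  th <- instantaneous_threshold(qif, numeric(0), bracket = c(-5, 39),
                                tol = 1e-5)
  expect_equal(th$theta, 30, tolerance = 1e-4)
  th2 <- instantaneous_threshold(pwl2, c(w = 0), bracket = c(1.6, 24.9),
                                 tol = 1e-6, horizon = 60)
  expect_equal(th2$theta, -B_THETA / K_THETA, tolerance = 1e-5)
  # HH from settled rest gating: a finite threshold between rest and 0 mV
  # whose two-sided perturbations flip the outcome
  thh <- instantaneous_threshold(hh, hh_rest[-1], bracket = c(-80, 0),
                                 tol = 1e-4, horizon = 50)
  expect_gt(thh$theta, hh_rest[[1]])
  expect_lt(thh$theta, 0)
  expect_true(fires(hh, c(thh$theta + 0.01, hh_rest[-1]), horizon = 50))
  expect_false(fires(hh, c(thh$theta - 0.01, hh_rest[-1]), horizon = 50))
  expect_error(instantaneous_threshold(pwl2, c(w = 0), bracket = c(1.6, 2),
                                       horizon = 60), "no spike/no-spike")
})

test_that("clamp relaxation is the exact solution of the clamped equations", {
  # boundary cases
  expect_equal(clamp_relax(pwl2, c(w = 0.3), 15, 0), c(w = 0.3))
  expect_equal(clamp_relax(pwl2, c(w = 0.3), 15, 1e9), c(w = 0.45 * 15),
               tolerance = 1e-12)
  expect_equal(unname(clamp_relax(pwl2, c(w = 0), 15, 5)),
               6.75 * (1 - exp(-1)), tolerance = 1e-12)
  # equals clamped integration, swept over a tau_c grid
  taus <- c(0.5, 2, 5, 10)
  ana <- clamp_relax(hh, hh_rest[-1], -30, taus)
  for (k in seq_along(taus)) {
    tr <- integrate_model(hh, hh_rest,
                          stimulus_protocol(stim_clamp(-30, taus[k])),
                          t_end = taus[k], dt = 0.001)
    expect_lt(max(abs(tr$states[nrow(tr$states), -1] - ana[k, ])), 1e-8)
  }
})

test_that("post-clamp firing flips at the analytic clamp boundary", {
  # depolarised clamp: fires below the boundary duration, not above
  tau_star <- pwl2d_clamp_boundary(pwl2, 15)
  expect_equal(tau_star, -5 * log(1 - (K_THETA * 15 + B_THETA) / 6.75),
               tolerance = 1e-12)
  expect_true(post_clamp_fires(pwl2, c(0, 0), 15, tau_star - 0.05,
                               horizon = 60))
  expect_false(post_clamp_fires(pwl2, c(0, 0), 15, tau_star + 0.05,
                                horizon = 60))
  # hyperpolarised clamp: short does not fire, long does
  # (post-inhibitory facilitation)
  expect_false(post_clamp_fires(pwl2, c(0, 0), -15, 1.5, horizon = 60))
  expect_true(post_clamp_fires(pwl2, c(0, 0), -15, 15, horizon = 60))
  # HH clamped at rest never fires
  for (tc in c(1, 5, 20))
    expect_false(post_clamp_fires(hh, hh_rest, hh_rest[[1]], tc,
                                  horizon = 50))
})

test_that("QIF threshold ODE under a ramp matches the root formula", {
  pr <- stimulus_protocol(stim_ramp(0, 150, 0, 10))
  tr <- threshold_trace(qif, pr, seq(0, 9.5, 0.5))
  # the bisect column is the analytic root formula here
  ie <- sepx:::protocol_current(pr, seq(0, 9.5, 0.5))
  expect_equal(tr$theta_bisect, (30 + sqrt(900 - 4 * ie)) / 2,
               tolerance = 1e-12)
  expect_lt(max(abs(tr$theta_ode - tr$theta_bisect)), 1e-6)
  # analytic partial matches finite differences of the root formula
  dth <- function(i) (30 + sqrt(900 - 4 * i)) / 2
  h <- 1e-4
  expect_equal(tr$partials$dtheta_die[1], (dth(h) - dth(-h)) / (2 * h),
               tolerance = 1e-6)
})

test_that("2D PWL clamp trace is a single exponential with tau_theta = tau_w", {
  tr <- threshold_trace(pwl2, stimulus_protocol(stim_clamp(10, 8)),
                        seq(0, 8, length.out = 21), tol = 1e-6,
                        rest_state = c(v = 0, w = 0), horizon = 60)
  expect_lt(max(abs(tr$theta_ode - tr$theta_bisect)), 5 * 1e-5)
  fit <- first_order_fit(tr, "ode")
  expect_equal(fit$tau_theta, pwl2$params$tau_w, tolerance = 0.01)
  expect_lt(fit$rms_residual, 1e-10)
  # theta_inf is the asymptotic threshold at the clamped recovery value
  sep <- pwl2d_separatrix(pwl2, 0)
  expect_equal(fit$theta_inf, (0.45 * 10 - sep$b_theta) / sep$k_theta,
               tolerance = 1e-6)
})

test_that("two recovery time constants obstruct the single-exponential fit", {
  tr3 <- threshold_trace(pwl3, stimulus_protocol(stim_clamp(10, 30)),
                         seq(0, 30, length.out = 31),
                         rest_state = c(v = 0, u = 0, w = 0),
                         method = "ode")
  fit3 <- first_order_fit(tr3, "ode")
  rel3 <- fit3$rms_residual / diff(range(tr3$theta_ode))
  # matched single-time-constant control: same amplitude, pure exponential
  ctrl <- list(times = tr3$times,
               theta = fit3$theta_inf + (tr3$theta_ode[1] - fit3$theta_inf) *
                 exp(-tr3$times / fit3$tau_theta))
  fitc <- first_order_fit(ctrl)
  relc <- fitc$rms_residual / diff(range(ctrl$theta))
  expect_gt(rel3, 1e-3)
  expect_lt(relc, 1e-9)
  expect_gt(rel3, 1000 * relc)
})

test_that("exponential fit recovers exact inputs and flags degenerate ones", {
  tt <- seq(0, 20, length.out = 50)
  fit <- first_order_fit(list(times = tt, theta = 3 + 4 * exp(-tt / 5)))
  expect_equal(fit$theta_inf, 3, tolerance = 1e-9)
  expect_equal(fit$tau_theta, 5, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)
  cf <- first_order_fit(list(times = tt, theta = rep(2, 50)))
  expect_true(is.na(cf$tau_theta))
  expect_match(cf$flagged, "unidentifiable")
  nm <- first_order_fit(list(times = tt, theta = sin(tt / 3) + 2))
  expect_match(nm$flagged, "non-monotone", all = FALSE)
})
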