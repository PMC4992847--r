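test_that("piecewise f(v) follows the half-open segment convention", {
  # left at 0, middle at the left breakpoint, right at the right breakpoint
  expect_equal(piecewise_f(pwl2, 0), 0)
  expect_equal(piecewise_f(pwl2, 1.5), 0.5 * 1.5 - 1.5)
  expect_equal(piecewise_f(pwl2, 25), -0.25 * 25 + 17.25)
  expect_equal(pwl_region(pwl2, c(0, 1.5, 24.99, 25)),
               c("left", "middle", "middle", "right"))
})

test_that("right-hand sides vanish at resting states and error on bad input", {
  expect_equal(unname(eval_rhs(qif, qif$params$v_r, i_e = 0)), 0)
  expect_equal(unname(eval_rhs(pwl2, c(0, 0), i_e = 0)), c(0, 0))
  expect_lt(max(abs(eval_rhs(hh, hh_rest))), 1e-6)
  expect_error(eval_rhs(pwl2, c(0, 0, 0)), "dimension")
  expect_error(eval_rhs(pwl2, c(NaN, 0)), "finite")
})

test_that("compiled and interpreted right-hand sides agree with hand formulas", {
  # 2D PWL in the middle region, evaluated by hand from the two linear
  # equations
  st <- c(10, 2); ie <- 0.5
  expect_equal(unname(eval_rhs(pwl2, st, ie)),
               c((0.5 * 10 - 1.5 - 2 + 0.5) / 1, (0.45 * 10 - 2) / 5))
  # QIF quadratic
  expect_equal(unname(eval_rhs(qif, 10, 7)), (10 - 0) * (10 - 30) + 7)
  # FHN adaptation form
  st <- c(0.3, -0.1)
  expect_equal(unname(eval_rhs(fhn, st, 0.2)),
               c(0.3 - 0.3^3 / 3 + 0.1 + 0.2,
                 (1.25 * 0.3 + 0.875 + 0.1) / 15))
})

test_that("model registry validates names, parameters and QIF ordering", {
  expect_error(neuron_model("nope"), "unknown model name")
  expect_error(neuron_model("pwl2d", list(bogus = 1)), "unknown parameter")
  expect_error(neuron_model("qif", list(v_peak = 10)),
               "v_peak > v_t > v_r > v_reset")
  m <- neuron_model("pwl2d", list(tau_w = 10))
  expect_identical(unname(m$provenance["tau_w"]), "user")
  expect_identical(unname(m$provenance["k_w"]), "default")
  expect_equal(m$params$tau_w, 10)
})

test_that("2D PWL equilibria: one real spiral and two virtual points", {
  eq <- find_equilibria(pwl2, i_e = 0)
  expect_length(eq, 3)
  v <- vapply(eq, function(e) unname(e$state[1]), numeric(1))
  expect_equal(v, c(0, 17.25 / 0.7, -1.5 / (0.45 - 0.5)), tolerance = 1e-12)
  expect_equal(vapply(eq, `[[`, character(1), "reality"),
               c("real", "virtual", "virtual"))
  expect_equal(vapply(eq, `[[`, character(1), "stability"),
               c("stable spiral", "stable spiral", "saddle"))
  # segment fixed points satisfy their defining linear equations exactly
  for (e in eq) {
    co <- sepx:::pwl_segment_coef(pwl2, e$region)
    expect_lt(abs(co["k"] * e$state[1] + co["b"] - e$state[2]), 1e-12)
    expect_lt(abs(0.45 * e$state[1] - e$state[2]), 1e-12)
  }
})

test_that("QIF equilibria are the quadratic roots; none beyond rheobase", {
  eq <- find_equilibria(qif, i_e = 0)
  expect_equal(vapply(eq, function(e) unname(e$state[1]), numeric(1)),
               c(0, 30))
  expect_equal(vapply(eq, `[[`, character(1), "stability"),
               c("stable", "unstable"))
  expect_error(find_equilibria(qif, i_e = 300), "rheobase")
})

test_that("Boltzmann-FHN portrait: stable point < saddle < unstable node", {
  eq <- find_equilibria(bfhn)   # baseline drive 0.62
  expect_length(eq, 3)
  v <- vapply(eq, function(e) unname(e$state[1]), numeric(1))
  expect_true(all(diff(v) > 0))
  cls <- vapply(eq, `[[`, character(1), "stability")
  expect_match(cls[1], "^stable")
  expect_identical(cls[2], "saddle")
  expect_identical(cls[3], "unstable node")
  # classic FHN has exactly one equilibrium (type II, quasi-threshold)
  expect_length(find_equilibria(fhn), 1)
  # fixture validation rejects parameter sets that break the portrait
  expect_error(neuron_model("boltzmann-fhn", list(a = 0.05)),
               "fixture validation")
})

test_that("analytic Jacobians match hand values and finite differences", {
  J <- jacobian(pwl2, c(10, 2))
  expect_equal(J, matrix(c(0.5, -1, 0.09, -0.2), 2, 2, byrow = TRUE))
  expect_equal(sum(diag(J)), 0.3)
  expect_equal(det(J), -0.01)
  expect_lt(det(J), 0)  # saddle
  # QIF at the resting root: derivative (v_r - v_t) < 0
  expect_equal(jacobian(qif, 0)[1, 1], -30)
  # finite-difference agreement for the smooth models
  for (m in list(fhn, bfhn, hh)) {
    st <- if (m$name == "hh") c(-60, 0.1, 0.5, 0.4) else c(0.2, 0.3)
    Ja <- jacobian(m, st)
    Jn <- sepx:::jacobian_fd(m, st)
    expect_lt(max(abs(Ja - Jn)) / max(abs(Ja)), 1e-6)
  }
  # breakpoint needs an explicit region id
  expect_error(jacobian(pwl2, c(1.5, 0)), "breakpoint")
  expect_silent(jacobian(pwl2, c(1.5, 0), region = "middle"))
})

test_that("eigenvalue classification agrees with trace/det sign analysis", {
  for (reg in c("left", "middle", "right")) {
    st <- sepx:::pwl_segment_fixed_point(pwl2, reg)
    J <- jacobian(pwl2, st, region = reg)
    ev <- eigen(J)$values
    if (det(J) < 0) {
      expect_true(all(abs(Im(ev)) < 1e-12) && prod(Re(ev)) < 0)
    } else if (sum(diag(J)) < 0) {
      expect_true(all(Re(ev) < 0))
    }
  }
  # 3D: characteristic cubic of the middle region (coefficients by hand:
  # trace 0.65, second invariant -0.115, det -0.002)
  J3 <- jacobian(pwl3, c(10, 0, 0), region = "middle")
  expect_equal(sum(diag(J3)), 0.65)
  expect_equal(det(J3), -0.002, tolerance = 1e-12)
  ev3 <- sort(Re(eigen(J3)$values))
  roots <- sort(Re(polyroot(c(0.002, -0.115, -0.65, 1))))
  expect_equal(ev3, roots, tolerance = 1e-9)
})

test_that("HH rates are positive, continuous, with singularities filled", {
  Vs <- seq(-120, 60, by = 0.1)
  for (V in c(-120, -77.3, -65, -55, -40, 0, 60)) {
    r <- hh_rates(V)
    expect_true(all(is.finite(unlist(r))))
    expect_true(all(r$x_inf > 0 & r$x_inf < 1))
    expect_true(all(r$tau > 0))
  }
  xm <- vapply(Vs, function(V) hh_rates(V)$alpha[["m"]], numeric(1))
  expect_true(all(is.finite(xm)))
  # removable singularities equal their limits (L'Hopital: alpha_m(-40) = 1,
  # alpha_n(-55) = 0.1)
  expect_equal(hh_rates(-40)$alpha[["m"]], 1, tolerance = 1e-9)
  expect_equal(hh_rates(-55)$alpha[["n"]], 0.1, tolerance = 1e-9)
  eps <- 1e-6
  expect_lt(abs(hh_rates(-40 + eps)$alpha[["m"]] -
                hh_rates(-40 - eps)$alpha[["m"]]), 1e-6)
  # settled rest gating equals x_inf(V_rest)
  expect_equal(unname(hh_rest[-1]), unname(hh_rates(hh_rest[1])$x_inf),
               tolerance = 1e-6)
})

test_that("adaptation derivative has the sign of (x_inf - x)", {
  for (m in list(pwl2, pwl3, fhn, bfhn, hh)) {
    for (v in c(-60, -1, 0.5, 10)) {
      tg <- adaptation_targets(m, v)
      if (!length(tg$x_inf)) next
      x <- tg$x_inf + 0.3 * c(1, -1)[seq_along(tg$x_inf) %% 2 + 1]
      dx <- eval_rhs(m, c(v, x))[-1]
      expect_true(all(sign(dx) == sign(tg$x_inf - x)))
    }
  }
})
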