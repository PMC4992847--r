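test_that("QIF threshold point follows the quadratic-root formula", {
  tp <- qif_threshold(qif, 0)
  expect_equal(tp$theta, 30)
  expect_equal(tp$v_rest, 0)
  tp50 <- qif_threshold(qif, 50)
  expect_equal(tp50$theta, (30 + sqrt(700)) / 2, tolerance = 1e-12)
  expect_equal(tp50$v_rest, (30 - sqrt(700)) / 2, tolerance = 1e-12)
  expect_error(qif_threshold(qif, 225), "rheobase")
  # theta decreasing, v_rest increasing, gap shrinking toward rheobase
  ies <- seq(0, 0.98 * 225, length.out = 25)
  th <- vapply(ies, function(i) qif_threshold(qif, i)$theta, numeric(1))
  vr <- vapply(ies, function(i) qif_threshold(qif, i)$v_rest, numeric(1))
  expect_true(all(diff(th) < 0))
  expect_true(all(diff(vr) > 0))
  expect_true(all(diff(th - vr) < 0))
})

test_that("QIF rheobase equals (v_t - v_r)^2 / 4 and brackets DC firing onset", {
  expect_equal(qif_rheobase(qif), 225)
  expect_equal(qif_rheobase(neuron_model("qif",
    list(v_r = 5, v_t = 25, v_peak = 40, v_reset = -5))), 100)
  # simulation oracle at +-1%
  below <- sepx:::free_run_summary(qif, 0, 100, 0.01, 225 * 0.99)
  above <- sepx:::free_run_summary(qif, 0, 100, 0.01, 225 * 1.01)
  expect_equal(below$n_spikes, 0)
  expect_gt(above$n_spikes, 2)
})

test_that("2D PWL separatrix line has the eigen-derived slope and intercept", {
  sep <- pwl2d_separatrix(pwl2, 0)
  expect_equal(sort(sep$eigenvalues), sort((0.3 + c(1, -1) * sqrt(0.13)) / 2),
               tolerance = 1e-12)
  expect_equal(sep$k_theta, K_THETA, tolerance = 1e-12)
  expect_equal(sep$b_theta, B_THETA, tolerance = 1e-12)
  # printed ordering constraint and saddle pass-through
  expect_true(sep$k_theta > pwl2$params$k_m &&
              pwl2$params$k_m > pwl2$params$k_w)
  expect_lt(abs(sep$k_theta * 30 + sep$b_theta - 0.45 * 30), 1e-10)
  # i_e shifts the intercept linearly, slope unchanged
  sep1 <- pwl2d_separatrix(pwl2, 1)
  sep2 <- pwl2d_separatrix(pwl2, 2)
  expect_equal(sep1$k_theta, sep$k_theta)
  expect_equal(sep2$b_theta - sep1$b_theta, sep1$b_theta - sep$b_theta,
               tolerance = 1e-12)
  expect_gt(sep1$b_theta, sep$b_theta)
  # rest lies on the non-firing side
  expect_false(on_firing_side(sep, c(0, 0)))
  # non-saddle middle segment is rejected
  expect_error(pwl2d_separatrix(neuron_model("pwl2d", list(k_m = -0.1))),
               "not a saddle")
})

test_that("traced stable manifold reproduces the analytic line and winds", {
  sad <- find_equilibria(pwl2)[[3]]
  expect_identical(sad$reality, "virtual")
  tm <- trace_manifold(pwl2, sad, "stable", horizon = 300, dt = 0.005)
  pts <- tm$points
  mid <- pts[, 1] > 2 & pts[, 1] < 24
  fit <- lm(pts[mid, 2] ~ pts[mid, 1])
  expect_lt(abs(coef(fit)[2] - K_THETA), 1e-6)
  expect_lt(abs(coef(fit)[1] - B_THETA), 1e-5)
  # the hyperpolarised continuation winds past the resting state
  expect_lt(min(pts[, 1]), -10)
})

test_that("AP classification agrees with the line's firing side", {
  sep <- pwl2d_separatrix(pwl2, 0)
  set.seed(42)
  v <- runif(100, 2, 15)
  w <- sep$k_theta * v + sep$b_theta + runif(100, -3, 3)
  pred <- w < sep$k_theta * v + sep$b_theta
  got <- mapply(function(vv, ww) fires(pwl2, c(vv, ww), horizon = 60), v, w)
  agree <- sum(pred == got)
  expect_gte(agree, 99)
  if (agree < 100) {
    off <- which(pred != got)
    expect_true(all(abs(w[off] - (sep$k_theta * v[off] + sep$b_theta)) < 1e-6))
  }
})

test_that("3D threshold plane is spanned by the non-dominant eigenpair", {
  sep <- pwl3d_separatrix(pwl3, 0)
  roots <- sort(Re(polyroot(c(0.002, -0.115, -0.65, 1))))
  expect_equal(sort(c(sep$r_i, sep$r_j)), roots[1:2], tolerance = 1e-9)
  expect_equal(sep$dominant_value, roots[3], tolerance = 1e-9)
  # normal orthogonal to both spanning eigenvectors; plane contains the
  # middle-segment equilibrium
  expect_lt(max(abs(t(sep$spanning_vectors) %*% sep$normal)), 1e-10)
  expect_equal(sep$point, sepx:::pwl_segment_fixed_point(pwl3, "middle"),
               tolerance = 1e-12)
  # rest on the non-firing side
  expect_false(on_firing_side(sep, c(0, 0, 0)))
  # degenerate/complex spectra are rejected with the eigenvalues listed
  expect_error(pwl3d_separatrix(neuron_model("pwl3d", list(k_m = 0.2))),
               "\\[")
})

test_that("trajectories started on the 3D plane stay on it; off-plane starts never cross", {
  sep <- pwl3d_separatrix(pwl3, 0)
  pt <- sep$point + 30 * sep$spanning_vectors[, 2]
  expect_gt(pt[1], 1.5)
  tr <- integrate_model(pwl3, pt, NULL, t_end = 15, dt = 0.001,
                        store_every = 10)
  inreg <- tr$states[, 1] >= 1.5 & tr$states[, 1] < 50
  d <- apply(tr$states, 1, function(s) sum(sep$normal * (s - sep$point)))
  expect_lt(max(abs(d[inreg])), 1e-6)
  # 50 deterministic off-plane starts: sign of the plane distance never
  # changes while the trajectory remains in the middle region
  set.seed(7)
  checked <- 0
  for (i in 1:50) {
    base <- sep$point + runif(1, 25, 45) * sep$spanning_vectors[, 2] +
      runif(1, -3, 3) * sep$spanning_vectors[, 1]
    st <- base + sample(c(-1, 1), 1) * runif(1, 1e-3, 1e-1) *
      sep$dominant_vector
    if (st[1] < 1.6 || st[1] > 45) next
    d0 <- sign(sum(sep$normal * (st - sep$point)))
    trj <- integrate_model(pwl3, st, NULL, t_end = 20, dt = 0.005,
                           store_every = 5)
    inr <- trj$states[, 1] >= 1.5 & trj$states[, 1] < 50
    stop_at <- which(!inr)
    keep <- if (length(stop_at)) seq_len(stop_at[1] - 1) else seq_len(nrow(trj$states))
    dd <- apply(trj$states[keep, , drop = FALSE], 1,
                function(s) sum(sep$normal * (s - sep$point)))
    expect_true(all(sign(dd) == d0))
    checked <- checked + 1
  }
  expect_gte(checked, 40)
})

test_that("paired starts across the 3D plane classify oppositely", {
  sep <- pwl3d_separatrix(pwl3, 0)
  pt <- sep$point + 30 * sep$spanning_vectors[, 2]
  up <- pt + 1e-3 * sep$dominant_vector
  dn <- pt - 1e-3 * sep$dominant_vector
  f_up <- fires(pwl3, up, horizon = 100)
  f_dn <- fires(pwl3, dn, horizon = 100)
  expect_true(xor(f_up, f_dn))
  expect_identical(f_up, on_firing_side(sep, up))
  expect_identical(f_dn, on_firing_side(sep, dn))
})

test_that("Boltzmann-FHN stable manifolds reproduce the type I geometry", {
  eq <- find_equilibria(bfhn)
  sad <- eq[[2]]; node <- eq[[3]]
  b1 <- trace_manifold(bfhn, sad, "stable", sign = -1, horizon = 300,
                       delta = 1e-5, dt = 0.01, i_e = 0.62,
                       v_box = c(-6, 4))
  b2 <- trace_manifold(bfhn, sad, "stable", sign = +1, horizon = 300,
                       delta = 1e-5, dt = 0.01, i_e = 0.62,
                       v_box = c(-6, 4))
  # one branch escapes to strongly negative voltages (truncated at the box)
  expect_true(b1$truncated)
  expect_lt(min(b1$points[, 1]), -5)
  # the other connects to the unstable node
  fin <- b2$points[nrow(b2$points), ]
  expect_lt(sqrt(sum((fin - node$state)^2)), 1e-6)
})

test_that("manifold tracing is continuous in the seed offset delta", {
  eq <- find_equilibria(bfhn)
  sad <- eq[[2]]
  b  <- trace_manifold(bfhn, sad, "stable", sign = +1, horizon = 150,
                       delta = 1e-4, dt = 0.01, i_e = 0.62, v_box = c(-6, 4))
  b2 <- trace_manifold(bfhn, sad, "stable", sign = +1, horizon = 150,
                       delta = 1e-5, dt = 0.01, i_e = 0.62, v_box = c(-6, 4))
  # compare over common arc length from the saddle
  arc <- function(p) c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  a1 <- arc(b$points); a2 <- arc(b2$points)
  amax <- min(max(a1), max(a2))
  s <- seq(0, amax, length.out = 200)
  i1 <- cbind(approx(a1, b$points[, 1], s)$y, approx(a1, b$points[, 2], s)$y)
  i2 <- cbind(approx(a2, b2$points[, 1], s)$y, approx(a2, b2$points[, 2], s)$y)
  expect_lt(max(sqrt(rowSums((i1 - i2)^2))), 1e-3)
})

test_that("bisection reproduces analytic separatrices and contracts with tol", {
  # 2D PWL horizontal ray from rest
  bb <- bisect_boundary(pwl2, NULL, c(0, 0), c(1, 0), c(0, 20), tol = 1e-7,
                        horizon = 60)
  expect_equal(bb$state[1], -B_THETA / K_THETA, tolerance = 1e-5)
  # QIF at DC drive
  bq <- bisect_boundary(qif, NULL, 0, 1, c(0, 40), tol = 1e-7,
                        horizon = 60, i_e = 50)
  expect_equal(bq$state[1], qif_threshold(qif, 50)$theta, tolerance = 1e-4)
  expect_error(bisect_boundary(pwl2, NULL, c(0, 0), c(1, 0), c(0, 1)),
               "no sign change")
  b1 <- bisect_boundary(pwl2, NULL, c(0, 0), c(1, 0), c(0, 20), tol = 1e-3,
                        horizon = 60)
  b2 <- bisect_boundary(pwl2, NULL, c(0, 0), c(1, 0), c(0, 20), tol = 5e-4,
                        horizon = 60)
  expect_lt(abs(b1$s - b2$s), 1e-3)
})
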