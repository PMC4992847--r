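# ---------------------------------------------------------------------------
# QIF: threshold point and rheobase
# ---------------------------------------------------------------------------

#' Rheobase of the quadratic integrate-and-fire model
#'
#' The saddle-node bifurcation current: the discriminant of `dv/dt = 0`,
#' `(v_t + v_r)^2 - 4 (v_r v_t + I_e)`, vanishes at
#' `I_e = (v_t - v_r)^2 / 4`.  Above it the two equilibria (resting point
#' and threshold) merge and disappear and the neuron fires periodically.
#'
#' @param model A `qif` [neuron_model()].
#' @return The rheobase current.
#' @export
qif_rheobase <- function(model) {
  p <- model$params
  (p$v_t - p$v_r)^2 / 4
}

#' Dynamic threshold point of the QIF model
#'
#' For a subthreshold constant current the two real roots of `dv/dt = 0`
#' are the dynamic resting potential and the dynamic threshold:
#' `(v_t + v_r)/2 +- sqrt((v_t + v_r)^2 - 4 (v_r v_t + i_e)) / 2`.
#' A depolarising current raises the resting potential and lowers the
#' threshold until they merge at rheobase.
#'
#' @param model A `qif` [neuron_model()].
#' @param i_e Constant external current (must be below [qif_rheobase()]).
#' @return An object of class `threshold_point` with fields `theta`,
#'   `v_rest`, `i_e`.
#' @export
qif_threshold <- function(model, i_e = 0) {
  p <- model$params
  rb <- qif_rheobase(model)
  if (i_e >= rb)
    stop("no threshold point: i_e = ", i_e, " >= rheobase = ", rb,
         " (saddle-node regime)")
  disc <- (p$v_t + p$v_r)^2 - 4 * (p$v_r * p$v_t + i_e)
  s <- sqrt(disc)
  structure(list(theta = ((p$v_t + p$v_r) + s) / 2,
                 v_rest = ((p$v_t + p$v_r) - s) / 2,
                 i_e = i_e), class = "threshold_point")
}

#' @export
print.threshold_point <- function(x, ...) {
  cat("<threshold_point> theta =", signif(x$theta, 8),
      " v_rest =", signif(x$v_rest, 8), " (i_e =", x$i_e, ")\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# 2D PWL: separatrix line
# ---------------------------------------------------------------------------

#' Analytic separatrix line of the 2D piecewise-linear model
#'
#' In the middle region the fixed point of the middle segment is a saddle
#' (possibly virtual) and its stable direction defines the threshold line
#' `w = k_theta v + b_theta` in the `v`-`w` plane.  The slope is
#' `k_theta = k_m / C - lambda_s` with `lambda_s` the negative eigenvalue of
#' the middle-region Jacobian (equivalently the stable eigenvector's `dw/dv`
#' slope), and the intercept is
#' `b_theta = (i_e + b_m)(k_w - k_theta)/(k_w - k_m)`, which places the line
#' exactly through the saddle.  States below the line fire
#' (`k_theta > k_m > k_w` makes the threshold decrease with depolarising
#' current); increasing `i_e` shifts the line up without changing the slope.
#'
#' @param model A `pwl2d` [neuron_model()].
#' @param i_e Constant external current.
#' @return An object of class `separatrix_line`: `k_theta`, `b_theta`,
#'   `validity` (middle-region voltage interval), `firing_side` (`"below"`),
#'   `saddle`, `i_e`.
#' @export
pwl2d_separatrix <- function(model, i_e = 0) {
  p <- model$params
  J <- jacobian(model, c((p$v_l + p$v_r) / 2, 0), i_e = i_e,
                region = "middle")
  if (det(J) >= 0)
    stop("middle-segment fixed point is not a saddle (det = ", det(J),
         "); no separatrix line")
  ev <- eigen(J)$values
  lam_s <- min(ev)
  k_theta <- p$k_m / p$C - lam_s
  b_theta <- (i_e + p$b_m) * (p$k_w - k_theta) / (p$k_w - p$k_m)
  saddle <- pwl_segment_fixed_point(model, "middle", i_e)
  structure(list(k_theta = k_theta, b_theta = b_theta,
                 validity = c(p$v_l, p$v_r), firing_side = "below",
                 saddle = setNames(saddle, model$state_names),
                 eigenvalues = ev, i_e = i_e),
            class = "separatrix_line")
}

#' @export
print.separatrix_line <- function(x, ...) {
  cat("<separatrix_line> w =", signif(x$k_theta, 8), "* v +",
      signif(x$b_theta, 8), "  (firing", x$firing_side,
      "; valid v in [", x$validity[1], ",", x$validity[2], "))\n")
  invisible(x)
}

#' Threshold voltage on an analytic separatrix at a given recovery state
#'
#' Solves the separatrix equation for the voltage coordinate: for the 2D
#' line `theta = (w - b_theta)/k_theta`; for the 3D plane the voltage at
#' which `(v, u, w)` sits on the plane.
#'
#' @param sep A `separatrix_line` or `threshold_plane`.
#' @param gating Recovery coordinates: `w` (2D) or `c(u, w)` (3D).
#' @return Threshold voltage.
#' @export
separatrix_theta <- function(sep, gating) {
  if (inherits(sep, "separatrix_line"))
    return((gating[[1]] - sep$b_theta) / sep$k_theta)
  if (inherits(sep, "threshold_plane")) {
    n <- sep$normal
    if (abs(n[1]) < 1e-12) stop("plane is vertical in v; theta undefined")
    return((sum(n * sep$point) - n[2] * gating[[1]] - n[3] * gating[[2]]) /
             n[1])
  }
  stop("unsupported separatrix object")
}

#' Which side of a separatrix does a state lie on?
#'
#' @param sep A `separatrix_line` or `threshold_plane`.
#' @param state Full state vector.
#' @return `TRUE` if the state is on the firing side.
#' @export
on_firing_side <- function(sep, state) {
  if (inherits(sep, "separatrix_line"))
    return(state[[2]] < sep$k_theta * state[[1]] + sep$b_theta)
  if (inherits(sep, "threshold_plane"))
    return(sign(sum(sep$normal * (as.numeric(state) - sep$point))) ==
             sep$firing_sign)
  stop("unsupported separatrix object")
}

# ---------------------------------------------------------------------------
# 3D PWL: threshold plane
# ---------------------------------------------------------------------------

#' Analytic threshold plane of the 3D piecewise-linear model
#'
#' The middle-region Jacobian has three real eigenvalues with exactly one
#' dominant positive one (the fast firing direction).  The plane spanned by
#' the eigenvectors of the two non-dominant eigenvalues (one stable, one
#' weakly unstable), anchored at the middle-segment equilibrium (real or
#' virtual), is invariant under the middle-region flow and separates firing
#' from non-firing states; the firing side is the side the dominant
#' eigenvector (oriented toward positive `v`) points to.
#'
#' @param model A `pwl3d` [neuron_model()].
#' @param i_e Constant external current.
#' @return An object of class `threshold_plane`: `normal`, `point`,
#'   spanning eigenvalues `r_i`, `r_j`, spanning eigenvectors, dominant
#'   eigenvalue/vector, `firing_sign`, `validity`.
#' @export
pwl3d_separatrix <- function(model, i_e = 0) {
  p <- model$params
  J <- jacobian(model, c((p$v_l + p$v_r) / 2, 0, 0), i_e = i_e,
                region = "middle")
  ed <- eigen(J)
  if (any(abs(Im(ed$values)) > 1e-10))
    stop("middle-region spectrum is not real: [",
         paste(signif(ed$values, 6), collapse = ", "), "]")
  ev <- Re(ed$values); V <- Re(ed$vectors)
  if (anyDuplicated(signif(ev, 12)))
    stop("degenerate middle-region spectrum: [",
         paste(signif(ev, 6), collapse = ", "), "]")
  dom <- which.max(abs(ev))
  if (ev[dom] <= 0)
    stop("no dominant positive eigenvalue: [",
         paste(signif(ev, 6), collapse = ", "), "]")
  span <- setdiff(1:3, dom)
  e1 <- V[, span[1]]; e2 <- V[, span[2]]
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  n <- n / sqrt(sum(n^2))
  point <- pwl_segment_fixed_point(model, "middle", i_e)
  edom <- V[, dom]
  if (edom[1] < 0) edom <- -edom  # orient toward positive v
  structure(list(normal = n, point = point,
                 r_i = ev[span[1]], r_j = ev[span[2]],
                 spanning_vectors = cbind(e1, e2),
                 dominant_value = ev[dom], dominant_vector = edom,
                 firing_sign = sign(sum(n * edom)),
                 validity = c(p$v_l, p$v_r), i_e = i_e),
            class = "threshold_plane")
}

#' @export
print.threshold_plane <- function(x, ...) {
  cat("<threshold_plane> normal = (",
      paste(signif(x$normal, 6), collapse = ", "),
      ") through (", paste(signif(x$point, 6), collapse = ", "), ")\n")
  cat("  spanning eigenvalues r_i =", signif(x$r_i, 6),
      ", r_j =", signif(x$r_j, 6),
      "; dominant =", signif(x$dominant_value, 6), "\n")
  invisible(x)
}

# signed distance (in state units) from the plane
plane_distance <- function(plane, state)
  sum(plane$normal * (as.numeric(state) - plane$point))

# ---------------------------------------------------------------------------
# Numerical manifold tracing
# ---------------------------------------------------------------------------

#' Trace a saddle manifold (global separatrix) by integration
#'
#' Integrates from `saddle + sign * delta * e` (with `e` the unit
#' eigenvector of the requested manifold), backward in time for the stable
#' manifold, forward for the unstable one, producing the global separatrix
#' including the winding branch around the resting state in the
#' hyperpolarised region.  For a *virtual* saddle (2D piecewise-linear
#' model) the start point is taken on the analytic separatrix line just
#' inside the middle region, since the virtual saddle itself lies in a
#' region governed by different dynamics.
#'
#' @param model A [neuron_model()].
#' @param saddle An `equilibrium` (from [find_equilibria()]) with a real
#'   eigenvalue of the requested sign.
#' @param which `"stable"` or `"unstable"`.
#' @param sign Which side of the saddle to leave from (`+1` or `-1`).
#' @param horizon Integration horizon (time units).
#' @param delta Offset from the saddle, relative to the state scale.
#' @param dt Step size.
#' @param i_e Constant current (stable-manifold tracing is autonomous).
#' @param v_box Voltage bounding box; the trace is truncated (and flagged)
#'   when it escapes.
#' @return An object of class `sampled_boundary`: matrix `points`, vector
#'   `param` (integration time), flags.
#' @export
trace_manifold <- function(model, saddle, which = c("stable", "unstable"),
                           sign = 1, horizon = 200, delta = 1e-6,
                           dt = model$dt_default, i_e = 0,
                           v_box = c(-50, 60)) {
  which <- match.arg(which)
  ev <- saddle$eigenvalues
  if (any(abs(Im(ev)) > 1e-10 & (Re(ev) < 0) == (which == "stable")))
    stop("saddle has no real ", which, " eigenvalue")
  idx <- if (which == "stable") which.min(Re(ev)) else which.max(Re(ev))
  lam <- Re(ev[idx])
  if ((which == "stable" && lam >= 0) || (which == "unstable" && lam <= 0))
    stop("saddle has no ", which, " manifold (eigenvalue ", signif(lam, 6),
         ")")
  e <- Re(saddle$eigenvectors[, idx]); e <- e / sqrt(sum(e^2))
  scale <- max(1, abs(saddle$state))
  start <- as.numeric(saddle$state) + sign * delta * scale * e

  if (identical(saddle$reality, "virtual") && model$name == "pwl2d") {
    sep <- pwl2d_separatrix(model, i_e = saddle$i_e)
    v0 <- model$params$v_r - 1e-3 * (model$params$v_r - model$params$v_l)
    start <- c(v0, sep$k_theta * v0 + sep$b_theta)
  }

  backward <- which == "stable"
  n <- max(1L, as.integer(round(horizon / dt)))
  stim <- if (i_e != 0) matrix(c(-Inf, Inf, i_e, i_e), 1, 4) else
    matrix(0, 0, 4)
  res <- integrate_core(model$model_id, pack_params(model), start, 0, dt, n,
                        stim, FALSE, 0, backward, 5L, Inf,
                        v_box[1], v_box[2])
  if (res$err) stop("non-finite state at t = ", res$err_time,
                    " while tracing manifold")
  pts <- res$states
  colnames(pts) <- model$state_names
  structure(list(points = pts, param = abs(res$times),
                 which = which, sign = sign, delta = delta,
                 truncated = isTRUE(res$truncated == 1 | res$truncated),
                 saddle = saddle$state),
            class = "sampled_boundary")
}

#' @export
print.sampled_boundary <- function(x, ...) {
  cat("<sampled_boundary>", nrow(x$points), "points",
      if (isTRUE(x$truncated)) "(truncated at bounding box)", "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Bisection onto a firing boundary
# ---------------------------------------------------------------------------

#' Locate a firing boundary point along a ray by bisection
#'
#' Deterministic bisection of `classifier(anchor + s * direction)` over
#' `s` in `bracket`; the classifier outcomes must differ at the bracket
#' ends.  Repeated calls along a family of rays sample the
#' (quasi-)separatrix of smooth models.
#'
#' @param model A [neuron_model()] (passed to the classifier).
#' @param classifier Function `(model, state) -> logical`; defaults to
#'   [fires()].
#' @param anchor Base state.
#' @param direction Ray direction (need not be unit length).
#' @param bracket `c(lo, hi)` offsets along the ray.
#' @param tol Bisection tolerance on the offset.
#' @param ... Passed to the classifier.
#' @return List: boundary `state`, offset `s`, `n_iter`.
#' @export
bisect_boundary <- function(model, classifier = NULL, anchor, direction,
                            bracket, tol = 1e-6, ...) {
  if (is.null(classifier))
    classifier <- function(model, state, ...) fires(model, state, ...)
  f <- function(s) classifier(model, as.numeric(anchor) + s * direction, ...)
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo == fhi)
    stop("no sign change in bracket [", lo, ", ", hi,
         "]; widen the bracket")
  n <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) == flo) lo <- mid else hi <- mid
    n <- n + 1L
    if (n > 200L) break
  }
  s <- (lo + hi) / 2
  list(state = as.numeric(anchor) + s * direction, s = s, n_iter = n)
}
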