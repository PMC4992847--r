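# ---------------------------------------------------------------------------
# Instantaneous threshold by bisection
# ---------------------------------------------------------------------------

#' Instantaneous threshold voltage for a frozen recovery state
#'
#' The instantaneous threshold `theta(X; i_e)` is the voltage such that
#' instantaneously shifting the membrane potential across it -- with the
#' recovery/gating coordinates frozen at `gating_state` -- flips the outcome
#' of the subsequent free evolution between action potential and
#' subthreshold response.  Found by deterministic bisection over the
#' voltage coordinate; a coarse pre-scan detects graded (quasi-threshold)
#' responses with several flips, in which case the flip nearest the resting
#' voltage is returned with a warning.  Hyperpolarised thresholds (brackets
#' below rest) are accepted.
#'
#' @param model A [neuron_model()].
#' @param gating_state Non-voltage coordinates (empty for QIF).
#' @param i_e_after Constant current applied during the free evolution.
#' @param bracket Voltage bracket `c(v_lo, v_hi)`.
#' @param tol Bisection tolerance (voltage units).
#' @param horizon,dt Free-evolution controls.
#' @param prescan Number of pre-scan nodes used to detect multiple flips.
#' @param rest_v Resting voltage used to pick among multiple flips.
#' @return Object of class `instantaneous_threshold` with `theta`,
#'   `gating_state`, `bracket`, `tol`, `n_flips`.
#' @export
instantaneous_threshold <- function(model, gating_state = numeric(0),
                                    i_e_after = 0, bracket, tol = 1e-4,
                                    horizon = model$horizon_default,
                                    dt = model$dt_default, prescan = 20L,
                                    rest_v = NULL) {
  if (length(gating_state) != model_dim(model) - 1)
    stop("gating_state must have length ", model_dim(model) - 1)
  cls <- function(v) fires(model, c(v, gating_state), horizon = horizon,
                           dt = dt, i_e = i_e_after)
  vs <- seq(bracket[1], bracket[2], length.out = max(2L, prescan))
  out <- vapply(vs, cls, logical(1))
  flips <- which(diff(out) != 0)
  if (!length(flips))
    stop("no spike/no-spike flip in bracket [", bracket[1], ", ",
         bracket[2], "] for the given gating state")
  if (length(flips) > 1) {
    warning(length(flips), " flips detected (graded/quasi-threshold ",
            "response); returning the flip nearest rest")
    if (is.null(rest_v)) rest_v <- bracket[1]
    flips <- flips[which.min(abs((vs[flips] + vs[flips + 1]) / 2 - rest_v))]
  }
  lo <- vs[flips]; hi <- vs[flips + 1]
  flo <- out[flips]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cls(mid) == flo) lo <- mid else hi <- mid
  }
  structure(list(theta = (lo + hi) / 2,
                 gating_state = gating_state, i_e_after = i_e_after,
                 bracket = bracket, tol = tol,
                 n_flips = length(which(diff(out) != 0))),
            class = "instantaneous_threshold")
}

#' @export
print.instantaneous_threshold <- function(x, ...) {
  cat("<instantaneous_threshold> theta =", signif(x$theta, 8),
      "(tol", x$tol, ")\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Voltage-clamp relaxation (closed form)
# ---------------------------------------------------------------------------

#' Closed-form gating relaxation under voltage clamp
#'
#' With the voltage held at `v_c` every recovery/gating coordinate relaxes
#' independently and exponentially:
#' `x(v_c, tau_c) = x_inf(v_c) + (x0 - x_inf(v_c)) exp(-tau_c / tau_x(v_c))`.
#' This is the exact solution of the clamped equations (the asymptote as
#' `tau_c -> Inf` is `x_inf(v_c)`).
#'
#' @param model A [neuron_model()].
#' @param x0 Initial recovery/gating coordinates.
#' @param v_c Clamped voltage.
#' @param tau_c Clamp duration (scalar or vector).
#' @return Relaxed coordinates; a matrix with one row per `tau_c` if
#'   `tau_c` is a vector.
#' @export
clamp_relax <- function(model, x0, v_c, tau_c) {
  tg <- adaptation_targets(model, v_c)
  if (length(x0) != length(tg$x_inf))
    stop("x0 must have length ", length(tg$x_inf))
  one <- function(tc) tg$x_inf + (x0 - tg$x_inf) * exp(-tc / tg$tau)
  if (length(tau_c) == 1) return(one(tau_c))
  out <- vapply(tau_c, one, numeric(length(x0)))
  out <- if (is.matrix(out)) t(out) else matrix(out, ncol = 1)
  colnames(out) <- names(tg$x_inf)
  out
}

#' Does the neuron fire after a voltage clamp?
#'
#' Computes the clamped gating state by [clamp_relax()] from the settled
#' rest, then classifies the free evolution from `(v_c, gating)` with no
#' further stimulus.  Equivalently: the neuron fires iff the clamped
#' voltage lies on the firing side of the instantaneous threshold
#' `theta(X(v_c, tau_c); 0)`.
#'
#' @param model A [neuron_model()].
#' @param rest_state Settled resting state (see [settle_rest()]).
#' @param v_c Clamped voltage.
#' @param tau_c Clamp duration.
#' @param horizon,dt Free-evolution controls.
#' @return Logical.
#' @export
post_clamp_fires <- function(model, rest_state, v_c, tau_c,
                             horizon = model$horizon_default,
                             dt = model$dt_default) {
  gating <- clamp_relax(model, rest_state[-1], v_c, tau_c)
  fires(model, c(v_c, gating), horizon = horizon, dt = dt, i_e = 0)
}

# ---------------------------------------------------------------------------
# Threshold evolution along a protocol
# ---------------------------------------------------------------------------

#' Threshold-evolution trace: ODE integration vs direct bisection
#'
#' Integrates the threshold-evolution equation
#' `dtheta/dt = (dtheta/di_e) di_e/dt + sum_x (dtheta/dx)(x_inf(v) - x)/tau_x(v)`
#' along a protocol, and (for cross-validation) also evaluates the
#' threshold by direct bisection on the same time grid.  Two protocol
#' families are supported:
#'
#' * a single `clamp` segment: the gating state follows the closed-form
#'   relaxation at `v_c` and the trace is `theta(X(v_c, t); 0)`.  For the
#'   piecewise-linear models the partials come from the analytic
#'   separatrix (line/plane); for Hodgkin-Huxley they are central finite
#'   differences of the bisection threshold.
#' * QIF under `dc`/`ramp` current: `theta(i_e(t))` with the analytic
#'   partial `dtheta/di_e = -1/sqrt(discriminant)`.
#'
#' @param model A [neuron_model()].
#' @param protocol A [stimulus_protocol()].
#' @param t_grid Time grid for the returned trace.
#' @param fd_step Finite-difference step per gating unit (HH).
#' @param tol Bisection tolerance for the direct trace.
#' @param rest_state Optional settled rest (computed if missing).
#' @param bracket Voltage bracket for the bisection trace.
#' @param method `"both"`, `"ode"` or `"bisect"`.
#' @param horizon,dt Free-evolution controls for the classifier.
#' @return Object of class `threshold_trace`: data frame `times`,
#'   `theta_ode`, `theta_bisect`.
#' @export
threshold_trace <- function(model, protocol, t_grid, fd_step = 5e-3,
                            tol = 1e-5, rest_state = NULL, bracket = NULL,
                            method = c("both", "ode", "bisect"),
                            horizon = model$horizon_default,
                            dt = model$dt_default) {
  method <- match.arg(method)
  parts <- protocol_parts(protocol)
  if (model$name == "qif") {
    res <- qif_threshold_trace(model, protocol, t_grid)
  } else if (!is.null(parts$clamp)) {
    res <- clamp_threshold_trace(model, parts$clamp$v_c, t_grid, fd_step,
                                 tol, rest_state, bracket, method, horizon,
                                 dt)
  } else {
    stop("threshold traces are implemented for clamp protocols and for ",
         "the QIF model under dc/ramp current")
  }
  structure(res, class = "threshold_trace")
}

qif_threshold_trace <- function(model, protocol, t_grid) {
  p <- model$params
  ie <- protocol_current(protocol, t_grid)
  disc <- (p$v_t + p$v_r)^2 - 4 * (p$v_r * p$v_t + ie)
  if (any(disc <= 0))
    stop("threshold undefined: i_e reaches rheobase at t = ",
         t_grid[which(disc <= 0)[1]])
  theta_exact <- ((p$v_t + p$v_r) + sqrt(disc)) / 2
  # ODE route: dtheta/dt = dtheta/di_e * di_e/dt on a refined grid
  tf <- seq(min(t_grid), max(t_grid), length.out = 2001)
  ief <- protocol_current(protocol, tf)
  discf <- (p$v_t + p$v_r)^2 - 4 * (p$v_r * p$v_t + ief)
  dthet <- -1 / sqrt(discf)            # dtheta/di_e
  steps <- (dthet[-1] + dthet[-length(dthet)]) / 2 * diff(ief)
  theta_f <- theta_exact[1] + c(0, cumsum(steps))
  theta_ode <- approx(tf, theta_f, xout = t_grid)$y
  list(times = t_grid, theta_ode = theta_ode, theta_bisect = theta_exact,
       partials = list(dtheta_die = -1 / sqrt(disc)), method = "analytic")
}

clamp_threshold_trace <- function(model, v_c, t_grid, fd_step, tol,
                                  rest_state, bracket, method, horizon, dt) {
  if (is.null(rest_state)) rest_state <- settle_rest(model)
  x0 <- rest_state[-1]
  tg <- adaptation_targets(model, v_c)
  X <- clamp_relax(model, x0, v_c, t_grid)
  if (is.null(dim(X))) X <- matrix(X, ncol = length(x0))
  if (is.null(bracket)) bracket <- default_bracket(model)

  bisect_at <- function(xg)
    instantaneous_threshold(model, xg, i_e_after = 0, bracket = bracket,
                            tol = tol, horizon = horizon, dt = dt,
                            rest_v = rest_state[1])$theta

  theta_bisect <- theta_ode <- rep(NA_real_, length(t_grid))
  if (method %in% c("both", "bisect"))
    theta_bisect <- vapply(seq_len(nrow(X)), function(i) bisect_at(X[i, ]),
                           numeric(1))

  if (method %in% c("both", "ode")) {
    grads <- analytic_theta_gradient(model)
    if (!is.null(grads)) {
      # constant partials: exact quadrature of the threshold ODE
      theta0 <- separatrix_theta(grads$sep, as.list(x0))
      terms <- vapply(seq_along(x0), function(j)
        grads$dtheta[j] * (tg$x_inf[j] - x0[j]) *
          (1 - exp(-t_grid / tg$tau[j])), numeric(length(t_grid)))
      theta_ode <- theta0 +
        if (is.matrix(terms)) rowSums(terms) else sum(terms)
    } else {
      # finite-difference gradients, sampled on internal nodes that resolve
      # the fastest gating transient (tau_m is sub-millisecond), then
      # spline-integrated
      tau_min <- min(tg$tau)
      extra <- min(t_grid) +
        tau_min * c(0.05, 0.1, 0.2, 0.35, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8)
      tnodes <- sort(unique(c(t_grid, extra[extra < max(t_grid)])))
      Xn <- clamp_relax(model, x0, v_c, tnodes)
      g <- vapply(seq_len(nrow(Xn)), function(i) {
        xg <- Xn[i, ]
        sum(vapply(seq_along(xg), function(j) {
          e <- rep(0, length(xg)); e[j] <- fd_step
          dth <- (bisect_at(xg + e) - bisect_at(xg - e)) / (2 * fd_step)
          dth * (tg$x_inf[j] - xg[j]) / tg$tau[j]
        }, numeric(1)))
      }, numeric(1))
      gfun <- splinefun(tnodes, g)
      tf <- seq(min(t_grid), max(t_grid), length.out = 4001)
      gf <- gfun(tf)
      h <- tf[2] - tf[1]
      cumint <- c(0, cumsum((gf[-1] + gf[-length(gf)]) / 2 * h))
      theta0 <- if (method == "both" && is.finite(theta_bisect[1]))
        theta_bisect[1] else bisect_at(X[1, ])
      theta_ode <- theta0 + approx(tf, cumint, xout = t_grid)$y
    }
  }
  list(times = t_grid, theta_ode = theta_ode, theta_bisect = theta_bisect,
       v_c = v_c, method = method)
}

default_bracket <- function(model) {
  switch(model$name,
    pwl2d = c(model$params$v_l + 0.1, model$params$v_r - 0.1),
    pwl3d = c(model$params$v_l + 0.1, model$params$v_r - 0.1),
    hh = c(-80, -20),
    fhn = , `boltzmann-fhn` = , fhn3d = c(-2, 1.5),
    qif = c(model$params$v_reset, model$params$v_peak))
}

# Constant threshold gradients for the models with an analytic separatrix;
# NULL when finite differences are needed.
analytic_theta_gradient <- function(model) {
  if (model$name == "pwl2d") {
    sep <- pwl2d_separatrix(model, i_e = 0)
    return(list(sep = sep, dtheta = c(w = 1 / sep$k_theta)))
  }
  if (model$name == "pwl3d") {
    sep <- pwl3d_separatrix(model, i_e = 0)
    n <- sep$normal
    return(list(sep = sep,
                dtheta = c(u = -n[2] / n[1], w = -n[3] / n[1])))
  }
  NULL
}

#' @export
print.threshold_trace <- function(x, ...) {
  cat("<threshold_trace>", length(x$times), "nodes")
  if (!is.null(x$v_c)) cat(", clamp at v_c =", x$v_c)
  cat("\n")
  ok <- is.finite(x$theta_ode) & is.finite(x$theta_bisect)
  if (any(ok))
    cat("  max |ode - bisect| =",
        signif(max(abs(x$theta_ode[ok] - x$theta_bisect[ok])), 4), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# First-order (single-exponential) reduction
# ---------------------------------------------------------------------------

#' Fit the first-order threshold equation to a trace
#'
#' Least-squares fit of `theta(t) = theta_inf + (theta0 - theta_inf)
#' exp(-t / tau_theta)`, the classic first-order threshold-accommodation
#' equation.  Initialisation is deterministic: on a uniform grid an exact
#' exponential satisfies the AR(1) relation
#' `theta_{i+1} = a + rho theta_i`, giving `tau = -dt/log(rho)` and
#' `theta_inf = a/(1 - rho)` by linear regression; a Nelder-Mead polish
#' follows.  A constant trace leaves `tau_theta` unidentifiable (flagged);
#' a non-monotone trace is fitted anyway but flagged.
#'
#' @param trace A `threshold_trace` (its ODE column, falling back to the
#'   bisection column) or a list/data frame with `times` and `theta`.
#' @param which For a `threshold_trace`: `"ode"` or `"bisect"`.
#' @return List: `theta_inf`, `tau_theta`, `theta0`, `rms_residual`,
#'   `flagged` (character vector of conditions).
#' @export
first_order_fit <- function(trace, which = c("ode", "bisect")) {
  which <- match.arg(which)
  if (inherits(trace, "threshold_trace")) {
    times <- trace$times
    theta <- if (which == "ode" && any(is.finite(trace$theta_ode)))
      trace$theta_ode else trace$theta_bisect
  } else {
    times <- trace$times; theta <- trace$theta
  }
  stopifnot(length(times) >= 10, all(is.finite(theta)))
  flagged <- character(0)

  if (diff(range(theta)) < 1e-12 * max(1, abs(theta[1]))) {
    return(list(theta_inf = mean(theta), tau_theta = NA_real_,
                theta0 = theta[1], rms_residual = 0,
                flagged = "constant trace: tau_theta unidentifiable"))
  }
  d <- diff(theta)
  if (any(d > 0) && any(d < 0) &&
      min(abs(range(d))) > 1e-9 * diff(range(theta)))
    flagged <- c(flagged, "non-monotone trace")

  # deterministic AR(1) initialisation (exact for a pure exponential)
  h <- diff(times)
  if (diff(range(h)) > 1e-8 * mean(h))
    stop("first_order_fit expects a uniform time grid")
  fit0 <- lm(theta[-1] ~ theta[-length(theta)])
  rho <- unname(coef(fit0)[2]); a <- unname(coef(fit0)[1])
  rho <- min(max(rho, 1e-8), 1 - 1e-10)
  tau0 <- -mean(h) / log(rho)
  inf0 <- a / (1 - rho)

  rss <- function(p) {
    pred <- p[1] + (theta[1] - p[1]) * exp(-(times - times[1]) / exp(p[2]))
    sum((theta - pred)^2)
  }
  op <- optim(c(inf0, log(tau0)), rss, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-15))
  theta_inf <- op$par[1]; tau_theta <- exp(op$par[2])
  list(theta_inf = theta_inf, tau_theta = tau_theta, theta0 = theta[1],
       rms_residual = sqrt(op$value / length(theta)), flagged = flagged)
}
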