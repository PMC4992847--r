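#' @useDynLib sepx, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats uniroot optim setNames splinefun coef lm approx
#' @importFrom utils modifyList write.csv read.csv
#' @importFrom tools file_ext
NULL

# ---------------------------------------------------------------------------
# Model registry
# ---------------------------------------------------------------------------

.model_registry <- list(
  qif = list(
    id = 1L, state_names = "v",
    params = list(v_r = 0, v_t = 30, v_peak = 40, v_reset = -5, C = 1),
    i_e_baseline = 0, ap_criterion = "reset",
    dt_default = 0.01, horizon_default = 100, rest_guess = NULL
  ),
  fhn = list(
    id = 2L, state_names = c("v", "w"),
    params = list(tau_w = 15, k_w = 1.25, b_w = 0.875, C = 1),
    i_e_baseline = 0, ap_criterion = 1.0,
    dt_default = 0.01, horizon_default = 100, rest_guess = NULL
  ),
  `boltzmann-fhn` = list(
    id = 3L, state_names = c("v", "w"),
    params = list(tau_w = 8, a = 2, b = 3, c = 0.27, C = 1),
    i_e_baseline = 0.62, ap_criterion = 1.0,
    dt_default = 0.01, horizon_default = 100, rest_guess = NULL
  ),
  fhn3d = list(
    id = 4L, state_names = c("v", "u", "w"),
    params = list(tau_w = 25, k_w = 1.25, b_w = 0,
                  tau_u = 15, k_u = 1.25, b_u = 0, C = 1),
    i_e_baseline = -2.5, ap_criterion = 1.0,
    dt_default = 0.01, horizon_default = 100, rest_guess = NULL
  ),
  pwl2d = list(
    id = 5L, state_names = c("v", "w"),
    params = list(k_l = -0.5, k_m = 0.5, k_r = -0.25,
                  b_l = 0, b_m = -1.5, b_r = 17.25,
                  v_l = 1.5, v_r = 25.0, tau_w = 5, k_w = 0.45, C = 1),
    i_e_baseline = 0, ap_criterion = 25.0,
    dt_default = 0.01, horizon_default = 100, rest_guess = NULL
  ),
  pwl3d = list(
    id = 6L, state_names = c("v", "u", "w"),
    params = list(k_l = -0.5, k_m = 0.95, k_r = -0.25,
                  b_l = 0, b_m = -2.175, b_r = 57.825,
                  v_l = 1.5, v_r = 50.0,
                  tau_u = 5, k_u = 0.45, tau_w = 10, k_w = 0.6, C = 1),
    i_e_baseline = 0, ap_criterion = 50.0,
    dt_default = 0.01, horizon_default = 100, rest_guess = NULL
  ),
  hh = list(
    id = 7L, state_names = c("V", "m", "h", "n"),
    params = list(C_m = 1, g_Na = 120, g_K = 36, g_L = 0.3,
                  E_Na = 50, E_K = -77, E_L = -54.4),
    i_e_baseline = 0, ap_criterion = 0.0,
    dt_default = 0.01, horizon_default = 100, rest_guess = NULL
  )
)

#' Available neuron models
#'
#' @return Character vector of model names accepted by [neuron_model()].
#' @export
list_models <- function() names(.model_registry)

#' Construct a neuron model from the built-in registry
#'
#' Each model is an excitable system written in the conductance-based normal
#' form: a voltage equation `C dv/dt = f(v, X) + i_e(t)` plus recovery/gating
#' variables that each relax as `dx/dt = (x_inf(v) - x) / tau_x(v)`.  The
#' registry holds the reference parameter sets:
#'
#' * `"qif"` -- quadratic integrate-and-fire,
#'   `dv/dt = (v - v_r)(v - v_t) + i_e` with reset at `v_peak`.
#' * `"fhn"` -- classic FitzHugh-Nagumo with a linear recovery nullcline
#'   `w = k_w v + b_w`.
#' * `"boltzmann-fhn"` -- FitzHugh-Nagumo with a Boltzmann (logistic)
#'   recovery nullcline `w_inf(v) = a / (1 + b exp(-v/c))`; a type I cell
#'   with a saddle whose stable manifolds form the separatrix.
#' * `"fhn3d"` -- FitzHugh-Nagumo with two recovery currents.
#' * `"pwl2d"`, `"pwl3d"` -- piecewise-linear voltage nullcline in three
#'   segments; the models with analytic separatrix line / plane.
#' * `"hh"` -- the classic Hodgkin-Huxley squid-axon equations (modern
#'   voltage convention, rest near -65 mV).
#'
#' @param name Model name, one of [list_models()].
#' @param params Named list of parameter overrides.
#' @param validate For `"boltzmann-fhn"`, check that the parameter set yields
#'   the expected three-equilibrium portrait (stable point, saddle, unstable
#'   node) and raise a fixture-validation error otherwise.
#' @return An object of class `neuron_model`.
#' @examples
#' m <- neuron_model("pwl2d")
#' eval_rhs(m, c(v = 0, w = 0), i_e = 0)
#' @export
neuron_model <- function(name, params = list(), validate = TRUE) {
  if (!name %in% names(.model_registry))
    stop("unknown model name '", name, "'; available: ",
         paste(list_models(), collapse = ", "))
  reg <- .model_registry[[name]]
  if (length(params)) {
    bad <- setdiff(names(params), names(reg$params))
    if (length(bad))
      stop("unknown parameter(s) for model '", name, "': ",
           paste(bad, collapse = ", "))
  }
  pars <- modifyList(reg$params, as.list(params))
  provenance <- setNames(
    ifelse(names(pars) %in% names(params), "user", "default"), names(pars))
  m <- structure(list(
    name = name, model_id = reg$id, state_names = reg$state_names,
    params = pars, C = if (name == "hh") pars$C_m else pars$C,
    i_e_baseline = reg$i_e_baseline, ap_criterion = reg$ap_criterion,
    dt_default = reg$dt_default, horizon_default = reg$horizon_default,
    provenance = provenance
  ), class = c(paste0("neuron_model_", sub("-", "_", name)), "neuron_model"))
  validate_model(m, portrait = validate)
  m
}

validate_model <- function(m, portrait = TRUE) {
  p <- m$params
  if (!all(vapply(p, is.numeric, logical(1))) ||
      !all(vapply(p, function(z) is.finite(z) && length(z) == 1, logical(1))))
    stop("all model parameters must be finite scalars")
  switch(m$name,
    qif = {
      if (!(p$v_peak > p$v_t && p$v_t > p$v_r && p$v_r > p$v_reset))
        stop("QIF parameters must satisfy v_peak > v_t > v_r > v_reset")
    },
    pwl2d = , pwl3d = {
      if (!(p$v_l < p$v_r)) stop("breakpoints must satisfy v_l < v_r")
      if (p$tau_w <= 0 || (m$name == "pwl3d" && p$tau_u <= 0))
        stop("time constants must be positive")
    },
    hh = {
      if (any(unlist(p[c("g_Na", "g_K", "g_L")]) <= 0))
        stop("HH conductances must be positive")
    },
    `boltzmann-fhn` = {
      if (isTRUE(portrait)) validate_bfhn_portrait(m)
    }
  )
  invisible(m)
}

# Fixture validation: the Boltzmann-FHN parameter set must produce the
# type I portrait (stable point < saddle < unstable node) under its
# baseline drive.
validate_bfhn_portrait <- function(m) {
  eq <- find_equilibria(m, i_e = m$i_e_baseline)
  cls <- vapply(eq, function(e) e$stability, character(1))
  ok <- length(eq) == 3 &&
    grepl("stable", cls[1]) && !grepl("unstable", cls[1]) &&
    cls[2] == "saddle" && cls[3] == "unstable node"
  if (!ok)
    stop("fixture validation failed for boltzmann-fhn: expected ",
         "stable point < saddle < unstable node, got [",
         paste(cls, collapse = ", "), "]")
  invisible(TRUE)
}

model_dim <- function(model) length(model$state_names)

# numeric parameter vector in the order the compiled right-hand sides expect
pack_params <- function(model) {
  p <- model$params
  switch(model$name,
    qif = c(p$v_r, p$v_t, p$v_peak, p$v_reset, p$C),
    fhn = c(p$tau_w, p$k_w, p$b_w, p$C),
    `boltzmann-fhn` = c(p$tau_w, p$a, p$b, p$c, p$C),
    fhn3d = c(p$tau_w, p$k_w, p$b_w, p$tau_u, p$k_u, p$b_u, p$C),
    pwl2d = c(p$k_l, p$k_m, p$k_r, p$b_l, p$b_m, p$b_r, p$v_l, p$v_r,
              p$tau_w, p$k_w, p$C),
    pwl3d = c(p$k_l, p$k_m, p$k_r, p$b_l, p$b_m, p$b_r, p$v_l, p$v_r,
              p$tau_u, p$k_u, p$tau_w, p$k_w, p$C),
    hh = c(p$C_m, p$g_Na, p$g_K, p$g_L, p$E_Na, p$E_K, p$E_L)
  )
}

#' @export
print.neuron_model <- function(x, ...) {
  cat("<neuron_model>", x$name, "\n")
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  if (x$i_e_baseline != 0) cat("  baseline drive i_e =", x$i_e_baseline, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Piecewise-linear voltage nullcline
# ---------------------------------------------------------------------------

#' Piecewise-linear voltage function f(v)
#'
#' Three-segment function `k_s v + b_s` with half-open segments: left for
#' `v < v_l`, middle for `v_l <= v < v_r`, right for `v >= v_r`.
#'
#' @param model A `pwl2d` or `pwl3d` [neuron_model()].
#' @param v Voltage (vectorised).
#' @return `f(v)`.
#' @export
piecewise_f <- function(model, v) {
  p <- model$params
  ifelse(v < p$v_l, p$k_l * v + p$b_l,
         ifelse(v < p$v_r, p$k_m * v + p$b_m, p$k_r * v + p$b_r))
}

#' Region of the voltage axis for a piecewise-linear model
#'
#' @inheritParams piecewise_f
#' @return `"left"`, `"middle"` or `"right"` (vectorised over `v`).
#' @export
pwl_region <- function(model, v) {
  p <- model$params
  ifelse(v < p$v_l, "left", ifelse(v < p$v_r, "middle", "right"))
}

pwl_segment_coef <- function(model, region) {
  p <- model$params
  switch(region,
    left = c(k = p$k_l, b = p$b_l),
    middle = c(k = p$k_m, b = p$b_m),
    right = c(k = p$k_r, b = p$b_r),
    stop("unknown region '", region, "'"))
}

# ---------------------------------------------------------------------------
# Right-hand side
# ---------------------------------------------------------------------------

#' Evaluate the model right-hand side
#'
#' @param model A [neuron_model()].
#' @param state Numeric state vector of the model's dimension.
#' @param i_e External current.
#' @return Vector of time derivatives, named as the state.
#' @export
eval_rhs <- function(model, state, i_e = 0) {
  if (length(state) != model_dim(model))
    stop("state has length ", length(state), " but model '", model$name,
         "' has dimension ", model_dim(model))
  if (!all(is.finite(state))) stop("non-finite state")
  dx <- rhs_cpp(model$model_id, pack_params(model), as.numeric(state), i_e)
  setNames(dx, model$state_names)
}

# ---------------------------------------------------------------------------
# Adaptation form: x_inf(v) and tau_x(v) for the non-voltage coordinates
# ---------------------------------------------------------------------------

#' Voltage-dependent targets and time constants of the recovery variables
#'
#' Every non-voltage coordinate of every model obeys
#' `dx/dt = (x_inf(v) - x) / tau_x(v)`; this returns both pieces, which is
#' what makes the voltage-clamp relaxation analytic ([clamp_relax()]).
#'
#' @param model A [neuron_model()].
#' @param v Voltage at which to evaluate.
#' @return List with named vectors `x_inf` and `tau` (empty for QIF).
#' @export
adaptation_targets <- function(model, v) {
  p <- model$params
  switch(model$name,
    qif = list(x_inf = numeric(0), tau = numeric(0)),
    fhn = list(x_inf = c(w = p$k_w * v + p$b_w), tau = c(w = p$tau_w)),
    `boltzmann-fhn` = list(
      x_inf = c(w = p$a / (1 + p$b * exp(-v / p$c))), tau = c(w = p$tau_w)),
    fhn3d = list(
      x_inf = c(u = p$k_u * v + p$b_u, w = p$k_w * v + p$b_w),
      tau = c(u = p$tau_u, w = p$tau_w)),
    pwl2d = list(x_inf = c(w = p$k_w * v), tau = c(w = p$tau_w)),
    pwl3d = list(x_inf = c(u = p$k_u * v, w = p$k_w * v),
                 tau = c(u = p$tau_u, w = p$tau_w)),
    hh = {
      r <- hh_rates(v)
      list(x_inf = r$x_inf, tau = r$tau)
    })
}

# ---------------------------------------------------------------------------
# Hodgkin-Huxley rate functions
# ---------------------------------------------------------------------------

#' Hodgkin-Huxley rate functions
#'
#' Standard squid-axon opening/closing rates in the modern voltage
#' convention (rest near -65 mV).  The removable singularities of `alpha_m`
#' (at -40 mV) and `alpha_n` (at -55 mV) are filled with their limits, so
#' all returned quantities are continuous in `V`.
#'
#' @param V Membrane potential in mV (scalar).
#' @return List with named vectors `alpha`, `beta`, `x_inf`
#'   (`= alpha/(alpha+beta)`) and `tau` (`= 1/(alpha+beta)`, ms), each with
#'   components `m`, `h`, `n`.
#' @export
hh_rates <- function(V) {
  if (!is.finite(V)) stop("V must be finite")
  phi <- function(u) ifelse(abs(u) < 1e-9, 1 + u / 2, u / (-expm1(-u)))
  a <- c(m = phi((V + 40) / 10),
         h = 0.07 * exp(-(V + 65) / 20),
         n = 0.1 * phi((V + 55) / 10))
  b <- c(m = 4 * exp(-(V + 65) / 18),
         h = 1 / (1 + exp(-(V + 35) / 10)),
         n = 0.125 * exp(-(V + 65) / 80))
  list(alpha = a, beta = b, x_inf = a / (a + b), tau = 1 / (a + b))
}

hh_rate_derivs <- function(V) {
  # d(alpha)/dV and d(beta)/dV, used by the analytic HH Jacobian
  phi <- function(u) ifelse(abs(u) < 1e-9, 1 + u / 2, u / (-expm1(-u)))
  dphi <- function(u) {
    if (abs(u) < 1e-6) return(0.5 + u / 6)
    e <- exp(-u)
    (1 - e - u * e) / (1 - e)^2
  }
  da <- c(m = dphi((V + 40) / 10) / 10,
          h = -0.07 * exp(-(V + 65) / 20) / 20,
          n = 0.1 * dphi((V + 55) / 10) / 10)
  s <- 1 / (1 + exp(-(V + 35) / 10))
  db <- c(m = -4 * exp(-(V + 65) / 18) / 18,
          h = s * (1 - s) / 10,
          n = -0.125 * exp(-(V + 65) / 80) / 80)
  list(dalpha = da, dbeta = db)
}

# ---------------------------------------------------------------------------
# Jacobian
# ---------------------------------------------------------------------------

#' Analytic Jacobian of the model right-hand side
#'
#' Exact derivatives for every model in the zoo.  For piecewise-linear
#' models the state must not sit exactly on a breakpoint unless `region`
#' names the segment to use.
#'
#' @param model A [neuron_model()].
#' @param state State vector.
#' @param i_e External current (enters only through segment selection).
#' @param region Optional region id (`"left"`, `"middle"`, `"right"`) for
#'   piecewise models, required at a breakpoint.
#' @return Square Jacobian matrix.
#' @export
jacobian <- function(model, state, i_e = 0, region = NULL) {
  p <- model$params
  v <- state[1]
  switch(model$name,
    qif = matrix(2 * v - p$v_r - p$v_t, 1, 1),
    fhn = matrix(c(1 - v^2, -1, p$k_w / p$tau_w, -1 / p$tau_w) / c(p$C, p$C, 1, 1),
                 2, 2, byrow = TRUE),
    `boltzmann-fhn` = {
      winf <- p$a / (1 + p$b * exp(-v / p$c))
      dwinf <- winf * (1 - winf / p$a) / p$c
      matrix(c((1 - v^2) / p$C, -1 / p$C, dwinf / p$tau_w, -1 / p$tau_w),
             2, 2, byrow = TRUE)
    },
    fhn3d = matrix(c((1 - v^2) / p$C, -1 / p$C, -1 / p$C,
                     p$k_u / p$tau_u, -1 / p$tau_u, 0,
                     p$k_w / p$tau_w, 0, -1 / p$tau_w), 3, 3, byrow = TRUE),
    pwl2d = {
      k <- pwl_jac_slope(model, v, region)
      matrix(c(k / p$C, -1 / p$C, p$k_w / p$tau_w, -1 / p$tau_w),
             2, 2, byrow = TRUE)
    },
    pwl3d = {
      k <- pwl_jac_slope(model, v, region)
      matrix(c(k / p$C, -1 / p$C, -1 / p$C,
               p$k_u / p$tau_u, -1 / p$tau_u, 0,
               p$k_w / p$tau_w, 0, -1 / p$tau_w), 3, 3, byrow = TRUE)
    },
    hh = {
      V <- state[1]; m <- state[2]; h <- state[3]; n <- state[4]
      r <- hh_rates(V); d <- hh_rate_derivs(V)
      J <- matrix(0, 4, 4)
      J[1, 1] <- (-p$g_Na * m^3 * h - p$g_K * n^4 - p$g_L) / p$C_m
      J[1, 2] <- -3 * p$g_Na * m^2 * h * (V - p$E_Na) / p$C_m
      J[1, 3] <- -p$g_Na * m^3 * (V - p$E_Na) / p$C_m
      J[1, 4] <- -4 * p$g_K * n^3 * (V - p$E_K) / p$C_m
      x <- c(m, h, n)
      for (j in 1:3) {
        J[j + 1, 1] <- d$dalpha[j] * (1 - x[j]) - d$dbeta[j] * x[j]
        J[j + 1, j + 1] <- -(r$alpha[j] + r$beta[j])
      }
      J
    })
}

pwl_jac_slope <- function(model, v, region) {
  p <- model$params
  if (is.null(region)) {
    if (v == p$v_l || v == p$v_r)
      stop("state sits on a breakpoint; pass the region id explicitly")
    region <- pwl_region(model, v)
  }
  unname(pwl_segment_coef(model, region)["k"])
}

# Finite-difference Jacobian (central differences); cross-check for the
# analytic forms.
jacobian_fd <- function(model, state, i_e = 0, h = 1e-6) {
  d <- model_dim(model)
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    e <- rep(0, d); e[j] <- h * max(1, abs(state[j]))
    J[, j] <- (eval_rhs(model, state + e, i_e) -
               eval_rhs(model, state - e, i_e)) / (2 * e[j])
  }
  J
}

# ---------------------------------------------------------------------------
# Equilibria
# ---------------------------------------------------------------------------

classify_stability <- function(ev) {
  re <- Re(ev)
  if (length(ev) == 1) return(if (re < 0) "stable" else "unstable")
  cplx <- any(abs(Im(ev)) > 1e-10)
  if (any(re > 1e-12) && any(re < -1e-12)) return("saddle")
  paste(if (all(re < 0)) "stable" else "unstable",
        if (cplx) "spiral" else "node")
}

make_equilibrium <- function(model, state, region = NA_character_,
                             reality = "real", i_e = 0) {
  J <- jacobian(model, state, i_e = i_e,
                region = if (is.na(region)) NULL else region)
  ed <- eigen(J)
  structure(list(
    state = setNames(as.numeric(state), model$state_names),
    region = region, reality = reality,
    stability = classify_stability(ed$values),
    eigenvalues = ed$values, eigenvectors = ed$vectors, jacobian = J,
    i_e = i_e), class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat("<equilibrium>",
      paste(names(x$state), signif(x$state, 6), sep = "=", collapse = ", "),
      "|", x$reality, x$stability,
      if (!is.na(x$region)) paste0("(", x$region, " segment)"), "\n")
  invisible(x)
}

#' Locate all equilibria of a model
#'
#' For piecewise-linear models each segment's linear fixed-point system is
#' solved exactly and the solution is flagged `real` or `virtual` according
#' to whether it lies inside the segment's own voltage region (a virtual
#' fixed point still organises the flow of neighbouring regions).  Smooth
#' models are scanned on a deterministic voltage grid and the bracketed
#' roots polished with [stats::uniroot()].  Each equilibrium carries the
#' eigen-decomposition of its Jacobian.
#'
#' @param model A [neuron_model()].
#' @param i_e Constant external current (defaults to the model's baseline
#'   drive, e.g. 0.62 for `boltzmann-fhn`).
#' @param window Voltage search window for smooth models.
#' @return List of `equilibrium` objects ordered by voltage.
#' @export
find_equilibria <- function(model, i_e = model$i_e_baseline, window = NULL) {
  p <- model$params
  eqs <- switch(model$name,
    qif = {
      disc <- (p$v_t + p$v_r)^2 - 4 * (p$v_r * p$v_t + i_e)
      if (disc < 0)
        stop("no equilibrium found: i_e = ", i_e,
             " is at or above rheobase (saddle-node regime)")
      roots <- ((p$v_t + p$v_r) + c(-1, 1) * sqrt(disc)) / 2
      lapply(roots, function(v) make_equilibrium(model, v, i_e = i_e))
    },
    pwl2d = , pwl3d = {
      ksum <- if (model$name == "pwl2d") p$k_w else p$k_u + p$k_w
      out <- list()
      for (reg in c("left", "middle", "right")) {
        co <- pwl_segment_coef(model, reg)
        if (abs(ksum - co["k"]) < 1e-14) next  # parallel: no fixed point
        v <- (co["b"] + i_e) / (ksum - co["k"])
        st <- if (model$name == "pwl2d") c(v, p$k_w * v)
              else c(v, p$k_u * v, p$k_w * v)
        reality <- if (pwl_region(model, v) == reg) "real" else "virtual"
        out[[length(out) + 1]] <-
          make_equilibrium(model, st, region = reg, reality = reality,
                           i_e = i_e)
      }
      out
    },
    # smooth scalar reductions: on the recovery nullclines the equilibrium
    # condition is a single equation in v
    fhn = , `boltzmann-fhn` = , fhn3d = , hh = {
      if (is.null(window))
        window <- if (model$name == "hh") c(-90, 20) else c(-3.5, 3.5)
      gfun <- equilibrium_residual(model, i_e)
      vs <- seq(window[1], window[2], length.out = 2001)
      gs <- vapply(vs, gfun, numeric(1))
      idx <- which(diff(sign(gs)) != 0)
      if (!length(idx))
        stop("no equilibrium found in search window [", window[1], ", ",
             window[2], "]")
      roots <- vapply(idx, function(i)
        uniroot(gfun, c(vs[i], vs[i + 1]), tol = 1e-12)$root, numeric(1))
      lapply(roots, function(v) {
        tg <- adaptation_targets(model, v)
        make_equilibrium(model, c(v, tg$x_inf), i_e = i_e)
      })
    })
  eqs[order(vapply(eqs, function(e) e$state[1], numeric(1)))]
}

equilibrium_residual <- function(model, i_e) {
  p <- model$params
  switch(model$name,
    fhn = function(v) v - v^3 / 3 - (p$k_w * v + p$b_w) + i_e,
    `boltzmann-fhn` = function(v)
      v - v^3 / 3 - p$a / (1 + p$b * exp(-v / p$c)) + i_e,
    fhn3d = function(v)
      v - v^3 / 3 - (p$k_u * v + p$b_u) - (p$k_w * v + p$b_w) + i_e,
    hh = function(v) {
      r <- hh_rates(v)
      (i_e - p$g_Na * r$x_inf["m"]^3 * r$x_inf["h"] * (v - p$E_Na) -
         p$g_K * r$x_inf["n"]^4 * (v - p$E_K) - p$g_L * (v - p$E_L)) / p$C_m
    })
}
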