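# ---------------------------------------------------------------------------
# Stimulus protocols
# ---------------------------------------------------------------------------

#' Stimulus segment constructors
#'
#' A protocol is an ordered list of segments.  Current segments (`dc`,
#' `step`, `ramp`) define `i_e(t)` on their time window (zero outside);
#' `impulse` is an instantaneous charge `q` applied at `t0`, realised as a
#' state jump `delta v = q / C`; `clamp` holds the voltage coordinate at
#' `v_c` for a duration `tau_c` while the other coordinates evolve, and may
#' only precede free evolution.
#'
#' @param amp,a0,a1 Current amplitudes.
#' @param t_start,t_end Segment window.
#' @param q Impulse charge.
#' @param t0 Impulse time.
#' @param v_c Clamped voltage.
#' @param tau_c Clamp duration.
#' @return A stimulus segment (list with a `kind` field).
#' @name stim_segments
NULL

#' @rdname stim_segments
#' @export
stim_dc <- function(amp, t_start = 0, t_end = Inf)
  list(kind = "dc", t_start = t_start, t_end = t_end, a0 = amp, a1 = amp)

#' @rdname stim_segments
#' @export
stim_step <- function(amp, t_start, t_end)
  list(kind = "step", t_start = t_start, t_end = t_end, a0 = amp, a1 = amp)

#' @rdname stim_segments
#' @export
stim_ramp <- function(a0, a1, t_start, t_end)
  list(kind = "ramp", t_start = t_start, t_end = t_end, a0 = a0, a1 = a1)

#' @rdname stim_segments
#' @export
stim_impulse <- function(q, t0)
  list(kind = "impulse", t_start = t0, t_end = t0, q = q)

#' @rdname stim_segments
#' @export
stim_clamp <- function(v_c, tau_c, t_start = 0)
  list(kind = "clamp", t_start = t_start, t_end = t_start + tau_c,
       v_c = v_c, tau_c = tau_c)

#' Assemble and validate a stimulus protocol
#'
#' @param ... Segments from the [stim_segments] constructors (or a single
#'   list of them).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(...) {
  segs <- list(...)
  if (length(segs) == 1 && is.list(segs[[1]]) && is.null(segs[[1]]$kind))
    segs <- segs[[1]]
  if (!all(vapply(segs, function(s) !is.null(s$kind), logical(1))))
    stop("malformed protocol: every segment needs a 'kind'")
  kinds <- vapply(segs, `[[`, character(1), "kind")
  bad <- setdiff(kinds, c("dc", "step", "ramp", "impulse", "clamp"))
  if (length(bad)) stop("unknown segment kind(s): ", paste(bad, collapse = ", "))
  clamps <- segs[kinds == "clamp"]
  if (length(clamps) > 1) stop("at most one clamp segment is supported")
  if (length(clamps) == 1) {
    cl <- clamps[[1]]
    if (cl$t_start != 0)
      stop("a clamp segment must start at t = 0 (before free evolution)")
    others <- segs[kinds != "clamp"]
    if (any(vapply(others, function(s) s$t_start < cl$t_end, logical(1))))
      stop("clamp segments may only appear before free-evolution segments")
  }
  cur <- segs[kinds %in% c("dc", "step", "ramp")]
  if (length(cur) > 1) {
    iv <- t(vapply(cur, function(s) c(s$t_start, s$t_end), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-12))
      stop("current segments overlap in time")
  }
  structure(list(segments = segs), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol>", length(x$segments), "segment(s)\n")
  for (s in x$segments)
    cat("  ", s$kind, " [", s$t_start, ", ", s$t_end, "]\n", sep = "")
  invisible(x)
}

protocol_parts <- function(protocol) {
  if (is.null(protocol)) return(list(clamp = NULL, impulses = list(),
                                     stim = matrix(0, 0, 4)))
  segs <- protocol$segments
  kinds <- vapply(segs, `[[`, character(1), "kind")
  clamp <- if (any(kinds == "clamp")) segs[[which(kinds == "clamp")]] else NULL
  impulses <- segs[kinds == "impulse"]
  cur <- segs[kinds %in% c("dc", "step", "ramp")]
  stim <- if (length(cur))
    t(vapply(cur, function(s) c(s$t_start, s$t_end, s$a0, s$a1), numeric(4)))
  else matrix(0, 0, 4)
  list(clamp = clamp, impulses = impulses, stim = stim)
}

# i_e(t) for a protocol (vectorised); impulses contribute nothing here.
protocol_current <- function(protocol, t) {
  parts <- protocol_parts(protocol)
  vapply(t, function(tt) {
    amp <- 0
    if (nrow(parts$stim)) for (r in seq_len(nrow(parts$stim))) {
      s <- parts$stim[r, ]
      if (tt >= s[1] && tt < s[2])
        amp <- amp + if (is.infinite(s[2]) || s[3] == s[4]) s[3] else
          s[3] + (s[4] - s[3]) * (tt - s[1]) / (s[2] - s[1])
    }
    amp
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Integration
# ---------------------------------------------------------------------------

new_trajectory <- function(model, times, states, ie, events) {
  colnames(states) <- model$state_names
  structure(list(times = times, states = states, stimulus = ie,
                 events = events, model = model$name),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$model, "|", length(x$times), "samples, t in [",
      min(x$times), ",", max(x$times), "]\n")
  if (nrow(x$events)) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events)))
      cat("   ", x$events$kind[i], "@", signif(x$events$time[i], 8), "\n")
  }
  invisible(x)
}

#' Integrate a neuron model under a stimulus protocol
#'
#' Deterministic fixed-step classic 4th-order Runge-Kutta.  During a clamp
#' segment the voltage coordinate is held at the clamped value while the
#' remaining coordinates evolve; impulses are applied as exact state jumps
#' `delta v = q / C` between steps; the QIF reset (`v <- v_reset` once
#' `v >= v_peak`) is applied at the first step that crosses the peak,
#' recording `spike_peak` and `reset` events.
#'
#' @param model A [neuron_model()].
#' @param state0 Initial state (ignored voltage under an initial clamp).
#' @param protocol A [stimulus_protocol()] or `NULL` for free evolution.
#' @param t_end End time.
#' @param dt Step size (default `model$dt_default`).
#' @param store_every Keep every `store_every`-th sample.
#' @param reset_cap Recorded-peak cap for the QIF overshoot step.
#' @return A `trajectory` object: `times`, `states` matrix, `stimulus`,
#'   `events` data frame.
#' @export
integrate_model <- function(model, state0, protocol = NULL, t_end,
                            dt = model$dt_default, store_every = 1L,
                            reset_cap = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (!all(is.finite(state0))) stop("state0 must be finite")
  if (length(state0) != model_dim(model))
    stop("state0 has length ", length(state0), " but model dimension is ",
         model_dim(model))
  if (is.null(reset_cap))
    reset_cap <- if (model$name == "qif") model$params$v_peak + 10 else Inf
  parts <- protocol_parts(protocol)

  events <- data.frame(time = numeric(0), kind = character(0))
  times <- numeric(0); states <- NULL; ie <- numeric(0)
  state <- as.numeric(state0)
  t_cur <- 0

  append_run <- function(res, drop_first) {
    if (res$err)
      stop("non-finite state at t = ", res$err_time,
           " during integration of '", model$name, "'")
    keep <- if (drop_first && length(res$times) > 1) -1L else TRUE
    times <<- c(times, res$times[keep])
    states <<- rbind(states, res$states[keep, , drop = FALSE])
    ie <<- c(ie, res$ie[keep])
    if (length(res$spike_t)) {
      events <<- rbind(events,
        data.frame(time = rep(res$spike_t, each = 2),
                   kind = rep(c("spike_peak", "reset"), length(res$spike_t))))
    }
    state <<- as.numeric(res$final_state)
  }

  run_span <- function(t0, t1, clamp, clamp_v) {
    if (t1 <= t0 + 1e-15) return(invisible())
    n <- max(1L, as.integer(round((t1 - t0) / dt)))
    res <- integrate_core(model$model_id, pack_params(model), state,
                          t0, dt, n, parts$stim, clamp, clamp_v, FALSE,
                          as.integer(store_every), reset_cap, -Inf, Inf)
    append_run(res, drop_first = t0 > 0)
    t_cur <<- t0 + n * dt
  }

  if (!is.null(parts$clamp)) {
    state[1] <- parts$clamp$v_c
    run_span(0, parts$clamp$t_end, TRUE, parts$clamp$v_c)
    events <- rbind(events, data.frame(time = t_cur, kind = "clamp_release"))
  }

  imp_t <- vapply(parts$impulses, `[[`, numeric(1), "t_start")
  ord <- order(imp_t)
  imp <- parts$impulses[ord]; imp_t <- imp_t[ord]
  for (k in seq_along(imp)) {
    run_span(t_cur, imp_t[k], FALSE, 0)
    state[1] <- state[1] + imp[[k]]$q / model$C
    if (is.null(states)) {  # impulse at t = 0 before any samples
      times <- c(times, t_cur); states <- matrix(state, 1)
      ie <- c(ie, 0)
    } else {
      times <- c(times, t_cur); states <- rbind(states, state)
      ie <- c(ie, ie[length(ie)])
    }
  }
  run_span(t_cur, t_end, FALSE, 0)
  if (is.null(states)) { times <- 0; states <- matrix(state, 1); ie <- 0 }
  events <- events[order(events$time), , drop = FALSE]
  rownames(states) <- NULL
  new_trajectory(model, times, states, ie, events)
}

# fast path: free evolution under constant current, no storage beyond summary
free_run_summary <- function(model, state0, horizon, dt = model$dt_default,
                             i_e = 0) {
  stim <- if (i_e != 0) matrix(c(0, Inf, i_e, i_e), 1, 4) else matrix(0, 0, 4)
  n <- max(1L, as.integer(round(horizon / dt)))
  res <- integrate_core(model$model_id, pack_params(model),
                        as.numeric(state0), 0, dt, n, stim, FALSE, 0, FALSE,
                        n, if (model$name == "qif")
                          model$params$v_peak + 10 else Inf, -Inf, Inf)
  if (res$err) stop("non-finite state at t = ", res$err_time)
  list(vmax = res$vmax, t_vmax = res$t_vmax, n_spikes = length(res$spike_t),
       final_state = res$final_state)
}

#' Does free evolution from a state produce an action potential?
#'
#' @param model A [neuron_model()].
#' @param state0 Initial state.
#' @param horizon Free-evolution horizon.
#' @param dt Step size.
#' @param i_e Constant current during the free evolution.
#' @return Logical.
#' @export
fires <- function(model, state0, horizon = model$horizon_default,
                  dt = model$dt_default, i_e = 0) {
  s <- free_run_summary(model, state0, horizon, dt, i_e)
  if (identical(model$ap_criterion, "reset")) s$n_spikes > 0
  else s$vmax >= model$ap_criterion
}

# ---------------------------------------------------------------------------
# Closed-form solution inside one linear region
# ---------------------------------------------------------------------------

#' Exact solution of a piecewise-linear model inside one region
#'
#' Within a single segment the system is affine-linear, so the solution is
#' the matrix-exponential closed form
#' `x(t) = x* + V exp(Lambda t) V^{-1} (x0 - x*)` around the segment's fixed
#' point `x*`.  The caller guarantees the trajectory stays in `region_id`
#' over `[0, t]`; a defective eigenbasis falls back to
#' [Matrix::expm()] (flagged in the `method` attribute).
#'
#' @param model A `pwl2d` or `pwl3d` [neuron_model()].
#' @param state0 Initial state.
#' @param region_id `"left"`, `"middle"` or `"right"`.
#' @param t Elapsed time (scalar).
#' @param i_e Constant current.
#' @return State vector at time `t`.
#' @export
linear_region_solution <- function(model, state0, region_id, t, i_e = 0) {
  if (!model$name %in% c("pwl2d", "pwl3d"))
    stop("closed-form region solution applies to piecewise-linear models")
  A <- jacobian(model, state0, i_e = i_e, region = region_id)
  xs <- pwl_segment_fixed_point(model, region_id, i_e)
  dx0 <- as.numeric(state0) - xs
  ed <- eigen(A)
  out <- if (rcond_complex(ed$vectors) > 1e-10) {
    sol <- ed$vectors %*% (exp(ed$values * t) * solve(ed$vectors, dx0))
    method <- "eigen"
    Re(sol)
  } else {
    method <- "expm"
    as.numeric(Matrix::expm(A * t) %*% dx0)
  }
  structure(setNames(as.numeric(xs + out), model$state_names),
            method = method)
}

rcond_complex <- function(M) {
  s <- svd(M)$d
  if (max(s) == 0) 0 else min(s) / max(s)
}

# segment fixed point (may be virtual), as a plain state vector
pwl_segment_fixed_point <- function(model, region_id, i_e = 0) {
  p <- model$params
  co <- pwl_segment_coef(model, region_id)
  ksum <- if (model$name == "pwl2d") p$k_w else p$k_u + p$k_w
  v <- (co["b"] + i_e) / (ksum - co["k"])
  unname(if (model$name == "pwl2d") c(v, p$k_w * v)
         else c(v, p$k_u * v, p$k_w * v))
}

# ---------------------------------------------------------------------------
# Action-potential classification
# ---------------------------------------------------------------------------

#' Classify a trajectory as action potential or subthreshold response
#'
#' The maximum voltage over the requested window is compared with the
#' model-specific criterion: 0 mV for Hodgkin-Huxley, the right breakpoint
#' of `f(v)` for the piecewise-linear models, 1.0 for the FitzHugh-Nagumo
#' family, and a reset event for QIF.
#'
#' @param traj A `trajectory`.
#' @param model The model that produced it.
#' @param window Time window `c(t0, t1)`; default is the free-evolution part
#'   (after the last clamp release) or the full trajectory.
#' @return List with `is_ap`, `v_max`, `t_of_max`.
#' @export
classify_ap <- function(traj, model, window = NULL) {
  if (is.null(window)) {
    rel <- traj$events$time[traj$events$kind == "clamp_release"]
    window <- c(if (length(rel)) max(rel) else min(traj$times),
                max(traj$times))
  }
  sel <- traj$times >= window[1] & traj$times <= window[2]
  if (!any(sel)) stop("empty classification window [", window[1], ", ",
                      window[2], "]")
  v <- traj$states[sel, 1]
  i <- which.max(v)
  v_max <- v[i]; t_of_max <- traj$times[sel][i]
  is_ap <- if (identical(model$ap_criterion, "reset")) {
    any(traj$events$kind == "spike_peak" &
          traj$events$time >= window[1] & traj$events$time <= window[2])
  } else v_max >= model$ap_criterion
  list(is_ap = is_ap, v_max = v_max, t_of_max = t_of_max)
}

# ---------------------------------------------------------------------------
# Settled resting state
# ---------------------------------------------------------------------------

#' Settle a model to its resting state
#'
#' Runs the model without stimulation (baseline drive only) for `t_settle`
#' time units and returns the final state; the residual derivative norm is
#' checked against `tol`.
#'
#' @param model A [neuron_model()].
#' @param t_settle Settling time (default 200).
#' @param dt Step size.
#' @param i_e Constant drive (defaults to the model's baseline).
#' @param tol Acceptable residual derivative norm.
#' @return Named resting state vector.
#' @export
settle_rest <- function(model, t_settle = 200, dt = model$dt_default,
                        i_e = model$i_e_baseline, tol = 1e-5) {
  guess <- switch(model$name,
    qif = {
      # analytic: lower root of the quadratic
      p <- model$params
      disc <- (p$v_t + p$v_r)^2 - 4 * (p$v_r * p$v_t + i_e)
      if (disc < 0) stop("no resting state: i_e at or above rheobase")
      return(setNames(((p$v_t + p$v_r) - sqrt(disc)) / 2, "v"))
    },
    hh = {
      v0 <- -65
      c(v0, unname(hh_rates(v0)$x_inf))
    },
    fhn = , fhn3d = , `boltzmann-fhn` = {
      v0 <- -1.2
      c(v0, unname(adaptation_targets(model, v0)$x_inf))
    },
    rep(0, model_dim(model)))
  s <- free_run_summary(model, guess, t_settle, dt, i_e)$final_state
  res <- eval_rhs(model, s, i_e)
  if (sqrt(sum(res^2)) > tol)
    warning("settled state residual ", signif(sqrt(sum(res^2)), 3),
            " exceeds tol = ", tol)
  setNames(as.numeric(s), model$state_names)
}

# ---------------------------------------------------------------------------
# Spike interruption by hyperpolarisation (QIF demonstration)
# ---------------------------------------------------------------------------

#' Can a hyperpolarising step interrupt an already-initiated spike?
#'
#' After the membrane potential has crossed the instantaneous threshold the
#' upstroke is fast but not instantaneous: a sufficiently strong and long
#' hyperpolarising current, which raises the threshold above the membrane
#' potential again, aborts the spike.  The outcome is monotone: once an
#' amplitude/duration suppresses the spike, any stronger or longer one does.
#'
#' @param model A `qif` [neuron_model()].
#' @param t_cross Time at which the baseline protocol has crossed threshold
#'   (the hyperpolarising step starts here).
#' @param I_hyp Magnitude of the hyperpolarising step (applied as
#'   `-abs(I_hyp)`).
#' @param dur Step duration.
#' @param protocol Baseline protocol; default: an impulse that lifts `v`
#'   just above `v_t`, which by itself always fires.
#' @param horizon,dt Integration controls.
#' @return Logical: does the spike still occur?
#' @export
abort_by_hyperpolarization <- function(model, t_cross = 0.02, I_hyp, dur,
                                       protocol = NULL,
                                       horizon = model$horizon_default,
                                       dt = model$dt_default) {
  if (model$name != "qif")
    stop("the spike-interruption demonstration is defined for the QIF model")
  p <- model$params
  if (is.null(protocol))
    protocol <- stimulus_protocol(stim_impulse(q = p$v_t + 1 - p$v_r, t0 = 0))
  segs <- protocol$segments
  if (abs(I_hyp) > 0 && dur > 0)
    segs[[length(segs) + 1]] <-
      stim_step(-abs(I_hyp), t_cross, t_cross + dur)
  rest <- settle_rest(model)
  traj <- integrate_model(model, rest, stimulus_protocol(segs),
                          t_end = horizon, dt = dt, store_every = 50L)
  any(traj$events$kind == "spike_peak")
}
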