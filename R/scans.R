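# ---------------------------------------------------------------------------
# Maximum-voltage maps over clamp / pulse parameter planes
# ---------------------------------------------------------------------------

new_vmax_map <- function(model, axis1, axis2, vmax, fired, protocol_kind,
                         fire_fun, axis_names, rest = NULL) {
  structure(list(axis1 = axis1, axis2 = axis2, vmax = vmax, fired = fired,
                 model = model$name, protocol_kind = protocol_kind,
                 criterion = model$ap_criterion, fire_fun = fire_fun,
                 axis_names = axis_names, model_obj = model, rest = rest),
            class = "vmax_map")
}

#' @export
print.vmax_map <- function(x, ...) {
  cat("<vmax_map>", x$model, x$protocol_kind, "scan:",
      length(x$axis1), "x", length(x$axis2), "cells (",
      paste(x$axis_names, collapse = " x "), ")\n")
  cat("  fired:", sum(x$fired, na.rm = TRUE), "cells;",
      sum(is.na(x$vmax)), "failed\n")
  invisible(x)
}

#' Maximum-voltage map after voltage clamps
#'
#' For every grid cell the gating state after clamping the settled rest at
#' `v_c` for `tau_c` is computed with the closed-form relaxation
#' ([clamp_relax()]); the model then evolves freely (no further stimulus)
#' and the maximum voltage is recorded.  The fire/no-fire border of the map
#' samples the projection of the separatrix onto the clamp parameter plane.
#'
#' @param model A [neuron_model()].
#' @param v_c_grid Clamp voltages (rows).
#' @param tau_c_grid Clamp durations (columns).
#' @param horizon Free-evolution horizon per cell.
#' @param dt Step size.
#' @param rest Settled resting state (computed once if missing).
#' @return A `vmax_map`; cells whose integration fails are `NaN` and
#'   reported in a warning summary.
#' @export
clamp_scan <- function(model, v_c_grid, tau_c_grid,
                       horizon = model$horizon_default,
                       dt = model$dt_default, rest = NULL) {
  stopifnot(length(v_c_grid) > 0, length(tau_c_grid) > 0)
  if (model_dim(model) < 2)
    stop("clamp scans need at least one recovery variable")
  if (is.null(rest)) rest <- settle_rest(model)
  x0 <- rest[-1]
  nv <- length(v_c_grid); nt <- length(tau_c_grid)
  vmax <- matrix(NA_real_, nv, nt)
  n_fail <- 0L
  for (i in seq_len(nv)) {
    gat <- clamp_relax(model, x0, v_c_grid[i], tau_c_grid)
    if (is.null(dim(gat))) gat <- matrix(gat, ncol = length(x0))
    for (j in seq_len(nt)) {
      s <- tryCatch(
        free_run_summary(model, c(v_c_grid[i], gat[j, ]), horizon, dt),
        error = function(e) NULL)
      if (is.null(s)) { vmax[i, j] <- NaN; n_fail <- n_fail + 1L }
      else vmax[i, j] <- if (identical(model$ap_criterion, "reset"))
        ifelse(s$n_spikes > 0, model$params$v_peak, s$vmax) else s$vmax
    }
  }
  if (n_fail > 0)
    warning(n_fail, " of ", nv * nt, " cells failed to integrate (NaN)")
  crit <- if (identical(model$ap_criterion, "reset"))
    model$params$v_peak else model$ap_criterion
  fired <- vmax >= crit
  fire_fun <- function(a1, a2)
    post_clamp_fires(model, rest, a1, a2, horizon = horizon, dt = dt)
  new_vmax_map(model, v_c_grid, tau_c_grid, vmax, fired, "clamp", fire_fun,
               c("v_c", "tau_c"), rest = rest)
}

#' Maximum-voltage map after current pulses
#'
#' Rectangular (`step`) or ramp current of each amplitude/duration is
#' applied from the settled rest, followed by free evolution; the maximum
#' voltage over the whole run is recorded.  The fire/no-fire border in the
#' amplitude-duration plane is the projection of the separatrix onto the
#' pulse parameter plane.
#'
#' @param model A [neuron_model()].
#' @param kind `"step"` or `"ramp"` (ramp rises linearly from 0 to the
#'   amplitude over the duration).
#' @param amp_grid Pulse amplitudes (rows).
#' @param dur_grid Pulse durations (columns).
#' @param horizon Post-pulse free-evolution horizon.
#' @param dt Step size.
#' @param rest Settled resting state (computed once if missing).
#' @return A `vmax_map`.
#' @export
pulse_scan <- function(model, kind = c("step", "ramp"), amp_grid, dur_grid,
                       horizon = model$horizon_default,
                       dt = model$dt_default, rest = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(amp_grid) > 0, length(dur_grid) > 0)
  if (is.null(rest)) rest <- settle_rest(model)
  base_ie <- model$i_e_baseline
  run <- function(amp, dur) {
    stim <- rbind(
      if (base_ie != 0) c(0, Inf, base_ie, base_ie),
      c(0, dur, if (kind == "step") amp else 0, amp))
    n <- max(1L, as.integer(round((dur + horizon) / dt)))
    res <- integrate_core(model$model_id, pack_params(model),
                          as.numeric(rest), 0, dt, n, stim, FALSE, 0, FALSE,
                          n, if (model$name == "qif")
                            model$params$v_peak + 10 else Inf, -Inf, Inf)
    if (res$err) stop("non-finite state at t = ", res$err_time)
    list(vmax = res$vmax, n_spikes = length(res$spike_t),
         final_state = res$final_state)
  }
  na <- length(amp_grid); nd <- length(dur_grid)
  vmax <- matrix(NA_real_, na, nd)
  n_fail <- 0L
  for (i in seq_len(na)) for (j in seq_len(nd)) {
    s <- tryCatch(run(amp_grid[i], dur_grid[j]), error = function(e) NULL)
    if (is.null(s)) { vmax[i, j] <- NaN; n_fail <- n_fail + 1L }
    else vmax[i, j] <- if (identical(model$ap_criterion, "reset"))
      ifelse(s$n_spikes > 0, model$params$v_peak, s$vmax) else s$vmax
  }
  if (n_fail > 0)
    warning(n_fail, " of ", na * nd, " cells failed to integrate (NaN)")
  crit <- if (identical(model$ap_criterion, "reset"))
    model$params$v_peak else model$ap_criterion
  fired <- vmax >= crit
  fire_fun <- function(a1, a2) {
    s <- run(a1, a2)
    if (identical(model$ap_criterion, "reset")) s$n_spikes > 0
    else s$vmax >= model$ap_criterion
  }
  new_vmax_map(model, amp_grid, dur_grid, vmax, fired, kind, fire_fun,
               c("amplitude", "duration"))
}

#' End state of a pulse protocol (helper for pulse-threshold analyses)
#'
#' @param model A [neuron_model()].
#' @param kind,amp,dur Pulse description as in [pulse_scan()].
#' @param rest Settled rest.
#' @param dt Step size.
#' @return State vector at the end of the pulse.
#' @export
pulse_end_state <- function(model, kind = c("step", "ramp"), amp, dur,
                            rest = NULL, dt = model$dt_default) {
  kind <- match.arg(kind)
  if (is.null(rest)) rest <- settle_rest(model)
  base_ie <- model$i_e_baseline
  stim <- rbind(
    if (base_ie != 0) c(0, Inf, base_ie, base_ie),
    c(0, dur, if (kind == "step") amp else 0, amp))
  n <- max(1L, as.integer(round(dur / dt)))
  res <- integrate_core(model$model_id, pack_params(model),
                        as.numeric(rest), 0, dt, n, stim, FALSE, 0, FALSE,
                        n, Inf, -Inf, Inf)
  if (res$err) stop("non-finite state at t = ", res$err_time)
  setNames(as.numeric(res$final_state), model$state_names)
}

# ---------------------------------------------------------------------------
# Boundary extraction
# ---------------------------------------------------------------------------

#' Extract the fire/no-fire boundary from a maximum-voltage map
#'
#' For each scan line (fixed first-axis value) the flips of the `fired`
#' indicator along the second axis are refined by deterministic bisection
#' of the map's underlying simulation to tolerance `tol`.  Lines with no
#' flip are omitted (and counted); lines with several flips return all of
#' them, flagged.  For clamp maps each boundary point is labelled
#' `"separatrix"` or `"zero-rate"` according to whether the release-time
#' voltage derivative is away from zero (low-voltage border, the projection
#' of the separatrix) or approximately zero (high-voltage border, the
#' `dv/dt = 0` line).
#'
#' @param map A `vmax_map` from [clamp_scan()] or [pulse_scan()].
#' @param tol Bisection tolerance on the second axis.
#' @return Object of class `threshold_boundary`: data frame with columns
#'   `axis1`, `axis2`, `direction` (`"on_to_off"`/`"off_to_on"`), `type`,
#'   `multiple`.
#' @export
extract_boundary <- function(map, tol = 1e-3) {
  stopifnot(inherits(map, "vmax_map"))
  rows <- list(); omitted <- 0L
  model_is_clamp <- map$protocol_kind == "clamp"
  for (i in seq_along(map$axis1)) {
    fr <- map$fired[i, ]
    ok <- !is.na(fr)
    flips <- which(diff(fr[ok]) != 0)
    if (!length(flips)) { omitted <- omitted + 1L; next }
    ax2 <- map$axis2[ok]
    for (k in flips) {
      lo <- ax2[k]; hi <- ax2[k + 1]
      flo <- fr[ok][k]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (map$fire_fun(map$axis1[i], mid) == flo) lo <- mid else hi <- mid
      }
      rows[[length(rows) + 1]] <- data.frame(
        axis1 = map$axis1[i], axis2 = (lo + hi) / 2,
        direction = if (flo) "on_to_off" else "off_to_on",
        multiple = length(flips) > 1)
    }
  }
  if (!length(rows))
    stop("no fire/no-fire flip on any scan line")
  df <- do.call(rbind, rows)
  names(df)[1:2] <- map$axis_names
  df$type <- NA_character_
  if (model_is_clamp) {
    model <- map$model_obj
    rest <- if (!is.null(map$rest)) map$rest else settle_rest(model)
    for (r in seq_len(nrow(df))) {
      gat <- clamp_relax(model, rest[-1], df[r, 1], df[r, 2])
      dv <- eval_rhs(model, c(df[r, 1], gat), i_e = 0)[1]
      # on the high-voltage border the release derivative itself vanishes;
      # on the separatrix border it stays away from zero
      dv_rest <- abs(eval_rhs(model, c(df[r, 1], rest[-1]), i_e = 0)[1])
      df$type[r] <- if (abs(dv) < 0.02 * max(1, dv_rest))
        "zero-rate" else "separatrix"
    }
  }
  structure(list(boundary = df, omitted = omitted, tol = tol,
                 model = map$model, protocol_kind = map$protocol_kind),
            class = "threshold_boundary")
}

#' @export
print.threshold_boundary <- function(x, ...) {
  cat("<threshold_boundary>", nrow(x$boundary), "points (",
      x$omitted, "lines without a flip )\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Analytic clamp boundary of the 2D piecewise-linear model
# ---------------------------------------------------------------------------

#' Analytic threshold clamping duration of the 2D piecewise-linear model
#'
#' Projecting the separatrix line into the clamp parameter plane: starting
#' from rest (`w = 0`), the clamped recovery variable
#' `w(tau_c) = k_w v_c (1 - exp(-tau_c/tau_w))` crosses the line
#' `w = k_theta v_c + b_theta` at
#' `tau_c = -tau_w log(1 - (k_theta v_c + b_theta)/(k_w v_c))`.
#' Defined for middle-region clamp voltages for which the crossing exists
#' (`NA` otherwise).
#'
#' @param model A `pwl2d` [neuron_model()].
#' @param v_c Clamp voltage (vectorised).
#' @param i_e Constant current defining the separatrix (0 after release).
#' @return Threshold clamp duration(s).
#' @export
pwl2d_clamp_boundary <- function(model, v_c, i_e = 0) {
  p <- model$params
  sep <- pwl2d_separatrix(model, i_e = i_e)
  arg <- 1 - (sep$k_theta * v_c + sep$b_theta) / (p$k_w * v_c)
  out <- ifelse(v_c >= p$v_l & v_c < p$v_r & arg > 0 & arg < 1,
                -p$tau_w * log(arg), NA_real_)
  unname(out)
}
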