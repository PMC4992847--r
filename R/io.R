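# ---------------------------------------------------------------------------
# Run configuration
# ---------------------------------------------------------------------------

#' Load and validate a run configuration (JSON or YAML)
#'
#' A configuration names a model (with optional parameter overrides), an
#' optional stimulus protocol, numerics and output paths.  Unknown keys are
#' rejected; the returned object echoes every default explicitly together
#' with its provenance (`"user"` or `"default"`), so a run is fully
#' reproducible from its echoed configuration (the package contains no
#' random number generation).
#'
#' Schema (all blocks optional except `model`):
#' \preformatted{
#' model:    name: one of list_models();  params: {symbol: value, ...}
#' protocol: [{kind: dc|step|ramp|impulse|clamp, ...segment fields}, ...]
#' numerics: dt, horizon, tol
#' outputs:  {trajectory: path, sidecar: path, ...}
#' }
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return Object of class `run_config`: `model` ([neuron_model()]),
#'   `protocol` ([stimulus_protocol()] or `NULL`), `numerics`, `outputs`,
#'   `echo` (fully-expanded configuration with provenance).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE),
    yaml = , yml = yaml::read_yaml(path),
    stop("unsupported config format '.", ext, "' (use JSON or YAML)"))
  known <- c("model", "protocol", "numerics", "outputs")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(raw$model) || is.null(raw$model$name))
    stop("config must contain model: name")
  bad <- setdiff(names(raw$model), c("name", "params"))
  if (length(bad))
    stop("unknown model config key(s): ", paste(bad, collapse = ", "))
  model <- neuron_model(raw$model$name,
                        params = as.list(raw$model$params))
  protocol <- NULL
  if (!is.null(raw$protocol)) {
    segs <- lapply(raw$protocol, function(s) {
      if (is.null(s$kind)) stop("malformed protocol: segment without kind")
      switch(s$kind,
        dc = stim_dc(s$amp, s$t_start %||% 0, s$t_end %||% Inf),
        step = stim_step(s$amp, s$t_start, s$t_end),
        ramp = stim_ramp(s$a0, s$a1, s$t_start, s$t_end),
        impulse = stim_impulse(s$q, s$t0 %||% 0),
        clamp = stim_clamp(s$v_c, s$tau_c, s$t_start %||% 0),
        stop("unknown protocol segment kind '", s$kind, "'"))
    })
    protocol <- stimulus_protocol(segs)
  }
  num_defaults <- list(dt = model$dt_default,
                       horizon = model$horizon_default, tol = 1e-4)
  bad <- setdiff(names(raw$numerics), names(num_defaults))
  if (length(bad))
    stop("unknown numerics key(s): ", paste(bad, collapse = ", "))
  numerics <- modifyList(num_defaults, as.list(raw$numerics))
  if (numerics$dt <= 0) stop("dt must be positive")
  if (numerics$horizon <= 0) stop("horizon must be positive")

  echo <- list(
    model = list(name = model$name, params = model$params,
                 provenance = as.list(model$provenance)),
    protocol = raw$protocol,
    numerics = c(numerics,
                 list(provenance = setNames(as.list(
                   ifelse(names(num_defaults) %in% names(raw$numerics),
                          "user", "default")), names(num_defaults)))),
    outputs = raw$outputs)
  structure(list(model = model, protocol = protocol, numerics = numerics,
                 outputs = raw$outputs, echo = echo),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> model:", x$model$name, "| dt =", x$numerics$dt,
      "horizon =", x$numerics$horizon, "\n")
  ov <- names(x$model$provenance)[x$model$provenance == "user"]
  if (length(ov)) cat("  user overrides:", paste(ov, collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Tabular output (CSV, 12 significant digits) + JSON sidecars
# ---------------------------------------------------------------------------

fmt12 <- function(x) {
  if (is.numeric(x)) formatC(x, format = "g", digits = 12) else as.character(x)
}

write_csv12 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt12), stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert package objects to data frames
#'
#' @param x A `trajectory`, `vmax_map` (long format), `threshold_trace` or
#'   `threshold_boundary`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  df <- data.frame(t = x$times, x$states, i_e = x$stimulus,
                   check.names = FALSE)
  ev <- rep("", nrow(df))
  if (nrow(x$events)) for (i in seq_len(nrow(x$events))) {
    j <- which.min(abs(df$t - x$events$time[i]))
    ev[j] <- if (nzchar(ev[j])) paste(ev[j], x$events$kind[i], sep = ";")
      else x$events$kind[i]
  }
  df$event <- ev
  df
}

#' @rdname as.data.frame.trajectory
#' @export
as.data.frame.vmax_map <- function(x, ...) {
  g <- expand.grid(a2 = x$axis2, a1 = x$axis1)
  df <- data.frame(a1 = g$a1, a2 = g$a2,
                   vmax = as.vector(t(x$vmax)),
                   fired = as.vector(t(x$fired)))
  names(df)[1:2] <- x$axis_names
  df
}

#' @rdname as.data.frame.trajectory
#' @export
as.data.frame.threshold_trace <- function(x, ...)
  data.frame(t = x$times, theta_ode = x$theta_ode,
             theta_bisect = x$theta_bisect)

#' @rdname as.data.frame.trajectory
#' @export
as.data.frame.threshold_boundary <- function(x, ...) x$boundary

#' Write a trajectory to CSV
#'
#' Columns: `t`, one per state variable, `i_e`, `event` (semicolon-joined
#' event flags).  Numeric formatting keeps 12 significant digits so that a
#' round trip through [read_trajectory()] reproduces the trajectory to
#' ~1e-12 relative error.
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) write_csv12(as.data.frame(traj), path)

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @param model The model that produced it (for state names).
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, model) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sn <- model$state_names
  ev <- df$event
  has <- which(!is.na(ev) & nzchar(ev))
  events <- if (length(has)) {
    do.call(rbind, lapply(has, function(j)
      data.frame(time = df$t[j],
                 kind = strsplit(ev[j], ";", fixed = TRUE)[[1]])))
  } else data.frame(time = numeric(0), kind = character(0))
  new_trajectory(model, df$t, as.matrix(df[sn]), df$i_e, events)
}

#' Write a maximum-voltage map (long format) to CSV
#'
#' @param map A `vmax_map`.
#' @param path Output path.
#' @export
write_vmax_map <- function(map, path) write_csv12(as.data.frame(map), path)

#' Write a threshold boundary to CSV
#'
#' @param boundary A `threshold_boundary`.
#' @param path Output path.
#' @export
write_boundary <- function(boundary, path)
  write_csv12(as.data.frame(boundary), path)

#' Write a threshold trace to CSV
#'
#' @param trace A `threshold_trace`.
#' @param path Output path.
#' @export
write_threshold_trace <- function(trace, path)
  write_csv12(as.data.frame(trace), path)

#' Write a JSON sidecar with analytic coefficients and the echoed config
#'
#' @param objects Named list of objects; `separatrix_line`,
#'   `threshold_plane` and `threshold_point` objects are serialised as
#'   their analytic coefficients, other entries as-is.
#' @param path Output `.json` path.
#' @param config Optional `run_config` whose echo is embedded.
#' @export
write_sidecar <- function(objects, path, config = NULL) {
  ser <- lapply(objects, function(o) {
    if (inherits(o, "separatrix_line"))
      list(type = "separatrix_line", k_theta = o$k_theta,
           b_theta = o$b_theta, validity = o$validity,
           firing_side = o$firing_side, i_e = o$i_e)
    else if (inherits(o, "threshold_plane"))
      list(type = "threshold_plane", normal = o$normal, point = o$point,
           r_i = o$r_i, r_j = o$r_j, firing_sign = o$firing_sign,
           i_e = o$i_e)
    else if (inherits(o, "threshold_point"))
      list(type = "threshold_point", theta = o$theta, v_rest = o$v_rest,
           i_e = o$i_e)
    else o
  })
  if (!is.null(config)) ser$config <- config$echo
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Command-line interface
# ---------------------------------------------------------------------------

cli_log <- function(...) cat(..., "\n", file = stderr())

cli_opts <- function(args) {
  opts <- list(); pos <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        opts[[key]] <- TRUE; i <- i + 1
      } else { opts[[key]] <- args[i + 1]; i <- i + 2 }
    } else { pos <- c(pos, a); i <- i + 1 }
  }
  list(opts = opts, pos = pos)
}

cli_model <- function(opts) {
  if (!is.null(opts$config)) {
    cfg <- load_config(opts$config)
    list(model = cfg$model, cfg = cfg)
  } else {
    if (is.null(opts$model)) stop("--model or --config is required")
    list(model = neuron_model(opts$model), cfg = NULL)
  }
}

num_opt <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Dispatches the `sepx` subcommands: `simulate`, `equilibria`,
#' `separatrix`, `threshold`, `clamp-scan`, `stim-scan`.  Used by the
#' `inst/cli/sepx.R` script; all results go to the `--out` CSV (with a JSON
#' sidecar for analytic coefficients) and one structured log line per stage
#' goes to stderr.  Everything is deterministic: repeated runs produce
#' byte-identical CSVs.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the primary result object.
#' @export
sepx_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cli_log("usage: sepx <simulate|equilibria|separatrix|threshold|",
            "clamp-scan|stim-scan> [--model M | --config F] [options]")
    return(invisible(NULL))
  }
  cmd <- args[1]
  pa <- cli_opts(args[-1])
  o <- pa$opts
  mc <- cli_model(o)
  model <- mc$model
  out <- o$out %||% stop("--out is required")
  dt <- num_opt(o, "dt", if (!is.null(mc$cfg)) mc$cfg$numerics$dt
                else model$dt_default)
  horizon <- num_opt(o, "horizon",
                     if (!is.null(mc$cfg)) mc$cfg$numerics$horizon
                     else model$horizon_default)
  t0 <- Sys.time()
  res <- switch(cmd,
    simulate = {
      protocol <- if (!is.null(mc$cfg)) mc$cfg$protocol else NULL
      state0 <- settle_rest(model, dt = dt)
      traj <- integrate_model(model, state0, protocol, t_end = horizon,
                              dt = dt)
      write_trajectory(traj, out)
      traj
    },
    equilibria = {
      eq <- find_equilibria(model, i_e = num_opt(o, "ie",
                                                 model$i_e_baseline))
      df <- do.call(rbind, lapply(eq, function(e)
        data.frame(t(e$state), region = e$region, reality = e$reality,
                   stability = e$stability)))
      write_csv12(df, out)
      eq
    },
    separatrix = {
      ie <- num_opt(o, "ie", 0)
      side <- sub("\\.csv$", ".json", out)
      if (model$name == "pwl2d") {
        sep <- pwl2d_separatrix(model, i_e = ie)
        vs <- seq(sep$validity[1], sep$validity[2], length.out = 201)
        write_csv12(data.frame(v = vs, w = sep$k_theta * vs + sep$b_theta),
                    out)
        write_sidecar(list(separatrix = sep), side, mc$cfg)
        sep
      } else if (model$name == "pwl3d") {
        sep <- pwl3d_separatrix(model, i_e = ie)
        write_sidecar(list(separatrix = sep), side, mc$cfg)
        sep
      } else if (model$name == "qif") {
        sep <- qif_threshold(model, i_e = ie)
        write_csv12(data.frame(theta = sep$theta, v_rest = sep$v_rest), out)
        write_sidecar(list(separatrix = sep), side, mc$cfg)
        sep
      } else {
        # numerical quasi-separatrix section through rest, along v
        rest <- settle_rest(model, dt = dt)
        bb <- bisect_boundary(model, NULL, rest, c(1, rep(0, model_dim(model) - 1)),
                              bracket = c(0, num_opt(o, "span", 60)),
                              tol = num_opt(o, "tol", 1e-4),
                              horizon = horizon, dt = dt)
        write_csv12(data.frame(t(setNames(bb$state, model$state_names))),
                    out)
        bb
      }
    },
    threshold = {
      vc <- num_opt(o, "vc", NA)
      tauc <- num_opt(o, "tauc", 10)
      if (is.na(vc)) stop("--vc is required for threshold traces")
      grid <- seq(0, tauc, length.out = as.integer(num_opt(o, "nodes", 21)))
      tr <- threshold_trace(model, stimulus_protocol(stim_clamp(vc, tauc)),
                            grid, method = o$method %||% "both",
                            horizon = horizon, dt = dt)
      write_threshold_trace(tr, out)
      tr
    },
    `clamp-scan` = {
      vgrid <- seq(num_opt(o, "v-from", -30), num_opt(o, "v-to", 40),
                   by = num_opt(o, "v-by", 0.5))
      tgrid <- seq(num_opt(o, "tau-by", 0.1), num_opt(o, "tau-to", 20),
                   by = num_opt(o, "tau-by", 0.1))
      map <- clamp_scan(model, vgrid, tgrid, horizon = horizon, dt = dt)
      write_vmax_map(map, out)
      if (!is.null(o$boundary))
        write_boundary(extract_boundary(map), o$boundary)
      map
    },
    `stim-scan` = {
      agrid <- seq(num_opt(o, "amp-from", 0), num_opt(o, "amp-to", 2),
                   length.out = as.integer(num_opt(o, "amp-n", 41)))
      dgrid <- seq(num_opt(o, "dur-by", 0.5), num_opt(o, "dur-to", 20),
                   by = num_opt(o, "dur-by", 0.5))
      map <- pulse_scan(model, o$kind %||% "step", agrid, dgrid,
                        horizon = horizon, dt = dt)
      write_vmax_map(map, out)
      if (!is.null(o$boundary))
        write_boundary(extract_boundary(map), o$boundary)
      map
    },
    stop("unknown subcommand '", cmd, "'"))
  cli_log(sprintf("sepx %s model=%s dt=%g horizon=%g elapsed=%.2fs",
                  cmd, model$name, dt, horizon,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(res)
}
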