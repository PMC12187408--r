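#' Write a trajectory to CSV (with JSON metadata sidecar)
#'
#' Columns are `time_min` followed by the channels with unit-suffixed names
#' (`M_cu`, `P_cu`, `sigma`; toggle: `A_cu`, `B_cu`, `sigma_A`,
#' `sigma_B`). Numbers are written with 17 significant digits so a
#' write/read round trip is bit-exact. Metadata (tier, seed, parameters)
#' goes to `<path>.json` unless `sidecar = FALSE`.
#'
#' @param traj a `burst_trajectory`.
#' @param path output CSV path.
#' @param sidecar write the JSON metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "burst_trajectory"))
  df <- as.data.frame(traj)
  names(df) <- vapply(names(df), function(nm) {
    if (nm == "time") "time_min"
    else if (nm %in% c("M", "P", "A", "B", "m", "p")) paste0(nm, "_cu")
    else nm
  }, character(1))
  cols <- lapply(df, function(col) {
    if (is.integer(col)) as.character(col) else sprintf("%.17g", col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  if (sidecar) {
    meta <- trajectory_meta(traj)
    meta_ser <- serialize_meta(meta)
    jsonlite::write_json(meta_ser, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

serialize_meta <- function(meta) {
  lapply(meta, function(v) {
    if (inherits(v, c("feedback_params", "toggle_params", "noise_scales",
                      "fixed_point", "noise_amplitudes")))
      lapply(unclass(v), function(x) if (is.list(x)) unclass(x) else x)
    else if (is.data.frame(v)) NULL  # switch histories go to their own CSV
    else v
  })
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A `burst_trajectory`; metadata is restored from the JSON sidecar
#'   if present (parameter lists come back as plain lists).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- sub("_cu$", "", names(df))
  nm[nm == "time_min"] <- "time"
  names(df) <- nm
  meta <- list()
  jp <- paste0(path, ".json")
  if (file.exists(jp)) meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
  sig <- intersect(c("sigma", "sigma_A", "sigma_B"), nm)
  for (s in sig) df[[s]] <- as.integer(df[[s]])
  for (s in setdiff(nm, sig)) df[[s]] <- as.double(df[[s]])
  new_trajectory(df$time, as.list(df[setdiff(nm, "time")]), meta = meta)
}

#' Read a run configuration file
#'
#' YAML with flat sections `model` (feedback keys `alpha_M`, `alpha_P`,
#' `mu_M`, `mu_P`, `h`, `P0`, `tau`, or toggle keys `alpha`, `mu`, `h`,
#' `P0` plus `motif: toggle`), `noise` (`omega`, `lam`, optional `V0`;
#' the strings `"Inf"`/`".inf"` are accepted), and `run` (`tier`, `T`,
#' `dt` or `sample_dt`, `seed`, `n_traj`, `discard`, `out`). All rates are
#' plain numbers (pre-compute expressions like ln2/30).
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with elements `model` (a
#'   parameters object), `noise`, and `run`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in c("model", "run"))
    if (is.null(cfg[[sec]])) stop("config is missing section `", sec, "`",
                                  call. = FALSE)
  num <- function(x) if (is.character(x)) as.numeric(x) else x
  ns <- cfg$noise
  noise <- noise_scales(
    omega = if (is.null(ns$omega)) Inf else num(ns$omega),
    lam = if (is.null(ns$lam)) Inf else num(ns$lam),
    V0 = if (is.null(ns$V0)) 523 else num(ns$V0))
  m <- cfg$model
  model <- if (identical(m$motif, "toggle")) {
    req <- c("alpha", "mu", "h", "P0")
    miss <- setdiff(req, names(m))
    if (length(miss)) stop("config [model] missing key(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    toggle_params(alpha = num(m$alpha), mu = num(m$mu), h = num(m$h),
                  P0 = num(m$P0), noise = noise)
  } else {
    req <- c("alpha_M", "alpha_P", "mu_M", "mu_P", "h", "P0", "tau")
    miss <- setdiff(req, names(m))
    if (length(miss)) stop("config [model] missing key(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    feedback_params(alpha_M = num(m$alpha_M), alpha_P = num(m$alpha_P),
                    mu_M = num(m$mu_M), mu_P = num(m$mu_P), h = num(m$h),
                    P0 = num(m$P0), tau = num(m$tau))
  }
  run <- cfg$run
  if (is.null(run$tier)) stop("config [run] missing key `tier`", call. = FALSE)
  structure(list(model = model, noise = noise, run = run), class = "run_config")
}

#' Run a simulation from a configuration
#'
#' Thin orchestration over the simulators: generates `n_traj` trajectories
#' of the configured tier (`full`, `copy-number-only`, `pdmp`, `cle`,
#' `lna`, `dde`, `toggle-ssa`, `toggle-cle`) with per-trajectory seeds
#' derived from the base seed, writes each as CSV plus JSON sidecar under
#' `out`, and returns the file paths.
#'
#' @param config a `run_config` from [read_run_config()], or a path to one.
#' @param out_dir output directory (overrides `run$out`); created if
#'   needed.
#' @return Character vector of trajectory CSV paths, invisibly.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  run <- config$run
  tier <- run$tier
  out_dir <- if (!is.null(out_dir)) out_dir
             else if (!is.null(run$out)) run$out else "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_traj <- if (is.null(run$n_traj)) 1L else as.integer(run$n_traj)
  base_seed <- if (is.null(run$seed)) 1L else as.integer(run$seed)
  T <- as.numeric(run$T)
  sample_dt <- if (!is.null(run$sample_dt)) as.numeric(run$sample_dt) else 1
  dt <- if (!is.null(run$dt)) as.numeric(run$dt) else 0.01
  paths <- character(n_traj)
  for (r in seq_len(n_traj)) {
    seed <- if (n_traj == 1L) base_seed else derive_seed(base_seed, r)
    tr <- switch(tier,
      "full" = ,
      "copy-number-only" = simulate_full(config$model, config$noise, T = T,
                                         sample_dt = sample_dt, seed = seed),
      "pdmp" = simulate_pdmp(config$model, lam = config$noise$lam, T = T,
                             sample_dt = sample_dt, seed = seed),
      "cle" = simulate_cle(config$model, config$noise, T = T, dt = dt,
                           seed = seed, sample_dt = sample_dt),
      "lna" = simulate_lna(config$model, config$noise, T = T, dt = dt,
                           seed = seed, sample_dt = sample_dt),
      "dde" = integrate_dde(config$model, T = T, dt = dt),
      "toggle-ssa" = simulate_toggle_ssa(config$model, T = T,
                                         sample_dt = sample_dt, seed = seed),
      "toggle-cle" = simulate_toggle_cle(config$model, T = T, dt = dt,
                                         seed = seed, sample_dt = sample_dt),
      stop("unknown tier: ", tier, call. = FALSE))
    paths[r] <- file.path(out_dir, sprintf("traj_%03d.csv", r))
    write_trajectory(tr, paths[r])
  }
  invisible(paths)
}

#' Compute and write an analytic spectrum from a configuration
#'
#' Deterministic (no simulation): evaluates [spectrum_analytic()] on a
#' uniform grid `[0, omega_max]` and writes columns `omega_per_min`,
#' `S_M`, `S_P`.
#'
#' @param config a `run_config` (or path); `run` may carry `omega_max`
#'   (default 1 /min) and `n_omega` (default 2000).
#' @param out_file output CSV (overrides `run$out`).
#' @return the output path, invisibly.
#' @export
run_spectrum <- function(config, out_file = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  run <- config$run
  omega_max <- if (is.null(run$omega_max)) 1 else as.numeric(run$omega_max)
  n_omega <- if (is.null(run$n_omega)) 2000L else as.integer(run$n_omega)
  grid <- seq(0, omega_max, length.out = n_omega)
  sp <- spectrum_analytic(grid, config$model, config$noise)
  out_file <- if (!is.null(out_file)) out_file
              else if (!is.null(run$out)) run$out else "spectrum.csv"
  df <- data.frame(omega_per_min = sprintf("%.17g", sp$omega),
                   S_M = sprintf("%.17g", sp$S_M),
                   S_P = sprintf("%.17g", sp$S_P))
  utils::write.csv(df, out_file, row.names = FALSE, quote = FALSE)
  invisible(out_file)
}

#' Run a relative-error sweep from a configuration
#'
#' Orchestrates [sweep_grid()]; `run` must carry `lambdas` and `omegas`
#' (vectors), and may override `tiers`, `T`, `discard`, `n_traj`. If the
#' output CSV already exists, completed `(lambda, omega, tier)` cells are
#' skipped and only missing ones are computed (resume support).
#'
#' @param config a `run_config` (or path).
#' @param out_file output CSV (overrides `run$out`).
#' @return the sweep data frame, invisibly.
#' @export
run_sweep <- function(config, out_file = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  run <- config$run
  out_file <- if (!is.null(out_file)) out_file
              else if (!is.null(run$out)) run$out else "sweep.csv"
  lambdas <- as.numeric(unlist(run$lambdas))
  omegas <- as.numeric(unlist(run$omegas))
  tiers <- if (is.null(run$tiers)) c("full", "cle", "lna", "lna-theory")
           else unlist(run$tiers)
  done <- NULL
  if (file.exists(out_file)) {
    done <- utils::read.csv(out_file)
    key <- function(l, o) paste(signif(l, 12), signif(o, 12))
    todo_l <- c(); todo_o <- c()
    for (l in lambdas) for (o in omegas)
      if (!any(key(done$lambda, done$omega) == key(l, o))) {
        todo_l <- c(todo_l, l); todo_o <- c(todo_o, o)
      }
    lambdas <- unique(todo_l); omegas <- unique(todo_o)
    if (length(lambdas) == 0L) {
      message("sweep already complete: ", out_file)
      return(invisible(done))
    }
  }
  sw <- sweep_grid(config$model, lambdas = lambdas, omegas = omegas,
                   tiers = tiers,
                   T = if (is.null(run$T)) 1e5 else as.numeric(run$T),
                   discard = if (is.null(run$discard)) 2000
                             else as.numeric(run$discard),
                   n_traj = run$n_traj,
                   base_seed = if (is.null(run$seed)) 1L
                               else as.integer(run$seed))
  out <- if (is.null(done)) sw else rbind(done, as.data.frame(sw))
  utils::write.csv(out, out_file, row.names = FALSE)
  invisible(out)
}

#' Extract toggle waiting times from a configuration
#'
#' Simulates the configured toggle tier (`toggle-ssa` or `toggle-cle`) and
#' applies [waiting_times()] with the reference procedure defaults
#' (sliding window 1000 min, threshold 4 cu), writing the dwell durations
#' as a one-column CSV.
#'
#' @param config a `run_config` (or path).
#' @param out_file output CSV (overrides `run$out`).
#' @return the `waiting_time_sample`, invisibly.
#' @export
run_waiting_times <- function(config, out_file = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  run <- config$run
  tier <- if (is.null(run$tier)) "toggle-ssa" else run$tier
  seed <- if (is.null(run$seed)) 1L else as.integer(run$seed)
  T <- as.numeric(run$T)
  sample_dt <- if (!is.null(run$sample_dt)) as.numeric(run$sample_dt) else 1
  tr <- switch(tier,
    "toggle-ssa" = simulate_toggle_ssa(config$model, T = T,
                                       sample_dt = sample_dt, seed = seed),
    "toggle-cle" = simulate_toggle_cle(config$model, T = T,
                                       dt = if (is.null(run$dt)) 1
                                            else as.numeric(run$dt),
                                       seed = seed, sample_dt = sample_dt),
    stop("waiting times need a toggle tier", call. = FALSE))
  wt <- waiting_times(tr,
    window = if (is.null(run$window)) 1000 else as.numeric(run$window),
    threshold = if (is.null(run$threshold)) 4 else as.numeric(run$threshold))
  out_file <- if (!is.null(out_file)) out_file
              else if (!is.null(run$out)) run$out else "waiting_times.csv"
  utils::write.csv(data.frame(duration_min = wt$durations), out_file,
                   row.names = FALSE)
  invisible(wt)
}
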