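#' Write a session to a plain-text archive directory
#'
#' Layout: `meta.json` (config echo and seed),
#' `calibration/stimulus_<s>/trial_<r>.csv` and
#' `test/stimulus_<s>/trial_<r>.csv`, each an `N x T` integer matrix without
#' headers. The round trip through [read_session()] is exact.
#'
#' @param session A [generate_session()] result.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "dni_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- session$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_group <- function(group, name) {
    for (s in seq_along(group)) {
      d <- file.path(dir, name, sprintf("stimulus_%d", s))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (r in seq_along(group[[s]]))
        utils::write.table(unclass(group[[s]][[r]]),
                           file.path(d, sprintf("trial_%d.csv", r)),
                           sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  write_group(session$calibration$responses, "calibration")
  write_group(session$test_pool, "test")
  invisible(dir)
}

#' Read a session archive written by [write_session()]
#'
#' @param dir Archive directory.
#' @return A `dni_session` (templates are regenerated from the stored
#'   config, responses are read back from the CSV trials).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cfg <- generator_config(S = meta$S, N = meta$N, T = meta$T,
                          dt_ms = meta$dt_ms, R_cal = meta$R_cal,
                          R_test = meta$R_test,
                          background_rate_hz = meta$background_rate_hz,
                          bump_rate_hz = meta$bump_rate_hz,
                          bump_sd_ms = meta$bump_sd_ms,
                          base_latency_ms = meta$base_latency_ms,
                          latency_spread_ms = meta$latency_spread_ms,
                          noise_model = meta$noise_model,
                          alpha = meta$alpha, beta = meta$beta,
                          seed = meta$seed)
  read_group <- function(name, n_trials) {
    lapply(seq_len(cfg$S), function(s) {
      d <- file.path(dir, name, sprintf("stimulus_%d", s))
      lapply(seq_len(n_trials), function(r) {
        m <- as.matrix(utils::read.table(
          file.path(d, sprintf("trial_%d.csv", r)), sep = ","))
        dimnames(m) <- NULL
        binned_response(m, dt_ms = cfg$dt_ms)
      })
    })
  }
  structure(list(
    calibration = calibration_set(read_group("calibration", cfg$R_cal),
                                  dt_ms = cfg$dt_ms),
    test_pool = read_group("test", cfg$R_test),
    templates = make_rate_templates(cfg),
    config = cfg), class = "dni_session")
}

#' Serialize fitted maps to JSON
#'
#' Writes the motor and sensory maps under `<dir>/maps/`; numeric content is
#' stored at full precision so the round trip through [read_maps()] is exact.
#'
#' @param motor_map,sensory_map Fitted maps.
#' @param dir Archive directory.
#' @return The maps directory, invisibly.
#' @export
write_maps <- function(motor_map, sensory_map, dir) {
  d <- file.path(dir, "maps")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  mm <- list(means = lapply(motor_map$means, unclass),
             gram = motor_map$gram, phi = motor_map$phi,
             gain = motor_map$gain, offset = motor_map$offset,
             d_center = motor_map$d_center, dt_ms = motor_map$dt_ms,
             offset_ms = motor_map$offset_ms,
             stimulus_labels = motor_map$stimulus_labels)
  jsonlite::write_json(mm, file.path(d, "motor_map.json"), digits = NA)
  jsonlite::write_json(unclass(sensory_map), file.path(d, "sensory_map.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(d)
}

#' Read maps written by [write_maps()]
#' @param dir Archive directory containing `maps/`.
#' @return List with elements `motor_map` and `sensory_map`.
#' @export
read_maps <- function(dir) {
  d <- file.path(dir, "maps")
  mm <- jsonlite::read_json(file.path(d, "motor_map.json"),
                            simplifyVector = TRUE)
  motor <- structure(list(
    means = lapply(seq_len(dim(mm$means)[1]), function(i)
      matrix(mm$means[i, , ], dim(mm$means)[2], dim(mm$means)[3])),
    gram = mm$gram, phi = mm$phi, gain = mm$gain,
    offset = as.numeric(mm$offset), d_center = as.numeric(mm$d_center),
    dt_ms = mm$dt_ms, offset_ms = mm$offset_ms,
    stimulus_labels = mm$stimulus_labels), class = "motor_map")
  sm <- jsonlite::read_json(file.path(d, "sensory_map.json"),
                            simplifyVector = TRUE)
  sensory <- structure(list(sites = matrix(unlist(sm$sites),
                                           ncol = 2, byrow = FALSE),
                            stimulus_ids = sm$stimulus_ids,
                            template_forces = matrix(unlist(sm$template_forces),
                                                     ncol = 2),
                            x0 = as.numeric(sm$x0), tie_rule = sm$tie_rule),
                       class = "sensory_map")
  list(motor_map = motor, sensory_map = sensory)
}

#' Export a trajectory as CSV
#'
#' Columns: `time_s, x_m, y_m, vx, vy, stimulus_id, fx_N, fy_N, converged`.
#'
#' @param traj A `dni_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- data.frame(time_s = traj$time_s, x_m = traj$x_m, y_m = traj$y_m,
                    vx = traj$vx, vy = traj$vy,
                    stimulus_id = traj$stimulus_id,
                    fx_N = traj$fx_N, fy_N = traj$fy_N,
                    converged = isTRUE(attr(traj, "converged")))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Assemble and validate a full experiment configuration
#'
#' Defaults follow the reference operating point of the interface: mass
#' 10 kg, viscosity 15 N s/m, isotropic stiffness 4 N/m, 5 ms bins over a
#' 600 ms window with zero offset, 1 s control steps.
#'
#' @param generator Named list overriding [generator_config()] defaults.
#' @param field Named list with `K`, `x0`, `workspace`.
#' @param plant Named list with `M`, `B`, `step_duration_s`.
#' @param binning Named list with `dt_ms`, `window_ms`, `offset_ms`.
#' @param runtime Named list with `max_steps`, `radius`, `max_speed`,
#'   `n_offline_traj`.
#' @param seed Integer master seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(generator = list(), field = list(),
                              plant = list(), binning = list(),
                              runtime = list(), seed = 1L) {
  binning_def <- list(dt_ms = 5, window_ms = 600, offset_ms = 0)
  binning <- utils::modifyList(binning_def, binning)
  ratio <- binning$window_ms / binning$dt_ms
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("validation error in field 'binning': dt_ms must divide window_ms",
         call. = FALSE)
  gen_args <- utils::modifyList(
    list(T = as.integer(round(ratio)), dt_ms = binning$dt_ms, seed = seed),
    generator)
  gen <- do.call(generator_config, gen_args)
  fld <- do.call(desired_field, utils::modifyList(list(K = 4), field))
  plt <- do.call(plant_params, plant)
  runtime <- list(max_steps = runtime$max_steps %||% 50,
                  radius = runtime$radius,
                  max_speed = runtime$max_speed %||% Inf,
                  n_offline_traj = runtime$n_offline_traj %||% 100)
  structure(list(generator = gen, field = fld, plant = plt,
                 binning = binning, runtime = runtime,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML or JSON
#'
#' Unset fields take the package defaults (see [experiment_config()]); an
#' empty file yields the all-default configuration. Validation failures name
#' the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("generator", "field", "plant", "binning", "runtime", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("validation error: unknown config field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(raw$field$K) && is.list(raw$field$K))
    raw$field$K <- matrix(unlist(raw$field$K), 2, 2, byrow = TRUE)
  if (!is.null(raw$field$workspace))
    raw$field$workspace <- unlist(raw$field$workspace)
  experiment_config(generator = raw$generator %||% list(),
                    field = raw$field %||% list(),
                    plant = raw$plant %||% list(),
                    binning = raw$binning %||% list(),
                    runtime = raw$runtime %||% list(),
                    seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save an experiment configuration to YAML
#' @param config An [experiment_config()].
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  out <- list(
    generator = unclass(config$generator),
    field = list(K = config$field$K, x0 = config$field$x0,
                 workspace = as.list(config$field$workspace)),
    plant = unclass(config$plant),
    binning = config$binning,
    runtime = config$runtime,
    seed = config$seed)
  out$field$K <- lapply(seq_len(2), function(i) as.numeric(config$field$K[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}
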