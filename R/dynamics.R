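#' Point-mass plant parameters
#'
#' A point mass moving on a plane through a viscous medium:
#' `M a + B v = F`. Forces decoded by the interface are held constant over
#' each control step (zero-order hold).
#'
#' @param M Mass (kg), default 10.
#' @param B Viscosity (N s/m), default 15.
#' @param step_duration_s Force-hold interval per control step (s), default 1.
#' @return Object of class `plant_params`.
#' @export
plant_params <- function(M = 10, B = 15, step_duration_s = 1) {
  if (M <= 0 || B <= 0 || step_duration_s <= 0)
    stop("M, B and step_duration_s must be positive", call. = FALSE)
  structure(list(M = M, B = B, step_duration_s = step_duration_s),
            class = "plant_params")
}

#' Point-mass state
#' @param position,velocity Numeric 2-vectors (m, m/s).
#' @param time Time stamp (s).
#' @return Object of class `point_mass_state`.
#' @export
point_mass_state <- function(position = c(0, 0), velocity = c(0, 0),
                             time = 0) {
  structure(list(position = as.numeric(position),
                 velocity = as.numeric(velocity), time = time),
            class = "point_mass_state")
}

#' Convergence criterion for closed-loop runs
#'
#' A trajectory counts as converged at the first recorded state whose
#' position lies within `radius` of the field equilibrium (and, if a finite
#' `max_speed` is set, whose speed is below it). When `radius` is `NULL` it
#' defaults at run time to 0.1 times the mean distance of the calibration
#' sites from the equilibrium, making the target region scale with the
#' geometry the calibration produced.
#'
#' @param radius Target radius (m) or `NULL` for the scale-free default.
#' @param max_speed Maximum speed (m/s) at the converged state; default `Inf`
#'   (position-only rule: under zero-order-hold stepping the mass keeps a
#'   residual step-boundary speed set by the local template force, so a tight
#'   speed gate would never fire).
#' @param path_subdivisions The plant path is continuous within each control
#'   step; the target region counts as reached if the closed-form path
#'   enters it at any of this many intermediate points per step (default 20;
#'   0 checks step boundaries only). Ignored when `max_speed` is finite.
#' @return Object of class `convergence_criterion`.
#' @export
convergence_criterion <- function(radius = NULL, max_speed = Inf,
                                  path_subdivisions = 20) {
  if (!is.null(radius) && radius <= 0)
    stop("radius must be positive", call. = FALSE)
  if (path_subdivisions < 0)
    stop("path_subdivisions must be >= 0", call. = FALSE)
  structure(list(radius = radius, max_speed = max_speed,
                 path_subdivisions = as.integer(path_subdivisions)),
            class = "convergence_criterion")
}

# does the closed-form path from `state` under constant `force` enter the
# target ball before the end of the step?
path_enters <- function(state, force, params, target, radius, nsub) {
  if (nsub < 1) return(FALSE)
  for (j in seq_len(nsub)) {
    st <- step_constant_force(state, force, params,
                              duration_s = params$step_duration_s * j / nsub)
    if (sqrt(sum((st$position - target)^2)) <= radius) return(TRUE)
  }
  FALSE
}

resolve_radius <- function(conv, sensory_map) {
  if (!is.null(conv$radius)) return(conv$radius)
  d <- sqrt(rowSums((sensory_map$sites -
                       matrix(sensory_map$x0, nrow(sensory_map$sites), 2,
                              byrow = TRUE))^2))
  0.1 * mean(d)
}

is_converged <- function(state, target, radius, max_speed) {
  sqrt(sum((state$position - target)^2)) <= radius &&
    sqrt(sum(state$velocity^2)) <= max_speed
}

#' Advance the point mass under a constant force
#'
#' Exact closed-form solution of `M a + B v = F` with `F` constant over the
#' step: `v(t) = F/B + (v0 - F/B) exp(-B t / M)` and
#' `x(t) = x0 + (F/B) t + (M/B)(v0 - F/B)(1 - exp(-B t / M))`, applied per
#' component.
#'
#' @param state A [point_mass_state()].
#' @param force Constant force 2-vector (N).
#' @param params A [plant_params()].
#' @param duration_s Hold duration; defaults to `params$step_duration_s`.
#' @return The new [point_mass_state()].
#' @export
step_constant_force <- function(state, force, params,
                                duration_s = params$step_duration_s) {
  force <- as.numeric(force)
  if (any(!is.finite(force)))
    stop("numeric error: non-finite force", call. = FALSE)
  vinf <- force / params$B
  decay <- exp(-params$B * duration_s / params$M)
  v <- vinf + (state$velocity - vinf) * decay
  x <- state$position + vinf * duration_s +
    (params$M / params$B) * (state$velocity - vinf) * (1 - decay)
  point_mass_state(x, v, state$time + duration_s)
}

#' Responder returning the per-stimulus mean calibration response
#'
#' The noiseless stand-in for the brain: every stimulus evokes exactly its
#' trial-averaged calibration response.
#'
#' @param calset A [calibration_set()].
#' @return A function `stimulus_id -> response matrix`.
#' @export
mean_responder <- function(calset) {
  means <- calset$means
  ids <- calset$stimulus_labels
  function(stimulus_id) means[[match(stimulus_id, ids)]]
}

#' Responder drawing from a per-stimulus pool of recorded responses
#'
#' Draws uniformly with replacement from the pool of the selected stimulus,
#' using the current R random stream.
#'
#' @param pool List of `S` lists of response matrices, indexed by stimulus.
#' @param stimulus_ids Stimulus ids matching the pool order (default
#'   `seq_along(pool)`).
#' @return A function `stimulus_id -> response matrix`.
#' @export
pool_responder <- function(pool, stimulus_ids = seq_along(pool)) {
  function(stimulus_id) {
    g <- pool[[match(stimulus_id, stimulus_ids)]]
    if (length(g) == 0)
      stop("simulation error: empty response pool for stimulus ",
           stimulus_id, call. = FALSE)
    g[[sample.int(length(g), 1)]]
  }
}

#' Run the closed loop: stimulate, decode, move
#'
#' Iterates the interface protocol: read the position, select the stimulus
#' (sensory map), obtain the evoked response from `responder`, decode the
#' force (motor map), and integrate the plant under that force for one step.
#' Stops when the convergence criterion is met at a step boundary or after
#' `max_steps` steps. Every intermediate quantity is recorded.
#'
#' @param start A [point_mass_state()] or a position 2-vector (velocity 0).
#' @param motor_map,sensory_map Fitted maps.
#' @param responder Function mapping a stimulus id to a response matrix.
#' @param params A [plant_params()].
#' @param max_steps Step budget (default 50).
#' @param conv A [convergence_criterion()].
#' @param volitional_force Constant force 2-vector (N) superposed on every
#'   decoded force, emulating a volitional command riding on the programmed
#'   field (shifts the equilibrium to `x0 + K^{-1} F_V`).
#' @param target Position whose neighbourhood counts as convergence; defaults
#'   to the field equilibrium recorded in the sensory map. Override it to
#'   analyse volitional runs against the shifted equilibrium.
#' @return Object of class `dni_trajectory`: a data frame with one row per
#'   recorded state (`step`, `time_s`, `x_m`, `y_m`, `vx`, `vy`,
#'   `stimulus_id`, `fx_N`, `fy_N` applied over the following step; `NA` on
#'   the final row) and attributes `converged`, `steps_to_convergence`,
#'   `target`, `radius`, `error` (message if the responder failed).
#' @export
run_closed_loop <- function(start, motor_map, sensory_map, responder,
                            params = plant_params(), max_steps = 50,
                            conv = convergence_criterion(),
                            volitional_force = c(0, 0), target = NULL) {
  if (!inherits(start, "point_mass_state")) start <- point_mass_state(start)
  radius <- resolve_radius(conv, sensory_map)
  if (is.null(target)) target <- sensory_map$x0
  nsub <- if (is.finite(conv$max_speed)) 0L else conv$path_subdivisions
  state_row <- function(k, state, s = NA_integer_, force = c(NA_real_, NA_real_))
    data.frame(step = k, time_s = state$time,
               x_m = state$position[1], y_m = state$position[2],
               vx = state$velocity[1], vy = state$velocity[2],
               stimulus_id = s, fx_N = force[1], fy_N = force[2])
  rows <- vector("list", max_steps + 1)
  state <- start
  converged <- FALSE
  steps_to_conv <- NA_integer_
  err <- NULL
  k <- 0
  repeat {
    if (is_converged(state, target, radius, conv$max_speed)) {
      converged <- TRUE
      steps_to_conv <- as.integer(k)
      rows[[k + 1]] <- state_row(k, state)
      break
    }
    if (k >= max_steps) {
      rows[[k + 1]] <- state_row(k, state)
      break
    }
    s <- select_stimulus(sensory_map, state$position)
    resp <- tryCatch(responder(s), error = function(e) e)
    if (inherits(resp, "error")) {
      err <- conditionMessage(resp)
      rows[[k + 1]] <- state_row(k, state, s)
      break
    }
    force <- decode_force(motor_map, resp) + volitional_force
    rows[[k + 1]] <- state_row(k, state, s, force)
    entered <- nsub > 0 &&
      path_enters(state, force, params, target, radius, nsub)
    state <- step_constant_force(state, force, params)
    k <- k + 1
    if (entered) {
      converged <- TRUE
      steps_to_conv <- as.integer(k)
      rows[[k + 1]] <- state_row(k, state)
      break
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(out, converged = converged,
            steps_to_convergence = steps_to_conv,
            target = target, radius = radius, error = err,
            class = c("dni_trajectory", class(out)))
}

#' Generate off-line trajectories from a response pool
#'
#' Runs the same protocol as [run_closed_loop()] with the responder replaced
#' by a seeded uniform draw (with replacement) from the per-stimulus test
#' pool, one trajectory per start.
#'
#' @param starts Matrix of starting positions (one per row) or a list of
#'   [point_mass_state()].
#' @param motor_map,sensory_map Fitted maps.
#' @param test_pool List of `S` per-stimulus lists of responses.
#' @param params A [plant_params()].
#' @param max_steps Step budget per trajectory.
#' @param conv A [convergence_criterion()].
#' @param seed Seed for the pool draws.
#' @param stimulus_ids Stimulus ids matching the pool order.
#' @return List of `dni_trajectory` objects.
#' @export
run_offline_trajectories <- function(starts, motor_map, sensory_map,
                                     test_pool, params = plant_params(),
                                     max_steps = 50,
                                     conv = convergence_criterion(),
                                     seed = 1L,
                                     stimulus_ids = seq_along(test_pool)) {
  if (is.matrix(starts))
    starts <- lapply(seq_len(nrow(starts)),
                     function(i) point_mass_state(starts[i, ]))
  if (any(vapply(test_pool, length, integer(1)) == 0))
    stop("simulation error: empty response pool", call. = FALSE)
  responder <- pool_responder(test_pool, stimulus_ids)
  withr::with_seed(seed, lapply(starts, function(st)
    run_closed_loop(st, motor_map, sensory_map, responder,
                    params = params, max_steps = max_steps, conv = conv)))
}

#' Equilibrium shift produced by a constant volitional force
#'
#' Superposing a constant force `F_V` on the programmed linear field
#' `-K (x - x0)` moves the equilibrium to `x0 + K^{-1} F_V`.
#'
#' @param field A [desired_field()] (or a 2 x 2 stiffness matrix / scalar).
#' @param F_V Volitional force 2-vector (N).
#' @return Equilibrium position 2-vector (m).
#' @export
volitional_equilibrium <- function(field, F_V) {
  if (inherits(field, "desired_field")) {
    K <- field$K; x0 <- field$x0
  } else {
    K <- if (length(field) == 1) diag(field, 2) else as.matrix(field)
    x0 <- c(0, 0)
  }
  if (abs(det(K)) < 1e-12) stop("singular stiffness matrix", call. = FALSE)
  as.vector(x0 + solve(K, as.numeric(F_V)))
}

#' Damping ratio of the ideal linear closed loop
#'
#' For the second-order plant `M a + B v + K x = 0` the damping ratio is
#' `B / (2 sqrt(M K))`; values above 1 mean the ideal (continuous, noiseless)
#' system is over-damped and approaches the equilibrium without oscillating.
#'
#' @param params A [plant_params()] (or mass `M` if `B` given separately).
#' @param K_scalar Stiffness magnitude (N/m).
#' @return Dimensionless damping ratio.
#' @export
damping_ratio <- function(params, K_scalar) {
  if (!inherits(params, "plant_params")) stop("need plant_params")
  if (K_scalar <= 0) stop("stiffness must be positive", call. = FALSE)
  params$B / (2 * sqrt(params$M * K_scalar))
}

#' Reference trajectory under the continuous desired field
#'
#' Integrates `M a + B v = -K (x - x0)` (the ideal field, bypassing the
#' interface) from a given initial state and returns positions at the
#' requested times. Used as the ideal trajectory for RMSE and as an
#' independent check of the stepped dynamics.
#'
#' @param start A [point_mass_state()] or position 2-vector.
#' @param field A [desired_field()].
#' @param params A [plant_params()].
#' @param times Increasing vector of times (s) at which to report the state.
#' @return Data frame `time_s, x_m, y_m, vx, vy`.
#' @export
ideal_trajectory <- function(start, field, params, times) {
  if (!inherits(start, "point_mass_state")) start <- point_mass_state(start)
  deriv <- function(t, y, p) {
    x <- y[1:2]; v <- y[3:4]
    a <- (as.vector(-field$K %*% (x - field$x0)) - params$B * v) / params$M
    list(c(v, a))
  }
  t_rel <- times - start$time
  stopifnot(all(diff(t_rel) > 0), t_rel[1] >= 0)
  tt <- unique(c(0, t_rel))
  sol <- deSolve::lsoda(c(start$position, start$velocity), tt, deriv,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  sol <- sol[match(t_rel, tt), , drop = FALSE]
  data.frame(time_s = times, x_m = sol[, 2], y_m = sol[, 3],
             vx = sol[, 4], vy = sol[, 5])
}

#' @export
print.dni_trajectory <- function(x, ...) {
  cat(sprintf("dni_trajectory: %d steps, converged = %s\n",
              max(x$step), attr(x, "converged")))
  NextMethod()
}
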