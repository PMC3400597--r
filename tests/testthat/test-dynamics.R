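test_that("the ZOH step matches the closed form and its limits", {
  p <- plant_params()        # M = 10 kg, B = 15 N s/m, 1 s steps
  s0 <- point_mass_state(c(0.3, -0.2), c(0.1, 0))
  # zero force from rest: equilibrium of the plant
  rest <- point_mass_state(c(1, 1))
  s1 <- step_constant_force(rest, c(0, 0), p)
  expect_equal(s1$position, c(1, 1))
  expect_equal(s1$velocity, c(0, 0))
  expect_equal(s1$time, 1)
  # frozen closed-form values for F = (15, 0) from rest over 1 s
  s2 <- step_constant_force(point_mass_state(), c(15, 0), p)
  expect_equal(s2$velocity[1], 0.7768698, tolerance = 1e-6)
  expect_equal(s2$position[1], 0.4820868, tolerance = 1e-6)
  # long horizon: terminal velocity F / B
  s3 <- step_constant_force(s0, c(3, -6), p, duration_s = 500)
  expect_equal(s3$velocity, c(3, -6) / 15, tolerance = 1e-9)
  # independent stiff-integrator cross-check on a generic step
  f <- c(4, -7)
  deriv <- function(t, y, parms) list(c(y[3:4], (f - p$B * y[3:4]) / p$M))
  sol <- deSolve::lsoda(c(s0$position, s0$velocity), c(0, 1), deriv,
                        parms = NULL, rtol = 1e-12, atol = 1e-12)
  s4 <- step_constant_force(s0, f, p)
  expect_equal(s4$position, unname(sol[2, 2:3]), tolerance = 1e-8)
  expect_equal(s4$velocity, unname(sol[2, 4:5]), tolerance = 1e-8)
  expect_error(step_constant_force(s0, c(NA, 0), p), "numeric error")
})

test_that("speed decays monotonically without applied force", {
  p <- plant_params()
  st <- point_mass_state(c(0, 0), c(0.8, -0.4))
  speeds <- numeric(10)
  for (k in 1:10) {
    st <- step_constant_force(st, c(0, 0), p, duration_s = 0.2)
    speeds[k] <- sqrt(sum(st$velocity^2))
  }
  expect_true(all(diff(speeds) < 0))
})

test_that("plant parameters and damping ratio follow the definitions", {
  expect_error(plant_params(M = 0), "positive")
  expect_equal(damping_ratio(plant_params(M = 1, B = 2), 1), 1)
  expect_equal(damping_ratio(plant_params(), 4), 15 / (2 * sqrt(40)))
  expect_gt(damping_ratio(plant_params(), 4), 1)     # over-damped defaults
  expect_lt(damping_ratio(plant_params(B = 1e-6), 4), 1e-6)
})

test_that("closed-loop runs converge, record every step and reproduce", {
  it <- fitted_interface(seed = 11)
  responder <- mean_responder(it$session$calibration)
  # start at the equilibrium: converged at step zero
  tr0 <- run_closed_loop(c(0, 0), it$motor, it$sensory, responder)
  expect_true(attr(tr0, "converged"))
  expect_equal(steps_to_convergence(tr0), 0)
  expect_equal(nrow(tr0), 1)

  tr <- run_closed_loop(c(1, -1), it$motor, it$sensory, responder)
  expect_true(attr(tr, "converged"))
  expect_true(all(diff(tr$time_s) > 0))
  expect_true(all(!is.na(tr$fx_N[-nrow(tr)])))
  expect_true(all(tr$stimulus_id[-nrow(tr)] %in% 1:4))

  # offline draws are reproducible from the seed
  starts <- grid_starts(3)
  t1 <- run_offline_trajectories(starts, it$motor, it$sensory,
                                 it$session$test_pool, seed = 42)
  t2 <- run_offline_trajectories(starts, it$motor, it$sensory,
                                 it$session$test_pool, seed = 42)
  expect_identical(t1, t2)

  # degenerate pool holding only the mean response equals the noiseless run
  mean_pool <- lapply(it$session$calibration$means, function(m) list(m))
  t3 <- run_offline_trajectories(starts, it$motor, it$sensory, mean_pool,
                                 seed = 1)
  t4 <- lapply(seq_len(nrow(starts)), function(i)
    run_closed_loop(starts[i, ], it$motor, it$sensory, responder))
  for (i in seq_along(t3))
    expect_equal(as.data.frame(t3[[i]]), as.data.frame(t4[[i]]))

  expect_error(run_offline_trajectories(starts, it$motor, it$sensory,
                                        list(list(), list(), list(), list())),
               "empty response pool")
})

test_that("a failing responder aborts with a partial trajectory", {
  it <- fitted_interface(seed = 11)
  n <- 0
  flaky <- function(s) {
    n <<- n + 1
    if (n > 3) stop("electrode dropped")
    it$session$calibration$means[[s]]
  }
  tr <- run_closed_loop(c(1, 1), it$motor, it$sensory, flaky)
  expect_false(attr(tr, "converged"))
  expect_match(attr(tr, "error"), "electrode dropped")
  expect_equal(nrow(tr), 4)   # three completed steps plus the aborted one
})

test_that("a constant volitional force shifts the equilibrium to K^-1 F_V", {
  fld <- desired_field()
  expect_equal(volitional_equilibrium(fld, c(0, 0)), c(0, 0))
  expect_equal(volitional_equilibrium(4, c(4, 0)), c(1, 0))
  expect_equal(volitional_equilibrium(desired_field(x0 = c(0.2, 0.1)),
                                      c(2, -2)), c(0.7, -0.4))
  expect_error(volitional_equilibrium(matrix(0, 2, 2), c(1, 0)), "singular")

  cal <- noiseless_calset()
  mm <- fit_motor_map(cal, fld)
  sm <- suppressWarnings(fit_sensory_map(mm, cal, fld))
  fv <- c(1, 0.5)
  pred <- volitional_equilibrium(fld, fv)
  tr <- run_closed_loop(c(-1, -1), mm, sm, mean_responder(cal),
                        volitional_force = fv, target = pred)
  expect_true(attr(tr, "converged"))
  expect_gt(sqrt(sum(pred^2)), attr(tr, "radius"))  # shifted, not at x0
})

test_that("the ideal continuous field contracts monotonically from rest", {
  fld <- desired_field()
  p <- plant_params()
  tr <- ideal_trajectory(point_mass_state(c(1, 0.5)), fld, p,
                         times = seq(0.5, 20, by = 0.5))
  d <- sqrt(tr$x_m^2 + tr$y_m^2)
  expect_true(all(diff(d) < 0))
  expect_lt(d[length(d)], 0.01)
})
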