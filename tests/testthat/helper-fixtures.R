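# Shared fixture builders. Everything is generated in code at test time.

# a small random calibration set with well-separated positive means
random_calset <- function(seed, S = 4, N = 3, T = 6, R = 3, noise_sd = 0.3) {
  withr::with_seed(seed, {
    means <- lapply(seq_len(S), function(s)
      matrix(stats::runif(N * T, 0, 4), N, T))
    responses <- lapply(means, function(m)
      lapply(seq_len(R), function(r)
        pmax(m + matrix(stats::rnorm(N * T, 0, noise_sd), N, T), 0)))
    calibration_set(responses, dt_ms = 5)
  })
}

# noiseless calibration: every trial equals its stimulus template
noiseless_calset <- function(config = generator_config(R_cal = 2, R_test = 0)) {
  tpl <- make_rate_templates(config)
  responses <- lapply(seq_len(config$S), function(s) {
    m <- matrix(tpl$lambda[s, , ], config$N, config$T)
    list(m, m)
  })
  calibration_set(responses, dt_ms = config$dt_ms)
}

# fitted maps for a default synthetic session
fitted_interface <- function(seed = 11, field = desired_field(), ...) {
  sess <- generate_session(generator_config(seed = seed, ...))
  mm <- fit_motor_map(sess$calibration, field)
  sm <- suppressWarnings(fit_sensory_map(mm, sess$calibration, field))
  list(session = sess, motor = mm, sensory = sm, field = field)
}

grid_starts <- function(n = 5, lim = 1) {
  as.matrix(expand.grid(seq(-lim, lim, length.out = n),
                        seq(-lim, lim, length.out = n)))
}

# independent plug-in MI oracle: explicit double loop over the joint table
mi_enumeration_oracle <- function(labels, responses) {
  n <- length(labels)
  ss <- unique(labels); rr <- unique(responses)
  mi <- 0
  for (s in ss) for (r in rr) {
    p_sr <- sum(labels == s & responses == r) / n
    if (p_sr > 0) {
      p_s <- sum(labels == s) / n
      p_r <- sum(responses == r) / n
      mi <- mi + p_sr * log2(p_sr / (p_s * p_r))
    }
  }
  mi
}
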