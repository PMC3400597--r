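#' Configuration of the stimulus-conditioned spike-count generator
#'
#' Describes a simulated recording session: `S` stimulation patterns, each
#' presented repeatedly while an `N`-neuron population response is binned into
#' `T` bins of width `dt_ms`. Stimulus identity is encoded in the latency of a
#' transient firing-rate bump riding on a background rate, so that the
#' information carried by the population lives in fine temporal structure:
#' with `latency_spread_ms = 0` all stimuli evoke identical expected
#' responses and the session is uninformative by construction.
#'
#' @param S Number of distinct stimulation patterns (>= 2).
#' @param N Number of recorded units (default 14, a typical multi-electrode
#'   session yield).
#' @param T Number of time bins per response.
#' @param dt_ms Bin width in milliseconds.
#' @param R_cal Calibration repetitions per stimulus.
#' @param R_test Test-pool repetitions per stimulus.
#' @param background_rate_hz Baseline firing rate common to all stimuli (Hz).
#' @param bump_rate_hz Peak amplitude of the stimulus-evoked rate transient
#'   (Hz). Zero gives a flat (background-only) template.
#' @param bump_sd_ms Temporal width (Gaussian s.d., ms) of the evoked bump.
#' @param base_latency_ms Response latency of the first stimulus (ms).
#' @param latency_spread_ms Latency separation between consecutive stimuli
#'   (ms); controls how informative the session is.
#' @param noise_model `"poisson"` or `"powerlaw"`. Under `"powerlaw"` each
#'   bin count has mean `m` and variance `alpha * m^beta`.
#' @param alpha,beta Parameters of the variance-mean power law (used when
#'   `noise_model = "powerlaw"`).
#' @param seed Integer seed; the whole session is reproducible from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(S = 4, N = 14, T = 120, dt_ms = 5,
                             R_cal = 100, R_test = 100,
                             background_rate_hz = 5, bump_rate_hz = 60,
                             bump_sd_ms = 12, base_latency_ms = 30,
                             latency_spread_ms = 40,
                             noise_model = c("poisson", "powerlaw"),
                             alpha = 0.7, beta = 0.93, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (S < 2 || N < 1 || T < 1)
    stop("configuration error: need S >= 2, N >= 1, T >= 1", call. = FALSE)
  if (dt_ms <= 0)
    stop("configuration error: dt_ms must be positive", call. = FALSE)
  if (R_cal < 2 || R_test < 0)
    stop("configuration error: need R_cal >= 2 and R_test >= 0", call. = FALSE)
  if (background_rate_hz < 0 || bump_rate_hz < 0 || latency_spread_ms < 0)
    stop("configuration error: rates and latency spread must be >= 0",
         call. = FALSE)
  if (alpha <= 0)
    stop("configuration error: alpha must be > 0", call. = FALSE)
  structure(list(S = as.integer(S), N = as.integer(N), T = as.integer(T),
                 dt_ms = as.numeric(dt_ms), R_cal = as.integer(R_cal),
                 R_test = as.integer(R_test),
                 background_rate_hz = as.numeric(background_rate_hz),
                 bump_rate_hz = as.numeric(bump_rate_hz),
                 bump_sd_ms = as.numeric(bump_sd_ms),
                 base_latency_ms = as.numeric(base_latency_ms),
                 latency_spread_ms = as.numeric(latency_spread_ms),
                 noise_model = noise_model, alpha = alpha, beta = beta,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Expected spike counts per bin for every stimulus
#'
#' Builds the `S x N x T` array of expected counts (the deterministic PSTH
#' templates underlying the generator). Each unit has a background rate plus
#' a Gaussian rate bump whose peak latency shifts by `latency_spread_ms` from
#' one stimulus to the next; unit-to-unit variation in amplitude, width and
#' base latency is drawn once from the configured seed, so the templates are
#' a deterministic function of the configuration.
#'
#' @param config A [generator_config()].
#' @return An object of class `rate_templates`: list with `lambda`
#'   (`S x N x T` array of expected counts per bin) and the `config`.
#' @export
make_rate_templates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  pars <- withr::with_seed(config$seed, {
    list(amp = config$bump_rate_hz * stats::runif(config$N, 0.5, 1.5),
         lat = config$base_latency_ms + stats::runif(config$N, 0, 25),
         sd  = config$bump_sd_ms * stats::runif(config$N, 0.8, 1.25))
  })
  t_mid <- (seq_len(config$T) - 0.5) * config$dt_ms
  lambda <- array(0, dim = c(config$S, config$N, config$T))
  for (s in seq_len(config$S)) {
    shift <- (s - 1) * config$latency_spread_ms
    for (n in seq_len(config$N)) {
      rate_hz <- config$background_rate_hz +
        pars$amp[n] * exp(-((t_mid - (pars$lat[n] + shift))^2) /
                            (2 * pars$sd[n]^2))
      lambda[s, n, ] <- rate_hz * config$dt_ms / 1000
    }
  }
  structure(list(lambda = lambda, config = config), class = "rate_templates")
}

#' Integer counts with prescribed mean and variance
#'
#' Draws non-negative integer counts whose first two moments match `m` and
#' `v` exactly. Over-dispersed targets (`v > m`) use a negative binomial,
#' `v = m` is Poisson, and under-dispersed targets (`v < m`) use a randomized
#' mixture of two binomial laws `Bin(n, m/n)`, `Bin(n+1, m/(n+1))` whose
#' variances bracket `v`. Targets below the minimum variance achievable for a
#' given mean on the integers (`frac(m) * (1 - frac(m))`) are clamped to the
#' two-point law on `floor(m)`, `floor(m) + 1`.
#'
#' @param m,v Vectors of target means and variances (recycled to a common
#'   length).
#' @return Integer vector of draws.
#' @keywords internal
rcounts_meanvar <- function(m, v) {
  n_draw <- max(length(m), length(v))
  m <- rep_len(m, n_draw); v <- rep_len(v, n_draw)
  out <- integer(n_draw)
  pos <- m > 0
  if (!any(pos)) return(out)
  m <- m[pos]; v <- v[pos]
  res <- integer(length(m))

  over  <- v > m * (1 + 1e-9)
  equi  <- !over & v >= m * (1 - 1e-9)
  under <- !over & !equi
  if (any(over)) {
    size <- m[over]^2 / (v[over] - m[over])
    res[over] <- stats::rnbinom(sum(over), size = size, mu = m[over])
  }
  if (any(equi)) res[equi] <- stats::rpois(sum(equi), m[equi])
  if (any(under)) {
    mu <- m[under]; vu <- v[under]
    fl <- floor(mu); q <- mu - fl
    vmin <- q * (1 - q)
    vu <- pmax(vu, vmin)                       # integer-support lower bound
    nstar <- ifelse(mu - vu > 0, mu^2 / (mu - vu), Inf)
    n1 <- pmax(floor(nstar), ceiling(mu))
    n1 <- pmin(n1, 1e6)
    n2 <- n1 + 1
    var1 <- mu * (1 - mu / n1)
    var2 <- mu * (1 - mu / n2)
    # weight on the lower-variance component; degenerate brackets -> w = 1
    w <- ifelse(var2 > var1, (var2 - vu) / (var2 - var1), 1)
    w <- pmin(pmax(w, 0), 1)
    pick1 <- stats::runif(length(mu)) < w
    nn <- ifelse(pick1, n1, n2)
    draw <- stats::rbinom(length(mu), size = nn, prob = mu / nn)
    # clamped cells: two-point law on floor(m), floor(m)+1 (minimal variance)
    clamp <- v[under] < vmin - 1e-12
    if (any(clamp))
      draw[clamp] <- fl[clamp] + stats::rbinom(sum(clamp), 1, q[clamp])
    res[under] <- draw
  }
  out[pos] <- res
  out
}

#' Sample one binned population response
#'
#' Draws an `N x T` matrix of non-negative integer spike counts for one
#' presentation of `stimulus_id`, from the expected-count templates and the
#' configured noise model. Uses the current R random stream: wrap calls in
#' [withr::with_seed()] (as [generate_session()] does) for reproducibility.
#'
#' @param templates A [make_rate_templates()] result.
#' @param stimulus_id Stimulus index in `1..S`.
#' @return A [binned_response()] matrix (`N x T`, integer counts).
#' @export
sample_binned_response <- function(templates, stimulus_id) {
  stopifnot(inherits(templates, "rate_templates"))
  cfg <- templates$config
  if (stimulus_id < 1 || stimulus_id > cfg$S)
    stop("stimulus_id out of range 1..S", call. = FALSE)
  lam <- templates$lambda[stimulus_id, , , drop = TRUE]
  lam <- matrix(lam, nrow = cfg$N, ncol = cfg$T)
  counts <- switch(cfg$noise_model,
    poisson  = matrix(stats::rpois(length(lam), lam), nrow = cfg$N),
    powerlaw = matrix(rcounts_meanvar(as.vector(lam),
                                      cfg$alpha * as.vector(lam)^cfg$beta),
                      nrow = cfg$N),
    stop("configuration error: unknown noise model ", cfg$noise_model,
         call. = FALSE))
  binned_response(counts, dt_ms = cfg$dt_ms)
}

#' Generate a full calibration + test session
#'
#' Samples `S x R_cal` calibration trials and `S x R_test` test-pool trials
#' from the same rate templates, entirely reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list of class `dni_session` with elements `calibration` (a
#'   [calibration_set()]), `test_pool` (list of `S` lists of responses),
#'   `templates` and `config`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  templates <- make_rate_templates(config)
  drawn <- withr::with_seed(config$seed, {
    cal <- lapply(seq_len(config$S), function(s)
      lapply(seq_len(config$R_cal), function(r)
        sample_binned_response(templates, s)))
    test <- lapply(seq_len(config$S), function(s)
      lapply(seq_len(config$R_test), function(r)
        sample_binned_response(templates, s)))
    list(cal = cal, test = test)
  })
  structure(list(calibration = calibration_set(drawn$cal,
                                               dt_ms = config$dt_ms),
                 test_pool = drawn$test,
                 templates = templates,
                 config = config),
            class = "dni_session")
}

#' Fit the variance-mean power law of spike counts
#'
#' Pools spike counts in post-stimulus windows across units (and, for a
#' calibration set, within each stimulus separately so that stimulus-locked
#' structure does not masquerade as noise), computes the across-trial mean
#' and variance of each (unit, window) cell, and fits
#' `log(var) = log(alpha) + beta * log(mean)` by least squares over cells
#' with positive mean and variance.
#'
#' @param responses Either a [calibration_set()] or a plain list of `N x T`
#'   count matrices recorded under one identical condition.
#' @param window_ms Window length for pooling counts (ms); `NULL` (default)
#'   keeps single bins. Must be a multiple of the bin width.
#' @param dt_ms Bin width, required when `responses` is a plain list and
#'   `window_ms` is given.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
fit_variance_mean_powerlaw <- function(responses, window_ms = NULL,
                                       dt_ms = NULL) {
  if (inherits(responses, "calibration_set")) {
    groups <- responses$responses
    dt_ms <- responses$dt_ms
  } else {
    groups <- list(responses)
  }
  agg <- function(mat) {
    mat <- unclass(mat) * 1.0
    if (is.null(window_ms)) return(mat)
    if (is.null(dt_ms))
      stop("dt_ms required to window a plain response list", call. = FALSE)
    k <- window_ms / dt_ms
    if (abs(k - round(k)) > 1e-9 || k < 1)
      stop("window_ms must be a positive multiple of dt_ms", call. = FALSE)
    k <- as.integer(round(k))
    nw <- ncol(mat) %/% k
    if (nw < 1) stop("window longer than the response", call. = FALSE)
    pool <- matrix(0, ncol(mat), nw)
    pool[cbind(seq_len(nw * k), rep(seq_len(nw), each = k))] <- 1
    mat %*% pool
  }
  mn <- c(); vr <- c()
  for (g in groups) {
    mats <- lapply(g, agg)
    arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
    mn <- c(mn, as.vector(apply(arr, c(1, 2), mean)))
    vr <- c(vr, as.vector(apply(arr, c(1, 2), stats::var)))
  }
  keep <- mn > 0 & vr > 0
  if (sum(keep) < 2 || length(unique(mn[keep])) < 2)
    stop("estimation error: fewer than 2 usable variance-mean points",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, log(mn[keep])), log(vr[keep]))
  c(alpha = unname(exp(fit$coefficients[1])),
    beta = unname(fit$coefficients[2]))
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "generator_config: S=%d stimuli, N=%d units, T=%d bins x %g ms\n",
    x$S, x$N, x$T, x$dt_ms))
  cat(sprintf("  R_cal=%d, R_test=%d, noise=%s, latency spread=%g ms, seed=%d\n",
              x$R_cal, x$R_test, x$noise_model, x$latency_spread_ms, x$seed))
  invisible(x)
}

#' @export
print.dni_session <- function(x, ...) {
  cat(sprintf("dni_session: %d calibration + %d test trials (%d stimuli)\n",
              x$config$S * x$config$R_cal, x$config$S * x$config$R_test,
              x$config$S))
  invisible(x)
}
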