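#' Equipopulated (quantile) discretization
#'
#' Assigns each value to one of `n_bins` bins so that bin populations are as
#' equal as possible: values are ranked (ties share the rank of their first
#' occurrence, hence identical values always share a bin) and the rank range
#' is split evenly. With distinct values the bin populations differ by at
#' most one.
#'
#' @param values Numeric vector, `length(values) >= n_bins`.
#' @param n_bins Number of bins (>= 2), default 5.
#' @return Integer vector of bin labels in `1..n_bins`.
#' @export
equipopulated_bins <- function(values, n_bins = 5) {
  if (n_bins < 2) stop("estimation error: n_bins must be >= 2", call. = FALSE)
  n <- length(values)
  if (n < n_bins)
    stop("estimation error: fewer values than bins", call. = FALSE)
  if (length(unique(values)) == 1) {
    warning("all values identical; a single bin is occupied", call. = FALSE)
    return(rep(1L, n))
  }
  r <- rank(values, ties.method = "min")
  as.integer(floor((r - 1) * n_bins / n) + 1L)
}

# plugin mutual information (bits) of a stimulus x response count table
mi_from_table <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  ps <- rowSums(p)
  pr <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(ps, pr)[nz]))
}

# plugin MI (bits) from a joint probability array p[s, r]
mi_from_probs <- function(p) {
  ps <- rowSums(p)
  pr <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(ps, pr)[nz]))
}

# first-order limited-sampling bias (bits) of plugin MI, from naive
# occupied-bin counts per stimulus
pt_bias <- function(tab) {
  n <- sum(tab)
  r_s <- apply(tab, 1, function(row) sum(row > 0))
  r_all <- sum(colSums(tab) > 0)
  (sum(r_s - 1) - (r_all - 1)) / (2 * n * log(2))
}

force_bin_matrix <- function(forces) {
  forces <- as.matrix(forces)
  if (ncol(forces) != 2)
    stop("dimension error: forces must be an n x 2 matrix", call. = FALSE)
  forces
}

#' Plugin mutual information between stimulus and decoded force
#'
#' Discretizes the two force components separately into equipopulated bins,
#' forms the joint (x-bin, y-bin) response alphabet, estimates probabilities
#' by counting, and evaluates the mutual information in bits. Because the
#' expected (template) force is in one-to-one correspondence with the
#' stimulus, the stimulus label stands in for the expected force.
#'
#' @param stimulus_labels Vector of stimulus labels, one per trial.
#' @param forces `n x 2` matrix of decoded forces (fx, fy).
#' @param n_bins Equipopulated bins per force component (default 5).
#' @return Mutual information (bits).
#' @export
mutual_information_plugin <- function(stimulus_labels, forces, n_bins = 5) {
  forces <- force_bin_matrix(forces)
  if (length(stimulus_labels) != nrow(forces))
    stop("dimension error: labels and forces differ in length", call. = FALSE)
  if (length(unique(stimulus_labels)) < 2)
    stop("need at least 2 distinct stimuli", call. = FALSE)
  bx <- equipopulated_bins(forces[, 1], n_bins)
  by <- equipopulated_bins(forces[, 2], n_bins)
  joint <- factor((bx - 1L) * n_bins + by, levels = seq_len(n_bins^2))
  mi_from_table(table(stimulus_labels, joint))
}

# helper shared by correct_bias and its bootstrap: the analytic + shuffle
# corrected estimator on pre-binned components
corrected_mi_binned <- function(stim, bx, by, n_bins, n_shuffles) {
  stim <- factor(stim)
  joint_levels <- seq_len(n_bins^2)
  joint <- function(x, y) factor((x - 1L) * n_bins + y, levels = joint_levels)
  tab <- table(stim, joint(bx, by))
  i_pl <- mi_from_table(tab)
  b_i <- pt_bias(tab)

  # conditional-independence model from empirical marginals
  tx <- table(stim, factor(bx, levels = seq_len(n_bins)))
  ty <- table(stim, factor(by, levels = seq_len(n_bins)))
  ps <- rowSums(tx) / sum(tx)
  p_ind <- matrix(0, nrow(tx), n_bins^2)
  for (s in seq_len(nrow(tx))) {
    px <- tx[s, ] / sum(tx[s, ])
    py <- ty[s, ] / sum(ty[s, ])
    p_ind[s, ] <- ps[s] * as.vector(t(outer(px, py)))
  }
  i_ind <- mi_from_probs(p_ind)
  b_ind <- pt_bias(tx) + pt_bias(ty)

  # shuffle: break within-stimulus correlation between the two components
  sh <- vapply(seq_len(n_shuffles), function(j) {
    bxs <- bx; bys <- by
    for (s in levels(stim)) {
      idx <- which(stim == s)
      bxs[idx] <- bxs[idx][sample.int(length(idx))]
      bys[idx] <- bys[idx][sample.int(length(idx))]
    }
    tsh <- table(stim, joint(bxs, bys))
    c(mi_from_table(tsh), pt_bias(tsh))
  }, numeric(2))
  i_sh <- mean(sh[1, ]); b_sh <- mean(sh[2, ])

  bias_shuffle <- (i_sh - b_sh) - (i_ind - b_ind)
  list(mi_plugin = i_pl,
       bias_analytic = b_i,
       bias_shuffle = bias_shuffle,
       mi_corrected = i_pl - b_i - bias_shuffle)
}

#' Bias-corrected mutual information estimate
#'
#' Applies the limited-sampling correction cascade to the plugin estimator:
#' (i) the first-order analytic bias term computed from occupied-bin counts
#' per stimulus is subtracted; (ii) a shuffle correction removes the extra
#' bias carried by the two-dimensional (joint fx, fy) alphabet, by comparing
#' the estimator on within-stimulus component-shuffled data against the
#' conditional-independence model built from the empirical marginals (the
#' two agree in expectation, so their difference is pure bias); (iii) a
#' bootstrap null - stimuli and forces paired at random - is run through the
#' same corrected estimator as a residual-bias diagnostic (expected about 0).
#' The reported fields satisfy
#' `mi_corrected = mi_plugin - bias_analytic - bias_shuffle`.
#'
#' @param stimulus_labels Vector of stimulus labels, one per trial (>= 2
#'   trials per stimulus).
#' @param forces `n x 2` matrix of decoded forces.
#' @param n_bins Equipopulated bins per component (default 5).
#' @param n_shuffles Shuffle repetitions (default 20).
#' @param n_bootstrap Bootstrap-null repetitions (default 20; 0 skips the
#'   diagnostic).
#' @param seed Optional seed scoping all shuffling and bootstrapping.
#' @return Object of class `mi_estimate`: `mi_plugin`, `mi_corrected`,
#'   `bias_analytic`, `bias_shuffle`, `bootstrap_null_mean`,
#'   `n_trials_per_stimulus` (all informations in bits).
#' @export
correct_bias <- function(stimulus_labels, forces, n_bins = 5,
                         n_shuffles = 20, n_bootstrap = 20, seed = NULL) {
  forces <- force_bin_matrix(forces)
  if (length(stimulus_labels) != nrow(forces))
    stop("dimension error: labels and forces differ in length", call. = FALSE)
  ntab <- table(stimulus_labels)
  if (length(ntab) < 2 || any(ntab < 2))
    stop("estimation error: need >= 2 trials for each of >= 2 stimuli",
         call. = FALSE)
  run <- function() {
    bx <- equipopulated_bins(forces[, 1], n_bins)
    by <- equipopulated_bins(forces[, 2], n_bins)
    est <- corrected_mi_binned(stimulus_labels, bx, by, n_bins, n_shuffles)
    boot <- NA_real_
    if (n_bootstrap > 0) {
      boot <- mean(vapply(seq_len(n_bootstrap), function(j) {
        perm <- sample.int(length(stimulus_labels))
        corrected_mi_binned(stimulus_labels[perm], bx, by, n_bins,
                            n_shuffles)$mi_corrected
      }, numeric(1)))
    }
    structure(c(est, list(bootstrap_null_mean = boot,
                          n_trials_per_stimulus = as.vector(ntab))),
              class = "mi_estimate")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("mi_estimate: plugin %.4f bits, corrected %.4f bits\n",
              x$mi_plugin, x$mi_corrected))
  cat(sprintf("  bias: analytic %.4f, shuffle %.4f; bootstrap null %.4f\n",
              x$bias_analytic, x$bias_shuffle, x$bootstrap_null_mean))
  invisible(x)
}

# aggregate adjacent time bins of a response matrix by an integer factor,
# after dropping offset bins from the front and truncating to the window
rebin_response <- function(mat, base_dt_ms, dt_ms, window_ms, offset_ms = 0) {
  mat <- unclass(mat)
  k <- dt_ms / base_dt_ms
  o <- offset_ms / base_dt_ms
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("configuration error: dt must be a multiple of the session bin width",
         call. = FALSE)
  if (abs(o - round(o)) > 1e-9 || o < 0)
    stop("configuration error: offset must align with the session bins",
         call. = FALSE)
  k <- as.integer(round(k)); o <- as.integer(round(o))
  nb <- window_ms / dt_ms
  if (abs(nb - round(nb)) > 1e-9 || nb < 1)
    stop("configuration error: dt must divide the window", call. = FALSE)
  nb <- as.integer(round(nb))
  if (o + nb * k > ncol(mat))
    stop("configuration error: offset + window exceeds the recorded response",
         call. = FALSE)
  sub <- mat[, o + seq_len(nb * k), drop = FALSE]
  pool <- matrix(0, ncol(sub), nb)
  pool[cbind(seq_len(nb * k), rep(seq_len(nb), each = k))] <- 1
  sub %*% pool
}

#' Sweep binning and population-size parameters
#'
#' For every combination of bin width, window duration, window offset and
#' unit fraction: rebins the session, refits the motor and sensory maps,
#' decodes the test pool to obtain the corrected mutual information between
#' stimulus (expected force) and decoded force, and runs off-line
#' trajectories to obtain the convergence rate and mean steps. Incompatible
#' grid points (bin width not dividing the window, window exceeding the
#' recording) are recorded with a note rather than failing the sweep.
#'
#' @param session A [generate_session()] result.
#' @param dt_list Bin widths to test (ms); multiples of the session bin.
#' @param window_list Window durations (ms).
#' @param offset_list Window offsets (ms).
#' @param unit_fractions Fractions of the population to keep (seeded
#'   subsample per fraction).
#' @param field A [desired_field()].
#' @param params A [plant_params()].
#' @param n_traj Off-line trajectories per grid point.
#' @param max_steps Step budget per trajectory.
#' @param n_shuffles Shuffles for the MI correction.
#' @param seed Seed for unit subsampling and trajectory draws.
#' @return Object of class `sweep_result`: data frame with one row per grid
#'   point (`dt_ms, window_ms, offset_ms, unit_fraction, n_units,
#'   mi_corrected, convergence_rate, mean_steps, note`).
#' @export
parameter_sweep <- function(session, dt_list, window_list = 600,
                            offset_list = 0, unit_fractions = 1,
                            field = desired_field(),
                            params = plant_params(), n_traj = 30,
                            max_steps = 50, n_shuffles = 10, seed = 1L) {
  stopifnot(inherits(session, "dni_session"))
  cfg <- session$config
  base_dt <- cfg$dt_ms
  grid <- expand.grid(dt_ms = dt_list, window_ms = window_list,
                      offset_ms = offset_list,
                      unit_fraction = unit_fractions,
                      KEEP.OUT.ATTRS = FALSE)
  unit_sets <- withr::with_seed(seed, {
    sets <- list()
    for (f in sort(unique(unit_fractions))) {
      nu <- max(1L, as.integer(round(cfg$N * f)))
      sets[[as.character(f)]] <- sort(sample.int(cfg$N, nu))
    }
    sets
  })
  starts <- withr::with_seed(seed + 1L, {
    ws <- field$workspace
    cbind(stats::runif(n_traj, ws["xmin"], ws["xmax"]),
          stats::runif(n_traj, ws["ymin"], ws["ymax"]))
  })
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    units <- unit_sets[[as.character(g$unit_fraction)]]
    res <- tryCatch({
      reb <- function(m) rebin_response(unclass(m)[units, , drop = FALSE],
                                        base_dt, g$dt_ms, g$window_ms,
                                        g$offset_ms)
      cal <- calibration_set(lapply(session$calibration$responses,
                                    function(gr) lapply(gr, reb)),
                             dt_ms = g$dt_ms, offset_ms = g$offset_ms)
      mm <- fit_motor_map(cal, field)
      sm <- fit_sensory_map(mm, cal, field)
      pool <- lapply(session$test_pool, function(gr) lapply(gr, reb))
      labels <- rep(seq_len(cfg$S), vapply(pool, length, integer(1)))
      forces <- t(vapply(unlist(pool, recursive = FALSE),
                         function(r) decode_force(mm, r), numeric(2)))
      mi <- correct_bias(labels, forces, n_shuffles = n_shuffles,
                         n_bootstrap = 0, seed = seed + i)
      trajs <- run_offline_trajectories(starts, mm, sm, pool,
                                        params = params,
                                        max_steps = max_steps,
                                        seed = seed + i)
      steps <- vapply(trajs, function(t) {
        s <- steps_to_convergence(t)
        if (is.na(s)) NA_real_ else as.numeric(s)
      }, numeric(1))
      data.frame(dt_ms = g$dt_ms, window_ms = g$window_ms,
                 offset_ms = g$offset_ms, unit_fraction = g$unit_fraction,
                 n_units = length(units),
                 mi_corrected = mi$mi_corrected,
                 convergence_rate = convergence_rate(trajs),
                 mean_steps = if (all(is.na(steps))) NA_real_
                              else mean(steps, na.rm = TRUE),
                 note = "")
    }, error = function(e)
      data.frame(dt_ms = g$dt_ms, window_ms = g$window_ms,
                 offset_ms = g$offset_ms, unit_fraction = g$unit_fraction,
                 n_units = length(units), mi_corrected = NA_real_,
                 convergence_rate = NA_real_, mean_steps = NA_real_,
                 note = conditionMessage(e)))
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Correlation between information and closed-loop performance
#'
#' Pearson correlation, across sweep grid points, of the corrected mutual
#' information with the convergence rate and with the inverse mean number of
#' steps to convergence.
#'
#' @param sweep A [parameter_sweep()] result (or any data frame with
#'   `mi_corrected`, `convergence_rate`, `mean_steps`).
#' @return List `r_cr`, `r_invsteps` (either is `NA` with a message when the
#'   corresponding variable has zero variance or fewer than 3 finite pairs).
#' @export
info_performance_correlation <- function(sweep) {
  safe_cor <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) { message("fewer than 3 finite grid points"); return(NA_real_) }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      message("zero variance; correlation undefined")
      return(NA_real_)
    }
    stats::cor(x[ok], y[ok])
  }
  list(r_cr = safe_cor(sweep$mi_corrected, sweep$convergence_rate),
       r_invsteps = safe_cor(sweep$mi_corrected, 1 / sweep$mean_steps))
}
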