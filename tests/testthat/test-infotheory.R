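test_that("equipopulated binning balances occupancy", {
  expect_equal(as.vector(table(equipopulated_bins(1:10, 5))), rep(2, 5))
  expect_warning(b <- equipopulated_bins(rep(3, 10), 5), "identical")
  expect_equal(unique(b), 1L)
  u <- withr::with_seed(1, runif(1000))
  pop <- table(equipopulated_bins(u, 5))
  expect_lte(max(pop) / min(pop), 1.02)
  # ties always share a bin
  v <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4)
  b <- equipopulated_bins(v, 5)
  expect_true(all(tapply(b, v, function(x) length(unique(x))) == 1))
  expect_error(equipopulated_bins(1:3, 5), "fewer values")
  expect_error(equipopulated_bins(1:10, 1), "n_bins")
})

test_that("plugin MI matches exhaustive enumeration of the definition", {
  # four stimuli deterministically hitting four distinct joint bins
  labels <- rep(1:4, each = 25)
  forces <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))[labels, ] * 2
  expect_equal(mutual_information_plugin(labels, forces), 2)

  # random small tables against the enumeration oracle
  withr::with_seed(6, for (k in 1:25) {
    n <- sample(20:40, 1)
    labels <- sample(1:4, n, replace = TRUE)
    labels[1:8] <- rep(1:4, 2)          # ensure every stimulus occurs twice
    forces <- matrix(rnorm(2 * n), ncol = 2)
    bx <- equipopulated_bins(forces[, 1], 3)
    by <- equipopulated_bins(forces[, 2], 3)
    expect_equal(mutual_information_plugin(labels, forces, n_bins = 3),
                 mi_enumeration_oracle(labels, (bx - 1) * 3 + by))
  })
  expect_error(mutual_information_plugin(1:4, matrix(0, 3, 2)),
               "dimension error")
})

test_that("plugin MI obeys its information-theoretic bounds", {
  withr::with_seed(11, for (k in 1:20) {
    n <- 60
    S <- sample(2:4, 1)
    labels <- rep(seq_len(S), length.out = n)
    forces <- matrix(rnorm(2 * n), ncol = 2)
    mi <- mutual_information_plugin(labels, forces)
    expect_gte(mi, 0)
    expect_lte(mi, log2(S) + 1e-12)
    bx <- equipopulated_bins(forces[, 1], 5)
    by <- equipopulated_bins(forces[, 2], 5)
    occupied <- length(unique((bx - 1) * 5 + by))
    expect_lte(mi, log2(occupied) + 1e-12)
  })
})

test_that("merging response bins never increases plugin MI", {
  mi_tab <- dnifield:::mi_from_table
  withr::with_seed(13, for (k in 1:30) {
    tab <- matrix(rpois(4 * 6, 3), 4, 6)
    tab[1, 1] <- tab[1, 1] + 1          # keep the table non-empty
    merged <- cbind(tab[, 1] + tab[, 2], tab[, -(1:2)])
    expect_lte(mi_tab(merged), mi_tab(tab) + 1e-12)
  })
})

test_that("the correction cascade removes the limited-sampling bias", {
  # deterministic separation: no sampling ambiguity, corrections near zero
  labels <- rep(1:4, each = 100)
  forces <- rbind(c(3, 3), c(3, -3), c(-3, 3), c(-3, -3))[labels, ]
  est <- correct_bias(labels, forces, n_shuffles = 10, n_bootstrap = 10,
                      seed = 1)
  expect_equal(est$mi_plugin, 2)
  expect_equal(est$mi_corrected, 2, tolerance = 0.05)
  expect_lt(abs(est$bias_analytic) + abs(est$bias_shuffle), 0.05)
  expect_lt(abs(est$bootstrap_null_mean), 0.05)
  # the reported decomposition is exact
  expect_equal(est$mi_corrected,
               est$mi_plugin - est$bias_analytic - est$bias_shuffle)

  # informative decoded session: bootstrap null far below the estimate
  it <- fitted_interface(seed = 11)
  pool <- unlist(it$session$test_pool, recursive = FALSE)
  forces <- t(vapply(pool, function(r) decode_force(it$motor, r), numeric(2)))
  est2 <- correct_bias(rep(1:4, each = 100), forces, n_shuffles = 10,
                       n_bootstrap = 10, seed = 2)
  expect_gt(est2$mi_corrected, 1)
  expect_lt(abs(est2$bootstrap_null_mean), est2$mi_corrected / 5)
  expect_error(correct_bias(c(1, 2), matrix(0, 2, 2)), "estimation error")
})

test_that("information grows with the latency separation of stimuli", {
  mi_of_spread <- function(spread) {
    it <- fitted_interface(seed = 17, latency_spread_ms = spread,
                           R_cal = 40, R_test = 40)
    pool <- unlist(it$session$test_pool, recursive = FALSE)
    forces <- t(vapply(pool, function(r) decode_force(it$motor, r),
                       numeric(2)))
    correct_bias(rep(1:4, each = 40), forces, n_shuffles = 10,
                 n_bootstrap = 0, seed = 3)$mi_corrected
  }
  mis <- vapply(c(0, 15, 40), mi_of_spread, numeric(1))
  expect_lt(mis[1], 0.3)                  # uninformative by construction
  expect_gt(mis[3], 1)
  # non-decreasing within Monte-Carlo slack
  expect_true(all(diff(mis) > -0.1))
})

test_that("parameter sweeps cover the grid and record incompatibilities", {
  sess <- generate_session(generator_config(seed = 4, R_cal = 40,
                                            R_test = 40))
  sw <- parameter_sweep(sess, dt_list = c(5, 10, 50, 100),
                        window_list = 600, n_traj = 6, seed = 2)
  expect_equal(nrow(sw), 4)
  expect_true(all(sw$note == ""))
  expect_true(all(is.finite(sw$mi_corrected)))
  # a bin width that does not divide the session bin is recorded, not fatal
  sw2 <- parameter_sweep(sess, dt_list = c(5, 7), n_traj = 4, seed = 2)
  expect_equal(nrow(sw2), 2)
  expect_match(sw2$note[sw2$dt_ms == 7], "configuration error")
  expect_true(is.na(sw2$mi_corrected[sw2$dt_ms == 7]))
  # unit subsampling records the population size used
  sw3 <- parameter_sweep(sess, dt_list = 5, unit_fractions = c(0.25, 1),
                         n_traj = 4, seed = 2)
  expect_equal(sort(sw3$n_units), c(4, 14))
})

test_that("information-performance correlations behave on known inputs", {
  lin <- data.frame(mi_corrected = 1:6, convergence_rate = (1:6) / 10,
                    mean_steps = 60 / (1:6))
  r <- info_performance_correlation(lin)
  expect_equal(r$r_cr, 1)
  expect_equal(r$r_invsteps, 1)
  anti <- lin
  anti$convergence_rate <- rev(anti$convergence_rate)
  expect_equal(info_performance_correlation(anti)$r_cr, -1)
  flat <- lin
  flat$convergence_rate <- 0.5
  expect_message(r0 <- info_performance_correlation(flat), "zero variance")
  expect_true(is.na(r0$r_cr))
})
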