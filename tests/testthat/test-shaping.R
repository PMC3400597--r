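test_that("inner product extends the Euclidean dot product over bins", {
  expect_equal(inner_product(matrix(c(1, 2), 1), matrix(c(3, 4), 1)), 11)
  a <- matrix(rnorm(12), 3, 4)
  expect_equal(inner_product(a, a), sum(a^2))
  b <- withr::with_seed(1, matrix(rnorm(40), 5, 8))
  a <- withr::with_seed(2, matrix(rnorm(40), 5, 8))
  expect_equal(inner_product(a, b), sum(as.vector(a) * as.vector(b)))
  expect_error(inner_product(a, matrix(0, 2, 2)), "dimension error")
})

test_that("gram matrix matches the pairwise inner-product oracle", {
  ortho <- list(diag(3)[, 1, drop = FALSE] %*% t(c(1, 0)),
                diag(3)[, 2, drop = FALSE] %*% t(c(1, 0)),
                diag(3)[, 3, drop = FALSE] %*% t(c(0, 1)))
  expect_equal(gram_matrix(ortho), diag(3))
  dup <- list(matrix(1:4, 2), matrix(1:4, 2), matrix(5:8, 2))
  expect_lt(abs(det(gram_matrix(dup))), 1e-10)
  means <- withr::with_seed(3, lapply(1:4, function(i) matrix(rnorm(10), 2)))
  g <- gram_matrix(means)
  for (i in 1:4) for (j in 1:4)
    expect_equal(g[i, j], inner_product(means[[i]], means[[j]]))
  expect_equal(g, t(g))
})

test_that("d-vector solves the basis expansion", {
  cal <- random_calset(4)
  gram <- gram_matrix(cal$means)
  for (i in 1:4) {
    d <- d_vector(cal$means[[i]], cal$means, gram)
    e <- rep(0, 4); e[i] <- 1
    expect_equal(d, e, tolerance = 1e-10)
  }
  # orthogonal basis: coefficients reduce to normalized inner products
  basis <- list(rbind(c(1, 0, 0, 0)) * 2, rbind(c(0, 3, 0, 0)),
                rbind(c(0, 0, 1, 1)))
  g <- gram_matrix(basis)
  r <- rbind(c(4, 6, 1, 1))
  d <- d_vector(r, basis, g)
  expect_equal(d, vapply(basis, function(b)
    inner_product(r, b) / inner_product(b, b), numeric(1)))
  # independent least-squares oracle on flattened vectors
  withr::with_seed(9, {
    means <- lapply(1:3, function(i) matrix(rnorm(8), 2, 4))
    resp <- matrix(rnorm(8), 2, 4)
  })
  d <- d_vector(resp, means, gram_matrix(means))
  X <- vapply(means, as.vector, numeric(8))
  oracle <- as.vector(qr.solve(crossprod(X), crossprod(X, as.vector(resp))))
  expect_equal(d, oracle, tolerance = 1e-10)
})

test_that("an expansion with d-vector coefficients beats perturbed ones", {
  cal <- random_calset(12)
  gram <- gram_matrix(cal$means)
  r <- cal$responses[[2]][[1]]
  d <- d_vector(r, cal$means, gram)
  recon <- function(coef) Reduce(`+`, Map(`*`, coef, cal$means))
  base_err <- sum((r - recon(d))^2)
  withr::with_seed(5, for (k in 1:20) {
    expect_gte(sum((r - recon(d + rnorm(4, 0, 0.05)))^2), base_err)
  })
})

test_that("singular Gram systems fall back to the pseudo-inverse", {
  means <- list(matrix(1:4, 2), matrix(1:4, 2), matrix(c(2, 1, 1, 2), 2))
  gram <- gram_matrix(means)
  expect_warning(d <- d_vector(means[[3]], means, gram), "pseudo-inverse")
  # the pseudo-inverse solution still reproduces the response
  recon <- Reduce(`+`, Map(`*`, d, means))
  expect_equal(recon, means[[3]], tolerance = 1e-8)
})

test_that("motor map projects templates onto the desired force range", {
  field <- desired_field()
  cal <- noiseless_calset()
  mm <- fit_motor_map(cal, field)
  expect_equal(tcrossprod(mm$phi), diag(2))        # orthonormal rows
  expect_true(all(diag(mm$gain) > 0))
  forces <- t(vapply(cal$means, function(m) decode_force(mm, m), numeric(2)))
  # componentwise force ranges equal the desired field's ranges over the box
  expect_equal(diff(range(forces[, 1])), 8)
  expect_equal(diff(range(forces[, 2])), 8)
  # noiseless templates project onto a regular polygon: equal radii
  radii <- sqrt(rowSums(forces^2))
  expect_equal(max(radii) - min(radii), 0, tolerance = 1e-8)
})

test_that("motor map is invariant to trial order and rejects degenerate sets", {
  field <- desired_field()
  cal <- random_calset(21, R = 5)
  mm <- fit_motor_map(cal, field)
  shuffled <- cal
  shuffled$responses <- lapply(cal$responses, function(g)
    g[withr::with_seed(1, sample(length(g)))])
  mm2 <- fit_motor_map(shuffled, field)
  expect_equal(mm2$phi, mm$phi)
  expect_equal(mm2$gain, mm$gain)
  expect_equal(mm2$offset, mm$offset)
  expect_equal(mm2$d_center, mm$d_center)

  same <- matrix(1:6, 2)
  degenerate <- calibration_set(
    lapply(1:3, function(s) list(same, same)), dt_ms = 5)
  expect_error(suppressWarnings(fit_motor_map(degenerate, field)),
               "calibration error")
  expect_error(fit_motor_map(random_calset(1, S = 2), field), "S >= 3")
})

test_that("sensory map inverts the field at the template forces", {
  field <- desired_field()   # K = 4 isotropic, x0 = (0, 0)
  # direct inversion: x = x0 - K^-1 F
  expect_equal(field_inverse(field, c(4, 0)), c(-1, 0))
  expect_equal(field_inverse(field, c(0, 0)), c(0, 0))
  ff <- rbind(c(4, 0), c(-4, 0), c(0, 4), c(0, -4))
  sites <- t(apply(ff, 1, function(f) field_inverse(field, f)))
  expect_equal(sites, rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))

  it <- fitted_interface(seed = 11)
  # exactness at calibration sites: decoded template force equals the field
  for (i in 1:4) {
    f_dec <- decode_force(it$motor, it$session$calibration$means[[i]])
    expect_equal(f_dec, field_force(it$field, it$sensory$sites[i, ]),
                 tolerance = 1e-8)
  }
  # coincident sites are a calibration error
  same <- noiseless_calset(generator_config(latency_spread_ms = 0, R_cal = 2))
  expect_error(suppressWarnings({
    mm <- fit_motor_map(same, field)
    fit_sensory_map(mm, same, field)
  }), "calibration error|collinear")
})

test_that("nearest-site regions partition the workspace", {
  it <- fitted_interface(seed = 3)
  grid <- grid_starts(21)
  labels <- apply(grid, 1, function(p) select_stimulus(it$sensory, p))
  expect_setequal(unique(labels), 1:4)
  # regions are contiguous around their own site
  for (i in 1:4)
    expect_equal(select_stimulus(it$sensory, it$sensory$sites[i, ]), i)
})
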