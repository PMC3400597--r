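#' Binned population response
#'
#' An `N x T` matrix of non-negative integer spike counts (units in rows,
#' time bins in columns) with the bin width and post-stimulus offset attached.
#'
#' @param counts `N x T` matrix of non-negative counts.
#' @param dt_ms Bin width (ms).
#' @param offset_ms Start of the counting window after stimulus end (ms).
#' @return The matrix with class `binned_response`.
#' @export
binned_response <- function(counts, dt_ms, offset_ms = 0) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(counts, dt_ms = dt_ms, offset_ms = offset_ms,
            class = c("binned_response", class(counts)))
}

#' Calibration set of stimulus-conditioned responses
#'
#' Holds the `S x R` calibration trials and the per-stimulus mean responses
#' (the basis fields used for the expansion of single trials).
#'
#' @param responses List of `S` lists, each with `R >= 2` response matrices
#'   of identical shape.
#' @param dt_ms Bin width (ms).
#' @param offset_ms Window offset (ms).
#' @param stimulus_labels Optional stimulus identifiers (default `1..S`).
#' @return Object of class `calibration_set` with elements `responses`,
#'   `means`, `stimulus_labels`, `dt_ms`, `offset_ms`.
#' @export
calibration_set <- function(responses, dt_ms, offset_ms = 0,
                            stimulus_labels = seq_along(responses)) {
  S <- length(responses)
  if (S < 2) stop("need at least 2 stimuli", call. = FALSE)
  shp <- dim(responses[[1]][[1]])
  for (s in seq_len(S)) {
    if (length(responses[[s]]) < 2)
      stop("need R >= 2 repetitions per stimulus", call. = FALSE)
    for (r in responses[[s]])
      if (!identical(dim(r), shp))
        stop("dimension error: all responses must share one (N, T) shape",
             call. = FALSE)
  }
  means <- lapply(responses, function(g)
    Reduce(`+`, lapply(g, function(m) unclass(m) * 1.0)) / length(g))
  structure(list(responses = responses, means = means,
                 stimulus_labels = stimulus_labels,
                 dt_ms = dt_ms, offset_ms = offset_ms),
            class = "calibration_set")
}

#' Inner product of two neural responses
#'
#' The Euclidean inner product extended over units and time bins:
#' the sum over all entries of the elementwise product.
#'
#' @param a,b Arrays of identical shape.
#' @return Scalar.
#' @export
inner_product <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!identical(dim(a), dim(b)))
    stop("dimension error: responses must share the same (N, T) shape",
         call. = FALSE)
  sum(a * b)
}

#' Gram matrix of the basis fields
#'
#' Matrix of pairwise inner products of the `S` per-stimulus mean responses.
#'
#' @param means List of `S >= 2` mean-response matrices of identical shape.
#' @return Symmetric `S x S` matrix.
#' @export
gram_matrix <- function(means) {
  S <- length(means)
  if (S < 2) stop("need at least 2 basis fields", call. = FALSE)
  flat <- vapply(means, function(m) as.vector(unclass(m) * 1.0),
                 numeric(length(means[[1]])))
  crossprod(flat)
}

#' Expansion coefficients of a response in the mean-response basis
#'
#' Solves the normal equations `gram %*% d = g`, `g_i = <response, mean_i>`,
#' giving the coefficients of the least-squares expansion of the response as
#' a weighted sum of the per-stimulus mean responses. An ill-conditioned Gram
#' matrix (condition number > 1e8) falls back to the Moore-Penrose
#' pseudo-inverse with a warning.
#'
#' @param response Response matrix of the calibration shape.
#' @param means List of basis fields (mean responses).
#' @param gram Their Gram matrix, as from [gram_matrix()].
#' @return Numeric vector of length `S`.
#' @export
d_vector <- function(response, means, gram) {
  g <- vapply(means, function(m) inner_product(response, m), numeric(1))
  kappa_val <- tryCatch(kappa(gram, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kappa_val) || kappa_val > 1e8) {
    warning("Gram matrix ill-conditioned (kappa > 1e8); using pseudo-inverse",
            call. = FALSE)
    return(as.vector(MASS::ginv(gram) %*% g))
  }
  as.vector(solve(gram, g))
}

#' Desired linear convergent force field
#'
#' The field `F(x) = -K (x - x0)` over an axis-aligned workspace. `K` must be
#' non-singular so that template forces can be inverted into calibration
#' sites.
#'
#' @param K Stiffness: scalar (isotropic, N/m) or 2 x 2 non-singular matrix.
#' @param x0 Equilibrium position (m), inside the workspace.
#' @param workspace Named numeric `c(xmin, xmax, ymin, ymax)` (m).
#' @return Object of class `desired_field`.
#' @export
desired_field <- function(K = 4, x0 = c(0, 0),
                          workspace = c(xmin = -1, xmax = 1,
                                        ymin = -1, ymax = 1)) {
  if (length(K) == 1) K <- diag(K, 2)
  K <- as.matrix(K)
  if (!all(dim(K) == c(2, 2)) || abs(det(K)) < 1e-12)
    stop("K must be a non-singular 2 x 2 stiffness matrix", call. = FALSE)
  ws <- unname(workspace)
  if (ws[1] >= ws[2] || ws[3] >= ws[4])
    stop("degenerate workspace", call. = FALSE)
  if (x0[1] < ws[1] || x0[1] > ws[2] || x0[2] < ws[3] || x0[2] > ws[4])
    stop("x0 must lie inside the workspace", call. = FALSE)
  structure(list(kind = "linear", K = K, x0 = as.numeric(x0),
                 workspace = c(xmin = ws[1], xmax = ws[2],
                               ymin = ws[3], ymax = ws[4])),
            class = "desired_field")
}

#' Force of the desired field at a position
#' @param field A [desired_field()].
#' @param x Position 2-vector (m).
#' @return Force 2-vector (N).
#' @export
field_force <- function(field, x) {
  as.vector(-field$K %*% (as.numeric(x) - field$x0))
}

#' Position at which the desired field produces a given force
#' @param field A [desired_field()].
#' @param force Force 2-vector (N).
#' @return Position 2-vector (m).
#' @export
field_inverse <- function(field, force) {
  as.vector(field$x0 - solve(field$K, as.numeric(force)))
}

# corners of the workspace box; a linear field attains its componentwise
# force extremes there
workspace_corners <- function(field) {
  ws <- field$workspace
  rbind(c(ws["xmin"], ws["ymin"]), c(ws["xmin"], ws["ymax"]),
        c(ws["xmax"], ws["ymin"]), c(ws["xmax"], ws["ymax"]))
}

#' Fit the motor map (neural response to force)
#'
#' Computes the d-vector of every calibration trial, takes the principal
#' plane of the per-stimulus mean d-vectors (the signal subspace spanned by
#' the stimulus vocabulary), and scales each axis so the projected
#' calibration cloud covers the componentwise force range of the desired
#' field over the workspace. The mean calibration d-vector is mapped to zero
#' force, so the population's average evoked response is the rest state of
#' the decoder.
#'
#' Eigendecomposition order is deterministic (descending eigenvalues) and
#' each principal axis sign is fixed so that its largest-magnitude loading is
#' positive. A perfectly noiseless calibration makes the d-vector covariance
#' exactly isotropic on the zero-sum contrast space (the cluster centers are
#' always the regular simplex of unit vectors), so the principal plane is
#' ill-defined; that exact tie is resolved with the harmonic contrast basis
#' (cosine and sine contrasts across the stimulus vocabulary), which projects
#' the cluster centers onto a regular polygon and hence spreads the template
#' forces evenly over the force plane. Noisy calibrations never hit the tie
#' and use the data-driven principal axes.
#'
#' @param calset A [calibration_set()] with `S >= 3` stimuli.
#' @param field A [desired_field()].
#' @return Object of class `motor_map`: `means`, `gram`, `phi` (2 x S),
#'   `gain` (2 x 2 diagonal), `offset` (2-vector), `d_center` (S-vector),
#'   plus binning metadata.
#' @export
fit_motor_map <- function(calset, field) {
  stopifnot(inherits(calset, "calibration_set"),
            inherits(field, "desired_field"))
  S <- length(calset$means)
  if (S < 3)
    stop("calibration error: a planar projection needs S >= 3 stimuli",
         call. = FALSE)
  gram <- gram_matrix(calset$means)
  D <- vapply(unlist(calset$responses, recursive = FALSE),
              function(r) d_vector(r, calset$means, gram), numeric(S))
  d_center <- rowMeans(D)
  Dc <- D - d_center
  total_var <- sum(Dc^2)
  if (total_var < 1e-20)
    stop("calibration error: all calibration d-vectors are identical",
         call. = FALSE)
  # Signal subspace: principal plane of the per-stimulus mean d-vectors.
  # By linearity d(mean_i) = e_i whenever the Gram system is well posed, so
  # the signal configuration is a regular simplex and its covariance is
  # isotropic on the zero-sum contrast space; the plane is then resolved by
  # the canonical tie-break below. Projecting the plane from the stimulus
  # means rather than the raw trial cloud keeps trial noise from tilting the
  # decoder towards noise directions.
  Dm <- vapply(calset$means, function(m) d_vector(m, calset$means, gram),
               numeric(S))
  cov_d <- tcrossprod(Dm - rowMeans(Dm)) / (S - 1)
  eig <- eigen(cov_d, symmetric = TRUE)
  if (eig$values[2] <= 1e-12 * eig$values[1])
    stop("calibration error: calibration d-vectors are collinear",
         call. = FALSE)
  ev <- eig$values
  if (ev[1] - ev[S - 1] <= 1e-9 * ev[1]) {
    # Fully degenerate spectrum: a noiseless symmetric calibration makes the
    # d-vector covariance isotropic on the zero-sum contrast space, so any
    # orthonormal pair there is a valid principal plane. Resolve the tie with
    # the harmonic contrasts, which project the S cluster centers onto a
    # regular S-gon: template forces spread evenly over the force plane.
    theta <- 2 * pi * (seq_len(S) - 1) / S
    u1 <- cos(theta); u2 <- sin(theta)
    phi <- rbind(u1 / sqrt(sum(u1^2)), u2 / sqrt(sum(u2^2)))
  } else {
    phi <- t(eig$vectors[, 1:2, drop = FALSE])
  }
  for (k in 1:2)                       # fix axis sign deterministically
    if (phi[k, which.max(abs(phi[k, ]))] < 0) phi[k, ] <- -phi[k, ]
  proj <- phi %*% Dc
  half_range <- function(x) diff(range(x)) / 2
  corner_forces <- t(apply(workspace_corners(field), 1,
                           function(x) field_force(field, x)))
  hf <- apply(corner_forces, 2, half_range)
  hp <- apply(proj, 1, half_range)
  if (any(hp <= 0))
    stop("calibration error: projected calibration cloud has zero extent",
         call. = FALSE)
  structure(list(means = calset$means, gram = gram, phi = phi,
                 gain = diag(hf / hp), offset = c(0, 0),
                 d_center = d_center,
                 dt_ms = calset$dt_ms, offset_ms = calset$offset_ms,
                 stimulus_labels = calset$stimulus_labels),
            class = "motor_map")
}

#' Fit the sensory map (position to stimulus)
#'
#' Decodes the template force of each stimulus from its mean calibration
#' response and inverts the desired field at that force to obtain the
#' calibration site: `x_i = x0 - K^{-1} F_i` for the linear field. Nearest
#' calibration site then selects the stimulus at run time, so the decoded
#' force at each site equals the desired field's force there by construction.
#'
#' @param motor_map A fitted [fit_motor_map()].
#' @param calset The [calibration_set()] used for fitting.
#' @param field The [desired_field()].
#' @param tol Sites closer than `tol` (m) are considered coincident and a
#'   calibration error is raised.
#' @return Object of class `sensory_map`: `sites` (S x 2 matrix, m),
#'   `stimulus_ids`, `template_forces` (S x 2, N), `x0`, `tie_rule`.
#' @export
fit_sensory_map <- function(motor_map, calset, field, tol = 1e-9) {
  stopifnot(inherits(motor_map, "motor_map"),
            inherits(field, "desired_field"))
  forces <- t(vapply(calset$means,
                     function(m) decode_force(motor_map, m), numeric(2)))
  sites <- t(apply(forces, 1, function(f) field_inverse(field, f)))
  dd <- as.matrix(stats::dist(sites))
  diag(dd) <- Inf
  if (min(dd) < tol) {
    idx <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "calibration error: coincident calibration sites %d and %d (distance %.3g m)",
      idx[1], idx[2], min(dd)), call. = FALSE)
  }
  ws <- field$workspace
  outside <- sites[, 1] < ws["xmin"] | sites[, 1] > ws["xmax"] |
             sites[, 2] < ws["ymin"] | sites[, 2] > ws["ymax"]
  if (any(outside))
    warning(sprintf("%d calibration site(s) fall outside the workspace",
                    sum(outside)), call. = FALSE)
  structure(list(sites = unname(sites),
                 stimulus_ids = calset$stimulus_labels,
                 template_forces = unname(forces),
                 x0 = field$x0, tie_rule = "lowest-index"),
            class = "sensory_map")
}

#' @export
print.calibration_set <- function(x, ...) {
  shp <- dim(x$means[[1]])
  cat(sprintf(
    "calibration_set: %d stimuli x %d trials, %d units x %d bins (%g ms)\n",
    length(x$means), length(x$responses[[1]]), shp[1], shp[2], x$dt_ms))
  invisible(x)
}

#' @export
print.motor_map <- function(x, ...) {
  cat(sprintf("motor_map: %d basis fields, gain = diag(%.3g, %.3g) N/unit\n",
              length(x$means), x$gain[1, 1], x$gain[2, 2]))
  invisible(x)
}

#' @export
print.sensory_map <- function(x, ...) {
  cat(sprintf("sensory_map: %d calibration sites, tie rule %s\n",
              nrow(x$sites), x$tie_rule))
  print(round(x$sites, 4))
  invisible(x)
}
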