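#' Decode a planar force from a binned population response
#'
#' The real-time linear filter of the motor interface:
#' `F = gain %*% phi %*% (d(response) - d_center) + offset`, where `d()` is
#' the expansion of the response in the mean-response basis. Affine in the
#' spike-count array; the mean calibration response decodes to the offset
#' (zero force by default).
#'
#' @param motor_map A fitted [fit_motor_map()].
#' @param response Response matrix with the calibration `(N, T)` shape.
#' @return Numeric force 2-vector `c(fx, fy)` in newtons.
#' @export
decode_force <- function(motor_map, response) {
  stopifnot(inherits(motor_map, "motor_map"))
  if (!identical(dim(unclass(response)), dim(unclass(motor_map$means[[1]]))))
    stop("dimension error: response shape does not match calibration",
         call. = FALSE)
  d <- d_vector(response, motor_map$means, motor_map$gram)
  as.vector(motor_map$gain %*% motor_map$phi %*% (d - motor_map$d_center)) +
    motor_map$offset
}

#' Select the stimulus for a position
#'
#' The sensory interface look-up: returns the stimulus whose calibration site
#' is Euclidean-nearest to `position`; exact ties go to the lowest index.
#' Defined for any finite position, including outside the workspace.
#'
#' @param sensory_map A fitted [fit_sensory_map()].
#' @param position Position 2-vector (m).
#' @return A stimulus id from `sensory_map$stimulus_ids`.
#' @export
select_stimulus <- function(sensory_map, position) {
  stopifnot(inherits(sensory_map, "sensory_map"))
  position <- as.numeric(position)
  if (length(position) != 2 || any(!is.finite(position)))
    stop("position must be a finite 2-vector", call. = FALSE)
  d2 <- (sensory_map$sites[, 1] - position[1])^2 +
        (sensory_map$sites[, 2] - position[2])^2
  sensory_map$stimulus_ids[which.min(d2)]
}
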