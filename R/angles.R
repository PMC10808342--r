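#' Angle conversion and wrapping utilities
#'
#' Helpers for working with circular data in degrees and radians. Signed
#' angular differences are wrapped to the half-open interval (-180, 180]
#' degrees (equivalently (-pi, pi] radians); positions on the circle are
#' wrapped to (0, 360].
#'
#' @param deg,rad Numeric vectors of angles in degrees or radians.
#' @return Numeric vector of converted or wrapped angles.
#' @name angles
NULL

#' @rdname angles
#' @export
deg2rad <- function(deg) deg * pi / 180

#' @rdname angles
#' @export
rad2deg <- function(rad) rad * 180 / pi

#' @rdname angles
#' @export
wrap_signed_deg <- function(deg) {
  out <- deg %% 360
  out[out > 180] <- out[out > 180] - 360
  # boundary maps to +180 by convention: x %% 360 == 180 stays 180
  out
}

#' @rdname angles
#' @export
wrap_position_deg <- function(deg) {
  out <- deg %% 360
  out[out == 0] <- 360
  out
}

#' Signed circular recall error
#'
#' The signed angular difference between a response location and the target
#' location, wrapped to (-180, 180] degrees. This is the quantity the
#' uniform + von Mises mixture model is fit to: a response 20 degrees
#' clockwise of the target gives -20, counter-clockwise +20, and a response
#' diametrically opposite gives +180 (the boundary is mapped to +180).
#'
#' @param response_deg Response angle(s) in degrees (any finite real).
#' @param target_deg Target angle(s) in degrees (any finite real).
#' @return Signed error(s) in degrees, in (-180, 180].
#' @examples
#' circular_error(10, 10)   # 0
#' circular_error(350, 10)  # -20
#' circular_error(190, 10)  # 180
#' @export
circular_error <- function(response_deg, target_deg) {
  if (!all(is.finite(response_deg)) || !all(is.finite(target_deg))) {
    stop("`response_deg` and `target_deg` must be finite", call. = FALSE)
  }
  wrap_signed_deg(response_deg - target_deg)
}
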