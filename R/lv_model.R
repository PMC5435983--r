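# Mapping from echocardiographic LV dimensions to truncated-prolate-spheroid
# axes. D is the short-axis diameter at end diastole; delta = D/L is the
# short/long-axis ratio, 0.45-0.62 in normal subjects.

#' Normal range of the LV short/long-axis ratio
#'
#' In normal subjects the ratio \eqn{\delta = D/L} of the LV short axis to
#' the long axis lies between 0.45 and 0.62. The model still computes for
#' ratios outside this band (dilated or otherwise abnormal geometries) but
#' flags them with a warning.
#'
#' @return Numeric vector `c(lower, upper)`.
#' @export
lv_delta_normal_range <- function() c(lower = 0.45, upper = 0.62)

.check_lv_inputs <- function(D, delta, warn = TRUE) {
  if (any(!is.finite(D) | D <= 0))
    stop("'D' (LV short-axis diameter) must be positive", call. = FALSE)
  if (any(!is.finite(delta) | delta <= 0 | delta >= 1))
    stop("'delta' (short/long-axis ratio) must lie in (0, 1)", call. = FALSE)
  rng <- lv_delta_normal_range()
  out_of_range <- delta < rng[["lower"]] | delta > rng[["upper"]]
  if (warn && any(out_of_range))
    warning(sprintf(
      "delta outside the normal LV range [%.2f, %.2f]: %s",
      rng[["lower"]], rng[["upper"]],
      paste(format(unique(delta[out_of_range])), collapse = ", ")),
      call. = FALSE)
  out_of_range
}

#' TPS axes of the left ventricle from short axis and axis ratio
#'
#' The LV is modeled as a truncated prolate spheroid whose equatorial
#' diameter equals the measured short axis `D` and whose long axis
#' `L = D / delta` spans the axial interval `[sigma, c]`. The truncation
#' plane (the mitral base) sits at the point dividing `L` in 1/3 : 2/3
#' proportion, so
#' \deqn{a = b = D/2, \quad c = \frac{2D}{3\delta}, \quad
#'       \sigma = -\frac{D}{3\delta}, \quad L = c + |\sigma| = D/\delta.}
#' `sigma` is stored negative (base below the equatorial plane, apex at
#' `z = +c`); reports quote \eqn{|\sigma|}.
#'
#' @param D LV short-axis diameter (cm), positive.
#' @param delta short/long-axis ratio `D/L`, in `(0, 1)`. Values outside the
#'   normal range ([lv_delta_normal_range()]) trigger a warning, not an
#'   error.
#' @return Data frame of class `"lv_axes"` with one row per input
#'   (recycled): `D`, `delta`, `a`, `b`, `c`, `sigma`, `abs_sigma`, `L`
#'   (all lengths in cm) and logical `delta_out_of_range`.
#' @seealso [lv_surface_area()]
#' @export
#' @examples
#' lv_axes(3, 0.5)           # a = 1.5, c = 4, sigma = -2, L = 6
#' lv_axes(4.6, 0.45)        # the women's total-average reference geometry
lv_axes <- function(D, delta) {
  n <- max(length(D), length(delta))
  D <- rep_len(as.numeric(D), n)
  delta <- rep_len(as.numeric(delta), n)
  oor <- .check_lv_inputs(D, delta)
  L <- D / delta
  ax <- data.frame(D = D, delta = delta,
                   a = D / 2, b = D / 2,
                   c = 2 * L / 3,
                   sigma = -L / 3, abs_sigma = L / 3,
                   L = L,
                   delta_out_of_range = oor)
  class(ax) <- c("lv_axes", "data.frame")
  ax
}

#' LV surface-area parameter from short axis and axis ratio
#'
#' Computes \eqn{A_\sigma(S)}, the lateral area of the truncated prolate
#' spheroid obtained from [lv_axes()]. Since `D_d` is an internal
#' end-diastolic diameter, the result estimates the internal (endocardial)
#' LV surface at end diastole. The area scales as \eqn{D^2} at fixed
#' `delta`, so ratios of areas at the same `delta` depend only on the
#' diameter ratio.
#'
#' @inheritParams lv_axes
#' @return Surface area (cm^2). Vectorized with recycling.
#' @export
#' @examples
#' lv_surface_area(4.9, 0.45)   # men's total-average reference: 145.40
#' lv_surface_area(4.6, 0.45)   # women's: 128.14
lv_surface_area <- function(D, delta) {
  ax <- lv_axes(D, delta)
  tps_area(ax$a, ax$c, ax$sigma)
}
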