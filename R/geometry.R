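# Closed-form and quadrature surface areas for spheroids and their
# truncations. All lengths in cm, all areas in cm^2; angles in radians.

# Relative eccentricity threshold below which the near-spherical series
# replaces the arcsin/sqrt closed forms (their naive evaluation is 0/0 at
# a = c). See the methods vignette for the conditioning argument.
.sphere_eps <- 1e-9

.check_positive <- function(value, field) {
  if (any(!is.finite(value) | value <= 0))
    stop(sprintf("'%s' must be positive and finite", field), call. = FALSE)
  invisible(value)
}

#' Surface area of a prolate spheroid
#'
#' Area of the ellipsoid of revolution with polar semi-axis `c_polar` and
#' equatorial radius `r_equatorial` (polar axis at least as long as the
#' equatorial one):
#' \deqn{S = 2\pi r^2 + \frac{2\pi r c^2}{\sqrt{c^2-r^2}}
#'       \arcsin\!\frac{\sqrt{c^2-r^2}}{c}.}
#' The sphere limit \eqn{r \to c} is handled analytically (returns
#' \eqn{4\pi r^2} with no precision loss).
#'
#' @param c_polar polar semi-axis (cm), positive.
#' @param r_equatorial equatorial radius (cm), positive, `<= c_polar`.
#' @return Surface area (cm^2). Vectorized with recycling.
#' @seealso [tps_area()] for a truncated spheroid, [split_prolate()].
#' @export
#' @examples
#' prolate_spheroid_area(10, 3)   # 306.73
#' prolate_spheroid_area(1, 1)    # 4 * pi
prolate_spheroid_area <- function(c_polar, r_equatorial) {
  n <- max(length(c_polar), length(r_equatorial))
  c_polar <- rep_len(as.numeric(c_polar), n)
  r_equatorial <- rep_len(as.numeric(r_equatorial), n)
  .check_positive(c_polar, "c_polar")
  .check_positive(r_equatorial, "r_equatorial")
  if (any(r_equatorial > c_polar * (1 + 1e-12)))
    stop("'r_equatorial' must not exceed 'c_polar' (prolate orientation)",
         call. = FALSE)
  r <- pmin(r_equatorial, c_polar)
  w2 <- (c_polar^2 - r^2) / c_polar^2        # squared eccentricity
  w <- sqrt(pmax(w2, 0))
  # asin(w)/w, series below the switch threshold
  asinc <- ifelse(w2 < .sphere_eps,
                  1 + w2 / 6 + 3 * w2^2 / 40,
                  suppressWarnings(asin(w) / w))
  asinc[w == 0] <- 1
  2 * pi * r^2 + 2 * pi * r * c_polar * asinc
}

#' Lateral surface area of a truncated prolate spheroid
#'
#' A truncated prolate spheroid (TPS) is the surface of revolution of
#' \eqn{x(z) = a\sqrt{1 - z^2/c^2}} about the polar `z`-axis, restricted to
#' \eqn{z \in [\sigma, c]}. Its lateral area has the closed form
#' \deqn{A_\sigma(S) = \pi a\left[
#'   \frac{c^2\left(\arcsin\frac{\sqrt{c^2-a^2}}{c}
#'         - \arcsin\frac{\sigma\sqrt{c^2-a^2}}{c^2}\right)}{\sqrt{c^2-a^2}}
#'   + a - \sigma\sqrt{1 + \frac{(a^2-c^2)\sigma^2}{c^4}}\right].}
#' Only the curved revolution surface is counted; the planar cut disk
#' \eqn{\pi x(\sigma)^2} is added only when `include_base = TRUE` (it must be
#' excluded for complementary pieces of a spheroid to sum to the full
#' spheroid area). At `sigma = -c` the full prolate spheroid is recovered;
#' as `a -> c` the value tends to the spherical-zone area
#' \eqn{2\pi c(c-\sigma)}, evaluated by a series expansion near the sphere
#' limit.
#'
#' @param a equatorial semi-axis (cm), positive, `<= c`.
#' @param c polar semi-axis (cm), positive.
#' @param sigma axial coordinate of the truncation plane (cm), in `[-c, c)`.
#' @param include_base if `TRUE`, add the area of the flat cut disk.
#' @return Lateral area (cm^2). Vectorized with recycling.
#' @seealso [tps_area_quadrature()] for the direct surface-of-revolution
#'   integral, [split_prolate()].
#' @export
#' @examples
#' tps_area(3, 10, -2)   # 190.83: the piece spanning [-2, 10]
#' tps_area(3, 10, 2)    # 115.89: the piece spanning [2, 10]
#' tps_area(2, 2, 0)     # 8 * pi: hemisphere as a spherical zone
tps_area <- function(a, c, sigma, include_base = FALSE) {
  n <- max(length(a), length(c), length(sigma))
  a <- rep_len(as.numeric(a), n)
  c <- rep_len(as.numeric(c), n)
  sigma <- rep_len(as.numeric(sigma), n)
  .check_positive(a, "a")
  .check_positive(c, "c")
  if (any(a > c * (1 + 1e-12)))
    stop("'a' must not exceed 'c' (prolate orientation)", call. = FALSE)
  a <- pmin(a, c)
  if (any(!is.finite(sigma) | sigma < -c | sigma >= c))
    stop("'sigma' must lie in [-c, c)", call. = FALSE)

  w2 <- (c^2 - a^2) / c^2
  w <- sqrt(pmax(w2, 0))
  u <- sigma / c
  # c * (asin(w) - asin(u*w)) / w; the series form keeps full precision when
  # the two arcsine arguments both collapse toward 0 (sphere limit)
  arc <- ifelse(w2 < .sphere_eps,
                c * ((1 - u) + w2 * (1 - u^3) / 6 + 3 * w2^2 * (1 - u^5) / 40),
                suppressWarnings(c * (asin(w) - asin(u * w)) / w))
  slant <- sigma * sqrt(pmax(1 + (a^2 - c^2) * sigma^2 / c^4, 0))
  area <- pi * a * (arc + a - slant)
  if (include_base) area <- area + pi * a^2 * (1 - u^2)
  area
}

#' TPS lateral area by adaptive quadrature
#'
#' Evaluates the defining surface-of-revolution integral
#' \deqn{A_\sigma(S) = 2\pi\int_\sigma^c x(z)\sqrt{1 + x'(z)^2}\,dz}
#' numerically, as an independent check on the closed form in [tps_area()].
#' The integrand's derivative singularity at the apex \eqn{z = c} is removed
#' by the substitution \eqn{z = c\sin\theta}, which turns the integrand into
#' the smooth \eqn{2\pi a c\cos\theta\sqrt{\cos^2\theta +
#' (a/c)^2\sin^2\theta}} before adaptive quadrature is applied.
#'
#' @inheritParams tps_area
#' @param rel_tol requested relative tolerance, in `(0, 1e-4]`.
#' @return Lateral area (cm^2); scalar arguments only.
#' @export
#' @examples
#' tps_area_quadrature(3, 10, 2)   # agrees with tps_area(3, 10, 2)
tps_area_quadrature <- function(a, c, sigma, rel_tol = 1e-10) {
  stopifnot(length(a) == 1L, length(c) == 1L, length(sigma) == 1L)
  .check_positive(a, "a")
  .check_positive(c, "c")
  if (a > c * (1 + 1e-12))
    stop("'a' must not exceed 'c' (prolate orientation)", call. = FALSE)
  if (!is.finite(sigma) || sigma < -c || sigma >= c)
    stop("'sigma' must lie in [-c, c)", call. = FALSE)
  if (!is.finite(rel_tol) || rel_tol <= 0 || rel_tol > 1e-4)
    stop("'rel_tol' must lie in (0, 1e-4]", call. = FALSE)
  ratio2 <- (a / c)^2
  integrand <- function(theta)
    2 * pi * a * c * cos(theta) *
      sqrt(cos(theta)^2 + ratio2 * sin(theta)^2)
  res <- stats::integrate(integrand, asin(sigma / c), pi / 2,
                          rel.tol = rel_tol, abs.tol = 0,
                          subdivisions = 500L)
  if (res$message != "OK")
    stop(sprintf("quadrature failed to converge (%s), error estimate %.3e",
                 res$message, res$abs.error), call. = FALSE)
  res$value
}

#' Amplitude and modulus for the general-ellipsoid area formula
#'
#' For semi-axes \eqn{a \ge b \ge c > 0} the classical Legendre reduction of
#' the ellipsoid area integral uses amplitude
#' \eqn{\phi = \arcsin(\sqrt{a^2-c^2}/a)} and modulus
#' \eqn{k^2 = a^2(b^2-c^2)/(b^2(a^2-c^2))}.
#'
#' @param a_major,b_mid,c_minor semi-axes (cm), `a_major >= b_mid >= c_minor > 0`.
#' @return List with elements `phi` (radians) and `k` (dimensionless);
#'   `a_major = c_minor` (a sphere) gives `phi = 0` and `k = 0`.
#' @export
ellipsoid_phi_k <- function(a_major, b_mid, c_minor) {
  .check_positive(a_major, "a_major")
  .check_positive(b_mid, "b_mid")
  .check_positive(c_minor, "c_minor")
  if (any(b_mid > a_major) || any(c_minor > b_mid))
    stop("semi-axes must satisfy a_major >= b_mid >= c_minor", call. = FALSE)
  phi <- asin(sqrt(pmax(a_major^2 - c_minor^2, 0)) / a_major)
  k2 <- ifelse(a_major == c_minor, 0,
               a_major^2 * (b_mid^2 - c_minor^2) /
                 (b_mid^2 * (a_major^2 - c_minor^2)))
  list(phi = phi, k = sqrt(pmin(pmax(k2, 0), 1)))
}

#' Surface area of a general ellipsoid
#'
#' Area of the ellipsoid with semi-axes \eqn{a \ge b \ge c > 0}. The
#' classical closed form
#' \deqn{S = 2\pi c^2 + \frac{2\pi b}{\sqrt{a^2-c^2}}
#'  \left[(a^2-c^2)E(\phi,k) + c^2 F(\phi,k)\right]}
#' (amplitude and modulus as in [ellipsoid_phi_k()]) is evaluated in the
#' algebraically equivalent Carlson form
#' \deqn{S = 2\pi c^2 + 2\pi a b\, R_F\!\left(\tfrac{c^2}{a^2},
#'   \tfrac{c^2}{b^2}, 1\right) - \frac{2\pi}{3}
#'   \frac{(a^2-c^2)(b^2-c^2)}{ab}\, R_D\!\left(\tfrac{c^2}{a^2},
#'   \tfrac{c^2}{b^2}, 1\right),}
#' which has no removable singularity at coincident axes: prolate
#' (`b = c`), oblate (`a = b`) and spherical degeneracies need no special
#' casing and reduce exactly to their one-parameter closed forms.
#'
#' @inheritParams ellipsoid_phi_k
#' @return Surface area (cm^2). Vectorized with recycling.
#' @seealso [prolate_spheroid_area()], [carlson_rf()]
#' @export
#' @examples
#' general_ellipsoid_area(10, 3, 3)   # 306.73, prolate reduction
#' general_ellipsoid_area(1, 1, 1)    # 4 * pi
general_ellipsoid_area <- function(a_major, b_mid, c_minor) {
  n <- max(length(a_major), length(b_mid), length(c_minor))
  a <- rep_len(as.numeric(a_major), n)
  b <- rep_len(as.numeric(b_mid), n)
  cc <- rep_len(as.numeric(c_minor), n)
  .check_positive(a, "a_major")
  .check_positive(b, "b_mid")
  .check_positive(cc, "c_minor")
  if (any(b > a * (1 + 1e-12)) || any(cc > b * (1 + 1e-12)))
    stop("semi-axes must satisfy a_major >= b_mid >= c_minor", call. = FALSE)
  b <- pmin(b, a)
  cc <- pmin(cc, b)
  x <- cc^2 / a^2
  y <- cc^2 / b^2
  2 * pi * cc^2 + 2 * pi * a * b * carlson_rf(x, y, 1) -
    (2 * pi / 3) * ((a^2 - cc^2) * (b^2 - cc^2) / (a * b)) *
      carlson_rd(x, y, 1)
}

#' Split a prolate spheroid into two complementary truncated pieces
#'
#' Cuts the spheroid by the plane `z = cut_z` and returns the lateral areas
#' of the two pieces. By the mirror symmetry of the spheroid, the lower
#' piece (spanning `[-c, cut_z]`) has the same area as a TPS truncated at
#' `-cut_z`; the two lateral areas always sum to the full spheroid area.
#'
#' @inheritParams prolate_spheroid_area
#' @param cut_z axial position of the cut (cm), strictly inside `(-c, c)`.
#' @return Named numeric vector with components `below` (area over
#'   `[-c, cut_z]`) and `above` (area over `[cut_z, c]`), in cm^2.
#' @export
#' @examples
#' split_prolate(10, 3, -2)   # c(below = 115.89, above = 190.83)
split_prolate <- function(c_polar, r_equatorial, cut_z) {
  stopifnot(length(c_polar) == 1L, length(r_equatorial) == 1L,
            length(cut_z) == 1L)
  .check_positive(c_polar, "c_polar")
  .check_positive(r_equatorial, "r_equatorial")
  if (!is.finite(cut_z) || cut_z <= -c_polar || cut_z >= c_polar)
    stop("'cut_z' must lie strictly inside (-c_polar, c_polar)",
         call. = FALSE)
  c(below = tps_area(r_equatorial, c_polar, -cut_z),
    above = tps_area(r_equatorial, c_polar, cut_z))
}
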