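# Spheroid and TPS areas. Frozen expected values below were computed with
# the surface-of-revolution quadrature oracle (theta-substituted adaptive
# quadrature at rel_tol 1e-10, cross-checked at 30-digit precision).

random_tps <- function(n, seed) {
  set.seed(seed)
  a <- runif(n, 0.2, 5)
  cc <- a * runif(n, 1.001, 4)
  sigma <- runif(n, -cc * 0.999, cc * 0.999)
  data.frame(a = a, c = cc, sigma = sigma)
}

test_that("prolate spheroid closed form matches frozen oracle values", {
  # 306.7270014264877 = quadrature over the full interval [-10, 10]
  expect_equal(prolate_spheroid_area(10, 3), 306.7270014264877,
               tolerance = 1e-12)
  expect_equal(prolate_spheroid_area(1, 1), 4 * pi, tolerance = 1e-14)
  expect_equal(prolate_spheroid_area(2, 1),
               tps_area_quadrature(1, 2, -2, rel_tol = 1e-10),
               tolerance = 1e-10)
})

test_that("TPS closed form reproduces the split-spheroid example", {
  expect_equal(tps_area(3, 10, -2), 190.8326393386931, tolerance = 1e-12)
  expect_equal(tps_area(3, 10, 2), 115.8943620877946, tolerance = 1e-12)
  expect_equal(tps_area(3, 10, -10), prolate_spheroid_area(10, 3),
               tolerance = 1e-14)
  expect_equal(tps_area(2, 2, 0), 8 * pi, tolerance = 1e-13)  # hemisphere
})

test_that("complementary TPS pieces add up to the full spheroid", {
  grid <- random_tps(100, seed = 21)
  s0 <- abs(grid$sigma)
  lhs <- tps_area(grid$a, grid$c, s0 * 0.999) +
    tps_area(grid$a, grid$c, -s0 * 0.999)
  expect_equal(lhs, prolate_spheroid_area(grid$c, grid$a),
               tolerance = 1e-10)
})

test_that("closed form agrees with the quadrature oracle on a random grid", {
  grid <- random_tps(120, seed = 22)
  for (i in seq_len(nrow(grid))) {
    closed <- tps_area(grid$a[i], grid$c[i], grid$sigma[i])
    quad <- tps_area_quadrature(grid$a[i], grid$c[i], grid$sigma[i],
                                rel_tol = 1e-10)
    expect_lt(abs(closed - quad) / closed, 1e-8)
  }
})

test_that("TPS area is strictly decreasing in sigma and scales as length^2", {
  sig <- seq(-9.99, 9.8, length.out = 60)
  areas <- tps_area(3, 10, sig)
  expect_true(all(diff(areas) < 0))
  expect_lt(tps_area(3, 10, 10 - 1e-9), 1e-3)   # vanishes at the apex
  grid <- random_tps(30, seed = 23)
  m <- 2.7
  expect_equal(tps_area(m * grid$a, m * grid$c, m * grid$sigma),
               m^2 * tps_area(grid$a, grid$c, grid$sigma),
               tolerance = 1e-12)
})

test_that("sphere limits are continuous with no precision blow-up", {
  for (eps in 10^-(4:12)) {
    r <- 2 * (1 - eps)
    expect_equal(prolate_spheroid_area(2, r), 4 * pi * 2^2,
                 tolerance = 1e-3)
    expect_equal(tps_area(r, 2, 0.5), 2 * pi * 2 * (2 - 0.5),
                 tolerance = 1e-3)
  }
  # well inside the series branch the zone formula is met to high precision
  r <- 2 * (1 - 1e-13)
  expect_equal(tps_area(r, 2, 0.5), 2 * pi * 2 * 1.5, tolerance = 1e-10)
})

test_that("cut disk is excluded by default and added on request", {
  a <- 3; cc <- 10; s <- 2
  disk <- pi * a^2 * (1 - s^2 / cc^2)
  expect_equal(tps_area(a, cc, s, include_base = TRUE),
               tps_area(a, cc, s) + disk, tolerance = 1e-12)
})

test_that("general ellipsoid area reduces along the degeneracy chain", {
  set.seed(24)
  for (i in 1:20) {
    cc <- runif(1, 0.5, 3); a <- cc * runif(1, 1.01, 4)
    # prolate reduction b = c (relabeled: polar axis = a_major)
    expect_equal(general_ellipsoid_area(a, cc, cc),
                 prolate_spheroid_area(a, cc),
                 tolerance = 1e-10)
    # oblate reduction a = b, classical closed form
    e <- sqrt(1 - cc^2 / a^2)
    oblate <- 2 * pi * a^2 + pi * cc^2 / e * log((1 + e) / (1 - e))
    expect_equal(general_ellipsoid_area(a, a, cc), oblate,
                 tolerance = 1e-10)
  }
  expect_equal(general_ellipsoid_area(1, 1, 1), 4 * pi, tolerance = 1e-13)
  expect_equal(general_ellipsoid_area(10, 3, 3), 306.7270014264877,
               tolerance = 1e-10)
})

test_that("general ellipsoid area matches the Legendre F/E route and a 2-D
           surface-integral oracle", {
  set.seed(25)
  for (i in 1:10) {
    cc <- runif(1, 0.3, 2)
    b <- cc * runif(1, 1.05, 2)
    a <- b * runif(1, 1.05, 2)
    # explicit amplitude/modulus formula (the one-line closed form)
    pk <- ellipsoid_phi_k(a, b, cc)
    legendre <- 2 * pi * cc^2 + 2 * pi * b / sqrt(a^2 - cc^2) *
      ((a^2 - cc^2) * ellip_E(pk$phi, pk$k) + cc^2 * ellip_F(pk$phi, pk$k))
    expect_equal(general_ellipsoid_area(a, b, cc), legendre,
                 tolerance = 1e-10)
  }
  # brute-force first-fundamental-form integration over parameter space
  area_el <- function(th, ph, a, b, cc) {
    st <- sin(th); ct <- cos(th)
    st * sqrt(b^2 * cc^2 * st^2 * cos(ph)^2 +
                a^2 * cc^2 * st^2 * sin(ph)^2 + a^2 * b^2 * ct^2)
  }
  for (ax in list(c(3, 2, 1), c(5, 4.5, 2), c(2, 1.2, 1.1))) {
    oracle <- pracma::integral2(function(th, ph)
      area_el(th, ph, ax[1], ax[2], ax[3]),
      0, pi, 0, 2 * pi, reltol = 1e-10)$Q
    expect_equal(general_ellipsoid_area(ax[1], ax[2], ax[3]), oracle,
                 tolerance = 1e-6)
  }
})

test_that("split_prolate returns complementary pieces for any cut", {
  sp <- split_prolate(10, 3, -2)
  expect_equal(unname(sp["above"]), tps_area(3, 10, -2), tolerance = 1e-13)
  expect_equal(unname(sp["below"]), tps_area(3, 10, 2), tolerance = 1e-13)
  expect_equal(sum(sp), prolate_spheroid_area(10, 3), tolerance = 1e-12)
  halves <- split_prolate(10, 3, 0)
  expect_equal(unname(halves["below"]), unname(halves["above"]),
               tolerance = 1e-13)
  expect_equal(sum(split_prolate(5, 2, 1.7)), prolate_spheroid_area(5, 2),
               tolerance = 1e-12)
  expect_error(split_prolate(5, 2, 5), "cut_z")
})

test_that("domain errors name the offending quantity", {
  expect_error(prolate_spheroid_area(-1, 1), "c_polar")
  expect_error(prolate_spheroid_area(1, 0), "r_equatorial")
  expect_error(prolate_spheroid_area(1, 2), "prolate")
  expect_error(tps_area(0, 1, 0), "'a'")
  expect_error(tps_area(2, 1, 0), "prolate")
  expect_error(tps_area(1, 2, 2), "sigma")
  expect_error(tps_area(1, 2, -2.5), "sigma")
  expect_error(tps_area_quadrature(1, 2, 0, rel_tol = 1e-3), "rel_tol")
  expect_error(general_ellipsoid_area(1, 2, 3), "semi-axes")
})
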