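test_that("Rayleigh resolution is the first PSF null and scales with frequency", {
  res <- rayleigh_resolution(cfg300)
  expect_equal(round(res$sigma_wavelengths, 3), 0.383)
  expect_lt(abs(besselJ(cfg300$k0 * res$sigma, 0)), 1e-8)
  # doubling the frequency halves sigma in meters, leaves wavelengths fixed
  res2 <- rayleigh_resolution(eis_config(600e6))
  expect_equal(res2$sigma, res$sigma / 2, tolerance = 1e-9)
  expect_equal(res2$sigma_wavelengths, res$sigma_wavelengths, tolerance = 1e-9)
})

test_that("Sparrow point resolution sits at the dip-emergence separation", {
  res <- sparrow_resolution_points(cfg300)
  expect_equal(round(res$sigma_wavelengths, 3), 0.344)
  expect_lt(res$sigma, rayleigh_resolution(cfg300)$sigma)
  expect_equal(res$gaussian_point, 0)
  # brute-force peak counting around the critical separation
  below <- two_point_profile(res$sigma - 0.01, c(1, 1), cfg300)
  above <- two_point_profile(res$sigma + 0.01, c(1, 1), cfg300)
  expect_equal(profile_peaks(below), 1L)
  expect_equal(profile_peaks(above), 2L)
  expect_error(sparrow_resolution_points(cfg300, weights = c(1, 2)), "equal")
})

test_that("cylinder Sparrow resolution: value, point limit, monotonicity", {
  res <- sparrow_resolution_cylinders(0.1, cfg300)
  expect_equal(round(res$sigma, 3), 0.152)
  expect_equal(res$critical_separation, res$sigma + 0.2, tolerance = 1e-12)
  # degenerate limit recovers the point criterion
  expect_equal(sparrow_resolution_cylinders(1e-5, cfg300)$sigma,
               sparrow_resolution_points(cfg300)$sigma, tolerance = 1e-4)
  # larger cylinders resolve finer (edge-to-edge)
  sig <- vapply(c(0.01, 0.04, 0.07, 0.10, 0.13, 0.15),
                function(r) sparrow_resolution_cylinders(r, cfg300)$sigma,
                numeric(1))
  expect_true(all(diff(sig) < 0))
  expect_warning(sparrow_resolution_cylinders(2, cfg300), "overlap")
})

test_that("inverse radius query matches the forward criterion", {
  r <- radius_for_target_resolution(0.25, cfg300)
  expect_equal(round(attr(r, "wavelengths"), 3), 0.048)
  # round trip within 1e-3 wavelengths
  expect_equal(sparrow_resolution_cylinders(as.numeric(r), cfg300)$sigma,
               0.25, tolerance = 1e-3)
  # the point limit is the largest achievable sigma
  r2 <- radius_for_target_resolution(0.34, cfg300)
  expect_lt(as.numeric(r2), 0.01)
  expect_error(radius_for_target_resolution(0.5, cfg300), "not achievable")
})

test_that("gaussian point: symmetric center, asymmetric displacement, residual", {
  sym <- two_point_profile(0.4, c(1, 1), cfg300)
  g0 <- gaussian_point(sym)
  expect_lt(abs(as.numeric(g0)), 1e-6)

  asym <- two_point_profile(0.42, c(0.1, 0.2), cfg300)
  g <- gaussian_point(asym)
  expect_lt(abs(attr(g, "residual")), 1e-10)
  expect_gt(abs(as.numeric(g)), 0.01)
  # dense-grid argmin oracle on the inter-peak dip
  xs <- seq(-0.4, 0.4, length.out = 40001)
  v <- asym$f(xs)
  pk <- which(diff(sign(diff(v))) == -2) + 1
  pk <- pk[v[pk] > 0.02 * max(v)]
  dip <- xs[pk[1] + which.min(v[(pk[1]):(pk[2])]) - 1]
  expect_equal(as.numeric(g), dip, tolerance = 1e-4)
  # dip lies on the weaker scatterer's side (weak component at -d/2)
  expect_lt(as.numeric(g), 0)
})

test_that("modified Sparrow reproduces asymmetric-pair resolutions", {
  pt <- modified_sparrow_resolution(scatterer("point", epsilon_r = 1.1),
                                    scatterer("point", epsilon_r = 1.2), cfg300)
  expect_equal(round(pt$sigma, 3), 0.382)
  # asymmetry worsens the resolution relative to the symmetric pair
  expect_gt(pt$sigma, sparrow_resolution_points(cfg300)$sigma)
  # the reported Gaussian point is a genuine saddle at criterion
  expect_lt(abs(pt$details$saddle_residuals["df"]), 1e-3)
  expect_lt(abs(pt$details$saddle_residuals["d2f"]), 0.5)

  cyl <- modified_sparrow_resolution(
    scatterer("cylinder", radius = 0.10, epsilon_r = 1.1),
    scatterer("cylinder", radius = 0.15, epsilon_r = 1.1), cfg300)
  expect_equal(round(cyl$sigma, 3), 0.147)
  expect_equal(cyl$critical_separation, cyl$sigma + 0.25, tolerance = 1e-12)
})

test_that("modified Sparrow reduces to the standard criterion for equal pairs", {
  lam <- cfg300$wavelength
  mp <- modified_sparrow_resolution(scatterer("point", epsilon_r = 1.1),
                                    scatterer("point", epsilon_r = 1.1), cfg300)
  expect_lt(abs(mp$sigma - sparrow_resolution_points(cfg300)$sigma),
            1e-6 * lam)
  expect_lt(abs(mp$gaussian_point), 1e-4)
  mc <- modified_sparrow_resolution(
    scatterer("cylinder", radius = 0.1, epsilon_r = 1.1),
    scatterer("cylinder", radius = 0.1, epsilon_r = 1.1), cfg300)
  expect_lt(abs(mc$sigma - sparrow_resolution_cylinders(0.1, cfg300)$sigma),
            1e-6 * lam)
})

test_that("every criterion separates one-peak from two-peak profiles", {
  eps <- 0.005 * cfg300$wavelength
  cases <- list(
    list(res = sparrow_resolution_points(cfg300),
         make = function(d) two_point_profile(d, c(1, 1), cfg300)),
    list(res = sparrow_resolution_cylinders(0.1, cfg300),
         make = function(d) two_cylinder_profile(d, 0.1, 0.1, c(1, 1), cfg300)),
    list(res = modified_sparrow_resolution(
           scatterer("point", epsilon_r = 1.1),
           scatterer("point", epsilon_r = 1.2), cfg300),
         make = function(d) two_point_profile(d, c(0.1, 0.2), cfg300)),
    list(res = modified_sparrow_resolution(
           scatterer("cylinder", radius = 0.10, epsilon_r = 1.1),
           scatterer("cylinder", radius = 0.15, epsilon_r = 1.1), cfg300),
         make = function(d) two_cylinder_profile(d, 0.1, 0.15, c(1, 1), cfg300)))
  for (cs in cases) {
    dstar <- cs$res$critical_separation
    expect_equal(profile_peaks(cs$make(dstar - eps)), 1L)
    expect_equal(profile_peaks(cs$make(dstar + eps)), 2L)
  }
  # unit coherence holds for all of them
  for (cs in cases)
    expect_equal(cs$res$sigma, cs$res$sigma_wavelengths * cfg300$wavelength,
                 tolerance = 1e-12)
})
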