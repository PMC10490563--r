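test_that("configuration invariants hold", {
  cfg <- eis_config(300e6)
  expect_equal(cfg$wavelength, 1)
  expect_equal(cfg$k0, 2 * pi)
  phys <- eis_config(300e6, speed_of_light = "physical")
  expect_equal(phys$wavelength, 299792458 / 300e6)
  expect_error(eis_config(-1), "frequency")

  dom <- imaging_domain(c(-1, 1, -1, 1), 0.02)
  expect_equal(dom$nx, 100)
  expect_equal(dom$ny, 100)
  # cells tile the extent exactly; row-major ordering is stable
  ctr <- cell_centers(dom)
  expect_equal(ctr[1, ], c(x = -0.99, y = -0.99))
  expect_equal(ctr[2, ], c(x = -0.97, y = -0.99))       # x varies fastest
  expect_equal(ctr[dom$nx + 1, ], c(x = -0.99, y = -0.97))
  expect_error(imaging_domain(c(-1, 1, -1, 1), 0.03), "tile")

  ring <- antenna_ring(10, 36, 36)
  expect_equal(diff(ring$tx_angles)[1], 2 * pi / 36)
  expect_equal(sqrt(rowSums(ring$rx_positions^2)), rep(10, 36))
})

test_that("scene rasterization follows the cell-center rule", {
  dom <- imaging_domain(c(-1, 1, -1, 1), 0.02)
  sc0 <- build_scene(list(), dom, cfg300)
  expect_true(all(sc0$chi == 0))

  # cylinder: nonzero cells are exactly the centers within the radius
  sc <- build_scene(list(scatterer("cylinder", c(0.1, -0.2), 0.1, 1.1)),
                    dom, cfg300)
  ctr <- cell_centers(dom)
  inside <- (ctr[, 1] - 0.1)^2 + (ctr[, 2] + 0.2)^2 <= 0.1^2
  expect_identical(which(sc$chi != 0), which(inside))
  expect_equal(unique(sc$chi[inside]), 0.1)

  # a point occupies exactly one cell
  sp <- build_scene(list(scatterer("point", c(0.5, 0.5), epsilon_r = 1.3)),
                    dom, cfg300)
  expect_equal(sum(sp$chi != 0), 1)
  expect_equal(max(sp$chi), 0.3)

  # cylinders with centers 0.2 m apart and radii 0.1 m touch, don't overlap
  s1 <- build_scene(list(scatterer("cylinder", c(-0.1, 0), 0.1, 1.1)), dom, cfg300)
  s2 <- build_scene(list(scatterer("cylinder", c(0.1, 0), 0.1, 1.1)), dom, cfg300)
  expect_length(intersect(which(s1$chi != 0), which(s2$chi != 0)), 0)
  both <- build_scene(list(scatterer("cylinder", c(-0.1, 0), 0.1, 1.1),
                           scatterer("cylinder", c(0.1, 0), 0.1, 1.1)), dom, cfg300)
  expect_equal(sum(both$chi != 0), sum(s1$chi != 0) + sum(s2$chi != 0))

  expect_error(build_scene(list(scatterer("cylinder", c(0.95, 0), 0.1, 1.1)),
                           dom, cfg300), "outside")
})

test_that("figure fixtures encode the stated geometries", {
  f4a <- figure_fixture("fig4a")
  expect_equal(f4a$separation, 0.12)
  expect_equal(f4a$convention, "edge")
  cens <- sapply(f4a$scene$specs, function(s) s$center[1])
  # edge-to-edge gap: centers at -+(gap/2 + r)
  expect_equal(diff(cens) - 0.2, 0.12)

  f5g <- figure_fixture("fig5g")
  expect_equal(sapply(f5g$scene$specs, function(s) s$epsilon_r), c(1.1, 1.2))
  expect_equal(diff(sapply(f5g$scene$specs, function(s) s$center[1])), 0.42)

  f2 <- figure_fixture("fig2")
  expect_length(f2$scene$specs, 1)
  expect_equal(f2$scene$specs[[1]]$kind, "point")
  expect_equal(f2$config$frequency, 3e8)

  # fig4g rasterizations are disjoint
  f4g <- figure_fixture("fig4g")
  m <- as.matrix(f4g$scene)
  expect_equal(sort(unique(as.vector(m))), c(0, 0.1))

  expect_error(figure_fixture("fig7"), "unknown")
})

test_that("equal-scatterer fixtures are mirror symmetric and deterministic", {
  for (nm in c("fig3a", "fig4g")) {
    m <- as.matrix(figure_fixture(nm)$scene)
    expect_identical(m, m[, rev(seq_len(ncol(m)))])
  }
  # byte-identical CSV on rebuild
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_grid(as.matrix(figure_fixture("fig3a")$scene), f1,
             domain = figure_fixture("fig3a")$scene$domain)
  write_grid(as.matrix(figure_fixture("fig3a")$scene), f2,
             domain = figure_fixture("fig3a")$scene$domain)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("grid CSV, JSON report and YAML config round-trip", {
  # coordinate header layout
  p <- tempfile(fileext = ".csv")
  write_grid(matrix(0, 2, 2), p, x = c(1, 2), y = c(3, 4))
  expect_length(readLines(p), 3)
  expect_equal(strsplit(readLines(p)[1], ",")[[1]], c("", "1", "2"))

  vals <- matrix(c(pi, exp(1), sqrt(2), 1 / 3), 2, 2)
  write_grid(vals, p, x = c(0.01, 0.03), y = c(-0.01, 0.01))
  rt <- read_grid(p)
  expect_identical(rt$values, vals)
  expect_identical(rt$x, c(0.01, 0.03))
  expect_error(write_grid(matrix(c(1, NA), 1, 2), p), "finite")

  # report: meters and wavelengths stay coherent
  res <- sparrow_resolution_points(cfg300)
  pj <- tempfile(fileext = ".json")
  write_report(res, pj)
  rep <- jsonlite::read_json(pj)
  expect_equal(rep$criterion, "sparrow")
  expect_equal(rep$sigma_m, rep$sigma_wavelengths * cfg300$wavelength,
               tolerance = 1e-12)

  # YAML scene config
  py <- tempfile(fileext = ".yaml")
  writeLines(c(
    "frequency_hz: 3.0e+08",
    "domain:",
    "  extent: [-1.0, 1.0, -1.0, 1.0]",
    "  cell_size: 0.02",
    "ring: {radius: 10.0, n_tx: 36, n_rx: 36}",
    "scatterers:",
    "  - {kind: cylinder, center: [-0.16, 0.0], radius: 0.1, epsilon_r: 1.1}",
    "  - {kind: cylinder, center: [0.16, 0.0], radius: 0.1, epsilon_r: 1.1}"), py)
  fx <- read_scene_config(py)
  ref <- figure_fixture("fig4a")
  expect_identical(fx$scene$chi, ref$scene$chi)
  expect_equal(fx$ring$radius, ref$ring$radius)
})

test_that("png rendering writes a readable grayscale image", {
  p <- tempfile(fileext = ".png")
  render_png(matrix(seq(0, 1, length.out = 12), 3, 4), p)
  img <- png::readPNG(p)
  expect_equal(dim(img), c(3, 4))
  expect_equal(range(img), c(0, 1))
})
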