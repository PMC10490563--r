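# Shared geometry and lazily cached heavy objects (one SVD per geometry is
# enough for every reconstruction test on the default grid).

cfg300 <- eis_config(300e6)

.cache <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (!exists(key, envir = .cache)) assign(key, force(value), envir = .cache)
  get(key, envir = .cache)
}

# default figure geometry: 2 m x 2 m grid, 0.02 m cells, 10 m ring, 36 rx/tx
default_ring <- function() antenna_ring(10, 36, 36)

default_svd <- function() memo("svd_default", {
  fx <- figure_fixture("fig2")
  ops <- build_operators(fx$scene$domain, fx$ring, fx$config, gd_cells = 1L)
  svd_operator(ops$GS)
})

# reconstruct a named figure fixture against the cached SVD
recon_fixture <- function(name, n_incidences = NULL) {
  fx <- figure_fixture(name)
  supp <- which(fx$scene$chi != 0)
  ops <- build_operators(fx$scene$domain, fx$ring, fx$config, gd_cells = supp)
  reconstruct(fx$scene, fx$ring, n_incidences = n_incidences,
              operators = ops, svd = default_svd())
}

# fine (0.01 m) grid used by the separation-scan property
fine_domain <- function() imaging_domain(c(-1, 1, -1, 1), 0.01)

fine_svd <- function() memo("svd_fine", {
  ops <- build_operators(fine_domain(), default_ring(), cfg300, gd_cells = 1L)
  svd_operator(ops$GS)
})

recon_two_points_fine <- function(d) {
  dom <- fine_domain()
  sc <- build_scene(list(scatterer("point", c(-d / 2, 0)),
                         scatterer("point", c(d / 2, 0))), dom, cfg300)
  supp <- which(sc$chi != 0)
  ops <- build_operators(dom, default_ring(), cfg300, gd_cells = supp)
  reconstruct(sc, default_ring(), operators = ops, svd = fine_svd())
}

# peak count of a reconstruction cross-section near the x-axis
section_peaks <- function(img, y = 0.01, window = 0.7, threshold = 0.05) {
  cs <- cross_section(img, y = y)
  count_local_maxima(cs$value[abs(cs$x) <= window], threshold)
}
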