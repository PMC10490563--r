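#' Physical configuration of the imaging experiment
#'
#' Bundles the global constants every field and spread-function expression
#' depends on: operating frequency, wavelength, free-space wavenumber
#' \eqn{k_0 = 2\pi/\lambda} and the (relative) background permittivity.
#'
#' By default the speed of light is taken as exactly `3e8` m/s so that a
#' 300 MHz configuration has a wavelength of exactly 1 m. This makes every
#' quantity quoted "per wavelength" an exact decimal at the canonical test
#' frequency; pass `speed_of_light = "physical"` for the CODATA value.
#'
#' @param frequency Operating frequency in Hz. Default 300 MHz.
#' @param background_permittivity Relative permittivity of the homogeneous
#'   background (1 for free space).
#' @param speed_of_light Either a numeric value in m/s, `"exact"` (3e8 m/s,
#'   the default) or `"physical"` (299792458 m/s).
#' @return An object of class `eis_config` with fields `frequency`,
#'   `wavelength`, `k0`, `background_permittivity`, `speed_of_light`.
#' @examples
#' cfg <- eis_config(300e6)
#' cfg$wavelength  # exactly 1 m
#' @export
eis_config <- function(frequency = 300e6, background_permittivity = 1,
                       speed_of_light = c("exact", "physical")) {
  if (is.character(speed_of_light)) {
    speed_of_light <- match.arg(speed_of_light)
    c0 <- switch(speed_of_light, exact = 3e8, physical = 299792458)
  } else {
    c0 <- as.numeric(speed_of_light)
  }
  stopifnot(is.numeric(frequency), length(frequency) == 1L, frequency > 0,
            c0 > 0, background_permittivity > 0)
  wavelength <- c0 / frequency
  structure(
    list(frequency = frequency,
         speed_of_light = c0,
         wavelength = wavelength,
         k0 = 2 * pi / wavelength,
         background_permittivity = background_permittivity),
    class = "eis_config")
}

#' @export
print.eis_config <- function(x, ...) {
  cat(sprintf("<eis_config> f = %.6g Hz, lambda = %.6g m, k0 = %.6g rad/m, eps_bg = %g\n",
              x$frequency, x$wavelength, x$k0, x$background_permittivity))
  invisible(x)
}

#' Square-cell imaging domain
#'
#' A rectangular region of interest tiled exactly by square cells. Cell
#' centers are stored in row-major order: the cell with linear index
#' `(iy - 1) * nx + ix` has center `(x[ix], y[iy])`, with `y` increasing
#' from `extent[3]` upward. This ordering is stable and shared by every
#' grid-valued quantity in the package.
#'
#' @param extent Numeric vector `c(xmin, xmax, ymin, ymax)` in meters.
#' @param cell_size Side of a square cell in meters; must tile the extent
#'   exactly (to within 1e-9 relative).
#' @return Object of class `imaging_domain` with fields `extent`,
#'   `cell_size`, `nx`, `ny`, `x`, `y` (cell-center coordinates) and
#'   `cell_area`.
#' @export
imaging_domain <- function(extent = c(-1, 1, -1, 1), cell_size = 0.02) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            cell_size > 0)
  lx <- extent[2] - extent[1]
  ly <- extent[4] - extent[3]
  nx <- round(lx / cell_size)
  ny <- round(ly / cell_size)
  if (abs(nx * cell_size - lx) > 1e-9 * lx || abs(ny * cell_size - ly) > 1e-9 * ly)
    stop("cell_size must tile the extent exactly")
  structure(
    list(extent = extent, cell_size = cell_size, nx = nx, ny = ny,
         x = extent[1] + (seq_len(nx) - 0.5) * cell_size,
         y = extent[3] + (seq_len(ny) - 0.5) * cell_size,
         cell_area = cell_size^2),
    class = "imaging_domain")
}

#' @export
print.imaging_domain <- function(x, ...) {
  cat(sprintf("<imaging_domain> [%g, %g] x [%g, %g] m, %d x %d cells of %g m\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4],
              x$nx, x$ny, x$cell_size))
  invisible(x)
}

#' Cell-center coordinates of a domain
#'
#' @param domain An [imaging_domain()].
#' @return A `(nx*ny) x 2` matrix of cell centers in the package's
#'   row-major cell order.
#' @export
cell_centers <- function(domain) {
  stopifnot(inherits(domain, "imaging_domain"))
  cbind(x = rep(domain$x, times = domain$ny),
        y = rep(domain$y, each = domain$nx))
}

#' Circular antenna ring
#'
#' Transmitters are unit-amplitude plane waves with uniformly spaced
#' incidence angles; receivers are ideal point samplers uniformly spaced on
#' a circle of the given radius. For the far-field Green-function
#' approximation to hold the radius should be at least ten wavelengths;
#' this is checked when operators are assembled.
#'
#' @param radius Ring radius in meters.
#' @param n_tx Number of transmit (incidence) angles.
#' @param n_rx Number of receivers.
#' @return Object of class `antenna_ring` with fields `radius`, `n_tx`,
#'   `n_rx`, `tx_angles` (rad) and `rx_positions` (n_rx x 2 matrix, m).
#' @export
antenna_ring <- function(radius = 10, n_tx = 36, n_rx = 36) {
  stopifnot(radius > 0, n_tx >= 1, n_rx >= 1)
  tx <- 2 * pi * (seq_len(n_tx) - 1) / n_tx
  phi <- 2 * pi * (seq_len(n_rx) - 1) / n_rx
  structure(
    list(radius = radius, n_tx = n_tx, n_rx = n_rx, tx_angles = tx,
         rx_positions = cbind(x = radius * cos(phi), y = radius * sin(phi))),
    class = "antenna_ring")
}

#' @export
print.antenna_ring <- function(x, ...) {
  cat(sprintf("<antenna_ring> radius %g m, %d transmitters, %d receivers\n",
              x$radius, x$n_tx, x$n_rx))
  invisible(x)
}

#' Parametric scatterer specification
#'
#' Describes one scatterer before rasterization. A point scatterer occupies
#' a single grid cell; a cylinder (circular cross-section in the 2-D TM
#' geometry) covers every cell whose center lies within `radius` of its
#' center. The dielectric contrast of the scatterer is
#' \eqn{\chi = (\epsilon_r - \epsilon_{bg})/\epsilon_{bg}}.
#'
#' @param kind `"point"` or `"cylinder"`.
#' @param center Numeric `c(x, y)` in meters.
#' @param radius Radius in meters; 0 (and ignored) for points.
#' @param epsilon_r Relative permittivity, at least the background value.
#' @return Object of class `scatterer_spec`.
#' @export
scatterer <- function(kind = c("point", "cylinder"), center = c(0, 0),
                      radius = 0, epsilon_r = 1.1) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 2, is.finite(center), is.finite(epsilon_r))
  if (kind == "cylinder" && radius <= 0)
    stop("a cylinder needs a positive radius")
  if (kind == "point") radius <- 0
  structure(
    list(kind = kind, center = as.numeric(center), radius = radius,
         epsilon_r = epsilon_r),
    class = "scatterer_spec")
}

#' @export
print.scatterer_spec <- function(x, ...) {
  cat(sprintf("<scatterer> %s at (%g, %g) m, radius %g m, eps_r %g\n",
              x$kind, x$center[1], x$center[2], x$radius, x$epsilon_r))
  invisible(x)
}
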