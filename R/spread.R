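#' Point spread function of far-field Born imaging
#'
#' The reconstructed image of an ideal point scatterer under the
#' Born-approximation pipeline is \eqn{[J_0(k_0 x)]^2}: the accessible
#' far-field data live on a ring of spatial frequencies of radius
#' \eqn{k_0/2\pi}, whose Fourier transform is \eqn{J_0}, and the
#' least-squares contrast step contributes a second \eqn{J_0} factor. The
#' profile is already normalized to 1 at the origin.
#'
#' @param x Distance(s) from the point image center, meters.
#' @param config An [eis_config()].
#' @return Intensity value(s) in `[0, 1]`.
#' @export
psf <- function(x, config = eis_config()) {
  bessel_j0(config$k0 * x)^2
}

#' Fourier transform of a thin spatial-frequency ring
#'
#' The 2-D Fourier transform of an annulus of radius \eqn{k_0/2\pi} and
#' small thickness `thickness` in the spatial-frequency plane, evaluated at
#' radial image distance `rho`: \eqn{k_0 \Delta R\, J_0(k_0 \rho)}. The
#' thickness only scales the amplitude; the shape (and hence every
#' resolution statement) is the \eqn{J_0} factor.
#'
#' @param rho Radial distance(s) in the image plane, meters.
#' @param thickness Ring thickness `Delta R` in 1/m.
#' @param config An [eis_config()].
#' @return Transform value(s).
#' @export
ring_fourier_transform <- function(rho, thickness, config = eis_config()) {
  stopifnot(thickness > 0)
  if (thickness > 0.2 * config$k0 / (2 * pi))
    warning("thin-ring approximation assumes thickness << ring radius")
  config$k0 * thickness * bessel_j0(config$k0 * rho)
}

#' Spread profile with analytic derivatives
#'
#' Internal constructor for the 1-D joint spread functions: a vectorized
#' evaluator plus closed-form first and second derivatives, as needed by
#' the resolution root-finders.
#'
#' @param f,df,d2f Vectorized functions of x (meters).
#' @param description Provenance string.
#' @param centers Component center abscissas (meters).
#' @param radii Component radii (0 for points).
#' @param weights Component weights.
#' @param config The [eis_config()] the profile was built under.
#' @return Object of class `spread_profile`; calling it is not supported,
#'   use `$f`, `$df`, `$d2f`.
#' @keywords internal
spread_profile <- function(f, df, d2f, description, centers, radii, weights,
                           config) {
  structure(list(f = f, df = df, d2f = d2f, description = description,
                 centers = centers, radii = radii, weights = weights,
                 config = config),
            class = "spread_profile")
}

#' @export
print.spread_profile <- function(x, ...) {
  cat("<spread_profile>", x$description, "\n")
  cat(sprintf("  components at x = %s m, radii %s m, weights %s\n",
              paste(signif(x$centers, 6), collapse = ", "),
              paste(signif(x$radii, 6), collapse = ", "),
              paste(signif(x$weights, 6), collapse = ", ")))
  invisible(x)
}

#' @export
plot.spread_profile <- function(x, xlim = NULL, n = 512, ...) {
  if (is.null(xlim))
    xlim <- range(x$centers) + c(-1, 1) * (max(x$radii) + x$config$wavelength)
  xs <- seq(xlim[1], xlim[2], length.out = n)
  graphics::plot(xs, x$f(xs), type = "l", xlab = "x (m)",
                 ylab = "intensity", main = x$description, ...)
  invisible(x)
}

# Shared builder: sum of weighted components, each either a point PSF
# J0^2(k0 (x - c)) or a cylinder interval integral
# int_{x - c - r}^{x - c + r} J0^2(k0 rho) drho. Derivatives are closed
# form; only f itself needs quadrature for cylinders.
profile_components <- function(centers, radii, weights, config,
                               description = "joint spread profile") {
  stopifnot(length(centers) == length(radii),
            length(centers) == length(weights), all(weights > 0),
            all(radii >= 0))
  k0 <- config$k0
  comp_f <- function(x, c0, r) {
    u <- x - c0
    if (r == 0) return(bessel_j0(k0 * u)^2)
    vapply(u, function(ui)
      stats::integrate(function(t) bessel_j0(k0 * t)^2, ui - r, ui + r,
                       rel.tol = 1e-10, abs.tol = 1e-12)$value,
      numeric(1))
  }
  comp_df <- function(x, c0, r) {
    u <- x - c0
    if (r == 0) return(k0 * d_j0sq(k0 * u))
    bessel_j0(k0 * (u + r))^2 - bessel_j0(k0 * (u - r))^2
  }
  comp_d2f <- function(x, c0, r) {
    u <- x - c0
    if (r == 0) return(k0^2 * dd_j0sq(k0 * u))
    k0 * (d_j0sq(k0 * (u + r)) - d_j0sq(k0 * (u - r)))
  }
  mix <- function(g) function(x) {
    s <- 0
    for (i in seq_along(centers))
      s <- s + weights[i] * g(x, centers[i], radii[i])
    s
  }
  spread_profile(mix(comp_f), mix(comp_df), mix(comp_d2f), description,
                 centers, radii, weights, config)
}

#' Joint spread profile of two weighted point scatterers
#'
#' \deqn{f(x) = w_1 [J_0(k_0(x + d/2))]^2 + w_2 [J_0(k_0(x - d/2))]^2,}
#' the superposition of the point spread functions of scatterers at
#' \eqn{\mp d/2} with image weights proportional to their contrasts.
#' First and second derivatives use
#' \eqn{d/du\,J_0^2(u) = -2 J_0(u) J_1(u)} in closed form.
#'
#' @param d Center-to-center separation in meters.
#' @param weights Length-2 positive weights (contrasts); component 1 sits
#'   at `-d/2`.
#' @param config An [eis_config()].
#' @return A `spread_profile`.
#' @export
two_point_profile <- function(d, weights = c(1, 1), config = eis_config()) {
  stopifnot(d > 0, length(weights) == 2)
  profile_components(c(-d / 2, d / 2), c(0, 0), weights, config,
                     sprintf("two points, d = %g m, weights %g/%g",
                             d, weights[1], weights[2]))
}

#' Joint spread profile of two cylinders (interval model)
#'
#' The 1-D reduction of the extended-scatterer spread function: each
#' cylinder of radius \eqn{r_i} centered at \eqn{\mp d/2} contributes the
#' integral of the squared-Bessel kernel over the interval it spans on the
#' x-axis,
#' \deqn{f(x) = \sum_i w_i \int_{x - c_i - r_i}^{x - c_i + r_i}
#'   [J_0(k_0 \rho)]^2 \, d\rho.}
#' Values use adaptive quadrature; first and second derivatives are closed
#' form (boundary-term differentiation), the second derivative being the
#' four-term \eqn{J_0 J_1} expression used by the cylinder Sparrow
#' criterion.
#'
#' @param d Center-to-center separation in meters.
#' @param r1,r2 Radii in meters (component 1 at `-d/2`).
#' @param weights Length-2 positive weights (contrasts).
#' @param config An [eis_config()].
#' @return A `spread_profile`.
#' @export
two_cylinder_profile <- function(d, r1, r2, weights = c(1, 1),
                                 config = eis_config()) {
  stopifnot(d > 0, r1 > 0, r2 > 0, length(weights) == 2)
  profile_components(c(-d / 2, d / 2), c(r1, r2), weights, config,
                     sprintf("two cylinders, d = %g m, radii %g/%g m", d, r1, r2))
}

#' General spread function of a rasterized scene
#'
#' The weak-scattering image model for an arbitrary contrast map: the 2-D
#' convolution of \eqn{\chi} with the radially symmetric kernel
#' \eqn{[J_0(k_0 |r|)]^2}, truncated at `truncation` (default three
#' wavelengths, where the kernel envelope has decayed below 1% of its
#' peak), normalized to peak 1. Computed as a direct sum over the scene's
#' nonzero cells, which is fast for sparse scenes.
#'
#' @param scene A [build_scene()] result.
#' @param config An [eis_config()] (default: the scene's).
#' @param truncation Kernel truncation radius in meters.
#' @return Object of class `gsf_image` with fields `values` (ny x nx
#'   matrix, peak 1), `normalization` (the peak before scaling), `domain`,
#'   `config`.
#' @export
gsf <- function(scene, config = scene$config,
                truncation = 3 * config$wavelength) {
  stopifnot(inherits(scene, "contrast_scene"))
  ctr <- cell_centers(scene$domain)
  supp <- which(scene$chi != 0)
  vals <- numeric(nrow(ctr))
  k0 <- config$k0
  for (i in supp) {
    d <- sqrt((ctr[, 1] - ctr[i, 1])^2 + (ctr[, 2] - ctr[i, 2])^2)
    w <- which(d <= truncation)
    vals[w] <- vals[w] + scene$chi[i] * bessel_j0(k0 * d[w])^2
  }
  peak <- max(vals)
  if (peak > 0) vals <- vals / peak
  structure(list(values = matrix(vals, nrow = scene$domain$ny,
                                 ncol = scene$domain$nx, byrow = TRUE),
                 normalization = peak, domain = scene$domain, config = config),
            class = "gsf_image")
}

#' @export
print.gsf_image <- function(x, ...) {
  cat(sprintf("<gsf_image> %d x %d cells, peak before normalization %.4g\n",
              nrow(x$values), ncol(x$values), x$normalization))
  invisible(x)
}

#' @export
plot.gsf_image <- function(x, ...) {
  graphics::image(x$domain$x, x$domain$y, t(x$values), asp = 1,
                  xlab = "x (m)", ylab = "y (m)", main = "general spread function", ...)
  invisible(x)
}
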