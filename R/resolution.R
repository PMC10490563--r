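#' @name resolution-criteria
#' @title Two-scatterer resolution criteria for Born imaging
#'
#' @description
#' Root-finding engines for the classical Rayleigh criterion, the Sparrow
#' criterion for symmetric point and cylinder pairs, the modified Sparrow
#' criterion for asymmetric pairs, and the inverse query for the cylinder
#' radius achieving a target resolution. All distances are returned both in
#' meters and in wavelengths of the supplied configuration.
#'
#' The Sparrow-type criteria locate the separation at which the dip between
#' the two image peaks just vanishes: for symmetric pairs this is the
#' smallest separation `d` with a vanishing second derivative of the joint
#' spread profile at the midpoint; for asymmetric pairs the midpoint is
#' replaced by the Gaussian point `g` (the stationary point of the profile
#' between the peaks), and the critical separation is where the dip minimum
#' and the weaker peak merge into a saddle (`f'(g) = 0` and `f''(g) = 0`
#' simultaneously). Edge-to-edge resolution is
#' `sigma = d - a1 - a2` with `a_i` the edge-to-center distance of each
#' scatterer (0 for points).
NULL

resolution_result <- function(criterion, d, edges, config, gaussian_point = NA,
                              details = NULL) {
  sigma <- d - sum(edges)
  structure(list(criterion = criterion, critical_separation = d,
                 sigma = sigma,
                 sigma_wavelengths = sigma / config$wavelength,
                 gaussian_point = gaussian_point, edges = edges,
                 config = config, details = details),
            class = "eis_resolution")
}

#' @export
print.eis_resolution <- function(x, ...) {
  cat(sprintf("<eis_resolution> %s criterion\n", x$criterion))
  cat(sprintf("  critical center separation d* = %.6f m\n",
              x$critical_separation))
  cat(sprintf("  edge-to-edge resolution sigma = %.6f m = %.6f wavelengths\n",
              x$sigma, x$sigma_wavelengths))
  if (!is.na(x$gaussian_point))
    cat(sprintf("  Gaussian point g = %.6g m\n", x$gaussian_point))
  invisible(x)
}

# -- stationary-point machinery ---------------------------------------------

# All stationary points of a spread profile inside [lo, hi]: dense sign scan
# of the analytic first derivative (samples_per_wavelength grid) polished by
# uniroot and a few guarded Newton steps.
stationary_points <- function(profile, lo, hi, samples_per_wavelength = 2000) {
  n <- max(64L, ceiling((hi - lo) / profile$config$wavelength *
                          samples_per_wavelength))
  xs <- seq(lo, hi, length.out = n)
  v <- profile$df(xs)
  idx <- which(v[-n] * v[-1] < 0 | v[-n] == 0)
  if (!length(idx))
    return(data.frame(x = numeric(0), f = numeric(0), d2f = numeric(0)))
  roots <- vapply(idx, function(i) {
    r <- stats::uniroot(profile$df, c(xs[i], xs[i + 1]),
                        tol = .Machine$double.eps^0.75)$root
    for (it in 1:4) {                      # Newton polish for a tiny residual
      step <- profile$df(r) / profile$d2f(r)
      if (!is.finite(step) || abs(step) > (xs[2] - xs[1])) break
      r <- r - step
    }
    r
  }, numeric(1))
  roots <- roots[roots > lo & roots < hi]
  roots <- sort(unique(round(roots, 14)))
  data.frame(x = roots, f = profile$f(roots), d2f = profile$d2f(roots))
}

# Search window for two-component profiles: padded beyond the outer centers
# by 0.45 wavelengths -- wide enough to hold a dip displaced past the weaker
# component's center, narrow enough to exclude the first sidelobe ring of
# either component (0.61 wavelengths out).
profile_window <- function(profile, pad = 0.45 * profile$config$wavelength) {
  c(min(profile$centers) - pad, max(profile$centers) + pad)
}

# Are the two components resolved? TRUE when the local maxima nearest the
# two component centers are distinct and a local minimum (the dip) lies
# between them.
profile_resolved <- function(profile, samples_per_wavelength = 2000) {
  w <- profile_window(profile)
  st <- stationary_points(profile, w[1], w[2], samples_per_wavelength)
  mx <- st$x[st$d2f < 0]
  if (length(mx) < 2) return(FALSE)
  p1 <- mx[which.min(abs(mx - profile$centers[1]))]
  p2 <- mx[which.min(abs(mx - profile$centers[2]))]
  if (p1 == p2) return(FALSE)
  mn <- st$x[st$d2f > 0]
  any(mn > min(p1, p2) & mn < max(p1, p2))
}

# Smallest separation at which the dip appears: coarse scan of the resolved
# predicate followed by bisection. make_profile(d) builds the profile family.
critical_separation <- function(make_profile, d_lo, d_hi, config,
                                scan_step = 0.005 * config$wavelength,
                                bisect_iter = 30L) {
  ds <- seq(d_lo, d_hi, by = scan_step)
  first <- NA_integer_
  for (i in seq_along(ds)) {
    if (profile_resolved(make_profile(ds[i]))) { first <- i; break }
  }
  if (is.na(first))
    stop(sprintf("no dip emerges for separations in [%g, %g] m", d_lo, d_hi))
  if (first == 1L)
    stop(sprintf("profile already resolved at the smallest scanned separation %g m", d_lo))
  lo <- ds[first - 1L]
  hi <- ds[first]
  for (it in seq_len(bisect_iter)) {
    mid <- (lo + hi) / 2
    if (profile_resolved(make_profile(mid))) hi <- mid else lo <- mid
  }
  list(d = (lo + hi) / 2, bracket = c(lo, hi))
}

# -- criteria ----------------------------------------------------------------

#' Rayleigh resolution of the point spread function
#'
#' The first null of the \eqn{[J_0(k_0 x)]^2} point spread function: two
#' point images are Rayleigh-resolved when one peak sits on the other's
#' first minimum, so the critical separation equals the first positive root
#' of \eqn{J_0(k_0 x)} (0.383 wavelengths).
#'
#' @param config An [eis_config()].
#' @return An `eis_resolution` result.
#' @examples
#' rayleigh_resolution(eis_config(300e6))$sigma_wavelengths  # 0.3827
#' @export
rayleigh_resolution <- function(config = eis_config()) {
  lam <- config$wavelength
  root <- stats::uniroot(function(x) bessel_j0(config$k0 * x),
                         c(0.1 * lam, 0.6 * lam),
                         tol = .Machine$double.eps^0.9)$root
  resolution_result("rayleigh", root, c(0, 0), config,
                    details = list(residual = bessel_j0(config$k0 * root)))
}

#' Sparrow resolution of two identical point scatterers
#'
#' The smallest separation `d` at which the second derivative of the joint
#' profile \eqn{f(x) = J_0^2(k_0(x + d/2)) + J_0^2(k_0(x - d/2))} vanishes
#' at the midpoint -- the separation where the central dip just disappears
#' (0.344 wavelengths).
#'
#' @param config An [eis_config()].
#' @param weights Length-2 weights; must be equal (use
#'   [modified_sparrow_resolution()] for unequal contrasts).
#' @return An `eis_resolution` result.
#' @export
sparrow_resolution_points <- function(config = eis_config(),
                                      weights = c(1, 1)) {
  if (length(weights) != 2 || weights[1] != weights[2])
    stop("the standard Sparrow criterion assumes equal weights; see modified_sparrow_resolution()")
  lam <- config$wavelength
  fpp0 <- function(d) two_point_profile(d, weights, config)$d2f(0)
  root <- stats::uniroot(fpp0, c(0.1 * lam, 0.5 * lam),
                         tol = .Machine$double.eps^0.9)$root
  resolution_result("sparrow", root, c(0, 0), config, gaussian_point = 0,
                    details = list(residual = fpp0(root)))
}

#' Sparrow resolution of two identical cylinders
#'
#' For two cylinders of radius `r`, the joint profile is the two-interval
#' integral of the squared-Bessel kernel; its closed-form second derivative
#' at the midpoint is the four-term \eqn{J_0 J_1} expression. The criterion
#' finds the smallest center separation `d` with a vanishing midpoint
#' second derivative and reports the edge-to-edge resolution
#' `sigma = d - 2r`.
#'
#' @param r Cylinder radius in meters.
#' @param config An [eis_config()].
#' @return An `eis_resolution` result.
#' @examples
#' sparrow_resolution_cylinders(0.1, eis_config(300e6))$sigma  # 0.152 m
#' @export
sparrow_resolution_cylinders <- function(r, config = eis_config()) {
  stopifnot(r > 0)
  lam <- config$wavelength
  k0 <- config$k0
  q <- function(u) bessel_j0(u) * bessel_j1(u)
  fpp0 <- function(d) 4 * k0 * (q(k0 * (d / 2 - r)) - q(k0 * (d / 2 + r)))
  ds <- seq(1e-3 * lam, 1.5 * lam, by = 2e-3 * lam)
  v <- fpp0(ds)
  i <- which(v[-length(v)] * v[-1] < 0)[1]
  if (is.na(i))
    stop(sprintf("no midpoint inflection for r = %g m within 1.5 wavelengths (radius too large for this wavelength?)", r))
  root <- stats::uniroot(fpp0, c(ds[i], ds[i + 1]),
                         tol = .Machine$double.eps^0.9)$root
  if (root <= 2 * r)
    warning(sprintf("criterion separation %.4g m does not exceed the combined cylinder size 2r = %.4g m: the cylinders overlap at criterion (radius large relative to the wavelength)", root, 2 * r))
  resolution_result("sparrow", root, c(r, r), config, gaussian_point = 0,
                    details = list(residual = fpp0(root)))
}

#' Cylinder radius achieving a target Sparrow resolution
#'
#' Inverts [sparrow_resolution_cylinders()] by an outer bisection on the
#' radius: the edge-to-edge resolution of an equal-cylinder pair decreases
#' as the cylinders grow, so the radius achieving a prescribed resolution
#' is unique within the searched range.
#'
#' @param sigma_target Target edge-to-edge resolution in meters.
#' @param config An [eis_config()].
#' @param r_range Radius search bracket in meters.
#' @return The radius in meters (also reported in wavelengths via the
#'   `"wavelengths"` attribute).
#' @examples
#' radius_for_target_resolution(0.25, eis_config(300e6))  # ~0.048 m
#' @export
radius_for_target_resolution <- function(sigma_target, config = eis_config(),
                                         r_range = c(1e-4, 0.2) *
                                           config$wavelength) {
  sig <- function(r) suppressWarnings(sparrow_resolution_cylinders(r, config)$sigma)
  g <- function(r) sig(r) - sigma_target
  glo <- g(r_range[1])
  ghi <- g(r_range[2])
  if (glo * ghi > 0)
    stop(sprintf("target resolution %g m not achievable for radii in [%g, %g] m (sigma range [%g, %g] m)",
                 sigma_target, r_range[1], r_range[2],
                 sig(r_range[2]), sig(r_range[1])))
  r <- stats::uniroot(g, r_range, tol = 1e-7 * config$wavelength)$root
  structure(r, wavelengths = r / config$wavelength)
}

#' Gaussian point of a joint spread profile
#'
#' The stationary point of the profile between the two component peaks: for
#' an asymmetric pair the dip of the joint image does not sit at the
#' midpoint, and the modified Sparrow criterion evaluates curvature at this
#' point instead. When the profile has an interior dip (a local minimum
#' between the peaks) that minimum is returned; for a fully merged profile
#' the single interior stationary point (the joint maximum) is returned.
#'
#' @param profile A `spread_profile` from [two_point_profile()],
#'   [two_cylinder_profile()] or `profile_components`.
#' @param d Center separation; default: taken from the profile.
#' @return The Gaussian point in meters, with attribute `"residual"`
#'   holding `f'(g)`.
#' @export
gaussian_point <- function(profile, d = diff(range(profile$centers))) {
  w <- profile_window(profile)
  st <- stationary_points(profile, w[1], w[2])
  if (!nrow(st)) stop("profile has no stationary point in the search window")
  mx <- st[st$d2f < 0, , drop = FALSE]
  g <- NA_real_
  if (nrow(mx) >= 2) {
    p1 <- mx$x[which.min(abs(mx$x - profile$centers[1]))]
    p2 <- mx$x[which.min(abs(mx$x - profile$centers[2]))]
    if (p1 != p2) {
      mn <- st[st$d2f > 0 & st$x > min(p1, p2) & st$x < max(p1, p2), ,
               drop = FALSE]
      if (nrow(mn)) g <- mn$x[which.min(mn$f)]
    }
  }
  if (is.na(g)) {
    # merged: the interior critical point between the centers
    inner <- st[st$x >= min(profile$centers) - 1e-12 &
                  st$x <= max(profile$centers) + 1e-12, , drop = FALSE]
    g <- if (nrow(inner)) inner$x[which.max(inner$f)] else
      st$x[which.min(abs(st$x - mean(profile$centers)))]
  }
  structure(g, residual = profile$df(g))
}

#' Modified Sparrow resolution for an asymmetric scatterer pair
#'
#' Generalizes the Sparrow criterion to two scatterers of unequal contrast
#' and/or size. Image weights default to the scatterer contrasts
#' (`epsilon_r - background`), as dictated by the linearity of the
#' weak-scattering image model. The critical separation `d*` is the
#' smallest separation at which a dip appears between the two image peaks;
#' there the profile's interior stationary point `g` (the Gaussian point)
#' satisfies `f'(g) = 0` and `f''(g) = 0` simultaneously. The edge-to-edge
#' resolution is `sigma = d* - a1 - a2`. For identical scatterers this
#' reduces exactly to the standard Sparrow criterion with `g = 0`.
#'
#' @param spec1,spec2 [scatterer()] specifications (component 1 placed at
#'   `-d/2`).
#' @param config An [eis_config()].
#' @param weights Optional explicit length-2 weights overriding the
#'   contrasts.
#' @return An `eis_resolution` result; `details` records the search
#'   bracket and the saddle residuals.
#' @examples
#' \donttest{
#' modified_sparrow_resolution(scatterer("point", epsilon_r = 1.1),
#'                             scatterer("point", epsilon_r = 1.2))$sigma
#' }
#' @export
modified_sparrow_resolution <- function(spec1, spec2, config = eis_config(),
                                        weights = NULL) {
  stopifnot(inherits(spec1, "scatterer_spec"), inherits(spec2, "scatterer_spec"))
  bg <- config$background_permittivity
  if (is.null(weights))
    weights <- c(spec1$epsilon_r - bg, spec2$epsilon_r - bg) / bg
  if (any(weights <= 0)) stop("scatterer contrasts must be positive")
  radii <- c(spec1$radius, spec2$radius)
  lam <- config$wavelength
  make_profile <- function(d)
    profile_components(c(-d / 2, d / 2), radii, weights, config,
                       "modified-Sparrow profile")
  d_lo <- max(sum(radii) + 0.02 * lam, 0.05 * lam)
  d_hi <- sum(radii) + 1.2 * lam
  cs <- critical_separation(make_profile, d_lo, d_hi, config)
  # the Gaussian point at criterion: the just-born dip on the resolved side
  g <- gaussian_point(make_profile(cs$bracket[2]))
  prof <- make_profile(cs$d)
  resolution_result("modified_sparrow", cs$d, radii, config,
                    gaussian_point = as.numeric(g),
                    details = list(bracket = cs$bracket,
                                   saddle_residuals = c(df = prof$df(as.numeric(g)),
                                                        d2f = prof$d2f(as.numeric(g))),
                                   weights = weights))
}
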