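# Independent oracles: each recomputes a quantity by a route that shares no
# code with the implementation it checks.

# Bessel/Hankel of arbitrary integer order (J_{-n} = (-1)^n J_n etc.)
.besj <- function(x, n) if (n >= 0) besselJ(x, n) else (-1)^(-n) * besselJ(x, -n)
.besy <- function(x, n) if (n >= 0) besselY(x, n) else (-1)^(-n) * besselY(x, -n)
.hank <- function(x, n) .besj(x, n) + 1i * .besy(x, n)
.dbesj <- function(x, n) (.besj(x, n - 1) - .besj(x, n + 1)) / 2
.dhank <- function(x, n) (.hank(x, n - 1) - .hank(x, n + 1)) / 2

# Exact TM scattering by a homogeneous dielectric cylinder at the origin,
# plane wave incident along +x: cylindrical mode matching (continuity of Ez
# and its radial derivative at rho = a). Returns Es at the given receiver
# positions. Validated in-suite by boundary-condition continuity.
cylinder_series_es <- function(radius, eps_r, config, rx_positions) {
  k0 <- config$k0
  k1 <- k0 * sqrt(eps_r)
  N <- ceiling(k0 * radius) + 12
  phi <- atan2(rx_positions[, 2], rx_positions[, 1])
  R <- sqrt(rowSums(rx_positions^2))
  es <- rep(0i, nrow(rx_positions))
  for (n in -N:N) {
    A <- .besj(k0 * radius, n); Ap <- .dbesj(k0 * radius, n)
    H <- .hank(k0 * radius, n); Hp <- .dhank(k0 * radius, n)
    B <- .besj(k1 * radius, n); Bp <- .dbesj(k1 * radius, n)
    an <- 1i^n * (k1 * Bp * A - k0 * Ap * B) / (k0 * Hp * B - k1 * Bp * H)
    es <- es + an * .hank(k0 * R, n) * exp(1i * n * phi)
  }
  es
}

# 2-D numerical quadrature (polar; inner radial integral by stats::integrate,
# outer angular by trapezoid) of k0^2 * (j/4) H0^(1)(k0 rho) over either an
# equal-area disc or the actual square cell centered on the observation point.
quad_self_term <- function(cell_size, config, region = c("disc", "square")) {
  region <- match.arg(region)
  k0 <- config$k0
  f_re <- function(rho) -besselY(k0 * rho, 0) * rho / 4   # Re of (j/4) H0
  f_im <- function(rho) besselJ(k0 * rho, 0) * rho / 4    # Im of (j/4) H0
  inner <- function(R) {
    stats::integrate(f_re, 0, R, rel.tol = 1e-12)$value +
      1i * stats::integrate(f_im, 0, R, rel.tol = 1e-12)$value
  }
  if (region == "disc") {
    a <- cell_size / sqrt(pi)
    return(k0^2 * 2 * pi * inner(a))
  }
  phis <- seq(0, 2 * pi, length.out = 2001)
  Rs <- (cell_size / 2) / pmax(abs(cos(phis)), abs(sin(phis)))
  vals <- vapply(Rs, inner, complex(1))
  k0^2 * sum((vals[-1] + vals[-length(vals)]) / 2 * diff(phis))
}

# Dense Riemann-sum 2-D Fourier integral of a thin annulus in the
# spatial-frequency plane, evaluated along the x-axis of the image plane.
# Cells are partial-volume weighted by 4x4 subsampling of |k|.
annulus_ft_riemann <- function(ring_radius, thickness, rho, subdiv = 8) {
  dk <- thickness / subdiv
  ks <- seq(-ring_radius - 4 * thickness, ring_radius + 4 * thickness, by = dk)
  g <- expand.grid(kx = ks, ky = ks)
  rad <- sqrt(g$kx^2 + g$ky^2)
  keep <- abs(rad - ring_radius) < thickness
  g <- g[keep, ]
  frac <- numeric(nrow(g))
  off <- (seq_len(4) - 2.5) / 4 * dk
  for (ox in off) for (oy in off) {
    rr <- sqrt((g$kx + ox)^2 + (g$ky + oy)^2)
    frac <- frac + (abs(rr - ring_radius) <= thickness / 2) / 16
  }
  vapply(rho, function(r) sum(frac * cos(2 * pi * g$kx * r)) * dk^2, numeric(1))
}

# dense sampling of a spread profile for brute-force peak counting
profile_peaks <- function(profile, window = NULL, samples_per_wavelength = 2000,
                          threshold = 1e-6) {
  if (is.null(window))
    window <- range(profile$centers) + c(-0.45, 0.45) * profile$config$wavelength
  xs <- seq(window[1], window[2],
            length.out = ceiling(diff(window) / profile$config$wavelength *
                                   samples_per_wavelength))
  count_local_maxima(profile$f(xs), threshold)
}
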