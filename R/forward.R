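#' Unit-amplitude incident plane wave
#'
#' Samples \eqn{E^i(x, y) = \exp(j k_0 (x\cos\theta + y\sin\theta))} at the
#' cell centers of a domain. The implied time convention is
#' \eqn{\exp(-j\omega t)}, consistent with outgoing first-kind Hankel
#' functions in the Green kernel.
#'
#' @param domain An [imaging_domain()].
#' @param angle Incidence angle in radians.
#' @param config An [eis_config()].
#' @return Complex vector over cells (row-major), unit magnitude everywhere.
#' @export
incident_plane_wave <- function(domain, angle, config = eis_config()) {
  ctr <- cell_centers(domain)
  exp(1i * config$k0 * (ctr[, 1] * cos(angle) + ctr[, 2] * sin(angle)))
}

#' Incident fields for a set of incidence angles
#'
#' @inheritParams incident_plane_wave
#' @param angles Vector of incidence angles in radians.
#' @return Complex matrix, cells x incidences.
#' @export
incident_fields <- function(domain, angles, config = eis_config()) {
  vapply(angles, function(a) incident_plane_wave(domain, a, config),
         complex(domain$nx * domain$ny))
}

#' Free-space 2-D Green kernel
#'
#' The scalar 2-D free-space Green function for the TM Helmholtz equation
#' under the \eqn{\exp(-j\omega t)} time convention,
#' \eqn{g(r, r') = (j/4) H_0^{(1)}(k_0 |r - r'|)}, the outgoing solution of
#' \eqn{(\nabla^2 + k_0^2) g = -\delta}. (The opposite overall sign is
#' sometimes seen in print; a sign-consistent forward/inverse pipeline
#' cannot tell the difference, but only this sign reproduces the exact
#' scattered field of a dielectric cylinder.) Coincident points are
#' rejected; the singular cell self-interaction is handled inside
#' [build_operators()] by an equal-area-circle integral.
#'
#' @param r,r_prime Points as numeric `c(x, y)`, or matrices with two
#'   columns (recycled against each other row-wise).
#' @param config An [eis_config()].
#' @return Complex kernel value(s).
#' @export
green_kernel <- function(r, r_prime, config = eis_config()) {
  r <- matrix(r, ncol = 2)
  r_prime <- matrix(r_prime, ncol = 2)
  d <- sqrt((r[, 1] - r_prime[, 1])^2 + (r[, 2] - r_prime[, 2])^2)
  if (any(d == 0))
    stop("green_kernel is singular at coincident points; use the operator self-term")
  0.25i * hankel1_0(config$k0 * d)
}

# Equal-area-circle self-term: k0^2 * integral of g over a disc of area h^2
# centered on the observation point. From  int_0^X H0(x) x dx = X H1(X) + 2j/pi
# (the constant fixes the Y1 ~ -2/(pi x) singularity at 0):
#   k0^2 int_disc g dA = (j pi k0 a / 2) H1^(1)(k0 a) - 1,  a = h / sqrt(pi).
self_term <- function(cell_size, config) {
  a <- cell_size / sqrt(pi)
  (0.5i * pi * config$k0 * a) * hankel1_1(config$k0 * a) - 1
}

#' Discretized Green operators of the scattering geometry
#'
#' Assembles the pulse-basis, point-matching method-of-moments operators of
#' the two coupled field equations: the domain operator `GD` (cells x
#' cells) and the data operator `GS` (receivers x cells). Both fold in the
#' \eqn{k_0^2} factor and the cell area, so the discrete equations read
#' `J = chi * (Ei + GD %*% J)` and `Es = GS %*% J` with no further scaling.
#' The singular `GD` diagonal integrates the kernel over an equal-area
#' circle in closed form.
#'
#' `GD` grows quadratically with the number of cells; for scenes whose
#' contrast occupies a small part of a large grid, pass the support indices
#' as `gd_cells` to assemble only the needed block (the forward solution is
#' exact on the support).
#'
#' @param domain An [imaging_domain()].
#' @param ring An [antenna_ring()].
#' @param config An [eis_config()].
#' @param gd_cells Integer cell indices over which to assemble `GD`
#'   (default: all cells).
#' @return Object of class `eis_operators` with fields `GS`, `GD`,
#'   `gd_cells`, `domain`, `ring`, `config`.
#' @export
build_operators <- function(domain, ring, config = eis_config(),
                            gd_cells = NULL) {
  stopifnot(inherits(domain, "imaging_domain"), inherits(ring, "antenna_ring"))
  if (domain$cell_size > config$wavelength / 10)
    warning("cell_size exceeds lambda/10; forward accuracy will suffer")
  if (ring$radius < 10 * config$wavelength)
    warning("antenna ring inside the 10-wavelength far-field bound")
  ctr <- cell_centers(domain)
  k0 <- config$k0
  scale <- k0^2 * domain$cell_area
  # GS: receivers x cells, all pairs are well separated
  dx <- outer(ring$rx_positions[, 1], ctr[, 1], "-")
  dy <- outer(ring$rx_positions[, 2], ctr[, 2], "-")
  GS <- scale * 0.25i * hankel1_0(k0 * sqrt(dx^2 + dy^2))
  dim(GS) <- c(ring$n_rx, nrow(ctr))
  if (is.null(gd_cells)) gd_cells <- seq_len(nrow(ctr))
  sub <- ctr[gd_cells, , drop = FALSE]
  ddx <- outer(sub[, 1], sub[, 1], "-")
  ddy <- outer(sub[, 2], sub[, 2], "-")
  dist <- sqrt(ddx^2 + ddy^2)
  GD <- matrix(0i, nrow(sub), nrow(sub))
  off <- dist > 0
  GD[off] <- scale * 0.25i * hankel1_0(k0 * dist[off])
  diag(GD) <- self_term(domain$cell_size, config)
  structure(list(GS = GS, GD = GD, gd_cells = gd_cells, domain = domain,
                 ring = ring, config = config),
            class = "eis_operators")
}

#' @export
print.eis_operators <- function(x, ...) {
  cat(sprintf("<eis_operators> GS %d x %d, GD over %d cells\n",
              nrow(x$GS), ncol(x$GS), length(x$gd_cells)))
  invisible(x)
}

#' Exact forward scattering solution
#'
#' Solves the domain equation `J = chi * (Ei + GD %*% J)` for the contrast
#' current of every incidence (a dense solve of
#' `(I - diag(chi) GD) J = chi * Ei` restricted to the support of `chi`,
#' where the solution is exact), then radiates `Es = GS %*% J` to the
#' receivers. A relative residual above `1e-10` or a computationally
#' singular system raises an error rather than returning an inaccurate
#' field.
#'
#' @param scene A [build_scene()] result.
#' @param operators A [build_operators()] result whose `gd_cells` cover the
#'   support of the scene's contrast.
#' @param angles Incidence angles (default: the ring's transmit angles).
#' @return Object of class `field_set` with complex matrices `Ei` (cells x
#'   incidences), `Es` (receivers x incidences), `J` (cells x incidences),
#'   and the achieved `residual`.
#' @export
solve_forward <- function(scene, operators, angles = operators$ring$tx_angles) {
  stopifnot(inherits(scene, "contrast_scene"),
            inherits(operators, "eis_operators"))
  domain <- scene$domain
  chi <- scene$chi
  Ei <- incident_fields(domain, angles, scene$config)
  n_cells <- length(chi)
  supp <- which(chi != 0)
  J <- matrix(0i, n_cells, length(angles))
  res <- 0
  if (length(supp)) {
    pos <- match(supp, operators$gd_cells)
    if (anyNA(pos))
      stop("operators' GD block does not cover the scene's support; rebuild with gd_cells")
    A <- diag(length(supp)) - chi[supp] * operators$GD[pos, pos, drop = FALSE]
    rhs <- chi[supp] * Ei[supp, , drop = FALSE]
    Js <- tryCatch(solve(A, rhs),
                   error = function(e) stop("forward system is singular (resonant contrast?): ",
                                            conditionMessage(e)))
    res <- sqrt(sum(Mod(A %*% Js - rhs)^2)) / max(sqrt(sum(Mod(rhs)^2)), 1e-300)
    if (res > 1e-10)
      stop(sprintf("forward solve residual %.3g exceeds 1e-10", res))
    J[supp, ] <- Js
  }
  Es <- operators$GS[, supp, drop = FALSE] %*% J[supp, , drop = FALSE]
  structure(list(Ei = Ei, Es = Es, J = J, residual = res, angles = angles,
                 scene = scene, operators = operators),
            class = "field_set")
}

#' @export
print.field_set <- function(x, ...) {
  cat(sprintf("<field_set> %d incidences, %d receivers, residual %.2g\n",
              ncol(x$Es), nrow(x$Es), x$residual))
  invisible(x)
}
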