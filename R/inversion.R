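#' Truncated singular value decomposition of the data operator
#'
#' Factors `GS = U diag(d) V*` and records the truncation index: singular
#' values below `rel_tol` times the largest are discarded when the operator
#' is (pseudo-)inverted. The truncation is the explicit, reproducible
#' counterpart of the finite effective thickness of the spatial-frequency
#' ring accessible from far-field data.
#'
#' @param GS Complex data operator (receivers x cells) or an
#'   `eis_operators` object.
#' @param rel_tol Relative singular value cutoff in (0, 1); default `1e-3`.
#' @return Object of class `eis_svd` with fields `u`, `d`, `v`, `k`
#'   (truncation index), `rel_tol`.
#' @export
svd_operator <- function(GS, rel_tol = 1e-3) {
  if (inherits(GS, "eis_operators")) GS <- GS$GS
  stopifnot(is.matrix(GS), rel_tol > 0, rel_tol < 1)
  s <- svd(GS)
  if (s$d[1] <= 0)
    stop("data operator has no nonzero singular values: no radiating information")
  k <- sum(s$d >= rel_tol * s$d[1])
  if (k == 0) stop("all singular values below tolerance: no radiating information")
  structure(list(u = s$u, d = s$d, v = s$v, k = k, rel_tol = rel_tol),
            class = "eis_svd")
}

#' @export
print.eis_svd <- function(x, ...) {
  cat(sprintf("<eis_svd> %d singular values, %d retained (rel_tol %.1g)\n",
              length(x$d), x$k, x$rel_tol))
  invisible(x)
}

#' Minimum-norm radiating current from far-field data
#'
#' Inverts the data equation `Es = GS %*% J` for the current of smallest
#' norm, `Jsol = V diag(1/d) U* Es` restricted to the retained singular
#' values. `Jsol` lies in the row space of `GS` (the radiating subspace);
#' the unobservable non-radiating component is zero by construction.
#'
#' @param Es Complex data matrix (receivers x incidences) or vector.
#' @param GS Data operator, `eis_operators`, or a precomputed [svd_operator()]
#'   factorization (preferred when inverting many data sets).
#' @param rel_tol Relative singular value cutoff (ignored if `GS` is already
#'   an `eis_svd`).
#' @return Complex matrix of currents, cells x incidences.
#' @export
min_norm_current <- function(Es, GS, rel_tol = 1e-3) {
  sv <- if (inherits(GS, "eis_svd")) GS else svd_operator(GS, rel_tol)
  Es <- as.matrix(Es)
  if (nrow(Es) != nrow(sv$u)) stop("Es rows must match the number of receivers")
  ks <- seq_len(sv$k)
  coef <- Conj(t(sv$u[, ks, drop = FALSE])) %*% Es / sv$d[ks]
  sv$v[, ks, drop = FALSE] %*% coef
}

#' Radiating / non-radiating decomposition of a current
#'
#' Splits a current into its component in the retained right-singular
#' subspace of `GS` (the part that radiates to the far field) and the
#' orthogonal remainder (invisible to the receivers). The two parts are
#' orthogonal and sum to the input exactly.
#'
#' @param J Complex current matrix (cells x incidences) or vector.
#' @param svd An [svd_operator()] factorization.
#' @return A list with `J_plus`, `J_minus`.
#' @export
decompose_current <- function(J, svd) {
  stopifnot(inherits(svd, "eis_svd"))
  J <- as.matrix(J)
  if (nrow(J) != nrow(svd$v)) stop("current length must match the cell count")
  Vk <- svd$v[, seq_len(svd$k), drop = FALSE]
  J_plus <- Vk %*% (Conj(t(Vk)) %*% J)
  list(J_plus = J_plus, J_minus = J - J_plus)
}

#' Least-squares Born contrast from currents and incident fields
#'
#' Under the weak-scattering (Born) linearization `J = chi * Ei`, the
#' per-cell least-squares estimate over all incidences is
#' \deqn{\chi_{sol} = \sum_n J_n E_n^{i*} / \sum_n E_n^i E_n^{i*},}
#' which for unit-magnitude plane waves divides by the number of
#' incidences.
#'
#' @param Jsol Complex currents, cells x incidences.
#' @param Ei Complex incident fields, cells x incidences.
#' @return Complex contrast estimate per cell.
#' @export
born_contrast <- function(Jsol, Ei) {
  Jsol <- as.matrix(Jsol)
  Ei <- as.matrix(Ei)
  stopifnot(dim(Jsol) == dim(Ei))
  denom <- rowSums(Ei * Conj(Ei))
  if (any(Mod(denom) == 0)) stop("zero incident field at a cell")
  rowSums(Jsol * Conj(Ei)) / denom
}

#' Two-step Born-approximation reconstruction
#'
#' The full imaging pipeline: solve the exact forward problem of the scene
#' to synthesize far-field data, invert the data for the minimum-norm
#' radiating current, and recover the contrast by the per-cell least-squares
#' step. The result is deterministic for a fixed configuration.
#'
#' @param scene A [build_scene()] result, or a fixture list from
#'   [figure_fixture()] / [read_scene_config()].
#' @param ring An [antenna_ring()]; taken from the fixture when `scene` is
#'   one.
#' @param n_incidences Number of equally spaced incidence angles (default:
#'   the ring's transmitter count).
#' @param rel_tol Relative singular value cutoff of the inversion.
#' @param operators Optional precomputed [build_operators()] for the scene's
#'   domain/ring (its `GD` must cover the scene support).
#' @param svd Optional precomputed [svd_operator()] of `operators$GS`;
#'   passing both makes repeated reconstructions on one geometry cheap.
#' @return Object of class `born_image` with the complex `chi_sol` per
#'   cell, its display normalization, and the ingredients of the fit.
#' @examples
#' \donttest{
#' fx <- figure_fixture("fig2")
#' img <- reconstruct(fx)
#' print(img)
#' }
#' @export
reconstruct <- function(scene, ring = antenna_ring(), n_incidences = NULL,
                        rel_tol = 1e-3, operators = NULL, svd = NULL) {
  if (!inherits(scene, "contrast_scene") && is.list(scene) &&
      !is.null(scene$scene)) {
    ring <- scene$ring %||% ring
    scene <- scene$scene
  }
  stopifnot(inherits(scene, "contrast_scene"))
  if (is.null(n_incidences)) n_incidences <- ring$n_tx
  angles <- 2 * pi * (seq_len(n_incidences) - 1) / n_incidences
  if (is.null(operators)) {
    supp <- which(scene$chi != 0)
    operators <- build_operators(scene$domain, ring, scene$config,
                                 gd_cells = if (length(supp)) supp else NULL)
  }
  if (is.null(svd)) svd <- svd_operator(operators$GS, rel_tol)
  fwd <- solve_forward(scene, operators, angles)
  Jsol <- min_norm_current(fwd$Es, svd)
  chi_sol <- born_contrast(Jsol, fwd$Ei)
  peak <- max(Mod(chi_sol))
  structure(list(chi_sol = chi_sol, normalization = peak,
                 domain = scene$domain, config = scene$config, scene = scene,
                 ring = ring, svd = svd, fields = fwd, Jsol = Jsol,
                 n_incidences = n_incidences, call = match.call()),
            class = "born_image")
}

#' @export
print.born_image <- function(x, ...) {
  cat(sprintf("<born_image> %d x %d cells, %d incidences, %d/%d singular values retained\n",
              x$domain$ny, x$domain$nx, x$n_incidences, x$svd$k,
              length(x$svd$d)))
  cat(sprintf("  peak |chi_sol| = %.4g (true max chi = %.4g)\n",
              x$normalization, max(x$scene$chi)))
  invisible(x)
}

#' @export
summary.born_image <- function(object, ...) {
  m <- Mod(object$chi_sol)
  i <- which.max(m)
  ctr <- cell_centers(object$domain)
  cat("Born-approximation reconstruction\n")
  print(object)
  cat(sprintf("  peak located at (%g, %g) m\n", ctr[i, 1], ctr[i, 2]))
  cat(sprintf("  data misfit |Es - GS Jsol| / |Es| = %.3g\n",
              misfit(object)))
  invisible(object)
}

misfit <- function(img) {
  pred <- img$fields$operators$GS %*% img$Jsol
  sqrt(sum(Mod(pred - img$fields$Es)^2)) /
    max(sqrt(sum(Mod(img$fields$Es)^2)), 1e-300)
}

#' @export
coef.born_image <- function(object, ...) {
  matrix(object$chi_sol, nrow = object$domain$ny, ncol = object$domain$nx,
         byrow = TRUE)
}

#' @export
fitted.born_image <- function(object, ...) {
  object$fields$operators$GS %*% object$Jsol
}

#' @export
residuals.born_image <- function(object, ...) {
  object$fields$Es - fitted(object)
}

#' @export
plot.born_image <- function(x, what = c("magnitude", "real", "imag"), ...) {
  what <- match.arg(what)
  v <- switch(what, magnitude = Mod(coef(x)), real = Re(coef(x)),
              imag = Im(coef(x)))
  graphics::image(x$domain$x, x$domain$y, t(v), asp = 1,
                  xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("|chi_sol| (%s)", what), ...)
  invisible(x)
}

#' Horizontal cross-section of a reconstructed image
#'
#' Extracts `|chi_sol|` along the grid row nearest to a given `y`, the
#' standard sectional view used when judging whether two scatterers are
#' resolved.
#'
#' @param image A [reconstruct()] result (or a `gsf_image`).
#' @param y Height of the section in meters (nearest cell row is used).
#' @param normalize Scale the section to peak 1?
#' @return A data frame with columns `x`, `value`.
#' @export
cross_section <- function(image, y = 0, normalize = TRUE) {
  v <- if (inherits(image, "born_image")) Mod(coef(image)) else image$values
  iy <- which.min(abs(image$domain$y - y))
  val <- v[iy, ]
  if (normalize && max(val) > 0) val <- val / max(val)
  data.frame(x = image$domain$x, value = val)
}
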