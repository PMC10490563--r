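#' Write a grid of values as coordinate-annotated CSV
#'
#' The first row holds the x-coordinates of the cell centers and the first
#' column the y-coordinates, so a `ny x nx` grid becomes a `(ny+1) x (nx+1)`
#' CSV. Values are written at full double precision and round-trip exactly
#' through [read_grid()].
#'
#' @param values Numeric `ny x nx` matrix (rows indexed by y ascending).
#' @param path Output file path.
#' @param x,y Coordinate vectors; defaults taken from `domain` if given.
#' @param domain Optional [imaging_domain()] supplying the coordinates.
#' @return Invisibly, the path.
#' @export
write_grid <- function(values, path, x = NULL, y = NULL, domain = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("grid values must be finite")
  if (!is.null(domain)) {
    x <- domain$x
    y <- domain$y
  }
  if (is.null(x)) x <- seq_len(ncol(values))
  if (is.null(y)) y <- seq_len(nrow(values))
  stopifnot(length(x) == ncol(values), length(y) == nrow(values))
  fmt <- function(v) sprintf("%.17g", v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", fmt(x)), collapse = ","), con)
  for (i in seq_along(y))
    writeLines(paste(c(fmt(y[i]), fmt(values[i, ])), collapse = ","), con)
  invisible(path)
}

#' Read a grid written by [write_grid()]
#'
#' @param path CSV file path.
#' @return A list with `values` (matrix), `x`, `y`.
#' @export
read_grid <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character")
  x <- as.numeric(raw[1, -1])
  y <- as.numeric(raw[-1, 1])
  values <- matrix(as.numeric(as.matrix(raw[-1, -1])), nrow = length(y))
  list(values = values, x = x, y = y)
}

#' Write a resolution result as a JSON report
#'
#' Fields: `criterion`, `sigma_m`, `sigma_wavelengths`,
#' `critical_separation_m` and `gaussian_point_m` (null when the criterion
#' has no Gaussian point).
#'
#' @param result An `eis_resolution` object.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "eis_resolution"))
  g <- result$gaussian_point
  rep <- list(criterion = result$criterion,
              sigma_m = result$sigma,
              sigma_wavelengths = result$sigma_wavelengths,
              critical_separation_m = result$critical_separation,
              gaussian_point_m = if (is.null(g) || is.na(g)) NULL else g)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Render a grid as a grayscale PNG image
#'
#' Values are affinely mapped to `[0, 1]` (black = minimum, white =
#' maximum) and written with [png::writePNG()]; rows are flipped so that y
#' increases upward in the image.
#'
#' @param values Numeric matrix (rows indexed by y ascending).
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
render_png <- function(values, path) {
  values <- as.matrix(values)
  rng <- range(values)
  norm <- if (diff(rng) > 0) (values - rng[1]) / diff(rng) else values * 0
  png::writePNG(norm[rev(seq_len(nrow(norm))), , drop = FALSE], path)
  invisible(path)
}

#' Read a scene description from a YAML config file
#'
#' Expected keys: `frequency_hz`; `domain:` with `extent` (4 numbers) and
#' `cell_size`; `ring:` with `radius`, `n_tx`, `n_rx`; `scatterers:` a list
#' of maps with `kind`, `center`, `radius` (optional for points) and
#' `epsilon_r`.
#'
#' @param path YAML file path.
#' @return A list with `scene`, `config`, `ring`, as for [figure_fixture()].
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  config <- eis_config(frequency = num(cfg$frequency_hz) %||% 300e6)
  dom <- cfg$domain %||% list()
  domain <- imaging_domain(extent = num(dom$extent) %||% c(-1, 1, -1, 1),
                           cell_size = num(dom$cell_size) %||% 0.02)
  rg <- cfg$ring %||% list()
  ring <- antenna_ring(radius = num(rg$radius) %||% 10,
                       n_tx = num(rg$n_tx) %||% 36,
                       n_rx = num(rg$n_rx) %||% 36)
  specs <- lapply(cfg$scatterers %||% list(), function(s)
    scatterer(kind = s$kind %||% "point", center = num(s$center),
              radius = num(s$radius) %||% 0,
              epsilon_r = num(s$epsilon_r) %||% 1.1))
  list(scene = build_scene(specs, domain, config), config = config,
       ring = ring)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
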