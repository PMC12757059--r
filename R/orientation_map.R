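#' Pinwheel orientation-preference maps
#'
#' A pinwheel map assigns a preferred orientation to every position of a
#' uniform grid covering the model cortical sheet
#' \eqn{\Gamma = [0,2] \times [0,1]}. The map is the argument of a sum of
#' `n_waves` complex plane waves of wavelength `lambda` (the average
#' orientation-column spacing), random propagation sign and random phase:
#' \deqn{z(x,y) = \sum_{j=0}^{n-1} \exp\!\big(i \tfrac{2\pi}{\Lambda} l_j
#'   [\cos(j\pi/n)x + \sin(j\pi/n)y] + i\phi_j\big),}
#' with the preferred orientation \eqn{\theta = \arg(z)/2} wrapped into
#' \eqn{[0,\pi)} (orientation is a half-angle variable).
#'
#' @param lambda average column spacing in domain units (default 0.125).
#' @param n_waves number of superposed plane waves (default 30).
#' @param seed integer seed; same seed gives the identical field.
#' @return an object of class `pinwheel_field` holding the wave parameters;
#'   evaluate it at positions with [eval_pinwheel()].
#' @export
pinwheel_field <- function(lambda = 0.125, n_waves = 30, seed = 1L) {
  if (!is.numeric(lambda) || lambda <= 0) stop("`lambda` must be positive")
  if (!is.numeric(n_waves) || n_waves < 1) stop("`n_waves` must be >= 1")
  n_waves <- as.integer(n_waves)
  old <- .Random.seed_save()
  set.seed(seed)
  l <- sample(c(-1, 1), n_waves, replace = TRUE)
  phi <- runif(n_waves, 0, 2 * pi)
  .Random.seed_restore(old)
  structure(list(lambda = lambda, n_waves = n_waves, l = l, phi = phi,
                 seed = as.integer(seed)),
            class = "pinwheel_field")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate a pinwheel field at positions
#'
#' @param field a [pinwheel_field()].
#' @param x,y numeric vectors of coordinates on \eqn{\Gamma}.
#' @return preferred orientations in radians, in `[0, pi)`.
#' @export
eval_pinwheel <- function(field, x, y) {
  stopifnot(inherits(field, "pinwheel_field"), length(x) == length(y))
  j <- seq_len(field$n_waves) - 1
  kx <- (2 * pi / field$lambda) * field$l * cos(j * pi / field$n_waves)
  ky <- (2 * pi / field$lambda) * field$l * sin(j * pi / field$n_waves)
  # args: positions x waves
  ph <- outer(x, kx) + outer(y, ky) +
    matrix(field$phi, length(x), field$n_waves, byrow = TRUE)
  z <- rowSums(cos(ph)) + 1i * rowSums(sin(ph))
  theta <- Arg(z) / 2
  theta %% pi
}

#' Uniform grid over the model cortical sheet
#'
#' Cell-centred `nx` by `ny` grid covering \eqn{\Gamma=[0,2]\times[0,1]}.
#'
#' @param nx,ny grid dimensions (x spans 2 units, y spans 1).
#' @return data.frame with columns `x`, `y` (row-major over columns of x).
#' @export
grid_positions <- function(nx, ny) {
  stopifnot(nx >= 1, ny >= 1)
  xs <- (seq_len(nx) - 0.5) * (2 / nx)
  ys <- (seq_len(ny) - 0.5) * (1 / ny)
  data.frame(x = rep(xs, each = ny), y = rep(ys, times = nx))
}

#' Generate a pinwheel orientation map on a grid
#'
#' @param nx,ny grid dimensions covering \eqn{\Gamma}.
#' @inheritParams pinwheel_field
#' @return an `orientation_map`: list with `positions` (data.frame `x`,`y`),
#'   `theta` (radians in `[0, pi)`), `nx`, `ny`, `lambda`, `n_waves`, `seed`
#'   and the generating `field`.
#' @examples
#' m <- generate_pinwheel_map(40, 20, seed = 7)
#' range(m$theta)
#' @export
generate_pinwheel_map <- function(nx, ny, lambda = 0.125, n_waves = 30,
                                  seed = 1L) {
  field <- pinwheel_field(lambda, n_waves, seed)
  pos <- grid_positions(nx, ny)
  theta <- eval_pinwheel(field, pos$x, pos$y)
  structure(list(positions = pos, theta = theta, nx = as.integer(nx),
                 ny = as.integer(ny), lambda = lambda,
                 n_waves = as.integer(n_waves), seed = as.integer(seed),
                 field = field),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("orientation_map: %d x %d grid, lambda = %g, n_waves = %d, seed = %d\n",
              x$nx, x$ny, x$lambda, x$n_waves, x$seed))
  invisible(x)
}

#' Write / read an orientation map as a columnar table
#'
#' Plain TSV with columns `x`, `y`, `theta`; grid dimensions and parameters
#' in a `#`-comment header line.
#'
#' @param map an `orientation_map`.
#' @param file path.
#' @export
write_orientation_map <- function(map, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# nx=%d ny=%d lambda=%g n_waves=%d seed=%d",
                     map$nx, map$ny, map$lambda, map$n_waves, map$seed), con)
  df <- cbind(map$positions, theta = map$theta)
  write.table(format(df, digits = 17), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_orientation_map
#' @export
read_orientation_map <- function(file) {
  hdr <- readLines(file, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.eE]+", hdr))[[1]]
  meta <- lapply(strsplit(kv, "="), function(p) as.numeric(p[2]))
  names(meta) <- vapply(strsplit(kv, "="), `[`, "", 1)
  df <- read.table(file, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(positions = df[c("x", "y")], theta = df$theta,
                 nx = as.integer(meta$nx), ny = as.integer(meta$ny),
                 lambda = meta$lambda, n_waves = as.integer(meta$n_waves),
                 seed = as.integer(meta$seed), field = NULL),
            class = "orientation_map")
}
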