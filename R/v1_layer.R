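#' Linear-nonlinear-Poisson V1 front end
#'
#' V1 neurons sit on a uniform grid covering \eqn{\Gamma}; neurons on the
#' left half (`x < 1`) form population V1_1 with receptive fields centred on
#' image location 1 at (0.5, 0.5), those on the right half form V1_2 centred
#' on (1.5, 0.5). Each neuron's receptive field is a Gabor filter at the
#' neuron's preferred orientation (from a V1 pinwheel map), with the same
#' envelope SD and wavelength as the stimuli. The instantaneous firing rate
#' is the half-rectified filter response to the noisy image,
#' \eqn{r_i(t) = g\,[F_i \cdot (m + \nu\,\xi(t))]_+}, and spikes are an
#' inhomogeneous Poisson process.
#'
#' @param map an `orientation_map` for the V1 grid (`nx` by `ny` over
#'   \eqn{\Gamma}); the left/right halves define the two populations.
#' @param sigma,lambda_wave Gabor filter envelope SD and wavelength.
#' @param npix,extent pixel lattice of the receptive-field patch.
#' @return a `v1_population`: filter matrices `F1`, `F2` (neurons x pixels),
#'   preferred orientations, positions, RF centres and patch geometry.
#'   `gain` and `noise_scale` are `NA` until [calibrate_gain()] is run.
#' @export
v1_population <- function(map, sigma = 0.2, lambda_wave = 0.6, npix = 25,
                          extent = 0.5) {
  stopifnot(inherits(map, "orientation_map"))
  left <- map$positions$x < 1
  make_filters <- function(theta, center) {
    lat <- pixel_lattice(center, npix, extent)
    dx <- lat$x - center[1]
    dy <- lat$y - center[2]
    env <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
    k <- 2 * pi / lambda_wave
    t(vapply(theta, function(th)
      env * cos(k * (dx * cos(th) + dy * sin(th))),
      numeric(npix^2)))
  }
  th1 <- map$theta[left]
  th2 <- map$theta[!left]
  structure(list(
    F1 = make_filters(th1, c(0.5, 0.5)),
    F2 = make_filters(th2, c(1.5, 0.5)),
    theta1 = th1, theta2 = th2,
    pos1 = map$positions[left, , drop = FALSE],
    pos2 = map$positions[!left, , drop = FALSE],
    rf_center = list(c(0.5, 0.5), c(1.5, 0.5)),
    sigma = sigma, lambda_wave = lambda_wave, npix = as.integer(npix),
    extent = extent, map_seed = map$seed,
    gain = NA_real_, noise_scale = NA_real_,
    tau_n = 40, sigma_n = 3.5), class = "v1_population")
}

#' @export
print.v1_population <- function(x, ...) {
  cat(sprintf(
    "v1_population: %d + %d neurons, npix = %d, gain = %s, noise_scale = %s\n",
    nrow(x$F1), nrow(x$F2), x$npix,
    format(x$gain, digits = 4), format(x$noise_scale, digits = 4)))
  invisible(x)
}

#' Calibrate V1 gain and effective noise amplitude
#'
#' Fixes the two free scales of the front end so that (i) with an image of
#' `reference_contrast` in its receptive field the population-and-time mean
#' rate of the driven V1 population is `target_driven` (10 Hz) and (ii) with
#' no image (pixel noise alone) the mean rate is `target_spont` (5 Hz). The
#' spontaneous rate comes entirely from rectified responses to the OU noise,
#' so the calibration jointly solves for the rate gain `g` and a noise scale
#' `nu` multiplying the noise contribution to the filter response.
#'
#' With \eqn{a_i = F_i\cdot m} and \eqn{s_i = \nu\,\|F_i\|\,\sigma_n/
#' \sqrt{2\tau_n}}, the stationary mean of the rectified response is
#' \eqn{a_i\Phi(a_i/s_i) + s_i\varphi(a_i/s_i)}; both constraints are solved
#' in closed form up to a scalar root find in `nu`.
#'
#' @param pop a [v1_population()].
#' @param reference_contrast contrast of the reference image (default 0.5).
#' @param theta_ref orientation of the reference image, radians.
#' @param target_driven,target_spont target mean rates, Hz.
#' @return the population with `gain` and `noise_scale` filled in, plus an
#'   attribute `calibration` holding the achieved rates.
#' @export
calibrate_gain <- function(pop, reference_contrast = 0.5, theta_ref = 0,
                           target_driven = 10, target_spont = 5) {
  stopifnot(inherits(pop, "v1_population"))
  if (pop$sigma_n <= 0)
    stop("calibration error: sigma_n = 0 makes the spontaneous rate 0")
  m <- gabor_image(reference_contrast, center = c(0.5, 0.5),
                   theta = theta_ref, sigma = pop$sigma, npix = pop$npix,
                   lambda_wave = pop$lambda_wave, extent = pop$extent)
  a <- as.numeric(pop$F1 %*% unclass(m))
  s0 <- sqrt(rowSums(pop$F1^2)) * pop$sigma_n / sqrt(2 * pop$tau_n)
  spont_unit <- mean(s0) / sqrt(2 * pi)     # E[(s Z)_+] = s/sqrt(2 pi)
  driven_mean <- function(nu) {
    s <- nu * s0
    mean(a * pnorm(a / s) + s * dnorm(a / s))
  }
  # ratio driven/spont decreases monotonically from Inf (nu -> 0) to 1
  ratio <- target_driven / target_spont
  f <- function(lnu) {
    nu <- exp(lnu)
    driven_mean(nu) / (nu * spont_unit) - ratio
  }
  sol <- uniroot(f, c(-12, 12), tol = 1e-12)
  nu <- exp(sol$root)
  g <- target_spont / (nu * spont_unit)
  pop$gain <- g
  pop$noise_scale <- nu
  attr(pop, "calibration") <- list(
    driven = g * driven_mean(nu), spont = g * nu * spont_unit,
    reference_contrast = reference_contrast, theta_ref = theta_ref)
  pop
}

#' Instantaneous V1 rates for a static image
#'
#' Reference (R-level) implementation of the rectified-linear rate used by
#' the network integrator: `gain * pmax(F (m + noise_scale * xi), 0)`.
#'
#' @param pop a calibrated [v1_population()].
#' @param image a `gabor_image` (pixel vector) or NULL for no image.
#' @param xi optional pixel-noise vector (same length as the pixel lattice).
#' @param population 1 or 2.
#' @return rate vector in Hz.
#' @export
v1_rates <- function(pop, image = NULL, xi = NULL, population = 1) {
  Fm <- if (population == 1) pop$F1 else pop$F2
  if (is.na(pop$gain)) stop("population is not calibrated; run calibrate_gain()")
  m <- if (is.null(image)) numeric(ncol(Fm)) else unclass(image)
  if (length(m) != ncol(Fm)) stop("image patch shape does not match filters")
  if (!is.null(xi)) {
    if (length(xi) != ncol(Fm)) stop("noise field shape does not match filters")
    m <- m + pop$noise_scale * xi
  }
  pop$gain * pmax(as.numeric(Fm %*% m), 0)
}

#' Inhomogeneous Poisson spikes by per-bin Bernoulli thinning
#'
#' @param rates either a vector (constant rates, Hz) or a matrix of rates
#'   with one row per time bin and one column per neuron.
#' @param dt bin width, ms.
#' @param T duration, ms (required when `rates` is a vector).
#' @param seed integer seed.
#' @return a `spike_raster`: data.frame with columns `unit` (1-based) and
#'   `time` (ms), attributes `T`, `dt`, `n_units`.
#' @export
poisson_spikes <- function(rates, dt, T = NULL, seed = 1L) {
  if (is.matrix(rates)) {
    n_bins <- nrow(rates)
    n_units <- ncol(rates)
    T <- n_bins * dt
  } else {
    if (is.null(T)) stop("`T` required for constant rates")
    n_bins <- round(T / dt)
    n_units <- length(rates)
  }
  p_max <- max(rates) * dt / 1000
  if (p_max >= 1) stop("rate * dt >= 1 in some bin; refine dt")
  old <- .Random.seed_save()
  set.seed(split_seed(seed, "poisson-spikes"))
  if (is.matrix(rates)) {
    hit <- which(matrix(runif(n_bins * n_units), n_bins, n_units) <
                   rates * (dt / 1000), arr.ind = TRUE)
    out <- data.frame(unit = hit[, 2], time = (hit[, 1] - 0.5) * dt)
  } else {
    p <- rates * (dt / 1000)
    res <- lapply(seq_len(n_units), function(i) {
      b <- which(runif(n_bins) < p[i])
      if (length(b)) data.frame(unit = i, time = (b - 0.5) * dt) else NULL
    })
    out <- do.call(rbind, res)
    if (is.null(out)) out <- data.frame(unit = integer(0), time = numeric(0))
  }
  .Random.seed_restore(old)
  out <- out[order(out$unit, out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, T = T, dt = dt, n_units = n_units, class = c("spike_raster",
                                                              "data.frame"))
}
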