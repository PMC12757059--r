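#' Pixel lattice of an image patch
#'
#' Images and receptive-field filters are sampled on a uniform `npix` by
#' `npix` lattice spanning a square patch of side `extent` (domain units)
#' centred on `center`. The patch extent defaults to 0.5, about
#' \eqn{\pm 1.25\sigma} of the Gaussian envelope; it is a configuration knob
#' that is held fixed across calibration and experiments.
#'
#' @param center length-2 numeric, patch centre.
#' @param npix pixels per side.
#' @param extent side length in domain units.
#' @return list with vectors `x`, `y` of length `npix^2` (column-major:
#'   y fastest).
#' @export
pixel_lattice <- function(center = c(0.5, 0.5), npix = 25, extent = 0.5) {
  if (npix < 1) stop("`npix` must be >= 1")
  u <- if (npix == 1) 0 else seq(-extent / 2, extent / 2, length.out = npix)
  list(x = rep(center[1] + u, each = npix),
       y = rep(center[2] + u, times = npix),
       npix = as.integer(npix), extent = extent, center = center)
}

#' Gabor image
#'
#' A Gabor patch of contrast `c`: Gaussian envelope (SD `sigma`) times a
#' cosine grating of wavelength `lambda_wave` at orientation `theta`,
#' \deqn{m(x,y) = c\, e^{-[(x-x_0)^2+(y-y_0)^2]/(2\sigma^2)}
#'   \cos\!\big(\tfrac{2\pi}{\lambda}[(x-x_0)\cos\theta+(y-y_0)\sin\theta]\big).}
#' The peak pixel value at the centre equals `c`, and the image is invariant
#' under `theta -> theta + pi`.
#'
#' @param contrast contrast `c >= 0`.
#' @param center patch centre (domain coordinates).
#' @param theta orientation in radians.
#' @param sigma Gaussian envelope SD (domain units).
#' @param lambda_wave grating wavelength (domain units).
#' @param npix pixels per side.
#' @param extent patch side (domain units).
#' @return a `gabor_image`: `npix^2`-vector of pixel values (column-major,
#'   matching [pixel_lattice()]) with parameter attributes.
#' @export
gabor_image <- function(contrast, center = c(0.5, 0.5), theta = 0,
                        sigma = 0.2, lambda_wave = 0.6, npix = 25,
                        extent = 0.5) {
  if (contrast < 0) stop("`contrast` must be >= 0")
  lat <- pixel_lattice(center, npix, extent)
  dx <- lat$x - center[1]
  dy <- lat$y - center[2]
  px <- contrast * exp(-(dx^2 + dy^2) / (2 * sigma^2)) *
    cos((2 * pi / lambda_wave) * (dx * cos(theta) + dy * sin(theta)))
  structure(px, class = "gabor_image", contrast = contrast, center = center,
            theta = theta, sigma = sigma, lambda_wave = lambda_wave,
            npix = npix, extent = extent)
}

#' Plaid (superimposed orthogonal Gabors)
#'
#' Pixelwise sum of two Gabors at one centre with orientations `theta` and
#' `theta + pi/2`; no clipping is applied.
#'
#' @inheritParams gabor_image
#' @param c1,c2 contrasts of the two components.
#' @export
plaid_image <- function(c1, c2, center = c(0.5, 0.5), theta = 0,
                        sigma = 0.2, lambda_wave = 0.6, npix = 25,
                        extent = 0.5) {
  g1 <- gabor_image(c1, center, theta, sigma, lambda_wave, npix, extent)
  g2 <- gabor_image(c2, center, theta + pi / 2, sigma, lambda_wave, npix,
                    extent)
  px <- unclass(g1) + unclass(g2)
  structure(px, class = "gabor_image", contrast = c(c1, c2), center = center,
            theta = c(theta, theta + pi / 2), sigma = sigma,
            lambda_wave = lambda_wave, npix = npix, extent = extent)
}

#' Ornstein-Uhlenbeck pixel noise
#'
#' Each pixel carries independent OU noise
#' \eqn{\tau_n\, d\xi = -\xi\, dt + \sigma_n\, dW} with \eqn{\tau_n = 40} ms
#' and \eqn{\sigma_n = 3.5}, so the stationary pixel variance is
#' \eqn{\sigma_n^2/(2\tau_n)}. `ou_noise_init` draws the stationary state;
#' `evolve_noise` advances it by Euler-Maruyama steps of `dt` ms.
#'
#' @param n_pixels number of pixels.
#' @param tau_n correlation time, ms.
#' @param sigma_n noise intensity (per sqrt(ms)).
#' @param dt time step, ms.
#' @param seed integer seed.
#' @param stationary logical; draw the initial state from the stationary
#'   distribution (default) or start at zero.
#' @return a `noise_field`: list with state vector `xi` and parameters.
#' @export
ou_noise_init <- function(n_pixels, tau_n = 40, sigma_n = 3.5, dt = 0.05,
                          seed = 1L, stationary = TRUE) {
  old <- .Random.seed_save()
  set.seed(split_seed(seed, "ou-init"))
  xi <- if (stationary) rnorm(n_pixels, 0, sigma_n / sqrt(2 * tau_n))
        else rep(0, n_pixels)
  .Random.seed_restore(old)
  structure(list(xi = xi, tau_n = tau_n, sigma_n = sigma_n, dt = dt),
            class = "noise_field")
}

#' @rdname ou_noise_init
#' @param state a `noise_field`.
#' @param n_steps number of Euler-Maruyama steps.
#' @param keep logical; if TRUE return the whole trajectory (`n_steps` x
#'   `n_pixels` matrix) in `$path`, otherwise only the final state.
#' @export
evolve_noise <- function(state, n_steps, seed = 1L, keep = FALSE) {
  stopifnot(inherits(state, "noise_field"))
  if (state$dt <= 0) stop("`dt` must be positive")
  old <- .Random.seed_save()
  set.seed(split_seed(seed, "ou-evolve"))
  xi <- state$xi
  np <- length(xi)
  a <- state$dt / state$tau_n
  b <- (state$sigma_n / state$tau_n) * sqrt(state$dt)
  path <- if (keep) matrix(0, n_steps, np) else NULL
  for (s in seq_len(n_steps)) {
    xi <- xi - a * xi + b * rnorm(np)
    if (keep) path[s, ] <- xi
  }
  .Random.seed_restore(old)
  out <- state
  out$xi <- xi
  out$path <- path
  out
}

#' Two-image contrast conditions
#'
#' Cartesian product of contrasts for image 1 (location 1, orientation
#' `theta`) and image 2 (location 2, orientation `theta + pi/2`).
#'
#' @param c1_values,c2_values non-negative contrast vectors.
#' @return data.frame with columns `c1`, `c2`.
#' @export
contrast_grid <- function(c1_values, c2_values) {
  if (length(c1_values) == 0 || length(c2_values) == 0)
    stop("contrast value lists must be nonempty")
  if (any(c1_values < 0) || any(c2_values < 0))
    stop("contrasts must be >= 0")
  expand.grid(c1 = c1_values, c2 = c2_values, KEEP.OUT.ATTRS = FALSE)
}

#' Contrast-difference sweep at fixed mean contrast
#'
#' Conditions `c1 = base + dc`, `c2 = base - dc` so the mean contrast stays
#' at `base` while the contrast difference `2 dc` grows.
#'
#' @param dc vector of contrast offsets.
#' @param base mean contrast (default 0.5).
#' @export
delta_contrast_conditions <- function(dc = seq(0, 0.5, by = 0.1),
                                      base = 0.5) {
  if (any(base + dc < 0) || any(base - dc < 0))
    stop("contrasts must remain >= 0")
  data.frame(dc = dc, c1 = base + dc, c2 = base - dc)
}

#' Naturalistic image surrogates
#'
#' Grayscale images with a 1/f-like (power-law) spatial power spectrum,
#' generated by spectrally shaping white Gaussian noise. These stand in for
#' downsampled photographs in the manifold-capacity experiment: each image is
#' distinct, spatially correlated, and scaled to the contrast range of the
#' Gabor stimuli (pixel SD 0.25, mean 0).
#'
#' @param n_images number of images (>= 2).
#' @param width,height image size in pixels.
#' @param exponent spectral exponent; amplitude falls as `f^-(exponent/2)`
#'   so power falls as `f^-exponent` (default 2, natural-image-like).
#' @param pixel_sd target pixel standard deviation.
#' @param seed integer seed.
#' @return list of `height x width` matrices.
#' @export
synthetic_natural_images <- function(n_images = 50, width = 114, height = 64,
                                     exponent = 2, pixel_sd = 0.25,
                                     seed = 1L) {
  if (n_images < 2) stop("`n_images` must be >= 2")
  old <- .Random.seed_save()
  set.seed(split_seed(seed, "natural-images"))
  fx <- c(0:(width %/% 2), -((width - width %/% 2 - 1):1)) / width
  fy <- c(0:(height %/% 2), -((height - height %/% 2 - 1):1)) / height
  f <- sqrt(outer(fy^2, fx^2, `+`))
  amp <- ifelse(f > 0, f^(-exponent / 2), 0)
  imgs <- vector("list", n_images)
  for (k in seq_len(n_images)) {
    w <- matrix(rnorm(height * width), height, width)
    z <- Re(fft(fft(w) * amp, inverse = TRUE)) / (height * width)
    z <- z - mean(z)
    imgs[[k]] <- z * (pixel_sd / sd(z))
  }
  .Random.seed_restore(old)
  imgs
}
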