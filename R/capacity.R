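#' Manifold coordinates for capacity analysis
#'
#' Embeds each manifold (the trial-by-trial population responses to one
#' image) in the affine span of its own points: the global mean over all
#' manifolds is subtracted, each manifold is centred on its trial mean,
#' an orthonormal basis of the centred trials (rank capped at `M - 1`)
#' defines the manifold axes, and coordinates are scaled by the centre
#' norm, so the manifold radius is measured relative to the centre.
#'
#' @param manifolds list of trials x units matrices (one per image).
#' @param tol relative singular-value tolerance for the rank.
#' @return list per manifold: `coords` (M x D), `center_norm`, `D`.
#' @export
manifold_coords <- function(manifolds, tol = 1e-10) {
  stopifnot(is.list(manifolds), length(manifolds) >= 1)
  gm <- colMeans(do.call(rbind, manifolds))
  lapply(manifolds, function(X) {
    X <- sweep(as.matrix(X), 2, gm)
    M <- nrow(X)
    ctr <- colMeans(X)
    cn <- sqrt(sum(ctr^2))
    Xc <- sweep(X, 2, ctr)
    sv <- svd(Xc, nu = 0)
    D <- min(M - 1, sum(sv$d > tol * max(sv$d, tol)))
    if (D < 1) {
      list(coords = matrix(0, M, 1), center_norm = cn, D = 0L)
    } else {
      co <- Xc %*% sv$v[, seq_len(D), drop = FALSE]
      # canonical column signs (largest-magnitude coordinate positive) so
      # the embedding is invariant to global rotations of response space
      for (j in seq_len(D)) {
        s <- sign(co[which.max(abs(co[, j])), j])
        if (s < 0) co[, j] <- -co[, j]
      }
      list(coords = co / max(cn, .Machine$double.eps),
           center_norm = cn, D = as.integer(D))
    }
  })
}

#' Anchor-point geometry of a single manifold
#'
#' Samples `n_t` Gaussian vectors in the manifold's `D + 1` coordinates
#' (axes plus centre direction) and solves the mean-field projection onto
#' the manifold's convex hull for each; the KKT solutions are the anchor
#' points. Reports the manifold dimension `D_M = <(t . s_hat)^2>` (square
#' of the projection of the Gaussian onto the anchor direction) and radius
#' `R_M = sqrt(<|s_tilde|^2>)` relative to the centre norm, plus the
#' per-manifold inverse capacity `<F>` used by [manifold_capacity()].
#'
#' A ball manifold of radius r in D dimensions gives `D_M -> D` and
#' `R_M -> r` (the calibration case); a point manifold gives `R_M = 0` and
#' capacity 2 (the Cover limit).
#'
#' @param coords M x D coordinate matrix from [manifold_coords()], or a
#'   raw trials x units matrix (coerced via [manifold_coords()] on the
#'   single manifold).
#' @param n_t number of Gaussian samples.
#' @param kappa margin (default 0).
#' @param seed integer seed.
#' @param t_samples optional pre-drawn samples (n_t x >= D + 1), reused
#'   across manifolds for variance reduction.
#' @return list: `D_M`, `R_M`, `alpha_inv`, `alpha`, `D`.
#' @export
anchor_geometry <- function(coords, n_t = 200, kappa = 0, seed = 1L,
                            t_samples = NULL) {
  if (is.list(coords)) coords <- coords$coords
  coords <- as.matrix(coords)
  M <- nrow(coords); D <- ncol(coords)
  if (M < 1) stop("manifold needs at least one point")
  S <- cbind(coords, 1)            # augmented points (centre coord = 1)
  if (is.null(t_samples)) {
    old <- .Random.seed_save()
    set.seed(split_seed(seed, "anchor-t"))
    t_samples <- matrix(rnorm(n_t * (D + 1)), n_t, D + 1)
    .Random.seed_restore(old)
  }
  Tm <- t_samples[seq_len(n_t), seq_len(D + 1), drop = FALSE]
  qp <- anchor_qp(S, Tm, kappa)
  anch <- qp$anchors[, seq_len(D), drop = FALSE]     # manifold-axis part
  an2 <- rowSums(anch^2)
  R_M <- sqrt(mean(an2))
  nz <- an2 > 0
  proj2 <- rep(0, n_t)
  if (any(nz)) {
    tpart <- Tm[, seq_len(D), drop = FALSE]
    proj2[nz] <- (rowSums(tpart[nz, , drop = FALSE] *
                            anch[nz, , drop = FALSE]) / sqrt(an2[nz]))^2
  }
  D_M <- mean(proj2)
  alpha_inv <- mean(qp$F)
  list(D_M = D_M, R_M = R_M, alpha_inv = alpha_inv,
       alpha = if (alpha_inv > 0) 1 / alpha_inv else Inf, D = D)
}

#' Mean-field manifold capacity of an ensemble
#'
#' The capacity `alpha = P/N` at which P image manifolds in an N-neuron
#' response space cease to be linearly separable under random labels,
#' computed from the anchor statistics of each manifold and composed by the
#' inverse mean `alpha = 1 / mean_k(1/alpha_k)`. The same Gaussian samples
#' are reused across manifolds (common random numbers).
#'
#' @param manifolds list of trials x units response matrices (one per
#'   image), `P >= 2`.
#' @inheritParams anchor_geometry
#' @return list: `alpha`, per-manifold `alpha_inv`, `D_M`, `R_M` vectors,
#'   and their means `mean_D_M`, `mean_R_M`.
#' @export
manifold_capacity <- function(manifolds, n_t = 200, kappa = 0, seed = 1L) {
  if (length(manifolds) < 2) stop("need at least 2 manifolds")
  mc <- manifold_coords(manifolds)
  D_max <- max(vapply(mc, `[[`, 0L, "D"), 1L)
  old <- .Random.seed_save()
  set.seed(split_seed(seed, "capacity-t"))
  t_samples <- matrix(rnorm(n_t * (D_max + 1)), n_t, D_max + 1)
  .Random.seed_restore(old)
  geo <- lapply(mc, function(m)
    anchor_geometry(pmax_coords(m), n_t = n_t, kappa = kappa,
                    t_samples = t_samples))
  ai <- vapply(geo, `[[`, 0, "alpha_inv")
  dm <- vapply(geo, `[[`, 0, "D_M")
  rm_ <- vapply(geo, `[[`, 0, "R_M")
  list(alpha = 1 / mean(ai), alpha_inv = ai, D_M = dm, R_M = rm_,
       mean_D_M = mean(dm), mean_R_M = mean(rm_))
}

# guard for degenerate (zero-rank) manifolds: keep a single zero axis
pmax_coords <- function(m) {
  if (m$D == 0L) list(coords = matrix(0, nrow(m$coords), 1)) else m
}

#' Capacity experiment across population sizes and network variants
#'
#' For each network variant: responses to each image are simulated once
#' (the V1 front end clamped to the image-driven rates), spike counts are
#' taken in consecutive `window`-ms bins as trials, and for each
#' subsampled population of `N` excitatory units (`M = round(0.2 N)`
#' trials per image) the mean-field capacity, manifold dimension and
#' radius are computed.
#'
#' @param cnets named list of `compiled_network`s (e.g. `default`,
#'   `matched`) sharing the same V1 grid.
#' @param images list of image matrices (e.g.
#'   [synthetic_natural_images()]), sized for the V1 grid (see
#'   [v1_natural_rates()]).
#' @param sample_sizes excitatory population sizes `N` to subsample.
#' @param n_subsamples random subsamples per size.
#' @param window count window, ms.
#' @param n_t,kappa capacity parameters.
#' @param seed root seed.
#' @param burnin per-image burn-in, ms.
#' @return data.frame: `variant`, `N`, `subsample`, `alpha`, `D_M`, `R_M`.
#' @export
capacity_experiment <- function(cnets, images, sample_sizes = c(50, 100),
                                n_subsamples = 5, window = 100, n_t = 200,
                                kappa = 0, seed = 1L, burnin = 500) {
  stopifnot(length(names(cnets)) == length(cnets))
  M_max <- round(0.2 * max(sample_sizes))
  out <- list()
  for (vn in names(cnets)) {
    cnet <- cnets[[vn]]
    n_e <- cnet$config$N_e
    counts <- vector("list", length(images))
    for (k in seq_along(images)) {
      rr <- v1_natural_rates(cnet, images[[k]])
      Tt <- burnin + M_max * window
      res <- simulate_network(cnet, stim_rates(rr$rates1, rr$rates2),
                              T = Tt, burnin = burnin,
                              seed = split_seed(seed, paste(vn, "img", k)))
      sp <- res$spikes[res$spikes$unit <= n_e &
                         res$spikes$time >= burnin, ]
      wb <- floor((sp$time - burnin) / window)
      idx <- (wb + 1L) + M_max * (sp$unit - 1L)
      counts[[k]] <- matrix(tabulate(idx, nbins = M_max * n_e), M_max, n_e)
    }
    old <- .Random.seed_save()
    set.seed(split_seed(seed, paste(vn, "subsample")))
    for (N in sample_sizes) {
      if (N > n_e) stop("insufficient units for requested sample size")
      M <- max(2L, round(0.2 * N))
      for (ss in seq_len(n_subsamples)) {
        units <- sample(n_e, N)
        mans <- lapply(counts, function(cm) cm[seq_len(M), units,
                                               drop = FALSE])
        cp <- manifold_capacity(mans, n_t = n_t, kappa = kappa,
                                seed = split_seed(seed, paste(vn, N, ss)))
        out[[length(out) + 1L]] <- data.frame(
          variant = vn, N = N, subsample = ss, alpha = cp$alpha,
          D_M = cp$mean_D_M, R_M = cp$mean_R_M)
      }
    }
    .Random.seed_restore(old)
  }
  do.call(rbind, out)
}

#' V1 rates for a whole-field image
#'
#' Rates of all V1 neurons for one grayscale image whose pixel grid tiles
#' the V1 sheet: neuron (ix, iy) of the `nx x ny` V1 grid reads the 15 x 15
#' patch with top-left corner (ix, iy), i.e. the image must be
#' `(ny + 14) x (nx + 14)` (rows x cols; 114 x 64 transposed at full
#' scale). Each neuron applies a 15 x 15 Gabor filter at its preferred
#' orientation; responses are half-rectified and scaled so the population
#' mean rate is `target_mean` (10 Hz).
#'
#' @param cnet a `compiled_network` (supplies the V1 grid and
#'   orientations) or a `connectivity`.
#' @param image matrix of size `(nx + 14) x (ny + 14)` (x by y).
#' @param target_mean population mean rate, Hz.
#' @param patch_pix patch side in pixels.
#' @return list: `rates1`, `rates2` (Hz, ordered as the front-end
#'   populations), `rates` (full grid order).
#' @export
v1_natural_rates <- function(cnet, image, target_mean = 10,
                             patch_pix = 15) {
  theta_f <- cnet$theta$f
  pos_f <- cnet$positions$f
  nx <- length(unique(pos_f$x)); ny <- length(unique(pos_f$y))
  if (!all(dim(image) == c(nx + patch_pix - 1, ny + patch_pix - 1)))
    stop(sprintf("image must be %d x %d for this V1 grid",
                 nx + patch_pix - 1, ny + patch_pix - 1))
  n_f <- nx * ny
  # patch matrix by im2col: one row per neuron (grid order: x major,
  # y fastest -- matching grid_positions)
  P <- matrix(0, n_f, patch_pix^2)
  col <- 0L
  for (px in seq_len(patch_pix)) for (py in seq_len(patch_pix)) {
    col <- col + 1L
    block <- image[px:(px + nx - 1), py:(py + ny - 1), drop = FALSE]
    P[, col] <- as.vector(t(block))      # y fastest within each x
  }
  # Gabor filters on the patch lattice (extent scaled from the 25-pixel
  # stimulus patch: same pixel pitch)
  v1 <- cnet$v1
  extent <- v1$extent * (patch_pix - 1) / (v1$npix - 1)
  u <- seq(-extent / 2, extent / 2, length.out = patch_pix)
  dx <- rep(u, each = patch_pix); dy <- rep(u, times = patch_pix)
  env <- exp(-(dx^2 + dy^2) / (2 * v1$sigma^2))
  kw <- 2 * pi / v1$lambda_wave
  Fm <- t(vapply(theta_f, function(th)
    env * cos(kw * (dx * cos(th) + dy * sin(th))), numeric(patch_pix^2)))
  # im2col used (x=px rows, y=py cols); filters built with y fastest:
  # reorder patch columns to (x fastest within y? ) -- both use px outer,
  # py inner consistently
  r <- pmax(rowSums(Fm * P), 0)
  if (mean(r) <= 0) stop("image evokes no V1 response")
  r <- r * target_mean / mean(r)
  left <- pos_f$x < 1
  list(rates1 = r[left], rates2 = r[!left], rates = r)
}
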