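#' Bias-corrected linear Fisher information
#'
#' Estimates the linear Fisher information of a fine stimulus change `dx`
#' from spike counts of two stimulus classes (`x +- dx/2`):
#' \deqn{\hat I_{bc} = \frac{(f_2-f_1)^\top}{\delta x}
#'   \Big(\frac{Q_1+Q_2}{2}\Big)^{-1} \frac{(f_2-f_1)}{\delta x}
#'   \cdot \frac{2N_{tr}-N-3}{2N_{tr}-2} - \frac{2N}{N_{tr}\,\delta x^2},}
#' the standard bias-corrected form; with Gaussian counts its expectation
#' equals the true `f' Sigma^-1 f'`. Requires `2 N_tr - 2 > N + 1`.
#'
#' @param X1,X2 trials x units count matrices for the two classes.
#' @param dx parameter offset between the classes.
#' @param ridge if TRUE, add `1e-6 * trace/N` to the diagonal when the
#'   pooled covariance is numerically singular (logged via a warning).
#' @return a `fisher_estimate` list: `I_bc`, `I_naive`, `N`, `N_tr`, `dx`.
#' @export
bias_corrected_fisher <- function(X1, X2, dx, ridge = TRUE) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  N <- ncol(X1)
  if (ncol(X2) != N) stop("class matrices must have the same units")
  N_tr <- floor((nrow(X1) + nrow(X2)) / 2)
  if (2 * N_tr - 2 <= N + 1)
    stop("estimability requires 2*N_tr - 2 > N + 1")
  f1 <- colMeans(X1); f2 <- colMeans(X2)
  Q <- (stats::cov(X1) + stats::cov(X2)) / 2
  d <- (f2 - f1) / dx
  if (all(d == 0)) {
    raw <- 0
  } else {
    sol <- tryCatch(solve(Q, d), error = function(e) NULL)
    if (is.null(sol)) {
      if (!ridge) stop("singular pooled covariance")
      lam <- max(1e-6 * sum(diag(Q)) / N, 1e-12)
      warning(sprintf("pooled covariance singular; ridge %.3g applied", lam))
      sol <- solve(Q + diag(lam, N), d)
    }
    raw <- sum(d * sol)
  }
  I_bc <- raw * (2 * N_tr - N - 3) / (2 * N_tr - 2) - 2 * N / (N_tr * dx^2)
  structure(list(I_bc = I_bc, I_naive = raw, N = N, N_tr = N_tr, dx = dx,
                 f1 = f1, f2 = f2), class = "fisher_estimate")
}

#' Spike counts under the Fisher ON/OFF protocol
#'
#' Runs `n_sims` simulations of a [stim_fisher()] protocol: image 1 is on
#' throughout; image 2 alternates 200-ms ON intervals (with the perturbed
#' parameter drawn at random per interval) and 300-ms OFF intervals during
#' which V1_2 fires independent Poisson spikes at 5 Hz. Spike counts of the
#' excitatory V4/MT units in the ON windows form the trials; the first
#' count of each simulation is dropped.
#'
#' @param cnet a `compiled_network`.
#' @param kind `"contrast"` or `"orientation"`.
#' @param T duration per simulation, ms.
#' @param n_sims number of simulations (connectivity fixed, initial states
#'   and noise re-randomised).
#' @param seed root seed.
#' @param ... passed to [stim_fisher()] (e.g. `delta`, `base_contrast`).
#' @return list: `counts` (trials x N_e), `class` (1/2 per trial), `dx`,
#'   `kind`, and `off_v1_rate` (measured OFF-interval V1_2 rate, Hz).
#' @export
fisher_trials <- function(cnet, kind = c("contrast", "orientation"),
                          T = 20000, n_sims = 1, seed = 1L, ...) {
  kind <- match.arg(kind)
  n_e <- cnet$config$N_e
  counts <- list(); cls <- list(); off_rate <- numeric(0)
  for (s in seq_len(n_sims)) {
    prot <- stim_fisher(kind = kind, T = T,
                        seed = split_seed(seed, paste("classes", s)), ...)
    res <- simulate_network(cnet, prot, T = T,
                            seed = split_seed(seed, paste("fisher", s)),
                            burnin = 0, record_v1 = TRUE)
    cyc <- prot$T_on + prot$T_off
    n_cyc <- prot$n_cycles
    sp <- res$spikes[res$spikes$unit <= n_e, ]
    on_bin <- floor(sp$time / cyc)
    in_on <- (sp$time - on_bin * cyc) < prot$T_on & on_bin < n_cyc
    idx <- (on_bin[in_on] + 1L) + n_cyc * (sp$unit[in_on] - 1L)
    cm <- matrix(tabulate(idx, nbins = n_cyc * n_e), n_cyc, n_e)
    counts[[s]] <- cm[-1L, , drop = FALSE]      # drop first count per sim
    cls[[s]] <- prot$classes[-1L]
    # OFF-interval rate of V1_2 (diagnostic)
    n1 <- nrow(cnet$v1$F1)
    v2 <- res$v1_spikes[res$v1_spikes$unit > n1, ]
    ob <- floor(v2$time / cyc)
    in_off <- (v2$time - ob * cyc) >= prot$T_on & ob < n_cyc
    off_rate[s] <- sum(in_off) /
      (n_cyc * (prot$T_off / 1000) * nrow(cnet$v1$F2))
  }
  list(counts = do.call(rbind, counts), class = unlist(cls),
       dx = stim_fisher(kind = kind, T = 1000, ...)$delta, kind = kind,
       off_v1_rate = off_rate)
}

#' Fisher information per spike across normalization strata
#'
#' Samples groups of units whose normalization index falls in a given
#' range, estimates the bias-corrected Fisher information of each group,
#' and divides by the group's trial-averaged total spike count in the ON
#' window. Group sizes follow a logarithmic schedule; the number of
#' samplings per size decreases proportionally with `log(N)` from
#' `reps_max` down to `reps_min` (then stays at `reps_tail` for
#' `N >= 545`), mirroring the standard protocol.
#'
#' @param counts trials x units matrix (e.g. from [fisher_trials()]).
#' @param classes class label (1/2) per trial.
#' @param dx parameter offset.
#' @param ni normalization index per unit.
#' @param ni_range length-2 range of NI to sample from.
#' @param sizes group sizes; default log-spaced within the stratum.
#' @param reps_max,reps_min,reps_tail sampling-count schedule.
#' @param seed integer seed.
#' @return data.frame: `N`, `rep`, `total_spikes`, `info`,
#'   `info_per_spike`.
#' @export
info_per_spike <- function(counts, classes, dx, ni, ni_range,
                           sizes = NULL, reps_max = 200, reps_min = 14,
                           reps_tail = 5, seed = 1L) {
  pool <- which(ni >= ni_range[1] & ni <= ni_range[2] & !is.na(ni))
  if (!length(pool)) {
    warning("empty NI stratum; skipped")
    return(NULL)
  }
  N_tr <- min(table(classes))
  n_max <- min(length(pool), 2 * N_tr - 4)
  if (is.null(sizes)) {
    sizes <- unique(round(exp(seq(log(1), log(n_max), length.out = 8))))
  }
  sizes <- sizes[sizes <= n_max]
  old <- .Random.seed_save()
  set.seed(split_seed(seed, "info-per-spike"))
  out <- list()
  for (N in sizes) {
    reps <- if (N >= 545) reps_tail else
      max(reps_min, round(reps_max * (1 - log(N) / log(545))))
    for (rp in seq_len(reps)) {
      u <- if (length(pool) == 1) pool else sample(pool, N,
                                                   replace = N > length(pool))
      X1 <- counts[classes == 1, u, drop = FALSE]
      X2 <- counts[classes == 2, u, drop = FALSE]
      fi <- bias_corrected_fisher(X1, X2, dx)
      tot <- mean(rowSums(counts[, u, drop = FALSE]))
      out[[length(out) + 1L]] <- data.frame(
        N = N, rep = rp, total_spikes = tot, info = fi$I_bc,
        info_per_spike = if (tot > 0) fi$I_bc / tot else NA_real_)
    }
  }
  .Random.seed_restore(old)
  do.call(rbind, out)
}

#' Extrapolate Fisher information to infinite population size
#'
#' Under information-limiting correlations, `1/I_N = (1/a)(1/N) + 1/I_inf`;
#' ordinary least squares of `1/I_N` on `1/N` yields the asymptote
#' `I_inf = 1/intercept` with a confidence interval from the fit
#' covariance. A non-positive intercept is reported as `I_inf = Inf`
#' (information not saturating), not an error.
#'
#' @param N population sizes.
#' @param I_N information estimates (> 0).
#' @param level confidence level.
#' @return list: `I_inf`, `ci` (length 2), `slope_inv_a`, `fit`.
#' @export
extrapolate_info <- function(N, I_N, level = 0.95) {
  stopifnot(length(N) == length(I_N))
  if (length(N) < 3) stop("need at least 3 points")
  if (any(I_N <= 0)) stop("all I_N must be positive")
  fit <- lm(y ~ x, data = data.frame(x = 1 / N, y = 1 / I_N))
  b0 <- coef(fit)[[1]]
  se <- sqrt(vcov(fit)[1, 1])
  tq <- qt(1 - (1 - level) / 2, df = fit$df.residual)
  lo <- b0 - tq * se; hi <- b0 + tq * se
  inv <- function(z) if (z > 0) 1 / z else Inf
  list(I_inf = inv(b0), ci = sort(c(inv(hi), inv(lo))),
       slope_inv_a = coef(fit)[[2]], fit = fit)
}

#' Analytic linear Fisher information of the V1 input
#'
#' Closed-form information about a parameter `s` of image 2 (contrast or
#' orientation) carried by the V1_2 spike counts in a `T`-ms window, given
#' the linear front end and OU pixel noise:
#' `f' = g T F dm/ds`, `Sigma = g^2 nu^2 (F F^T) Var(xi_T) + diag(g T F m)`
#' with `Var(xi_T) = sigma_n^2 [T - tau_n (1 - exp(-T/tau_n))]` (the OU
#' integrated-noise variance; -> `sigma_n^2 T` for `T >> tau_n`).
#'
#' @param v1 a calibrated [v1_population()].
#' @param kind `"contrast"` or `"orientation"`.
#' @param contrast,theta image-2 parameters at the operating point
#'   (defaults 0.5 and pi/2).
#' @param T count window, ms.
#' @param h step for the numerical orientation derivative.
#' @return information in units of the parameter^-2.
#' @export
v1_input_information <- function(v1, kind = c("contrast", "orientation"),
                                 contrast = 0.5, theta = pi / 2, T = 200,
                                 h = 1e-4) {
  kind <- match.arg(kind)
  if (is.na(v1$gain)) stop("population is not calibrated")
  g2 <- function(cc, th)
    unclass(gabor_image(cc, center = v1$rf_center[[2]], theta = th,
                        sigma = v1$sigma, lambda_wave = v1$lambda_wave,
                        npix = v1$npix, extent = v1$extent))
  m <- g2(contrast, theta)
  dm <- if (kind == "contrast") m / contrast else
    (g2(contrast, theta + h) - g2(contrast, theta - h)) / (2 * h)
  Fm <- v1$F2
  g <- v1$gain; nu <- v1$noise_scale
  fp <- g * (T / 1000) * as.numeric(Fm %*% dm)          # d(counts)/ds
  mean_counts <- pmax(g * (T / 1000) * as.numeric(Fm %*% m), 0)
  # rectified-silent units have zero rate derivative and zero Poisson
  # variance in the linearised model; drop them (they carry no information
  # and make the diagonal singular)
  keep <- mean_counts > 0
  Fm <- Fm[keep, , drop = FALSE]
  fp <- fp[keep]
  mean_counts <- mean_counts[keep]
  var_xiT <- v1$sigma_n^2 * (T - v1$tau_n * (1 - exp(-T / v1$tau_n)))
  Sig <- (g * nu / 1000)^2 * var_xiT * tcrossprod(Fm) + diag(mean_counts)
  sol <- tryCatch(solve(Sig, fp), error = function(e) NULL)
  if (is.null(sol)) {
    lam <- 1e-6 * sum(diag(Sig)) / nrow(Sig)
    warning(sprintf("singular input covariance; ridge %.3g applied", lam))
    sol <- solve(Sig + diag(lam, nrow(Sig)), fp)
  }
  sum(fp * sol)
}
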