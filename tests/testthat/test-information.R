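test_that("bias-corrected Fisher estimator matches its closed-form cases", {
  # f2 == f1 forces the pure correction term -2N/(Ntr dx^2)
  X <- matrix(1, 100, 1)
  expect_equal(suppressWarnings(
    bias_corrected_fisher(X, X, 0.01)$I_bc), -2 * 1 / (100 * 1e-4))
  # invariance under unit relabelling
  set.seed(1)
  X1 <- matrix(rnorm(600), 100); X2 <- matrix(rnorm(600, 0.3), 100)
  p <- sample(6)
  expect_equal(bias_corrected_fisher(X1, X2, 0.1)$I_bc,
               bias_corrected_fisher(X1[, p], X2[, p], 0.1)$I_bc,
               tolerance = 1e-10)
  # 1/dx^2 scaling identity on fixed counts
  a <- bias_corrected_fisher(X1, X2, 0.1)
  b <- bias_corrected_fisher(X1, X2, 0.2)
  expect_equal(a$I_bc, 4 * b$I_bc, tolerance = 1e-10)
  # estimability guard
  expect_error(bias_corrected_fisher(X1[1:3, ], X2[1:3, ], 0.1),
               "estimability")
})

test_that("bias correction removes the finite-trial bias (Gaussian oracle)", {
  set.seed(2)
  N <- 10; Ntr <- 5000; dx <- 0.1; reps <- 200
  fp <- rnorm(N)
  Sig <- crossprod(matrix(rnorm(N * N), N)) / N + diag(N)
  truth <- sum(fp * solve(Sig, fp))
  L <- chol(Sig)
  est <- replicate(reps, {
    X1 <- matrix(rnorm(Ntr * N), Ntr) %*% L
    X2 <- sweep(matrix(rnorm(Ntr * N), Ntr) %*% L, 2, -fp * dx)
    fi <- bias_corrected_fisher(X1, X2, dx)
    c(fi$I_bc, fi$I_naive)
  })
  se <- sd(est[1, ]) / sqrt(reps)
  expect_lt(abs(mean(est[1, ]) - truth), 2 * se)
  # the naive estimator is biased upward (paired sign test)
  n_up <- sum(est[2, ] > est[1, ])
  expect_lt(binom.test(n_up, reps, alternative = "greater")$p.value, 0.01)
})

test_that("1/N extrapolation recovers the information asymptote", {
  a <- 2; I_inf <- 500
  N <- c(8, 32, 125, 500, 2000, 12000)
  I_N <- 1 / (1 / (a * N) + 1 / I_inf)
  ex <- extrapolate_info(N, I_N)
  expect_equal(ex$I_inf, 500, tolerance = 1e-9)
  expect_equal(ex$slope_inv_a, 1 / a, tolerance = 1e-9)
  # non-saturating case: I_N linear in N gives the Inf branch
  ex2 <- extrapolate_info(N, a * N)
  expect_equal(ex2$I_inf, Inf)
  # 5% multiplicative noise: median recovery within 10% over 100 reps
  set.seed(3)
  recs <- replicate(100, {
    ey <- I_N * exp(rnorm(length(N), 0, 0.05))
    extrapolate_info(N, ey)$I_inf
  })
  expect_lt(abs(median(recs) - I_inf) / I_inf, 0.1)
  expect_error(extrapolate_info(N[1:2], I_N[1:2]), "3 points")
  expect_error(extrapolate_info(N, -I_N), "positive")
})

test_that("analytic V1 input information matches its limits and oracle", {
  v1 <- fx_model()$v1
  # the stated OU integrated-noise variance against brute-force integration
  tau_n <- 40; sig_n <- 3.5; T <- 200
  var_stated <- sig_n^2 * (T - tau_n * (1 - exp(-T / tau_n)))
  set.seed(4)
  nrep <- 4000
  st <- ou_noise_init(nrep, dt = 0.5, seed = 4)
  path <- evolve_noise(st, n_steps = T / 0.5, seed = 5, keep = TRUE)$path
  var_bf <- var(colSums(path) * 0.5)
  expect_equal(var_bf, var_stated, tolerance = 0.1)
  # with vanishing pixel noise the information approaches the Poisson
  # diagonal form sum T f_i'^2 / f_i
  v1b <- v1
  v1b$noise_scale <- 1e-8
  m <- gabor_image(0.5, center = c(1.5, 0.5), theta = pi / 2)
  f <- pmax(v1$gain * 0.2 * as.numeric(v1$F2 %*% unclass(m)), 0)
  fp <- v1$gain * 0.2 * as.numeric(v1$F2 %*% (unclass(m) / 0.5))
  keep <- f > 1e-12
  expect_equal(v1_input_information(v1b, "contrast"),
               sum(fp[keep]^2 / f[keep]), tolerance = 0.02)
  # full information is finite, positive, below the no-noise bound
  I_in <- v1_input_information(v1, "contrast")
  expect_gt(I_in, 0)
  expect_lt(I_in, sum(fp[keep]^2 / f[keep]))
  expect_gt(v1_input_information(v1, "orientation"), 0)
})

test_that("Fisher ON/OFF protocol yields the stated trial structure", {
  cnet <- fx_tiny()
  ft <- fisher_trials(cnet, "contrast", T = 20000, n_sims = 1, seed = 31)
  # 40 ON intervals; first count dropped
  expect_equal(nrow(ft$counts), 39)
  expect_equal(ncol(ft$counts), cnet$config$N_e)
  expect_equal(ft$dx, 0.01)
  # class labels balanced to within one
  expect_lte(abs(diff(as.numeric(table(ft$class)))), 1)
  # OFF intervals: V1_2 fires independent Poisson at 5 Hz
  expect_equal(mean(ft$off_v1_rate), 5, tolerance = 0.15)
  # orientation variant default offset
  ft2 <- fisher_trials(cnet, "orientation", T = 5000, n_sims = 1, seed = 32)
  expect_equal(ft2$dx, 0.02)
})

test_that("info-per-spike sampling respects strata and determinism", {
  set.seed(5)
  n_units <- 60; n_tr <- 400
  ni <- runif(n_units, 1, 3)
  hi <- ni > 2                                  # only high-NI units carry signal
  f1 <- rep(5, n_units); f2 <- f1 + ifelse(hi, 0.8, 0)
  counts <- rbind(matrix(rpois(n_tr * n_units, f1), n_tr, n_units,
                         byrow = TRUE),
                  matrix(rpois(n_tr * n_units, f2), n_tr, n_units,
                         byrow = TRUE))
  classes <- rep(1:2, each = n_tr)
  lo_df <- info_per_spike(counts, classes, 0.1, ni, c(1, 2),
                          sizes = c(4, 8), seed = 6)
  hi_df <- info_per_spike(counts, classes, 0.1, ni, c(2, 3),
                          sizes = c(4, 8), seed = 6)
  expect_gt(mean(hi_df$info_per_spike), mean(lo_df$info_per_spike))
  # determinism given the seed
  expect_identical(info_per_spike(counts, classes, 0.1, ni, c(2, 3),
                                  sizes = c(4, 8), seed = 6), hi_df)
  # information non-negative in the well-sampled regime (Ntr >= 50 N)
  expect_true(all(hi_df$info[hi_df$N <= n_tr / 50] > 0))
  expect_warning(info_per_spike(counts, classes, 0.1, ni, c(5, 6)),
                 "empty")
})
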