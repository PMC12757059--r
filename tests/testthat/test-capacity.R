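test_that("anchor geometry reproduces the calibration cases", {
  set.seed(1)
  Nn <- 50
  # point manifolds: zero radius, capacity at the Cover limit of 2
  pts <- lapply(1:30, function(k) {
    p <- rnorm(Nn)
    matrix(rep(p, 5), 5, Nn, byrow = TRUE)
  })
  cp <- manifold_capacity(pts, n_t = 4000, seed = 2)
  expect_equal(cp$mean_R_M, 0)
  expect_equal(cp$alpha, 2, tolerance = 0.1)
  # ball manifold in its own coordinates (radius r relative to a
  # unit-norm centre): D_M -> D and R_M -> r
  D <- 5; r <- 0.4; M <- 400
  s <- matrix(rnorm(M * D), M)
  s <- s / sqrt(rowSums(s^2)) * r
  g <- anchor_geometry(s, n_t = 2000, seed = 3)
  expect_equal(g$D_M, D, tolerance = 0.1)
  expect_equal(g$R_M, r, tolerance = 0.1)
  # determinism
  g2 <- anchor_geometry(s, n_t = 2000, seed = 3)
  expect_identical(g, g2)
})

test_that("mean-field capacity agrees with the LP separability oracle", {
  Nn <- 50
  for (sd_ in c(11, 12)) {
    mans <- blob_manifolds(P = 160, N = Nn, M = 6, radius = 0.6,
                           seed = sd_)
    a_mf <- manifold_capacity(mans[1:60], n_t = 1000, seed = 1)$alpha
    a_or <- oracle_critical_load(mans, Nn, P_lo = 10, n_dich = 24,
                                 seed = sd_)
    expect_equal(a_mf, a_or, tolerance = 0.2)
  }
})

test_that("dilation lowers capacity in both the theory and the oracle", {
  Nn <- 40
  mans <- blob_manifolds(P = 80, N = Nn, M = 6, radius = 0.5, seed = 5)
  dil <- lapply(mans, function(X) {
    ctr <- colMeans(X)
    sweep(sweep(X, 2, ctr) * 2, 2, -ctr)
  })
  a1 <- manifold_capacity(mans, n_t = 600, seed = 6)$alpha
  a2 <- manifold_capacity(dil, n_t = 600, seed = 6)$alpha
  expect_gt(a1, a2)
  o1 <- oracle_critical_load(mans, Nn, P_lo = 6, n_dich = 16, seed = 7)
  o2 <- oracle_critical_load(dil, Nn, P_lo = 6, n_dich = 16, seed = 7)
  expect_gt(o1, o2)
})

test_that("capacity is invariant to rotations and to joint dilation", {
  set.seed(8)
  Nn <- 30
  mans <- blob_manifolds(P = 12, N = Nn, M = 5, radius = 0.4, seed = 9)
  base <- manifold_capacity(mans, n_t = 300, seed = 10)
  # global orthogonal rotation of response space
  Q <- qr.Q(qr(matrix(rnorm(Nn * Nn), Nn)))
  rot <- lapply(mans, function(X) X %*% Q)
  rotated <- manifold_capacity(rot, n_t = 300, seed = 10)
  expect_equal(rotated$alpha, base$alpha, tolerance = 1e-6)
  expect_equal(rotated$R_M, base$R_M, tolerance = 1e-6)
  # R_M is relative to the centre norm: joint dilation leaves it unchanged
  lam <- 3.7
  scaled <- manifold_capacity(lapply(mans, function(X) lam * X),
                              n_t = 300, seed = 10)
  expect_equal(scaled$R_M, base$R_M, tolerance = 1e-9)
})

test_that("capacity experiment follows the subsampling protocol", {
  cnet <- fx_tiny()
  nx <- cnet$config$dims$f[1]; ny <- cnet$config$dims$f[2]
  imgs <- lapply(synthetic_natural_images(4, width = nx + 14,
                                          height = ny + 14, seed = 3), t)
  ce <- capacity_experiment(list(default = cnet), imgs,
                            sample_sizes = c(30, 60), n_subsamples = 2,
                            n_t = 100, seed = 4, burnin = 300)
  expect_equal(nrow(ce), 4)                    # 2 sizes x 2 subsamples
  expect_true(all(ce$alpha > 0))
  expect_true(all(ce$D_M > 0 & ce$R_M >= 0))
  # rate normalisation of the naturalistic front end
  rr <- v1_natural_rates(cnet, imgs[[1]])
  expect_equal(mean(rr$rates), 10, tolerance = 1e-9)
  expect_true(all(rr$rates >= 0))
  expect_error(v1_natural_rates(cnet, imgs[[1]][-1, ]), "image must be")
})
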