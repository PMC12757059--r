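test_that("network_config derives sizes, degrees and probabilities", {
  cfg <- network_config(scale = 1)
  expect_equal(cfg$N_e, 20000)
  expect_equal(cfg$N_i, 5000)
  expect_equal(cfg$N_f, 5000)
  # K_out = p * N_target identity for every projection
  expect_equal(unname(cfg$K_out),
               c(200, 800, 150, 200, 1000, 250))
  # weights carry sign: E/F sources positive, I sources negative
  expect_true(all(cfg$J[c("ee", "ie", "eF", "iF")] > 0))
  expect_true(all(cfg$J[c("ei", "ii")] < 0))
  cfg2 <- network_config(scale = 0.25)
  expect_equal(cfg2$N_e, 5000)
  expect_equal(unname(cfg2$K_out), c(50, 200, 38, 50, 250, 62))
})

test_that("wrapped Gaussian is a normalised, symmetric, converged density", {
  # normalisation: cell sum over the domain ~ 1
  g <- expand.grid(x = seq(-1 + 1/128, 1, by = 1/64),
                   y = seq(-0.5 + 1/128, 0.5, by = 1/64))
  dens <- wrapped_gaussian(g$x, g$y, sigma = 0.2)
  expect_equal(sum(dens) * (1 / 64)^2, 1, tolerance = 1e-6)
  # symmetry
  expect_equal(wrapped_gaussian(0.3, 0.1, 0.2),
               wrapped_gaussian(-0.3, -0.1, 0.2), tolerance = 1e-15)
  # series truncation converged
  expect_equal(wrapped_gaussian(g$x[1:50], g$y[1:50], 0.2, k_trunc = 3),
               wrapped_gaussian(g$x[1:50], g$y[1:50], 0.2, k_trunc = 10),
               tolerance = 1e-12)
  expect_error(wrapped_gaussian(0, 0, sigma = 0), "sigma")
})

test_that("default builder: exact out-degrees, long-range rule, spatial profile", {
  cnet <- fx_model()
  net <- attr(cnet, "net")
  cfg <- net$config
  # exact out-degrees for every projection
  for (pn in c("ee", "ie", "ei", "ii", "eF", "iF"))
    expect_true(all(degree_table(net, pn, "out") == cfg$K_out[[pn]]),
                label = paste("out-degree", pn))
  # 15% of E->E outgoing edges are long-range, uniformly per neuron
  ee <- net$edges$ee
  lr_per_pre <- tabulate(ee$pre[ee$long], nbins = cfg$N_e)
  expect_true(all(lr_per_pre == round(0.15 * cfg$K_out[["ee"]])))
  expect_true(all(!net$edges$ei$long))         # I projections purely spatial
  expect_true(all(!net$edges$ie$long))
  # all long-range edges satisfy the tuning threshold
  th_pre <- net$theta$e[ee$pre[ee$long]]
  th_post <- net$theta$e[ee$post[ee$long]]
  expect_true(all(cos(th_pre - th_post) >= 0.6 - 1e-12))
  # local E->E x-displacement matches the wrapped-Gaussian marginal
  # (CDF compared at cell edges to avoid discretisation bias)
  loc <- net$edges$ee[!net$edges$ee$long, ]
  px <- net$positions$e$x
  dx <- (px[loc$post] - px[loc$pre] + 1) %% 2 - 1   # wrap to [-1, 1)
  pitch <- 2 / cfg$dims$e[1]
  edges <- seq(-1, 1, by = pitch)
  xs <- seq(-1 + pitch / 2000, 1, by = pitch / 1000)
  marg <- function(x) {                        # marginal over y
    ks <- -5:5
    rowSums(vapply(ks, function(k)
      stats::dnorm(x + 2 * k, 0, 0.2), numeric(length(x))))
  }
  cdf_th <- cumsum(marg(xs)) * (pitch / 1000)
  cdf_at <- stats::approx(xs, cdf_th / max(cdf_th), xout = edges,
                          rule = 2)$y
  cdf_emp <- stats::ecdf(dx + pitch / 2)(edges)    # snap centres to edges
  expect_lt(max(abs(cdf_emp - cdf_at)), 0.05)
})

test_that("matched-in-degree builder fixes in-degrees exactly", {
  cm <- fx_matched()
  net <- attr(cm, "net")
  cfg <- net$config
  spec <- list(ee = c("e", "e"), ie = c("e", "i"), ei = c("i", "e"),
               ii = c("i", "i"), eF = c("f", "e"), iF = c("f", "i"))
  sizes <- c(e = cfg$N_e, i = cfg$N_i, f = cfg$N_f)
  for (pn in names(spec)) {
    K_in <- round(cfg$K_out[[pn]] * sizes[[spec[[pn]][1]]] /
                    sizes[[spec[[pn]][2]]])
    din <- degree_table(net, pn, "in")
    expect_true(all(din == K_in), label = paste("in-degree", pn))
    expect_equal(var(as.numeric(din)), 0)
  }
  # spatial profile of in-edges still follows sigma_e
  ee <- net$edges$ee[!net$edges$ee$long, ]
  px <- net$positions$e$x
  dx <- (px[ee$post] - px[ee$pre] + 1) %% 2 - 1
  expect_lt(abs(sd(dx) - 0.2), 0.02)
})

test_that("random builder controls feedforward target overlap", {
  cfg <- network_config(scale = 0.02)
  m4 <- generate_pinwheel_map(cfg$dims$e[1], cfg$dims$e[2], seed = 1)
  m1 <- generate_pinwheel_map(cfg$dims$f[1], cfg$dims$f[2], seed = 2)
  for (ov in c(0, 0.5, 1)) {
    net <- build_network(cfg, m4, m1, variant = "random", overlap = ov,
                         seed = 3)
    left <- net$positions$f$x < 1
    t1 <- unique(net$edges$eF$post[left[net$edges$eF$pre]])
    t2 <- unique(net$edges$eF$post[!left[net$edges$eF$pre]])
    m <- round(cfg$N_e / (2 - ov))
    # target sets live in the designed index ranges
    expect_lte(max(t1), m)
    expect_gte(min(t2), cfg$N_e - m + 1)
    shared <- length(intersect(t1, t2)) / m
    if (ov == 0) expect_equal(shared, 0)       # disjoint target sets
    if (ov == 1) expect_gt(shared, 0.8)        # identical (up to coverage)
    if (ov == 0.5) {
      expect_gt(shared, 0.3)
      expect_lt(shared, 0.55)
    }
    # degrees still exact
    expect_true(all(degree_table(net, "ee", "out") == cfg$K_out[["ee"]]))
  }
  expect_error(build_network(cfg, m4, m1, variant = "random",
                             overlap = 2), "overlap")
})

test_that("connectivity serialisation round-trips the edge multiset", {
  net <- attr(fx_tiny(), "net")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity(net, tf)
  back <- read_connectivity_edges(tf)
  for (pn in names(net$edges)) {
    a <- net$edges[[pn]][order(net$edges[[pn]]$pre, net$edges[[pn]]$post), ]
    b <- back[[pn]][order(back[[pn]]$pre, back[[pn]]$post), ]
    expect_equal(a$pre, b$pre)
    expect_equal(a$post, b$post)
    expect_equal(a$long, b$long)
  }
})
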