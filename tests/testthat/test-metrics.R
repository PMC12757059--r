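test_that("normalization, current and selectivity indices are exact", {
  expect_equal(normalization_index(10, 10, 20), 1)
  expect_equal(normalization_index(15, 15, 20), 1.5)
  expect_equal(normalization_index(5, 5, 20), 0.5)
  expect_true(is.na(normalization_index(5, 5, 0)))
  expect_equal(current_norm_index(3, 3, 3), 2)
  expect_equal(current_norm_index(2, 4, 6), 1)
  expect_equal(current_norm_index(-3, -3, -4), 1.5)   # sign cancels
  expect_true(is.na(current_norm_index(1, 1, 0)))
  expect_equal(selectivity(10, 10), 0)
  expect_equal(selectivity(10, 0), 1)
  expect_equal(selectivity(30, 10), 0.5)
  expect_true(is.na(selectivity(0, 0)))
})

test_that("tuning similarity is the Pearson correlation of curves", {
  th <- seq(0, pi - pi / 18, by = pi / 18)
  f1 <- exp(cos(2 * (th - 0.5)))               # von-Mises-like
  f2 <- exp(cos(2 * (th - 0.5 - pi / 2)))      # offset by 90 degrees
  ts <- tuning_similarity(cbind(f1, f1, -f1, f2, rep(1, 18)))
  expect_equal(ts[1, 2], 1)
  expect_equal(ts[1, 3], -1)
  expect_lt(ts[1, 4], 0)                       # orthogonal preference
  expect_true(is.na(ts[1, 5]))                 # zero-variance curve
})

test_that("sliding counts and correlations behave on constructed rasters", {
  sp <- data.frame(unit = c(1, 1, 1, 2), time = c(10, 60, 260, 110))
  cnt <- sliding_counts(sp, 2, 0, 400, window = 200, step = 50)
  expect_equal(dim(cnt), c(5, 2))
  expect_equal(cnt[1, ], c(2, 1))              # [0,200): unit1 x2, unit2 x1
  expect_equal(cnt[2, ], c(1, 1))              # [50,250)
  # a unit against itself correlates at 1
  spp <- poisson_spikes(10, dt = 1, T = 60000, seed = 2)
  scc <- spike_count_correlations(list(rbind(
    spp, transform(spp, unit = 2))), 1:2, 0, 60000)
  expect_equal(scc$r[1, 2], 1)
  # independent Poisson units decorrelate
  spq <- transform(poisson_spikes(10, dt = 1, T = 60000, seed = 3),
                   unit = 2)
  scc2 <- spike_count_correlations(list(rbind(spp, spq)), 1:2, 0, 60000)
  expect_lt(abs(scc2$r[1, 2]), 0.1)
  # shared slow gain induces positive correlation (doubly stochastic)
  set.seed(4)
  gain <- rep(exp(rnorm(120, 0, 0.5)), each = 500)   # 500-ms gain epochs
  rts <- cbind(10 * gain, 10 * gain)
  spg <- poisson_spikes(rts, dt = 1, seed = 5)
  scc3 <- spike_count_correlations(list(spg), 1:2, 0, 60000)
  expect_gt(scc3$r[1, 2], 0.2)
})

test_that("rate inclusion keeps units within one population SD", {
  set.seed(1)
  rates <- cbind(rnorm(500, 10, 2), rnorm(500, 8, 2), rnorm(500, 12, 2))
  inc <- rate_inclusion(rates)
  for (k in 1:3)
    expect_true(all(abs(rates[inc, k] - mean(rates[, k])) <=
                      sd(rates[, k])))
  expect_false(all(inc))
})

test_that("NI binning is symmetric and flat under label shuffling", {
  set.seed(6)
  n <- 120
  ni <- runif(n, 1, 3)
  # correlations decaying with |dNI| by construction
  r <- outer(ni, ni, function(a, b) 0.1 - 0.03 * abs(a - b)) +
    matrix(rnorm(n * n, 0, 0.005), n)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  bb <- bin_by_normalization(r, ni)
  hm <- bb$heatmap
  expect_equal(hm, t(hm))                      # symmetric under pair swap
  expect_equal(bb$heatmap_breaks, seq(1, 3, by = 0.25))
  # monotone decrease of r with |dNI| is recovered
  cur <- bb$by_dni[!is.na(bb$by_dni$r) & bb$by_dni$n > 30, ]
  expect_lt(cor(cur$dni, cur$r), -0.9)
  # shuffled NI labels flatten the curve (slope within permutation band)
  slopes <- replicate(200, {
    nis <- sample(ni)
    bs <- bin_by_normalization(r, nis)$by_dni
    bs <- bs[!is.na(bs$r) & bs$n > 30, ]
    coef(lm(r ~ dni, bs))[[2]]
  })
  obs <- coef(lm(r ~ dni, cur))[[2]]
  expect_lt(obs, quantile(slopes, 0.025))      # real slope outside band
  expect_gt(mean(abs(obs) > abs(slopes)), 0.9)
  # empty bins reported as NA, never zero
  ni2 <- c(runif(60, 1, 1.4), runif(60, 2.6, 3))
  hm2 <- bin_by_normalization(r, ni2)$heatmap
  expect_true(anyNA(hm2))
  expect_false(any(hm2 == 0, na.rm = TRUE))
})

test_that("covariance decomposition satisfies the bilinearity identity", {
  set.seed(7)
  ns <- 400
  tr <- list(ff = matrix(abs(rnorm(ns * 4)), ns),
             re = matrix(abs(rnorm(ns * 4)), ns),
             ri = -matrix(abs(rnorm(ns * 4)), ns))
  pairs <- rbind(c(1, 2), c(3, 4), c(1, 4))
  cd <- covariance_decomposition(tr, pairs)
  for (p in 1:3) {
    E <- tr$ff + tr$re
    tot <- cov(E[, pairs[p, 1]] + tr$ri[, pairs[p, 1]],
               E[, pairs[p, 2]] + tr$ri[, pairs[p, 2]])
    expect_equal(cd$total[p], tot, tolerance = 1e-9)
    expect_equal(cd$total[p], cd$ee[p] + cd$ei[p] + cd$ie[p] + cd$ii[p],
                 tolerance = 1e-9)
  }
  # independent traces give near-zero components
  expect_lt(max(abs(c(cd$ee, cd$ei, cd$ie, cd$ii))), 4 / sqrt(ns))
  # constructed anti-correlation: I2 = -E1 gives Cov(E1, I2) = -Var(E1)
  tr2 <- tr
  E1 <- tr$ff[, 1] + tr$re[, 1]
  tr2$ri[, 2] <- -E1
  cd2 <- covariance_decomposition(tr2, cbind(1, 2))
  expect_equal(cd2$ei, -var(E1), tolerance = 1e-12)
})

test_that("contrast sensitivity summarises relative rate spread", {
  set.seed(8)
  n <- 300
  ni <- runif(n, 1, 3)
  dc <- c(0, 0.1, 0.2)
  # spread of r/r0 grows with dc, more for high-NI units
  r0 <- runif(n, 5, 15)
  rates <- sapply(dc, function(d) r0 * exp(rnorm(n, 0, d * ni)))
  rates[, 1] <- r0
  cs <- contrast_sensitivity(rates, dc, ni, ni_breaks = c(1, 2, 3))
  expect_true(all(cs$rel[, 1] == 1))
  st <- cs$sd_table
  expect_equal(st$sd[st$dc == 0], c(0, 0))
  for (b in 1:2) {
    sdb <- st$sd[st$ni_bin == b]
    expect_true(all(diff(sdb) > 0))            # increasing in dc
  }
  hi <- st$sd[st$ni_bin == 2 & st$dc > 0]
  lo <- st$sd[st$ni_bin == 1 & st$dc > 0]
  expect_true(all(hi > lo))                    # increasing in NI
  # r0 = 0 units are excluded
  rates2 <- rates; rates2[1, ] <- 0
  expect_false(contrast_sensitivity(rates2, dc, ni)$included[1])
})

test_that("empirical data conventions clean count matrices as stated", {
  set.seed(9)
  counts <- matrix(rpois(200 * 6, 10), 200, 6)
  cond <- rep(c("a", "b"), each = 100)
  counts[7, 3] <- 10 + 10 * sd(counts[cond == "a", 3])   # planted outlier
  out <- empirical_data_conventions(counts, cond)
  expect_false(out$kept_trials[7])
  expect_equal(sum(!out$kept_trials[cond == "a"][-7]), 0)
  # all-identical counts: no exclusion unless a trial deviates
  cc <- matrix(5, 40, 2)
  expect_true(all(empirical_data_conventions(cc, rep("a", 40))$kept_trials))
  cc[3, 1] <- 6
  expect_false(empirical_data_conventions(cc, rep("a", 40))$kept_trials[3])
  # responsive vs unresponsive units under the contrast t-test
  contr <- rep(c(0, 0.5), each = 100)
  resp <- cbind(c(rpois(100, 2), rpois(100, 12)),   # responsive
                rpois(200, 5))                      # unresponsive
  out2 <- empirical_data_conventions(resp, rep("c", 200), contrast = contr)
  expect_true(out2$unit_included[1])
  expect_false(out2$unit_included[2])
  # same-electrode pairs flagged
  out3 <- empirical_data_conventions(counts, cond,
                                     electrode = c(1, 1, 2, 3, 3, 3))
  expect_true(out3$same_electrode[1, 2])
  expect_false(out3$same_electrode[1, 3])
  expect_error(empirical_data_conventions(counts, cond[1:10]), "labels")
})
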