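test_that("EIF converges to the analytic subthreshold fixed point", {
  for (I0 in c(0.1, 0.2, 0.3)) {
    out <- sim_one(2000, I0)
    root <- uniroot(function(V)
      -(V + 60) / 15 + (2 / 15) * exp((V + 50) / 2) + I0,
      c(-60, -52), tol = 1e-10)$root
    expect_lt(abs(out$V - root), 0.05)
    expect_equal(length(out$spike_time), 0L)
  }
})

test_that("EIF in the small-DeltaT limit matches the LIF rate formula", {
  I0 <- 1.0                                     # V_inf = -45 > V_T
  out <- sim_one(20000, I0, DT = 1e-6)
  Vinf <- -60 + 15 * I0
  rate_th <- 1000 / (1.5 + 15 * log((Vinf + 65) / (Vinf + 50)))  # Hz
  rate <- length(out$spike_time) / 20
  expect_equal(rate, rate_th, tolerance = 0.02)
})

test_that("resting neuron stays at the leak reversal", {
  out <- sim_one(1000, 0, V0 = -60)
  expect_equal(length(out$spike_time), 0L)
  expect_lt(abs(out$V - (-60)), 0.02 + 2 / 15)  # Delta_T leak term bound
})

test_that("numerical blow-up is reported with context", {
  expect_error(sim_one(1000, -20), "blow-up")
})

test_that("synaptic kernel has unit integral and the analytic peak", {
  dt <- 0.005
  tr <- kernel_filter(0, tau_r = 1, tau_d = 5, dt = dt, T = 250)
  expect_equal(sum(tr) * dt, 1, tolerance = 1e-6)
  t_peak <- (which.max(tr) - 1) * dt
  expect_equal(t_peak, 1 * 5 * log(5) / 4, tolerance = 0.01)  # 2.012 ms
  # slow feedforward component
  trs <- kernel_filter(0, tau_r = 2, tau_d = 100, dt = dt, T = 2000)
  expect_equal(sum(trs) * dt, 1, tolerance = 1e-6)
  # empty spike train and degenerate kernel
  expect_equal(kernel_filter(numeric(0), 1, 5, 0.1, 10), rep(0, 100))
  expect_error(kernel_filter(0, 2, 2, 0.1, 10), "degenerate")
})

test_that("network simulation is deterministic and respects refractoriness", {
  cnet <- fx_tiny()
  conds <- normalization_conditions(cnet$v1)
  r1 <- simulate_network(cnet, conds$both, T = 1500, seed = 9)
  r2 <- simulate_network(cnet, conds$both, T = 1500, seed = 9)
  expect_identical(r1$spikes, r2$spikes)        # bit-identical rasters
  expect_identical(r1$cur_mean, r2$cur_mean)
  r3 <- simulate_network(cnet, conds$both, T = 1500, seed = 10)
  expect_false(identical(r1$spikes, r3$spikes))
  # no ISI shorter than tau_ref (E: 1.5 ms, I: 0.5 ms)
  n_e <- cnet$config$N_e
  for (pp in list(c(1, n_e, 1.5), c(n_e + 1, n_e + cnet$config$N_i, 0.5))) {
    sp <- r1$spikes[r1$spikes$unit >= pp[1] & r1$spikes$unit <= pp[2], ]
    isi <- unlist(tapply(sp$time, sp$unit, diff))
    if (length(isi)) expect_gte(min(isi), pp[3])
  }
})

test_that("desk-scale network sits in a stable asynchronous-irregular regime", {
  ex <- fx_norm()
  cnet <- fx_model()
  n_e <- cnet$config$N_e
  sp <- ex$spikes$both[[1]]
  # rate stability: population rate drift between epoch halves < 20%
  mid <- 1000 + (8000 - 1000) / 2
  r_a <- sum(sp$time >= 1000 & sp$time < mid)
  r_b <- sum(sp$time >= mid)
  expect_lt(abs(r_b - r_a) / r_a, 0.2)
  # ISI CV of E neurons near 1 (Poisson-like irregularity)
  spe <- sp[sp$unit <= n_e, ]
  isis <- tapply(spe$time, spe$unit, diff)
  isis <- isis[!vapply(isis, is.null, TRUE)]
  cvs <- vapply(isis[lengths(isis) >= 20], function(x) sd(x) / mean(x),
                numeric(1))
  expect_gt(mean(cvs), 0.8)
  expect_lt(mean(cvs), 1.3)
  # mean pairwise spike-count correlation small
  inc <- which(ex$included)
  set.seed(1)
  units <- sample(inc, min(300, length(inc)))
  scc <- spike_count_correlations(ex$spikes$both, units, 1000, 8000)
  rv <- scc$r[upper.tri(scc$r)]
  expect_lt(abs(mean(rv, na.rm = TRUE)), 0.05)
  # current traces: cadence, sign structure
  tr <- ex$traces$both[[1]]
  expect_equal(unique(diff(tr$times)), 10)
  expect_true(all(tr$ri <= 0))
  expect_true(all(tr$ff >= 0))
  expect_true(all(tr$re >= 0))
})

test_that("excitation and inhibition individually dominate the net current", {
  # balance improves with size; test at the largest desk-affordable scale
  cnet <- build_model(scale = 0.5, seed = 3)
  res <- simulate_network(cnet, normalization_conditions(cnet$v1)$both,
                          T = 2000, seed = 5, burnin = 500)
  cm <- colMeans(res$cur_mean[res$pop == "e", ])
  net_cur <- abs(sum(cm))
  expect_lt(net_cur, 0.3 * (cm[["ff"]] + cm[["re"]]))   # vs excitation
  expect_lt(net_cur, 0.3 * abs(cm[["ri"]]))             # vs inhibition
})
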