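#' Compile a connectivity graph for simulation
#'
#' Converts the per-projection edge tables into compressed (CSR) adjacency
#' keyed by presynaptic neuron, with the \eqn{J/\sqrt{N}} weight applied,
#' and aligns the V1 front end's population ordering with the feedforward
#' edges. Compiling once and reusing the result across simulations avoids
#' repeating this work.
#'
#' @param net a `connectivity` from [build_network()].
#' @param v1 a calibrated [v1_population()] built from a map on the same V1
#'   grid as `net`.
#' @return a `compiled_network`.
#' @export
compile_network <- function(net, v1) {
  stopifnot(inherits(net, "connectivity"), inherits(v1, "v1_population"))
  cfg <- net$config
  n_e <- cfg$N_e; n_i <- cfg$N_i; n_f <- cfg$N_f
  if (nrow(v1$F1) + nrow(v1$F2) != n_f)
    stop("V1 population size does not match the network's V1 grid")
  if (is.na(v1$gain)) stop("V1 population is not calibrated")
  sqn <- sqrt(cfg$N)

  # V1 grid index -> front-end source index (population 1 first)
  left <- net$positions$f$x < 1
  f_map <- integer(n_f)
  f_map[left] <- seq_len(sum(left))
  f_map[!left] <- sum(left) + seq_len(sum(!left))

  csr <- function(pre, post, w, n_src) {
    o <- order(pre)
    ptr <- c(0L, cumsum(tabulate(pre, nbins = n_src)))
    list(ptr = ptr, tgt = post[o] - 1L, w = w[o])
  }
  e_ed <- rbind(
    data.frame(pre = net$edges$ee$pre, post = net$edges$ee$post,
               w = cfg$J[["ee"]] / sqn),
    data.frame(pre = net$edges$ie$pre, post = n_e + net$edges$ie$post,
               w = cfg$J[["ie"]] / sqn))
  i_ed <- rbind(
    data.frame(pre = net$edges$ei$pre, post = net$edges$ei$post,
               w = cfg$J[["ei"]] / sqn),
    data.frame(pre = net$edges$ii$pre, post = n_e + net$edges$ii$post,
               w = cfg$J[["ii"]] / sqn))
  f_ed <- rbind(
    data.frame(pre = f_map[net$edges$eF$pre], post = net$edges$eF$post,
               w = cfg$J[["eF"]] / sqn),
    data.frame(pre = f_map[net$edges$iF$pre], post = n_e + net$edges$iF$post,
               w = cfg$J[["iF"]] / sqn))
  structure(list(
    e = csr(e_ed$pre, e_ed$post, e_ed$w, n_e),
    i = csr(i_ed$pre, i_ed$post, i_ed$w, n_i),
    f = csr(f_ed$pre, f_ed$post, f_ed$w, n_f),
    config = cfg, variant = net$variant, v1 = v1,
    theta = net$theta, positions = net$positions,
    net_seed = net$seed), class = "compiled_network")
}

#' @export
print.compiled_network <- function(x, ...) {
  cat(sprintf("compiled_network (%s): N_e = %d, N_i = %d, N_f = %d\n",
              x$variant, x$config$N_e, x$config$N_i, x$config$N_f))
  invisible(x)
}

#' Stimulus protocols
#'
#' A protocol describes what each V1 population sees over the course of one
#' simulation, as a piecewise schedule. `stim_static` presents fixed images
#' (or nothing, i.e. pixel noise only) for the whole run; `stim_rates`
#' clamps the V1 rates to given vectors (used for natural-image responses,
#' where the front end is rate- rather than pixel-driven); `stim_fisher`
#' builds the ON/OFF interleaving used for Fisher-information estimation.
#'
#' @param image1,image2 `gabor_image` pixel vectors (or NULL for no image)
#'   shown to V1 population 1 and 2 respectively.
#' @return a `stim_protocol`.
#' @export
stim_static <- function(image1 = NULL, image2 = NULL) {
  structure(list(type = "static", image1 = image1, image2 = image2),
            class = "stim_protocol")
}

#' @rdname stim_static
#' @param rates1,rates2 rate vectors (Hz), one entry per V1 neuron of each
#'   population.
#' @export
stim_rates <- function(rates1, rates2) {
  structure(list(type = "rates", rates1 = rates1, rates2 = rates2),
            class = "stim_protocol")
}

#' @rdname stim_static
#' @param kind `"contrast"` or `"orientation"`: which parameter of image 2
#'   is perturbed.
#' @param base_contrast contrast `c` of both images (default 0.5).
#' @param delta parameter offset `dx`: ON intervals use `x + delta/2` or
#'   `x - delta/2` at random (defaults: 0.01 for contrast, 0.02 rad for
#'   orientation).
#' @param theta1 orientation of image 1 (image 2 is orthogonal, at
#'   `theta1 + pi/2`).
#' @param T_on,T_off ON/OFF interval durations, ms.
#' @param T total simulated time, ms.
#' @param seed seed for the per-interval class randomisation.
#' @export
stim_fisher <- function(kind = c("contrast", "orientation"),
                        base_contrast = 0.5, delta = NULL, theta1 = 0,
                        T_on = 200, T_off = 300, T = 20000, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(delta)) delta <- if (kind == "contrast") 0.01 else 0.02
  if (delta <= 0) stop("`delta` must be positive")
  n_cyc <- floor(T / (T_on + T_off))
  old <- .Random.seed_save()
  set.seed(split_seed(seed, "fisher-classes"))
  classes <- sample(rep(1:2, length.out = n_cyc))
  .Random.seed_restore(old)
  structure(list(type = "fisher", kind = kind, base_contrast = base_contrast,
                 delta = delta, theta1 = theta1, T_on = T_on, T_off = T_off,
                 n_cycles = n_cyc, classes = classes),
            class = "stim_protocol")
}

# build the C++ schedule (segments + base-response matrices) for a protocol
.build_schedule <- function(protocol, v1, T) {
  n1 <- nrow(v1$F1); n2 <- nrow(v1$F2)
  base_of <- function(Fm, image) {
    if (is.null(image)) numeric(nrow(Fm))
    else {
      m <- unclass(image)
      if (length(m) != ncol(Fm)) stop("image patch shape does not match filters")
      as.numeric(Fm %*% m)
    }
  }
  if (protocol$type == "static") {
    list(bases1 = cbind(base_of(v1$F1, protocol$image1)),
         bases2 = cbind(base_of(v1$F2, protocol$image2)),
         modes = matrix(c(0L, 0L, 0L, 0L), 1, 4),
         tend = T, rate1 = 0, rate2 = 0)
  } else if (protocol$type == "rates") {
    stopifnot(length(protocol$rates1) == n1, length(protocol$rates2) == n2)
    list(bases1 = cbind(protocol$rates1), bases2 = cbind(protocol$rates2),
         modes = matrix(c(2L, 0L, 2L, 0L), 1, 4),
         tend = T, rate1 = 0, rate2 = 0)
  } else if (protocol$type == "fisher") {
    cc <- protocol$base_contrast
    th1 <- protocol$theta1
    th2 <- th1 + pi / 2
    g2 <- function(contrast, theta)
      gabor_image(contrast, center = v1$rf_center[[2]], theta = theta,
                  sigma = v1$sigma, lambda_wave = v1$lambda_wave,
                  npix = v1$npix, extent = v1$extent)
    if (protocol$kind == "contrast") {
      imgs2 <- list(g2(cc + protocol$delta / 2, th2),
                    g2(cc - protocol$delta / 2, th2))
    } else {
      imgs2 <- list(g2(cc, th2 + protocol$delta / 2),
                    g2(cc, th2 - protocol$delta / 2))
    }
    img1 <- gabor_image(cc, center = v1$rf_center[[1]], theta = th1,
                        sigma = v1$sigma, lambda_wave = v1$lambda_wave,
                        npix = v1$npix, extent = v1$extent)
    bases1 <- cbind(base_of(v1$F1, img1))
    bases2 <- cbind(base_of(v1$F2, imgs2[[1]]), base_of(v1$F2, imgs2[[2]]))
    cyc <- protocol$T_on + protocol$T_off
    n_cyc <- protocol$n_cycles
    tend <- modes <- NULL
    seg_t <- seg_m <- list()
    for (k in seq_len(n_cyc)) {
      seg_t[[2 * k - 1]] <- (k - 1) * cyc + protocol$T_on       # ON end
      seg_m[[2 * k - 1]] <- c(0L, 0L, 0L, protocol$classes[k] - 1L)
      seg_t[[2 * k]] <- k * cyc                                  # OFF end
      seg_m[[2 * k]] <- c(0L, 0L, 1L, 0L)
    }
    if (n_cyc * cyc < T) {        # trailing partial segment: OFF
      seg_t[[2 * n_cyc + 1]] <- T
      seg_m[[2 * n_cyc + 1]] <- c(0L, 0L, 1L, 0L)
    }
    nseg <- length(seg_t)
    list(bases1 = bases1, bases2 = bases2,
         modes = matrix(unlist(seg_m), nseg, 4, byrow = TRUE),
         tend = unlist(seg_t), rate1 = rep(0, nseg),
         rate2 = rep(5, nseg))     # OFF: independent Poisson at 5 Hz
  } else stop("unknown protocol type")
}

#' Simulate the V4/MT network
#'
#' Forward-Euler integration (time step `dt` = 0.05 ms) of the EIF network
#' with double-exponential synapses, driven by Poisson V1 spikes whose
#' rates follow the stimulus protocol. Records the spike raster, per-neuron
#' spike counts after burn-in, time-averaged per-type synaptic currents
#' (feedforward E, recurrent E, recurrent I, in mV/ms), and optionally full
#' current traces for selected neurons at a 10-ms cadence.
#'
#' @param cnet a [compile_network()] result (or a `connectivity`, compiled
#'   on the fly, in which case `v1` must be given).
#' @param protocol a `stim_protocol`.
#' @param T duration, ms.
#' @param seed integer seed for all in-simulation randomness (initial
#'   voltages, OU noise, Poisson spikes).
#' @param dt integration step, ms.
#' @param rate_dt cadence at which V1 rates and OU noise are refreshed, ms.
#' @param rec_dt current-recording cadence, ms.
#' @param burnin initial transient excluded from counts/current averages, ms.
#' @param trace_units global neuron indices (1-based; E neurons first) whose
#'   current traces are kept.
#' @param record_v1 keep the V1 spike raster too.
#' @param v1 V1 population when `cnet` is not compiled.
#' @param I_ext constant external drive `c(E, I)` in mV/ms (testing aid).
#' @param V0 optional initial voltages (vector of length `N_e + N_i`).
#' @return a `simulation_result` list; see Details in the vignette.
#' @export
simulate_network <- function(cnet, protocol, T, seed = 1L, dt = 0.05,
                             rate_dt = 1, rec_dt = 10, burnin = 1000,
                             trace_units = integer(0), record_v1 = FALSE,
                             v1 = NULL, I_ext = c(0, 0), V0 = numeric(0)) {
  if (inherits(cnet, "connectivity")) {
    if (is.null(v1)) stop("pass a compiled network or supply `v1`")
    cnet <- compile_network(cnet, v1)
  }
  stopifnot(inherits(cnet, "compiled_network"),
            inherits(protocol, "stim_protocol"))
  if (rec_dt %% dt > 1e-9 && abs(rec_dt %% dt - dt) > 1e-9)
    stop("`dt` must divide `rec_dt`")
  cfg <- cnet$config
  v1p <- cnet$v1
  sch <- .build_schedule(protocol, v1p, T)
  epar <- c(15, -60, -50, -10, 2, -65, 1.5)
  ipar <- c(10, -60, -50, -10, 0.5, -65, 0.5)
  res <- sim_eif_network(
    cfg$N_e, cfg$N_i, epar, ipar,
    cnet$e$ptr, cnet$e$tgt, cnet$e$w,
    cnet$i$ptr, cnet$i$tgt, cnet$i$w,
    cnet$f$ptr, cnet$f$tgt, cnet$f$w,
    c(1, 5, 1, 8, 2, 100, 0.2, 0.8),
    v1p$F1, v1p$F2, sch$bases1, sch$bases2,
    sch$modes, sch$tend, sch$rate1, sch$rate2,
    v1p$gain, v1p$noise_scale, v1p$tau_n, v1p$sigma_n,
    T, dt, rate_dt, rec_dt, burnin,
    as.integer(trace_units) - 1L, record_v1,
    I_ext[1], I_ext[2], V0,
    split_seed(seed, "simulate"))
  n_e <- cfg$N_e
  dur_s <- (T - burnin) / 1000
  traces <- NULL
  if (length(trace_units)) {
    idx <- function(k) seq(k, by = 3, length.out = length(trace_units))
    traces <- list(ff = res$traces[, idx(1), drop = FALSE],
                   re = res$traces[, idx(2), drop = FALSE],
                   ri = res$traces[, idx(3), drop = FALSE],
                   times = res$trace_times, units = trace_units)
  }
  structure(list(
    spikes = data.frame(unit = res$spike_unit + 1L, time = res$spike_time),
    counts = res$counts,
    rates = res$counts / dur_s,
    pop = rep(c("e", "i"), c(n_e, cfg$N_i)),
    v1_counts = res$v1_counts,
    v1_rates = res$v1_counts / dur_s,
    v1_spikes = if (record_v1)
      data.frame(unit = res$v1_unit + 1L, time = res$v1_time) else NULL,
    cur_mean = `colnames<-`(res$cur_mean, c("ff", "re", "ri")),
    traces = traces,
    T = T, dt = dt, burnin = burnin, rec_dt = rec_dt,
    seed = as.integer(seed), variant = cnet$variant,
    protocol = protocol), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "simulation_result: T = %g ms (burn-in %g), %d spikes, mean E rate %.2f Hz\n",
    x$T, x$burnin, nrow(x$spikes), mean(x$rates[x$pop == "e"])))
  invisible(x)
}

#' The three normalization conditions
#'
#' Image 1 alone, image 2 alone, and both together. Image 1 is a Gabor of
#' orientation `theta1` at location 1; image 2 is the orthogonal Gabor
#' (`theta1 + pi/2`) at location 2. With `plaid = TRUE` the protocol instead
#' presents each stimulus superimposed at both locations ("stim1" = Gabor at
#' `theta1` shown at both locations, "both" = plaid of the two orientations
#' at both locations), as used for the plaid-rotation analysis.
#'
#' @param v1 a [v1_population()] (for patch geometry).
#' @param contrast stimulus contrast (default 0.5).
#' @param theta1 orientation of stimulus 1, radians.
#' @param plaid logical, superimposed presentation.
#' @return named list of three `stim_protocol`s: `stim1`, `stim2`, `both`.
#' @export
normalization_conditions <- function(v1, contrast = 0.5, theta1 = 0,
                                     plaid = FALSE) {
  th2 <- theta1 + pi / 2
  g <- function(k, theta, contrast_ = contrast)
    gabor_image(contrast_, center = v1$rf_center[[k]], theta = theta,
                sigma = v1$sigma, lambda_wave = v1$lambda_wave,
                npix = v1$npix, extent = v1$extent)
  pl <- function(k)
    plaid_image(contrast, contrast, center = v1$rf_center[[k]],
                theta = theta1, sigma = v1$sigma,
                lambda_wave = v1$lambda_wave, npix = v1$npix,
                extent = v1$extent)
  if (!plaid) {
    list(stim1 = stim_static(image1 = g(1, theta1)),
         stim2 = stim_static(image2 = g(2, th2)),
         both = stim_static(image1 = g(1, theta1), image2 = g(2, th2)))
  } else {
    list(stim1 = stim_static(image1 = g(1, theta1), image2 = g(2, theta1)),
         stim2 = stim_static(image1 = g(1, th2), image2 = g(2, th2)),
         both = stim_static(image1 = pl(1), image2 = pl(2)))
  }
}

#' Run a set of stimulus conditions, pooling repeated simulations
#'
#' Simulates each condition `n_sims` times with distinct seeds, pooling
#' spike counts and time-averaged currents across simulations. Used by the
#' normalization, contrast-sweep and plaid experiments.
#'
#' @param cnet a `compiled_network`.
#' @param protocols named list of `stim_protocol`s.
#' @param T duration per simulation, ms.
#' @param n_sims simulations per condition.
#' @param seed root seed; each (condition, sim) gets a split seed.
#' @param trace_units,record_v1,burnin passed to [simulate_network()].
#' @param keep_spikes keep the spike rasters (one per condition and sim).
#' @return list with `rates` (units x conditions), `cur_mean` (list of
#'   units x 3 matrices per condition), `spikes` (nested list or NULL),
#'   `pop`, `T`, `burnin`, `n_sims`.
#' @export
run_condition_set <- function(cnet, protocols, T = 10000, n_sims = 2,
                              seed = 1L, trace_units = integer(0),
                              record_v1 = FALSE, burnin = 1000,
                              keep_spikes = FALSE) {
  stopifnot(inherits(cnet, "compiled_network"))
  n <- cnet$config$N_e + cnet$config$N_i
  rates <- matrix(0, n, length(protocols),
                  dimnames = list(NULL, names(protocols)))
  cur <- lapply(protocols, function(p) matrix(0, n, 3,
    dimnames = list(NULL, c("ff", "re", "ri"))))
  traces <- spikes <- stats::setNames(vector("list", length(protocols)),
                                      names(protocols))
  pop <- NULL
  for (ci in seq_along(protocols)) {
    cond <- names(protocols)[ci]
    tr_list <- sp_list <- vector("list", n_sims)
    for (s in seq_len(n_sims)) {
      r <- simulate_network(cnet, protocols[[ci]], T = T,
                            seed = split_seed(seed, paste(cond, s)),
                            trace_units = trace_units,
                            record_v1 = record_v1, burnin = burnin)
      rates[, ci] <- rates[, ci] + r$rates / n_sims
      cur[[ci]] <- cur[[ci]] + r$cur_mean / n_sims
      if (keep_spikes) sp_list[[s]] <- r$spikes
      if (length(trace_units)) tr_list[[s]] <- r$traces
      pop <- r$pop
    }
    if (keep_spikes) spikes[[cond]] <- sp_list
    if (length(trace_units)) traces[[cond]] <- tr_list
  }
  list(rates = rates, cur_mean = cur,
       spikes = if (keep_spikes) spikes else NULL,
       traces = if (length(trace_units)) traces else NULL,
       pop = pop, T = T, burnin = burnin, n_sims = n_sims,
       conditions = names(protocols))
}
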