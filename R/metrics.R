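#' Normalization index
#'
#' `(FR_stim1 + FR_stim2) / FR_both`: the sum of a neuron's firing rates to
#' each stimulus alone divided by its rate when both are shown together.
#' 1 means linear summation, > 1 sublinear (normalizing), < 1 facilitation.
#' Units with `FR_both <= 0` are undefined and return `NA`.
#'
#' @param fr1,fr2,frboth firing rates (Hz), vectorised.
#' @return numeric vector of normalization indices.
#' @export
normalization_index <- function(fr1, fr2, frboth) {
  out <- (fr1 + fr2) / frboth
  out[!(frboth > 0)] <- NA_real_
  out
}

#' Current normalization index
#'
#' Same ratio applied to time-averaged signed synaptic currents of one type
#' (feedforward E, recurrent E or recurrent I). For inhibition the ratio of
#' negative quantities is positive, as conventionally reported. Units with
#' `Iboth == 0` return `NA`.
#'
#' @param i1,i2,iboth time-averaged currents in the three conditions.
#' @export
current_norm_index <- function(i1, i2, iboth) {
  out <- (i1 + i2) / iboth
  out[iboth == 0] <- NA_real_
  out
}

#' Stimulus selectivity
#'
#' `(FR_stim1 - FR_stim2) / (FR_stim1 + FR_stim2)`, in `[-1, 1]`; 0 means no
#' preference. Units with `FR_stim1 + FR_stim2 <= 0` return `NA`.
#'
#' @param fr1,fr2 firing rates (Hz).
#' @export
selectivity <- function(fr1, fr2) {
  s <- fr1 + fr2
  out <- (fr1 - fr2) / s
  out[!(s > 0)] <- NA_real_
  out
}

#' Tuning similarity
#'
#' Pearson correlation between two neurons' orientation tuning curves
#' (sampled on a common orientation grid, e.g. 0 to 170 degrees in 10-degree
#' steps with the image at location 1). Pairs involving a zero-variance
#' curve return `NA`.
#'
#' @param curves matrix, orientations x units.
#' @return units x units correlation matrix.
#' @export
tuning_similarity <- function(curves) {
  v <- apply(curves, 2, stats::var)
  out <- suppressWarnings(cor(curves))
  out[v == 0, ] <- NA_real_
  out[, v == 0] <- NA_real_
  out
}

#' Rate-based unit inclusion filter
#'
#' Keeps units whose mean rate lies within one population SD of the
#' population mean in all three stimulus conditions.
#'
#' @param rates units x 3 matrix of rates (stim1, stim2, both).
#' @param n_sd inclusion width in population SDs (default 1).
#' @return logical vector.
#' @export
rate_inclusion <- function(rates, n_sd = 1) {
  ok <- rep(TRUE, nrow(rates))
  for (k in seq_len(ncol(rates))) {
    mu <- mean(rates[, k]); s <- sd(rates[, k])
    ok <- ok & abs(rates[, k] - mu) <= n_sd * s
  }
  ok
}

#' Sliding-window spike counts
#'
#' Counts in `window`-ms windows stepped by `step` ms across
#' `[t_start, t_end)`, per unit.
#'
#' @param spikes data.frame with `unit`, `time` (ms).
#' @param n_units number of units (columns of the output).
#' @param t_start,t_end analysis epoch, ms.
#' @param window,step window length and step, ms.
#' @return windows x units count matrix.
#' @export
sliding_counts <- function(spikes, n_units, t_start, t_end, window = 200,
                           step = 50) {
  stopifnot(window %% step == 0)
  nb <- floor((t_end - t_start) / step)
  keep <- spikes$time >= t_start & spikes$time < t_start + nb * step
  u <- spikes$unit[keep]
  b <- floor((spikes$time[keep] - t_start) / step)    # 0-based step bin
  fine <- matrix(0L, nb, n_units)
  idx <- b + 1L + nb * (u - 1L)
  tab <- tabulate(idx, nbins = nb * n_units)
  fine[] <- tab
  k <- window %/% step
  nw <- nb - k + 1L
  if (nw < 1) stop("epoch shorter than one window")
  cs <- rbind(0, apply(fine, 2, cumsum))
  cs[(k + 1):(nw + k), , drop = FALSE] - cs[1:nw, , drop = FALSE]
}

#' Spike-count correlations
#'
#' Pearson correlations of sliding-window spike counts (200-ms windows,
#' 50-ms steps) between pairs of units, pooled over all simulations of a
#' condition. Windows are overlapping and autocorrelated by construction;
#' no decorrelation correction is applied, matching the standard analysis.
#'
#' @param spike_list list of spike data.frames (one per simulation).
#' @param units unit indices to include (columns of the result).
#' @param t_start,t_end analysis epoch within each simulation, ms.
#' @param window,step window geometry, ms.
#' @return list: `r` (units x units Pearson matrix, `NA` where a unit had
#'   zero count variance), `counts` (pooled windows x units matrix).
#' @export
spike_count_correlations <- function(spike_list, units, t_start, t_end,
                                     window = 200, step = 50) {
  n_units_all <- max(vapply(spike_list, function(s)
    if (nrow(s)) max(s$unit) else 0L, numeric(1)), max(units))
  mats <- lapply(spike_list, function(sp)
    sliding_counts(sp, n_units_all, t_start, t_end, window, step)[, units,
                                                                  drop = FALSE])
  counts <- do.call(rbind, mats)
  v <- apply(counts, 2, stats::var)
  r <- suppressWarnings(cor(counts))
  r[v == 0, ] <- NA_real_
  r[, v == 0] <- NA_real_
  list(r = r, counts = counts)
}

#' Bin pairwise correlations by normalization index
#'
#' Produces the standard summaries of how spike-count correlations depend
#' on the pair's normalization indices: (i) a 2-D mean-r map over (NI1,
#' NI2) bins; (ii) r versus |dNI| for pairs at fixed mean NI; (iii) r
#' versus mean NI for similar-NI pairs; (iv) similar- versus distinct-NI
#' mean r across tuning-similarity bins (when `tuning` is supplied).
#'
#' @param r units x units correlation matrix (symmetric; diagonal ignored).
#' @param ni normalization index per unit (same order as `r` columns).
#' @param breaks NI bin edges for the heatmap (default width 0.25 over
#'   `[1, 3]`).
#' @param mean_target,mean_halfwidth mean-NI band for the |dNI| curve
#'   (default 1.5 +- 0.25).
#' @param dni_max similarity threshold |dNI| for "similar" pairs (0.5).
#' @param tuning optional units x units tuning-similarity matrix.
#' @param tuning_breaks bin edges for tuning similarity.
#' @return list of data.frames: `heatmap`, `by_dni`, `by_meanni`,
#'   `by_tuning`. Empty bins are reported as `NA`, never zero-filled.
#' @export
bin_by_normalization <- function(r, ni, breaks = seq(1, 3, by = 0.25),
                                 mean_target = 1.5, mean_halfwidth = 0.25,
                                 dni_max = 0.5, tuning = NULL,
                                 tuning_breaks = seq(-1, 1, by = 0.5)) {
  n <- length(ni)
  stopifnot(nrow(r) == n)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]
  ni1 <- ni[ut[, 1]]; ni2 <- ni[ut[, 2]]
  ok <- !is.na(rv) & !is.na(ni1) & !is.na(ni2)
  ut <- ut[ok, , drop = FALSE]; rv <- rv[ok]
  ni1 <- ni1[ok]; ni2 <- ni2[ok]
  lo <- pmin(ni1, ni2); hi <- pmax(ni1, ni2)
  nb <- length(breaks) - 1
  b1 <- cut(lo, breaks, labels = FALSE, include.lowest = TRUE)
  b2 <- cut(hi, breaks, labels = FALSE, include.lowest = TRUE)
  hm <- matrix(NA_real_, nb, nb)
  inb <- !is.na(b1) & !is.na(b2)
  if (any(inb)) {
    agg <- tapply(rv[inb], list(b1[inb], b2[inb]), mean)
    hm[cbind(as.integer(rownames(agg)[row(agg)]),
             as.integer(colnames(agg)[col(agg)]))] <- agg
    hm[lower.tri(hm)] <- t(hm)[lower.tri(hm)]   # symmetric under pair swap
  }
  mid <- (head(breaks, -1) + tail(breaks, -1)) / 2
  mean_ni <- (ni1 + ni2) / 2
  dni <- abs(ni1 - ni2)
  # (ii) r vs |dNI| at fixed mean NI
  sel <- abs(mean_ni - mean_target) <= mean_halfwidth
  dbr <- seq(0, max(c(dni[sel], 1)) + 0.25, by = 0.25)
  db <- cut(dni[sel], dbr, labels = FALSE, include.lowest = TRUE)
  by_dni <- data.frame(
    dni = (head(dbr, -1) + tail(dbr, -1)) / 2,
    r = as.numeric(tapply(rv[sel], factor(db, seq_len(length(dbr) - 1)),
                          mean)),
    n = as.numeric(table(factor(db, seq_len(length(dbr) - 1)))))
  # (iii) r vs mean NI for similar pairs
  sel2 <- dni < dni_max
  mb <- cut(mean_ni[sel2], breaks, labels = FALSE, include.lowest = TRUE)
  by_meanni <- data.frame(
    mean_ni = mid,
    r = as.numeric(tapply(rv[sel2], factor(mb, seq_len(nb)), mean)),
    n = as.numeric(table(factor(mb, seq_len(nb)))))
  # (iv) similar vs distinct across tuning-similarity bins
  by_tuning <- NULL
  if (!is.null(tuning)) {
    tv <- tuning[cbind(ut[, 1], ut[, 2])]
    okt <- !is.na(tv)
    tb <- cut(tv[okt], tuning_breaks, labels = FALSE, include.lowest = TRUE)
    grp <- ifelse(dni[okt] < dni_max, "similar", "distinct")
    ntb <- length(tuning_breaks) - 1
    agg <- tapply(rv[okt], list(factor(tb, seq_len(ntb)), grp), mean)
    by_tuning <- data.frame(
      tuning = (head(tuning_breaks, -1) + tail(tuning_breaks, -1)) / 2,
      similar = agg[, "similar"],
      distinct = agg[, "distinct"])
  }
  list(heatmap = hm, heatmap_breaks = breaks, by_dni = by_dni,
       by_meanni = by_meanni, by_tuning = by_tuning)
}

#' Current covariance decomposition for neuron pairs
#'
#' Decomposes the covariance between two neurons' total synaptic currents
#' into the four excitatory/inhibitory components,
#' `Cov(Total1, Total2) = Cov(E1,E2) + Cov(E1,I2) + Cov(I1,E2) + Cov(I1,I2)`,
#' where E combines feedforward and recurrent excitation. Current traces
#' are the 10-ms-cadence recordings from [simulate_network()].
#'
#' @param traces a `$traces` element of a simulation result (matrices
#'   `ff`, `re`, `ri` of size samples x units) or a list of such elements
#'   (trials pooled by averaging covariances across list entries).
#' @param pairs 2-column matrix of unit positions (columns of the trace
#'   matrices) to decompose.
#' @return data.frame with columns `i`, `j`, `ee`, `ei`, `ie`, `ii`,
#'   `total` per pair.
#' @export
covariance_decomposition <- function(traces, pairs) {
  if (!is.null(traces$ff)) traces <- list(traces)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  acc <- matrix(0, nrow(pairs), 5)
  for (tr in traces) {
    E <- tr$ff + tr$re
    I <- tr$ri
    if (nrow(E) < 2) stop("trace too short for covariance")
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      cee <- stats::cov(E[, i], E[, j])
      cei <- stats::cov(E[, i], I[, j])
      cie <- stats::cov(I[, i], E[, j])
      cii <- stats::cov(I[, i], I[, j])
      acc[p, ] <- acc[p, ] + c(cee, cei, cie, cii, cee + cei + cie + cii)
    }
  }
  acc <- acc / length(traces)
  data.frame(i = pairs[, 1], j = pairs[, 2],
             ee = acc[, 1], ei = acc[, 2], ie = acc[, 3], ii = acc[, 4],
             total = acc[, 5])
}

#' Contrast-sensitivity analysis
#'
#' For a sweep of contrast differences (`c1 = 0.5 + dc`, `c2 = 0.5 - dc`),
#' computes each unit's relative rate change `r/r0` (rate divided by its
#' rate at `dc = 0`) and the SD of the `r/r0` distribution per (dc, NI
#' bin). Units with `r0 <= 0` are excluded.
#'
#' @param rates units x conditions matrix of rates; one column per `dc`.
#' @param dc contrast offsets for the columns; must include 0.
#' @param ni normalization index per unit.
#' @param ni_breaks NI bin edges.
#' @return list: `rel` (units x dc matrix of r/r0), `sd_table`
#'   (data.frame dc x NI bin with the SD of r/r0), `included`.
#' @export
contrast_sensitivity <- function(rates, dc, ni,
                                 ni_breaks = c(1, 1.5, 2, 3)) {
  i0 <- which(dc == 0)
  if (length(i0) != 1) stop("`dc` must contain 0 exactly once")
  r0 <- rates[, i0]
  inc <- r0 > 0 & !is.na(ni)
  rel <- rates[inc, , drop = FALSE] / r0[inc]
  nib <- cut(ni[inc], ni_breaks, labels = FALSE, include.lowest = TRUE)
  nb <- length(ni_breaks) - 1
  out <- expand.grid(dc = dc, ni_bin = seq_len(nb))
  out$sd <- mapply(function(d, b) {
    v <- rel[which(nib == b), which(dc == d)]
    if (length(v) >= 2) sd(v) else NA_real_
  }, out$dc, out$ni_bin)
  out$ni_lo <- ni_breaks[out$ni_bin]
  out$ni_hi <- ni_breaks[out$ni_bin + 1]
  list(rel = rel, sd_table = out, included = inc)
}

#' Data-analysis conventions for recorded count matrices
#'
#' Generic implementation of the conventions used for trial x unit spike
#' count matrices from electrophysiology: (i) per condition, drop trials in
#' which any unit's count is more than 3 SDs from its mean (units with zero
#' SD exclude any deviating trial); (ii) include units whose response to
#' 0%-contrast stimuli differs from the mean response to >= 50%-contrast
#' stimuli (t-test, p < 0.01); (iii) flag same-electrode pairs for
#' exclusion from correlation analyses.
#'
#' @param counts trials x units matrix.
#' @param condition condition label per trial.
#' @param contrast numeric max-contrast per trial (for the unit inclusion
#'   test; 0 rows vs rows with contrast >= 0.5). NULL skips that test.
#' @param electrode optional electrode id per unit.
#' @param sd_limit trial outlier threshold in SDs.
#' @param p_limit unit inclusion p threshold.
#' @return list: `counts` (cleaned matrix), `kept_trials`, `unit_included`,
#'   `same_electrode` (units x units logical or NULL).
#' @export
empirical_data_conventions <- function(counts, condition, contrast = NULL,
                                       electrode = NULL, sd_limit = 3,
                                       p_limit = 0.01) {
  if (length(condition) != nrow(counts)) stop("missing trial labels")
  keep <- rep(TRUE, nrow(counts))
  for (cond in unique(condition)) {
    idx <- which(condition == cond)
    sub <- counts[idx, , drop = FALSE]
    mu <- colMeans(sub)
    s <- apply(sub, 2, sd)
    dev <- abs(sweep(sub, 2, mu))
    # zero-SD guard: any nonzero deviation from a constant unit is an outlier
    lim <- ifelse(s > 0, sd_limit * s, 0)
    bad <- rowSums(sweep(dev, 2, lim, `>`)) > 0
    keep[idx[bad]] <- FALSE
  }
  unit_included <- rep(TRUE, ncol(counts))
  if (!is.null(contrast)) {
    z <- contrast == 0
    hi <- contrast >= 0.5
    if (any(z) && any(hi)) {
      unit_included <- vapply(seq_len(ncol(counts)), function(u) {
        a <- counts[keep & z, u]; b <- counts[keep & hi, u]
        if (stats::var(a) + stats::var(b) == 0) return(FALSE)
        stats::t.test(a, b)$p.value < p_limit
      }, logical(1))
    }
  }
  same_el <- NULL
  if (!is.null(electrode))
    same_el <- outer(electrode, electrode, `==`)
  list(counts = counts[keep, , drop = FALSE], kept_trials = keep,
       unit_included = unit_included, same_electrode = same_el)
}
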