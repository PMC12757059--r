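#' Build a ready-to-simulate model
#'
#' Convenience constructor: generates independent V1 and V4/MT pinwheel
#' maps, builds and calibrates the V1 front end, samples the connectivity
#' and compiles it. All randomness is split hierarchically from `seed`
#' (map, connectivity, calibration are independently reproducible).
#'
#' @param scale population scale factor (1 = full size).
#' @param seed root integer seed.
#' @param variant connectivity variant (`"default"`, `"matched"`,
#'   `"random"`).
#' @param overlap feedforward overlap for the random variant.
#' @param config optional [network_config()] (built from `scale` if NULL).
#' @param reference_contrast V1 calibration contrast.
#' @param ... further arguments to [network_config()].
#' @return a `compiled_network`, with the `connectivity` in attribute
#'   `"net"`.
#' @export
build_model <- function(scale = 0.25, seed = 1L, variant = "default",
                        overlap = 1, config = NULL,
                        reference_contrast = 0.5, ...) {
  if (is.null(config)) config <- network_config(scale = scale, ...)
  dims <- config$dims
  map_v4 <- generate_pinwheel_map(dims$e[1], dims$e[2],
                                  seed = split_seed(seed, "map-v4"))
  map_v1 <- generate_pinwheel_map(dims$f[1], dims$f[2],
                                  seed = split_seed(seed, "map-v1"))
  v1 <- v1_population(map_v1)
  v1 <- calibrate_gain(v1, reference_contrast = reference_contrast)
  net <- build_network(config, map_v4, map_v1, variant = variant,
                       overlap = overlap,
                       seed = split_seed(seed, "wiring"))
  cnet <- compile_network(net, v1)
  attr(cnet, "net") <- net
  cnet
}

#' Normalization experiment: three conditions, indices and currents
#'
#' Simulates the three stimulus conditions (image 1 alone, image 2 alone,
#' both) with matched seeds, and assembles the per-unit normalization
#' table: firing rates, normalization index, selectivity, per-current-type
#' normalization indices and the one-SD inclusion flag. With
#' `keep_spikes = TRUE` the rasters are returned for correlation analyses.
#'
#' @param cnet a `compiled_network` (see [build_model()]).
#' @param contrast stimulus contrast.
#' @param theta1 orientation of image 1 (image 2 orthogonal).
#' @param plaid superimposed presentation (see
#'   [normalization_conditions()]).
#' @param T,n_sims duration (ms) per simulation and simulations per
#'   condition.
#' @param seed root seed.
#' @param keep_spikes,trace_units passed through to [run_condition_set()].
#' @return list: `table` (data.frame per excitatory unit), `rates`,
#'   `cur_mean`, `spikes`, `included`, and the run metadata.
#' @export
run_normalization_experiment <- function(cnet, contrast = 0.5, theta1 = 0,
                                         plaid = FALSE, T = 10000,
                                         n_sims = 2, seed = 1L,
                                         keep_spikes = FALSE,
                                         trace_units = integer(0)) {
  stopifnot(inherits(cnet, "compiled_network"))
  conds <- normalization_conditions(cnet$v1, contrast = contrast,
                                    theta1 = theta1, plaid = plaid)
  rs <- run_condition_set(cnet, conds, T = T, n_sims = n_sims, seed = seed,
                          keep_spikes = keep_spikes,
                          trace_units = trace_units)
  n_e <- cnet$config$N_e
  e_idx <- seq_len(n_e)
  fr <- rs$rates[e_idx, , drop = FALSE]
  ni <- normalization_index(fr[, "stim1"], fr[, "stim2"], fr[, "both"])
  sel <- selectivity(fr[, "stim1"], fr[, "stim2"])
  cni <- sapply(c("ff", "re", "ri"), function(k)
    current_norm_index(rs$cur_mean$stim1[e_idx, k],
                       rs$cur_mean$stim2[e_idx, k],
                       rs$cur_mean$both[e_idx, k]))
  included <- rate_inclusion(fr) & !is.na(ni)
  tab <- data.frame(
    unit = e_idx, fr_stim1 = fr[, "stim1"], fr_stim2 = fr[, "stim2"],
    fr_both = fr[, "both"], norm_index = ni, selectivity = sel,
    ni_ff = cni[, "ff"], ni_re = cni[, "re"], ni_ri = cni[, "ri"],
    theta = cnet$theta$e, included = included)
  list(table = tab, rates = rs$rates, cur_mean = rs$cur_mean,
       spikes = rs$spikes, traces = rs$traces, included = included,
       contrast = contrast, theta1 = theta1, plaid = plaid, T = T,
       n_sims = n_sims, seed = seed, variant = cnet$variant)
}

#' Orientation tuning curves of the V4/MT excitatory units
#'
#' Presents a Gabor at location 1 at orientations 0 to 170 degrees in
#' `step_deg` steps and returns the mean-rate tuning curve per excitatory
#' unit.
#'
#' @param cnet a `compiled_network`.
#' @param contrast stimulus contrast.
#' @param step_deg orientation spacing, degrees (default 10).
#' @param T,seed simulation duration (ms) and seed.
#' @return matrix orientations x units; orientations (rad) as rownames.
#' @export
tuning_curves <- function(cnet, contrast = 0.5, step_deg = 10, T = 3000,
                          seed = 1L) {
  v1 <- cnet$v1
  thetas <- seq(0, pi - 1e-9, by = step_deg * pi / 180)
  n_e <- cnet$config$N_e
  out <- matrix(0, length(thetas), n_e)
  for (k in seq_along(thetas)) {
    g <- gabor_image(contrast, center = v1$rf_center[[1]],
                     theta = thetas[k], sigma = v1$sigma,
                     lambda_wave = v1$lambda_wave, npix = v1$npix,
                     extent = v1$extent)
    res <- simulate_network(cnet, stim_static(image1 = g), T = T,
                            seed = split_seed(seed, paste("tc", k)))
    out[k, ] <- res$rates[seq_len(n_e)]
  }
  rownames(out) <- format(thetas, digits = 4)
  out
}

#' Contrast-sweep experiment
#'
#' Simulates the contrast-difference sweep (`c1 = base + dc`,
#' `c2 = base - dc`) and returns per-unit rates per condition, ready for
#' [contrast_sensitivity()].
#'
#' @param cnet a `compiled_network`.
#' @param dc contrast offsets (must include 0).
#' @param base mean contrast.
#' @param theta1 orientation of image 1.
#' @param T,n_sims,seed simulation parameters.
#' @return list: `rates` (E units x conditions), `dc`.
#' @export
run_contrast_sweep <- function(cnet, dc = seq(0, 0.4, by = 0.1),
                               base = 0.5, theta1 = 0, T = 5000,
                               n_sims = 1, seed = 1L) {
  v1 <- cnet$v1
  conds <- delta_contrast_conditions(dc, base)
  prot <- list()
  for (k in seq_len(nrow(conds))) {
    g1 <- gabor_image(conds$c1[k], center = v1$rf_center[[1]],
                      theta = theta1, sigma = v1$sigma,
                      lambda_wave = v1$lambda_wave, npix = v1$npix,
                      extent = v1$extent)
    g2 <- gabor_image(conds$c2[k], center = v1$rf_center[[2]],
                      theta = theta1 + pi / 2, sigma = v1$sigma,
                      lambda_wave = v1$lambda_wave, npix = v1$npix,
                      extent = v1$extent)
    prot[[sprintf("dc%g", conds$dc[k])]] <- stim_static(g1, g2)
  }
  rs <- run_condition_set(cnet, prot, T = T, n_sims = n_sims, seed = seed)
  list(rates = rs$rates[seq_len(cnet$config$N_e), , drop = FALSE],
       dc = conds$dc)
}

#' Small fixture model for fast tests
#'
#' A miniature model bundle (about 250 recurrent neurons) whose end-to-end
#' simulation runs in seconds; regeneration with the same seed is
#' identical.
#'
#' @param seed integer seed.
#' @param scale scale factor (default 0.01).
#' @return a `compiled_network` (see [build_model()]).
#' @export
make_fixtures <- function(seed = 1L, scale = 0.01) {
  build_model(scale = scale, seed = seed)
}
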