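#' Network configuration for the V4/MT layer
#'
#' Holds population sizes, synaptic weights, connection probabilities,
#' out-degrees and projection widths of the recurrent layer and its
#' feedforward input. Defaults are the full-scale model; `scale` shrinks all
#' population sizes (and hence out-degrees) while preserving the mean
#' connection probabilities and the \eqn{J/\sqrt{N}} weight scaling, for
#' desk-scale runs.
#'
#' Grid layout: excitatory neurons on a `2k x k` grid with `k =
#' round(100 sqrt(scale))`, inhibitory and V1 neurons on `k x k/2`-style
#' grids at half the linear density, all covering \eqn{\Gamma}.
#'
#' @param scale population scale factor (1 = full: 20000 E, 5000 I, 5000 V1).
#' @param J_ee,J_ei,J_ie,J_ii,J_eF,J_iF synaptic weights, mV (pre-scaling;
#'   first index = target, second = source; I-source weights are negative).
#' @param p_ee,p_ei,p_ie,p_ii,p_eF,p_iF mean connection probabilities.
#' @param sigma_e,sigma_i,sigma_ffwd projection widths (domain units).
#' @param long_range_fraction fraction of E-source connections onto E
#'   neurons drawn from similarly tuned neurons irrespective of distance.
#' @param tuning_threshold cosine-similarity threshold for "similarly
#'   tuned".
#' @param tuning_convention `"cos"` uses `cos(theta_i - theta_j)` exactly as
#'   stated for the model; `"cos2"` uses the orientation-doubled
#'   `cos(2(theta_i - theta_j))`.
#' @return a `network_config` list. Derived fields: `N_e`, `N_i`, `N_f`,
#'   grid dims, out-degrees `K_out` (`round(p * N_target)`), and `N = N_e +
#'   N_i` used in the weight scaling.
#' @export
network_config <- function(scale = 1,
                           J_ee = 80, J_ei = -240, J_ie = 40, J_ii = -300,
                           J_eF = 160, J_iF = 140,
                           p_ee = 0.01, p_ei = 0.04, p_ie = 0.03,
                           p_ii = 0.04, p_eF = 0.05, p_iF = 0.05,
                           sigma_e = 0.2, sigma_i = 0.2, sigma_ffwd = 0.1,
                           long_range_fraction = 0.15,
                           tuning_threshold = 0.6,
                           tuning_convention = c("cos", "cos2")) {
  stopifnot(scale > 0)
  tuning_convention <- match.arg(tuning_convention)
  k_e <- max(4L, round(100 * sqrt(scale)))
  k_i <- max(2L, round(k_e / 2))
  k_f <- k_i
  dims <- list(e = c(2L * k_e, k_e), i = c(2L * k_i, k_i),
               f = c(2L * k_f, k_f))
  N_e <- prod(dims$e); N_i <- prod(dims$i); N_f <- prod(dims$f)
  p <- c(ee = p_ee, ei = p_ei, ie = p_ie, ii = p_ii, eF = p_eF, iF = p_iF)
  N_target <- c(ee = N_e, ei = N_e, ie = N_i, ii = N_i, eF = N_e, iF = N_i)
  K_out <- round(p * N_target)
  structure(list(
    scale = scale, N_e = N_e, N_i = N_i, N_f = N_f, N = N_e + N_i,
    dims = dims,
    J = c(ee = J_ee, ei = J_ei, ie = J_ie, ii = J_ii, eF = J_eF, iF = J_iF),
    p = p, K_out = K_out,
    sigma = c(e = sigma_e, i = sigma_i, ffwd = sigma_ffwd),
    long_range_fraction = long_range_fraction,
    tuning_threshold = tuning_threshold,
    tuning_convention = tuning_convention), class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("network_config: scale = %g, N_e = %d, N_i = %d, N_f = %d\n",
              x$scale, x$N_e, x$N_i, x$N_f))
  cat("K_out:", paste(names(x$K_out), x$K_out, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Wrapped-Gaussian connection density on the periodic domain
#'
#' Product of one-dimensional wrapped Gaussians with periods 2 (x) and
#' 1 (y):
#' \deqn{g(x,y;\sigma) = \frac{1}{2\pi\sigma^2}
#'   \sum_k e^{-(x+2k)^2/2\sigma^2} \sum_k e^{-(y+k)^2/2\sigma^2}.}
#' The series is truncated at `|k| <= k_trunc` (error < 1e-12 for
#' `sigma <= 0.2` at the default truncation).
#'
#' @param dx,dy displacement components (vectors recycle).
#' @param sigma width, domain units.
#' @param k_trunc series truncation.
#' @return density values (integrates to 1 over \eqn{\Gamma}).
#' @export
wrapped_gaussian <- function(dx, dy, sigma, k_trunc = 5) {
  if (sigma <= 0) stop("`sigma` must be positive")
  ks <- -k_trunc:k_trunc
  sx <- rowSums(matrix(vapply(ks, function(k)
    exp(-(dx + 2 * k)^2 / (2 * sigma^2)), numeric(length(dx))),
    nrow = length(dx)))
  sy <- rowSums(matrix(vapply(ks, function(k)
    exp(-(dy + k)^2 / (2 * sigma^2)), numeric(length(dy))),
    nrow = length(dy)))
  sx * sy / (2 * pi * sigma^2)
}

# sorted-theta lookup tables for uniform sampling from the similarly tuned
# set {j : cos(theta_i - theta_j) >= thr} (or cos-doubled variant)
.tuned_sampler <- function(theta_targets, threshold, convention) {
  if (convention == "cos") {
    half <- acos(threshold)                  # |dtheta| <= half, no wrap
    ord <- order(theta_targets)
    ts <- theta_targets[ord]
    list(kind = "lin", ord = ord, ts = ts, half = half,
         n = length(ts))
  } else {
    half <- acos(threshold)                  # on doubled angle, circular
    phi <- (2 * theta_targets) %% (2 * pi)
    ord <- order(phi)
    ts <- phi[ord]
    list(kind = "circ", ord = ord, ts = c(ts, ts + 2 * pi),
         ord2 = c(ord, ord), half = half, n = length(ts))
  }
}

# draw k uniform samples from the tuned set of each pre neuron (vectorized)
.tuned_draw <- function(sampler, theta_pre, k) {
  if (k == 0L) return(integer(0))
  if (sampler$kind == "lin") {
    lo <- findInterval(theta_pre - sampler$half, sampler$ts) + 1L
    hi <- findInterval(theta_pre + sampler$half, sampler$ts)
    cnt <- hi - lo + 1L
    if (any(cnt < 1L)) stop("empty similarly-tuned candidate set")
    loR <- rep(lo, each = k)
    cntR <- rep(cnt, each = k)
    idx <- loR + floor(runif(length(loR)) * cntR)
    sampler$ord[idx]
  } else {
    phi <- (2 * theta_pre) %% (2 * pi)
    a <- phi - sampler$half
    shift <- ifelse(a < 0, 2 * pi, 0)   # keep window within [0, 4pi)
    lo <- findInterval(a + shift, sampler$ts) + 1L
    hi <- findInterval(phi + sampler$half + shift, sampler$ts)
    cnt <- hi - lo + 1L
    if (any(cnt < 1L)) stop("empty similarly-tuned candidate set")
    loR <- rep(lo, each = k)
    cntR <- rep(cnt, each = k)
    idx <- loR + floor(runif(length(loR)) * cntR)
    sampler$ord2[idx]
  }
}

# sample spatial targets: continuous wrapped-normal displacement from each
# pre position, snapped to the containing cell of the target grid
.spatial_draw <- function(x_pre, y_pre, k, sigma, dims_target) {
  nx <- dims_target[1]; ny <- dims_target[2]
  n <- length(x_pre) * k
  tx <- (rep(x_pre, each = k) + rnorm(n, 0, sigma)) %% 2
  ty <- (rep(y_pre, each = k) + rnorm(n, 0, sigma)) %% 1
  ix <- pmin(floor(tx / (2 / nx)), nx - 1)
  iy <- pmin(floor(ty / (1 / ny)), ny - 1)
  as.integer(ix * ny + iy + 1)
}

.projection_spec <- function() {
  # source pop, target pop, sigma key, long-range?
  list(ee = list(src = "e", tgt = "e", sig = "e",    lr = TRUE),
       ie = list(src = "e", tgt = "i", sig = "e",    lr = FALSE),
       ei = list(src = "i", tgt = "e", sig = "i",    lr = FALSE),
       ii = list(src = "i", tgt = "i", sig = "i",    lr = FALSE),
       eF = list(src = "f", tgt = "e", sig = "ffwd", lr = TRUE),
       iF = list(src = "f", tgt = "i", sig = "ffwd", lr = FALSE))
}

#' Build the V4/MT connectivity graph
#'
#' Samples, for every presynaptic neuron and projection type, exactly
#' `K_out` postsynaptic targets (multiple contacts onto one target are
#' allowed and stored as repeated edges). For the default variant, 85% of
#' E-source connections onto excitatory neurons (and all other projections)
#' follow a wrapped-Gaussian distance profile; the remaining 15% are drawn
#' uniformly from similarly tuned neurons anywhere on the sheet. The
#' `matched` variant instead fixes every neuron's in-degree at the
#' population mean of the default network (out-degrees free) while keeping
#' the same spatial/tuning sampling distributions. The `random` variant has
#' no spatial or tuning structure; its two feedforward source populations
#' project onto target sets sharing a fraction `overlap` of neurons.
#'
#' @param config a [network_config()].
#' @param map_v4 `orientation_map` of the V4/MT layer, evaluated on both the
#'   E and I grids internally (pass the generating field via its `field`).
#' @param map_v1 `orientation_map` of the V1 layer (for feedforward tuning).
#' @param variant `"default"`, `"matched"` or `"random"`.
#' @param overlap feedforward target-set overlap for the random variant.
#' @param seed integer seed.
#' @return a `connectivity` object: per-projection edge tables
#'   (`pre`, `post` 1-based within their populations, `long` flag), the
#'   per-neuron orientations, and the config.
#' @export
build_network <- function(config, map_v4, map_v1,
                          variant = c("default", "matched", "random"),
                          overlap = 1, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "network_config"),
            inherits(map_v4, "orientation_map"),
            inherits(map_v1, "orientation_map"))
  if (overlap < 0 || overlap > 1) stop("`overlap` must be in [0, 1]")
  dims <- config$dims
  pos_e <- grid_positions(dims$e[1], dims$e[2])
  pos_i <- grid_positions(dims$i[1], dims$i[2])
  pos_f <- grid_positions(dims$f[1], dims$f[2])
  theta_e <- eval_pinwheel(map_v4$field, pos_e$x, pos_e$y)
  theta_i <- eval_pinwheel(map_v4$field, pos_i$x, pos_i$y)
  theta_f <- eval_pinwheel(map_v1$field, pos_f$x, pos_f$y)
  pops <- list(e = list(pos = pos_e, theta = theta_e, dims = dims$e),
               i = list(pos = pos_i, theta = theta_i, dims = dims$i),
               f = list(pos = pos_f, theta = theta_f, dims = dims$f))
  old <- .Random.seed_save()
  set.seed(split_seed(seed, paste0("connectivity-", variant)))
  spec <- .projection_spec()
  edges <- vector("list", length(spec))
  names(edges) <- names(spec)
  for (pn in names(spec)) {
    sp <- spec[[pn]]
    src <- pops[[sp$src]]; tgt <- pops[[sp$tgt]]
    n_src <- nrow(src$pos)
    if (variant == "random") {
      K <- config$K_out[[pn]]
      if (sp$src == "f") {
        n_t <- nrow(tgt$pos)
        m <- round(n_t / (2 - overlap))
        left <- src$pos$x < 1      # population F1
        sets <- list(seq_len(m), seq.int(n_t - m + 1L, n_t))
        post <- integer(n_src * K)
        for (w in 1:2) {
          idx <- if (w == 1) which(left) else which(!left)
          draws <- sets[[w]][ceiling(runif(length(idx) * K) * m)]
          slot <- as.vector(outer(seq_len(K), (idx - 1L) * K, `+`))
          post[slot] <- draws
        }
      } else {
        post <- ceiling(runif(n_src * K) * nrow(tgt$pos))
      }
      edges[[pn]] <- data.frame(pre = rep(seq_len(n_src), each = K),
                                post = as.integer(post),
                                long = FALSE)
      next
    }
    if (variant == "default") {
      K <- config$K_out[[pn]]
      k_long <- if (sp$lr) round(config$long_range_fraction * K) else 0L
      k_loc <- K - k_long
      post_loc <- .spatial_draw(src$pos$x, src$pos$y, k_loc,
                                config$sigma[[sp$sig]], tgt$dims)
      pre_loc <- rep(seq_len(n_src), each = k_loc)
      if (k_long > 0L) {
        samp <- .tuned_sampler(tgt$theta, config$tuning_threshold,
                               config$tuning_convention)
        post_lr <- .tuned_draw(samp, src$theta, k_long)
        pre_lr <- rep(seq_len(n_src), each = k_long)
        edges[[pn]] <- data.frame(
          pre = c(pre_loc, pre_lr), post = c(post_loc, post_lr),
          long = rep(c(FALSE, TRUE), c(length(pre_loc), length(pre_lr))))
      } else {
        edges[[pn]] <- data.frame(pre = pre_loc, post = post_loc,
                                  long = FALSE)
      }
    } else {                      # matched in-degrees
      n_tgt <- nrow(tgt$pos)
      K_in <- round(config$K_out[[pn]] * n_src / n_tgt)
      k_long <- if (sp$lr) round(config$long_range_fraction * K_in) else 0L
      k_loc <- K_in - k_long
      pre_loc <- .spatial_draw(tgt$pos$x, tgt$pos$y, k_loc,
                               config$sigma[[sp$sig]], src$dims)
      post_loc <- rep(seq_len(n_tgt), each = k_loc)
      if (k_long > 0L) {
        samp <- .tuned_sampler(src$theta, config$tuning_threshold,
                               config$tuning_convention)
        pre_lr <- .tuned_draw(samp, tgt$theta, k_long)
        post_lr <- rep(seq_len(n_tgt), each = k_long)
        edges[[pn]] <- data.frame(
          pre = c(pre_loc, pre_lr), post = c(post_loc, post_lr),
          long = rep(c(FALSE, TRUE), c(length(post_loc), length(post_lr))))
      } else {
        edges[[pn]] <- data.frame(pre = pre_loc, post = post_loc,
                                  long = FALSE)
      }
    }
  }
  .Random.seed_restore(old)
  structure(list(edges = edges, config = config, variant = variant,
                 overlap = overlap, seed = as.integer(seed),
                 positions = list(e = pos_e, i = pos_i, f = pos_f),
                 theta = list(e = theta_e, i = theta_i, f = theta_f)),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("connectivity (%s): N_e = %d, N_i = %d, N_f = %d\n",
              x$variant, x$config$N_e, x$config$N_i, x$config$N_f))
  for (pn in names(x$edges))
    cat(sprintf("  %s: %d edges (%d long-range)\n", pn,
                nrow(x$edges[[pn]]), sum(x$edges[[pn]]$long)))
  invisible(x)
}

#' Per-neuron degrees of a projection
#'
#' @param net a `connectivity` object.
#' @param projection one of `"ee"`, `"ie"`, `"ei"`, `"ii"`, `"eF"`, `"iF"`.
#' @param side `"out"` (per presynaptic neuron) or `"in"`.
#' @return integer vector of degrees over the full source/target population.
#' @export
degree_table <- function(net, projection, side = c("out", "in")) {
  side <- match.arg(side)
  ed <- net$edges[[projection]]
  sp <- .projection_spec()[[projection]]
  n <- nrow(net$positions[[if (side == "out") sp$src else sp$tgt]])
  tabulate(if (side == "out") ed$pre else ed$post, nbins = n)
}

#' Write / read a connectivity graph as a columnar edge list
#'
#' TSV with columns `proj`, `pre`, `post`, `long`; round-trips the edge
#' multiset losslessly.
#'
#' @param net a `connectivity` object.
#' @param file path.
#' @export
write_connectivity <- function(net, file) {
  all <- do.call(rbind, lapply(names(net$edges), function(pn)
    cbind(proj = pn, net$edges[[pn]])))
  write.table(all, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_connectivity
#' @export
read_connectivity_edges <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "integer",
                                  "logical"))
  split(df[c("pre", "post", "long")], df$proj)
}
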