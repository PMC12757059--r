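# Brute-force linear-separability oracle for the capacity tests,
# independent of the mean-field anchor-point machinery.
#
# A dichotomy (y_k in {-1, +1} per manifold) is linearly separable iff
# there is a w with y_k (w . x) > 0 for every point x of every manifold;
# by Gordan's theorem this fails iff 0 lies in the convex hull of the
# signed points. We run Frank-Wolfe on min ||Z' mu||^2 over the simplex:
# if the current iterate v separates all signed points we stop (v is a
# separating certificate); if ||v|| collapses below tolerance the origin
# is (numerically) in the hull and the dichotomy is inseparable.

separable_dichotomy <- function(points, labels, max_iter = 2000,
                                tol = 1e-6) {
  Z <- do.call(rbind, lapply(seq_along(points), function(k)
    labels[k] * points[[k]]))
  Z <- Z / pmax(sqrt(rowSums(Z^2)), 1e-12)       # normalise rows
  v <- colMeans(Z)
  for (it in seq_len(max_iter)) {
    sc <- as.numeric(Z %*% v)
    if (min(sc) > 0) return(TRUE)                # certificate found
    nv2 <- sum(v^2)
    if (nv2 < tol^2) return(FALSE)               # origin in hull
    j <- which.min(sc)
    d <- Z[j, ] - v
    step <- -sum(v * d) / sum(d^2)               # exact line search
    step <- min(max(step, 0), 1)
    v <- v + step * d
  }
  sum(v^2) >= tol^2 && min(as.numeric(Z %*% v)) > 0
}

# fraction of random +-1 dichotomies of the first P manifolds separable
separability_fraction <- function(manifolds, P, n_dich = 20, seed = 1) {
  pts <- manifolds[seq_len(P)]
  gm <- colMeans(do.call(rbind, pts))
  pts <- lapply(pts, function(X) sweep(as.matrix(X), 2, gm))
  set.seed(seed)
  mean(replicate(n_dich, {
    y <- sample(c(-1, 1), P, replace = TRUE)
    separable_dichotomy(pts, y)
  }))
}

# critical load P*/N at which separability crosses 50%, by bisection on P
oracle_critical_load <- function(manifolds, N, P_lo = 2,
                                 P_hi = length(manifolds), n_dich = 20,
                                 seed = 1) {
  f_lo <- separability_fraction(manifolds, P_lo, n_dich, seed)
  f_hi <- separability_fraction(manifolds, P_hi, n_dich, seed)
  if (f_hi >= 0.5) return(P_hi / N)              # never crosses: bound
  if (f_lo < 0.5) return(P_lo / N)
  while (P_hi - P_lo > 1) {
    P_mid <- (P_lo + P_hi) %/% 2
    if (separability_fraction(manifolds, P_mid, n_dich, seed) >= 0.5)
      P_lo <- P_mid
    else
      P_hi <- P_mid
  }
  (P_lo + P_hi) / 2 / N
}

# random Gaussian-blob manifold ensemble in N dimensions
blob_manifolds <- function(P, N, M = 8, radius = 0.2, seed = 1) {
  set.seed(seed)
  lapply(seq_len(P), function(k) {
    ctr <- rnorm(N)
    ctr <- ctr / sqrt(sum(ctr^2))
    sweep(matrix(rnorm(M * N, 0, radius / sqrt(N)), M), 2, -ctr)
  })
}
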