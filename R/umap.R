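# Uniform manifold approximation and projection, implemented in-package.
#
# The construction follows the standard algorithm: a fuzzy simplicial set is
# built from the k-nearest-neighbour graph (per-point connectivity rho_i =
# distance to the nearest neighbour, bandwidth sigma_i calibrated by binary
# search so the smoothed neighbourhood cardinality equals log2(k)),
# symmetrised with the probabilistic t-conorm; the low-dimensional layout
# minimises the fuzzy-set cross-entropy under the 1/(1 + a d^(2b)) output
# kernel, with (a, b) fitted from min_dist. Optimisation here applies the
# attractive and (sampled) repulsive forces of all edges simultaneously per
# epoch with a decaying step, rather than per-edge stochastic updates; the
# embedding is initialised from the first principal components, so results
# are deterministic given the seed. Exact kNN is computed from the full
# distance matrix, which is appropriate at the sample sizes of this domain.

# Fit a,b of the output kernel 1/(1+a d^(2b)) to the target curve
# exp(-(d - min_dist)) for d > min_dist (1 below it).
umap_ab <- function(min_dist, spread = 1) {
  d <- seq(0, 3 * spread, length.out = 300)
  target <- ifelse(d <= min_dist, 1, exp(-(d - min_dist) / spread))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * d^(2 * b)) - target)^2)
  }
  p <- optim(c(log(1.6), log(0.9)), obj, method = "Nelder-Mead")$par
  c(a = exp(p[1]), b = exp(p[2]))
}

# Smooth-kNN calibration: for one point's ascending neighbour distances,
# find sigma with sum_j exp(-max(0, d_j - rho)/sigma) = log2(k).
umap_sigma <- function(d, rho, target, n_iter = 64) {
  lo <- 1e-12; hi <- max(d) * 4 + 1
  for (it in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    s <- sum(exp(-pmax(d - rho, 0) / mid))
    if (abs(s - target) < 1e-5) break
    if (s > target) hi <- mid else lo <- mid
  }
  mid
}

umap_graph <- function(x, n_neighbors) {
  n <- nrow(x)
  k <- min(n_neighbors, n - 1L)
  dm <- as.matrix(dist(x))
  diag(dm) <- Inf
  target <- log2(k + 1)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ])[seq_len(k)]
    d <- dm[i, ord]
    rho <- d[1]
    sig <- umap_sigma(d, rho, target)
    w <- exp(-pmax(d - rho, 0) / sig)
    rows <- c(rows, rep.int(i, k)); cols <- c(cols, ord); vals <- c(vals, w)
  }
  p <- matrix(0, n, n)
  p[cbind(rows, cols)] <- vals
  g <- p + t(p) - p * t(p)  # probabilistic t-conorm symmetrisation
  g
}

umap_layout <- function(graph, init, n_epochs, a, b, seed,
                        neg_samples = 5, lr0 = 1) {
  n <- nrow(init)
  emb <- init
  idx <- which(graph > 0 & upper.tri(graph), arr.ind = TRUE)
  w <- graph[idx]
  i1 <- idx[, 1]; i2 <- idx[, 2]
  with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      alpha <- lr0 * (1 - (ep - 1) / n_epochs)
      diffv <- emb[i1, , drop = FALSE] - emb[i2, , drop = FALSE]
      d2 <- rowSums(diffv^2)
      # attractive gradient of the cross-entropy under the output kernel
      coef_a <- (-2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
      coef_a[!is.finite(coef_a)] <- 0
      grad_a <- diffv * (coef_a * w)
      s1 <- rowsum(grad_a, i1)
      s2 <- rowsum(-grad_a, i2)
      upd <- matrix(0, n, ncol(emb))
      upd[as.integer(rownames(s1)), ] <- upd[as.integer(rownames(s1)), ] + s1
      upd[as.integer(rownames(s2)), ] <- upd[as.integer(rownames(s2)), ] + s2
      # sampled repulsion
      for (r in seq_len(neg_samples)) {
        j <- sample.int(n, length(i1), replace = TRUE)
        diffr <- emb[i1, , drop = FALSE] - emb[j, , drop = FALSE]
        d2r <- rowSums(diffr^2)
        coef_r <- (2 * b) / ((0.001 + d2r) * (1 + a * d2r^b))
        gr <- diffr * (coef_r * w)
        sr <- rowsum(gr, i1)
        upd[as.integer(rownames(sr)), ] <- upd[as.integer(rownames(sr)), ] + sr
      }
      step <- alpha * upd
      step[step > 4] <- 4; step[step < -4] <- -4
      emb <- emb + step
    }
  })
  emb
}

umap_fit <- function(z, n_components = 2, n_neighbors = 15, min_dist = 0.1,
                     seed = 42, n_epochs = 200) {
  n <- nrow(z)
  if (n < 4L) stop_validation("UMAP needs at least 4 samples")
  ab <- umap_ab(min_dist)
  graph <- umap_graph(z, n_neighbors)
  p <- prcomp(z, center = FALSE)
  nc <- min(n_components, ncol(p$x))
  init <- p$x[, seq_len(nc), drop = FALSE]
  if (nc < n_components) {
    init <- cbind(init, matrix(0, n, n_components - nc))
  }
  init <- init / max(1e-12, max(abs(init))) * 10
  emb <- umap_layout(graph, init, n_epochs, ab["a"], ab["b"], seed)
  list(embedding = emb, train_z = z, n_neighbors = n_neighbors,
       a = ab["a"], b = ab["b"], seed = seed)
}

# Out-of-sample projection: each new point is embedded at the membership-
# weighted average of the embeddings of its k nearest training points.
umap_transform <- function(fit, znew) {
  k <- min(fit$n_neighbors, nrow(fit$train_z))
  out <- matrix(0, nrow(znew), ncol(fit$embedding))
  for (i in seq_len(nrow(znew))) {
    d <- sqrt(colSums((t(fit$train_z) - znew[i, ])^2))
    ord <- order(d)[seq_len(k)]
    dd <- d[ord]
    rho <- dd[1]
    sig <- umap_sigma(dd, rho, log2(k + 1))
    w <- exp(-pmax(dd - rho, 0) / sig)
    w <- w / sum(w)
    out[i, ] <- colSums(fit$embedding[ord, , drop = FALSE] * w)
  }
  out
}
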