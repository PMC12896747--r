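# Conv-Attention-MLP network: a dual-branch 1D network for spectral feature
# vectors, written directly in R with hand-derived backpropagation.
#
# Conv branch: two 1D convolutions (defaults: 64 then 256 filters, kernel
# sizes 5 and 3, same padding, ReLU), squeeze-and-excitation channel
# attention, a convolutional spatial-attention gate over positions, then
# global max pooling. MLP branch: one dense layer with a residual block.
# The branches are concatenated and projected through a fused dense head to
# a softmax output, which serves as class probabilities (classifier) or as
# the 5-oil composition simplex (quantifier).
#
# Activations are stored as (batch, position, channel) arrays; convolutions
# are evaluated as im2col matrix products, so the same code path serves
# forward and backward passes efficiently without compiled code.

#' Conv-Attention-MLP architecture description
#'
#' @param input_len Length of the input feature vector (e.g. 3338 for the
#'   full representation, or the reduced PCA/UMAP dimension).
#' @param filters Filter counts of the two convolution layers.
#' @param kernels Kernel sizes of the two convolution layers.
#' @param se_reduction Squeeze-and-excitation bottleneck reduction factor.
#' @param spatial_kernel Kernel size of the spatial-attention gate.
#' @param mlp_units Width of the parallel MLP branch.
#' @param fuse_units Width of the fused head.
#' @return A list of class `cnn_architecture`.
#' @export
cnn_architecture <- function(input_len, filters = c(64, 256), kernels = c(5, 3),
                             se_reduction = 16, spatial_kernel = 7,
                             mlp_units = 128, fuse_units = 64) {
  if (input_len < max(kernels)) {
    stop_validation("input length (%d) shorter than largest kernel (%d)",
                    input_len, max(kernels))
  }
  stopifnot(length(filters) == 2L, length(kernels) == 2L)
  structure(list(input_len = as.integer(input_len),
                 filters = as.integer(filters), kernels = as.integer(kernels),
                 se_reduction = se_reduction,
                 spatial_kernel = as.integer(spatial_kernel),
                 mlp_units = as.integer(mlp_units),
                 fuse_units = as.integer(fuse_units)),
            class = "cnn_architecture")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- 1D convolution (same padding) -----------------------------------------

conv1d_forward <- function(x, w, b, kernel) {
  dm <- dim(x)
  B <- dm[1]; L <- dm[2]; cin <- dm[3]
  cout <- ncol(w)
  pad <- (kernel - 1L) %/% 2L
  xpad <- array(0, c(B, L + 2L * pad, cin))
  xpad[, pad + seq_len(L), ] <- x
  xcol <- array(0, c(B, L, kernel * cin))
  for (k in seq_len(kernel)) {
    xcol[, , (k - 1L) * cin + seq_len(cin)] <- xpad[, k + seq_len(L) - 1L, , drop = FALSE]
  }
  dim(xcol) <- c(B * L, kernel * cin)
  y <- xcol %*% w
  y <- sweep(y, 2L, b, "+")
  dim(y) <- c(B, L, cout)
  list(y = y, xcol = xcol)
}

conv1d_backward <- function(dy, cache, w, kernel, cin, B, L) {
  cout <- ncol(w)
  dim(dy) <- c(B * L, cout)
  dw <- crossprod(cache$xcol, dy)
  db <- colSums(dy)
  dxcol <- dy %*% t(w)
  dim(dxcol) <- c(B, L, kernel * cin)
  pad <- (kernel - 1L) %/% 2L
  dxpad <- array(0, c(B, L + 2L * pad, cin))
  for (k in seq_len(kernel)) {
    dxpad[, k + seq_len(L) - 1L, ] <- dxpad[, k + seq_len(L) - 1L, , drop = FALSE] +
      dxcol[, , (k - 1L) * cin + seq_len(cin), drop = FALSE]
  }
  dx <- dxpad[, pad + seq_len(L), , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}


# ---- fast array helpers ----------------------------------------------------
# Activations are (batch, position, channel). These helpers implement the
# broadcasts/reductions of the attention blocks via flat-matrix primitives
# (column indexing, rowsum, max.col), which are several-fold faster than
# array()/aperm() construction at these shapes.

bc_channel <- function(g, L) {            # (B, C) -> (B, L, C)
  E <- g[, rep(seq_len(ncol(g)), each = L), drop = FALSE]
  dim(E) <- c(nrow(g), L, ncol(g))
  E
}

flat_bl <- function(H) {                  # (B, L, C) -> (B*L, C)
  d <- dim(H)
  dim(H) <- c(d[1] * d[2], d[3])
  H
}

mean_over_l <- function(H) {              # (B, L, C) -> (B, C)
  d <- dim(H)
  rowsum(flat_bl(H), rep(seq_len(d[1]), times = d[2]), reorder = TRUE) / d[2]
}

sum_over_l <- function(H) {
  d <- dim(H)
  rowsum(flat_bl(H), rep(seq_len(d[1]), times = d[2]), reorder = TRUE)
}

# ---- parameter initialisation ----------------------------------------------

he_mat <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

cam_init <- function(arch, n_out, seed) {
  L <- arch$input_len
  f1 <- arch$filters[1]; f2 <- arch$filters[2]
  k1 <- arch$kernels[1]; k2 <- arch$kernels[2]
  r <- max(4L, as.integer(round(f2 / arch$se_reduction)))
  M <- arch$mlp_units; D <- arch$fuse_units
  with_seed(seed, list(
    c1_w = he_mat(k1 * 1L, f1), c1_b = numeric(f1),
    c2_w = he_mat(k2 * f1, f2), c2_b = numeric(f2),
    se_w1 = he_mat(f2, r), se_b1 = numeric(r),
    se_w2 = he_mat(r, f2), se_b2 = numeric(f2),
    sp_w = he_mat(arch$spatial_kernel * 2L, 1L), sp_b = numeric(1L),
    m1_w = he_mat(L, M), m1_b = numeric(M),
    mr_w = he_mat(M, M), mr_b = numeric(M),
    fu_w = he_mat(f2 + M, D), fu_b = numeric(D),
    out_w = he_mat(D, n_out), out_b = numeric(n_out)
  ))
}

# ---- forward ---------------------------------------------------------------

cam_forward <- function(params, x, arch) {
  B <- nrow(x); L <- ncol(x)
  f1 <- arch$filters[1]; f2 <- arch$filters[2]
  x3 <- array(x, c(B, L, 1L))
  cv1 <- conv1d_forward(x3, params$c1_w, params$c1_b, arch$kernels[1])
  h1 <- relu(cv1$y)
  cv2 <- conv1d_forward(h1, params$c2_w, params$c2_b, arch$kernels[2])
  h2 <- relu(cv2$y)
  # channel attention (squeeze-and-excitation)
  s <- mean_over_l(h2)                               # (B, f2)
  z1 <- relu(s %*% params$se_w1 + matrix(params$se_b1, B, length(params$se_b1), byrow = TRUE))
  g <- sigmoid(z1 %*% params$se_w2 + matrix(params$se_b2, B, f2, byrow = TRUE))
  gexp <- bc_channel(g, L)
  hc <- h2 * gexp
  # spatial attention: channel-mean and channel-max maps through a conv gate
  hcf <- flat_bl(hc)                                 # (B*L, f2)
  am <- matrix(rowMeans(hcf), B, L)
  argc_f <- max.col(hcf, ties.method = "first")
  mx <- matrix(hcf[cbind(seq_len(B * L), argc_f)], B, L)
  argc <- matrix(argc_f, B, L)
  spin <- array(0, c(B, L, 2L))
  spin[, , 1L] <- am; spin[, , 2L] <- mx
  cvs <- conv1d_forward(spin, params$sp_w, params$sp_b, arch$spatial_kernel)
  gate <- sigmoid(cvs$y[, , 1L])
  if (B == 1L) gate <- matrix(gate, 1L, L)
  hs <- hc * array(gate, c(B, L, f2))
  # global max pooling over positions
  pool <- hs[, 1L, ]
  if (B == 1L) pool <- matrix(pool, 1L, f2)
  argl <- matrix(1L, B, f2)
  if (L > 1L) {
    for (ll in 2:L) {
      cur <- hs[, ll, ]
      if (B == 1L) cur <- matrix(cur, 1L, f2)
      upd <- cur > pool
      argl[upd] <- ll
      pool[upd] <- cur[upd]
    }
  }
  # MLP branch with a residual block
  a1 <- relu(x %*% params$m1_w + matrix(params$m1_b, B, arch$mlp_units, byrow = TRUE))
  ar_pre <- a1 %*% params$mr_w + matrix(params$mr_b, B, arch$mlp_units, byrow = TRUE)
  ar <- a1 + relu(ar_pre)
  # fused head
  cat_ <- cbind(pool, ar)
  fu <- relu(cat_ %*% params$fu_w + matrix(params$fu_b, B, arch$fuse_units, byrow = TRUE))
  logits <- fu %*% params$out_w + matrix(params$out_b, B, ncol(params$out_w), byrow = TRUE)
  lmax <- apply(logits, 1L, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  list(probs = probs, logits = logits,
       cache = list(x = x, x3 = x3, cv1 = cv1, h1 = h1, cv2 = cv2, h2 = h2,
                    s = s, z1 = z1, g = g, gexp = gexp, hc = hc, am = am,
                    mx = mx, argc = argc, spin = spin, cvs = cvs, gate = gate,
                    hs = hs, pool = pool, argl = argl, a1 = a1,
                    ar_pre = ar_pre, ar = ar, cat_ = cat_, fu = fu))
}

# ---- loss and gradient -----------------------------------------------------

# loss = cross-entropy (classifier) or mean squared error on the softmax
# output (quantifier). Returns loss and d(loss)/d(logits).
cam_loss_grad <- function(probs, y, loss = c("ce", "mse")) {
  loss <- match.arg(loss)
  B <- nrow(probs)
  if (loss == "ce") {
    eps <- 1e-12
    l <- -mean(rowSums(y * log(probs + eps)))
    dlogits <- (probs - y) / B
  } else {
    l <- mean((probs - y)^2)
    dp <- 2 * (probs - y) / (B * ncol(probs))
    dot <- rowSums(dp * probs)
    dlogits <- probs * (dp - dot)
  }
  list(loss = l, dlogits = dlogits)
}

cam_backward <- function(params, arch, fw, dlogits) {
  ca <- fw$cache
  B <- nrow(ca$x); L <- ncol(ca$x)
  f1 <- arch$filters[1]; f2 <- arch$filters[2]
  M <- arch$mlp_units
  g <- list()
  # head
  g$out_w <- crossprod(ca$fu, dlogits); g$out_b <- colSums(dlogits)
  dfu <- dlogits %*% t(params$out_w)
  dfu[ca$fu <= 0] <- 0
  g$fu_w <- crossprod(ca$cat_, dfu); g$fu_b <- colSums(dfu)
  dcat <- dfu %*% t(params$fu_w)
  dpool <- dcat[, seq_len(f2), drop = FALSE]
  dar <- dcat[, f2 + seq_len(M), drop = FALSE]
  # MLP branch (residual): ar = a1 + relu(ar_pre)
  dr <- dar
  dr[ca$ar_pre <= 0] <- 0
  g$mr_w <- crossprod(ca$a1, dr); g$mr_b <- colSums(dr)
  da1 <- dar + dr %*% t(params$mr_w)
  da1[ca$a1 <= 0] <- 0
  g$m1_w <- crossprod(ca$x, da1); g$m1_b <- colSums(da1)
  dx_mlp <- da1 %*% t(params$m1_w)
  # global max pool: scatter to argmax positions
  dhs <- array(0, c(B, L, f2))
  bI <- rep(seq_len(B), times = f2)
  cI <- rep(seq_len(f2), each = B)
  dhs[cbind(bI, as.vector(ca$argl), cI)] <- as.vector(dpool)
  # spatial gate: hs = hc * gate
  gmat <- array(ca$gate, c(B, L, f2))
  dhc <- dhs * gmat
  prod_ <- dhs * ca$hc
  dim(prod_) <- c(B * L, f2)
  dgate <- matrix(rowSums(prod_), B, L)
  dpre <- dgate * ca$gate * (1 - ca$gate)
  dpre3 <- array(dpre, c(B, L, 1L))
  cbk <- conv1d_backward(dpre3, ca$cvs, params$sp_w, arch$spatial_kernel, 2L, B, L)
  g$sp_w <- cbk$dw; g$sp_b <- cbk$db
  dam <- cbk$dx[, , 1L]; dmx <- cbk$dx[, , 2L]
  if (B == 1L) { dam <- matrix(dam, 1L, L); dmx <- matrix(dmx, 1L, L) }
  # channel-mean map: spread over channels
  dhc <- dhc + array(dam / f2, c(B, L, f2))
  # channel-max map: scatter to argmax channels
  bI2 <- rep(seq_len(B), times = L)
  lI2 <- rep(seq_len(L), each = B)
  idx <- cbind(bI2, lI2, as.vector(ca$argc))
  dhc[idx] <- dhc[idx] + as.vector(dmx)
  # channel attention: hc = h2 * g
  dh2 <- dhc * ca$gexp
  dg <- sum_over_l(dhc * ca$h2)
  dz2 <- dg * ca$g * (1 - ca$g)
  g$se_w2 <- crossprod(ca$z1, dz2); g$se_b2 <- colSums(dz2)
  dz1 <- dz2 %*% t(params$se_w2)
  dz1[ca$z1 <= 0] <- 0
  g$se_w1 <- crossprod(ca$s, dz1); g$se_b1 <- colSums(dz1)
  ds <- dz1 %*% t(params$se_w1)
  dh2 <- dh2 + bc_channel(ds / L, L)
  # conv stack
  dh2[ca$cv2$y <= 0] <- 0
  cb2 <- conv1d_backward(dh2, ca$cv2, params$c2_w, arch$kernels[2], f1, B, L)
  g$c2_w <- cb2$dw; g$c2_b <- cb2$db
  dh1 <- cb2$dx
  dh1[ca$cv1$y <= 0] <- 0
  cb1 <- conv1d_backward(dh1, ca$cv1, params$c1_w, arch$kernels[1], 1L, B, L)
  g$c1_w <- cb1$dw; g$c1_b <- cb1$db
  g
}

# ---- Adam optimiser --------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- training loop ---------------------------------------------------------

cam_evaluate_loss <- function(params, arch, x, y, loss, chunk = 256L) {
  n <- nrow(x)
  tot <- 0
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    fw <- cam_forward(params, x[st:en, , drop = FALSE], arch)
    lg <- cam_loss_grad(fw$probs, y[st:en, , drop = FALSE], loss)
    tot <- tot + lg$loss * (en - st + 1L)
  }
  tot / n
}

clip_global_norm <- function(grads, max_norm) {
  tot <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(tot) && tot > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / tot))
  }
  grads
}

# One optimisation phase: runs up to `epochs` epochs of minibatch Adam with
# optional linear learning-rate warmup, plateau decay and early stopping,
# starting from the supplied parameter/optimiser state. Returns the updated
# state, the best-validation snapshot seen, and the epoch-level curve.
cam_train_phase <- function(st, xtr, ytr, xva, yva, arch, loss, epochs,
                            batch, lr, warmup, patience, lr_patience,
                            lr_factor, min_lr, clip, seed, epoch_offset = 0L,
                            plateau_restarts = 0L) {
  ntr <- nrow(xtr)
  curve <- tibble(epoch = integer(0), train_loss = numeric(0),
                  val_loss = numeric(0), lr = numeric(0))
  for (ep in seq_len(epochs)) {
    gep <- epoch_offset + ep
    cur_lr <- if (gep <= warmup) st$base_lr * gep / (warmup + 1) else st$lr
    ord <- with_seed(derive_seed(seed, 1000L + gep), sample.int(ntr))
    ep_loss <- 0
    for (bs in seq(1L, ntr, by = batch)) {
      be <- min(bs + batch - 1L, ntr)
      bi <- ord[bs:be]
      fw <- cam_forward(st$params, xtr[bi, , drop = FALSE], arch)
      lg <- cam_loss_grad(fw$probs, ytr[bi, , drop = FALSE], loss)
      grads <- clip_global_norm(cam_backward(st$params, arch, fw, lg$dlogits), clip)
      upd <- adam_step(st$params, grads, st$state, cur_lr)
      st$params <- upd$params; st$state <- upd$state
      ep_loss <- ep_loss + lg$loss * length(bi)
    }
    ep_loss <- ep_loss / ntr
    val_loss <- cam_evaluate_loss(st$params, arch, xva, yva, loss)
    curve <- dplyr::bind_rows(curve, tibble(epoch = gep, train_loss = ep_loss,
                                            val_loss = val_loss, lr = cur_lr))
    if (val_loss < st$best$val - 1e-9) {
      st$best <- list(val = val_loss, params = st$params, epoch = gep)
      st$since_best <- 0L; st$since_lr <- 0L
    } else if (gep > warmup) {
      st$since_best <- st$since_best + 1L
      st$since_lr <- st$since_lr + 1L
      if (st$since_lr >= lr_patience && st$lr > min_lr) {
        st$lr <- max(min_lr, st$lr * lr_factor)
        st$since_lr <- 0L
      }
      if (st$since_best >= patience) {
        if (st$restarts_left > 0L) {
          # warm restart: return to the base learning rate and keep going
          # from the best snapshot seen so far
          st$restarts_left <- st$restarts_left - 1L
          st$params <- st$best$params
          st$state <- adam_state(st$params)
          st$lr <- st$base_lr
          st$since_best <- 0L; st$since_lr <- 0L
        } else {
          st$stopped <- TRUE
          break
        }
      }
    }
  }
  st$curve <- dplyr::bind_rows(st$curve, curve)
  st
}

# Train with Adam: a short multi-start phase (n_starts seeded
# initialisations, each run for start_epochs with linear warmup) followed by
# full training of the start with the lowest validation loss. The restart
# phase makes the optimisation robust to unlucky initialisations of the
# saturating softmax head; selection uses only the validation split.
cam_train <- function(x, y, arch, loss = c("ce", "mse"), epochs = 200,
                      batch = 32, lr = 1e-3, val_frac = 0.2, patience = 20,
                      lr_patience = 8, lr_factor = 0.5, min_lr = 1e-5,
                      clip = 5, warmup = 5, n_starts = 1, start_epochs = 40,
                      plateau_restarts = 0, seed = 42, verbose = FALSE) {
  loss <- match.arg(loss)
  n <- nrow(x)
  stopifnot(nrow(y) == n)
  idx <- with_seed(derive_seed(seed, 2L), sample.int(n))
  n_val <- max(1L, round(val_frac * n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  xtr <- x[tr_idx, , drop = FALSE]; ytr <- y[tr_idx, , drop = FALSE]
  xva <- x[val_idx, , drop = FALSE]; yva <- y[val_idx, , drop = FALSE]
  init_state <- function(s) {
    params <- cam_init(arch, ncol(y), seed = derive_seed(seed, 10L + s))
    if (loss == "mse") params$out_b <- log(colMeans(y) + 1e-8)
    list(params = params, state = adam_state(params), lr = lr, base_lr = lr,
         best = list(val = Inf, params = params, epoch = 0L),
         since_best = 0L, since_lr = 0L, stopped = FALSE,
         restarts_left = 0L,
         curve = tibble(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0)))
  }
  n_starts <- max(1L, n_starts)
  phase1 <- min(start_epochs, epochs)
  starts <- lapply(seq_len(n_starts), function(s) {
    cam_train_phase(init_state(s), xtr, ytr, xva, yva, arch, loss,
                    epochs = phase1, batch = batch, lr = lr, warmup = warmup,
                    patience = patience, lr_patience = lr_patience,
                    lr_factor = lr_factor, min_lr = min_lr, clip = clip,
                    seed = derive_seed(seed, 20L + s))
  })
  vals <- vapply(starts, function(s) s$best$val, numeric(1))
  pick <- which.min(vals)
  if (verbose) {
    message(sprintf("multi-start validation losses: %s; continuing start %d",
                    paste(sprintf("%.4g", vals), collapse = ", "), pick))
  }
  st <- starts[[pick]]
  st$restarts_left <- as.integer(plateau_restarts)
  if (!st$stopped && epochs > phase1) {
    st <- cam_train_phase(st, xtr, ytr, xva, yva, arch, loss,
                          epochs = epochs - phase1, batch = batch, lr = lr,
                          warmup = warmup, patience = patience,
                          lr_patience = lr_patience, lr_factor = lr_factor,
                          min_lr = min_lr, clip = clip,
                          seed = derive_seed(seed, 20L + pick),
                          epoch_offset = phase1)
  }
  list(params = st$best$params, arch = arch, loss = loss, curve = st$curve,
       best_epoch = st$best$epoch, val_loss = st$best$val,
       n_starts = n_starts, picked_start = pick)
}

cam_predict <- function(fit, x, chunk = 512L) {
  n <- nrow(x)
  out <- NULL
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    fw <- cam_forward(fit$params, x[st:en, , drop = FALSE], fit$arch)
    out <- rbind(out, fw$probs)
  }
  out
}
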