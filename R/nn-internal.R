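# Internal neural-network machinery: im2col convolutions, batch
# normalization, global max pooling, multi-head outputs, Adam. Everything
# is plain matrix algebra so training stays deterministic under set.seed().

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.99
PROB_EPS <- 1e-7

# Gather geometry for one conv layer. Positions are ordered column-major
# over the (Hout, Wout) output grid; a sentinel index (H*W + 1) addresses
# an all-zero padding row appended to the input plane.
.conv_geom <- function(H, W, k, s) {
  pad <- (k - 1) %/% 2
  Hout <- (H + 2L * pad - k) %/% s + 1L
  Wout <- (W + 2L * pad - k) %/% s + 1L
  npos <- Hout * Wout
  sentinel <- H * W + 1L
  ro <- rep(seq_len(Hout), times = Wout)
  co <- rep(seq_len(Wout), each = Hout)
  G <- matrix(sentinel, npos, k * k)
  j <- 0L
  for (uc in seq_len(k)) {
    for (ur in seq_len(k)) {
      j <- j + 1L
      r <- (ro - 1L) * s + ur - pad
      c_ <- (co - 1L) * s + uc - pad
      ok <- r >= 1L & r <= H & c_ >= 1L & c_ <= W
      G[ok, j] <- r[ok] + (c_[ok] - 1L) * H
    }
  }
  list(G = G, H = H, W = W, Hout = Hout, Wout = Wout, npos = npos,
       k2 = k * k, cache = new.env(parent = emptyenv()))
}

# Gather indices are pure functions of (geometry, batch size); memoise them
# in the geometry's environment so repeated minibatches reuse them.
.gather_idx_cached <- function(geom, B) {
  key <- paste0("B", B)
  got <- geom$cache[[key]]
  if (is.null(got)) {
    got <- lapply(seq_len(geom$k2), function(j) .batch_gather_idx(geom, j, B))
    geom$cache[[key]] <- got
  }
  got
}

# Batch gather indices for kernel offset j. The minibatch is one
# ((B*npix + 1) x Cin) row-stacked matrix (sample-b rows contiguous, last
# row the all-zero padding sentinel); the result indexes the patch pixel j
# of every output position of every sample, in (position, sample) order.
.batch_gather_idx <- function(geom, j, B) {
  base <- geom$G[, j]
  npix <- geom$H * geom$W
  out <- rep(base, B) + rep.int((seq_len(B) - 1L) * npix, rep.int(geom$npos, B))
  out[rep.int(base > npix, B)] <- B * npix + 1L
  out
}

# im2col by cbind of per-offset gathers (no array transposition): column
# block j holds the Cin input channels at kernel offset j, so conv weights
# are stored with rows ordered (j-1)*Cin + c. One fat matmul per layer.
.conv_forward <- function(X, W, geom, B, cin, keep = FALSE) {
  gidx <- .gather_idx_cached(geom, B)
  Xcol <- do.call(cbind, lapply(gidx, function(gj) X[gj, , drop = FALSE]))
  Z <- Xcol %*% W
  list(Z = Z, Xcol = if (keep) Xcol else NULL, gidx = if (keep) gidx else NULL)
}

# Conv gradients. For a fixed kernel offset the output-to-input pixel map
# is injective, so the scatter back onto the (row-stacked) input planes is
# a plain indexed add per offset; only padding-sentinel entries are
# dropped.
.conv_backward <- function(dZ, W, cache, geom, B, cin, need_dx = TRUE) {
  dW <- crossprod(cache$Xcol, dZ)
  if (!need_dx) return(list(dW = dW, dX = NULL))
  dXcol <- dZ %*% t(W)
  npixB <- B * geom$H * geom$W
  dX <- matrix(0, npixB, cin)
  for (j in seq_len(geom$k2)) {
    cols <- ((j - 1L) * cin + 1L):(j * cin)
    gj <- cache$gidx[[j]]
    ok <- gj <= npixB
    idx <- gj[ok]
    dX[idx, ] <- dX[idx, , drop = FALSE] + dXcol[ok, cols, drop = FALSE]
  }
  list(dW = dW, dX = dX)
}

.bn_forward <- function(Z, gamma, beta, run_mean, run_var, train) {
  N <- nrow(Z)
  if (train) {
    mu <- colMeans(Z)
    Zc <- Z - rep(mu, each = N)
    va <- colMeans(Zc * Zc)
  } else {
    mu <- run_mean
    va <- run_var
    Zc <- Z - rep(mu, each = N)
  }
  invstd <- 1 / sqrt(va + BN_EPS)
  xhat <- Zc * rep(invstd, each = N)
  Y <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  list(Y = Y, xhat = xhat, invstd = invstd, mu = mu, va = va)
}

.bn_backward <- function(dY, cache, gamma) {
  N <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = N)
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * xhat)
  dZ <- (dxhat - rep(t1 / N, each = N) - xhat * rep(t2 / N, each = N)) *
    rep(cache$invstd, each = N)
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

.softmax_rows <- function(Z) {
  m <- apply(Z, 1, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.clip_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

# Forward pass through the trunk and heads.
# planes: list of B ((128*128) x Cin) matrices (coords appended).
# Returns outputs plus caches when `train`.
.net_forward <- function(model, planes, train = FALSE, dropout = 0) {
  p <- model$params
  bn <- model$bn
  geoms <- model$geoms
  B <- length(planes)
  cin <- ncol(planes[[1]])
  X <- rbind(do.call(rbind, planes), 0)
  caches <- vector("list", length(geoms))
  A <- NULL
  for (l in seq_along(geoms)) {
    g <- geoms[[l]]
    cv <- .conv_forward(X, p[[paste0("conv", l, ".W")]], g, B, cin,
                        keep = train)
    bnc <- .bn_forward(
      cv$Z, p[[paste0("conv", l, ".gamma")]], p[[paste0("conv", l, ".beta")]],
      bn[[paste0("conv", l, ".mean")]], bn[[paste0("conv", l, ".var")]],
      train
    )
    A <- bnc$Y * (bnc$Y > 0)
    caches[[l]] <- if (train) {
      list(Xcol = cv$Xcol, gidx = cv$gidx, bn = bnc, mask = bnc$Y > 0,
           cin = cin)
    } else NULL
    cin <- ncol(A)
    if (l < length(geoms)) X <- rbind(A, 0)
  }
  # global max pool over the last feature map
  lastg <- geoms[[length(geoms)]]
  npos <- lastg$npos
  Fdim <- ncol(A)
  P <- matrix(0, B, Fdim)
  arg <- matrix(1L, B, Fdim)
  for (b in seq_len(B)) {
    blk <- A[((b - 1) * npos + 1):(b * npos), , drop = FALSE]
    am <- max.col(t(blk), ties.method = "first")
    arg[b, ] <- am
    P[b, ] <- blk[cbind(am, seq_len(Fdim))]
  }
  dmask <- NULL
  Pd <- P
  if (train && dropout > 0) {
    dmask <- matrix(
      (stats::runif(B * Fdim) >= dropout) / (1 - dropout), B, Fdim
    )
    Pd <- P * dmask
  }
  z_fp <- Pd %*% p$fp.W + rep(p$fp.b, each = B)
  z_cl <- Pd %*% p$class.W + rep(p$class.b, each = B)
  z_mw <- as.vector(Pd %*% p$mw.W) + p$mw.b
  z_gl <- as.vector(Pd %*% p$gly.W) + p$gly.b
  list(
    fp = .sigmoid(z_fp),
    class_probs = .softmax_rows(z_cl),
    mw = exp(pmin(pmax(z_mw, -20), 20)),
    gly = .sigmoid(z_gl),
    Pd = Pd, dmask = dmask, arg = arg, caches = caches,
    last_npos = lastg$npos, Fdim = Fdim, B = B
  )
}

# Loss and gradients at the heads. truth: list(Yfp (B x nbits), class (B),
# mw (B), gly (B)). Returns loss components and dPd.
.head_loss_grads <- function(fw, truth, w) {
  B <- fw$B
  nb <- ncol(fw$fp)
  p_fp <- .clip_prob(fw$fp)
  L_fp <- -mean(truth$Yfp * log(p_fp) + (1 - truth$Yfp) * log(1 - p_fp))
  d_fp <- (fw$fp - truth$Yfp) / (B * nb)

  pc <- fw$class_probs
  idx <- cbind(seq_len(B), truth$class)
  L_cl <- -mean(log(.clip_prob(pc[idx])))
  d_cl <- pc / B
  d_cl[idx] <- d_cl[idx] - 1 / B

  mwp <- fw$mw
  L_mw <- mean(100 * abs(mwp - truth$mw) / truth$mw)
  d_zmw <- 100 * sign(mwp - truth$mw) / truth$mw * mwp / B

  p_gl <- .clip_prob(fw$gly)
  yg <- as.numeric(truth$gly)
  L_gl <- -mean(yg * log(p_gl) + (1 - yg) * log(1 - p_gl))
  d_zgl <- (fw$gly - yg) / B

  list(
    loss = w[["fp"]] * L_fp + w[["class"]] * L_cl +
      w[["mw"]] * L_mw + w[["gly"]] * L_gl,
    parts = c(fp = L_fp, class = L_cl, mw = L_mw, gly = L_gl),
    d_fp = w[["fp"]] * d_fp, d_cl = w[["class"]] * d_cl,
    d_zmw = w[["mw"]] * d_zmw, d_zgl = w[["gly"]] * d_zgl
  )
}

# Full backward pass; returns gradient list keyed like model$params.
.net_backward <- function(model, fw, hg) {
  p <- model$params
  B <- fw$B
  grads <- list()
  grads$fp.W <- crossprod(fw$Pd, hg$d_fp)
  grads$fp.b <- colSums(hg$d_fp)
  grads$class.W <- crossprod(fw$Pd, hg$d_cl)
  grads$class.b <- colSums(hg$d_cl)
  grads$mw.W <- crossprod(fw$Pd, matrix(hg$d_zmw, ncol = 1))
  grads$mw.b <- sum(hg$d_zmw)
  grads$gly.W <- crossprod(fw$Pd, matrix(hg$d_zgl, ncol = 1))
  grads$gly.b <- sum(hg$d_zgl)

  dPd <- hg$d_fp %*% t(p$fp.W) + hg$d_cl %*% t(p$class.W) +
    matrix(hg$d_zmw, ncol = 1) %*% t(p$mw.W) +
    matrix(hg$d_zgl, ncol = 1) %*% t(p$gly.W)
  if (!is.null(fw$dmask)) dPd <- dPd * fw$dmask

  # un-pool: route each pooled gradient to its argmax position
  npos <- fw$last_npos
  Fdim <- fw$Fdim
  dA <- matrix(0, B * npos, Fdim)
  garg <- fw$arg + (seq_len(B) - 1L) * npos
  dA[cbind(as.vector(garg), rep(seq_len(Fdim), each = B))] <- as.vector(dPd)

  geoms <- model$geoms
  for (l in rev(seq_along(geoms))) {
    cache <- fw$caches[[l]]
    dY <- dA * cache$mask
    bb <- .bn_backward(dY, cache$bn, p[[paste0("conv", l, ".gamma")]])
    grads[[paste0("conv", l, ".gamma")]] <- bb$dgamma
    grads[[paste0("conv", l, ".beta")]] <- bb$dbeta
    Wk <- paste0("conv", l, ".W")
    cb <- .conv_backward(bb$dZ, p[[Wk]], cache, geoms[[l]], B, cache$cin,
                         need_dx = l > 1)
    grads[[Wk]] <- cb$dW
    if (l > 1) dA <- cb$dX
  }
  grads
}

# Update batch-norm running statistics from a training forward pass.
.bn_update <- function(model, fw) {
  for (l in seq_along(model$geoms)) {
    bnc <- fw$caches[[l]]$bn
    km <- paste0("conv", l, ".mean")
    kv <- paste0("conv", l, ".var")
    model$bn[[km]] <- BN_MOMENTUM * model$bn[[km]] + (1 - BN_MOMENTUM) * bnc$mu
    model$bn[[kv]] <- BN_MOMENTUM * model$bn[[kv]] + (1 - BN_MOMENTUM) * bnc$va
  }
  model
}

.adam_init <- function(params) {
  list(
    m = lapply(params, function(x) x * 0),
    v = lapply(params, function(x) x * 0),
    t = 0L
  )
}

.adam_step <- function(params, grads, state, lr, decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  lr_t <- lr / (1 + decay * state$t)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr_t * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Convert an hsqc_image (or raw array) to the plane matrix the net eats,
# appending normalized coordinate channels when configured.
.image_planes <- function(img, cfg) {
  grid <- if (inherits(img, "hsqc_image")) img$grid else img
  d <- dim(grid)
  if (length(d) != 3 || d[1] != IMG_SIZE || d[2] != IMG_SIZE) {
    abort("image must be a 128 x 128 x C array")
  }
  if (d[3] != cfg$channels) {
    abort(sprintf(
      "image has %d channel(s) but the model expects %d", d[3], cfg$channels
    ))
  }
  X <- matrix(grid, IMG_SIZE * IMG_SIZE, d[3])
  if (isTRUE(cfg$coord_channels)) {
    r <- (rep(seq_len(IMG_SIZE), times = IMG_SIZE) - 1) / (IMG_SIZE - 1)
    c_ <- (rep(seq_len(IMG_SIZE), each = IMG_SIZE) - 1) / (IMG_SIZE - 1)
    X <- cbind(X, r, c_)
  }
  unname(X)
}
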