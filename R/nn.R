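# Minimal vectorized neural-network layers for the tied backbone and the
# relation head. Tensors are 4-D arrays dim = (N, H, W, C); every heavy step
# is a BLAS matrix product, so batches of a few hundred 16x16 patches train
# in seconds on one CPU.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9  # running-statistics decay

# ---- convolution (3x3, same padding) ---------------------------------------

# weights W have dim (3, 3, Cin, Cout); as a gemm operand they are reshaped
# to (9 * Cin, Cout) with the 9 kernel offsets as the fastest-varying index
# of the im2col column blocks built below.
conv_forward <- function(X, W, b) {
  d <- dim(X); N <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Cout <- dim(W)[4]
  Xp <- array(0, c(N, H + 2L, Wd + 2L, Cin))
  Xp[, 2:(H + 1L), 2:(Wd + 1L), ] <- X
  M <- N * H * Wd
  cols <- matrix(0, M, 9L * Cin)
  j <- 0L
  for (cc in seq_len(Cin)) for (dx in 0:2) for (dy in 0:2) {
    j <- j + 1L
    cols[, j] <- Xp[, (1L + dy):(H + dy), (1L + dx):(Wd + dx), cc]
  }
  Wm <- matrix(W, 9L * Cin, Cout)
  out <- cols %*% Wm + matrix(b, M, Cout, byrow = TRUE)
  list(out = array(out, c(N, H, Wd, Cout)), cols = cols,
       in_dim = d)
}

conv_backward <- function(dOut, cache, W) {
  d <- dim(dOut); N <- d[1]; H <- d[2]; Wd <- d[3]; Cout <- d[4]
  Cin <- cache$in_dim[4]
  M <- N * H * Wd
  dOut_m <- matrix(dOut, M, Cout)
  Wm <- matrix(W, 9L * Cin, Cout)
  dW <- array(crossprod(cache$cols, dOut_m), dim(W))
  dCols <- dOut_m %*% t(Wm)
  dXp <- array(0, c(N, H + 2L, Wd + 2L, Cin))
  j <- 0L
  for (cc in seq_len(Cin)) for (dx in 0:2) for (dy in 0:2) {
    j <- j + 1L
    ys <- (1L + dy):(H + dy); xs <- (1L + dx):(Wd + dx)
    dXp[, ys, xs, cc] <- dXp[, ys, xs, cc, drop = FALSE] +
      array(dCols[, j], c(N, H, Wd, 1L))
  }
  list(dX = dXp[, 2:(H + 1L), 2:(Wd + 1L), , drop = FALSE],
       dW = dW, db = colSums(dOut_m))
}

# ---- batch normalization (per channel over N, H, W) ------------------------

bn_forward <- function(X, gamma, beta, running, train) {
  d <- dim(X); C <- d[4]; M <- prod(d[1:3])
  Xm <- matrix(X, M, C)
  if (train) {
    mu <- colMeans(Xm)
    var <- colMeans(Xm^2) - mu^2
    running$mean <- BN_MOMENTUM * running$mean + (1 - BN_MOMENTUM) * mu
    running$var <- BN_MOMENTUM * running$var + (1 - BN_MOMENTUM) * var
  } else {
    mu <- running$mean
    var <- running$var
  }
  inv <- 1 / sqrt(var + BN_EPS)
  xhat <- (Xm - rep(mu, each = M)) * rep(inv, each = M)
  Y <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  list(out = array(Y, d), xhat = xhat, inv = inv, running = running, dims = d)
}

bn_backward <- function(dOut, cache, gamma) {
  d <- cache$dims; C <- d[4]; M <- prod(d[1:3])
  dY <- matrix(dOut, M, C)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  # standard batch-norm gradient with biased batch variance
  t1 <- dY - rep(dbeta / M, each = M) -
    cache$xhat * rep(dgamma / M, each = M)
  dX <- t1 * rep(gamma * cache$inv, each = M)
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU ------------------------------------------------------------------

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

relu_backward <- function(dOut, cache) dOut * cache$mask

# ---- 2x2 max pooling, stride 2 (odd trailing row/col dropped) --------------

pool_forward <- function(X) {
  d <- dim(X); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  ys <- seq.int(1L, by = 2L, length.out = H2)
  xs <- seq.int(1L, by = 2L, length.out = W2)
  s <- list(
    X[, ys, xs, , drop = FALSE], X[, ys, xs + 1L, , drop = FALSE],
    X[, ys + 1L, xs, , drop = FALSE], X[, ys + 1L, xs + 1L, , drop = FALSE]
  )
  out <- s[[1]]; arg <- array(1L, dim(out))
  for (j in 2:4) {
    upd <- s[[j]] > out
    out[upd] <- s[[j]][upd]
    arg[upd] <- j
  }
  list(out = out, arg = arg, in_dim = d, ys = ys, xs = xs)
}

pool_backward <- function(dOut, cache) {
  dX <- array(0, cache$in_dim)
  ys <- cache$ys; xs <- cache$xs
  off <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  for (j in 1:4) {
    g <- dOut * (cache$arg == j)
    dX[, ys + off[[j]][1], xs + off[[j]][2], ] <-
      dX[, ys + off[[j]][1], xs + off[[j]][2], , drop = FALSE] + g
  }
  dX
}

# ---- global average pooling ------------------------------------------------

gap_forward <- function(X) {
  d <- dim(X); N <- d[1]; P <- d[2] * d[3]; C <- d[4]
  X3 <- array(X, c(N, P, C))
  feat <- matrix(colMeans(matrix(aperm(X3, c(2, 1, 3)), P, N * C)), N, C)
  list(out = feat, in_dim = d)
}

gap_backward <- function(dOut, cache) {
  d <- cache$in_dim; N <- d[1]; P <- d[2] * d[3]; C <- d[4]
  # broadcast dFeat / P over the spatial positions
  g3 <- aperm(array(t(dOut) / P, c(C, N, P)), c(2, 3, 1))
  array(g3, d)
}

# ---- fully connected -------------------------------------------------------

fc_forward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2, b, `+`), X = X)
}

fc_backward <- function(dOut, cache, W) {
  list(dX = dOut %*% t(W), dW = crossprod(cache$X, dOut), db = colSums(dOut))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- parameter containers --------------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

init_backbone <- function(channels = 32L) {
  blocks <- list()
  cin <- 1L
  for (i in 1:3) {
    blocks[[i]] <- list(
      W = he_init(c(3, 3, cin, channels), 9 * cin),
      b = numeric(channels),
      gamma = rep(1, channels),
      beta = numeric(channels),
      running = list(mean = numeric(channels), var = rep(1, channels))
    )
    cin <- channels
  }
  structure(list(blocks = blocks, channels = channels),
            class = "backbone_params")
}

init_head <- function(in_dim = 32L, hidden = c(64L, 64L)) {
  structure(list(
    W1 = he_init(c(in_dim, hidden[1]), in_dim), b1 = numeric(hidden[1]),
    W2 = he_init(c(hidden[1], hidden[2]), hidden[1]), b2 = numeric(hidden[2]),
    W3 = he_init(c(hidden[2], 2L), hidden[2]), b3 = numeric(2L),
    hidden = as.integer(hidden)
  ), class = "head_params")
}

# ---- backbone forward/backward over a batch --------------------------------

backbone_forward <- function(params, X, train = FALSE) {
  caches <- vector("list", 3)
  A <- X
  for (i in 1:3) {
    bl <- params$blocks[[i]]
    cv <- conv_forward(A, bl$W, bl$b)
    bn <- bn_forward(cv$out, bl$gamma, bl$beta, bl$running, train)
    if (train) params$blocks[[i]]$running <- bn$running
    rl <- relu_forward(bn$out)
    pl <- pool_forward(rl$out)
    caches[[i]] <- list(cv = cv, bn = bn, rl = rl, pl = pl)
    A <- pl$out
  }
  gp <- gap_forward(A)
  list(features = gp$out, caches = caches, gap = gp, params = params)
}

backbone_backward <- function(params, fwd, dFeat) {
  grads <- vector("list", 3)
  dA <- gap_backward(dFeat, fwd$gap)
  for (i in 3:1) {
    ch <- fwd$caches[[i]]
    bl <- params$blocks[[i]]
    dA <- pool_backward(dA, ch$pl)
    dA <- relu_backward(dA, ch$rl)
    bnb <- bn_backward(dA, ch$bn, bl$gamma)
    cvb <- conv_backward(bnb$dX, ch$cv, bl$W)
    grads[[i]] <- list(dW = cvb$dW, db = cvb$db, dgamma = bnb$dgamma,
                       dbeta = bnb$dbeta)
    dA <- cvb$dX
  }
  grads
}

head_forward <- function(head, V) {
  f1 <- fc_forward(V, head$W1, head$b1); r1 <- relu_forward(f1$out)
  f2 <- fc_forward(r1$out, head$W2, head$b2); r2 <- relu_forward(f2$out)
  f3 <- fc_forward(r2$out, head$W3, head$b3)
  probs <- softmax_rows(f3$out)
  list(probs = probs, logits = f3$out, f1 = f1, r1 = r1, f2 = f2, r2 = r2,
       f3 = f3)
}

head_backward <- function(head, fwd, dLogits) {
  g3 <- fc_backward(dLogits, fwd$f3, head$W3)
  d2 <- relu_backward(g3$dX, fwd$r2)
  g2 <- fc_backward(d2, fwd$f2, head$W2)
  d1 <- relu_backward(g2$dX, fwd$r1)
  g1 <- fc_backward(d1, fwd$f1, head$W1)
  list(dV = g1$dX,
       dW1 = g1$dW, db1 = g1$db, dW2 = g2$dW, db2 = g2$db,
       dW3 = g3$dW, db3 = g3$db)
}
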