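# Minimal neural-network engine on base matrix operations.
#
# Tensors are numeric arrays with dim c(B, W, C): batch, sequence position,
# channel. Convolutions go through im2col + BLAS matrix multiply; every
# primitive has an explicit backward pass. Correctness is pinned down by
# numerical gradient-check tests.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

# --- conv1d (stride 1, 'same' zero padding, odd kernel) ---------------------

conv1d_init <- function(k, c_in, c_out) {
  list(W = .rnorm_mat(k * c_in, c_out, sd = sqrt(2 / (k * c_in))),
       b = numeric(c_out), k = k, c_in = c_in, c_out = c_out)
}

# 'same' padding: k-1 zeros split (k-1)%/%2 left, rest right (symmetric for
# odd kernels, one extra on the right for even ones)
.im2col <- function(x, k) {
  d <- dim(x); B <- d[1]; W <- d[2]; C <- d[3]
  p <- (k - 1) %/% 2
  xp <- array(0, c(B, W + k - 1, C))
  xp[, (p + 1):(p + W), ] <- x
  cols <- array(0, c(B, W, k * C))
  for (j in seq_len(k))
    cols[, , ((j - 1) * C + 1):(j * C)] <- xp[, j:(j + W - 1), , drop = FALSE]
  dim(cols) <- c(B * W, k * C)
  cols
}

conv1d_forward <- function(layer, x) {
  d <- dim(x); B <- d[1]; W <- d[2]
  Xm <- .im2col(x, layer$k)
  Y <- Xm %*% layer$W
  Y <- Y + rep(layer$b, each = B * W)
  dim(Y) <- c(B, W, layer$c_out)
  list(y = Y, cache = list(Xm = Xm, B = B, W = W))
}

conv1d_backward <- function(layer, cache, dY) {
  B <- cache$B; W <- cache$W; k <- layer$k; C <- layer$c_in
  dim(dY) <- c(B * W, layer$c_out)
  dW <- crossprod(cache$Xm, dY)
  db <- colSums(dY)
  dcols <- tcrossprod(dY, layer$W)          # (B*W, k*C)
  dim(dcols) <- c(B, W, k * C)
  p <- (k - 1) %/% 2
  dxp <- array(0, c(B, W + k - 1, C))
  for (j in seq_len(k)) {
    sl <- ((j - 1) * C + 1):(j * C)
    dxp[, j:(j + W - 1), ] <- dxp[, j:(j + W - 1), , drop = FALSE] +
      dcols[, , sl, drop = FALSE]
  }
  dx <- dxp[, (p + 1):(p + W), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# --- elementwise / pooling ---------------------------------------------------

relu_forward <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_backward <- function(mask, dY) { dY[!mask] <- 0; dY }

maxpool2_forward <- function(x) {
  d <- dim(x); W <- d[2]
  stopifnot(W %% 2 == 0)
  odd <- seq(1, W, 2); even <- seq(2, W, 2)
  a <- x[, odd, , drop = FALSE]; b <- x[, even, , drop = FALSE]
  m <- a >= b                     # ties go to the earlier position
  y <- a; y[!m] <- b[!m]
  list(y = y, cache = list(m = m, d = d))
}

maxpool2_backward <- function(cache, dY) {
  d <- cache$d; m <- cache$m
  odd <- seq(1, d[2], 2); even <- seq(2, d[2], 2)
  dx <- array(0, d)
  da <- dY; da[!m] <- 0
  db <- dY; db[m] <- 0
  dx[, odd, ] <- da
  dx[, even, ] <- db
  dx
}

upsample2_forward <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1], 2 * d[2], d[3]))
  odd <- seq(1, 2 * d[2], 2)
  y[, odd, ] <- x
  y[, odd + 1, ] <- x
  y
}

upsample2_backward <- function(dY) {
  d <- dim(dY)
  odd <- seq(1, d[2], 2)
  dY[, odd, , drop = FALSE] + dY[, odd + 1, , drop = FALSE]
}

concat_forward <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3]))
  y[, , 1:da[3]] <- a
  y[, , (da[3] + 1):(da[3] + db[3])] <- b
  list(y = y, c1 = da[3])
}

concat_backward <- function(dY, c1) {
  list(da = dY[, , 1:c1, drop = FALSE],
       db = dY[, , (c1 + 1):dim(dY)[3], drop = FALSE])
}

# --- embedding / one-hot input ----------------------------------------------
# Index 0 is padding; embedding row for padding is frozen at zero.

embedding_init <- function(n_tokens, d) {
  E <- .rnorm_mat(n_tokens + 1, d, sd = 0.05)   # row 1 = padding
  E[1, ] <- 0
  E
}

embedding_forward <- function(E, idx) {
  B <- nrow(idx); W <- ncol(idx)
  iv <- as.vector(idx) + 1L
  X <- E[iv, , drop = FALSE]
  dim(X) <- c(B, W, ncol(E))
  list(y = X, iv = iv)
}

embedding_backward <- function(E, iv, dY) {
  dim(dY) <- c(length(iv), ncol(E))
  dE <- matrix(0, nrow(E), ncol(E))
  agg <- rowsum(dY, group = iv)
  dE[as.integer(rownames(agg)), ] <- agg
  dE[1, ] <- 0                                  # padding row stays zero
  dE
}

onehot_input <- function(idx, n_channels) {
  B <- nrow(idx); W <- ncol(idx)
  x <- array(0, c(B, W, n_channels))
  nz <- which(idx > 0)
  if (length(nz)) {
    b <- ((nz - 1) %% B) + 1
    w <- ((nz - 1) %/% B) + 1
    x[cbind(b, w, as.vector(idx)[nz])] <- 1
  }
  x
}

# --- dense / softmax ---------------------------------------------------------

dense_init <- function(c_in, c_out) {
  list(W = .rnorm_mat(c_in, c_out, sd = sqrt(2 / c_in)), b = numeric(c_out))
}

dense_forward <- function(layer, x) {
  y <- x %*% layer$W
  y + rep(layer$b, each = nrow(x))
}

dense_backward <- function(layer, x, dY) {
  list(dx = tcrossprod(dY, layer$W), dW = crossprod(x, dY), db = colSums(dY))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy over a (n, n_classes) probability matrix with integer
# targets in 1..n_classes and per-row weights; returns loss and dlogits.
ce_loss_grad <- function(probs, target, weight = NULL) {
  n <- nrow(probs)
  if (is.null(weight)) weight <- rep(1, n)
  wsum <- sum(weight)
  picked <- probs[cbind(seq_len(n), target)]
  loss <- -sum(weight * log(pmax(picked, 1e-12))) / wsum
  dlogits <- probs
  dlogits[cbind(seq_len(n), target)] <- dlogits[cbind(seq_len(n), target)] - 1
  dlogits <- dlogits * (weight / wsum)
  list(loss = loss, dlogits = dlogits)
}

# --- LSTM --------------------------------------------------------------------
# Gate order i, f, g, o; forget-gate bias initialized to 1.

lstm_init <- function(d_in, H) {
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1
  list(Wx = .rnorm_mat(d_in, 4 * H, sd = sqrt(1 / d_in)),
       Wh = .rnorm_mat(H, 4 * H, sd = sqrt(1 / H)),
       b = b, H = H, d_in = d_in)
}

lstm_forward <- function(layer, x, mask) {
  d <- dim(x); B <- d[1]; W <- d[2]; H <- layer$H
  h <- matrix(0, B, H); cs <- matrix(0, B, H)
  caches <- vector("list", W)
  bmat <- rep(layer$b, each = B)
  for (t in seq_len(W)) {
    xt <- x[, t, , drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, B, d[3])
    z <- xt %*% layer$Wx + h %*% layer$Wh + bmat
    ii <- .sigmoid(z[, 1:H, drop = FALSE])
    ff <- .sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    oo <- .sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cnew <- ff * cs + ii * gg
    tc <- tanh(cnew)
    hnew <- oo * tc
    m <- mask[, t]
    caches[[t]] <- list(xt = xt, hprev = h, cprev = cs, i = ii, f = ff,
                        g = gg, o = oo, tc = tc, m = m)
    h <- hnew * m + h * (1 - m)
    cs <- cnew * m + cs * (1 - m)
  }
  list(h = h, caches = caches)
}

lstm_backward <- function(layer, caches, dh_final) {
  W <- length(caches); H <- layer$H
  dWx <- matrix(0, nrow(layer$Wx), ncol(layer$Wx))
  dWh <- matrix(0, nrow(layer$Wh), ncol(layer$Wh))
  db <- numeric(4 * H)
  dh <- dh_final
  dc <- matrix(0, nrow(dh_final), H)
  dx <- array(0, c(nrow(dh_final), W, layer$d_in))
  for (t in rev(seq_len(W))) {
    cc <- caches[[t]]
    m <- cc$m
    dh_new <- dh * m; dh_skip <- dh * (1 - m)
    dc_new <- dc * m; dc_skip <- dc * (1 - m)
    do_ <- dh_new * cc$tc
    dc_new <- dc_new + dh_new * cc$o * (1 - cc$tc^2)
    di <- dc_new * cc$g
    df <- dc_new * cc$cprev
    dg <- dc_new * cc$i
    dc_prev <- dc_new * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$xt, dz)
    dWh <- dWh + crossprod(cc$hprev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- tcrossprod(dz, layer$Wx)
    dh <- tcrossprod(dz, layer$Wh) + dh_skip
    dc <- dc_prev + dc_skip
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
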