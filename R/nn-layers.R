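# Low-level 1-D network layers with hand-written reverse-mode gradients.
#
# Signals are channels x samples matrices. Convolution weights are stored as
# (out_ch, in_ch, k) arrays; transposed-convolution weights as (in_ch, out_ch, k)
# so that trainable-parameter counts follow the in*out*k + out convention.

#' Output length of a 1-D convolution
#'
#' `floor((L + pad_l + pad_r - d*(k-1) - 1)/s) + 1`.
#' @keywords internal
#' @noRd
conv1d_out_len <- function(L, k, s, d, pad_l, pad_r = pad_l) {
  (L + pad_l + pad_r - d * (k - 1L) - 1L) %/% s + 1L
}

#' Output length of a 1-D transposed convolution
#'
#' `(L - 1)*s - 2*p + d*(k-1) + op + 1`.
#' @keywords internal
#' @noRd
tconv1d_out_len <- function(L, k, s, d, p, op) {
  (L - 1L) * s - 2L * p + d * (k - 1L) + op + 1L
}

# Convolution weights are stored as a list of k per-tap matrices
# (out_ch x in_ch each; in_ch x out_ch for transposed convolutions), which
# keeps the per-tap matrix products allocation-free.

conv1d_forward <- function(X, W, b, s, d, pad_l, pad_r = pad_l) {
  Cin <- nrow(X); L <- ncol(X)
  k <- length(W)
  Lp <- L + pad_l + pad_r
  Xp <- matrix(0, Cin, Lp)
  Xp[, (pad_l + 1L):(pad_l + L)] <- X
  Lout <- conv1d_out_len(L, k, s, d, pad_l, pad_r)
  Y <- matrix(b, nrow(W[[1L]]), Lout)
  base <- (0:(Lout - 1L)) * s
  for (j in seq_len(k)) {
    cols <- base + (j - 1L) * d + 1L
    Y <- Y + W[[j]] %*% Xp[, cols, drop = FALSE]
  }
  list(out = Y, cache = list(Xp = Xp, L = L, s = s, d = d, k = k,
                             pad_l = pad_l, Lout = Lout))
}

conv1d_backward <- function(dY, W, cache) {
  k <- cache$k; s <- cache$s; d <- cache$d
  Xp <- cache$Xp
  Cin <- nrow(Xp)
  dW <- vector("list", k)
  dXp <- matrix(0, Cin, ncol(Xp))
  base <- (0:(cache$Lout - 1L)) * s
  for (j in seq_len(k)) {
    cols <- base + (j - 1L) * d + 1L
    dW[[j]] <- tcrossprod(dY, Xp[, cols, drop = FALSE])
    dXp[, cols] <- dXp[, cols, drop = FALSE] + crossprod(W[[j]], dY)
  }
  dX <- dXp[, (cache$pad_l + 1L):(cache$pad_l + cache$L), drop = FALSE]
  list(dX = dX, dW = dW, db = rowSums(dY))
}

tconv1d_forward <- function(X, W, b, s, d, p, op) {
  L <- ncol(X)
  k <- length(W)
  Lfull <- (L - 1L) * s + (k - 1L) * d + 1L
  Lout <- tconv1d_out_len(L, k, s, d, p, op)
  Yfull <- matrix(0, ncol(W[[1L]]), Lfull + op)
  base <- (0:(L - 1L)) * s
  for (j in seq_len(k)) {
    cols <- base + (j - 1L) * d + 1L
    Yfull[, cols] <- Yfull[, cols, drop = FALSE] + crossprod(W[[j]], X)
  }
  Y <- Yfull[, (p + 1L):(p + Lout), drop = FALSE] + b
  list(out = Y, cache = list(X = X, L = L, s = s, d = d, k = k, p = p, op = op,
                             Lfull = Lfull, Lout = Lout))
}

tconv1d_backward <- function(dY, W, cache) {
  k <- cache$k; s <- cache$s; d <- cache$d; p <- cache$p
  X <- cache$X
  Cout <- ncol(W[[1L]])
  dYfull <- matrix(0, Cout, cache$Lfull + cache$op)
  dYfull[, (p + 1L):(p + cache$Lout)] <- dY
  dW <- vector("list", k)
  dX <- matrix(0, nrow(X), ncol(X))
  base <- (0:(cache$L - 1L)) * s
  for (j in seq_len(k)) {
    cols <- base + (j - 1L) * d + 1L
    dYc <- dYfull[, cols, drop = FALSE]
    dW[[j]] <- tcrossprod(X, dYc)
    dX <- dX + W[[j]] %*% dYc
  }
  list(dX = dX, dW = dW, db = rowSums(dY))
}

# Instance normalization: per-channel over time, learnable affine (gamma, beta).
# Population variance; epsilon keeps zero-activation channels finite.
instnorm_forward <- function(X, gamma, beta, eps = 1e-5) {
  L <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  Xhat <- Xc * inv
  Y <- Xhat * gamma + beta
  list(out = Y, cache = list(Xhat = Xhat, inv = inv, gamma = gamma, L = L))
}

instnorm_backward <- function(dY, cache) {
  Xhat <- cache$Xhat
  dgamma <- rowSums(dY * Xhat)
  dbeta <- rowSums(dY)
  dXhat <- dY * cache$gamma
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * Xhat)
  dX <- cache$inv * (dXhat - m1 - Xhat * m2)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

leakyrelu_forward <- function(X, slope = 0.2) {
  m <- (X > 0) + 0
  m[m == 0] <- slope
  list(out = X * m, cache = list(mult = m))
}

leakyrelu_backward <- function(dY, cache) {
  dY * cache$mult
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

linear_forward <- function(x, W, b) {
  list(out = drop(W %*% x) + b, cache = list(x = x))
}

linear_backward <- function(dy, W, cache) {
  list(dx = drop(crossprod(W, dy)), dW = outer(dy, cache$x), db = dy)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# fan-in scaled uniform initialization (paper silent on initialization);
# convolution kernels as per-tap matrix lists
init_taps <- function(k, nr, nc, fan_in) {
  a <- 1 / sqrt(fan_in)
  lapply(seq_len(k), function(j) matrix(stats::runif(nr * nc, -a, a), nr, nc))
}
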