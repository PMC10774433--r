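# Batched forward/backward passes for training.
#
# A batch of B windows is laid out as one channels x (B * L) matrix with each
# window occupying a contiguous column block. Convolutions use precomputed
# column index maps (per tap), so one batch costs k matrix products per layer
# regardless of B, and the weight gradient over the whole batch is a single
# tcrossprod. Instance normalization uses per-window block averaging
# matrices. Numerically identical to the per-window path in nn-layers.R
# (same operations, same order of summation per window block).

# index plan for a batched convolution layer
conv_ix <- function(L, k, s, d, pad_l, pad_r, B) {
  Lp <- L + pad_l + pad_r
  Lout <- conv1d_out_len(L, k, s, d, pad_l, pad_r)
  offs <- (0:(B - 1L)) * Lp
  idx_in <- as.vector(outer(pad_l + seq_len(L), offs, "+"))
  cols <- lapply(seq_len(k), function(j)
    as.vector(outer((0:(Lout - 1L)) * s + (j - 1L) * d + 1L, offs, "+")))
  list(L = L, Lp = Lp, Lout = Lout, B = B, k = k, idx_in = idx_in,
       cols = cols)
}

# index plan for a batched transposed convolution layer
tconv_ix <- function(L, k, s, d, p, op, B) {
  Lfull <- (L - 1L) * s + (k - 1L) * d + 1L
  Lout <- tconv1d_out_len(L, k, s, d, p, op)
  W_full <- Lfull + op
  offs <- (0:(B - 1L)) * W_full
  cols <- lapply(seq_len(k), function(j)
    as.vector(outer((0:(L - 1L)) * s + (j - 1L) * d + 1L, offs, "+")))
  idx_out <- as.vector(outer(p + seq_len(Lout), offs, "+"))
  list(L = L, W_full = W_full, Lout = Lout, B = B, k = k, cols = cols,
       idx_out = idx_out)
}

# block-averaging matrix: (B*L) x B, column b averages window b
block_avg <- function(L, B) {
  A <- matrix(0, B * L, B)
  for (b in seq_len(B)) A[((b - 1L) * L + 1L):(b * L), b] <- 1 / L
  A
}

conv1d_forward_b <- function(X, W, b, ix) {
  Cin <- nrow(X)
  Xp <- matrix(0, Cin, ix$B * ix$Lp)
  Xp[, ix$idx_in] <- X
  Y <- matrix(b, nrow(W[[1L]]), ix$B * ix$Lout)
  for (j in seq_len(ix$k))
    Y <- Y + W[[j]] %*% Xp[, ix$cols[[j]], drop = FALSE]
  list(out = Y, cache = Xp)
}

conv1d_backward_b <- function(dY, W, Xp, ix) {
  dW <- vector("list", ix$k)
  dXp <- matrix(0, nrow(Xp), ncol(Xp))
  for (j in seq_len(ix$k)) {
    cl <- ix$cols[[j]]
    dW[[j]] <- tcrossprod(dY, Xp[, cl, drop = FALSE])
    dXp[, cl] <- dXp[, cl, drop = FALSE] + crossprod(W[[j]], dY)
  }
  list(dX = dXp[, ix$idx_in, drop = FALSE], dW = dW, db = rowSums(dY))
}

tconv1d_forward_b <- function(X, W, b, ix) {
  Yfull <- matrix(0, ncol(W[[1L]]), ix$B * ix$W_full)
  for (j in seq_len(ix$k)) {
    cl <- ix$cols[[j]]
    Yfull[, cl] <- Yfull[, cl, drop = FALSE] + crossprod(W[[j]], X)
  }
  Y <- Yfull[, ix$idx_out, drop = FALSE] + b
  list(out = Y, cache = X)
}

tconv1d_backward_b <- function(dY, W, X, ix) {
  Cout <- ncol(W[[1L]])
  dYfull <- matrix(0, Cout, ix$B * ix$W_full)
  dYfull[, ix$idx_out] <- dY
  dW <- vector("list", ix$k)
  dX <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(ix$k)) {
    dYc <- dYfull[, ix$cols[[j]], drop = FALSE]
    dW[[j]] <- tcrossprod(X, dYc)
    dX <- dX + W[[j]] %*% dYc
  }
  list(dX = dX, dW = dW, db = rowSums(dY))
}

# per-window instance normalization on the batched layout
instnorm_forward_b <- function(X, gamma, beta, avg, eps = 1e-5) {
  B <- ncol(avg); L <- nrow(avg) / B
  rep_ix <- rep(seq_len(B), each = L)
  mu <- X %*% avg
  Xc <- X - mu[, rep_ix, drop = FALSE]
  v <- (Xc * Xc) %*% avg
  inv <- 1 / sqrt(v + eps)
  Xhat <- Xc * inv[, rep_ix, drop = FALSE]
  list(out = Xhat * gamma + beta,
       cache = list(Xhat = Xhat, inv = inv, gamma = gamma, avg = avg,
                    rep_ix = rep_ix))
}

instnorm_backward_b <- function(dY, cache) {
  Xhat <- cache$Xhat; rep_ix <- cache$rep_ix
  dgamma <- rowSums(dY * Xhat)
  dbeta <- rowSums(dY)
  dXhat <- dY * cache$gamma
  m1 <- (dXhat %*% cache$avg)[, rep_ix, drop = FALSE]
  m2 <- ((dXhat * Xhat) %*% cache$avg)[, rep_ix, drop = FALSE]
  dX <- cache$inv[, rep_ix, drop = FALSE] * (dXhat - m1 - Xhat * m2)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# precomputed per-layer index plans for a batch of B windows of length L0
build_batch_plan <- function(arch, B, L0 = 1920L) {
  enc <- vector("list", 8L)
  L <- L0
  for (i in seq_len(8L)) {
    l <- arch$encoder[[i]]
    ix <- conv_ix(L, l$k, l$s, l$d, l$pad_l, l$pad_r, B)
    enc[[i]] <- list(ix = ix, avg = block_avg(ix$Lout, B))
    L <- ix$Lout
  }
  dec <- vector("list", 9L)
  for (i in seq_len(9L)) {
    l <- arch$decoder[[i]]
    if (identical(l$op, "tconv")) {
      ix <- tconv_ix(L, l$k, l$s, l$d, l$p, l$op_pad, B)
      dec[[i]] <- list(ix = ix, avg = block_avg(ix$Lout, B))
    } else {
      ix <- conv_ix(L, l$k, l$s, l$d, l$pad_l, l$pad_r, B)
      dec[[i]] <- list(ix = ix)
    }
    L <- ix$Lout
  }
  list(encoder = enc, decoder = dec, B = B, L0 = L0)
}

encoder_forward_bat <- function(net, plan, Xb, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", 8L) else NULL
  skips <- vector("list", 4L)
  out <- Xb
  for (i in seq_len(8L)) {
    p <- net$encoder[[i]]
    pl <- plan$encoder[[i]]
    cv <- conv1d_forward_b(out, p$W, p$b, pl$ix)
    lr <- leakyrelu_forward(cv$out)
    nn <- instnorm_forward_b(lr$out, p$gamma, p$beta, pl$avg)
    out <- nn$out
    if (i %in% c(1L, 3L, 5L, 7L)) skips[[(i + 1L) %/% 2L]] <- out
    if (keep_cache) caches[[i]] <- list(conv = cv$cache, lrelu = lr$cache,
                                        inorm = nn$cache)
  }
  list(latent = out, skips = skips, caches = caches)
}

encoder_backward_bat <- function(net, plan, fwd, d_latent, d_skips = NULL) {
  grads <- vector("list", 8L)
  dout <- d_latent
  for (i in 8L:1L) {
    p <- net$encoder[[i]]
    pl <- plan$encoder[[i]]
    ca <- fwd$caches[[i]]
    if (i %in% c(1L, 3L, 5L, 7L) && !is.null(d_skips)) {
      ds <- d_skips[[(i + 1L) %/% 2L]]
      if (!is.null(ds)) dout <- dout + ds
    }
    nb <- instnorm_backward_b(dout, ca$inorm)
    dl <- leakyrelu_backward(nb$dX, ca$lrelu)
    cb <- conv1d_backward_b(dl, p$W, ca$conv, pl$ix)
    grads[[i]] <- list(W = cb$dW, b = cb$db, gamma = nb$dgamma,
                       beta = nb$dbeta)
    dout <- cb$dX
  }
  list(grads = grads, dX = dout)
}

decoder_forward_bat <- function(net, plan, latent, skips, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", 9L) else NULL
  out <- latent
  for (i in seq_len(9L)) {
    l <- net$arch$decoder[[i]]
    p <- net$decoder[[i]]
    pl <- plan$decoder[[i]]
    skip_rows <- 0L
    if (!is.null(l$skip_source) && !is.na(l$skip_source)) {
      sk <- skips[[(l$skip_source + 1L) %/% 2L]]
      skip_rows <- nrow(sk)
      out <- rbind(out, sk)
    }
    if (identical(l$op, "tconv")) {
      cv <- tconv1d_forward_b(out, p$W, p$b, pl$ix)
      lr <- leakyrelu_forward(cv$out)
      nn <- instnorm_forward_b(lr$out, p$gamma, p$beta, pl$avg)
      out <- nn$out
      if (keep_cache) caches[[i]] <- list(conv = cv$cache, lrelu = lr$cache,
                                          inorm = nn$cache,
                                          skip_rows = skip_rows)
    } else {
      cv <- conv1d_forward_b(out, p$W, p$b, pl$ix)
      out <- cv$out
      if (keep_cache) caches[[i]] <- list(conv = cv$cache,
                                          skip_rows = skip_rows)
    }
  }
  list(out = out, caches = caches)
}

decoder_backward_bat <- function(net, plan, fwd, dY) {
  grads <- vector("list", 9L)
  d_skips <- vector("list", 4L)
  dout <- dY
  for (i in 9L:1L) {
    l <- net$arch$decoder[[i]]
    p <- net$decoder[[i]]
    pl <- plan$decoder[[i]]
    ca <- fwd$caches[[i]]
    if (identical(l$op, "tconv")) {
      nb <- instnorm_backward_b(dout, ca$inorm)
      dl <- leakyrelu_backward(nb$dX, ca$lrelu)
      cb <- tconv1d_backward_b(dl, p$W, ca$conv, pl$ix)
      grads[[i]] <- list(W = cb$dW, b = cb$db, gamma = nb$dgamma,
                         beta = nb$dbeta)
    } else {
      cb <- conv1d_backward_b(dout, p$W, ca$conv, pl$ix)
      grads[[i]] <- list(W = cb$dW, b = cb$db)
    }
    dout <- cb$dX
    if (ca$skip_rows > 0L) {
      nr <- nrow(dout)
      d_skips[[(l$skip_source + 1L) %/% 2L]] <-
        dout[(nr - ca$skip_rows + 1L):nr, , drop = FALSE]
      dout <- dout[1L:(nr - ca$skip_rows), , drop = FALSE]
    }
  }
  list(grads = grads, d_latent = dout, d_skips = d_skips)
}
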