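# Network construction and forward/backward passes.
#
# A built network holds weight tensors for the encoder, decoder and
# discriminator. Forward passes optionally keep per-layer caches so the
# training loop can run hand-written reverse-mode gradients.

#' Build a denoising network
#'
#' Allocates and seed-initializes the weights of the encoder, decoder and
#' discriminator described by [architecture_spec()]. Initialization is
#' fan-in-scaled uniform; instance-norm scales start at 1 and shifts at 0.
#'
#' @param width_scale See [architecture_spec()].
#' @param seed Integer seed controlling initialization.
#' @return An object of class `fecg_network`.
#' @export
build_network <- function(width_scale = 1, seed = 1L) {
  arch <- architecture_spec(width_scale)
  net <- withr::with_seed(seed, {
    enc <- lapply(arch$encoder, function(l) {
      list(W = init_taps(l$k, l$out_ch, l$in_ch, l$in_ch * l$k),
           b = stats::runif(l$out_ch, -1, 1) / sqrt(l$in_ch * l$k),
           gamma = rep(1, l$out_ch), beta = rep(0, l$out_ch))
    })
    dec <- lapply(arch$decoder, function(l) {
      if (identical(l$op, "tconv")) {
        list(W = init_taps(l$k, l$in_ch, l$out_ch, l$in_ch * l$k),
             b = stats::runif(l$out_ch, -1, 1) / sqrt(l$in_ch * l$k),
             gamma = rep(1, l$out_ch), beta = rep(0, l$out_ch))
      } else {
        list(W = init_taps(l$k, l$out_ch, l$in_ch, l$in_ch * l$k),
             b = stats::runif(l$out_ch, -1, 1) / sqrt(l$in_ch * l$k))
      }
    })
    disc <- lapply(arch$discriminator, function(l) {
      list(W = matrix(stats::runif(l$in_ch * l$out_ch, -1, 1) / sqrt(l$in_ch),
                      l$out_ch, l$in_ch),
           b = stats::runif(l$out_ch, -1, 1) / sqrt(l$in_ch))
    })
    list(encoder = enc, decoder = dec, discriminator = disc)
  })
  structure(c(net, list(arch = arch, seed = seed)), class = "fecg_network")
}

#' @export
print.fecg_network <- function(x, ...) {
  cat(sprintf("fecg_network (width_scale = %g, seed = %d)\n",
              x$arch$width_scale, x$seed))
  print(x$arch)
  invisible(x)
}

check_window_shape <- function(X, arg = "window") {
  if (!is.matrix(X) || nrow(X) != 4L)
    stop(arg, " must be a 4 x L numeric matrix", call. = FALSE)
  if (!all(is.finite(X)))
    stop(arg, " contains non-finite values", call. = FALSE)
  invisible(X)
}

# ---- encoder ---------------------------------------------------------------

encoder_forward <- function(net, X, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", 8L) else NULL
  skips <- vector("list", 4L)  # encoder layers 1,3,5,7 post-IN outputs
  out <- X
  for (i in seq_len(8L)) {
    l <- net$arch$encoder[[i]]
    p <- net$encoder[[i]]
    cv <- conv1d_forward(out, p$W, p$b, l$s, l$d, l$pad_l, l$pad_r)
    lr <- leakyrelu_forward(cv$out)
    nn <- instnorm_forward(lr$out, p$gamma, p$beta)
    out <- nn$out
    if (i %in% c(1L, 3L, 5L, 7L)) skips[[(i + 1L) %/% 2L]] <- out
    if (keep_cache) caches[[i]] <- list(conv = cv$cache, lrelu = lr$cache,
                                        inorm = nn$cache)
  }
  list(latent = out, skips = skips, caches = caches)
}

# d_latent: gradient on the latent; d_skips: list of 4 gradients on the
# stored skip outputs (or NULL). Returns parameter gradients and dX.
encoder_backward <- function(net, fwd, d_latent, d_skips = NULL,
                             want_param_grads = TRUE) {
  grads <- if (want_param_grads) vector("list", 8L) else NULL
  dout <- d_latent
  for (i in 8L:1L) {
    l <- net$arch$encoder[[i]]
    p <- net$encoder[[i]]
    ca <- fwd$caches[[i]]
    if (i %in% c(1L, 3L, 5L, 7L) && !is.null(d_skips)) {
      ds <- d_skips[[(i + 1L) %/% 2L]]
      if (!is.null(ds)) dout <- dout + ds
    }
    nb <- instnorm_backward(dout, ca$inorm)
    dl <- leakyrelu_backward(nb$dX, ca$lrelu)
    cb <- conv1d_backward(dl, p$W, ca$conv)
    if (want_param_grads)
      grads[[i]] <- list(W = cb$dW, b = cb$db, gamma = nb$dgamma, beta = nb$dbeta)
    dout <- cb$dX
  }
  list(grads = grads, dX = dout)
}

# ---- decoder ---------------------------------------------------------------

decoder_forward <- function(net, latent, skips, keep_cache = FALSE) {
  if (is.null(skips) || length(skips) != 4L || any(vapply(skips, is.null, TRUE)))
    stop("decoder requires the four stored encoder skip activations",
         call. = FALSE)
  caches <- if (keep_cache) vector("list", 9L) else NULL
  out <- latent
  for (i in seq_len(9L)) {
    l <- net$arch$decoder[[i]]
    p <- net$decoder[[i]]
    skip_rows <- 0L
    if (!is.null(l$skip_source) && !is.na(l$skip_source)) {
      sk <- skips[[(l$skip_source + 1L) %/% 2L]]
      skip_rows <- nrow(sk)
      out <- rbind(out, sk)
    }
    if (identical(l$op, "tconv")) {
      cv <- tconv1d_forward(out, p$W, p$b, l$s, l$d, l$p, l$op_pad)
      lr <- leakyrelu_forward(cv$out)
      nn <- instnorm_forward(lr$out, p$gamma, p$beta)
      out <- nn$out
      if (keep_cache) caches[[i]] <- list(conv = cv$cache, lrelu = lr$cache,
                                          inorm = nn$cache, skip_rows = skip_rows)
    } else {
      cv <- conv1d_forward(out, p$W, p$b, l$s, l$d, l$pad_l, l$pad_r)
      out <- cv$out  # final layer: no activation, no normalization
      if (keep_cache) caches[[i]] <- list(conv = cv$cache, skip_rows = skip_rows)
    }
  }
  list(out = out, caches = caches)
}

decoder_backward <- function(net, fwd, dY) {
  grads <- vector("list", 9L)
  d_skips <- vector("list", 4L)
  dout <- dY
  for (i in 9L:1L) {
    l <- net$arch$decoder[[i]]
    p <- net$decoder[[i]]
    ca <- fwd$caches[[i]]
    if (identical(l$op, "tconv")) {
      nb <- instnorm_backward(dout, ca$inorm)
      dl <- leakyrelu_backward(nb$dX, ca$lrelu)
      cb <- tconv1d_backward(dl, p$W, ca$conv)
      grads[[i]] <- list(W = cb$dW, b = cb$db, gamma = nb$dgamma, beta = nb$dbeta)
    } else {
      cb <- conv1d_backward(dout, p$W, ca$conv)
      grads[[i]] <- list(W = cb$dW, b = cb$db)
    }
    dout <- cb$dX
    if (ca$skip_rows > 0L) {
      n <- nrow(dout)
      d_skips[[(l$skip_source + 1L) %/% 2L]] <-
        dout[(n - ca$skip_rows + 1L):n, , drop = FALSE]
      dout <- dout[1L:(n - ca$skip_rows), , drop = FALSE]
    }
  }
  list(grads = grads, d_latent = dout, d_skips = d_skips)
}

# ---- discriminator ---------------------------------------------------------

discriminator_forward <- function(net, X, keep_cache = FALSE) {
  x <- as.vector(X)
  caches <- if (keep_cache) vector("list", 4L) else NULL
  features <- NULL
  for (i in seq_len(4L)) {
    p <- net$discriminator[[i]]
    lf <- linear_forward(x, p$W, p$b)
    if (i < 4L) {
      rf <- relu_forward(lf$out)
      if (keep_cache) caches[[i]] <- list(lin = lf$cache, mask = rf$cache)
      x <- rf$out
      if (i == 3L) features <- x
    } else {
      if (keep_cache) caches[[i]] <- list(lin = lf$cache)
      x <- lf$out
    }
  }
  list(features = features, logit = x, prob = sigmoid(x), caches = caches,
       input_dim = dim(X))
}

# d_features: gradient on the 3rd-layer post-ReLU features; d_logit: gradient
# on the final pre-sigmoid scalar. Either may be NULL.
discriminator_backward <- function(net, fwd, d_features = NULL, d_logit = NULL,
                                   want_param_grads = TRUE) {
  grads <- if (want_param_grads) vector("list", 4L) else NULL
  dx <- 0
  if (!is.null(d_logit)) {
    p <- net$discriminator[[4L]]
    lb <- linear_backward(d_logit, p$W, fwd$caches[[4L]]$lin)
    if (want_param_grads) grads[[4L]] <- list(W = lb$dW, b = lb$db)
    dx <- lb$dx
  } else if (want_param_grads) {
    p <- net$discriminator[[4L]]
    grads[[4L]] <- list(W = matrix(0, nrow(p$W), ncol(p$W)), b = 0 * p$b)
  }
  for (i in 3L:1L) {
    p <- net$discriminator[[i]]
    ca <- fwd$caches[[i]]
    if (i == 3L && !is.null(d_features)) dx <- dx + d_features
    dx <- dx * as.numeric(ca$mask)
    lb <- linear_backward(dx, p$W, ca$lin)
    if (want_param_grads) grads[[i]] <- list(W = lb$dW, b = lb$db)
    dx <- lb$dx
  }
  list(grads = grads, dX = matrix(dx, fwd$input_dim[1L], fwd$input_dim[2L]))
}

# Batched discriminator passes: columns of M are flattened windows. Used by
# the training loop so one batch costs one matrix product per layer.
discriminator_forward_batch <- function(net, M) {
  x <- M
  caches <- vector("list", 4L)
  features <- NULL
  for (i in seq_len(4L)) {
    p <- net$discriminator[[i]]
    Z <- p$W %*% x + p$b
    if (i < 4L) {
      mask <- Z > 0
      caches[[i]] <- list(x = x, mask = mask)
      x <- Z * mask
      if (i == 3L) features <- x
    } else {
      caches[[i]] <- list(x = x)
      x <- Z
    }
  }
  list(features = features, logit = as.numeric(x),
       prob = sigmoid(as.numeric(x)), caches = caches)
}

discriminator_backward_batch <- function(net, fwd, d_features = NULL,
                                         d_logit = NULL,
                                         want_param_grads = TRUE) {
  grads <- if (want_param_grads) vector("list", 4L) else NULL
  dx <- NULL
  if (!is.null(d_logit)) {
    p <- net$discriminator[[4L]]
    dZ <- matrix(d_logit, 1L)
    if (want_param_grads)
      grads[[4L]] <- list(W = tcrossprod(dZ, fwd$caches[[4L]]$x),
                          b = rowSums(dZ))
    dx <- crossprod(p$W, dZ)
  } else if (want_param_grads) {
    p <- net$discriminator[[4L]]
    grads[[4L]] <- list(W = matrix(0, nrow(p$W), ncol(p$W)), b = 0 * p$b)
  }
  for (i in 3L:1L) {
    p <- net$discriminator[[i]]
    ca <- fwd$caches[[i]]
    if (is.null(dx)) dx <- 0
    if (i == 3L && !is.null(d_features)) dx <- dx + d_features
    dZ <- dx * ca$mask
    if (want_param_grads)
      grads[[i]] <- list(W = tcrossprod(dZ, ca$x), b = rowSums(dZ))
    dx <- crossprod(p$W, dZ)
  }
  list(grads = grads, dX = dx)
}

# ---- public API ------------------------------------------------------------

#' Encode a window to its latent code
#'
#' Runs the eight-layer dilated-convolution encoder. For a 4x1920 input the
#' latent code is `latent_channels` x 15 (2048 x 15 at full width). The
#' post-normalization outputs of layers 1, 3, 5, 7 are returned as the skip
#' stack consumed by [decode()].
#'
#' @param net A [build_network()] object.
#' @param window 4 x L numeric matrix (standardized window).
#' @return List with `latent` and `skips`.
#' @export
encode <- function(net, window) {
  stopifnot(inherits(net, "fecg_network"))
  check_window_shape(window)
  fwd <- encoder_forward(net, window)
  list(latent = fwd$latent, skips = fwd$skips)
}

#' Decode a latent code back to a signal window
#'
#' Runs the decoder: eight transposed-convolution layers (with the encoder
#' skip activations concatenated onto the inputs of layers 2, 4, 6, 8) and a
#' final plain convolution with no activation or normalization, so outputs
#' are unbounded.
#'
#' @param net A [build_network()] object.
#' @param latent Latent code from [encode()].
#' @param skips Skip stack from [encode()].
#' @return 4 x L denoised window.
#' @export
decode <- function(net, latent, skips) {
  stopifnot(inherits(net, "fecg_network"))
  decoder_forward(net, latent, skips)$out
}

#' Discriminator forward pass
#'
#' Flattens the window and applies four linear layers with ReLU activations
#' (sigmoid on the final scalar). The length-120 (at full width) post-ReLU
#' activation of the third layer is the feature vector used by the
#' adversarial feature-matching loss.
#'
#' @param net A [build_network()] object.
#' @param window 4 x L numeric matrix.
#' @return List with `features` (non-negative vector) and `prob` in \[0, 1\].
#' @export
discriminate <- function(net, window) {
  stopifnot(inherits(net, "fecg_network"))
  check_window_shape(window)
  fwd <- discriminator_forward(net, window)
  list(features = fwd$features, prob = as.numeric(fwd$prob))
}

#' Denoise a window
#'
#' The inference filter f = f_D o f_E: encode then decode. Deterministic for
#' fixed weights.
#'
#' @param net A [build_network()] object (or [identity_denoiser()]).
#' @param window 4 x L numeric matrix.
#' @return 4 x L denoised window.
#' @export
denoise <- function(net, window) {
  UseMethod("denoise")
}

#' @export
denoise.fecg_network <- function(net, window) {
  check_window_shape(window)
  enc <- encoder_forward(net, window)
  decoder_forward(net, enc$latent, enc$skips)$out
}

#' Identity denoiser stub
#'
#' Returns its input unchanged. Useful as a reference point: with the
#' identity filter, the output SNR equals the input SNR and the SNR
#' improvement is exactly 0 dB.
#'
#' @return An object usable with [denoise()] and [evaluate_checkpoint()].
#' @export
identity_denoiser <- function() {
  structure(list(), class = c("identity_denoiser"))
}

#' @export
denoise.identity_denoiser <- function(net, window) window
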