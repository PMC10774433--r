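# Training objective: reconstruction loss, contractive Jacobian penalty,
# adversarial feature-matching loss, latent-consistency loss, and their
# weighted total. Losses are computed along each channel and then averaged.

#' Loss weights
#'
#' Weights of the four terms of the training objective. The defaults
#' (w_enc = 4, w_adv = 1e-2, w_rec = 25, w_omega = 1e-4) are the published
#' settings found to give fast convergence.
#'
#' @param w_enc Weight of the latent-consistency loss.
#' @param w_adv Weight of the adversarial feature-matching loss.
#' @param w_rec Weight of the reconstruction loss.
#' @param w_omega Weight of the contractive Jacobian penalty.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(w_enc = 4, w_adv = 1e-2, w_rec = 25, w_omega = 1e-4) {
  w <- c(w_enc = w_enc, w_adv = w_adv, w_rec = w_rec, w_omega = w_omega)
  if (!all(is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and non-negative", call. = FALSE)
  structure(as.list(w), class = "loss_weights")
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("inputs must have identical shapes", call. = FALSE)
}

#' Reconstruction loss
#'
#' Mean squared error between the clean window and the denoised window,
#' computed along each channel and then averaged over channels.
#'
#' @param x Clean window (channels x samples).
#' @param xt Denoised window, same shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(x, xt) {
  check_same_shape(x, xt)
  mean(rowMeans((x - xt)^2))
}

#' Latent-consistency loss
#'
#' Mean squared error between the latent code of the clean window and the
#' latent code of the noisy window, z = f_E(x) vs z-hat = f_E(x-hat). Forcing
#' the two codes together makes the encoder discard noise when encoding.
#'
#' @param x Clean window.
#' @param xhat Noisy window, same shape.
#' @param net A [build_network()] object.
#' @return Non-negative scalar.
#' @export
latent_consistency_loss <- function(x, xhat, net) {
  check_same_shape(x, xhat)
  z <- encoder_forward(net, x)$latent
  zh <- encoder_forward(net, xhat)$latent
  mean(rowMeans((z - zh)^2))
}

#' Adversarial feature-matching loss
#'
#' Mean squared error between the discriminator's internal feature
#' representation (the 120-unit penultimate post-ReLU activation) of the
#' clean window and of the generated window. It depends only on the feature
#' layer, not on the discriminator's final sigmoid output.
#'
#' @param x Clean window.
#' @param xt Generated (denoised) window.
#' @param net A [build_network()] object.
#' @return Non-negative scalar.
#' @export
adversarial_feature_loss <- function(x, xt, net) {
  check_same_shape(x, xt)
  fx <- discriminator_forward(net, x)$features
  ft <- discriminator_forward(net, xt)$features
  mean((fx - ft)^2)
}

#' Discriminator binary cross-entropy
#'
#' Standard non-saturating GAN discriminator loss: the clean window is
#' labelled 1 and the generated window 0; the generated window is treated as
#' a constant (detached), so this loss only trains the discriminator. A
#' discriminator outputting 0.5 for both yields log(2).
#'
#' @inheritParams adversarial_feature_loss
#' @return Non-negative scalar (average of the two cross-entropy terms).
#' @export
discriminator_loss <- function(x, xt, net) {
  pr <- discriminator_forward(net, x)$prob
  pf <- discriminator_forward(net, xt)$prob
  eps <- 1e-12
  -(log(pmax(pr, eps)) + log(pmax(1 - pf, eps))) / 2
}

# ---- contractive penalty ---------------------------------------------------

#' Simple encoder wrappers for gradient verification
#'
#' `encoder_fn()` wraps a plain forward map and its vector-Jacobian product
#' into an object accepted by [contractive_penalty()]. `identity_encoder()`
#' and `linear_encoder()` are analytic references (Jacobian identity / W), and
#' `toy_encoder()` is a seed-initialized two-layer convolutional encoder
#' (4 x 32 input, 16-dimensional output, 198 parameters) small enough for
#' exact-Jacobian and finite-difference cross-checks.
#'
#' @param forward Function mapping a numeric input to a numeric output.
#' @param vjp Function `(x, v)` returning `t(J(x)) %*% v`.
#' @return An object of class `fecg_encoder_fn`.
#' @export
encoder_fn <- function(forward, vjp) {
  structure(list(forward = forward, vjp = vjp), class = "fecg_encoder_fn")
}

#' @rdname encoder_fn
#' @export
identity_encoder <- function() {
  encoder_fn(forward = function(x) x, vjp = function(x, v) v)
}

#' @rdname encoder_fn
#' @param W Weight matrix of a linear map.
#' @export
linear_encoder <- function(W) {
  encoder_fn(forward = function(x) drop(W %*% as.vector(x)),
             vjp = function(x, v) drop(crossprod(W, v)))
}

#' @rdname encoder_fn
#' @param seed Integer seed for the toy encoder's weights.
#' @export
toy_encoder <- function(seed = 1L) {
  p <- withr::with_seed(seed, list(
    W1 = init_taps(8L, 4L, 4L, 32L), b1 = stats::runif(4L, -0.1, 0.1),
    W2 = init_taps(8L, 2L, 4L, 32L), b2 = stats::runif(2L, -0.1, 0.1)))
  fwd_full <- function(x) {
    X <- matrix(x, 4L, 32L)
    c1 <- conv1d_forward(X, p$W1, p$b1, s = 2L, d = 2L, pad_l = 7L)
    r1 <- leakyrelu_forward(c1$out)
    c2 <- conv1d_forward(r1$out, p$W2, p$b2, s = 2L, d = 2L, pad_l = 7L)
    list(out = as.vector(c2$out), c1 = c1$cache, r1 = r1$cache,
         c2 = c2$cache, mid_dim = dim(r1$out), out_dim = dim(c2$out))
  }
  encoder_fn(
    forward = function(x) fwd_full(x)$out,
    vjp = function(x, v) {
      f <- fwd_full(x)
      dY <- matrix(v, f$out_dim[1L], f$out_dim[2L])
      d2 <- conv1d_backward(dY, p$W2, f$c2)$dX
      d1 <- leakyrelu_backward(d2, f$r1)
      as.vector(conv1d_backward(d1, p$W1, f$c1)$dX)
    })
}

#' Contractive penalty
#'
#' Squared Frobenius norm of the encoder's input-output Jacobian evaluated at
#' the noisy window, penalizing the encoder's sensitivity to input
#' perturbations. Two estimators are available: `"exact"` assembles the full
#' Jacobian one vector-Jacobian product per output coordinate (tractable only
#' for small encoders) and `"stochastic"` is the unbiased Hutchinson estimate
#' `mean_v ||t(J) v||^2` with standard-normal probe vectors.
#'
#' For the identity map the penalty equals the input dimension; for a linear
#' map with matrix W it equals `sum(W^2)`.
#'
#' @param encoder A [build_network()] object (its encoder is used) or an
#'   [encoder_fn()] wrapper.
#' @param x Input at which the Jacobian is evaluated (4 x L matrix for a
#'   network; any numeric for a wrapper).
#' @param mode `"stochastic"` (default) or `"exact"`.
#' @param n_probes Number of Hutchinson probes (stochastic mode).
#' @return Non-negative scalar.
#' @export
contractive_penalty <- function(encoder, x, mode = c("stochastic", "exact"),
                                n_probes = 1L) {
  mode <- match.arg(mode)
  if (inherits(encoder, "fecg_network")) {
    fwd <- encoder_forward(encoder, x, keep_cache = TRUE)
    out_dim <- dim(fwd$latent)
    vjp <- function(v) {
      encoder_backward(encoder, fwd, matrix(v, out_dim[1L], out_dim[2L]),
                       want_param_grads = FALSE)$dX
    }
    n_out <- prod(out_dim)
  } else if (inherits(encoder, "fecg_encoder_fn")) {
    y <- encoder$forward(x)
    vjp <- function(v) encoder$vjp(x, v)
    n_out <- length(y)
  } else {
    stop("encoder must be an fecg_network or an encoder_fn", call. = FALSE)
  }
  val <- if (mode == "exact") {
    total <- 0
    for (i in seq_len(n_out)) {
      e <- numeric(n_out); e[i] <- 1
      total <- total + sum(vjp(e)^2)
    }
    total
  } else {
    probes <- vapply(seq_len(n_probes),
                     function(i) sum(vjp(stats::rnorm(n_out))^2), 0)
    mean(probes)
  }
  if (!is.finite(val)) stop("contractive penalty is non-finite", call. = FALSE)
  val
}

#' Central finite-difference Jacobian
#'
#' Independent numerical Jacobian of a vector-valued map, used to verify the
#' analytic gradients of the network layers and the exact contractive
#' penalty.
#'
#' @param f Function from numeric vector to numeric vector.
#' @param x Evaluation point.
#' @param h Step size.
#' @return Jacobian matrix (length(f(x)) x length(x)).
#' @export
finite_difference_jacobian <- function(f, x, h = 1e-4) {
  x <- as.numeric(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# ---- total -----------------------------------------------------------------

#' Total training objective
#'
#' Weighted combination of the four loss terms:
#' `L = w_enc*L_enc + w_adv*L_adv + w_rec*L_rec + w_omega*Omega`,
#' together with the contractive-autoencoder identity `L_ctr = L_rec + Omega`.
#'
#' @param L_rec,Omega,L_adv,L_enc Component losses (non-negative scalars).
#' @param weights A [loss_weights()] object.
#' @return An object of class `loss_breakdown`: list with the components,
#'   `L_ctr` and `L_total`.
#' @export
total_objective <- function(L_rec, Omega, L_adv, L_enc,
                            weights = loss_weights()) {
  comps <- c(L_rec = L_rec, Omega = Omega, L_adv = L_adv, L_enc = L_enc)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad))
    stop("non-finite loss component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(
    L_rec = L_rec, Omega = Omega, L_adv = L_adv, L_enc = L_enc,
    L_ctr = L_rec + Omega,
    L_total = weights$w_enc * L_enc + weights$w_adv * L_adv +
      weights$w_rec * L_rec + weights$w_omega * Omega),
    class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss breakdown: L_rec=%.6g Omega=%.6g L_adv=%.6g L_enc=%.6g | L_ctr=%.6g L_total=%.6g\n",
    x$L_rec, x$Omega, x$L_adv, x$L_enc, x$L_ctr, x$L_total))
  invisible(x)
}
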