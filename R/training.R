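# Adversarial training loop: encoder+decoder trained on the weighted
# objective, discriminator trained on binary cross-entropy with the generated
# window detached, alternating one discriminator step per generator step.
# Optimizer: decoupled-weight-decay Adam (AdamW).

#' Training configuration
#'
#' Published defaults: batch size 8, learning rate 1e-5, weight decay 5e-2,
#' 20 epochs, loss weights (4, 1e-2, 25, 1e-4). `width_scale` shrinks every
#' internal channel count proportionally so the pipeline can be trained at
#' desk scale; 1 is the full published architecture.
#'
#' @param batch_size Batch size B (>= 1).
#' @param learning_rate AdamW learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param epochs Number of epochs (>= 1).
#' @param weights A [loss_weights()] object.
#' @param seed Integer seed controlling initialization, shuffling and probes.
#' @param width_scale Architecture width multiplier in (0, 1].
#' @param fd_epsilon Step of the finite-difference probe used for the
#'   contractive-penalty gradient.
#' @param beta1,beta2 Adam moment decay rates.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, learning_rate = 1e-5,
                         weight_decay = 5e-2, epochs = 20L,
                         weights = loss_weights(), seed = 1L,
                         width_scale = 1, fd_epsilon = 1e-3,
                         beta1 = 0.9, beta2 = 0.999) {
  stopifnot(batch_size >= 1L, epochs >= 1L,
            width_scale > 0, width_scale <= 1,
            inherits(weights, "loss_weights"))
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), weights = weights,
                 seed = as.integer(seed), width_scale = width_scale,
                 fd_epsilon = fd_epsilon, beta1 = beta1, beta2 = beta2),
            class = "train_config")
}

# ---- flat-parameter utilities ---------------------------------------------
# Parameters live in nested lists of numeric tensors; the optimizer works on
# the flattened vector (one allocation per vector op instead of one per
# tensor) and the result is written back into the structured form.

tree_flatten <- function(p) unlist(p, use.names = FALSE)

tree_unflatten <- function(template, vec) {
  pos <- 0L
  rec <- function(tp) {
    if (is.list(tp)) {
      for (i in seq_along(tp)) tp[[i]] <- rec(tp[[i]])
      tp
    } else {
      n <- length(tp)
      tp[] <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      tp
    }
  }
  rec(template)
}

# one decoupled-weight-decay Adam step on flat vectors
adamw_flat <- function(p, g, m, v, lr, wd, b1, b2, t, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  p <- p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps) - lr * wd * p
  list(p = p, m = m, v = v)
}

# ---- training --------------------------------------------------------------

#' Train the denoising network
#'
#' For each batch: encodes the noisy window to z-hat and the clean window to
#' z, decodes z-hat (with skips) to the generated window, and updates the
#' encoder and decoder on the weighted total objective
#' (reconstruction + contractive penalty + adversarial feature matching +
#' latent consistency). The discriminator is then updated on binary
#' cross-entropy with the generated window treated as a constant, so neither
#' update touches the other sub-network's weights. The contractive penalty is
#' estimated once per batch with a finite-difference directional probe.
#'
#' @param windows List of paired windows, each a list with `x` (standardized
#'   clean target) and `xhat` (standardized noisy), both 4 x 1920 - e.g. from
#'   [prepare_paired_windows()]. Must contain at least `batch_size` pairs.
#' @param config A [train_config()].
#' @param verbose Print a line per epoch.
#' @return An object of class `fecg_checkpoint`: list with `network`,
#'   `history` (one row per step: epoch, step and the loss breakdown),
#'   `config`, `aborted`.
#' @export
train <- function(windows, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  n <- length(windows)
  if (n == 0L) stop("empty training dataset", call. = FALSE)
  B <- config$batch_size
  if (B > n)
    stop("batch size (", B, ") exceeds dataset size (", n, ")", call. = FALSE)
  w <- config$weights
  net <- build_network(config$width_scale, seed = config$seed)
  gen_tpl <- list(encoder = net$encoder, decoder = net$decoder)
  gen_flat <- tree_flatten(gen_tpl)
  disc_flat <- tree_flatten(net$discriminator)
  n_enc <- length(tree_flatten(net$encoder))
  st_gen <- list(m = 0 * gen_flat, v = 0 * gen_flat)
  st_disc <- list(m = 0 * disc_flat, v = 0 * disc_flat)
  history <- list()
  aborted <- FALSE
  t_step <- 0L

  plan <- build_batch_plan(net$arch, B)
  Lw <- 1920L
  Lz <- layer_output_shapes(net$arch)$encoder[[8L]][2L]

  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      n_batches <- n %/% B
      for (bi in seq_len(n_batches)) {
        idx <- ord[((bi - 1L) * B + 1L):(bi * B)]

        # batch layout: windows side by side in one 4 x (B*1920) matrix
        Xb <- do.call(cbind, lapply(idx, function(ii) windows[[ii]]$x))
        Xh <- do.call(cbind, lapply(idx, function(ii) windows[[ii]]$xhat))

        fe_hat <- encoder_forward_bat(net, plan, Xh, keep_cache = TRUE)
        fe_x <- encoder_forward_bat(net, plan, Xb, keep_cache = TRUE)
        fd <- decoder_forward_bat(net, plan, fe_hat$latent, fe_hat$skips,
                                  keep_cache = TRUE)
        Xt <- fd$out

        L_rec <- mean((Xb - Xt)^2)
        d_xt <- w$w_rec * 2 * (Xt - Xb) / length(Xt)

        # discriminator: window blocks become columns
        fx <- discriminator_forward_batch(net, matrix(Xb, nrow = 4L * Lw))
        ft <- discriminator_forward_batch(net, matrix(Xt, nrow = 4L * Lw))
        fdim <- nrow(fx$features)
        L_adv <- mean((fx$features - ft$features)^2)
        adv_b <- discriminator_backward_batch(
          net, ft,
          d_features = w$w_adv * 2 * (ft$features - fx$features) / (fdim * B),
          want_param_grads = FALSE)
        d_xt <- d_xt + matrix(adv_b$dX, nrow = 4L)

        L_enc <- mean((fe_x$latent - fe_hat$latent)^2)
        d_z <- w$w_enc * 2 * (fe_x$latent - fe_hat$latent) /
          length(fe_x$latent)

        dec_b <- decoder_backward_bat(net, plan, fd, d_xt)
        d_latent_hat <- dec_b$d_latent - d_z

        # contractive penalty: one finite-difference probe per batch,
        # on the batch's first noisy window
        eps_fd <- config$fd_epsilon
        xh1 <- Xh[, seq_len(Lw), drop = FALSE]
        v_probe <- matrix(stats::rnorm(length(xh1)), nrow(xh1))
        fe_p <- encoder_forward(net, xh1 + eps_fd * v_probe,
                                keep_cache = TRUE)
        zhat1 <- fe_hat$latent[, seq_len(Lz), drop = FALSE]
        dz_fd <- (fe_p$latent - zhat1) / eps_fd
        omega_hat <- sum(dz_fd^2)
        d_probe <- w$w_omega * 2 * dz_fd / eps_fd
        pb <- encoder_backward(net, fe_p, d_probe)
        d_latent_hat[, seq_len(Lz)] <-
          d_latent_hat[, seq_len(Lz), drop = FALSE] - d_probe

        eb_hat <- encoder_backward_bat(net, plan, fe_hat, d_latent_hat,
                                       dec_b$d_skips)
        eb_x <- encoder_backward_bat(net, plan, fe_x, d_z)
        g_enc <- tree_flatten(eb_hat$grads) + tree_flatten(eb_x$grads) +
          tree_flatten(pb$grads)
        g_dec <- tree_flatten(dec_b$grads)

        # discriminator BCE, generated windows detached (1/B in d_logit)
        p_r <- fx$prob; p_f <- ft$prob
        L_disc <- mean(-(log(pmax(p_r, 1e-12)) +
                           log(pmax(1 - p_f, 1e-12))) / 2)
        db_r <- discriminator_backward_batch(net, fx,
                                             d_logit = (p_r - 1) / (2 * B))
        db_f <- discriminator_backward_batch(net, ft, d_logit = p_f / (2 * B))
        g_disc <- tree_flatten(db_r$grads) + tree_flatten(db_f$grads)

        bd <- total_objective(L_rec, omega_hat, L_adv, L_enc, w)
        if (!is.finite(bd$L_total)) {
          warning("non-finite loss at epoch ", epoch, ", batch ", bi,
                  "; aborting with last-good checkpoint")
          aborted <- TRUE
          break
        }
        t_step <- t_step + 1L
        r <- adamw_flat(gen_flat, c(g_enc, g_dec), st_gen$m, st_gen$v,
                        config$learning_rate, config$weight_decay,
                        config$beta1, config$beta2, t_step)
        gen_flat <- r$p; st_gen$m <- r$m; st_gen$v <- r$v
        r <- adamw_flat(disc_flat, g_disc, st_disc$m, st_disc$v,
                        config$learning_rate, config$weight_decay,
                        config$beta1, config$beta2, t_step)
        disc_flat <- r$p; st_disc$m <- r$m; st_disc$v <- r$v
        gen_new <- tree_unflatten(gen_tpl, gen_flat)
        net$encoder <- gen_new$encoder
        net$decoder <- gen_new$decoder
        net$discriminator <- tree_unflatten(net$discriminator, disc_flat)

        history[[length(history) + 1L]] <- data.frame(
          epoch = epoch, step = t_step,
          L_rec = bd$L_rec, Omega = bd$Omega, L_adv = bd$L_adv,
          L_enc = bd$L_enc, L_ctr = bd$L_ctr, L_total = bd$L_total,
          L_disc = L_disc)
      }
      if (aborted) break
      if (verbose) {
        eh <- do.call(rbind, history)
        eh <- eh[eh$epoch == epoch, ]
        message(sprintf("epoch %d: L_rec %.4f  L_total %.4f",
                        epoch, mean(eh$L_rec), mean(eh$L_total)))
      }
    }
  })
  structure(list(network = net, history = do.call(rbind, history),
                 config = config, aborted = aborted),
            class = "fecg_checkpoint")
}

#' @export
print.fecg_checkpoint <- function(x, ...) {
  h <- x$history
  cat(sprintf("fecg_checkpoint: %d steps over %d epochs (width_scale %g)%s\n",
              nrow(h), max(h$epoch), x$config$width_scale,
              if (x$aborted) " [aborted]" else ""))
  cat(sprintf("  first-epoch mean L_rec %.5f -> final-epoch mean L_rec %.5f\n",
              mean(h$L_rec[h$epoch == min(h$epoch)]),
              mean(h$L_rec[h$epoch == max(h$epoch)])))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Checkpoints are serialized with the network weights, architecture
#' specification and training configuration.
#'
#' @param ckpt An `fecg_checkpoint`.
#' @param path File path.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "fecg_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "fecg_checkpoint"))
    stop("not a checkpoint file: ", path, call. = FALSE)
  ckpt
}

#' Evaluate a checkpoint on paired windows
#'
#' Denoises every noisy window, restores physical units with the noisy
#' window's standardization statistics, and computes the divergence metrics
#' (input/output SNR, SNR improvement, RMSE, PRD) against the clean window -
#' per channel, averaged over windows, plus the channel average.
#'
#' @param ckpt An `fecg_checkpoint`, an `fecg_network`, or
#'   [identity_denoiser()].
#' @param windows Paired windows from [prepare_paired_windows()].
#' @return data.frame with one row per channel plus an `"average"` row.
#' @export
evaluate_checkpoint <- function(ckpt, windows) {
  net <- if (inherits(ckpt, "fecg_checkpoint")) ckpt$network else ckpt
  stopifnot(length(windows) >= 1L)
  per <- lapply(windows, function(wd) {
    xt_std <- denoise(net, wd$xhat)
    xt_phys <- xt_std * wd$sigma + wd$mu
    cm <- channel_metrics(wd$x_phys, wd$xhat_phys, xt_phys)
    cm[cm$channel != "average", -1L]
  })
  avg <- Reduce(`+`, per) / length(per)
  out <- rbind(avg, colMeans(avg))
  out <- cbind(channel = c(as.character(seq_len(nrow(avg))), "average"), out)
  rownames(out) <- NULL
  out
}
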