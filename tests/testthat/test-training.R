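tiny_windows <- function(n, seed = 1) {
  withr::with_seed(seed, replicate(n, {
    x <- matrix(stats::rnorm(4 * 1920), 4)
    list(x = x, xhat = x + matrix(stats::rnorm(4 * 1920, sd = 0.5), 4))
  }, simplify = FALSE))
}

test_that("training is seed-deterministic and records a full loss history", {
  wins <- tiny_windows(8)
  cfg <- train_config(batch_size = 4, epochs = 2, width_scale = 0.0625,
                      seed = 11)
  ck1 <- train(wins, cfg)
  ck2 <- train(wins, cfg)
  expect_identical(ck1$history, ck2$history)
  expect_identical(ck1$network$encoder, ck2$network$encoder)

  h <- ck1$history
  expect_equal(nrow(h), 4)
  expect_named(h, c("epoch", "step", "L_rec", "Omega", "L_adv", "L_enc",
                    "L_ctr", "L_total", "L_disc"))
  expect_true(all(is.finite(as.matrix(h))))
  expect_equal(h$L_ctr, h$L_rec + h$Omega, tolerance = 1e-14)
  expect_equal(h$L_total,
               4 * h$L_enc + 1e-2 * h$L_adv + 25 * h$L_rec + 1e-4 * h$Omega,
               tolerance = 1e-12)
})

test_that("contract errors: oversized batch and empty dataset", {
  wins <- tiny_windows(4)
  expect_error(train(wins, train_config(batch_size = 8, epochs = 1,
                                        width_scale = 0.0625)),
               "exceeds dataset size")
  expect_error(train(list(), train_config()), "empty")
})

test_that("discriminator updates do not leak into encoder/decoder weights", {
  wins <- tiny_windows(4)
  # zero generator loss weights + zero weight decay: the only gradients in
  # the step belong to the discriminator, so encoder/decoder must not move
  cfg <- train_config(batch_size = 4, epochs = 1, width_scale = 0.0625,
                      weights = loss_weights(0, 0, 0, 0), weight_decay = 0,
                      learning_rate = 1e-3, seed = 5)
  ck <- train(wins, cfg)
  init <- build_network(0.0625, seed = 5)
  expect_equal(ck$network$encoder, init$encoder, tolerance = 1e-14)
  expect_equal(ck$network$decoder, init$decoder, tolerance = 1e-14)
  expect_false(isTRUE(all.equal(ck$network$discriminator,
                                init$discriminator, tolerance = 1e-10)))
})

test_that("generator updates move encoder/decoder but follow the objective", {
  wins <- tiny_windows(8)
  cfg <- train_config(batch_size = 8, epochs = 4, width_scale = 0.0625,
                      learning_rate = 1e-3, seed = 2)
  ck <- train(wins, cfg)
  h <- ck$history
  expect_lt(h$L_rec[nrow(h)], h$L_rec[1])
  init <- build_network(0.0625, seed = 2)
  expect_false(isTRUE(all.equal(ck$network$encoder, init$encoder,
                                tolerance = 1e-10)))
})

test_that("checkpoint evaluation reports all divergence metrics per channel", {
  rec <- fixture_record()
  wins <- prepare_paired_windows(rec)[1:3]
  ev <- evaluate_checkpoint(identity_denoiser(), wins)
  expect_named(ev, c("channel", "snr_in", "snr_out", "snr_imp", "rmse", "prd"))
  expect_equal(nrow(ev), 5)
  expect_equal(ev$snr_imp, rep(0, 5))  # identity filter: x-tilde == x-hat
  expect_equal(ev$snr_out, ev$snr_in)

  net <- build_network(0.0625, seed = 1)
  ev2 <- evaluate_checkpoint(net, wins)
  expect_true(all(is.finite(ev2$snr_imp)))
})

test_that("checkpoints serialize and reload", {
  wins <- tiny_windows(4)
  cfg <- train_config(batch_size = 4, epochs = 1, width_scale = 0.0625,
                      seed = 3)
  ck <- train(wins, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  expect_identical(ck2$history, ck$history)
  w <- random_window(1)
  expect_identical(denoise(ck2$network, w$xhat), denoise(ck$network, w$xhat))

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), "not a checkpoint")
})
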