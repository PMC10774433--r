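test_that("reconstruction loss matches a naive per-channel loop", {
  w <- random_window(1)
  expect_equal(reconstruction_loss(w$x, w$x), 0)
  expect_equal(reconstruction_loss(w$x, w$x + 1), 1.0)

  naive <- 0
  for (ch in 1:4) {
    s <- 0
    for (t in 1:1920) s <- s + (w$x[ch, t] - w$xhat[ch, t])^2
    naive <- naive + s / 1920
  }
  naive <- naive / 4
  expect_equal(reconstruction_loss(w$x, w$xhat), naive, tolerance = 1e-12)
  expect_error(reconstruction_loss(w$x, w$x[, 1:10]), "identical shapes")
})

test_that("latent-consistency loss is an MSE over codes", {
  net <- build_network(width_scale = 0.125, seed = 1)
  w <- random_window(2)
  expect_equal(latent_consistency_loss(w$x, w$x, net), 0)
  expect_equal(latent_consistency_loss(w$x, w$xhat, net),
               latent_consistency_loss(w$xhat, w$x, net))
  z <- encode(net, w$x)$latent
  zh <- encode(net, w$xhat)$latent
  naive <- sum((z - zh)^2) / length(z)
  expect_equal(latent_consistency_loss(w$x, w$xhat, net), naive,
               tolerance = 1e-12)
})

test_that("adversarial loss matches features and ignores the final sigmoid", {
  net <- build_network(width_scale = 0.125, seed = 1)
  w <- random_window(3)
  expect_equal(adversarial_feature_loss(w$x, w$x, net), 0)

  fx <- discriminate(net, w$x)$features
  ft <- discriminate(net, w$xhat)$features
  expect_equal(adversarial_feature_loss(w$x, w$xhat, net),
               mean((fx - ft)^2), tolerance = 1e-12)

  # perturbing the final (sigmoid) layer leaves the loss unchanged
  before <- adversarial_feature_loss(w$x, w$xhat, net)
  net$discriminator[[4]]$W <- net$discriminator[[4]]$W * 10 + 3
  net$discriminator[[4]]$b <- net$discriminator[[4]]$b - 7
  expect_identical(adversarial_feature_loss(w$x, w$xhat, net), before)
})

test_that("contractive penalty has its analytic values for simple maps", {
  x <- stats::rnorm(12)
  expect_equal(contractive_penalty(identity_encoder(), x, mode = "exact"), 12)
  W <- matrix(stats::rnorm(5 * 12), 5, 12)
  expect_equal(contractive_penalty(linear_encoder(W), x, mode = "exact"),
               sum(W^2), tolerance = 1e-12)
})

test_that("exact contractive penalty agrees with central finite differences", {
  enc <- toy_encoder(seed = 2)
  x <- withr::with_seed(8, stats::rnorm(4 * 32))
  J_fd <- finite_difference_jacobian(enc$forward, x, h = 1e-4)
  omega_fd <- sum(J_fd^2)
  omega <- contractive_penalty(enc, x, mode = "exact")
  expect_lt(abs(omega - omega_fd) / omega_fd, 1e-4)
})

test_that("stochastic contractive estimate is consistent with the exact value", {
  enc <- toy_encoder(seed = 2)
  x <- withr::with_seed(9, stats::rnorm(4 * 32))
  exact <- contractive_penalty(enc, x, mode = "exact")
  est <- withr::with_seed(10,
    contractive_penalty(enc, x, mode = "stochastic", n_probes = 400))
  expect_lt(abs(est - exact) / exact, 0.2)
})

test_that("total objective combines components with the published weights", {
  expect_equal(total_objective(2, 0, 0, 0, loss_weights(0, 0, 1, 0))$L_total,
               2)
  bd <- total_objective(1, 1, 1, 1, loss_weights())
  expect_equal(bd$L_total, 29.0101)
  expect_identical(bd$L_ctr, bd$L_rec + bd$Omega)
  expect_equal(total_objective(0, 0, 0, 0)$L_total, 0)
  expect_error(total_objective(NaN, 0, 0, 0), "L_rec")
  expect_error(loss_weights(w_rec = -1), "non-negative")

  w <- random_window(4)
  net <- build_network(width_scale = 0.125, seed = 1)
  bd2 <- total_objective(
    reconstruction_loss(w$x, w$xhat),
    contractive_penalty(net, w$xhat, n_probes = 1),
    adversarial_feature_loss(w$x, w$xhat, net),
    latent_consistency_loss(w$x, w$xhat, net))
  expect_identical(bd2$L_ctr, bd2$L_rec + bd2$Omega)
  expect_equal(bd2$L_total,
               4 * bd2$L_enc + 1e-2 * bd2$L_adv + 25 * bd2$L_rec +
                 1e-4 * bd2$Omega)
  expect_true(all(unlist(bd2) >= 0))
})

test_that("discriminator cross-entropy has its reference values", {
  net <- build_network(width_scale = 0.125, seed = 1)
  # force the output logit to 0 -> probability 0.5 for any input
  net$discriminator[[4]]$W[] <- 0
  net$discriminator[[4]]$b[] <- 0
  w <- random_window(5)
  expect_equal(discriminator_loss(w$x, w$xhat, net), log(2))

  # perfect discrimination drives the loss to zero
  net$discriminator[[4]]$b[] <- 50
  expect_lt(-log(discriminate(net, w$x)$prob) / 2, 1e-12)
})
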