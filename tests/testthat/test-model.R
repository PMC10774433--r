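# The published per-layer output shapes and trainable-parameter counts that
# the full-width architecture must reproduce exactly.
ENC_SHAPES <- list(c(16, 960), c(32, 480), c(64, 240), c(128, 120),
                   c(256, 60), c(512, 30), c(1024, 15), c(2048, 15))
DEC_SHAPES <- list(c(1024, 15), c(512, 30), c(256, 60), c(128, 120),
                   c(64, 240), c(32, 480), c(16, 960), c(4, 1920),
                   c(4, 1920))
ENC_CONV_PARAMS <- c(528, 4128, 16448, 65664, 262400, 1049088, 4195328,
                     16779264)
ENC_IN_PARAMS <- c(32, 64, 128, 256, 512, 1024, 2048, 4096)
DEC_CONV_PARAMS <- c(16778240, 8389120, 1048832, 524416, 65600, 32800, 4112,
                     1028, 132)
DEC_IN_PARAMS <- c(2048, 1024, 512, 256, 128, 64, 32, 8)
DISC_PARAMS <- c(14747520, 922080, 57720, 121)

test_that("layer shapes reproduce the published architecture table", {
  arch <- architecture_spec()
  sh <- layer_output_shapes(arch, c(4, 1920))
  for (i in 1:8) expect_equal(sh$encoder[[i]], ENC_SHAPES[[i]])
  for (i in 1:9) expect_equal(sh$decoder[[i]], DEC_SHAPES[[i]])
  # fully convolutional: doubling the input length doubles temporal extents
  sh2 <- layer_output_shapes(arch, c(4, 3840))
  for (i in 1:8) {
    expect_equal(sh2$encoder[[i]][1], sh$encoder[[i]][1])
    expect_equal(sh2$encoder[[i]][2], 2 * sh$encoder[[i]][2])
  }
})

test_that("parameter counts reproduce the published table cell by cell", {
  arch <- architecture_spec()
  pt <- parameter_table(arch)
  enc_conv <- pt$params[pt$network == "encoder" & grepl("^Conv", pt$op)]
  enc_in <- pt$params[pt$network == "encoder" & grepl("IN", pt$op)]
  dec_conv <- pt$params[pt$network == "decoder" & grepl("Conv", pt$op)]
  dec_in <- pt$params[pt$network == "decoder" & grepl("IN", pt$op)]
  disc <- pt$params[pt$network == "discriminator"]
  expect_equal(enc_conv, ENC_CONV_PARAMS)
  expect_equal(enc_in, ENC_IN_PARAMS)
  expect_equal(dec_conv, DEC_CONV_PARAMS)
  expect_equal(dec_in, DEC_IN_PARAMS)
  expect_equal(disc, DISC_PARAMS)

  # independent formula oracle: in*out*k + out, 2*ch, in*out + out
  for (l in arch$encoder)
    expect_equal(l$in_ch * l$out_ch * 8 + l$out_ch + 2 * l$out_ch,
                 sum(fecgdenoise:::layer_param_count(l)))
  expect_equal(count_parameters(arch, "encoder"),
               sum(ENC_CONV_PARAMS) + sum(ENC_IN_PARAMS))
  expect_equal(count_parameters(arch, "decoder"),
               sum(DEC_CONV_PARAMS) + sum(DEC_IN_PARAMS))
  expect_equal(count_parameters(arch, "discriminator"), sum(DISC_PARAMS))
  expect_equal(count_parameters(arch, "total"),
               count_parameters(arch, "encoder") +
                 count_parameters(arch, "decoder") +
                 count_parameters(arch, "discriminator"))
})

test_that("skip concatenation doubles decoder input channels at layers 2,4,6,8", {
  arch <- architecture_spec()
  dec <- arch$decoder
  base_in <- c(2048, 1024, 512, 256, 128, 64, 32, 16)
  for (i in c(2, 4, 6, 8)) {
    expect_equal(dec[[i]]$in_ch, 2 * base_in[i])
    expect_equal(dec[[i]]$skip_source, c(NA, 7, NA, 5, NA, 3, NA, 1)[i])
  }
  for (i in c(1, 3, 5, 7)) expect_equal(dec[[i]]$in_ch, base_in[i])
})

test_that("encode/decode run at reduced width with consistent shapes", {
  net <- build_network(width_scale = 0.125, seed = 1)
  x <- matrix(stats::rnorm(4 * 1920), 4)
  e <- encode(net, x)
  expect_equal(dim(e$latent), c(256L, 15L))
  expect_equal(vapply(e$skips, dim, c(1L, 1L)),
               matrix(c(2L, 960L, 8L, 240L, 32L, 60L, 128L, 15L), 2))
  y <- decode(net, e$latent, e$skips)
  expect_equal(dim(y), c(4L, 1920L))
  expect_identical(denoise(net, x), denoise(net, x))
  expect_error(decode(net, e$latent, NULL), "skip")
  expect_error(encode(net, matrix(0, 3, 1920)), "4 x L")
})

test_that("all-zero input stays finite through instance normalization", {
  net <- build_network(width_scale = 0.125, seed = 2)
  y <- denoise(net, matrix(0, 4, 1920))
  expect_true(all(is.finite(y)))
})

test_that("discriminator outputs a probability and non-negative features", {
  net <- build_network(width_scale = 0.125, seed = 1)
  for (s in 1:3) {
    x <- matrix(stats::rnorm(4 * 1920, sd = s), 4)
    d <- discriminate(net, x)
    expect_gte(d$prob, 0); expect_lte(d$prob, 1)
    expect_true(all(d$features >= 0))
    expect_length(d$features, 15L)  # 120 * width_scale
  }
  expect_equal(architecture_spec()$discriminator[[1]]$in_ch, 7680L)
})

test_that("final decoder layer is unbounded (no activation/normalization)", {
  net <- build_network(width_scale = 0.125, seed = 5)
  # scale up the last layer: outputs must follow linearly (no squashing)
  y1 <- denoise(net, matrix(stats::rnorm(4 * 1920), 4))
  net$decoder[[9]]$W <- lapply(net$decoder[[9]]$W, function(w) w * 100)
  net$decoder[[9]]$b <- net$decoder[[9]]$b * 100
  x <- matrix(stats::rnorm(4 * 1920), 4)
  y <- denoise(net, x)
  expect_gt(max(y), 1)
  expect_lt(min(y), -1)
})

test_that("batched training pipeline matches the single-window pipeline", {
  net <- build_network(width_scale = 0.125, seed = 4)
  plan <- fecgdenoise:::build_batch_plan(net$arch, 2L)
  x1 <- matrix(stats::rnorm(4 * 1920), 4)
  x2 <- matrix(stats::rnorm(4 * 1920), 4)
  fb <- fecgdenoise:::encoder_forward_bat(net, plan, cbind(x1, x2))
  f1 <- fecgdenoise:::encoder_forward(net, x1)
  f2 <- fecgdenoise:::encoder_forward(net, x2)
  expect_equal(fb$latent, cbind(f1$latent, f2$latent), tolerance = 1e-12)
  db <- fecgdenoise:::decoder_forward_bat(net, plan, fb$latent, fb$skips)
  d1 <- fecgdenoise:::decoder_forward(net, f1$latent, f1$skips)
  d2 <- fecgdenoise:::decoder_forward(net, f2$latent, f2$skips)
  expect_equal(db$out, cbind(d1$out, d2$out), tolerance = 1e-12)
})
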