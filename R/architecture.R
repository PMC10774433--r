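# Architecture specification for the encoder / decoder / discriminator.
#
# The denoising filter is f = f_D o f_E: an eight-layer dilated-convolution
# encoder compressing a 4x1920 window to a 2048x15 latent code, and a
# nine-layer decoder (eight transposed convolutions + one plain convolution)
# upsampling back to 4x1920. Skip connections concatenate the encoder outputs
# of layers 1, 3, 5, 7 onto the inputs of decoder layers 8, 6, 4, 2. The
# discriminator is a four-layer perceptron on the flattened window, ending in
# a sigmoid; its 120-unit penultimate post-ReLU activation is the feature
# vector used by the adversarial feature-matching loss.
#
# Paddings are chosen so the published per-layer output shapes hold with
# kernel size 8:
#   conv  s2 d2 -> p 7;  conv s2 d4 -> p 14;  conv s1 d2 -> p 7
#   final conv s1 d1 -> asymmetric padding (3 left, 4 right)
#   tconv s1 d2 -> p 7, op 0;  tconv s2 d2 -> p 7, op 1;  tconv s2 d4 -> p 14, op 1

KERNEL_SIZE <- 8L

#' Network architecture specification
#'
#' Builds the metadata description of the encoder, decoder and discriminator:
#' per-layer operation, channel counts, stride/dilation/padding, activation,
#' normalization, and skip topology. The specification is weight-free;
#' [count_parameters()] and [layer_output_shapes()] operate on it directly, so
#' the full-width architecture can be audited without allocating ~50M weights.
#'
#' @param width_scale Multiplier in (0, 1] applied to every internal channel
#'   count (and discriminator width), rounded and clamped to >= 1. The input
#'   and output stay at 4 channels. `1` is the published architecture; smaller
#'   values give proportionally shrunk networks for desk-scale training.
#' @return An object of class `fecg_architecture`.
#' @export
#' @examples
#' arch <- architecture_spec()
#' count_parameters(arch, "encoder")
architecture_spec <- function(width_scale = 1) {
  stopifnot(is.numeric(width_scale), length(width_scale) == 1L,
            width_scale > 0, width_scale <= 1)
  ws <- function(ch) max(1L, as.integer(round(ch * width_scale)))

  enc_out <- vapply(c(16L, 32L, 64L, 128L, 256L, 512L, 1024L, 2048L), ws, 1L)
  enc_s <- c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L)
  enc_d <- c(2L, 2L, 4L, 4L, 4L, 4L, 2L, 2L)
  enc_p <- ifelse(enc_d == 4L, 14L, 7L)
  enc_in <- c(4L, enc_out[-8L])
  encoder <- lapply(seq_len(8L), function(i) {
    list(op = "conv", in_ch = enc_in[i], out_ch = enc_out[i], k = KERNEL_SIZE,
         s = enc_s[i], d = enc_d[i], pad_l = enc_p[i], pad_r = enc_p[i],
         activation = "leakyrelu", norm = "instance")
  })

  # decoder layers 2,4,6,8 consume channel-concatenated skips from encoder
  # layers 7,5,3,1 (post-normalization outputs)
  dec_out <- vapply(c(1024L, 512L, 256L, 128L, 64L, 32L, 16L), ws, 1L)
  dec_out <- c(dec_out, 4L)
  dec_s <- c(1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L)
  dec_d <- c(2L, 4L, 4L, 4L, 4L, 2L, 2L, 2L)
  dec_p <- ifelse(dec_d == 4L, 14L, 7L)
  dec_op <- ifelse(dec_s == 2L, 1L, 0L)
  skip_src <- c(NA, 7L, NA, 5L, NA, 3L, NA, 1L)
  dec_in_base <- c(enc_out[8L], dec_out[-8L])
  decoder <- lapply(seq_len(8L), function(i) {
    skip_ch <- if (is.na(skip_src[i])) 0L else enc_out[skip_src[i]]
    list(op = "tconv", in_ch = dec_in_base[i] + skip_ch, out_ch = dec_out[i],
         k = KERNEL_SIZE, s = dec_s[i], d = dec_d[i], p = dec_p[i],
         op_pad = dec_op[i], skip_source = skip_src[i],
         activation = "leakyrelu", norm = "instance")
  })
  decoder[[9L]] <- list(op = "conv", in_ch = 4L, out_ch = 4L, k = KERNEL_SIZE,
                        s = 1L, d = 1L, pad_l = 3L, pad_r = 4L,
                        skip_source = NA, activation = "none", norm = "none")

  disc_widths <- vapply(c(1920L, 480L, 120L), ws, 1L)
  disc_in <- c(4L * 1920L, disc_widths)
  disc_out <- c(disc_widths, 1L)
  discriminator <- lapply(seq_len(4L), function(i) {
    list(op = "linear", in_ch = disc_in[i], out_ch = disc_out[i],
         activation = if (i < 4L) "relu" else "sigmoid")
  })

  structure(list(encoder = encoder, decoder = decoder,
                 discriminator = discriminator,
                 width_scale = width_scale,
                 latent_channels = enc_out[8L],
                 feature_dim = disc_widths[3L]),
            class = "fecg_architecture")
}

layer_param_count <- function(layer) {
  w <- switch(layer$op,
              conv = ,
              tconv = layer$in_ch * layer$out_ch * layer$k + layer$out_ch,
              linear = layer$in_ch * layer$out_ch + layer$out_ch)
  n <- if (identical(layer$norm, "instance")) 2L * layer$out_ch else 0L
  c(main = w, norm = n)
}

#' Count trainable parameters
#'
#' Every trainable scalar is counted: convolution / linear weights and biases
#' plus the learnable scale and shift of each instance normalization
#' (`in_ch * out_ch * k + out_ch` per convolution, `2 * out_ch` per
#' normalization, `in * out + out` per linear layer).
#'
#' @param arch An [architecture_spec()] (or an object carrying one, e.g. a
#'   built network).
#' @param part `"encoder"`, `"decoder"`, `"discriminator"` or `"total"`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(arch, part = c("total", "encoder", "decoder",
                                            "discriminator")) {
  if (inherits(arch, "fecg_network")) arch <- arch$arch
  stopifnot(inherits(arch, "fecg_architecture"))
  part <- match.arg(part)
  one <- function(layers) sum(vapply(layers, function(l) sum(layer_param_count(l)), 0))
  res <- switch(part,
                encoder = one(arch$encoder),
                decoder = one(arch$decoder),
                discriminator = one(arch$discriminator),
                total = one(arch$encoder) + one(arch$decoder) +
                  one(arch$discriminator))
  as.double(res)
}

#' Per-layer parameter and shape table
#'
#' One row per operation (convolution/linear rows and their normalization
#' rows separately), mirroring how architecture summaries are usually printed.
#'
#' @inheritParams count_parameters
#' @param input_shape `c(channels, samples)` of the network input.
#' @return A data.frame with columns `network`, `layer`, `op`, `out_channels`,
#'   `out_len`, `params`.
#' @export
parameter_table <- function(arch, input_shape = c(4L, 1920L)) {
  if (inherits(arch, "fecg_network")) arch <- arch$arch
  stopifnot(inherits(arch, "fecg_architecture"))
  shapes <- layer_output_shapes(arch, input_shape)
  rows <- list()
  add <- function(network, layer, op, shp, params) {
    rows[[length(rows) + 1L]] <<- data.frame(
      network = network, layer = layer, op = op,
      out_channels = shp[1L], out_len = shp[2L], params = params)
  }
  walk <- function(layers, network, shp_list) {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      pc <- layer_param_count(l)
      lab <- switch(l$op,
                    conv = sprintf("Convolution(s=%d, d=%d)", l$s, l$d),
                    tconv = sprintf("Transposed Convolution(s=%d, d=%d)", l$s, l$d),
                    linear = sprintf("Linear(in=%d, out=%d)", l$in_ch, l$out_ch))
      add(network, i, lab, shp_list[[i]], pc[["main"]])
      if (identical(l$norm, "instance"))
        add(network, i, "LeakyReLU(0.2) + IN", shp_list[[i]], pc[["norm"]])
    }
  }
  walk(arch$encoder, "encoder", shapes$encoder)
  walk(arch$decoder, "decoder", shapes$decoder)
  walk(arch$discriminator, "discriminator", shapes$discriminator)
  do.call(rbind, rows)
}

#' Per-layer output shapes
#'
#' Applies the convolution / transposed-convolution length formulas to an
#' input shape and returns the ordered output shape of every layer. For the
#' published architecture and a 4x1920 input, the encoder halves the temporal
#' extent at layers 1-7 and keeps it at layer 8 (latent 2048x15); the decoder
#' mirrors the encoder back to 4x1920. The network is fully convolutional, so
#' doubling the input length doubles every temporal extent.
#'
#' @inheritParams parameter_table
#' @return A list with elements `encoder`, `decoder`, `discriminator`, each a
#'   list of `c(channels, length)` shapes.
#' @export
layer_output_shapes <- function(arch, input_shape = c(4L, 1920L)) {
  if (inherits(arch, "fecg_network")) arch <- arch$arch
  stopifnot(inherits(arch, "fecg_architecture"), length(input_shape) == 2L)
  L <- as.integer(input_shape[2L])
  enc <- list()
  for (l in arch$encoder) {
    L <- conv1d_out_len(L, l$k, l$s, l$d, l$pad_l, l$pad_r)
    enc[[length(enc) + 1L]] <- c(l$out_ch, L)
  }
  dec <- list()
  for (l in arch$decoder) {
    L <- if (identical(l$op, "tconv")) {
      tconv1d_out_len(L, l$k, l$s, l$d, l$p, l$op_pad)
    } else {
      conv1d_out_len(L, l$k, l$s, l$d, l$pad_l, l$pad_r)
    }
    dec[[length(dec) + 1L]] <- c(l$out_ch, L)
  }
  disc <- lapply(arch$discriminator, function(l) c(1L, l$out_ch))
  list(encoder = enc, decoder = dec, discriminator = disc)
}

#' @export
print.fecg_architecture <- function(x, ...) {
  cat(sprintf("fECG denoiser architecture (width_scale = %g)\n", x$width_scale))
  cat(sprintf("  encoder: 8 dilated conv layers -> latent %d x 15 (for 4x1920 input)\n",
              x$latent_channels))
  cat("  decoder: 8 transposed conv layers + 1 conv, skips at layers 2,4,6,8\n")
  cat(sprintf("  discriminator: 4 linear layers, feature dim %d\n", x$feature_dim))
  cat(sprintf("  trainable parameters: %.0f\n", count_parameters(x)))
  invisible(x)
}
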