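#' U-Net architecture configuration
#'
#' An encoder--decoder segmentation network with skip connections.  Each
#' encoder stage applies 3x3 same-padding convolutions (ReLU after every
#' convolution) followed by 2x2 stride-2 max pooling; the decoder mirrors
#' it with nearest-neighbour upsampling, a channel-halving convolution,
#' concatenation with the same-level encoder output and two further
#' convolutions; a final 1x1 convolution maps the first-stage width to
#' the class scores.  Fully size-configurable so a tiny variant trains on
#' a CPU in minutes.
#'
#' @param in_channels Input channels (default 3; grayscale images are
#'   replicated).
#' @param num_classes Output classes including background.
#' @param depth Number of pooling stages.
#' @param widths Channel widths, one per encoder stage plus the
#'   bottleneck (`depth + 1` values, strictly increasing).
#' @param encoder `"plain"` (two convolutions per stage) or `"vgg16"`
#'   (the standard 13-convolution VGG16 stack truncated to its first 12
#'   convolutions: stage depths 2/2/3/3 plus a 2-convolution bottleneck,
#'   widths 64/128/256/512/512; requires `depth = 4`).
#' @param bottleneck_factor Pooling/upsampling factor at the bottom level
#'   (2, the default, or 4).
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(in_channels = 3, num_classes = 3, depth = 4,
                        widths = c(32, 64, 128, 256, 512),
                        encoder = c("plain", "vgg16"),
                        bottleneck_factor = 2) {
  encoder <- match.arg(encoder)
  if (encoder == "vgg16") {
    if (depth != 4)
      stop("the vgg16 encoder preset requires depth = 4", call. = FALSE)
    widths <- c(64, 128, 256, 512, 512)
  }
  stopifnot(depth >= 1, length(widths) == depth + 1,
            bottleneck_factor %in% c(2, 4))
  if (encoder == "plain" && any(diff(widths) <= 0))
    stop("widths must be strictly increasing along the encoder",
         call. = FALSE)
  conv_counts <- if (encoder == "vgg16") c(2, 2, 3, 3) else rep(2, depth)
  structure(list(in_channels = in_channels, num_classes = num_classes,
                 depth = depth, widths = widths, encoder = encoder,
                 conv_counts = conv_counts,
                 bottleneck_factor = bottleneck_factor),
            class = "unet_config")
}

new_conv <- function(k, cin, cout) {
  list(W = matrix(0, k * k * cin, cout), b = numeric(cout), k = k,
       cin = cin, cout = cout)
}

#' Build a U-Net model
#'
#' Constructs the parameter set for a [unet_config()].  Weights are zero
#' until initialised; pass `seed` to initialise immediately via
#' [init_weights()].
#'
#' @param config A [unet_config()].
#' @param seed Optional seed for immediate weight initialisation.
#' @return An object of class `unet`.
#' @export
build_unet <- function(config, seed = NULL) {
  stopifnot(inherits(config, "unet_config"))
  w <- config$widths
  d <- config$depth
  params <- list()
  cin <- config$in_channels
  for (s in seq_len(d)) {
    for (j in seq_len(config$conv_counts[s])) {
      params[[sprintf("enc%d.%d", s, j)]] <- new_conv(3, cin, w[s])
      cin <- w[s]
    }
  }
  params[["bot.1"]] <- new_conv(3, w[d], w[d + 1])
  params[["bot.2"]] <- new_conv(3, w[d + 1], w[d + 1])
  for (s in d:1) {
    params[[sprintf("dec%d.up", s)]] <- new_conv(3, w[s + 1], w[s])
    params[[sprintf("dec%d.1", s)]] <- new_conv(3, 2 * w[s], w[s])
    params[[sprintf("dec%d.2", s)]] <- new_conv(3, w[s], w[s])
  }
  params[["head"]] <- new_conv(1, w[1], config$num_classes)
  model <- structure(list(config = config, params = params), class = "unet")
  if (!is.null(seed)) model <- init_weights(model, seed)
  model
}

#' Initialise network weights
#'
#' Every convolution weight is drawn from a zero-mean Gaussian with
#' variance `2 / N`, where `N` is the layer fan-in (kernel area times
#' input channels); biases are zero.  Reproducible under `seed`.
#'
#' @param model A [build_unet()] model.
#' @param seed Integer seed.
#' @return The initialised model.
#' @export
init_weights <- function(model, seed = 1) {
  stopifnot(inherits(model, "unet"))
  with_seed(seed, {
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      fan_in <- nrow(p$W)
      model$params[[nm]]$W <- matrix(rnorm(length(p$W), 0,
                                           sqrt(2 / fan_in)),
                                     nrow(p$W), ncol(p$W))
      model$params[[nm]]$b <- numeric(length(p$b))
    }
    model
  })
}

check_input_size <- function(model, h, w) {
  cfg <- model$config
  mult <- 2^(cfg$depth - 1) * cfg$bottleneck_factor
  if (h %% mult != 0 || w %% mult != 0)
    stop("input spatial size ", h, "x", w,
         " must be a multiple of ", mult, " for depth ", cfg$depth,
         call. = FALSE)
}

# forward pass to logits (H x W x num_classes array)
unet_forward <- function(model, x) {
  cfg <- model$config
  check_input_size(model, dim(x)[1], dim(x)[2])
  .unet_infer(unname(model$params), as.integer(cfg$conv_counts),
              cfg$depth, cfg$bottleneck_factor, x)
}

# fused forward + loss + backward; returns list(L, H, J, dW, db) with
# gradients ordered as model$params
unet_loss_grad <- function(model, x, mask, eps = 1,
                           include_background = FALSE) {
  cfg <- model$config
  check_input_size(model, dim(x)[1], dim(x)[2])
  storage.mode(mask) <- "integer"
  .unet_grad(unname(model$params), as.integer(cfg$conv_counts),
             cfg$depth, cfg$bottleneck_factor, x, mask, eps,
             include_background)
}

# grayscale matrix (0-255) or H x W x C array -> normalised input cube
prepare_input <- function(img, in_channels) {
  if (is.matrix(img)) {
    x <- img / 255
    array(rep(x, in_channels), dim = c(nrow(img), ncol(img), in_channels))
  } else {
    stopifnot(length(dim(img)) == 3, dim(img)[3] == in_channels)
    img / 255
  }
}

#' Predict class probabilities and a mask for one image
#'
#' Applies the network and a per-pixel softmax; the mask is the per-pixel
#' argmax with ties broken toward the lower class index.
#'
#' @param object A trained or initialised `unet` model.
#' @param img Grayscale matrix (0--255, replicated across input channels)
#'   or an `H x W x C` array on the 0--255 scale.
#' @param ... Unused.
#' @return List with `prob` (`H x W x num_classes` array, each pixel
#'   summing to 1) and `mask` (integer class matrix).
#' @export
predict.unet <- function(object, img, ...) {
  x <- prepare_input(img, object$config$in_channels)
  logits <- unet_forward(object, x)
  prob <- softmax3(logits)
  mask <- argmax3(prob)
  list(prob = prob, mask = mask)
}

softmax3 <- function(logits) {
  dm <- dim(logits)
  m <- matrix(logits, dm[1] * dm[2], dm[3])
  m <- exp(m - apply(m, 1, max))
  m <- m / rowSums(m)
  array(m, dm)
}

argmax3 <- function(prob) {
  dm <- dim(prob)
  m <- matrix(prob, dm[1] * dm[2], dm[3])
  matrix(as.integer(max.col(m, ties.method = "first") - 1L), dm[1], dm[2])
}

#' Number of trainable parameters of a model
#' @param model A `unet` model.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params,
             function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "U-Net (%s encoder): depth %d, widths %s, %d classes, %s parameters\n",
    cfg$encoder, cfg$depth, paste(cfg$widths, collapse = "/"),
    cfg$num_classes, format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Describe a model layer by layer
#'
#' @param object A `unet` model.
#' @param ... Unused.
#' @return Data frame (layer, kernel, in, out, params), printed with the
#'   total parameter count.
#' @export
summary.unet <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$params), function(nm) {
    p <- object$params[[nm]]
    data.frame(layer = nm, kernel = sprintf("%dx%d", p$k, p$k),
               in_ch = p$cin, out_ch = p$cout,
               params = length(p$W) + length(p$b))
  }))
  print(object)
  tab
}

#' Load externally supplied encoder weights
#'
#' Replaces the encoder (and bottleneck) convolution weights with values
#' from an RDS file holding a named list of `list(W, b)` entries keyed by
#' layer name (`enc1.1`, ..., `bot.2`), e.g. converted VGG16 weights for
#' the `vgg16` preset.  Shapes are validated; nothing is downloaded.
#'
#' @param model A `unet` model.
#' @param path RDS file path.
#' @return The model with replaced weights.
#' @export
load_encoder_weights <- function(model, path) {
  ext <- readRDS(path)
  for (nm in names(ext)) {
    if (!nm %in% names(model$params))
      stop("unknown layer in weight file: ", nm, call. = FALSE)
    if (!grepl("^(enc|bot)", nm))
      stop("only encoder/bottleneck layers may be loaded: ", nm,
           call. = FALSE)
    p <- model$params[[nm]]
    if (!all(dim(ext[[nm]]$W) == dim(p$W)))
      stop("shape mismatch for layer ", nm, call. = FALSE)
    model$params[[nm]]$W <- ext[[nm]]$W
    model$params[[nm]]$b <- as.numeric(ext[[nm]]$b)
  }
  model
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the configuration and all
#' weights.
#'
#' @param model A `unet` model.
#' @param path File path.
#' @return `save_unet` returns the path invisibly; `load_unet` the model.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "unet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet"))
  model
}
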