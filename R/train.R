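#' Training configuration
#'
#' Optimisation and augmentation hyperparameters for the three-phase
#' protocol: `base` (supervised training on labelled mixed images),
#' `single` (pretraining on auto-labelled single-kind images) and
#' `transfer` (fine-tuning the pretrained model on a small labelled
#' mixed set at half the learning rate, all layers trainable).
#'
#' @param phase `"base"`, `"single"` or `"transfer"`.
#' @param epochs Training epochs.
#' @param batch Mini-batch size (default 4).
#' @param lr Learning rate; defaults to 0.001, halved to 0.0005 for the
#'   transfer phase.
#' @param beta1,beta2 Adaptive-moment decay rates (0.9 / 0.999).
#' @param adam_eps Adam numerical epsilon.
#' @param rotation Rotation range in degrees for augmentation.
#' @param scale Scale range for augmentation.
#' @param gray_shift Additive intensity shift range for augmentation.
#' @param augment Enable augmentation.
#' @param include_background Include the background class in the
#'   soft-Jaccard term of the loss.
#' @param freeze_encoder Keep encoder/bottleneck weights fixed (off by
#'   default; fine-tuning trains all layers).
#' @param seed Seed for shuffling, augmentation draws and any weight
#'   initialisation inside the loop.
#' @return A list of class `train_config`.
#' @export
train_config <- function(phase = c("base", "single", "transfer"),
                         epochs = 20, batch = 4, lr = NULL,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         rotation = c(-30, 30), scale = c(0.9, 1.1),
                         gray_shift = c(-20, 20), augment = TRUE,
                         include_background = FALSE,
                         freeze_encoder = FALSE, seed = 1) {
  phase <- match.arg(phase)
  if (is.null(lr)) lr <- if (phase == "transfer") 5e-4 else 1e-3
  stopifnot(batch >= 1, epochs >= 0, lr > 0,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1)
  structure(list(phase = phase, epochs = epochs, batch = batch, lr = lr,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 rotation = rotation, scale = scale,
                 gray_shift = gray_shift, augment = augment,
                 include_background = include_background,
                 freeze_encoder = freeze_encoder, seed = seed),
            class = "train_config")
}

one_hot <- function(mask, k) {
  dm <- dim(mask)
  y <- matrix(0, dm[1] * dm[2], k)
  y[cbind(seq_len(dm[1] * dm[2]), as.vector(mask) + 1L)] <- 1
  y
}

#' Soft Jaccard index of a probability map against a class mask
#'
#' Differentiable Jaccard: per class `c`,
#' `J_c = (sum p_c y_c + eps) / (sum p_c + sum y_c - sum p_c y_c + eps)`
#' over pixels, with one-hot truth `y`.  The result is the mean over the
#' foreground classes present in the truth (background is excluded by
#' default so the dominant class does not swamp the term); 1 when no such
#' class is present.
#'
#' @param prob `H x W x k` probability array.
#' @param true Integer class mask.
#' @param eps Smoothing constant (default 1).
#' @param include_background Include class 0 in the mean.
#' @return Scalar in (0, 1\].
#' @export
soft_jaccard <- function(prob, true, eps = 1, include_background = FALSE) {
  dm <- dim(prob)
  if (!all(dim(true) == dm[1:2]))
    stop("probability map and mask have different shapes", call. = FALSE)
  p <- matrix(prob, dm[1] * dm[2], dm[3])
  y <- one_hot(true, dm[3])
  cls <- which(colSums(y) > 0)
  if (!include_background) cls <- setdiff(cls, 1L)
  if (!length(cls)) return(1)
  S <- colSums(p[, cls, drop = FALSE] * y[, cls, drop = FALSE])
  D <- colSums(p[, cls, drop = FALSE]) + colSums(y[, cls, drop = FALSE]) - S
  mean((S + eps) / (D + eps))
}

#' Combined cross-entropy and soft-Jaccard segmentation loss
#'
#' `L = H - log J`, where `H` is the mean per-pixel cross-entropy of the
#' predicted probabilities against the one-hot truth and `J` is
#' [soft_jaccard()].  Both terms vanish for a perfect one-hot prediction.
#'
#' @inheritParams soft_jaccard
#' @return List with `L`, `H` and `J`.
#' @export
seg_loss <- function(prob, true, eps = 1, include_background = FALSE) {
  dm <- dim(prob)
  if (!all(dim(true) == dm[1:2]))
    stop("probability map and mask have different shapes", call. = FALSE)
  p <- matrix(prob, dm[1] * dm[2], dm[3])
  pt <- p[cbind(seq_len(nrow(p)), as.vector(true) + 1L)]
  H <- -mean(log(pmax(pt, 1e-12)))
  J <- soft_jaccard(prob, true, eps, include_background)
  list(L = H - log(J), H = H, J = J)
}

# gradient of seg_loss with respect to the logits (softmax input);
# returns an H x W x k array.  Used by the training loop.
seg_loss_grad <- function(prob, true, eps = 1,
                          include_background = FALSE) {
  dm <- dim(prob)
  n <- dm[1] * dm[2]
  p <- matrix(prob, n, dm[3])
  y <- one_hot(true, dm[3])
  # cross-entropy: dH/dz = (p - y) / n  (direct softmax shortcut)
  dz <- (p - y) / n
  # -log J term via dJ/dp chained through the softmax
  cls <- which(colSums(y) > 0)
  if (!include_background) cls <- setdiff(cls, 1L)
  if (length(cls)) {
    S <- colSums(p[, cls, drop = FALSE] * y[, cls, drop = FALSE])
    D <- colSums(p[, cls, drop = FALSE]) +
      colSums(y[, cls, drop = FALSE]) - S
    J <- mean((S + eps) / (D + eps))
    g <- matrix(0, n, dm[3])
    for (i in seq_along(cls)) {
      c <- cls[i]
      dJc <- (y[, c] * (D[i] + eps) - (S[i] + eps) * (1 - y[, c])) /
        (D[i] + eps)^2
      g[, c] <- -(1 / J) * dJc / length(cls)
    }
    dz <- dz + p * (g - rowSums(g * p))
  }
  array(dz, dm)
}

#' Joint geometric and photometric augmentation
#'
#' Applies the same random rotation and scaling to image and mask
#' (bilinear resampling for the image, nearest-neighbour for the mask, so
#' class indices are preserved), then an additive gray-value shift to the
#' image only, clamped to \[0, 255\].  Out-of-frame samples replicate the
#' nearest border pixel.
#'
#' @param img Grayscale integer matrix.
#' @param mask Integer class mask of the same shape.
#' @param rotation,scale,gray_shift Ranges for the uniform draws; zero
#'   width ranges give the identity transform.
#' @param seed Optional seed (caller RNG restored).
#' @return List with `img` and `mask`.
#' @export
augment <- function(img, mask, rotation = c(-30, 30),
                    scale = c(0.9, 1.1), gray_shift = c(-20, 20),
                    seed = NULL) {
  stopifnot(all(dim(img) == dim(mask)))
  with_seed(seed, {
    ang <- runif(1, rotation[1], rotation[2]) * pi / 180
    sc <- runif(1, scale[1], scale[2])
    sh <- runif(1, gray_shift[1], gray_shift[2])
    nr <- nrow(img); nc <- ncol(img)
    ctr_r <- (nr + 1) / 2; ctr_c <- (nc + 1) / 2
    out_r <- rep(seq_len(nr), times = nc) - ctr_r
    out_c <- rep(seq_len(nc), each = nr) - ctr_c
    # inverse map: rotate by -ang, scale by 1/sc
    src_r <- (cos(ang) * out_r - sin(ang) * out_c) / sc + ctr_r
    src_c <- (sin(ang) * out_r + cos(ang) * out_c) / sc + ctr_c
    # nearest neighbour for the mask
    mr <- pmin(pmax(round_px(src_r), 1), nr)
    mc <- pmin(pmax(round_px(src_c), 1), nc)
    new_mask <- matrix(mask[cbind(mr, mc)], nr, nc)
    # bilinear for the image, replicate borders
    r0 <- pmin(pmax(floor(src_r), 1), nr); r1 <- pmin(r0 + 1, nr)
    c0 <- pmin(pmax(floor(src_c), 1), nc); c1 <- pmin(c0 + 1, nc)
    fr <- pmin(pmax(src_r - r0, 0), 1); fc <- pmin(pmax(src_c - c0, 0), 1)
    v <- (1 - fr) * (1 - fc) * img[cbind(r0, c0)] +
      fr * (1 - fc) * img[cbind(r1, c0)] +
      (1 - fr) * fc * img[cbind(r0, c1)] +
      fr * fc * img[cbind(r1, c1)]
    new_img <- matrix(as.integer(clamp8(round_px(v + sh))), nr, nc)
    list(img = new_img, mask = new_mask)
  })
}

adam_state <- function(params) {
  lapply(params, function(p)
    list(mW = matrix(0, nrow(p$W), ncol(p$W)), vW = 0 * p$W,
         mb = numeric(length(p$b)), vb = numeric(length(p$b))))
}

adam_step <- function(model, st, gW, gb, cfg, t, trainable) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; lr <- cfg$lr; e <- cfg$adam_eps
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (i in trainable) {
    s <- st[[i]]
    s$mW <- b1 * s$mW + (1 - b1) * gW[[i]]
    s$vW <- b2 * s$vW + (1 - b2) * gW[[i]]^2
    s$mb <- b1 * s$mb + (1 - b1) * gb[[i]]
    s$vb <- b2 * s$vb + (1 - b2) * gb[[i]]^2
    model$params[[i]]$W <- model$params[[i]]$W -
      lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + e)
    model$params[[i]]$b <- model$params[[i]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + e)
    st[[i]] <- s
  }
  list(model = model, st = st)
}

#' Train a U-Net with the combined loss
#'
#' Iterates shuffled mini-batches with optional augmentation, optimises
#' `L = H - log J` by adaptive moment estimation, logs the per-epoch loss
#' decomposition (`loss` and `H` as arithmetic means over steps, `J` as
#' the geometric mean, so `loss = H - log(J)` holds exactly for the
#' logged values) and, when a validation set is given, the validation
#' mIoU; the best-validation weights are kept and restored at the end.
#' Deterministic for a given seed.
#'
#' @param model An initialised `unet` model.
#' @param images List of grayscale matrices.
#' @param masks List of integer class masks (manual labels or
#'   auto-labels), one per image.
#' @param config A [train_config()].
#' @param val_images,val_masks Optional validation set.
#' @param checkpoint Optional path; the best model so far is saved there
#'   after each validation.
#' @param verbose Print a line per epoch.
#' @return Object of class `unet_fit`: the trained model with a `log`
#'   data frame (`epoch`, `loss`, `H`, `J`, `val_miou`) attached.
#' @export
train_unet <- function(model, images, masks, config = train_config(),
                       val_images = NULL, val_masks = NULL,
                       checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "unet"), inherits(config, "train_config"))
  if (!length(images)) stop("empty training split", call. = FALSE)
  if (length(images) != length(masks))
    stop("images and masks differ in length", call. = FALSE)
  for (i in seq_along(images))
    if (!all(dim(images[[i]]) == dim(masks[[i]])))
      stop("image/mask shape mismatch at index ", i, call. = FALSE)
  k <- model$config$num_classes
  trainable <- seq_along(model$params)
  if (config$freeze_encoder)
    trainable <- trainable[!grepl("^(enc|bot)", names(model$params))]

  log_rows <- vector("list", config$epochs)
  best <- list(miou = -Inf, params = model$params)
  with_seed(config$seed, {
    st <- adam_state(model$params)
    t <- 0
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(images))
      sums <- c(L = 0, H = 0, J = 0); nb <- 0
      for (start in seq(1, length(ord), by = config$batch)) {
        idx <- ord[start:min(start + config$batch - 1, length(ord))]
        accW <- NULL; accb <- NULL
        batch_loss <- c(L = 0, H = 0, J = 0)
        for (i in idx) {
          pair <- if (config$augment)
            augment(images[[i]], masks[[i]], config$rotation,
                    config$scale, config$gray_shift)
          else list(img = images[[i]], mask = masks[[i]])
          x <- prepare_input(pair$img, model$config$in_channels)
          g <- unet_loss_grad(model, x, pair$mask,
                              include_background =
                                config$include_background)
          batch_loss <- batch_loss + c(g$L, g$H, log(g$J))
          if (is.null(accW)) {
            accW <- g$dW; accb <- g$db
          } else {
            accW <- Map(`+`, accW, g$dW)
            accb <- Map(`+`, accb, g$db)
          }
        }
        accW <- lapply(accW, `/`, length(idx))
        accb <- lapply(accb, `/`, length(idx))
        t <- t + 1
        up <- adam_step(model, st, accW, accb, config, t, trainable)
        model <- up$model; st <- up$st
        sums <- sums + batch_loss / length(idx)
        nb <- nb + 1
      }
      val_miou <- NA_real_
      if (!is.null(val_images)) {
        cm <- Reduce(`+`, lapply(seq_along(val_images), function(i)
          unclass(confusion(val_masks[[i]],
                            predict(model, val_images[[i]])$mask, k))))
        val_miou <- miou(structure(cm, class = c("confusion", "matrix")))
        if (val_miou >= best$miou) {
          best <- list(miou = val_miou, params = model$params)
          if (!is.null(checkpoint)) save_unet(model, checkpoint)
        }
      }
      # J is aggregated geometrically so that loss = H - log(J) holds
      # exactly for the logged epoch values as it does per step
      log_rows[[ep]] <- data.frame(epoch = ep, loss = sums[["L"]] / nb,
                                   H = sums[["H"]] / nb,
                                   J = exp(sums[["J"]] / nb),
                                   val_miou = val_miou)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  H %.4f  J %.4f  val %.4f",
                        ep, sums[["L"]] / nb, sums[["H"]] / nb,
                        exp(sums[["J"]] / nb), val_miou))
    }
    if (is.finite(best$miou)) model$params <- best$params
  })
  model$log <- if (config$epochs > 0) do.call(rbind, log_rows) else
    data.frame(epoch = integer(), loss = numeric(), H = numeric(),
               J = numeric(), val_miou = numeric())
  model$phase <- config$phase
  class(model) <- c("unet_fit", "unet")
  model
}

#' Fine-tune a pretrained model on a small labelled set
#'
#' Same loop as [train_unet()] with transfer-phase defaults (half
#' learning rate, all layers trainable).  Zero epochs return the model
#' unchanged.
#'
#' @param model A pretrained `unet` model.
#' @param images,masks Small labelled mixed-cell split.
#' @param config A [train_config()]; its phase is forced to `transfer`.
#' @param ... Passed to [train_unet()].
#' @return A `unet_fit` object.
#' @export
finetune_unet <- function(model, images, masks,
                          config = train_config(phase = "transfer",
                                                epochs = 10), ...) {
  if (config$phase != "transfer") {
    config$phase <- "transfer"
  }
  if (config$epochs == 0) {
    model$log <- data.frame(epoch = integer(), loss = numeric(),
                            H = numeric(), J = numeric(),
                            val_miou = numeric())
    model$phase <- "transfer"
    class(model) <- c("unet_fit", "unet")
    return(model)
  }
  train_unet(model, images, masks, config, ...)
}

#' @export
print.unet_fit <- function(x, ...) {
  NextMethod()
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("trained %d epoch(s) [phase %s]: final loss %.4f (H %.4f, J %.4f)%s\n",
                nrow(x$log), x$phase, last$loss, last$H, last$J,
                if (is.na(last$val_miou)) "" else
                  sprintf(", val mIoU %.4f", last$val_miou)))
  }
  invisible(x)
}
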