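# Independent brute-force reference implementations used to validate the
# package's operators.  They share no code with the implementation: plain
# nested loops and set arithmetic only.

# window min/max filter with replicate padding, full square support
oracle_minmax <- function(img, size, type = c("min", "max")) {
  type <- match.arg(type)
  f <- if (type == "min") min else max
  h <- (size - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (r in seq_len(nr))
    for (c in seq_len(nc)) {
      rr <- pmin(pmax(r + (-h:h), 1), nr)
      cc <- pmin(pmax(c + (-h:h), 1), nc)
      out[r, c] <- f(img[rr, cc])
    }
  out
}

# symmetric (half-sample) reflection of an out-of-range index
oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# dense 2-D convolution of a normalised Gaussian, reflective borders
oracle_gauss_conv <- function(img, size, sigma) {
  h <- (size - 1) / 2
  k1 <- exp(-((-h:h)^2) / (2 * sigma^2))
  k2 <- outer(k1, k1) / sum(k1)^2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr))
    for (c in seq_len(nc)) {
      s <- 0
      for (dr in -h:h)
        for (dc in -h:h)
          s <- s + k2[dr + h + 1, dc + h + 1] *
            img[oracle_reflect(r + dr, nr), oracle_reflect(c + dc, nc)]
      out[r, c] <- s
    }
  out
}

# per-pixel Gaussian-weighted-mean threshold, strict inequality
oracle_adaptive <- function(img, window, C, sigma, darker = TRUE) {
  wm <- oracle_gauss_conv(img, window, sigma)
  if (darker) (img < wm - C) + 0L else (img > wm + C) + 0L
}

# connected components by breadth-first flood fill
oracle_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8)
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  else
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  nextlab <- 0L
  for (r in seq_len(nr))
    for (c in seq_len(nc)) {
      if (mask[r, c] == 0 || lab[r, c] != 0) next
      nextlab <- nextlab + 1L
      queue <- matrix(c(r, c), 1)
      lab[r, c] <- nextlab
      while (nrow(queue)) {
        p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (o in seq_len(nrow(offs))) {
          r2 <- p[1] + offs[o, 1]; c2 <- p[2] + offs[o, 2]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              mask[r2, c2] != 0 && lab[r2, c2] == 0) {
            lab[r2, c2] <- nextlab
            queue <- rbind(queue, c(r2, c2))
          }
        }
      }
    }
  lab
}

# pixel-loop confusion matrix and derived metrics
oracle_confusion <- function(true, pred, k1) {
  cm <- matrix(0, k1, k1)
  for (r in seq_len(nrow(true)))
    for (c in seq_len(ncol(true)))
      cm[true[r, c] + 1, pred[r, c] + 1] <- cm[true[r, c] + 1,
                                               pred[r, c] + 1] + 1
  cm
}

oracle_iou_per_class <- function(cm) {
  k1 <- nrow(cm)
  sapply(seq_len(k1), function(i) {
    denom <- sum(cm[i, ]) + sum(cm[, i]) - cm[i, i]
    if (denom == 0) NaN else cm[i, i] / denom
  })
}

oracle_miou <- function(cm) {
  iou <- oracle_iou_per_class(cm)
  mean(iou[!is.nan(iou)])
}

oracle_fwiou <- function(cm) {
  iou <- oracle_iou_per_class(cm)
  freq <- rowSums(cm) / sum(cm)
  s <- 0
  for (i in seq_along(iou)) if (freq[i] > 0) s <- s + freq[[i]] * iou[[i]]
  s
}

oracle_jaccard <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
  }
  if (na + nb == 0) 1 else inter / (na + nb - inter)
}

oracle_dice <- function(a, b) {
  inter <- sum(a & b)
  if (sum(a) + sum(b) == 0) 1 else 2 * inter / (sum(a) + sum(b))
}

# direct evaluation of the combined loss from first principles
oracle_loss <- function(prob, truth, eps = 1) {
  k <- dim(prob)[3]
  H <- 0; n <- 0
  for (r in seq_len(nrow(truth)))
    for (c in seq_len(ncol(truth))) {
      H <- H - log(max(prob[r, c, truth[r, c] + 1], 1e-12))
      n <- n + 1
    }
  H <- H / n
  cls <- setdiff(sort(unique(as.vector(truth))), 0)
  J <- if (!length(cls)) 1 else {
    js <- sapply(cls, function(cl) {
      p <- as.vector(prob[, , cl + 1])
      y <- as.vector(truth == cl) + 0
      s <- sum(p * y)
      (s + eps) / (sum(p) + sum(y) - s + eps)
    })
    mean(js)
  }
  list(L = H - log(J), H = H, J = J)
}

random_mask <- function(nr, nc, k = 2, p_fg = 0.4) {
  matrix(sample(0:(k - 1), nr * nc, replace = TRUE,
                prob = c(1 - p_fg, rep(p_fg / (k - 1), k - 1))),
         nr, nc)
}

tiny_unet <- function(seed = 1, depth = 2, widths = c(4, 8, 16)) {
  build_unet(unet_config(depth = depth, widths = widths), seed = seed)
}
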