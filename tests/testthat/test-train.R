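test_that("soft Jaccard matches direct summation and is monotone", {
  set.seed(31)
  truth <- random_mask(16, 16, 3)
  prob <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  prob <- prob / array(apply(prob, c(1, 2), sum), dim = dim(prob))
  o <- oracle_loss(prob, truth)
  expect_equal(soft_jaccard(prob, truth), o$J, tolerance = 1e-12)

  # uniform 1/3 prediction, truth half class 1: closed-form check
  tr <- matrix(0L, 16, 16); tr[, 1:8] <- 1L
  pu <- array(1 / 3, dim = c(16, 16, 3))
  n <- 256; s <- (1 / 3) * 128
  expect_equal(soft_jaccard(pu, tr),
               (s + 1) / (n / 3 + 128 - s + 1), tolerance = 1e-12)

  # one-hot prediction equal to truth: J = 1 up to the epsilon smoothing
  ph <- array(0, dim = c(32, 32, 3))
  trh <- random_mask(32, 32, 3, p_fg = 0.5)
  for (k in 0:2) ph[, , k + 1][trh == k] <- 1
  expect_gt(soft_jaccard(ph, trh), 1 - 1e-3)

  # moving probability mass toward the true class increases J
  p2 <- pu
  p2[1, 1, ] <- c(0.2, 0.6, 0.2)  # truth at (1,1) is class 1
  expect_gt(soft_jaccard(p2, tr), soft_jaccard(pu, tr))

  expect_error(soft_jaccard(pu, matrix(0L, 4, 4)), "shapes")
})

test_that("the combined loss decomposes as L = H - log J", {
  set.seed(32)
  truth <- random_mask(16, 16, 3)
  prob <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  prob <- prob / array(apply(prob, c(1, 2), sum), dim = dim(prob))
  ls <- seg_loss(prob, truth)
  o <- oracle_loss(prob, truth)
  expect_equal(ls$L, o$L, tolerance = 1e-12)
  expect_equal(ls$H, o$H, tolerance = 1e-12)
  expect_equal(ls$L, ls$H - log(ls$J), tolerance = 1e-12)
  expect_gt(ls$L, 0)

  # perfect one-hot prediction: both terms vanish (epsilon-tolerance)
  ph <- array(0, dim = c(32, 32, 3))
  trh <- random_mask(32, 32, 3, p_fg = 0.5)
  for (k in 0:2) ph[, , k + 1][trh == k] <- 1
  lp <- seg_loss(ph, trh)
  expect_lt(lp$H, 1e-10)
  expect_lt(lp$L, 1e-3)

  # strictly decreasing as mass moves to the true class at one pixel,
  # the rest of the prediction held fixed and correct
  tr1 <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  mk <- function(p1) {
    a <- array(0, dim = c(2, 2, 3))
    a[, , 1] <- 1                               # correct background
    a[1, 1, ] <- c((1 - p1) / 2, p1, (1 - p1) / 2)
    a
  }
  losses <- sapply(c(0.34, 0.5, 0.7, 0.9, 0.99),
                   function(p) seg_loss(mk(p), tr1)$L)
  expect_true(all(diff(losses) < 0))
})

test_that("the fused training gradient agrees with numerical differentiation", {
  set.seed(33)
  m <- tiny_unet(seed = 42)
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  mask <- random_mask(16, 16, 3)
  g <- cellseg:::unet_loss_grad(m, x, mask)
  lossfn <- function(mm)
    seg_loss(cellseg:::softmax3(cellseg:::unet_forward(mm, x)), mask)$L
  expect_equal(g$L, lossfn(m), tolerance = 1e-10)
  eps <- 1e-5
  for (li in sample(seq_along(m$params), 4)) {
    W <- m$params[[li]]$W
    i <- sample(nrow(W), 1); j <- sample(ncol(W), 1)
    mp <- m; mp$params[[li]]$W[i, j] <- W[i, j] + eps
    mm2 <- m; mm2$params[[li]]$W[i, j] <- W[i, j] - eps
    num <- (lossfn(mp) - lossfn(mm2)) / (2 * eps)
    expect_equal(g$dW[[li]][i, j], num, tolerance = 1e-4)
  }
})

test_that("augmentation is label-preserving, seeded, and exact at 90 degrees", {
  set.seed(34)
  img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  mask <- random_mask(32, 32, 3)

  # zero-width ranges give the identity
  id <- augment(img, mask, rotation = c(0, 0), scale = c(1, 1),
                gray_shift = c(0, 0))
  expect_identical(id$img, img)
  expect_identical(id$mask, mask)

  # class values never leave the original set
  for (s in 1:5) {
    a <- augment(img, mask, seed = s)
    expect_true(all(a$mask %in% unique(as.vector(mask))))
    expect_identical(augment(img, mask, seed = s)$mask, a$mask)
  }

  # 90-degree rotation equals the index-remap oracle:
  # out(r, c) <- in(n + 1 - c, r) for rotation about the centre
  r90 <- augment(img, mask, rotation = c(90, 90), scale = c(1, 1),
                 gray_shift = c(0, 0))
  n <- 32
  oracle <- matrix(0L, n, n)
  for (r in seq_len(n)) for (c in seq_len(n))
    oracle[r, c] <- mask[n + 1 - c, r]
  expect_identical(r90$mask, oracle)

  # gray shift is clamped to [0, 255]
  sh <- augment(img, mask, rotation = c(0, 0), scale = c(1, 1),
                gray_shift = c(300, 300))
  expect_true(all(sh$img == 255L))
})

test_that("training reduces the loss and logs the exact decomposition", {
  cfg <- synth_config(size = 32, rbc_radius = c(3, 4),
                      mac_radius = c(6, 8), rbc_count = c(1, 3),
                      mac_count = c(0, 1), adhesion_p = 0)
  set.seed(35)
  scenes <- lapply(1:8, function(i) generate_scene(cfg, "mixed"))
  imgs <- lapply(scenes, `[[`, "image")
  masks <- lapply(scenes, `[[`, "mask")
  net <- build_unet(unet_config(depth = 2, widths = c(6, 12, 24)),
                    seed = 1)
  fit <- train_unet(net, imgs, masks,
                    train_config(phase = "base", epochs = 6, seed = 1))
  expect_s3_class(fit, "unet_fit")
  expect_identical(nrow(fit$log), 6L)
  expect_lt(fit$log$loss[6], fit$log$loss[1])
  expect_equal(fit$log$loss, fit$log$H - log(fit$log$J), tolerance = 1e-6)

  # determinism under the seed
  fit2 <- train_unet(net, imgs, masks,
                     train_config(phase = "base", epochs = 6, seed = 1))
  expect_identical(fit$params, fit2$params)

  # validation logging and checkpointing plumbing
  ck <- tempfile(fileext = ".rds")
  fit3 <- train_unet(net, imgs[1:4], masks[1:4],
                     train_config(phase = "base", epochs = 1, seed = 1),
                     val_images = imgs[5:6], val_masks = masks[5:6],
                     checkpoint = ck)
  expect_identical(nrow(fit3$log), 1L)
  expect_false(is.na(fit3$log$val_miou[1]))
  expect_true(file.exists(ck))
})

test_that("fine-tuning defaults to half learning rate and can be a no-op", {
  cfg0 <- train_config(phase = "transfer")
  expect_identical(cfg0$lr, 5e-4)
  expect_identical(train_config(phase = "single")$lr, 1e-3)

  m <- tiny_unet(seed = 5)
  ft0 <- finetune_unet(m, list(), list(),
                       train_config(phase = "transfer", epochs = 0))
  expect_identical(ft0$params, m$params)

  # loss decreases over fine-tuning on a small split
  cfg <- synth_config(size = 32, rbc_radius = c(3, 4),
                      mac_radius = c(6, 8), rbc_count = c(1, 3),
                      mac_count = c(0, 1), adhesion_p = 0)
  set.seed(36)
  scenes <- lapply(1:4, function(i) generate_scene(cfg, "mixed"))
  net <- build_unet(unet_config(depth = 2, widths = c(6, 12, 24)),
                    seed = 2)
  ft <- finetune_unet(net, lapply(scenes, `[[`, "image"),
                      lapply(scenes, `[[`, "mask"),
                      train_config(phase = "transfer", epochs = 5,
                                   seed = 2))
  expect_lt(ft$log$loss[5], ft$log$loss[1])
  expect_identical(ft$phase, "transfer")
})

test_that("empty splits and mismatched shapes are rejected", {
  m <- tiny_unet()
  expect_error(train_unet(m, list(), list(), train_config(epochs = 1)),
               "empty")
  expect_error(train_unet(m, list(matrix(0L, 16, 16)),
                          list(matrix(0L, 8, 8)),
                          train_config(epochs = 1)), "mismatch")
})
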