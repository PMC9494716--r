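test_that("output shape equals input shape across configurations", {
  # tiny preset: depth 3, widths 8/16/32/64, 64x64 input
  m <- build_unet(unet_config(depth = 3, widths = c(8, 16, 32, 64)),
                  seed = 1)
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  logits <- cellseg:::unet_forward(m, x)
  expect_identical(dim(logits), c(64L, 64L, 3L))

  # smaller net, rectangular input
  m2 <- tiny_unet()
  x2 <- array(runif(16 * 24 * 3), dim = c(16, 24, 3))
  expect_identical(dim(cellseg:::unet_forward(m2, x2)), c(16L, 24L, 3L))

  # indivisible size is rejected with the required multiple in the error
  m4 <- build_unet(unet_config(), seed = 1)
  x3 <- array(0, dim = c(60, 60, 3))
  expect_error(cellseg:::unet_forward(m4, x3), "multiple of 16")
})

test_that("the full-scale preset maps a 3-channel 512-multiple input to 3 classes", {
  cfg <- unet_config()
  expect_identical(cfg$widths, c(32, 64, 128, 256, 512))
  m <- build_unet(cfg, seed = 1)
  # run at 128x128 (same divisibility contract, feasible on CPU) and
  # check the head really maps 32 channels to num_classes
  x <- array(runif(128 * 128 * 3), dim = c(128, 128, 3))
  expect_identical(dim(cellseg:::unet_forward(m, x)), c(128L, 128L, 3L))
  expect_identical(dim(m$params$head$W), c(32L, 3L))
})

test_that("vgg16 encoder preset has the truncated 12-convolution stack", {
  cfg <- unet_config(encoder = "vgg16")
  expect_identical(cfg$conv_counts, c(2, 2, 3, 3))
  expect_identical(cfg$widths, c(64, 128, 256, 512, 512))
  m <- build_unet(cfg, seed = 1)
  enc_names <- grep("^(enc|bot)", names(m$params), value = TRUE)
  expect_length(enc_names, 12)
  expect_error(unet_config(encoder = "vgg16", depth = 3), "depth = 4")

  # externally supplied encoder weights load with shape validation
  ext <- list(enc1.1 = list(W = matrix(0.5, 27, 64), b = rep(1, 64)))
  p <- tempfile(fileext = ".rds"); saveRDS(ext, p)
  m2 <- load_encoder_weights(m, p)
  expect_true(all(m2$params$enc1.1$W == 0.5))
  bad <- list(dec1.up = list(W = matrix(0, 2, 2), b = 0))
  saveRDS(bad, p)
  expect_error(load_encoder_weights(m, p), "encoder")
})

test_that("weight initialisation is He-scaled, zero-biased, reproducible", {
  m1 <- tiny_unet(seed = 7)
  m2 <- tiny_unet(seed = 7)
  expect_identical(m1$params, m2$params)
  m3 <- tiny_unet(seed = 8)
  expect_false(identical(m1$params, m3$params))

  for (p in m1$params) expect_true(all(p$b == 0))

  # sample variance of a large layer approximates 2 / fan-in
  big <- build_unet(unet_config(depth = 2, widths = c(64, 128, 256)),
                    seed = 1)
  W <- big$params$enc2.2$W           # fan-in 9 * 128 = 1152
  expect_equal(var(as.vector(W)), 2 / 1152, tolerance = 0.2 * 2 / 1152)
  expect_lt(abs(mean(as.vector(W))), 3 * sqrt(2 / 1152 / length(W)) * 10)
})

test_that("prediction yields normalised probabilities and first-index ties", {
  m <- tiny_unet(seed = 2)
  img <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
  pr <- predict(m, img)
  expect_identical(dim(pr$prob), c(16L, 16L, 3L))
  sums <- apply(pr$prob, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  # repeat call is bit-identical
  expect_identical(predict(m, img), pr)
  # argmax contract with deterministic tie-break toward lower class
  p <- array(1 / 3, dim = c(2, 2, 3))
  expect_true(all(cellseg:::argmax3(p) == 0L))
  p[1, 1, ] <- c(0.1, 0.2, 0.7)
  expect_identical(cellseg:::argmax3(p)[1, 1], 2L)
})

test_that("shifting the input shifts the interior of the output", {
  m <- tiny_unet(seed = 3)               # depth 2 -> period 4
  set.seed(9)
  base <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  big <- matrix(127L, 56, 56)
  big[9:48, 9:48] <- base
  shifted <- matrix(127L, 56, 56)
  shifted[13:52, 13:52] <- base          # shifted by one period (4 px)
  a <- predict(m, big)$prob
  b <- predict(m, shifted)$prob
  # the receptive field spans the whole frame, so border effects never
  # vanish entirely; covariance shows as the aligned windows agreeing
  # far better than misaligned ones
  aligned <- mean(abs(a[21:36, 21:36, ] - b[25:40, 25:40, ]))
  misaligned <- mean(abs(a[21:36, 21:36, ] - b[21:36, 21:36, ]))
  expect_lt(aligned, 1e-3)
  expect_gt(misaligned, 20 * aligned)
})

test_that("parameter count is a pure function of the configuration", {
  f <- function() n_params(build_unet(unet_config(depth = 2,
                                                  widths = c(4, 8, 16)),
                                      seed = sample(1e4, 1)))
  expect_identical(f(), f())
  # hand-counted tiny model: conv params = k^2*cin*cout + cout
  m <- build_unet(unet_config(depth = 1, widths = c(4, 8),
                              num_classes = 2), seed = 1)
  expected <- (9 * 3 * 4 + 4) + (9 * 4 * 4 + 4) +      # enc1
    (9 * 4 * 8 + 8) + (9 * 8 * 8 + 8) +                # bottleneck
    (9 * 8 * 4 + 4) + (9 * 8 * 4 + 4) + (9 * 4 * 4 + 4) + # dec1
    (1 * 4 * 2 + 2)                                    # head
  expect_equal(n_params(m), expected)
  tab <- summary(m)
  expect_equal(sum(tab$params), expected)
})

test_that("checkpoints round-trip through a single file", {
  m <- tiny_unet(seed = 4)
  p <- tempfile(fileext = ".rds")
  save_unet(m, p)
  m2 <- load_unet(p)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
})
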