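test_that("gaussian smoothing matches a dense convolution oracle", {
  # normalised kernels preserve constants
  const <- matrix(100L, 8, 8)
  expect_identical(gaussian_smooth(const, 3, 0.8), const)
  expect_identical(gaussian_smooth(const, 5, 2), const)

  # impulse response equals round(255 * K)
  imp <- matrix(0L, 9, 9); imp[5, 5] <- 255L
  got <- gaussian_smooth(imp, 3, 0.8)
  h <- exp(-((-1:1)^2) / (2 * 0.8^2))
  K <- outer(h, h) / sum(h)^2
  expect_identical(got[4:6, 4:6],
                   matrix(as.integer(floor(255 * K + 0.5)), 3, 3))

  # linearity before rounding: smoothed sums equal summed raw convolutions
  set.seed(2)
  a <- matrix(sample(0:100, 64, TRUE), 8, 8)
  b <- matrix(sample(0:100, 64, TRUE), 8, 8)
  ka <- oracle_gauss_conv(a, 3, 0.8)
  kb <- oracle_gauss_conv(b, 3, 0.8)
  kab <- oracle_gauss_conv(a + b, 3, 0.8)
  expect_equal(kab, ka + kb, tolerance = 1e-12)

  # full-matrix agreement with the dense oracle on random images
  for (i in 1:5) {
    img <- matrix(sample(0:255, 100, TRUE), 10, 10)
    expect_identical(gaussian_smooth(img, 5, 1.2),
                     matrix(as.integer(
                       floor(oracle_gauss_conv(img, 5, 1.2) + 0.5)),
                       10, 10))
  }

  expect_error(gaussian_smooth(const, 4, 1), "odd")
})

test_that("adaptive threshold equals the brute-force weighted-mean oracle", {
  # constant image with positive offset is all background
  const <- matrix(77L, 6, 6)
  expect_true(all(adaptive_threshold(const, 3, 2) == 0))
  # and even at C = 0 ties go to background
  expect_true(all(adaptive_threshold(const, 3, 0) == 0))

  # single bright row example against the oracle
  row <- matrix(c(10L, 10L, 200L, 10L, 10L), 1, 5)
  sig <- cellseg:::adaptive_sigma(3)
  expect_identical(adaptive_threshold(row, 3, 0),
                   oracle_adaptive(row, 3, 0, sig))

  # polarity symmetry: inverting the image and flipping polarity keeps
  # the foreground set when C = 0
  set.seed(3)
  img <- matrix(sample(0:255, 144, TRUE), 12, 12)
  expect_identical(adaptive_threshold(img, 5, 0, "darker"),
                   adaptive_threshold(255L - img, 5, 0, "lighter"))

  for (i in 1:100) {
    img <- matrix(sample(0:255, 256, TRUE), 16, 16)
    w <- sample(c(3, 5), 1); C <- sample(0:5, 1)
    expect_identical(adaptive_threshold(img, w, C),
                     oracle_adaptive(img, w, C, cellseg:::adaptive_sigma(w)),
                     info = sprintf("case %d w=%d C=%d", i, w, C))
  }

  expect_error(adaptive_threshold(img, 4, 2), "odd")
})

test_that("erosion and dilation equal brute-force window min/max", {
  # 3x3 square erodes to its centre pixel
  sq <- matrix(0L, 7, 7); sq[3:5, 3:5] <- 1L
  er <- erode(sq, 3)
  expect_identical(which(er == 1L), which(matrix(seq_len(49), 7, 7) == 25))
  expect_true(all(erode(matrix(0L, 5, 5), 3) == 0))
  # single pixel dilates to the full 3x3 square
  px <- matrix(0L, 7, 7); px[4, 4] <- 1L
  expect_identical(dilate(px, 3), sq)

  set.seed(4)
  for (i in 1:200) {
    img <- matrix(sample(0:1, 256, TRUE), 16, 16)
    expect_identical(erode(img, 3), oracle_minmax(img, 3, "min"))
    expect_identical(dilate(img, 3), oracle_minmax(img, 3, "max"))
  }
  # grayscale too, and a 5x5 support
  g <- matrix(sample(0:255, 256, TRUE), 16, 16)
  expect_identical(erode(g, 5), oracle_minmax(g, 5, "min"))
  expect_identical(dilate(g, 5), oracle_minmax(g, 5, "max"))
})

test_that("opening splits bridges, is idempotent and anti-extensive", {
  # two 5x5 squares joined by a 1-px bridge separate under 3x3 opening
  m <- matrix(0L, 9, 15)
  m[3:7, 2:6] <- 1L; m[3:7, 10:14] <- 1L; m[5, 7:9] <- 1L
  expect_identical(max(oracle_components(m)), 1L)
  op <- open_morph(m, 3)
  expect_identical(max(oracle_components(op)), 2L)

  # an isolated square at least as large as the kernel is unchanged
  sq <- matrix(0L, 9, 9); sq[3:7, 3:7] <- 1L
  expect_identical(open_morph(sq, 3), sq)

  set.seed(5)
  for (i in 1:20) {
    x <- matrix(sample(0:1, 144, TRUE, prob = c(0.4, 0.6)), 12, 12)
    op <- open_morph(x, 3)
    expect_identical(open_morph(op, 3), op)       # idempotent
    expect_true(all(op <= x))                     # opening is anti-extensive
    expect_true(all(x <= erode(dilate(x, 3), 3))) # closing is extensive
  }
})

test_that("contour extraction counts match flood fill; filling inverts it", {
  expect_identical(find_contours(matrix(0L, 5, 5)), list())

  sq <- matrix(0L, 6, 6); sq[2:4, 2:4] <- 1L
  cts <- find_contours(sq)
  expect_length(cts, 1)
  expect_identical(cts[[1]]$area, 9L)
  expect_true(cts[[1]]$closed)

  set.seed(6)
  for (i in 1:100) {
    m <- matrix(sample(0:1, 32 * 32, TRUE, prob = c(0.7, 0.3)), 32, 32)
    cts <- find_contours(m)
    expect_identical(length(cts), max(oracle_components(m)),
                     info = paste("case", i))
    # consecutive boundary points are 8-connected and the curve closes
    for (ct in cts) {
      if (nrow(ct$points) > 1) {
        d <- abs(diff(ct$points))
        expect_true(all(pmax(d[, 1], d[, 2]) == 1))
        expect_lte(max(abs(ct$points[1, ] - ct$points[nrow(ct$points), ])), 1)
      }
    }
    # round trip: filling recovers the hole-filled mask exactly
    filled <- fill_contours(cts, dim(m), 1)
    ref <- matrix(0L, 32, 32)
    ref[cellseg:::.fill_holes(m > 0)] <- 1L
    expect_identical(filled, ref)
  }

  # a ring becomes a full disc
  ring <- matrix(0L, 9, 9)
  for (r in 1:9) for (c in 1:9)
    if (abs(sqrt((r - 5)^2 + (c - 5)^2) - 3) < 0.8) ring[r, c] <- 1L
  cts <- find_contours(ring)
  expect_length(cts, 1)
  disc <- fill_contours(cts, c(9, 9), 1)
  expect_true(all(disc[ring == 1] == 1))
  expect_identical(disc[5, 5], 1L)  # hole closed
  inside <- sum(disc)
  expect_gt(inside, sum(ring))
})

test_that("small-area filtering keeps order and respects the bound", {
  m <- matrix(0L, 12, 24)
  m[2:3, 2:4] <- 1L          # area 6
  m[6:10, 6:10] <- 1L        # area 25
  cts <- find_contours(m)
  areas <- sapply(cts, `[[`, "area")
  expect_identical(sort(areas), c(6L, 25L))
  expect_identical(sapply(filter_small(cts, 10), `[[`, "area"), 25L)
  expect_identical(filter_small(cts, 0), cts)
  expect_identical(filter_small(cts, 100), list())
})

test_that("out-of-bounds contours are rejected when filling", {
  ct <- list(list(points = cbind(c(1, 2), c(5, 6)), closed = TRUE,
                  area = 2))
  expect_error(fill_contours(ct, c(4, 4), 1), "out of bounds")
})

test_that("auto-labelling a blank image yields an all-background mask", {
  blank <- matrix(180L, 32, 32)
  al <- autolabel_image(blank, autolabel_config(), 1)
  expect_true(all(al == 0))
})

test_that("auto-labels recover synthetic ground truth closely", {
  cfg <- synth_config(size = 128, rbc_count = c(4, 8), mac_count = c(1, 2))
  ious <- sapply(1:5, function(s) {
    sc <- generate_scene(cfg, "rbc", seed = s)
    al <- autolabel_image(sc$image, autolabel_config_for(cfg, "rbc"), 1)
    expect_true(all(al %in% c(0L, 1L)))
    jaccard(sc$mask == 1, al == 1)
  })
  expect_gt(mean(ious), 0.9)
})

test_that("morphology restores adhesive macrophage counts", {
  cfg <- synth_config(size = 128, adhesion_p = 1, mac_count = c(2, 2),
                      rbc_count = c(0, 0))
  hit_m <- 0; hit_n <- 0; n_adh <- 0
  for (s in 1:10) {
    sc <- generate_scene(cfg, "macrophage", seed = s)
    if (!any(sc$instances$adhesive)) next
    n_adh <- n_adh + 1
    conf <- autolabel_config_for(cfg, "macrophage")
    al_m <- autolabel_image(sc$image, conf, 2)
    conf$morphology <- FALSE
    al_n <- autolabel_image(sc$image, conf, 2)
    if (max(oracle_components(al_m)) == sc$counts[["2"]]) hit_m <- hit_m + 1
    if (max(oracle_components(al_n)) < sc$counts[["2"]]) hit_n <- hit_n + 1
  }
  expect_gt(n_adh, 4)
  expect_gt(hit_m, n_adh / 2)   # opening mostly restores the true count
  expect_gt(hit_n, n_adh / 2)   # without it the pair stays merged
})
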