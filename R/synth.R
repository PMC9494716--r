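#' Configuration for the synthetic cell-scene generator
#'
#' The generator emulates bright-field images of red blood cells (RBCs,
#' small near-circular discs) and macrophages (larger adherent cells) on a
#' brighter background, with per-cell intensity jitter, additive Gaussian
#' sensor noise, a smooth linear illumination gradient, and occasional
#' adhesive macrophage pairs placed tangent to each other, so that
#' thresholding sees one blob with a thin neck unless morphological
#' opening separates it.
#'
#' Default pixel radii preserve the ~2.5x physical size ratio between
#' macrophages (13--20 um) and RBCs (5--7 um); the pixels-per-micron
#' factor is free, so radii are configured directly in pixels.
#'
#' @param size Image side length in pixels (square images).
#' @param rbc_radius,mac_radius Length-2 ranges of cell radii in pixels;
#'   the macrophage minimum must exceed the RBC maximum so the classes
#'   stay separable by area.
#' @param rbc_count,mac_count Length-2 inclusive ranges of per-image cell
#'   counts (mixed scenes; single-kind scenes use only their own class).
#' @param adhesion_p Probability that a macrophage beyond the first in a
#'   single-kind macrophage scene is placed adhesively against an
#'   earlier macrophage, in \[0,1\].  Mixed scenes place all cells
#'   independently (suspended preparations).
#' @param adhesion_bridge Half-width in pixels of the optical contact
#'   zone rendered between an adhesive pair (the membranes of adherent
#'   cells appear merged over a contact zone); the ground-truth mask
#'   keeps the instances separate.
#' @param cell_means Named mean intensities for cell interiors,
#'   `c(rbc = , mac = )`, on the 0--255 scale (darker polarity).
#' @param bg_mean Background mean intensity.
#' @param intensity_jitter Half-width of the uniform per-cell intensity
#'   jitter.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param gradient_amp Amplitude of the linear illumination gradient
#'   (approximate intensity change across the frame).
#' @param polarity `"darker"` (cells darker than background, default) or
#'   `"lighter"` (intensities mirrored).
#' @param ecc_jitter Maximum relative axis-ratio jitter of the ellipses.
#' @param max_tries Placement attempts per cell before failing.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(size = 256,
                         rbc_radius = c(4, 6),
                         mac_radius = c(10, 16),
                         rbc_count = c(8, 20),
                         mac_count = c(1, 4),
                         adhesion_p = 0.2,
                         adhesion_bridge = 2,
                         cell_means = c(rbc = 100, mac = 70),
                         bg_mean = 180,
                         intensity_jitter = 10,
                         noise_sd = 10,
                         gradient_amp = 20,
                         polarity = c("darker", "lighter"),
                         ecc_jitter = 0.15,
                         max_tries = 200) {
  polarity <- match.arg(polarity)
  stopifnot(size >= 16,
            length(rbc_radius) == 2, length(mac_radius) == 2,
            all(rbc_radius > 0), all(mac_radius > 0),
            diff(rbc_radius) >= 0, diff(mac_radius) >= 0,
            mac_radius[1] > rbc_radius[2],
            adhesion_p >= 0, adhesion_p <= 1, adhesion_bridge >= 0,
            all(c("rbc", "mac") %in% names(cell_means)),
            noise_sd >= 0, gradient_amp >= 0, intensity_jitter >= 0,
            ecc_jitter >= 0, ecc_jitter < 0.5)
  structure(list(size = size, rbc_radius = rbc_radius,
                 mac_radius = mac_radius, rbc_count = rbc_count,
                 mac_count = mac_count, adhesion_p = adhesion_p,
                 adhesion_bridge = adhesion_bridge,
                 cell_means = cell_means, bg_mean = bg_mean,
                 intensity_jitter = intensity_jitter, noise_sd = noise_sd,
                 gradient_amp = gradient_amp, polarity = polarity,
                 ecc_jitter = ecc_jitter, max_tries = max_tries),
            class = "synth_config")
}

#' Global threshold guaranteed to separate cells from background
#'
#' In the zero-noise, zero-gradient limit every cell pixel lies strictly
#' below this value and every background pixel strictly above it (darker
#' polarity); this is the generator's contrast contract.
#'
#' @param config A [synth_config()].
#' @return Scalar intensity threshold.
#' @export
separation_threshold <- function(config) {
  (max(config$cell_means) + config$bg_mean) / 2
}

# rasterize a rotated ellipse; returns 1-based (row, col) index matrix
ellipse_pixels <- function(r0, c0, a, b, theta, nr, nc) {
  ext <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
  cols <- max(1L, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
  dr <- rep(rows - r0, times = length(cols))
  dc <- rep(cols - c0, each = length(rows))
  u <- (dc * cos(theta) + dr * sin(theta)) / a
  v <- (-dc * sin(theta) + dr * cos(theta)) / b
  keep <- u * u + v * v <= 1
  cbind(rep(rows, times = length(cols))[keep],
        rep(cols, each = length(rows))[keep])
}

# boundary distance from the centre of an ellipse (semi-axes a along
# direction theta, b across) along absolute direction phi
ellipse_radius <- function(a, b, theta, phi) {
  1 / sqrt((cos(phi - theta) / a)^2 + (sin(phi - theta) / b)^2)
}

# grow a pixel set by one pixel in 8-connectivity (clipped to the image)
grow1 <- function(idx, nr, nc) {
  off <- expand.grid(dr = -1:1, dc = -1:1)
  out <- do.call(rbind, lapply(seq_len(nrow(off)), function(i)
    cbind(idx[, 1] + off$dr[i], idx[, 2] + off$dc[i])))
  out <- out[out[, 1] >= 1 & out[, 1] <= nr &
             out[, 2] >= 1 & out[, 2] <= nc, , drop = FALSE]
  out
}

sample_range <- function(rng) {
  if (rng[1] == rng[2]) as.integer(rng[1])
  else sample(rng[1]:rng[2], 1)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate one synthetic cell scene with exact ground truth
#'
#' Cells are filled, slightly eccentric ellipses placed without overlap
#' (candidates must stay 8-disconnected from all earlier cells, so
#' connected components of the ground-truth mask always equal the true
#' counts).  Single-kind macrophage scenes may contain adhesive pairs: a
#' second macrophage placed rim-to-rim with an earlier one, the masks
#' kept separate (annotator convention) while the rendered image bridges
#' the gap with a darkened contact zone -- the artifact morphological
#' opening is meant to repair.
#'
#' @param config A [synth_config()].
#' @param kind `"rbc"`, `"macrophage"` or `"mixed"`.
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   on exit.
#' @return A list of class `synth_scene` with elements `image` (gray
#'   matrix), `mask` (class mask, 0/1/2), `counts` (named integer vector
#'   `c("1" = , "2" = )`), and `instances` (data frame with one row per
#'   cell: class, row, col, radius, a, b, theta, adhesive).
#' @export
generate_scene <- function(config, kind = c("mixed", "rbc", "macrophage"),
                           seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    n <- config$size
    n_rbc <- if (kind %in% c("rbc", "mixed"))
      sample_range(config$rbc_count) else 0L
    n_mac <- if (kind %in% c("macrophage", "mixed"))
      sample_range(config$mac_count) else 0L

    mask <- matrix(0L, n, n)
    blocked <- matrix(FALSE, n, n)   # foreground grown by 1 px
    inst <- list()
    shade <- numeric(0)              # per-cell interior intensity

    place_cell <- function(class, rng_r, partner = NULL) {
      for (try in seq_len(config$max_tries)) {
        r <- runif(1, rng_r[1], rng_r[2])
        f <- 1 + runif(1, 0, config$ecc_jitter)
        a <- r * f; b <- r / f
        theta <- runif(1, 0, pi)
        if (is.null(partner)) {
          m <- ceiling(max(a, b)) + 2
          if (2 * m >= n) next
          r0 <- runif(1, m, n - m); c0 <- runif(1, m, n - m)
        } else {
          # adhesive: point contact with a small rim gap; the masks stay
          # 8-disconnected (annotator separation) while the rendered
          # image later bridges the gap with a thin contact zone
          phi <- runif(1, 0, 2 * pi)
          d <- ellipse_radius(partner$a, partner$b, partner$theta, phi) +
            ellipse_radius(a, b, theta, phi + pi) +
            config$adhesion_bridge
          r0 <- partner$row + d * sin(phi)
          c0 <- partner$col + d * cos(phi)
          m <- ceiling(max(a, b)) + 1
          if (r0 < m || r0 > n - m || c0 < m || c0 > n - m) next
        }
        px <- ellipse_pixels(r0, c0, a, b, theta, n, n)
        if (!nrow(px)) next
        if (any(blocked[px])) next
        mask[px] <<- class
        g <- grow1(px, n, n)
        blocked[g] <<- TRUE
        return(list(class = class, row = r0, col = c0, radius = r,
                    a = a, b = b, theta = theta,
                    adhesive = !is.null(partner),
                    partner_idx = partner$idx))
      }
      stop("could not place a cell of class ", class, " after ",
           config$max_tries, " attempts; scene too crowded", call. = FALSE)
    }

    macs <- list()
    for (i in seq_len(n_mac)) {
      partner <- NULL
      # adhesive pairs occur in single-kind macrophage scenes (adherent
      # culture frames); mixed scenes model suspended, mixed-for-counting
      # preparations where cells are placed independently
      if (kind == "macrophage" && i > 1 && runif(1) < config$adhesion_p) {
        pj <- sample(length(macs), 1)
        partner <- macs[[pj]]
        partner$idx <- pj
      }
      cell <- tryCatch(place_cell(2L, config$mac_radius, partner),
                       error = function(e) NULL)
      if (is.null(cell) && !is.null(partner))  # fall back to free placement
        cell <- place_cell(2L, config$mac_radius, NULL)
      if (is.null(cell))
        stop("macrophage placement failed", call. = FALSE)
      macs[[length(macs) + 1]] <- cell
      inst[[length(inst) + 1]] <- cell
      shade <- c(shade, config$cell_means[["mac"]] +
                   runif(1, -config$intensity_jitter,
                         config$intensity_jitter))
    }
    for (i in seq_len(n_rbc)) {
      cell <- place_cell(1L, config$rbc_radius, NULL)
      inst[[length(inst) + 1]] <- cell
      shade <- c(shade, config$cell_means[["rbc"]] +
                   runif(1, -config$intensity_jitter,
                         config$intensity_jitter))
    }

    # render: background plane + gradient, then cells, noise last
    ctr <- (n + 1) / 2
    ang <- runif(1, 0, 2 * pi)
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    grad <- config$gradient_amp *
      ((cols - ctr) * cos(ang) + (rows - ctr) * sin(ang)) / n
    img <- matrix(config$bg_mean, n, n) + grad
    for (i in seq_along(inst)) {
      cell <- inst[[i]]
      px <- ellipse_pixels(cell$row, cell$col, cell$a, cell$b, cell$theta,
                           n, n)
      img[px] <- shade[i] + grad[px]
    }
    # optical adhesion bridges: each adhesively placed macrophage gets a
    # darkened contact zone towards its partner in the image, while the
    # mask keeps the instances separate (as an annotator would draw
    # them).  Chains of three or more adherent cells can thereby enclose
    # interstitial background, the artifact that makes morphological
    # separation matter for hole-closing contour filling.
    br <- config$adhesion_bridge
    for (i in seq_along(inst)) {
      c1 <- inst[[i]]
      if (!isTRUE(c1$adhesive) || br == 0) next
      c2 <- inst[[c1$partner_idx]]
      e1 <- ellipse_pixels(c1$row, c1$col, c1$a + br, c1$b + br,
                           c1$theta, n, n)
      e2 <- ellipse_pixels(c2$row, c2$col, c2$a + br, c2$b + br,
                           c2$theta, n, n)
      common <- intersect((e1[, 2] - 1L) * n + e1[, 1],
                          (e2[, 2] - 1L) * n + e2[, 1])
      common <- common[mask[common] == 0L]
      if (length(common))
        img[common] <- mean(c(shade[i], shade[c1$partner_idx])) +
          grad[common]
    }
    if (config$noise_sd > 0)
      img <- img + matrix(rnorm(n * n, 0, config$noise_sd), n, n)
    img <- matrix(as.integer(clamp8(round_px(img))), n, n)
    if (config$polarity == "lighter") img <- 255L - img

    instances <- if (length(inst)) {
      do.call(rbind, lapply(inst, function(z)
        data.frame(class = z$class, row = z$row, col = z$col,
                   radius = z$radius, a = z$a, b = z$b, theta = z$theta,
                   adhesive = z$adhesive)))
    } else {
      data.frame(class = integer(), row = numeric(), col = numeric(),
                 radius = numeric(), a = numeric(), b = numeric(),
                 theta = numeric(), adhesive = logical())
    }
    structure(list(image = img, mask = mask,
                   counts = c("1" = n_rbc, "2" = n_mac),
                   instances = instances, kind = kind),
              class = "synth_scene")
  })
}

#' @export
print.synth_scene <- function(x, ...) {
  cat("synthetic", x$kind, "scene:", nrow(x$image), "x", ncol(x$image),
      "px,", x$counts[["1"]], "RBC(s),", x$counts[["2"]],
      "macrophage(s)\n")
  invisible(x)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` image/mask pairs under `out_root/<kind>/{images,masks}` and a
#' `manifest.json` with per-image true counts.  Fully reproducible from
#' `(config, seed)`.
#'
#' @param config A [synth_config()].
#' @param kind Scene kind, as in [generate_scene()].
#' @param n Number of scenes.
#' @param out_root Output directory (created if needed).
#' @param seed Integer seed.
#' @return The manifest as a data frame (`image`, `mask`, `rbc`, `mac`),
#'   invisibly.
#' @export
generate_dataset <- function(config, kind, n, out_root, seed = 1) {
  stopifnot(n >= 0)
  img_dir <- file.path(out_root, kind, "images")
  msk_dir <- file.path(out_root, kind, "masks")
  if (n > 0) {
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_scene(config, kind, seed = seed + i - 1)
    stem <- sprintf("%s_%04d.png", kind, i)
    write_image(sc$image, file.path(img_dir, stem))
    write_mask(sc$mask, file.path(msk_dir, stem))
    rows[[i]] <- data.frame(image = file.path(kind, "images", stem),
                            mask = file.path(kind, "masks", stem),
                            rbc = sc$counts[["1"]], mac = sc$counts[["2"]],
                            stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0) do.call(rbind, rows) else
    data.frame(image = character(), mask = character(),
               rbc = integer(), mac = integer())
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    lapply(seq_len(nrow(manifest)), function(i)
      list(image = manifest$image[i], mask = manifest$mask[i],
           counts = list("1" = manifest$rbc[i], "2" = manifest$mac[i]))),
    file.path(out_root, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
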