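#' Study conditions for the desk-scale transfer protocol
#'
#' The three-regime experiment (supervised baseline, auto-label
#' pretraining, fine-tuning) replicated at a size that trains on one CPU
#' in minutes: 64x64 scenes, a tiny U-Net (depth 3, widths 8/16/32/64),
#' 200 auto-labelled single-kind training images, a 10-image manually
#' labelled (here: ground-truth) mixed fine-tuning set, and a 30-image
#' mixed test set.  Cell radii scale with the frame so both classes stay
#' separable by area (RBC 3--4 px, macrophage 8--11 px).
#'
#' @return Named list of conditions consumed by
#'   [run_transfer_protocol()].
#' @export
transfer_conditions <- function() {
  scene <- synth_config(size = 64,
                        rbc_radius = c(3, 4), mac_radius = c(8, 11),
                        rbc_count = c(6, 10), mac_count = c(1, 2))
  scene_mac <- scene
  scene_mac$mac_count <- c(2, 3)   # single-kind macrophage frames
  list(scene = scene, scene_mac = scene_mac,
       n_single = 200, n_val = 20, n_finetune = 10, n_test = 30,
       epochs_single = 20, epochs_finetune = 10,
       n_base = 50, epochs_base = 20,
       net = unet_config(depth = 3, widths = c(8, 16, 32, 64)))
}

gen_scenes <- function(config, kind, n) {
  lapply(seq_len(n), function(i) generate_scene(config, kind))
}

#' Run the scaled-down transfer-learning protocol
#'
#' Pretrains a tiny U-Net on auto-labelled synthetic single-kind images
#' (U-Single), fine-tunes it on a small ground-truth-labelled mixed set
#' at half the learning rate (U-Transfer), optionally trains a
#' supervised baseline on labelled mixed images (U-Base), and evaluates
#' all regimes on held-out mixed scenes: mIoU, FWIoU, Dice and per-class
#' counting accuracy with default minimum-area counting.
#'
#' @param seed Integer seed controlling data generation, initialisation
#'   and training.
#' @param include_base Also train the supervised baseline.
#' @param conditions Conditions list from [transfer_conditions()].
#' @param verbose Print per-epoch training lines.
#' @return List with per-regime test metrics (`single`, `transfer` and
#'   optionally `base`, each with `miou`, `fwiou`, `dice`), counting
#'   results `count_accuracy` (percent, per class, U-Transfer),
#'   `true_counts`, `pred_counts`, and the fitted models.
#' @export
run_transfer_protocol <- function(seed = 1, include_base = FALSE,
                                  conditions = transfer_conditions(),
                                  verbose = FALSE) {
  cn <- conditions
  with_seed(seed, {
    # --- data ---------------------------------------------------------
    n_half <- cn$n_single / 2
    rbc_scenes <- gen_scenes(cn$scene, "rbc", n_half)
    mac_scenes <- gen_scenes(cn$scene_mac, "macrophage", n_half)
    cfg_rbc <- autolabel_config_for(cn$scene, "rbc")
    cfg_mac <- autolabel_config_for(cn$scene_mac, "macrophage")
    train_imgs <- c(lapply(rbc_scenes, `[[`, "image"),
                    lapply(mac_scenes, `[[`, "image"))
    train_masks <- c(lapply(rbc_scenes, function(s)
                       autolabel_image(s$image, cfg_rbc, 1)),
                     lapply(mac_scenes, function(s)
                       autolabel_image(s$image, cfg_mac, 2)))
    val_rbc <- gen_scenes(cn$scene, "rbc", cn$n_val / 2)
    val_mac <- gen_scenes(cn$scene_mac, "macrophage", cn$n_val / 2)
    val_imgs <- c(lapply(val_rbc, `[[`, "image"),
                  lapply(val_mac, `[[`, "image"))
    val_masks <- c(lapply(val_rbc, function(s)
                     autolabel_image(s$image, cfg_rbc, 1)),
                   lapply(val_mac, function(s)
                     autolabel_image(s$image, cfg_mac, 2)))
    tune_scenes <- gen_scenes(cn$scene, "mixed", cn$n_finetune)
    test_scenes <- gen_scenes(cn$scene, "mixed", cn$n_test)

    # --- U-Single: pretrain on auto-labels ----------------------------
    net <- build_unet(cn$net, seed = seed)
    fit_single <- train_unet(net, train_imgs, train_masks,
                             train_config(phase = "single",
                                          epochs = cn$epochs_single,
                                          seed = seed),
                             val_imgs, val_masks, verbose = verbose)

    # --- U-Transfer: fine-tune on the small labelled mixed set --------
    fit_transfer <- finetune_unet(fit_single,
                                  lapply(tune_scenes, `[[`, "image"),
                                  lapply(tune_scenes, `[[`, "mask"),
                                  train_config(phase = "transfer",
                                               epochs = cn$epochs_finetune,
                                               seed = seed + 1),
                                  verbose = verbose)

    # --- optional U-Base: supervised on labelled mixed images ---------
    fit_base <- NULL
    if (include_base) {
      base_scenes <- gen_scenes(cn$scene, "mixed", cn$n_base)
      fit_base <- train_unet(build_unet(cn$net, seed = seed + 2),
                             lapply(base_scenes, `[[`, "image"),
                             lapply(base_scenes, `[[`, "mask"),
                             train_config(phase = "base",
                                          epochs = cn$epochs_base,
                                          seed = seed + 2),
                             verbose = verbose)
    }

    # --- evaluation on held-out mixed scenes --------------------------
    true_masks <- lapply(test_scenes, `[[`, "mask")
    evaluate <- function(fit) {
      preds <- lapply(test_scenes, function(s) predict(fit, s$image)$mask)
      ev <- eval_masks(true_masks, preds,
                       num_classes = cn$net$num_classes)
      list(miou = ev$miou, fwiou = ev$fwiou, dice = ev$dice,
           preds = preds)
    }
    ev_single <- evaluate(fit_single)
    ev_transfer <- evaluate(fit_transfer)
    ev_base <- if (include_base) evaluate(fit_base)

    ma <- min_areas_for(cn$scene)
    pred_counts <- Reduce(`+`, lapply(ev_transfer$preds, function(m)
      count_cells(m, ma)$counts))
    true_counts <- Reduce(`+`, lapply(test_scenes, `[[`, "counts"))
    acc <- count_accuracy(pred_counts, true_counts)

    out <- list(single = ev_single[c("miou", "fwiou", "dice")],
                transfer = ev_transfer[c("miou", "fwiou", "dice")],
                count_accuracy = acc,
                pred_counts = pred_counts, true_counts = true_counts,
                fit_single = fit_single, fit_transfer = fit_transfer)
    if (include_base) {
      out$base <- ev_base[c("miou", "fwiou", "dice")]
      out$fit_base <- fit_base
    }
    out
  })
}
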