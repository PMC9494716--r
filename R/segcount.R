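#' Connected components of a class mask
#'
#' Components are computed per class value independently with
#' 8-connectivity; ids are assigned in raster order of each component's
#' top-left-most pixel, classes in ascending order.
#'
#' @param mask Integer class mask.
#' @return Data frame with one row per component: `id`, `class`, `area`,
#'   `centroid_row`, `centroid_col`, `bbox_*` (row/col min/max) and
#'   `touches_border`.
#' @export
components <- function(mask) {
  storage.mode(mask) <- "integer"
  nr <- nrow(mask); nc <- ncol(mask)
  classes <- sort(setdiff(unique(as.vector(mask)), 0L))
  rows <- list()
  id <- 0L
  for (cl in classes) {
    lab <- .label_components(matrix(as.integer(mask == cl), nr, nc))
    for (i in seq_len(max(lab))) {
      w <- which(lab == i)
      r <- ((w - 1L) %% nr) + 1L
      c <- ((w - 1L) %/% nr) + 1L
      id <- id + 1L
      rows[[id]] <- data.frame(
        id = id, class = cl, area = length(w),
        centroid_row = mean(r), centroid_col = mean(c),
        bbox_rmin = min(r), bbox_rmax = max(r),
        bbox_cmin = min(c), bbox_cmax = max(c),
        touches_border = any(r == 1L | r == nr | c == 1L | c == nc))
    }
  }
  if (!length(rows))
    return(data.frame(id = integer(), class = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      bbox_rmin = integer(), bbox_rmax = integer(),
                      bbox_cmin = integer(), bbox_cmax = integer(),
                      touches_border = logical()))
  do.call(rbind, rows)
}

#' Count cells per class from a predicted mask
#'
#' Components smaller than the per-class minimum area are discarded as
#' false positives; each surviving component counts as one cell.  With
#' `split_large = TRUE`, a component larger than 1.5 times the class's
#' typical area instead contributes `round(area / typical_area)` cells,
#' approximating merged clusters.
#'
#' @param mask Integer class mask.
#' @param min_area Named numeric vector of per-class minimum areas, e.g.
#'   `c("1" = 12, "2" = 75)`.  Classes present in the mask must be named
#'   here.
#' @param split_large Divide oversized components by the typical area.
#' @param typical_area Named per-class typical areas (required when
#'   `split_large = TRUE`).
#' @return List of class `count_report`: `counts` (named integer),
#'   `min_area`, `split_large`, `components` (retained components with a
#'   `cells` column).
#' @export
count_cells <- function(mask, min_area, split_large = FALSE,
                        typical_area = NULL) {
  stopifnot(all(min_area >= 0))
  if (split_large && is.null(typical_area))
    stop("typical_area is required when split_large = TRUE", call. = FALSE)
  comp <- components(mask)
  present <- unique(comp$class)
  unknown <- setdiff(as.character(present), names(min_area))
  if (length(unknown))
    stop("mask contains class value(s) with no min_area entry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  keep <- comp[comp$area >= min_area[as.character(comp$class)], ,
               drop = FALSE]
  keep$cells <- rep(1L, nrow(keep))
  if (split_large && nrow(keep)) {
    ta <- typical_area[as.character(keep$class)]
    big <- !is.na(ta) & keep$area > 1.5 * ta
    keep$cells[big] <- pmax(1L, as.integer(round(keep$area[big] /
                                                   ta[big])))
  }
  counts <- vapply(names(min_area), function(cl)
    sum(keep$cells[keep$class == as.integer(cl)]), integer(1))
  structure(list(counts = counts, min_area = min_area,
                 split_large = split_large, components = keep),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat("cell counts (min area ",
      paste(sprintf("%s: %g", names(x$min_area), x$min_area),
            collapse = ", "),
      if (x$split_large) "; large components split" else "", "):\n",
      sep = "")
  for (cl in names(x$counts))
    cat("  class ", cl, ": ", x$counts[[cl]], "\n", sep = "")
  invisible(x)
}

#' Counting accuracy against ground-truth counts
#'
#' Predicted over true counts per class, as a percentage (100 = exact);
#' `NA` where the truth is zero.
#'
#' @param report A [count_cells()] report (or a named count vector).
#' @param truth Named ground-truth counts.
#' @return Named numeric vector of percentages.
#' @export
count_accuracy <- function(report, truth) {
  counts <- if (inherits(report, "count_report")) report$counts else report
  stopifnot(all(truth >= 0))
  out <- sapply(names(truth), function(cl) {
    if (truth[[cl]] == 0) return(NA_real_)
    100 * counts[[cl]] / truth[[cl]]
  })
  setNames(out, names(truth))
}

#' Default per-class minimum areas for a synthetic configuration
#'
#' Half the smallest true cell area per class, the same rule used by the
#' auto-label presets.
#'
#' @param config A [synth_config()].
#' @return Named numeric vector `c("1" = , "2" = )`.
#' @export
min_areas_for <- function(config) {
  c("1" = floor(pi * config$rbc_radius[1]^2 / 2),
    "2" = floor(pi * config$mac_radius[1]^2 / 2))
}
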