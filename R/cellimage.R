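#' Count podosomes in a cortactin/actin image pair
#'
#' Podosomes are segmented in the cortactin channel (maximum-intensity
#' z-projection) by thresholding (Otsu by default), labelling connected
#' components and discarding components smaller than `min_area_px` pixels
#' (16 px, about 2.58 um^2 at 0.402 um/px). A component is accepted only if
#' the mean actin intensity inside it is at least `coloc_factor` times the
#' median actin intensity outside all cortactin objects (the actin
#' coincidence check). Optionally, clusters are split into individual
#' podosomes by a watershed on the distance transform.
#'
#' @param cortactin Matrix (z-projected cortactin channel) or a
#'   `two_channel_image` (then `ch1` is cortactin and `ch2` actin).
#' @param actin Matrix; ignored when `cortactin` is a `two_channel_image`.
#' @param threshold `"auto"` (default: midway between the background median
#'   and the 99.9th intensity percentile, robust when objects cover a small
#'   pixel fraction), `"otsu"`, or an absolute value.
#' @param min_area_px Minimal object area in pixels, default 16.
#' @param coloc_factor Actin-coincidence factor, default 1.5.
#' @param split Split multi-peak clusters by distance-transform watershed.
#' @return A `podosome_detection`: `count`, `objects` (centroid and area per
#'   accepted object) and a `rejected` log (`size_filtered`,
#'   `non_colocalised`, `cluster_split_added`).
#' @export
count_podosomes <- function(cortactin, actin = NULL, threshold = "auto",
                            min_area_px = 16, coloc_factor = 1.5,
                            split = FALSE) {
  if (inherits(cortactin, "two_channel_image")) {
    actin <- cortactin$ch2; cortactin <- cortactin$ch1
  }
  if (is.null(actin)) stop_param("an actin channel image is required")
  if (!all(dim(cortactin) == dim(actin)))
    stop_param("cortactin and actin images must have the same shape")
  if (any(cortactin < 0) || any(actin < 0))
    stop_param("channel intensities must be non-negative")

  empty <- structure(list(count = 0L,
                          objects = data.frame(cx = numeric(0), cy = numeric(0),
                                               area_px = numeric(0)),
                          rejected = list(size_filtered = 0L,
                                          non_colocalised = 0L,
                                          cluster_split_added = 0L)),
                     class = "podosome_detection")
  rng <- range(cortactin)
  if (diff(rng) == 0) return(empty)

  if (identical(threshold, "auto")) {
    thr <- 0.5 * (stats::median(cortactin) +
                    stats::quantile(cortactin, 0.999, names = FALSE))
  } else if (identical(threshold, "otsu")) {
    norm <- (cortactin - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm)) * diff(rng) + rng[1]
  } else thr <- as.numeric(threshold)
  bw <- cortactin > thr
  if (!any(bw)) return(empty)

  mask <- EBImage::Image(bw * 1)
  if (split) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 2)
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  labm <- EBImage::imageData(lab)
  n_obj <- max(labm)
  n_before_split <- max(EBImage::imageData(EBImage::bwlabel(mask)))

  areas <- tabulate(labm[labm > 0], nbins = n_obj)
  bg_actin <- stats::median(actin[labm == 0])

  size_rej <- 0L; coloc_rej <- 0L
  keep <- logical(n_obj)
  for (o in seq_len(n_obj)) {
    if (areas[o] < min_area_px) { size_rej <- size_rej + 1L; next }
    mean_act <- mean(actin[labm == o])
    if (mean_act < coloc_factor * bg_actin) {
      coloc_rej <- coloc_rej + 1L; next
    }
    keep[o] <- TRUE
  }
  objs <- do.call(rbind, lapply(which(keep), function(o) {
    idx <- which(labm == o)
    rr <- (idx - 1) %% nrow(cortactin) + 1
    cc <- (idx - 1) %/% nrow(cortactin) + 1
    data.frame(cx = mean(rr), cy = mean(cc), area_px = areas[o])
  }))
  if (is.null(objs))
    objs <- data.frame(cx = numeric(0), cy = numeric(0), area_px = numeric(0))
  structure(list(count = sum(keep), objects = objs,
                 rejected = list(size_filtered = size_rej,
                                 non_colocalised = coloc_rej,
                                 cluster_split_added =
                                   max(n_obj - n_before_split, 0L))),
            class = "podosome_detection")
}

#' @export
print.podosome_detection <- function(x, ...) {
  cat(sprintf("Podosome detection: %d accepted (%d size-filtered, %d non-colocalised)\n",
              x$count, x$rejected$size_filtered, x$rejected$non_colocalised))
  invisible(x)
}

#' Tail-enrichment ratio of a two-channel cell image
#'
#' Per channel, the enrichment of signal at the cell tail is
#' `(mean_tail - mean_background) / (mean_cytoplasm - mean_background)`.
#' The ratio is invariant to affine intensity rescaling (gain and offset)
#' of a channel. The GFP:mCherry ratio-of-ratios (channel 1 over channel 2)
#' is also returned.
#'
#' @param img A `two_channel_image` or a list of two matrices.
#' @param masks A `region_masks` with disjoint `tail`, `cytoplasm`,
#'   `background` masks of at least 25 px each.
#' @return List with `ratio` (length 2, per channel) and `channel_ratio`
#'   (channel 1 / channel 2).
#' @export
enrichment_ratio <- function(img, masks) {
  stopifnot(inherits(masks, "region_masks"))
  chans <- list(img$ch1, img$ch2)
  for (m in masks) if (sum(m) < 25)
    stop_param("each region mask must contain at least 25 pixels")
  if (any(masks$tail & masks$cytoplasm) || any(masks$tail & masks$background) ||
      any(masks$cytoplasm & masks$background))
    stop_param("region masks must be pairwise disjoint")
  ratio <- vapply(chans, function(ch) {
    tail_m <- mean(ch[masks$tail])
    cyto_m <- mean(ch[masks$cytoplasm])
    bg_m <- mean(ch[masks$background])
    if (cyto_m - bg_m <= 0)
      stop_param("cytoplasm minus background is not positive: ratio undefined")
    (tail_m - bg_m) / (cyto_m - bg_m)
  }, numeric(1))
  list(ratio = ratio, channel_ratio = ratio[1] / ratio[2])
}
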