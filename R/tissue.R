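# Tissue/background segmentation: darkest-channel composite, mean filter,
# percentile thresholds with fixed 8-bit offsets, and area-based cleanup.

#' Darkest-channel composite
#'
#' Per-pixel minimum over the three colour channels. Tissue absorbs light
#' in at least one channel, so its darkest channel separates it from the
#' near-white glass background.
#'
#' @param rgb `[row, col, 3]` array or a `slide` object.
#' @return numeric matrix.
#' @export
darkest_channel <- function(rgb) {
  if (inherits(rgb, "slide")) rgb <- rgb$rgb
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    rlang::abort("rgb must be a [row, col, 3] array")
  }
  pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3])
}

#' Sliding-window mean filter
#'
#' Square mean filter assigning the window mean to the central pixel,
#' computed exactly via an integral image. Borders are handled by mirror
#' (symmetric) padding so edges are not darkened, which would bias the
#' percentile thresholds downstream.
#'
#' @param raster numeric matrix.
#' @param window_px odd window edge length in pixels.
#' @return filtered matrix of the same size.
#' @export
mean_filter <- function(raster, window_px) {
  if (window_px < 1 || window_px %% 2 == 0) {
    rlang::abort("window_px must be an odd positive integer")
  }
  box_mean(as_raster_matrix(raster), as.integer(window_px))
}

#' Initial tissue mask
#'
#' Thresholds the filtered darkest image at
#' `T = percentile(init_centile) - init_offset`; tissue is the darker
#' side, `value < T` (strict). Percentiles use linear interpolation
#' between order statistics (R's default type 7).
#'
#' @param filtered mean-filtered darkest-channel matrix (8-bit scale).
#' @param config a [tissue_config()].
#' @return logical tissue mask.
#' @export
initial_tissue_mask <- function(filtered, config = tissue_config()) {
  filtered <- as_raster_matrix(filtered)
  if (length(filtered) == 0) rlang::abort("empty raster")
  thr <- stats::quantile(filtered, config$init_centile / 100, names = FALSE) -
    config$init_offset
  structure(filtered < thr, threshold = thr)
}

#' Refine the background against its own percentile
#'
#' Computes `T2 = percentile(background values, bg_centile) - bg_offset`
#' and reclassifies tissue pixels brighter than `T2` (strict `>`) as
#' background. If the mask has no background pixels it is returned
#' unchanged with a warning.
#'
#' @param filtered filtered darkest-channel matrix.
#' @param mask logical tissue mask from [initial_tissue_mask()].
#' @param config a [tissue_config()].
#' @return refined logical tissue mask.
#' @export
refine_background <- function(filtered, mask, config = tissue_config()) {
  filtered <- as_raster_matrix(filtered)
  stopifnot(identical(dim(filtered), dim(mask)))
  bg <- !mask
  if (!any(bg)) {
    rlang::warn("mask has no background; refinement skipped")
    return(mask)
  }
  thr <- stats::quantile(filtered[bg], config$bg_centile / 100, names = FALSE) -
    config$bg_offset
  out <- mask & !(filtered > thr)
  structure(out, threshold = thr)
}

#' Area-based mask cleanup
#'
#' Two passes, in order: (1) connected components (8-connectivity) of
#' tissue, then of background, with area below `min_area_um2` are flipped
#' to the surrounding class; (2) tissue components with area below
#' `min_tissue_fraction` of the total tissue area are removed.
#'
#' @param mask logical tissue mask.
#' @param pixel_size_um micrometers per pixel edge.
#' @param config a [tissue_config()].
#' @return cleaned logical tissue mask.
#' @export
clean_mask <- function(mask, pixel_size_um, config = tissue_config()) {
  stopifnot(pixel_size_um > 0)
  px_area <- pixel_size_um^2
  min_px <- config$min_area_um2 / px_area
  drop_small <- function(m) {
    lab <- label_components(m)
    if (max(lab) == 0) return(m)
    areas <- component_areas(lab)
    small <- which(areas < min_px)
    if (length(small)) m[lab %in% small] <- FALSE
    m
  }
  mask <- drop_small(mask)               # small tissue islands -> background
  mask <- !drop_small(!mask)             # small background holes -> tissue
  lab <- label_components(mask)
  if (max(lab) > 0) {
    areas <- component_areas(lab)
    total <- sum(areas)
    small <- which(areas < config$min_tissue_fraction * total)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  mask
}

#' Select regions of interest within tissue
#'
#' Automates the manual 4-region selection of the original workflow: the
#' tissue bounding box is split into a `ceiling(sqrt(n))` grid and each
#' tile is intersected with tissue. Alternatively a user-supplied label
#' raster (integers 1..n) is intersected with tissue and returned
#' verbatim. Empty ROIs are dropped with a warning.
#'
#' @param mask logical tissue mask.
#' @param n_rois number of ROIs for the automatic grid (default 4).
#' @param roi_labels optional integer label raster of user regions.
#' @return list of logical ROI masks.
#' @export
select_rois <- function(mask, n_rois = 4L, roi_labels = NULL) {
  if (!any(mask)) rlang::abort("tissue mask is empty")
  if (!is.null(roi_labels)) {
    roi_labels <- as_raster_matrix(roi_labels)
    stopifnot(identical(dim(roi_labels), dim(mask)))
    ids <- sort(unique(roi_labels[roi_labels > 0]))
    rois <- lapply(ids, function(i) roi_labels == i & mask)
  } else {
    rc <- which(mask, arr.ind = TRUE)
    r0 <- range(rc[, 1]); c0 <- range(rc[, 2])
    g <- ceiling(sqrt(n_rois))
    rbreaks <- round(seq(r0[1] - 1, r0[2], length.out = g + 1))
    cbreaks <- round(seq(c0[1] - 1, c0[2], length.out = g + 1))
    rois <- list()
    for (i in seq_len(g)) {
      for (j in seq_len(g)) {
        if (length(rois) >= n_rois) break
        m <- matrix(FALSE, nrow(mask), ncol(mask))
        rows <- (rbreaks[i] + 1):rbreaks[i + 1]
        cols <- (cbreaks[j] + 1):cbreaks[j + 1]
        m[rows, cols] <- TRUE
        rois <- c(rois, list(m & mask))
      }
    }
  }
  keep <- vapply(rois, any, logical(1))
  if (!all(keep)) {
    rois <- rois[keep]
    rlang::warn(sprintf("%d empty ROI(s) dropped; %d non-empty ROI(s) available",
                        sum(!keep), length(rois)))
  }
  rois
}

#' Full tissue-identification stage
#'
#' Runs darkest channel, optional block-average downsampling, mean
#' filtering, initial and refined thresholding and area cleanup, then
#' returns the mask at the original resolution.
#'
#' @param slide a `slide` object or RGB array.
#' @param config a [tissue_config()].
#' @param pixel_size_um pixel size; taken from the slide if absent.
#' @return list with the logical `mask` and the `thresholds` used
#'   (class `tissue_result`).
#' @export
identify_tissue <- function(slide, config = tissue_config(),
                            pixel_size_um = NULL) {
  if (inherits(slide, "slide")) {
    pixel_size_um <- pixel_size_um %||% slide$pixel_size_um
    rgb <- slide$rgb
  } else {
    rgb <- slide
  }
  if (is.null(pixel_size_um)) {
    rlang::abort("pixel_size_um is required (slide metadata or argument)")
  }
  dk <- darkest_channel(rgb)
  f <- config$downsample
  work <- if (f > 1) block_mean(dk, f) else dk
  filtered <- mean_filter(work, config$filter_window_px)
  m <- initial_tissue_mask(filtered, config)
  t1 <- attr(m, "threshold")
  m <- refine_background(filtered, m, config)
  t2 <- attr(m, "threshold")
  m <- clean_mask(strip_mask_attrs(m), pixel_size_um * f, config)
  if (f > 1) m <- upsample_nn(m, nrow(dk), ncol(dk), f)
  structure(
    list(mask = m,
         thresholds = c(initial = unname(t1), background = unname(t2 %||% NA)),
         pixel_size_um = pixel_size_um, downsample = f),
    class = "tissue_result"
  )
}

strip_mask_attrs <- function(m) {
  matrix(as.logical(m), nrow(m), ncol(m))
}

#' Write / read a binary mask as single-channel PNG or TIFF
#'
#' Masks are stored as 0/255 8-bit rasters; the format follows the file
#' extension (`.png` or `.tif`/`.tiff`).
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path` (write) or a logical matrix (read).
#' @export
write_mask <- function(mask, path) {
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
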