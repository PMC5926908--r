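# Nucleus detection, merged-nucleus splitting, cell-body growth, DAB
# positivity rules and the positive-cell density report.

#' Detect nuclei from the normalized-blue raster
#'
#' Candidate pixels are those with normalized blue strictly above
#' `nb_threshold` inside tissue; 8-connected components with area strictly
#' above `min_nucleus_area_um2` are kept, merged nuclei are split by
#' watershed on the distance transform, and components still larger than
#' `max_nucleus_area_um2` after splitting are discarded as staining
#' artifacts. Labels are renumbered `1..n` in raster order.
#'
#' @param nblue normalized-blue matrix (AU).
#' @param tissue logical tissue mask.
#' @param config a [cell_config()].
#' @param pixel_size_um micrometers per pixel edge.
#' @return integer label matrix of nuclei.
#' @export
detect_nuclei <- function(nblue, tissue, config = cell_config(),
                          pixel_size_um = config$ref_pixel_size_um) {
  nblue <- as_raster_matrix(nblue)
  stopifnot(identical(dim(nblue), dim(tissue)), pixel_size_um > 0)
  px_area <- pixel_size_um^2
  cand <- (nblue > config$nb_threshold) & tissue
  lab <- label_components(cand)
  lab <- drop_labels_by_area(lab, min_px = config$min_nucleus_area_um2 / px_area)
  lab <- split_merged_nuclei(lab, nblue, config, pixel_size_um)
  lab <- drop_labels_by_area(lab, max_px = config$max_nucleus_area_um2 / px_area)
  relabel_seq(lab)
}

# Keep labels with area strictly above min_px and not above max_px.
drop_labels_by_area <- function(lab, min_px = NULL, max_px = NULL) {
  if (max(lab) == 0) return(lab)
  areas <- component_areas(lab)
  bad <- rep(FALSE, length(areas))
  if (!is.null(min_px)) bad <- bad | !(areas > min_px)
  if (!is.null(max_px)) bad <- bad | (areas > max_px)
  if (any(bad)) lab[lab %in% which(bad)] <- 0L
  lab
}

relabel_seq <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(lab)
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], ids)
  storage.mode(out) <- "integer"
  out
}

#' Split merged nuclei
#'
#' Each labelled component is re-segmented by watershed on the negated
#' distance transform (EBImage's watershed on the distance map), with the
#' `watershed_h` tolerance acting as an h-maxima depth that suppresses
#' spurious splits of convex nuclei. Fragments below the minimum nucleus
#' area are merged back into their largest adjacent fragment. Re-running
#' the operator on an already split raster is a no-op.
#'
#' @param lab integer nucleus label matrix.
#' @param nblue normalized-blue raster (kept for interface symmetry; the
#'   split is driven by shape, not intensity).
#' @param config a [cell_config()].
#' @param pixel_size_um micrometers per pixel edge.
#' @return integer label matrix with merged nuclei separated.
#' @export
split_merged_nuclei <- function(lab, nblue = NULL, config = cell_config(),
                                pixel_size_um = config$ref_pixel_size_um) {
  if (max(lab) == 0) return(lab)
  min_px <- config$min_nucleus_area_um2 / pixel_size_um^2
  mask <- lab > 0
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::imageData(
    EBImage::watershed(d, tolerance = config$watershed_h, ext = 1)
  )
  # watershed labels are global; keep fragments nested within original labels
  frag <- ws
  frag[!mask] <- 0
  frag <- merge_small_fragments(frag, min_px)
  relabel_seq(frag)
}

# Merge fragments smaller than min_px into their largest 8-neighbour
# fragment (if any); isolated small fragments are left untouched here
# (the area floor upstream already removed true undersized components).
merge_small_fragments <- function(lab, min_px) {
  repeat {
    areas <- component_areas(lab)
    if (!length(areas)) return(lab)
    small <- which(areas > 0 & areas < min_px)
    merged_any <- FALSE
    for (s in small) {
      m <- lab == s
      ring <- dilate3(m) & !m
      nb <- lab[ring]
      nb <- nb[nb > 0]
      if (!length(nb)) next
      nb_ids <- unique(nb)
      tgt <- nb_ids[which.max(areas[nb_ids])]
      lab[m] <- tgt
      merged_any <- TRUE
    }
    if (!merged_any) return(lab)
  }
}

#' Grow cell bodies around nuclei
#'
#' Each nucleus is surrounded by cell body to a configurable pixel depth
#' (7 px at 0.45 um/px; rescaled at other pixel sizes to preserve the
#' physical halo) by geodesic dilation within tissue. Body pixels exclude
#' all nucleus pixels; pixels reachable from several nuclei are assigned
#' to the nearest nucleus (Euclidean distance to its pixels), ties broken
#' by the lower label id.
#'
#' @param nuclei integer nucleus label matrix.
#' @param tissue logical tissue mask.
#' @param config a [cell_config()].
#' @param pixel_size_um micrometers per pixel edge (drives depth rescaling).
#' @return integer body label matrix (same label ids as `nuclei`).
#' @export
grow_cell_bodies <- function(nuclei, tissue, config = cell_config(),
                             pixel_size_um = config$ref_pixel_size_um) {
  stopifnot(identical(dim(nuclei), dim(tissue)))
  depth <- body_depth_for(config, pixel_size_um)
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  if (max(nuclei) == 0 || depth == 0) return(out)
  nucmask <- nuclei > 0
  reach <- nucmask
  for (i in seq_len(depth)) reach <- (dilate3(reach) & tissue) | nucmask
  body <- reach & !nucmask
  if (!any(body)) return(out)
  best_d <- matrix(Inf, nrow(nuclei), ncol(nuclei))
  for (l in sort(unique(nuclei[nucmask]))) {
    dl <- distance_to(nuclei == l)
    upd <- body & (dl < best_d)
    best_d[upd] <- dl[upd]
    out[upd] <- l
  }
  out
}

#' Classify cells by DAB coverage
#'
#' Pixels with brown-positive strictly above `dab_pixel_threshold` are DAB
#' stain. A cell body with coverage strictly above
#' `body_positive_fraction` is a positive body, a nucleus with coverage
#' strictly above `nucleus_positive_fraction` is a positive nucleus, and
#' a cell with a positive nucleus and/or a positive body is a positive
#' cell. Empty regions get coverage 0 with a warning.
#'
#' @param nuclei,bodies congruent label matrices from [detect_nuclei()]
#'   and [grow_cell_bodies()].
#' @param brownpos brown-positive matrix (AU).
#' @param config a [cell_config()].
#' @return tibble with one row per cell: areas, centroid, DAB coverage
#'   fractions and positivity flags.
#' @export
classify_cells <- function(nuclei, bodies, brownpos, config = cell_config()) {
  brownpos <- as_raster_matrix(brownpos)
  stopifnot(identical(dim(nuclei), dim(brownpos)),
            identical(dim(bodies), dim(brownpos)))
  ids <- sort(unique(nuclei[nuclei > 0]))
  if (!length(ids)) {
    return(tibble::tibble(
      cell_id = integer(), centroid_row = numeric(), centroid_col = numeric(),
      nucleus_area_px = integer(), body_area_px = integer(),
      nucleus_dab_fraction = numeric(), body_dab_fraction = numeric(),
      nucleus_positive = logical(), body_positive = logical(),
      cell_positive = logical()
    ))
  }
  dab <- brownpos > config$dab_pixel_threshold
  any_empty_body <- FALSE
  rows <- lapply(ids, function(l) {
    nuc <- which(nuclei == l)
    bod <- which(bodies == l)
    rc <- arrayInd(nuc, dim(nuclei))
    nf <- mean(dab[nuc])
    if (length(bod)) {
      bf <- mean(dab[bod])
    } else {
      any_empty_body <<- TRUE
      bf <- 0
    }
    np <- nf > config$nucleus_positive_fraction
    bp <- bf > config$body_positive_fraction
    tibble::tibble(
      cell_id = l,
      centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]),
      nucleus_area_px = length(nuc), body_area_px = length(bod),
      nucleus_dab_fraction = nf, body_dab_fraction = bf,
      nucleus_positive = np, body_positive = bp,
      cell_positive = np || bp
    )
  })
  if (any_empty_body) rlang::warn("cell(s) with empty body: coverage set to 0")
  dplyr::bind_rows(rows)
}

#' Positive-cell density per ROI
#'
#' A cell belongs to the ROI containing its nucleus centroid. Per-ROI
#' density is positive cells divided by the ROI's tissue area in square
#' micrometers; the report's summary is the arithmetic mean over ROIs,
#' i.e. the average number of positive cells per square micrometer of
#' tissue over the regions of interest. ROIs with zero tissue area are
#' excluded with a warning; cells whose centroid falls outside every ROI
#' are excluded from densities but remain in the cell table.
#'
#' @param cells cell tibble from [classify_cells()].
#' @param rois list of logical ROI masks.
#' @param tissue logical tissue mask.
#' @param pixel_size_um micrometers per pixel edge.
#' @return `density_report` object; see [tidy.density_report()].
#' @export
density_report <- function(cells, rois, tissue, pixel_size_um) {
  stopifnot(pixel_size_um > 0, length(rois) >= 1)
  px_area <- pixel_size_um^2
  keep <- vapply(rois, function(r) sum(r & tissue) > 0, logical(1))
  if (!all(keep)) {
    rlang::warn(sprintf("%d ROI(s) with zero tissue area excluded",
                        sum(!keep)))
    rois <- rois[keep]
  }
  if (!length(rois)) rlang::abort("no ROI with tissue area")
  pos <- cells[cells$cell_positive, , drop = FALSE]
  per_roi <- purrr::map_dfr(seq_along(rois), function(i) {
    r <- rois[[i]]
    area_um2 <- sum(r & tissue) * px_area
    n_pos <- if (nrow(pos)) {
      sum(vapply(seq_len(nrow(pos)), function(k) {
        ri <- max(1L, min(nrow(r), as.integer(round(pos$centroid_row[k]))))
        ci <- max(1L, min(ncol(r), as.integer(round(pos$centroid_col[k]))))
        r[ri, ci]
      }, logical(1)))
    } else 0L
    tibble::tibble(roi = i, positive_cells = n_pos,
                   tissue_area_um2 = area_um2,
                   density_per_um2 = n_pos / area_um2)
  })
  structure(
    list(per_roi = per_roi,
         mean_density_per_um2 = mean(per_roi$density_per_um2),
         n_cells = nrow(cells), n_positive = nrow(pos),
         pixel_size_um = pixel_size_um),
    class = "density_report"
  )
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf(
    "IHC density report: %d cells (%d positive), %d ROI(s)\n",
    x$n_cells, x$n_positive, nrow(x$per_roi)
  ))
  cat(sprintf("mean positive-cell density: %.6g cells/um^2 tissue\n",
              x$mean_density_per_um2))
  invisible(x)
}

#' Tidy a density report
#'
#' @param x a `density_report`.
#' @param ... unused.
#' @return tibble with one row per ROI plus the mean as attributes-free
#'   columns (`roi = NA` row holds the mean).
#' @export
tidy.density_report <- function(x, ...) {
  dplyr::bind_rows(
    x$per_roi,
    tibble::tibble(roi = NA_integer_,
                   positive_cells = x$n_positive,
                   tissue_area_um2 = sum(x$per_roi$tissue_area_um2),
                   density_per_um2 = x$mean_density_per_um2)
  )
}
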