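# Ground-truthed synthetic brightfield slides. The forward model is
# Beer-Lambert: per-channel intensity I = I0 * exp(-A_hema * e_hema -
# A_dab * e_dab), quantized to 8 bits after additive Gaussian noise.
# Inverting this model is exactly what the HSD stain stage does, so the
# generator provides ground truth for every downstream raster operation.

#' Optical model for synthetic slides
#'
#' @param i0 background (incident) intensity per channel, 8-bit.
#' @param extinction_hema,extinction_dab per-channel optical-density
#'   vectors; defaults are the Ruifrok-Johnston constants normalized to
#'   mean 1 (see [stain_vectors()]), so planted amounts are in the same
#'   absorbance units the HSD stage reports.
#' @param noise_sd additive Gaussian noise sd on the 8-bit scale, applied
#'   before quantization.
#' @return an `optical_model` list.
#' @export
optical_model <- function(i0 = c(255, 255, 255),
                          extinction_hema = stain_vectors()$hema,
                          extinction_dab = stain_vectors()$dab,
                          noise_sd = 2) {
  stopifnot(all(i0 > 0), all(extinction_hema >= 0), all(extinction_dab >= 0),
            noise_sd >= 0)
  structure(list(i0 = i0, extinction_hema = extinction_hema,
                 extinction_dab = extinction_dab, noise_sd = noise_sd),
            class = "optical_model")
}

#' Specification of a synthetic IHC slide
#'
#' Defines the planted geometry and staining of a synthetic slide: an
#' elliptical tissue region on glass, elliptical nuclei placed by
#' rejection sampling with a minimum centroid distance, haematoxylin in
#' every nucleus and faintly in the stroma, and DAB planted for positive
#' cells on a cytoplasmic ring (and optionally over the nucleus). A
#' merged-pair mode places pairs of nuclei closer than the minimum
#' distance to exercise the merged-nucleus splitting step.
#'
#' @param width_px,height_px raster size in pixels.
#' @param pixel_size_um micrometers per pixel edge (0.45).
#' @param n_positive,n_negative planted DAB-positive and negative cells.
#' @param n_merged_pairs extra pairs of overlapping (negative) nuclei.
#' @param tissue_margin_px glass margin around the tissue ellipse.
#' @param nucleus_radii_um semi-axes of the nucleus ellipse (3 um).
#' @param min_centroid_dist_um minimum distance between planted centroids.
#' @param merged_dist_um centroid distance within a merged pair.
#' @param hema_nucleus_au,hema_stroma_au haematoxylin amounts (AU) in
#'   nuclei and stroma.
#' @param dab_ring_au,dab_nucleus_au DAB amounts (AU) on the cytoplasmic
#'   ring and over the nucleus of positive cells.
#' @param ring_width_px width of the DAB cytoplasmic ring in pixels.
#' @param max_place_tries rejection-sampling retries per cell before an
#'   overcrowded spec raises a capacity error.
#' @return a `slide_spec` list.
#' @export
slide_spec <- function(width_px = 900L, height_px = 700L,
                       pixel_size_um = 0.45,
                       n_positive = 60L, n_negative = 40L,
                       n_merged_pairs = 0L,
                       tissue_margin_px = 60L,
                       nucleus_radii_um = c(3, 3),
                       min_centroid_dist_um = 11,
                       merged_dist_um = 5.5,
                       hema_nucleus_au = 0.9, hema_stroma_au = 0.10,
                       dab_ring_au = 0.8, dab_nucleus_au = 0,
                       ring_width_px = 5L,
                       max_place_tries = 200L) {
  stopifnot(n_positive >= 0, n_negative >= 0, n_merged_pairs >= 0,
            pixel_size_um > 0, all(nucleus_radii_um > 0),
            min_centroid_dist_um > 0)
  nucleus_area_um2 <- pi * prod(nucleus_radii_um)
  if (nucleus_area_um2 <= 10) {
    rlang::abort("nucleus radii too small: area must exceed the 10 um^2 detection floor")
  }
  structure(as.list(environment()), class = "slide_spec")
}

#' Generate a ground-truthed synthetic IHC slide
#'
#' @param spec a [slide_spec()].
#' @param optics an [optical_model()].
#' @param seed RNG seed; identical spec + seed reproduce the raster
#'   byte for byte.
#' @return list with `slide` (class `slide`: `rgb` array `[row, col, 3]`
#'   in 0..255 plus `pixel_size_um`) and `truth` (class
#'   `slide_ground_truth`: `tissue_mask`, `nucleus_labels`, `dab_mask`,
#'   and a `cells` tibble with centroids and positivity flags).
#' @export
generate_ihc_slide <- function(spec = slide_spec(), optics = optical_model(),
                               seed = 1L) {
  stopifnot(inherits(spec, "slide_spec"), inherits(optics, "optical_model"))
  withr::local_seed(as.integer(seed))
  nr <- spec$height_px; nc <- spec$width_px
  px <- spec$pixel_size_um

  # tissue: ellipse inscribed in the margin-reduced frame
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cy0 <- (nr + 1) / 2; cx0 <- (nc + 1) / 2
  ry <- (nr - 2 * spec$tissue_margin_px) / 2
  rx <- (nc - 2 * spec$tissue_margin_px) / 2
  stopifnot(ry > 0, rx > 0)
  tissue <- ((rr - cy0) / ry)^2 + ((cc - cx0) / rx)^2 <= 1

  # nucleus geometry in pixels
  rady <- spec$nucleus_radii_um[1] / px
  radx <- spec$nucleus_radii_um[2] / px
  min_d <- spec$min_centroid_dist_um / px
  # keep whole cell (nucleus + ring + body halo) inside tissue
  inner_margin <- max(rady, radx) + spec$ring_width_px + 8

  n_single <- spec$n_positive + spec$n_negative
  centres <- matrix(numeric(0), 0, 2)
  place_one <- function(centres, min_dist_to_existing) {
    for (try in seq_len(spec$max_place_tries)) {
      r <- cy0 + (stats::runif(1) * 2 - 1) * (ry - inner_margin)
      c <- cx0 + (stats::runif(1) * 2 - 1) * (rx - inner_margin)
      if (((r - cy0) / (ry - inner_margin))^2 +
          ((c - cx0) / (rx - inner_margin))^2 > 1) next
      if (nrow(centres) == 0 ||
          min(sqrt((centres[, 1] - r)^2 + (centres[, 2] - c)^2)) >=
            min_dist_to_existing) {
        return(c(r, c))
      }
    }
    rlang::abort(
      "cell placement failed: spec is overcrowded for the tissue area",
      class = "resolvequant_capacity_error"
    )
  }
  for (i in seq_len(n_single)) {
    centres <- rbind(centres, place_one(centres, min_d))
  }
  # merged pairs: anchor placed at min distance from everything, partner
  # closer than the minimum to force a merged blob
  pair_partner <- integer(0)
  for (i in seq_len(spec$n_merged_pairs)) {
    a <- place_one(centres, min_d)
    ang <- stats::runif(1, 0, 2 * pi)
    b <- a + spec$merged_dist_um / px * c(sin(ang), cos(ang))
    centres <- rbind(centres, a, b)
    pair_partner <- c(pair_partner, nrow(centres) - 1L, nrow(centres))
  }

  n_cells <- nrow(centres)
  is_positive <- c(rep(TRUE, spec$n_positive),
                   rep(FALSE, spec$n_negative),
                   rep(FALSE, 2L * spec$n_merged_pairs))

  nucleus_labels <- matrix(0L, nr, nc)
  A_h <- matrix(0, nr, nc)
  A_d <- matrix(0, nr, nc)
  A_h[tissue] <- spec$hema_stroma_au
  dab_mask <- matrix(FALSE, nr, nc)

  for (i in seq_len(n_cells)) {
    e <- ((rr - centres[i, 1]) / rady)^2 + ((cc - centres[i, 2]) / radx)^2
    nuc <- e <= 1
    nucleus_labels[nuc] <- i
    A_h[nuc] <- A_h[nuc] + spec$hema_nucleus_au
    if (is_positive[i]) {
      ring_ry <- rady + spec$ring_width_px
      ring_rx <- radx + spec$ring_width_px
      ring <- (((rr - centres[i, 1]) / ring_ry)^2 +
                 ((cc - centres[i, 2]) / ring_rx)^2 <= 1) & !nuc
      if (spec$dab_ring_au > 0) {
        A_d[ring] <- A_d[ring] + spec$dab_ring_au
        dab_mask <- dab_mask | ring
      }
      if (spec$dab_nucleus_au > 0) {
        A_d[nuc] <- A_d[nuc] + spec$dab_nucleus_au
        dab_mask <- dab_mask | nuc
      }
    }
  }

  rgb <- array(0, c(nr, nc, 3))
  for (ch in 1:3) {
    analog <- optics$i0[ch] *
      exp(-A_h * optics$extinction_hema[ch] - A_d * optics$extinction_dab[ch])
    if (optics$noise_sd > 0) {
      analog <- analog + stats::rnorm(nr * nc, 0, optics$noise_sd)
    }
    rgb[, , ch] <- pmin(255, pmax(0, round(analog)))
  }

  cells <- tibble::tibble(
    cell_id = seq_len(n_cells),
    centroid_row = centres[, 1], centroid_col = centres[, 2],
    is_dab_positive = is_positive,
    in_merged_pair = seq_len(n_cells) %in% pair_partner
  )
  list(
    slide = structure(list(rgb = rgb, pixel_size_um = px), class = "slide"),
    truth = structure(
      list(tissue_mask = tissue, nucleus_labels = nucleus_labels,
           dab_mask = dab_mask, cells = cells, pixel_size_um = px,
           absorbance_hema = A_h, absorbance_dab = A_d),
      class = "slide_ground_truth"
    )
  )
}

#' Write / read a slide as TIFF with a YAML sidecar
#'
#' The RGB raster is written as an 8-bit TIFF and the physical pixel size
#' as a YAML sidecar (`<path>.yml`), which [read_slide()] requires.
#'
#' @param slide a `slide` object.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "slide"))
  tiff::writeTIFF(slide$rgb / 255, path, bits.per.sample = 8L)
  yaml::write_yaml(list(pixel_size_um = slide$pixel_size_um),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_slide
#' @param path TIFF path previously written by [write_slide()].
#' @export
read_slide <- function(path) {
  sidecar <- paste0(path, ".yml")
  if (!file.exists(sidecar)) {
    rlang::abort(
      paste0("missing pixel-size sidecar: ", sidecar,
             " (field pixel_size_um is required)"),
      class = "resolvequant_data_error"
    )
  }
  meta <- yaml::read_yaml(sidecar)
  img <- tiff::readTIFF(path)
  structure(list(rgb = round(img * 255), pixel_size_um = meta$pixel_size_um),
            class = "slide")
}
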