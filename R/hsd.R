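# Hue-saturation-density stain separation.
#
# In transmitted-light brightfield, per-channel optical density is
# -ln(I/I0) and is additive over co-localized stains (Beer-Lambert). The
# HSD representation splits the three channel densities into an overall
# density D (the achromatic part) and two chromatic coordinates (cx, cy)
# that carry hue/saturation independently of stain amount, which is what
# makes it suited to stain quantification.

# Chromatic coordinates of a direction in channel-density space.
hue_of_vector <- function(v) {
  d <- v / mean(v)
  cx <- d[1] - 1
  cy <- (d[2] - d[3]) / sqrt(3)
  atan2(cy, cx)
}

#' RGB to hue-saturation-density transform
#'
#' Converts an 8-bit RGB raster to per-pixel overall optical density and
#' chromatic coordinates. Channel densities use a +1 regularization,
#' `d = -ln((v + 1) / (i0 + 1))`, so a 0 grey level stays finite; overall
#' density is the mean of the three channel densities, and
#' `cx = d_R / D - 1`, `cy = (d_G - d_B) / (sqrt(3) D)`. Pixels with
#' density below `density_eps` are achromatic (`cx = cy = 0`).
#'
#' @param rgb numeric array `[row, col, 3]` with values in `[0, i0]`, or a
#'   `slide` object from [generate_ihc_slide()] / [read_slide()].
#' @param i0 incident-light intensity (default 255).
#' @param density_eps achromatic guard on D.
#' @return list of matrices `density`, `cx`, `cy` (class `hsd_image`).
#' @export
rgb_to_hsd <- function(rgb, i0 = 255, density_eps = 1e-6) {
  if (inherits(rgb, "slide")) rgb <- rgb$rgb
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    rlang::abort("rgb must be a [row, col, 3] array")
  }
  if (min(rgb) < 0 || max(rgb) > i0) {
    rlang::abort("channel values must lie in [0, i0]")
  }
  d <- -log((rgb + 1) / (i0 + 1))
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  dR <- matrix(d[, , 1], nr, nc)
  dG <- matrix(d[, , 2], nr, nc)
  dB <- matrix(d[, , 3], nr, nc)
  D <- (dR + dG + dB) / 3
  chroma <- D >= density_eps
  cx <- matrix(0, nr, nc)
  cy <- cx
  cx[chroma] <- dR[chroma] / D[chroma] - 1
  cy[chroma] <- (dG[chroma] - dB[chroma]) / (sqrt(3) * D[chroma])
  structure(list(density = D, cx = cx, cy = cy), class = "hsd_image")
}

# Smallest absolute angular difference, in [0, pi].
angle_diff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Per-pixel stain intensity from an HSD image
#'
#' Intensity of one stain is the overall density weighted by angular
#' proximity of the pixel's chromatic coordinates to the stain's reference
#' hue. The weight is a raised cosine,
#' `w = (1 + cos(pi * d / half_angle)) / 2` for angular distance
#' `d < half_angle` and 0 beyond: 1 at an exact hue match with zero local
#' slope (so 8-bit quantization of a pure-stain pixel barely perturbs its
#' recovered intensity), falling smoothly to 0 at `half_angle`.
#' Achromatic pixels get weight 0.
#'
#' @param hsd an `hsd_image` from [rgb_to_hsd()].
#' @param reference_hue reference chromatic angle (radians), e.g.
#'   `stain_config()$dab_hue`.
#' @param half_angle angular falloff limit (radians).
#' @param density_eps achromatic guard.
#' @return matrix of stain intensities in absorbance units.
#' @export
stain_intensity <- function(hsd, reference_hue, half_angle = pi / 3,
                            density_eps = 1e-6) {
  stopifnot(inherits(hsd, "hsd_image"), is.finite(reference_hue))
  theta <- atan2(hsd$cy, hsd$cx)
  d <- angle_diff(theta, reference_hue)
  w <- ifelse(d < half_angle, (1 + cos(pi * d / half_angle)) / 2, 0)
  w[hsd$density < density_eps] <- 0
  hsd$density * w
}

#' Brown-positive raster
#'
#' Subtracts blue (haematoxylin) from brown (DAB) stain intensity per
#' pixel. Values may be negative; downstream positivity rules use strict
#' `>` thresholds.
#'
#' @param brown,blue congruent stain-intensity matrices.
#' @return matrix `brown - blue`.
#' @export
brown_positive <- function(brown, blue) {
  brown <- as_raster_matrix(brown); blue <- as_raster_matrix(blue)
  if (!identical(dim(brown), dim(blue))) {
    rlang::abort("brown and blue rasters must have identical dimensions")
  }
  brown - blue
}

#' Normalized blue raster
#'
#' Difference of a small and a large mean filter of the blue intensity
#' (windows 3 and 101 by default), kept only where it exceeds the 0.05 AU
#' floor (strict), zero elsewhere. Subtracting the local background level
#' of blue enhances the real peaks in staining that represent nuclei.
#'
#' @param blue blue stain-intensity matrix (AU).
#' @param config a [stain_config()].
#' @return matrix of normalized blue values (AU).
#' @export
normalized_blue <- function(blue, config = stain_config()) {
  blue <- as_raster_matrix(blue)
  n <- box_mean(blue, config$blue_small_window) -
    box_mean(blue, config$blue_large_window)
  n[n <= config$blue_floor] <- 0
  n
}

#' Compute all stain rasters for a slide
#'
#' Convenience wrapper running [rgb_to_hsd()], [stain_intensity()] for
#' both stains, [brown_positive()] and [normalized_blue()].
#'
#' @param slide a `slide` object or RGB array.
#' @param config a [stain_config()].
#' @return list with `hsd`, `brown`, `blue`, `brown_positive`,
#'   `normalized_blue` (class `stain_maps`).
#' @export
stain_maps <- function(slide, config = stain_config()) {
  hsd <- rgb_to_hsd(slide, i0 = config$i0, density_eps = config$density_eps)
  brown <- stain_intensity(hsd, config$dab_hue, config$half_angle,
                           config$density_eps)
  blue <- stain_intensity(hsd, config$hema_hue, config$half_angle,
                          config$density_eps)
  structure(
    list(
      hsd = hsd, brown = brown, blue = blue,
      brown_positive = brown_positive(brown, blue),
      normalized_blue = normalized_blue(blue, config)
    ),
    class = "stain_maps"
  )
}
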