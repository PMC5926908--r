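# Configuration objects. Every threshold used anywhere in the pipeline is
# a field of one of these constructors so that run manifests can snapshot
# the exact values used.

#' Stain optical-density vectors
#'
#' Per-channel (R, G, B) optical-density directions for haematoxylin and
#' DAB, the widely used stain-deconvolution constants of Ruifrok &
#' Johnston. Each vector is normalized to mean 1 so that a stain "amount"
#' of *a* absorbance units produces an overall HSD density of *a* at a
#' pure-stain pixel.
#'
#' @return named list with `hema` and `dab` numeric length-3 vectors.
#' @export
stain_vectors <- function() {
  norm1 <- function(v) v / mean(v)
  list(
    hema = norm1(c(0.650, 0.704, 0.286)),
    dab  = norm1(c(0.268, 0.570, 0.776))
  )
}

#' Tissue-identification configuration
#'
#' Parameters of the tissue/background segmentation stage: a darkest-channel
#' composite is mean-filtered with a square window, thresholded at the 99th
#' centile minus 15 grey levels, refined against the 10th centile of the
#' background minus 10, and cleaned of components below 50 square
#' micrometers and of tissue pieces below 1% of total tissue area.
#'
#' @param filter_window_px odd mean-filter window (pixels at the working
#'   resolution), default 25.
#' @param init_centile,init_offset percentile and subtracted offset (8-bit
#'   grey levels) of the initial threshold (99, 15).
#' @param bg_centile,bg_offset percentile of the background region and
#'   subtracted offset of the refinement threshold (10, 10).
#' @param min_area_um2 area floor for tissue and background islands, in
#'   square micrometers (50).
#' @param min_tissue_fraction minimum fraction of total tissue area a
#'   tissue component must reach (0.01).
#' @param downsample integer factor by which the darkest-channel image is
#'   block-averaged before filtering/thresholding; the tissue stage of the
#'   original workflow ran at half the magnification of the stain stage.
#' @return a `tissue_config` list.
#' @export
tissue_config <- function(filter_window_px = 25L,
                          init_centile = 99,
                          init_offset = 15,
                          bg_centile = 10,
                          bg_offset = 10,
                          min_area_um2 = 50,
                          min_tissue_fraction = 0.01,
                          downsample = 2L) {
  stopifnot(
    filter_window_px >= 1, filter_window_px %% 2 == 1,
    init_centile > 0, init_centile < 100,
    bg_centile > 0, bg_centile < 100,
    init_offset >= 0, bg_offset >= 0,
    min_area_um2 >= 0,
    min_tissue_fraction > 0, min_tissue_fraction < 1,
    downsample >= 1
  )
  structure(
    list(
      filter_window_px = as.integer(filter_window_px),
      init_centile = init_centile, init_offset = init_offset,
      bg_centile = bg_centile, bg_offset = bg_offset,
      min_area_um2 = min_area_um2,
      min_tissue_fraction = min_tissue_fraction,
      downsample = as.integer(downsample)
    ),
    class = "tissue_config"
  )
}

#' Stain-detection configuration
#'
#' Parameters of the HSD stain stage. Reference hues are the chromatic
#' angles of the haematoxylin and DAB optical-density vectors (the same
#' vectors the synthetic generator uses); pixel stain intensity is overall
#' density weighted by angular proximity to the reference hue with a
#' raised-cosine falloff reaching 0 at `half_angle` (see
#' [stain_intensity()]).
#'
#' @param vectors stain OD vectors, see [stain_vectors()].
#' @param half_angle radians beyond which a pixel contributes nothing to a
#'   stain (default pi/3).
#' @param blue_small_window,blue_large_window odd windows of the two blue
#'   mean filters whose difference yields normalized blue (3, 101).
#' @param blue_floor normalized blue is kept only where the filter
#'   difference exceeds this, in absorbance units (0.05 AU, strict).
#' @param i0 incident (background) 8-bit intensity, default 255.
#' @param density_eps densities below this are treated as achromatic.
#' @return a `stain_config` list with derived `hema_hue`/`dab_hue` angles.
#' @export
stain_config <- function(vectors = stain_vectors(),
                         half_angle = pi / 3,
                         blue_small_window = 3L,
                         blue_large_window = 101L,
                         blue_floor = 0.05,
                         i0 = 255,
                         density_eps = 1e-6) {
  stopifnot(
    blue_small_window %% 2 == 1, blue_large_window %% 2 == 1,
    blue_small_window < blue_large_window,
    blue_floor >= 0, half_angle > 0, i0 > 0
  )
  structure(
    list(
      vectors = vectors,
      hema_hue = hue_of_vector(vectors$hema),
      dab_hue = hue_of_vector(vectors$dab),
      half_angle = half_angle,
      blue_small_window = as.integer(blue_small_window),
      blue_large_window = as.integer(blue_large_window),
      blue_floor = blue_floor,
      i0 = i0,
      density_eps = density_eps
    ),
    class = "stain_config"
  )
}

#' Cell-quantification configuration
#'
#' Thresholds of nucleus detection, cell-body growth and DAB positivity.
#' All comparisons are strict (`>`), exactly as the rules are stated.
#'
#' @param nb_threshold normalized-blue floor for nucleus candidate pixels
#'   (0.1 AU).
#' @param min_nucleus_area_um2 nuclei must exceed this area (10 um^2).
#' @param max_nucleus_area_um2 components larger than this after splitting
#'   are discarded as staining artifacts (default 150 um^2; the original
#'   rule excludes "large nuclear shapes" without a printed value).
#' @param body_depth_px cell-body depth in pixels at the reference pixel
#'   size (7 px at 0.45 um/px); at other pixel sizes the depth is rescaled
#'   to preserve the physical halo.
#' @param ref_pixel_size_um pixel size at which `body_depth_px` is defined.
#' @param dab_pixel_threshold brown-positive level above which a pixel is
#'   DAB (0.1 AU).
#' @param body_positive_fraction,nucleus_positive_fraction DAB coverage
#'   fractions above which a body / nucleus is positive (0.20, 0.40).
#' @param watershed_h h-maxima depth (pixels) used when splitting merged
#'   nuclei on the distance transform.
#' @return a `cell_config` list.
#' @export
cell_config <- function(nb_threshold = 0.1,
                        min_nucleus_area_um2 = 10,
                        max_nucleus_area_um2 = 150,
                        body_depth_px = 7L,
                        ref_pixel_size_um = 0.45,
                        dab_pixel_threshold = 0.1,
                        body_positive_fraction = 0.20,
                        nucleus_positive_fraction = 0.40,
                        watershed_h = 1) {
  stopifnot(
    min_nucleus_area_um2 < max_nucleus_area_um2,
    body_positive_fraction > 0, body_positive_fraction < 1,
    nucleus_positive_fraction > 0, nucleus_positive_fraction < 1,
    body_depth_px >= 0, ref_pixel_size_um > 0, watershed_h > 0
  )
  structure(
    list(
      nb_threshold = nb_threshold,
      min_nucleus_area_um2 = min_nucleus_area_um2,
      max_nucleus_area_um2 = max_nucleus_area_um2,
      body_depth_px = as.integer(body_depth_px),
      ref_pixel_size_um = ref_pixel_size_um,
      dab_pixel_threshold = dab_pixel_threshold,
      body_positive_fraction = body_positive_fraction,
      nucleus_positive_fraction = nucleus_positive_fraction,
      watershed_h = watershed_h
    ),
    class = "cell_config"
  )
}

body_depth_for <- function(config, pixel_size_um) {
  if (is.null(pixel_size_um)) return(config$body_depth_px)
  max(0L, as.integer(round(
    config$body_depth_px * config$ref_pixel_size_um / pixel_size_um
  )))
}
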