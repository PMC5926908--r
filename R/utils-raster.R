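# Raster helpers shared by the tissue and cell stages. Images are plain
# numeric matrices indexed [row, col]; EBImage primitives are orientation
# agnostic so no transposition is needed.

as_raster_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) rlang::abort("expected a 2-d raster (matrix)")
  x
}

#' Label connected components with 8-connectivity
#'
#' `EBImage::bwlabel()` labels 4-connected components; blob cleanup here is
#' specified with 8-connectivity, so 4-connected labels that touch
#' diagonally are merged with a union-find pass and relabelled `1..n`.
#'
#' @param mask logical (or 0/1) matrix.
#' @return integer matrix of component labels, 0 = background.
#' @export
label_components <- function(mask) {
  mask <- as_raster_matrix(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  if (n <= 1L) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs with differing labels
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  storage.mode(out) <- "integer"
  out
}

# Mirror (symmetric) index extension: 1..n reflected with the edge pixel
# repeated, so windows larger than the raster still resolve.
mirror_index <- function(n, r) {
  v <- seq.int(1 - r, n + r)
  m <- (v - 1) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# Exact box mean via integral image on a mirror-padded copy.
box_mean <- function(x, window_px) {
  x <- as_raster_matrix(x)
  if (window_px == 1L) return(x)
  r <- (window_px - 1L) %/% 2L
  mp <- x[mirror_index(nrow(x), r), mirror_index(ncol(x), r), drop = FALSE]
  S <- matrix(0, nrow(mp) + 1L, ncol(mp) + 1L)
  S[-1, -1] <- t(apply(apply(mp, 2, cumsum), 1, cumsum))
  i <- seq_len(nrow(x)); j <- seq_len(ncol(x))
  w <- window_px
  (S[i + w, j + w, drop = FALSE] + S[i, j, drop = FALSE] -
     S[i, j + w, drop = FALSE] - S[i + w, j, drop = FALSE]) / (w * w)
}

# Block mean downsampling by an integer factor; ragged edge blocks are
# averaged over the pixels they actually contain.
block_mean <- function(x, factor) {
  x <- as_raster_matrix(x)
  if (factor == 1L) return(x)
  ri <- ceiling(seq_len(nrow(x)) / factor)
  ci <- ceiling(seq_len(ncol(x)) / factor)
  sums <- rowsum(x, ri)
  sums <- t(rowsum(t(sums), ci))
  cnt <- tcrossprod(as.vector(table(ri)), as.vector(table(ci)))
  sums / cnt
}

# Nearest-neighbour upsampling back to an original size (inverse of the
# block grouping used by block_mean).
upsample_nn <- function(x, nrow_out, ncol_out, factor) {
  x[ceiling(seq_len(nrow_out) / factor), ceiling(seq_len(ncol_out) / factor),
    drop = FALSE]
}

# 3x3 binary dilation (chessboard unit ball).
dilate3 <- function(mask) {
  m <- EBImage::dilate(EBImage::Image(mask * 1), EBImage::makeBrush(3, "box"))
  EBImage::imageData(m) > 0
}

# Euclidean distance from every pixel to the nearest TRUE pixel of `mask`.
distance_to <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  EBImage::imageData(EBImage::distmap(EBImage::Image((!mask) * 1)))
}

component_areas <- function(labels) {
  tab <- tabulate(labels[labels > 0])
  stats::setNames(tab, seq_along(tab))
}
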