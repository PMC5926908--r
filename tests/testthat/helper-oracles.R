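# Independent brute-force oracles and shared fixture builders. These are
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the vectorized implementations.

# Windowed mean with mirror padding, computed by direct summation.
oracle_box_mean <- function(x, w) {
  r <- (w - 1) / 2
  n <- nrow(x); m <- ncol(x)
  refl <- function(i, nn) {
    k <- (i - 1) %% (2 * nn)
    if (k < nn) k + 1 else 2 * nn - k
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          s <- s + x[refl(i + di, n), refl(j + dj, m)]
        }
      }
      out[i, j] <- s / w^2
    }
  }
  out
}

# Per-pixel, per-region DAB coverage classification by explicit loops.
oracle_classify <- function(nuclei, bodies, brownpos, config) {
  ids <- sort(unique(nuclei[nuclei > 0]))
  out <- NULL
  for (l in ids) {
    ncov <- 0; ntot <- 0; bcov <- 0; btot <- 0
    for (i in seq_len(nrow(nuclei))) {
      for (j in seq_len(ncol(nuclei))) {
        dab <- brownpos[i, j] > config$dab_pixel_threshold
        if (nuclei[i, j] == l) {
          ntot <- ntot + 1
          if (dab) ncov <- ncov + 1
        }
        if (bodies[i, j] == l) {
          btot <- btot + 1
          if (dab) bcov <- bcov + 1
        }
      }
    }
    nf <- if (ntot > 0) ncov / ntot else 0
    bf <- if (btot > 0) bcov / btot else 0
    np <- nf > config$nucleus_positive_fraction
    bp <- bf > config$body_positive_fraction
    out <- rbind(out, data.frame(
      cell_id = l, nucleus_dab_fraction = nf, body_dab_fraction = bf,
      nucleus_positive = np, body_positive = bp,
      cell_positive = np || bp
    ))
  }
  out
}

# Exhaustive-loop identification: for every entry count matched ions and
# apply the RT + >= 6 ion rule; best entry by ions then RT distance.
oracle_identify <- function(rt, ions, library, rt_tol = 0.1, mz_tol = 0.01,
                            min_ions = 6) {
  best_name <- NA_character_; best_ions <- -1; best_rt <- Inf
  for (i in seq_len(nrow(library))) {
    lib_ions <- library$diagnostic_ions[[i]]
    matched <- 0
    for (mz in lib_ions) {
      hit <- FALSE
      for (o in ions) if (abs(o - mz) <= mz_tol) hit <- TRUE
      if (hit) matched <- matched + 1
    }
    drt <- abs(rt - library$retention_time_min[i])
    if (drt <= rt_tol && matched >= min_ions) {
      if (matched > best_ions || (matched == best_ions && drt < best_rt)) {
        best_name <- library$name[i]; best_ions <- matched; best_rt <- drt
      }
    }
  }
  best_name
}

# Geodesic-reachability + Euclidean-nearest body assignment, per pixel.
oracle_grow_bodies <- function(nuclei, tissue, depth) {
  n <- nrow(nuclei); m <- ncol(nuclei)
  # chessboard geodesic distance from the nucleus set, within tissue
  gd <- matrix(Inf, n, m)
  gd[nuclei > 0] <- 0
  for (it in seq_len(depth)) {
    nxt <- gd
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        if (!tissue[i, j] || nuclei[i, j] > 0) next
        for (di in -1:1) {
          for (dj in -1:1) {
            ii <- i + di; jj <- j + dj
            if (ii < 1 || ii > n || jj < 1 || jj > m) next
            if (gd[ii, jj] + 1 < nxt[i, j]) nxt[i, j] <- gd[ii, jj] + 1
          }
        }
      }
    }
    gd <- nxt
  }
  nuc_px <- which(nuclei > 0, arr.ind = TRUE)
  nuc_lab <- nuclei[nuclei > 0]
  out <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (nuclei[i, j] > 0 || !is.finite(gd[i, j]) || gd[i, j] > depth) next
      d2 <- (nuc_px[, 1] - i)^2 + (nuc_px[, 2] - j)^2
      best <- min(d2)
      out[i, j] <- min(nuc_lab[d2 == best])
    }
  }
  out
}

# Greedy centroid matching; returns F1 at the given pixel tolerance.
centroid_f1 <- function(truth_rc, det_rc, tol_px = 5) {
  if (nrow(det_rc) == 0 || nrow(truth_rc) == 0) return(0)
  used <- rep(FALSE, nrow(det_rc))
  tp <- 0
  for (i in seq_len(nrow(truth_rc))) {
    d <- sqrt((det_rc[, 1] - truth_rc[i, 1])^2 +
                (det_rc[, 2] - truth_rc[i, 2])^2)
    j <- which(!used & d <= tol_px)
    if (length(j)) {
      used[j[which.min(d[j])]] <- TRUE
      tp <- tp + 1
    }
  }
  prec <- tp / nrow(det_rc)
  rec <- tp / nrow(truth_rc)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Fixture: congruent nucleus/body label rasters on a 64x64 canvas with
# region sizes chosen so 20% / 40% coverages land on exact pixel counts
# (nucleus 4x5 = 20 px, body 10x10 - nucleus = 80 px).
make_cell_fixture <- function(seed, n_boundary = 1) {
  set.seed(seed)
  nuclei <- matrix(0L, 64, 64)
  bodies <- matrix(0L, 64, 64)
  brown <- matrix(stats::runif(64 * 64, -0.05, 0.08), 64, 64)
  anchors <- expand.grid(r = c(5, 25, 45), c = c(5, 25, 45))
  k <- sample(3:9, 1)
  pick <- anchors[sample.int(nrow(anchors), k), , drop = FALSE]
  thr <- 0.1
  for (l in seq_len(k)) {
    r0 <- pick$r[l] + sample(0:4, 1)
    c0 <- pick$c[l] + sample(0:4, 1)
    blk <- cbind(rep(r0:(r0 + 9), 10), rep(c0:(c0 + 9), each = 10))
    nuc <- blk[blk[, 1] %in% (r0 + 3):(r0 + 6) & blk[, 2] %in% (c0 + 3):(c0 + 7), ]
    bod <- blk[!(blk[, 1] %in% (r0 + 3):(r0 + 6) & blk[, 2] %in% (c0 + 3):(c0 + 7)), ]
    nuclei[nuc] <- l
    bodies[bod] <- l
    # plant DAB coverage; some cells sit exactly on the 20% / 40% boundary
    n_dab_nuc <- if (l <= n_boundary) 8L else sample(0:20, 1)   # 8/20 = 40%
    n_dab_bod <- if (l <= n_boundary) 16L else sample(0:80, 1)  # 16/80 = 20%
    brown[nuc[seq_len(n_dab_nuc), , drop = FALSE]] <- thr + 0.05
    if (n_dab_nuc < 20) {
      brown[nuc[(n_dab_nuc + 1):20, , drop = FALSE]] <- thr - 0.05
    }
    brown[bod[seq_len(n_dab_bod), , drop = FALSE]] <- thr + 0.05
    if (n_dab_bod < 80) {
      brown[bod[(n_dab_bod + 1):80, , drop = FALSE]] <- thr - 0.05
    }
    # a pixel exactly at the threshold: strict >, so never DAB
    if (n_dab_bod < 80) brown[bod[80, 1], bod[80, 2]] <- thr
  }
  list(nuclei = nuclei, bodies = bodies, brown = brown)
}
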