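# Partial least squares discriminant analysis by NIPALS against a
# centred one-hot group response, with per-group 95% confidence ellipses
# on the 2-component score plane.

#' Pivot a long mediator table to a samples-by-mediators matrix
#'
#' @param data long tibble `donor`, `time_h`, `mediator`,
#'   `concentration_pg`.
#' @return list with numeric matrix `x` (rows = donor samples) and the
#'   factor `group` of time points.
#' @export
exudate_wide <- function(data) {
  wide <- tidyr::pivot_wider(data, id_cols = c("donor", "time_h"),
                             names_from = "mediator",
                             values_from = "concentration_pg")
  x <- as.matrix(wide[, setdiff(names(wide), c("donor", "time_h"))])
  rownames(x) <- wide$donor
  list(x = x, group = factor(wide$time_h))
}

#' Partial least squares discriminant analysis
#'
#' Iterative NIPALS latent-variable extraction of `x` against the centred
#' one-hot indicator matrix of `group`. Predictors are centred and, by
#' default, scaled to unit variance (the metabolomics autoscaling
#' convention; pareto scaling is available). Missing values are imputed
#' as half the minimum observed value of the mediator, with a message.
#' Score columns are mean-zero; reported loadings are the unit-norm
#' NIPALS weight vectors. Per-group 95% confidence ellipses come from the
#' 2-component score covariance via the chi-square(2 df) 0.95 quantile.
#'
#' @param x numeric matrix (samples x mediators) or data frame.
#' @param group factor of sample groups (>= 2 levels).
#' @param n_components latent components to extract (2).
#' @param scale `"unit"` (autoscaling, default), `"pareto"`, or `"none"`.
#' @param max_iter,tol NIPALS iteration controls.
#' @return a `plsda` object with `scores`, `loadings`,
#'   `explained_variance`, `ellipses`.
#' @export
plsda <- function(x, group, n_components = 2L,
                  scale = c("unit", "pareto", "none"),
                  max_iter = 500L, tol = 1e-10) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  group <- factor(group)
  if (nlevels(group) < 2) rlang::abort("need >= 2 groups")
  if (nrow(x) < 2) rlang::abort("need >= 2 samples")
  stopifnot(nrow(x) == length(group))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))

  # half-minimum imputation per mediator
  if (anyNA(x)) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) {
        if (all(nas)) rlang::abort(paste0("mediator ", colnames(x)[j],
                                          " has no observed values"))
        x[nas, j] <- min(x[!nas, j]) / 2
        rlang::inform(sprintf("imputed %d value(s) of %s as half-minimum",
                              sum(nas), colnames(x)[j]))
      }
    }
  }

  mu <- colMeans(x)
  sdev <- switch(scale,
                 unit = apply(x, 2, stats::sd),
                 pareto = sqrt(apply(x, 2, stats::sd)),
                 none = rep(1, ncol(x)))
  sdev[sdev == 0] <- 1
  X <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  Y <- stats::model.matrix(~ group - 1)
  Y <- sweep(Y, 2, colMeans(Y))

  n_components <- min(n_components, ncol(X), nrow(X) - 1L)
  ssx0 <- sum(X^2)
  W <- matrix(0, ncol(X), n_components)
  TT <- matrix(0, nrow(X), n_components)
  P <- matrix(0, ncol(X), n_components)
  expl <- numeric(n_components)
  Xr <- X; Yr <- Y
  a_done <- 0L
  for (a in seq_len(n_components)) {
    u <- Yr[, which.max(colSums(Yr^2))]
    t_old <- rep(Inf, nrow(X))
    degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xr, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) {
        # X (or Y) residual exhausted: no further structure to extract
        degenerate <- TRUE
        break
      }
      w <- w / nw
      tt <- drop(Xr %*% w)
      cc <- drop(crossprod(Yr, tt)) / sum(tt^2)
      u <- drop(Yr %*% cc) / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    if (degenerate) {
      rlang::inform(sprintf(
        "predictor residual exhausted: returning %d component(s)", a_done))
      break
    }
    p <- drop(crossprod(Xr, tt)) / sum(tt^2)
    Xr <- Xr - tcrossprod(tt, p)
    Yr <- Yr - tcrossprod(tt, cc)
    W[, a] <- w; TT[, a] <- tt; P[, a] <- p
    expl[a] <- sum(tt^2) * sum(p^2) / ssx0
    a_done <- a
  }
  if (a_done == 0L) rlang::abort("no extractable PLS component")
  n_components <- a_done
  W <- W[, seq_len(a_done), drop = FALSE]
  TT <- TT[, seq_len(a_done), drop = FALSE]
  expl <- expl[seq_len(a_done)]
  comp_names <- paste0("comp", seq_len(n_components))
  scores <- tibble::as_tibble(stats::setNames(as.data.frame(TT), comp_names))
  scores <- dplyr::mutate(scores,
                          sample = rownames(x) %||% as.character(seq_len(nrow(x))),
                          group = group, .before = 1)
  loadings <- tibble::as_tibble(stats::setNames(as.data.frame(W), comp_names))
  loadings <- dplyr::mutate(loadings, variable = colnames(x), .before = 1)

  ellipses <- if (n_components >= 2) {
    purrr::map_dfr(levels(group), function(lv) {
      S <- TT[group == lv, 1:2, drop = FALSE]
      if (nrow(S) < 3) {
        return(tibble::tibble(group = lv, center_x = mean(S[, 1]),
                              center_y = mean(S[, 2]), radius_x = NA_real_,
                              radius_y = NA_real_, angle = NA_real_))
      }
      cv <- stats::cov(S)
      eg <- eigen(cv, symmetric = TRUE)
      r <- sqrt(pmax(0, eg$values) * stats::qchisq(0.95, df = 2))
      tibble::tibble(group = lv,
                     center_x = mean(S[, 1]), center_y = mean(S[, 2]),
                     radius_x = r[1], radius_y = r[2],
                     angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]))
    })
  } else {
    tibble::tibble()
  }

  structure(
    list(scores = scores, loadings = loadings,
         explained_variance = stats::setNames(expl, comp_names),
         ellipses = ellipses, scale = scale,
         n_components = n_components, group_levels = levels(group)),
    class = "plsda"
  )
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d samples, %d mediators, %d groups, %d components\n",
              nrow(x$scores), nrow(x$loadings),
              length(x$group_levels), x$n_components))
  cat("explained X variance:",
      paste(sprintf("%s %.1f%%", names(x$explained_variance),
                    100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy / summarize a PLS-DA fit
#'
#' `tidy()` returns per-sample scores (`matrix = "scores"`) or per-mediator
#' loadings (`matrix = "loadings"`); `glance()` returns one row of
#' explained-variance fractions.
#'
#' @param x a `plsda` object.
#' @param matrix `"scores"` or `"loadings"`.
#' @param ... unused.
#' @export
tidy.plsda <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") x$scores else x$loadings
}

#' @rdname tidy.plsda
#' @export
glance.plsda <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$explained_variance))
  names(out) <- paste0("explained_", names(out))
  dplyr::mutate(out, n_components = x$n_components,
                n_groups = length(x$group_levels))
}

ellipse_path <- function(e, n = 120) {
  th <- seq(0, 2 * pi, length.out = n)
  ca <- cos(e$angle); sa <- sin(e$angle)
  px <- e$radius_x * cos(th); py <- e$radius_y * sin(th)
  tibble::tibble(group = e$group,
                 x = e$center_x + px * ca - py * sa,
                 y = e$center_y + px * sa + py * ca)
}

#' Score plot of a PLS-DA fit
#'
#' Two-dimensional score plot coloured by group, with per-group 95%
#' confidence ellipses.
#'
#' @param object a `plsda` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.plsda <- function(object, ...) {
  if (object$n_components < 2) rlang::abort("score plot needs 2 components")
  sc <- object$scores
  paths <- purrr::map_dfr(
    seq_len(nrow(object$ellipses)),
    function(i) {
      e <- object$ellipses[i, ]
      if (is.na(e$radius_x)) return(tibble::tibble())
      ellipse_path(e)
    }
  )
  ev <- 100 * object$explained_variance
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$comp1, y = .data$comp2,
                                        colour = .data$group)) +
    ggplot2::geom_point(size = 2)
  if (nrow(paths)) {
    p <- p + ggplot2::geom_path(
      data = paths,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$group),
      colour = "grey50", linewidth = 0.4
    )
  }
  p + ggplot2::labs(
    x = sprintf("Component 1 (%.1f%%)", ev[1]),
    y = sprintf("Component 2 (%.1f%%)", ev[2]),
    colour = "group"
  ) + ggplot2::theme_minimal()
}

#' Loading plot of a PLS-DA fit
#'
#' @param object a `plsda` object.
#' @param n_label label the `n_label` mediators with the largest
#'   component-1 loading magnitude.
#' @return a ggplot.
#' @export
plot_loadings <- function(object, n_label = 5L) {
  stopifnot(inherits(object, "plsda"))
  ld <- object$loadings
  ld$label <- ifelse(rank(-abs(ld$comp1)) <= n_label, ld$variable, "")
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$comp1, y = .data$comp2)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "Component 1 loading", y = "Component 2 loading") +
    ggplot2::theme_minimal()
}
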