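# Lipid-mediator identification, calibration and nonparametric
# time-course testing.

#' Identify a mediator feature against a standards library
#'
#' A feature is identified as entry E iff its retention time is within
#' `rt_tolerance_min` of E's and at least `min_ions` of E's diagnostic
#' ions appear in the observed ion list (each library ion counts once if
#' any observed ion lies within `mz_tolerance`). When several entries
#' qualify, the one with the most matched ions wins; ties go to the
#' smallest retention-time difference.
#'
#' @param rt_min observed retention time (minutes).
#' @param ions numeric vector of observed fragment m/z values.
#' @param library standards tibble, see [default_standard_library()].
#' @param rt_tolerance_min retention-time tolerance (0.1 min).
#' @param mz_tolerance m/z tolerance for an ion match (0.01).
#' @param min_ions minimum matched diagnostic ions (6).
#' @return one-row tibble: `name` (NA if unidentified), `n_ions_matched`,
#'   `rt_delta_min`.
#' @export
identify_mediator <- function(rt_min, ions, library = default_standard_library(),
                              rt_tolerance_min = 0.1, mz_tolerance = 0.01,
                              min_ions = 6L) {
  if (nrow(library) == 0) rlang::abort("empty standards library")
  cand <- purrr::map_dfr(seq_len(nrow(library)), function(i) {
    lib_ions <- library$diagnostic_ions[[i]]
    matched <- sum(vapply(lib_ions, function(mz) {
      any(abs(ions - mz) <= mz_tolerance)
    }, logical(1)))
    tibble::tibble(
      name = library$name[i],
      n_ions_matched = matched,
      rt_delta_min = abs(rt_min - library$retention_time_min[i])
    )
  })
  ok <- cand[cand$rt_delta_min <= rt_tolerance_min &
               cand$n_ions_matched >= min_ions, , drop = FALSE]
  if (nrow(ok) == 0) {
    best <- cand[order(-cand$n_ions_matched, cand$rt_delta_min), ][1, ]
    return(tibble::tibble(name = NA_character_,
                          n_ions_matched = best$n_ions_matched,
                          rt_delta_min = best$rt_delta_min))
  }
  ok[order(-ok$n_ions_matched, ok$rt_delta_min), ][1, ]
}

#' Identify a table of features
#'
#' Vectorized wrapper of [identify_mediator()] over a feature tibble such
#' as produced by [generate_msms_features()].
#'
#' @param features tibble with `rt_min` and list-column `ions`.
#' @inheritParams identify_mediator
#' @return `features` with `name`, `n_ions_matched`, `rt_delta_min`
#'   columns appended.
#' @export
identify_mediators <- function(features, library = default_standard_library(),
                               rt_tolerance_min = 0.1, mz_tolerance = 0.01,
                               min_ions = 6L) {
  res <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    identify_mediator(features$rt_min[i], features$ions[[i]], library,
                      rt_tolerance_min, mz_tolerance, min_ions)
  })
  dplyr::bind_cols(features, res)
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of response on amount over the standard series
#' (the usual grid is 0.78, 1.56, 3.12, 6.25, 12.5, 25, 50, 100, 200 pg).
#'
#' @param amounts_pg standard amounts (pg), >= 3 distinct positive values.
#' @param responses observed responses (peak area ratio to the deuterated
#'   internal standard).
#' @param mediator optional mediator name carried into the object.
#' @return a `calibration_curve` with `slope`, `intercept`, `r2`.
#' @export
fit_calibration <- function(amounts_pg, responses, mediator = NA_character_) {
  stopifnot(length(amounts_pg) == length(responses))
  if (length(amounts_pg) < 3) rlang::abort("need >= 3 calibration points")
  if (any(amounts_pg <= 0)) rlang::abort("amounts must be strictly positive")
  if (length(unique(amounts_pg)) < 2) {
    rlang::abort("degenerate calibration: constant amounts")
  }
  fit <- stats::lm(responses ~ amounts_pg)
  sst <- sum((responses - mean(responses))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
  structure(
    list(mediator = mediator,
         amounts_pg = amounts_pg, responses = responses,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = r2),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration%s: response = %.6g * amount + %.6g (r2 = %.4f, %d points)\n",
              if (is.na(x$mediator)) "" else paste0(" [", x$mediator, "]"),
              x$slope, x$intercept, x$r2, length(x$amounts_pg)))
  invisible(x)
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, n = length(x$amounts_pg))
}

#' Quantify a feature against a calibration curve
#'
#' The response is the feature peak area divided by its internal-standard
#' peak area; the amount is `(response - intercept) / slope`, floored at
#' 0 pg with a warning when the response falls below the intercept.
#'
#' @param peak_area,istd_peak_area feature and internal-standard areas
#'   (vectors recycle).
#' @param curve a `calibration_curve`.
#' @return amounts in pg.
#' @export
quantify_amount <- function(peak_area, istd_peak_area, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(istd_peak_area <= 0)) {
    rlang::abort("internal-standard peak area must be > 0")
  }
  if (curve$slope == 0) rlang::abort("calibration slope is 0")
  amount <- ((peak_area / istd_peak_area) - curve$intercept) / curve$slope
  if (any(amount < 0)) {
    rlang::warn(sprintf("%d amount(s) below 0 floored at 0 pg",
                        sum(amount < 0)))
    amount <- pmax(0, amount)
  }
  amount
}

#' Kruskal-Wallis time-course test with many-to-one post hocs
#'
#' Omnibus Kruskal-Wallis test (tie-corrected) of one mediator's
#' concentrations across time points, followed by Dunn's rank-based
#' many-to-one comparisons of every time point against the reference
#' (baseline) time, with multiplicity adjustment. Dunn's z uses the
#' tie-corrected variance `N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))`.
#'
#' @param data long tibble with `time_h`, `mediator`, `concentration_pg`.
#' @param mediator mediator name to test.
#' @param reference_time baseline time point (0 h).
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @return a `temporal_test` object; see [tidy.temporal_test()].
#' @export
temporal_test <- function(data, mediator, reference_time = 0,
                          p_adjust = "holm") {
  d <- data[data$mediator == mediator, , drop = FALSE]
  if (nrow(d) == 0) rlang::abort(paste0("no rows for mediator ", mediator))
  if (!reference_time %in% d$time_h) {
    rlang::abort("reference_time has no observations")
  }
  g <- factor(d$time_h)
  counts <- table(g)
  if (length(counts) < 2 || any(counts < 2)) {
    rlang::abort("need >= 2 time groups with >= 2 observations each")
  }
  x <- d$concentration_pg
  if (length(unique(x)) == 1) {
    h <- 0; p <- 1
  } else {
    kw <- stats::kruskal.test(x, g)
    h <- unname(kw$statistic); p <- kw$p.value
  }
  # Dunn many-to-one z against the reference time
  N <- length(x)
  rk <- rank(x)
  ties <- table(x)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, g, mean)
  n_i <- as.vector(counts)
  names(n_i) <- names(counts)
  ref <- as.character(reference_time)
  others <- setdiff(names(rbar), ref)
  z <- vapply(others, function(lv) {
    (rbar[[lv]] - rbar[[ref]]) / sqrt(s2 * (1 / n_i[[lv]] + 1 / n_i[[ref]]))
  }, numeric(1))
  praw <- 2 * stats::pnorm(-abs(z))
  posthoc <- tibble::tibble(
    time_h = as.numeric(others),
    z = unname(z),
    p_value = unname(praw),
    p_adjusted = stats::p.adjust(praw, method = p_adjust)
  )
  structure(
    list(mediator = mediator, h_statistic = h, p_value = p,
         reference_time = reference_time, posthoc = posthoc,
         p_adjust = p_adjust),
    class = "temporal_test"
  )
}

#' @export
print.temporal_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis time course for %s: H = %.4g, p = %.4g\n",
              x$mediator, x$h_statistic, x$p_value))
  cat(sprintf("Dunn many-to-one vs %g h (%s-adjusted):\n",
              x$reference_time, x$p_adjust))
  print(as.data.frame(x$posthoc), row.names = FALSE)
  invisible(x)
}

#' Tidy a temporal test
#'
#' @param x a `temporal_test`.
#' @param ... unused.
#' @return tibble of the post-hoc comparisons with the omnibus H and p
#'   repeated per row.
#' @export
tidy.temporal_test <- function(x, ...) {
  dplyr::mutate(x$posthoc, mediator = x$mediator,
                h_statistic = x$h_statistic, omnibus_p = x$p_value,
                .before = 1)
}

#' Test all mediators in a table
#'
#' Maps [temporal_test()] over every mediator of a long table and binds
#' the tidied results.
#'
#' @inheritParams temporal_test
#' @return tibble of tidied tests for all mediators.
#' @export
temporal_test_all <- function(data, reference_time = 0, p_adjust = "holm") {
  purrr::map_dfr(unique(data$mediator), function(m) {
    tidy(temporal_test(data, m, reference_time, p_adjust))
  })
}
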