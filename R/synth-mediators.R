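# Synthetic lipid-mediator data: time-course concentration tables with
# the temporal structure seen in UV-killed E. coli skin blister exudates
# (onset eicosanoids peaking at 4 h, later-rising SPMs, MaR1 dipping at
# 8 h), and labelled LC-MS/MS feature fixtures for the identification
# rules. All numeric library values (retention times, transitions,
# diagnostic ions) are synthetic fixtures, not measured reference data.

#' Default mediator panel with temporal profiles
#'
#' Twenty mediators spanning the arachidonic acid, EPA and DHA
#' metabolomes. `temporal_effect` columns are multiplicative factors over
#' the default time points (0, 4, 8, 14, 24 h): onset eicosanoids and
#' their further metabolites peak at 4 h; RvE3 peaks at 8 h; LXA4 rises
#' late; MaR1 dips to a minimum at 8 h and recovers above baseline by
#' 24 h; the remaining mediators are held flat. Baselines are plausible
#' exudate picogram levels; magnitudes are illustrative, only the
#' directional profiles are modelled.
#'
#' @return tibble with `mediator`, `baseline_pg` and one `t<h>` column of
#'   multiplicative effects per time point.
#' @export
default_mediator_panel <- function() {
  onset <- c(1, 4, 2.5, 1.5, 1)
  tibble::tribble(
    ~mediator,      ~baseline_pg, ~profile,
    "PGE2",         60,  onset,
    "PGF2a",        45,  onset,
    "PGD2",         30,  c(1, 2, 1.5, 1, 1),
    "TxB2",         80,  onset,
    "LTB4",         25,  onset,
    "20-OH-LTB4",   20,  onset,
    "20-COOH-LTB4", 15,  onset,
    "LXA4",         12,  c(1, 1.2, 1.5, 2.5, 3),
    "LXB4",         10,  c(1, 3, 1.8, 1.2, 1),
    "5-HETE",       90,  c(1, 1.8, 1.5, 1.2, 1),
    "15-HETE",      70,  c(1, 1.5, 1.2, 1, 1),
    "RvE1",          8,  c(1, 1, 1.4, 1.6, 1.5),
    "RvE2",          6,  c(1, 1, 1.3, 1.4, 1.2),
    "RvE3",          9,  c(1, 1.5, 3, 2, 1.5),
    "18-HEPE",      40,  c(1, 1.2, 1.6, 1.4, 1.2),
    "RvD1",          7,  c(1, 1, 1.2, 1.5, 1.4),
    "RvD2",          5,  c(1, 1, 1.2, 1.4, 1.3),
    "PD1",           6,  c(1, 1, 1.1, 1.3, 1.2),
    "MaR1",         14,  c(1, 0.6, 0.35, 0.8, 1.4),
    "17-HDHA",      50,  c(1, 1.2, 1.5, 1.6, 1.4)
  )
}

#' Specification of a synthetic mediator time-course table
#'
#' @param panel tibble like [default_mediator_panel()]: `mediator`,
#'   `baseline_pg`, and a `profile` list-column of multiplicative effects,
#'   one per time point.
#' @param time_points_h sampling times in hours (0, 4, 8, 14, 24).
#' @param donors_per_time donors per time point (6, matching the 6-7
#'   volunteers per interval of the study design).
#' @param noise_cv lognormal coefficient of variation of biological +
#'   assay noise (mean-1 multiplicative noise, so expected concentration
#'   at time t is exactly `baseline_pg * temporal_effect(t)`).
#' @return a `mediator_sim_spec` list.
#' @export
mediator_sim_spec <- function(panel = default_mediator_panel(),
                              time_points_h = c(0, 4, 8, 14, 24),
                              donors_per_time = 6L,
                              noise_cv = 0.3) {
  stopifnot(donors_per_time >= 1, length(time_points_h) >= 1)
  if (noise_cv < 0) rlang::abort("noise_cv must be >= 0")
  if (any(panel$baseline_pg < 0)) rlang::abort("baselines must be >= 0")
  bad <- vapply(panel$profile, function(p) length(p) != length(time_points_h),
                logical(1))
  if (any(bad)) {
    rlang::abort("each profile needs one effect per time point")
  }
  structure(list(panel = panel, time_points_h = time_points_h,
                 donors_per_time = as.integer(donors_per_time),
                 noise_cv = noise_cv),
            class = "mediator_sim_spec")
}

#' Generate a mediator concentration table
#'
#' Long-format donor x time x mediator table. Concentrations are
#' `baseline_pg * temporal_effect(t) * noise`, with mean-1 lognormal
#' noise of coefficient of variation `noise_cv`; all values are >= 0 by
#' construction and a fixed seed reproduces the table exactly.
#'
#' @param spec a [mediator_sim_spec()].
#' @param seed RNG seed.
#' @return tibble `donor`, `time_h`, `mediator`, `concentration_pg`.
#' @export
generate_mediator_table <- function(spec = mediator_sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "mediator_sim_spec"))
  withr::local_seed(as.integer(seed))
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  grid <- tidyr::expand_grid(
    time_idx = seq_along(spec$time_points_h),
    donor_idx = seq_len(spec$donors_per_time),
    med_idx = seq_len(nrow(spec$panel))
  )
  mu <- vapply(seq_len(nrow(grid)), function(k) {
    spec$panel$baseline_pg[grid$med_idx[k]] *
      spec$panel$profile[[grid$med_idx[k]]][grid$time_idx[k]]
  }, numeric(1))
  noise <- if (spec$noise_cv > 0) {
    exp(stats::rnorm(nrow(grid), -sdlog^2 / 2, sdlog))
  } else {
    rep(1, nrow(grid))
  }
  tibble::tibble(
    donor = sprintf("d%02d_t%02d", grid$donor_idx, grid$time_idx),
    time_h = spec$time_points_h[grid$time_idx],
    mediator = spec$panel$mediator[grid$med_idx],
    concentration_pg = mu * noise
  )
}

#' Synthetic standards library
#'
#' Ten mediator entries with retention time, MRM transition, a paired
#' deuterated internal standard and eight diagnostic MS/MS ions each
#' (every entry satisfies the >= 6 diagnostic ions the identification
#' rule needs). Values are synthetic fixtures with realistic magnitudes;
#' retention times are spaced > 1 min apart so RT-shifted decoys cannot
#' collide with a neighbouring entry.
#'
#' @return tibble with one row per standard; `diagnostic_ions` is a
#'   list-column of m/z values.
#' @export
default_standard_library <- function() {
  mk <- function(base) base + c(0, 18.2, 30.1, 44.3, 58.2, 70.9, 84.4, 96.7)
  tibble::tibble(
    name = c("PGE2", "TxB2", "LTB4", "LXA4", "LXB4",
             "RvE1", "RvE3", "RvD1", "RvD2", "MaR1"),
    retention_time_min = c(5.1, 6.4, 8.0, 9.3, 10.6, 12.0, 13.3, 14.7, 16.1, 17.5),
    parent_mz = c(351.2, 369.2, 335.2, 351.2, 351.2, 349.2, 333.2, 375.2, 375.2, 359.2),
    product_mz = c(271.2, 169.1, 195.1, 115.1, 221.1, 195.1, 201.1, 141.1, 175.1, 250.2),
    istd_name = paste0("d4-", c("PGE2", "TxB2", "LTB4", "LXA4", "LXB4",
                                "RvE1", "RvE3", "RvD1", "RvD2", "MaR1")),
    diagnostic_ions = lapply(c(101, 117, 133, 149, 165, 181, 197, 213, 229, 245), mk)
  )
}

#' Generate labelled MS/MS feature fixtures
#'
#' True features match a library entry (retention time within
#' `rt_jitter`, all of its diagnostic ions present with small m/z
#' jitter); decoys violate the identification rule in one of three ways:
#' exactly 5 matching ions, retention time shifted beyond tolerance with
#' all ions intact, or both. Truth labels are returned alongside.
#'
#' @param library standards tibble, see [default_standard_library()].
#' @param n_true,n_decoy counts of identifiable and decoy features.
#' @param rt_jitter max |RT error| of true features, minutes (0.05).
#' @param seed RNG seed.
#' @param rt_shift_min decoy RT displacement (0.5 min).
#' @param mz_jitter max |m/z error| of planted ions (0.004).
#' @return tibble of features: `feature_id`, observed `rt_min`, `ions`
#'   (list-column), `peak_area`, `istd_peak_area`, truth columns
#'   `true_name` (NA for decoys), `identifiable`, `decoy_type`.
#' @export
generate_msms_features <- function(library = default_standard_library(),
                                   n_true = 10L, n_decoy = 10L,
                                   rt_jitter = 0.05, seed = 1L,
                                   rt_shift_min = 0.5, mz_jitter = 0.004) {
  if (nrow(library) == 0) rlang::abort("empty standards library")
  n_ions <- vapply(library$diagnostic_ions, length, integer(1))
  if (any(n_ions < 6)) {
    rlang::abort("every library entry needs >= 6 diagnostic ions")
  }
  withr::local_seed(as.integer(seed))
  decoy_types <- c("few_ions", "bad_rt", "both")
  # junk ions far from every library ion
  all_ions <- sort(unlist(library$diagnostic_ions))
  junk_pool <- setdiff(round(seq(300.05, 320.05, by = 0.5), 3),
                       round(all_ions, 3))
  one <- function(k, truth) {
    e <- library[sample.int(nrow(library), 1), ]
    ions <- e$diagnostic_ions[[1]]
    type <- NA_character_
    if (truth) {
      rt <- e$retention_time_min + stats::runif(1, -rt_jitter, rt_jitter)
      obs <- ions + stats::runif(length(ions), -mz_jitter, mz_jitter)
    } else {
      type <- decoy_types[(k - 1L) %% length(decoy_types) + 1L]
      rt <- e$retention_time_min
      obs <- ions + stats::runif(length(ions), -mz_jitter, mz_jitter)
      if (type %in% c("few_ions", "both")) {
        keep <- sample.int(length(obs), 5L)
        obs <- c(obs[keep], sample(junk_pool, length(ions) - 5L))
      }
      if (type %in% c("bad_rt", "both")) {
        rt <- rt + sample(c(-1, 1), 1) * (rt_shift_min + stats::runif(1, 0, 0.1))
      } else {
        rt <- rt + stats::runif(1, -rt_jitter, rt_jitter)
      }
    }
    tibble::tibble(
      rt_min = rt, ions = list(sort(obs)),
      peak_area = stats::runif(1, 1e4, 1e6),
      istd_peak_area = stats::runif(1, 5e4, 2e5),
      true_name = if (truth) e$name else NA_character_,
      identifiable = truth, decoy_type = type
    )
  }
  out <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_true), one, truth = TRUE),
    purrr::map_dfr(seq_len(n_decoy), one, truth = FALSE)
  )
  dplyr::mutate(out, feature_id = dplyr::row_number(), .before = 1)
}
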