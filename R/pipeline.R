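#' Analysis settings for a single-cell FCS measurement
#'
#' @param m_per_octave Multi-tau lags per octave.
#' @param max_lag Largest correlation lag in seconds (NULL: automatic).
#' @param n_segments Blocks for the correlation error estimate.
#' @param coarse_bin Re-binning width for the photobleaching fit, seconds
#'   (capped at a tenth of the trace duration at run time).
#' @param fit_offset Float a baseline offset in the diffusion fits.
#' @param chi2_max Reduced-chi-square threshold above which a fit fails QC.
#' @param crosscorr_lags Leading lags averaged for the co-diffusion
#'   read-out.
#' @return A list of settings for [run_cell()].
#' @export
cell_settings <- function(m_per_octave = 16, max_lag = NULL, n_segments = 10,
                          coarse_bin = 1, fit_offset = TRUE, chi2_max = 5,
                          crosscorr_lags = 8) {
  list(
    m_per_octave = m_per_octave, max_lag = max_lag,
    n_segments = n_segments, coarse_bin = coarse_bin,
    fit_offset = fit_offset, chi2_max = chi2_max,
    crosscorr_lags = crosscorr_lags
  )
}

#' Analyse one cell measurement
#'
#' Runs the full per-cell chain in the standard order: photobleaching
#' detrend, multi-tau correlation of the GG, RR and GR pairs, diffusion-model
#' fits of the two autocorrelations, background correction of the fitted
#' amplitudes, and conversion to diffusion coefficients and concentrations
#' with the per-channel calibrations. The GR amplitude and its standard
#' error are recorded as the co-diffusion read-out. A failing channel is
#' flagged and excluded from summaries; the other channel is still reported.
#'
#' @param trace An [intensity_trace()].
#' @param calib_G,calib_R Per-channel [calibrate()] results (or
#'   [calibration_from_volume()] for synthetic ground truth).
#' @param background A [background_estimate()] or NULL for none.
#' @param settings A [cell_settings()] list.
#' @param cell_id,condition,compartment Labels carried into the result.
#' @param keep_intermediates Also return curves, fits and bleach models.
#' @return A data frame with one row per channel: labels, mean rates,
#'   `N_apparent`, `N_corrected`, `bleach_factor`, `bg_factor`, `tau_D`,
#'   `D`, `c`,
#'   `chi2_reduced`, `converged`, `qc_pass`, `gr_amplitude`, `gr_se`,
#'   `gr_significant`, `bleach_tau`, `note`. With `keep_intermediates` a
#'   list with elements `cells`, `curves`, `fits`, `bleach`.
#' @export
run_cell <- function(trace, calib_G, calib_R, background = NULL,
                     settings = cell_settings(), cell_id = "cell",
                     condition = NA_character_, compartment = "cytosol",
                     keep_intermediates = FALSE) {
  stopifnot(
    inherits(trace, "intensity_trace"),
    inherits(calib_G, "fcs_calibration"),
    inherits(calib_R, "fcs_calibration")
  )
  coarse <- min(settings$coarse_bin, trace$duration / 10)

  bleach <- list(
    G = tryCatch(fit_bleach(trace, "G", coarse), error = function(e) NULL),
    R = tryCatch(fit_bleach(trace, "R", coarse), error = function(e) NULL)
  )
  detr <- detrend(trace, bleach$G, bleach$R)

  curves <- list()
  for (pair in c("GG", "RR", "GR")) {
    curves[[pair]] <- tryCatch(
      correlate_multitau(detr, pair,
        m_per_octave = settings$m_per_octave,
        max_lag = settings$max_lag, n_segments = settings$n_segments
      ),
      error = function(e) NULL
    )
  }
  gr <- if (!is.null(curves$GR)) {
    crosscorr_amplitude(curves$GR, settings$crosscorr_lags)
  } else {
    list(G0 = NA_real_, se = NA_real_, significant = NA)
  }

  fits <- list()
  rows <- list()
  for (ch in c("G", "R")) {
    calib <- if (ch == "G") calib_G else calib_R
    pair <- if (ch == "G") "GG" else "RR"
    curve <- curves[[pair]]
    rate <- mean_count_rate(detr, ch)
    note <- "ok"
    fit <- NULL
    if (is.null(curve)) {
      note <- "correlation failed"
    } else {
      fit <- tryCatch(
        fit_curve(curve, kappa = calib$kappa,
                  fit_offset = settings$fit_offset),
        error = function(e) {
          note <<- conditionMessage(e)
          NULL
        }
      )
    }
    fits[[ch]] <- fit
    converged <- !is.null(fit) && isTRUE(fit$converged)
    N_app <- if (converged) fit$N else NA_real_
    # the sqrt-detrend leaves the amplitude attenuated by mean(f); fold the
    # complementary factor into the molecule number before the background step
    bfac <- if (!is.null(bleach[[ch]])) {
      bleach_amplitude_factor(bleach[[ch]], trace$duration)
    } else {
      1
    }
    N_bl <- N_app * bfac
    corr <- list(N_corrected = NA_real_, factor = NA_real_)
    if (converged && !is.null(background)) {
      corr <- tryCatch(
        correct_background(N_bl, rate, background, ch),
        error = function(e) {
          note <<- conditionMessage(e)
          converged <<- FALSE
          list(N_corrected = NA_real_, factor = NA_real_)
        }
      )
    } else if (converged) {
      corr <- list(N_corrected = N_bl, factor = 1)
    }
    qc <- converged && is.finite(corr$N_corrected) &&
      !is.null(fit) && fit$chi2_reduced <= settings$chi2_max
    if (converged && !is.null(fit) &&
      fit$chi2_reduced > settings$chi2_max) {
      note <- sprintf("chi2_reduced %.3g above threshold", fit$chi2_reduced)
    }
    rows[[ch]] <- data.frame(
      cell_id = cell_id, condition = condition, compartment = compartment,
      channel = ch, mean_rate = rate,
      N_apparent = N_app,
      N_corrected = corr$N_corrected,
      bleach_factor = bfac, bg_factor = corr$factor,
      tau_D = if (converged) fit$tau_D else NA_real_,
      D = if (qc) to_diffusion(fit, calib) else NA_real_,
      c = if (qc) to_concentration(corr$N_corrected, calib) else NA_real_,
      chi2_reduced = if (!is.null(fit)) fit$chi2_reduced else NA_real_,
      converged = converged, qc_pass = qc,
      gr_amplitude = gr$G0, gr_se = gr$se,
      gr_significant = isTRUE(gr$significant),
      bleach_tau = if (!is.null(bleach[[ch]]) && !bleach[[ch]]$negligible) {
        bleach[[ch]]$tau_b
      } else {
        Inf
      },
      note = note, stringsAsFactors = FALSE
    )
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  if (keep_intermediates) {
    list(cells = cells, curves = curves, fits = fits, bleach = bleach)
  } else {
    cells
  }
}

#' Configuration of a synthetic multi-condition FCS experiment
#'
#' Each condition names a list of [species_spec()]s (plus optional
#' `background_G`/`background_R` overrides) describing the cells measured
#' under that condition.
#'
#' @param conditions Named list; each element is a list with `species`
#'   (list of [species_spec()]) and optional `background_G`, `background_R`
#'   (Hz), `compartment` label.
#' @param n_cells Cells per condition.
#' @param volume A [detection_volume()].
#' @param duration,base_bin,time_step,box_factor Trace discretisation,
#'   passed to [simulation_config()].
#' @param background A [background_estimate()] used in the analysis step
#'   (NULL derives it from the simulated background rates).
#' @param settings A [cell_settings()] list.
#' @param seed Master seed; cell k of condition j uses
#'   `seed + 1000 * j + k` so cells are independent yet reproducible.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(conditions, n_cells = 45,
                              volume = detection_volume(),
                              duration = 120, base_bin = 2e-6,
                              time_step = 1e-6, box_factor = 8,
                              background = NULL,
                              settings = cell_settings(), seed = 1) {
  stopifnot(is.list(conditions), length(conditions) >= 1,
            !is.null(names(conditions)))
  structure(
    list(
      conditions = conditions, n_cells = n_cells, volume = volume,
      duration = duration, base_bin = base_bin, time_step = time_step,
      box_factor = box_factor, background = background,
      settings = settings, seed = seed
    ),
    class = "experiment_config"
  )
}

#' Run a synthetic multi-condition experiment end to end
#'
#' Simulates `n_cells` traces per condition, analyses each with
#' [run_cell()] against the ground-truth calibration of the configured
#' detection volume, and aggregates condition-level summaries and pairwise
#' Mann-Whitney comparisons. Deterministic for a fixed seed.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, the per-cell table,
#'   summaries, comparisons and calibration are written as tab-separated /
#'   YAML files.
#' @return List with `cells` (per-cell table), `summary`, `comparisons_D`,
#'   `comparisons_c`, and the `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  calib_G <- calibration_from_volume(config$volume, "G")
  calib_R <- calibration_from_volume(config$volume, "R")
  all_rows <- list()
  for (j in seq_along(config$conditions)) {
    cond_name <- names(config$conditions)[j]
    cond <- config$conditions[[j]]
    bg_G <- cond$background_G %||% 0
    bg_R <- cond$background_R %||% 0
    background <- config$background %||%
      background_estimate(bg_G, bg_R, cond$compartment %||% "cytosol")
    for (k in seq_len(config$n_cells)) {
      cell_seed <- config$seed + 1000L * j + k
      sim <- simulation_config(
        species = cond$species, volume = config$volume,
        background_G = bg_G, background_R = bg_R,
        duration = config$duration, base_bin = config$base_bin,
        time_step = config$time_step, box_factor = config$box_factor,
        seed = cell_seed
      )
      trace <- simulate_trace(sim)
      all_rows[[length(all_rows) + 1]] <- run_cell(
        trace, calib_G, calib_R,
        background = background,
        settings = config$settings,
        cell_id = sprintf("%s_%03d", cond_name, k),
        condition = cond_name,
        compartment = cond$compartment %||% "cytosol"
      )
    }
  }
  cells <- do.call(rbind, all_rows)
  rownames(cells) <- NULL
  summary <- summarize_cells(cells)
  comparisons_D <- compare_conditions(cells, "D")
  comparisons_c <- compare_conditions(cells, "c")
  res <- list(
    cells = cells, summary = summary,
    comparisons_D = comparisons_D, comparisons_c = comparisons_c,
    config = config
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) {
      write.table(d, file.path(out_dir, f),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    wt(cells, "cells.tsv")
    wt(summary, "summary.tsv")
    if (nrow(comparisons_D)) wt(comparisons_D, "comparisons_D.tsv")
    if (nrow(comparisons_c)) wt(comparisons_c, "comparisons_c.tsv")
    write_calibration(calib_G, file.path(out_dir, "calibration_G.yaml"))
    write_calibration(calib_R, file.path(out_dir, "calibration_R.yaml"))
  }
  res
}
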