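#' Pipeline run configuration
#'
#' Collects every tunable parameter of the analysis stages with its
#' default. All applied parameters are echoed into reports together with a
#' configuration hash, so a run is reproducible from its output alone.
#'
#' @param normalize_target Calibrated dw-mode intensity (see [rescale()]).
#' @param normalize_n_bins,normalize_smooth_window,normalize_floor_fraction
#'   Passed to [dw_intensity_mode()].
#' @param mask_rule,mask_tau_b0,mask_dw_floor Passed to [combined_mask()].
#' @param hist_max_adc,hist_bin_width ADC histogram binning, mm2/s.
#' @param peak_window,peak_smooth_window Passed to [find_tissue_peak()].
#' @param basis_level Fraction of the peak height defining the left basis.
#' @param seed Integer seed recorded with the run.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(normalize_target = 250,
                       normalize_n_bins = 256L,
                       normalize_smooth_window = 5L,
                       normalize_floor_fraction = 0.05,
                       mask_rule = "and",
                       mask_tau_b0 = 50,
                       mask_dw_floor = 1,
                       hist_max_adc = 4e-3,
                       hist_bin_width = 0.02e-3,
                       peak_window = c(0.3e-3, 1.2e-3),
                       peak_smooth_window = 3L,
                       basis_level = 0.01,
                       seed = 1L) {
  cfg <- list(
    normalize_target = normalize_target,
    normalize_n_bins = as.integer(normalize_n_bins),
    normalize_smooth_window = as.integer(normalize_smooth_window),
    normalize_floor_fraction = normalize_floor_fraction,
    mask_rule = mask_rule,
    mask_tau_b0 = mask_tau_b0,
    mask_dw_floor = mask_dw_floor,
    hist_max_adc = hist_max_adc,
    hist_bin_width = hist_bin_width,
    peak_window = peak_window,
    peak_smooth_window = as.integer(peak_smooth_window),
    basis_level = basis_level,
    seed = as.integer(seed)
  )
  structure(cfg, class = "run_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Analyze one subject's volume pair
#'
#' Runs the per-subject chain in the fixed order rescale -> mask -> ADC ->
#' histogram.
#'
#' @param pair A raw [volume_pair()].
#' @param config A [run_config()].
#' @return A list with `histogram` (an `adc_histogram`) and `meta`
#'   (one-row tibble: `scale_factor`, `dw_mode`, `mask_count`).
#' @export
analyze_subject <- function(pair, config = run_config()) {
  stopifnot(inherits(pair, "volume_pair"), inherits(config, "run_config"))
  scaled <- rescale(pair,
                    target = config$normalize_target,
                    n_bins = config$normalize_n_bins,
                    smooth_window = config$normalize_smooth_window,
                    floor_fraction = config$normalize_floor_fraction)
  mask <- combined_mask(scaled,
                        tau_b0 = config$mask_tau_b0,
                        dw_floor = config$mask_dw_floor,
                        rule = config$mask_rule)
  adc <- compute_adc(scaled, mask)
  hist <- build_histogram(adc, adc_bin_edges(config$hist_max_adc,
                                             config$hist_bin_width))
  list(
    histogram = hist,
    meta = tibble::tibble(scale_factor = scaled$scale_factor,
                          dw_mode = scaled$dw_mode,
                          mask_count = mask$count)
  )
}

read_manifest_pair <- function(row, b_value = 1000) {
  dw <- row$dw_path
  if (is.null(dw) || is.na(dw)) dw <- NULL
  tryCatch(
    suppressWarnings(read_volume_pair(row$b0_path, dw, b_value = b_value)),
    error = function(e) {
      stop(sprintf("subject '%s': %s", row$subject_id, conditionMessage(e)),
           call. = FALSE)
    }
  )
}

#' End-to-end cohort analysis
#'
#' Runs every subject through the per-subject chain, averages the
#' percent-normalized histograms, derives a single characteristic ADC value
#' from the cohort average (peak + mirrored 1%-basis), applies it to every
#' subject's histogram to obtain brain-tissue percentages, and summarises
#' the cohort as age-group statistics, adjacent-group t-tests and quadratic
#' age-trajectory fits for all subjects and each sex.
#'
#' @param manifest Cohort manifest tibble; needs `subject_id`, `age`, `sex`
#'   and either `b0_path`(/`dw_path`) columns or an entry in `pairs`.
#' @param config A [run_config()].
#' @param pairs Optional named list of in-memory [volume_pair()] objects
#'   keyed by `subject_id`, bypassing file I/O (used for simulation
#'   studies).
#' @param b_value Diffusion weighting assumed when reading files, s/mm2.
#' @param fit If `TRUE` (default), quadratic fits and group statistics are
#'   computed; cohorts too small to fit (n < 3) raise an error unless
#'   `fit = FALSE`.
#' @param per_subject_characteristic If `TRUE`, each subject is partitioned
#'   at a characteristic value derived from their own histogram instead of
#'   the cohort-average one (sensitivity analysis; the standard analysis
#'   fixes one cohort-level value).
#' @return An object of class `adc_cohort_analysis`: list with
#'   `characteristic` (a `characteristic_value`), `average_histogram`,
#'   `results` (per-subject tibble), and — when `fit = TRUE` —
#'   `group_summary`, `comparisons`, `fits` (named list of `adc_quadfit`
#'   for all/female/male where estimable), plus `config` and `config_hash`.
#' @export
analyze_cohort <- function(manifest, config = run_config(), pairs = NULL,
                           b_value = 1000, fit = TRUE,
                           per_subject_characteristic = FALSE) {
  stopifnot(inherits(config, "run_config"), nrow(manifest) >= 1L)
  if (anyDuplicated(manifest$subject_id)) {
    stop("manifest has duplicated subject ids", call. = FALSE)
  }
  manifest <- dplyr::arrange(manifest, .data$subject_id)

  per_subject <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    pair <- if (!is.null(pairs)) {
      pairs[[row$subject_id]] %||%
        stop(sprintf("subject '%s': no volume pair supplied", row$subject_id),
             call. = FALSE)
    } else {
      read_manifest_pair(row, b_value = b_value)
    }
    analyze_subject(pair, config)
  })

  histograms <- purrr::map(per_subject, "histogram")
  avg <- average_histogram(histograms)
  peak <- find_tissue_peak(avg, window = config$peak_window,
                           smooth_window = config$peak_smooth_window)
  basis <- find_left_basis(avg, peak, level = config$basis_level)
  cv <- characteristic_value(peak, basis, level = config$basis_level)

  fractions <- purrr::map2_dbl(histograms, per_subject, function(h, ps) {
    if (per_subject_characteristic) {
      pk <- find_tissue_peak(h, window = config$peak_window,
                             smooth_window = config$peak_smooth_window)
      bs <- find_left_basis(h, pk, level = config$basis_level)
      brain_fraction(h, characteristic_value(pk, bs, level = config$basis_level))
    } else {
      brain_fraction(h, cv)
    }
  })

  results <- dplyr::bind_cols(
    manifest[, intersect(c("subject_id", "age", "sex"), names(manifest))],
    tibble::tibble(brain_fraction = fractions),
    dplyr::bind_rows(purrr::map(per_subject, "meta"))
  )

  out <- list(
    characteristic = cv,
    average_histogram = avg,
    results = results,
    config = config,
    config_hash = config_hash(config),
    n_subjects = nrow(manifest)
  )

  if (fit) {
    out$group_summary <- group_summary(results)
    groups <- assign_age_group(results$age)
    counts <- tabulate(groups, nbins = 4L)
    out$comparisons <- if (all(counts >= 2)) {
      compare_adjacent_groups(results)
    } else {
      NULL
    }
    out$fits <- list(all = fit_quadratic(results, "all"))
    for (s in c("female", "male")) {
      sub <- results[results$sex == s, ]
      if (nrow(sub) >= 3 && length(unique(sub$age)) >= 3) {
        out$fits[[s]] <- fit_quadratic(results, s)
      }
    }
  }
  structure(out, class = "adc_cohort_analysis")
}

#' @export
print.adc_cohort_analysis <- function(x, ...) {
  cat("<adc_cohort_analysis> ", x$n_subjects, " subjects\n", sep = "")
  print(x$characteristic)
  if (!is.null(x$fits)) for (f in x$fits) print(f)
  invisible(x)
}

#' Write a cohort analysis report
#'
#' Emits `characteristic.json` (peak, basis, characteristic value, level,
#' binning, subject count, full configuration and its hash), `results.csv`
#' (per-subject), `group_summary.csv`, `comparisons.csv` and
#' `average_histogram.tsv` into a directory.
#'
#' @param analysis An `adc_cohort_analysis`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "adc_cohort_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cv <- analysis$characteristic
  report <- list(
    peak_adc = cv$peak_adc, peak_height = cv$peak_height,
    left_basis = cv$left_basis, a_char = cv$a_char, level = cv$level,
    bin_width = analysis$config$hist_bin_width,
    max_adc = analysis$config$hist_max_adc,
    n_subjects = analysis$n_subjects,
    config = unclass(analysis$config),
    config_hash = analysis$config_hash
  )
  if (!is.null(analysis$fits)) {
    report$fits <- purrr::map(analysis$fits, function(f) {
      list(stratum = f$stratum, n = f$n, c0 = f$c0, c1 = f$c1, c2 = f$c2,
           rmse = f$rmse,
           slopes = list(age_20 = slope_at_age(f, 20),
                         age_50 = slope_at_age(f, 50),
                         age_80 = slope_at_age(f, 80)))
    })
  }
  jsonlite::write_json(report, file.path(dir, "characteristic.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(analysis$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  if (!is.null(analysis$group_summary)) {
    utils::write.csv(analysis$group_summary,
                     file.path(dir, "group_summary.csv"), row.names = FALSE)
  }
  if (!is.null(analysis$comparisons)) {
    utils::write.csv(analysis$comparisons,
                     file.path(dir, "comparisons.csv"), row.names = FALSE)
  }
  write_histogram_tsv(analysis$average_histogram,
                      file.path(dir, "average_histogram.tsv"))
  invisible(dir)
}

#' Read a cohort manifest CSV
#'
#' Validates that subject ids are unique and, when path columns are
#' present, that every referenced file exists before analysis starts.
#'
#' @param path Manifest CSV path.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  m <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (anyDuplicated(m$subject_id)) {
    stop("manifest has duplicated subject ids", call. = FALSE)
  }
  paths <- c(m$b0_path, m$dw_path)
  paths <- paths[!is.na(paths)]
  missing <- unique(paths[!file.exists(paths)])
  if (length(missing) > 0) {
    stop("manifest references missing files: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  m
}
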