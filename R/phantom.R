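#' Phantom acquisition configuration
#'
#' Parameters of the synthetic DWI head phantom: grid geometry, compartment
#' ADC distributions, compartment b0 signal levels, Rician noise level and
#' partial-volume shell thickness. Defaults emulate a routine axial DWI
#' acquisition (224 x 224 matrix, 230 mm FOV, 30 slices of 4 mm with 0.8 mm
#' gap, b = 0 / 1000 s/mm2): brain tissue with a Gaussian ADC distribution
#' centred at 0.75e-3 mm2/s and CSF as free water near 3.1e-3 mm2/s, bright
#' in b0 and strongly attenuated in the diffusion-weighted image.
#'
#' @param grid_shape Integer vector of voxels per axis.
#' @param voxel_size Voxel dimensions in mm (x, y, z including gap).
#' @param b_value Diffusion weighting of the dw volume, s/mm2.
#' @param tissue_adc_mean,tissue_adc_sd Mean and SD of the brain-tissue ADC
#'   distribution, mm2/s. The SD controls where the tissue peak's left
#'   1%-of-maximum basis falls, and hence the characteristic value.
#' @param csf_adc_mean,csf_adc_sd Mean and SD of the CSF ADC distribution,
#'   mm2/s; the mean must exceed `tissue_adc_mean`.
#' @param s0_tissue,s0_csf Non-diffusion-weighted signal of tissue and CSF in
#'   arbitrary scanner units; CSF is brighter (`s0_csf > s0_tissue`).
#' @param noise_sigma Per-channel Gaussian noise SD of the complex signal;
#'   the magnitude images carry Rician noise. `0` gives a noise-free phantom.
#' @param partial_volume_shell Thickness, in voxels, of the mixed tissue/CSF
#'   zone at compartment boundaries; `0` disables partial volume. At the
#'   default 1 the mixed population is 10% of in-head voxels (the folded,
#'   largely atrophy-independent cortical interface) plus 25% of the
#'   CSF-space voxels (widening sulci, expanding ventricles).
#' @param ventricle_share Share of CSF voxels placed in the central
#'   ventricle blob (the rest forms the peripheral sulcal rim).
#' @param fast_n_voxels Number of voxels drawn in fast (flat-array) mode.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(224L, 224L, 30L),
                           voxel_size = c(230 / 224, 230 / 224, 4.8),
                           b_value = 1000,
                           tissue_adc_mean = 0.75e-3,
                           tissue_adc_sd = 0.13e-3,
                           csf_adc_mean = 3.1e-3,
                           csf_adc_sd = 0.4e-3,
                           s0_tissue = 300,
                           s0_csf = 600,
                           noise_sigma = 3,
                           partial_volume_shell = 1,
                           ventricle_share = 0.4,
                           fast_n_voxels = 120000L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(
    length(grid_shape) == 3L, all(grid_shape >= 1L),
    length(voxel_size) == 3L, all(voxel_size > 0),
    b_value > 0,
    tissue_adc_mean > 0, tissue_adc_sd > 0,
    csf_adc_mean > 0, csf_adc_sd > 0,
    csf_adc_mean > tissue_adc_mean,
    s0_tissue > 0, s0_csf > s0_tissue,
    partial_volume_shell >= 0,
    ventricle_share >= 0, ventricle_share <= 1,
    fast_n_voxels >= 100L
  )
  if (noise_sigma < 0) {
    stop("`noise_sigma` must be >= 0 (0 selects noise-free mode)", call. = FALSE)
  }
  if (s0_tissue <= noise_sigma) {
    stop("`s0_tissue` must exceed `noise_sigma`", call. = FALSE)
  }
  structure(
    list(
      grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
      b_value = b_value,
      tissue_adc_mean = tissue_adc_mean, tissue_adc_sd = tissue_adc_sd,
      csf_adc_mean = csf_adc_mean, csf_adc_sd = csf_adc_sd,
      s0_tissue = s0_tissue, s0_csf = s0_csf,
      noise_sigma = noise_sigma,
      partial_volume_shell = partial_volume_shell,
      ventricle_share = ventricle_share,
      fast_n_voxels = as.integer(fast_n_voxels)
    ),
    class = "phantom_config"
  )
}

#' Quadratic age trajectory of the brain-tissue fraction
#'
#' Generating-side counterpart of the fitted cohort trajectory: the expected
#' brain-tissue percentage at age x is `c0 + c1*x + c2*x^2`, with Gaussian
#' between-subject scatter of SD `subject_sd` percentage points.
#'
#' @param c0 Intercept, percent.
#' @param c1 Linear term, percent/year.
#' @param c2 Quadratic term, percent/year^2.
#' @param subject_sd Between-subject scatter, percent.
#' @return An object of class `age_trajectory`.
#' @export
age_trajectory <- function(c0 = 83.5, c1 = -0.068, c2 = -0.0027,
                           subject_sd = 1.5) {
  if (subject_sd < 0) stop("`subject_sd` must be >= 0", call. = FALSE)
  traj <- structure(
    list(c0 = c0, c1 = c1, c2 = c2, subject_sd = subject_sd),
    class = "age_trajectory"
  )
  vals <- true_fraction(traj, seq(0, 90, by = 0.5))
  if (any(vals <= 0 | vals >= 100)) {
    stop("trajectory leaves (0, 100) percent within ages 0-90", call. = FALSE)
  }
  traj
}

#' Evaluate an age trajectory
#'
#' @param trajectory An [age_trajectory()].
#' @param age Age(s) in decimal years, >= 0.
#' @return Expected brain-tissue percentage `c0 + c1*age + c2*age^2`.
#' @export
true_fraction <- function(trajectory, age) {
  stopifnot(inherits(trajectory, "age_trajectory"), all(age >= 0))
  trajectory$c0 + trajectory$c1 * age + trajectory$c2 * age^2
}

#' Sample a synthetic cohort manifest
#'
#' Draws `n` subjects with ages uniform over `age_range`, sexes
#' Bernoulli(0.5), and a ground-truth brain-tissue fraction
#' `c0 + c1*age + c2*age^2 + N(0, subject_sd)` clipped to (1, 99) percent.
#' Each subject receives its own derived seed so that volume synthesis is
#' reproducible subject by subject. Optionally applies a random per-subject
#' global intensity scale, emulating inconsistent scanner export scaling.
#'
#' @param n Number of subjects (>= 1).
#' @param age_range Length-2 numeric, within [0, 90].
#' @param trajectory An [age_trajectory()].
#' @param seed Integer seed; the manifest is deterministic given it.
#' @param scale_range Length-2 range of the per-subject global intensity
#'   multiplier, drawn log-uniformly; `c(1, 1)` disables rescaling.
#' @return A tibble manifest with columns `subject_id`, `age`, `sex`,
#'   `true_brain_fraction`, `global_scale`, `seed`.
#' @export
sample_cohort <- function(n, age_range = c(5, 85), trajectory = age_trajectory(),
                          seed = 1L, scale_range = c(1, 1)) {
  stopifnot(n >= 1, length(age_range) == 2L, inherits(trajectory, "age_trajectory"))
  if (age_range[1] >= age_range[2]) stop("empty age range", call. = FALSE)
  if (age_range[1] < 0 || age_range[2] > 90) {
    stop("`age_range` must lie within [0, 90]", call. = FALSE)
  }
  stopifnot(length(scale_range) == 2L, all(scale_range > 0),
            scale_range[1] <= scale_range[2])
  withr::with_seed(as.integer(seed), {
    age <- stats::runif(n, age_range[1], age_range[2])
    sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
    frac <- true_fraction(trajectory, age) +
      stats::rnorm(n, 0, trajectory$subject_sd)
    frac <- pmin(pmax(frac, 1), 99)
    scale <- exp(stats::runif(n, log(scale_range[1]), log(scale_range[2])))
    subj_seed <- sample.int(.Machine$integer.max - 1L, n)
    tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex,
      true_brain_fraction = frac,
      global_scale = scale,
      seed = subj_seed
    )
  })
}

# Partition n_head in-head voxels (ordered by normalized radius) into
# [ventricle CSF | inner PV | tissue | outer PV | sulcal rim CSF] so that the
# pure-tissue count is exactly round(n_head * f / 100). The partial-volume
# count is a fixed share of the CSF-space voxels: the sulcal/ventricular
# interface is convoluted, so at DWI slice thicknesses a roughly constant
# fraction of CSF-space voxels is mixed, independent of head size.
partition_head <- function(n_head, fraction, config) {
  n_tissue <- round(n_head * fraction / 100)
  n_rest <- n_head - n_tissue
  if (n_rest < 1 || n_tissue < 1) {
    stop("brain fraction infeasible for the phantom geometry", call. = FALSE)
  }
  n_pv <- 0L
  if (config$partial_volume_shell > 0) {
    # mixed voxels live on the folded tissue/CSF interface. Its area is
    # dominated by the (atrophy-independent) cortical folding pattern, with
    # a secondary term growing as CSF spaces widen and ventricles expand.
    n_pv <- round(config$partial_volume_shell *
                    (0.10 * n_head + 0.25 * n_rest))
    n_pv <- min(n_rest, n_pv)
  }
  n_csf <- n_rest - n_pv
  n_vent <- round(n_csf * config$ventricle_share)
  n_rim <- n_csf - n_vent
  n_pv_in <- round(n_pv * config$ventricle_share)
  n_pv_out <- n_pv - n_pv_in
  # labels in radial rank order
  c(
    rep(2L, n_vent), rep(3L, n_pv_in), rep(1L, n_tissue),
    rep(3L, n_pv_out), rep(2L, n_rim)
  )
}

rician <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  pmax(x, 0)
}

#' Synthesize a b0/dw phantom volume pair for one subject
#'
#' Builds an ellipsoidal head inside the configured grid, partitions in-head
#' voxels into pure tissue, pure CSF (central ventricle blob plus peripheral
#' sulcal rim) and a linear-mixing partial-volume shell, draws per-voxel ADC
#' from the compartment distributions (truncated at 0), sets the b0 signal
#' per compartment and derives the dw signal as `b0 * exp(-b * ADC)`. Rician
#' noise (magnitude of a complex Gaussian) is added to both volumes before
#' the subject's global intensity scale is applied. The pure-tissue share of
#' in-head voxels matches `true_brain_fraction` to within 0.5 percentage
#' points (exactly, up to rounding of the voxel count).
#'
#' In fast mode the same voxel-value distributions are emitted as flat
#' arrays (`fast_n_voxels` voxels, 30% background) without 3-D geometry;
#' the downstream analysis consumes only intensity distributions, so fast
#' phantoms exercise the full pipeline at a fraction of the cost.
#'
#' @param subject One manifest row (list or single-row data frame) with at
#'   least `true_brain_fraction`, `global_scale` and `seed`.
#' @param config A [phantom_config()].
#' @param fast If `TRUE`, emit flat voxel arrays instead of full volumes.
#' @return A [volume_pair()] with attributes `labels` (integer array:
#'   0 background, 1 tissue, 2 CSF, 3 partial volume) and `adc_true`
#'   (the noise-free per-voxel ADC, `NA` for background).
#' @export
synthesize_volumes <- function(subject, config = phantom_config(), fast = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  subject <- as.list(subject)
  fraction <- subject$true_brain_fraction
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 100) {
    stop("`true_brain_fraction` must lie in (0, 100)", call. = FALSE)
  }
  gscale <- subject$global_scale %||% 1
  stopifnot(gscale > 0)
  seed <- as.integer(subject$seed %||% 0L)

  if (fast) {
    n_head <- round(0.7 * config$fast_n_voxels)
    # lay the flat voxel array out as a plane: axis lengths must respect the
    # NIfTI-1 per-dimension limit
    nx <- 512L
    ny <- as.integer(ceiling(config$fast_n_voxels / nx))
    dims <- c(nx, ny, 1L)
    n_total <- nx * ny
    head_idx <- seq_len(n_head)  # already "radially ordered" by construction
  } else {
    dims <- config$grid_shape
    ax <- (dims - 1) / 2
    semi <- c(0.45, 0.45, 0.48) * dims
    gx <- (seq_len(dims[1]) - 1 - ax[1]) / semi[1]
    gy <- (seq_len(dims[2]) - 1 - ax[2]) / semi[2]
    gz <- (seq_len(dims[3]) - 1 - ax[3]) / semi[3]
    # flattened along z (6th power): every slice of the stack holds head,
    # as in an axial acquisition planned to cover the brain
    r2 <- outer(outer(gx^2, gy^2, `+`), gz^6, `+`)
    inside <- which(r2 <= 1)
    head_idx <- inside[order(r2[inside])]
    n_head <- length(head_idx)
    n_total <- prod(dims)
  }

  labels_head <- partition_head(n_head, fraction, config)

  withr::with_seed(seed, {
    n_pv <- sum(labels_head == 3L)
    adc_head <- numeric(n_head)
    s0_head <- numeric(n_head)
    is_t <- labels_head == 1L
    is_c <- labels_head == 2L
    is_p <- labels_head == 3L
    adc_head[is_t] <- rnorm_trunc0(sum(is_t), config$tissue_adc_mean,
                                   config$tissue_adc_sd)
    adc_head[is_c] <- rnorm_trunc0(sum(is_c), config$csf_adc_mean,
                                   config$csf_adc_sd)
    s0_head[is_t] <- config$s0_tissue
    s0_head[is_c] <- config$s0_csf
    if (n_pv > 0) {
      w <- stats::runif(n_pv)
      adc_head[is_p] <- w * rnorm_trunc0(n_pv, config$tissue_adc_mean,
                                         config$tissue_adc_sd) +
        (1 - w) * rnorm_trunc0(n_pv, config$csf_adc_mean, config$csf_adc_sd)
      s0_head[is_p] <- w * config$s0_tissue + (1 - w) * config$s0_csf
    }

    b0 <- numeric(n_total)
    dw <- numeric(n_total)
    labels <- integer(n_total)
    adc_true <- rep(NA_real_, n_total)
    b0[head_idx] <- s0_head
    dw[head_idx] <- s0_head * exp(-config$b_value * adc_head)
    labels[head_idx] <- labels_head
    adc_true[head_idx] <- adc_head

    b0 <- rician(b0, config$noise_sigma) * gscale
    dw <- rician(dw, config$noise_sigma) * gscale
  })

  dim(b0) <- dims
  dim(dw) <- dims
  dim(labels) <- dims
  dim(adc_true) <- dims
  pair <- volume_pair(b0, dw, b_value = config$b_value)
  attr(pair, "labels") <- labels
  attr(pair, "adc_true") <- adc_true
  pair
}

#' Write a phantom cohort to disk
#'
#' Synthesizes every subject in a manifest, writes the volumes as NIfTI
#' (two 3-D files per subject, or one 4-D file with volume 0 = b0 and
#' volume 1 = dw) and the manifest as CSV.
#'
#' @param manifest A manifest tibble from [sample_cohort()].
#' @param config A [phantom_config()].
#' @param dir Output directory (created if missing).
#' @param format `"3d"` (b0/dw file pair) or `"4d"` (single file).
#' @param fast Passed to [synthesize_volumes()].
#' @return The manifest tibble with `b0_path`/`dw_path` (or `path`) columns,
#'   invisibly also written to `<dir>/manifest.csv`.
#' @export
write_phantom_cohort <- function(manifest, config = phantom_config(),
                                 dir, format = c("3d", "4d"), fast = FALSE) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopifnot(!anyDuplicated(manifest$subject_id))
  affine <- diag(c(config$voxel_size, 1))
  paths <- purrr::pmap(manifest, function(...) {
    subject <- list(...)
    pair <- synthesize_volumes(subject, config, fast = fast)
    if (format == "3d") {
      b0_path <- file.path(dir, paste0(subject$subject_id, "_b0.nii"))
      dw_path <- file.path(dir, paste0(subject$subject_id, "_dw.nii"))
      write_volume_pair(pair, b0_path, dw_path, voxel_size = config$voxel_size)
      list(b0_path = b0_path, dw_path = dw_path)
    } else {
      path <- file.path(dir, paste0(subject$subject_id, "_dwi.nii"))
      write_volume_pair(pair, path, voxel_size = config$voxel_size)
      list(b0_path = path, dw_path = NA_character_)
    }
  })
  out <- dplyr::bind_cols(manifest, dplyr::bind_rows(paths))
  utils::write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  out
}
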