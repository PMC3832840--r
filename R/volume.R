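#' A co-registered b0 / diffusion-weighted volume pair
#'
#' The two magnitude images a DWI acquisition yields for each slice stack:
#' the non-diffusion-weighted image (`b0`) and the diffusion-weighted image
#' (`dw`) at `b_value` s/mm2. Intensities are in arbitrary scanner units.
#'
#' @param b0,dw Numeric arrays of identical shape, non-negative.
#' @param b_value Diffusion weighting of `dw`, s/mm2 (> 0).
#' @return An object of class `volume_pair`.
#' @export
volume_pair <- function(b0, dw, b_value = 1000) {
  stopifnot(is.numeric(b0), is.numeric(dw), b_value > 0)
  if (!identical(dim2(b0), dim2(dw))) {
    stop("`b0` and `dw` must have identical shape", call. = FALSE)
  }
  if (anyNA(b0) || anyNA(dw)) stop("volumes contain NA/NaN voxels", call. = FALSE)
  if (min(b0) < 0 || min(dw) < 0) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(list(b0 = b0, dw = dw, b_value = b_value), class = "volume_pair")
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' @export
print.volume_pair <- function(x, ...) {
  cat("<volume_pair> ", paste(dim2(x$b0), collapse = " x "),
      " voxels, b = ", x$b_value, " s/mm2", sep = "")
  if (!is.null(x$scale_factor)) {
    cat(sprintf(", rescaled (dw mode %.4g -> scale %.4g)",
                x$dw_mode, x$scale_factor))
  }
  cat("\n")
  invisible(x)
}

#' Read a b0/dw volume pair from NIfTI
#'
#' Accepts either two 3-D files or a single 4-D file whose first volume is
#' b0 and second is dw.
#'
#' @param b0_path Path to the b0 NIfTI, or to a 4-D NIfTI when `dw_path`
#'   is `NULL`.
#' @param dw_path Path to the dw NIfTI, or `NULL` for 4-D input.
#' @param b_value Diffusion weighting of the dw volume, s/mm2.
#' @return A [volume_pair()].
#' @export
read_volume_pair <- function(b0_path, dw_path = NULL, b_value = 1000) {
  if (is.null(dw_path) || is.na(dw_path)) {
    img <- RNifti::readNifti(b0_path)
    arr <- as.array(img)
    if (length(dim(arr)) != 4L || dim(arr)[4] < 2L) {
      stop("4-D input must hold at least 2 volumes (b0, dw)", call. = FALSE)
    }
    b0 <- arr[, , , 1, drop = TRUE]
    dw <- arr[, , , 2, drop = TRUE]
  } else {
    b0 <- as.array(RNifti::readNifti(b0_path))
    dw <- as.array(RNifti::readNifti(dw_path))
  }
  if (anyNA(b0) || anyNA(dw)) {
    stop("input volumes contain NaN voxels", call. = FALSE)
  }
  volume_pair(b0, dw, b_value = b_value)
}

#' Write a volume pair as NIfTI
#'
#' @param pair A [volume_pair()].
#' @param b0_path Output path; when `dw_path` is `NULL` a single 4-D file
#'   (volume 0 = b0, volume 1 = dw) is written here.
#' @param dw_path Output path of the dw volume, or `NULL` for 4-D output.
#' @param voxel_size Voxel dimensions in mm, used for the RAS affine.
#' @return The path(s) written, invisibly.
#' @export
write_volume_pair <- function(pair, b0_path, dw_path = NULL,
                              voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(pair, "volume_pair"))
  as_img <- function(arr) {
    pd <- rep(1, length(dim2(arr)))
    pd[seq_len(min(3L, length(pd)))] <- voxel_size[seq_len(min(3L, length(pd)))]
    attr(arr, "pixdim") <- pd
    RNifti::asNifti(arr, datatype = "float")
  }
  if (is.null(dw_path)) {
    arr <- array(c(pair$b0, pair$dw), dim = c(dim2(pair$b0), 2L))
    RNifti::writeNifti(as_img(arr), b0_path)
    return(invisible(b0_path))
  }
  RNifti::writeNifti(as_img(pair$b0), b0_path)
  RNifti::writeNifti(as_img(pair$dw), dw_path)
  invisible(c(b0_path, dw_path))
}
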