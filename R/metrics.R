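#' Per-voxel and global r.m.s. prediction error
#'
#' The error in voxel `v` is the root mean square of the prediction residual
#' over the diffusion-weighted directions,
#' `e_rms(v) = sqrt(mean_theta (y - y_hat)^2)`, computed on the relative
#' (attenuation) demeaned signal. The global error is the arithmetic mean of
#' `e_rms(v)`. By default the average runs over the voxels containing at
#' least one tensor entry (`occupied`); in voxels no fascicle traverses the
#' model predicts identically zero, and those voxels are reported separately.
#'
#' @param y,y_hat measured and predicted demeaned relative signal, stacked
#'   voxel-major (as produced by [demean] and [predict.life]).
#' @param n_dwi number of diffusion-weighted directions per voxel.
#' @param occupied optional integer vector of 1-based voxel indices with at
#'   least one tensor entry; when omitted, all voxels enter the average.
#' @return An object of class `error_report`: `e_rms` (per-voxel vector),
#'   `mean_rms` (mean over `occupied`), `mean_rms_all`, `occupied`,
#'   `n_used`, `n_empty`.
#' @export
rmse_map <- function(y, y_hat, n_dwi, occupied = NULL) {
  if (length(y) != length(y_hat))
    stop("y and y_hat have different lengths", call. = FALSE)
  if (length(y) %% n_dwi != 0)
    stop("length(y) is not a multiple of n_dwi", call. = FALSE)
  n_vox <- length(y) %/% n_dwi
  r2 <- matrix((y - y_hat)^2, n_dwi, n_vox)
  e <- sqrt(colMeans(r2))
  occupied <- occupied %||% seq_len(n_vox)
  structure(list(e_rms = e, mean_rms = mean(e[occupied]),
                 mean_rms_all = mean(e), occupied = occupied,
                 n_used = length(occupied),
                 n_empty = n_vox - length(occupied)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "r.m.s. error: %.5f over %d occupied voxels (%.5f over all %d; %d empty)\n",
    x$mean_rms, x$n_used, x$mean_rms_all, x$n_used + x$n_empty, x$n_empty))
  invisible(x)
}

#' Relative model-approximation error (Frobenius)
#'
#' `|| M - M_hat ||_F / || M ||_F`, comparing the exact explicit model
#' matrix with its dictionary-times-sparse-tensor reconstruction.
#'
#' @param M,M_hat matrices of identical shape (dense or `Matrix` sparse).
#' @return scalar relative error.
#' @export
model_error <- function(M, M_hat) {
  if (!identical(dim(M), dim(M_hat)))
    stop("matrices have different shapes", call. = FALSE)
  den <- sqrt(sum(M^2))
  if (den == 0) stop("||M||_F = 0: relative error undefined", call. = FALSE)
  sqrt(sum((M - M_hat)^2)) / den
}

#' Relative weight-approximation error (Euclidean)
#'
#' `|| w - w_hat || / || w ||`.
#'
#' @param w,w_hat weight vectors of equal length.
#' @return scalar relative error.
#' @export
weight_error <- function(w, w_hat) {
  if (length(w) != length(w_hat))
    stop("weight vectors have different lengths", call. = FALSE)
  den <- sqrt(sum(w^2))
  if (den == 0) stop("||w|| = 0: relative error undefined", call. = FALSE)
  sqrt(sum((w - w_hat)^2)) / den
}

#' Volumetric resolution gain between two isotropic voxel sizes
#'
#' The percentage increase in voxels per unit volume when moving from
#' `coarse_mm` to `fine_mm` isotropic voxels:
#' `((coarse/fine)^3 - 1) * 100`. Moving from 1.25 mm to 1.05 mm voxels,
#' for example, gains 68.7%.
#'
#' @param coarse_mm,fine_mm isotropic voxel edge lengths (mm).
#' @return percentage gain.
#' @export
volumetric_resolution_gain <- function(coarse_mm, fine_mm) {
  stopifnot(coarse_mm > 0, fine_mm > 0)
  ((coarse_mm / fine_mm)^3 - 1) * 100
}
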