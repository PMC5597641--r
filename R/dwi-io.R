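#' Diffusion-weighted volumes
#'
#' Bundles a 4D diffusion signal array with its gradient table, brain mask and
#' voxel-to-world affine. `S0` is the per-voxel mean of the `b = 0` volumes;
#' in-mask voxels where `S0 <= 0` are removed from the mask with a warning
#' (nothing can be expressed as attenuation there).
#'
#' The affine maps 0-based voxel indices to world mm; a continuous voxel
#' coordinate `p` belongs to voxel `floor(p + 0.5)` (voxel-center convention).
#'
#' @param signal 4D numeric array (x, y, z, volume), scanner units.
#' @param gtab [gradient_table] matching the 4th dimension.
#' @param mask logical/0-1 3D array, same spatial shape as `signal`.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @return An object of class `diffusion_volume` with elements `signal`,
#'   `gtab`, `mask`, `affine`, `S0` (3D array), `voxel_map` (`N_v x 3` matrix
#'   of 1-based in-mask voxel indices, fixing the voxel ordering used
#'   throughout), and `n_vox`.
#' @export
diffusion_volume <- function(signal, gtab, mask, affine = diag(4)) {
  stopifnot(inherits(gtab, "gradient_table"))
  dims <- dim(signal)
  if (length(dims) != 4)
    stop("signal must be a 4D array", call. = FALSE)
  if (dims[4] != length(gtab$bvals))
    stop("4th dimension of signal does not match the gradient table",
         call. = FALSE)
  mask <- array(as.logical(mask), dim = dims[1:3])
  if (!identical(dim(mask), dims[1:3]))
    stop("mask shape does not match signal", call. = FALSE)
  if (!any(gtab$b0))
    stop("no b = 0 volume: cannot compute S0 or demean", call. = FALSE)
  b0_idx <- which(gtab$b0)
  S0 <- apply(signal[, , , b0_idx, drop = FALSE], 1:3, mean)
  bad <- mask & S0 <= 0
  if (any(bad)) {
    warning(sum(bad), " in-mask voxel(s) with S0 <= 0 removed from mask")
    mask[bad] <- FALSE
  }
  voxel_map <- which(mask, arr.ind = TRUE)
  colnames(voxel_map) <- c("i", "j", "k")
  structure(
    list(signal = signal, gtab = gtab, mask = mask, affine = affine,
         S0 = S0, voxel_map = voxel_map, n_vox = nrow(voxel_map)),
    class = "diffusion_volume"
  )
}

#' Read a 4D diffusion dataset from NIfTI + FSL gradient files
#'
#' @param nifti_4d path to the 4D diffusion NIfTI.
#' @param bvals,bvecs paths to FSL-dialect gradient text files.
#' @param mask path to a 3D mask NIfTI, or `NULL` to take all voxels.
#' @inheritParams gradient_table
#' @return A [diffusion_volume].
#' @export
read_dwi <- function(nifti_4d, bvals, bvecs, mask = NULL, b0_threshold = 50) {
  img <- RNifti::readNifti(nifti_4d)
  affine <- structure(RNifti::xform(img), class = "matrix")
  sig <- array(as.numeric(img), dim = dim(img))
  gtab <- read_gradient_table(bvals, bvecs, b0_threshold = b0_threshold)
  if (is.null(mask)) {
    m <- array(TRUE, dim = dim(sig)[1:3])
  } else {
    mimg <- RNifti::readNifti(mask)
    m <- array(as.numeric(mimg) > 0, dim = dim(mimg))
    if (!identical(dim(m), dim(sig)[1:3]))
      stop("mask and signal spatial shapes differ", call. = FALSE)
  }
  diffusion_volume(sig, gtab, m, affine = affine)
}

#' Write a diffusion volume (and its mask) to NIfTI
#'
#' @param dwi a [diffusion_volume].
#' @param nifti_path output path for the 4D signal.
#' @param mask_path optional output path for the binary mask.
#' @return Invisibly, the paths written.
#' @export
write_dwi <- function(dwi, nifti_path, mask_path = NULL) {
  stopifnot(inherits(dwi, "diffusion_volume"))
  img <- RNifti::asNifti(dwi$signal)
  RNifti::qform(img) <- structure(dwi$affine, code = 2L)
  RNifti::sform(img) <- structure(dwi$affine, code = 2L)
  RNifti::writeNifti(img, nifti_path)
  if (!is.null(mask_path)) {
    mimg <- RNifti::asNifti(array(as.numeric(dwi$mask), dim = dim(dwi$mask)))
    RNifti::qform(mimg) <- structure(dwi$affine, code = 2L)
    RNifti::sform(mimg) <- structure(dwi$affine, code = 2L)
    RNifti::writeNifti(mimg, mask_path)
  }
  invisible(c(nifti_path, mask_path))
}

#' @export
print.diffusion_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat("Diffusion volume: ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " volumes (", x$gtab$n_dwi, " dwi), ",
      x$n_vox, " in mask\n", sep = "")
  invisible(x)
}
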