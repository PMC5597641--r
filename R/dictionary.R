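#' Canonical axial orientation atoms
#'
#' Places `L` quasi-uniform, sign-free (axial) orientations on the upper
#' hemisphere using a deterministic spherical Fibonacci lattice:
#' `z_i = 1 - (i - 0.5)/L` with azimuths advancing by the golden angle. The
#' construction is deterministic for fixed `L`, contains no antipodal
#' duplicates (all points have `z > 0` except the degenerate `L = 1` case,
#' which returns the z axis), and its covering radius shrinks as `L` grows.
#'
#' @param L number of atoms (>= 1).
#' @return `L x 3` matrix of unit vectors with `z >= 0`.
#' @export
build_atoms <- function(L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be >= 1", call. = FALSE)
  if (L == 1L) return(matrix(c(0, 0, 1), 1, 3))
  i <- seq_len(L)
  z <- 1 - (i - 0.5) / L
  r <- sqrt(pmax(0, 1 - z^2))
  az <- pi * (3 - sqrt(5)) * (i - 1)
  cbind(r * cos(az), r * sin(az), z)
}

#' Demeaned diffusion kernel for one axial orientation
#'
#' The single-fascicle forward kernel is the diffusion-tensor attenuation for
#' a prolate ("stick" when `lambda_radial = 0`) tensor aligned with `u`,
#' demeaned across the diffusion-weighted directions:
#' `O(theta) = exp(-b t(theta) Q theta) - mean_theta exp(-b t(theta) Q theta)`
#' with `Q = R diag(lambda_axial, lambda_radial, lambda_radial) t(R)` and `R`
#' any rotation taking the z axis to `u`. Only the squared projection
#' `(theta . u)^2` enters, so the kernel is even in `u` (axial) and the choice
#' of `R` is immaterial.
#'
#' @param u unit 3-vector (fascicle orientation).
#' @param gtab [gradient_table]; only `b > 0` directions contribute.
#' @param lambda_axial,lambda_radial diffusivities (mm^2/s). A configuration
#'   with `lambda_axial < lambda_radial` violates the prolate assumption and
#'   triggers a warning.
#' @return numeric vector of length `gtab$n_dwi`, mean zero.
#' @export
kernel_column <- function(u, gtab, lambda_axial = 1.5e-3, lambda_radial = 0) {
  stopifnot(inherits(gtab, "gradient_table"))
  if (gtab$n_dwi < 2) stop("need at least 2 dwi directions", call. = FALSE)
  if (abs(vec_norm(u) - 1) > 1e-6) stop("|u| must be 1", call. = FALSE)
  if (lambda_axial < lambda_radial)
    warning("lambda_axial < lambda_radial: oblate kernel requested")
  dwi <- !gtab$b0
  th <- gtab$bvecs[dwi, , drop = FALSE]
  b <- gtab$bvals[dwi]
  t2 <- as.vector(th %*% u)^2
  e <- exp(-b * (lambda_radial + (lambda_axial - lambda_radial) * t2))
  e - mean(e)
}

#' Orientation dictionary: atoms and their demeaned kernels
#'
#' Builds the `L` axial atoms together with the `N_theta x L` kernel matrix
#' `D` whose columns are precomputed demeaned diffusion predictions, one per
#' canonical orientation. The dictionary is tied to a single-shell gradient
#' table; multi-shell input is rejected.
#'
#' @inheritParams build_atoms
#' @inheritParams kernel_column
#' @param b0_round b-values are rounded to this granularity (s/mm^2) when
#'   checking the single-shell assumption.
#' @return An object of class `orientation_dictionary`: `atoms` (`L x 3`),
#'   `D` (`N_theta x L`, each column mean zero), `L`, the diffusivities and
#'   the shell b-value.
#' @export
orientation_dictionary <- function(gtab, L = 362, lambda_axial = 1.5e-3,
                                   lambda_radial = 0, b0_round = 100) {
  stopifnot(inherits(gtab, "gradient_table"))
  shells <- unique(round(gtab$bvals[!gtab$b0] / b0_round))
  if (length(shells) > 1)
    stop("multi-shell gradient table: the kernel dictionary assumes one shell",
         call. = FALSE)
  atoms <- build_atoms(L)
  D <- vapply(seq_len(nrow(atoms)),
              function(a) kernel_column(atoms[a, ], gtab,
                                        lambda_axial, lambda_radial),
              numeric(gtab$n_dwi))
  structure(
    list(atoms = atoms, D = matrix(D, nrow = gtab$n_dwi), L = nrow(atoms),
         lambda_axial = lambda_axial, lambda_radial = lambda_radial,
         b = mean(gtab$bvals[!gtab$b0]), n_dwi = gtab$n_dwi),
    class = "orientation_dictionary"
  )
}

#' @export
print.orientation_dictionary <- function(x, ...) {
  cat("Orientation dictionary: L =", x$L, "atoms,",
      x$n_dwi, "directions, b =", round(x$b), "s/mm^2\n")
  cat("  lambda_axial =", x$lambda_axial, "lambda_radial =",
      x$lambda_radial, "mm^2/s\n")
  invisible(x)
}

#' Nearest dictionary atom to an orientation
#'
#' Axial similarity: returns `argmax_a |atoms[a, ] . t|`. Ties break to the
#' lowest atom index, deterministically.
#'
#' @param t unit 3-vector, or `n x 3` matrix of unit rows.
#' @param dict an [orientation_dictionary] (or a bare atom matrix).
#' @return integer atom index (vector for matrix input).
#' @export
nearest_atom <- function(t, dict) {
  atoms <- if (inherits(dict, "orientation_dictionary")) dict$atoms else dict
  tm <- matrix(t, ncol = 3)
  n <- sqrt(rowSums(tm^2))
  if (any(n < 1e-12)) stop("zero orientation vector", call. = FALSE)
  sims <- abs((tm / n) %*% t(atoms))
  out <- max.col(sims, ties.method = "first")
  if (is.matrix(t) && nrow(t) > 1) out else out[1]
}
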