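#' Demean a diffusion volume
#'
#' Computes the relative demeaned signal the LiFE model predicts:
#' `y(theta, v) = (S(theta, v) - I_v) / S0(v)` over the `b > 0` directions,
#' where `I_v` is the per-voxel mean of `S` across those directions. Dividing
#' by `S0` expresses the data as diffusion attenuation, so prediction errors
#' are directly comparable across scanners; the `S0`-scaled signal is
#' recovered by multiplying each voxel column by `S0(v)`.
#'
#' @param dwi a [diffusion_volume].
#' @return An object of class `demeaned_dwi`: `y` (`N_theta x N_v` matrix,
#'   each column mean zero), `I_v`, `S0_v`, `voxel_map`, `n_dwi`, `n_vox`.
#'   Vectorized orderings are voxel-major: `as.vector(y)` stacks voxel blocks
#'   of length `N_theta`.
#' @export
demean <- function(dwi) {
  stopifnot(inherits(dwi, "diffusion_volume"))
  gtab <- dwi$gtab
  if (gtab$n_dwi < 2) stop("need at least 2 dwi directions", call. = FALSE)
  grid_dim <- dim(dwi$signal)[1:3]
  lin <- dwi$voxel_map[, 1] +
    grid_dim[1] * (dwi$voxel_map[, 2] - 1 + grid_dim[2] * (dwi$voxel_map[, 3] - 1))
  sig2 <- matrix(dwi$signal, prod(grid_dim), length(gtab$bvals))
  S <- t(sig2[lin, !gtab$b0, drop = FALSE])          # N_theta x N_v
  S0_v <- dwi$S0[lin]
  stopifnot(all(S0_v > 0))
  I_v <- colMeans(S)
  y <- sweep(sweep(S, 2, I_v), 2, S0_v, "/")
  structure(list(y = y, I_v = I_v, S0_v = S0_v, voxel_map = dwi$voxel_map,
                 n_dwi = gtab$n_dwi, n_vox = ncol(y), ordering = "voxel-major"),
            class = "demeaned_dwi")
}

## Factorized prediction: contract Phi's fascicle mode with w, multiply by D.
life_predict_core <- function(phi, D, w) {
  A <- Matrix::sparseMatrix(i = phi$atom, j = phi$voxel,
                            x = phi$value * w[phi$fascicle],
                            dims = c(phi$dims[1], phi$dims[2]))
  as.vector(D %*% A)
}

## Adjoint of life_predict_core.
life_transpose_core <- function(phi, D, r) {
  R <- matrix(r, nrow(D), phi$dims[2])
  G <- crossprod(D, R)                               # L x N_v
  vals <- phi$value * G[cbind(phi$atom, phi$voxel)]
  g <- numeric(phi$dims[3])
  if (length(vals)) {
    tmp <- rowsum(vals, phi$fascicle)
    g[as.integer(rownames(tmp))] <- tmp[, 1]
  }
  g
}

#' Fit the Linear Fascicle Evaluation model to diffusion data
#'
#' `life()` is the package's central fitting function. It builds the
#' orientation dictionary, encodes the candidate fascicles as the sparse
#' 3-way tensor `Phi`, demeans the measured signal, and (by default)
#' estimates non-negative fascicle weights `w` by solving
#' `min_w 0.5 || y - M w ||^2, w >= 0` with a matrix-free projected-gradient
#' Barzilai-Borwein solver, where `M w` is evaluated through the factorized
#' model (dictionary times sparse tensor) without ever materializing `M`.
#'
#' @param dwi a [diffusion_volume].
#' @param tg a [tractogram] of candidate fascicles (world mm).
#' @param L number of dictionary atoms.
#' @param lambda_axial,lambda_radial kernel diffusivities (mm^2/s).
#' @param method entry construction passed to [encode_connectome].
#' @param k neighbourhood size for `method = "interp"`.
#' @param fit if `FALSE`, return the encoded (unfitted) model.
#' @param control solver settings from [life_control].
#' @return An object of class `life`: `tensor`, `dictionary`, `data`
#'   (the [demean]ed signal), `gtab`, `affine`, `mask_dim`, `weights`
#'   (or `NULL`), `fit` (a `life_fit`, or `NULL`) and `call`. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' cfg <- phantom_config(dim = c(7L, 7L, 7L), n_spurious = 2L,
#'                       bundles = list(bundle_spec("b1", 0, n = 5L),
#'                                      bundle_spec("b2", 90, n = 5L)),
#'                       snr = Inf, seed = 1L)
#' ph <- life_phantom(cfg)
#' m <- life(ph$dwi, ph$tg, L = 42)
#' summary(m)
#' @export
life <- function(dwi, tg, L = 362, lambda_axial = 1.5e-3, lambda_radial = 0,
                 method = c("interp", "nearest"), k = 16L, fit = TRUE,
                 control = life_control()) {
  stopifnot(inherits(dwi, "diffusion_volume"), inherits(tg, "tractogram"))
  method <- match.arg(method)
  dict <- orientation_dictionary(dwi$gtab, L = L, lambda_axial = lambda_axial,
                                 lambda_radial = lambda_radial)
  phi <- encode_connectome(tg, dwi$mask, dwi$affine, dict, dwi$gtab,
                           method = method, k = k)
  dd <- demean(dwi)
  obj <- structure(
    list(tensor = phi, dictionary = dict, data = dd, gtab = dwi$gtab,
         affine = dwi$affine, mask_dim = dim(dwi$mask),
         weights = NULL, fit = NULL, call = match.call()),
    class = "life")
  if (fit) {
    fr <- fit_nnls(obj, control = control)
    obj$weights <- fr$w
    obj$fit <- fr
  }
  obj
}

#' @rdname life
#' @export
print.life <- function(x, ...) {
  d <- x$tensor$dims
  cat("LiFE connectome model (factorized)\n")
  cat("  ", d[3], " candidate fascicles, ", d[2], " voxels, ",
      x$data$n_dwi, " directions, L = ", d[1], " atoms\n", sep = "")
  if (!is.null(x$weights)) {
    cat("  fitted: ", sum(x$weights > 0), " fascicles with positive weight",
        " (", x$fit$iterations, " iterations, ",
        if (x$fit$converged) "converged" else "not converged", ")\n", sep = "")
  } else cat("  unfitted\n")
  invisible(x)
}

#' @rdname life
#' @param object,x a fitted `life` model.
#' @param ... unused.
#' @export
summary.life <- function(object, ...) {
  out <- list(dims = object$tensor$dims, nnz = length(object$tensor$value),
              n_incidence = length(object$tensor$inc_fascicle),
              mem = memory_footprint(object))
  if (!is.null(object$weights)) {
    out$resolution <- sum(object$weights > 0)
    rep <- rmse_map(as.vector(object$data$y), fitted(object),
                    n_dwi = object$data$n_dwi,
                    occupied = sort(unique(object$tensor$inc_voxel)))
    out$rmse <- rep
    out$fit <- object$fit[c("iterations", "converged", "reason")]
  }
  class(out) <- "summary.life"
  out
}

#' @export
print.summary.life <- function(x, ...) {
  d <- x$dims
  cat("LiFE model summary\n")
  cat("  Phi: ", paste(d, collapse = " x "), ", nnz = ", x$nnz,
      " (", x$n_incidence, " fascicle-voxel incidences)\n", sep = "")
  cat(sprintf("  memory: dense-equivalent %.1f MB, factorized %.2f MB (%.0fx)\n",
              x$mem$dense_bytes / 2^20, x$mem$factorized_bytes / 2^20,
              x$mem$ratio))
  if (!is.null(x$resolution)) {
    cat("  connectome resolution (fascicles with w > 0):", x$resolution, "\n")
    cat(sprintf("  global rms error (occupied voxels): %.5f\n",
                x$rmse$mean_rms))
    cat("  solver:", x$fit$iterations, "iterations,", x$fit$reason, "\n")
  }
  invisible(x)
}

#' @rdname life
#' @export
coef.life <- function(object, ...) object$weights

#' Predict the demeaned relative signal from a LiFE model
#'
#' Evaluates the factorized forward model for a given weight vector without
#' materializing the dense matrix. The result is the voxel-major stacked
#' vector matching `as.vector(object$data$y)`.
#'
#' @param object a `life` model.
#' @param w weight vector (defaults to the fitted weights).
#' @param ... unused.
#' @return numeric vector of length `N_theta * N_v`.
#' @export
predict.life <- function(object, w = NULL, ...) {
  w <- w %||% object$weights
  if (is.null(w)) stop("model is unfitted and no weights were supplied",
                       call. = FALSE)
  if (length(w) != object$tensor$dims[3])
    stop("weight vector has wrong length", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  life_predict_core(object$tensor, object$dictionary$D, w)
}

#' @rdname life
#' @export
fitted.life <- function(object, ...) predict.life(object)

#' @rdname life
#' @export
residuals.life <- function(object, ...) {
  as.vector(object$data$y) - fitted(object)
}

#' @rdname life
#' @export
plot.life <- function(x, ...) {
  if (is.null(x$weights)) stop("nothing to plot: model is unfitted",
                               call. = FALSE)
  rep <- rmse_map(as.vector(x$data$y), fitted(x), n_dwi = x$data$n_dwi,
                  occupied = sort(unique(x$tensor$inc_voxel)))
  graphics::hist(rep$e_rms[rep$occupied], breaks = 30,
                 main = "Per-voxel r.m.s. prediction error",
                 xlab = "r.m.s. error (relative signal)", ...)
  invisible(rep)
}

#' Adjoint application of the LiFE forward operator
#'
#' Computes `t(M) r` through the factorization; together with
#' [predict.life] it satisfies the inner-product identity
#' `<predict(w), r> == <w, transpose_apply(r)>`.
#'
#' @param object a `life` model.
#' @param r residual-shaped vector, length `N_theta * N_v` (voxel-major).
#' @return numeric vector of length `N_f`.
#' @export
transpose_apply <- function(object, r) {
  stopifnot(inherits(object, "life"))
  if (length(r) != object$data$n_dwi * object$data$n_vox)
    stop("r has wrong length", call. = FALSE)
  life_transpose_core(object$tensor, object$dictionary$D, r)
}

#' Explicit LiFE design matrix (exact or reconstructed)
#'
#' Builds the explicit matrix `M` (`N_theta N_v x N_f`, voxel-major rows) of
#' the linear forward model in the relative-signal convention. `exact = TRUE`
#' evaluates the demeaned kernel of the true per-(fascicle, voxel)
#' orientation; `exact = FALSE` reconstructs `M_hat` from the dictionary and
#' the sparse tensor entries (the matrix the factorized model implicitly
#' applies). The matrix is returned in sparse column storage since fascicle
#' columns vanish outside the voxels the fascicle traverses; a size guard
#' refuses problems whose dense element count exceeds `budget`.
#'
#' @param object a `life` model.
#' @param exact see above.
#' @param budget maximum `N_theta * N_v * N_f` for which an explicit matrix
#'   will be built.
#' @return a `Matrix::dgCMatrix`.
#' @export
build_dense_matrix <- function(object, exact = TRUE, budget = 5e8) {
  stopifnot(inherits(object, "life"))
  phi <- object$tensor
  n_dwi <- object$data$n_dwi
  nel <- as.numeric(n_dwi) * phi$dims[2] * phi$dims[3]
  if (nel > budget)
    stop("explicit matrix would hold ", format(nel, big.mark = ","),
         " elements (budget ", format(budget, big.mark = ","),
         "); use the factorized operators instead", call. = FALSE)
  dict <- object$dictionary
  if (exact) {
    gtab <- object$gtab
    dwi_sel <- !gtab$b0
    th <- gtab$bvecs[dwi_sel, , drop = FALSE]
    b <- gtab$bvals[dwi_sel]
    t2 <- (th %*% t(phi$inc_tangent))^2
    E <- exp(-b * (dict$lambda_radial +
                     (dict$lambda_axial - dict$lambda_radial) * t2))
    E <- sweep(E, 2, colMeans(E))
    i <- rep((phi$inc_voxel - 1) * n_dwi, each = n_dwi) + seq_len(n_dwi)
    j <- rep(phi$inc_fascicle, each = n_dwi)
    x <- as.vector(E)
  } else {
    i <- rep((phi$voxel - 1) * n_dwi, each = n_dwi) + seq_len(n_dwi)
    j <- rep(phi$fascicle, each = n_dwi)
    x <- as.vector(dict$D[, phi$atom, drop = FALSE]) * rep(phi$value, each = n_dwi)
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(n_dwi * phi$dims[2], phi$dims[3]))
}

#' Memory accounting: explicit matrix vs factorized model
#'
#' Reports the storage a double-precision explicit `M` would need
#' (`8 N_theta N_v N_f` bytes) against the factorized representation
#' (double values plus three 4-byte integer index vectors for the tensor
#' entries, plus the `N_theta x L` dictionary).
#'
#' @param object a `life` model.
#' @return list with `dense_bytes`, `factorized_bytes`, `ratio`.
#' @export
memory_footprint <- function(object) {
  stopifnot(inherits(object, "life"))
  phi <- object$tensor
  dense <- 8 * as.numeric(object$data$n_dwi) * phi$dims[2] * phi$dims[3]
  fact <- 8 * length(phi$value) + 3 * 4 * length(phi$value) +
    8 * as.numeric(object$data$n_dwi) * phi$dims[1]
  list(dense_bytes = dense, factorized_bytes = fact, ratio = dense / fact)
}
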