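#' Tract voxels and path-neighborhood
#'
#' For a tract `F` (a set of fascicle indices), `V_F` is the set of voxels
#' touched by `F` and the path-neighborhood `P_F` is the set of all fascicles
#' passing through `V_F`, excluding `F` itself. Both are read directly off
#' the sparse tensor's support.
#'
#' @param phi a `connectome_tensor`.
#' @param F non-empty integer vector of 1-based fascicle indices.
#' @return list with `V_F` (voxel indices) and `P_F` (fascicle indices,
#'   disjoint from `F`).
#' @export
path_neighborhood <- function(phi, F) {
  if (length(F) == 0) stop("F must be non-empty", call. = FALSE)
  V_F <- touched_voxels(phi, F)
  P_F <- setdiff(fascicles_through(phi, V_F), as.integer(F))
  list(V_F = V_F, P_F = P_F)
}

#' Virtual lesion of a tract
#'
#' Compares the model's prediction error in the tract's voxels with and
#' without the tract: the unlesioned model predicts the signal in `V_F` from
#' the full fitted weights, the lesioned model sets the weights of `F` to
#' zero and keeps every other weight unchanged (no refit). The two per-voxel
#' r.m.s. error distributions over `V_F` are summarized by their earth mover
#' distance and a bootstrap strength of evidence.
#'
#' @param object a fitted `life` model.
#' @param F 1-based fascicle indices of the tract.
#' @param w weights to use (defaults to the fitted weights).
#' @param n_boot,seed bootstrap settings for [strength_of_evidence].
#' @return An object of class `life_lesion`: `F`, `V_F`, `P_F`,
#'   `rmse_unlesioned`, `rmse_lesioned` (per-voxel values on `V_F`), `emd`,
#'   `soe`, `degenerate` (TRUE when the lesioned weights were all zero
#'   already), `n_boot`, `seed`.
#' @export
virtual_lesion <- function(object, F, w = NULL, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(object, "life"))
  w <- w %||% object$weights
  if (is.null(w)) stop("model is unfitted", call. = FALSE)
  F <- check_fascicle_set(object$tensor, F)
  if (length(F) == 0) stop("F must be non-empty", call. = FALSE)
  nb <- path_neighborhood(object$tensor, F)
  V_F <- nb$V_F
  if (length(V_F) == 0)
    stop("tract touches no voxel", call. = FALSE)
  degenerate <- all(w[F] == 0)
  w_les <- w
  w_les[F] <- 0
  n_dwi <- object$data$n_dwi
  y <- as.vector(object$data$y)
  yhat_full <- predict(object, w)
  yhat_les <- predict(object, w_les)
  rows <- as.vector(outer(seq_len(n_dwi), (V_F - 1) * n_dwi, `+`))
  rep_full <- rmse_map(y[rows], yhat_full[rows], n_dwi)
  rep_les <- rmse_map(y[rows], yhat_les[rows], n_dwi)
  emd <- earth_mover_distance(rep_full$e_rms, rep_les$e_rms)
  soe <- strength_of_evidence(rep_full$e_rms, rep_les$e_rms,
                              n_boot = n_boot, seed = seed)
  structure(list(F = F, V_F = V_F, P_F = nb$P_F,
                 rmse_unlesioned = rep_full$e_rms,
                 rmse_lesioned = rep_les$e_rms,
                 emd = emd, soe = soe, degenerate = degenerate,
                 n_boot = n_boot, seed = seed),
            class = "life_lesion")
}

#' @export
print.life_lesion <- function(x, ...) {
  cat("Virtual lesion: |F| =", length(x$F), "fascicles,",
      length(x$V_F), "voxels, |P_F| =", length(x$P_F), "\n")
  cat(sprintf("  mean rms without lesion %.5f, with lesion %.5f\n",
              mean(x$rmse_unlesioned), mean(x$rmse_lesioned)))
  cat(sprintf("  EMD = %.5f, strength of evidence = %.2f%s\n",
              x$emd, x$soe,
              if (x$degenerate) "  [degenerate: tract weights were all 0]" else ""))
  invisible(x)
}

#' Earth mover (Wasserstein-1) distance between two empirical samples
#'
#' Computed exactly on the empirical distributions (no histogram): the
#' integral of the absolute difference of the two empirical CDFs, which for
#' equal-sized samples equals the mean absolute difference of the sorted
#' values.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return non-negative scalar, symmetric in its arguments.
#' @export
earth_mover_distance <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("samples must be non-empty", call. = FALSE)
  xs <- sort(unique(c(sample_a, sample_b)))
  if (length(xs) == 1) return(0)
  Fa <- stats::ecdf(sample_a)(xs)
  Fb <- stats::ecdf(sample_b)(xs)
  n <- length(xs)
  sum(abs(Fa[-n] - Fb[-n]) * diff(xs))
}

#' Bootstrap strength of evidence between two error distributions
#'
#' Bootstraps the mean of each sample `n_boot` times and returns the
#' standardized difference
#' `(E[mean_b] - E[mean_a]) / sqrt((Var[mean_a] + Var[mean_b]) / 2)`,
#' a d-prime-like effect size. In the virtual-lesion setting `sample_a` is
#' the unlesioned and `sample_b` the lesioned error distribution, so a
#' positive value means the lesion worsened the prediction. Swapping the
#' samples negates the sign.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed RNG seed for the bootstrap (the caller's RNG state is left
#'   untouched).
#' @return scalar; signed `Inf` (with a warning) when the pooled bootstrap
#'   variance is zero.
#' @export
strength_of_evidence <- function(sample_a, sample_b, n_boot = 10000L,
                                 seed = 1L) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("samples must be non-empty", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  na <- length(sample_a); nb <- length(sample_b)
  with_seed(seed, {
    ma <- vapply(seq_len(n_boot),
                 function(i) mean(sample_a[sample.int(na, na, replace = TRUE)]),
                 numeric(1))
    mb <- vapply(seq_len(n_boot),
                 function(i) mean(sample_b[sample.int(nb, nb, replace = TRUE)]),
                 numeric(1))
    pooled <- sqrt((var(ma) + var(mb)) / 2)
    if (pooled == 0) {
      d <- mean(mb) - mean(ma)
      if (d == 0) return(0)
      warning("zero pooled bootstrap variance; returning signed infinity")
      return(sign(d) * Inf)
    }
    (mean(mb) - mean(ma)) / pooled
  })
}
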