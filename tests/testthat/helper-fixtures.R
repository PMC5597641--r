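# Shared fixtures. Heavy objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## Small noiseless two-bundle phantom (fast unit-test workhorse).
small_phantom <- function() {
  cached("small_phantom", function() {
    cfg <- phantom_config(dim = c(9L, 9L, 9L), n_spurious = 4L,
                          bundles = list(bundle_spec("b1", 0, n = 8L),
                                         bundle_spec("b2", 90, n = 8L)),
                          snr = Inf, seed = 11L)
    ph <- life_phantom(cfg)
    ph$model <- life(ph$dwi, ph$tg, L = 42, fit = FALSE)
    ph
  })
}

## The standard phantom used by the acceptance checks: 15^3 voxels at
## 1.25 mm, 90 directions at b = 2000 s/mm^2, three bundles crossing the
## reference bundle at 0/45/90 degrees plus spurious curves, SNR 20.
standard_phantom <- function() {
  cached("standard_phantom", function() {
    ph <- life_phantom(phantom_config(seed = 0L))
    ph$model <- life(ph$dwi, ph$tg, L = 362, fit = FALSE)
    ph$M_exact <- build_dense_matrix(ph$model, exact = TRUE)
    ph$M_hat <- build_dense_matrix(ph$model, exact = FALSE)
    ph
  })
}

## Matched-algorithm fits of the explicit and factorized models on the
## standard phantom (deep convergence so the weight vectors settle).
standard_fits <- function() {
  cached("standard_fits", function() {
    ph <- standard_phantom()
    ctl <- life_control(tol = 1e-10, max_iter = 2000L)
    y <- as.vector(ph$model$data$y)
    M <- ph$M_exact
    fit_M <- bb_nnls(function(w) as.vector(M %*% w),
                     function(r) as.vector(Matrix::crossprod(M, r)),
                     y, ncol(M), control = ctl)
    fit_T <- fit_nnls(ph$model, control = ctl)
    list(fit_M = fit_M, fit_T = fit_T, y = y)
  })
}

## Independent streamline rasterizer used as oracle: resamples with its own
## interpolation code at the same step and collects distinct in-mask voxels.
oracle_incidences <- function(tg, mask, affine, step) {
  inv <- solve(affine)
  total <- 0L
  for (s in tg$streamlines) {
    seg <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
    keep <- c(TRUE, seg > 0)
    s <- s[keep, , drop = FALSE]
    if (nrow(s) < 2) next
    seg <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
    cum <- c(0, cumsum(seg))
    len <- cum[length(cum)]
    n_out <- max(2L, as.integer(ceiling(len / step)) + 1L)
    ts <- seq(0, len, length.out = n_out)
    pts <- sapply(1:3, function(d) stats::approx(cum, s[, d], xout = ts)$y)
    vox <- floor((cbind(pts, 1) %*% t(inv))[, 1:3] + 0.5)
    ok <- vox[, 1] >= 0 & vox[, 1] < dim(mask)[1] &
          vox[, 2] >= 0 & vox[, 2] < dim(mask)[2] &
          vox[, 3] >= 0 & vox[, 3] < dim(mask)[3]
    vox <- vox[ok, , drop = FALSE]
    if (nrow(vox) == 0) next
    lin <- 1 + vox[, 1] + dim(mask)[1] * (vox[, 2] + dim(mask)[2] * vox[, 3])
    lin <- lin[mask[lin]]
    total <- total + length(unique(lin))
  }
  total
}

## Six-direction gradient table used in hand-evaluated kernel checks.
six_dir_gtab <- function(b = 2000) {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0) / sqrt(2), c(0, 1, 1) / sqrt(2), c(1, 0, 1) / sqrt(2))
  gradient_table(c(0, rep(b, 6)), rbind(c(0, 0, 0), dirs))
}
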