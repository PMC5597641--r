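test_that("demeaning yields the zero-mean relative signal", {
  ph <- small_phantom()
  dd <- demean(ph$dwi)
  expect_lt(max(abs(colMeans(dd$y))), 1e-10)
  expect_equal(dim(dd$y), c(ph$gtab$n_dwi, ph$dwi$n_vox))

  ## two-direction toy: S = (90, 110), S0 = 100 -> y = (-0.1, +0.1)
  gt <- gradient_table(c(0, 1000, 1000),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  sig <- array(100, dim = c(1, 1, 1, 3))
  sig[1, 1, 1, 2] <- 90; sig[1, 1, 1, 3] <- 110
  dv <- diffusion_volume(sig, gt, array(TRUE, c(1, 1, 1)))
  dd2 <- demean(dv)
  expect_equal(as.vector(dd2$y), c(-0.1, 0.1))

  ## a signal constant across directions demeans to zero
  sig[] <- 77
  dvc <- diffusion_volume(sig, gt, array(TRUE, c(1, 1, 1)))
  expect_equal(as.vector(demean(dvc)$y), c(0, 0))
})

test_that("factorized prediction is linear and matches the dense oracle", {
  ph <- small_phantom()
  m <- ph$model
  n_f <- m$tensor$dims[3]
  expect_equal(predict(m, rep(0, n_f)),
               rep(0, m$data$n_dwi * m$data$n_vox))
  set.seed(13)
  w1 <- runif(n_f); w2 <- runif(n_f)
  expect_equal(predict(m, w1 + w2), predict(m, w1) + predict(m, w2),
               tolerance = 1e-12)

  Mh <- build_dense_matrix(m, exact = FALSE)
  expect_lt(max(abs(predict(m, w1) - as.vector(Mh %*% w1))), 1e-10)
  r <- rnorm(nrow(Mh))
  expect_lt(max(abs(transpose_apply(m, r) -
                      as.vector(Matrix::crossprod(Mh, r)))), 1e-10)
})

test_that("forward and adjoint operators satisfy the inner-product identity", {
  ph <- small_phantom()
  m <- ph$model
  set.seed(17)
  for (i in 1:20) {
    w <- runif(m$tensor$dims[3])
    r <- rnorm(m$data$n_dwi * m$data$n_vox)
    lhs <- sum(predict(m, w) * r)
    rhs <- sum(w * transpose_apply(m, r))
    expect_lt(abs(lhs - rhs), 1e-10 * max(1, abs(lhs)))
  }
  expect_equal(transpose_apply(m, numeric(m$data$n_dwi * m$data$n_vox)),
               numeric(m$tensor$dims[3]))
})

test_that("atom-aligned orientations make the factorization exact", {
  gt <- six_dir_gtab()
  cfg <- phantom_config(dim = c(9L, 9L, 9L), n_spurious = 2L,
                        bundles = list(bundle_spec("a", 0, n = 4L),
                                       bundle_spec("b", 90, n = 4L)),
                        snr = Inf, seed = 19L)
  gtab <- phantom_gradient_table(cfg)
  dict <- orientation_dictionary(gtab, L = 162)
  tg <- make_bundles(cfg)
  dwi <- simulate_signal(tg, phantom_weights(tg, cfg), cfg, gtab,
                         snap_to_atoms = dict)
  m <- life(dwi, tg, L = 162, method = "nearest", fit = FALSE)
  ## replace the stored true tangents by their atoms: M becomes M_hat
  m$tensor$inc_tangent <- dict$atoms[m$tensor$inc_atom, , drop = FALSE]
  M <- build_dense_matrix(m, exact = TRUE)
  Mh <- build_dense_matrix(m, exact = FALSE)
  expect_lt(max(abs(M - Mh)), 1e-12)
})

test_that("an isotropic kernel gives an all-zero model matrix", {
  ph <- small_phantom()
  m_iso <- life(ph$dwi, ph$tg, L = 21, lambda_axial = 1e-3,
                lambda_radial = 1e-3, method = "nearest", fit = FALSE)
  Mh <- build_dense_matrix(m_iso, exact = FALSE)
  expect_lt(max(abs(Mh)), 1e-14)
})

test_that("model approximation error decreases with dictionary resolution", {
  ph <- small_phantom()
  errs <- vapply(c(42, 162, 362), function(L) {
    m <- life(ph$dwi, ph$tg, L = L, fit = FALSE)
    model_error(build_dense_matrix(m, exact = TRUE),
                build_dense_matrix(m, exact = FALSE))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("memory accounting reports the documented byte counts", {
  ph <- small_phantom()
  m <- ph$model
  fp <- memory_footprint(m)
  expect_equal(fp$dense_bytes,
               8 * m$data$n_dwi * m$tensor$dims[2] * m$tensor$dims[3])
  expect_equal(fp$factorized_bytes,
               8 * length(m$tensor$value) + 12 * length(m$tensor$value) +
                 8 * m$data$n_dwi * m$tensor$dims[1])
  expect_gt(fp$ratio, 1)
  ## the element budget guard refuses oversized explicit matrices
  expect_error(build_dense_matrix(m, budget = 10), "budget")
})
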