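test_that("gradient tables classify, renormalize and round-trip", {
  set.seed(4)
  n <- 96
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs[1:10, ] <- 0
  bvals <- c(rep(0, 10), rep(2000, n - 10))
  gt <- gradient_table(bvals, dirs)
  expect_equal(gt$n_dwi, 86)
  expect_true(all(abs(sqrt(rowSums(gt$bvecs[!gt$b0, ]^2)) - 1) < 1e-6))

  ## a (2, 0, 0) direction with b = 2000 is stored as (1, 0, 0)
  gt2 <- gradient_table(c(0, 2000), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(gt2$bvecs[2, ], c(1, 0, 0))

  ## FSL 3 x n layout and write/read identity
  bval_f <- tempfile(); bvec_f <- tempfile()
  write_gradient_table(gt, bval_f, bvec_f)
  gt_rt <- read_gradient_table(bval_f, bvec_f)
  expect_equal(gt_rt$bvals, gt$bvals, tolerance = 1e-12)
  expect_equal(gt_rt$bvecs, gt$bvecs, tolerance = 1e-12)

  expect_error(gradient_table(c(0, 1000), matrix(1, 3, 3)), "different numbers")
  expect_error(gradient_table(c(0, NA), matrix(1, 2, 3)), "non-finite")
})

test_that("TCK files round-trip in world mm and reject degenerate streamlines", {
  set.seed(5)
  sl <- replicate(3, matrix(rnorm(15, sd = 10), ncol = 3), simplify = FALSE)
  tg <- tractogram(sl)
  path <- tempfile(fileext = ".tck")
  write_tck(tg, path)
  tg2 <- read_tractogram(path)
  expect_equal(tg2$n_fascicles, 3)
  dev <- max(mapply(function(a, b) max(abs(a - b)), tg$streamlines,
                    tg2$streamlines))
  expect_lt(dev, 1e-4)

  ## 1-point streamlines are rejected with a logged count
  expect_message(tractogram(c(sl, list(matrix(1, 1, 3)))), "dropped 1")

  ## an empty file is an error, not an empty tractogram
  empty <- tempfile(fileext = ".tck")
  file.create(empty)
  expect_error(read_tractogram(empty), "empty")
})

test_that("TRK voxel-mm points map to world through the affine", {
  affine <- diag(c(2, 2, 2, 1))
  affine[1, 4] <- 10
  ## world points whose voxel-mm representation is (2,2,2) and (4,4,4):
  ## voxel index (1,1,1) -> world (12, 2, 2); index (2,2,2) -> (14, 4, 4)
  tg <- tractogram(list(rbind(c(12, 2, 2), c(14, 4, 4))))
  path <- tempfile(fileext = ".trk")
  write_trk(tg, path, affine, voxel_size = c(2, 2, 2), dim = c(10L, 10L, 10L))
  tg2 <- read_tractogram(path)
  expect_equal(tg2$streamlines[[1]],
               rbind(c(12, 2, 2), c(14, 4, 4)), tolerance = 1e-5)
  ## the header affine disagreeing with the reference is a geometry error
  expect_error(read_tractogram(path, reference_affine = diag(4)),
               "disagrees")
})

test_that("read_dwi computes S0 as the b=0 mean and drops dead voxels", {
  dims <- c(4L, 4L, 4L)
  gt <- gradient_table(c(0, 0, 1000, 1000),
                       rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  sig <- array(50, dim = c(dims, 4))
  sig[2, 2, 2, 1] <- 100; sig[2, 2, 2, 2] <- 102
  mask <- array(TRUE, dims)
  dv <- diffusion_volume(sig, gt, mask)
  expect_equal(dv$S0[2, 2, 2], 101)

  sig[1, 1, 1, 1:2] <- 0
  expect_warning(dv2 <- diffusion_volume(sig, gt, mask), "S0 <= 0")
  expect_equal(dv2$n_vox, prod(dims) - 1)

  ## no b=0 volume: demeaning impossible
  gt_no0 <- gradient_table(c(1000, 1000, 1000, 1000), matrix(rnorm(12), 4, 3))
  expect_error(diffusion_volume(sig, gt_no0, mask), "no b = 0")

  ## NIfTI round-trip preserves values to float precision
  ph <- small_phantom()
  d <- tempfile(); dir.create(d)
  paths <- write_phantom(ph, d)
  dv3 <- read_dwi(paths[["dwi"]], paths[["bval"]], paths[["bvec"]],
                  paths[["mask"]])
  expect_equal(dv3$signal, ph$dwi$signal, tolerance = 1e-6)
  expect_equal(dv3$n_vox, ph$dwi$n_vox)
  tgr <- read_tractogram(paths[["tck"]])
  expect_equal(tgr$n_fascicles, ph$tg$n_fascicles)
})

test_that("model containers reproduce predictions bit-compatibly", {
  ph <- small_phantom()
  m <- life(ph$dwi, ph$tg, L = 42, fit = TRUE,
            control = life_control(max_iter = 50L))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(length(m2$tensor$value), length(m$tensor$value))
  w <- runif(ph$tg$n_fascicles)
  expect_identical(predict(m2, w), predict(m, w))
  expect_identical(coef(m2), coef(m))

  ## version / structure errors
  bad <- readRDS(path); bad$version <- "other"; saveRDS(bad, path)
  expect_error(load_model(path), "version")
  bad$version <- lifet:::CONTAINER_VERSION; bad$tensor <- NULL
  saveRDS(bad, path)
  expect_error(load_model(path), "tensor")
})

test_that("tract index lists round-trip with 0-based on-disk convention", {
  p <- tempfile()
  write_tract_indices(c(1L, 5L, 7L), p)
  expect_equal(readLines(p), c("0", "4", "6"))
  expect_equal(read_tract_indices(p), c(1L, 5L, 7L))
})
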