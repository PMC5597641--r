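test_that("straight streamlines yield one axial orientation per voxel", {
  mask <- array(TRUE, c(5, 3, 3))
  affine <- diag(4)                      # 1 mm voxels
  sl <- rbind(c(0, 1, 1), c(2, 1, 1))    # along +x through voxels x = 0..2
  fvo <- fascicle_voxel_orientations(sl, mask, affine)
  expect_equal(nrow(fvo$voxel), 3)
  expect_equal(fvo$voxel[, 2], rep(2L, 3), ignore_attr = TRUE)
  expect_true(all(abs(abs(fvo$tangent %*% c(1, 0, 0)) - 1) < 1e-12))

  ## point-order reversal leaves the axial orientations unchanged
  fvo_r <- fascicle_voxel_orientations(sl[2:1, ], mask, affine)
  expect_equal(abs(fvo$tangent %*% t(fvo_r$tangent))[cbind(1:3, 3:1)],
               rep(1, 3), tolerance = 1e-12)

  expect_error(fascicle_voxel_orientations(matrix(1, 1, 3), mask, affine),
               "at least 2")
})

test_that("in-voxel tangent averaging matches the chord of a sampled arc", {
  ## quarter circle of radius 0.4 mm inside one 1 mm voxel
  mask <- array(TRUE, c(3, 3, 3))
  affine <- diag(4)
  th <- seq(0, pi / 2, length.out = 200)
  arc <- cbind(0.8 + 0.4 * cos(th), 1.0 + 0.4 * sin(th), 1.0)
  fvo <- fascicle_voxel_orientations(arc, mask, affine, step = 0.005)
  v_row <- which(fvo$voxel[, 1] == 2 & fvo$voxel[, 2] == 2 & fvo$voxel[, 3] == 2)
  expect_length(v_row, 1)
  ## the mean unit tangent of a circular arc points along its chord
  chord <- arc[nrow(arc), ] - arc[1, ]
  chord <- chord / sqrt(sum(chord^2))
  expect_gt(abs(sum(fvo$tangent[v_row, ] * chord)), 1 - 1e-6)
})

test_that("encoding produces one incidence per fascicle-voxel pair", {
  mask <- array(TRUE, c(7, 3, 3))
  affine <- diag(4)
  gt <- six_dir_gtab()
  dict <- orientation_dictionary(gt, L = 42)
  sl <- rbind(c(0.2, 1, 1), c(4.4, 1, 1))
  tg <- tractogram(list(sl, sl))          # two identical fascicles
  phi <- encode_connectome(tg, mask, affine, dict, gt, method = "nearest")
  ## 5 voxels each, one atom, one entry per incidence in nearest mode
  expect_equal(length(phi$value), 10)
  expect_equal(length(unique(phi$atom)), 1)
  expect_true(all(phi$value == 1))
  ## identical fascicles have identical (atom, voxel) patterns
  e1 <- phi$voxel[phi$fascicle == 1]
  e2 <- phi$voxel[phi$fascicle == 2]
  expect_equal(sort(e1), sort(e2))
})

test_that("incidence count matches an independent rasterizer on the phantom", {
  ph <- small_phantom()
  phi <- ph$model$tensor
  n_oracle <- oracle_incidences(ph$tg, ph$dwi$mask, ph$affine, phi$step)
  expect_equal(length(phi$inc_fascicle), n_oracle)
  ## nearest mode: nnz(Phi) equals the incidence count exactly
  dict <- ph$model$dictionary
  phi_n <- encode_connectome(ph$tg, ph$dwi$mask, ph$affine, dict, ph$gtab,
                             method = "nearest")
  expect_equal(length(phi_n$value), n_oracle)
})

test_that("encoding is invariant to whole-voxel translation", {
  mask <- array(TRUE, c(9, 9, 9))
  affine <- diag(4)
  gt <- six_dir_gtab()
  dict <- orientation_dictionary(gt, L = 42)
  sl <- rbind(c(1, 1.2, 1.3), c(5, 3.1, 2.2))
  tg1 <- tractogram(list(sl))
  tg2 <- tractogram(list(sweep(sl, 2, c(2, 1, 0), "+")))   # integer voxels
  p1 <- encode_connectome(tg1, mask, affine, dict, gt)
  p2 <- encode_connectome(tg2, mask, affine, dict, gt)
  expect_equal(length(p1$value), length(p2$value))
  v1 <- p1$voxel_map[p1$inc_voxel, , drop = FALSE]
  v2 <- p2$voxel_map[p2$inc_voxel, , drop = FALSE]
  expect_equal(sweep(v2, 2, c(2L, 1L, 0L)), v1, ignore_attr = TRUE)
  expect_equal(p1$inc_atom, p2$inc_atom)
  expect_equal(sort(p1$value), sort(p2$value), tolerance = 1e-12)
})

test_that("subtensor queries match a brute-force coordinate scan", {
  ph <- small_phantom()
  phi <- ph$model$tensor
  set.seed(3)
  F <- sample(phi$dims[3], 5)
  V_F <- touched_voxels(phi, F)
  expect_equal(V_F, sort(unique(phi$voxel[phi$fascicle %in% F])))
  P <- fascicles_through(phi, V_F)
  expect_equal(P, sort(unique(phi$fascicle[phi$voxel %in% V_F])))
  expect_equal(touched_voxels(phi, integer()), integer())
  expect_equal(touched_voxels(phi, seq_len(phi$dims[3])),
               sort(unique(phi$voxel)))
  expect_error(touched_voxels(phi, phi$dims[3] + 1L), "out of range")

  sub <- tract_subtensor(phi, F)
  expect_true(all(sub$fascicle %in% F))
  expect_equal(sum(phi$fascicle %in% F), length(sub$value))
})
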