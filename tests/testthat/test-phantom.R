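test_that("bundle geometry honours the designed crossing angles", {
  cfg <- phantom_config(dim = c(11L, 11L, 11L), n_spurious = 0L,
                        bundles = list(bundle_spec("a", 0, n = 6L),
                                       bundle_spec("b", 90, n = 6L)),
                        seed = 2L)
  tg <- make_bundles(cfg)
  expect_setequal(unique(tg$labels), c("a", "b"))
  dirs <- t(vapply(tg$streamlines, function(s) {
    d <- s[nrow(s), ] - s[1, ]; d / sqrt(sum(d^2))
  }, numeric(3)))
  da <- dirs[tg$labels == "a", , drop = FALSE]
  db <- dirs[tg$labels == "b", , drop = FALSE]
  ang <- acos(pmin(1, abs(da %*% t(db)))) * 180 / pi
  expect_lt(abs(mean(ang) - 90), 1)

  ## determinism: same seed, identical coordinates
  tg2 <- make_bundles(cfg)
  expect_identical(tg$streamlines, tg2$streamlines)

  ## a bundle that cannot fit is a geometry error
  cfg_bad <- phantom_config(dim = c(4L, 4L, 4L), voxel_size = 1,
                            bundles = list(bundle_spec("a", 0, n = 2L,
                                                       radius = 10)))
  expect_error(make_bundles(cfg_bad), "radius exceeds")
})

test_that("the simulated signal follows the isotropic-plus-sticks model", {
  cfg <- phantom_config(dim = c(9L, 9L, 9L), n_spurious = 0L,
                        bundles = list(bundle_spec("a", 0, n = 4L)),
                        snr = Inf, seed = 3L)
  tg <- make_bundles(cfg)
  gtab <- phantom_gradient_table(cfg)

  ## all weights zero: only the isotropic compartment survives,
  ## constant across directions at S0 * w0 * exp(-A0)
  dwi0 <- simulate_signal(tg, rep(0, tg$n_fascicles), cfg, gtab)
  v <- dwi0$voxel_map[1, ]
  dwi_vals <- dwi0$signal[v[1], v[2], v[3], !gtab$b0]
  expect_equal(dwi_vals, rep(cfg$S0 * cfg$w0 * exp(-cfg$A0), gtab$n_dwi),
               tolerance = 1e-12)
  expect_equal(dwi0$signal[v[1], v[2], v[3], gtab$b0], rep(cfg$S0, cfg$n_b0),
               ignore_attr = TRUE)

  ## single fascicle along z, direction parallel to z: attenuation exp(-3)
  gt_z <- gradient_table(c(0, 2000, 2000),
                         rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0)))
  sl_z <- tractogram(list(rbind(c(4.5, 4.5, 1), c(4.5, 4.5, 8))))
  cfg_z <- phantom_config(dim = c(9L, 9L, 9L), voxel_size = 1, n_spurious = 0L,
                          w0 = 0, snr = Inf, seed = 1L,
                          bundles = list(bundle_spec("a", 0, n = 1L)))
  dwi_z <- simulate_signal(sl_z, 1, cfg_z, gt_z, lambda_axial = 1.5e-3,
                           lambda_radial = 0)
  vz <- dwi_z$voxel_map[2, ]
  s <- dwi_z$signal[vz[1], vz[2], vz[3], ]
  expect_equal(s[2] / cfg_z$S0, exp(-2000 * 1.5e-3), tolerance = 1e-12)
  expect_equal(s[3] / cfg_z$S0, 1, tolerance = 1e-12)  # perpendicular stick
})

test_that("noise at a stated SNR perturbs per-voxel means as expected", {
  cfg0 <- phantom_config(dim = c(9L, 9L, 9L), n_spurious = 0L,
                         bundles = list(bundle_spec("a", 0, n = 6L)),
                         snr = Inf, seed = 5L)
  cfg1 <- phantom_config(dim = c(9L, 9L, 9L), n_spurious = 0L,
                         bundles = list(bundle_spec("a", 0, n = 6L)),
                         snr = 20, noise = "gaussian", seed = 5L)
  tg <- make_bundles(cfg0)
  gtab <- phantom_gradient_table(cfg0)
  w <- phantom_weights(tg, cfg0)
  d0 <- simulate_signal(tg, w, cfg0, gtab)
  d1 <- simulate_signal(tg, w, cfg1, gtab)
  lin <- d0$voxel_map
  m0 <- apply(d0$signal[, , , !gtab$b0, drop = FALSE], 1:3, mean)
  m1 <- apply(d1$signal[, , , !gtab$b0, drop = FALSE], 1:3, mean)
  sigma <- cfg1$S0 / cfg1$snr
  devs <- abs(m1[lin] - m0[lin]) / (sigma / sqrt(gtab$n_dwi))
  expect_gt(mean(devs < 3), 0.98)
  expect_lt(max(devs), 6)
})

test_that("demeaning removes the isotropic term exactly when atom-aligned", {
  gt <- six_dir_gtab()
  dict <- orientation_dictionary(gt, L = 162)
  cfg <- phantom_config(dim = c(9L, 9L, 9L), n_spurious = 2L,
                        bundles = list(bundle_spec("a", 0, n = 5L),
                                       bundle_spec("b", 45, n = 5L)),
                        snr = Inf, seed = 7L, n_dirs = 90L)
  tg <- make_bundles(cfg)
  w_star <- phantom_weights(tg, cfg)
  gtab <- phantom_gradient_table(cfg)
  dict_full <- orientation_dictionary(gtab, L = 162)
  dwi <- simulate_signal(tg, w_star, cfg, gtab, snap_to_atoms = dict_full)
  m <- life(dwi, tg, L = 162, method = "nearest", fit = FALSE)
  resid <- as.vector(m$data$y) - predict(m, w_star)
  expect_lt(max(abs(resid)), 1e-12)
})
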