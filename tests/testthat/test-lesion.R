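make_fitted_small <- function() {
  cached("fitted_small", function() {
    ph <- small_phantom()
    m <- life(ph$dwi, ph$tg, L = 42, fit = TRUE,
              control = life_control(tol = 1e-8, max_iter = 500L))
    list(ph = ph, m = m)
  })
}

test_that("path-neighborhood is the complement of the tract in its voxels", {
  ph <- small_phantom()
  phi <- ph$model$tensor
  F <- which(ph$labels == "b1")
  nb <- path_neighborhood(phi, F)
  expect_equal(nb$V_F, touched_voxels(phi, F))
  expect_length(intersect(nb$P_F, F), 0)
  ## brute-force coordinate scan
  expect_equal(nb$P_F,
               setdiff(sort(unique(phi$fascicle[phi$voxel %in% nb$V_F])), F))
  expect_error(path_neighborhood(phi, integer()), "non-empty")

  ## two fully overlapping fascicles: each is the other's neighborhood
  mask <- array(TRUE, c(7, 3, 3))
  gt <- six_dir_gtab()
  dict <- orientation_dictionary(gt, L = 21)
  sl <- rbind(c(0.5, 1, 1), c(4.5, 1, 1))
  tg2 <- tractogram(list(sl, sl))
  phi2 <- encode_connectome(tg2, mask, diag(4), dict, gt)
  expect_equal(path_neighborhood(phi2, 1L)$P_F, 2L)
  ## a tract alone in its voxels has an empty neighborhood
  tg3 <- tractogram(list(sl, sl + 100))
  expect_error(encode_connectome(tg3, mask, diag(4), dict, gt), NA)
  phi3 <- encode_connectome(tg3, mask, diag(4), dict, gt)
  expect_length(path_neighborhood(phi3, 1L)$P_F, 0)
})

test_that("virtual lesion worsens the fit when a true bundle is removed", {
  fx <- make_fitted_small()
  F <- which(fx$ph$labels == "b1")
  vl <- virtual_lesion(fx$m, F, n_boot = 500L, seed = 2L)
  expect_gt(mean(vl$rmse_lesioned), mean(vl$rmse_unlesioned))
  expect_gt(vl$emd, 0)
  expect_gt(vl$soe, 0)
  expect_false(vl$degenerate)
  expect_length(intersect(vl$F, vl$P_F), 0)

  ## lesioning fascicles that carry no weight changes nothing
  w0 <- coef(fx$m)
  w0[F[1]] <- 0
  vl0 <- virtual_lesion(fx$m, F[1], w = w0, n_boot = 500L, seed = 2L)
  expect_identical(vl0$rmse_lesioned, vl0$rmse_unlesioned)
  expect_equal(vl0$emd, 0)
  expect_true(vl0$degenerate)
})

test_that("lesioning every fascicle leaves the raw signal as the error", {
  fx <- make_fitted_small()
  allF <- seq_len(fx$ph$tg$n_fascicles)
  vl <- virtual_lesion(fx$m, allF, n_boot = 500L, seed = 3L)
  n_dwi <- fx$m$data$n_dwi
  y <- as.vector(fx$m$data$y)
  rows <- as.vector(outer(seq_len(n_dwi), (vl$V_F - 1) * n_dwi, `+`))
  raw <- rmse_map(y[rows], numeric(length(rows)), n_dwi)
  expect_equal(vl$rmse_lesioned, raw$e_rms)
})

test_that("earth mover distance is exact on empirical distributions", {
  expect_equal(earth_mover_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(earth_mover_distance(c(0, 0), c(1, 1)), 1)
  ## equal-size samples: mean absolute difference of sorted values
  set.seed(41)
  a <- rnorm(50); b <- rnorm(50, 0.5)
  expect_equal(earth_mover_distance(a, b), mean(abs(sort(a) - sort(b))),
               tolerance = 1e-12)
  ## symmetry and triangle inequality on random triples
  for (i in 1:5) {
    x <- rnorm(30); y <- rnorm(25, 1); z <- rexp(40)
    expect_equal(earth_mover_distance(x, y), earth_mover_distance(y, x))
    expect_lte(earth_mover_distance(x, z),
               earth_mover_distance(x, y) + earth_mover_distance(y, z) + 1e-12)
  }
  expect_error(earth_mover_distance(numeric(), 1), "non-empty")
})

test_that("EMD agrees with a discretized optimal-transport solution", {
  ## greedy transport on sorted bins is optimal in 1-D
  transport_1d <- function(a, b, nbins = 20) {
    rng <- range(c(a, b))
    br <- seq(rng[1], rng[2], length.out = nbins + 1)
    mid <- (br[-1] + br[-length(br)]) / 2
    pa <- tabulate(findInterval(a, br, rightmost.closed = TRUE), nbins) / length(a)
    pb <- tabulate(findInterval(b, br, rightmost.closed = TRUE), nbins) / length(b)
    cost <- 0; i <- 1; j <- 1
    while (i <= nbins && j <= nbins) {
      m <- min(pa[i], pb[j])
      cost <- cost + m * abs(mid[i] - mid[j])
      pa[i] <- pa[i] - m; pb[j] <- pb[j] - m
      if (pa[i] <= 1e-15) i <- i + 1
      if (pb[j] <= 1e-15) j <- j + 1
    }
    cost
  }
  set.seed(43)
  for (i in 1:5) {
    a <- rnorm(200); b <- rnorm(150, 0.7, 1.3)
    bin <- diff(range(c(a, b))) / 20
    expect_lt(abs(earth_mover_distance(a, b) - transport_1d(a, b)), bin)
  }
})

test_that("strength of evidence behaves like a bootstrap d-prime", {
  set.seed(47)
  x <- rnorm(80, 0.15, 0.02)
  expect_lt(abs(strength_of_evidence(x, x, n_boot = 10000L, seed = 5L)), 0.2)

  a <- rnorm(100, 0.1, 0.01)
  b <- rnorm(100, 0.2, 0.01)
  soe <- strength_of_evidence(a, b, n_boot = 10000L, seed = 5L)
  ## normal-theory d-prime on the means of these exact samples
  dprime <- (mean(b) - mean(a)) /
    sqrt((var(a) / 100 + var(b) / 100) / 2)
  expect_lt(abs(soe - dprime) / dprime, 0.05)
  ## antisymmetry
  soe_sw <- strength_of_evidence(b, a, n_boot = 10000L, seed = 5L)
  expect_equal(soe_sw, -soe, tolerance = 0.05)
  expect_error(strength_of_evidence(a, b, n_boot = 10L), "n_boot")
})
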