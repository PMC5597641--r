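#' Configuration for the synthetic crossing-bundle diffusion phantom
#'
#' The phantom emulates a small white-matter volume containing a few straight
#' or arched fiber bundles crossing at controlled angles, plus zero-weight
#' "spurious" candidate fascicles (smooth random curves), with the diffusion
#' signal generated from the isotropic-plus-sticks forward model: for each
#' diffusion-weighted direction
#' `S(theta, v) = S0 (w0 exp(-A0) + sum_{f in v} w_f exp(-b t(theta) Q_{f,v}
#' theta))`, and `S = S0` for `b = 0` volumes. Rician or Gaussian measurement
#' noise is added at `sigma = S0 / SNR`.
#'
#' Defaults mirror a typical high-quality single-shell acquisition: a
#' 15x15x15 grid of 1.25 mm isotropic voxels, 90 diffusion directions at
#' b = 2000 s/mm^2 plus 10 b = 0 volumes, three 60-fascicle bundles crossing
#' the reference bundle at 0/45/90 degrees, 20 spurious curves, SNR 20.
#'
#' @param dim integer length-3 grid shape (voxels).
#' @param voxel_size voxel edge lengths (mm), length 1 or 3.
#' @param bundles list of bundle specs from [bundle_spec].
#' @param n_spurious number of spurious (ground-truth weight 0) fascicles.
#' @param w_true ground-truth weight given to every fascicle of each bundle
#'   (recycled across bundles). Signal-fraction units of the forward model.
#' @param w0 isotropic compartment weight.
#' @param A0 isotropic apparent diffusion exponent (unitless; `exp(-A0)` is
#'   the isotropic attenuation at the shell b-value).
#' @param S0 non-diffusion-weighted signal level (scanner units).
#' @param snr signal-to-noise ratio `S0 / sigma`; must be > 0 (use `Inf` for
#'   noiseless data).
#' @param noise `"rician"` (magnitude MR noise, default) or `"gaussian"`.
#' @param n_dirs,bval,n_b0 gradient scheme: number of dwi directions, shell
#'   b-value (s/mm^2), number of leading b = 0 volumes.
#' @param seed integer seed; all phantom randomness flows from it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(dim = c(15L, 15L, 15L), voxel_size = 1.25,
                           bundles = list(
                             bundle_spec("bundle1", angle = 0, n = 60),
                             bundle_spec("bundle2", angle = 45, n = 60),
                             bundle_spec("bundle3", angle = 90, n = 60)),
                           n_spurious = 20L, w_true = 0.06,
                           w0 = 0.4, A0 = 2, S0 = 100,
                           snr = 20, noise = c("rician", "gaussian"),
                           n_dirs = 90L, bval = 2000, n_b0 = 10L,
                           seed = 0L) {
  noise <- match.arg(noise)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (!(snr > 0)) stop("SNR must be > 0", call. = FALSE)
  w_true <- rep_len(w_true, length(bundles))
  if (any(w_true < 0)) stop("ground-truth weights must be >= 0", call. = FALSE)
  angs <- vapply(bundles, function(b) b$angle, numeric(1))
  if (any(angs < 0 | angs > 90))
    stop("crossing angles must lie in [0, 90] degrees", call. = FALSE)
  structure(list(dim = as.integer(dim), voxel_size = voxel_size,
                 bundles = bundles, n_spurious = as.integer(n_spurious),
                 w_true = w_true, w0 = w0, A0 = A0, S0 = S0, snr = snr,
                 noise = noise, n_dirs = as.integer(n_dirs), bval = bval,
                 n_b0 = as.integer(n_b0), seed = as.integer(seed)),
            class = "phantom_config")
}

#' @rdname phantom_config
#' @param name bundle label.
#' @param angle crossing angle to the reference (+x) bundle, degrees in
#'   [0, 90]; the bundle axis is the +x axis rotated by `angle` in the
#'   x-y plane.
#' @param n number of fascicles in the bundle.
#' @param radius bundle radius (mm): fascicles are parallel copies of the
#'   centerline offset uniformly within a disk of this radius.
#' @param type centerline shape, `"straight"` or `"arc"` (a circular arc in
#'   the plane spanned by the bundle axis and z, spanning `arc_span`
#'   degrees).
#' @param arc_span angular extent of an arc centerline (degrees).
#' @export
bundle_spec <- function(name, angle = 0, n = 60L, radius = 2.5,
                        type = c("straight", "arc"), arc_span = 90) {
  type <- match.arg(type)
  list(name = name, angle = angle, n = as.integer(n), radius = radius,
       type = type, arc_span = arc_span)
}

phantom_affine <- function(config) {
  a <- diag(4)
  a[1, 1] <- config$voxel_size[1]
  a[2, 2] <- config$voxel_size[2]
  a[3, 3] <- config$voxel_size[3]
  a
}

#' Deterministic single-shell gradient table for the phantom
#'
#' `n_b0` leading b = 0 volumes followed by `n_dirs` quasi-uniform directions
#' (spherical Fibonacci lattice over the full sphere) at the shell b-value.
#'
#' @param config a [phantom_config].
#' @return A [gradient_table].
#' @export
phantom_gradient_table <- function(config) {
  n <- config$n_dirs
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  az <- pi * (3 - sqrt(5)) * (i - 1)
  dirs <- cbind(r * cos(az), r * sin(az), z)
  gradient_table(c(rep(0, config$n_b0), rep(config$bval, n)),
                 rbind(matrix(0, config$n_b0, 3), dirs))
}

bundle_centerline <- function(spec, config) {
  ext <- config$dim * config$voxel_size          # grid extent, mm
  ctr <- ext / 2
  a <- spec$angle * pi / 180
  dir <- c(cos(a), sin(a), 0)
  if (spec$type == "straight") {
    half <- min(ext) * 0.75
    s <- seq(-half, half, length.out = 2 * max(config$dim))
    pts <- cbind(ctr[1] + s * dir[1], ctr[2] + s * dir[2], ctr[3])
  } else {
    ## circular arc in the plane spanned by the bundle axis and z
    rad <- min(ext) * 0.4
    span <- spec$arc_span * pi / 180
    phi <- seq(-span / 2, span / 2, length.out = 4 * max(config$dim))
    along <- rad * sin(phi)
    up <- rad * (cos(phi) - cos(span / 2))
    pts <- cbind(ctr[1] + along * dir[1], ctr[2] + along * dir[2],
                 ctr[3] + up)
  }
  pts
}

#' Generate the phantom tractogram (bundles + spurious curves)
#'
#' Bundle fascicles are parallel copies of the bundle centerline, offset
#' uniformly within a disk of the bundle radius perpendicular to its axis and
#' clipped to the grid. Spurious fascicles are smooth random quadratic Bezier
#' curves through the volume. All randomness flows from `config$seed`.
#'
#' @param config a [phantom_config].
#' @return A [tractogram] whose `labels` give the bundle name per fascicle
#'   (`"spurious"` for spurious curves).
#' @export
make_bundles <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  ext <- config$dim * config$voxel_size
  for (sp in config$bundles)
    if (2 * sp$radius > min(ext))
      stop("bundle '", sp$name, "' radius exceeds the grid", call. = FALSE)
  with_seed(config$seed, {
    sl <- list(); labels <- character()
    for (sp in config$bundles) {
      cl <- bundle_centerline(sp, config)
      a <- sp$angle * pi / 180
      dir <- c(cos(a), sin(a), 0)
      ## orthonormal frame perpendicular to the bundle axis
      e1 <- c(-sin(a), cos(a), 0)
      e2 <- c(0, 0, 1)
      rr <- sp$radius * sqrt(runif(sp$n))
      th <- runif(sp$n, 0, 2 * pi)
      for (q in seq_len(sp$n)) {
        off <- rr[q] * (cos(th[q]) * e1 + sin(th[q]) * e2)
        pts <- sweep(cl, 2, off, "+")
        pts <- clip_to_grid(pts, ext)
        if (nrow(pts) >= 2) {
          sl[[length(sl) + 1L]] <- pts
          labels <- c(labels, sp$name)
        }
      }
    }
    for (q in seq_len(config$n_spurious)) {
      p0 <- runif(3, 0.15, 0.85) * ext
      p2 <- runif(3, 0.15, 0.85) * ext
      p1 <- (p0 + p2) / 2 + runif(3, -0.2, 0.2) * ext
      tt <- seq(0, 1, length.out = 2 * max(config$dim))
      pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
        outer(tt^2, p2)
      pts <- clip_to_grid(matrix(pts, ncol = 3), ext)
      if (nrow(pts) >= 2) {
        sl[[length(sl) + 1L]] <- pts
        labels <- c(labels, "spurious")
      }
    }
    tractogram(sl, labels = labels)
  })
}

## keep the longest contiguous run of points inside the volume
clip_to_grid <- function(pts, ext) {
  inside <- pts[, 1] >= 0 & pts[, 1] <= ext[1] &
            pts[, 2] >= 0 & pts[, 2] <= ext[2] &
            pts[, 3] >= 0 & pts[, 3] <= ext[3]
  if (!any(inside)) return(pts[0, , drop = FALSE])
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  pts[starts[best]:ends[best], , drop = FALSE]
}

#' Ground-truth fascicle weights of a phantom tractogram
#'
#' @param tg tractogram produced by [make_bundles] (labels required).
#' @param config the matching [phantom_config].
#' @return numeric vector: per-bundle `w_true` for bundle fascicles, 0 for
#'   spurious ones.
#' @export
phantom_weights <- function(tg, config) {
  stopifnot(!is.null(tg$labels))
  names(config$w_true) <- vapply(config$bundles, `[[`, "", "name")
  w <- rep(0, tg$n_fascicles)
  for (nm in names(config$w_true))
    w[tg$labels == nm] <- config$w_true[[nm]]
  w
}

#' Simulate the diffusion signal of a phantom tractogram
#'
#' Evaluates the isotropic-plus-sticks forward model exactly (see
#' [phantom_config]) using one orientation per fascicle-voxel pair computed
#' with the same resampling/averaging convention as the encoding, then adds
#' measurement noise at `sigma = S0 / snr` (none when `snr = Inf`). `b = 0`
#' volumes carry the value `S0` plus noise. The mask is the set of voxels
#' traversed by at least one fascicle.
#'
#' @param tg a [tractogram].
#' @param w_star ground-truth weights, length `tg$n_fascicles`.
#' @param config a [phantom_config].
#' @param gtab a [gradient_table]; default [phantom_gradient_table].
#' @param lambda_axial,lambda_radial stick diffusivities (mm^2/s), the same
#'   parameters the kernel dictionary uses.
#' @param snap_to_atoms optional [orientation_dictionary]; when supplied,
#'   each fascicle-voxel orientation is replaced by its nearest atom before
#'   simulation, making the factorized model exact (used for
#'   parameter-recovery oracles).
#' @return A [diffusion_volume].
#' @export
simulate_signal <- function(tg, w_star, config, gtab = phantom_gradient_table(config),
                            lambda_axial = 1.5e-3, lambda_radial = 0,
                            snap_to_atoms = NULL) {
  stopifnot(inherits(tg, "tractogram"), inherits(config, "phantom_config"))
  if (length(w_star) != tg$n_fascicles)
    stop("w_star length does not match fascicle count", call. = FALSE)
  if (any(w_star < 0)) stop("w_star must be >= 0", call. = FALSE)
  affine <- phantom_affine(config)
  grid_dim <- config$dim
  step <- min(config$voxel_size) / 2

  inc_v <- list(); inc_t <- list(); inc_w <- list()
  for (f in seq_along(tg$streamlines)) {
    pts <- resample_polyline(tg$streamlines[[f]], step)
    if (nrow(pts) < 2) next
    tang <- polyline_tangents(pts)
    vox0 <- voxel_of(world_to_voxel(affine, pts))
    red <- reduce_nodes_to_voxels(vox0, tang, grid_dim)
    if (nrow(red$voxel) == 0) next
    inc_v[[length(inc_v) + 1L]] <- red$linear
    inc_t[[length(inc_t) + 1L]] <- red$tangent
    inc_w[[length(inc_w) + 1L]] <- rep(w_star[f], length(red$linear))
  }
  inc_v <- unlist(inc_v); inc_w <- unlist(inc_w)
  inc_t <- do.call(rbind, inc_t)
  if (length(inc_v) == 0)
    stop("no fascicle intersects the volume", call. = FALSE)
  if (!is.null(snap_to_atoms)) {
    idx <- nearest_atom(inc_t, snap_to_atoms)
    inc_t <- snap_to_atoms$atoms[idx, , drop = FALSE]
  }

  dwi_sel <- !gtab$b0
  th <- gtab$bvecs[dwi_sel, , drop = FALSE]
  b <- gtab$bvals[dwi_sel]
  t2 <- (th %*% t(inc_t))^2
  E <- exp(-b * (lambda_radial + (lambda_axial - lambda_radial) * t2))
  n_dwi <- nrow(th)

  nvx <- prod(grid_dim)
  aniso <- matrix(0, n_dwi, nvx)
  contrib <- sweep(E, 2, inc_w, "*")
  for (ii in seq_along(inc_v))
    aniso[, inc_v[ii]] <- aniso[, inc_v[ii]] + contrib[, ii]

  mask <- array(FALSE, dim = grid_dim)
  mask[unique(inc_v)] <- TRUE

  n_vol <- length(gtab$bvals)
  sig <- array(0, dim = c(grid_dim, n_vol))
  sig2 <- matrix(sig, nvx, n_vol)
  iso <- config$S0 * config$w0 * exp(-config$A0)
  sig2[, gtab$b0] <- config$S0
  sig2[, !gtab$b0] <- t(iso + config$S0 * aniso)

  if (is.finite(config$snr)) {
    sigma <- config$S0 / config$snr
    sig2 <- with_seed(config$seed + 1L, {
      if (config$noise == "gaussian") {
        sig2 + sigma * matrix(rnorm(length(sig2)), nrow(sig2))
      } else {
        re <- sig2 + sigma * matrix(rnorm(length(sig2)), nrow(sig2))
        im <- sigma * matrix(rnorm(length(sig2)), nrow(sig2))
        sqrt(re^2 + im^2)
      }
    })
  }
  sig <- array(sig2, dim = c(grid_dim, n_vol))
  diffusion_volume(sig, gtab, mask, affine = affine)
}

#' Generate a complete phantom: tractogram, ground truth and signal
#'
#' @inheritParams simulate_signal
#' @param config a [phantom_config].
#' @return list with `dwi` ([diffusion_volume]), `tg` ([tractogram]),
#'   `gtab`, `w_star`, `labels`, `config`, `affine`.
#' @export
life_phantom <- function(config = phantom_config(), lambda_axial = 1.5e-3,
                         lambda_radial = 0, snap_to_atoms = NULL) {
  tg <- make_bundles(config)
  w_star <- phantom_weights(tg, config)
  gtab <- phantom_gradient_table(config)
  dwi <- simulate_signal(tg, w_star, config, gtab,
                         lambda_axial = lambda_axial,
                         lambda_radial = lambda_radial,
                         snap_to_atoms = snap_to_atoms)
  list(dwi = dwi, tg = tg, gtab = gtab, w_star = w_star,
       labels = tg$labels, config = config, affine = phantom_affine(config))
}

#' Write a phantom to disk (NIfTI + bvals/bvecs + TCK + ground-truth JSON)
#'
#' @param ph result of [life_phantom].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of paths written.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dwi = file.path(dir, "dwi.nii.gz"),
             mask = file.path(dir, "mask.nii.gz"),
             bval = file.path(dir, "dwi.bval"),
             bvec = file.path(dir, "dwi.bvec"),
             tck = file.path(dir, "fascicles.tck"),
             truth = file.path(dir, "ground_truth.json"))
  write_dwi(ph$dwi, paths[["dwi"]], paths[["mask"]])
  write_gradient_table(ph$gtab, paths[["bval"]], paths[["bvec"]])
  write_tck(ph$tg, paths[["tck"]])
  jsonlite::write_json(
    list(labels = ph$labels, w_star = ph$w_star, seed = ph$config$seed,
         snr = ph$config$snr, noise = ph$config$noise,
         dim = ph$config$dim, voxel_size = ph$config$voxel_size),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
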