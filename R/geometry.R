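#' Pairwise crossing angles between two tracts
#'
#' For every voxel shared by tracts `F1` and `F2`, forms all pairs of
#' orientation-atom indices (one per fascicle-voxel incidence, read off the
#' tensor's first mode) and computes the axial angle
#' `acos(|U_a1 . U_a2|)` in degrees. Fascicle orientation is an axis, not a
#' vector, so angles lie in [0, 90]. When a weight vector is supplied, only
#' statistically supported fascicles (`w > 0`) contribute.
#'
#' @param phi a `connectome_tensor`.
#' @param dict the [orientation_dictionary] used for the encoding.
#' @param F1,F2 disjoint 1-based fascicle index sets (for tract versus
#'   path-neighborhood, pass `F2 = path_neighborhood(phi, F1)$P_F`).
#' @param weights optional fascicle weights; fascicles with `w <= 0` are
#'   discarded before the angle computation.
#' @return numeric vector of angles (degrees), one per (voxel, fascicle
#'   pair); empty with a warning when the tracts share no voxel. The result
#'   is invariant under swapping `F1` and `F2`.
#' @export
pairwise_angles <- function(phi, dict, F1, F2, weights = NULL) {
  F1 <- check_fascicle_set(phi, F1)
  F2 <- check_fascicle_set(phi, F2)
  if (length(intersect(F1, F2)) > 0)
    stop("F1 and F2 must be disjoint", call. = FALSE)
  if (!is.null(weights)) {
    F1 <- F1[weights[F1] > 0]
    F2 <- F2[weights[F2] > 0]
  }
  if (length(F1) == 0 || length(F2) == 0) {
    warning("no supported fascicles in one of the tracts")
    return(numeric())
  }
  V <- intersect(touched_voxels(phi, F1), touched_voxels(phi, F2))
  if (length(V) == 0) {
    warning("tracts share no voxel")
    return(numeric())
  }
  in1 <- phi$inc_fascicle %in% F1 & phi$inc_voxel %in% V
  in2 <- phi$inc_fascicle %in% F2 & phi$inc_voxel %in% V
  d1 <- data.frame(v = phi$inc_voxel[in1], a = phi$inc_atom[in1])
  d2 <- data.frame(v = phi$inc_voxel[in2], a = phi$inc_atom[in2])
  pairs <- merge(d1, d2, by = "v")
  if (nrow(pairs) == 0) return(numeric())
  dots <- abs(rowSums(dict$atoms[pairs$a.x, , drop = FALSE] *
                        dict$atoms[pairs$a.y, , drop = FALSE]))
  acos(pmin(pmax(dots, 0), 1)) * 180 / pi
}

#' Summarize a crossing-angle sample: histogram, peak and width
#'
#' Bins the angles over [0, 90] degrees, reports the peak angle `mu` (center
#' of the modal bin; ties break to the smaller angle) and the width at half
#' height `sigma`: the full width of the histogram at half the modal count,
#' with linear interpolation between bin centers at the two half-height
#' crossings (clamped to the domain when the histogram never drops below
#' half height on one side). Secondary modes (local maxima reaching at least
#' half the modal count) are listed in `modes`.
#'
#' @param angles non-empty numeric vector of angles in [0, 90] degrees.
#' @param bin_width histogram bin width (degrees).
#' @return An object of class `angle_distribution`: `angles`, `breaks`,
#'   `counts`, `mids`, `mu`, `sigma`, `modes`, `bin_width`.
#' @export
summarize_angles <- function(angles, bin_width = 1) {
  if (length(angles) == 0) stop("empty angle sample", call. = FALSE)
  if (any(angles < -1e-9 | angles > 90 + 1e-9))
    stop("angles must lie in [0, 90] degrees", call. = FALSE)
  angles <- pmin(pmax(angles, 0), 90)
  breaks <- seq(0, 90 + bin_width, by = bin_width)
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  counts <- h$counts
  mids <- h$mids
  jmax <- which.max(counts)                    # which.max takes the first tie
  cmax <- counts[jmax]
  half <- cmax / 2
  ## left half-height crossing
  left <- 0
  for (j in seq(jmax, 1)) {
    if (counts[j] < half) {
      left <- mids[j] + (half - counts[j]) / (counts[j + 1] - counts[j]) *
        bin_width
      break
    }
  }
  right <- 90
  for (j in seq(jmax, length(counts))) {
    if (counts[j] < half) {
      right <- mids[j] - (half - counts[j]) / (counts[j - 1] - counts[j]) *
        bin_width
      break
    }
  }
  sigma <- max(0, right - left)
  ## local maxima at or above half the modal count
  is_peak <- vapply(seq_along(counts), function(j) {
    cl <- if (j > 1) counts[j - 1] else -Inf
    cr <- if (j < length(counts)) counts[j + 1] else -Inf
    counts[j] >= half & counts[j] >= cl & counts[j] >= cr & counts[j] > 0
  }, logical(1))
  structure(list(angles = angles, breaks = breaks, counts = counts,
                 mids = mids, mu = mids[jmax], sigma = sigma,
                 modes = mids[is_peak], bin_width = bin_width),
            class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf(
    "Crossing-angle distribution: n = %d, peak mu = %.1f deg, width at half height sigma = %.1f deg\n",
    length(x$angles), x$mu, x$sigma))
  if (length(x$modes) > 1)
    cat("  modes:", paste(sprintf("%.1f", x$modes), collapse = ", "), "deg\n")
  invisible(x)
}

#' @export
plot.angle_distribution <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "h",
                 xlab = "axial angle (degrees)", ylab = "count",
                 main = sprintf("mu = %.1f deg, sigma = %.1f deg", x$mu, x$sigma),
                 ...)
  graphics::abline(v = x$mu, lty = 2)
  invisible(x)
}
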