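# Internal geometry and RNG helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats approx rnorm runif var sd setNames
#' @importFrom utils head tail
NULL

## Apply a 4x4 affine to 0-based continuous voxel coordinates (n x 3).
apply_affine <- function(affine, pts) {
  pts <- matrix(pts, ncol = 3)
  out <- cbind(pts, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}

## World mm -> 0-based continuous voxel coordinates.
world_to_voxel <- function(affine, pts) {
  apply_affine(solve(affine), pts)
}

## Voxel-center convention: continuous coordinate p belongs to voxel
## floor(p + 0.5) (0-based).
voxel_of <- function(p) {
  floor(p + 0.5)
}

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

vec_norm <- function(x) sqrt(sum(x^2))

## Resample a polyline (n x 3, mm) at fixed arc-length step, keeping both
## endpoints. Zero-length segments are dropped before resampling.
resample_polyline <- function(pts, step) {
  pts <- matrix(pts, ncol = 3)
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  len <- s[length(s)]
  n_out <- max(2L, as.integer(ceiling(len / step)) + 1L)
  si <- seq(0, len, length.out = n_out)
  out <- vapply(1:3, function(d) approx(s, pts[, d], xout = si)$y, numeric(n_out))
  matrix(out, ncol = 3)
}

## Unit tangents by central differences, one-sided at the endpoints.
polyline_tangents <- function(pts) {
  n <- nrow(pts)
  if (n == 2) {
    t1 <- pts[2, ] - pts[1, ]
    tt <- rbind(t1, t1)
  } else {
    tt <- rbind(
      pts[2, ] - pts[1, ],
      pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
      pts[n, ] - pts[n - 1, ]
    )
  }
  unit_rows(tt)
}

## Run expr with a temporary RNG state seeded by `seed`; the caller's global
## RNG stream is restored afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
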