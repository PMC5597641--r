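#' Diffusion gradient tables
#'
#' A gradient table pairs each diffusion-weighted volume with its sensitization
#' `b` (s/mm^2) and unit gradient direction. Directions with `b` at or below
#' `b0_threshold` are treated as non-diffusion-weighted (`b = 0`) volumes; all
#' diffusion-weighted directions are renormalized to unit length.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs numeric matrix of gradient directions, `n x 3` or `3 x n`.
#' @param b0_threshold b-values at or below this are flagged as b = 0.
#'   Defaults to 50 s/mm^2; real scanner tables rarely contain exact zeros.
#' @return An object of class `gradient_table` with elements `bvals`, `bvecs`
#'   (`n x 3`, unit rows where `b > 0`), logical `b0` flags, and `n_dwi`, the
#'   number of diffusion-weighted (`b > 0`) directions.
#' @examples
#' gt <- gradient_table(c(0, 2000, 2000), rbind(c(0, 0, 0), diag(3)[1:2, ]))
#' gt$n_dwi
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3 && nrow(bvecs) == 3) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3)
    stop("bvecs must be an n x 3 or 3 x n matrix", call. = FALSE)
  if (nrow(bvecs) != length(bvals))
    stop("bvals and bvecs describe different numbers of volumes", call. = FALSE)
  if (any(!is.finite(bvals)) || any(!is.finite(bvecs)))
    stop("non-finite values in gradient table", call. = FALSE)
  b0 <- bvals <= b0_threshold
  if (any(!b0)) {
    nrm <- sqrt(rowSums(bvecs[!b0, , drop = FALSE]^2))
    if (any(nrm == 0))
      stop("zero-length gradient direction with b > 0", call. = FALSE)
    bvecs[!b0, ] <- bvecs[!b0, , drop = FALSE] / nrm
  }
  structure(
    list(bvals = bvals, bvecs = bvecs, b0 = b0,
         n_dwi = sum(!b0), b0_threshold = b0_threshold),
    class = "gradient_table"
  )
}

#' Read an FSL-dialect gradient table
#'
#' Accepts the usual FSL text layout (`bvecs` as 3 rows by n columns) as well
#' as the transposed n-by-3 layout; `bvals` is a flat whitespace-separated
#' vector.
#'
#' @param bval_source,bvec_source file paths to whitespace-separated numeric
#'   text.
#' @inheritParams gradient_table
#' @return A [gradient_table].
#' @export
read_gradient_table <- function(bval_source, bvec_source, b0_threshold = 50) {
  bvals <- scan(bval_source, what = numeric(), quiet = TRUE)
  vec_lines <- readLines(bvec_source)
  vec_lines <- vec_lines[nzchar(trimws(vec_lines))]
  rows <- lapply(vec_lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  nc <- unique(lengths(rows))
  if (length(nc) != 1)
    stop("ragged bvec file: rows have differing lengths", call. = FALSE)
  m <- do.call(rbind, rows)
  if (nrow(m) == 3 && nc != 3) {
    bvecs <- t(m)
  } else if (nc == 3) {
    bvecs <- m
  } else {
    stop("bvec file is neither 3 x n nor n x 3", call. = FALSE)
  }
  gradient_table(bvals, bvecs, b0_threshold = b0_threshold)
}

#' Write a gradient table as FSL bvals/bvecs text
#'
#' @param gtab a [gradient_table].
#' @param bval_path,bvec_path output file paths; `bvecs` is written in the
#'   3-row FSL layout.
#' @return Invisibly, `gtab`.
#' @export
write_gradient_table <- function(gtab, bval_path, bvec_path) {
  stopifnot(inherits(gtab, "gradient_table"))
  writeLines(paste(format(gtab$bvals, digits = 17), collapse = " "), bval_path)
  writeLines(apply(t(gtab$bvecs), 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), bvec_path)
  invisible(gtab)
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("Gradient table:", length(x$bvals), "volumes,",
      x$n_dwi, "diffusion-weighted,", sum(x$b0), "b=0\n")
  if (x$n_dwi > 0)
    cat("  b (dwi): ", paste(unique(round(x$bvals[!x$b0])), collapse = ", "),
        " s/mm^2\n", sep = "")
  invisible(x)
}
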