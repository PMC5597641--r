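#' Tractograms: collections of candidate white-matter fascicles
#'
#' A fascicle is a polyline in world coordinates (mm). Fascicle indices are
#' assigned by order (1-based in R; reported 0-based in serialized index
#' lists). Streamlines with fewer than two points violate the tangent
#' definition and are rejected at construction with a message stating how many
#' were dropped.
#'
#' @param streamlines list of `n x 3` numeric matrices, points in world mm.
#' @param labels optional character vector of per-fascicle labels (e.g. bundle
#'   names), recycled checks apply.
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, labels = NULL) {
  streamlines <- lapply(streamlines, function(s) matrix(as.numeric(s), ncol = 3))
  ok <- vapply(streamlines, nrow, integer(1)) >= 2L
  if (any(!ok)) {
    message("dropped ", sum(!ok), " streamline(s) with fewer than 2 points")
    streamlines <- streamlines[ok]
    if (!is.null(labels)) labels <- labels[ok]
  }
  if (length(streamlines) == 0)
    stop("empty tractogram", call. = FALSE)
  if (!is.null(labels) && length(labels) != length(streamlines))
    stop("labels length does not match streamline count", call. = FALSE)
  structure(list(streamlines = streamlines, labels = labels,
                 n_fascicles = length(streamlines)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat("Tractogram:", x$n_fascicles, "fascicles,",
      sum(np), "points (median", stats::median(np), "per fascicle)\n")
  if (!is.null(x$labels))
    cat("  labels:", paste(names(table(x$labels)), table(x$labels),
                           sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Read a tractogram from TCK or TRK
#'
#' The dialect is auto-detected from the file's magic bytes. TCK points are
#' already world mm. TRK points are stored in voxel-mm; they are converted to
#' world coordinates as `affine %*% (point / voxel_size)`, i.e. voxel-mm
#' divided by the header voxel sizes gives the 0-based continuous voxel
#' coordinate.
#'
#' @param path file path.
#' @param reference_affine 4x4 voxel-to-world matrix used to place TRK
#'   voxel-mm points in world space when the TRK header carries no usable
#'   affine, and checked against the header affine when it does.
#' @param tol tolerance for the TRK header/reference affine comparison (mm).
#' @return A [tractogram].
#' @export
read_tractogram <- function(path, reference_affine = NULL, tol = 1e-3) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 13)
  close(con)
  if (length(magic) == 0)
    stop("empty tractogram file: ", path, call. = FALSE)
  if (length(magic) >= 13 && identical(magic, charToRaw("mrtrix tracks"))) {
    read_tck(path)
  } else if (length(magic) >= 5 &&
             identical(magic[1:5], charToRaw("TRACK"))) {
    read_trk(path, reference_affine = reference_affine, tol = tol)
  } else {
    stop("unrecognized tractogram format (expected TCK or TRK): ", path,
         call. = FALSE)
  }
}

read_tck <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  txt_end <- grepRaw("\nEND\n", raw_all, fixed = TRUE)
  if (length(txt_end) == 0)
    stop("malformed TCK header: no END marker", call. = FALSE)
  hdr_txt <- rawToChar(raw_all[seq_len(txt_end)])
  lines <- strsplit(hdr_txt, "\n")[[1]]
  kv <- lines[grepl(":", lines, fixed = TRUE)]
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  dt <- vals[keys == "datatype"]
  if (length(dt) && !dt %in% c("Float32LE", "Float32"))
    stop("unsupported TCK datatype: ", dt, call. = FALSE)
  off <- vals[keys == "file"]
  if (!length(off)) stop("malformed TCK header: no file offset", call. = FALSE)
  offset <- as.integer(sub("^\\.\\s*", "", off[1]))
  n_float <- (length(raw_all) - offset) %/% 4L
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, where = offset)
  x <- readBin(con, "numeric", n = n_float, size = 4, endian = "little")
  m <- matrix(x, ncol = 3, byrow = TRUE)
  is_nan <- rowSums(is.na(m)) == 3
  is_inf <- rowSums(is.infinite(m) & m > 0) == 3
  stop_row <- which(is_inf)[1]
  if (!is.na(stop_row)) m <- m[seq_len(stop_row - 1), , drop = FALSE]
  is_nan <- rowSums(is.na(m)) == 3
  grp <- cumsum(c(TRUE, head(is_nan, -1)))
  keep <- !is_nan
  sl <- split.data.frame(m[keep, , drop = FALSE], grp[keep])
  sl <- lapply(sl, function(s) matrix(as.numeric(as.matrix(s)), ncol = 3))
  if (length(sl) == 0) stop("TCK file contains no streamlines", call. = FALSE)
  tractogram(unname(sl))
}

#' Write a tractogram as TCK (world mm, Float32LE)
#'
#' @param tg a [tractogram].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tck <- function(tg, path) {
  stopifnot(inherits(tg, "tractogram"))
  fixed <- c("mrtrix tracks",
             "datatype: Float32LE",
             paste0("count: ", tg$n_fascicles))
  ## the offset field participates in its own value; iterate to fixpoint
  offset <- 0L
  for (i in 1:3) {
    hdr <- c(fixed, paste0("file: . ", offset), "END")
    hdr_txt <- paste0(paste(hdr, collapse = "\n"), "\n")
    offset <- nchar(hdr_txt, type = "bytes")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr_txt, con, eos = NULL)
  for (s in tg$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

read_trk <- function(path, reference_affine = NULL, tol = 1e-3) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", n = 6)
  if (!identical(rawToChar(id[1:5]), "TRACK"))
    stop("not a TRK file", call. = FALSE)
  readBin(con, "integer", n = 3, size = 2)                 # dim
  voxel_size <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # origin
  n_scalars <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  readBin(con, "raw", n = 200)                              # scalar names
  n_props <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  readBin(con, "raw", n = 200)                              # property names
  vox2ras <- matrix(readBin(con, "numeric", n = 16, size = 4,
                            endian = "little"), 4, 4, byrow = TRUE)
  readBin(con, "raw", n = 444 + 4 + 4 + 24 + 2 + 6)         # reserved..padding
  n_count <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  readBin(con, "integer", n = 1, size = 4, endian = "little")  # version
  hdr_size <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (hdr_size != 1000L)
    stop("malformed TRK header (hdr_size != 1000)", call. = FALSE)
  if (any(voxel_size <= 0))
    stop("TRK header has non-positive voxel sizes", call. = FALSE)
  affine <- if (any(vox2ras != 0) && vox2ras[4, 4] != 0) vox2ras else reference_affine
  if (is.null(affine))
    stop("TRK file has no affine and no reference_affine was supplied",
         call. = FALSE)
  if (!is.null(reference_affine) && any(vox2ras != 0) && vox2ras[4, 4] != 0 &&
      max(abs(vox2ras - reference_affine)) > tol)
    stop("TRK header affine disagrees with the reference affine", call. = FALSE)
  sl <- list()
  repeat {
    n_pts <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (length(n_pts) == 0) break
    vals <- readBin(con, "numeric", n = n_pts * (3 + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0)
      readBin(con, "numeric", n = n_props, size = 4, endian = "little")
    pm <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(pm, 2, voxel_size, "/")
    sl[[length(sl) + 1L]] <- apply_affine(affine, vox)
  }
  if (length(sl) == 0) stop("TRK file contains no streamlines", call. = FALSE)
  if (n_count > 0 && length(sl) != n_count)
    warning("TRK n_count (", n_count, ") differs from streamlines read (",
            length(sl), ")")
  tractogram(sl)
}

#' Write a tractogram as TRK (voxel-mm dialect)
#'
#' World points are converted to voxel-mm as
#' `world_to_voxel(affine, p) * voxel_size`, the inverse of the read
#' convention.
#'
#' @param tg a [tractogram].
#' @param path output path.
#' @param affine 4x4 voxel-to-world matrix stored in the header.
#' @param voxel_size length-3 voxel dimensions (mm).
#' @param dim length-3 grid dimensions.
#' @return Invisibly, `path`.
#' @export
write_trk <- function(tg, path, affine, voxel_size, dim = c(0L, 0L, 0L)) {
  stopifnot(inherits(tg, "tractogram"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")
  writeBin(rep(0, 3), con, size = 4, endian = "little")        # origin
  writeBin(0L, con, size = 2, endian = "little")               # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")               # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                      # reserved
  writeBin(c(charToRaw("RAS"), as.raw(0)), con)                # voxel_order
  writeBin(raw(4), con)                                        # pad2
  writeBin(rep(0, 6), con, size = 4, endian = "little")        # img orientation
  writeBin(raw(2), con)                                        # pad1
  writeBin(raw(6), con)                                        # invert/swap
  writeBin(length(tg$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")               # version
  writeBin(1000L, con, size = 4, endian = "little")            # hdr_size
  for (s in tg$streamlines) {
    vox <- world_to_voxel(affine, s)
    pm <- sweep(vox, 2, voxel_size, "*")
    writeBin(nrow(pm), con, size = 4, endian = "little")
    writeBin(as.numeric(t(pm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read / write plain-text fascicle index lists
#'
#' Tract definitions are exchanged as text files holding one 0-based fascicle
#' index per line; in R the indices are used 1-based.
#'
#' @param path file path.
#' @return `read_tract_indices`: integer vector of 1-based fascicle indices.
#' @export
read_tract_indices <- function(path) {
  idx <- scan(path, what = integer(), quiet = TRUE)
  if (any(idx < 0)) stop("negative fascicle index in ", path, call. = FALSE)
  as.integer(idx) + 1L
}

#' @rdname read_tract_indices
#' @param indices integer vector of 1-based fascicle indices.
#' @export
write_tract_indices <- function(indices, path) {
  writeLines(as.character(as.integer(indices) - 1L), path)
  invisible(path)
}
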