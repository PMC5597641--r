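CONTAINER_VERSION <- "lifet-container-1"

#' Serialize / restore a LiFE model container
#'
#' The container stores everything needed to reproduce predictions
#' bit-compatibly: the sparse tensor coordinates and values, the
#' per-incidence orientation record, the dictionary (atoms, kernels,
#' diffusivities), the gradient table, the per-voxel `S0` and demeaned data,
#' the voxel index map and the fitted weights when present. Containers are
#' written with R's native serialization (RDS) and carry a format version
#' field; a version mismatch is refused with a message.
#'
#' @param object a `life` model (fitted or not).
#' @param path file path (conventionally `.rds`).
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   restored `life` object.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "life"))
  container <- list(version = CONTAINER_VERSION,
                    tensor = object$tensor,
                    dictionary = object$dictionary,
                    data = object$data,
                    gtab = object$gtab,
                    affine = object$affine,
                    mask_dim = object$mask_dim,
                    weights = object$weights,
                    fit = object$fit)
  saveRDS(container, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  container <- readRDS(path)
  if (!is.list(container) || is.null(container$version))
    stop("not a LiFE model container: ", path, call. = FALSE)
  if (!identical(container$version, CONTAINER_VERSION))
    stop("container version '", container$version,
         "' does not match supported version '", CONTAINER_VERSION, "'",
         call. = FALSE)
  for (grp in c("tensor", "dictionary", "data", "gtab"))
    if (is.null(container[[grp]]))
      stop("model container is missing required group '", grp, "'",
           call. = FALSE)
  structure(list(tensor = container$tensor, dictionary = container$dictionary,
                 data = container$data, gtab = container$gtab,
                 affine = container$affine, mask_dim = container$mask_dim,
                 weights = container$weights, fit = container$fit,
                 call = quote(load_model())),
            class = "life")
}
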