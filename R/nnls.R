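#' Solver settings for the Barzilai-Borwein NNLS fit
#'
#' @param tol relative convergence tolerance: iteration stops when the
#'   projected-gradient infinity norm falls below `tol` times its initial
#'   value, or the relative objective decrease over 5 iterations falls below
#'   `tol`.
#' @param max_iter iteration cap.
#' @param memory window of the non-monotone line-search safeguard.
#' @param support_tol relative support-identification floor: after
#'   convergence, weights at or below `support_tol * max(w)` are set to
#'   exactly zero. Projected-gradient iterates approach inactive bounds
#'   asymptotically rather than landing on them, leaving weights many orders
#'   of magnitude below the solution scale; the floor turns those into the
#'   exact zeros the optimized-connectome support is defined on. Set to 0 to
#'   disable.
#' @return list of class `life_control`.
#' @export
life_control <- function(tol = 1e-6, max_iter = 500L, memory = 10L,
                         support_tol = 1e-6) {
  stopifnot(tol > 0, max_iter >= 1, support_tol >= 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 memory = as.integer(memory), support_tol = support_tol),
            class = "life_control")
}

#' Non-negative least-squares fit by projected-gradient Barzilai-Borwein
#'
#' Minimizes `0.5 || y - M w ||^2` subject to `w >= 0` using only the
#' factorized forward and adjoint operators (the matrix `M` is never formed).
#' Steps alternate the two Barzilai-Borwein step lengths, projected onto the
#' non-negative orthant, with a non-monotone Armijo safeguard over a sliding
#' window of accepted objective values. The first step is a Cauchy
#' (exact line-search) step along the projected steepest-descent direction
#' from `w = 0`. The solver is deterministic: identical inputs give bitwise
#' identical weights.
#'
#' @param object a `life` model (or any list with `tensor`, `dictionary`).
#' @param y demeaned relative signal vector (voxel-major); defaults to the
#'   model's own data.
#' @param control a [life_control].
#' @return An object of class `life_fit`: `w` (non-negative weights),
#'   `objective` (trace over accepted iterates), `iterations`, `converged`,
#'   `reason`, `pg_norm` (final projected-gradient infinity norm) and
#'   `control`.
#' @export
fit_nnls <- function(object, y = NULL, control = life_control()) {
  stopifnot(inherits(object, "life") || (is.list(object) &&
            !is.null(object$tensor) && !is.null(object$dictionary)))
  phi <- object$tensor
  D <- object$dictionary$D
  y <- y %||% as.vector(object$data$y)
  if (length(y) != nrow(D) * phi$dims[2])
    stop("y has wrong length for this model", call. = FALSE)
  bb_nnls(function(w) life_predict_core(phi, D, w),
          function(r) life_transpose_core(phi, D, r),
          y, phi$dims[3], control = control)
}

#' Operator-form Barzilai-Borwein NNLS
#'
#' The solver behind [fit_nnls], exposed for fitting any linear model given
#' as a forward/adjoint operator pair — in particular the explicit matrix
#' form of the LiFE model, so that the explicit and factorized models can be
#' fitted with the identical algorithm and iteration schedule.
#'
#' @param Aop forward operator, `w -> M w`.
#' @param Atop adjoint operator, `r -> t(M) r`.
#' @param y response vector.
#' @param n_f number of weights (columns of `M`).
#' @inheritParams fit_nnls
#' @return A `life_fit`, see [fit_nnls].
#' @export
bb_nnls <- function(Aop, Atop, y, n_f, control = life_control()) {
  fobj <- function(resid) 0.5 * sum(resid^2)
  w <- numeric(n_f)
  resid <- Aop(w) - y
  f <- fobj(resid)
  g <- Atop(resid)
  pg <- w - pmax(0, w - g)
  pg0 <- max(abs(pg))
  if (pg0 == 0) {
    return(structure(list(w = w, objective = f, iterations = 0L,
                          converged = TRUE, reason = "stationary at w = 0",
                          pg_norm = 0, control = control),
                     class = "life_fit"))
  }
  tol_pg <- control$tol * pg0
  ## Cauchy first step along the projected steepest-descent direction
  d <- pmax(0, w - g) - w
  Ad <- Aop(d)
  denom <- sum(Ad^2)
  alpha <- if (denom > 0) -sum(g * d) / denom else 1
  w_new <- pmax(0, w + min(1, alpha) * d)
  f_hist <- rep(f, control$memory)
  obj_trace <- f
  reason <- "max_iter reached"
  converged <- FALSE
  w_old <- w; g_old <- g
  w <- w_new
  resid <- Aop(w) - y
  f <- fobj(resid)
  g <- Atop(resid)
  f_hist[1 + (1L %% control$memory)] <- f
  obj_trace <- c(obj_trace, f)
  it <- 1L
  while (it < control$max_iter) {
    it <- it + 1L
    s <- w - w_old
    yv <- g - g_old
    sy <- sum(s * yv)
    if (sy <= 0) {
      alpha <- 1 / max(abs(g))
    } else if (it %% 2L == 0L) {
      alpha <- sum(s * s) / sy                     # BB1
    } else {
      alpha <- sy / sum(yv * yv)                   # BB2
    }
    alpha <- min(max(alpha, 1e-12), 1e12)
    f_ref <- max(f_hist)
    ## backtracking on the projected arc, non-monotone Armijo
    ok <- FALSE
    for (bt in 0:30) {
      w_try <- pmax(0, w - alpha * g)
      resid_try <- Aop(w_try) - y
      f_try <- fobj(resid_try)
      if (f_try <= f_ref + 1e-4 * sum(g * (w_try - w))) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) { reason <- "line search failed"; break }
    if (!is.finite(f_try))
      stop("non-finite objective in NNLS solver (iteration ", it, ")",
           call. = FALSE)
    w_old <- w; g_old <- g
    w <- w_try; resid <- resid_try; f <- f_try
    g <- Atop(resid)
    f_hist[1 + (it %% control$memory)] <- f
    obj_trace <- c(obj_trace, f)
    pg <- w - pmax(0, w - g)
    if (max(abs(pg)) < tol_pg) {
      converged <- TRUE; reason <- "projected gradient below tolerance"; break
    }
    n_tr <- length(obj_trace)
    if (n_tr > 5) {
      f5 <- obj_trace[n_tr - 5]
      if (abs(f5 - f) / max(f5, .Machine$double.eps) < control$tol) {
        converged <- TRUE
        reason <- "objective change below tolerance"
        break
      }
    }
  }
  st <- control$support_tol %||% 0
  if (st > 0 && any(w > 0)) w[w <= st * max(w)] <- 0
  structure(list(w = w, objective = obj_trace, iterations = it,
                 converged = converged, reason = reason,
                 pg_norm = max(abs(w - pmax(0, w - g))), control = control),
            class = "life_fit")
}

#' @export
print.life_fit <- function(x, ...) {
  cat("NNLS fit:", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      paste0("(", x$reason, ")"), "\n")
  cat(sprintf("  objective %.6g -> %.6g, support %d / %d\n",
              x$objective[1], tail(x$objective, 1),
              sum(x$w > 0), length(x$w)))
  invisible(x)
}

#' Optimized connectome: fascicles retained by the fit
#'
#' The optimized connectome is the subset of candidate fascicles assigned a
#' strictly positive weight; its cardinality is the connectome resolution
#' (the number of fascicles the data support).
#'
#' @param fit a `life_fit`, or a fitted `life` model.
#' @return list with `support` (1-based fascicle indices with `w > 0`) and
#'   `resolution` (their count).
#' @export
optimized_connectome <- function(fit) {
  if (inherits(fit, "life")) {
    if (is.null(fit$weights)) stop("model is unfitted", call. = FALSE)
    w <- fit$weights
  } else if (inherits(fit, "life_fit")) {
    w <- fit$w
  } else stop("need a life_fit or fitted life model", call. = FALSE)
  support <- which(w > 0)
  list(support = support, resolution = length(support))
}

#' Reference active-set non-negative least squares
#'
#' A Lawson-Hanson active-set solve operating on the normal equations
#' (`G = t(M) M`, `h = t(M) y`), used as the exact reference against which
#' the large-scale Barzilai-Borwein solver is validated. Suitable for
#' problems with at most a few thousand columns.
#'
#' @param M design matrix (dense or `Matrix` sparse), or `NULL` when `gram`
#'   and `rhs` are given directly.
#' @param y response vector.
#' @param gram,rhs optional precomputed `t(M) M` and `t(M) y`.
#' @param tol dual feasibility tolerance, relative to `max |h|`.
#' @param max_iter cap on active-set changes.
#' @return list with `w`, `iterations`, `passive` (final support).
#' @export
nnls_ref <- function(M = NULL, y = NULL, gram = NULL, rhs = NULL,
                     tol = 1e-10, max_iter = NULL) {
  if (is.null(gram)) {
    stopifnot(!is.null(M), !is.null(y))
    gram <- as.matrix(Matrix::crossprod(M))
    rhs <- as.vector(Matrix::crossprod(M, y))
  }
  n <- length(rhs)
  max_iter <- max_iter %||% (10L * n)
  w <- numeric(n)
  passive <- logical(n)
  tol_abs <- tol * max(abs(rhs), 1)
  it <- 0L
  repeat {
    grad <- rhs - as.vector(gram %*% w)
    cand <- which(!passive & grad > tol_abs)
    if (length(cand) == 0 || it >= max_iter) break
    passive[cand[which.max(grad[cand])]] <- TRUE
    repeat {
      it <- it + 1L
      P <- which(passive)
      z <- numeric(n)
      z[P] <- solve(gram[P, P, drop = FALSE], rhs[P])
      if (all(z[P] > 0)) { w <- z; break }
      neg <- P[z[P] <= 0]
      denom <- w[neg] - z[neg]
      a <- min(ifelse(denom > 0, w[neg] / denom, 0))
      w <- w + a * (z - w)
      passive[w <= tol_abs * 1e-6 & passive] <- FALSE
      w[!passive] <- 0
      if (it >= max_iter) break
    }
  }
  list(w = w, iterations = it, passive = which(passive))
}
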