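#' Linear deconvolution of a mixture spectrum
#'
#' `fit_ls()` solves the (optionally ridge-regularized) least-squares
#' problem \deqn{\min_c \|y - X c\|^2 + \lambda \|c\|^2,} where the columns
#' of X are the basis-set pure-component spectra; coefficients are
#' unconstrained and may be negative. `fit_nnls()` minimizes the same
#' objective subject to \eqn{c \ge 0} using the Lawson--Hanson active-set
#' algorithm; the ridge term is folded in by augmenting the design matrix
#' with \eqn{\sqrt\lambda I} rows and zeros on the target, so \eqn{\lambda
#' = 0} reduces exactly to plain NNLS.
#'
#' Non-convergence of the active-set iteration (possible under heavy basis
#' collinearity) is not an error: the result is returned with `converged =
#' FALSE`, and downstream benchmarking counts such mixtures as incorrect
#' predictions.
#'
#' @param y a mixture `ir_spectrum` on the basis grid.
#' @param basis a [basis_set()] or [ir_library()].
#' @param lambda ridge penalty, >= 0 (default 0: ordinary LS / NNLS).
#' @param max_iter active-set iteration cap; default `3 *` basis size.
#' @return An `unmix_result`: named `coefficients` (one per basis entry,
#'   basis order), `residual_sse` (\eqn{\sum_\nu (y - Xc)^2} on the data,
#'   excluding any ridge term), `converged`, `lambda`, `n_iter`.
#' @seealso [pairwise_interpolation()] for the brute-force two-component
#'   baseline, [rank_candidates()] to turn coefficients into predictions.
#' @export
fit_ls <- function(y, basis, lambda = 0) {
  pr <- unmix_problem(y, basis, lambda)
  A <- pr$XtX
  if (lambda > 0) diag(A) <- diag(A) + lambda
  co <- tryCatch(
    drop(solve(A, pr$Xty)),
    error = function(e) ls_pinv(pr$X, pr$yv, lambda)
  )
  names(co) <- pr$ids
  unmix_result(co, pr, lambda, converged = TRUE, n_iter = 0L)
}

# Minimum-norm solution via SVD for rank-deficient designs.
ls_pinv <- function(X, y, lambda) {
  s <- svd(X)
  d <- s$d / (s$d^2 + lambda)
  d[s$d < max(dim(X)) * max(s$d) * .Machine$double.eps] <- 0
  drop(s$v %*% (d * crossprod(s$u, y)))
}

#' @rdname fit_ls
#' @export
fit_nnls <- function(y, basis, lambda = 0, max_iter = NULL) {
  pr <- unmix_problem(y, basis, lambda)
  A <- pr$XtX
  if (lambda > 0) diag(A) <- diag(A) + lambda
  sol <- nnls_active_set(A, pr$Xty, max_iter)
  co <- sol$x
  names(co) <- pr$ids
  unmix_result(co, pr, lambda, converged = sol$converged,
               n_iter = sol$n_iter)
}

# Shared problem setup: grid checks + normal-equation pieces.
unmix_problem <- function(y, basis, lambda) {
  basis <- basis_set(basis)
  stopifnot(inherits(y, "ir_spectrum"))
  if (!grids_identical(y$grid, basis$grid))
    stop("mixture and basis are on incompatible grids", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop("`lambda` must be a single non-negative number", call. = FALSE)
  yv <- y$intensities
  cache <- attr(basis, "gram")
  if (is.null(cache)) {
    XtX <- crossprod(basis$X)
  } else XtX <- cache
  list(ids = basis$ids, X = basis$X, yv = yv, XtX = XtX,
       Xty = drop(crossprod(basis$X, yv)))
}

# Attach a precomputed Gram matrix so repeated fits against one basis
# skip the O(n p^2) crossprod. Used by the benchmark drivers.
with_gram <- function(basis) {
  basis <- basis_set(basis)
  attr(basis, "gram") <- crossprod(basis$X)
  basis
}

unmix_result <- function(coefficients, pr, lambda, converged, n_iter) {
  resid <- pr$yv - drop(pr$X %*% coefficients)
  structure(list(coefficients = coefficients,
                 residual_sse = sum(resid^2),
                 converged = isTRUE(converged),
                 lambda = lambda,
                 n_iter = n_iter),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  nz <- sum(abs(x$coefficients) > 0)
  top <- sort(abs(x$coefficients), decreasing = TRUE)
  cat(sprintf(
    "<unmix_result> %d/%d nonzero coefficients, residual SSE %.4g%s\n",
    nz, length(x$coefficients), x$residual_sse,
    if (x$converged) "" else " [NOT CONVERGED]"))
  print(utils::head(sort(x$coefficients, decreasing = TRUE), 5))
  invisible(x)
}

# Lawson-Hanson NNLS on the normal equations: minimize ||y - Xc||^2 s.t.
# c >= 0, given A = X'X (+ lambda I) and b = X'y. Active-set with the
# standard inner feasibility loop; hitting max_iter flags converged = FALSE.
nnls_active_set <- function(A, b, max_iter = NULL) {
  p <- length(b)
  if (is.null(max_iter)) max_iter <- max(3L * p, 30L)
  x <- numeric(p)
  passive <- logical(p)
  tol <- 1e-10 * max(1, max(abs(b)))
  n_iter <- 0L
  converged <- FALSE
  repeat {
    w <- b - drop(A %*% x)
    cand <- which(!passive & w > tol)
    if (!length(cand)) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      n_iter <- n_iter + 1L
      P <- which(passive)
      s <- numeric(p)
      sP <- tryCatch(drop(solve(A[P, P, drop = FALSE], b[P])),
                     error = function(e) rep(-1, length(P)))
      s[P] <- sP
      if (all(sP > tol)) { x <- s; break }
      # step toward s until the first passive coefficient hits zero
      neg <- P[s[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      drop_idx <- P[x[P] <= tol]
      x[drop_idx] <- 0
      passive[drop_idx] <- FALSE
      if (!any(passive)) { x[] <- 0; break }
      if (n_iter >= max_iter) break
    }
    if (n_iter >= max_iter && !all(b - drop(A %*% x) <= tol | passive)) {
      # out of budget with optimality unverified
      break
    }
  }
  if (!converged) {
    # final optimality check in case the loop exited at the boundary
    w <- b - drop(A %*% x)
    converged <- all(w <= tol | passive)
  }
  list(x = x, converged = converged, n_iter = n_iter)
}

#' Brute-force pairwise convex interpolation baseline
#'
#' For every unordered pair of basis spectra \eqn{(x_i, x_j)} the
#' least-squares optimal convex coefficient \eqn{\alpha^* =
#' \mathrm{clamp}_{[0,1]}\langle y - x_j, x_i - x_j\rangle / \|x_i -
#' x_j\|^2} is computed in closed form, and the pair with the smallest
#' residual wins (ties broken by library order; identical pair spectra get
#' \eqn{\alpha = 0.5} by convention). This is the reference baseline for
#' two-component mixtures under the same linear mixing assumption as the
#' gas phase.
#'
#' @inheritParams fit_ls
#' @return A `pair_interpolation`: `pair` (two ids), `alpha` (weight of
#'   the first id), `residual_sse`, plus `alpha_by` naming the pair member
#'   `alpha` applies to.
#' @export
pairwise_interpolation <- function(y, basis) {
  basis <- basis_set(basis)
  stopifnot(inherits(y, "ir_spectrum"))
  if (!grids_identical(y$grid, basis$grid))
    stop("mixture and basis are on incompatible grids", call. = FALSE)
  m <- length(basis$ids)
  if (m < 2)
    stop("pairwise interpolation needs a basis with at least 2 entries",
         call. = FALSE)
  yv <- y$intensities
  G <- attr(basis, "gram")
  if (is.null(G)) G <- crossprod(basis$X)
  xty <- drop(crossprod(basis$X, yv))
  yty <- sum(yv^2)
  ij <- utils::combn(m, 2)         # column-major pair order = library order
  i <- ij[1, ]; j <- ij[2, ]
  Gii <- diag(G)[i]; Gjj <- diag(G)[j]; Gij <- G[cbind(i, j)]
  denom <- Gii - 2 * Gij + Gjj     # ||x_i - x_j||^2
  num <- xty[i] - xty[j] - Gij + Gjj
  alpha <- ifelse(denom <= 0, 0.5, pmin(1, pmax(0, num / denom)))
  # ||y - a x_i - (1-a) x_j||^2 via the Gram expansion
  resid <- yty - 2 * alpha * xty[i] - 2 * (1 - alpha) * xty[j] +
    alpha^2 * Gii + 2 * alpha * (1 - alpha) * Gij + (1 - alpha)^2 * Gjj
  best <- which.min(resid)         # first minimum -> library-order ties
  structure(list(pair = basis$ids[c(i[best], j[best])],
                 alpha = unname(alpha[best]),
                 alpha_by = basis$ids[i[best]],
                 residual_sse = unname(max(0, resid[best]))),
            class = "pair_interpolation")
}

#' @export
print.pair_interpolation <- function(x, ...) {
  cat(sprintf("<pair_interpolation> %s (%.3f) + %s (%.3f), SSE %.4g\n",
              x$pair[1], x$alpha, x$pair[2], 1 - x$alpha, x$residual_sse))
  invisible(x)
}
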