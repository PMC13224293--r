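#' Cumulative reconstruction trace of a deconvolved mixture
#'
#' Starting from a zero-intensity spectrum, basis components are added in
#' descending order of their (absolute) fitted coefficients, each scaled
#' by its coefficient. After each addition the partial reconstruction
#' \eqn{\hat y} is compared to the target \eqn{y} by three metrics:
#' \itemize{
#'   \item cumulative explained variance \eqn{R^2 = 1 - \sum_\nu (y -
#'     \hat y)^2 / \sum_\nu (y - \bar y)^2}, with \eqn{\bar y} the mean
#'     intensity of the target over the grid;
#'   \item cumulative MSE between \eqn{\hat y} and \eqn{y};
#'   \item signed mean difference between the running cumulative-intensity
#'     curves of \eqn{y} and \eqn{\hat y} (partial reconstructions are not
#'     unit-area, so plain running integrals are compared).
#' }
#' The trace is the basis of component-count inference: once all real
#' components are included, \eqn{R^2} plateaus.
#'
#' @param y the target mixture `ir_spectrum`.
#' @param result an `unmix_result` computed for `y` against `basis`.
#' @param basis the [basis_set()] / [ir_library()] used for the fit.
#' @param max_steps cap on trace length; `NULL` = all nonzero
#'   coefficients.
#' @return A `reconstruction_trace` data frame with columns `step`,
#'   `component`, `coefficient`, `r2`, `mse`, `avg_cdf_diff`, plus
#'   attributes `r2_empty` (the step-0 baseline at \eqn{\hat y = 0}) and
#'   `target_sse`.
#' @export
reconstruction_trace <- function(y, result, basis, max_steps = NULL) {
  basis <- basis_set(basis)
  stopifnot(inherits(y, "ir_spectrum"), inherits(result, "unmix_result"))
  if (!grids_identical(y$grid, basis$grid))
    stop("target and basis are on incompatible grids", call. = FALSE)
  if (!identical(sort(names(result$coefficients)), sort(basis$ids)))
    stop("`result` was not computed against `basis`", call. = FALSE)
  co <- result$coefficients[basis$ids]
  ord <- order(-abs(co))
  ord <- ord[abs(co[ord]) > 0]
  if (!is.null(max_steps)) ord <- utils::head(ord, max_steps)
  yv <- y$intensities
  step_cm <- y$grid$step
  ss_tot <- sum((yv - mean(yv))^2)
  yhat <- numeric(length(yv))
  rows <- vector("list", length(ord))
  for (s in seq_along(ord)) {
    j <- ord[s]
    yhat <- yhat + co[j] * basis$X[, j]
    rows[[s]] <- data.frame(
      step = s, component = basis$ids[j], coefficient = unname(co[j]),
      r2 = 1 - sum((yv - yhat)^2) / ss_tot,
      mse = mean((yv - yhat)^2),
      avg_cdf_diff = mean(cumsum(yv) * step_cm - cumsum(yhat) * step_cm),
      stringsAsFactors = FALSE)
  }
  tr <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(0), component = character(0),
               coefficient = numeric(0), r2 = numeric(0), mse = numeric(0),
               avg_cdf_diff = numeric(0))
  attr(tr, "r2_empty") <- 1 - sum(yv^2) / ss_tot
  attr(tr, "target_sse") <- ss_tot
  class(tr) <- c("reconstruction_trace", "data.frame")
  tr
}

#' Infer the number of mixture components from a reconstruction trace
#'
#' Reads the plateau of the cumulative explained-variance curve: the
#' inferred count is the smallest n for which the R-squared increment
#' contributed by step n+1 falls below `increment_threshold`. If every
#' increment stays at or above the threshold the full trace length is
#' returned. Increments are measured against the previous step (step 1
#' against the empty-reconstruction baseline).
#'
#' @param trace a [reconstruction_trace()].
#' @param increment_threshold minimum R-squared gain for a step to count
#'   as a real component (default 0.01, i.e. 1 percentage point).
#' @return Integer component count >= 1 (0 for an empty trace).
#' @export
infer_component_count <- function(trace, increment_threshold = 0.01) {
  stopifnot(inherits(trace, "reconstruction_trace"))
  n_steps <- nrow(trace)
  if (n_steps == 0) return(0L)
  r2 <- c(attr(trace, "r2_empty"), trace$r2)
  inc <- diff(r2)                       # inc[s] = gain of step s
  for (n in seq_len(n_steps - 1)) {
    if (inc[n + 1] < increment_threshold) return(n)
  }
  n_steps
}

#' Leave-one-out component importance
#'
#' Quantifies how much a single basis component matters for explaining a
#' mixture spectrum: the basis is refit without it, and the degradation of
#' the full reconstruction \eqn{\hat y = X c} is reported as the drop in
#' \eqn{R^2} and the corresponding increases in MSE and mean
#' cumulative-curve difference (absolute). A removed component with a zero
#' coefficient leaves all three deltas at zero; removing one of several
#' spectrally degenerate duplicates also leaves them near zero, which is
#' exactly the ambiguity signal the metric is designed to expose.
#'
#' @param y the mixture `ir_spectrum`.
#' @param basis a [basis_set()] or [ir_library()].
#' @param id the component to remove.
#' @param algorithm `"nnls"` (default) or `"ls"`.
#' @param lambda ridge penalty passed to the fits.
#' @return Named numeric: `delta_r2`, `delta_mse`, `delta_avg_cdf`
#'   (positive = the component mattered), plus attribute `metrics` with
#'   the full- and reduced-basis values.
#' @export
leave_one_out_importance <- function(y, basis, id,
                                     algorithm = c("nnls", "ls"),
                                     lambda = 0) {
  algorithm <- match.arg(algorithm)
  basis <- basis_set(basis)
  if (!(id %in% basis$ids))
    stop(sprintf("unknown component id '%s'", id), call. = FALSE)
  fitf <- if (algorithm == "nnls") fit_nnls else fit_ls
  keep <- setdiff(basis$ids, id)
  sub <- structure(list(ids = keep, grid = basis$grid,
                        X = basis$X[, keep, drop = FALSE]),
                   class = "basis_set")
  full <- reconstruction_metrics(y, fitf(y, basis, lambda), basis)
  red <- reconstruction_metrics(y, fitf(y, sub, lambda), sub)
  out <- c(delta_r2 = full["r2"] - red["r2"],
           delta_mse = red["mse"] - full["mse"],
           delta_avg_cdf = red["avg_cdf"] - full["avg_cdf"])
  names(out) <- c("delta_r2", "delta_mse", "delta_avg_cdf")
  attr(out, "metrics") <- rbind(full = full, reduced = red)
  out
}

# R^2 / MSE / |mean cumulative gap| of the full fitted reconstruction.
reconstruction_metrics <- function(y, result, basis) {
  yv <- y$intensities
  yhat <- drop(basis$X %*% result$coefficients[basis$ids])
  step_cm <- y$grid$step
  c(r2 = 1 - sum((yv - yhat)^2) / sum((yv - mean(yv))^2),
    mse = mean((yv - yhat)^2),
    avg_cdf = mean(abs(cumsum(yv) - cumsum(yhat))) * step_cm)
}
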