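#' Rigidly shift a spectrum by a random-signed amount
#'
#' Emulates peak-position perturbations (e.g. matrix effects or
#' calibration drift): the whole spectrum is translated by \eqn{\delta}
#' cm^-1 with \eqn{|\delta|} = `magnitude` and random sign, realized
#' on-grid by rounding \eqn{\delta}/step bins; vacated bins are
#' zero-filled and the result is renormalized (shifting mass off the grid
#' edge would otherwise lose area).
#'
#' @param spec a normalized `ir_spectrum`.
#' @param magnitude shift magnitude in cm^-1, >= 0; must not exceed half
#'   the grid span.
#' @param seed integer seed for the sign draw, or `NULL` to use the
#'   current RNG state.
#' @param sign force `+1` / `-1` instead of a random sign.
#' @return A normalized, shifted `ir_spectrum` with attribute
#'   `shift_cm1` (the signed realized shift).
#' @export
apply_random_shift <- function(spec, magnitude, seed = NULL, sign = NULL) {
  stopifnot(inherits(spec, "ir_spectrum"))
  if (!is.numeric(magnitude) || length(magnitude) != 1 || magnitude < 0)
    stop("`magnitude` must be a single non-negative number", call. = FALSE)
  if (magnitude > grid_span(spec$grid) / 2)
    stop("shift magnitude exceeds half the grid span", call. = FALSE)
  if (is.null(sign)) {
    sgn <- if (is.null(seed)) {
      if (stats::runif(1) < 0.5) -1 else 1
    } else with_seed(seed, if (stats::runif(1) < 0.5) -1 else 1)
  } else {
    sgn <- base::sign(sign)
    if (sgn == 0) sgn <- 1
  }
  delta <- sgn * magnitude
  bins <- round(delta / spec$grid$step)
  y <- spec$intensities
  n <- length(y)
  out <- numeric(n)
  if (bins >= 0) {
    if (bins < n) out[(bins + 1):n] <- y[seq_len(n - bins)]
  } else {
    if (-bins < n) out[seq_len(n + bins)] <- y[(1 - bins):n]
  }
  if (spec$normalized) {
    area <- sum(out) * spec$grid$step
    if (area <= 0)
      stop("shift moved all intensity off the grid", call. = FALSE)
    out <- out / area
  }
  res <- ir_spectrum(spec$grid, out, normalized = spec$normalized)
  attr(res, "shift_cm1") <- bins * spec$grid$step
  res
}

#' Identification accuracy versus peak-shift magnitude
#'
#' For each shift magnitude, every mixture is rebuilt as the
#' fraction-weighted sum of its true components' pure spectra after each
#' has been independently and rigidly shifted (random sign, fixed
#' magnitude), while the identification basis keeps the unshifted library
#' spectra. Exact top-k accuracy is recorded per magnitude; at magnitude 0
#' the curve reproduces the unperturbed benchmark accuracy for the same
#' seed exactly.
#'
#' @param mixtures list of [mixture_record()]s (their `true_components`
#'   and `mole_fractions` define the rebuilds; their stored spectra are
#'   ignored).
#' @param library an [ir_library()] providing the unshifted pure spectra.
#' @param algorithm deconvolution algorithm (see
#'   [run_distractor_benchmark()]).
#' @param magnitudes non-negative shift magnitudes in cm^-1, sorted.
#' @param seed master seed for the sign draws.
#' @param k top-k cutoff; `NULL` = each mixture's true size.
#' @param basis_ids optional basis subset; default: the whole library.
#' @param lambda ridge penalty.
#' @return Data frame with columns `magnitude`, `accuracy`,
#'   `n_mixtures`, `n_unconverged`.
#' @export
shift_robustness_curve <- function(mixtures, library, algorithm = "nnls",
                                   magnitudes = c(0, 2, 4, 8, 16, 32),
                                   seed = 1, k = NULL, basis_ids = NULL,
                                   lambda = 0) {
  algorithm <- match.arg(algorithm, unmix_algorithms)
  stopifnot(all(magnitudes >= 0), !is.unsorted(magnitudes))
  basis <- with_gram(basis_set(library, basis_ids))
  rows <- vector("list", length(magnitudes))
  for (gi in seq_along(magnitudes)) {
    mag <- magnitudes[gi]
    correct <- 0L
    n_unconv <- 0L
    for (mi in seq_along(mixtures)) {
      m <- mixtures[[mi]]
      mix <- with_seed(derive_rng(seed, gi * 100003L + mi), {
        acc <- numeric(library$grid$n_points)
        for (ci in seq_along(m$true_components)) {
          pure <- library_entry(library, m$true_components[ci])$spectrum
          shifted <- if (mag > 0)
            apply_random_shift(pure, mag) else pure
          acc <- acc + m$mole_fractions[ci] * shifted$intensities
        }
        area <- sum(acc) * library$grid$step
        ir_spectrum(library$grid, acc / area, normalized = TRUE)
      })
      pred <- identify_components(mix, basis, algorithm, lambda)
      kk <- if (is.null(k)) length(m$true_components) else k
      if (!pred$converged) n_unconv <- n_unconv + 1L
      if (evaluate_exact(pred, m$true_components, kk))
        correct <- correct + 1L
    }
    rows[[gi]] <- data.frame(magnitude = mag,
                             accuracy = correct / length(mixtures),
                             n_mixtures = length(mixtures),
                             n_unconverged = n_unconv)
  }
  do.call(rbind, rows)
}

#' Nearest spectral neighbours of a library component
#'
#' Ranks all other library spectra by spectral distance (MSE) to the
#' query, ascending; spectrally degenerate molecules (near-identical
#' spectra) surface at the top, which is what bounds achievable
#' identification accuracy.
#'
#' @param query_id a library component id.
#' @param library an [ir_library()].
#' @param m number of neighbours to return.
#' @return Data frame `id`, `spectral_mse`, ascending, ties by library
#'   order.
#' @export
nearest_spectral_neighbors <- function(query_id, library, m = 3) {
  stopifnot(inherits(library, "ir_library"), m >= 1)
  ids <- library_ids(library)
  if (!(query_id %in% ids))
    stop(sprintf("unknown component id '%s'", query_id), call. = FALSE)
  q <- library_entry(library, query_id)$spectrum
  others <- setdiff(ids, query_id)
  mse <- vapply(others, function(id)
    spectral_mse(q, library_entry(library, id)$spectrum), numeric(1))
  ord <- order(mse)                 # stable: ties keep library order
  utils::head(data.frame(id = others[ord], spectral_mse = mse[ord],
                         row.names = NULL, stringsAsFactors = FALSE), m)
}

#' Aggregate misidentification categories over a benchmark report
#'
#' For every failed mixture in a report (run with `keep_predictions =
#' TRUE`), the true components missing from the top-k are paired to the
#' false-positive candidates by minimal spectral MSE (greedy, closest pair
#' first); each pair is classified with
#' [classify_misidentification()]; a mixture whose pairs span two or more
#' of the named categories (isomer, substitution, carbon_difference) is
#' labelled `mixed`. Percentages are reported over failed mixtures.
#'
#' @param report a `benchmark_report` carrying predictions.
#' @param library the [ir_library()] with spectra and formulas.
#' @param h_tolerance passed to [classify_misidentification()].
#' @return A `misid_profile`: `$percentages` (named, summing to 100 over
#'   failed mixtures, empty if none failed), `$n_failed`, `$pairs` (one
#'   row per true/false pair with its category and spectral MSE).
#' @export
profile_misidentifications <- function(report, library, h_tolerance = 0) {
  stopifnot(inherits(report, "benchmark_report"))
  if (is.null(report$predictions))
    stop("report has no predictions; rerun with keep_predictions = TRUE",
         call. = FALSE)
  formulas <- library_formulas(library)
  pair_rows <- list()
  mixture_labels <- character(0)
  for (p in report$predictions) {
    if (isTRUE(p$correct)) next
    if (!p$converged) {
      # unidentifiable, no candidate pairs to attribute
      mixture_labels <- c(mixture_labels, "other")
      next
    }
    missed <- setdiff(p$truth, p$top_k)
    false_pos <- setdiff(p$top_k, p$truth)
    cats <- character(0)
    while (length(missed) && length(false_pos)) {
      d <- outer(missed, false_pos, Vectorize(function(a, b)
        spectral_mse(library_entry(library, a)$spectrum,
                     library_entry(library, b)$spectrum)))
      hit <- which(d == min(d), arr.ind = TRUE)[1, ]
      tru <- missed[hit[1]]; fp <- false_pos[hit[2]]
      cat_pair <- classify_misidentification(formulas[[tru]],
                                             formulas[[fp]],
                                             h_tolerance = h_tolerance)
      cats <- c(cats, cat_pair)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        mixture_id = p$mixture_id, true_id = tru, predicted_id = fp,
        category = cat_pair, spectral_mse = d[hit[1], hit[2]],
        stringsAsFactors = FALSE)
      missed <- missed[-hit[1]]
      false_pos <- false_pos[-hit[2]]
    }
    named <- intersect(unique(cats),
                       c("isomer", "substitution", "carbon_difference"))
    label <- if (length(named) >= 2) "mixed"
      else if (length(named) == 1) named
      else "other"
    mixture_labels <- c(mixture_labels, label)
  }
  lv <- c("isomer", "substitution", "carbon_difference", "mixed", "other")
  pct <- if (length(mixture_labels))
    100 * table(factor(mixture_labels, levels = lv)) /
      length(mixture_labels)
  else table(factor(character(0), levels = lv))
  structure(list(
    percentages = stats::setNames(as.numeric(pct), lv),
    n_failed = length(mixture_labels),
    pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else
      data.frame(mixture_id = character(0), true_id = character(0),
                 predicted_id = character(0), category = character(0),
                 spectral_mse = numeric(0))),
    class = "misid_profile")
}

#' @export
print.misid_profile <- function(x, ...) {
  cat(sprintf("<misid_profile> %d failed mixtures\n", x$n_failed))
  if (x$n_failed > 0)
    print(round(x$percentages, 1))
  invisible(x)
}
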