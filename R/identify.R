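#' Rank basis components by coefficient magnitude
#'
#' Converts an [fit_nnls()] / [fit_ls()] result (or a
#' [pairwise_interpolation()] result) into a prediction: component ids
#' ranked in descending order of the absolute value of their
#' coefficients, ties broken by basis order for determinism.
#'
#' @param result an `unmix_result` or `pair_interpolation`.
#' @return A `prediction`: `ranked_ids`, `coefficients` (in ranked
#'   order), `converged`.
#' @export
rank_candidates <- function(result) {
  if (inherits(result, "pair_interpolation")) {
    co <- c(result$alpha, 1 - result$alpha)
    names(co) <- result$pair
    ord <- order(-abs(co))
    return(structure(list(ranked_ids = names(co)[ord],
                          coefficients = co[ord], converged = TRUE),
                     class = "prediction"))
  }
  stopifnot(inherits(result, "unmix_result"))
  co <- result$coefficients
  ord <- order(-abs(co))            # stable: ties keep basis order
  structure(list(ranked_ids = names(co)[ord], coefficients = co[ord],
                 converged = result$converged),
            class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat("<prediction>", if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  print(utils::head(x$coefficients, 5))
  invisible(x)
}

#' Top-k identification criteria
#'
#' `evaluate_exact()` is the strict criterion: every true component must
#' appear within the top k ranked candidates. `evaluate_any()` requires at
#' least one. A prediction flagged unconverged is always counted as
#' incorrect under both criteria.
#'
#' @param prediction a `prediction` from [rank_candidates()].
#' @param truth character vector of true component ids.
#' @param k number of top candidates considered.
#' @return Logical scalar.
#' @export
evaluate_exact <- function(prediction, truth, k) {
  stopifnot(inherits(prediction, "prediction"), k >= 1)
  if (!prediction$converged) return(FALSE)
  top <- utils::head(prediction$ranked_ids, k)
  all(truth %in% top)
}

#' @rdname evaluate_exact
#' @export
evaluate_any <- function(prediction, truth, k) {
  stopifnot(inherits(prediction, "prediction"), k >= 1)
  if (!prediction$converged) return(FALSE)
  top <- utils::head(prediction$ranked_ids, k)
  any(truth %in% top)
}

#' Atom-composition filter on ranked candidates
#'
#' When the element composition of a mixture is known (e.g. from
#' elemental analysis or mass spectrometry), candidate combinations whose
#' pooled elements cannot reproduce it are pruned. Size-k combinations
#' from the top-`pool_size` candidates are scanned in descending
#' joint-|coefficient| order; the first combination whose union of element
#' sets equals the mixture's element set becomes the new top k (remaining
#' candidates keep their relative order). If no combination in the pool
#' qualifies, the unfiltered prediction is returned with attribute
#' `filter_fallback = TRUE`.
#'
#' With `mode = "count"` combinations must additionally match exact atom
#' counts (requires `mixture_elements` to be a `mol_formula` of the pooled
#' composition at known mole ratios); the default set mode uses only
#' element presence/absence.
#'
#' @param prediction a `prediction`.
#' @param mixture_elements character vector of element symbols present in
#'   the mixture, or (for `mode = "count"`) a `mol_formula`.
#' @param formulas named character vector (or list of `mol_formula`)
#'   mapping component ids to formulas, e.g. [library_formulas()].
#' @param k combination size (the known/assumed number of components).
#' @param pool_size how deep into the ranking combinations are drawn from.
#' @param mode `"set"` (element presence) or `"count"` (exact counts).
#' @return A `prediction` whose first k ids satisfy the filter when
#'   possible.
#' @export
atom_filter <- function(prediction, mixture_elements, formulas, k,
                        pool_size = 10, mode = c("set", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(prediction, "prediction"), k >= 1)
  pool <- utils::head(prediction$ranked_ids, pool_size)
  if (length(pool) < k) return(prediction)
  fml <- formulas[pool]
  if (any(vapply(fml, function(f) is.null(f) || (is.character(f) && is.na(f)),
                 logical(1))))
    stop("atom_filter requires a formula for every pooled candidate",
         call. = FALSE)
  parsed <- lapply(fml, as_formula)
  co <- abs(prediction$coefficients)
  names(co) <- prediction$ranked_ids
  combos <- utils::combn(pool, k, simplify = FALSE)
  joint <- vapply(combos, function(cc) sum(co[cc]), numeric(1))
  ord <- order(-joint)
  target_set <- if (inherits(mixture_elements, "mol_formula"))
    sort(names(mixture_elements)) else sort(as.character(mixture_elements))
  for (ci in ord) {
    cc <- combos[[ci]]
    if (mode == "set") {
      elems <- sort(unique(unlist(lapply(parsed[cc], names))))
      ok <- identical(elems, target_set)
    } else {
      if (!inherits(mixture_elements, "mol_formula"))
        stop("mode = \"count\" needs `mixture_elements` as a mol_formula",
             call. = FALSE)
      tot <- Reduce(function(acc, f) {
        syms <- union(names(acc), names(f))
        out <- ifelse(syms %in% names(acc), acc[syms], 0L) +
          ifelse(syms %in% names(f), f[syms], 0L)
        names(out) <- syms
        out
      }, parsed[cc], integer(0))
      syms <- union(names(tot), names(mixture_elements))
      ok <- all(ifelse(syms %in% names(tot), tot[syms], 0L) ==
                  ifelse(syms %in% names(mixture_elements),
                         mixture_elements[syms], 0L))
    }
    if (ok) {
      rest <- setdiff(prediction$ranked_ids, cc)
      new_ids <- c(cc, rest)
      out <- prediction
      out$ranked_ids <- new_ids
      out$coefficients <- prediction$coefficients[
        match(new_ids, prediction$ranked_ids)]
      names(out$coefficients) <- new_ids
      attr(out, "filter_fallback") <- FALSE
      return(out)
    }
  }
  attr(prediction, "filter_fallback") <- TRUE
  warning("no atom-compatible candidate combination in the pool; ",
          "returning the unfiltered prediction", call. = FALSE)
  prediction
}

# Fit one mixture with the configured algorithm and rank the result.
identify_components <- function(y, basis, algorithm = "nnls", lambda = 0,
                                max_iter = NULL) {
  res <- switch(
    algorithm,
    "nnls" = fit_nnls(y, basis, lambda = 0, max_iter = max_iter),
    "ls" = fit_ls(y, basis, lambda = 0),
    "nnls-ridge" = fit_nnls(y, basis, lambda = lambda, max_iter = max_iter),
    "ls-ridge" = fit_ls(y, basis, lambda = lambda),
    "pairwise" = pairwise_interpolation(y, basis),
    stop(sprintf("unknown algorithm '%s'", algorithm), call. = FALSE)
  )
  rank_candidates(res)
}

unmix_algorithms <- c("ls", "nnls", "ls-ridge", "nnls-ridge", "pairwise")

#' Distractor-protocol identification benchmark
#'
#' The standard benchmark: for each repeat, the basis set contains the
#' pure spectra of every component occurring in any mixture plus an equal
#' number of "distractor" spectra of molecules in none of them, sampled
#' without replacement with a repeat-specific seed. Each mixture is
#' deconvolved against this basis and scored with the exact top-k
#' criterion at k = its true component count (unless `k` is given).
#' Reported accuracy is the mean over repeats, with its standard
#' deviation.
#'
#' @param mixtures list of [mixture_record()]s.
#' @param library an [ir_library()] containing all true components and at
#'   least as many other spectra as distractors requested.
#' @param algorithm one of `"nnls"`, `"ls"`, `"nnls-ridge"`, `"ls-ridge"`,
#'   `"pairwise"`.
#' @param k top-k cutoff; `NULL` uses each mixture's true size.
#' @param n_repeats distractor resampling repeats (default 8).
#' @param seed master seed; every repeat derives its own stream.
#' @param lambda ridge penalty for the ridge variants.
#' @param n_distractors distractors per repeat; `NULL` = as many as there
#'   are distinct true components (equal-size protocol). 0 is allowed for
#'   reduced, truth-only bases.
#' @param keep_predictions retain per-mixture ranked predictions (needed
#'   by [profile_misidentifications()]).
#' @return A `benchmark_report` with `$records` (one row per repeat) and
#'   `$accuracy_mean`, `$accuracy_sd`.
#' @export
run_distractor_benchmark <- function(mixtures, library, algorithm = "nnls",
                                     k = NULL, n_repeats = 8, seed = 1,
                                     lambda = 0, n_distractors = NULL,
                                     keep_predictions = FALSE) {
  algorithm <- match.arg(algorithm, unmix_algorithms)
  stopifnot(is.list(mixtures), length(mixtures) > 0,
            inherits(library, "ir_library"))
  truth_ids <- sort(unique(unlist(lapply(mixtures,
                                         function(m) m$true_components))))
  all_ids <- library_ids(library)
  if (!all(truth_ids %in% all_ids))
    stop("library is missing true components", call. = FALSE)
  others <- setdiff(all_ids, truth_ids)
  if (is.null(n_distractors)) n_distractors <- length(truth_ids)
  if (n_distractors > length(others))
    stop(sprintf(
      "library has %d non-component spectra but %d distractors requested",
      length(others), n_distractors), call. = FALSE)

  records <- vector("list", n_repeats)
  predictions <- if (keep_predictions) list() else NULL
  for (r in seq_len(n_repeats)) {
    rng <- derive_rng(seed, r)
    distractors <- if (n_distractors > 0)
      sample_with_rng(rng, others, n_distractors) else character(0)
    basis_ids <- c(truth_ids, distractors)
    basis <- with_gram(basis_set(library, basis_ids))
    correct <- 0L
    n_unconv <- 0L
    for (m in mixtures) {
      pred <- identify_components(m$spectrum, basis, algorithm, lambda)
      kk <- if (is.null(k)) length(m$true_components) else k
      if (!pred$converged) n_unconv <- n_unconv + 1L
      hit <- evaluate_exact(pred, m$true_components, kk)
      if (hit) correct <- correct + 1L
      if (keep_predictions)
        predictions[[length(predictions) + 1L]] <- list(
          repeat_index = r, mixture_id = m$id,
          truth = m$true_components, k = kk,
          top_k = utils::head(pred$ranked_ids, kk),
          converged = pred$converged, correct = hit)
    }
    records[[r]] <- data.frame(
      repeat_index = r, criterion = "exact",
      k = if (is.null(k)) NA_integer_ else as.integer(k),
      basis_size = length(basis_ids),
      accuracy = correct / length(mixtures),
      n_mixtures = length(mixtures), n_unconverged = n_unconv,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, records)
  structure(list(protocol = "distractor", algorithm = algorithm,
                 records = records,
                 accuracy_mean = mean(records$accuracy),
                 accuracy_sd = stats::sd(records$accuracy),
                 seed = seed, predictions = predictions),
            class = "benchmark_report")
}

#' Nested basis-size sweep benchmark
#'
#' Accuracy as a function of basis-set size under nested growth: the
#' smallest basis is exactly the union of all mixtures' true components;
#' each larger size adds further library spectra in a seeded random order,
#' so every basis contains all smaller ones. Accuracy is recorded for each
#' (size, criterion, k) combination; unconverged fits count as incorrect
#' and are tallied.
#'
#' @inheritParams run_distractor_benchmark
#' @param sizes increasing basis sizes; the first must be >= the number of
#'   distinct true components (it is padded up to that union if equal).
#' @param criteria subset of `c("exact", "any")`.
#' @param k_values top-k cutoffs to evaluate.
#' @return A `benchmark_report` with one record per (size, criterion, k).
#' @export
run_basis_sweep <- function(mixtures, library, algorithm = "nnls",
                            sizes, criteria = c("exact", "any"),
                            k_values = 2, seed = 1, lambda = 0,
                            keep_predictions = FALSE) {
  algorithm <- match.arg(algorithm, unmix_algorithms)
  criteria <- match.arg(criteria, c("exact", "any"), several.ok = TRUE)
  truth_ids <- sort(unique(unlist(lapply(mixtures,
                                         function(m) m$true_components))))
  all_ids <- library_ids(library)
  if (!all(truth_ids %in% all_ids))
    stop("library is missing true components", call. = FALSE)
  sizes <- sort(unique(as.integer(sizes)))
  if (sizes[1] < length(truth_ids))
    stop(sprintf("smallest size %d < %d distinct true components",
                 sizes[1], length(truth_ids)), call. = FALSE)
  if (max(sizes) > length(all_ids))
    stop("largest size exceeds the library", call. = FALSE)
  rng <- derive_rng(seed, 0)
  growth <- sample_with_rng(rng, setdiff(all_ids, truth_ids),
                            length(all_ids) - length(truth_ids))
  full_order <- c(truth_ids, growth)   # nested prefixes

  records <- list()
  predictions <- if (keep_predictions) list() else NULL
  for (size in sizes) {
    basis_ids <- full_order[seq_len(size)]
    basis <- with_gram(basis_set(library, basis_ids))
    preds <- lapply(mixtures, function(m)
      identify_components(m$spectrum, basis, algorithm, lambda))
    n_unconv <- sum(!vapply(preds, function(p) p$converged, logical(1)))
    for (crit in criteria) {
      evalf <- if (crit == "exact") evaluate_exact else evaluate_any
      for (kk in k_values) {
        hits <- mapply(function(p, m) evalf(p, m$true_components, kk),
                       preds, mixtures)
        records[[length(records) + 1L]] <- data.frame(
          repeat_index = 1L, criterion = crit, k = as.integer(kk),
          basis_size = size, accuracy = mean(hits),
          n_mixtures = length(mixtures), n_unconverged = n_unconv,
          stringsAsFactors = FALSE)
      }
    }
    if (keep_predictions)
      for (mi in seq_along(mixtures)) {
        m <- mixtures[[mi]]
        predictions[[length(predictions) + 1L]] <- list(
          repeat_index = 1L, mixture_id = m$id, basis_size = size,
          truth = m$true_components, k = min(k_values),
          top_k = utils::head(preds[[mi]]$ranked_ids, min(k_values)),
          converged = preds[[mi]]$converged,
          correct = evaluate_exact(preds[[mi]], m$true_components,
                                   min(k_values)))
      }
  }
  records <- do.call(rbind, records)
  structure(list(protocol = "sweep", algorithm = algorithm,
                 records = records, seed = seed,
                 predictions = predictions),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> protocol=%s algorithm=%s\n",
              x$protocol, x$algorithm))
  if (!is.null(x$accuracy_mean))
    cat(sprintf("  mean accuracy %.3f (sd %.3f) over %d repeats\n",
                x$accuracy_mean, x$accuracy_sd, nrow(x$records)))
  print(utils::head(x$records, 12))
  invisible(x)
}

# Seeded child generators: one independent L'Ecuyer-ish stream per
# (master seed, index) pair without touching the global .Random.seed.
derive_rng <- function(seed, index) {
  s <- (as.integer(seed) %% 1000003L) * 2654L + as.integer(index) * 97L
  s %% 2147483647L
}

# Draw `size` elements without replacement using an isolated RNG state.
sample_with_rng <- function(seed, x, size) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  x[sample.int(length(x), size)]
}

# Run a seeded block with the global RNG restored afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
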