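#' Spectral libraries of identified pure components
#'
#' An `ir_library` is the "basis set" for deconvolution: a set of
#' pure-component spectra, all on one shared grid and all unit-area, each
#' carrying an id, a human-readable name, a Hill-notation formula and a
#' phase label (`"gas"` or `"liquid"`).
#'
#' @param entries a list of entries, each a list with fields `id`, `name`,
#'   `formula` (may be `NA`), `phase`, and `spectrum` (a normalized
#'   [ir_spectrum()]).
#' @return An `ir_library`.
#' @export
ir_library <- function(entries) {
  if (!is.list(entries) || length(entries) < 1)
    stop("a library needs at least one entry", call. = FALSE)
  ids <- vapply(entries, function(e) as.character(e$id), character(1))
  if (anyDuplicated(ids))
    stop("library ids must be unique", call. = FALSE)
  g <- entries[[1]]$spectrum$grid
  for (e in entries) {
    if (!inherits(e$spectrum, "ir_spectrum"))
      stop("every entry needs an ir_spectrum", call. = FALSE)
    if (!grids_identical(e$spectrum$grid, g))
      stop("all library spectra must share one grid", call. = FALSE)
    if (!e$spectrum$normalized)
      stop(sprintf("library spectrum '%s' is not normalized", e$id),
           call. = FALSE)
  }
  structure(list(entries = entries, grid = g), class = "ir_library")
}

#' @export
print.ir_library <- function(x, ...) {
  ph <- table(vapply(x$entries, function(e) e$phase %||% NA_character_,
                     character(1)))
  cat(sprintf("<ir_library> %d spectra on %d-point grid (%s)\n",
              length(x$entries), x$grid$n_points,
              paste(sprintf("%s: %d", names(ph), ph), collapse = ", ")))
  invisible(x)
}

#' @export
length.ir_library <- function(x) length(x$entries)

#' @rdname ir_library
#' @param library an `ir_library`.
#' @export
library_ids <- function(library) {
  vapply(library$entries, function(e) as.character(e$id), character(1))
}

#' @rdname ir_library
#' @param id a component id.
#' @export
library_entry <- function(library, id) {
  i <- match(id, library_ids(library))
  if (is.na(i))
    stop(sprintf("unknown component id '%s'", id), call. = FALSE)
  library$entries[[i]]
}

#' @rdname ir_library
#' @param ids component ids to keep, in the given order.
#' @export
library_subset <- function(library, ids) {
  all_ids <- library_ids(library)
  i <- match(ids, all_ids)
  if (anyNA(i))
    stop(sprintf("unknown component id(s): %s",
                 paste(ids[is.na(i)], collapse = ", ")), call. = FALSE)
  ir_library(library$entries[i])
}

#' @rdname ir_library
#' @export
library_formulas <- function(library) {
  out <- vapply(library$entries, function(e) {
    f <- e$formula
    if (is.null(f) || is.na(f)) NA_character_ else as.character(f)
  }, character(1))
  names(out) <- library_ids(library)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Basis set for linear unmixing
#'
#' Packs a library (or a subset of it) into the dense matrix form the
#' solvers consume: one column of X per pure-component spectrum.
#'
#' @param library an [ir_library()].
#' @param ids optional ordered subset of component ids.
#' @return A `basis_set`: ids, grid and the n_points x n_components
#'   intensity matrix `X`.
#' @export
basis_set <- function(library, ids = NULL) {
  if (inherits(library, "basis_set") && is.null(ids)) return(library)
  stopifnot(inherits(library, "ir_library"))
  if (!is.null(ids)) library <- library_subset(library, ids)
  X <- vapply(library$entries, function(e) e$spectrum$intensities,
              numeric(library$grid$n_points))
  X <- matrix(X, nrow = library$grid$n_points)
  colnames(X) <- library_ids(library)
  structure(list(ids = library_ids(library), grid = library$grid, X = X),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %d components x %d grid points\n",
              length(x$ids), nrow(x$X)))
  invisible(x)
}

#' Mixture records
#'
#' Ground-truth container for benchmarking: the true component identities
#' and mole fractions together with the observed mixture spectrum.
#'
#' @param id mixture identifier.
#' @param true_components character vector of component ids (2 or 3 for
#'   the binary/ternary benchmarks, but any size >= 1 is accepted).
#' @param mole_fractions numeric, same length, summing to 1.
#' @param spectrum a normalized [ir_spectrum()].
#' @return A `mixture_record`.
#' @export
mixture_record <- function(id, true_components, mole_fractions, spectrum) {
  true_components <- as.character(true_components)
  mole_fractions <- as.numeric(mole_fractions)
  if (length(true_components) < 1)
    stop("a mixture needs at least one component", call. = FALSE)
  if (length(mole_fractions) != length(true_components))
    stop("`mole_fractions` must match `true_components`", call. = FALSE)
  if (abs(sum(mole_fractions) - 1) > 1e-9)
    stop("mole fractions must sum to 1", call. = FALSE)
  if (anyDuplicated(true_components))
    stop("duplicate true components", call. = FALSE)
  stopifnot(inherits(spectrum, "ir_spectrum"))
  structure(list(id = as.character(id), true_components = true_components,
                 mole_fractions = mole_fractions, spectrum = spectrum),
            class = "mixture_record")
}

#' @export
print.mixture_record <- function(x, ...) {
  cat(sprintf("<mixture_record> %s: %s\n", x$id,
              paste(sprintf("%s (%.3g)", x$true_components,
                            x$mole_fractions), collapse = " + ")))
  invisible(x)
}
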