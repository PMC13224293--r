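#' Parse a Hill-notation molecular formula
#'
#' Parses strings like `"C6H13N3"` or `"CH4"` into a named integer vector
#' of atom counts (class `mol_formula`). Element symbols are one capital
#' letter optionally followed by one lowercase letter; a missing count
#' means 1. Isotopes, charges and structural groups are not supported.
#'
#' @param text a single non-empty formula string.
#' @return Named integer vector of class `mol_formula`.
#' @examples
#' parse_formula("C4H10N2")
#' format_formula(parse_formula("H4C"))  # canonical Hill order: "CH4"
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(text))
    stop("`text` must be a single non-empty string", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || length(tokens) == 0)
    stop(sprintf("malformed formula: '%s'", text), call. = FALSE)
  syms <- sub("[0-9]*$", "", tokens)
  bad <- setdiff(syms, element_symbols)
  if (length(bad))
    stop(sprintf("unknown element symbol(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  counts <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(counts == "", 1L, suppressWarnings(as.integer(counts)))
  if (any(is.na(counts)) || any(counts < 1))
    stop(sprintf("malformed atom count in formula: '%s'", text),
         call. = FALSE)
  out <- tapply(counts, syms, sum)
  f <- as.integer(out)
  names(f) <- names(out)
  structure(f[order_hill(names(f))], class = "mol_formula")
}

# Hill order: C first, then H, then other elements alphabetically;
# without carbon, everything alphabetical.
order_hill <- function(syms) {
  if ("C" %in% syms) {
    rank <- match(syms, c("C", "H"))
    rank[is.na(rank)] <- 3
    order(rank, syms)
  } else {
    order(syms)
  }
}

#' @rdname parse_formula
#' @param f a `mol_formula`.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "mol_formula") || (is.numeric(f) && !is.null(names(f))))
  f <- f[order_hill(names(f))]
  paste0(names(f), ifelse(f == 1, "", f), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula>", format_formula(x), "\n")
  invisible(x)
}

# IUPAC element symbols (through organesson); enough to validate input.
element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi",
  "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am",
  "Cm", "Bk", "Cf", "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg",
  "Bh", "Hs", "Mt", "Ds", "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

as_formula <- function(x) {
  if (inherits(x, "mol_formula")) x else parse_formula(x)
}

#' Classify a true/false-positive formula pair
#'
#' Misidentified components fall into recurring chemical classes:
#' \describe{
#'   \item{isomer}{identical molecular formulas (structural isomers — the
#'     spectra belong to different connectivities of the same formula).}
#'   \item{substitution}{a single-atom substitution: one element has one
#'     atom fewer and another one atom more, all other counts equal.}
#'   \item{carbon_difference}{only the carbon count differs, by exactly
#'     one (with `h_tolerance = 0`, the default, hydrogens must match
#'     exactly too).}
#'   \item{other}{none of the above.}
#' }
#' The `mixed` label of aggregated profiles is assigned at mixture level
#' (see [profile_misidentifications()]), never to a single pair.
#'
#' @param true_f,pred_f `mol_formula` objects or formula strings.
#' @param h_tolerance allow the hydrogen count to differ by up to this
#'   much in the `carbon_difference` class (0 = strict reading; a CH2-unit
#'   homologue check would use 2).
#' @return One of `"isomer"`, `"substitution"`, `"carbon_difference"`,
#'   `"other"`.
#' @export
classify_misidentification <- function(true_f, pred_f, h_tolerance = 0) {
  a <- as_formula(true_f)
  b <- as_formula(pred_f)
  syms <- union(names(a), names(b))
  ca <- ifelse(syms %in% names(a), as.integer(a[syms]), 0L)
  cb <- ifelse(syms %in% names(b), as.integer(b[syms]), 0L)
  d <- cb - ca
  if (all(d == 0)) return("isomer")
  # single-atom substitution: exactly one +1 and one -1, rest equal
  if (sum(d != 0) == 2 && sum(d == 1) == 1 && sum(d == -1) == 1)
    return("substitution")
  # carbon difference of exactly one; optionally tolerate small H change
  dc <- d[syms == "C"]
  dh <- if ("H" %in% syms) d[syms == "H"] else 0L
  rest <- d[!(syms %in% c("C", "H"))]
  if (length(dc) == 1 && abs(dc) == 1 && all(rest == 0) &&
      abs(dh) <= h_tolerance)
    return("carbon_difference")
  "other"
}

#' Element set of a formula
#'
#' @param f a `mol_formula` or formula string.
#' @return Character vector of element symbols, sorted.
#' @export
formula_elements <- function(f) sort(names(as_formula(f)))
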