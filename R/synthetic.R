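#' Default style configuration for the synthetic spectrum generator
#'
#' Gas-like spectra are sums of a few sharp peaks (default 3--8 Gaussian
#' peaks of width 4--10 cm^-1, emulating rovibrational bands of
#' non-interacting molecules); the liquid-like transform of the same
#' molecule broadens every peak by a common factor (2--6x) and rigidly
#' shifts the band positions (uniform -30..+30 cm^-1, mimicking
#' intermolecular-interaction-driven red/blue shifts). Formulas are drawn
#' over C/H/N/O/S/Cl/Br; with probability `isomer_rate` a molecule reuses
#' an earlier molecule's formula exactly (a planted structural-isomer
#' trap), and with probability `substitution_rate` it copies an earlier
#' formula with one halogen/chalcogen swapped (a planted single-atom
#' substitution trap).
#'
#' @param ... overrides of the defaults listed below.
#' @return A named list of style parameters.
#' @export
synthetic_style <- function(...) {
  style <- list(
    n_peaks_range = c(3L, 8L),
    center_range = c(200, 3800),      # cm^-1, inside the default grid
    sigma_range = c(4, 10),           # cm^-1, sharp gas-phase widths
    height_range = c(0.2, 1),
    shape = "gaussian",
    liquid_broadening_range = c(2, 6),
    liquid_shift_range = c(-30, 30),  # cm^-1
    isomer_rate = 0.05,
    substitution_rate = 0.05,
    carbon_range = c(2L, 10L)
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(style))
  if (length(unknown))
    stop(sprintf("unknown style parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  style[names(ov)] <- ov
  if (any(style$sigma_range <= 0) || style$liquid_broadening_range[1] < 1)
    stop("invalid style ranges: sigma > 0 and broadening >= 1 required",
         call. = FALSE)
  style
}

#' Generate a seeded synthetic spectral library
#'
#' Builds `n_molecules` synthetic molecules (peak models + formulas, see
#' [synthetic_style()]) and their unit-area pure-component spectra in the
#' requested phase. Fully deterministic in `seed`; the molecule metadata
#' (peaks, liquid transform parameters, planted trap annotations) is
#' attached as attribute `"molecules"` so mixtures and the matching
#' other-phase library can be rebuilt.
#'
#' @param n_molecules number of molecules, >= 1.
#' @param grid target [ir_grid()].
#' @param style a [synthetic_style()] list.
#' @param seed integer seed.
#' @param phase `"gas"` or `"liquid"`.
#' @return An [ir_library()] with attribute `"molecules"`.
#' @export
generate_library <- function(n_molecules, grid = default_grid(),
                             style = synthetic_style(), seed = 1,
                             phase = c("gas", "liquid")) {
  phase <- match.arg(phase)
  stopifnot(n_molecules >= 1)
  nu_max <- grid$start + (grid$n_points - 1) * grid$step
  center_range <- c(max(style$center_range[1], grid$start),
                    min(style$center_range[2], nu_max))
  if (center_range[1] >= center_range[2])
    stop("style center_range does not intersect the grid", call. = FALSE)
  style$center_range <- center_range
  molecules <- with_seed(derive_rng(seed, 7L), {
    mols <- vector("list", n_molecules)
    for (i in seq_len(n_molecules)) {
      mols[[i]] <- make_synthetic_molecule(i, mols[seq_len(i - 1)], style)
    }
    mols
  })
  entries <- lapply(molecules, function(mol) {
    list(id = mol$id, name = mol$id, formula = format_formula(mol$formula),
         phase = phase,
         spectrum = build_molecule_spectrum(mol, phase, grid))
  })
  lib <- ir_library(entries)
  attr(lib, "molecules") <- molecules
  lib
}

# One synthetic molecule: peaks, liquid transform, formula (with traps).
make_synthetic_molecule <- function(i, previous, style) {
  n_peaks <- sample(style$n_peaks_range[1]:style$n_peaks_range[2], 1)
  peaks <- data.frame(
    center = stats::runif(n_peaks, style$center_range[1],
                          style$center_range[2]),
    sigma = stats::runif(n_peaks, style$sigma_range[1],
                         style$sigma_range[2]),
    height = stats::runif(n_peaks, style$height_range[1],
                          style$height_range[2]))
  liquid_shift <- stats::runif(1, style$liquid_shift_range[1],
                               style$liquid_shift_range[2])
  liquid_broadening <- stats::runif(1, style$liquid_broadening_range[1],
                                    style$liquid_broadening_range[2])
  u <- stats::runif(1)
  trap <- "none"
  if (length(previous) > 0 && u < style$isomer_rate) {
    src <- previous[[sample(length(previous), 1)]]
    formula <- src$formula
    trap <- paste0("isomer_of:", src$id)
  } else if (length(previous) > 0 &&
             u < style$isomer_rate + style$substitution_rate) {
    src <- previous[[sample(length(previous), 1)]]
    formula <- substitute_one_atom(src$formula)
    trap <- paste0("substitution_of:", src$id)
  } else {
    formula <- random_formula(style)
  }
  list(id = sprintf("mol%04d", i), formula = formula, peaks = peaks,
       shape = style$shape, liquid_shift = liquid_shift,
       liquid_broadening = liquid_broadening, trap = trap)
}

random_formula <- function(style) {
  nc <- sample(style$carbon_range[1]:style$carbon_range[2], 1)
  nh <- sample(max(1, nc):(2 * nc + 2), 1)
  counts <- c(C = nc, H = nh)
  for (el in c("N", "O")) {
    k <- sample(0:2, 1, prob = c(0.5, 0.3, 0.2))
    if (k > 0) counts[el] <- k
  }
  for (el in c("S", "Cl", "Br")) {
    if (stats::runif(1) < 0.12) counts[el] <- 1
  }
  structure(as.integer(counts)[order_hill(names(counts))],
            names = names(counts)[order_hill(names(counts))],
            class = "mol_formula")
}

# Swap one heteroatom for another element (Cl<->Br, O<->S, N<->O ...),
# producing a single-atom-substitution partner of `f`.
substitute_one_atom <- function(f) {
  swaps <- list(c("Cl", "Br"), c("Br", "Cl"), c("O", "S"), c("S", "O"),
                c("N", "O"), c("O", "N"), c("Cl", "F"), c("F", "Cl"))
  avail <- Filter(function(sw) sw[1] %in% names(f), swaps)
  if (!length(avail)) {
    # fall back: swap one H for F
    avail <- list(c("H", "F"))
    if (!("H" %in% names(f)) || f[["H"]] < 2) return(f)
  }
  sw <- avail[[sample(length(avail), 1)]]
  out <- as.integer(f)
  names(out) <- names(f)
  out[sw[1]] <- out[sw[1]] - 1L
  out <- out[out > 0]
  out[sw[2]] <- (if (sw[2] %in% names(out)) out[sw[2]] else 0L) + 1L
  structure(out[order_hill(names(out))], class = "mol_formula")
}

#' Build a molecule's pure spectrum in a given phase
#'
#' Evaluates the molecule's peak models on the grid: gas phase uses the
#' peaks as-is; liquid phase broadens every sigma by the molecule's
#' broadening factor and shifts every center by its global liquid shift.
#' The result is clipped and unit-area normalized.
#'
#' @param mol a molecule record from [generate_library()]'s `"molecules"`
#'   attribute.
#' @param phase `"gas"` or `"liquid"`.
#' @param grid an [ir_grid()].
#' @param center_offsets optional per-peak additive center offsets
#'   (cm^-1), e.g. for nonlinear mixing perturbations.
#' @param height_factors optional per-peak multiplicative intensity
#'   factors.
#' @return A normalized `ir_spectrum`.
#' @export
build_molecule_spectrum <- function(mol, phase, grid,
                                    center_offsets = 0,
                                    height_factors = 1) {
  pk <- mol$peaks
  centers <- pk$center + center_offsets
  sigmas <- pk$sigma
  heights <- pk$height * height_factors
  if (phase == "liquid") {
    centers <- centers + mol$liquid_shift
    sigmas <- sigmas * mol$liquid_broadening
  }
  nu <- grid_wavenumbers(grid)
  y <- numeric(length(nu))
  for (p in seq_len(nrow(pk))) {
    y <- y + if (identical(mol$shape, "lorentzian")) {
      heights[p] / (1 + ((nu - centers[p]) / sigmas[p])^2)
    } else {
      heights[p] * exp(-0.5 * ((nu - centers[p]) / sigmas[p])^2)
    }
  }
  preprocess_spectrum(ir_spectrum(grid, y), smooth_sigma = 0,
                      clip = TRUE, normalize = TRUE)
}

#' Compose a mixture spectrum from library components
#'
#' With zero nonlinearity the mixture is exactly the mole-fraction
#' weighted sum of the stored pure spectra — the linear regime of
#' non-interacting (gas-phase) molecules, and the model every linear
#' unmixing algorithm assumes. Nonzero `shift_sd` rigidly shifts each
#' component's bands by an independent normal draw and `jitter_sd`
#' perturbs individual peak intensities before summation (then
#' renormalization), emulating the interaction-driven nonlinear mixing of
#' the liquid phase.
#'
#' @param library an [ir_library()] from [generate_library()] (molecule
#'   metadata required when nonlinearity is nonzero).
#' @param components character vector of component ids.
#' @param fractions mole fractions summing to 1 (default equimolar).
#' @param nonlinearity list with `shift_sd` and `jitter_sd` (both default
#'   0; cm^-1 and relative units).
#' @param seed integer seed for the nonlinear draws.
#' @param id mixture id.
#' @return A [mixture_record()].
#' @export
make_mixture <- function(library, components,
                         fractions = NULL,
                         nonlinearity = list(shift_sd = 0, jitter_sd = 0),
                         seed = 1, id = NULL) {
  stopifnot(inherits(library, "ir_library"))
  components <- as.character(components)
  if (is.null(fractions))
    fractions <- rep(1 / length(components), length(components))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  if (length(fractions) != length(components))
    stop("`fractions` must match `components`", call. = FALSE)
  shift_sd <- nonlinearity$shift_sd %||% 0
  jitter_sd <- nonlinearity$jitter_sd %||% 0
  grid <- library$grid
  if (shift_sd == 0 && jitter_sd == 0) {
    acc <- numeric(grid$n_points)
    for (ci in seq_along(components)) {
      acc <- acc +
        fractions[ci] * library_entry(library, components[ci])$spectrum$intensities
    }
    spec <- ir_spectrum(grid, acc, normalized = TRUE)
  } else {
    molecules <- attr(library, "molecules")
    if (is.null(molecules))
      stop("nonlinear mixing needs a library with molecule metadata",
           call. = FALSE)
    mol_ids <- vapply(molecules, function(m) m$id, character(1))
    phase <- library$entries[[1]]$phase
    spec <- with_seed(derive_rng(seed, 13L), {
      acc <- numeric(grid$n_points)
      for (ci in seq_along(components)) {
        mol <- molecules[[match(components[ci], mol_ids)]]
        n_pk <- nrow(mol$peaks)
        off <- stats::rnorm(1, 0, shift_sd)     # rigid per-component shift
        hf <- pmax(0.05, 1 + stats::rnorm(n_pk, 0, jitter_sd))
        pure <- build_molecule_spectrum(mol, phase, grid,
                                        center_offsets = off,
                                        height_factors = hf)
        acc <- acc + fractions[ci] * pure$intensities
      }
      area <- sum(acc) * grid$step
      ir_spectrum(grid, acc / area, normalized = TRUE)
    })
  }
  if (is.null(id)) id <- paste(components, collapse = "+")
  mixture_record(id, components, fractions, spec)
}

#' Generate a complete benchmark suite
#'
#' One call that emits everything the identification benchmarks consume:
#' a seeded synthetic library, equimolar binary (and optionally ternary)
#' mixtures drawn from a component pool occupying `component_pool_frac`
#' of the library (the rest of the library serves as the distractor
#' reservoir), and the ground-truth assignments carried by the mixture
#' records themselves.
#'
#' @param config list of suite parameters; recognized keys (with
#'   defaults): `n_molecules` (200), `n_binary` (100), `n_ternary` (0),
#'   `phase` ("gas"), `component_pool_frac` (0.5), `nonlinearity`
#'   (`list(shift_sd = 0, jitter_sd = 0)`), `style`
#'   ([synthetic_style()]), `grid` ([default_grid()]).
#' @param seed integer master seed.
#' @return List with `library` and `mixtures`.
#' @export
generate_benchmark_suite <- function(config = list(), seed = 1) {
  defaults <- list(n_molecules = 200L, n_binary = 100L, n_ternary = 0L,
                   phase = "gas", component_pool_frac = 0.5,
                   nonlinearity = list(shift_sd = 0, jitter_sd = 0),
                   style = synthetic_style(), grid = default_grid())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown suite config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  lib <- generate_library(cfg$n_molecules, grid = cfg$grid,
                          style = cfg$style, seed = seed,
                          phase = cfg$phase)
  ids <- library_ids(lib)
  pool_n <- max(2, floor(cfg$component_pool_frac * length(ids)))
  pool <- ids[seq_len(pool_n)]
  mixtures <- with_seed(derive_rng(seed, 29L), {
    out <- list()
    for (b in seq_len(cfg$n_binary)) {
      comp <- sample(pool, 2)
      out[[length(out) + 1L]] <- make_mixture(
        lib, comp, nonlinearity = cfg$nonlinearity,
        seed = derive_rng(seed, 1000L + b),
        id = sprintf("bin%04d", b))
    }
    if (cfg$n_ternary > 0 && pool_n >= 3) {
      for (t in seq_len(cfg$n_ternary)) {
        comp <- sample(pool, 3)
        out[[length(out) + 1L]] <- make_mixture(
          lib, comp, nonlinearity = cfg$nonlinearity,
          seed = derive_rng(seed, 2000L + t),
          id = sprintf("ter%04d", t))
      }
    }
    out
  })
  list(library = lib, mixtures = mixtures)
}
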