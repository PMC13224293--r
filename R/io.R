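#' Read and write two-column spectrum CSV files
#'
#' The on-disk spectrum format is a UTF-8 CSV with header
#' `wavenumber_cm-1,intensity`, '.' decimal separator, wavenumbers
#' strictly increasing. Reading is strict: format violations name the
#' offending line.
#'
#' @param path file path.
#' @return [read_spectrum()]: a [raw_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1)
  cols <- trimws(strsplit(header, ",")[[1]])
  if (length(cols) != 2 || !identical(cols, c("wavenumber_cm-1", "intensity")))
    stop(sprintf(
      "line 1: expected header 'wavenumber_cm-1,intensity', got '%s'",
      header), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  wn <- suppressWarnings(as.numeric(df[[1]]))
  it <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(wn) | is.na(it))
  if (length(bad))
    stop(sprintf("line %d: non-numeric value", bad[1] + 1L), call. = FALSE)
  dec <- which(diff(wn) <= 0)
  if (length(dec))
    stop(sprintf("line %d: wavenumbers not strictly increasing",
                 dec[1] + 2L), call. = FALSE)
  raw_spectrum(wn, it)
}

#' @rdname read_spectrum
#' @param spec a `raw_spectrum` or `ir_spectrum`.
#' @export
write_spectrum <- function(spec, path) {
  if (inherits(spec, "ir_spectrum")) {
    wn <- grid_wavenumbers(spec$grid)
    it <- spec$intensities
  } else if (inherits(spec, "raw_spectrum")) {
    wn <- spec$wavenumber
    it <- spec$intensity
  } else stop("`spec` must be a raw_spectrum or ir_spectrum", call. = FALSE)
  df <- data.frame(a = format(wn, digits = 15, trim = TRUE, scientific = FALSE),
                   b = format(it, digits = 17, trim = TRUE))
  names(df) <- c("wavenumber_cm-1", "intensity")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

LIBRARY_SCHEMA <- "irmix-library/1"

#' Read and write spectral-library JSON bundles
#'
#' The library bundle is a JSON object `{"schema": "irmix-library/1",
#' "entries": [...]}` where each entry carries `id`, `name`, `formula`
#' (Hill notation, may be null), `phase` ("gas" or "liquid"), `grid`
#' (`start`, `step`, `n_points`) and `intensities`. Round trips are
#' value-stable; schema violations raise errors naming the JSON path.
#'
#' @param path file path.
#' @param warn_missing_formula warn when entries lack formulas (they are
#'   tolerated until atom filtering or misidentification profiling needs
#'   them).
#' @return [read_library()]: an [ir_library()].
#' @export
read_library <- function(path, warn_missing_formula = TRUE) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(js$schema, LIBRARY_SCHEMA))
    stop(sprintf("$.schema: expected '%s'", LIBRARY_SCHEMA), call. = FALSE)
  if (is.null(js$entries) || !length(js$entries))
    stop("$.entries: missing or empty", call. = FALSE)
  entries <- lapply(seq_along(js$entries), function(i) {
    e <- js$entries[[i]]
    at <- function(f) sprintf("$.entries[%d].%s", i, f)
    for (f in c("id", "phase", "grid", "intensities"))
      if (is.null(e[[f]])) stop(at(f), ": missing", call. = FALSE)
    if (!(e$phase %in% c("gas", "liquid")))
      stop(at("phase"), ": must be 'gas' or 'liquid'", call. = FALSE)
    g <- e$grid
    for (f in c("start", "step", "n_points"))
      if (is.null(g[[f]])) stop(at(paste0("grid.", f)), ": missing",
                                call. = FALSE)
    grid <- ir_grid(g$start, g$step, g$n_points)
    intens <- as.numeric(unlist(e$intensities))
    if (length(intens) != grid$n_points)
      stop(at("intensities"), sprintf(": length %d != n_points %d",
                                      length(intens), grid$n_points),
           call. = FALSE)
    list(id = as.character(e$id),
         name = as.character(e$name %||% e$id),
         formula = if (is.null(e$formula)) NA_character_ else
           as.character(e$formula),
         phase = e$phase,
         spectrum = ir_spectrum(grid, intens, normalized = TRUE))
  })
  ids <- vapply(entries, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop(sprintf("$.entries: duplicate id '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  lib <- ir_library(entries)
  if (warn_missing_formula && anyNA(library_formulas(lib)))
    warning("some library entries have no formula; atom filtering and ",
            "misidentification profiling will be unavailable for them",
            call. = FALSE)
  lib
}

#' @rdname read_library
#' @param library an [ir_library()].
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "ir_library"))
  entries <- lapply(library$entries, function(e) {
    g <- e$spectrum$grid
    list(id = e$id, name = e$name %||% e$id,
         formula = if (is.null(e$formula) || is.na(e$formula)) NULL else
           e$formula,
         phase = e$phase,
         grid = list(start = g$start, step = g$step,
                     n_points = g$n_points),
         intensities = e$spectrum$intensities)
  })
  jsonlite::write_json(list(schema = LIBRARY_SCHEMA, entries = entries),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read and write mixture-record JSON bundles
#'
#' Format: `{"schema": "irmix-mixtures/1", "mixtures": [{id,
#' true_components, mole_fractions, grid, intensities}]}`.
#'
#' @param path file path.
#' @return [read_mixtures()]: a list of [mixture_record()]s.
#' @export
read_mixtures <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(js$schema, "irmix-mixtures/1"))
    stop("$.schema: expected 'irmix-mixtures/1'", call. = FALSE)
  lapply(js$mixtures, function(m) {
    grid <- ir_grid(m$grid$start, m$grid$step, m$grid$n_points)
    mixture_record(m$id, unlist(m$true_components),
                   as.numeric(unlist(m$mole_fractions)),
                   ir_spectrum(grid, as.numeric(unlist(m$intensities)),
                               normalized = TRUE))
  })
}

#' @rdname read_mixtures
#' @param mixtures list of [mixture_record()]s.
#' @export
write_mixtures <- function(mixtures, path) {
  out <- lapply(mixtures, function(m) {
    g <- m$spectrum$grid
    list(id = m$id, true_components = m$true_components,
         mole_fractions = m$mole_fractions,
         grid = list(start = g$start, step = g$step, n_points = g$n_points),
         intensities = m$spectrum$intensities)
  })
  jsonlite::write_json(list(schema = "irmix-mixtures/1", mixtures = out),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Adapt an externally deposited spectral dataset
#'
#' Maps a user-downloaded archive of pure-component spectra (e.g. the
#' published simulation deposit) onto the internal library schema via a
#' declarative mapping, without ever downloading anything. The mapping is
#' a YAML/JSON file (or list) with fields:
#' \describe{
#'   \item{type}{currently `"csv_dir"`: a directory of two-column
#'     spectrum CSVs, one per component.}
#'   \item{pattern}{glob for the spectrum files, e.g. `"*.csv"`.}
#'   \item{wavenumber_column,intensity_column}{column names in the CSVs.}
#'   \item{metadata}{optional CSV path (relative to the dataset root)
#'     with columns `id`, `formula`, `phase`.}
#'   \item{phase}{default phase when no metadata row applies.}
#' }
#' Component ids default to file names without extension. Spectra are
#' regridded to `grid` and preprocessed.
#'
#' @param path dataset root directory.
#' @param mapping mapping list, or path to a YAML/JSON mapping file.
#' @param grid target [ir_grid()].
#' @param smooth_sigma smoothing passed to [preprocess_spectrum()].
#' @return An [ir_library()].
#' @export
adapt_external_dataset <- function(path, mapping, grid = default_grid(),
                                   smooth_sigma = 0) {
  if (!dir.exists(path))
    stop(sprintf(
      "dataset directory not found: %s\n(download the deposit manually and point `path` at its root)",
      path), call. = FALSE)
  if (is.character(mapping) && length(mapping) == 1)
    mapping <- yaml::read_yaml(mapping)
  required <- c("type", "pattern", "wavenumber_column", "intensity_column")
  missing <- setdiff(required, names(mapping))
  if (length(missing))
    stop(sprintf("mapping is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!identical(mapping$type, "csv_dir"))
    stop(sprintf("unsupported mapping type '%s'", mapping$type),
         call. = FALSE)
  files <- Sys.glob(file.path(path, mapping$pattern))
  if (!length(files))
    stop(sprintf("no files match '%s' under %s", mapping$pattern, path),
         call. = FALSE)
  meta <- NULL
  if (!is.null(mapping$metadata)) {
    mf <- file.path(path, mapping$metadata)
    if (!file.exists(mf))
      stop(sprintf("metadata file not found: %s", mf), call. = FALSE)
    meta <- utils::read.csv(mf, stringsAsFactors = FALSE)
    if (!("id" %in% names(meta)))
      stop("metadata CSV needs an 'id' column", call. = FALSE)
  }
  default_phase <- mapping$phase %||% "liquid"
  entries <- lapply(files, function(f) {
    df <- utils::read.csv(f, check.names = FALSE)
    for (col in c(mapping$wavenumber_column, mapping$intensity_column))
      if (!(col %in% names(df)))
        stop(sprintf("%s: mapped column '%s' not present", f, col),
             call. = FALSE)
    ord <- order(df[[mapping$wavenumber_column]])
    raw <- raw_spectrum(df[[mapping$wavenumber_column]][ord],
                        df[[mapping$intensity_column]][ord])
    id <- sub("\\.[^.]*$", "", basename(f))
    formula <- NA_character_
    phase <- default_phase
    if (!is.null(meta)) {
      row <- meta[meta$id == id, , drop = FALSE]
      if (nrow(row) == 1) {
        if ("formula" %in% names(row)) formula <- row$formula
        if ("phase" %in% names(row)) phase <- row$phase
      }
    }
    list(id = id, name = id, formula = formula, phase = phase,
         spectrum = preprocess_spectrum(regrid(raw, grid),
                                        smooth_sigma = smooth_sigma))
  })
  ir_library(entries)
}

#' Read a dipole trajectory CSV
#'
#' Columns `t_fs,mx,my,mz`; the time step is inferred from the (uniform)
#' time column.
#'
#' @param path file path.
#' @return A [dipole_trajectory()].
#' @export
read_dipole_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_fs", "mx", "my", "mz")
  if (!all(need %in% names(df)))
    stop("dipole CSV needs columns t_fs,mx,my,mz", call. = FALSE)
  dt <- diff(df$t_fs)
  if (any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1)))
    stop("time column is not uniformly spaced", call. = FALSE)
  dipole_trajectory(dt[1], as.matrix(df[, c("mx", "my", "mz")]))
}

#' Validate a run-configuration list
#'
#' Strict validation of benchmark/CLI configuration: unknown keys are
#' rejected, value domains checked before any computation starts.
#'
#' @param config a named list.
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config = list()) {
  defaults <- list(algorithm = "nnls", lambda = 0, k = NULL,
                   criteria = c("exact", "any"), protocol = "distractor",
                   sizes = NULL, repeats = 8L, seed = 1L,
                   increment_threshold = 0.01, pool_size = 10L,
                   magnitudes = c(0, 2, 4, 8, 16, 32))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (!(cfg$algorithm %in% unmix_algorithms))
    stop(sprintf("algorithm must be one of: %s",
                 paste(unmix_algorithms, collapse = ", ")), call. = FALSE)
  if (!is.numeric(cfg$lambda) || cfg$lambda < 0)
    stop("lambda must be >= 0", call. = FALSE)
  if (!(cfg$protocol %in% c("distractor", "sweep")))
    stop("protocol must be 'distractor' or 'sweep'", call. = FALSE)
  if (cfg$repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  if (!is.null(cfg$k) && any(cfg$k < 1)) stop("k must be >= 1",
                                              call. = FALSE)
  cfg
}

#' Write a reproducibility manifest
#'
#' Records the configuration (content-hashed), seed and package version
#' next to a result file so a run can be reproduced byte-for-byte.
#'
#' @param path output path for the manifest JSON.
#' @param config the validated configuration list.
#' @param seed the master seed used.
#' @export
write_manifest <- function(path, config, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package = "irmixid",
    version = as.character(utils::packageVersion("irmixid")),
    seed = seed,
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    r_version = R.version.string)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
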