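# Shared fixtures and independent oracles for the test suite.

tiny_grid <- function(n = 8, step = 4, start = 0) irmixid::ir_grid(start, step, n)

# a unit-area spectrum with all mass in one bin
spike_spectrum <- function(grid, bin) {
  y <- numeric(grid$n_points)
  y[bin] <- 1 / grid$step
  irmixid::ir_spectrum(grid, y, normalized = TRUE)
}

# a smooth random unit-area spectrum
random_spectrum <- function(grid) {
  y <- abs(stats::rnorm(grid$n_points)) + 0.05
  irmixid::ir_spectrum(grid, y / (sum(y) * grid$step), normalized = TRUE)
}

# wrap raw columns into a basis_set; normalize = FALSE keeps the columns
# verbatim (tests of the bare solvers), bypassing the library invariant
matrix_basis <- function(X, grid, normalize = TRUE) {
  if (normalize) {
    X <- sweep(X, 2, colSums(X) * grid$step, "/")
    entries <- lapply(seq_len(ncol(X)), function(j) {
      list(id = sprintf("b%02d", j), name = sprintf("b%02d", j),
           formula = NA_character_, phase = "gas",
           spectrum = irmixid::ir_spectrum(grid, X[, j], normalized = TRUE))
    })
    return(irmixid::basis_set(irmixid::ir_library(entries)))
  }
  ids <- sprintf("b%02d", seq_len(ncol(X)))
  colnames(X) <- ids
  structure(list(ids = ids, grid = grid, X = X), class = "basis_set")
}

# Independent NNLS oracle: enumerate every support set, solve the
# unconstrained LS restricted to it, keep feasible (non-negative)
# solutions, return the one with the smallest residual. Exact for the
# convex problem; tractable only for tiny p.
nnls_oracle <- function(X, y) {
  p <- ncol(X)
  best <- list(coef = numeric(p), sse = sum(y^2))
  for (mask in 1:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(p - 1))) > 0)
    XS <- X[, S, drop = FALSE]
    cS <- tryCatch(qr.solve(XS, y), error = function(e) NULL)
    if (is.null(cS) || any(cS < -1e-12)) next
    r <- sum((y - XS %*% cS)^2)
    if (r < best$sse - 1e-15) {
      coef <- numeric(p)
      coef[S] <- cS
      best <- list(coef = coef, sse = r)
    }
  }
  best$coef
}

# brute-force pairwise interpolation oracle over a dense alpha grid
pairwise_oracle <- function(X, y, alpha_step = 1e-3) {
  p <- ncol(X)
  alphas <- seq(0, 1, by = alpha_step)
  best <- NULL
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    for (a in alphas) {
      r <- sum((y - a * X[, i] - (1 - a) * X[, j])^2)
      if (is.null(best) || r < best$sse - 1e-15)
        best <- list(i = i, j = j, alpha = a, sse = r)
    }
  }
  best
}

# small library with controllable spectra/formulas for misid tests
manual_library <- function(specs, formulas, phase = "liquid") {
  entries <- lapply(seq_along(specs), function(i) {
    list(id = names(specs)[i], name = names(specs)[i],
         formula = formulas[[i]], phase = phase, spectrum = specs[[i]])
  })
  irmixid::ir_library(entries)
}

# peaked spectrum helper: gaussians at given centers on a grid
peaked_spectrum <- function(grid, centers, sigma = 12, heights = 1) {
  nu <- irmixid::grid_wavenumbers(grid)
  heights <- rep_len(heights, length(centers))
  y <- numeric(length(nu))
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-0.5 * ((nu - centers[i]) / sigma)^2)
  irmixid::preprocess_spectrum(irmixid::ir_spectrum(grid, y))
}
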