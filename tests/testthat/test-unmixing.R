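test_that("fit_ls recovers exact mixing coefficients", {
  set.seed(10)
  g <- tiny_grid(40)
  X <- matrix(abs(rnorm(40 * 3)) + 0.1, 40, 3)
  basis <- matrix_basis(X, g)
  y_int <- 0.3 * basis$X[, 1] + 0.7 * basis$X[, 2]
  y <- ir_spectrum(g, y_int, normalized = TRUE)
  fit <- fit_ls(y, basis)
  # hand oracle: normal equations solved independently
  oracle <- solve(crossprod(basis$X), crossprod(basis$X, y_int))
  expect_equal(unname(fit$coefficients), as.vector(oracle),
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[1:2]), c(0.3, 0.7), tolerance = 1e-8)
  expect_lt(fit$residual_sse, 1e-16)
})

test_that("fit_ls identity member and ridge shrinkage limit", {
  g <- tiny_grid(16)
  X <- diag(16)[, 1:4] + 0.01
  basis <- matrix_basis(X, g)
  y <- ir_spectrum(g, basis$X[, 2], normalized = TRUE)
  fit <- fit_ls(y, basis)
  expect_equal(unname(fit$coefficients), c(0, 1, 0, 0), tolerance = 1e-8)
  # coefficients shrink to zero monotonically in lambda
  norms <- sapply(c(0, 1, 100, 1e4, 1e8), function(l)
    sqrt(sum(fit_ls(y, basis, lambda = l)$coefficients^2)))
  expect_true(all(diff(norms) < 1e-12))
  expect_lt(norms[5], 1e-4)
})

test_that("fit_nnls exactly recovers convex combinations and clamps at zero", {
  set.seed(11)
  g <- tiny_grid(30)
  X <- matrix(abs(rnorm(30 * 4)) + 0.05, 30, 4)
  basis <- matrix_basis(X, g)
  y_int <- 0.5 * basis$X[, 1] + 0.5 * basis$X[, 3]
  y <- ir_spectrum(g, y_int, normalized = TRUE)
  fit <- fit_nnls(y, basis)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), c(0.5, 0, 0.5, 0),
               tolerance = 1e-8)
  expect_lt(fit$residual_sse, 1e-16)
  # all-zero target -> all-zero coefficients
  y0 <- ir_spectrum(g, numeric(30))
  expect_equal(unname(fit_nnls(y0, basis)$coefficients), rep(0, 4))
})

test_that("an anticorrelated basis entry gets coefficient exactly zero", {
  # 2-basis toy where unconstrained LS goes negative on entry 2
  g <- tiny_grid(3, step = 1)
  X <- cbind(c(1, 1, 0.2), c(0.1, 0.1, 1))
  basis <- matrix_basis(X, g, normalize = FALSE)
  y <- ir_spectrum(g, c(1, 1, 0))
  ls <- fit_ls(y, basis)
  expect_lt(ls$coefficients[2], 0)          # sanity: LS wants negative
  nn <- fit_nnls(y, basis)
  expect_identical(unname(nn$coefficients[2]), 0)
  # and the active-set oracle agrees
  expect_equal(unname(nn$coefficients), nnls_oracle(X, c(1, 1, 0)),
               tolerance = 1e-10)
})

test_that("NNLS equals LS whenever LS is already feasible", {
  set.seed(12)
  g <- tiny_grid(12, step = 1)
  for (i in 1:50) {
    X <- matrix(runif(12 * 3, 0.1, 1), 12, 3)
    co <- runif(3, 0.2, 1)
    y_int <- drop(X %*% co) + rnorm(12, 0, 1e-3)
    basis <- matrix_basis(X, g, normalize = FALSE)
    y <- ir_spectrum(g, pmax(y_int, 0))
    ls <- fit_ls(y, basis)
    if (all(ls$coefficients >= 0)) {
      nn <- fit_nnls(y, basis)
      expect_equal(nn$coefficients, ls$coefficients, tolerance = 1e-7)
    }
  }
})

test_that("NNLS matches exhaustive active-set enumeration on small instances", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:8, 1)   # overdetermined: coefficients are identifiable
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    g <- tiny_grid(n, step = 1)
    basis <- matrix_basis(abs(X) + 0.01, g, normalize = FALSE)
    yv <- abs(y)
    fit <- fit_nnls(ir_spectrum(g, yv), basis)
    expect_equal(unname(fit$coefficients),
                 nnls_oracle(abs(X) + 0.01, yv), tolerance = 1e-8)
  }
})

test_that("NNLS residual never increases as the basis grows", {
  set.seed(14)
  g <- tiny_grid(25, step = 1)
  X <- matrix(runif(25 * 6, 0, 1), 25, 6)
  y <- ir_spectrum(g, runif(25))
  res <- sapply(2:6, function(p)
    fit_nnls(y, matrix_basis(X[, 1:p], g, normalize = FALSE))$residual_sse)
  expect_true(all(diff(res) <= 1e-10))
})

test_that("ridge NNLS is continuous in lambda and equals NNLS at zero", {
  set.seed(15)
  g <- tiny_grid(20, step = 1)
  X <- matrix(runif(20 * 3, 0, 1), 20, 3)
  basis <- matrix_basis(X, g, normalize = FALSE)
  y <- ir_spectrum(g, drop(X %*% c(0.2, 0.5, 0.3)))
  f0 <- fit_nnls(y, basis, lambda = 0)
  fr <- fit_nnls(y, basis, lambda = 1e-12)
  expect_equal(f0$coefficients, fr$coefficients, tolerance = 1e-6)
  lambdas <- 10^seq(-6, 2, length.out = 30)
  path <- t(sapply(lambdas, function(l)
    fit_nnls(y, basis, lambda = l)$coefficients))
  jumps <- apply(abs(diff(path)), 1, max)
  expect_lt(max(jumps), 0.2)       # no discontinuities along the path
})

test_that("pairwise interpolation finds the true pair and alpha", {
  set.seed(16)
  g <- tiny_grid(30)
  X <- matrix(abs(rnorm(30 * 5)) + 0.05, 30, 5)
  basis <- matrix_basis(X, g)
  y <- ir_spectrum(g, 0.5 * (basis$X[, 1] + basis$X[, 2]),
                   normalized = TRUE)
  pi <- pairwise_interpolation(y, basis)
  expect_setequal(pi$pair, c("b01", "b02"))
  expect_equal(pi$alpha, 0.5, tolerance = 1e-8)
  expect_lt(pi$residual_sse, 1e-16)
  # pure component: winning pair contains it with full weight
  y3 <- ir_spectrum(g, basis$X[, 3], normalized = TRUE)
  pi3 <- pairwise_interpolation(y3, basis)
  expect_true("b03" %in% pi3$pair)
  w3 <- if (pi3$alpha_by == "b03") pi3$alpha else 1 - pi3$alpha
  expect_equal(w3, 1, tolerance = 1e-8)
})

test_that("pairwise interpolation matches the dense grid-search oracle", {
  set.seed(17)
  for (rep in 1:5) {
    g <- tiny_grid(12, step = 1)
    X <- matrix(runif(12 * 5, 0, 1), 12, 5)
    basis <- matrix_basis(X, g, normalize = FALSE)
    y <- runif(12)
    got <- pairwise_interpolation(ir_spectrum(g, y), basis)
    oracle <- pairwise_oracle(X, y)
    expect_setequal(got$pair,
                    c(sprintf("b%02d", oracle$i), sprintf("b%02d", oracle$j)))
    expect_equal(got$residual_sse, oracle$sse, tolerance = 1e-5)
  }
  expect_error(
    pairwise_interpolation(ir_spectrum(tiny_grid(4, 1), runif(4)),
                           matrix_basis(matrix(1, 4, 1), tiny_grid(4, 1),
                                        normalize = FALSE)),
    "at least 2")
})

test_that("identical pair spectra fall back to alpha = 0.5", {
  g <- tiny_grid(6, step = 1)
  X <- cbind(rep(1, 6), rep(1, 6))
  basis <- matrix_basis(X, g, normalize = FALSE)
  pi <- pairwise_interpolation(ir_spectrum(g, rep(1, 6)), basis)
  expect_equal(pi$alpha, 0.5)
  expect_lt(pi$residual_sse, 1e-16)
})
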