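fake_result <- function(coefs, converged = TRUE) {
  structure(list(coefficients = coefs, residual_sse = 0,
                 converged = converged, lambda = 0, n_iter = 0L),
            class = "unmix_result")
}

test_that("rank_candidates sorts by |coefficient| with basis-order ties", {
  p <- rank_candidates(fake_result(c(a = 0.7, b = 0.3, c = 0)))
  expect_equal(p$ranked_ids, c("a", "b", "c"))
  # negatives rank by magnitude
  p2 <- rank_candidates(fake_result(c(a = -0.9, b = 0.5)))
  expect_equal(p2$ranked_ids, c("a", "b"))
  # exact tie: earlier basis entry wins
  p3 <- rank_candidates(fake_result(c(a = 0.5, b = 0.5)))
  expect_equal(p3$ranked_ids, c("a", "b"))
  p4 <- rank_candidates(fake_result(c(b = 0.5, a = 0.5)))
  expect_equal(p4$ranked_ids, c("b", "a"))
})

test_that("exact and any criteria behave as set predicates", {
  p <- rank_candidates(fake_result(c(a = 0.6, c = 0.3, b = 0.1)))
  expect_true(evaluate_exact(p, c("a", "c"), 2))
  expect_false(evaluate_exact(p, c("a", "b"), 2))
  expect_true(evaluate_any(p, c("a", "b"), 2))
  expect_false(evaluate_any(p, c("b"), 2))
  # monotone in k; any >= exact
  for (k in 1:3) {
    expect_gte(evaluate_any(p, c("a", "b"), k),
               evaluate_exact(p, c("a", "b"), k))
    if (k > 1) {
      expect_gte(evaluate_exact(p, c("a", "b"), k),
                 evaluate_exact(p, c("a", "b"), k - 1))
    }
  }
})

test_that("unconverged predictions always count as incorrect", {
  p <- rank_candidates(fake_result(c(a = 0.6, b = 0.4), converged = FALSE))
  expect_false(evaluate_exact(p, c("a", "b"), 2))
  expect_false(evaluate_any(p, c("a"), 2))
})

test_that("atom filter promotes the first element-compatible combination", {
  # leader contains S but the mixture is C/H/O only
  p <- rank_candidates(fake_result(c(sulf = 0.8, alc = 0.5, ket = 0.4)))
  formulas <- c(sulf = "C2H6S", alc = "C2H6O", ket = "C3H6O")
  filt <- atom_filter(p, c("C", "H", "O"), formulas, k = 2)
  expect_equal(filt$ranked_ids[1:2], c("alc", "ket"))
  expect_false(attr(filt, "filter_fallback"))
  # all compatible -> unchanged
  filt2 <- atom_filter(p, c("C", "H", "O", "S"), formulas, k = 2)
  expect_equal(filt2$ranked_ids, p$ranked_ids)
  # nothing compatible -> fallback with warning
  expect_warning(
    filt3 <- atom_filter(p, c("C", "H", "N"), formulas, k = 2),
    "unfiltered")
  expect_equal(filt3$ranked_ids, p$ranked_ids)
  expect_true(attr(filt3, "filter_fallback"))
  expect_error(atom_filter(p, c("C"), c(sulf = NA_character_), k = 1),
               "formula")
})

test_that("distractor benchmark is perfect on linear gas-like mixtures", {
  suite <- generate_benchmark_suite(
    list(n_molecules = 60, n_binary = 25), seed = 101)
  rep <- run_distractor_benchmark(suite$mixtures, suite$library,
                                  "nnls", n_repeats = 8, seed = 101)
  expect_equal(rep$records$accuracy, rep(1, 8))
  expect_equal(rep$accuracy_sd, 0)
  expect_equal(rep$records$n_unconverged, rep(0L, 8))
})

test_that("distractor benchmark is deterministic and validates inputs", {
  suite <- generate_benchmark_suite(
    list(n_molecules = 30, n_binary = 8), seed = 7)
  r1 <- run_distractor_benchmark(suite$mixtures, suite$library,
                                 n_repeats = 3, seed = 42,
                                 keep_predictions = TRUE)
  r2 <- run_distractor_benchmark(suite$mixtures, suite$library,
                                 n_repeats = 3, seed = 42,
                                 keep_predictions = TRUE)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$predictions, r2$predictions)
  # zero-distractor, truth-only basis also works
  r0 <- run_distractor_benchmark(suite$mixtures, suite$library,
                                 n_repeats = 1, seed = 1,
                                 n_distractors = 0)
  expect_equal(r0$records$accuracy, 1)
  expect_error(
    run_distractor_benchmark(suite$mixtures, suite$library,
                             n_distractors = 1000),
    "distractors")
})

test_that("basis sweep keeps nesting and logical criterion ordering", {
  suite <- generate_benchmark_suite(
    list(n_molecules = 50, n_binary = 15, component_pool_frac = 0.4),
    seed = 33)
  truth_n <- length(unique(unlist(lapply(suite$mixtures,
                                         function(m) m$true_components))))
  rep <- run_basis_sweep(suite$mixtures, suite$library,
                         sizes = c(truth_n, truth_n + 10, 50),
                         criteria = c("exact", "any"),
                         k_values = c(2, 5), seed = 9)
  rec <- rep$records
  # exact linear mixtures at the minimal basis: perfect recovery
  expect_equal(rec$accuracy[rec$basis_size == truth_n &
                              rec$criterion == "exact" & rec$k == 2], 1)
  # any >= exact at every condition
  for (sz in unique(rec$basis_size)) for (k in c(2, 5)) {
    a <- rec$accuracy[rec$basis_size == sz & rec$criterion == "any" &
                        rec$k == k]
    e <- rec$accuracy[rec$basis_size == sz & rec$criterion == "exact" &
                        rec$k == k]
    expect_gte(a, e)
  }
  # accuracy non-decreasing in k for a fixed basis and criterion
  for (sz in unique(rec$basis_size)) for (cr in c("exact", "any")) {
    acc_k <- rec$accuracy[rec$basis_size == sz & rec$criterion == cr]
    expect_gte(acc_k[2], acc_k[1])
  }
  expect_error(
    run_basis_sweep(suite$mixtures, suite$library, sizes = c(2, 10)),
    "true components")
  expect_error(
    run_basis_sweep(suite$mixtures, suite$library, sizes = c(truth_n, 500)),
    "exceeds")
})

test_that("reports are bit-identical for a fixed seed across sweeps", {
  suite <- generate_benchmark_suite(
    list(n_molecules = 30, n_binary = 6), seed = 2)
  truth_n <- length(unique(unlist(lapply(suite$mixtures,
                                         function(m) m$true_components))))
  s1 <- run_basis_sweep(suite$mixtures, suite$library,
                        sizes = c(truth_n, 30), seed = 5)
  s2 <- run_basis_sweep(suite$mixtures, suite$library,
                        sizes = c(truth_n, 30), seed = 5)
  expect_identical(s1$records, s2$records)
})
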