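test_that("apply_random_shift translates rigidly and renormalizes", {
  g <- ir_grid(0, 4, 500)
  s <- peaked_spectrum(g, 1000)
  # magnitude 0: identity
  expect_equal(apply_random_shift(s, 0, seed = 1)$intensities,
               s$intensities)
  # forced positive 8 cm^-1: peak moves two bins up
  up <- apply_random_shift(s, 8, sign = +1)
  nu <- grid_wavenumbers(g)
  expect_equal(nu[which.max(up$intensities)],
               nu[which.max(s$intensities)] + 8)
  expect_equal(sum(up$intensities) * g$step, 1, tolerance = 1e-9)
  # CDF/shift identity holds for the realized shift
  expect_equal(avg_cdf_difference(s, up), 8 / grid_span(g),
               tolerance = 1e-6)
  # first moment moves by ~delta
  expect_equal(mean_wavenumber(up) - mean_wavenumber(s), 8,
               tolerance = 0.1)
  expect_error(apply_random_shift(s, grid_span(g)), "half the grid span")
  # seeded sign draw is deterministic
  a <- apply_random_shift(s, 12, seed = 99)
  b <- apply_random_shift(s, 12, seed = 99)
  expect_identical(a$intensities, b$intensities)
})

test_that("shift robustness curve starts perfect and degrades monotonically", {
  suite <- generate_benchmark_suite(
    list(n_molecules = 40, n_binary = 15), seed = 31)
  cv <- shift_robustness_curve(suite$mixtures, suite$library,
                               magnitudes = c(0, 8, 24, 60), seed = 31)
  expect_equal(cv$accuracy[1], 1)
  # non-increasing within small-sample tolerance over 3 seeds
  acc <- sapply(1:3, function(s)
    shift_robustness_curve(suite$mixtures, suite$library,
                           magnitudes = c(0, 8, 24, 60),
                           seed = s)$accuracy)
  mean_acc <- rowMeans(acc)
  expect_true(all(diff(mean_acc) <= 1 / nrow(acc) + 1e-9))
})

test_that("broad liquid-phase spectra tolerate shifts better than gas", {
  accs <- sapply(c("gas", "liquid"), function(ph) {
    suite <- generate_benchmark_suite(
      list(n_molecules = 50, n_binary = 25, phase = ph), seed = 77)
    cv <- shift_robustness_curve(suite$mixtures, suite$library,
                                 magnitudes = c(8, 16), seed = 77)
    cv$accuracy
  })
  # at 8 cm^-1 and at the harsher 16 cm^-1 the broadened liquid suite
  # must do at least as well as the sharp gas suite
  expect_gte(accs[1, "liquid"], accs[1, "gas"])
  expect_gte(accs[2, "liquid"], accs[2, "gas"])
  expect_gt(sum(accs[, "liquid"]), sum(accs[, "gas"]) - 1e-9)
})

test_that("Hill formula parsing round-trips and rejects junk", {
  expect_equal(unclass(parse_formula("C4H10N2"))[c("C", "H", "N")],
               c(C = 4L, H = 10L, N = 2L))
  expect_equal(unclass(parse_formula("CH4"))[c("C", "H")],
               c(C = 1L, H = 4L))
  expect_equal(format_formula(parse_formula("C6H13N3")), "C6H13N3")
  expect_equal(format_formula(parse_formula("H4C")), "CH4")   # canonical
  expect_equal(format_formula(parse_formula("BrClH")), "BrClH")
  expect_error(parse_formula("Xx3"), "unknown element")
  expect_error(parse_formula("C0H2"), "malformed")
  expect_error(parse_formula(""), "non-empty")
})

test_that("misidentification categories follow the formula rules", {
  expect_equal(classify_misidentification("C3H8O", "C3H8O"), "isomer")
  expect_equal(classify_misidentification("C2H5Cl", "C2H5Br"),
               "substitution")
  expect_equal(classify_misidentification("C4H8", "C3H8"),
               "carbon_difference")
  # hydrogens differing too -> not a pure carbon difference by default
  expect_equal(classify_misidentification("C4H10", "C3H8"), "other")
  expect_equal(classify_misidentification("C4H10", "C3H8",
                                          h_tolerance = 2),
               "carbon_difference")
  # the carboximidamide pair: same family, very different formulas
  expect_equal(classify_misidentification("C4H10N2", "C6H13N3"), "other")
  # symmetry of all three named categories
  pairs <- list(c("C3H8O", "C3H8O"), c("C2H5Cl", "C2H5Br"),
                c("C4H8", "C5H8"))
  for (p in pairs)
    expect_equal(classify_misidentification(p[1], p[2]),
                 classify_misidentification(p[2], p[1]))
})

test_that("nearest spectral neighbours are exact and ordered", {
  g <- ir_grid(0, 4, 400)
  specs <- list(
    q = peaked_spectrum(g, c(800, 1400)),
    dup = peaked_spectrum(g, c(800, 1400)),
    near = peaked_spectrum(g, c(812, 1400)),
    far = peaked_spectrum(g, c(400, 1000, 1502))
  )
  lib <- manual_library(specs, list("C2H6O", "C2H6O", "C2H6S", "C6H6"))
  nn <- nearest_spectral_neighbors("q", lib, m = 3)
  expect_equal(nn$id[1], "dup")
  expect_equal(nn$spectral_mse[1], 0)
  expect_true(all(diff(nn$spectral_mse) >= 0))
  # m = 1 equals the brute-force argmin
  all_mse <- sapply(c("dup", "near", "far"), function(id)
    spectral_mse(specs$q, library_entry(lib, id)$spectrum))
  expect_equal(nearest_spectral_neighbors("q", lib, 1)$id,
               names(which.min(all_mse)))
  expect_error(nearest_spectral_neighbors("zz", lib), "unknown")
})

test_that("misidentification profiling recovers planted categories", {
  g <- ir_grid(0, 4, 400)
  # the mixtures are secretly built from "iso", a structural isomer of A
  # with nearly identical bands, so NNLS must pick iso over A: planted
  # isomer misidentifications
  specs <- list(
    A = peaked_spectrum(g, c(608, 1800)),
    iso = peaked_spectrum(g, c(600, 1800)),
    B = peaked_spectrum(g, c(1000, 2600)),
    C = peaked_spectrum(g, c(1400, 3000))
  )
  lib <- manual_library(specs, list("C3H8O", "C3H8O", "C2H6O2", "C5H12"))
  mixes <- list(
    mixture_record("m1", c("A", "B"), c(0.5, 0.5),
                   make_mixture(lib, c("iso", "B"))$spectrum),
    mixture_record("m2", c("A", "C"), c(0.5, 0.5),
                   make_mixture(lib, c("iso", "C"))$spectrum))
  rep <- run_distractor_benchmark(mixes, lib, n_repeats = 1, seed = 4,
                                  n_distractors = 1,
                                  keep_predictions = TRUE)
  prof <- profile_misidentifications(rep, lib)
  expect_equal(prof$n_failed, 2)
  expect_equal(unname(prof$percentages[["isomer"]]), 100)
  expect_true(all(prof$pairs$category == "isomer"))
  expect_equal(prof$pairs$true_id, c("A", "A"))
  expect_equal(prof$pairs$predicted_id, c("iso", "iso"))
  # all-correct report yields an empty profile
  mixes_ok <- list(make_mixture(lib, c("B", "C"), id = "m3"))
  rep_ok <- run_distractor_benchmark(mixes_ok, lib, n_repeats = 1,
                                     seed = 4, n_distractors = 0,
                                     keep_predictions = TRUE)
  prof_ok <- profile_misidentifications(rep_ok, lib)
  expect_equal(prof_ok$n_failed, 0)
  expect_equal(nrow(prof_ok$pairs), 0)
  expect_error(profile_misidentifications(
    run_distractor_benchmark(mixes_ok, lib, n_repeats = 1, seed = 1,
                             n_distractors = 0), lib),
    "keep_predictions")
})

test_that("planted traps in the synthetic generator are real traps", {
  lib <- generate_library(150, seed = 55,
                          style = synthetic_style(isomer_rate = 0.3))
  mols <- attr(lib, "molecules")
  traps <- Filter(function(m) startsWith(m$trap, "isomer_of:"), mols)
  expect_gt(length(traps), 0)
  forms <- library_formulas(lib)
  for (tr in traps) {
    src <- sub("isomer_of:", "", tr$trap)
    expect_identical(forms[[tr$id]], forms[[src]])
  }
})
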