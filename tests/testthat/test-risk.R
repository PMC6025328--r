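toy_tox <- tibble::tibble(
  id = "X", rfd_o = 1e-3, rfd_i = 1e-3, csf_o = 1, csf_i = 1,
  abs_skin = 0.1, vf_s = NA_real_, pef = 1.316e9, volatile = FALSE
)

test_that("noncarcinogenic SSL matches the hand-arithmetic oracle", {
  # independent oracle: assemble the three pathway terms explicitly
  ingestion <- (1 / 1e-3) * (100 / 1e6)
  dermal <- (1 / 1e-3) * (3470 * 0.12 * 0.1 / 1e6)
  inhalation <- (1 / 1e-3) * (20 / 1.316e9)
  oracle <- (1 * 15 * (25 * 365)) / (250 * 25 * (ingestion + dermal + inhalation))
  got <- ssl_noncarcinogenic(toy_tox)$ssl_mg_kg
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, 154.6008, tolerance = 1e-4)

  # linear in THQ, monotone in ABS
  expect_equal(ssl_noncarcinogenic(toy_tox, noncarc_scenario(thq = 2))$ssl_mg_kg,
               2 * got, tolerance = 1e-12)
  smaller_abs <- dplyr::mutate(toy_tox, abs_skin = 1e-6)
  expect_gt(ssl_noncarcinogenic(smaller_abs)$ssl_mg_kg, got)
})

test_that("carcinogenic SSL matches the hand-arithmetic oracle", {
  ingestion <- 100 * 1 / 1e6
  dermal <- 361 * 0.1 * 1 / 1e6
  inhalation <- 11 * 1 / 1.316e9
  oracle <- (1e-6 * 25550) / (250 * (ingestion + dermal + inhalation))
  got <- ssl_carcinogenic(toy_tox)$ssl_mg_kg
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, 0.7508723, tolerance = 1e-6)

  expect_equal(ssl_carcinogenic(toy_tox, carc_scenario(tr = 5e-7))$ssl_mg_kg,
               got / 2, tolerance = 1e-12)
  expect_gt(got, ssl_carcinogenic(dplyr::mutate(toy_tox, csf_o = 2))$ssl_mg_kg)
})

test_that("missing toxicity routes and bad parameters are rejected", {
  no_rfd <- dplyr::mutate(toy_tox, rfd_o = NA_real_)
  expect_error(ssl_noncarcinogenic(no_rfd), "rfd_o")
  expect_error(noncarc_scenario(bw_c = -1), "positive")
  no_dilution <- dplyr::mutate(toy_tox, pef = NA_real_)
  expect_error(ssl_noncarcinogenic(no_dilution), "emission factor")
})

test_that("hazard quotient converts units and guards its domain", {
  expect_identical(hazard_quotient(1000, 1), 1)
  expect_identical(hazard_quotient(0, 2), 0)
  # consistency with the reference survey's BaP median
  expect_equal(hazard_quotient(44.50, 0.2911), 0.152897, tolerance = 1e-3)
  expect_error(hazard_quotient(1, 0), "positive")
  expect_error(hazard_quotient(-1, 1), "nonnegative")
})

test_that("hazard index sums quotients and flags the benchmark", {
  hi <- hazard_index(c(0.5, 0.3, 0.2))
  expect_equal(as.numeric(hi), 1)
  expect_false(attr(hi, "exceeds_benchmark"))
  expect_true(attr(hazard_index(c(0.9, 0.2)), "exceeds_benchmark"))
  expect_equal(as.numeric(hazard_index(rep(0, 5))), 0)

  # summation over the full reference median-quotient column
  ref <- pop_reference_summary()
  expect_equal(as.numeric(hazard_index(ref$med_hq)), 0.2124235, tolerance = 1e-7)
})

test_that("risk contributions close to 1 and are scale invariant", {
  expect_equal(risk_contributions(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(risk_contributions(5), 1)
  expect_error(risk_contributions(c(0, 0)), "undefined")

  ref <- pop_reference_summary()
  p <- risk_contributions(ref$med_hq)
  expect_equal(p[ref$id == "BaP"], 0.7198, tolerance = 1e-3)
  expect_equal(sum(p), 1)
  for (k in c(0.1, 3, 1e4)) {
    expect_equal(risk_contributions(k * ref$med_hq), p, tolerance = 1e-12)
  }
})

test_that("evaluate_sites reproduces a hand-set three-compound screen", {
  tox <- make_tox(c(A = 1, B = 2, C = 4))
  expect_equal(ssl_noncarcinogenic(tox)$ssl_mg_kg, c(1, 2, 4), tolerance = 1e-10)
  samples <- tibble::tibble(site_id = "s1", compound = c("A", "B", "C"),
                            conc_ug_kg = 1000, below_dl = FALSE)
  out <- evaluate_sites(samples, tox, basis = "noncarcinogenic")
  expect_equal(out$hq, c(1, 0.5, 0.25), tolerance = 1e-10)
  expect_equal(unique(out$hi), 1.75, tolerance = 1e-10)
  expect_equal(out$contribution, c(4, 2, 1) / 7, tolerance = 1e-10)
  expect_true(all(out$exceeds_benchmark))
})

test_that("zero survey gives zero index and undefined contributions", {
  tox <- make_tox(c(A = 1, B = 2))
  samples <- tibble::tibble(site_id = "s1", compound = c("A", "B"),
                            conc_ug_kg = 0, below_dl = FALSE)
  out <- evaluate_sites(samples, tox, basis = "noncarcinogenic")
  expect_equal(unique(out$hi), 0)
  expect_true(all(is.na(out$contribution)))
  expect_error(contribution_matrix(out), "zero hazard index")
})

test_that("scaling all concentrations scales HI and fixes contributions", {
  svy <- generate_survey(n_sites = 6, seed = 5, censor = FALSE)
  base <- evaluate_sites(svy$samples, basis = "noncarcinogenic")
  scaled <- evaluate_sites(dplyr::mutate(svy$samples, conc_ug_kg = 3 * conc_ug_kg),
                           basis = "noncarcinogenic")
  expect_equal(scaled$hi, 3 * base$hi, tolerance = 1e-10)
  expect_equal(scaled$contribution, base$contribution, tolerance = 1e-10)
})

test_that("combined basis takes the conservative per-compound minimum", {
  tox <- pop_toxicity()
  ssl <- soil_screening_levels(tox, "combined")
  expect_equal(ssl$ssl_mg_kg,
               pmin(ssl$ssl_noncarc, ssl$ssl_carc, na.rm = TRUE),
               tolerance = 1e-12)
  # compounds below every screening level stay under HQ = 1
  pec_mg <- 0.9 * min(ssl$ssl_mg_kg)
  expect_true(all(hazard_quotient(pec_mg * 1000, ssl$ssl_mg_kg) < 1))
})
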