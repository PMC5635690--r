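contains_mz <- function(fr, mz, tol = 1e-3) any(abs(fr$mz - mz) <= tol)

test_that("key published fragments are predicted at the plain-sum convention", {
  m1 <- candidate_by_id("M1")
  fr <- predict_fragments(m1)
  expect_true(contains_mz(fr, 137.0239))  # DHB acylium C7H5O3
  expect_true(contains_mz(fr, 194.0817))  # intact + H - NH3, C10H12NO3
  expect_identical(fr$formula[abs(fr$mz - 137.0239) < 1e-3], "C7H5O3")

  m5 <- candidate_by_id("M5")
  fr5 <- predict_fragments(m5)
  expect_true(contains_mz(fr5, 72.0813))   # C4H10N alkyl-amine cation
  expect_true(contains_mz(fr5, 208.0974))  # intact + H - NH3
  # plain-sum convention: DHB acylium is the bare formula sum, no proton
  expect_equal(fr$mz[fr$formula == "C7H5O3"], oracle_mass("C7H5O3"),
               tolerance = 1e-9)
})

test_that("backbone C-N cleavage covers secondary-amine polyamines", {
  fr2 <- predict_fragments(candidate_by_id("M2"))       # spermidine
  expect_true(contains_mz(fr2, 194.0817))  # DHB-aminopropyl cation
  expect_true(contains_mz(fr2, 72.0813))
  expect_true(contains_mz(fr2, 129.1392))  # protonated spermidine - NH3
  expect_true(contains_mz(fr2, 265.1552))
  fr6 <- predict_fragments(candidate_by_id("M6Tc"))     # norspermidine analog
  expect_true(contains_mz(fr6, 194.0817))
  expect_true(contains_mz(fr6, 277.1188))  # cap-side backbone fragment
  fr9 <- predict_fragments(candidate_by_id("M9"))
  expect_true(contains_mz(fr9, 91.0548))   # benzylic cation C7H7
  expect_true(contains_mz(fr9, 180.0661))
})

test_that("intact-only species and depth limits behave per contract", {
  dhb <- raw_product("C7H6O4", "DHB")
  fr <- predict_fragments(dhb, losses = character(0))
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$description, "intact [M+H]+")
  expect_equal(fr$mz, protonated_mz(monoisotopic_mass("C7H6O4")),
               tolerance = 1e-12)
  expect_error(predict_fragments(dhb, max_cleavages = 2L), "unsupported")
  expect_gt(nrow(predict_fragments(candidate_by_id("M1"), max_cleavages = 0L)),
            1L)  # intact plus neutral losses only
  expect_error(predict_fragments(dhb, losses = "CO"), "unknown neutral loss")
})

test_that("amide cleavage conserves mass: acylium + aminium = parent + 2H", {
  for (id in c("M1", "M2", "M5", "M9", "M21", "M2Tc", "M6To")) {
    p <- candidate_by_id(id)
    fr <- predict_fragments(p)
    acyl <- fr[fr$description == "amide cleavage, acylium" |
               grepl("acylium", fr$description), , drop = FALSE]
    amine <- fr[grepl("protonated amine side", fr$description), , drop = FALSE]
    expect_gt(nrow(acyl), 0)
    expect_gt(nrow(amine), 0)
    # the DHB acylium and the full amine-side cation partition the parent:
    # acylium + protonated amine side = parent + 2 H
    dhb_acyl <- parse_formula("C7H5O3")
    full_amine <- p$formula + ef(H = 2) - dhb_acyl
    expect_true(any(vapply(amine$formula, function(s)
      parse_formula(s) == full_amine, TRUE)))
    expect_equal(monoisotopic_mass(dhb_acyl) + monoisotopic_mass(full_amine),
                 p$neutral_mass + 2 * 1.0078250319, tolerance = 1e-9)
  }
})

test_that("every fragment stays within the parent mass bound", {
  for (p in default_candidates()[c(1, 5, 20, 40, 60, 80, 100, 106)]) {
    fr <- predict_fragments(p)
    expect_true(all(fr$mz <= p$mz + 0.01))
    expect_true(all(fr$mz > 0))
    expect_false(any(duplicated(fr$formula)))
    expect_true(all(diff(fr$mz) <= 0))  # sorted descending
  }
})

test_that("enterobactin ester-chain fragments are emitted", {
  ent <- candidate_by_id("Ent")
  fr <- predict_fragments(ent)
  expect_true(contains_mz(fr, 137.0239))
  expect_true(contains_mz(fr, 224.0559))  # unit acylium C10H10NO5
  expect_true(contains_mz(fr, 447.1040))  # dimer acylium
  trim <- predict_fragments(candidate_by_id("Ent trimer"))
  expect_true(contains_mz(trim, 447.1040))
  mono <- predict_fragments(candidate_by_id("Ent monomer"))
  expect_false(contains_mz(mono, 447.1040))  # no ester bond to cleave
})

test_that("fragment coverage is a greedy one-to-one ppm match", {
  fr <- predict_fragments(candidate_by_id("M1"))
  cov <- fragment_coverage(fr, c(137.0231, 194.0809), tol_ppm = 10)
  expect_equal(cov$coverage, 1.0)
  expect_identical(nrow(cov$pairs), 2L)
  expect_equal(fragment_coverage(fr, numeric(0))$coverage, 1.0)
  expect_identical(nrow(fragment_coverage(fr, numeric(0))$pairs), 0L)
  expect_equal(fragment_coverage(fr, 500.0, tol_ppm = 10)$coverage, 0.0)
  # one prediction cannot absorb two observed peaks
  cov2 <- fragment_coverage(data.frame(mz = 137.0239), c(137.0238, 137.0240),
                            tol_ppm = 10)
  expect_equal(cov2$coverage, 0.5)
  expect_error(fragment_coverage(fr, 137.0, tol_ppm = 0), "tol_ppm")
})
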