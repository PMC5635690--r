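test_that("formula parsing round-trips and rejects bad input", {
  cases <- list(
    c("C7H6O4", "C7H6O4"),
    c("H2O", "H2O"),
    c("C10H11NO6", "C10H11NO6"),
    c("CH4N2O", "CH4N2O"),
    c("", "")
  )
  for (cs in cases) {
    f <- parse_formula(cs[1])
    expect_identical(format_formula(f), cs[2])
    expect_identical(format_formula(parse_formula(format_formula(f))), cs[2])
  }
  expect_equal(unclass(parse_formula("C7H6O4"))[["C"]], 7)
  expect_equal(unclass(parse_formula("H2O"))[["O"]], 1)
  expect_error(parse_formula("C7Xx2"), "unknown element")
  expect_error(parse_formula("7CH"), "malformed")
  expect_error(ef(C = -1), "non-negative")
})

test_that("monoisotopic masses match the element-sum oracle", {
  # expected values frozen from the independent oracle in helper-mutasynth.R
  expect_identical(monoisotopic_mass(ef()), 0)
  for (f in c("C7H6O4", "C3H10N2", "C30H27N3O15", "C7H5O3", "S2H2")) {
    expect_equal(monoisotopic_mass(f), oracle_mass(f), tolerance = 1e-12)
  }
  expect_equal(round(monoisotopic_mass("C7H6O4"), 4), 154.0266)
  expect_equal(round(monoisotopic_mass("C3H10N2"), 4), 74.0844)
  expect_equal(mass_constants()$water, 18.0105646, tolerance = 1e-7)
  expect_error(monoisotopic_mass(structure(c(Xx = 1), class = "elemental_formula",
                                           names = "Xx")), "no mass entry")
})

test_that("protonated m/z follows the proton-mass convention", {
  expect_equal(round(protonated_mz(0), 4), 1.0073)
  expect_equal(round(protonated_mz(monoisotopic_mass("C10H14N2O3")), 4),
               211.1077)
  expect_equal(round(protonated_mz(monoisotopic_mass("C30H27N3O15")), 4),
               670.1515)
  expect_error(protonated_mz(-1), "non-negative")
})

test_that("condense implements a + b - n waters with feasibility checks", {
  expect_identical(format_formula(condense("C7H6O4", "C3H10N2", 1)),
                   "C10H14N2O3")
  f <- parse_formula("C7H6O4")
  expect_identical(format_formula(condense(f, ef(), 0)), "C7H6O4")
  # open DHB-Thr cap: mass difference between capped-open and bare
  # intermediate species
  expect_equal(round(monoisotopic_mass(condense("C7H6O4", "C4H9NO3", 2)), 4),
               237.0637)
  expect_error(condense("H2O", "H2O", 3), "infeasible")
})

test_that("formula arithmetic is commutative, associative, additive in mass", {
  set.seed(7)
  els <- c("C", "H", "N", "O", "S")
  rand_f <- function() {
    n <- sample(2:4, 1)
    picks <- sample(els, n)
    ef(stats::setNames(sample(1:20, n, replace = TRUE), picks))
  }
  for (i in 1:25) {
    # guarantee a water is available so condense() is feasible
    a <- rand_f() + ef(H = 2, O = 1); b <- rand_f(); c <- rand_f()
    expect_true(a + b == b + a)
    expect_true((a + b) + c == a + (b + c))
    expect_equal(monoisotopic_mass(a + b),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-12)
    expect_equal(monoisotopic_mass(condense(a, b, 1)),
                 monoisotopic_mass(a) + monoisotopic_mass(b) - 18.0105646,
                 tolerance = 1e-7)
  }
})

test_that("shipped registry reproduces every published intermediate mass", {
  reg <- read_precursor_registry()
  expect_identical(nrow(reg), 25L)
  expect_identical(reg$name[reg$id == 5], "putrescine")
  ref <- reference_dataset("products")
  interm <- ref[grepl("^[0-9]+$", ref$molecule), ]
  # partial-incorporation precursors of the source study
  expect_setequal(as.integer(interm$molecule),
                  c(1, 2, 4, 5, 6, 7, 9, 10, 11, 12, 21))
  for (i in seq_len(nrow(interm))) {
    p <- precursor(as.integer(interm$molecule[i]), reg)
    mz <- protonated_mz(monoisotopic_mass(condense(building_block("DHB")$formula,
                                                   p$formula, 1)))
    expect_lt(abs(mz - interm$calc_mz[i]), 5e-4)
  }
})

test_that("registry reader validates structure and formulas", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tformula\tn_primary_amines\tn_secondary_amines\tconcentration",
               "1\tbadmol\tC7Qq\t1\t0\t1 mM"), tmp)
  expect_error(read_precursor_registry(tmp), "row 1")
  writeLines("id\tname\tformula", tmp)
  expect_error(read_precursor_registry(tmp), "missing column")
})
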