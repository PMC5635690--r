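test_that("cap compositions are the four DHB-amino-acid acyl groups", {
  caps <- acyl_caps()
  adds <- vapply(caps, function(cp) round(monoisotopic_mass(cp$addition), 4), 0)
  expect_equal(adds, c(Tc = 219.0532, To = 237.0637, Sc = 205.0375,
                       So = 223.0481))
  expect_identical(format_formula(caps$Tc$addition), "C11H9NO4")
  expect_identical(format_formula(caps$So$addition), "C10H9NO5")
  expect_true(caps$Tc$cyclized)
  expect_false(caps$To$cyclized)
})

test_that("intermediates and full analogs reproduce published masses", {
  # published calc [M+H]+ values, verified against the element-sum oracle
  cases <- list(
    list(id = 5, cap = NULL, mz = 225.1234),   # aminochelin
    list(id = 21, cap = NULL, mz = 281.1860),
    list(id = 1, cap = "Tc", mz = 430.1609),   # serratiochelin
    list(id = 2, cap = "So", mz = 505.2293),
    list(id = 9, cap = "Sc", mz = 492.1765)
  )
  for (cs in cases) {
    prod <- make_intermediate(precursor(cs$id))
    if (!is.null(cs$cap)) prod <- make_full_analog(prod, cs$cap)
    expect_equal(round(prod$mz, 4), cs$mz)
    expect_equal(prod$mz, prod$neutral_mass + 1.00727646, tolerance = 1e-12)
    expect_equal(prod$neutral_mass, monoisotopic_mass(prod$formula),
                 tolerance = 1e-12)
  }
  expect_identical(make_full_analog(make_intermediate(precursor(1)), "Tc")$id,
                   "M1Tc")
})

test_that("precursors without usable amines are rejected", {
  expect_error(make_intermediate(precursor(18)), "no acylatable amine") # urea
  # a single-site precursor cannot take a cap
  p25 <- make_intermediate(precursor(25))
  expect_error(make_full_analog(p25, "Tc"), "second acylatable amine")
  # secondary amines can be switched off: benzylethylenediamine then has 1 site
  p9 <- make_intermediate(precursor(9), secondary_ok = FALSE)
  expect_error(make_full_analog(p9, "Tc", secondary_ok = FALSE),
               "second acylatable amine")
})

test_that("enumerate_products obeys the count law and collapses isobars", {
  reg <- read_precursor_registry()
  # brute-force count law on small sub-registries
  for (ids in list(c(1), c(1, 5), c(1, 9, 18), c(2, 4, 6, 7, 21))) {
    sub <- reg[reg$id %in% ids, ]
    for (caps in list(character(0), "Tc", c("Tc", "To", "Sc", "So"))) {
      cfg <- enumeration_config(caps = caps)
      prods <- suppressWarnings(enumerate_products(sub, cfg))
      expected <- 0L
      for (id in ids) {
        s <- n_acyl_sites(precursor(id, reg))
        if (s >= 1L) expected <- expected + 1L
        if (s >= 2L) expected <- expected + length(caps)
      }
      expect_length(prods, expected)
    }
  }
  # the two aromatic C8H12N2 diamines give mass-identical intermediates
  sub <- reg[reg$id %in% c(7, 11), ]
  prods <- enumerate_products(sub, enumeration_config(caps = character(0)))
  expect_length(prods, 2L)
  expect_equal(round(prods[[1]]$mz, 4), 273.1234)
  expect_equal(prods[[1]]$mz, prods[[2]]$mz, tolerance = 1e-12)
  # regio-isomeric placements collapse to one product with multiplicity
  expect_identical(make_intermediate(precursor(1))$multiplicity, 2L)
  expect_length(enumerate_products(reg[0, ], enumeration_config()), 0L)
  expect_warning(enumerate_products(reg[reg$id == 18, ]), "skipped")
})

test_that("Ser/Thr swap and cyclization shift masses by CH2 and H2O", {
  cands <- default_candidates()
  ids <- vapply(cands, `[[`, "", "id")
  mz <- vapply(cands, `[[`, 0, "mz")
  swapped <- function(id) chartr("TS", "ST", id)  # Tc<->Sc, To<->So
  for (i in seq_along(ids)) {
    id2 <- swapped(ids[i])
    if (id2 != ids[i] && id2 %in% ids) {
      delta <- mz[i] - mz[match(id2, ids)]
      expect_equal(abs(delta), 14.0157, tolerance = 1e-4)
    }
    # closed vs open cap of the same amino acid differ by one water
    if (grepl("c$", ids[i])) {
      id3 <- sub("c$", "o", ids[i])
      if (id3 %in% ids)
        expect_equal(mz[match(id3, ids)] - mz[i], 18.0106, tolerance = 1e-4)
    }
  }
})

test_that("vibriobactin (double-DHB species) is never emitted", {
  cands <- default_candidates()
  for (p in cands) {
    steps <- p$provenance$steps
    if (!is.null(steps)) {
      expect_lte(sum(vapply(steps, function(s) s$block == "DHB", TRUE)), 1L)
      expect_lte(length(steps), 2L)  # one DHB amide + at most one cap
    }
  }
  # no candidate reaches the mass of a doubly-capped norspermidine species
  m6tc <- candidate_by_id("M6Tc")
  double <- m6tc$mz + monoisotopic_mass(acyl_caps("Tc")$Tc$addition)
  expect_false(any(abs(vapply(cands, `[[`, 0, "mz") - double) < 0.01))
})

test_that("enterobactin series masses and naming follow the published set", {
  expect_equal(round(ent_oligomer("Ser", 3, cyclic = TRUE)$mz, 4), 670.1515)
  expect_equal(round(ent_oligomer("Ser", 3)$mz, 4), 688.1621)
  expect_equal(round(ent_oligomer("Ser", 2)$mz, 4), 465.1140)
  expect_equal(round(ent_oligomer("Ser", 1)$mz, 4), 242.0659)
  expect_equal(round(ent_oligomer("Thr", 2)$mz, 4), 493.1453)
  expect_identical(ent_oligomer("Ser", 3, cyclic = TRUE)$id, "Ent")
  expect_identical(ent_oligomer("Ser", 3)$id, "Ent trimer")
  expect_identical(ent_oligomer("Thr", 2)$id, "Thr-Ent dimer")
  # linear trimer exceeds the macrocycle by exactly one water
  expect_equal(ent_oligomer("Ser", 3)$mz - ent_oligomer("Ser", 3, TRUE)$mz,
               18.0105646, tolerance = 1e-7)
  expect_error(ent_oligomer("Ser", 2, cyclic = TRUE), "n = 3")
  expect_length(enumerate_ent_series("Ser", 3, "linear"), 3L)
})
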