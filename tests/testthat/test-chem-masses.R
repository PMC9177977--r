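test_that("formula masses reproduce hand-summed monoisotopic values", {
  expect_identical(formulaMass(elementalFormula()), 0)
  # hand sums from the monoisotopic atomic masses
  expect_equal(formulaMass("C10H13N5O4"), 267.0968, tolerance = 1e-4 / 267)
  expect_equal(formulaMass("H2O"), 18.0106, tolerance = 1e-4 / 18)
  expect_error(elementalFormula(C = -1), "non-negative")
  expect_error(parseFormula("C2Xx3"), "unsupported|parse")
})

test_that("formula arithmetic is element-wise and never goes negative", {
  set.seed(1)
  for (i in 1:20) {
    a <- elementalFormula(C = sample(0:20, 1), H = sample(0:30, 1),
                          N = sample(0:5, 1), O = sample(0:10, 1))
    b <- elementalFormula(C = sample(0:20, 1), H = sample(0:30, 1),
                          P = sample(0:2, 1), S = sample(0:2, 1))
    expect_equal(formulaMass(addFormula(a, b)),
                 formulaMass(a) + formulaMass(b))
    expect_equal(subtractFormula(addFormula(a, b), b), a)
  }
  expect_error(subtractFormula("CO", "H2O"), "negative")
})

test_that("digest products match the quoted instrument m/z values", {
  # quoted 2-dp values are truncations of the computed masses
  expect_equal(truncateAt(mzMH(buildProduct("P", "Fmoc", "RNaseI"))), 587.22)
  expect_equal(truncateAt(mzMH(buildProduct("M", "formyl", "RNaseI"))), 427.13)
  # the 476.1057 isobar value equals the NEUTRAL monoisotopic mass of
  # Glu-AMP (and N-acetyl-Ser-AMP), although reported as an [M+H]+ ion
  expect_equal(round(neutralMass(buildProduct("E", "none", "NucleaseP1")), 4),
               476.1057)
  expect_equal(round(neutralMass(buildProduct("S", "acetyl", "NucleaseP1")), 4),
               476.1057)
  expect_error(buildProduct("X", "none", "RNaseI"), "unknown amino-acid")
})

test_that("digestion and modification mass shifts are the expected constants", {
  for (aa in c("G", "E", "M", "W", "P")) {
    dP1 <- neutralMass(buildProduct(aa, "none", "NucleaseP1")) -
      neutralMass(buildProduct(aa, "none", "RNaseI"))
    expect_equal(dP1, 79.9663, tolerance = 1e-4 / 80)  # HPO3
    dAc <- neutralMass(buildProduct(aa, "acetyl", "RNaseI")) -
      neutralMass(buildProduct(aa, "none", "RNaseI"))
    expect_equal(dAc, 42.0106, tolerance = 1e-4 / 42)  # ketene condensation
  }
})

test_that("structural isomers and isobars group as expected", {
  # Leu/Ile identical under every modification; Glu == N-acetyl-Ser
  for (mod in c("none", "acetyl", "Fmoc")) {
    expect_identical(productFormula(buildProduct("L", mod, "NucleaseP1")),
                     productFormula(buildProduct("I", mod, "NucleaseP1")))
  }
  expect_identical(productFormula(buildProduct("E", "none", "NucleaseP1")),
                   productFormula(buildProduct("S", "acetyl", "NucleaseP1")))

  g1 <- findIsobars(list(buildProduct("L", "acetyl", "NucleaseP1"),
                         buildProduct("I", "acetyl", "NucleaseP1")), 5)
  expect_length(g1, 1)
  g2 <- findIsobars(list(buildProduct("E", "none", "NucleaseP1"),
                         buildProduct("S", "acetyl", "NucleaseP1")), 5)
  expect_length(g2, 1)
  g3 <- findIsobars(list(buildProduct("G", "acetyl", "NucleaseP1"),
                         buildProduct("W", "acetyl", "NucleaseP1")), 5)
  expect_length(g3, 2)
  expect_true(all(lengths(g3) == 1))
})

test_that("the species table carries masses and isobar ids for all 20 aa", {
  tab <- digestProductTable("NucleaseP1", mods = c("none", "acetyl"))
  expect_equal(nrow(tab), 40)
  expect_true(all(tab$neutral_mass > 0))
  expect_equal(tab$mz_mh - tab$neutral_mass, rep(1.0072765, 40))
  # Glu(none) and Ser(acetyl) share an isobar group
  gE <- tab$isobar_group[tab$code == "E" & tab$modification == "none"]
  gS <- tab$isobar_group[tab$code == "S" & tab$modification == "acetyl"]
  expect_identical(gE, gS)
  aat <- aminoAcidTable()
  expect_equal(nrow(aat), 20)
  expect_identical(aat$formula[aat$code == "L"], aat$formula[aat$code == "I"])
})
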