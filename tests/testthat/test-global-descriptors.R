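# Independent re-evaluation of every descriptor formula, deliberately coded
# through the (sum, gap) parametrization rather than the HOMO/LUMO one used
# by the implementation.
bruteDescriptors <- function(h, l) {
  s <- h + l
  d <- l - h
  list(chi = -s / 2, eta = d, softness = 1 / d,
       omega = (s / 2)^2 / (2 * d),
       omega_minus = (2 * s - d)^2 / (16 * d),
       omega_plus = (2 * s + d)^2 / (16 * d))
}

test_that("each descriptor reproduces the published apratoxin values", {
  expect_equal(electronegativity(-6.24, -1.22), 3.73)
  expect_equal(electronegativity(-6.20, -1.74), 3.97)
  expect_equal(chemicalPotential(-6.24, -1.22), -3.73)
  expect_equal(hardness(-6.24, -1.22), 5.02)
  expect_equal(hardness(-6.04, -1.76), 4.28)
  expect_equal(round(softness(5.02), 2), 0.20)
  expect_equal(round(softness(4.39), 2), 0.23)
  expect_equal(round(electrophilicity(-6.24, -1.22), 2), 1.39)
  expect_equal(round(electrophilicity(-6.04, -1.76), 2), 1.78)
  expect_equal(round(electrodonatingPower(-6.24, -1.22), 2), 4.95)
  expect_equal(round(electrodonatingPower(-6.12, -1.79), 2), 5.86)
  expect_equal(round(electroacceptingPower(-6.24, -1.22), 2), 1.22)
  expect_equal(round(electroacceptingPower(-6.12, -1.79), 2), 1.91)
  expect_equal(netElectrophilicity(4.95, 1.22), 6.17)
  expect_equal(netElectrophilicity(0, 0), 0)
})

test_that("symmetric frontier orbitals give the closed-form limits", {
  for (x in c(0.5, 1, 2.5)) {
    expect_equal(electronegativity(-x, x), 0)
    expect_equal(electrophilicity(-x, x), 0)
    expect_equal(electrodonatingPower(-x, x), x / 8)
    expect_equal(electroacceptingPower(-x, x), x / 8)
    expect_equal(hardness(-x, 0), x)
  }
})

test_that("preconditions and domain errors are enforced", {
  expect_error(electronegativity(-1, -2), "strictly below")
  expect_error(softness(0), "positive")
  expect_error(softness(-1), "positive")
  expect_error(classifyElectrophile(-0.1), "non-negative")
})

test_that("computeGlobalDescriptors agrees with an independent oracle", {
  set.seed(23)
  rec <- randomRecords(100, with_gs = FALSE, with_somo = FALSE)
  got <- computeGlobalDescriptors(rec, ref = -8.79)
  ora <- bruteDescriptors(unname(epsHOMO(rec)), unname(epsLUMO(rec)))
  for (col in names(ora))
    expect_equal(got[[col]], ora[[col]], tolerance = 1e-12)
  expect_equal(got$nucleophilicity, unname(epsHOMO(rec)) + 8.79,
               tolerance = 1e-12)
  expect_equal(got$net_electrophilicity, ora$omega_minus + ora$omega_plus,
               tolerance = 1e-12)
  expect_equal(got$mu, -got$chi)
})

test_that("algebraic identities hold across random valid inputs", {
  set.seed(29)
  n <- 1e4
  h <- runif(n, -12, -2)
  l <- h + runif(n, 0.1, 8)
  chi <- electronegativity(h, l)
  eta <- hardness(h, l)
  wm <- electrodonatingPower(h, l)
  wp <- electroacceptingPower(h, l)
  expect_lt(max(abs(wm - wp - chi)), 1e-9)
  expect_lt(max(abs(netElectrophilicity(wm, wp) - (wm + wp))), 1e-12)
  expect_lt(max(abs(softness(eta) * eta - 1)), 1e-12)
  expect_true(all(wm >= 0 & wp >= 0 &
                  electrophilicity(h, l) >= 0 & eta > 0))
})

test_that("descriptors respond monotonically to the frontier energies", {
  # hardness strictly increases in the LUMO energy at fixed HOMO
  l_grid <- seq(-3, 1, length.out = 30)
  expect_true(all(diff(hardness(-7, l_grid)) > 0))
  # electrophilicity strictly increases in |HOMO+LUMO| at fixed gap
  gap <- 4
  shift <- seq(0, 4, length.out = 25)
  omega <- electrophilicity(-4 - gap / 2 - shift, -4 + gap / 2 - shift)
  expect_true(all(diff(omega) > 0))
})

test_that("the nucleophilicity reference calibrates from (HOMO, N) pairs", {
  # brute-force oracle: offset model solved as the mean difference
  h <- apratoxinFixture()
  n_printed <- apratoxinPrintedDescriptors()$nucleophilicity
  expected_ref <- mean(unname(epsHOMO(h)) - n_printed)
  ref <- calibrateNucleophilicityReference(unname(epsHOMO(h)), n_printed)
  expect_equal(ref@epsHomoRef, expected_ref)
  expect_equal(round(ref@epsHomoRef, 2), -8.79)
  expect_lt(ref@residualSd, 0.01)

  single <- calibrateNucleophilicityReference(-6.0, 2.0)
  expect_equal(single@epsHomoRef, -8.0)
  dup <- calibrateNucleophilicityReference(c(-6.0, -6.0), c(2.0, 2.0))
  expect_equal(dup@epsHomoRef, single@epsHomoRef)
  expect_error(calibrateNucleophilicityReference(numeric(0), numeric(0)),
               "at least one")

  expect_equal(nucleophilicity(-6.04, ref = -8.79), 2.75)
  expect_equal(nucleophilicity(-8.79, ref = -8.79), 0)
})

test_that("classification follows the published scales with weak boundaries", {
  expect_identical(as.character(classifyElectrophile(c(1.39, 0.5, 1.81))),
                   c("moderate", "marginal", "strong"))
  # boundary points go to the weaker class (the quoted scale is strict)
  expect_identical(as.character(classifyElectrophile(c(1.5, 0.8))),
                   c("moderate", "marginal"))
  expect_identical(as.character(classifyNucleophile(c(2.56, 3.5, 1.9))),
                   c("moderate", "strong", "marginal"))
  # the nucleophile scale closes both boundaries on moderate
  expect_identical(as.character(classifyNucleophile(c(2.0, 3.0))),
                   c("moderate", "moderate"))
})

test_that("the full descriptor table is rebuilt from the packaged energies", {
  got <- computeGlobalDescriptors(apratoxinFixture())
  ref <- apratoxinPrintedDescriptors()
  cols <- setdiff(names(ref), "id")
  # the published inputs are rounded to 2 dp; the worst propagated error
  # across the 56 cells is 0.0152 (net electrophilicity of B)
  for (col in cols)
    expect_lt(max(abs(got[[col]] - ref[[col]])), 0.016)
  expect_identical(as.character(got$nucleophile_class), rep("moderate", 7))
  # row A rebuilt from its printed inputs matches print at 2 dp for every
  # column computed from the orbital energies alone (the calibrated
  # nucleophilicity lands at 2.553 vs the printed 2.56)
  for (col in setdiff(cols, "nucleophilicity"))
    expect_equal(round(got[[col]][got$id == "A"], 2),
                 ref[[col]][ref$id == "A"])
})
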