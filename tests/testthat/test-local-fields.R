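singleVoxelTriplet <- function(vm1, v, vp1) {
  mk <- function(x) scalarField(array(x, dim = c(1, 1, 1)))
  densityTriplet(mk(vm1), mk(v), mk(vp1))
}

test_that("Fukui functions and dual descriptor obey the single-voxel arithmetic", {
  t1 <- singleVoxelTriplet(4, 5, 6)
  expect_equal(as.vector(fieldValues(fukuiPlus(t1))), 1.0)
  expect_equal(as.vector(fieldValues(fukuiMinus(t1))), 1.0)
  t2 <- singleVoxelTriplet(4, 5, 7)
  expect_equal(as.vector(fieldValues(dualDescriptor(t2))), 1.0)  # 7 - 10 + 4

  same <- singleVoxelTriplet(5, 5, 5)
  expect_equal(as.vector(fieldValues(fukuiPlus(same))), 0)
  expect_equal(as.vector(fieldValues(dualDescriptor(same))), 0)
})

test_that("geometry mismatches are rejected with the offending header field", {
  a <- scalarField(array(1, dim = c(2, 2, 2)))
  b <- scalarField(array(1, dim = c(2, 2, 2)), origin = c(1, 0, 0))
  expect_error(a - b, "origin")
  c2 <- scalarField(array(1, dim = c(2, 2, 3)))
  expect_error(a - c2, "counts")
  expect_error(densityTriplet(a, b, a), "origin")
})

test_that("synthetic triplets satisfy the Fukui/dual integral identities", {
  spec <- syntheticSpec(seed = 31, grid_counts = c(32L, 32L, 32L),
                        n_atoms = 4L, electron_count = 12L)
  tr <- generateDensityTriplet(spec)
  expect_equal(fieldIntegral(tr@rhoNm1), 11, tolerance = 1e-9)
  expect_equal(fieldIntegral(tr@rhoN), 12, tolerance = 1e-9)
  expect_equal(fieldIntegral(tr@rhoNp1), 13, tolerance = 1e-9)

  fp <- fukuiPlus(tr); fm <- fukuiMinus(tr); dd <- dualDescriptor(tr)
  expect_lt(abs(fieldIntegral(fp) - 1), 1e-3)
  expect_lt(abs(fieldIntegral(fm) - 1), 1e-3)
  expect_lt(abs(fieldIntegral(dd)), 2e-3)
  # dual descriptor is exactly the difference of the Fukui fields
  expect_equal(fieldValues(dd), fieldValues(fp) - fieldValues(fm),
               tolerance = 1e-12)
  # outputs preserve the input grid header bit-for-bit
  for (f in list(fp, fm, dd)) {
    expect_identical(gridOrigin(f), gridOrigin(tr@rhoN))
    expect_identical(gridAxes(f), gridAxes(tr@rhoN))
    expect_identical(gridAtoms(f), gridAtoms(tr@rhoN))
  }
})

test_that("sign partition splits and reconstructs a field exactly", {
  f <- scalarField(array(c(-2, -0.5, 0.5, 2, 0, 1, -1, 0.25),
                         dim = c(2, 2, 2)))
  parts <- signPartition(f, isovalue = 1)
  expect_equal(sort(unique(as.vector(fieldValues(parts$positive)))), c(0, 2))
  expect_equal(sort(unique(as.vector(fieldValues(parts$negative)))), c(-2, 0))

  # with isovalue 0 the two parts partition the field exactly
  p0 <- signPartition(f, 0)
  expect_equal(fieldValues(p0$positive) + fieldValues(p0$negative),
               fieldValues(f))
  expect_true(all(fieldValues(p0$positive) >= 0))
  expect_true(all(fieldValues(p0$negative) <= 0))

  zero <- scalarField(array(0, dim = c(1, 1, 1)))
  z <- signPartition(zero)
  expect_equal(as.vector(fieldValues(z$positive)), 0)
  expect_equal(as.vector(fieldValues(z$negative)), 0)
  expect_error(signPartition(f, -0.1), "non-negative")
})

test_that("field integration is the voxel-volume-weighted sum and is linear", {
  unit <- scalarField(array(1, dim = c(1, 1, 1)))  # 1 bohr^3 voxel
  expect_equal(fieldIntegral(unit), 1.0)

  set.seed(37)
  f <- randomField(c(4L, 3L, 2L))
  g <- f; g@values <- array(rnorm(24), dim = dim(f@values))
  expect_equal(fieldIntegral(2.5 * f + -1.25 * g),
               2.5 * fieldIntegral(f) - 1.25 * fieldIntegral(g),
               tolerance = 1e-12)
  # non-orthogonal axes: the parallelepiped determinant is the voxel volume
  skew <- scalarField(array(1, dim = c(1, 1, 1)),
                      axes = matrix(c(1, 0.2, 0, 0, 1, 0.3, 0, 0, 1), 3, 3,
                                    byrow = TRUE))
  expect_equal(fieldIntegral(skew), det(gridAxes(skew)))
})

test_that("condensed dual descriptor works per atom and balances to zero", {
  expect_equal(condensedDual(p_nm1 = c(0.5, 0.5), p_n = c(1, 1),
                             p_np1 = c(1.8, 1.2)), c(0.3, -0.3))
  expect_equal(condensedDual(p_nm1 = c(1, 2), p_n = c(1, 2),
                             p_np1 = c(1, 2)), c(0, 0))
  expect_error(condensedDual(p_nm1 = 1, p_n = c(1, 2), p_np1 = c(1, 2)),
               "atom counts")

  # populations that sum to each state's electron count balance exactly
  set.seed(41)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    N <- 10
    shares <- function(total) { w <- runif(k); total * w / sum(w) }
    dd <- condensedDual(data.frame(p_nm1 = shares(N - 1), p_n = shares(N),
                                   p_np1 = shares(N + 1)))
    expect_equal(sum(dd), 0, tolerance = 1e-12)
  }
})

test_that("dual-descriptor lobes export as a readable cube pair", {
  spec <- syntheticSpec(seed = 43, grid_counts = c(8L, 8L, 8L),
                        n_atoms = 2L, electron_count = 4L)
  tr <- generateDensityTriplet(spec)
  stem <- file.path(withr::local_tempdir(), "mol")
  paths <- writeDualDescriptorCubes(tr, stem)
  expect_true(all(file.exists(paths)))
  pos <- readCube(paths[1]); neg <- readCube(paths[2])
  expect_true(all(fieldValues(pos) >= 0))
  expect_true(all(fieldValues(neg) <= 0))
  dd <- dualDescriptor(tr)
  expect_equal(fieldValues(pos) + fieldValues(neg), fieldValues(dd),
               tolerance = 1e-5)
})
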