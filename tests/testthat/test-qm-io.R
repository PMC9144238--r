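test_that("energy records are read from delimited text with unit handling", {
  txt <- c("id,label,eps_homo,eps_lumo,eps_somo_anion,unit",
           "A,Apratoxin A,-6.24,-1.22,-1.18,eV")
  rec <- readEnergyRecords(txt)
  expect_s4_class(rec, "EnergyRecordSet")
  expect_equal(unname(epsHOMO(rec)), -6.24)
  expect_equal(unname(epsLUMO(rec)), -1.22)
  expect_equal(unname(epsSOMOAnion(rec)), -1.18)

  # hartree rows are converted on input; eV is the only internal unit
  hr <- readEnergyRecords(c("id,eps_homo,eps_lumo,unit",
                            "X,-0.22930,-0.04483,hartree"))
  expect_equal(unname(epsHOMO(hr)), -0.22930 * 27.211386245988)
  expect_equal(round(unname(epsHOMO(hr)), 4), -6.2396)
  expect_equal(round(unname(epsLUMO(hr)), 4), -1.2199)

  # header-only file gives an empty, valid set
  empty <- readEnergyRecords("id,eps_homo,eps_lumo")
  expect_length(empty, 0)

  # tab-separated input is auto-detected
  tsv <- readEnergyRecords(c("id\teps_homo\teps_lumo", "A\t-6.0\t-1.0"))
  expect_equal(unname(epsHOMO(tsv)), -6.0)
})

test_that("energy-record schema and validity violations are reported by name", {
  expect_error(readEnergyRecords(c("id,eps_homo", "A,-6.0")), "eps_lumo")
  expect_error(readEnergyRecords(c("id,eps_homo,eps_lumo", "bad,-1.0,-6.0")),
               "bad")
  expect_error(readEnergyRecords(c("id,eps_homo,eps_lumo,unit",
                                   "A,-6,-1,kcal")), "kcal")
  expect_error(readEnergyRecords(c("id,eps_homo,eps_lumo", "A,oops,-1.0")),
               "eps_homo")
  expect_error(energyRecords("A", eps_homo = -1, eps_lumo = -1),
               "strictly below")
  expect_error(energyRecords(c("A", "A"), eps_homo = -6, eps_lumo = -1),
               "unique")
})

test_that("records round-trip through writeEnergyRecords", {
  set.seed(11)
  rec <- randomRecords(5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeEnergyRecords(rec, path)
  back <- readEnergyRecords(path)
  num_cols <- c("eps_homo", "eps_lumo", "eps_somo_anion",
                "e_gs_nm1", "e_gs_n", "e_gs_np1")
  expect_identical(recordIds(back), recordIds(rec))
  expect_equal(recordData(back)[, num_cols], recordData(rec)[, num_cols],
               tolerance = 1e-12)
})

test_that("unit conversion is an exact linear bijection", {
  x <- c(-1000, -1, 0, 1e-9, 27.211386245988)
  expect_equal(evToHartree(hartreeToEV(x)), x, tolerance = 1e-12)
  expect_equal(hartreeToEV(1), 27.211386245988)
})

test_that("cube reading honours the file ordering and the format corners", {
  lines <- c("comment 1", "comment 2",
             "    1    0.0 0.0 0.0",
             "    2    1.0 0.0 0.0",
             "    2    0.0 1.0 0.0",
             "    2    0.0 0.0 1.0",
             "    6    6.0 0.5 0.5 0.5",
             " 0.0 1.0 2.0 3.0 4.0 5.0",
             " 6.0 7.0")
  f <- readCube(lines)
  expect_equal(gridCounts(f), c(2L, 2L, 2L))
  # file order is last-axis-fastest: zero-based (1,0,0) holds value 4
  expect_equal(fieldValues(f)[2, 1, 1], 4.0)
  expect_equal(fieldValues(f)[1, 1, 2], 1.0)
  expect_equal(fieldValues(f)[1, 2, 1], 2.0)

  one <- readCube(c("c", "c", " 1 0 0 0", " 1 1 0 0", " 1 0 1 0", " 1 0 0 1",
                    " 1 1.0 0 0 0", " 2.0"))
  expect_equal(as.vector(fieldValues(one)), 2.0)

  # negative atom count: the extra orbital-index line is skipped
  neg <- readCube(c("c", "c", " -1 0 0 0", " 1 1 0 0", " 1 0 1 0",
                    " 1 0 0 1", " 1 1.0 0 0 0", " 1 1", " 3.5"))
  expect_equal(as.vector(fieldValues(neg)), 3.5)

  # truncation and non-numeric tokens are reported
  expect_error(readCube(lines[1:8]), "truncation")
  bad <- lines; bad[8] <- " 0.0 1.0 oops 3.0 4.0 5.0"
  expect_error(readCube(bad), "line 8")
})

test_that("a written 1x1x1 cube has the standard 8-line layout", {
  f <- scalarField(array(2.0, dim = c(1, 1, 1)))
  lines <- writeCube(f)
  expect_length(lines, 8)
  expect_identical(writeCube(f), lines)  # byte-deterministic
})

test_that("cube write/read round-trips metadata exactly and values to 1e-6", {
  set.seed(42)
  for (counts in list(c(1L, 1L, 1L), c(2L, 3L, 4L), c(5L, 5L, 5L))) {
    f <- randomField(counts)
    path <- withr::local_tempfile(fileext = ".cube")
    writeCube(f, path)
    g <- readCube(path)
    expect_identical(gridCounts(g), gridCounts(f))
    expect_equal(gridOrigin(g), gridOrigin(f), tolerance = 1e-6)
    expect_equal(gridAxes(g), gridAxes(f), tolerance = 1e-6)
    expect_equal(fieldValues(g), fieldValues(f), tolerance = 1e-6)
  }
})

test_that("scalar-field validity rejects degenerate grids", {
  expect_error(scalarField(array(1, dim = c(1, 1, 1)), axes = -diag(3)),
               "volume")
  expect_error(scalarField(array(NA_real_, dim = c(1, 1, 1))), "finite")
  expect_error(scalarField(1:7, counts = c(2, 2, 2)), "prod")
})
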