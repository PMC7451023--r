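# Ensemble container and structure/boost/grid I/O.

test_that("multi-model PDB reading preserves frames, atoms and order", {
  f1 <- cbind(c(0, 1, 2), 0, 0)
  f2 <- f1 + 1
  path <- write_pdb_fixture(list(f1, f2), tempfile(fileext = ".pdb"),
                            names = c("N", "CA", "C"))
  ens <- read_multimodel_pdb(path)
  expect_equal(n_frames(ens), 2L)
  expect_equal(n_atoms(ens), 3L)
  expect_equal(ens$atoms$name, c("N", "CA", "C"))
  expect_equal(frame_coords(ens, 1), f1, ignore_attr = TRUE)
  expect_equal(frame_coords(ens, 2), f2, ignore_attr = TRUE)

  ca <- read_multimodel_pdb(path, selection = "CA")
  expect_equal(n_atoms(ca), 1L)
  expect_equal(n_frames(ca), 2L)
  # reader/selection commute: selecting after reading equals selecting within
  expect_equal(ca$coords, select_atoms(ens, "CA")$coords)
})

test_that("single-block PDB yields one frame", {
  path <- write_pdb_fixture(list(cbind(0:2, 0, 0)),
                            tempfile(fileext = ".pdb"))
  lines <- readLines(path)
  writeLines(lines[!grepl("^(MODEL|ENDMDL)", lines)], path)
  expect_equal(n_frames(read_multimodel_pdb(path)), 1L)
})

test_that("structurally inconsistent MODELs are rejected with the model id", {
  f1 <- cbind(c(0, 1, 2), 0, 0)
  path <- write_pdb_fixture(list(f1, f1), tempfile(fileext = ".pdb"))
  lines <- readLines(path)
  drop <- max(grep("^ATOM", lines))
  writeLines(lines[-drop], path)
  expect_error(read_multimodel_pdb(path), "MODEL 2",
               class = "surfplast_structure_error")
})

test_that("unparseable coordinates raise a parse error with the line number", {
  path <- write_pdb_fixture(list(cbind(0:2, 0, 0)),
                            tempfile(fileext = ".pdb"))
  lines <- readLines(path)
  bad <- grep("^ATOM", lines)[2]
  substr(lines[bad], 33, 36) <- "abcd"
  writeLines(lines, path)
  expect_error(read_multimodel_pdb(path), paste0("line ", bad),
               class = "surfplast_parse_error")
})

test_that("boost tables read values, skip comments, and reject bad input", {
  p <- tempfile()
  writeLines(c("# header", "0.0", "1.5", "", "2.0 # inline"), p)
  b <- read_boost_series(p, 300)
  expect_equal(b$delta_v, c(0, 1.5, 2))
  expect_equal(b$temperature, 300)

  writeLines(c("# only comments", ""), p)
  expect_error(read_boost_series(p, 300), class = "surfplast_empty_error")

  writeLines(c("0.0", "-1.0"), p)
  expect_error(read_boost_series(p, 300), class = "surfplast_domain_error")

  writeLines(c("0.0", "oops"), p)
  expect_error(read_boost_series(p, 300), "line 2",
               class = "surfplast_parse_error")
})

test_that("boost series round-trips through its text format", {
  b <- boost_series(c(0, 0.123456789, 2.5), 310)
  p <- tempfile()
  write_boost_series(b, p)
  b2 <- read_boost_series(p, 310)
  expect_equal(b2$delta_v, b$delta_v)
})

test_that("boost/ensemble pairing is validated where they meet", {
  ens <- toy_ensemble(array(rnorm(2 * 3 * 3), c(2, 3, 3)))
  expect_error(check_boost_pairing(ens, boost_series(c(1, 2, 3), 300)),
               class = "surfplast_dimension_error")
  expect_true(check_boost_pairing(ens, boost_series(c(1, 2), 300)))
})

test_that("OpenDX grids round-trip geometry exactly and values closely", {
  g <- scalar_grid(c(0, 0, 0), 1, c(2, 2, 2), array(1, c(2, 2, 2)))
  p <- tempfile(fileext = ".dx")
  write_dx_grid(g, p)
  lines <- readLines(p)
  expect_match(lines[1], "gridpositions counts 2 2 2")

  vals <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  g2 <- scalar_grid(c(-1.5, 2, 0.25), 0.5, c(3, 4, 5), vals)
  write_dx_grid(g2, p)
  back <- read_dx_grid(p)
  expect_identical(back$dims, g2$dims)
  expect_equal(back$origin, g2$origin)
  expect_equal(back$spacing, g2$spacing)
  expect_lt(max(abs(back$values - g2$values)), 1e-6)

  expect_error(scalar_grid(c(0, 0, 0), 1, c(0, 2, 2)),
               class = "surfplast_domain_error")
})

test_that("B-factor export formats, clamps and validates values", {
  ens <- toy_ensemble(array(rep(c(0, 3.8, 7.6), each = 1), c(1, 3, 3)))
  p <- tempfile(fileext = ".pdb")
  write_bfactor_pdb(ens, c(1.234, 1e6, -5), p)
  atom_lines <- grep("^ATOM", readLines(p), value = TRUE)
  expect_equal(substr(atom_lines[1], 61, 66), "  1.23")
  expect_equal(substr(atom_lines[2], 61, 66), "999.99")
  expect_equal(substr(atom_lines[3], 61, 66), "  0.00")
  expect_error(write_bfactor_pdb(ens, c(1, 2), p),
               class = "surfplast_dimension_error")
})

test_that("ensembles reject inconsistent or non-finite input", {
  expect_error(structure_ensemble(tibble::tibble(serial = 1:2),
                                  array(0, c(1, 3, 3))),
               class = "surfplast_dimension_error")
  bad <- array(0, c(1, 2, 3))
  bad[1, 1, 1] <- NaN
  expect_error(toy_ensemble(bad), class = "surfplast_domain_error")
})
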