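test_that("peptide masses agree with the element-composition oracle", {
  tbl <- residue_mass_table()
  expect_equal(peptide_monoisotopic_mass("G"), 75.03203, tolerance = 1e-7)
  expect_equal(peptide_monoisotopic_mass("G"), oracle_peptide_mass("G"),
               tolerance = 1e-4)
  expect_equal(peptide_monoisotopic_mass("DALSSVQESQVAQQAR"),
               oracle_peptide_mass("DALSSVQESQVAQQAR"), tolerance = 1e-4)
  expect_equal(peptide_monoisotopic_mass("DALSSVQESQVAQQAR"), 1715.8438,
               tolerance = 1e-4)

  # every single residue agrees with its elemental formula
  for (code in names(tbl$residues)) {
    expect_equal(unname(tbl$residues[code]), oracle_residue_mass(code),
                 tolerance = 1e-4, label = code)
  }

  expect_error(peptide_monoisotopic_mass(""), "non-empty")
  expect_error(peptide_monoisotopic_mass("GAX"), "X")
})

test_that("mass is additive over concatenation", {
  set.seed(301)
  pool <- names(residue_mass_table()$residues)
  for (rep in 1:20) {
    a <- paste(sample(pool, sample(2:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(pool, sample(2:12, 1), replace = TRUE), collapse = "")
    expect_equal(peptide_monoisotopic_mass(paste0(a, b)),
                 peptide_monoisotopic_mass(a) + peptide_monoisotopic_mass(b) -
                   residue_mass_table()$water_mass)
  }
})

test_that("precursor m/z follows the protonation algebra", {
  tbl <- residue_mass_table()
  # the worked doubly charged tryptic peptide
  expect_equal(precursor_mz("DALSSVQESQVAQQAR", 2), 858.93, tolerance = 0.05)

  set.seed(302)
  pool <- names(tbl$residues)
  for (rep in 1:10) {
    pep <- paste(sample(pool, 8, replace = TRUE), collapse = "")
    mz1 <- precursor_mz(pep, 1)
    mz2 <- precursor_mz(pep, 2)
    expect_equal(mz1, 2 * mz2 - tbl$proton_mass)
    # m/z decreases with charge for fixed mass
    expect_true(all(diff(vapply(1:4, function(z) precursor_mz(pep, z),
                                numeric(1))) < 0))
  }
  expect_error(precursor_mz("GAG", 0), "charge")
})

test_that("b/y fragment series agree with the oracle and are complementary", {
  tbl <- residue_mass_table()
  fr <- fragment_mzs("DALSSVQESQVAQQAR")
  # y1 of an R-terminated peptide; b2 = D + A residues + proton
  expect_equal(fr$y[1], 175.119, tolerance = 1e-3)
  expect_equal(fr$y[1], oracle_residue_mass("R") +
                 oracle_formula_mass(c(H = 2, O = 1)) + oracle_proton,
               tolerance = 1e-4)
  expect_equal(fr$b[2], 187.071, tolerance = 1e-3)
  expect_equal(fr$b[2], oracle_residue_mass("D") + oracle_residue_mass("A") +
                 oracle_proton, tolerance = 1e-4)

  set.seed(303)
  pool <- names(tbl$residues)
  for (rep in 1:15) {
    pep <- paste(sample(pool, sample(2:15, 1), replace = TRUE), collapse = "")
    fr <- fragment_mzs(pep)
    n <- nchar(pep)
    expect_length(fr$b, n - 1)
    expect_length(fr$y, n - 1)
    expect_false(is.unsorted(fr$b))
    expect_false(is.unsorted(fr$y))
    # complementarity: b_{n-1} + y_1 = M + 2 protons (likewise all i)
    M <- peptide_monoisotopic_mass(pep)
    for (i in seq_len(n - 1)) {
      expect_equal(fr$b[i] + fr$y[n - i], M + 2 * tbl$proton_mass)
    }
  }
  expect_error(fragment_mzs("G"), "at least 2")
})

test_that("synthetic MS2 spectra have the advertised structure", {
  set.seed(304)
  sp <- synth_msms_spectrum("DALSSVQESQVAQQAR", 2L, 10L, 5.0,
                            precursor_scan = 9L)
  n <- nchar("DALSSVQESQVAQQAR")
  expect_length(sp$mz, 2 * (n - 1))
  expect_length(sp$noise, 2 * (n - 1))
  expect_true(all(sp$charge == 1L))
  expect_true(all(sp$intensity > 0))
  expect_equal(max(sp$intensity), 1e4)
  expect_true(all(sp$noise > 0))
  # every fragment below the protonated neutral mass
  expect_true(all(sp$mz < peptide_monoisotopic_mass("DALSSVQESQVAQQAR") +
                    residue_mass_table()$proton_mass))
  expect_true(sp$is_centroid)
})

test_that("the generator is seed-deterministic and seed-sensitive", {
  p <- synth_params(n_ms1 = 2, seed = 77)
  expect_identical(synth_run(p), synth_run(p))
  other <- synth_run(synth_params(n_ms1 = 2, seed = 78))
  expect_false(identical(synth_run(p), other))
  # and it does not disturb the caller's RNG stream
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(synth_run(p)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("run shape follows the acquisition cycle parameters", {
  run <- synth_run(synth_params(n_ms1 = 1, peptides_per_ms1 = 2,
                                max_ms_level = 2, seed = 1))
  expect_length(run, 3)
  forest <- build_scan_tree(run)
  expect_length(forest, 1)
  expect_length(forest[[1]]$children, 2)

  run3 <- synth_run(synth_params(n_ms1 = 2, peptides_per_ms1 = 1,
                                 max_ms_level = 3, seed = 1))
  lv <- vapply(run3$spectra, `[[`, integer(1), "ms_level")
  expect_true(3L %in% lv)
  ms3 <- run3$spectra[[which(lv == 3L)[1]]]
  parent <- Filter(function(s) s$scan_number == ms3$precursor_scan,
                   run3$spectra)[[1]]
  expect_equal(parent$ms_level, 2L)

  # MS1 scans are profile stencils over the pool precursors
  ms1 <- run3$spectra[[1]]
  expect_false(ms1$is_centroid)
  expect_equal(length(ms1$mz) %% 5, 0)
})

test_that("generated runs survive every storage path", {
  run <- synth_run(synth_params(n_ms1 = 2, max_ms_level = 3, seed = 31))
  expect_equal(nrow(validate_run(run)), 0)
  mzml <- withr::local_tempfile(fileext = ".mzML")
  h5r <- withr::local_tempfile(fileext = ".h5")
  h5t <- withr::local_tempfile(fileext = ".h5")
  write_mzml(run, mzml)
  expect_identical(parse_mzml(mzml), run)
  expect_identical(read_run(write_ragged(run, h5r)), run)
  expect_identical(read_run(write_tree(run, h5t)), run)
})
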