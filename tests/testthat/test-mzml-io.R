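test_that("binary codec matches byte-level expectations", {
  # eight zero bytes: IEEE-754 double 0.0, little-endian
  expect_equal(encode_binary_array(0.0), "AAAAAAAAAAA=")
  expect_equal(encode_binary_array(numeric(0)), "")
  expect_equal(decode_binary_array("", 64), numeric(0))

  v <- c(100.0, 200.5, 300.25)
  expect_identical(decode_binary_array(encode_binary_array(v, 64), 64), v)

  # 32-bit loses precision but stays within float32 relative error
  got <- decode_binary_array(encode_binary_array(v, 32, "zlib"), 32, "zlib")
  expect_equal(got, v, tolerance = 1e-6)
})

test_that("codec round-trip is the identity across precision x compression", {
  set.seed(202)
  for (rep in 1:25) {
    v <- stats::runif(sample(1:500, 1), 0, 2000)
    for (comp in c("none", "zlib")) {
      expect_identical(decode_binary_array(encode_binary_array(v, 64, comp),
                                           64, comp), v)
      got32 <- decode_binary_array(encode_binary_array(v, 32, comp), 32, comp)
      expect_equal(got32, v, tolerance = 1e-6)
    }
  }
})

test_that("codec errors are specific", {
  expect_error(encode_binary_array(c(1, NA)), "non-finite")
  expect_error(encode_binary_array(c(1, Inf)), "non-finite")
  expect_error(decode_binary_array("!!!not base64!!!", 64), "base64")
  # 6 bytes is not a multiple of 8
  six <- base64enc::base64encode(as.raw(1:6))
  expect_error(decode_binary_array(six, 64), "truncated")
  # valid base64, invalid zlib stream
  junk <- base64enc::base64encode(as.raw(rep(7, 16)))
  expect_error(decode_binary_array(junk, 64, "zlib"), "zlib")
})

test_that("mzML writer/reader round-trips a synthetic run", {
  run <- synth_run(synth_params(n_ms1 = 3, max_ms_level = 3, seed = 7))
  path <- withr::local_tempfile(fileext = ".mzML")

  # 64-bit, no compression: bit-exact reconstruction
  write_mzml(run, path)
  expect_identical(parse_mzml(path), run)

  # indexedmzML wrapper is transparent
  write_mzml(run, path, indexed = TRUE)
  expect_identical(parse_mzml(path), run)

  # 32-bit + zlib: arrays equal within float32 error
  write_mzml(run, path, precision = 32, compression = "zlib")
  got <- parse_mzml(path)
  for (i in seq_along(run$spectra)) {
    expect_equal(got$spectra[[i]]$mz, run$spectra[[i]]$mz, tolerance = 1e-6)
    expect_equal(got$spectra[[i]]$noise, run$spectra[[i]]$noise,
                 tolerance = 1e-6)
  }
})

test_that("reader never invents peaks", {
  run <- synth_run(synth_params(n_ms1 = 4, seed = 13))
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, path)
  got <- parse_mzml(path)
  expect_equal(sum(vapply(got$spectra, function(s) length(s$mz), integer(1))),
               sum(vapply(run$spectra, function(s) length(s$mz), integer(1))))
})

test_that("empty runs survive the writer and reader", {
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(ms_run(source_file = "empty"), path)
  got <- parse_mzml(path)
  expect_length(got$spectra, 0)
})

test_that("hand-built mzML features are honoured", {
  mk <- function(extra_spectrum_xml, rt_cvparam) {
    b64 <- encode_binary_array(c(100, 200))
    sprintf('<?xml version="1.0"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
<run id="r"><spectrumList count="1">
<spectrum index="0" id="scan=5" defaultArrayLength="2">
<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>
<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>
<scanList count="1"><scan>%s</scan></scanList>
<binaryDataArrayList count="2">
<binaryDataArray><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>
<binary>%s</binary></binaryDataArray>
<binaryDataArray><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>
<binary>%s</binary></binaryDataArray>
%s
</binaryDataArrayList>
</spectrum></spectrumList></run></mzML>', rt_cvparam, b64, b64,
            extra_spectrum_xml)
  }

  # seconds are converted to minutes
  path <- withr::local_tempfile(fileext = ".mzML")
  writeLines(mk("", '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="90" unitAccession="UO:0000010" unitName="second"/>'), path)
  got <- parse_mzml(path)
  expect_equal(got$spectra[[1]]$rt, 1.5)
  expect_equal(got$spectra[[1]]$scan_number, 5L)  # from the id token

  # a missing unit warns and assumes minutes
  writeLines(mk("", '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="2.5"/>'), path)
  expect_warning(got <- parse_mzml(path), "assuming minutes")
  expect_equal(got$spectra[[1]]$rt, 2.5)

  # a non-standard data array named "noise" lands in the noise slot
  noise_xml <- sprintf('<binaryDataArray><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
<cvParam cvRef="MS" accession="MS:1000786" name="non-standard data array" value="noise"/>
<binary>%s</binary></binaryDataArray>', encode_binary_array(c(0.5, 0.7)))
  writeLines(mk(noise_xml, '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="1" unitAccession="UO:0000031" unitName="minute"/>'), path)
  got <- parse_mzml(path)
  expect_equal(got$spectra[[1]]$noise, c(0.5, 0.7))

  # an unrecognized array accession is preserved under extra_arrays
  other_xml <- sprintf('<binaryDataArray><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
<cvParam cvRef="MS" accession="MS:1000517" name="signal to noise array"/>
<binary>%s</binary></binaryDataArray>', encode_binary_array(c(9, 9)))
  writeLines(mk(other_xml, '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="1" unitAccession="UO:0000031" unitName="minute"/>'), path)
  got <- parse_mzml(path)
  expect_equal(got$spectra[[1]]$extra_arrays[["MS:1000517"]], c(9, 9))
})

test_that("a spectrum without peak arrays is a format error", {
  path <- withr::local_tempfile(fileext = ".mzML")
  writeLines('<?xml version="1.0"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
<run id="r"><spectrumList count="1">
<spectrum index="0" id="scan=1" defaultArrayLength="0">
<binaryDataArrayList count="0"/>
</spectrum></spectrumList></run></mzML>', path)
  expect_error(parse_mzml(path), "scan=1")
})

test_that("an independent mzML implementation reads what we write", {
  # mzR (ProteoWizard) as cross-implementation oracle
  run <- synth_run(synth_params(n_ms1 = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, path)
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  expect_equal(nrow(h), length(run))
  expect_equal(h$msLevel, vapply(run$spectra, `[[`, integer(1), "ms_level"))
  # mzR reports seconds
  expect_equal(h$retentionTime,
               vapply(run$spectra, `[[`, numeric(1), "rt") * 60,
               tolerance = 1e-9)
  i <- 2L
  pk <- mzR::peaks(f, i)
  expect_equal(pk[, 1], run$spectra[[i]]$mz)
  expect_equal(pk[, 2], run$spectra[[i]]$intensity)
  expect_equal(h$precursorMZ[i], run$spectra[[i]]$precursor_mz)
})
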