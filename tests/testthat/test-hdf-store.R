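ragged_file <- function(run, ...) {
  path <- tempfile(fileext = ".h5")
  handle <- write_ragged(run, path, ...)
  list(path = path, handle = handle)
}

test_that("ragged stores round-trip bit-exactly", {
  for (seed in c(42, 8)) {
    run <- synth_run(synth_params(n_ms1 = 5, max_ms_level = 3, seed = seed))
    st <- ragged_file(run)
    expect_identical(read_run(st$handle), run)
    unlink(st$path)
  }
})

test_that("tree stores round-trip and agree with the ragged layout", {
  run <- synth_run(synth_params(n_ms1 = 4, max_ms_level = 3, seed = 42))
  tp <- withr::local_tempfile(fileext = ".h5")
  rp <- withr::local_tempfile(fileext = ".h5")
  ht <- write_tree(run, tp)
  hr <- write_ragged(run, rp)
  expect_identical(read_run(ht), run)
  expect_identical(read_run(ht), read_run(hr))

  # nesting follows the scan tree; a product scan group records its precursor
  ls <- rhdf5::h5ls(tp)
  expect_true("/scans/scan_000001" %in% paste0(sub("/$", "", ls$group), "/", ls$name)[ls$otype == "H5I_GROUP"] |
              any(ls$group == "/scans" & ls$name == "scan_000001"))
  expect_true(any(ls$group == "/scans/scan_000001" &
                    grepl("^scan_", ls$name)))
  at <- rhdf5::h5readAttributes(tp, "scans/scan_000001/scan_000002")
  expect_false(is.nan(as.numeric(at$precursor_mz)))
})

test_that("an MS1-only run yields a flat forest of scan groups", {
  flat <- ms_run(lapply(1:3, function(i) {
    ms_spectrum(i, 1L, i / 10, mz = c(1, 2), intensity = c(3, 4))
  }))
  tp <- withr::local_tempfile(fileext = ".h5")
  write_tree(flat, tp)
  ls <- rhdf5::h5ls(tp)
  groups <- ls[ls$otype == "H5I_GROUP" & grepl("^scan_", ls$name), ]
  expect_true(all(groups$group == "/scans"))
})

test_that("empty runs produce valid, fully annotated stores", {
  st <- ragged_file(ms_run(source_file = "none"))
  expect_equal(st$handle$n_spectra, 0)
  expect_identical(read_run(st$handle), ms_run(source_file = "none"))
  ann <- list_annotations(st$handle)
  expect_gt(nrow(ann), 0)
  expect_equal(sum(ann$violation), 0)
  expect_length(read_bpc(st$path)$value, 0)
  unlink(st$path)
})

test_that("existing files are refused without overwrite", {
  run <- synth_run(synth_params(n_ms1 = 1, seed = 1))
  path <- withr::local_tempfile(fileext = ".h5")
  write_ragged(run, path)
  expect_error(write_ragged(run, path), "exists")
  expect_silent(write_ragged(run, path, overwrite = TRUE))
})

test_that("open_store rejects foreign files and enforces versioning", {
  # an HDF5 file that is not a store
  alien <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(alien)
  rhdf5::h5write(1:3, alien, "junk")
  expect_error(open_store(alien), "not a recognized")
  expect_error(open_store(withr::local_tempfile()), "no such file")

  # a future major version is refused
  run <- synth_run(synth_params(n_ms1 = 1, seed = 1))
  path <- withr::local_tempfile(fileext = ".h5")
  write_ragged(run, path)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5deleteAttribute(fid, "/", "format_version")
  rhdf5::h5writeAttribute("2.0", fid, "format_version", asScalar = TRUE)
  rhdf5::H5Fclose(fid)
  expect_error(open_store(path), "newer than supported")
})

test_that("random access returns single spectra identical to the source", {
  run <- synth_run(synth_params(n_ms1 = 4, max_ms_level = 3, seed = 21))
  rp <- withr::local_tempfile(fileext = ".h5")
  tp <- withr::local_tempfile(fileext = ".h5")
  hr <- write_ragged(run, rp)
  ht <- write_tree(run, tp)

  picks <- c(1L, 2L, length(run))
  for (i in picks) {
    sn <- run$spectra[[i]]$scan_number
    expect_identical(get_spectrum(hr, sn), run$spectra[[i]])
    expect_identical(get_spectrum(ht, sn), run$spectra[[i]])
  }
  expect_error(get_spectrum(hr, 9999L), "not present")

  # the deepest MS3 scan's parent chain walks back to an MS1 root
  ms3 <- Filter(function(s) s$ms_level == 3L, run$spectra)
  deepest <- ms3[[length(ms3)]]$scan_number
  s3 <- get_spectrum(ht, deepest)
  s2 <- get_spectrum(ht, s3$precursor_scan)
  s1 <- get_spectrum(ht, s2$precursor_scan)
  expect_equal(c(s1$ms_level, s2$ms_level, s3$ms_level), 1:3)
  expect_true(is.na(s1$precursor_scan))
})

test_that("every dataset in both layouts is CV-annotated", {
  run <- synth_run(synth_params(n_ms1 = 3, max_ms_level = 3, seed = 6))
  for (writer in list(write_ragged, write_tree)) {
    path <- tempfile(fileext = ".h5")
    h <- writer(run, path)
    ann <- list_annotations(h)
    expect_equal(sum(ann$violation), 0)
    expect_equal(ann$accession[ann$dataset == "bpc"], "MS:1000628")
    expect_equal(ann$name[ann$dataset == "bpc"], "basepeak chromatogram")
    noise_rows <- ann[grepl("(^|/)noise$", ann$dataset), ]
    expect_gt(nrow(noise_rows), 0)
    expect_true(all(noise_rows$accession == "MS:1000513"))
    unlink(path)
  }

  # tree mode annotates every per-scan mz dataset independently
  tp <- withr::local_tempfile(fileext = ".h5")
  ht <- write_tree(run, tp)
  ann <- list_annotations(ht)
  mz_rows <- ann[grepl("/mz$", ann$dataset), ]
  expect_equal(nrow(mz_rows), length(run))
  expect_true(all(mz_rows$accession == "MS:1000514"))
})

test_that("removing an annotation is reported as a violation, not an error", {
  run <- synth_run(synth_params(n_ms1 = 1, seed = 2))
  path <- withr::local_tempfile(fileext = ".h5")
  h <- write_ragged(run, path)
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "bpc")
  rhdf5::H5Adelete(did, "PSI-MS_ID")
  rhdf5::H5Adelete(did, "PSI-MS_NAME")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  ann <- list_annotations(open_store(path))
  expect_true(ann$violation[ann$dataset == "bpc"])
  expect_equal(sum(ann$violation), 1)
})

test_that("gzip level 6 never inflates the file relative to level 0", {
  run <- synth_run(synth_params(n_ms1 = 50, seed = 42))
  p0 <- withr::local_tempfile(fileext = ".h5")
  p6 <- withr::local_tempfile(fileext = ".h5")
  write_ragged(run, p0, store_layout("ragged", compression_level = 0))
  write_ragged(run, p6, store_layout("ragged", compression_level = 6))
  expect_lte(file.size(p6), file.size(p0))
})

test_that("centroid export drops profile scans and records the mode", {
  run <- synth_run(synth_params(n_ms1 = 3, seed = 4))  # MS1 scans are profile
  path <- withr::local_tempfile(fileext = ".h5")
  h <- write_ragged(run, path,
                    store_layout("ragged", store_profile = FALSE))
  expect_true(h$centroid_export)
  got <- read_run(h)
  expect_true(all(vapply(got$spectra, `[[`, logical(1), "is_centroid")))
  # orphaned product scans lose the parent reference but keep their data
  expect_true(all(is.na(vapply(got$spectra, `[[`, integer(1),
                               "precursor_scan"))))
  expect_equal(length(got),
               sum(vapply(run$spectra, `[[`, logical(1), "is_centroid")))
})

test_that("stored peak columns are true 64-bit vlen datasets", {
  run <- synth_run(synth_params(n_ms1 = 2, seed = 11))
  st <- ragged_file(run)
  for (nm in c("mz", "intensity", "noise")) {
    expect_true(.Call(msh5:::msh5_is_vlen, st$path, nm), label = nm)
  }
  expect_false(.Call(msh5:::msh5_is_vlen, st$path, "rt"))
  unlink(st$path)
})
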