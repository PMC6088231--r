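#' Describe a store layout
#'
#' @param mode `"ragged"` (default; one variable-length row per scan in
#'   flat root-level datasets) or `"tree"` (one HDF5 group per scan, nested
#'   by MSn parentage).
#' @param compression_level gzip level 0-9 for dataset chunks; 0 stores
#'   uncompressed chunks.  The byte-shuffle filter is enabled alongside
#'   gzip (lossless; improves float compression).
#' @param store_profile When `FALSE`, profile-mode spectra are excluded at
#'   write time and only centroid scans are stored (the centroid-export
#'   option); orphaned product-ion scans keep their data but lose the
#'   parent-scan reference.
#' @return A `store_layout` list.
#' @export
store_layout <- function(mode = c("ragged", "tree"), compression_level = 4L,
                         store_profile = TRUE) {
  mode <- match.arg(mode)
  compression_level <- as.integer(compression_level)
  stopifnot(compression_level >= 0L, compression_level <= 9L)
  structure(list(mode = mode, compression_level = compression_level,
                 store_profile = isTRUE(store_profile)),
            class = "store_layout")
}

.format_version <- "1.0"

## dataset name -> annotation role
.dataset_roles <- c(
  mz = "mz", intensity = "intensity", noise = "noise", charge = "charge",
  scan_number = "scan_number", ms_level = "ms_level", rt = "rt",
  precursor_mz = "precursor_mz", precursor_charge = "precursor_charge",
  parent_scan = "parent_scan", filter_string = "filter_string",
  is_centroid = "is_centroid",
  bpc = "bpc", bpc_rt = "chrom_rt", tic = "tic", tic_rt = "chrom_rt")

.h5_write_attr <- function(fid, obj_path, name, value) {
  oid <- rhdf5::H5Oopen(fid, obj_path)
  on.exit(rhdf5::H5Oclose(oid))
  rhdf5::h5writeAttribute(value, oid, name, asScalar = length(value) == 1)
}

.h5_annotate <- function(fid, obj_path, ann) {
  .h5_write_attr(fid, obj_path, "PSI-MS_ID", ann$accession)
  .h5_write_attr(fid, obj_path, "PSI-MS_NAME", ann$name)
  ## the accession-named convention seen in generic viewers
  .h5_write_attr(fid, obj_path, ann$accession, ann$name)
}

.h5_write_fixed <- function(fid, name, values, level) {
  n <- length(values)
  storage <- if (is.character(values)) "character" else storage.mode(values)
  size <- if (is.character(values)) max(nchar(values, type = "bytes"), 1L) + 1L
  if (n == 0L || level == 0L) {
    rhdf5::h5createDataset(fid, name, dims = n, storage.mode = storage,
                           size = size, level = 0L)
  } else {
    rhdf5::h5createDataset(fid, name, dims = n, storage.mode = storage,
                           size = size, chunk = min(n, 4096L),
                           level = level, shuffle = !is.character(values),
                           filter = "GZIP")
  }
  if (n > 0) rhdf5::h5write(values, fid, name)
  invisible(NULL)
}

.run_centroid_filter <- function(run, layout) {
  if (layout$store_profile) return(run)
  keep <- vapply(run$spectra, function(s) s$is_centroid, logical(1))
  kept <- run$spectra[keep]
  kept_sn <- vapply(kept, function(s) s$scan_number, integer(1))
  kept <- lapply(kept, function(s) {
    if (!is.na(s$precursor_scan) && !(s$precursor_scan %in% kept_sn)) {
      s$precursor_scan <- NA_integer_
    }
    s
  })
  ms_run(kept, source_file = run$source_file,
         instrument_model = run$instrument_model, centroid_export = TRUE)
}

.check_store_preconditions <- function(run, path, layout, catalog, overwrite,
                                       mode) {
  stopifnot(inherits(run, "ms_run"), inherits(layout, "store_layout"))
  if (layout$mode != mode) {
    stop("layout mode is '", layout$mode, "', expected '", mode, "'",
         call. = FALSE)
  }
  if (file.exists(path) && !overwrite) {
    stop("file exists: '", path, "' (use overwrite = TRUE)", call. = FALSE)
  }
  problems <- validate_run(run)
  if (nrow(problems)) {
    stop("run fails validation (", nrow(problems), " problem(s)); first: ",
         problems$message[1], call. = FALSE)
  }
  ## resolve every annotation before touching the file so a configuration
  ## error never leaves a half-written store behind
  anns <- lapply(unique(unname(.dataset_roles)), function(role) {
    annotation_for_role(catalog, role)
  })
  names(anns) <- unique(unname(.dataset_roles))
  anns
}

.write_root_attrs <- function(fid, run, layout) {
  .h5_write_attr(fid, "/", "format_version", .format_version)
  .h5_write_attr(fid, "/", "layout_mode", layout$mode)
  .h5_write_attr(fid, "/", "gzip_level", layout$compression_level)
  .h5_write_attr(fid, "/", "source_file", run$source_file)
  .h5_write_attr(fid, "/", "instrument_model", run$instrument_model)
  .h5_write_attr(fid, "/", "centroid_export", as.integer(run$centroid_export))
}

.write_chromatograms <- function(fid, run, level, catalog, anns) {
  bpc <- compute_bpc(run, catalog = catalog)
  tic <- compute_tic(run, catalog = catalog)
  .h5_write_fixed(fid, "bpc", bpc$value, level)
  .h5_write_fixed(fid, "bpc_rt", bpc$rt, level)
  .h5_write_fixed(fid, "tic", tic$value, level)
  .h5_write_fixed(fid, "tic_rt", tic$rt, level)
  for (nm in c("bpc", "bpc_rt", "tic", "tic_rt")) {
    .h5_annotate(fid, nm, anns[[.dataset_roles[[nm]]]])
  }
}

#' Write a run as a ragged-array HDF5 store
#'
#' The default layout: every per-peak element type is a root-level
#' variable-length dataset of 64-bit floats with one row per scan (`mz`,
#' `intensity`, and `noise` / `charge` when any scan carries them), next to
#' fixed-length per-scan metadata datasets (`scan_number`, `ms_level`,
#' `rt`, `precursor_mz`, `precursor_charge`, `parent_scan`,
#' `filter_string`, `is_centroid`) and the derived `bpc` / `tic`
#' chromatograms with their retention-time axes.  Every dataset carries the
#' `PSI-MS_ID` / `PSI-MS_NAME` attribute pair plus an attribute named by
#' the accession itself, so generic HDF5 viewers show the controlled
#' vocabulary annotation directly.  Stored m/z values are the literal
#' values -- self-description is favoured over compression tricks such as
#' delta-encoding, which would make the file unreadable to standard
#' viewers.
#'
#' Sentinels (HDF5 numeric datasets cannot hold nulls): `parent_scan` is -1
#' when a scan has no precursor reference, `precursor_mz` is NaN for MS1
#' scans, `precursor_charge` 0 means unknown.  Missing optional rows
#' (noise/charge) are stored as empty variable-length rows so every column
#' has one row per scan.
#'
#' @param run A valid [ms_run()].
#' @param path Output file; refused if it exists unless `overwrite`.
#' @param layout A [store_layout()] with `mode = "ragged"`.
#' @param catalog Term catalog for annotation lookup.
#' @param overwrite Replace an existing file.
#' @return An `ms_store` handle (see [open_store()]).
#' @export
write_ragged <- function(run, path, layout = store_layout("ragged"),
                         catalog = msh5_default_catalog(), overwrite = FALSE) {
  anns <- .check_store_preconditions(run, path, layout, catalog, overwrite,
                                     "ragged")
  run <- .run_centroid_filter(run, layout)
  level <- layout$compression_level
  spectra <- run$spectra

  col <- function(f, proto) vapply(spectra, f, proto)
  scan_number <- col(function(s) s$scan_number, integer(1))
  has_noise <- any(vapply(spectra, function(s) !is.null(s$noise), logical(1)))
  has_charge <- any(vapply(spectra, function(s) !is.null(s$charge), logical(1)))

  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  ok <- FALSE
  tryCatch({
    .h5_write_fixed(fid, "scan_number", scan_number, level)
    .h5_write_fixed(fid, "ms_level", col(function(s) s$ms_level, integer(1)), level)
    .h5_write_fixed(fid, "rt", col(function(s) s$rt, numeric(1)), level)
    pmz <- col(function(s) s$precursor_mz, numeric(1))
    pmz[is.na(pmz)] <- NaN
    .h5_write_fixed(fid, "precursor_mz", pmz, level)
    .h5_write_fixed(fid, "precursor_charge",
                    col(function(s) s$precursor_charge, integer(1)), level)
    parent <- col(function(s) s$precursor_scan, integer(1))
    parent[is.na(parent)] <- -1L
    .h5_write_fixed(fid, "parent_scan", parent, level)
    .h5_write_fixed(fid, "is_centroid",
                    col(function(s) as.integer(s$is_centroid), integer(1)), level)
    .h5_write_fixed(fid, "filter_string",
                    col(function(s) s$filter_string, character(1)), level)
    .write_chromatograms(fid, run, level, catalog, anns)
    for (nm in c("scan_number", "ms_level", "rt", "precursor_mz",
                 "precursor_charge", "parent_scan", "is_centroid",
                 "filter_string")) {
      .h5_annotate(fid, nm, anns[[.dataset_roles[[nm]]]])
    }
    .write_root_attrs(fid, run, layout)
    ok <- TRUE
  }, finally = {
    rhdf5::H5Fclose(fid)
    if (!ok) unlink(path)
  })

  ## ragged peak columns: true HDF5 VLEN datasets, written through the C API
  shuffle <- level > 0
  vcols <- list(mz = lapply(spectra, function(s) s$mz),
                intensity = lapply(spectra, function(s) s$intensity))
  if (has_noise) {
    vcols$noise <- lapply(spectra, function(s) {
      if (is.null(s$noise)) numeric(0) else s$noise
    })
  }
  if (has_charge) {
    vcols$charge <- lapply(spectra, function(s) {
      if (is.null(s$charge)) numeric(0) else as.numeric(s$charge)
    })
  }
  for (nm in names(vcols)) {
    .Call(msh5_write_vlen, path, nm, vcols[[nm]], level, shuffle)
  }
  fid <- rhdf5::H5Fopen(path)
  tryCatch({
    for (nm in names(vcols)) .h5_annotate(fid, nm, anns[[.dataset_roles[[nm]]]])
  }, finally = rhdf5::H5Fclose(fid))

  open_store(path)
}

.tree_group_paths <- function(run) {
  forest <- build_scan_tree(run)
  paths <- character(0)
  rec <- function(node, prefix) {
    p <- sprintf("%s/scan_%06d", prefix, node$scan_number)
    paths[[as.character(node$scan_number)]] <<- p
    for (ch in node$children) rec(ch, p)
  }
  for (node in forest) rec(node, "scans")
  paths
}

#' Write a run as a hierarchical (scan-tree) HDF5 store
#'
#' The alternative layout for MSn acquisitions: one group per scan, named
#' `scan_<zero-padded number>`, nested under its precursor's group (survey
#' scans sit directly under a top-level `scans` group), so the group
#' hierarchy is the scan tree.  Each group holds that scan's `mz` /
#' `intensity` (and optional `noise` / `charge`) datasets -- each one
#' annotated independently with its controlled-vocabulary term, as in the
#' mzML data model -- plus scalar attributes for the scan metadata.
#' Chromatograms are stored at the root exactly as in the ragged layout.
#'
#' @inheritParams write_ragged
#' @param layout A [store_layout()] with `mode = "tree"`.
#' @return An `ms_store` handle.
#' @export
write_tree <- function(run, path, layout = store_layout("tree"),
                       catalog = msh5_default_catalog(), overwrite = FALSE) {
  anns <- .check_store_preconditions(run, path, layout, catalog, overwrite,
                                     "tree")
  run <- .run_centroid_filter(run, layout)
  level <- layout$compression_level
  paths <- .tree_group_paths(run)

  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  ok <- FALSE
  tryCatch({
    rhdf5::h5createGroup(fid, "scans")
    ## create groups in scan order so parents always precede children
    for (s in run$spectra) {
      g <- paths[[as.character(s$scan_number)]]
      rhdf5::h5createGroup(fid, g)
      .h5_write_attr(fid, g, "scan_number", s$scan_number)
      .h5_write_attr(fid, g, "ms_level", s$ms_level)
      .h5_write_attr(fid, g, "rt", s$rt)
      .h5_write_attr(fid, g, "precursor_mz",
                     if (is.na(s$precursor_mz)) NaN else s$precursor_mz)
      .h5_write_attr(fid, g, "precursor_charge", s$precursor_charge)
      .h5_write_attr(fid, g, "filter_string", s$filter_string)
      .h5_write_attr(fid, g, "is_centroid", as.integer(s$is_centroid))
      arrays <- list(mz = s$mz, intensity = s$intensity)
      if (!is.null(s$noise)) arrays$noise <- s$noise
      if (!is.null(s$charge)) arrays$charge <- as.numeric(s$charge)
      for (nm in names(arrays)) {
        dp <- paste0(g, "/", nm)
        .h5_write_fixed(fid, dp, arrays[[nm]], level)
        .h5_annotate(fid, dp, anns[[.dataset_roles[[nm]]]])
      }
    }
    .write_chromatograms(fid, run, level, catalog, anns)
    .write_root_attrs(fid, run, layout)
    ok <- TRUE
  }, finally = {
    rhdf5::H5Fclose(fid)
    if (!ok) unlink(path)
  })
  open_store(path)
}

#' Open an HDF5 store written by this package
#'
#' Lazy open: reads root attributes and the scan index, never the peak
#' data.  Files without a `format_version` root attribute are refused, as
#' are files written by a later major format version.
#'
#' @param path Path to a store file.
#' @return An `ms_store` handle: `path`, `layout`, `n_spectra`,
#'   `scan_numbers` and (tree mode) the per-scan group paths.
#' @export
open_store <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (is.null(attrs$format_version)) {
    stop("'", path, "' is not a recognized msh5 store ",
         "(missing format_version attribute)", call. = FALSE)
  }
  ver <- as.character(attrs$format_version)
  if (as.integer(sub("\\..*$", "", ver)) >
      as.integer(sub("\\..*$", "", .format_version))) {
    stop("store format version ", ver, " is newer than supported (",
         .format_version, ")", call. = FALSE)
  }
  mode <- as.character(attrs$layout_mode)
  if (!mode %in% c("ragged", "tree")) {
    stop("unknown layout mode '", mode, "'", call. = FALSE)
  }

  if (mode == "ragged") {
    scan_numbers <- as.integer(rhdf5::h5read(path, "scan_number"))
    group_paths <- NULL
  } else {
    ls <- rhdf5::h5ls(path, recursive = TRUE)
    grp <- ls[ls$otype == "H5I_GROUP" & grepl("^scan_[0-9]+$", ls$name), ]
    full <- file.path(sub("^/", "", grp$group), grp$name)
    sn <- as.integer(sub("^scan_", "", grp$name))
    o <- order(sn)
    scan_numbers <- sn[o]
    group_paths <- stats::setNames(full[o], scan_numbers)
  }

  structure(list(
    path = path,
    layout = store_layout(mode,
                          compression_level = as.integer(attrs$gzip_level)),
    format_version = ver,
    source_file = as.character(attrs$source_file),
    instrument_model = as.character(attrs$instrument_model),
    centroid_export = as.integer(attrs$centroid_export) == 1L,
    n_spectra = length(scan_numbers),
    scan_numbers = scan_numbers,
    group_paths = group_paths
  ), class = "ms_store")
}

#' @export
print.ms_store <- function(x, ...) {
  cat(sprintf("<ms_store> %s layout  %d spectra  gzip %d  [%s]\n",
              x$layout$mode, x$n_spectra, x$layout$compression_level, x$path))
  invisible(x)
}

.read_scalar_ragged <- function(path, name, i) {
  rhdf5::h5read(path, name, index = list(i))[1]
}

.tree_parent_scan <- function(group_path) {
  parts <- strsplit(group_path, "/", fixed = TRUE)[[1]]
  if (length(parts) <= 2L) return(NA_integer_)  # "scans/scan_xxxxxx"
  as.integer(sub("^scan_", "", parts[length(parts) - 1L]))
}

.spectrum_from_tree_group <- function(path, g) {
  at <- rhdf5::h5readAttributes(path, g)
  ls <- rhdf5::h5ls(path)
  here <- ls[ls$group == paste0("/", g) & ls$otype == "H5I_DATASET", "name"]
  rd <- function(nm) as.numeric(rhdf5::h5read(path, paste0(g, "/", nm)))
  pmz <- as.numeric(at$precursor_mz)
  ms_spectrum(
    scan_number = as.integer(at$scan_number),
    ms_level = as.integer(at$ms_level),
    rt = as.numeric(at$rt),
    mz = rd("mz"), intensity = rd("intensity"),
    noise = if ("noise" %in% here) rd("noise"),
    charge = if ("charge" %in% here) as.integer(rd("charge")),
    precursor_mz = if (is.nan(pmz)) NA_real_ else pmz,
    precursor_charge = as.integer(at$precursor_charge),
    precursor_scan = .tree_parent_scan(g),
    filter_string = as.character(at$filter_string),
    is_centroid = as.integer(at$is_centroid) == 1L)
}

#' Retrieve one spectrum from a store by scan number
#'
#' Random access is the point of the format: in ragged mode only that
#' scan's variable-length rows and scalar entries are read; in tree mode
#' only that scan's group.
#'
#' @param handle An `ms_store` from [open_store()].
#' @param scan_number Scan to fetch.
#' @return An [ms_spectrum()].
#' @export
get_spectrum <- function(handle, scan_number) {
  stopifnot(inherits(handle, "ms_store"))
  i <- match(as.integer(scan_number), handle$scan_numbers)
  if (is.na(i)) {
    stop("scan ", scan_number, " not present in store '", handle$path, "'",
         call. = FALSE)
  }
  path <- handle$path
  if (handle$layout$mode == "tree") {
    return(.spectrum_from_tree_group(path, handle$group_paths[[as.character(scan_number)]]))
  }

  ls <- rhdf5::h5ls(path)
  root_ds <- ls[ls$group == "/" & ls$otype == "H5I_DATASET", "name"]
  row <- function(nm) .Call(msh5_read_vlen_row, path, nm, i)
  pmz <- as.numeric(.read_scalar_ragged(path, "precursor_mz", i))
  parent <- as.integer(.read_scalar_ragged(path, "parent_scan", i))
  noise <- if ("noise" %in% root_ds) row("noise")
  charge <- if ("charge" %in% root_ds) row("charge")
  ms_spectrum(
    scan_number = as.integer(scan_number),
    ms_level = as.integer(.read_scalar_ragged(path, "ms_level", i)),
    rt = as.numeric(.read_scalar_ragged(path, "rt", i)),
    mz = row("mz"), intensity = row("intensity"),
    noise = if (!is.null(noise) && length(noise)) noise,
    charge = if (!is.null(charge) && length(charge)) as.integer(charge),
    precursor_mz = if (is.nan(pmz)) NA_real_ else pmz,
    precursor_charge = as.integer(.read_scalar_ragged(path, "precursor_charge", i)),
    precursor_scan = if (parent < 0) NA_integer_ else parent,
    filter_string = as.character(.read_scalar_ragged(path, "filter_string", i)),
    is_centroid = as.integer(.read_scalar_ragged(path, "is_centroid", i)) == 1L)
}

#' Read a whole store back into a run
#'
#' Full reconstruction; composing with either writer is the identity on
#' runs (bit-exact float arrays), so the two layouts are interchangeable
#' views of the same data.
#'
#' @param handle An `ms_store`.
#' @return An [ms_run()].
#' @export
read_run <- function(handle) {
  stopifnot(inherits(handle, "ms_store"))
  path <- handle$path
  n <- handle$n_spectra

  if (handle$layout$mode == "tree") {
    spectra <- lapply(as.character(handle$scan_numbers), function(k) {
      .spectrum_from_tree_group(path, handle$group_paths[[k]])
    })
  } else {
    ls <- rhdf5::h5ls(path)
    root_ds <- ls[ls$group == "/" & ls$otype == "H5I_DATASET", "name"]
    vget <- function(nm) .Call(msh5_read_vlen, path, nm)
    mz <- vget("mz"); intensity <- vget("intensity")
    noise <- if ("noise" %in% root_ds) vget("noise")
    charge <- if ("charge" %in% root_ds) vget("charge")
    scalars <- list(
      scan_number = as.integer(rhdf5::h5read(path, "scan_number")),
      ms_level = as.integer(rhdf5::h5read(path, "ms_level")),
      rt = as.numeric(rhdf5::h5read(path, "rt")),
      precursor_mz = as.numeric(rhdf5::h5read(path, "precursor_mz")),
      precursor_charge = as.integer(rhdf5::h5read(path, "precursor_charge")),
      parent_scan = as.integer(rhdf5::h5read(path, "parent_scan")),
      filter_string = as.character(rhdf5::h5read(path, "filter_string")),
      is_centroid = as.integer(rhdf5::h5read(path, "is_centroid")))
    lens <- c(vapply(scalars, length, integer(1)),
              mz = length(mz), intensity = length(intensity),
              noise = if (!is.null(noise)) length(noise),
              charge = if (!is.null(charge)) length(charge))
    if (any(lens != n)) {
      stop("corrupted store: per-scan dataset lengths disagree (",
           paste0(names(lens)[lens != n], "=", lens[lens != n],
                  collapse = ", "), " vs ", n, " scans)", call. = FALSE)
    }
    spectra <- lapply(seq_len(n), function(i) {
      pmz <- scalars$precursor_mz[i]
      ms_spectrum(
        scan_number = scalars$scan_number[i],
        ms_level = scalars$ms_level[i],
        rt = scalars$rt[i],
        mz = mz[[i]], intensity = intensity[[i]],
        noise = if (!is.null(noise) && length(noise[[i]])) noise[[i]],
        charge = if (!is.null(charge) && length(charge[[i]]))
          as.integer(charge[[i]]),
        precursor_mz = if (is.nan(pmz)) NA_real_ else pmz,
        precursor_charge = scalars$precursor_charge[i],
        precursor_scan = if (scalars$parent_scan[i] < 0) NA_integer_
                         else scalars$parent_scan[i],
        filter_string = scalars$filter_string[i],
        is_centroid = scalars$is_centroid[i] == 1L)
    })
  }

  ms_run(spectra, source_file = handle$source_file,
         instrument_model = handle$instrument_model,
         centroid_export = handle$centroid_export)
}

#' List the controlled-vocabulary annotations of every dataset
#'
#' Walks all datasets in the file (both layouts) and reports the
#' `PSI-MS_ID` / `PSI-MS_NAME` attribute pair of each.  Datasets missing
#' either attribute are reported as completeness violations, not raised --
#' the annotation-completeness contract is "100% of spectral and
#' chromatogram datasets annotated", and this is the function that makes
#' it assertable.
#'
#' @param handle An `ms_store`.
#' @return Data frame with columns `dataset` (full path), `accession`,
#'   `name`, `violation` (logical).
#' @export
list_annotations <- function(handle) {
  stopifnot(inherits(handle, "ms_store"))
  path <- handle$path
  ls <- rhdf5::h5ls(path, recursive = TRUE)
  ds <- ls[ls$otype == "H5I_DATASET", ]
  full <- ifelse(ds$group == "/", ds$name,
                 paste0(sub("^/", "", ds$group), "/", ds$name))
  rows <- lapply(full, function(p) {
    at <- rhdf5::h5readAttributes(path, p)
    acc <- at[["PSI-MS_ID"]]
    nm <- at[["PSI-MS_NAME"]]
    data.frame(dataset = p,
               accession = if (is.null(acc)) NA_character_ else as.character(acc),
               name = if (is.null(nm)) NA_character_ else as.character(nm),
               violation = is.null(acc) || is.null(nm))
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(dataset = character(0), accession = character(0),
                  name = character(0), violation = logical(0))
}
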