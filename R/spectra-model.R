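#' Construct a single mass spectrum record
#'
#' One acquisition: scan metadata plus parallel peak arrays.  Peaks are
#' sorted ascending by m/z on construction (ties allowed -- profile data
#' may sample the same m/z twice).
#'
#' @param scan_number Positive integer, unique within a run.
#' @param ms_level Integer >= 1 (1 = survey scan, 2 = product ion scan, ...).
#' @param rt Retention time in minutes, non-negative.
#' @param mz,intensity Numeric vectors of equal length; intensities >= 0.
#' @param noise Optional per-peak noise estimate vector (vendor convention:
#'   one value per centroid).
#' @param charge Optional per-peak integer charge estimates.
#' @param precursor_mz Selected-ion m/z of the fragmented precursor;
#'   `NA` for MS1 scans.
#' @param precursor_charge Precursor charge state; `0` encodes unknown.
#' @param precursor_scan Scan number of the parent acquisition, or `NA`.
#' @param filter_string Free-text vendor scan descriptor (may be empty).
#' @param is_centroid `TRUE` for centroided peak lists, `FALSE` for profile.
#' @param extra_arrays Named list of additional per-peak arrays keyed by CV
#'   accession (arrays a reader preserved but does not model).
#' @return An `ms_spectrum` object.
#' @export
ms_spectrum <- function(scan_number, ms_level, rt, mz, intensity,
                        noise = NULL, charge = NULL,
                        precursor_mz = NA_real_, precursor_charge = 0L,
                        precursor_scan = NA_integer_, filter_string = "",
                        is_centroid = TRUE, extra_arrays = NULL) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    if (!is.null(noise)) noise <- noise[o]
    if (!is.null(charge)) charge <- charge[o]
  }
  structure(list(
    scan_number = as.integer(scan_number),
    ms_level = as.integer(ms_level),
    rt = as.numeric(rt),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    precursor_scan = as.integer(precursor_scan),
    filter_string = as.character(filter_string),
    is_centroid = isTRUE(is_centroid),
    mz = mz,
    intensity = intensity,
    noise = if (!is.null(noise)) as.numeric(noise),
    charge = if (!is.null(charge)) as.integer(charge),
    extra_arrays = extra_arrays
  ), class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> scan %d  MS%d  rt %.3f min  %d peaks%s\n",
              x$scan_number, x$ms_level, x$rt, length(x$mz),
              if (!is.na(x$precursor_mz))
                sprintf("  precursor %.4f (z=%d)", x$precursor_mz,
                        x$precursor_charge) else ""))
  invisible(x)
}

#' Construct a run: an ordered collection of spectra
#'
#' The in-memory lingua franca between the mzML reader, the HDF5 store and
#' the synthetic generator.  Spectra are reordered by ascending scan number.
#'
#' @param spectra List of [ms_spectrum()] records.
#' @param source_file Provenance string (originating file).
#' @param instrument_model Free-text instrument description (may be empty).
#' @param centroid_export `TRUE` when the run holds centroid data only
#'   (profile scans excluded at export time).
#' @return An `ms_run` object.
#' @export
ms_run <- function(spectra = list(), source_file = "",
                   instrument_model = "", centroid_export = FALSE) {
  stopifnot(is.list(spectra))
  if (length(spectra)) {
    sn <- vapply(spectra, function(s) s$scan_number, integer(1))
    spectra <- spectra[order(sn)]
  }
  structure(list(spectra = spectra,
                 source_file = as.character(source_file),
                 instrument_model = as.character(instrument_model),
                 centroid_export = isTRUE(centroid_export)),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  lv <- vapply(x$spectra, function(s) s$ms_level, integer(1))
  cat(sprintf("<ms_run> %d spectra (%s)%s\n", length(x$spectra),
              if (length(lv)) paste0("MS", sort(unique(lv)), ": ",
                                     tabulate(lv)[sort(unique(lv))],
                                     collapse = ", ") else "empty",
              if (nzchar(x$source_file)) paste0("  [", x$source_file, "]") else ""))
  invisible(x)
}

#' @export
length.ms_run <- function(x) length(x$spectra)

#' Validate the structural invariants of a run
#'
#' Checks every invariant the store and the scan-tree builder rely on:
#' equal peak-array lengths, sorted m/z, non-negative intensities, strictly
#' increasing scan numbers, non-decreasing retention times, and precursor
#' references that point to an earlier scan exactly one MS level up.
#' Violations are data, not errors.
#'
#' @param run An [ms_run()].
#' @return A data frame with columns `scan_number` (`NA` for run-level
#'   findings) and `message`; zero rows means the run is valid.
#' @export
validate_run <- function(run) {
  stopifnot(inherits(run, "ms_run"))
  bad <- list()
  note <- function(scan, msg) {
    bad[[length(bad) + 1L]] <<- data.frame(scan_number = scan, message = msg)
  }

  by_scan <- list()
  for (s in run$spectra) {
    sn <- s$scan_number
    if (length(s$mz) != length(s$intensity)) {
      note(sn, sprintf("mz/intensity length mismatch (%d vs %d)",
                       length(s$mz), length(s$intensity)))
    }
    if (!is.null(s$noise) && length(s$noise) != length(s$mz)) {
      note(sn, "noise array length differs from mz")
    }
    if (!is.null(s$charge) && length(s$charge) != length(s$mz)) {
      note(sn, "charge array length differs from mz")
    }
    if (is.unsorted(s$mz)) note(sn, "mz values not non-decreasing")
    if (any(s$intensity < 0)) note(sn, "negative intensity")
    if (s$ms_level < 1) note(sn, "ms_level < 1")
    if (s$rt < 0) note(sn, "negative retention time")
    if (s$ms_level == 1 &&
        (!is.na(s$precursor_mz) || !is.na(s$precursor_scan))) {
      note(sn, "MS1 scan carries precursor information")
    }
    if (s$ms_level > 1 && !is.na(s$precursor_scan)) {
      parent <- by_scan[[as.character(s$precursor_scan)]]
      if (is.null(parent)) {
        note(sn, sprintf("precursor_scan %d missing or later in the run",
                         s$precursor_scan))
      } else if (parent$ms_level != s$ms_level - 1L) {
        note(sn, sprintf("precursor_scan %d has ms_level %d, expected %d",
                         s$precursor_scan, parent$ms_level, s$ms_level - 1L))
      }
    }
    by_scan[[as.character(sn)]] <- s
  }

  sn <- vapply(run$spectra, function(s) s$scan_number, integer(1))
  if (anyDuplicated(sn)) note(NA_integer_, "duplicate scan numbers")
  if (length(sn) > 1 && any(diff(sn) <= 0)) {
    note(NA_integer_, "scan numbers not strictly increasing")
  }
  rt <- vapply(run$spectra, function(s) s$rt, numeric(1))
  if (length(rt) > 1 && any(diff(rt) < 0)) {
    note(NA_integer_, "retention times decrease")
  }

  if (length(bad)) do.call(rbind, bad)
  else data.frame(scan_number = integer(0), message = character(0))
}

#' Build the MSn scan forest of a run
#'
#' Every MS1 scan becomes a root; every scan with a `precursor_scan`
#' reference becomes a child of that scan.  Ordering by scan number is
#' preserved at every level and each spectrum appears exactly once, so a
#' depth-first flatten in scan order reproduces the run's scan list.  Scans
#' of level > 1 without a precursor reference become roots of their own.
#'
#' @param run A valid [ms_run()].
#' @return List of `scan_tree_node` records (`scan_number`, `children`).
#' @seealso [flatten_scan_tree()]
#' @export
build_scan_tree <- function(run) {
  stopifnot(inherits(run, "ms_run"))
  sn <- vapply(run$spectra, function(s) s$scan_number, integer(1))
  kids <- vector("list", length(sn))       # child indices per spectrum
  roots <- integer(0)
  for (i in seq_along(run$spectra)) {
    s <- run$spectra[[i]]
    if (is.na(s$precursor_scan)) {
      roots <- c(roots, i)
    } else {
      p <- match(s$precursor_scan, sn)
      if (is.na(p) || p >= i) {
        stop("scan ", s$scan_number, ": precursor_scan ", s$precursor_scan,
             " is missing or not earlier in the run", call. = FALSE)
      }
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  grow <- function(i) {
    structure(list(scan_number = sn[i],
                   children = lapply(kids[[i]], grow)),
              class = "scan_tree_node")
  }
  lapply(roots, grow)
}

#' Flatten a scan forest depth-first into scan numbers
#'
#' @param forest Output of [build_scan_tree()] (or a single node).
#' @return Integer vector of scan numbers in depth-first order.
#' @export
flatten_scan_tree <- function(forest) {
  if (inherits(forest, "scan_tree_node")) forest <- list(forest)
  out <- integer(0)
  rec <- function(node) {
    out <<- c(out, node$scan_number)
    for (ch in node$children) rec(ch)
  }
  for (node in forest) rec(node)
  out
}

.chromatogram <- function(run, ms_level, role, f, catalog) {
  stopifnot(inherits(run, "ms_run"))
  keep <- Filter(function(s) s$ms_level == ms_level, run$spectra)
  rt <- vapply(keep, function(s) s$rt, numeric(1))
  value <- vapply(keep, function(s) if (length(s$intensity)) f(s$intensity) else 0,
                  numeric(1))
  structure(list(role = role, rt = rt, value = value,
                 annotation = annotation_for_role(catalog, role)),
            class = "ms_chromatogram")
}

#' Base peak chromatogram of a run
#'
#' One point per scan at the requested MS level: the scan's maximum peak
#' intensity against retention time (PSI-MS accession MS:1000628).  Empty
#' peak lists contribute 0, keeping the trace aligned with scan indices; a
#' run with no scans at the level yields an empty chromatogram.
#'
#' @param run A valid [ms_run()].
#' @param ms_level MS level to trace (default 1, the survey scans).
#' @param catalog Term catalog used for the CV annotation.
#' @return An `ms_chromatogram`: `role`, `rt`, `value`, `annotation`.
#' @export
compute_bpc <- function(run, ms_level = 1L, catalog = msh5_default_catalog()) {
  .chromatogram(run, ms_level, "bpc", max, catalog)
}

#' Total ion current chromatogram of a run
#'
#' Companion trace to [compute_bpc()]: the per-scan sum of intensities
#' (PSI-MS accession MS:1000235).
#'
#' @inheritParams compute_bpc
#' @return An `ms_chromatogram`.
#' @export
compute_tic <- function(run, ms_level = 1L, catalog = msh5_default_catalog()) {
  .chromatogram(run, ms_level, "tic", sum, catalog)
}

#' @export
print.ms_chromatogram <- function(x, ...) {
  cat(sprintf("<ms_chromatogram> %s  %d points  [%s %s]\n", x$role,
              length(x$rt), x$annotation$accession, x$annotation$name))
  invisible(x)
}

#' Export a spectrum as viewer-ready JSON
#'
#' Serializes the peak list in the array-of-pairs dialect consumed by
#' web spectrum viewers such as Lorikeet: a JSON array of
#' `[mz, intensity]` pairs in ascending m/z, numbers at full precision.
#' The sidecar object form wraps the peaks together with scan metadata.
#'
#' @param spectrum An [ms_spectrum()].
#' @param sidecar If `TRUE`, emit an object carrying `scan_number`,
#'   `ms_level`, `precursor_mz`, `precursor_charge` and `peaks`; otherwise
#'   the bare peak array.
#' @return A single JSON string (class `json`).
#' @export
to_peaklist_json <- function(spectrum, sidecar = FALSE) {
  stopifnot(inherits(spectrum, "ms_spectrum"))
  peaks <- lapply(seq_along(spectrum$mz), function(i) {
    c(spectrum$mz[i], spectrum$intensity[i])
  })
  if (!sidecar) {
    return(jsonlite::toJSON(peaks, digits = I(17), auto_unbox = FALSE))
  }
  obj <- list(scan_number = jsonlite::unbox(spectrum$scan_number),
              ms_level = jsonlite::unbox(spectrum$ms_level),
              precursor_mz = jsonlite::unbox(spectrum$precursor_mz),
              precursor_charge = jsonlite::unbox(spectrum$precursor_charge),
              peaks = peaks)
  jsonlite::toJSON(obj, digits = I(17), na = "null")
}
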