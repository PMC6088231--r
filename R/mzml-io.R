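#' Encode a numeric vector as an mzML binary data array
#'
#' mzML stores peak data as little-endian IEEE-754 floats, optionally
#' zlib-compressed (RFC 1950), then base64-encoded.  MS-Numpress codecs are
#' deliberately not supported.
#'
#' @param values Finite numeric vector.
#' @param precision 64 (default) or 32 bits per element.
#' @param compression `"none"` or `"zlib"`.
#' @return Base64 text (empty string for an empty vector).
#' @export
encode_binary_array <- function(values, precision = 64,
                                compression = c("none", "zlib")) {
  compression <- match.arg(compression)
  if (!precision %in% c(32, 64)) stop("precision must be 32 or 64", call. = FALSE)
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop("cannot encode non-finite values in a binary data array", call. = FALSE)
  }
  if (!length(values)) return("")
  raw <- writeBin(values, raw(), size = precision / 8, endian = "little")
  if (compression == "zlib") raw <- memCompress(raw, type = "gzip")
  base64enc::base64encode(raw)
}

#' Decode an mzML binary data array
#'
#' Inverse of [encode_binary_array()].  32-bit values are widened to
#' doubles on return.
#'
#' @param b64 Base64 text.
#' @param precision 64 or 32 bits per element.
#' @param compression `"none"` or `"zlib"`.
#' @return Numeric vector.
#' @export
decode_binary_array <- function(b64, precision = 64,
                                compression = c("none", "zlib")) {
  compression <- match.arg(compression)
  if (!precision %in% c(32, 64)) stop("precision must be 32 or 64", call. = FALSE)
  b64 <- gsub("[ \t\r\n]", "", b64)
  if (!nzchar(b64)) return(numeric(0))
  if (!grepl("^[A-Za-z0-9+/]+={0,2}$", b64) || nchar(b64) %% 4 != 0) {
    stop("invalid base64 in binary data array", call. = FALSE)
  }
  raw <- base64enc::base64decode(b64)
  if (compression == "zlib") {
    raw <- tryCatch(memDecompress(raw, type = "gzip"),
                    error = function(e) stop("corrupt zlib stream in binary data array",
                                             call. = FALSE))
  }
  size <- precision / 8
  if (length(raw) %% size != 0) {
    stop("binary data array truncated: ", length(raw),
         " bytes is not a multiple of ", size, call. = FALSE)
  }
  readBin(raw, what = "double", n = length(raw) / size,
          size = size, endian = "little")
}

## cvParam accessions the reader and writer understand
.mzml_cv <- list(
  ms_level = "MS:1000511", centroid = "MS:1000127", profile = "MS:1000128",
  scan_start = "MS:1000016", filter_string = "MS:1000512",
  selected_mz = "MS:1000744", charge_state = "MS:1000041",
  mz_array = "MS:1000514", intensity_array = "MS:1000515",
  charge_array = "MS:1000516", nonstandard = "MS:1000786",
  f64 = "MS:1000523", f32 = "MS:1000521",
  zlib = "MS:1000574", no_compression = "MS:1000576")

.scan_number_from_id <- function(id, fallback) {
  m <- regmatches(id, regexpr("scan=([0-9]+)", id))
  if (length(m) && nzchar(m)) as.integer(sub("scan=", "", m)) else fallback
}

.cv_accessions <- function(node) {
  ps <- xml2::xml_find_all(node, "./cvParam")
  stats::setNames(xml2::xml_attr(ps, "value"), xml2::xml_attr(ps, "accession"))
}

#' Read an mzML file into a run
#'
#' Accepts bare `mzML` documents and the `indexedmzML` wrapper (the index is
#' skipped, not verified -- the HDF5 store provides its own random access).
#' Each `spectrum` element yields one [ms_spectrum()]: MS level,
#' centroid/profile flag, retention time (converted to minutes when the
#' scan start time is declared in seconds; an absent unit is assumed to be
#' minutes, with a warning), precursor m/z / charge / parent-scan reference,
#' filter string, and all binary data arrays mapped to roles by their CV
#' accessions.  A "non-standard data array" named `noise` populates the
#' noise vector; other unrecognized arrays are preserved in `extra_arrays`.
#' Chromatogram elements in the source are ignored (traces are recomputed
#' downstream).  Scan numbers come from the `scan=` token of the spectrum
#' id, else the 1-based position.
#'
#' @param path Path to an mzML (or indexedmzML) file.
#' @return An [ms_run()].
#' @export
parse_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  root <- doc
  if (xml2::xml_name(root) == "indexedmzML") {
    root <- xml2::xml_find_first(root, "./mzML")
    if (inherits(root, "xml_missing")) {
      stop("indexedmzML wrapper without an mzML child", call. = FALSE)
    }
  }
  if (xml2::xml_name(root) != "mzML") {
    stop("not an mzML document: root element <", xml2::xml_name(root), ">",
         call. = FALSE)
  }

  source_file <- xml2::xml_attr(
    xml2::xml_find_first(root, ".//fileDescription/sourceFileList/sourceFile"),
    "name")
  if (is.na(source_file)) source_file <- basename(path)
  instrument <- xml2::xml_attr(
    xml2::xml_find_first(root, ".//cvParam[@accession='MS:1000031']"), "value")
  if (is.na(instrument)) instrument <- ""

  spec_nodes <- xml2::xml_find_all(root, ".//run/spectrumList/spectrum")
  spectra <- vector("list", length(spec_nodes))

  for (i in seq_along(spec_nodes)) {
    sp <- spec_nodes[[i]]
    id <- xml2::xml_attr(sp, "id")
    sn <- .scan_number_from_id(id, i)

    cv <- .cv_accessions(sp)
    ms_level <- if (.mzml_cv$ms_level %in% names(cv)) {
      as.integer(cv[[.mzml_cv$ms_level]])
    } else 1L
    is_centroid <- .mzml_cv$centroid %in% names(cv)

    ## scan start time
    rt <- 0
    scan_node <- xml2::xml_find_first(sp, "./scanList/scan")
    filter_string <- ""
    if (!inherits(scan_node, "xml_missing")) {
      st <- xml2::xml_find_first(scan_node,
              sprintf("./cvParam[@accession='%s']", .mzml_cv$scan_start))
      if (!inherits(st, "xml_missing")) {
        rt <- as.numeric(xml2::xml_attr(st, "value"))
        unit <- xml2::xml_attr(st, "unitAccession")
        unit_name <- xml2::xml_attr(st, "unitName")
        if (identical(unit, "UO:0000010") || identical(unit_name, "second")) {
          rt <- rt / 60
        } else if (is.na(unit) && is.na(unit_name)) {
          warning("spectrum '", id,
                  "': scan start time has no unit; assuming minutes",
                  call. = FALSE)
        }
      }
      fs <- xml2::xml_find_first(scan_node,
              sprintf("./cvParam[@accession='%s']", .mzml_cv$filter_string))
      if (!inherits(fs, "xml_missing")) filter_string <- xml2::xml_attr(fs, "value")
    }

    ## precursor (first one wins)
    precursor_mz <- NA_real_; precursor_charge <- 0L; precursor_scan <- NA_integer_
    precs <- xml2::xml_find_all(sp, "./precursorList/precursor")
    if (length(precs)) {
      if (length(precs) > 1) {
        warning("spectrum '", id, "': ", length(precs),
                " precursors; keeping the first", call. = FALSE)
      }
      p <- precs[[1]]
      ref <- xml2::xml_attr(p, "spectrumRef")
      if (!is.na(ref)) {
        psn <- .scan_number_from_id(ref, NA_integer_)
        if (is.na(psn)) {
          warning("spectrum '", id, "': unparseable precursor scan reference '",
                  ref, "'; recorded as absent", call. = FALSE)
        } else precursor_scan <- psn
      }
      ion <- xml2::xml_find_first(p, "./selectedIonList/selectedIon")
      if (!inherits(ion, "xml_missing")) {
        icv <- .cv_accessions(ion)
        if (.mzml_cv$selected_mz %in% names(icv)) {
          precursor_mz <- as.numeric(icv[[.mzml_cv$selected_mz]])
        }
        if (.mzml_cv$charge_state %in% names(icv)) {
          precursor_charge <- as.integer(icv[[.mzml_cv$charge_state]])
        }
      }
    }

    ## binary data arrays
    mz <- NULL; intensity <- NULL; noise <- NULL; charge <- NULL
    extra <- list()
    for (bda in xml2::xml_find_all(sp, "./binaryDataArrayList/binaryDataArray")) {
      bcv <- .cv_accessions(bda)
      accs <- names(bcv)
      precision <- if (.mzml_cv$f32 %in% accs) 32 else 64
      compression <- if (.mzml_cv$zlib %in% accs) "zlib" else "none"
      b64 <- xml2::xml_text(xml2::xml_find_first(bda, "./binary"))
      if (is.na(b64)) b64 <- ""
      vals <- decode_binary_array(b64, precision, compression)

      if (.mzml_cv$mz_array %in% accs) {
        mz <- vals
      } else if (.mzml_cv$intensity_array %in% accs) {
        intensity <- vals
      } else if (.mzml_cv$charge_array %in% accs) {
        charge <- vals
      } else if (.mzml_cv$nonstandard %in% accs &&
                 identical(bcv[[.mzml_cv$nonstandard]], "noise")) {
        noise <- vals
      } else {
        role_acc <- setdiff(accs, unlist(.mzml_cv[c("f64", "f32", "zlib",
                                                    "no_compression")]))
        key <- if (length(role_acc)) role_acc[1] else "unknown"
        extra[[key]] <- vals
      }
    }
    if (is.null(mz) || is.null(intensity)) {
      stop("spectrum '", id, "': missing m/z or intensity binary data array",
           call. = FALSE)
    }

    spectra[[i]] <- ms_spectrum(
      scan_number = sn, ms_level = ms_level, rt = rt,
      mz = mz, intensity = intensity, noise = noise,
      charge = if (!is.null(charge)) as.integer(round(charge)),
      precursor_mz = precursor_mz, precursor_charge = precursor_charge,
      precursor_scan = precursor_scan, filter_string = filter_string,
      is_centroid = is_centroid,
      extra_arrays = if (length(extra)) extra)
  }

  ms_run(spectra, source_file = source_file, instrument_model = instrument)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

.cvparam <- function(accession, name, value = NULL, unit = NULL) {
  s <- sprintf('<cvParam cvRef="MS" accession="%s" name="%s"', accession,
               .xml_escape(name))
  if (!is.null(value)) s <- paste0(s, sprintf(' value="%s"', .xml_escape(as.character(value))))
  if (!is.null(unit)) {
    s <- paste0(s, sprintf(' unitCvRef="UO" unitAccession="%s" unitName="%s"',
                           unit[1], unit[2]))
  }
  paste0(s, "/>")
}

.binary_block <- function(values, precision, compression, role_params) {
  b64 <- encode_binary_array(values, precision, compression)
  c(sprintf('<binaryDataArray encodedLength="%d">', nchar(b64)),
    .cvparam(if (precision == 64) "MS:1000523" else "MS:1000521",
             if (precision == 64) "64-bit float" else "32-bit float"),
    .cvparam(if (compression == "zlib") "MS:1000574" else "MS:1000576",
             if (compression == "zlib") "zlib compression" else "no compression"),
    role_params,
    paste0("<binary>", b64, "</binary>"),
    "</binaryDataArray>")
}

#' Write a run as minimal, schema-shaped mzML
#'
#' Emits the subset of mzML the reader understands: per-spectrum CV params
#' for MS level, centroid/profile mode, scan start time (minutes), filter
#' string and precursor, plus binary data arrays for m/z, intensity and the
#' optional noise (as a named "non-standard data array") and charge arrays.
#' Intended for fixture generation and converter testing;
#' `parse_mzml(write_mzml(run))` reproduces the run (bit-exactly at 64-bit
#' precision without compression).
#'
#' @param run A valid [ms_run()].
#' @param path Output file path.
#' @param precision 64 (default) or 32 bits for all binary arrays.
#' @param compression `"none"` or `"zlib"`.
#' @param indexed Wrap the document in an `indexedmzML` element (the index
#'   offsets are not emitted; readers that require them should re-index).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path, precision = 64,
                       compression = c("none", "zlib"), indexed = FALSE) {
  stopifnot(inherits(run, "ms_run"))
  compression <- match.arg(compression)

  out <- c('<?xml version="1.0" encoding="utf-8"?>')
  if (indexed) {
    out <- c(out, '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml">')
  }
  out <- c(out,
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>',
    '<fileDescription>',
    '<fileContent/>',
    '<sourceFileList count="1">',
    sprintf('<sourceFile id="SF1" name="%s" location="file:///"/>',
            .xml_escape(if (nzchar(run$source_file)) run$source_file else "synthetic")),
    '</sourceFileList>',
    '</fileDescription>',
    '<softwareList count="1">',
    '<software id="msh5" version="0.1.0"/>',
    '</softwareList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1">',
    if (nzchar(run$instrument_model)) {
      .cvparam("MS:1000031", "instrument model", run$instrument_model)
    } else "<cvParam cvRef=\"MS\" accession=\"MS:1000031\" name=\"instrument model\"/>",
    '</instrumentConfiguration>',
    '</instrumentConfigurationList>',
    '<dataProcessingList count="1">',
    '<dataProcessing id="DP1"><processingMethod order="1" softwareRef="msh5"/></dataProcessing>',
    '</dataProcessingList>',
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1">'),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="DP1">',
            length(run$spectra)))

  for (i in seq_along(run$spectra)) {
    s <- run$spectra[[i]]
    out <- c(out,
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
              i - 1L, s$scan_number, length(s$mz)),
      .cvparam("MS:1000511", "ms level", s$ms_level),
      if (s$is_centroid) .cvparam("MS:1000127", "centroid spectrum")
      else .cvparam("MS:1000128", "profile spectrum"),
      '<scanList count="1">',
      '<scan>',
      .cvparam("MS:1000016", "scan start time", format(s$rt, digits = 17),
               unit = c("UO:0000031", "minute")),
      if (nzchar(s$filter_string)) {
        .cvparam("MS:1000512", "filter string", s$filter_string)
      },
      '</scan>',
      '</scanList>')

    if (s$ms_level > 1) {
      prec_open <- if (!is.na(s$precursor_scan)) {
        sprintf('<precursor spectrumRef="scan=%d">', s$precursor_scan)
      } else "<precursor>"
      out <- c(out, '<precursorList count="1">', prec_open,
        '<selectedIonList count="1">',
        '<selectedIon>',
        if (!is.na(s$precursor_mz)) {
          .cvparam("MS:1000744", "selected ion m/z",
                   format(s$precursor_mz, digits = 17))
        },
        if (s$precursor_charge > 0) {
          .cvparam("MS:1000041", "charge state", s$precursor_charge)
        },
        '</selectedIon>',
        '</selectedIonList>',
        '<activation/>',
        '</precursor>',
        '</precursorList>')
    }

    n_arrays <- 2L + (!is.null(s$noise)) + (!is.null(s$charge))
    out <- c(out, sprintf('<binaryDataArrayList count="%d">', n_arrays),
      .binary_block(s$mz, precision, compression,
                    .cvparam("MS:1000514", "m/z array")),
      .binary_block(s$intensity, precision, compression,
                    .cvparam("MS:1000515", "intensity array")))
    if (!is.null(s$noise)) {
      out <- c(out, .binary_block(s$noise, precision, compression,
                                  .cvparam("MS:1000786", "non-standard data array",
                                           "noise")))
    }
    if (!is.null(s$charge)) {
      out <- c(out, .binary_block(as.numeric(s$charge), precision, compression,
                                  .cvparam("MS:1000516", "charge array")))
    }
    out <- c(out, '</binaryDataArrayList>', '</spectrum>')
  }

  out <- c(out, '</spectrumList>', '</run>', '</mzML>')
  if (indexed) out <- c(out, '</indexedmzML>')
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
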