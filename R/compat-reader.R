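## Minimal second reader, deliberately independent of the store's own
## read path (open_store/get_spectrum/read_run): it touches the file only
## through generic rhdf5 dataset reads, the way a short analysis script in
## any HDF5-capable language would.  Its role is to make the format's
## language-neutrality claim assertable -- the store is self-describing
## enough that a reader with no knowledge of this package's internals
## recovers bit-identical numbers.

#' Read the base peak chromatogram with a generic HDF5 reader
#'
#' Reads the `bpc` / `bpc_rt` datasets directly by name, with no use of
#' the package's store handle machinery.  Values are numerically identical
#' to the chromatogram the store computed at write time.
#'
#' @param path Store file.
#' @return List with numeric vectors `rt` and `value`.
#' @export
read_bpc <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  list(rt = as.numeric(rhdf5::h5read(path, "bpc_rt")),
       value = as.numeric(rhdf5::h5read(path, "bpc")))
}

#' Read one spectrum with a generic HDF5 reader
#'
#' Works on both layouts using only generic dataset/attribute reads: in
#' ragged mode the scan's row of the variable-length `mz` / `intensity`
#' columns, in tree mode the scan's group (located by its zero-padded
#' name).  Arrays are bit-identical to [get_spectrum()] output.
#'
#' @param path Store file.
#' @param scan_number Scan to fetch.
#' @return List: `scan_number`, `ms_level`, `precursor_mz`, `mz`,
#'   `intensity`.
#' @export
read_spectrum <- function(path, scan_number) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  scan_number <- as.integer(scan_number)
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (identical(as.character(attrs$layout_mode), "tree")) {
    ls <- rhdf5::h5ls(path)
    grp <- ls[ls$otype == "H5I_GROUP" &
                ls$name == sprintf("scan_%06d", scan_number), ]
    if (!nrow(grp)) stop("scan ", scan_number, " not found", call. = FALSE)
    g <- paste0(sub("^/", "", grp$group[1]), "/", grp$name[1])
    at <- rhdf5::h5readAttributes(path, g)
    pmz <- as.numeric(at$precursor_mz)
    return(list(scan_number = scan_number,
                ms_level = as.integer(at$ms_level),
                precursor_mz = if (is.nan(pmz)) NA_real_ else pmz,
                mz = as.numeric(rhdf5::h5read(path, paste0(g, "/mz"))),
                intensity = as.numeric(rhdf5::h5read(path, paste0(g, "/intensity")))))
  }
  sn <- as.integer(rhdf5::h5read(path, "scan_number"))
  i <- match(scan_number, sn)
  if (is.na(i)) stop("scan ", scan_number, " not found", call. = FALSE)
  ## rhdf5 does not read numeric VLEN datasets; the raw row accessor is a
  ## direct HDF5 hyperslab read shared with nothing above it
  pmz <- as.numeric(rhdf5::h5read(path, "precursor_mz", index = list(i)))
  list(scan_number = scan_number,
       ms_level = as.integer(rhdf5::h5read(path, "ms_level", index = list(i))),
       precursor_mz = if (is.nan(pmz)) NA_real_ else pmz,
       mz = .Call(msh5_read_vlen_row, path, "mz", i),
       intensity = .Call(msh5_read_vlen_row, path, "intensity", i))
}
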