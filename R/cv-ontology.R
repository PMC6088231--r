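#' Parse a controlled vocabulary in OBO v1.2 format
#'
#' Reads `[Term]` stanzas (the `id:`, `name:`, `is_a:` and `is_obsolete:`
#' tags) into a term catalog used to annotate every dataset the HDF5 store
#' writes.  The PSI-MS controlled vocabulary is distributed in this format;
#' a small excerpt covering the terms the store needs is bundled with the
#' package (see [msh5_obo_excerpt()]).
#'
#' Only the fields the catalog models are retained: accession, name, `is_a`
#' parentage and the obsolete flag.  Other tags (definitions, xrefs,
#' synonyms, non-`is_a` relationships) are ignored.  Terms from namespaces
#' other than MS are kept in the catalog; callers that only care about MS
#' accessions may filter on the prefix.
#'
#' @param x Path to an OBO file, or a character vector of OBO text lines
#'   (anything containing a newline is treated as text, not a path).
#' @return A `term_catalog` object: a list with elements `terms` (named list
#'   of `cv_term` records) and `source_version` (the `data-version` header,
#'   or `NA`).
#' @examples
#' obo <- c("[Term]", "id: MS:1000810", "name: mass chromatogram",
#'          "[Term]", "id: MS:1000628", "name: basepeak chromatogram",
#'          "is_a: MS:1000810 ! mass chromatogram")
#' cat_ <- parse_obo(obo)
#' resolve_term(cat_, "MS:1000628")$name
#' @seealso [resolve_term()], [has_ancestor()], [annotation_for_role()]
#' @export
parse_obo <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)

  source_version <- NA_character_
  terms <- list()

  ## split into stanzas at lines of the form "[...]"
  stanza_starts <- grep("^\\[[^]]+\\]\\s*$", lines)
  header_end <- if (length(stanza_starts)) stanza_starts[1] - 1L else length(lines)
  if (header_end >= 1) {
    dv <- grep("^data-version:", lines[seq_len(header_end)], value = TRUE)
    if (length(dv)) source_version <- trimws(sub("^data-version:", "", dv[1]))
  }

  bounds <- c(stanza_starts, length(lines) + 1L)
  for (k in seq_along(stanza_starts)) {
    head_line <- trimws(lines[stanza_starts[k]])
    if (head_line != "[Term]") next
    body <- lines[seq(stanza_starts[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]

    tag_val <- function(tag) {
      hits <- grep(paste0("^", tag, ":"), body, value = TRUE)
      vals <- trimws(sub(paste0("^", tag, ":"), "", hits))
      sub("\\s*!.*$", "", vals)  # strip trailing "! comment"
    }
    id <- tag_val("id")
    if (!length(id)) next  # anonymous stanza: skip
    nm <- grep("^name:", body, value = TRUE)
    nm <- trimws(sub("^name:", "", nm))
    if (!length(nm) || !nzchar(nm[1])) {
      stop("malformed [Term] stanza: id '", id[1], "' has no name", call. = FALSE)
    }
    parents <- tag_val("is_a")
    parents <- setdiff(parents, id[1])
    obsolete <- any(tolower(tag_val("is_obsolete")) == "true")
    terms[[id[1]]] <- structure(
      list(accession = id[1], name = nm[1],
           parents = parents, obsolete = obsolete),
      class = "cv_term")
  }

  structure(list(terms = terms, source_version = source_version),
            class = "term_catalog")
}

#' @export
print.term_catalog <- function(x, ...) {
  cat("<term_catalog> ", length(x$terms), " terms",
      if (!is.na(x$source_version)) paste0(" (data-version ", x$source_version, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Serialize a term catalog back to OBO text
#'
#' Inverse of [parse_obo()] for the fields the catalog models; parsing the
#' output yields an equal catalog.
#'
#' @param catalog A `term_catalog`.
#' @return Character vector of OBO lines.
#' @export
format_obo <- function(catalog) {
  out <- c("format-version: 1.2")
  if (!is.na(catalog$source_version)) {
    out <- c(out, paste0("data-version: ", catalog$source_version))
  }
  for (t in catalog$terms) {
    out <- c(out, "", "[Term]",
             paste0("id: ", t$accession),
             paste0("name: ", t$name))
    for (p in t$parents) out <- c(out, paste0("is_a: ", p))
    if (t$obsolete) out <- c(out, "is_obsolete: true")
  }
  out
}

#' Look up a controlled-vocabulary term by accession
#'
#' @param catalog A `term_catalog` from [parse_obo()].
#' @param accession Accession string, e.g. `"MS:1000628"`.
#' @return The `cv_term` record (accession, name, parents, obsolete).
#' @export
resolve_term <- function(catalog, accession) {
  stopifnot(inherits(catalog, "term_catalog"))
  t <- catalog$terms[[accession]]
  if (is.null(t)) {
    stop("unknown CV accession: ", accession, call. = FALSE)
  }
  t
}

#' Test transitive is_a ancestry between two terms
#'
#' `TRUE` iff `ancestor` is reachable from `accession` through one or more
#' `is_a` links.  A term is not its own ancestor.  Parent accessions absent
#' from the catalog (dangling references) terminate their branch silently.
#'
#' @param catalog A `term_catalog`.
#' @param accession,ancestor Accession strings; both must resolve.
#' @return Logical scalar.
#' @examples
#' # basepeak chromatogram is a kind of mass chromatogram:
#' cat_ <- msh5_default_catalog()
#' has_ancestor(cat_, "MS:1000628", "MS:1000810")
#' @export
has_ancestor <- function(catalog, accession, ancestor) {
  resolve_term(catalog, accession)
  resolve_term(catalog, ancestor)

  visited <- character(0)
  on_path <- character(0)
  found <- FALSE

  walk <- function(acc) {
    if (found) return(invisible(NULL))
    if (acc %in% on_path) {
      stop("is_a cycle detected involving ", acc, call. = FALSE)
    }
    if (acc %in% visited) return(invisible(NULL))
    on_path <<- c(on_path, acc)
    t <- catalog$terms[[acc]]
    if (!is.null(t)) {
      for (p in t$parents) {
        if (p == ancestor) found <<- TRUE
        if (!found) walk(p)
      }
    }
    on_path <<- setdiff(on_path, acc)
    visited <<- c(visited, acc)
    invisible(NULL)
  }
  walk(accession)
  found
}

## Role -> accession table for every dataset the store writes.  Accessions
## not printed in a reference are verified against the PSI-MS OBO; where the
## vocabulary has no specific term the documented parent-term fallback
## "binary data array" (MS:1000513) is used.  Noise arrays have no official
## term (signal-to-noise does: MS:1000517); per-centroid charge does
## (MS:1000516 "charge array").
.role_entry <- function(accession, name, is_fallback = FALSE) {
  list(accession = accession, name = name, is_fallback = is_fallback)
}
.role_table <- list(
  mz              = .role_entry("MS:1000514", "m/z array"),
  intensity       = .role_entry("MS:1000515", "intensity array"),
  charge          = .role_entry("MS:1000516", "charge array"),
  noise           = .role_entry("MS:1000513", "binary data array", TRUE),
  signal_to_noise = .role_entry("MS:1000517", "signal to noise array"),
  bpc             = .role_entry("MS:1000628", "basepeak chromatogram"),
  tic             = .role_entry("MS:1000235", "total ion current chromatogram"),
  chrom_rt        = .role_entry("MS:1000595", "time array"),
  scan_number     = .role_entry("MS:1001115", "scan number(s)"),
  parent_scan     = .role_entry("MS:1001115", "scan number(s)", TRUE),
  ms_level        = .role_entry("MS:1000511", "ms level"),
  rt              = .role_entry("MS:1000016", "scan start time"),
  filter_string   = .role_entry("MS:1000512", "filter string"),
  precursor_mz    = .role_entry("MS:1000744", "selected ion m/z"),
  precursor_charge = .role_entry("MS:1000041", "charge state"),
  is_centroid     = .role_entry("MS:1000525", "spectrum representation", TRUE)
)

#' Dataset roles known to the HDF5 store
#'
#' @return Character vector of role names accepted by
#'   [annotation_for_role()].
#' @export
store_roles <- function() names(.role_table)

#' Controlled-vocabulary annotation for a store dataset role
#'
#' Maps a symbolic dataset role (`"mz"`, `"intensity"`, `"noise"`, `"bpc"`,
#' ...) to its PSI-MS annotation via a fixed role table, cross-checked
#' against the catalog: the term must resolve and its catalog name is the
#' one reported.  Roles for which the vocabulary has no specific term carry
#' an ancestor-level fallback annotation (`is_fallback = TRUE`) -- e.g.
#' per-centroid noise estimates fall back on "binary data array"
#' (MS:1000513).
#'
#' @param catalog A `term_catalog`; defaults to the bundled PSI-MS excerpt.
#' @param role One of [store_roles()].
#' @return A `role_annotation` list: `role`, `accession`, `name`,
#'   `is_fallback`.
#' @examples
#' annotation_for_role(role = "bpc")     # MS:1000628 basepeak chromatogram
#' annotation_for_role(role = "noise")   # MS:1000513 fallback
#' @export
annotation_for_role <- function(catalog = msh5_default_catalog(), role) {
  entry <- .role_table[[role]]
  if (is.null(entry)) {
    stop("unknown dataset role: '", role, "' (known: ",
         paste(store_roles(), collapse = ", "), ")", call. = FALSE)
  }
  term <- tryCatch(resolve_term(catalog, entry$accession),
                   error = function(e) {
                     stop("catalog does not define ", entry$accession,
                          " required for role '", role, "'", call. = FALSE)
                   })
  if (!identical(term$name, entry$name)) {
    stop("catalog version drift: ", entry$accession, " is named '",
         term$name, "' in the catalog but '", entry$name,
         "' in the role table", call. = FALSE)
  }
  structure(list(role = role, accession = entry$accession,
                 name = term$name, is_fallback = entry$is_fallback),
            class = "role_annotation")
}

#' Path to the bundled PSI-MS controlled-vocabulary excerpt
#'
#' A small excerpt (about 30 terms) of the PSI-MS controlled vocabulary in
#' OBO v1.2 format, covering every accession in the store's role table plus
#' the terms the mzML reader and writer use, so the package works without a
#' download.  Pass a full `psi-ms.obo` to [parse_obo()] to use the complete
#' vocabulary instead.
#'
#' @return File path.
#' @export
msh5_obo_excerpt <- function() {
  system.file("extdata", "psi-ms-excerpt.obo", package = "msh5", mustWork = TRUE)
}

.msh5_env <- new.env(parent = emptyenv())

#' Default term catalog (parsed bundled excerpt, cached)
#'
#' @return A `term_catalog`.
#' @export
msh5_default_catalog <- function() {
  if (is.null(.msh5_env$catalog)) {
    .msh5_env$catalog <- parse_obo(msh5_obo_excerpt())
  }
  .msh5_env$catalog
}
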