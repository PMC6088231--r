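---
title: "The msh5 storage format: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The msh5 storage format: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msh5)
```

## The problem

Mass spectrometry runs are long sequences of scans, each scan a pair of
parallel numeric arrays (m/z and intensity, sometimes per-centroid noise
and charge-state estimates) plus a handful of scalar metadata.  The data
is numeric, regular and large; the community interchange format, mzML, is
textual XML with peak arrays base64-encoded in the middle of it.  Every
consumer therefore needs format-specific code before it can touch a
single number, and the ecosystem has accumulated work-arounds (external
binary adjunct files, extra compression codecs, side indexes) that each
erode the original goal of a self-describing interchange format.

`msh5` takes the other road: HDF5 *is* a self-describing container with
mature tooling in every scientific language, so spectral data is stored
as plain HDF5 datasets of doubles with self-explanatory names, and the
*meaning* of each dataset is pinned down by PSI-MS controlled-vocabulary
annotations carried as HDF5 attributes.  Nothing about the layout
requires this package to read: the claim, made assertable in the test
suite, is that a generic HDF5 walker recovers every number bit-exactly.

## Layouts

**Ragged mode** (default).  Each element type across all scans forms one
variable-length (VLEN) dataset at the file root: row *i* of `mz` is the
m/z array of the *i*-th scan.  Scalar per-scan metadata are ordinary
fixed-length columns in the same row order.  This keeps the whole run
browsable as a table of ragged rows in any HDF5 viewer, and single-scan
random access is a one-row hyperslab read.

**Tree mode.**  Tandem acquisitions are trees: a survey scan's selected
precursors yield MS2 scans, whose fragments may themselves be selected
for MS3.  Tree mode maps this structure onto HDF5 groups: each scan is a
group `scan_<number, zero-padded to 6 digits>` nested under its
precursor's group (survey scans under a top-level `scans` group).  The
zero-padding makes lexicographic ordering equal numeric ordering in
viewers.  Each group holds that scan's peak datasets, each annotated
independently — useful when per-scan annotation fidelity matters more
than flat browsability.  Both layouts store the same information;
`read_run()` output is identical (this is a tested invariant), so the
choice is purely a view preference.

Chromatograms (`bpc`, `tic`) are computed at write time and stored at
the root in both modes, as paired value/retention-time datasets
(`bpc`/`bpc_rt`, `tic`/`tic_rt`).  Storing the axis separately rather
than as a 2×N matrix keeps each dataset one-dimensional and
independently annotatable.

## Controlled-vocabulary annotation

Two attribute conventions coexist in the wild: an explicit
`PSI-MS_ID` / `PSI-MS_NAME` attribute pair, and a single attribute whose
*key* is the accession and whose value is the term name (which is what a
viewer surfaces most directly).  The store writes both; they are
redundant by construction and `list_annotations()` checks the pair.

The role → accession table is hard-coded and verified against the
catalog at write time (a renamed or missing term is a configuration
error and the file is not written).  Three cases deserve note:

* per-centroid **noise** estimates have no specific PSI-MS term — not to
  be confused with the signal-to-noise array, MS:1000517 — so the store
  falls back on the parent term "binary data array" (MS:1000513), with
  `is_fallback = TRUE` in the annotation record;
* per-centroid **charge** does have a term (MS:1000516, "charge array"),
  so no fallback is needed;
* scalar metadata columns are annotated too (`rt` → MS:1000016 "scan
  start time", `filter_string` → MS:1000512, and so on), with
  ancestor-level fallbacks where the vocabulary is silent
  (`is_centroid` → MS:1000525 "spectrum representation").

A ~30-term excerpt of the PSI-MS vocabulary, restricted to the
`id`/`name`/`is_a` tags the catalog models, is bundled so the package
works offline; the full `psi-ms.obo` can be supplied to `parse_obo()`
or the CLI's `--obo` flag, and the role table is then re-verified
against it.

## Numerical and encoding choices

* **All peak data is stored as 64-bit floats**, whatever the source
  precision; 32-bit mzML arrays are widened on import.  Stored m/z
  values are the literal values — self-description is deliberately
  favoured over the extra compression that delta-encoding would buy,
  because delta-encoded files are unreadable to standard viewers.
* **Retention time is minutes everywhere.**  mzML declaring seconds is
  converted on import; an absent unit is assumed minutes, with a
  warning.
* **Sentinels**: HDF5 numeric datasets cannot hold nulls, so
  `parent_scan` is −1 for scans without a precursor reference,
  `precursor_mz` is NaN for survey scans (mapped back to `NA` on read),
  and `precursor_charge` 0 means "unknown" (the vendor convention,
  passed through JSON export untouched).
* **Compression**: gzip per dataset chunk, default level 4, with the
  byte-shuffle filter (lossless, helps deflate on floats); level 0
  stores uncompressed chunks.  The tested size property is qualitative —
  a level-6 file is no larger than a level-0 file of the same run —
  because absolute ratios depend entirely on the data.
* **mzML codecs**: little-endian IEEE floats, optionally zlib
  (RFC 1950), then base64.  MS-Numpress is intentionally unsupported;
  it is exactly the kind of adjunct codec the format avoids needing.
* **Empty peak lists** contribute a zero point to chromatograms (not a
  gap), keeping traces index-aligned with scans; missing optional
  arrays are empty VLEN rows so every column has one row per scan.
* **Scan numbers** are 1-based and taken from the `scan=` token of mzML
  spectrum ids when present, else sequential position; ties in m/z are
  allowed (profile data), and peak lists are sorted ascending on
  ingest.
* **Multiple precursors** per spectrum: the first wins, the rest are
  dropped with a warning (multiplexed acquisitions are out of scope).
* Chromatogram level: `compute_bpc()`/`compute_tic()` default to MS1
  but take `ms_level` as a parameter, since the right behaviour for
  MS2-only acquisitions is genuinely underdetermined.

The VLEN datasets are written through a small C layer against the HDF5
library (numeric VLEN is not exposed by the high-level R bindings); an
alternative flat-array-plus-offset-index encoding would also be
possible but loses the one-row-per-scan browsability that motivates the
ragged layout, so it is documented here and not implemented.

One caveat inherited from HDF5 itself: dataset filters do not reach the
VLEN heap payload, so gzip acts on the fixed columns and row
descriptors only.  This is a known trade-off of VLEN storage and
another reason the compression claim above is qualitative.

## Centroid vs profile export

Instruments produce profile spectra; vendors also provide centroided
versions with per-centroid noise and charge estimates.  The store makes
this a write-time option (`store_profile` in `store_layout()`): when
`FALSE`, profile-mode spectra are excluded and the root attribute
`centroid_export` records the choice.  Product-ion scans whose survey
parent was excluded keep their peak data but lose the parent-scan
reference — the data is real, the tree link is not reconstructible.  No
peak picking is performed; centroiding is a vendor/upstream concern.

## The synthetic generator

The generator exists so every code path is exercisable without vendor
files; it emulates the *structure* of an LC-MS/MS run, not instrument
physics:

* survey scans carry 5-point Gaussian stencils (σ = 0.01 Th spacing)
  around each pool peptide's doubly protonated m/z, scaled by a
  Gaussian elution profile (apexes uniform over the central 60% of the
  gradient, width = gradient/10) and a log-normal per-peptide abundance
  (median 10⁶);
* each survey scan is followed by MS2 spectra of pool peptides over the
  singly charged b/y series, intensities log-normal (sdlog 0.5) scaled
  to a base peak of 10⁴, with multiplicative jitter `noise_sd`
  (default 0.1); per-centroid noise is uniform(0.5, 2) × √intensity,
  mimicking the shape of vendor noise estimates; at `max_ms_level = 3`
  each MS2 gets one MS3 child fragmenting the peptide's C-terminal half
  with the corresponding y ion as precursor;
* retention times are evenly spaced over `rt_span` (default 30 min,
  50 survey cycles, 2 precursors per cycle — a miniature but
  structurally complete acquisition);
* masses are monoisotopic throughout, built from a residue table whose
  every entry is cross-checked in the tests against an independent
  element-composition oracle; the default peptide pool is headed by
  DALSSVQESQVAQQAR, whose doubly charged ion at 858.93 m/z is the
  package's worked example.

What passing tests therefore show: structural correctness — round
trips, tree construction, annotation completeness, codec identity —
under realistic array shapes and value ranges.  What they cannot show:
behaviour on real files' quirks (vendor filter-string dialects,
nonstandard CV usage, chromatogram-centric SRM files), isotope
envelopes, or realistic noise statistics.  The mzML reader is
cross-checked against an independent implementation (ProteoWizard via
`mzR`) on generated files, which mitigates but does not remove that
gap.

## Problem sizes and determinism

The test suite and the acceptance script use runs of 3–50 survey cycles
(9–150 scans, ~30 peaks per MS2 scan) and 1,000-case codec sweeps;
these sizes give bit-level assertions comfortable headroom on one CPU
while exercising every branch (MS3 trees, empty runs, empty peak
lists).  All randomness flows from explicit seeds; `synth_run()`
restores the caller's RNG state, so generation is reproducible and
side-effect-free.

## Known limitations

* No vendor RAW ingestion; mzML (or the generator) is the way in.
* mzML metadata beyond the modelled fields (software chains, full
  instrument configurations) is not carried through; unknown per-peak
  arrays are preserved in memory (`extra_arrays`) but only the modelled
  arrays are stored in HDF5.
* Files are written once — no append or edit.
* `indexedmzML` indexes are skipped, not verified; the store provides
  its own random access.
* Spectrum JSON export targets the array-of-pairs viewer dialect;
  fragment annotation is the viewer's job.
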