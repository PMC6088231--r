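# msh5 — self-describing HDF5 storage for mass spectrometry runs

LC-MS/MS instruments emit either proprietary vendor files or mzML, an
XML interchange format that base64-encodes every peak array.  Both hide
the numbers: vendor files need platform-locked libraries, and mzML needs
format-specific decoding before a single m/z value is usable.  `msh5`
implements the alternative: store runs in plain ("vanilla") HDF5, where
every dataset is a straightforward vector of 64-bit floats with a
self-explanatory name, and every dataset carries its PSI-MS
controlled-vocabulary annotation as HDF5 attributes.  Any generic HDF5
tool — HDFView, `h5py`, `rhdf5`, an h5serv instance — can then discover,
read and serve the data with no knowledge of this package.

The package is aimed at proteomics/metabolomics tool builders and data
managers who need an efficient, random-access, language-neutral on-disk
representation of spectral data.

## The format

Two layouts, chosen at write time and recorded in the file:

* **ragged** (default): one root-level variable-length (VLEN) dataset per
  element type — `mz`, `intensity`, and `noise` / `charge` when present —
  with one row per scan, alongside fixed-length per-scan metadata columns
  (`scan_number`, `ms_level`, `rt`, `precursor_mz`, `precursor_charge`,
  `parent_scan`, `filter_string`, `is_centroid`) and the derived base-peak
  and total-ion chromatograms (`bpc`/`bpc_rt`, `tic`/`tic_rt`).
* **tree**: one HDF5 group per scan, nested under its precursor's group,
  so the group hierarchy *is* the MSⁿ scan tree; each group holds that
  scan's peak datasets, each annotated independently.

Every dataset is tagged with the accession (`PSI-MS_ID`) and name
(`PSI-MS_NAME`) of the controlled-vocabulary term that best describes it,
plus an attribute named by the accession itself (e.g. `MS:1000628` =
`"basepeak chromatogram"` on the `bpc` dataset).  Where PSI-MS has no
specific term — per-centroid noise estimates, for example — the store
falls back on the parent term "binary data array" (MS:1000513).  Stored
m/z values are the literal values: no delta-encoding or other
representation tricks that would defeat generic viewers.

Around the store, the package provides an mzML reader (bare and
`indexedmzML`, 32/64-bit, zlib or uncompressed binary arrays), a minimal
mzML writer for fixtures, chromatogram computation, JSON peak-list export
for Lorikeet-style web viewers, a PSI-MS OBO parser with a bundled
vocabulary excerpt, and a seeded synthetic LC-MS/MS generator built on
peptide b/y fragment-mass arithmetic, so everything is testable without
vendor data.

## Worked example

The peptide DALSSVQESQVAQQAR (a tryptic peptide of Bovine Apolipoprotein
C-III) as a doubly protonated precursor:

```r
library(msh5)
peptide_monoisotopic_mass("DALSSVQESQVAQQAR")
#> [1] 1715.844
precursor_mz("DALSSVQESQVAQQAR", 2)
#> [1] 858.9292
```

858.93 m/z — within 0.01 Th of the instrument-reported 858.92 for this
ion.  A synthetic run built around such peptides, stored and inspected:

```r
run <- synth_run(synth_params(n_ms1 = 3, seed = 42))
handle <- write_ragged(run, "demo.h5")
get_spectrum(handle, 2)
#> <ms_spectrum> scan 2  MS2  rt 1.667 min  30 peaks  precursor 858.9292 (z=2)
```

or from the shell (`inst/cli/msh5`):

```
$ msh5 synth --seed 42 --n-ms1 3 demo
$ msh5 inspect demo.h5
store:   demo.h5
layout:  ragged
scans:   9
version: 1.0
dataset                      class    dim      CV annotation
bpc                          FLOAT    3        MS:1000628 basepeak chromatogram
bpc_rt                       FLOAT    3        MS:1000595 time array
charge                       VLEN     9        MS:1000516 charge array
filter_string                STRING   9        MS:1000512 filter string
intensity                    VLEN     9        MS:1000515 intensity array
...
```

Nine scans (3 survey cycles × [1 MS1 + 2 MS2]), ragged columns of
variable-length rows, every dataset annotated.  `msh5 convert in.mzML
out.h5` converts existing mzML files; `msh5 extract --scan 2 demo.h5`
emits the scan as viewer-ready JSON.

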