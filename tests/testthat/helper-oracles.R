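# Independent oracles, kept deliberately separate from the implementation.

# --- element-composition mass oracle -----------------------------------
# Monoisotopic isotope masses (CODATA/AME); residue elemental formulas.
# Peptide masses in the package come from a residue-mass lookup table;
# this oracle rebuilds them from element counts.
.elem <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
           O = 15.9949146196, S = 31.97207100)

.residue_formula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

oracle_formula_mass <- function(counts) {
  sum(.elem[names(counts)] * counts)
}

oracle_residue_mass <- function(code) {
  oracle_formula_mass(.residue_formula[[code]])
}

oracle_peptide_mass <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  sum(vapply(aa, oracle_residue_mass, numeric(1))) +
    oracle_formula_mass(c(H = 2, O = 1))
}

oracle_proton <- 1.00727646688

# --- brute-force DAG reachability --------------------------------------
# edges: data.frame(from, to); reachable iff `to` appears in the closure
# of `from` (excluding from itself unless revisited through a longer path)
oracle_reachable <- function(edges, from, to) {
  frontier <- edges$to[edges$from == from]
  seen <- character(0)
  while (length(frontier)) {
    if (to %in% frontier) return(TRUE)
    seen <- union(seen, frontier)
    frontier <- setdiff(edges$to[edges$from %in% frontier], seen)
  }
  FALSE
}

# --- tiny run builders --------------------------------------------------
make_simple_run <- function() {
  ms_run(list(
    ms_spectrum(1L, 1L, 0.0, mz = c(100, 200, 300), intensity = c(1, 5, 3),
                is_centroid = FALSE),
    ms_spectrum(2L, 2L, 0.1, mz = c(50, 150), intensity = c(2, 4),
                noise = c(0.1, 0.2), charge = c(1L, 1L),
                precursor_mz = 200.0, precursor_charge = 2L,
                precursor_scan = 1L),
    ms_spectrum(3L, 2L, 0.2, mz = c(60, 160), intensity = c(7, 1),
                precursor_mz = 300.0, precursor_charge = 2L,
                precursor_scan = 1L),
    ms_spectrum(4L, 3L, 0.3, mz = 75, intensity = 9,
                precursor_mz = 150.0, precursor_charge = 1L,
                precursor_scan = 2L)),
    source_file = "fixture", instrument_model = "toy")
}

toy_obo <- c(
  "format-version: 1.2",
  "data-version: toy-1",
  "",
  "[Term]",
  "id: MS:1000810",
  "name: mass chromatogram",
  "",
  "[Term]",
  "id: MS:1000628",
  "name: basepeak chromatogram",
  "is_a: MS:1000810 ! mass chromatogram",
  "",
  "[Term]",
  "id: MS:1000235",
  "name: total ion current chromatogram",
  "is_a: MS:1000810")
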