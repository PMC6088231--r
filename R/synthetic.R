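#' Monoisotopic residue mass table
#'
#' Monoisotopic masses (Da) of the 20 standard amino-acid residues (the
#' chain residue, i.e. amino acid minus water), plus the water and proton
#' constants used in peptide and fragment m/z arithmetic.  No
#' modifications; average masses are out of scope.
#'
#' @return A `residue_mass_table` list: `residues` (named numeric vector),
#'   `water_mass`, `proton_mass`.
#' @export
residue_mass_table <- function() {
  structure(list(
    residues = c(
      G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276384,
      V = 99.06841390, T = 101.04767846, C = 103.00918447, L = 113.08406396,
      I = 113.08406396, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
      K = 128.09496300, E = 129.04259308, M = 131.04048459, H = 137.05891186,
      F = 147.06841390, R = 156.10111102, Y = 163.06332852, W = 186.07931294),
    water_mass = 18.01056468,
    proton_mass = 1.00727646688
  ), class = "residue_mass_table")
}

.residues_of <- function(sequence, table) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("peptide sequence must be a non-empty string", call. = FALSE)
  }
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(aa, names(table$residues))
  if (length(unknown)) {
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(table$residues[aa])
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water (the terminal H and OH).
#'
#' @param sequence Peptide as one-letter codes, e.g. `"DALSSVQESQVAQQAR"`.
#' @param table A [residue_mass_table()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_monoisotopic_mass("DALSSVQESQVAQQAR")  # ~1715.84 Da
#' @export
peptide_monoisotopic_mass <- function(sequence, table = residue_mass_table()) {
  sum(.residues_of(sequence, table)) + table$water_mass
}

#' Theoretical precursor m/z of a protonated peptide
#'
#' `(M + z * m_proton) / z` for the `[M + zH]^z+` ion.
#'
#' @inheritParams peptide_monoisotopic_mass
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @examples
#' # doubly protonated DALSSVQESQVAQQAR (Bovine Apolipoprotein C-III tryptic
#' # peptide): ~858.93 m/z
#' precursor_mz("DALSSVQESQVAQQAR", 2)
#' @export
precursor_mz <- function(sequence, charge, table = residue_mass_table()) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1) stop("charge must be >= 1", call. = FALSE)
  (peptide_monoisotopic_mass(sequence, table) + charge * table$proton_mass) /
    charge
}

#' Singly charged b- and y-ion series of a peptide
#'
#' Backbone cleavage fragments: `b_i` is the N-terminal prefix of `i`
#' residues plus a proton; `y_i` the C-terminal suffix of `i` residues plus
#' water and a proton (`i = 1 .. n-1`).  Both series are ascending in `i`.
#'
#' @inheritParams peptide_monoisotopic_mass
#' @return List with numeric vectors `b` and `y`.
#' @export
fragment_mzs <- function(sequence, table = residue_mass_table()) {
  res <- .residues_of(sequence, table)
  n <- length(res)
  if (n < 2) stop("need at least 2 residues to fragment", call. = FALSE)
  b <- cumsum(res[-n]) + table$proton_mass
  y <- cumsum(rev(res)[-n]) + table$water_mass + table$proton_mass
  list(b = unname(b), y = unname(y))
}

#' Parameters for the synthetic LC-MS/MS generator
#'
#' The generator is the package's stand-in for vendor data: peptide-like
#' precursors, b/y fragment MS2 spectra, optional MS3 children, per-centroid
#' noise and charge arrays.  Identical seed, identical run.
#'
#' @param n_ms1 Number of MS1 survey scans.
#' @param peptides_per_ms1 Precursors fragmented after each survey scan.
#' @param sequence_pool Peptides cycled through as precursors.
#' @param max_ms_level 2 or 3; at 3 every MS2 scan gets one MS3 child.
#' @param rt_span Gradient length in minutes; scans are evenly spaced.
#' @param noise_sd Relative (fractional) intensity jitter applied to
#'   fragment intensities.
#' @param seed RNG seed driving all stochastic choices.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_ms1 = 50L, peptides_per_ms1 = 2L,
                         sequence_pool = c("DALSSVQESQVAQQAR",
                                           "LGEYGFQNALIVR",
                                           "VATVSLPR",
                                           "TCVADESHAGCEK",
                                           "YICDNQDTISSK"),
                         max_ms_level = 2L, rt_span = 30, noise_sd = 0.1,
                         seed = 1L) {
  stopifnot(n_ms1 >= 1, peptides_per_ms1 >= 1, length(sequence_pool) >= 1,
            max_ms_level %in% c(2L, 3L), rt_span > 0, noise_sd >= 0)
  structure(list(n_ms1 = as.integer(n_ms1),
                 peptides_per_ms1 = as.integer(peptides_per_ms1),
                 sequence_pool = sequence_pool,
                 max_ms_level = as.integer(max_ms_level),
                 rt_span = as.numeric(rt_span),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "synth_params")
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthesize one fragment (MSn) spectrum of a peptide
#'
#' Centroid spectrum over the singly charged b/y series with log-normal
#' intensities (meanlog 0, sdlog 0.5) scaled to a base peak of 1e4, a
#' per-centroid noise vector (uniform(0.5, 2) x sqrt(intensity), mimicking
#' vendor noise estimates) and a per-centroid charge vector of 1.  Uses the
#' caller's RNG state; seed at the run level for determinism.
#'
#' @param sequence,charge Precursor peptide and charge state.
#' @param scan_number,rt Scan metadata for the record.
#' @param precursor_scan Parent scan number (or `NA`).
#' @param ms_level MS level of the product spectrum (2 or 3).
#' @param noise_sd Relative intensity jitter.
#' @param table Residue mass table.
#' @return An [ms_spectrum()].
#' @export
synth_msms_spectrum <- function(sequence, charge, scan_number, rt,
                                precursor_scan = NA_integer_, ms_level = 2L,
                                noise_sd = 0.1,
                                table = residue_mass_table()) {
  fr <- fragment_mzs(sequence, table)
  mz <- c(fr$b, fr$y)
  inten <- stats::rlnorm(length(mz), meanlog = 0, sdlog = 0.5)
  if (noise_sd > 0) {
    inten <- inten * pmax(1 + stats::rnorm(length(mz), sd = noise_sd), 0.01)
  }
  inten <- inten / max(inten) * 1e4
  noise <- stats::runif(length(mz), 0.5, 2.0) * sqrt(inten)
  ms_spectrum(
    scan_number = scan_number, ms_level = ms_level, rt = rt,
    mz = mz, intensity = inten, noise = noise,
    charge = rep(1L, length(mz)),
    precursor_mz = precursor_mz(sequence, charge, table),
    precursor_charge = charge,
    precursor_scan = precursor_scan,
    filter_string = sprintf("FTMS + p NSI d Full ms%d %.4f@hcd28.00",
                            ms_level, precursor_mz(sequence, charge, table)),
    is_centroid = TRUE)
}

.ms1_profile_scan <- function(scan_number, rt, pool_mz, abundance) {
  ## 5-point Gaussian stencil per precursor so profile-mode export has
  ## profile-shaped content
  offsets <- seq(-0.02, 0.02, by = 0.01)
  shape <- exp(-(offsets / 0.01)^2 / 2)
  mz <- as.vector(vapply(pool_mz, function(m) m + offsets,
                         numeric(length(offsets))))
  inten <- as.vector(vapply(abundance, function(a) a * shape,
                            numeric(length(shape))))
  ms_spectrum(scan_number = scan_number, ms_level = 1L, rt = rt,
              mz = mz, intensity = inten,
              filter_string = "FTMS + p NSI Full ms",
              is_centroid = FALSE)
}

#' Generate a deterministic synthetic LC-MS/MS run
#'
#' Survey scans carry Gaussian-profile precursor peaks for every pool
#' peptide, with a Gaussian elution profile across the gradient; each
#' survey scan is followed by MS2 scans of `peptides_per_ms1` pool peptides
#' (doubly charged), each MS2 optionally followed by one MS3 scan that
#' fragments the peptide's C-terminal half (precursor = the corresponding
#' y ion).  Scan numbers are sequential from 1; retention times are evenly
#' spaced over `rt_span`.  The output always passes [validate_run()].
#'
#' @param params A [synth_params()].
#' @return An [ms_run()].
#' @examples
#' run <- synth_run(synth_params(n_ms1 = 2, seed = 42))
#' length(run)
#' @export
synth_run <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  with_local_seed(params$seed, {
    table <- residue_mass_table()
    pool <- params$sequence_pool
    pool_mz <- vapply(pool, function(p) precursor_mz(p, 2L, table), numeric(1))
    apex <- stats::runif(length(pool), 0.2, 0.8) * params$rt_span
    width <- params$rt_span / 10
    base_abund <- stats::rlnorm(length(pool), meanlog = log(1e6), sdlog = 0.3)

    per_cycle <- 1L +
      params$peptides_per_ms1 * (1L + (params$max_ms_level == 3L))
    n_total <- params$n_ms1 * per_cycle
    rts <- seq(0, params$rt_span, length.out = n_total)

    spectra <- vector("list", n_total)
    scan <- 0L
    pep_cursor <- 0L
    for (cyc in seq_len(params$n_ms1)) {
      scan <- scan + 1L
      elution <- base_abund * exp(-((rts[scan] - apex) / width)^2 / 2)
      spectra[[scan]] <- .ms1_profile_scan(scan, rts[scan], pool_mz,
                                           pmax(elution, 1))
      ms1_scan <- scan
      for (k in seq_len(params$peptides_per_ms1)) {
        pep_cursor <- pep_cursor + 1L
        pep <- pool[(pep_cursor - 1L) %% length(pool) + 1L]
        scan <- scan + 1L
        spectra[[scan]] <- synth_msms_spectrum(
          pep, 2L, scan, rts[scan], precursor_scan = ms1_scan,
          ms_level = 2L, noise_sd = params$noise_sd, table = table)
        if (params$max_ms_level == 3L) {
          ms2_scan <- scan
          half <- substr(pep, nchar(pep) %/% 2 + 1L, nchar(pep))
          scan <- scan + 1L
          spectra[[scan]] <- synth_msms_spectrum(
            half, 1L, scan, rts[scan], precursor_scan = ms2_scan,
            ms_level = 3L, noise_sd = params$noise_sd, table = table)
        }
      }
    }
    ms_run(spectra,
           source_file = sprintf("synthetic(seed=%d)", params$seed),
           instrument_model = "synthetic orbitrap")
  })
}
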