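# Monoisotopic mass bookkeeping for peptides, fragments and modifications.

# CODATA-ish monoisotopic atomic masses (Da)
.ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

.PROTON <- 1.00727646688
.WATER  <- 2 * 1.0078250319 + 15.9949146221

# Residue (not free amino acid) monoisotopic masses
.RESIDUE_MASS <- c(
  G =  57.02146372, A =  71.03711378, S =  87.03202840, P =  97.05276384,
  V =  99.06841390, T = 101.04767846, C = 103.00918447, L = 113.08406396,
  I = 113.08406396, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496300, E = 129.04259308, M = 131.04048491, H = 137.05891186,
  F = 147.06841390, R = 156.10111102, Y = 163.06332852, W = 186.07931294
)

#' Monoisotopic mass of an elemental composition
#'
#' Parses a molecular formula such as `"C8H7NO2"` (the NAPQI cysteine adduct)
#' or `"C2H3NO"` (carbamidomethyl) and returns the monoisotopic mass delta in
#' Dalton. Supported elements: C, H, N, O, S, P. An empty string has mass 0.
#'
#' @param formula Character scalar elemental composition.
#' @return Monoisotopic mass in Da (numeric scalar).
#' @examples
#' modification_mass("C8H7NO2")  # NAPQI adduct on cysteine, ~149.048 Da
#' modification_mass("C2H3NO")   # carbamidomethyl, ~57.021 Da
#' @export
modification_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (!nzchar(formula)) return(0.0)
  # tokenize element + optional count
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  total <- 0.0
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    ct <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(ct)) as.integer(ct) else 1L
    if (!el %in% names(.ELEMENT_MASS)) stop("unknown element: ", el)
    total <- total + .ELEMENT_MASS[[el]] * n
  }
  total
}

# Split a peptide string into residue tokens; a residue may carry a
# modification in square brackets, e.g. "PEPC[C8H7NO2]IDEK".
.tokenize_peptide <- function(peptide) {
  m <- gregexpr("[A-Z](\\[[A-Za-z0-9]*\\])?", peptide)[[1]]
  toks <- regmatches(peptide, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(peptide)) {
    stop("cannot parse peptide sequence: ", peptide)
  }
  toks
}

.residue_masses <- function(peptide) {
  toks <- .tokenize_peptide(peptide)
  vapply(toks, function(tok) {
    aa <- substr(tok, 1L, 1L)
    if (!aa %in% names(.RESIDUE_MASS)) stop("unknown residue: ", aa)
    mass <- .RESIDUE_MASS[[aa]]
    if (nchar(tok) > 2L) {
      mass <- mass + modification_mass(substr(tok, 3L, nchar(tok) - 1L))
    }
    mass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass of a peptide given as a residue string with
#' optional bracketed modification formulas (e.g. `"PEPC[C2H3NO]IDEK"`).
#'
#' @param peptide Character scalar peptide sequence.
#' @return Neutral mass in Da.
#' @export
peptide_mass <- function(peptide) {
  sum(.residue_masses(peptide)) + .WATER
}

#' Precursor m/z of a peptide ion
#'
#' @param peptide Peptide sequence (see [peptide_mass()]).
#' @param charge Positive integer charge state.
#' @return m/z of the protonated precursor.
#' @export
precursor_mz <- function(peptide, charge) {
  stopifnot(charge >= 1)
  (peptide_mass(peptide) + charge * .PROTON) / charge
}

#' Fragment ion m/z values for a peptide
#'
#' Computes singly- or multiply-protonated b- and y-ion m/z values from the
#' residue ladder of `peptide`.
#'
#' @param peptide Peptide sequence.
#' @param ion_type `"b"` or `"y"` (vectorized).
#' @param ordinal Fragment ordinal (number of residues in the ion), vectorized.
#' @param charge Fragment charge state(s).
#' @return Numeric vector of fragment m/z values.
#' @export
fragment_mz <- function(peptide, ion_type, ordinal, charge = 1L) {
  res <- .residue_masses(peptide)
  n <- length(res)
  k <- length(ion_type)
  ordinal <- rep_len(ordinal, k)
  charge <- rep_len(charge, k)
  csum <- cumsum(res)
  out <- numeric(k)
  for (i in seq_len(k)) {
    o <- ordinal[i]
    if (o < 1L || o >= n) stop("fragment ordinal out of range: ", o)
    neutral <- switch(ion_type[i],
      b = csum[o],
      y = csum[n] - csum[n - o] + .WATER,
      stop("unsupported ion type: ", ion_type[i])
    )
    out[i] <- (neutral + charge[i] * .PROTON) / charge[i]
  }
  out
}
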