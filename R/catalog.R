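# Synthetic assay catalogs: the ground-truth peptide/fragment population the
# DIA and DDA simulators draw from. Sequences are random tryptic-like strings
# (C-terminal K/R); masses are computed from real residue masses so precursor
# and fragment m/z values are physically consistent.

.AA_INTERNAL <- c("G","A","S","P","V","T","C","L","I","N","D","Q","E","M",
                  "H","F","Y","W")

#' Simulate an assay catalog
#'
#' Generates the peptide-level ground truth for a benchmark: background
#' proteins, optional spike-in proteins, a set of iRT reference (anchor)
#' peptides that are always present at constant level, and optionally
#' proteins flagged *absent* -- these get catalog entries (so extraction
#' assays exist for them) but are never placed into any simulated run,
#' mimicking a foreign-organism library used for null validation.
#'
#' @param n_background_proteins Number of background proteins.
#' @param spike_proteins Character vector of spike-in protein ids (may be
#'   empty); typically `names(design$spike_group)` minus the background.
#' @param peptides_per_protein List with `mean` (Poisson mean) and `min`
#'   (lower bound) for the per-protein peptide count.
#' @param n_reference_peptides Number of iRT anchor peptides (>= 3,
#'   default 11); their true iRTs are evenly spaced over `irt_span`.
#' @param n_absent_proteins Number of truly-absent proteins.
#' @param n_fragments_range Integer range of annotated fragments per peptide.
#' @param irt_span Numeric length-2: the true iRT scale of the catalog.
#' @param mz_range Precursor m/z acceptance range (matches the survey scan).
#' @param seed Integer seed; fixed seed gives a byte-identical catalog.
#' @return Object of class `assay_catalog`: list with `precursors`
#'   (data.frame `assay_id`, `peptide`, `charge`, `precursor_mz`, `irt`,
#'   `protein`, `reference`, `absent`) and `fragments` (data.frame
#'   `assay_id`, `ion_type`, `ordinal`, `frag_charge`, `mz`,
#'   `rel_intensity`).
#' @export
simulate_catalog <- function(n_background_proteins = 30L,
                             spike_proteins = character(0),
                             peptides_per_protein = list(mean = 5, min = 2),
                             n_reference_peptides = 11L,
                             n_absent_proteins = 0L,
                             n_fragments_range = c(5L, 10L),
                             irt_span = c(0, 100),
                             mz_range = c(400, 1220),
                             seed = 1L) {
  stopifnot(n_background_proteins >= 0L, n_absent_proteins >= 0L,
            n_reference_peptides >= 3L)
  .with_seed(seed, {
    proteins <- c(
      setNames(rep("background", n_background_proteins),
               sprintf("BG%03d", seq_len(n_background_proteins))),
      setNames(rep("spike", length(spike_proteins)), spike_proteins),
      setNames(rep("absent", n_absent_proteins),
               sprintf("ABSENT%03d", seq_len(n_absent_proteins)))
    )
    prec <- list(); frag <- list()
    seen <- new.env(parent = emptyenv())

    add_peptide <- function(protein, irt, reference, absent) {
      for (try in 1:100) {
        len <- sample(7:18, 1L)
        pep <- paste0(
          paste(sample(.AA_INTERNAL, len - 1L, replace = TRUE), collapse = ""),
          sample(c("K", "R"), 1L)
        )
        charge <- sample(c(2L, 3L), 1L, prob = c(0.7, 0.3))
        mz <- precursor_mz(pep, charge)
        key <- paste0(pep, "/", charge)
        if (mz >= mz_range[1] && mz < mz_range[2] &&
            !exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          nf <- if (n_fragments_range[1] == n_fragments_range[2]) {
            n_fragments_range[1]
          } else {
            sample(seq(n_fragments_range[1], n_fragments_range[2]), 1L)
          }
          cand <- expand.grid(ion_type = c("b", "y"),
                              ordinal = seq(2L, len - 1L),
                              stringsAsFactors = FALSE)
          w <- ifelse(cand$ion_type == "y", 0.75, 0.25)
          nf <- min(nf, nrow(cand))
          pick <- cand[sample(nrow(cand), nf, prob = w), , drop = FALSE]
          ri <- stats::runif(nf)^1.5
          ri <- ri / max(ri)
          prec[[length(prec) + 1L]] <<- data.frame(
            assay_id = key, peptide = pep, charge = charge, precursor_mz = mz,
            irt = irt, protein = protein, reference = reference,
            absent = absent, stringsAsFactors = FALSE
          )
          frag[[length(frag) + 1L]] <<- data.frame(
            assay_id = key, ion_type = pick$ion_type, ordinal = pick$ordinal,
            frag_charge = 1L,
            mz = fragment_mz(pep, pick$ion_type, pick$ordinal, 1L),
            rel_intensity = ri, stringsAsFactors = FALSE
          )
          return(invisible(TRUE))
        }
      }
      stop("failed to generate a peptide in the precursor m/z range")
    }

    # iRT kit anchors: evenly spaced, always-present constant-level peptides
    ref_irts <- seq(irt_span[1], irt_span[2],
                    length.out = n_reference_peptides)
    for (i in seq_len(n_reference_peptides)) {
      add_peptide("IRT_KIT", ref_irts[i], reference = TRUE, absent = FALSE)
    }
    for (pid in names(proteins)) {
      npep <- max(peptides_per_protein$min,
                  stats::rpois(1L, peptides_per_protein$mean))
      for (j in seq_len(npep)) {
        add_peptide(pid, stats::runif(1, irt_span[1], irt_span[2]),
                    reference = FALSE, absent = proteins[[pid]] == "absent")
      }
    }
    out <- list(
      precursors = do.call(rbind, prec),
      fragments = do.call(rbind, frag),
      irt_span = irt_span
    )
  })
  rownames(out$precursors) <- NULL
  rownames(out$fragments) <- NULL
  class(out) <- "assay_catalog"
  out
}

#' @export
print.assay_catalog <- function(x, ...) {
  p <- x$precursors
  cat(sprintf(
    "Assay catalog: %d precursors (%d proteins, %d reference, %d absent), %d fragments\n",
    nrow(p), length(unique(p$protein)), sum(p$reference), sum(p$absent),
    nrow(x$fragments)
  ))
  invisible(x)
}

#' Truth-labeled spectral library from an assay catalog
#'
#' Converts the generator's ground-truth catalog directly into a
#' `spectral_library` (consensus iRT = true iRT, library intensities = the
#' fragment templates). This bypasses the DDA/consensus route and is meant
#' for calibration experiments where library-building noise is not under
#' study.
#'
#' @param catalog An `assay_catalog`.
#' @return A `spectral_library` of target assays.
#' @export
library_from_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "assay_catalog"))
  p <- catalog$precursors
  assays <- data.frame(
    assay_id = p$assay_id, peptide = p$peptide, charge = p$charge,
    precursor_mz = p$precursor_mz, irt = p$irt, protein = p$protein,
    proteotypic = TRUE, decoy = FALSE, n_obs = 1L,
    stringsAsFactors = FALSE
  )
  fr <- catalog$fragments
  fr <- fr[order(fr$assay_id, -fr$rel_intensity), ]
  rownames(fr) <- NULL
  out <- list(assays = assays, fragments = fr,
              provenance = list(source = "catalog truth"))
  class(out) <- "spectral_library"
  out
}
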