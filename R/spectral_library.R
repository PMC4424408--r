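# iRT-normalized consensus spectral libraries: calibration fits, quality
# filters, scrambled decoys, and the tabular transition-list format.

#' Fit a linear iRT calibration from reference observations
#'
#' Least-squares line `irt = slope * rt + intercept` through reference
#' peptide observations. With `robust = TRUE`, observations with residuals
#' beyond 3 residual SDs are discarded and the line refit (iterated until
#' stable, at most 5 passes), which protects the calibration against grossly
#' mis-picked anchors.
#'
#' @param observed_rt Observed retention times (minutes).
#' @param reference_irt The corresponding reference iRT values.
#' @param robust Discard >3-SD outliers and refit (default TRUE).
#' @return Object of class `irt_fit`: list with `slope`, `intercept`,
#'   `residual_sd` (in iRT units), `n_used`, `used` (logical vector).
#' @export
fit_irt_map <- function(observed_rt, reference_irt, robust = TRUE) {
  stopifnot(length(observed_rt) == length(reference_irt))
  ok <- is.finite(observed_rt) & is.finite(reference_irt)
  observed_rt <- observed_rt[ok]; reference_irt <- reference_irt[ok]
  if (length(observed_rt) < 3L) stop("need at least 3 reference points")
  if (stats::sd(observed_rt) == 0) stop("degenerate calibration: observed rts all equal")
  keep <- rep(TRUE, length(observed_rt))
  for (pass in 1:5) {
    fit <- stats::lm.fit(cbind(1, observed_rt[keep]), reference_irt[keep])
    res_all <- reference_irt - (fit$coefficients[1] + fit$coefficients[2] * observed_rt)
    s <- stats::sd(res_all[keep])
    if (!robust || !is.finite(s) || s == 0) break
    new_keep <- abs(res_all) <= 3 * s
    if (sum(new_keep) < 3L || all(new_keep == keep)) break
    keep <- new_keep
  }
  res <- res_all[keep]
  out <- list(
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    residual_sd = if (length(res) > 2L) stats::sd(res) else 0,
    n_used = sum(keep),
    used = keep
  )
  class(out) <- "irt_fit"
  out
}

#' @export
print.irt_fit <- function(x, ...) {
  cat(sprintf("iRT calibration: irt = %.4f * rt + %.4f (residual sd %.4g iRT, n = %d)\n",
              x$slope, x$intercept, x$residual_sd, x$n_used))
  invisible(x)
}

#' Map between iRT and retention time with a fitted calibration
#'
#' @param fit An `irt_fit`.
#' @param irt,rt Values to convert.
#' @return `predict_rt` gives minutes from iRT; `predict_irt` the inverse.
#' @export
predict_rt <- function(fit, irt) (irt - fit$intercept) / fit$slope

#' @rdname predict_rt
#' @export
predict_irt <- function(fit, rt) fit$intercept + fit$slope * rt

#' Build an iRT-normalized consensus spectral library from PSM tables
#'
#' Per run, duplicate identifications of one precursor are resolved by
#' keeping the most intense. Observed retention times are converted to iRT
#' with the per-run calibration; per precursor, observations whose iRT
#' deviates from the median by more than `irt_sd_limit` robust standard
#' deviations (MAD-consistent estimate, so an outlier cannot widen its own
#' acceptance band) are discarded; the consensus iRT is the median of the
#' survivors and the
#' consensus fragment intensities are per-fragment medians renormalized to
#' max 1. Assays with fewer than `min_fragments` fragments are dropped.
#'
#' @param psms A `psm_table` (possibly concatenated over runs).
#' @param irt_maps Named list of `irt_fit` per `run_id`.
#' @param min_fragments Minimum fragments per retained assay (default 6).
#' @param irt_sd_limit iRT outlier cut in SD units (default 5).
#' @return A `spectral_library`: list with `assays`, `fragments`,
#'   `provenance`.
#' @export
build_library <- function(psms, irt_maps, min_fragments = 6L,
                          irt_sd_limit = 5) {
  stopifnot(inherits(psms, "psm_table"))
  p <- psms$psms
  if (is.null(p) || nrow(p) == 0L) {
    warning("empty PSM input; returning empty library")
    return(.empty_library(min_fragments, irt_sd_limit))
  }
  miss <- setdiff(unique(p$run_id), names(irt_maps))
  if (length(miss)) stop("no iRT map for run(s): ", paste(miss, collapse = ", "))

  # within-run precursor dedup: keep the most intense identification
  key_run <- paste(p$run_id, p$peptide, p$charge, sep = "\r")
  o <- order(key_run, -p$total_intensity)
  p <- p[o[!duplicated(key_run[o])], , drop = FALSE]

  p$irt_obs <- vapply(seq_len(nrow(p)), function(i) {
    predict_irt(irt_maps[[p$run_id[i]]], p$rt[i])
  }, numeric(1))

  frag <- psms$fragments
  frag <- frag[frag$psm_id %in% p$psm_id, , drop = FALSE]
  frag_by_psm <- split(seq_len(nrow(frag)), frag$psm_id)

  assay_key <- paste(p$peptide, p$charge, sep = "/")
  groups <- split(seq_len(nrow(p)), assay_key)
  assays <- list(); frows <- list()
  n_irt_dropped <- 0L; n_underfragmented <- 0L

  for (aid in names(groups)) {
    gi <- groups[[aid]]
    irts <- p$irt_obs[gi]
    keep <- rep(TRUE, length(gi))
    if (length(gi) >= 3L) {
      # robust scale (MAD-consistent SD) so a single gross shift cannot
      # inflate its own acceptance band
      s <- stats::mad(irts)
      if (!is.finite(s) || s == 0) s <- stats::sd(irts)
      if (is.finite(s) && s > 0) {
        keep <- abs(irts - stats::median(irts)) <= irt_sd_limit * s
        if (!any(keep)) keep <- rep(TRUE, length(gi))
      }
    }
    n_irt_dropped <- n_irt_dropped + sum(!keep)
    gi <- gi[keep]
    fidx <- unlist(frag_by_psm[p$psm_id[gi]], use.names = FALSE)
    fsub <- frag[fidx, , drop = FALSE]
    fk <- paste(fsub$ion_type, fsub$ordinal, fsub$frag_charge, sep = "_")
    med_int <- tapply(fsub$intensity, fk, stats::median)
    if (length(med_int) < min_fragments) {
      n_underfragmented <- n_underfragmented + 1L
      next
    }
    first <- fsub[!duplicated(fk), , drop = FALSE]
    first <- first[match(names(med_int), paste(first$ion_type, first$ordinal,
                                               first$frag_charge, sep = "_")), ]
    ri <- as.numeric(med_int) / max(med_int)
    ord <- order(-ri)
    i1 <- gi[1]
    assays[[length(assays) + 1L]] <- data.frame(
      assay_id = aid, peptide = p$peptide[i1], charge = p$charge[i1],
      precursor_mz = p$precursor_mz[i1],
      irt = stats::median(p$irt_obs[gi]),
      protein = p$protein[i1],
      proteotypic = length(unique(p$protein[gi])) == 1L,
      decoy = FALSE, n_obs = length(gi), stringsAsFactors = FALSE
    )
    frows[[length(frows) + 1L]] <- data.frame(
      assay_id = aid, ion_type = first$ion_type[ord],
      ordinal = first$ordinal[ord], frag_charge = first$frag_charge[ord],
      mz = first$mz[ord], rel_intensity = ri[ord], stringsAsFactors = FALSE
    )
  }
  if (length(assays) == 0L) {
    warning("no assay passed the library filters; returning empty library")
    return(.empty_library(min_fragments, irt_sd_limit))
  }
  out <- list(
    assays = do.call(rbind, assays),
    fragments = do.call(rbind, frows),
    provenance = list(
      n_runs = length(unique(psms$psms$run_id)),
      min_fragments = min_fragments, irt_sd_limit = irt_sd_limit,
      n_irt_outliers_dropped = n_irt_dropped,
      n_assays_dropped_fragments = n_underfragmented
    )
  )
  rownames(out$assays) <- NULL; rownames(out$fragments) <- NULL
  class(out) <- "spectral_library"
  out
}

.empty_library <- function(min_fragments, irt_sd_limit) {
  out <- list(
    assays = data.frame(assay_id = character(), peptide = character(),
                        charge = integer(), precursor_mz = numeric(),
                        irt = numeric(), protein = character(),
                        proteotypic = logical(), decoy = logical(),
                        n_obs = integer(), stringsAsFactors = FALSE),
    fragments = data.frame(assay_id = character(), ion_type = character(),
                           ordinal = integer(), frag_charge = integer(),
                           mz = numeric(), rel_intensity = numeric(),
                           stringsAsFactors = FALSE),
    provenance = list(n_runs = 0L, min_fragments = min_fragments,
                      irt_sd_limit = irt_sd_limit)
  )
  class(out) <- "spectral_library"
  out
}

#' @export
print.spectral_library <- function(x, ...) {
  a <- x$assays
  cat(sprintf(
    "Spectral library: %d assays (%d targets, %d decoys; %d proteins), %d fragment rows\n",
    nrow(a), sum(!a$decoy), sum(a$decoy),
    length(unique(a$protein[!a$decoy])), nrow(x$fragments)
  ))
  invisible(x)
}

#' Cumulative library growth over runs
#'
#' Rebuilds the library on runs `1..k` of `order` and reports the cumulative
#' peptide and protein counts, the standard saturation diagnostic for
#' deciding how many shotgun runs a library needs.
#'
#' @param psms A `psm_table` covering all runs.
#' @param irt_maps Named list of per-run `irt_fit`s.
#' @param order Character vector of run ids defining the accumulation order
#'   (default: sorted unique run ids).
#' @param ... Passed to [build_library()].
#' @return data.frame `runs_used`, `peptides`, `proteins`.
#' @export
library_growth <- function(psms, irt_maps, order = NULL, ...) {
  stopifnot(inherits(psms, "psm_table"))
  if (is.null(order)) order <- sort(unique(psms$psms$run_id))
  stopifnot(length(order) >= 1L)
  out <- lapply(seq_along(order), function(k) {
    sel <- psms$psms$run_id %in% order[seq_len(k)]
    sub <- list(psms = psms$psms[sel, , drop = FALSE],
                fragments = psms$fragments[
                  psms$fragments$psm_id %in% psms$psms$psm_id[sel], ,
                  drop = FALSE])
    class(sub) <- "psm_table"
    lib <- suppressWarnings(build_library(sub, irt_maps, ...))
    data.frame(runs_used = k,
               peptides = length(unique(lib$assays$peptide)),
               proteins = length(unique(lib$assays$protein)))
  })
  do.call(rbind, out)
}

# scramble internal residue tokens keeping the C-terminal residue fixed;
# single draw (positional-shift fallback for degenerate sequences)
.scramble_peptide <- function(peptide) {
  toks <- .tokenize_peptide(peptide)
  n <- length(toks)
  if (n <= 2L) return(peptide)
  head_idx <- seq_len(n - 1L)
  for (try in 1:10) {
    perm <- sample(head_idx)
    if (!all(perm == head_idx)) {
      return(paste(c(toks[head_idx][perm], toks[n]), collapse = ""))
    }
  }
  # positional shift fallback (e.g. all residues identical)
  paste(c(toks[c(head_idx[-1], head_idx[1])], toks[n]), collapse = "")
}

# scramble repeatedly, preferring a permutation whose recomputed fragment
# ladder shares no m/z with the target's within collision_ppm -- otherwise a
# decoy co-extracts its own (real) target signal and is no longer null
.scramble_avoiding_collisions <- function(peptide, fr, target_mz,
                                          collision_ppm, attempts = 10L) {
  best <- NULL
  best_coll <- Inf
  for (try in seq_len(attempts)) {
    dp <- .scramble_peptide(peptide)
    if (dp == peptide) next
    dmz <- fragment_mz(dp, fr$ion_type, fr$ordinal, fr$frag_charge)
    ncoll <- sum(vapply(dmz, function(m) {
      any(abs(target_mz - m) / m < collision_ppm * 1e-6)
    }, logical(1)))
    if (ncoll < best_coll) {
      best <- list(peptide = dp, mz = dmz)
      best_coll <- ncoll
    }
    if (ncoll == 0L) break
  }
  if (is.null(best)) {
    dp <- .scramble_peptide(peptide)
    best <- list(peptide = dp,
                 mz = fragment_mz(dp, fr$ion_type, fr$ordinal,
                                  fr$frag_charge))
  }
  best
}

#' Append scrambled decoy assays to a library
#'
#' One decoy per target: the peptide's non-terminal residues are randomly
#' permuted with the C-terminal residue fixed (scrambles identical to the
#' target are re-drawn up to 10 times, then a positional shift is applied),
#' fragment m/z values are recomputed from the scrambled sequence keeping
#' ion types, ordinals and charges, and the target's library intensities and
#' iRT are inherited. Amino-acid composition -- hence precursor mass -- is
#' preserved. Scrambles whose recomputed ladder leaves any fragment within
#' `collision_ppm` of a target fragment are re-drawn too (best of 10 kept):
#' a mass-coincident decoy fragment would co-extract the target's own real
#' signal and bias the null distribution away from truly-absent peptides.
#'
#' @param library A `spectral_library` of targets.
#' @param seed Integer seed.
#' @param collision_ppm Self-collision tolerance in ppm (default 25, i.e.
#'   slightly wider than the default 20 ppm extraction tolerance).
#' @return The library with decoy assays appended (`decoy = TRUE`,
#'   `assay_id`/`protein` prefixed `DECOY_`).
#' @export
generate_decoys <- function(library, seed = 1L, collision_ppm = 25) {
  stopifnot(inherits(library, "spectral_library"))
  tgt <- library$assays[!library$assays$decoy, , drop = FALSE]
  if (nrow(tgt) == 0L) stop("library has no target assays")
  frag_by_assay <- split(library$fragments, library$fragments$assay_id)
  .with_seed(seed, {
    dec_assays <- tgt
    dec_frags <- vector("list", nrow(tgt))
    dec_assays$assay_id <- paste0("DECOY_", tgt$assay_id)
    dec_assays$protein <- paste0("DECOY_", tgt$protein)
    dec_assays$decoy <- TRUE
    for (i in seq_len(nrow(tgt))) {
      fr <- frag_by_assay[[tgt$assay_id[i]]]
      sc <- .scramble_avoiding_collisions(tgt$peptide[i], fr, fr$mz,
                                          collision_ppm)
      dec_assays$peptide[i] <- sc$peptide
      fr$assay_id <- dec_assays$assay_id[i]
      fr$mz <- sc$mz
      dec_frags[[i]] <- fr
    }
  })
  out <- library
  out$assays <- rbind(library$assays, dec_assays)
  out$fragments <- rbind(library$fragments, do.call(rbind, dec_frags))
  rownames(out$assays) <- NULL; rownames(out$fragments) <- NULL
  out$provenance$decoys <- "scrambled, 1:1"
  out
}

#' Derive variable-modification assays
#'
#' For every target assay containing `residue`, emits one additional assay
#' per residue position carrying the modification `formula` (e.g.
#' `"C8H7NO2"`, the NAPQI adduct, on cysteine): the precursor m/z is shifted
#' by the modification mass and fragment m/z values are recomputed from the
#' annotated sequence so only fragments covering the modified position shift.
#'
#' @param library A `spectral_library`.
#' @param formula Elemental composition of the modification.
#' @param residue Single-letter residue code to modify (default `"C"`).
#' @return A `spectral_library` of the modified assays only.
#' @export
modified_assays <- function(library, formula, residue = "C") {
  stopifnot(inherits(library, "spectral_library"))
  tgt <- library$assays[!library$assays$decoy, , drop = FALSE]
  frag_by_assay <- split(library$fragments, library$fragments$assay_id)
  assays <- list(); frows <- list()
  for (i in seq_len(nrow(tgt))) {
    toks <- .tokenize_peptide(tgt$peptide[i])
    pos <- which(substr(toks, 1L, 1L) == residue & nchar(toks) == 1L)
    for (k in pos) {
      toks2 <- toks
      toks2[k] <- paste0(residue, "[", formula, "]")
      pep2 <- paste(toks2, collapse = "")
      aid2 <- paste(pep2, tgt$charge[i], sep = "/")
      fr <- frag_by_assay[[tgt$assay_id[i]]]
      fr$assay_id <- aid2
      fr$mz <- fragment_mz(pep2, fr$ion_type, fr$ordinal, fr$frag_charge)
      a2 <- tgt[i, , drop = FALSE]
      a2$assay_id <- aid2
      a2$peptide <- pep2
      a2$precursor_mz <- precursor_mz(pep2, a2$charge)
      assays[[length(assays) + 1L]] <- a2
      frows[[length(frows) + 1L]] <- fr
    }
  }
  out <- list(
    assays = if (length(assays)) do.call(rbind, assays) else tgt[0, ],
    fragments = if (length(frows)) do.call(rbind, frows) else
      library$fragments[0, ],
    provenance = list(modification = formula, residue = residue)
  )
  rownames(out$assays) <- NULL; rownames(out$fragments) <- NULL
  class(out) <- "spectral_library"
  out
}

#' Write / read a spectral library in tabular transition-list format
#'
#' Tab-separated, one fragment per row, columns `PrecursorId`,
#' `ModifiedPeptide`, `PrecursorCharge`, `PrecursorMz`, `iRT`, `ProteinId`,
#' `IsProteotypic`, `IsDecoy`, `FragmentType`, `FragmentNumber`,
#' `FragmentCharge`, `FragmentMz`, `LibraryIntensity`.
#'
#' @param library A `spectral_library`.
#' @param path File path.
#' @return `read_library_tsv` returns a `spectral_library`.
#' @export
write_library_tsv <- function(library, path) {
  a <- library$assays
  f <- library$fragments
  i <- match(f$assay_id, a$assay_id)
  long <- data.frame(
    PrecursorId = f$assay_id, ModifiedPeptide = a$peptide[i],
    PrecursorCharge = a$charge[i], PrecursorMz = a$precursor_mz[i],
    iRT = a$irt[i], ProteinId = a$protein[i],
    IsProteotypic = a$proteotypic[i], IsDecoy = a$decoy[i],
    FragmentType = f$ion_type, FragmentNumber = f$ordinal,
    FragmentCharge = f$frag_charge, FragmentMz = f$mz,
    LibraryIntensity = f$rel_intensity, stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  first <- !duplicated(long$PrecursorId)
  out <- list(
    assays = data.frame(
      assay_id = long$PrecursorId[first], peptide = long$ModifiedPeptide[first],
      charge = long$PrecursorCharge[first],
      precursor_mz = long$PrecursorMz[first], irt = long$iRT[first],
      protein = long$ProteinId[first], proteotypic = long$IsProteotypic[first],
      decoy = long$IsDecoy[first],
      n_obs = NA_integer_, stringsAsFactors = FALSE
    ),
    fragments = data.frame(
      assay_id = long$PrecursorId, ion_type = long$FragmentType,
      ordinal = long$FragmentNumber, frag_charge = long$FragmentCharge,
      mz = long$FragmentMz, rel_intensity = long$LibraryIntensity,
      stringsAsFactors = FALSE
    ),
    provenance = list(source = path)
  )
  class(out) <- "spectral_library"
  out
}
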