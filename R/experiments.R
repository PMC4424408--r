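# Calibration experiments: self-contained simulation studies quantifying
# two core properties of the workflow -- dynamic-iRT extraction-window
# coverage, and peptide-level FDR calibration against truly-absent targets.

#' Dynamic-iRT extraction window coverage experiment
#'
#' Simulates replicate DIA runs of a catalog of present peptides, calibrates
#' each run from its reference (anchor) assays alone, sets the dynamic
#' extraction half-width to `max(k x residual SD, floor_frac x iRT span)`,
#' and measures the fraction of present peptides whose generator-truth apex
#' falls inside `[predicted RT - half-width, predicted RT + half-width]`.
#' This quantifies the claim that a narrow dynamic window (a few percent of
#' the gradient) captures over 99% of peptides.
#'
#' @param seeds Integer vector of simulation seeds (one run per seed).
#' @param n_peptides Target number of present (non-anchor) peptides.
#' @param rt_jitter_frac Apex jitter SD as a fraction of the gradient
#'   (default 0.002).
#' @param gradient_length Gradient length in minutes (default 120).
#' @param k,floor_frac Dynamic half-width parameters, see [calibrate_run()].
#' @param peptides_per_protein Mean peptides per simulated protein.
#' @return List with `per_run` (data.frame `seed`, `n_present`, `n_covered`,
#'   `fraction`, `half_width_min`, `residual_sd`) and `mean_fraction`.
#' @export
coverage_experiment <- function(seeds = 1:5, n_peptides = 2000,
                                rt_jitter_frac = 0.002,
                                gradient_length = 120,
                                k = 3, floor_frac = 0.01,
                                peptides_per_protein = 5) {
  n_prot <- max(1L, round(n_peptides / peptides_per_protein))
  catalog <- simulate_catalog(
    n_background_proteins = n_prot,
    peptides_per_protein = list(mean = peptides_per_protein, min = 2),
    n_reference_peptides = 11L, n_absent_proteins = 0L,
    seed = seeds[1]
  )
  lib <- library_from_catalog(catalog)
  scheme <- default_hrm_scheme()
  conc <- setNames(
    rep(20, n_prot),
    unique(catalog$precursors$protein[!catalog$precursors$reference])
  )
  rows <- lapply(seeds, function(s) {
    run <- simulate_dia_run(
      catalog, conc, scheme,
      noise = list(rt_jitter = rt_jitter_frac * gradient_length),
      gradient_length = gradient_length,
      run_id = sprintf("COV%02d", s), seed = s
    )
    cal <- calibrate_run(run, lib, k = k, floor_frac = floor_frac)
    tr <- run$truth[run$truth$present, ]
    # exclude the anchors themselves: coverage is about scheduled peptides
    anchors <- catalog$precursors$assay_id[catalog$precursors$reference]
    tr <- tr[!tr$assay_id %in% anchors, ]
    irt <- catalog$precursors$irt[match(tr$assay_id,
                                        catalog$precursors$assay_id)]
    pred <- predict_rt(cal$fit, irt)
    covered <- abs(tr$apex_rt - pred) <= cal$half_width_min
    rm(run)
    data.frame(
      seed = s, n_present = nrow(tr), n_covered = sum(covered),
      fraction = mean(covered), half_width_min = cal$half_width_min,
      residual_sd = cal$fit$residual_sd
    )
  })
  per_run <- do.call(rbind, rows)
  list(per_run = per_run, mean_fraction = mean(per_run$fraction))
}

#' Peptide-level FDR calibration experiment with truly-absent targets
#'
#' Builds one catalog in which a fraction of target proteins is truly
#' absent (assays exist, signal does not), appends 1:1 scrambled decoys,
#' then for each seed simulates a DIA run, scores every assay, trains the
#' discriminant, and measures the realized false discovery proportion --
#' absent targets among the targets passing `q <= fdr` -- against the
#' nominal target-decoy estimate. Also returns the Cscores of decoys and
#' absent targets from the first seed for null-mimicry validation.
#'
#' @param seeds Integer vector of run seeds.
#' @param n_targets Approximate number of target assays (default 5000).
#' @param absent_frac Fraction of truly-absent targets (default 0.2).
#' @param fdr q-value cutoff (default 0.01).
#' @param gradient_length Gradient length in minutes (default 20; a short
#'   gradient keeps the co-elution density high and the run small).
#' @return List with `per_seed` (data.frame `seed`, `n_discoveries`,
#'   `n_false`, `fdp`), `mean_fdp`, and `null_scores` (list with `decoy`
#'   and `absent` Cscore vectors from the first seed).
#' @export
fdr_experiment <- function(seeds = 1:20, n_targets = 5000,
                           absent_frac = 0.2, fdr = 0.01,
                           gradient_length = 20) {
  ppp <- 5
  n_bg <- max(1L, round(n_targets * (1 - absent_frac) / ppp))
  n_abs <- max(1L, round(n_targets * absent_frac / ppp))
  catalog <- simulate_catalog(
    n_background_proteins = n_bg, n_absent_proteins = n_abs,
    peptides_per_protein = list(mean = ppp, min = 2),
    n_fragments_range = c(6L, 6L),
    n_reference_peptides = 11L, seed = seeds[1] + 1000L
  )
  lib <- generate_decoys(library_from_catalog(catalog),
                         seed = seeds[1] + 2000L)
  scheme <- default_hrm_scheme()
  conc <- setNames(
    rep(20, n_bg + n_abs),
    unique(catalog$precursors$protein[!catalog$precursors$reference])
  )
  a <- lib$assays
  f <- lib$fragments[lib$fragments$assay_id %in%
                       a$assay_id[a$decoy | grepl("^ABSENT", a$protein)], ]
  extra <- data.frame(
    precursor_mz = a$precursor_mz[match(f$assay_id, a$assay_id)],
    mz = f$mz
  )
  absent_proteins <- unique(catalog$precursors$protein[catalog$precursors$absent])
  null_scores <- NULL
  rows <- lapply(seeds, function(s) {
    run <- simulate_dia_run(
      catalog, conc, scheme, gradient_length = gradient_length,
      extra_mz = extra, run_id = sprintf("FDR%02d", s), seed = s
    )
    cal <- calibrate_run(run, lib)
    scored <- score_run(run, lib, cal)
    rm(run)
    scored <- train_discriminant(scored, seed = 1L)
    hits <- scored[!scored$decoy & scored$qvalue <= fdr, ]
    n_false <- sum(hits$protein %in% absent_proteins)
    if (s == seeds[1]) {
      null_scores <<- list(
        decoy = scored$cscore[scored$decoy],
        absent = scored$cscore[!scored$decoy &
                                 scored$protein %in% absent_proteins]
      )
    }
    data.frame(
      seed = s, n_discoveries = nrow(hits), n_false = n_false,
      fdp = if (nrow(hits)) n_false / nrow(hits) else 0
    )
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed, mean_fdp = mean(per_seed$fdp),
       null_scores = null_scores)
}
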