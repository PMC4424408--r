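# MS2-level quantification: precursor x run intensity matrices, local
# (retention-time-windowed) normalization, and completeness/CV metrics.

#' Assemble the precursor x run quantification matrix
#'
#' One cell per (precursor, run): the interference-corrected fragment area
#' sum of the best peak group, present only where the run-level q-value
#' passes `fdr_cutoff`. No alignment and no imputation: a precursor not
#' identified in a run stays missing. Precursors are not merged across
#' modified forms or charge states.
#'
#' @param scored_runs List of `hrm_scores` data.frames, one per run (all
#'   scored against the same library).
#' @param run_info data.frame with `run_id`, `sample` and optionally
#'   `block` (replicate) per run, e.g. from [block_randomize()].
#' @param fdr_cutoff Run-level q-value cutoff (default 0.01).
#' @return Object of class `quant_matrix`: list with `values` (precursor x
#'   run matrix, `NA` = missing), `sample`/`replicate` per column, `protein`
#'   per row, `row_rt` (median apex RT per precursor).
#' @export
quantify <- function(scored_runs, run_info, fdr_cutoff = 0.01) {
  stopifnot(is.list(scored_runs), length(scored_runs) >= 1L)
  long <- do.call(rbind, lapply(scored_runs, function(s) {
    s <- s[!s$decoy & s$qvalue <= fdr_cutoff & s$quant_area > 0, ,
           drop = FALSE]
    s[, c("assay_id", "protein", "run_id", "apex_rt", "quant_area")]
  }))
  run_ids <- run_info$run_id
  rows <- sort(unique(long$assay_id))
  m <- matrix(NA_real_, length(rows), length(run_ids),
              dimnames = list(rows, run_ids))
  m[cbind(match(long$assay_id, rows), match(long$run_id, run_ids))] <-
    long$quant_area
  first <- long[!duplicated(long$assay_id), ]
  out <- list(
    values = m,
    sample = setNames(run_info$sample, run_info$run_id),
    replicate = if ("block" %in% names(run_info)) {
      setNames(run_info$block, run_info$run_id)
    } else setNames(rep(1L, nrow(run_info)), run_info$run_id),
    protein = setNames(first$protein, first$assay_id)[rows],
    row_rt = tapply(long$apex_rt, long$assay_id, stats::median)[rows]
  )
  class(out) <- "quant_matrix"
  out
}

#' @export
print.quant_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "Quant matrix: %d precursors x %d runs, %.1f%% missing\n",
    nrow(v), ncol(v), 100 * mean(is.na(v))
  ))
  invisible(x)
}

#' Local (retention-time-windowed) intensity normalization
#'
#' Compensates loading differences and spray bias: per run, the log2
#' deviation of each precursor from its across-run median is summarized by a
#' running median over retention time (window = `window_frac` of the
#' gradient) and subtracted in log space, which also equalizes the median
#' log2 intensity of shared precursors across runs. With fewer than
#' `min_shared` complete rows the method falls back to global median
#' normalization with a warning.
#'
#' @param qm A `quant_matrix`.
#' @param window_frac RT window width as a fraction of the observed RT span
#'   (default 0.1).
#' @param min_shared Minimum complete rows required for the RT-resolved
#'   curve (default 20).
#' @return The normalized `quant_matrix`, with `curves` attached: per run, a
#'   data.frame of the RT grid and the subtracted log2 correction.
#' @export
local_normalize <- function(qm, window_frac = 0.1, min_shared = 20L) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (ncol(qm$values) < 2L) return(qm)
  lv <- log2(qm$values)
  complete <- rowSums(is.na(lv)) == 0L
  ref <- apply(lv, 1L, stats::median, na.rm = TRUE)
  rt <- as.numeric(qm$row_rt)
  curves <- list()
  if (sum(complete) < min_shared) {
    warning("fewer than ", min_shared,
            " complete rows: falling back to global median normalization")
    for (j in seq_len(ncol(lv))) {
      off <- stats::median(lv[complete, j] - ref[complete])
      if (!is.finite(off)) off <- 0
      lv[, j] <- lv[, j] - off
      curves[[colnames(lv)[j]]] <- data.frame(rt = NA_real_, correction = off)
    }
  } else {
    span <- diff(range(rt[complete]))
    half <- max(window_frac * span / 2, .Machine$double.eps)
    for (j in seq_len(ncol(lv))) {
      dev <- lv[, j] - ref
      ok <- complete & is.finite(dev)
      corr <- vapply(rt, function(t0) {
        sel <- ok & abs(rt - t0) <= half
        if (!any(sel)) sel <- ok
        stats::median(dev[sel])
      }, numeric(1))
      lv[, j] <- lv[, j] - corr
      grid <- sort(unique(round(rt, 2)))
      curves[[colnames(lv)[j]]] <- data.frame(
        rt = grid,
        correction = vapply(grid, function(t0) {
          sel <- ok & abs(rt - t0) <= half
          if (!any(sel)) sel <- ok
          stats::median(dev[sel])
        }, numeric(1))
      )
    }
  }
  qm$values <- 2^lv
  qm$curves <- curves
  qm
}

#' Completeness and precision metrics of a quantification matrix
#'
#' Computes the missing-value fraction, the full-profile curve (number of
#' precursors quantified without a missing value in the first `k` runs, for
#' `k = 1..K` in acquisition order), and per-precursor coefficients of
#' variation within each sample's technical replicates (computed on
#' linear-scale intensities).
#'
#' @param qm A `quant_matrix`.
#' @return List with `missing_fraction`, `full_profiles` (data.frame `k`,
#'   `complete_rows`), `cv` (data.frame `assay_id`, `sample`, `cv`),
#'   `cv_summary` (median and mean CV).
#' @export
completeness_and_cv <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  v <- qm$values
  miss <- mean(is.na(v))
  full <- vapply(seq_len(ncol(v)), function(k) {
    sum(rowSums(is.na(v[, seq_len(k), drop = FALSE])) == 0L)
  }, integer(1))
  smp <- qm$sample[colnames(v)]
  cv_rows <- list()
  for (s in unique(smp)) {
    cols <- which(smp == s)
    if (length(cols) < 2L) next
    sub <- v[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    ok <- n_obs >= 2L & mu > 0
    if (any(ok)) {
      cv_rows[[s]] <- data.frame(
        assay_id = rownames(v)[ok], sample = s, cv = (sdv / mu)[ok],
        stringsAsFactors = FALSE
      )
    }
  }
  cv <- if (length(cv_rows)) do.call(rbind, cv_rows) else
    data.frame(assay_id = character(), sample = character(), cv = numeric())
  rownames(cv) <- NULL
  list(
    missing_fraction = miss,
    full_profiles = data.frame(k = seq_len(ncol(v)), complete_rows = full),
    cv = cv,
    cv_summary = c(median_cv = stats::median(cv$cv),
                   mean_cv = mean(cv$cv))
  )
}

#' Write a quantification matrix as tab-separated text
#'
#' Wide format: precursors as rows, runs as columns, with `protein` and
#' `row_rt` annotation columns.
#'
#' @param qm A `quant_matrix`.
#' @param path File path.
#' @export
write_quant_tsv <- function(qm, path) {
  df <- data.frame(assay_id = rownames(qm$values),
                   protein = qm$protein,
                   row_rt = as.numeric(qm$row_rt),
                   qm$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
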