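# Targeted extraction: dynamic iRT calibration per run, XIC extraction from
# DIA windows, peak-group detection with subscores, and interference
# detection on the fragment level.

# row indices of trace keys within +/- tol_ppm of mz (keys sorted ascending)
.key_rows <- function(keys, mz, tol_ppm) {
  if (length(keys) == 0L) return(integer(0))
  tol <- mz * tol_ppm * 1e-6
  lo <- findInterval(mz - tol, keys) + 1L
  hi <- findInterval(mz + tol, keys)
  if (hi < lo) integer(0) else lo:hi
}

# Extend a peak boundary from the apex in direction dir on the smoothed
# summed trace s. Small upward wiggles (< 20% of the peak prominence above
# the running minimum) are walked through -- boundaries on noisy pedestals
# would otherwise truncate at the first counting-noise dip -- while a
# sustained rise (a flanking peak) or reaching baseline level stops the
# walk. The boundary is the position of the running minimum.
.walk_boundary <- function(s, apex, dir, frac, base) {
  h <- s[apex]
  prom <- max(h - base, .Machine$double.eps)
  i <- apex
  best <- apex
  minv <- h
  n <- length(s)
  repeat {
    j <- i + dir
    if (j < 1L || j > n) break
    if (s[j] <= minv) {
      minv <- s[j]
      best <- j
    } else if (s[j] - minv > 0.2 * prom) {
      break
    }
    i <- j
    if (minv <= base + frac * prom) break
  }
  best
}

# fragment x cycle intensity matrix for a set of fragment m/z in one window
.xic_matrix <- function(win, mzs, tol_ppm, cols,
                        rows_list = lapply(mzs, .key_rows,
                                           keys = win$keys,
                                           tol_ppm = tol_ppm)) {
  out <- matrix(0, length(mzs), length(cols))
  for (i in seq_along(mzs)) {
    r <- rows_list[[i]]
    if (length(r) == 1L) {
      out[i, ] <- win$traces[r, cols]
    } else if (length(r) > 1L) {
      out[i, ] <- colSums(win$traces[r, cols, drop = FALSE])
    }
  }
  out
}

#' Extract an ion chromatogram from a DIA run
#'
#' Sums all trace keys within `tolerance_ppm` of `mz` in the given isolation
#' window, optionally restricted to `rt_center +/- rt_half_width`. A region
#' with no matching keys yields an all-zero chromatogram on the restricted
#' grid; a retention-time range reaching outside the gradient is clipped
#' with a warning.
#'
#' @param run A `dia_run`.
#' @param mz Fragment m/z to extract.
#' @param window_index Isolation window index (from [assign_window()]).
#' @param tolerance_ppm Extraction tolerance in ppm (default 20).
#' @param rt_center,rt_half_width Optional extraction window in minutes;
#'   omitted means the whole gradient.
#' @return Object of class `chromatogram`: list with `times` (minutes) and
#'   `intensities`.
#' @export
extract_xic <- function(run, mz, window_index, tolerance_ppm = 20,
                        rt_center = NULL, rt_half_width = NULL) {
  stopifnot(inherits(run, "dia_run"),
            window_index >= 1L, window_index <= length(run$windows))
  times <- run$cycle_times
  cols <- seq_along(times)
  if (!is.null(rt_center)) {
    stopifnot(!is.null(rt_half_width), rt_half_width > 0)
    lo <- rt_center - rt_half_width
    hi <- rt_center + rt_half_width
    if (lo < times[1] || hi > times[length(times)]) {
      warning("extraction range clipped to the gradient")
    }
    cols <- which(times >= lo & times <= hi)
    if (length(cols) == 0L) cols <- integer(0)
  }
  win <- run$windows[[window_index]]
  ints <- if (length(cols)) as.numeric(.xic_matrix(win, mz, tolerance_ppm, cols)) else numeric(0)
  out <- list(times = times[cols], intensities = ints,
              fragment_mz = mz, window = window_index)
  class(out) <- "chromatogram"
  out
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("XIC m/z %.4f (window %d): %d points, max %.3g\n",
              x$fragment_mz, x$window, length(x$times),
              if (length(x$intensities)) max(x$intensities) else NA))
  invisible(x)
}

#' Detect candidate peak groups in a set of fragment chromatograms
#'
#' Candidate apexes are local maxima of the Gaussian-smoothed summed trace;
#' boundaries extend to the flanking local minima (walking through upward
#' wiggles below 20% of the peak prominence, which would otherwise truncate
#' peaks sitting on a noisy pedestal) or to where the smoothed trace falls
#' to `boundary_frac` of the apex prominence above baseline. Per candidate,
#' fragment
#' areas are obtained by trapezoidal integration of the baseline-subtracted
#' trace inside the boundaries (per-fragment baseline = median of the
#' out-of-peak portion of the extraction window, an unbiased estimate of
#' the counting-noise floor; the resulting area is clamped at zero) and
#' subscores are computed: `co_elution` (mean pairwise Pearson correlation of
#' the in-peak fragment traces), `shape_correlation` (mean correlation of
#' each fragment with the summed consensus), `library_correlation` (Pearson
#' correlation of fragment areas with library intensities),
#' `irt_deviation` (|apex iRT - assay iRT|), `mass_accuracy` (mean ppm
#' deviation of matched trace keys, supplied by the caller) and `log_area`.
#'
#' @param xic_mat Fragment x cycle intensity matrix (>= 3 fragments).
#' @param times Cycle times (minutes) of the matrix columns.
#' @param lib_intensities Library relative intensities of the fragments.
#' @param expected_rt Predicted apex retention time (minutes); `NA` sets the
#'   `irt_deviation` subscore to 0 (used for unconstrained anchor search).
#' @param irt_per_min Calibration slope converting minutes to iRT units.
#' @param mass_accuracy Precomputed mean ppm deviation subscore (scalar).
#' @param smooth Gaussian smoothing SD in cycles (default 1).
#' @param max_candidates Maximum number of candidates returned (default 5).
#' @param boundary_frac Boundary threshold as a fraction of apex (default
#'   0.01).
#' @return List of candidate peak groups, each a list with `apex_rt`,
#'   `apex_idx`, `left`, `right` (minutes), `left_idx`, `right_idx`,
#'   `areas`, `subscores` (named numeric). Empty list when the matrix is
#'   all zero.
#' @export
detect_peak_groups <- function(xic_mat, times, lib_intensities,
                               expected_rt = NA_real_, irt_per_min = 1,
                               mass_accuracy = 0, smooth = 1,
                               max_candidates = 5L, boundary_frac = 0.01) {
  stopifnot(nrow(xic_mat) >= 3L, ncol(xic_mat) == length(times))
  total <- colSums(xic_mat)
  if (all(total == 0)) return(list())
  s <- .gauss_smooth(total, smooth)
  peaks <- .local_maxima(s)
  peaks <- peaks[s[peaks] > 0]
  if (length(peaks) == 0L) return(list())
  peaks <- peaks[order(-s[peaks])]
  peaks <- peaks[seq_len(min(length(peaks), max_candidates))]

  nq <- ncol(xic_mat)
  # fallback baseline when a peak fills the whole window: lower quartile
  bl_fallback <- apply(xic_mat, 1L, function(y) sort(y)[max(1L, floor(0.25 * nq))])

  # pedestal level of the summed trace (for boundary prominence decisions)
  s_base <- sort(s)[max(1L, floor(0.25 * nq))]

  lapply(peaks, function(apex) {
    li <- .walk_boundary(s, apex, -1L, boundary_frac, s_base)
    ri <- .walk_boundary(s, apex, +1L, boundary_frac, s_base)
    # the acquisition design targets 6-8 points per peak: never integrate
    # over fewer than 3 cycles on each side of the apex
    li <- min(li, max(1L, apex - 3L))
    ri <- max(ri, min(nq, apex + 3L))
    inpeak <- xic_mat[, li:ri, drop = FALSE]
    m <- ncol(inpeak)
    # per-fragment baseline from the out-of-peak region (median, so the
    # subtraction is unbiased for counting noise); only the final area is
    # clamped at zero
    out_idx <- setdiff(seq_len(nq), li:ri)
    bl <- if (length(out_idx) >= 5L) {
      apply(xic_mat[, out_idx, drop = FALSE], 1L, stats::median)
    } else bl_fallback
    sig <- inpeak - bl
    areas <- if (m >= 2L) {
      pmax(as.numeric((sig[, -1L, drop = FALSE] + sig[, -m, drop = FALSE]) %*%
                        (diff(times[li:ri]) / 2)), 0)
    } else numeric(nrow(inpeak))
    nf <- nrow(inpeak)
    co <- 0; shape <- 0
    if (m >= 3L) {
      cm <- .row_cor(inpeak)
      ut <- cm[upper.tri(cm)]
      ut <- ut[is.finite(ut)]
      if (length(ut)) co <- mean(ut)
      sh <- .rows_vs_vector_cor(inpeak, colSums(inpeak))
      sh <- sh[is.finite(sh)]
      if (length(sh)) shape <- mean(sh)
    }
    libcor <- .safe_cor(areas, lib_intensities)
    irt_dev <- if (is.na(expected_rt)) 0 else
      abs(times[apex] - expected_rt) * irt_per_min
    list(
      apex_rt = times[apex], apex_idx = apex,
      left = times[li], right = times[ri], left_idx = li, right_idx = ri,
      areas = areas,
      interference_flags = rep(FALSE, nf),
      subscores = c(
        co_elution = co, shape_correlation = shape,
        library_correlation = libcor, irt_deviation = irt_dev,
        mass_accuracy = mass_accuracy,
        log_area = log1p(sum(areas))
      )
    )
  })
}

#' Flag interfered fragments in a peak group
#'
#' A fragment is flagged as interfered when its in-peak trace correlates
#' with the consensus of the remaining fragments below `threshold`, or when
#' its observed area share exceeds `area_mult` times its library-predicted
#' share. The `min_keep` best-correlating fragments are always retained for
#' quantification, so groups with `min_keep` or fewer fragments are never
#' flagged.
#'
#' @param group A peak group from [detect_peak_groups()].
#' @param xic_mat,times The matrices the group was detected on.
#' @param lib_intensities Library relative intensities of the fragments.
#' @param threshold Consensus correlation threshold (default 0.75).
#' @param area_mult Allowed area inflation over the library share (default 5).
#' @param min_keep Minimum fragments retained (default 3).
#' @return The group with updated `interference_flags`, plus `quant_area`:
#'   the area sum over unflagged fragments divided by the retained library
#'   intensity share, so excluding a fragment does not shift the quantity
#'   scale.
#' @export
detect_interference <- function(group, xic_mat, times, lib_intensities,
                                threshold = 0.75, area_mult = 5,
                                min_keep = 3L) {
  nf <- nrow(xic_mat)
  stopifnot(nf >= 3L, length(group$areas) == nf)
  li <- group$left_idx; ri <- group$right_idx
  inpeak <- xic_mat[, li:ri, drop = FALSE]
  # r of each fragment vs the consensus of the others (= total minus itself)
  tot <- colSums(inpeak)
  m <- ncol(inpeak)
  Sx <- rowSums(inpeak)
  Sxx <- rowSums(inpeak * inpeak)
  Sxt <- as.numeric(inpeak %*% tot)
  varx <- Sxx - Sx^2 / m
  St <- sum(tot); Stt <- sum(tot * tot)
  Sy <- St - Sx                       # per-fragment consensus sums
  Sxy <- Sxt - Sxx
  vary <- (Stt - 2 * Sxt + Sxx) - Sy^2 / m
  den <- sqrt(varx * vary)
  rcons <- ifelse(is.finite(den) & den > 0 & m >= 3L,
                  (Sxy - Sx * Sy / m) / den, 0)
  flags <- rep(FALSE, nf)
  if (nf > min_keep) {
    obs_share <- group$areas / max(sum(group$areas), .Machine$double.eps)
    lib_share <- lib_intensities / sum(lib_intensities)
    flags <- rcons < threshold | obs_share > area_mult * lib_share
    keep_best <- order(-rcons)[seq_len(min_keep)]
    flags[keep_best] <- FALSE
  }
  group$interference_flags <- flags
  group$fragment_consensus_cor <- rcons
  # renormalize by the retained library share so corrected quantities stay
  # on the full-assay scale when fragments are excluded
  share_kept <- sum(lib_intensities[!flags]) / sum(lib_intensities)
  group$quant_area <- sum(group$areas[!flags]) / max(share_kept, 0.01)
  group
}

#' Calibrate a run's iRT map from reference assays (dynamic iRT)
#'
#' Locates the library's anchor assays by unconstrained whole-gradient
#' extraction, picking per anchor the candidate with the best co-elution
#' (height breaking ties), fits a robust linear iRT calibration through the
#' observed apexes, and derives the dynamic extraction half-width
#' `max(k * residual SD, floor_frac * iRT span)` in iRT units -- narrow when
#' the run is well-behaved, widening automatically with calibration noise.
#'
#' @param run A `dia_run`.
#' @param library A `spectral_library` containing the anchor assays.
#' @param anchors Assay ids to use as anchors; default: all assays of
#'   protein `"IRT_KIT"`.
#' @param k Half-width multiplier on the residual SD (default 3).
#' @param floor_frac Half-width floor as a fraction of the library iRT span
#'   (default 0.01).
#' @param tolerance_ppm Extraction tolerance (default 20 ppm).
#' @param smooth Smoothing SD in cycles.
#' @return Object of class `run_calibration`: list with `fit` (an
#'   `irt_fit`), `half_width_irt`, `half_width_min` (converted with the
#'   fitted slope), `anchors` (data.frame of located anchors).
#' @export
calibrate_run <- function(run, library, anchors = NULL, k = 3,
                          floor_frac = 0.01, tolerance_ppm = 20, smooth = 1) {
  stopifnot(inherits(run, "dia_run"), inherits(library, "spectral_library"))
  a <- library$assays
  if (is.null(anchors)) anchors <- a$assay_id[!a$decoy & a$protein == "IRT_KIT"]
  if (length(anchors) < 3L) stop("calibration failed: need >= 3 anchor assays")
  frag_by_assay <- split(library$fragments, library$fragments$assay_id)
  rows <- list()
  for (aid in anchors) {
    ai <- match(aid, a$assay_id)
    w <- assign_window(a$precursor_mz[ai], run$scheme)
    if (is.na(w)) next
    fr <- frag_by_assay[[aid]]
    if (is.null(fr) || nrow(fr) < 3L) next
    xm <- .xic_matrix(run$windows[[w]], fr$mz, tolerance_ppm,
                      seq_along(run$cycle_times))
    cand <- detect_peak_groups(xm, run$cycle_times, fr$rel_intensity,
                               expected_rt = NA, smooth = smooth,
                               max_candidates = 5L)
    if (length(cand) == 0L) next
    co <- vapply(cand, function(g) g$subscores[["co_elution"]], numeric(1))
    ht <- vapply(cand, function(g) g$subscores[["log_area"]], numeric(1))
    best <- cand[[order(-co, -ht)[1]]]
    rows[[length(rows) + 1L]] <- data.frame(
      assay_id = aid, rt = best$apex_rt, irt = a$irt[ai],
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) < 3L) stop("calibration failed: fewer than 3 anchors located")
  anc <- do.call(rbind, rows)
  fit <- fit_irt_map(anc$rt, anc$irt, robust = TRUE)
  irt_span <- diff(range(a$irt[!a$decoy]))
  hw_irt <- max(k * fit$residual_sd, floor_frac * irt_span)
  out <- list(
    fit = fit,
    half_width_irt = hw_irt,
    half_width_min = hw_irt / fit$slope,
    k = k, floor_frac = floor_frac,
    anchors = anc
  )
  class(out) <- "run_calibration"
  out
}

#' @export
print.run_calibration <- function(x, ...) {
  cat(sprintf(
    "Run calibration: %d anchors, residual sd %.3g iRT, half-width %.3g iRT (%.3g min)\n",
    nrow(x$anchors), x$fit$residual_sd, x$half_width_irt, x$half_width_min
  ))
  invisible(x)
}

#' Score every library assay against one DIA run
#'
#' For each assay (targets and decoys): predicts the apex retention time
#' from the calibrated iRT map, extracts the fragment XIC matrix inside the
#' dynamic window, detects candidate peak groups, selects the best candidate
#' by the seed score (`co_elution - irt_deviation / half_width`), and runs
#' interference detection on it.
#'
#' @param run A `dia_run`.
#' @param library A `spectral_library` (typically with decoys appended).
#' @param calibration A `run_calibration`; computed from `library` when
#'   omitted.
#' @param tolerance_ppm Extraction tolerance in ppm.
#' @param smooth Smoothing SD in cycles.
#' @param max_candidates Candidates examined per assay.
#' @param interference_threshold,area_mult,min_keep See
#'   [detect_interference()].
#' @param interference_correction Use the interference-corrected fragment
#'   subset for `quant_area` (default TRUE); otherwise all fragments are
#'   summed.
#' @return data.frame with one row per assay that produced at least one
#'   candidate: identifiers, decoy flag, apex and boundaries, the six
#'   subscores, `quant_area` and `n_flagged`.
#' @export
score_run <- function(run, library, calibration = NULL, tolerance_ppm = 20,
                      smooth = 1, max_candidates = 5L,
                      interference_threshold = 0.75, area_mult = 5,
                      min_keep = 3L, interference_correction = TRUE) {
  stopifnot(inherits(run, "dia_run"), inherits(library, "spectral_library"))
  if (is.null(calibration)) calibration <- calibrate_run(run, library)
  a <- library$assays
  fit <- calibration$fit
  hw_min <- calibration$half_width_min
  times <- run$cycle_times
  ncyc <- length(times)
  frag_by_assay <- split(library$fragments, library$fragments$assay_id)
  wins <- assign_window(a$precursor_mz, run$scheme)
  pred_rt <- predict_rt(fit, a$irt)

  n <- nrow(a)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    w <- wins[i]
    if (is.na(w)) next
    fr <- frag_by_assay[[a$assay_id[i]]]
    if (is.null(fr) || nrow(fr) < 3L) next
    c0 <- max(1L, findInterval(pred_rt[i] - hw_min, times))
    c1 <- min(ncyc, findInterval(pred_rt[i] + hw_min, times) + 1L)
    if (c1 - c0 < 4L) next
    cols <- c0:c1
    win <- run$windows[[w]]
    rows_list <- lapply(fr$mz, .key_rows, keys = win$keys,
                        tol_ppm = tolerance_ppm)
    xm <- .xic_matrix(win, fr$mz, tolerance_ppm, cols, rows_list = rows_list)
    # mean ppm deviation of the matched trace keys (mass-accuracy proxy)
    ppm <- vapply(seq_len(nrow(fr)), function(f) {
      r <- rows_list[[f]]
      if (length(r) == 0L) return(tolerance_ppm)
      mean(abs(win$keys[r] - fr$mz[f]) / fr$mz[f] * 1e6)
    }, numeric(1))
    cand <- detect_peak_groups(
      xm, times[cols], fr$rel_intensity, expected_rt = pred_rt[i],
      irt_per_min = fit$slope, mass_accuracy = mean(ppm), smooth = smooth,
      max_candidates = max_candidates
    )
    if (length(cand) == 0L) next
    seed <- vapply(cand, function(g) {
      g$subscores[["co_elution"]] -
        g$subscores[["irt_deviation"]] / calibration$half_width_irt
    }, numeric(1))
    best <- cand[[which.max(seed)]]
    best <- detect_interference(best, xm, times[cols], fr$rel_intensity,
                                threshold = interference_threshold,
                                area_mult = area_mult, min_keep = min_keep)
    quant <- if (interference_correction) best$quant_area else sum(best$areas)
    res[[i]] <- c(i, best$apex_rt, best$left, best$right, best$subscores,
                  quant, nrow(fr), sum(best$interference_flags))
  }
  keep <- !vapply(res, is.null, logical(1))
  if (!any(keep)) {
    return(data.frame(assay_id = character(), decoy = logical()))
  }
  m <- do.call(rbind, res[keep])
  i <- m[, 1]
  out <- data.frame(
    assay_id = a$assay_id[i], peptide = a$peptide[i], charge = a$charge[i],
    protein = a$protein[i], decoy = a$decoy[i],
    run_id = run$run_id,
    apex_rt = m[, 2], left = m[, 3], right = m[, 4],
    co_elution = m[, 5], shape_correlation = m[, 6],
    library_correlation = m[, 7], irt_deviation = m[, 8],
    mass_accuracy = m[, 9], log_area = m[, 10],
    quant_area = m[, 11], n_fragments = as.integer(m[, 12]),
    n_flagged = as.integer(m[, 13]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
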