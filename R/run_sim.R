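# DIA run and DDA PSM simulators.
#
# A simulated DIA run holds, per isolation window, a matrix of fragment-level
# elution traces on the cycle-time grid. Trace rows are keyed by fragment m/z
# rounded to 4 decimals. Present peptides contribute Gaussian elution peaks
# (apex at the iRT-mapped retention time plus jitter, height proportional to
# concentration x fragment template intensity x multiplicative lognormal
# error); every trace carries a Poisson baseline. Traces are materialized for
# every m/z key that will be queried downstream -- including assays of absent
# proteins and any `extra_mz` keys (e.g. decoy fragments) -- because real DIA
# spectra contain baseline signal at any m/z.

.TRACE_DIGITS <- 4L

.default_rt_map <- function(gradient_length, irt_span) {
  slope <- 0.9 * gradient_length / diff(irt_span)
  c(slope = slope, intercept = 0.05 * gradient_length - slope * irt_span[1])
}

#' Default noise model of the DIA simulator
#'
#' @param gradient_length Gradient length in minutes.
#' @return List of noise parameters: `peak_sigma` (chromatographic peak SD,
#'   minutes; the default gives ~7 points per peak at a 3.5 s cycle),
#'   `rt_jitter` (SD of the apex around the mapped retention time; default
#'   0.2% of the gradient), `intensity_cv` (multiplicative lognormal CV of
#'   fragment peak heights), `baseline_rate` (Poisson mean of the per-cycle
#'   baseline), `interference_rate`/`interference_mag` (probability and
#'   relative magnitude of an off-apex co-isolated interferent per fragment),
#'   `height_unit` (apex height per concentration unit; places the lowest
#'   spike level at ~3x the baseline RMS).
#' @export
default_noise <- function(gradient_length = 120) {
  list(
    peak_sigma = 0.10,
    rt_jitter = 0.002 * gradient_length,
    intensity_cv = 0.10,
    baseline_rate = 100,
    interference_rate = 0.05,
    interference_mag = 1,
    height_unit = 30
  )
}

#' Simulate one DIA run
#'
#' @param catalog An `assay_catalog`.
#' @param concentrations Named numeric vector protein -> concentration for
#'   this run's sample. Every non-absent, non-reference catalog protein must
#'   be covered; reference (iRT anchor) peptides are always present at
#'   `reference_level`.
#' @param scheme A `dia_scheme`; precursors outside the survey range are
#'   dropped (count reported in the `dropped` field).
#' @param noise Noise parameter list, see [default_noise()]. Partial lists
#'   are completed with the defaults.
#' @param rt_map Length-2 numeric `c(slope, intercept)` mapping iRT to
#'   minutes (`rt = intercept + slope * irt`); default maps the catalog iRT
#'   span onto the central 90% of the gradient.
#' @param gradient_length Gradient length in minutes (default 120).
#' @param extra_mz Optional data.frame with columns `precursor_mz` and `mz`:
#'   additional fragment trace keys (e.g. decoy assay fragments) that receive
#'   baseline-only traces in the window of their precursor.
#' @param reference_level Constant concentration of the iRT anchors.
#' @param run_id Run label.
#' @param seed Integer seed.
#' @return Object of class `dia_run`: list with `run_id`, `scheme`,
#'   `gradient_length`, `cycle_times` (minutes), `windows` (per window:
#'   `keys` sorted m/z keys, `traces` key x cycle matrix), `rt_map`,
#'   `noise`, `truth` (per-assay apex ground truth), `fragment_truth`
#'   (per-fragment heights and interference flags), `dropped`.
#' @export
simulate_dia_run <- function(catalog, concentrations, scheme,
                             noise = list(), rt_map = NULL,
                             gradient_length = 120, extra_mz = NULL,
                             reference_level = 50, run_id = "R01",
                             seed = 1L) {
  stopifnot(inherits(catalog, "assay_catalog"), inherits(scheme, "dia_scheme"))
  noise <- utils::modifyList(default_noise(gradient_length), noise)
  if (is.null(rt_map)) rt_map <- .default_rt_map(gradient_length, catalog$irt_span)
  prec <- catalog$precursors
  frag <- catalog$fragments

  needed <- unique(prec$protein[!prec$absent & !prec$reference])
  missing_conc <- setdiff(needed, names(concentrations))
  if (length(missing_conc)) {
    stop("no concentration for protein(s): ",
         paste(utils::head(missing_conc, 5), collapse = ", "))
  }
  conc_of <- c(concentrations, setNames(reference_level, "IRT_KIT"))

  cycle_times <- seq(0, gradient_length, by = scheme$cycle_period / 60)
  ncyc <- length(cycle_times)

  win <- assign_window(prec$precursor_mz, scheme)
  dropped <- sum(is.na(win))
  prec_win <- setNames(win, prec$assay_id)

  # --- collect trace keys per window -------------------------------------
  fkey <- round(frag$mz, .TRACE_DIGITS)
  fwin <- prec_win[frag$assay_id]
  keys_by_win <- lapply(seq_len(nrow(scheme$windows)), function(w) {
    k <- fkey[!is.na(fwin) & fwin == w]
    if (!is.null(extra_mz)) {
      ew <- assign_window(extra_mz$precursor_mz, scheme)
      k <- c(k, round(extra_mz$mz[!is.na(ew) & ew == w], .TRACE_DIGITS))
    }
    sort(unique(k))
  })

  .with_seed(seed, {
    windows <- lapply(keys_by_win, function(keys) {
      nk <- length(keys)
      tr <- if (nk == 0L) {
        matrix(0, 0L, ncyc)
      } else if (noise$baseline_rate > 0) {
        matrix(as.numeric(stats::rpois(nk * ncyc, noise$baseline_rate)),
               nk, ncyc)
      } else matrix(0, nk, ncyc)
      list(keys = keys, traces = tr)
    })

    present <- !prec$absent & !is.na(win)
    sdlog <- sqrt(log(1 + noise$intensity_cv^2))
    truth <- data.frame(
      assay_id = prec$assay_id, present = present, window = win,
      apex_rt = NA_real_, stringsAsFactors = FALSE
    )
    ftruth <- list()
    frag_by_assay <- split(seq_len(nrow(frag)), frag$assay_id)

    for (i in which(present)) {
      aid <- prec$assay_id[i]
      w <- win[i]
      conc <- conc_of[[prec$protein[i]]]
      if (is.na(conc) || conc <= 0) next
      apex <- rt_map[["intercept"]] + rt_map[["slope"]] * prec$irt[i] +
        stats::rnorm(1, 0, noise$rt_jitter)
      truth$apex_rt[i] <- apex
      fi <- frag_by_assay[[aid]]
      heights <- conc * noise$height_unit * frag$rel_intensity[fi]
      if (noise$intensity_cv > 0) {
        heights <- heights *
          exp(stats::rnorm(length(fi), 0, sdlog) - sdlog^2 / 2)
      }
      i0 <- max(1L, findInterval(apex - 4.5 * noise$peak_sigma, cycle_times))
      i1 <- min(ncyc, findInterval(apex + 4.5 * noise$peak_sigma, cycle_times) + 1L)
      if (i1 < i0) next
      tt <- cycle_times[i0:i1]
      shape <- exp(-(tt - apex)^2 / (2 * noise$peak_sigma^2))
      rows <- match(fkey[fi], windows[[w]]$keys)
      agg <- rowsum(heights, rows)
      urows <- as.integer(rownames(agg))
      windows[[w]]$traces[urows, i0:i1] <-
        windows[[w]]$traces[urows, i0:i1] + agg[, 1] %o% shape

      interfered <- noise$interference_rate > 0 &
        stats::runif(length(fi)) < noise$interference_rate
      if (any(interfered)) {
        for (j in which(interfered)) {
          off <- sample(c(-1, 1), 1L) * stats::runif(1, 1.5, 3) * noise$peak_sigma
          h2 <- heights[j] * noise$interference_mag * stats::runif(1, 0.8, 1.5)
          shape2 <- exp(-(tt - apex - off)^2 / (2 * noise$peak_sigma^2))
          r <- rows[j]
          windows[[w]]$traces[r, i0:i1] <-
            windows[[w]]$traces[r, i0:i1] + h2 * shape2
        }
      }
      ftruth[[length(ftruth) + 1L]] <- data.frame(
        assay_id = aid, mz = frag$mz[fi], key = fkey[fi],
        height = heights, interfered = interfered, stringsAsFactors = FALSE
      )
    }
  })

  out <- list(
    run_id = run_id, scheme = scheme, gradient_length = gradient_length,
    cycle_times = cycle_times, windows = windows, rt_map = rt_map,
    noise = noise,
    truth = truth,
    fragment_truth = if (length(ftruth)) do.call(rbind, ftruth) else NULL,
    dropped = dropped
  )
  class(out) <- "dia_run"
  out
}

#' @export
print.dia_run <- function(x, ...) {
  nk <- sum(vapply(x$windows, function(w) length(w$keys), integer(1)))
  cat(sprintf(
    "DIA run %s: %d windows, %d fragment traces, %d cycles over %.0f min (%d/%d assays present)\n",
    x$run_id, length(x$windows), nk, length(x$cycle_times),
    x$gradient_length, sum(x$truth$present), nrow(x$truth)
  ))
  invisible(x)
}

#' Simulate DDA (shotgun) peptide-spectrum-match tables
#'
#' Emulates semistochastic shotgun sampling over a set of runs: each present
#' peptide is identified with an abundance-dependent probability (logistic in
#' log2 concentration, monotone non-decreasing), its observed retention time
#' is the iRT-mapped truth plus Gaussian error, and fragment intensities are
#' the catalog templates under multiplicative noise. A small chimeric rate
#' produces duplicate identifications of the same precursor within a run.
#' Absent-protein peptides never appear.
#'
#' @param catalog An `assay_catalog`.
#' @param design A `ground_truth_design` providing per-sample concentrations.
#' @param run_order data.frame from [block_randomize()] (columns `run_id`,
#'   `sample`).
#' @param sampling List: `p_max` (asymptotic detection probability),
#'   `mid_log2`, `slope_log2` (logistic midpoint/scale on log2 abundance),
#'   `rt_sd` (RT error SD, minutes), `intensity_cv`, `chimeric_rate`.
#' @param rt_map,gradient_length As in [simulate_dia_run()].
#' @param reference_level Concentration of the iRT anchors.
#' @param seed Integer seed.
#' @return Object of class `psm_table`: list with `psms` (one row per
#'   identification) and `fragments` (one row per annotated fragment,
#'   keyed by `psm_id`).
#' @export
simulate_dda_psms <- function(catalog, design, run_order,
                              sampling = list(), rt_map = NULL,
                              gradient_length = 120, reference_level = 50,
                              seed = 1L) {
  stopifnot(inherits(catalog, "assay_catalog"))
  sampling <- utils::modifyList(
    list(p_max = 0.85, mid_log2 = 1.5, slope_log2 = 1.2, rt_sd = 0.3,
         intensity_cv = 0.2, chimeric_rate = 0.05),
    sampling
  )
  if (is.null(rt_map)) rt_map <- .default_rt_map(gradient_length, catalog$irt_span)
  prec <- catalog$precursors[!catalog$precursors$absent, , drop = FALSE]
  frag <- catalog$fragments
  frag_by_assay <- split(seq_len(nrow(frag)), frag$assay_id)
  sdlog <- sqrt(log(1 + sampling$intensity_cv^2))

  psms <- list(); frows <- list(); psm_n <- 0L
  .with_seed(seed, {
    for (r in seq_len(nrow(run_order))) {
      rid <- run_order$run_id[r]
      smp <- run_order$sample[r]
      conc <- c(design$concentrations[, smp],
                setNames(reference_level, "IRT_KIT"))
      a <- conc[prec$protein]
      p_det <- ifelse(prec$reference, sampling$p_max,
                      sampling$p_max *
                        stats::plogis((log2(a) - sampling$mid_log2) /
                                        sampling$slope_log2))
      hit <- stats::runif(nrow(prec)) < p_det
      for (i in which(hit)) {
        n_copies <- 1L +
          (stats::runif(1) < sampling$chimeric_rate)
        for (cp in seq_len(n_copies)) {
          psm_n <- psm_n + 1L
          pid <- sprintf("%s_P%06d", rid, psm_n)
          rt <- rt_map[["intercept"]] + rt_map[["slope"]] * prec$irt[i] +
            stats::rnorm(1, 0, sampling$rt_sd)
          rt <- min(max(rt, 0), gradient_length)
          fi <- frag_by_assay[[prec$assay_id[i]]]
          scale <- a[i] * (if (cp == 1L) 1 else stats::runif(1, 0.2, 0.6))
          ints <- scale * frag$rel_intensity[fi] *
            exp(stats::rnorm(length(fi), 0, sdlog) - sdlog^2 / 2)
          psms[[psm_n]] <- data.frame(
            psm_id = pid, run_id = rid, sample = smp,
            peptide = prec$peptide[i], charge = prec$charge[i],
            precursor_mz = prec$precursor_mz[i], protein = prec$protein[i],
            reference = prec$reference[i], irt_true = prec$irt[i],
            rt = rt, score = stats::plogis(log2(a[i]) / 3 + stats::rnorm(1, 0, 0.5)),
            total_intensity = sum(ints), stringsAsFactors = FALSE
          )
          frows[[psm_n]] <- data.frame(
            psm_id = pid, ion_type = frag$ion_type[fi],
            ordinal = frag$ordinal[fi], frag_charge = frag$frag_charge[fi],
            mz = frag$mz[fi], intensity = ints, stringsAsFactors = FALSE
          )
        }
      }
    }
  })
  out <- list(psms = do.call(rbind, psms), fragments = do.call(rbind, frows))
  class(out) <- "psm_table"
  out
}

#' @export
print.psm_table <- function(x, ...) {
  cat(sprintf("PSM table: %d identifications over %d runs (%d peptides)\n",
              nrow(x$psms), length(unique(x$psms$run_id)),
              length(unique(x$psms$peptide))))
  invisible(x)
}

#' Write / read a PSM table as tab-separated text
#'
#' Long format: one row per annotated fragment, PSM-level columns repeated.
#'
#' @param psm_table A `psm_table`.
#' @param path File path.
#' @return `read_psm_table` returns a `psm_table`.
#' @export
write_psm_table <- function(psm_table, path) {
  long <- merge(psm_table$psms, psm_table$fragments, by = "psm_id")
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  psm_cols <- c("psm_id", "run_id", "sample", "peptide", "charge",
                "precursor_mz", "protein", "reference", "irt_true",
                "rt", "score", "total_intensity")
  frag_cols <- c("psm_id", "ion_type", "ordinal", "frag_charge", "mz",
                 "intensity")
  out <- list(
    psms = unique(long[, intersect(psm_cols, names(long))]),
    fragments = long[, intersect(frag_cols, names(long))]
  )
  rownames(out$psms) <- NULL
  class(out) <- "psm_table"
  out
}
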