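# mProphet-style semi-supervised discriminant scoring (Cscore), target-decoy
# q-values at the peptide level, and the truly-absent null validation.

.SUBSCORE_COLS <- c("co_elution", "shape_correlation", "library_correlation",
                    "irt_deviation", "mass_accuracy", "log_area")

#' Train the semi-supervised linear discriminant (Cscore)
#'
#' mProphet-style loop over per-assay best peak groups: iteration 0 ranks by
#' the seed score (z-standardized `co_elution` minus z-standardized
#' `irt_deviation`); each subsequent iteration takes targets at
#' `q <= train_fdr` as positives and all decoys as negatives, fits a linear
#' discriminant on the standardized subscores, and rescores. The final
#' discriminant projection is z-normalized against the decoy distribution
#' (decoys: mean 0, SD 1), giving the normalized Cscore.
#'
#' With fewer than 50 scored targets or decoys the discriminant cannot be
#' trained reliably and the seed score is returned with a warning.
#' Zero-variance subscores are dropped from the model with a warning.
#'
#' @param candidates data.frame from [score_run()] (one best peak group per
#'   assay, with the subscore columns and a logical `decoy`).
#' @param n_iterations Training iterations (default 5).
#' @param train_fdr q-value threshold defining training positives
#'   (default 0.01).
#' @param seed Integer seed (the procedure is deterministic; the seed guards
#'   the tie-break shuffle).
#' @return Object of class `hrm_scores`: `candidates` with added `cscore`
#'   and `qvalue` columns, plus attributes `weights` (named discriminant
#'   weights on the standardized subscores) and `iterations`.
#' @export
train_discriminant <- function(candidates, n_iterations = 5L,
                               train_fdr = 0.01, seed = 1L) {
  stopifnot(is.data.frame(candidates), "decoy" %in% names(candidates))
  sub_cols <- intersect(.SUBSCORE_COLS, names(candidates))
  X <- as.matrix(candidates[, sub_cols, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  degenerate <- !is.finite(sds) | sds == 0
  if (any(degenerate)) {
    warning("dropping zero-variance subscore(s): ",
            paste(sub_cols[degenerate], collapse = ", "))
    X <- X[, !degenerate, drop = FALSE]
  }
  Z <- scale(X)
  decoy <- candidates$decoy

  seed_score <- numeric(nrow(Z))
  if ("co_elution" %in% colnames(Z)) seed_score <- seed_score + Z[, "co_elution"]
  if ("irt_deviation" %in% colnames(Z)) seed_score <- seed_score - Z[, "irt_deviation"]
  score <- seed_score
  weights <- NULL

  if (sum(!decoy) < 50L || sum(decoy) < 50L) {
    warning("fewer than 50 targets or decoys: falling back to the seed score")
    n_iterations <- 0L
  }
  .with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      q <- assign_qvalues(score, decoy)
      pos <- !decoy & q <= train_fdr
      if (sum(pos) < 10L) {
        # too few confident targets at the training threshold: take the
        # top-ranked targets instead so the iteration can proceed
        topn <- min(50L, sum(!decoy))
        pos <- !decoy & rank(-score, ties.method = "first") <= topn * 2L
        pos <- pos & !decoy
        if (sum(pos) < 10L) break
      }
      train_idx <- which(pos | decoy)
      grp <- factor(ifelse(decoy[train_idx], "decoy", "target"))
      fit <- tryCatch(
        MASS::lda(Z[train_idx, , drop = FALSE], grouping = grp),
        error = function(e) NULL
      )
      if (is.null(fit)) break
      proj <- as.numeric(Z %*% fit$scaling[, 1])
      wts <- setNames(as.numeric(fit$scaling[, 1]), colnames(Z))
      if (mean(proj[!decoy]) < mean(proj[decoy])) {
        proj <- -proj
        wts <- -wts
      }
      score <- proj
      weights <- wts
    }
  })
  # normalize against the decoy distribution
  mu <- mean(score[decoy]); sdv <- stats::sd(score[decoy])
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  cscore <- (score - mu) / sdv
  out <- candidates
  out$cscore <- cscore
  out$qvalue <- assign_qvalues(cscore, decoy)
  attr(out, "weights") <- weights
  attr(out, "iterations") <- n_iterations
  class(out) <- c("hrm_scores", class(out))
  out
}

#' Target-decoy q-values
#'
#' At score threshold `c`, the FDR estimate is
#' `#{decoys >= c} / #{targets >= c}` (1:1 decoys, no pi0 rescaling); the
#' q-value is the running minimum of the estimate from high to low score,
#' clipped to `[0, 1]`. Ties are resolved conservatively (decoys counted
#' before targets at an equal score).
#'
#' @param scores Numeric discriminant scores (higher = more target-like).
#' @param decoy Logical decoy flags (at least one target and one decoy).
#' @return Numeric q-values aligned with `scores`.
#' @export
assign_qvalues <- function(scores, decoy) {
  stopifnot(length(scores) == length(decoy))
  if (!any(decoy)) stop("no decoys: cannot estimate FDR")
  if (all(decoy)) stop("no targets: cannot estimate FDR")
  # decoys first within ties -> conservative
  o <- order(-scores, !decoy)
  d_cum <- cumsum(decoy[o])
  t_cum <- cumsum(!decoy[o])
  fdr <- ifelse(t_cum > 0, d_cum / t_cum, 1)
  q <- rev(cummin(rev(pmin(fdr, 1))))
  out <- numeric(length(scores))
  out[o] <- q
  out
}

#' Collapse charge states to peptide-level q-values
#'
#' Keeps the best (maximum) Cscore per (peptide, decoy) and recomputes
#' q-values on the collapsed set, implementing peptide-level FDR control.
#'
#' @param scores An `hrm_scores` data.frame (needs `peptide`, `decoy`,
#'   `cscore`).
#' @return data.frame with one row per peptide and a `qvalue` column.
#' @export
peptide_qvalues <- function(scores) {
  stopifnot(all(c("peptide", "decoy", "cscore") %in% names(scores)))
  o <- order(scores$peptide, scores$decoy, -scores$cscore)
  s <- scores[o, ]
  s <- s[!duplicated(paste(s$peptide, s$decoy)), , drop = FALSE]
  s$qvalue <- assign_qvalues(s$cscore, s$decoy)
  rownames(s) <- NULL
  s
}

#' Compare decoy and truly-absent score distributions
#'
#' Two-sample Kolmogorov-Smirnov comparison of the Cscore distributions of
#' decoy assays and assays of truly-absent proteins. A small KS statistic
#' indicates that scrambled decoys statistically mimic the truly-absent
#' null, validating the decoy model behind the FDR estimate.
#'
#' @param scores_absent Cscores of truly-absent target assays (>= 100).
#' @param scores_decoy Cscores of decoy assays (>= 100).
#' @param breaks Number of histogram bins for the returned table.
#' @return List with `ks_statistic`, `p_value` and `histogram` (data.frame
#'   `mid`, `density_absent`, `density_decoy` on the common Cscore axis).
#' @export
validate_null <- function(scores_absent, scores_decoy, breaks = 30L) {
  if (length(scores_absent) < 100L || length(scores_decoy) < 100L) {
    stop("need at least 100 scores in each set")
  }
  ks <- suppressWarnings(stats::ks.test(scores_absent, scores_decoy))
  rng <- range(c(scores_absent, scores_decoy))
  br <- seq(rng[1], rng[2], length.out = breaks + 1L)
  ha <- graphics::hist(scores_absent, breaks = br, plot = FALSE)
  hd <- graphics::hist(scores_decoy, breaks = br, plot = FALSE)
  list(
    ks_statistic = unname(ks$statistic),
    p_value = unname(ks$p.value),
    histogram = data.frame(mid = ha$mids, density_absent = ha$density,
                           density_decoy = hd$density)
  )
}
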