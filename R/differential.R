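# Per-protein linear mixed-effects differential abundance testing in the
# MSstats style: log2 precursor intensities modeled as
#   value = mu + Sample_i + Precursor_j + Run_k(random) + error,
# fit by REML, with all pairwise sample contrasts, Satterthwaite degrees of
# freedom, Benjamini-Hochberg adjustment across proteins, candidate
# filtering, and ROC/DeLong benchmarking against a ground truth.

#' Fit the mixed-effects model for one protein
#'
#' Fixed sample and precursor effects with a random run intercept, fit by
#' REML (runs are nested in samples: one MS injection per technical
#' replicate). With a single precursor the precursor term is dropped; when
#' the random run effect is inestimable (e.g. one observation per run and
#' one precursor) the model falls back to a fixed-effects linear model and
#' the fit is tagged accordingly. Samples without data are excluded;
#' contrasts involving them are reported as infeasible by
#' [pairwise_compare()].
#'
#' @param data data.frame with columns `sample`, `precursor`, `run`,
#'   `value` (log2 intensity) for one protein; missing values are rows that
#'   are simply absent.
#' @param protein_id Optional protein label carried through.
#' @return Object of class `protein_fit`: list with `model` (`lmerMod` or
#'   `lm`), `method` (`"REML"` or `"fixed"`), `sigma2` (residual variance),
#'   `sigma2_run` (run variance, 0 for fixed fits), `samples` (levels with
#'   data), `n_precursors`, `n_runs`, `data`.
#' @export
fit_protein <- function(data, protein_id = NA_character_) {
  stopifnot(all(c("sample", "precursor", "run", "value") %in% names(data)))
  data <- data[is.finite(data$value), , drop = FALSE]
  if (nrow(data) == 0L) stop("no finite observations")
  data$sample <- factor(data$sample)
  data$precursor <- factor(data$precursor)
  data$run <- factor(data$run)
  data <- droplevels(data)
  if (nlevels(data$sample) < 2L) stop("need data in at least 2 samples")

  p <- nlevels(data$precursor)
  many_prec <- p > 1L
  n_runs <- nlevels(data$run)
  # a random run intercept needs replication within runs or across precursors
  run_estimable <- many_prec || any(table(data$run) > 1L)

  model <- NULL; method <- "fixed"; s2 <- NA_real_; s2run <- 0
  if (run_estimable && n_runs > nlevels(data$sample)) {
    form <- if (many_prec) value ~ sample + precursor + (1 | run) else
      value ~ sample + (1 | run)
    model <- tryCatch(
      suppressMessages(lmerTest::lmer(
        form, data = data,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = TRUE)
      )),
      error = function(e) NULL
    )
  }
  if (!is.null(model)) {
    method <- "REML"
    vc <- lme4::VarCorr(model)
    s2 <- stats::sigma(model)^2
    s2run <- as.numeric(vc$run[1, 1])
  } else {
    form <- if (many_prec) value ~ sample + precursor else value ~ sample
    model <- stats::lm(form, data = data)
    s2 <- stats::sigma(model)^2
  }
  out <- list(
    protein_id = protein_id, model = model, method = method,
    sigma2 = s2, sigma2_run = s2run,
    samples = levels(data$sample),
    n_precursors = p, n_runs = n_runs, data = data
  )
  class(out) <- "protein_fit"
  out
}

#' @export
print.protein_fit <- function(x, ...) {
  cat(sprintf(
    "Protein model fit%s (%s): %d samples, %d precursors, %d runs; sigma2 = %.4g, sigma2_run = %.4g\n",
    if (is.na(x$protein_id)) "" else paste0(" [", x$protein_id, "]"),
    x$method, length(x$samples), x$n_precursors, x$n_runs,
    x$sigma2, x$sigma2_run
  ))
  invisible(x)
}

#' @export
coef.protein_fit <- function(object, ...) {
  if (inherits(object$model, "merMod")) lme4::fixef(object$model) else
    stats::coef(object$model)
}

# fixed-effect contrast vector for sample a - b at a common precursor level
.sample_contrast <- function(fit, a, b) {
  data <- fit$data
  nd <- data[c(1L, 1L), , drop = FALSE]
  nd$sample <- factor(c(a, b), levels = levels(data$sample))
  nd$precursor <- factor(rep(levels(data$precursor)[1], 2L),
                         levels = levels(data$precursor))
  trms <- stats::delete.response(stats::terms(
    stats::formula(fit$model, fixed.only = inherits(fit$model, "merMod"))
  ))
  X <- stats::model.matrix(trms, nd)
  X[1, ] - X[2, ]
}

#' All pairwise sample comparisons for one protein
#'
#' One result per unordered sample pair among `samples` (`n(n-1)/2`
#' results). Contrast estimates and model-based standard errors come from
#' the fitted model; degrees of freedom are Satterthwaite for REML fits and
#' residual df for fixed fits. Pairs involving a sample with no data are
#' infeasible: the p value is set to 1 and the estimate is missing.
#'
#' @param fit A `protein_fit`.
#' @param samples Sample labels to compare (default: the design's samples,
#'   i.e. the levels with data; pass the full design to get infeasible rows
#'   for absent samples).
#' @return data.frame of class `comparison_result`: `protein`, `contrast`,
#'   `log2fc`, `se`, `df`, `t`, `p`, `adj_p` (`NA`, filled by
#'   [adjust_bh()]), `feasible`.
#' @export
pairwise_compare <- function(fit, samples = NULL) {
  stopifnot(inherits(fit, "protein_fit"))
  if (is.null(samples)) samples <- fit$samples
  stopifnot(length(samples) >= 2L)
  pairs <- utils::combn(samples, 2L)
  n <- ncol(pairs)
  out <- data.frame(
    protein = rep(fit$protein_id, n),
    contrast = paste(pairs[1, ], "vs", pairs[2, ]),
    log2fc = NA_real_, se = NA_real_, df = NA_real_, t = NA_real_,
    p = 1, adj_p = NA_real_, feasible = FALSE,
    stringsAsFactors = FALSE
  )
  is_mer <- inherits(fit$model, "merMod")
  for (k in seq_len(n)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (!(a %in% fit$samples) || !(b %in% fit$samples)) next
    L <- .sample_contrast(fit, a, b)
    if (is_mer) {
      ct <- tryCatch(
        lmerTest::contest1D(fit$model, L, ddf = "Satterthwaite"),
        error = function(e) NULL
      )
      if (is.null(ct) || !is.finite(ct$`Pr(>|t|)`)) next
      out$log2fc[k] <- ct$Estimate
      out$se[k] <- ct$`Std. Error`
      out$df[k] <- ct$df
      out$t[k] <- ct$`t value`
      out$p[k] <- ct$`Pr(>|t|)`
    } else {
      est <- sum(L * stats::coef(fit$model))
      V <- stats::vcov(fit$model)
      se <- sqrt(drop(t(L) %*% V %*% L))
      df <- fit$model$df.residual
      if (!is.finite(se) || se <= 0 || df < 1) next
      tval <- est / se
      out$log2fc[k] <- est
      out$se[k] <- se
      out$df[k] <- df
      out$t[k] <- tval
      out$p[k] <- 2 * stats::pt(-abs(tval), df)
    }
    out$feasible[k] <- TRUE
  }
  class(out) <- c("comparison_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjusted p values (monotone, bounded by 1), a thin
#' validated wrapper around [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values.
#' @export
adjust_bh <- function(pvalues) {
  stopifnot(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)))
  stats::p.adjust(pvalues, method = "BH")
}

#' Filter comparison results into a candidate list
#'
#' Keeps feasible results with `adj_p <= fdr` and a fold change of more than
#' `100 * (min_fold_change - 1)` percent in either direction
#' (`|log2fc| > log2(min_fold_change)`). Infeasible results (p set to 1)
#' never pass.
#'
#' @param results A `comparison_result` data.frame with `adj_p` filled.
#' @param fdr Adjusted-p cutoff (default 0.05).
#' @param min_fold_change Fold-change cutoff as a ratio (default 1.5, i.e. a
#'   more-than-50% change in either direction).
#' @return The filtered subset.
#' @export
candidate_list <- function(results, fdr = 0.05, min_fold_change = 1.5) {
  stopifnot(all(c("adj_p", "log2fc", "feasible") %in% names(results)))
  keep <- results$feasible &
    !is.na(results$adj_p) & results$adj_p <= fdr &
    !is.na(results$log2fc) & abs(results$log2fc) > log2(min_fold_change)
  results[keep, , drop = FALSE]
}

#' Run the differential analysis over all proteins
#'
#' Fits the mixed model per protein on a long-format log2 intensity table,
#' performs all pairwise sample comparisons, and applies BH adjustment
#' across proteins within each contrast (`bh_scope = "per_contrast"`,
#' the MSstats convention) or across everything (`"global"`).
#'
#' @param long data.frame `protein`, `sample`, `precursor`, `run`, `value`
#'   (log2 intensity).
#' @param samples Full sample set of the design (absent samples yield
#'   infeasible rows).
#' @param bh_scope `"per_contrast"` or `"global"`.
#' @return data.frame of all comparison results with `adj_p` filled.
#' @export
differential_analysis <- function(long, samples = NULL,
                                  bh_scope = c("per_contrast", "global")) {
  bh_scope <- match.arg(bh_scope)
  stopifnot(all(c("protein", "sample", "precursor", "run", "value") %in%
                  names(long)))
  if (is.null(samples)) samples <- sort(unique(long$sample))
  res <- lapply(split(long, long$protein), function(d) {
    pid <- d$protein[1]
    fit <- tryCatch(fit_protein(d, protein_id = pid), error = function(e) NULL)
    if (is.null(fit)) {
      pairs <- utils::combn(samples, 2L)
      return(data.frame(
        protein = pid, contrast = paste(pairs[1, ], "vs", pairs[2, ]),
        log2fc = NA_real_, se = NA_real_, df = NA_real_, t = NA_real_,
        p = 1, adj_p = NA_real_, feasible = FALSE, stringsAsFactors = FALSE
      ))
    }
    pairwise_compare(fit, samples)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  if (bh_scope == "per_contrast") {
    for (ct in unique(res$contrast)) {
      i <- res$contrast == ct
      res$adj_p[i] <- adjust_bh(res$p[i])
    }
  } else {
    res$adj_p <- adjust_bh(res$p)
  }
  res
}

#' Long-format log2 intensity table from a quantification matrix
#'
#' @param qm A `quant_matrix`.
#' @return data.frame `protein`, `sample`, `precursor`, `run`, `value`
#'   (log2 intensity), one row per observed cell.
#' @export
quant_to_long <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  v <- qm$values
  idx <- which(!is.na(v) & v > 0, arr.ind = TRUE)
  data.frame(
    protein = unname(qm$protein[rownames(v)[idx[, 1]]]),
    sample = unname(qm$sample[colnames(v)[idx[, 2]]]),
    precursor = rownames(v)[idx[, 1]],
    run = colnames(v)[idx[, 2]],
    value = log2(v[idx]),
    stringsAsFactors = FALSE
  )
}

#' ROC curve and AUC for differential-abundance detection
#'
#' Threshold sweep of `score` (higher = called differential more readily)
#' against the binary `truth`, via pROC.
#'
#' @param score Numeric ranking, e.g. `1 - adj_p` or `-log10(adj_p)`.
#' @param truth Logical (or 0/1) ground-truth differential labels; both
#'   classes must occur.
#' @return List with `auc`, `roc` (the pROC object), `points` (data.frame
#'   `fpr`, `tpr`).
#' @export
roc_and_auc <- function(score, truth) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2L) stop("truth must contain both classes")
  stopifnot(length(score) == length(truth))
  r <- pROC::roc(response = truth, predictor = score, quiet = TRUE,
                 direction = "<", levels = c(FALSE, TRUE))
  list(
    auc = as.numeric(pROC::auc(r)),
    roc = r,
    points = data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  )
}

#' DeLong comparison of two correlated AUCs
#'
#' Paired DeLong test (structural components variance) for two score
#' vectors over the same cases, via pROC. Identical score vectors (zero
#' variance of the AUC difference) return p = 1.
#'
#' @param score_a,score_b Paired score vectors.
#' @param truth Shared ground-truth labels.
#' @return List with `auc_a`, `auc_b`, `p_value`.
#' @export
delong_compare <- function(score_a, score_b, truth) {
  truth <- as.logical(truth)
  stopifnot(length(score_a) == length(truth),
            length(score_b) == length(truth))
  ra <- pROC::roc(response = truth, predictor = score_a, quiet = TRUE,
                  direction = "<", levels = c(FALSE, TRUE))
  rb <- pROC::roc(response = truth, predictor = score_b, quiet = TRUE,
                  direction = "<", levels = c(FALSE, TRUE))
  if (isTRUE(all.equal(score_a, score_b))) {
    return(list(auc_a = as.numeric(pROC::auc(ra)),
                auc_b = as.numeric(pROC::auc(rb)), p_value = 1))
  }
  tst <- tryCatch(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE),
    error = function(e) NULL
  )
  p <- if (is.null(tst) || !is.finite(tst$p.value)) 1 else tst$p.value
  list(auc_a = as.numeric(pROC::auc(ra)),
       auc_b = as.numeric(pROC::auc(rb)),
       p_value = p)
}
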