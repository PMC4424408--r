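# Ground-truth concentration designs and run-order randomization for the
# profiling standard benchmark: a constant background proteome plus 12
# spike-in proteins in three master mixes across 8 samples.

#' Ground-truth spike-in design for the profiling standard sample set
#'
#' Builds the protein-by-sample concentration matrix of the benchmark design:
#' a constant background, two master mixes carrying small concentration
#' changes (+10% and +60%) at three abundance levels (1, 10, 50; the lowest
#' spike level defines concentration unit 1), and a third master mix pipetted
#' as a fourfold dilution series `1, 4, 16, ..., 4^(n_samples-1)`.
#'
#' Master mix 1 proteins follow the within-sample multiplier pattern
#' `1, 1.1, 1.6, ...` (recycled over samples); master mix 2 uses the same
#' pattern rotated by one sample so the two mixes are not collinear. Each
#' mix's proteins cycle through the base levels.
#'
#' @param background_proteins Character vector of background protein ids
#'   (>= 1).
#' @param spike_proteins Character vector of spike-in protein ids (default 12
#'   generated names), assigned to the three mixes in order (default 4/4/4).
#' @param mix_sizes Integer vector of length 3 partitioning the spike
#'   proteins into master mixes.
#' @param base_levels Abundance levels for mix 1/2 proteins.
#' @param changes Relative concentration changes introduced by mixes 1 and 2
#'   (default `c(0.10, 0.60)`).
#' @param dilution_ratio Fold change per step of the mix-3 series (default 4).
#' @param n_samples Number of samples (default 8).
#' @param background_level Constant background concentration (default 20).
#' @return Object of class `ground_truth_design`: list with `samples`,
#'   `concentrations` (protein x sample matrix), `spike_group` (named factor
#'   `background`/`mix1`/`mix2`/`mix3`).
#' @export
make_profiling_design <- function(background_proteins = sprintf("BG%03d", 1:30),
                                  spike_proteins = sprintf("SPIKE%02d", 1:12),
                                  mix_sizes = c(4L, 4L, 4L),
                                  base_levels = c(1, 10, 50),
                                  changes = c(0.10, 0.60),
                                  dilution_ratio = 4,
                                  n_samples = 8L,
                                  background_level = 20) {
  stopifnot(length(background_proteins) >= 1L,
            sum(mix_sizes) == length(spike_proteins),
            length(mix_sizes) == 3L, n_samples >= 2L)
  if (background_level <= 0 || any(base_levels <= 0) || dilution_ratio <= 0) {
    stop("concentration levels and ratios must be positive")
  }
  samples <- sprintf("S%d", seq_len(n_samples))
  proteins <- c(background_proteins, spike_proteins)
  conc <- matrix(NA_real_, length(proteins), n_samples,
                 dimnames = list(proteins, samples))
  conc[background_proteins, ] <- background_level
  group <- setNames(rep("background", length(proteins)), proteins)
  mix_of <- rep(paste0("mix", 1:3), times = mix_sizes)
  group[spike_proteins] <- mix_of

  multipliers <- c(1, 1 + changes)  # e.g. 1, 1.1, 1.6
  for (m in 1:2) {
    prots <- spike_proteins[mix_of == paste0("mix", m)]
    pattern <- rep_len(multipliers, n_samples)
    if (m == 2L) pattern <- pattern[c(seq(2, n_samples), 1L)]  # rotate
    for (i in seq_along(prots)) {
      base <- base_levels[((i - 1L) %% length(base_levels)) + 1L]
      conc[prots[i], ] <- base * pattern
    }
  }
  prots3 <- spike_proteins[mix_of == "mix3"]
  series <- dilution_ratio^(seq_len(n_samples) - 1L)
  for (p in prots3) conc[p, ] <- series

  out <- list(samples = samples, concentrations = conc,
              spike_group = factor(group,
                levels = c("background", "mix1", "mix2", "mix3")))
  class(out) <- "ground_truth_design"
  out
}

#' @export
print.ground_truth_design <- function(x, ...) {
  cat(sprintf("Ground-truth design: %d proteins x %d samples (%s)\n",
              nrow(x$concentrations), length(x$samples),
              paste(sprintf("%s=%d", levels(x$spike_group),
                            tabulate(x$spike_group)), collapse = ", ")))
  invisible(x)
}

#' True log2 fold changes of a design
#'
#' Per-protein log2 concentration ratios for every unordered sample pair;
#' used as the ground truth for fold-change recovery and ROC analyses.
#'
#' @param design A `ground_truth_design`.
#' @return data.frame with `protein`, `contrast` (`"Sa vs Sb"`), `log2fc`.
#' @export
design_true_log2fc <- function(design) {
  s <- design$samples
  pairs <- utils::combn(s, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    data.frame(
      protein = rownames(design$concentrations),
      contrast = paste(a, "vs", b),
      log2fc = log2(design$concentrations[, a] / design$concentrations[, b]),
      row.names = NULL
    )
  }))
  out
}

#' Block-randomized run order
#'
#' Arranges `replicates` acquisition blocks, each containing every sample
#' exactly once in random order, so technical replicates are spread across
#' the measurement sequence.
#'
#' @param samples Character vector of sample labels (or a
#'   `ground_truth_design`).
#' @param replicates Number of technical replicates (blocks), >= 1.
#' @param seed Integer seed.
#' @return data.frame `run_id`, `block` (replicate index), `sample`,
#'   `position` (overall acquisition position).
#' @export
block_randomize <- function(samples, replicates = 3L, seed = 1L) {
  if (inherits(samples, "ground_truth_design")) samples <- samples$samples
  stopifnot(length(samples) >= 1L, replicates >= 1L)
  .with_seed(seed, {
    order_all <- unlist(lapply(seq_len(replicates), function(b) {
      if (length(samples) == 1L) samples else sample(samples)
    }))
  })
  n <- length(samples)
  data.frame(
    run_id = sprintf("R%02d", seq_len(n * replicates)),
    block = rep(seq_len(replicates), each = n),
    sample = order_all,
    position = seq_len(n * replicates),
    stringsAsFactors = FALSE
  )
}
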