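# Shared fixtures. Heavy simulations are memoized so acceptance checks and
# unit tests can share one computation per configuration.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# --- small deterministic catalog + run ----------------------------------

small_catalog <- function(seed = 7) {
  simulate_catalog(
    n_background_proteins = 10L, n_absent_proteins = 3L,
    peptides_per_protein = list(mean = 3, min = 2),
    n_reference_peptides = 11L, seed = seed
  )
}

flat_concentrations <- function(catalog, level = 20) {
  prots <- unique(catalog$precursors$protein[!catalog$precursors$reference])
  setNames(rep(level, length(prots)), prots)
}

# data.frame of decoy/absent fragment keys for baseline-trace materialization
extra_keys <- function(library) {
  a <- library$assays
  sel <- a$decoy | grepl("^ABSENT", a$protein)
  f <- library$fragments[library$fragments$assay_id %in% a$assay_id[sel], ,
                         drop = FALSE]
  data.frame(
    precursor_mz = a$precursor_mz[match(f$assay_id, a$assay_id)],
    mz = f$mz
  )
}

# --- mixed-model simulation ---------------------------------------------

# balanced long-format log2 data: fixed sample/precursor effects, random run
# (nested in sample), iid residuals
make_lmm_data <- function(n_samples = 8, p = 5, r = 3,
                          sigma2 = 0.04, sigma2_run = 0.01,
                          sample_effects = rep(0, n_samples),
                          mu = 10) {
  d <- expand.grid(
    sample = sprintf("S%d", seq_len(n_samples)),
    precursor = sprintf("P%d", seq_len(p)),
    rep = seq_len(r),
    stringsAsFactors = FALSE
  )
  d$run <- paste0(d$sample, "_", d$rep)
  run_eff <- stats::rnorm(n_samples * r, 0, sqrt(sigma2_run))
  names(run_eff) <- unique(d$run)
  prec_eff <- seq_len(p) * 0.3
  d$value <- mu +
    sample_effects[as.integer(sub("S", "", d$sample))] +
    prec_eff[as.integer(sub("P", "", d$precursor))] +
    run_eff[d$run] +
    stats::rnorm(nrow(d), 0, sqrt(sigma2))
  d[, c("sample", "precursor", "run", "value")]
}

# independent brute-force REML oracle: profiled -2*REML criterion on a grid
# over lambda = sigma2_run / sigma2, iteratively refined
reml_grid_oracle <- function(data, n_stages = 40, grid_n = 31, hi0 = 10) {
  X <- stats::model.matrix(~ sample + precursor, data)
  Z <- stats::model.matrix(~ 0 + run, data)
  y <- data$value
  n <- length(y); px <- qr(X)$rank
  crit <- function(lam) {
    W <- diag(n) + lam * tcrossprod(Z)
    cW <- chol(W)
    Wi_X <- backsolve(cW, forwardsolve(t(cW), X))
    XtWiX <- crossprod(X, Wi_X)
    beta <- solve(XtWiX, crossprod(Wi_X, y))
    resid <- y - X %*% beta
    Wi_r <- backsolve(cW, forwardsolve(t(cW), resid))
    s2 <- drop(crossprod(resid, Wi_r)) / (n - px)
    ld_W <- 2 * sum(log(diag(cW)))
    ld_X <- as.numeric(determinant(XtWiX, logarithm = TRUE)$modulus)
    list(val = (n - px) * log(s2) + ld_W + ld_X, s2 = s2)
  }
  lo <- 0; hi <- hi0
  for (stage in seq_len(n_stages)) {
    grid <- seq(lo, hi, length.out = grid_n)
    vals <- vapply(grid, function(l) crit(l)$val, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(grid_n, i + 1L)]
  }
  lam <- grid[i]
  s2 <- crit(lam)$s2
  c(sigma2 = s2, sigma2_run = lam * s2)
}

# closed-form balanced two-stage statistic: average precursors per run, then
# a two-sample t on run-level means with the variance pooled over all samples
two_stage_t <- function(data, a, b) {
  rl <- stats::aggregate(value ~ sample + run, data, mean)
  r <- table(rl$sample)[[1]]
  n_s <- length(unique(rl$sample))
  msw <- sum(tapply(rl$value, rl$sample,
                    function(v) sum((v - mean(v))^2))) / (n_s * (r - 1))
  est <- mean(rl$value[rl$sample == a]) - mean(rl$value[rl$sample == b])
  list(t = est / sqrt(2 * msw / r), df = n_s * (r - 1), estimate = est)
}

# --- shared heavy experiments (used by the acceptance checks) ------------

fdr_experiment_memo <- function() {
  memo_fixture("fdr_experiment_20seeds", fdr_experiment(seeds = 1:20))
}

# --- end-to-end benchmarks (shared by several checks) --------------------

# Desk-scale benchmark: like the full design but a 60-min gradient and a
# reduced (but still dominant) constant background, so the invariant-majority
# assumption behind local normalization holds as it does in the real
# experiment where the background proteome dwarfs the 12 spike-ins.
small_benchmark_config <- function(seed = 1L, ...) {
  benchmark_config(
    seed = seed,
    gradient_length = 60,
    design = list(n_background = 40L),
    catalog = list(n_absent_proteins = 3L),
    ...
  )
}

default_benchmark <- function() {
  memo_fixture("default_benchmark", {
    suppressWarnings(run_benchmark(small_benchmark_config(seed = 1L),
                                   verbose = FALSE))
  })
}

zero_noise_benchmark <- function() {
  memo_fixture("zero_noise_benchmark", {
    suppressWarnings(run_benchmark(
      small_benchmark_config(
        seed = 1L,
        noise = list(rt_jitter = 0, intensity_cv = 0, baseline_rate = 0,
                     interference_rate = 0),
        dda = list(p_max = 1, mid_log2 = -20, rt_sd = 0, intensity_cv = 0,
                   chimeric_rate = 0),
        # zero-noise runs leave (almost) no scored decoys, so the
        # target-decoy q-value is not meaningful; quantification is gated
        # open (and needs no normalization), as in the noise-free
        # completeness conventions
        quant = list(fdr_cutoff = 1, normalize = FALSE),
        compare_dda = FALSE
      ),
      verbose = FALSE
    ))
  })
}
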