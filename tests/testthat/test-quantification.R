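# Quantification matrices, local normalization, and completeness/CV metrics.

mk_scored <- function(run_id, assays, q, area, rt = seq_along(assays)) {
  data.frame(
    assay_id = assays, peptide = assays, charge = 2L,
    protein = sub("_.*", "", assays), decoy = FALSE, run_id = run_id,
    apex_rt = rt, qvalue = q, quant_area = area, stringsAsFactors = FALSE
  )
}

mk_qm <- function(values, sample, replicate = NULL, rt = NULL,
                  protein = NULL) {
  qm <- list(
    values = values,
    sample = setNames(sample, colnames(values)),
    replicate = setNames(
      if (is.null(replicate)) seq_along(sample) else replicate,
      colnames(values)),
    protein = setNames(
      if (is.null(protein)) sub("_.*", "", rownames(values)) else protein,
      rownames(values)),
    row_rt = setNames(
      if (is.null(rt)) seq_len(nrow(values)) else rt, rownames(values))
  )
  class(qm) <- "quant_matrix"
  qm
}

test_that("quantify places cells only where q passes and leaves gaps", {
  runs <- list(
    R1 = mk_scored("R1", c("P1_a", "P2_a"), q = c(0.001, 0.001), area = c(10, 20)),
    R2 = mk_scored("R2", c("P1_a", "P2_a"), q = c(0.001, 0.5), area = c(11, 21))
  )
  info <- data.frame(run_id = c("R1", "R2"), sample = c("S1", "S2"))
  qm <- quantify(runs, info, fdr_cutoff = 0.01)
  expect_equal(dim(qm$values), c(2L, 2L))
  expect_equal(qm$values["P1_a", ], c(R1 = 10, R2 = 11))
  expect_true(is.na(qm$values["P2_a", "R2"]))   # exactly one missing cell
  expect_equal(sum(is.na(qm$values)), 1L)
})

test_that("pipeline cells are proportional to design concentrations at zero noise", {
  b <- zero_noise_benchmark()
  qm <- b$quant_raw
  conc <- b$design$concentrations
  sam <- qm$sample[colnames(qm$values)]
  # exact proportionality only holds for precursors whose fragment keys are
  # free of chimeric collisions (no other protein's fragment within twice
  # the 20 ppm extraction tolerance)
  la <- b$library$assays
  lf <- b$library$fragments[
    b$library$fragments$assay_id %in% la$assay_id[!la$decoy], ]
  i <- match(lf$assay_id, la$assay_id)
  lf$protein <- la$protein[i]
  lf$window <- assign_window(la$precursor_mz[i], default_hrm_scheme())
  collided <- vapply(unique(lf$assay_id), function(aid) {
    sel <- lf$assay_id == aid
    own <- lf$mz[sel]
    other <- lf$mz[lf$window == lf$window[sel][1] &
                     lf$protein != lf$protein[sel][1]]
    any(vapply(own, function(m) any(abs(other - m) / m < 40e-6), logical(1)))
  }, logical(1))
  names(collided) <- unique(lf$assay_id)
  spikes <- rownames(qm$values)[grepl("^SPIKE", qm$protein)]
  clean <- spikes[!collided[spikes]]
  expect_gt(length(clean), 10)
  for (a in clean) {
    v <- qm$values[a, ]
    expected <- conc[qm$protein[[a]], sam]
    ok <- !is.na(v)
    expect_gt(sum(ok), 12)
    ratio <- v[ok] / expected[ok]
    expect_lt(diff(range(ratio)) / median(ratio), 1e-6)
  }
})

test_that("a constant loading offset is removed exactly", {
  set.seed(3)
  base <- 2^rnorm(60, 10, 1)
  v <- cbind(A = base, B = 2 * base, C = 0.5 * base)
  rownames(v) <- sprintf("P%02d_a", 1:60)
  qm <- mk_qm(v, sample = c("S1", "S2", "S3"))
  qn <- local_normalize(qm)
  expect_equal(qn$values[, "B"] / qn$values[, "A"], rep(1, 60),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(qn$values[, "C"] / qn$values[, "A"], rep(1, 60),
               tolerance = 1e-9, ignore_attr = TRUE)
  # idempotence on balanced input
  qn2 <- local_normalize(qn)
  expect_equal(qn2$values, qn$values, tolerance = 1e-9)
  # rank order within each run is preserved under the flat correction
  for (j in 1:3) {
    expect_equal(order(qn$values[, j]), order(qm$values[, j]))
  }
})

test_that("an RT-dependent bias is flattened by the running-median curve", {
  set.seed(4)
  n <- 300
  rt <- sort(runif(n, 0, 100))
  base <- 2^rnorm(n, 10, 1)
  bias <- 2^(0.01 * rt - 0.5)      # linear in rt on the log2 scale
  v <- cbind(A = base, B = base * bias)
  rownames(v) <- sprintf("P%03d_a", 1:n)
  qm <- mk_qm(v, sample = c("S1", "S2"), rt = rt)
  qn <- local_normalize(qm, window_frac = 0.1)
  lr <- log2(qn$values[, "B"] / qn$values[, "A"])
  for (w in split(seq_len(n), cut(rt, 5))) {
    expect_lt(abs(median(lr[w])), log2(1.05))
  }
})

test_that("sparse matrices fall back to global median normalization", {
  set.seed(5)
  v <- matrix(2^rnorm(40, 10, 1), 20, 2,
              dimnames = list(sprintf("P%02d_a", 1:20), c("A", "B")))
  v[1:15, 2] <- NA
  qm <- mk_qm(v, sample = c("S1", "S2"))
  expect_warning(local_normalize(qm), "global median")
})

test_that("completeness and CV metrics match hand computation", {
  v <- matrix(c(100, 110, 90, 50, NA, 60), nrow = 2, byrow = TRUE,
              dimnames = list(c("P1_a", "P2_a"), c("R1", "R2", "R3")))
  qm <- mk_qm(v, sample = c("S1", "S1", "S1"), replicate = c(1, 2, 3))
  m <- completeness_and_cv(qm)
  expect_equal(m$missing_fraction, 1 / 6)
  expect_equal(m$full_profiles$complete_rows, c(2L, 1L, 1L))
  # CV oracle: sd/mean of (100, 110, 90) = 10/100
  expect_equal(m$cv$cv[m$cv$assay_id == "P1_a"], 0.1)

  # complete matrix: no missing values, full profiles everywhere
  v2 <- matrix(1:12, 3, 4, dimnames = list(paste0("P", 1:3, "_a"),
                                           paste0("R", 1:4)))
  m2 <- completeness_and_cv(mk_qm(v2, sample = rep(c("S1", "S2"), each = 2)))
  expect_equal(m2$missing_fraction, 0)
  expect_equal(m2$full_profiles$complete_rows, rep(3L, 4))
})

test_that("observed replicate CV tracks the simulated intensity CV", {
  # lognormal multiplicative noise: observed CV within a band around the
  # generator parameter (small-CV approximation)
  set.seed(6)
  cvs <- c(0.05, 0.20)
  bands <- list(c(0.03, 0.07), c(0.15, 0.25))
  for (i in seq_along(cvs)) {
    sdlog <- sqrt(log(1 + cvs[i]^2))
    n <- 400
    v <- matrix(1000 * exp(rnorm(n * 6, 0, sdlog) - sdlog^2 / 2), n, 6,
                dimnames = list(sprintf("P%03d_a", 1:n), paste0("R", 1:6)))
    qm <- mk_qm(v, sample = rep(c("S1", "S2"), each = 3),
                replicate = rep(1:3, 2))
    m <- completeness_and_cv(qm)
    med <- median(m$cv$cv)
    expect_gt(med, bands[[i]][1])
    expect_lt(med, bands[[i]][2])
  }
})

test_that("end-to-end zero-noise pipeline has no missing values and ~0 CVs", {
  b <- zero_noise_benchmark()
  m <- completeness_and_cv(b$quant_raw)
  # absent-protein assays never pass, all present assays always do
  expect_equal(m$missing_fraction, 0)
  expect_lt(median(m$cv$cv), 1e-6)
  expect_false(any(grepl("^ABSENT", b$quant$protein)))
})

test_that("quant matrix round-trips as wide TSV", {
  v <- matrix(c(1.5, 2.5, NA, 4), 2, 2,
              dimnames = list(c("P1_a", "P2_a"), c("R1", "R2")))
  qm <- mk_qm(v, sample = c("S1", "S2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_tsv(qm, path)
  df <- read.delim(path, check.names = FALSE)
  expect_equal(df$assay_id, rownames(v))
  expect_equal(df$R1, unname(v[, "R1"]))
  expect_true(is.na(df$R2[1]))
})
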