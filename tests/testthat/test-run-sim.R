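# DIA run and DDA PSM simulators: signal placement, linearity, conservation,
# reproducibility, and shotgun undersampling.

noiseless <- list(rt_jitter = 0, intensity_cv = 0, baseline_rate = 0,
                  interference_rate = 0)

test_that("noiseless fragment traces peak exactly at the recorded apex", {
  cat <- small_catalog()
  sch <- default_hrm_scheme()
  run <- simulate_dia_run(cat, flat_concentrations(cat), sch,
                          noise = noiseless, gradient_length = 40, seed = 1)
  tr <- run$truth[run$truth$present, ]
  ft <- run$fragment_truth
  shared <- ft$key[duplicated(ft$key)]
  set.seed(2)
  for (aid in sample(tr$assay_id, 10)) {
    w <- tr$window[tr$assay_id == aid]
    apex <- tr$apex_rt[tr$assay_id == aid]
    keys <- setdiff(ft$key[ft$assay_id == aid], shared)
    for (key in keys[seq_len(min(2, length(keys)))]) {
      y <- run$windows[[w]]$traces[match(key, run$windows[[w]]$keys), ]
      # a single local maximum, at the apex cycle
      expect_equal(run$cycle_times[which.max(y)], apex,
                   tolerance = run$scheme$cycle_period / 60)
      expect_length(hrmdia:::.local_maxima(y), 1L)
    }
  }
})

test_that("absent proteins leave only baseline in their traces", {
  cat <- small_catalog()
  sch <- default_hrm_scheme()
  run <- simulate_dia_run(cat, flat_concentrations(cat), sch,
                          noise = noiseless, gradient_length = 40, seed = 1)
  absent <- cat$precursors$assay_id[cat$precursors$absent]
  f <- cat$fragments[cat$fragments$assay_id %in% absent, ]
  present_keys <- unique(run$fragment_truth$key)
  for (i in seq_len(nrow(f))) {
    key <- round(f$mz[i], 4)
    if (key %in% present_keys) next  # shared key with a present fragment
    w <- run$truth$window[run$truth$assay_id == f$assay_id[i]]
    if (is.na(w)) next
    r <- match(key, run$windows[[w]]$keys)
    expect_false(is.na(r))
    expect_equal(sum(run$windows[[w]]$traces[r, ]), 0)
  }
})

test_that("fragment areas scale linearly with concentration", {
  cat <- small_catalog()
  sch <- default_hrm_scheme()
  conc1 <- flat_concentrations(cat, 10)
  conc2 <- conc1 * 2
  r1 <- simulate_dia_run(cat, conc1, sch, noise = noiseless,
                         gradient_length = 40, reference_level = 10, seed = 5)
  r2 <- simulate_dia_run(cat, conc2, sch, noise = noiseless,
                         gradient_length = 40, reference_level = 20, seed = 5)
  # identical seed + zero CV: every trace doubles exactly
  for (w in seq_along(r1$windows)) {
    expect_equal(r2$windows[[w]]$traces, 2 * r1$windows[[w]]$traces,
                 tolerance = 1e-12)
  }
})

test_that("total injected signal is conserved at zero noise", {
  cat <- small_catalog()
  sch <- default_hrm_scheme()
  conc <- flat_concentrations(cat, 7)
  run <- simulate_dia_run(cat, conc, sch, noise = noiseless,
                          gradient_length = 40, seed = 3)
  # expected: sum over present fragments of height * Gaussian mass on the grid
  total_observed <- sum(vapply(run$windows,
                               function(w) sum(w$traces), numeric(1)))
  ft <- run$fragment_truth
  tr <- run$truth
  dt_sigma <- run$noise$peak_sigma
  expected <- 0
  tt <- run$cycle_times
  for (aid in unique(ft$assay_id)) {
    apex <- tr$apex_rt[tr$assay_id == aid]
    # injection support: same half-open index convention as the generator
    i0 <- max(1L, findInterval(apex - 4.5 * dt_sigma, tt))
    i1 <- min(length(tt), findInterval(apex + 4.5 * dt_sigma, tt) + 1L)
    shape_sum <- sum(exp(-(tt[i0:i1] - apex)^2 / (2 * dt_sigma^2)))
    expected <- expected + sum(ft$height[ft$assay_id == aid]) * shape_sum
  }
  expect_equal(total_observed, expected, tolerance = 1e-8)
})

test_that("runs are reproducible by seed and vary across seeds", {
  cat <- small_catalog()
  sch <- default_hrm_scheme()
  conc <- flat_concentrations(cat)
  a <- simulate_dia_run(cat, conc, sch, gradient_length = 30, seed = 8)
  b <- simulate_dia_run(cat, conc, sch, gradient_length = 30, seed = 8)
  c <- simulate_dia_run(cat, conc, sch, gradient_length = 30, seed = 9)
  expect_identical(a$windows, b$windows)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$truth$apex_rt, c$truth$apex_rt))
})

test_that("missing concentrations are rejected", {
  cat <- small_catalog()
  conc <- flat_concentrations(cat)
  expect_error(
    simulate_dia_run(cat, conc[-1], default_hrm_scheme(), seed = 1),
    "no concentration"
  )
})

test_that("DDA with certain detection yields one exact PSM per peptide", {
  cat <- small_catalog()
  design <- make_profiling_design(
    background_proteins = unique(
      cat$precursors$protein[!cat$precursors$reference &
                               !cat$precursors$absent]),
    spike_proteins = character(0), mix_sizes = c(0L, 0L, 0L)
  )
  ro <- block_randomize(design, 1, seed = 2)
  psms <- simulate_dda_psms(
    cat, design, ro,
    sampling = list(p_max = 1, mid_log2 = -50, rt_sd = 0, intensity_cv = 0,
                    chimeric_rate = 0),
    gradient_length = 40, seed = 4
  )
  present <- cat$precursors[!cat$precursors$absent, ]
  per_run <- table(psms$psms$run_id)
  expect_true(all(per_run == nrow(present)))
  # observed RT equals the mapped truth
  m <- merge(psms$psms, present[, c("peptide", "charge", "irt")])
  rt_map <- hrmdia:::.default_rt_map(40, cat$irt_span)
  expect_equal(m$rt, rt_map[["intercept"]] + rt_map[["slope"]] * m$irt,
               tolerance = 1e-9)
})

test_that("detection counts follow the binomial at p = 0.5", {
  cat <- simulate_catalog(n_background_proteins = 200,
                          peptides_per_protein = list(mean = 5, min = 2),
                          n_reference_peptides = 3, seed = 31)
  prots <- unique(cat$precursors$protein[!cat$precursors$reference])
  design <- make_profiling_design(background_proteins = prots,
                                  spike_proteins = character(0),
                                  mix_sizes = c(0L, 0L, 0L), n_samples = 2)
  ro <- block_randomize(design, 1, seed = 2)
  # logistic midpoint at the (constant) abundance gives p = p_max * 0.5
  psms <- simulate_dda_psms(
    cat, design, ro,
    sampling = list(p_max = 1, mid_log2 = log2(20), slope_log2 = 1),
    gradient_length = 40, seed = 6
  )
  n_pep <- sum(!cat$precursors$reference)
  n_det <- sum(!psms$psms$reference & psms$psms$run_id == ro$run_id[1])
  ci <- qbinom(c(0.005, 0.995), n_pep, 0.5)
  expect_gt(n_det, ci[1])
  expect_lt(n_det, ci[2])
})

test_that("absent peptides never appear in PSM tables", {
  cat <- small_catalog()
  prots <- unique(cat$precursors$protein[!cat$precursors$reference &
                                           !cat$precursors$absent])
  design <- make_profiling_design(background_proteins = prots,
                                  spike_proteins = character(0),
                                  mix_sizes = c(0L, 0L, 0L))
  ro <- block_randomize(design, 3, seed = 2)
  psms <- simulate_dda_psms(cat, design, ro, gradient_length = 40, seed = 4)
  absent_peps <- cat$precursors$peptide[cat$precursors$absent]
  expect_false(any(psms$psms$peptide %in% absent_peps))
  # PSM table text round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, path)
  psms2 <- read_psm_table(path)
  expect_equal(nrow(psms2$psms), nrow(psms$psms))
  expect_equal(sort(psms2$fragments$mz), sort(psms$fragments$mz),
               tolerance = 1e-9)
})
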