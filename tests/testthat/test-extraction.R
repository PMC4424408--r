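# XIC extraction, dynamic iRT calibration, peak-group detection and
# interference handling.

# synthetic XIC matrix: Gaussian peaks at given apexes with per-fragment
# heights; the direct construction oracle for the peak detector
mk_xics <- function(times, apexes, heights, sigma = 0.1, baseline = 0) {
  nf <- length(heights)
  m <- matrix(baseline, nf, length(times))
  for (a in apexes) {
    for (f in seq_len(nf)) {
      m[f, ] <- m[f, ] + heights[f] * exp(-(times - a)^2 / (2 * sigma^2))
    }
  }
  m
}

sim_with_lib <- function(seed = 1, noise = list(), gradient = 40,
                         catalog = small_catalog()) {
  lib <- generate_decoys(library_from_catalog(catalog), seed = 3)
  run <- simulate_dia_run(catalog, flat_concentrations(catalog),
                          default_hrm_scheme(), noise = noise,
                          gradient_length = gradient,
                          extra_mz = extra_keys(lib), seed = seed)
  list(run = run, lib = lib, catalog = catalog)
}

test_that("extract_xic returns the simulated signal and obeys tolerance", {
  s <- sim_with_lib(noise = list(rt_jitter = 0, intensity_cv = 0,
                                 baseline_rate = 0, interference_rate = 0))
  run <- s$run
  tr <- run$truth[run$truth$present, ]
  ft <- run$fragment_truth
  aid <- tr$assay_id[5]
  w <- tr$window[tr$assay_id == aid]
  mz <- ft$mz[ft$assay_id == aid][1]
  x <- extract_xic(run, mz, w)
  expect_s3_class(x, "chromatogram")
  expect_equal(x$times[which.max(x$intensities)],
               tr$apex_rt[tr$assay_id == aid],
               tolerance = run$scheme$cycle_period / 60)

  # an m/z with no signal anywhere gives all zeros
  x0 <- extract_xic(run, 1799.77, w)
  expect_true(all(x0$intensities == 0))

  # doubling the tolerance can only add signal
  x1 <- extract_xic(run, mz, w, tolerance_ppm = 20)
  x2 <- extract_xic(run, mz, w, tolerance_ppm = 40)
  expect_true(all(x2$intensities >= x1$intensities - 1e-12))

  # restriction and clipping
  expect_warning(
    xr <- extract_xic(run, mz, w, rt_center = 1, rt_half_width = 5),
    "clipped"
  )
  expect_true(all(xr$times <= 6))
})

test_that("noiseless calibration recovers the true map at the floor width", {
  s <- sim_with_lib(noise = list(rt_jitter = 0, intensity_cv = 0,
                                 baseline_rate = 0, interference_rate = 0))
  cal <- calibrate_run(s$run, s$lib)
  truth <- s$run$rt_map
  # fitted inverse map: irt = slope * rt + intercept
  expect_equal(cal$fit$slope, 1 / truth[["slope"]], tolerance = 1e-3)
  expect_equal(-cal$fit$intercept / cal$fit$slope, truth[["intercept"]],
               tolerance = 0.05)
  # residual limited only by the cycle-time discretization of the apex
  expect_lt(cal$fit$residual_sd, 0.1)
  irt_span <- diff(range(s$lib$assays$irt[!s$lib$assays$decoy]))
  expect_equal(cal$half_width_irt, 0.01 * irt_span)
})

test_that("extraction half-width grows with retention-time jitter", {
  hw <- vapply(c(0, 0.1, 0.3), function(sg) {
    s <- sim_with_lib(seed = 17, noise = list(rt_jitter = sg))
    calibrate_run(s$run, s$lib)$half_width_irt
  }, numeric(1))
  expect_true(all(diff(hw) >= 0))
  expect_gt(hw[3], hw[1])
})

test_that("calibration fails without locatable anchors", {
  cat <- small_catalog()
  lib <- library_from_catalog(cat)
  lib$assays <- lib$assays[lib$assays$protein != "IRT_KIT", ]
  run <- simulate_dia_run(cat, flat_concentrations(cat),
                          default_hrm_scheme(), gradient_length = 30,
                          seed = 1)
  expect_error(calibrate_run(run, lib), "calibration failed")
})

test_that("a clean constructed peak yields one near-perfect candidate", {
  times <- seq(0, 10, by = 0.05)
  heights <- c(100, 80, 60, 40, 20)
  xm <- mk_xics(times, apexes = 5, heights = heights)
  cand <- detect_peak_groups(xm, times, heights, expected_rt = 5,
                             irt_per_min = 2)
  expect_equal(length(cand), 1L)
  g <- cand[[1]]
  expect_equal(g$apex_rt, 5, tolerance = 0.051)
  expect_gt(g$subscores[["co_elution"]], 0.99)
  expect_gt(g$subscores[["library_correlation"]], 0.99)
  expect_lt(g$subscores[["irt_deviation"]], 0.11)
  # areas proportional to heights
  expect_equal(g$areas / g$areas[1], heights / heights[1], tolerance = 1e-6)
})

test_that("two disjoint peaks are found with correct apex ordering", {
  times <- seq(0, 10, by = 0.05)
  h <- c(50, 40, 30)
  xm <- mk_xics(times, apexes = 3, heights = h) +
    mk_xics(times, apexes = 7, heights = h * 2)
  cand <- detect_peak_groups(xm, times, h, expected_rt = NA)
  expect_equal(length(cand), 2L)
  # ranked by height: the taller (7 min) peak first
  expect_equal(cand[[1]]$apex_rt, 7, tolerance = 0.051)
  expect_equal(cand[[2]]$apex_rt, 3, tolerance = 0.051)
  expect_error(detect_peak_groups(xm[1:2, ], times, h[1:2]), "nrow")
})

test_that("area additivity: scaling traces scales all areas", {
  times <- seq(0, 10, by = 0.05)
  h <- c(50, 40, 30, 20)
  xm <- mk_xics(times, apexes = 5, heights = h)
  g1 <- detect_peak_groups(xm, times, h)[[1]]
  g2 <- detect_peak_groups(3 * xm, times, h)[[1]]
  expect_equal(g2$areas, 3 * g1$areas, tolerance = 1e-12)
})

test_that("decoy assays score poorly against real signal", {
  s <- sim_with_lib(seed = 23)
  cal <- calibrate_run(s$run, s$lib)
  sc <- score_run(s$run, s$lib, cal)
  present <- s$run$truth$assay_id[s$run$truth$present &
    !s$run$truth$assay_id %in%
      s$catalog$precursors$assay_id[s$catalog$precursors$reference]]
  co_t <- sc$co_elution[sc$assay_id %in% present]
  co_d <- sc$co_elution[sc$decoy]
  expect_gte(length(co_d), 50)
  expect_lt(median(co_d), 0.4)
  expect_gt(median(co_t), median(co_d) + 0.3)
})

test_that("interference detection flags the injected fragment only", {
  times <- seq(0, 10, by = 0.05)
  h <- c(100, 80, 60, 40, 20)
  xm <- mk_xics(times, apexes = 5, heights = h)
  # fragment 4 receives a strong co-isolated shoulder inside the peak
  xm[4, ] <- xm[4, ] + 150 * exp(-(times - 5.25)^2 / (2 * 0.1^2))
  g <- detect_peak_groups(xm, times, h)[[1]]
  g <- detect_interference(g, xm, times, h)
  expect_equal(which(g$interference_flags), 4L)
  share_kept <- sum(h[-4]) / sum(h)
  expect_equal(g$quant_area, sum(g$areas[-4]) / share_kept)

  # clean data: no flags
  xm0 <- mk_xics(times, apexes = 5, heights = h)
  g0 <- detect_peak_groups(xm0, times, h)[[1]]
  g0 <- detect_interference(g0, xm0, times, h)
  expect_false(any(g0$interference_flags))

  # retention floor: a 3-fragment group can never be flagged
  xm3 <- mk_xics(times, apexes = 5, heights = h[1:3])
  xm3[2, ] <- xm3[2, ] + 500 * exp(-(times - 5.5)^2 / (2 * 0.1^2))
  g3 <- detect_peak_groups(xm3, times, h[1:3])[[1]]
  g3 <- detect_interference(g3, xm3, times, h[1:3])
  expect_false(any(g3$interference_flags))
})

test_that("interference correction improves quantification accuracy", {
  s <- sim_with_lib(seed = 29, noise = list(interference_rate = 0.1,
                                            interference_mag = 2))
  cal <- calibrate_run(s$run, s$lib)
  sc_on <- score_run(s$run, s$lib, cal, interference_correction = TRUE)
  sc_off <- score_run(s$run, s$lib, cal, interference_correction = FALSE)
  # truth: the clean injected height total per assay (interferent excluded)
  # is proportional to the ideal quantity; compare median-centered log
  # ratios so the area-per-height constant cancels
  ft <- s$run$fragment_truth
  clean <- tapply(ft$height, ft$assay_id, sum)
  err <- function(sc) {
    m <- match(names(clean), sc$assay_id)
    ok <- !is.na(m) & sc$quant_area[m] > 0
    lr <- log2(sc$quant_area[m[ok]] / as.numeric(clean)[ok])
    abs(lr - median(lr))
  }
  e_on <- err(sc_on); e_off <- err(sc_off)
  expect_lt(median(e_on), median(e_off) + 1e-9)
})
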