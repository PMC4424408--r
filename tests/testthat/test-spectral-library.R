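# iRT calibration fits, library consensus building and filters, scrambled
# decoys, modification assays, and the tabular library format.

mk_psms <- function(runs, peptide = "SAMPLEK", charge = 2L, rt = 30,
                    nfrag = 8L, protein = "P1", intensity = 100,
                    irt_true = 50) {
  frag <- data.frame(
    ion_type = rep(c("y", "b"), length.out = nfrag),
    ordinal = rep(2:((nfrag %/% 2) + 2), length.out = nfrag),
    frag_charge = 1L
  )
  frag <- frag[!duplicated(frag), ][seq_len(nfrag), ]
  frag$mz <- fragment_mz(peptide, frag$ion_type, frag$ordinal, frag$frag_charge)
  rt <- rep_len(rt, length(runs))
  intensity <- rep_len(intensity, length(runs))
  psms <- do.call(rbind, lapply(seq_along(runs), function(i) {
    data.frame(
      psm_id = sprintf("%s_p%d", runs[i], i), run_id = runs[i], sample = "S1",
      peptide = peptide, charge = charge,
      precursor_mz = precursor_mz(peptide, charge), protein = protein,
      reference = FALSE, irt_true = irt_true, rt = rt[i], score = 0.9,
      total_intensity = intensity[i], stringsAsFactors = FALSE
    )
  }))
  frags <- do.call(rbind, lapply(psms$psm_id, function(id) {
    f <- frag; f$psm_id <- id
    f$intensity <- f$mz * 0 + seq(nfrag, 1)  # fixed descending pattern
    f
  }))
  out <- list(psms = psms, fragments = frags)
  class(out) <- "psm_table"
  out
}

identity_maps <- function(run_ids) {
  # irt = 1 * rt + 0
  setNames(lapply(run_ids, function(r) {
    structure(list(slope = 1, intercept = 0, residual_sd = 0, n_used = 3L),
              class = "irt_fit")
  }), run_ids)
}

test_that("iRT map recovers an exact line and resists a gross outlier", {
  rt <- seq(5, 50, length.out = 10)
  irt <- 2 * rt + 10
  f <- fit_irt_map(rt, irt)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 10, tolerance = 1e-10)
  expect_equal(f$residual_sd, 0, tolerance = 1e-10)

  # one gross outlier, robust refit recovers the clean line
  f2 <- fit_irt_map(c(rt, 30), c(irt, 200), robust = TRUE)
  expect_equal(f2$slope, 2, tolerance = 1e-6)
  expect_equal(f2$intercept, 10, tolerance = 1e-6)
  expect_equal(f2$n_used, 10L)

  expect_error(fit_irt_map(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_irt_map(rep(3, 5), 1:5), "degenerate")

  # idempotence: refitting points generated from the fitted map is exact
  f3 <- fit_irt_map(rt, predict_irt(f, rt))
  expect_equal(f3$slope, f$slope, tolerance = 1e-9)
  expect_equal(f3$intercept, f$intercept, tolerance = 1e-9)
})

test_that("consensus of identical observations is that observation", {
  psms <- mk_psms(c("R1", "R2", "R3"), rt = 42)
  lib <- build_library(psms, identity_maps(c("R1", "R2", "R3")))
  expect_equal(nrow(lib$assays), 1L)
  expect_equal(sum(lib$fragments$assay_id == lib$assays$assay_id), 8L)
  expect_equal(lib$assays$irt, 42)
  expect_equal(lib$assays$n_obs, 3L)
  # intensities renormalized to max 1, sorted decreasing
  fr <- lib$fragments
  expect_equal(max(fr$rel_intensity), 1)
  expect_true(all(diff(fr$rel_intensity) <= 0))
})

test_that("under-fragmented assays are excluded at the six-fragment filter", {
  psms <- mk_psms("R1", nfrag = 5L)
  lib <- suppressWarnings(build_library(psms, identity_maps("R1")))
  expect_equal(nrow(lib$assays), 0L)
  lib2 <- build_library(psms, identity_maps("R1"), min_fragments = 5L)
  expect_equal(nrow(lib2$assays), 1L)
})

test_that("iRT outliers are discarded from the consensus", {
  psms <- mk_psms(c("R1", "R2", "R3", "R4"), rt = c(50, 50.1, 49.9, 90))
  lib <- build_library(psms, identity_maps(c("R1", "R2", "R3", "R4")))
  # oracle: median/robust-SD on (50, 50.1, 49.9, 90): the 90 sits > 5 SD out
  obs <- c(50, 50.1, 49.9, 90)
  expect_true(abs(90 - median(obs)) > 5 * mad(obs))
  expect_equal(lib$assays$n_obs, 3L)
  expect_equal(lib$assays$irt, median(c(50, 50.1, 49.9)))
})

test_that("within-run duplicates resolve to the most intense identification", {
  psms <- mk_psms(c("R1", "R1"), rt = c(30, 60), intensity = c(10, 500))
  lib <- build_library(psms, identity_maps("R1"))
  expect_equal(nrow(lib$assays), 1L)
  expect_equal(lib$assays$irt, 60)  # the intense copy's retention time
})

test_that("library filters are monotone in their thresholds", {
  cat <- small_catalog()
  prots <- unique(cat$precursors$protein[!cat$precursors$reference &
                                           !cat$precursors$absent])
  design <- make_profiling_design(background_proteins = prots,
                                  spike_proteins = character(0),
                                  mix_sizes = c(0L, 0L, 0L))
  ro <- block_randomize(design, 3, seed = 2)
  psms <- simulate_dda_psms(cat, design, ro, gradient_length = 40, seed = 4)
  maps <- lapply(split(psms$psms, psms$psms$run_id), function(d) {
    refs <- d[d$reference, ]
    fit_irt_map(refs$rt, refs$irt_true)
  })
  n_assay <- function(minf, sdlim) {
    nrow(suppressWarnings(
      build_library(psms, maps, min_fragments = minf, irt_sd_limit = sdlim)
    )$assays)
  }
  expect_gte(n_assay(5, 5), n_assay(6, 5))
  expect_gte(n_assay(6, 5), n_assay(7, 5))
  expect_gte(n_assay(6, 5), n_assay(6, 1))
})

test_that("library growth is non-decreasing and saturates on repeats", {
  psms <- mk_psms(c("R1", "R2", "R3"))
  g <- library_growth(psms, identity_maps(c("R1", "R2", "R3")))
  expect_equal(g$runs_used, 1:3)
  expect_true(all(diff(g$peptides) >= 0))
  expect_equal(g$peptides, rep(1L, 3))  # identical runs: flat after run 1

  # disjoint peptides: strictly increasing
  p1 <- mk_psms("R1", peptide = "SAMPLEK")
  p2 <- mk_psms("R2", peptide = "ELVISLIVESK", nfrag = 8L)
  both <- list(psms = rbind(p1$psms, p2$psms),
               fragments = rbind(p1$fragments, p2$fragments))
  class(both) <- "psm_table"
  g2 <- library_growth(both, identity_maps(c("R1", "R2")))
  expect_equal(g2$peptides, 1:2)
})

test_that("scrambled decoys preserve composition and recompute fragments", {
  cat <- small_catalog()
  lib <- library_from_catalog(cat)
  lib <- generate_decoys(lib, seed = 13)
  a <- lib$assays
  tgt <- a[!a$decoy, ]; dec <- a[a$decoy, ]
  expect_equal(nrow(dec), nrow(tgt))  # 1:1, no decoy limit

  m <- match(paste0("DECOY_", tgt$assay_id), dec$assay_id)
  expect_false(any(is.na(m)))
  for (i in seq_len(nrow(tgt))) {
    dp <- dec$peptide[m[i]]; tp <- tgt$peptide[i]
    expect_equal(nchar(dp), nchar(tp))
    expect_equal(sort(strsplit(dp, "")[[1]]), sort(strsplit(tp, "")[[1]]))
    expect_equal(substr(dp, nchar(dp), nchar(dp)),
                 substr(tp, nchar(tp), nchar(tp)))  # C-terminus fixed
  }
  expect_true(mean(dec$peptide[m] == tgt$peptide) < 0.05)
  # composition preserved => identical precursor mass
  expect_equal(mapply(peptide_mass, dec$peptide[m]),
               mapply(peptide_mass, tgt$peptide), tolerance = 1e-9,
               ignore_attr = TRUE)
  # decoy iRT and intensities inherited
  expect_equal(dec$irt[m], tgt$irt)
})

test_that("decoy fragment ladders differ whenever prefix sums change", {
  # hand-built oracle on one 7-mer: scramble changes the b/y ladders
  lib0 <- list(
    assays = data.frame(
      assay_id = "SAMPLEK/2", peptide = "SAMPLEK", charge = 2L,
      precursor_mz = precursor_mz("SAMPLEK", 2), irt = 10, protein = "P1",
      proteotypic = TRUE, decoy = FALSE, n_obs = 1L, stringsAsFactors = FALSE
    ),
    fragments = data.frame(
      assay_id = "SAMPLEK/2", ion_type = c("y", "y", "b"), ordinal = c(3, 5, 4),
      frag_charge = 1L, mz = fragment_mz("SAMPLEK", c("y", "y", "b"),
                                         c(3, 5, 4)),
      rel_intensity = c(1, 0.5, 0.25), stringsAsFactors = FALSE
    ),
    provenance = list()
  )
  class(lib0) <- "spectral_library"
  lib <- generate_decoys(lib0, seed = 5)
  dp <- lib$assays$peptide[lib$assays$decoy]
  df <- lib$fragments[lib$fragments$assay_id == paste0("DECOY_", "SAMPLEK/2"), ]
  expect_equal(df$mz, fragment_mz(dp, df$ion_type, df$ordinal, df$frag_charge),
               tolerance = 1e-10)
  # prefix sums changed for this scramble -> ladder m/z differ from target
  expect_false(isTRUE(all.equal(sort(df$mz), sort(lib0$fragments$mz))))
})

test_that("library TSV round-trips", {
  cat <- small_catalog()
  lib <- generate_decoys(library_from_catalog(cat), seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library_tsv(lib, path)
  lib2 <- read_library_tsv(path)
  expect_equal(nrow(lib2$assays), nrow(lib$assays))
  expect_equal(lib2$assays$precursor_mz,
               lib$assays$precursor_mz[match(lib2$assays$assay_id,
                                             lib$assays$assay_id)],
               tolerance = 1e-9)
  expect_equal(sort(lib2$fragments$mz), sort(lib$fragments$mz),
               tolerance = 1e-9)
  expect_equal(sum(lib2$assays$decoy), sum(lib$assays$decoy))
})

test_that("variable-modification assays shift only covering fragments", {
  lib0 <- library_from_catalog(small_catalog())
  has_c <- grepl("C", lib0$assays$peptide, fixed = TRUE)
  mod <- modified_assays(lib0, "C8H7NO2", "C")
  expect_true(nrow(mod$assays) >= sum(has_c))
  delta <- modification_mass("C8H7NO2")
  i <- 1L
  aid <- mod$assays$assay_id[i]
  base <- sub("\\[C8H7NO2\\]", "", mod$assays$peptide[i])
  expect_equal(
    mod$assays$precursor_mz[i] - precursor_mz(base, mod$assays$charge[i]),
    delta / mod$assays$charge[i], tolerance = 1e-9
  )
  fr <- mod$fragments[mod$fragments$assay_id == aid, ]
  base_mz <- fragment_mz(base, fr$ion_type, fr$ordinal, fr$frag_charge)
  shift <- fr$mz - base_mz
  expect_true(all(abs(shift) < 1e-9 | abs(shift - delta / fr$frag_charge) < 1e-9))
  expect_true(any(abs(shift) > 1e-9))
})
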