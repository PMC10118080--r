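test_that("window half-widths combine relative and absolute terms", {
  w <- tolerance_windows()
  hw <- window_halfwidths(413.3429, 24.81, w)
  expect_equal(hw$mz_hw, 413.3429 * 5e-6 + 0.002, tolerance = 1e-12)
  expect_equal(hw$mz_hw, 0.0040667, tolerance = 1e-5)
  expect_equal(hw$rt_hw, 24.81 * 0.001 + 0.15, tolerance = 1e-12)
  expect_equal(hw$rt_hw, 0.17481, tolerance = 1e-7)
  w2 <- tolerance_windows(mz_ppm = 0, mz_mda = 0.002)
  expect_equal(window_halfwidths(100, 5, w2)$mz_hw, 0.002)
  expect_equal(window_halfwidths(100, 0, w)$rt_hw, w$rt_abs)
  expect_error(tolerance_windows(rt_rel = 0, rt_abs = 0), "positive")
})

test_that("greedy alignment merges and splits according to the windows", {
  two <- tibble::tibble(
    sample_id = c("s1", "s2"),
    mz = c(413.3429, 413.3440),
    rt = c(24.70, 24.90),
    height = c(1e5, 9e4), quality = 95)
  fm <- align_features(two)
  expect_equal(nrow(fm$consensus), 1)
  expect_equal(fm$consensus$n_members, 2)
  # intensity-weighted consensus coordinates
  expect_equal(fm$consensus$mz,
               sum(two$mz * two$height) / sum(two$height))
  far <- tibble::tibble(
    sample_id = c("s1", "s2"),
    mz = c(413.3429, 413.3600),
    rt = c(24.70, 24.75),
    height = c(1e5, 9e4), quality = 95)
  expect_equal(nrow(align_features(far)$consensus), 2)
})

test_that("a single sample aligns to itself, one column", {
  feats <- tibble::tibble(sample_id = "only",
                          mz = c(100.1, 200.2, 300.3),
                          rt = c(1, 2, 3), height = c(1, 2, 3) * 1e4,
                          quality = 90)
  fm <- align_features(feats)
  expect_equal(dim(fm), c(3L, 1L))
  expect_equal(sort(fm$consensus$mz), sort(feats$mz))
})

test_that("alignment partitions the input and respects one-per-sample", {
  set.seed(31)
  feats <- tibble::tibble(
    sample_id = sample(paste0("s", 1:6), 300, replace = TRUE),
    mz = runif(300, 100, 1000),
    rt = runif(300, 1, 29),
    height = rlnorm(300, log(5e4), 1),
    quality = runif(300, 80, 100))
  fm <- align_features(feats)
  expect_equal(sum(fm$consensus$n_members), nrow(feats))
  expect_equal(nrow(fm$members), nrow(feats))
  dup <- fm$members %>%
    dplyr::count(feature_id, sample_id) %>%
    dplyr::filter(n > 1)
  expect_equal(nrow(dup), 0)
  # every member lies within the combined windows of its consensus reference
  w <- fm$windows
  joined <- dplyr::left_join(fm$members, fm$consensus,
                             by = "feature_id", suffix = c("", "_ref"))
  hw_m <- window_halfwidths(joined$mz, joined$rt, w)
  hw_r <- window_halfwidths(joined$mz_ref, joined$rt_ref, w)
  expect_true(all(abs(joined$mz - joined$mz_ref) <=
                    hw_m$mz_hw + hw_r$mz_hw + 1e-12))
  expect_true(all(abs(joined$rt - joined$rt_ref) <=
                    hw_m$rt_hw + hw_r$rt_hw + 1e-12))
})

test_that("alignment is invariant to input order", {
  set.seed(7)
  feats <- tibble::tibble(
    sample_id = sample(paste0("s", 1:4), 120, replace = TRUE),
    mz = runif(120, 100, 800),
    rt = runif(120, 1, 25),
    height = rlnorm(120, log(2e4), 1),
    quality = 90)
  fm1 <- align_features(feats)
  fm2 <- align_features(feats[sample(nrow(feats)), ])
  expect_equal(fm1$consensus$mz, fm2$consensus$mz)
  expect_equal(fm1$consensus$rt, fm2$consensus$rt)
  expect_equal(fm1$abundance, fm2$abundance)
})

test_that("greedy alignment matches single-linkage on separated instances", {
  w <- tolerance_windows()
  for (seed in 1:5) {
    set.seed(seed)
    # well-separated cluster centres, members jittered well inside windows
    centres <- tibble::tibble(mz = runif(10, 100, 1000),
                              rt = runif(10, 1, 29))
    feats <- purrr::map_dfr(seq_len(nrow(centres)), function(i) {
      k <- sample(1:4, 1)
      tibble::tibble(sample_id = paste0("s", seq_len(k)),
                     mz = centres$mz[i] + runif(k, -4e-4, 4e-4),
                     rt = centres$rt[i] + runif(k, -0.02, 0.02),
                     height = rlnorm(k, log(1e4), 0.5),
                     quality = 90)
    })
    fm <- align_features(feats, windows = w)
    oracle <- single_linkage_oracle(feats, w)
    expect_equal(nrow(fm$consensus), length(unique(oracle)))
    # identical partitions: same members grouped together
    greedy_part <- fm$members %>%
      dplyr::arrange(sample_id, mz) %>%
      dplyr::pull(feature_id)
    ord <- order(feats$sample_id, feats$mz)
    expect_equal(length(unique(paste(greedy_part, oracle[ord]))),
                 length(unique(oracle)))
  }
})

test_that("flag filtering applies inclusive height and quality thresholds", {
  feats <- tibble::tibble(
    sample_id = "s1",
    mz = c(100.1, 200.2, 300.3, 400.4),
    rt = 1:4,
    height = c(599, 600, 10000, 10000),
    quality = c(95, 95, 80, 79.9))
  fm <- align_features(feats)
  filt <- filter_flags(fm, min_height = 600, min_quality = 80)
  kept <- sort(filt$consensus$mz)
  expect_equal(kept, c(200.2, 300.3), tolerance = 1e-9)
})

test_that("frequency filtering keeps features by class detection fraction", {
  feats <- purrr::map_dfr(1:8, function(i) {
    tibble::tibble(sample_id = paste0("sun_", i),
                   mz = c(100.1, 200.2, if (i <= 4) 300.3),
                   rt = c(1, 2, if (i <= 4) 3),
                   height = 1e4, quality = 90)
  })
  feats <- feats[!(feats$sample_id == "sun_8" & feats$mz == 200.2), ]
  samples <- tibble::tibble(sample_id = paste0("sun_", 1:8),
                            species = "sunflower", producer = "", batch = "",
                            role = "oil")
  fm <- align_features(feats, samples)
  expect_equal(nrow(filter_frequency(fm, "sunflower", 1.0)$consensus), 1)
  # 4/8 passes at fraction 0.5, as do 7/8 and 8/8
  expect_equal(nrow(filter_frequency(fm, "sunflower", 0.5)$consensus), 3)
  expect_equal(nrow(filter_frequency(fm, "sunflower", 0.9)$consensus), 1)
  # fraction 0 keeps every detected feature
  expect_equal(nrow(filter_frequency(fm, "sunflower", 0)$consensus), 3)
  expect_error(filter_frequency(fm, "rapeseed"), "no samples")
})

test_that("blank subtraction removes exactly the planted solvent set", {
  ds <- simulate_dataset(noise_free_design(n_background = 30, seed = 8))
  fm <- align_features(ds$features, ds$samples)
  fm2 <- subtract_blanks(fm)
  solvent_mz <- unique(ds$truth$mz_true[ds$truth$kind == "solvent"])
  # no solvent-derived consensus survives
  expect_false(any(vapply(fm2$consensus$mz, function(m) {
    any(abs(solvent_mz - m) < 1e-6)
  }, logical(1))))
  # everything removed was solvent; feature count drops by the solvent count
  expect_equal(nrow(fm$consensus) - nrow(fm2$consensus), length(solvent_mz))
  # markers survive
  lib <- read_marker_library()
  expect_equal(sum(vapply(lib$precursor_mz, function(m) {
    any(abs(fm2$consensus$mz - m) < 0.01)
  }, logical(1))), 29)
  expect_false(any(fm2$samples$role == "blank"))
})

test_that("the compound-abundance QC gate drops weak samples with a warning", {
  feats <- dplyr::bind_rows(
    tibble::tibble(sample_id = "good", mz = 100.1, rt = 1, height = 60000,
                   quality = 90),
    tibble::tibble(sample_id = "weak", mz = 100.1, rt = 1, height = 1000,
                   quality = 90))
  expect_warning(fm <- align_features(feats, min_compound_abundance = 50000),
                 "weak")
  expect_equal(nrow(fm$members), 1)
})
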