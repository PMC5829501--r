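# The annulus quantification chain, each arithmetic step checked against an
# exhaustive per-pixel oracle, plus its invariances.

test_that("seed detection finds the blurred maximum and honours tie-breaks", {
  f <- matrix(0, 41, 51); f[20, 30] <- 1000
  s <- detect_seed(f)
  expect_identical(c(s[["y"]], s[["x"]]), c(20L, 30L))
  expect_false(attr(s, "low_confidence"))
  # ties broken towards smallest y then x (blur off for exact ties)
  cfg0 <- quant_config(blur_sigma = 0)
  g <- matrix(0, 21, 21); g[5, 5] <- 7; g[9, 9] <- 7
  expect_identical(c(detect_seed(g, cfg0)[["y"]], detect_seed(g, cfg0)[["x"]]), c(5L, 5L))
  h <- matrix(0, 21, 21); h[9, 2] <- 7; h[2, 9] <- 7
  expect_identical(c(detect_seed(h, cfg0)[["y"]], detect_seed(h, cfg0)[["x"]]), c(2L, 9L))
  # all-constant frame: flagged, not fatal
  s0 <- detect_seed(matrix(5, 25, 25))
  expect_true(attr(s0, "low_confidence"))
  # tracking restricts the search to a window around the prior
  two <- matrix(0, 60, 60); two[15, 15] <- 100; two[45, 45] <- 200
  s_tr <- detect_seed(two, prior = c(16, 14))
  expect_identical(c(s_tr[["y"]], s_tr[["x"]]), c(15L, 15L))
  s_gl <- detect_seed(two)
  expect_identical(c(s_gl[["y"]], s_gl[["x"]]), c(45L, 45L))
  expect_error(detect_seed(matrix(0, 10, 10)), "at least")
})

test_that("seed of a noiseless rendered spot lands within 1 px of the true centre", {
  sim <- single_spot_sim(kinetic_truth(), n_frames = 1)
  tr <- sim$truth[sim$truth$centrosome == "anterior", ][1, ]
  s <- detect_seed(sum_project(sim)$data[, , 1])
  expect_lte(abs(s["y"] - tr$y), 1)
  expect_lte(abs(s["x"] - tr$x), 1)
})

test_that("annulus background matches the exhaustive pixel loop", {
  set.seed(10)
  for (i in 1:20) {
    f <- random_frame(sample(30:64, 1), sample(30:64, 1))
    c0 <- c(sample(11:(nrow(f) - 10), 1), sample(11:(ncol(f) - 10), 1))
    bg <- estimate_background(f, c0)
    or <- oracle_annulus(f, c0, 7, 10)
    expect_rel_equal(bg$mean_bg, or$mean)
    expect_rel_equal(bg$stdev_bg, or$sd)
    expect_identical(bg$n_pixels, or$n)
    expect_false(bg$edge_clipped)
  }
  # constant frame: mean = value, sd = 0
  bg7 <- estimate_background(matrix(7, 31, 31), c(16, 16))
  expect_identical(bg7$mean_bg, 7)
  expect_identical(bg7$stdev_bg, 0)
  # a spot wholly inside the inner circle does not touch the background
  f <- matrix(50, 41, 41)
  f[18:24, 18:24] <- 5000  # extent ~3 px around (21, 21), inside r = 7
  expect_identical(estimate_background(f, c(21, 21))$mean_bg, 50)
})

test_that("clipped and empty annuli are flagged or rejected", {
  f <- matrix(rnorm(40 * 40, 100, 5), 40, 40)
  expect_true(estimate_background(f, c(5, 20))$edge_clipped)
  near <- estimate_background(f, c(5, 20))
  # clipped annulus still equals the loop oracle on the surviving pixels
  or <- oracle_annulus(f, c(5, 20), 7, 10)
  expect_rel_equal(near$mean_bg, or$mean)
  expect_identical(near$n_pixels, or$n)
  expect_error(estimate_background(matrix(1, 5, 5), c(3, 3)), "empty annulus")
  expect_error(estimate_background(f, c(0, 10)), "inside the frame")
})

test_that("threshold is mean_bg + k * stdev_bg", {
  bg <- structure(list(mean_bg = 100, stdev_bg = 10), class = "background_estimate")
  expect_identical(compute_threshold(bg), 130)
  expect_identical(compute_threshold(bg, quant_config(k_sigma = 1.5)), 115)
  bg0 <- structure(list(mean_bg = 42, stdev_bg = 0), class = "background_estimate")
  expect_identical(compute_threshold(bg0), 42)
})

test_that("ROI is the seed-connected suprathreshold component (8-connectivity)", {
  f <- matrix(100, 31, 31)
  f[10:14, 10:14] <- 200
  roi <- segment_roi(f, 130, c(12, 12))
  expect_identical(roi$area, 25L)
  expect_identical(roi$indices, oracle_flood_fill(f > 130, c(12, 12)))
  # sub-threshold seed: empty, flagged, zero mass
  e <- segment_roi(f, 250, c(12, 12))
  expect_true(e$empty)
  expect_identical(integrated_mass(f, e, 250), 0)
  # two blobs: only the seed's own (smaller) one is kept
  f2 <- matrix(100, 41, 41)
  f2[5:7, 5:7] <- 200          # small blob
  f2[20:35, 20:35] <- 300      # large blob
  roi2 <- segment_roi(f2, 150, c(6, 6))
  expect_identical(roi2$area, 9L)
  expect_identical(roi2$indices, oracle_flood_fill(f2 > 150, c(6, 6)))
  # diagonal neighbours belong to the same component
  f3 <- matrix(0, 21, 21)
  f3[cbind(5:9, 5:9)] <- 10
  expect_identical(segment_roi(f3, 5, c(5, 5))$area, 5L)
})

test_that("integrated mass equals sum(pixel - threshold) over the ROI", {
  f <- matrix(100, 31, 31); f[5:9, 10:19] <- 200
  roi <- segment_roi(f, 130, c(6, 12))
  expect_identical(roi$area, 50L)
  expect_identical(integrated_mass(f, roi, 130), (200 - 130) * 50)
  f2 <- matrix(0, 21, 21); f2[3, 3:5] <- c(131, 132, 133)
  roi2 <- segment_roi(f2, 130, c(3, 4))
  expect_identical(integrated_mass(f2, roi2, 130), 6)
  # random suprathreshold blob against the summation oracle
  set.seed(2)
  for (i in 1:20) {
    f3 <- random_frame(48, 48)
    c0 <- attr(f3, "blob_center")
    thr <- compute_threshold(estimate_background(f3, c0))
    roi3 <- segment_roi(f3, thr, c0)
    if (roi3$area == 0) next
    expect_rel_equal(integrated_mass(f3, roi3, thr),
                     sum(f3[oracle_flood_fill(f3 > thr, c0)] - thr))
  }
})

test_that("scalar outputs scale exactly with the frame and ROI membership is preserved", {
  set.seed(3)
  for (i in 1:10) {
    f <- random_frame(40, 40)
    c0 <- attr(f, "blob_center")
    for (c_mult in c(0.25, 3, 1000)) {
      bg1 <- estimate_background(f, c0)
      bg2 <- estimate_background(c_mult * f, c0)
      expect_rel_equal(bg2$mean_bg, c_mult * bg1$mean_bg, 1e-12)
      expect_rel_equal(bg2$stdev_bg, c_mult * bg1$stdev_bg, 1e-12)
      t1 <- compute_threshold(bg1); t2 <- compute_threshold(bg2)
      expect_rel_equal(t2, c_mult * t1, 1e-12)
      r1 <- segment_roi(f, t1, c0); r2 <- segment_roi(c_mult * f, t2, c0)
      expect_identical(r1$indices, r2$indices)
      expect_rel_equal(integrated_mass(c_mult * f, r2, t2),
                       c_mult * integrated_mass(f, r1, t1), 1e-12)
    }
  }
})

test_that("integer translation leaves every scalar output unchanged", {
  set.seed(4)
  f <- matrix(rnorm(30 * 30, 100, 10), 30, 30)
  f[14:16, 14:16] <- f[14:16, 14:16] + 150
  big <- matrix(100, 70, 70)
  place <- function(dy, dx) { g <- big; g[(1:30) + dy, (1:30) + dx] <- f; g }
  ref <- place(10, 10)
  bg_r <- estimate_background(ref, c(25, 25))
  thr_r <- compute_threshold(bg_r)
  m_r <- integrated_mass(ref, segment_roi(ref, thr_r, c(25, 25)), thr_r)
  for (sh in list(c(0, 17), c(23, 5), c(19, 21))) {
    g <- place(10 + sh[1], 10 + sh[2])
    ctr <- c(25 + sh[1], 25 + sh[2])
    bg <- estimate_background(g, ctr)
    expect_identical(bg$mean_bg, bg_r$mean_bg)
    expect_identical(bg$stdev_bg, bg_r$stdev_bg)
    thr <- compute_threshold(bg)
    expect_identical(integrated_mass(g, segment_roi(g, thr, ctr), thr), m_r)
  }
})

test_that("pure-background frames almost never yield mass at the +3 sigma threshold", {
  set.seed(5)
  zero <- replicate(100, {
    f <- matrix(rnorm(48 * 48, 100, 10), 48, 48)
    c0 <- c(24, 24)
    thr <- compute_threshold(estimate_background(f, c0))
    integrated_mass(f, segment_roi(f, thr, c0), thr) == 0
  })
  expect_gte(mean(zero), 0.95)
})

test_that("adding non-negative signal to ROI pixels never decreases the mass", {
  set.seed(6)
  for (i in 1:10) {
    f <- random_frame(36, 36)
    c0 <- attr(f, "blob_center")
    thr <- compute_threshold(estimate_background(f, c0))
    roi <- segment_roi(f, thr, c0)
    if (roi$area == 0) next
    m1 <- integrated_mass(f, roi, thr)
    g <- f
    g[roi$indices] <- g[roi$indices] + runif(roi$area, 0, 40)
    roi2 <- segment_roi(g, thr, c0)
    expect_gte(integrated_mass(g, roi2, thr), m1)
  }
})

test_that("a noiseless movie is quantified to within a few percent of truth", {
  sim <- single_spot_sim(kinetic_truth(), n_frames = 40)
  fq <- quantify_movie(crop_post_nebd(sum_project(sim)))
  truth <- sim$truth$true_mass[sim$truth$centrosome == "anterior"]
  # frame-0 threshold is the (near-constant) background: masses track truth
  bright <- truth > 2000
  expect_true(all(abs(fq$integrated_mass[bright] - truth[bright]) /
                    truth[bright] < 0.05))
  # threshold was fixed on frame 1 and never re-estimated
  expect_identical(unique(fq$threshold), fq$threshold[1])
})

test_that("a vanished spot yields zero mass with the empty-ROI flag", {
  d <- array(100, c(40, 40, 6))
  for (i in 1:3) d[16:20, 16:20, i] <- 900 - 100 * i
  proj <- sum_project(movie_stack(d, 10))
  fq <- quantify_movie(proj, quant_config(track_seed_per_frame = FALSE))
  expect_true(all(fq$integrated_mass[1:3] > 0))
  expect_true(all(fq$integrated_mass[4:6] == 0))
  expect_true(all(fq$empty_roi[4:6]))
  expect_false(any(fq$empty_roi[1:3]))
})

test_that("merged mode halves the unresolvable pair and matches single-spot truth", {
  sim <- render_movie(condition_preset("double_depleted"), noise = zero_noise(),
                      n_frames = 10, seed = 1)
  fq <- quantify_movie(crop_post_nebd(sum_project(sim)),
                       quant_config(merged_mode = TRUE))
  truth_single <- sim$truth$true_mass[sim$truth$centrosome == "anterior" &
                                        sim$truth$frame <= 10]
  expect_true(all(abs(fq$integrated_mass - truth_single) / truth_single < 0.15))
  # undoing the divide-by-two recovers the whole pair's mass
  truth_pair <- with(subset(sim$truth, frame <= 10),
                     tapply(true_mass, frame, sum))
  expect_true(all(abs(2 * fq$integrated_mass - truth_pair) / truth_pair < 0.15))
})

test_that("config validation and YAML overrides work", {
  expect_error(quant_config(inner_radius = 10, outer_radius = 7), "inner_radius")
  expect_error(quant_config(k_sigma = 0), "k_sigma")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("blur_sigma: 2", "k_sigma: 4", "merged_mode: yes"), path)
  cfg <- read_quant_config(path)
  expect_equal(cfg$blur_sigma, 2)
  expect_equal(cfg$k_sigma, 4)
  expect_true(cfg$merged_mode)
  expect_identical(cfg$inner_radius, 7)  # untouched defaults survive
  writeLines("bogus_field: 1", path)
  expect_error(read_quant_config(path), "unknown config field")
})
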