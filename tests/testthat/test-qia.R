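disk_image <- function(h, w, cx, cy, r, value = 100, bg = 0) {
  xs <- matrix(rep(seq_len(w) - 1L, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 1L, times = w), h, w)
  img <- matrix(bg, h, w)
  for (i in seq_along(cx))
    img[(xs - cx[i])^2 + (ys - cy[i])^2 <= r[i]^2] <- value
  img
}

test_that("nucleus segmentation recovers synthetic disk geometry", {
  # blank image: no nuclei (constant, so the threshold is undefined)
  expect_warning(blank <- segment_nuclei(matrix(0, 50, 50)), "constant")
  expect_equal(max(blank), 0)
  expect_warning(lab <- segment_nuclei(matrix(7, 50, 50)), "constant")
  expect_equal(max(lab), 0)
  # one bright disk of radius 10 px
  img <- disk_image(64, 64, 30, 28, 10)
  lab <- segment_nuclei(img, smooth_sigma = 2, min_area = 50)
  expect_equal(max(lab), 1)
  rec <- extract_nuclear_intensities(lab, list(hoechst = img))
  expect_lt(abs(rec$centroid_x - 30), 1)
  expect_lt(abs(rec$centroid_y - 28), 1)
  expect_lt(abs(rec$area_px - pi * 100) / (pi * 100), 0.1)
  # tiny specks below min_area are removed
  speck <- disk_image(64, 64, c(20, 50), c(20, 50), c(10, 2))
  expect_equal(max(segment_nuclei(speck, min_area = 50)), 1)
})

test_that("segmentation finds all non-overlapping synthetic nuclei", {
  sc <- synthesize_image_series(50, channel_model_concordance(),
                                noise_sd = 2, seed = 31, n_frames = 1,
                                width = 360, height = 360)
  lab <- segment_nuclei(sc$stack[1, "hoechst", , ])
  expect_equal(max(lab), 50)
  rec <- extract_nuclear_intensities(lab, list(
    gfp = sc$stack[1, "gfp", , ]))
  # one-to-one match to ground-truth centroids within 2 px
  d <- as.matrix(dist(rbind(cbind(rec$centroid_x, rec$centroid_y),
                            cbind(sc$truth$cx_px, sc$truth$cy_px))))
  cross <- d[1:50, 51:100]
  nearest <- apply(cross, 1, which.min)
  expect_equal(sort(as.integer(nearest)), 1:50)
  expect_true(all(apply(cross, 1, min) <= 2))
})

test_that("intensity extraction is exact on noiseless fixtures", {
  img <- disk_image(64, 64, c(18, 45), c(20, 44), c(8, 8))
  lab <- segment_nuclei(img, smooth_sigma = 0, min_area = 20)
  expect_equal(max(lab), 2)
  # uniform channel: every mean equals the constant exactly
  rec <- extract_nuclear_intensities(lab, list(ch = matrix(3.5, 64, 64)))
  expect_equal(rec$mean_ch, c(3.5, 3.5))
  # noiseless synthetic scene: recovered means equal ground truth exactly
  sc <- synthesize_image_series(8, channel_model_concordance(),
                                noise_sd = 0, seed = 33, width = 200,
                                height = 200)
  lab2 <- segment_nuclei(sc$stack[1, "hoechst", , ], smooth_sigma = 0,
                         min_area = 20)
  expect_equal(max(lab2), 8)
  rec2 <- extract_nuclear_intensities(lab2, list(
    gfp = sc$stack[1, "gfp", , ],
    antibody = sc$stack[1, "antibody", , ]))
  tr <- sc$truth[order(sc$truth$cx_px), ]
  rec2 <- rec2[order(rec2$centroid_x), ]
  expect_equal(rec2$mean_gfp, tr$true_gfp)
  expect_equal(rec2$mean_antibody, tr$true_antibody)
  # permuting label ids leaves the multiset of records unchanged
  perm <- lab2
  perm[lab2 == 1] <- max(lab2); perm[lab2 == max(lab2)] <- 1L
  rec3 <- extract_nuclear_intensities(perm, list(
    gfp = sc$stack[1, "gfp", , ],
    antibody = sc$stack[1, "antibody", , ]))
  expect_equal(sort(rec3$mean_gfp), sort(rec2$mean_gfp))
  expect_error(extract_nuclear_intensities(lab2, list(
    bad = matrix(0, 10, 10))), "shape")
})

test_that("QIA is invariant to whole-scene translation", {
  sc <- synthesize_image_series(6, channel_model_concordance(),
                                noise_sd = 0, seed = 35, width = 220,
                                height = 220)
  shift <- c(dx = 11L, dy = 7L)
  shifted <- sc
  for (ch in seq_along(sc$channels)) {
    img <- sc$stack[1, ch, , ]
    new <- matrix(0, 220, 220)
    new[(1 + shift["dy"]):220, (1 + shift["dx"]):220] <-
      img[1:(220 - shift["dy"]), 1:(220 - shift["dx"])]
    shifted$stack[1, ch, , ] <- new
  }
  # nuclei sit well inside the frame, so nothing is clipped by the shift
  r1 <- quantify_scene(sc)
  r2 <- quantify_scene(shifted)
  expect_equal(nrow(r2), nrow(r1))
  o1 <- order(r1$centroid_x, r1$centroid_y)
  o2 <- order(r2$centroid_x, r2$centroid_y)
  expect_equal(r2$centroid_x[o2] - r1$centroid_x[o1],
               rep(11, nrow(r1)), tolerance = 1e-6)
  expect_equal(r2$centroid_y[o2] - r1$centroid_y[o1],
               rep(7, nrow(r1)), tolerance = 1e-6)
  expect_equal(r2$mean_gfp[o2], r1$mean_gfp[o1])
  expect_equal(r2$area_px[o2], r1$area_px[o1])
})

test_that("distribution timecourses share bins and track the mean", {
  rec <- data.frame(timepoint_h = rep(c(24, 48, 72), each = 40),
                    mean_gfp = c(rnorm(40, 100, 5), rnorm(40, 200, 5),
                                 rnorm(40, 300, 5)))
  tc <- intensity_distribution_timecourse(rec, bins = 20)
  m <- tc$means[tc$means$channel == "gfp", ]
  expect_true(all(diff(m$mean) > 0))   # upward-shifting mixture
  # shared binning per channel
  b24 <- tc$histograms$gfp[["24"]]$breaks
  b72 <- tc$histograms$gfp[["72"]]$breaks
  expect_identical(b24, b72)
  expect_equal(sum(tc$histograms$gfp[["48"]]$counts), 40)
  # single record: degenerate histogram, mean equals the value
  one <- intensity_distribution_timecourse(
    data.frame(timepoint_h = 5, mean_gfp = 123), bins = 10)
  expect_equal(one$means$mean, 123)
  expect_equal(sum(one$histograms$gfp[["5"]]$counts), 1)
  # requested but absent timepoint yields a missing-value entry
  holes <- intensity_distribution_timecourse(rec, timepoints = c(24, 96))
  expect_true(is.na(holes$means$mean[holes$means$timepoint_h == 96]))
})

test_that("reporter mean rises then falls across the differentiation course", {
  # per-timepoint event populations stand in for per-nucleus reporter
  # records: the pulse model should produce a wave profile
  p <- get_preset("act_chi")
  ev <- simulate_event_population(p, c(24, 48, 72, 96), 4000, 1, seed = 37)
  rec <- data.frame(timepoint_h = ev$timepoint_h,
                    mean_gfp = ev$intensity_afu)
  tc <- intensity_distribution_timecourse(rec)
  m <- tc$means$mean[order(tc$means$timepoint_h)]
  expect_gt(m[2], m[1])             # rise into the wave
  expect_lt(m[4], max(m[2], m[3]))  # decline after the plateau
})

test_that("correlation timecourses behave at the null, self and baseline", {
  set.seed(41)
  rec <- data.frame(timepoint_h = rep(c(0, 24), each = 500),
                    mean_a = rnorm(1000), mean_b = rnorm(1000))
  ct <- pairwise_correlation_timecourse(rec, list(c("a", "b")))
  expect_true(all(abs(ct$r) < 0.1))
  self <- pairwise_correlation_timecourse(rec, list(c("a", "a")))
  expect_true(all(abs(self$r - 1) < 1e-12))
  # zero-variance channel flagged, not an error
  rec$mean_c <- 5
  flat <- pairwise_correlation_timecourse(rec, list(c("a", "c")))
  expect_true(all(flat$flag == "undefined-correlation"))
  expect_true(all(is.na(flat$r)))
  # baseline correlation computed once from the reference condition
  base <- data.frame(timepoint_h = 0, mean_a = rnorm(200))
  base$mean_b <- base$mean_a
  cb <- pairwise_correlation_timecourse(rec, list(c("a", "b")),
                                        baseline_records = base)
  expect_true(all(abs(cb$baseline_r - 1) < 1e-12))
})

test_that("correlation recovery matches the sampling-theory bound", {
  # mean sample correlation over 200 replicates stays within
  # 1.96 (1 - rho^2) / sqrt(n) of the generating rho
  set.seed(43)
  n <- 500
  for (rho in c(0, 0.5, 0.773, 0.95)) {
    rs <- replicate(200, {
      z <- bvn_pair(n, rho)
      rec <- data.frame(timepoint_h = 0, mean_a = z$a, mean_b = z$b)
      pairwise_correlation_timecourse(rec, list(c("a", "b")))$r
    })
    expect_lt(abs(mean(rs) - rho), 1.96 * (1 - rho^2) / sqrt(n))
  }
})

test_that("track-ROI readout recovers a known moving pulse", {
  h <- 80; w <- 120
  t <- seq(0, 1, by = 1 / 6)          # 7 frames
  xs_um <- seq(20, 45, length.out = 7)
  ys_um <- rep(20, 7)
  pulse <- c(0, 0, 50, 100, 100, 50, 0)
  px <- 0.5
  stack <- array(0, dim = c(7, 2, h, w),
                 dimnames = list(NULL, c("hoechst", "gfp"), NULL, NULL))
  for (f in 1:7)
    stack[f, "gfp", , ] <- disk_image(h, w, xs_um[f] / px, ys_um[f] / px,
                                      12, value = pulse[f])
  scene <- structure(list(stack = stack, channels = c("hoechst", "gfp"),
                          pixel_size = px, times = t, truth = NULL),
                    class = "image_scene")
  track <- make_track(t, xs_um, ys_um)
  # ROI radius smaller than the rendered disk: mean equals the pulse
  roi <- track_roi_intensity(scene, track, radius_um = 2, channel = "gfp")
  expect_equal(roi$mean_afu, pulse)
  expect_false(any(roi$clipped))
  # uniform frames return the constant; blank frames return 0
  uni <- scene
  for (f in 1:7) uni$stack[f, "gfp", , ] <- 7.5
  expect_equal(track_roi_intensity(uni, track, radius_um = 2,
                                   channel = "gfp")$mean_afu, rep(7.5, 7))
  # default 10-um ROI near the edge is flagged as clipped
  edge_track <- make_track(t, rep(2, 7), rep(2, 7))
  roi_edge <- track_roi_intensity(scene, edge_track, radius_um = 10,
                                  channel = "gfp")
  expect_true(all(roi_edge$clipped))
  expect_error(track_roi_intensity(scene, track[1:3, ], radius_um = 2),
               "frame count")
})
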