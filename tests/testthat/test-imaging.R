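test_that("frame averaging is the pixelwise mean and suppresses noise as 1/sqrt(F)", {
  f1 <- matrix(c(0, 4, 2, 6), 2, 2)
  f2 <- matrix(c(2, 0, 0, 2), 2, 2)
  st <- image_stack(array(c(f1, f2), c(2, 2, 2)))
  expect_equal(average_frames(st), matrix(c(1, 2, 1, 4), 2, 2))
  expect_equal(average_frames(image_stack(f1)), f1)  # single frame identity
  expect_error(average_frames(array(0, c(2, 2, 0))), "at least one|empty")
  # CLT: residual sd of a 50-frame average of sigma-noise ~ sigma/sqrt(50)
  set.seed(5)
  ratios <- replicate(100, {
    frames <- array(10 + rnorm(16 * 16 * 50, sd = 2), c(16, 16, 50))
    sd(average_frames(frames) - 10) / (2 / sqrt(50))
  })
  expect_equal(mean(ratios), 1, tolerance = 0.2)
})

test_that("difference-of-Gaussians bandpass removes background, keeps spots", {
  const <- matrix(7, 64, 64)
  expect_lt(max(abs(bandpass_blur(const))), 1e-8)       # DC removal
  set.seed(2)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(bandpass_blur(3 * img), 3 * bandpass_blur(img),
               tolerance = 1e-12)                       # linearity
  expect_error(bandpass_blur(img, low_sigma = 5, high_sigma = 2), "low_sigma")

  # background of period >> high_sigma attenuated >95%, 4-px spot kept
  n <- 512
  rr <- matrix(0:(n - 1), n, n); cc <- t(rr)
  bg <- 10 * sin(2 * pi * rr / 512) * sin(2 * pi * cc / 512)
  spot <- matrix(0, n, n)
  spot[(rr - 256)^2 + (cc - 256)^2 <= 2^2] <- 5     # 4-px-diameter disk
  f_bg <- bandpass_blur(bg, high_sigma = 15)
  expect_lt(max(abs(f_bg)) / 10, 0.05)
  spot_peak <- max(bandpass_blur(spot, high_sigma = 15))
  # reference: the spot after the same low-sigma + final smoothing only
  smoothed <- aggrekin:::gaussian_blur(aggrekin:::gaussian_blur(spot, 1), 1)
  expect_gt(spot_peak / max(smoothed), 0.8)
})

test_that("connected-component labelling honours connectivity and ordering", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE          # diagonal contact
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
  # labels are deterministic, ordered by top-left pixel
  m[5, 1] <- TRUE
  lab <- label_components(m, 8)
  expect_equal(lab[2, 2], 1L)
  expect_equal(lab[5, 1], 2L)
  expect_equal(label_components(matrix(FALSE, 3, 3)), matrix(0L, 3, 3))
})

test_that("segmentation finds planted disks with sub-pixel centroids", {
  sc <- disk_scene(n = 5, seed = 3)
  g <- gen_image_stack(sc)
  filt <- bandpass_blur(average_frames(g$stack))
  seg <- segment_particles(filt)
  expect_equal(nrow(seg$table), 5)
  m <- match_to_truth(data.frame(centroid_row = seg$table$centroid_row,
                                 centroid_col = seg$table$centroid_col),
                      g$truth, tol = 1)
  expect_equal(m$tp, 5)   # all centroids within 1 px of ground truth
  # empty image segments to nothing
  expect_equal(nrow(segment_particles(matrix(0, 32, 32),
                                      intensity_threshold = 1)$table), 0)
  # area bookkeeping: total labelled pixels cannot exceed the image
  expect_lte(sum(seg$table$area_px), length(filt))
})

test_that("a sub-threshold 1-px gap separates two disks under 8-connectivity", {
  img <- matrix(0, 32, 32)
  img[10:14, 10:14] <- 10       # disk 1
  img[10:14, 16:20] <- 10       # disk 2, one dark column between
  seg <- segment_particles(img, intensity_threshold = 5, min_area_px = 4)
  expect_equal(nrow(seg$table), 2)
  # bridging the gap merges them
  img[12, 15] <- 10
  seg2 <- segment_particles(img, intensity_threshold = 5, min_area_px = 4)
  expect_equal(nrow(seg2$table), 1)
})

test_that("SBR intensity matches its definition and is scale invariant", {
  img <- matrix(4, 16, 16)
  bg <- matrix(2, 16, 16)
  px <- as.matrix(expand.grid(row = 2:6, col = 3:4))  # 10 pixels, 0-based
  expect_equal(sbr_intensity(img, px, bg), 10)        # I = 2*bg each
  expect_equal(sbr_intensity(bg, px, bg), 0)          # I = bg
  set.seed(9)
  img2 <- matrix(runif(256, 1, 5), 16, 16)
  bg2 <- matrix(runif(256, 0.5, 2), 16, 16)
  base <- sbr_intensity(img2, px, bg2)
  for (c in c(0.5, 3, 10))
    expect_equal(sbr_intensity(c * img2, px, c * bg2), base)
  bad_bg <- bg; bad_bg[3, 4] <- 0
  expect_error(sbr_intensity(img, px, bad_bg), "row=2, col=3")
})

test_that("median background estimation tracks the true background", {
  const <- matrix(3.7, 32, 32)
  expect_equal(estimate_background(const), const)     # constant fixed point
  expect_error(estimate_background(const, window_px = 2), "at least 3")
  sc <- disk_scene(n = 4, shape = c(256L, 256L), seed = 8, frames = 5L)
  g <- gen_image_stack(sc)
  avg <- average_frames(g$stack)
  est <- estimate_background(avg, 25)
  true_bg <- aggrekin:::scene_background(sc)
  spot_free <- g$clean - true_bg < 1e-6
  rel <- abs(est - true_bg) / true_bg
  expect_lt(stats::quantile(rel[spot_free], 0.99), 0.02)
  # linear scaling of the image scales the map
  expect_equal(estimate_background(2 * avg, 25), 2 * est, tolerance = 1e-9)
})

test_that("per-FOV summaries report counts and calibrated areas", {
  empty <- summarize_fov(data.frame(area_um2 = numeric(0),
                                    sbr_intensity = numeric(0),
                                    touches_border = logical(0)))
  expect_equal(empty$count, 0)
  one <- data.frame(fov_id = "f", timepoint_h = 8, particle_id = 1L,
                    centroid_row = 5, centroid_col = 5, area_px = 100L,
                    area_um2 = 100 * 0.322^2, sbr_intensity = 50,
                    touches_border = FALSE)
  sm <- summarize_fov(one)
  expect_equal(sm$areas, 10.3684)     # 100 px at 322 nm/px
  expect_equal(sm$total_sbr, 50)
  expect_equal(sm$timepoint_h, 8)
})

test_that("detection achieves precision and recall >= 0.95 at SBR >= 3 (20 seeds)", {
  tp <- fp <- fn <- 0
  for (s in 1:20) {
    g <- gen_image_stack(disk_scene(n = 8, shape = c(192L, 192L), sbr = 3,
                                    seed = 100 + s, frames = 10L))
    det <- detect_particles(g$stack)
    m <- match_to_truth(det, g$truth, tol = 2)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  expect_gte(tp / (tp + fp), 0.95)   # precision
  expect_gte(tp / (tp + fn), 0.95)   # recall
})

test_that("centroid localisation is within 1 px RMS on isolated disks", {
  se <- c()
  for (s in 1:5) {
    g <- gen_image_stack(disk_scene(n = 5, seed = 200 + s))
    det <- detect_particles(g$stack)
    for (i in seq_len(nrow(g$truth))) {
      d2 <- (det$centroid_row - g$truth$row[i])^2 +
            (det$centroid_col - g$truth$col[i])^2
      se <- c(se, min(d2))
    }
  }
  expect_lt(sqrt(mean(se)), 1)
})

test_that("the detection pipeline is deterministic for identical input", {
  g <- gen_image_stack(disk_scene(n = 5, seed = 31))
  t1 <- detect_particles(g$stack)
  t2 <- detect_particles(g$stack)
  expect_identical(t1, t2)
})
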