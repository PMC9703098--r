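test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_tht_trace(wt_params(), initial_state(1e-6), mult_sigma = 0.05,
                     seed = 7)
  b <- gen_tht_trace(wt_params(), initial_state(1e-6), mult_sigma = 0.05,
                     seed = 7)
  expect_identical(a$trace$intensity, b$trace$intensity)
  sc <- disk_scene(n = 3, shape = c(96L, 96L), seed = 7, frames = 3L)
  expect_identical(gen_image_stack(sc)$stack$frames,
                   gen_image_stack(sc)$stack$frames)
  expect_identical(gen_pk_pair(n_particles = 20, seed = 7),
                   gen_pk_pair(n_particles = 20, seed = 7))
  expect_identical(gen_slb_image(data.frame(row = 40, col = 40, radius = 6),
                                 shape = c(96L, 96L), seed = 7)$image,
                   gen_slb_image(data.frame(row = 40, col = 40, radius = 6),
                                 shape = c(96L, 96L), seed = 7)$image)
})

test_that("a noiseless trace is an exact affine image of the simulated mass", {
  g <- gen_tht_trace(mut_params(), initial_state(1e-6), mult_sigma = 0,
                     add_sd = 0, scale = 5e8, n_points = 60, seed = 1)
  sim <- simulate_aggregation(mut_params(), initial_state(1e-6),
                              g$trace$time_h * 3600)
  expect_equal(g$trace$intensity, 5e8 * sim$mass, tolerance = 1e-12)
  expect_equal(g$truth$lambda, 2e-8)
})

test_that("rendered stacks carry truthful particle photometry", {
  sc <- disk_scene(n = 4, shape = c(160L, 160L), radius = 3, sbr = 5,
                   seed = 5, frames = 10L)
  g <- gen_image_stack(sc)
  # no-noise scene: averaged image equals background exactly off-particle
  quiet <- scene_spec(shape = c(64L, 64L), frames = 2L, read_sd = 0,
                      shot = FALSE, seed = 1)
  gq <- gen_image_stack(quiet)
  expect_equal(average_frames(gq$stack), gq$clean, tolerance = 1e-12)
  # peak SBR of the clean image within 10% of specification
  bg <- aggrekin:::scene_background(sc)
  peak <- max((g$clean - bg) / bg)
  expect_equal(peak, 5, tolerance = 0.10)
  # shot noise: per-pixel variance ~ mean over frames
  shot <- scene_spec(shape = c(48L, 48L), frames = 50L, read_sd = 0,
                     shot = TRUE, mod_amplitude = 0, offset = 200, seed = 3)
  gs <- gen_image_stack(shot)
  v <- apply(gs$stack$frames, c(1, 2), var)
  expect_equal(mean(v) / 200, 1, tolerance = 0.15)
})

test_that("growth series plants counts from the kinetic model and is detectable", {
  series <- gen_growth_series(mut_params(), initial_state(1e-6),
                              timepoints_h = c(8, 24, 48, 72),
                              count_scale = 1.5e5,
                              meanlog_growth_per_h = 0.012, sdlog = 0.15,
                              shape = c(192L, 192L), frames = 6L, seed = 9)
  planted <- vapply(series, `[[`, numeric(1), "n_planted")
  expect_true(all(diff(planted) >= 0))
  expect_gt(planted[4], planted[1])
  # one fixed threshold across all timepoints, as in a real time-lapse run
  dets <- lapply(series, function(s)
    detect_particles(s$stack, intensity_threshold = 50))
  detected <- vapply(dets, nrow, numeric(1))
  expect_true(all(abs(detected - planted) <= pmax(1, 0.1 * planted)))
  # planted vs recovered median sizes track each other across timepoints
  med_planted <- vapply(series, function(s) stats::median(s$truth$radius),
                        numeric(1))
  med_detected <- vapply(dets, function(d) stats::median(d$area_um2),
                         numeric(1))
  expect_gte(stats::cor(med_planted, med_detected, method = "spearman"), 0.9)
  # lambda = 0: nothing to image at any timepoint
  empty <- gen_growth_series(rate_parameters(0, 7e-7), initial_state(1e-6),
                             timepoints_h = c(8, 24), count_scale = 1.5e5,
                             shape = c(96L, 96L), frames = 2L, seed = 2)
  expect_equal(vapply(empty, `[[`, numeric(1), "n_planted"), c(0, 0))
})

test_that("PK pair generator honours degenerate class mixtures", {
  all_res <- gen_pk_pair(n_particles = 15,
                         class_fractions = c(sensitive = 0, partial = 0,
                                             resistant = 1),
                         loss_bands = list(sensitive = c(0.8, 0.9),
                                           partial = c(0.4, 0.6),
                                           resistant = c(0, 0)),
                         jitter_px = 0, seed = 3)
  expect_equal(all_res$after$sbr_intensity, all_res$before$sbr_intensity)
  all_sens <- gen_pk_pair(n_particles = 15,
                          class_fractions = c(sensitive = 1, partial = 0,
                                              resistant = 0),
                          loss_bands = list(sensitive = c(1, 1),
                                            partial = c(0.4, 0.6),
                                            resistant = c(0, 0.2)),
                          jitter_px = 0, seed = 3)
  expect_true(all(all_sens$after$sbr_intensity == 0))
  expect_error(gen_pk_pair(class_fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("SLB generator geometry: doubling hole radii quadruples the area", {
  set.seed(12)
  pos <- aggrekin:::place_particles(5, c(384, 384), 16, margin = 40,
                                   min_sep = 70)
  small <- data.frame(row = pos$row, col = pos$col, radius = 6)
  big <- transform(small, radius = 12)
  a1 <- gen_slb_image(small, shape = c(384L, 384L), noise_sd = 8,
                      seed = 13)
  a2 <- gen_slb_image(big, shape = c(384L, 384L), noise_sd = 8, seed = 13)
  m1 <- slb_hole_metrics(a1$image)
  m2 <- slb_hole_metrics(a2$image)
  expect_equal(m1$n_holes, 5)
  expect_equal(m2$n_holes, 5)
  expect_equal(m2$total_hole_area_um2 / m1$total_hole_area_um2, 4,
               tolerance = 0.10)
})

test_that("blot generator: noise-free inversion and small bias under noise", {
  g0 <- gen_blot_standards(unknown_concs = 300, seed = 1)
  curve <- fit_standard_curve(g0$standards$amount, g0$standards$intensity)
  expect_equal(quantify_monomer(curve, g0$unknowns$intensity)$amount, 300,
               tolerance = 1e-9)
  # 2% multiplicative noise, 20 seeds: mean bias of the estimate < 3%
  est <- vapply(1:20, function(s) {
    g <- gen_blot_standards(noise_frac = 0.02, unknown_concs = 300, seed = s)
    cv <- fit_standard_curve(g$standards$amount, g$standards$intensity)
    quantify_monomer(cv, g$unknowns$intensity)$amount
  }, numeric(1))
  expect_lt(abs(mean(est) - 300) / 300, 0.03)
})
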