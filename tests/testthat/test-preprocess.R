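# small hand-built clouds exercise the labelling rules; the full chain runs
# on generator output in test-acceptance.R

test_that("marker labelling applies the stationary, floor and template rules", {
  tpl <- default_templates()
  nfr <- 40
  frames <- seq_len(nfr)
  # stationary marker fixed at one point; lure-height moving marker;
  # backpack quadruple moving at altitude plus one far stray point
  stationary <- tibble::tibble(frame = frames, x = 2, y = 2, z = 0.25)
  lure_pt <- tibble::tibble(frame = frames, x = 0.1 * frames, y = 1, z = 0.05)
  bp <- dplyr::bind_rows(lapply(frames, function(f) {
    off <- tpl$backpack$offsets
    tibble::tibble(frame = f, x = 5 + 0.04 * f + off[, 1],
                   y = 3 + off[, 2], z = 0.9 + off[, 3])
  }))
  stray <- tibble::tibble(frame = frames, x = 15 - 0.05 * frames, y = 5.5,
                          z = 1.2)
  cloud <- dplyr::bind_rows(stationary, lure_pt, bp, stray)
  cloud$time_s <- (cloud$frame - 1) / 200
  lab <- label_markers(cloud, tpl)
  expect_true(all(lab$label[lab$x == 2 & lab$y == 2] == "stationary"))
  expect_true(all(lab$label[lab$z == 0.05] == "lure"))
  expect_true(all(lab$label[lab$z >= 0.85 & lab$z <= 0.95] == "backpack"))
  expect_true(all(lab$label[lab$y == 5.5] == "bird_other"))
})

test_that("labelling is invariant to point order within frames", {
  tpl <- default_templates()
  fl <- gen_flight(synthetic_spec(law = "inertial_pn", N = 1, tau = 0.055,
                                  dt = test_dt, noise_sigma = 0,
                                  occlusion_rate = 0, spike_rate = 0,
                                  seed = 13L))
  cloud <- generate_marker_cloud(fl, synthetic_spec(seed = 13L), tpl)
  cloud <- cloud[cloud$frame <= 60, ]
  shuffled <- withr::with_seed(1, {
    cloud[order(cloud$frame, sample.int(nrow(cloud))), ]
  })
  la <- label_markers(cloud, tpl)
  lb <- label_markers(shuffled, tpl)
  key_a <- paste(la$frame, round(la$x, 9), round(la$y, 9), la$label)
  key_b <- paste(lb$frame, round(lb$x, 9), round(lb$y, 9), lb$label)
  expect_setequal(key_a, key_b)
})

test_that("two-pass outlier elimination removes spikes at the documented thresholds", {
  t <- seq(0, 1, by = 1 / 200)
  track <- tibble::tibble(time_s = t, x = 2 + 3 * t, y = 1 + 0.5 * t)
  big <- track; big$x[100] <- big$x[100] + 0.6     # 600 mm spike
  out <- clean_trajectory(big)
  expect_true(is.na(out$x[100]))
  # the 600 mm spike already exceeds the pass-1 threshold
  pass1 <- clean_trajectory(big, thresholds = 0.5)
  expect_true(is.na(pass1$x[100]))
  mod <- track; mod$y[50] <- mod$y[50] + 0.1       # 100 mm spike
  pass1 <- clean_trajectory(mod, thresholds = 0.5)
  expect_false(is.na(pass1$y[50]))                  # survives pass 1
  out <- clean_trajectory(mod)
  expect_true(is.na(out$y[50]))                     # removed in pass 2
  # spike-free track unchanged, and cleaning is idempotent
  expect_identical(clean_trajectory(track), track)
  once <- clean_trajectory(big)
  expect_identical(clean_trajectory(once), once)
})

test_that("quintic smoothing reproduces known derivatives", {
  # noise-free constant velocity: evaluated velocity exact to < 1e-6
  t <- seq(0, 1.5, by = 1 / 200)
  track <- tibble::tibble(time_s = t, x = 1 + 2.5 * t, y = 4 - 1.2 * t)
  sm <- smooth_and_differentiate(track, tolerance = 0.03, out_rate = 2000)
  expect_lt(max(abs(sm$vx - 2.5)), 1e-6)
  expect_lt(max(abs(sm$vy + 1.2)), 1e-6)
  # output grid spacing is exactly 1/out_rate
  expect_equal(unique(round(diff(sm$time_s), 12)), 1 / 2000)
  sm20 <- smooth_and_differentiate(track[1:31, ], tolerance = 0.03,
                                   out_rate = 20000)
  expect_equal(unique(round(diff(sm20$time_s), 12)), 5e-5)
  # noisy quadratic: acceleration recovered within 5% of the generator
  a_true <- 6
  track2 <- withr::with_seed(23, tibble::tibble(
    time_s = t,
    x = 0.5 * a_true * t^2 + rnorm(length(t), 0, 0.001),
    y = 2 * t + rnorm(length(t), 0, 0.001)))
  sm2 <- smooth_and_differentiate(track2, tolerance = 0.03, out_rate = 2000)
  mid <- sm2$time_s > 0.2 & sm2$time_s < 1.3
  expect_lt(max(abs(sm2$ax[mid] - a_true)) / a_true, 0.05)
  # residual stays within the tolerance
  expect_lte(attr(sm2, "residual"), 0.03 + 1e-9)
  # gaps are filled by interpolation before fitting
  gappy <- track
  gappy$x[40:44] <- NA; gappy$y[40:44] <- NA
  smg <- smooth_and_differentiate(gappy, tolerance = 0.03, out_rate = 1000)
  expect_lt(max(abs(smg$vx - 2.5)), 1e-4)
  expect_error(smooth_and_differentiate(track[1:4, ], 0.03), "insufficient")
})

test_that("quality control enforces reconstruction, visibility and intercept rules", {
  t <- seq(0, 1, by = 1 / 200)
  n <- length(t)
  bird <- tibble::tibble(time_s = t, x = seq(0, 5, length.out = n), y = 1)
  lure <- tibble::tibble(time_s = t, x = seq(2, 5.02, length.out = n), y = 1)
  # closing gap: 2 m down to 20 mm at the last frame
  qc <- qc_and_crop(bird, lure, reconstruction_fraction = 0.9)
  expect_s3_class(qc, "qc_flight")
  d_end <- abs(qc$bird$x[nrow(qc$bird)] - qc$lure$x[nrow(qc$lure)])
  expect_lte(d_end, 0.03)
  # reconstruction fraction at or below 0.5 rejects
  rej <- qc_and_crop(bird, lure, reconstruction_fraction = 0.40)
  expect_s3_class(rej, "flight_rejection")
  expect_match(rej$reason, "template")
  # minimum distance 31 mm is not an intercept
  lure31 <- lure; lure31$x <- bird$x + 0.031
  rej <- qc_and_crop(bird, lure31, reconstruction_fraction = 0.9)
  expect_s3_class(rej, "flight_rejection")
  expect_match(rej$reason, "intercept")
  # cropping starts at the first mutually visible frame
  bird_gap <- bird; bird_gap$x[1:10] <- NA
  qc <- qc_and_crop(bird_gap, lure, reconstruction_fraction = 0.9)
  expect_equal(qc$t0, t[11])
  # no mutually visible frame
  rej <- qc_and_crop(dplyr::mutate(bird, x = NA_real_), lure, 0.9)
  expect_s3_class(rej, "flight_rejection")
})

test_that("centroids require three markers per template and track occlusion", {
  tpl <- default_templates()
  spec <- synthetic_spec(law = "inertial_pn", N = 1, tau = 0.055,
                         dt = test_dt, noise_sigma = 0, occlusion_rate = 0,
                         spike_rate = 0, seed = 41L)
  fl <- gen_flight(spec)
  cloud <- generate_marker_cloud(fl, spec, tpl)
  # occlude the whole tail mount in frame 5 and one backpack marker in frame 8
  drop_tail5 <- cloud$frame == 5 & cloud$label_true == "tailmount"
  bp8 <- which(cloud$frame == 8 & cloud$label_true == "backpack")[1]
  cloud2 <- cloud[-c(which(drop_tail5), bp8), ]
  cent <- labelled_centroids(label_markers(cloud2, tpl))
  expect_true(is.na(cent$bird_x[cent$frame == 5]))   # < 3 tail markers
  expect_false(is.na(cent$bird_x[cent$frame == 8]))  # 3 of 4 backpack ok
  tf <- fl$meta$truth_frames
  ok <- !is.na(cent$bird_x)
  expect_lt(max(abs(cent$bird_x[ok][1:20] - tf$hawk_x[cent$frame[ok][1:20]])),
            0.02)
})
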