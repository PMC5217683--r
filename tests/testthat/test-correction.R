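# Detector subtraction, shading estimation, background estimation, and the
# composed image correction.

test_that("detector map is the pixel-wise mean of dark frames", {
  f <- matrix(rnorm(64, 32, 2), 8, 8)
  expect_identical(estimate_detector(list(f)), f)
  expect_equal(estimate_detector(list(matrix(5, 4, 4), matrix(7, 4, 4))),
               matrix(6, 4, 4))
  expect_error(estimate_detector(list()), class = "platetalk_missing_input")
  expect_error(estimate_detector(list(matrix(0, 4, 4), matrix(0, 5, 5))),
               class = "platetalk_config_error")
})

test_that("the detector estimate concentrates on the true offset", {
  frames <- withr::with_seed(42, {
    lapply(1:50, function(i) matrix(rnorm(256, 32, 2), 16, 16))
  })
  est <- estimate_detector(frames)
  expect_true(all(abs(est - 32) < 1))
})

test_that("shading estimation recovers flat and known fields", {
  det <- matrix(0, 64, 64)
  flat <- tibble::tibble(well_id = "R01", role = "reference", field = 1L,
                         channel = "hoechst",
                         image = list(matrix(500, 64, 64)))
  est <- estimate_shading(flat, det, smooth_sigma = 2)
  expect_equal(est[["1"]][["hoechst"]], matrix(1, 64, 64), tolerance = 1e-12)

  # a known smooth field is recovered pointwise within 1%
  s <- make_shading_field(c(128, 128), amplitude = 0.3, seed = 3)
  refs <- tibble::tibble(well_id = "R01", role = "reference", field = 1L,
                         channel = "hoechst", image = list(800 * s))
  est2 <- estimate_shading(refs, matrix(0, 128, 128),
                           smooth_sigma = 0.5)[["1"]][["hoechst"]]
  expect_lt(max(abs(est2 - s) / s), 0.01)

  # unit-mean normalisation makes the estimate scale invariant
  refs10 <- refs
  refs10$image <- list(10 * refs$image[[1]])
  est3 <- estimate_shading(refs10, matrix(0, 128, 128),
                           smooth_sigma = 0.5)[["1"]][["hoechst"]]
  expect_equal(est3, est2, tolerance = 1e-12)
})

test_that("background is the mean below the 0.001 quantile", {
  expect_equal(estimate_background(matrix(7, 40, 40)), 7)  # tie fallback

  img <- matrix(100, 1000, 1000)
  img[seq_len(999)] <- 0
  expect_equal(estimate_background(img), 0)

  base <- matrix(rnorm(5000, 50, 5), 50, 100)
  expect_equal(estimate_background(base + 12.5),
               estimate_background(base) + 12.5)

  bad <- base; bad[1] <- NA
  expect_error(estimate_background(bad), class = "platetalk_invalid_image")
  expect_error(estimate_background(matrix(1, 10, 10)),
               class = "platetalk_invalid_image")
})

test_that("background estimator agrees with a full-sort oracle", {
  results <- withr::with_seed(7, {
    replicate(100, {
      img <- matrix(rlnorm(2500, 3, 1), 50, 50)
      # independent oracle: explicit sort + type-7 interpolation
      s <- sort(as.vector(img))
      h <- (length(s) - 1) * 0.001
      cut <- s[floor(h) + 1] + (h - floor(h)) * (s[floor(h) + 2] - s[floor(h) + 1])
      lo <- s[s < cut]
      oracle <- if (length(lo)) mean(lo) else s[1]
      abs(estimate_background(img) - oracle)
    })
  })
  expect_true(all(results == 0))
})

test_that("correction is identity when the model is trivial", {
  img <- matrix(runif(64 * 64, 0, 100), 64, 64)
  img[1] <- 0                      # pin the quantile set
  model <- structure(list(detector = matrix(0, 64, 64),
                          shading = list(`1` = list(hoechst = matrix(1, 64, 64)))),
                     class = "correction_model")
  out <- correct_image(img, model, 1, "hoechst")
  bg <- attr(out, "background")
  expect_equal(matrix(out, 64, 64) + bg, img, tolerance = 1e-12)
  expect_error(correct_image(img, model, 2, "hoechst"),
               class = "platetalk_missing_reference")
})

test_that("the composed correction equals its step-by-step application", {
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                           fields_per_well = 1, channels = "hoechst")
  sim <- simulate_plate(layout, params = synth_params(density = 10), seed = 6)
  model <- fit_correction_model(sim$images)
  raw <- sim$images$image[[which(sim$images$well_id == "S02" &
                                   sim$images$channel == "hoechst")]]
  corr <- correct_image(raw, model, 1, "hoechst")

  # order contract: detector first, shading second, background last
  step1 <- raw - model$detector
  step2 <- step1 / model$shading[["1"]][["hoechst"]]
  step3 <- step2 - estimate_background(step2)
  expect_equal(matrix(corr, nrow(raw)), step3, tolerance = 1e-12)
})

test_that("noiseless corrected images recover the truth scene within 1%", {
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                           fields_per_well = 1, channels = "hoechst")
  p <- synth_params(density = 8, debris_fraction = 0,
                    nucleus_texture = c(0, 0))    # deterministic scene
  sim <- simulate_plate(layout, params = p, seed = 8, noise = FALSE)
  corrected <- correct_plate(sim$images, smooth_sigma = 0.5)
  i <- which(corrected$well_id == "S02" & corrected$channel == "hoechst")
  corr <- corrected$image[[i]]
  # rebuild the noiseless scene from the truth table
  tw <- sim$truth$nuclei[sim$truth$nuclei$well_id == "S02", ]
  scene <- matrix(0, nrow(corr), ncol(corr))
  for (k in seq_len(nrow(tw))) {
    scene <- platetalk:::add_blob(scene, tw$row[k], tw$col[k], tw$radius[k],
                                  tw$total_hoechst[k], profile = "disc")
  }
  # corrected = scene + (true background - estimated background): a constant
  diff <- corr - scene
  bright <- scene > 50
  expect_lt(max(abs(diff[bright] - median(diff))) / mean(scene[bright]), 0.01)
})

test_that("flat-field correction restores reference uniformity", {
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                           fields_per_well = 1, channels = "hoechst")
  p <- synth_params(density = 5, shading_amplitude = 0.3)
  sim <- simulate_plate(layout, params = p, seed = 10)
  corrected <- correct_plate(sim$images)
  ref_raw <- sim$images$image[[which(sim$images$role == "reference")[1]]]
  i_ref <- which(corrected$role == "reference")[1]
  ref_corr <- corrected$image[[i_ref]] + corrected$background[i_ref]
  cv <- function(x) sd(x) / mean(x)
  expect_gte(cv(ref_raw) / cv(ref_corr), 5)

  # corrected reference noise is close to an unshaded noisy flat render
  p0 <- synth_params(density = 5, shading_amplitude = 0)
  sim0 <- simulate_plate(layout, params = p0, seed = 10)
  ref_flat <- sim0$images$image[[which(sim0$images$role == "reference")[1]]]
  expect_lte(cv(ref_corr), cv(ref_flat) * 1.1)
})

test_that("correction models serialise and reload", {
  dir <- withr::local_tempdir()
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                           fields_per_well = 1, channels = "hoechst")
  sim <- simulate_plate(layout, params = synth_params(density = 5), seed = 12)
  model <- fit_correction_model(sim$images)
  write_correction_model(model, dir)
  back <- read_correction_model(dir)
  expect_equal(back$detector, model$detector, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$shading[["1"]][["hoechst"]],
               model$shading[["1"]][["hoechst"]],
               tolerance = 1e-12, ignore_attr = TRUE)
})
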