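# Synthetic plate generator: shading fields, ground-truth sampling, rendering.

test_that("shading fields are unit-mean, bounded below, and deterministic", {
  s <- make_shading_field(c(96, 96), position_index = 0, amplitude = 0.3,
                          seed = 1)
  expect_equal(mean(s), 1, tolerance = 1e-9)
  expect_gte(min(s), 1 - 0.3)
  expect_true(all(s > 0))

  s2 <- make_shading_field(c(96, 96), position_index = 0, amplitude = 0.3,
                           seed = 1)
  expect_identical(s, s2)
  s3 <- make_shading_field(c(96, 96), position_index = 1, amplitude = 0.3,
                           seed = 1)
  expect_false(identical(s, s3))

  flat <- make_shading_field(c(32, 32), amplitude = 0)
  expect_identical(flat, matrix(1, 32, 32))

  expect_error(make_shading_field(c(32, 32), amplitude = 1),
               class = "platetalk_invalid_parameter")
})

test_that("DNA-class sampling follows the G1 fraction", {
  layout <- plate_layout(
    tibble::tibble(well_id = c("C1", "S1", "R1"),
                   role = c("control", "sample", "reference"),
                   condition = c("control", "Wnt3A", NA),
                   ligands = c("", "Wnt3A=1e-9", ""),
                   replicate = c(1L, 1L, NA), time_h = c(2, 2, NA)),
    fields_per_well = 100, channels = "hoechst")
  truth <- sample_nuclei(layout, params = synth_params(density = 50,
                                                       debris_fraction = 0),
                         seed = 7)
  n <- nrow(truth$nuclei)
  expect_gte(n, 10000)
  obs <- mean(truth$nuclei$dna_class == "2N")
  ci <- qbinom(c(0.005, 0.995), n, 0.7) / n   # exact binomial 99% interval
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
  # 4N expected total Hoechst is twice the 2N expectation
  ratio <- mean(truth$nuclei$total_hoechst[truth$nuclei$dna_class == "4N"]) /
    mean(truth$nuclei$total_hoechst[truth$nuclei$dna_class == "2N"])
  expect_equal(ratio, 2, tolerance = 0.02)
})

test_that("degenerate G1 fraction labels every nucleus 2N", {
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                           fields_per_well = 1)
  truth <- sample_nuclei(layout,
                         params = synth_params(g1_fraction = 1,
                                               debris_fraction = 0),
                         seed = 1)
  expect_true(all(truth$nuclei$dna_class == "2N"))
})

test_that("condition effect multipliers scale TF truth and control is baseline", {
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                           fields_per_well = 10)
  p <- synth_params(density = 50, debris_fraction = 0)
  truth <- sample_nuclei(layout, c(Wnt3A = 2), params = p, seed = 4)
  ctrl <- truth$nuclei$total_tf1[truth$nuclei$well_id == "S01"]
  trt <- truth$nuclei$total_tf1[truth$nuclei$well_id == "S02"]
  # control draws sit at the baseline lognormal median; treated at 2x
  expect_equal(median(ctrl), p$tf_total, tolerance = 0.05)
  expect_equal(median(trt) / median(ctrl), 2, tolerance = 0.1)
  expect_error(sample_nuclei(layout, c(Wnt3A = -1), params = p),
               class = "platetalk_invalid_parameter")
})

test_that("overfull fields raise a placement error", {
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                           fields_per_well = 1, image_shape = c(96, 96))
  expect_error(sample_nuclei(layout, params = synth_params(density = 60),
                             seed = 1),
               class = "platetalk_placement_failure")
})

test_that("the all-off render is identically the background level", {
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                           fields_per_well = 1, image_shape = c(128, 128),
                           channels = "hoechst")
  p <- synth_params(density = 0.2, debris_fraction = 0,  # rounds to empty
                    shading_amplitude = 0, detector_offset = 0,
                    read_noise = 0, shot_noise = 0)
  sim <- simulate_plate(layout, params = p, seed = 1, noise = FALSE)
  img <- sim$images$image[[which(sim$images$well_id == "S02" &
                                   sim$images$channel == "hoechst")[1]]]
  expect_true(all(img == p$background_level))
})

test_that("a reference image divided by its own shading field is flat", {
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                           fields_per_well = 1, channels = "hoechst")
  p <- synth_params(density = 1)
  sim <- simulate_plate(layout, params = p, seed = 2, noise = FALSE)
  ref <- sim$images[sim$images$role == "reference", ]
  img <- ref$image[[1]]
  flat <- (img - p$detector_offset) / sim$truth$shading[[1]][["hoechst"]]
  expect_lt(sd(flat) / mean(flat), 0.005)  # rounding only
  expect_equal(mean(flat), p$reference_level + p$background_level,
               tolerance = 0.01)
})

test_that("noiseless rendered intensity sums match the truth table", {
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                           fields_per_well = 2, channels = "hoechst")
  p <- synth_params(density = 4, debris_fraction = 0, shading_amplitude = 0,
                    detector_offset = 0, background_level = 0)
  sim <- simulate_plate(layout, params = p, seed = 3, noise = FALSE)
  cells <- sim$images[sim$images$role %in% c("sample", "control"), ]
  for (i in seq_len(nrow(cells))) {
    tw <- sim$truth$nuclei[sim$truth$nuclei$well_id == cells$well_id[i] &
                             sim$truth$nuclei$field == cells$field[i], ]
    expect_equal(sum(cells$image[[i]]), sum(tw$total_hoechst),
                 tolerance = 0.005)
  }
})

test_that("identical seeds give bit-identical plates", {
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                           fields_per_well = 1)
  a <- simulate_plate(layout, c(Wnt3A = 2), synth_params(density = 10),
                      seed = 5)
  b <- simulate_plate(layout, c(Wnt3A = 2), synth_params(density = 10),
                      seed = 5)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  expect_identical(a$images$image, b$images$image)
})

test_that("truth tables and layouts round-trip losslessly through disk", {
  dir <- withr::local_tempdir()
  layout <- default_layout(conditions = "Wnt3A", n_replicates = 2,
                           fields_per_well = 1)
  sim <- simulate_plate(layout, c(Wnt3A = 2), synth_params(density = 6),
                        seed = 9, dir = dir)
  back <- platetalk:::read_truth_table(file.path(dir, "truth_nuclei.csv"))
  expect_equal(as.data.frame(back), as.data.frame(sim$truth$nuclei))
  lay2 <- read_plate_layout(file.path(dir, "layout.tsv"))
  expect_equal(lay2$wells, layout$wells)
  expect_identical(lay2$image_shape, layout$image_shape)
  expect_identical(lay2$channels, layout$channels)
  # and written images read back exactly
  img <- read_field_tiff(file.path(dir, "S01_f01_hoechst.tif"))
  expect_identical(img, sim$images$image[[which(sim$images$well_id == "S01" &
    sim$images$field == 1 & sim$images$channel == "hoechst")]])
})

test_that("rendered plates show the 2x DNA-content bimodality", {
  fx <- dense_hoechst_plate()
  fit <- fit_hoechst_mixture(fx$nuclei$total_hoechst)
  expect_false(fit$collapsed)
  expect_gte(nrow(fx$nuclei), 2000)
  expect_equal(fit$mean[2] / fit$mean[1], 2, tolerance = 0.05)
})
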