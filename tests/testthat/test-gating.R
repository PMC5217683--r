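# DNA-content mixture fitting, the G1/0 gate, and MAD quality windows.

test_that("the EM fit recovers well-separated mixture parameters", {
  x <- withr::with_seed(1, c(rnorm(700, 100, 5), rnorm(300, 200, 5)))
  fit <- fit_hoechst_mixture(x)
  expect_equal(fit$mean[1], 100, tolerance = 0.02)
  expect_equal(fit$mean[2], 200, tolerance = 0.02)
  expect_lt(abs(fit$weight[1] - 0.7), 0.05)
  expect_false(fit$collapsed)

  # independent cross-check: model-based clustering on the same data
  library(mclust)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.01)

  # broom-style accessors
  td <- tidy(fit)
  expect_identical(names(td), c("component", "weight", "mean", "sd"))
  expect_true(glance(fit)$converged)
})

test_that("the fit is invariant to input order and deterministic", {
  x <- withr::with_seed(2, c(rnorm(500, 100, 6), rnorm(250, 200, 9)))
  f1 <- fit_hoechst_mixture(x)
  f2 <- fit_hoechst_mixture(sample(x))
  expect_equal(f1$mean, f2$mean)
  expect_equal(f1$sd, f2$sd)
  expect_equal(f1$weight, f2$weight)
})

test_that("unimodal data collapse to near-identical components covering the bulk", {
  x <- withr::with_seed(3, rnorm(500, 100, 8))
  fit <- fit_hoechst_mixture(x)
  expect_true(fit$collapsed)
  expect_equal(fit$mean[1], fit$mean[2])
  inside <- mean(x >= fit$mean[1] - 2 * fit$sd[1] &
                   x <= fit$mean[1] + 2 * fit$sd[1])
  expect_gte(inside, 0.9)
})

test_that("the EM log-likelihood is non-decreasing", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, c(rlnorm(300, log(100), 0.1),
                                  rlnorm(150, log(200), 0.1)))
    fit <- fit_hoechst_mixture(x)
    expect_true(all(diff(fit$loglik) >= -1e-8))
  }
  expect_error(fit_hoechst_mixture(rnorm(10, 100, 5)),
               class = "platetalk_insufficient_data")
})

test_that("the G1 window is closed at its boundaries", {
  fit <- structure(list(weight = c(0.7, 0.3), mean = c(100, 200),
                        sd = c(5, 5), loglik = 0, n = 100,
                        sd_floored = FALSE, collapsed = FALSE,
                        converged = TRUE),
                   class = "hoechst_mixture")
  rec <- tibble::tibble(total_hoechst = c(90, 110, 100, 89.9, 110.1, 100))
  out <- gate_g1(rec, fit)
  expect_equal(out$window, c(90, 110))
  expect_identical(nrow(out$records), 4L)      # both boundary values retained
  all_at_mean <- tibble::tibble(total_hoechst = rep(100, 5))
  expect_identical(nrow(gate_g1(all_at_mean, fit)$records), 5L)
})

test_that("the gated fraction recovers the true G1 fraction at scale", {
  # ~5,000 nuclei, 2N fraction 0.7, 2x mode separation (truth level)
  layout <- plate_layout(
    tibble::tibble(well_id = c("C1", "S1", "R1"),
                   role = c("control", "sample", "reference"),
                   condition = c("control", "Wnt3A", NA),
                   ligands = c("", "Wnt3A=1e-9", ""),
                   replicate = c(1L, 1L, NA), time_h = c(2, 2, NA)),
    fields_per_well = 50, channels = "hoechst")
  truth <- sample_nuclei(layout, params = synth_params(density = 50,
                                                       debris_fraction = 0),
                         seed = 17)
  totals <- truth$nuclei$total_hoechst
  expect_gte(length(totals), 4800)
  fit <- fit_hoechst_mixture(totals)
  gated <- gate_g1(tibble::tibble(total_hoechst = totals), fit)
  expect_lt(abs(nrow(gated$records) / length(totals) - 0.7), 0.05)
})

test_that("the MAD windows match the worked oracle and its degenerate cases", {
  rec <- tibble::tibble(area = c(1, 2, 3, 4, 100),
                        cv_hoechst = rep(0.5, 5))
  rec <- rec[rep(1:5, 2), ]        # >= 10 records
  expect_warning(out <- mad_filter(rec), "zero MAD")
  expect_equal(out$area_window, c(1, 5))       # median 3, MAD 1
  expect_true(all(out$records$area %in% 1:4))
  expect_false(any(out$records$area == 100))

  same <- tibble::tibble(area = rep(7, 12), cv_hoechst = rep(0.2, 12))
  expect_warning(expect_warning(out2 <- mad_filter(same), "zero MAD"),
                 "zero MAD")   # both the area and the CV window collapse
  expect_identical(nrow(out2$records), 12L)    # all equal the median

  expect_error(mad_filter(same[1:5, ]), class = "platetalk_insufficient_data")
})

test_that("quality filtering removes debris but spares genuine G1 nuclei", {
  fx <- demo_plate()
  labelled <- label_detections(fx$nuclei, fx$truth$nuclei)
  # count per class surviving the full per-well G1 gate + pooled QC windows
  g1_counts <- vapply(split(labelled, labelled$well_id), function(w) {
    fit <- fit_hoechst_mixture(w$total_hoechst)
    g1 <- gate_g1(w, fit)$records
    c(sum(g1$dna_class == "2N"), sum(g1$dna_class == "debris"))
  }, numeric(2))
  gated <- label_detections(fx$gated, fx$truth$nuclei)
  frac_2n_kept <- sum(gated$dna_class == "2N") / sum(g1_counts[1, ])
  frac_debris_kept <- sum(gated$dna_class == "debris") / sum(g1_counts[2, ])
  expect_gte(frac_2n_kept, 0.9)
  expect_lte(frac_debris_kept, 0.1)
})

test_that("gate counts are monotone and filtering is nearly idempotent", {
  layout <- default_layout(conditions = c("Wnt3A", "TGFb3"), n_replicates = 3,
                           fields_per_well = 3)
  sim <- simulate_plate(layout, c(Wnt3A = 2, TGFb3 = 1.5), seed = 2)
  nuclei <- quantify_plate(correct_plate(sim$images))
  g <- suppressWarnings(gate_cells(nuclei))
  expect_true(all(g$report$n_input >= g$report$n_after_hoechst))
  expect_true(all(g$report$n_after_hoechst >= g$report$n_after_qc))
  g2 <- suppressWarnings(gate_cells(g$records, per_well = FALSE))
  expect_lt(1 - nrow(g2$records) / nrow(g$records), 0.10)
})
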