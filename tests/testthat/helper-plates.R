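# Shared fixtures, built in code and cached for the duration of a test run.

# Match detected nuclei to ground-truth objects by nearest centre (< 4 px)
# and return the nucleus table with the truth DNA class attached.
label_detections <- function(nuclei, truth) {
  cls <- character(nrow(nuclei))
  matched <- logical(nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    tw <- truth[truth$well_id == nuclei$well_id[i] &
                  truth$field == nuclei$field[i], ]
    d <- sqrt((tw$row - nuclei$centroid_row[i])^2 +
                (tw$col - nuclei$centroid_col[i])^2)
    j <- which.min(d)
    cls[i] <- tw$dna_class[j]
    matched[i] <- d[j] < 4
  }
  nuclei$dna_class <- cls
  nuclei$matched <- matched
  nuclei
}

# A rendered crosstalk demo plate: 4 conditions x 3 replicates x 2 fields
# (24 cell fields), canonical ligand effect 2.0, a half-effect ligand at 1.5
# and a no-effect ligand at 1.0 on the tf1 readout.  Built once, reused by
# the segmentation, gating, response and acceptance tests.
# A dense Hoechst-only plate (2 cell wells x 19 fields x ~55 nuclei, >2000
# cells) for distribution-level DNA-content checks.
dense_hoechst_plate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      layout <- default_layout(conditions = "Wnt3A", n_replicates = 1,
                               n_reference = 1, n_dark = 1,
                               fields_per_well = 19, channels = "hoechst")
      sim <- simulate_plate(layout, params = synth_params(density = 55),
                            seed = 21)
      nuclei <- quantify_plate(correct_plate(sim$images))
      cache <<- list(layout = layout, truth = sim$truth, nuclei = nuclei)
    }
    cache
  }
})

demo_plate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      layout <- default_layout(conditions = c("Wnt3A", "TGFb3", "BMP4"),
                               n_replicates = 3, fields_per_well = 2)
      sim <- simulate_plate(layout,
                            effect_table = c(Wnt3A = 2, TGFb3 = 1.5, BMP4 = 1),
                            seed = 11)
      corrected <- correct_plate(sim$images)
      nuclei <- quantify_plate(corrected)
      gate <- suppressWarnings(gate_cells(nuclei))
      cache <<- list(layout = layout, truth = sim$truth, images = sim$images,
                     corrected = corrected, nuclei = nuclei,
                     gated = gate$records, gate_report = gate$report)
    }
    cache
  }
})
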