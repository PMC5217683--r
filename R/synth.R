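# Synthetic plate generator: renders multi-channel fields with known ground
# truth so that correction, segmentation, gating and response statistics can
# all be validated by parameter recovery.

#' Generator parameters for synthetic plates
#'
#' Defaults emulate a low-noise sCMOS acquisition of Hoechst-stained nuclei
#' near confluence: nuclei are radially smooth flattened discs (sigmoid edge)
#' with bounded radius jitter; total nuclear Hoechst intensity is bimodal (2N vs 4N DNA
#' content, the 4N mode at twice the 2N mean); transcription-factor (TF)
#' channels share the nuclear footprint with lognormally distributed totals
#' scaled by per-condition effect multipliers.  The camera model is
#' `shading * (scene + background) + detector offset + noise`, with values
#' clipped to the 11-bit range [0, 2047] and stored as 16-bit TIFF.
#'
#' @param density Nuclei per field of view.
#' @param g1_fraction Fraction of nuclei in G1/0 (2N DNA content).
#' @param radius_min,radius_max Bounds of the uniform nucleus-radius draw
#'   (pixels).  A bounded draw keeps the healthy-nucleus size distribution
#'   light-tailed, so the downstream ±2 MAD quality windows remove outliers
#'   (debris) rather than the tails of the genuine population.
#' @param g2_size_factor Radius multiplier for 4N (G2/M) nuclei, whose
#'   doubled DNA content occupies a visibly larger nucleus.  Keeping the 4N
#'   plateau brightness close to the 2N one also keeps the automatic
#'   threshold below the dimmest nucleus.
#' @param hoechst_total_2n Mean total Hoechst intensity of a 2N nucleus (a.u.,
#'   summed over the nucleus); the 4N mean is twice this.
#' @param hoechst_cv Staining coefficient of variation of total Hoechst
#'   intensity, on top of the size-driven variation: within a class the DNA
#'   amount is fixed, so a nucleus's total scales with its area (constant
#'   chromatin concentration) times a `1 + N(0, hoechst_cv)` staining factor.
#' @param tf_total Median total TF intensity of an untreated nucleus (a.u.).
#' @param tf_cv Cell-to-cell coefficient of variation of total TF intensity.
#' @param background_level Additive scene background (a.u.), applied before
#'   shading.
#' @param reference_level Uniform scene level of reference wells (a.u.).
#' @param detector_offset Constant detector (dark) offset (a.u.).
#' @param read_noise Gaussian read noise SD (a.u.).
#' @param shot_noise Signal-dependent noise scale; the noise SD of a pixel
#'   with expected signal `s` is `read_noise + shot_noise * sqrt(s)`.
#' @param shading_amplitude Peak-to-trough fraction of the multiplicative
#'   shading field, in `[0, 1)`.
#' @param shading_smoothness Length scale (pixels) of the shading field;
#'   `NULL` means half the larger image dimension.
#' @param nucleus_texture Range of the per-nucleus chromatin-texture speckle
#'   SD (multiplicative, bounded).  Drawn per nucleus from an arcsine
#'   (U-shaped) law on this range: cells cluster towards compact or open
#'   chromatin states, so the within-nucleus intensity CV -- the texture QC
#'   feature -- spans its range with heavy shoulders rather than bell tails.
#' @param debris_fraction Fraction of extra debris objects injected per field:
#'   small, speckled objects whose total Hoechst intensity mimics a 2N nucleus
#'   (so they pass the DNA-content gate and must be caught by the size and
#'   texture quality filters).
#' @param debris_texture Within-object multiplicative speckle SD for debris.
#' @param min_separation Minimum extra gap (pixels) between nucleus borders.
#' @param max_value Clipping ceiling before images are written (11-bit camera).
#' @return A named list of generator parameters.
#' @export
synth_params <- function(density = 30,
                         g1_fraction = 0.7,
                         radius_min = 7.5, radius_max = 9.5,
                         g2_size_factor = 1.25,
                         hoechst_total_2n = 60000, hoechst_cv = 0.06,
                         tf_total = 10000, tf_cv = 0.15,
                         background_level = 50,
                         reference_level = 1200,
                         detector_offset = 32,
                         read_noise = 2,
                         shot_noise = 0.3,
                         shading_amplitude = 0.3,
                         shading_smoothness = NULL,
                         nucleus_texture = c(0.08, 0.25),
                         debris_fraction = 0.02,
                         debris_texture = 0.5,
                         min_separation = 3,
                         max_value = 2047) {
  stopifnot_scalar_number(density, "density", lower = 0)
  stopifnot_scalar_number(g1_fraction, "g1_fraction", lower = 0, upper = 1,
                          strict_lower = TRUE)
  stopifnot_scalar_number(shading_amplitude, "shading_amplitude",
                          lower = 0, upper = 1, strict_upper = TRUE)
  stopifnot_scalar_number(debris_fraction, "debris_fraction", lower = 0, upper = 0.5)
  as.list(environment())
}

#' Simulate a smooth multiplicative shading field
#'
#' Draws a smooth, strictly positive, unit-mean surface modelling uneven
#' illumination for one within-well field position.  A Gaussian-smoothed
#' random field is range-normalised to `[0, 1]`, mapped to
#' `[1 - amplitude, 1]`, and rescaled to mean exactly 1; the minimum therefore
#' never falls below `1 - amplitude`.  The surface is deterministic given
#' `seed` and `position_index`.
#'
#' @param shape Integer vector `c(rows, cols)` in pixels.
#' @param position_index Within-well field position (0-based or 1-based; only
#'   used to decorrelate fields).
#' @param smoothness Length scale of the field in pixels.
#' @param amplitude Fractional depth of the shading, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `shape` matrix with mean 1 (to within 1e-9), minimum at least
#'   `1 - amplitude`, strictly positive.
#' @examples
#' s <- make_shading_field(c(64, 64), position_index = 1,
#'                         smoothness = 32, amplitude = 0.3, seed = 1)
#' mean(s); range(s)
#' @export
make_shading_field <- function(shape, position_index = 1L,
                               smoothness = max(shape) / 2,
                               amplitude = 0.3, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 2L)) {
    abort("`shape` must be two positive pixel dimensions",
          class = "platetalk_invalid_parameter")
  }
  stopifnot_scalar_number(amplitude, "amplitude", lower = 0, upper = 1,
                          strict_upper = TRUE)
  if (amplitude == 0) return(matrix(1, shape[1], shape[2]))
  with_seed(as.integer(seed) + 7919L * (as.integer(position_index) + 1L), {
    raw <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    sm <- smooth_gaussian(raw, sigma = smoothness / 2)
    # histogram-equalise the smooth field so the shading depth is spread
    # uniformly over [1 - amplitude, 1] (rank transform preserves smoothness)
    g01 <- matrix((rank(sm) - 1) / (length(sm) - 1), shape[1], shape[2])
    s0 <- 1 - amplitude * g01
    s0 / mean(s0)
  })
}

# Normalise an effect specification to a tibble(condition, channel, multiplier).
# Accepts a named numeric vector (condition -> multiplier, applied to every TF
# channel) or a data frame with those three columns.
normalize_effect_table <- function(effect_table, conditions, tf_channels) {
  if (is.numeric(effect_table) && !is.null(names(effect_table))) {
    effect_table <- tidyr::expand_grid(
      condition = names(effect_table), channel = tf_channels
    ) |>
      mutate(multiplier = unname(effect_table[.data$condition]))
  }
  et <- as_tibble(effect_table)
  stopifnot(all(c("condition", "channel", "multiplier") %in% names(et)))
  if (any(et$multiplier <= 0)) {
    abort("effect multipliers must be positive",
          class = "platetalk_invalid_parameter")
  }
  missing <- setdiff(conditions, unique(et$condition))
  # unspecified conditions (including the control) default to multiplier 1
  if (length(missing)) {
    et <- bind_rows(et, tidyr::expand_grid(condition = missing,
                                           channel = tf_channels,
                                           multiplier = 1))
  }
  et[et$channel %in% tf_channels, ]
}

# The DNA channel is the one labelled "hoechst" if present, else the first.
hoechst_channel <- function(layout) {
  if ("hoechst" %in% layout$channels) "hoechst" else layout$channels[1]
}

tf_channels <- function(layout) setdiff(layout$channels, hoechst_channel(layout))

# Dart-throwing placement of n discs with radii r inside a field, keeping a
# clear margin from the border and `min_separation` px between disc borders.
place_nuclei <- function(n, radii, shape, min_separation, max_tries = 200L) {
  rows <- numeric(n); cols <- numeric(n)
  placed_r <- numeric(0); placed_row <- numeric(0); placed_col <- numeric(0)
  for (i in seq_len(n)) {
    margin <- 1.4 * radii[i] + 2
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r0 <- runif(1, margin, shape[1] - 1 - margin)
      c0 <- runif(1, margin, shape[2] - 1 - margin)
      if (length(placed_r)) {
        d <- sqrt((placed_row - r0)^2 + (placed_col - c0)^2)
        if (any(d < placed_r + radii[i] + min_separation)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      abort(sprintf(
        "could not place nucleus %d of %d in a %dx%d field after %d tries; lower `density`",
        i, n, shape[1], shape[2], max_tries),
        class = "platetalk_placement_failure")
    }
    rows[i] <- r0; cols[i] <- c0
    placed_r <- c(placed_r, radii[i])
    placed_row <- c(placed_row, r0); placed_col <- c(placed_col, c0)
  }
  tibble(row = rows, col = cols)
}

#' Sample ground-truth nuclei for a plate
#'
#' Draws per-nucleus ground truth for every cell-bearing (sample or control)
#' well of a layout: non-overlapping positions, lognormal radii, a Bernoulli
#' 2N/4N DNA-content class (4N total Hoechst intensity is twice 2N in
#' expectation), and per-channel total TF intensities equal to a baseline
#' lognormal draw times the condition's effect multiplier.  A configurable
#' fraction of debris objects (small, high-texture, 2N-like Hoechst total) is
#' appended.
#'
#' @param layout A [plate_layout()].
#' @param effect_table Condition effects: either a named numeric vector
#'   (condition to multiplier, applied to every TF channel) or a data frame
#'   with columns `condition`, `channel`, `multiplier`.  Conditions absent
#'   from the table (including the control) get multiplier 1.
#' @param params A [synth_params()] list.
#' @param seed Integer seed; the same seed reproduces the same truth.
#' @return An object of class `synthetic_truth`: a list with `nuclei` (tibble:
#'   `well_id`, `field`, `nucleus`, `row`, `col` (0-based pixel centers),
#'   `radius`, `dna_class` in `{2N, 4N, debris}`, `total_<channel>` columns),
#'   `effects`, `shading` (per position per channel), `detector` (offset map),
#'   `params`, and `seed`.
#' @export
sample_nuclei <- function(layout, effect_table = NULL,
                          params = synth_params(), seed = 1L) {
  stopifnot(inherits(layout, "plate_layout"))
  hch <- hoechst_channel(layout)
  tfs <- tf_channels(layout)
  conds <- unique(stats::na.omit(layout$wells$condition))
  effects <- normalize_effect_table(
    effect_table %||% setNames(numeric(0), character(0)), conds, tfs)
  eff_lookup <- function(cond, ch) {
    m <- effects$multiplier[effects$condition == cond & effects$channel == ch]
    if (length(m)) m[1] else 1
  }
  shape <- layout$image_shape
  cells <- layout$wells[layout$wells$role %in% c("sample", "control"), ]
  n_field <- round(params$density)
  tf_sdlog <- sqrt(log(1 + params$tf_cv^2))
  n_debris <- round(params$debris_fraction * n_field)

  nuclei <- with_seed(seed, {
    out <- vector("list", nrow(cells) * layout$fields_per_well)
    k <- 0L
    for (w in seq_len(nrow(cells))) {
      for (f in seq_len(layout$fields_per_well)) {
        n <- n_field
        base_radius <- sqrt(runif(n, params$radius_min^2, params$radius_max^2))
        is_debris <- rep(c(FALSE, TRUE), c(n, n_debris))
        if (n_debris > 0) base_radius <- c(base_radius, runif(n_debris, 4.0, 4.8))
        ntot <- n + n_debris
        mean_sq_radius <- (params$radius_min^2 + params$radius_max^2) / 2
        g1 <- rbinom(ntot, 1L, params$g1_fraction) == 1L
        dna <- ifelse(g1, "2N", "4N")
        dna[is_debris] <- "debris"
        radius <- base_radius
        radius[dna == "4N"] <- radius[dna == "4N"] * params$g2_size_factor
        pos <- place_nuclei(ntot, radius, shape, params$min_separation)
        # constant chromatin concentration within a class: total scales with
        # the (pre-G2-enlargement) nuclear area, times a staining factor
        size_scale <- base_radius^2 / mean_sq_radius
        size_scale[is_debris] <- 1
        hmean <- ifelse(dna == "4N", 2, 1) * params$hoechst_total_2n * size_scale
        htot <- pmax(hmean * (1 + rnorm(ntot, 0, params$hoechst_cv)),
                     0.1 * params$hoechst_total_2n)
        texture <- params$nucleus_texture[1] +
          diff(params$nucleus_texture) * rbeta(ntot, 0.5, 0.5)
        texture[is_debris] <- params$debris_texture
        rec <- tibble(
          well_id = cells$well_id[w], field = f, nucleus = seq_len(ntot),
          row = pos$row, col = pos$col, radius = radius, dna_class = dna,
          texture = texture
        )
        rec[[paste0("total_", hch)]] <- htot
        for (ch in tfs) {
          mult <- eff_lookup(cells$condition[w], ch)
          base <- rlnorm(ntot, log(params$tf_total), tf_sdlog)
          rec[[paste0("total_", ch)]] <- base * mult
        }
        k <- k + 1L
        out[[k]] <- rec
      }
    }
    bind_rows(out)
  })

  shading <- with_seed(seed + 13L, {
    lapply(seq_len(layout$fields_per_well), function(p) {
      chs <- lapply(seq_along(layout$channels), function(ci) {
        make_shading_field(
          shape, position_index = p * 31L + ci,
          smoothness = params$shading_smoothness %||% (max(shape) / 2),
          amplitude = params$shading_amplitude, seed = seed)
      })
      setNames(chs, layout$channels)
    })
  })
  detector <- matrix(params$detector_offset, shape[1], shape[2])

  structure(
    list(nuclei = nuclei, effects = effects, shading = shading,
         detector = detector, params = params, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$nuclei), " objects (",
      sum(x$nuclei$dna_class == "debris"), " debris) in ",
      length(unique(x$nuclei$well_id)), " wells; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Render one object of integrated intensity `total` centred at a (possibly
# fractional, 0-based) position into `scene`.  The discrete kernel is
# renormalised so the rendered pixel sum equals `total` exactly.
#
# Two radially smooth profiles:
#  - "disc": a flattened disc with a sigmoid edge (edge width 0.15 * radius).
#    Its thresholded footprint is ~ pi * radius^2 whatever the threshold, so
#    measured nuclear area reflects morphology rather than DNA content.
#  - "gaussian": a peaked Gaussian blob (sigma = radius / 2), used for debris.
add_blob <- function(scene, row0, col0, radius, total, texture_sd = 0,
                     profile = c("disc", "gaussian")) {
  profile <- match.arg(profile)
  sigma <- radius / 2
  w <- ceiling(if (profile == "disc") 2.2 * radius else 4 * sigma)
  r1 <- max(1L, floor(row0 + 1 - w)); r2 <- min(nrow(scene), ceiling(row0 + 1 + w))
  c1 <- max(1L, floor(col0 + 1 - w)); c2 <- min(ncol(scene), ceiling(col0 + 1 + w))
  rr <- r1:r2; cc <- c1:c2
  d2 <- outer((rr - 1 - row0)^2, (cc - 1 - col0)^2, `+`)
  k <- if (profile == "disc") {
    1 / (1 + exp((sqrt(d2) - radius) / max(0.04 * radius, 0.25)))
  } else {
    exp(-d2 / (2 * sigma^2))
  }
  if (texture_sd > 0) {
    # bounded multiplicative speckle (mean 1, SD texture_sd) cannot push a
    # plateau pixel below the segmentation threshold
    k <- k * (1 + texture_sd * sqrt(3) * runif(length(k), -1, 1))
  }
  scene[rr, cc] <- scene[rr, cc] + total * k / sum(k)
  scene
}

#' Render a synthetic plate to images
#'
#' Applies the camera model to the ground truth: for cell-bearing and
#' reference wells, `pixel = shading * (scene + background) + detector +
#' noise`; dark frames contain only `detector + noise`.  The scene of a
#' reference well is spatially uniform.  Pixel values are rounded and clipped
#' to `[0, max_value]` so written TIFFs are lossless.
#'
#' @param truth A [sample_nuclei()] result.
#' @param layout The [plate_layout()] the truth was sampled for.
#' @param noise If `FALSE`, renders without pixel noise (clipping and rounding
#'   still apply) — useful for oracle tests.
#' @return A tibble with one row per image: `well_id`, `role`, `field`,
#'   `channel`, and a list-column `image` of integer-valued matrices.
#' @export
render_plate <- function(truth, layout, noise = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(layout, "plate_layout"))
  p <- truth$params
  shape <- layout$image_shape
  hch <- hoechst_channel(layout)
  if (!all(names(truth$shading[[1]]) == layout$channels)) {
    abort("channel labels of truth and layout disagree",
          class = "platetalk_config_error")
  }
  nuc <- truth$nuclei
  grid <- tidyr::expand_grid(
    layout$wells[, c("well_id", "role")],
    field = seq_len(layout$fields_per_well),
    channel = layout$channels
  )
  images <- with_seed(truth$seed + 29L, {
    pmap(grid, function(well_id, role, field, channel) {
      if (role == "dark") {
        img <- truth$detector +
          if (noise) matrix(rnorm(prod(shape), 0, p$read_noise), shape[1]) else 0
        return(round_clip(img, p$max_value))
      }
      scene <- matrix(0, shape[1], shape[2])
      if (role == "reference") {
        scene[] <- p$reference_level
      } else {
        sel <- nuc[nuc$well_id == well_id & nuc$field == field, ]
        tot <- sel[[paste0("total_", channel)]]
        for (i in seq_len(nrow(sel))) {
          debris <- sel$dna_class[i] == "debris"
          scene <- add_blob(scene, sel$row[i], sel$col[i], sel$radius[i],
                            tot[i], texture_sd = sel$texture[i],
                            profile = "disc")
        }
      }
      expected <- truth$shading[[field]][[channel]] * (scene + p$background_level)
      img <- expected + truth$detector
      if (noise) {
        sdmap <- p$read_noise + p$shot_noise * sqrt(pmax(expected, 0))
        img <- img + matrix(rnorm(prod(shape), 0, 1), shape[1]) * sdmap
      }
      round_clip(img, p$max_value)
    })
  })
  grid$image <- images
  grid
}

round_clip <- function(img, max_value) {
  img <- round(img)
  img[img < 0] <- 0
  img[img > max_value] <- max_value
  img
}

#' Simulate a plate end to end and optionally write it to disk
#'
#' Convenience wrapper: samples ground truth, renders all images, and — when
#' `dir` is given — writes the layout file, one 16-bit grayscale TIFF per
#' (well, field, channel) named `<well>_f<field>_<channel>.tif`, and
#' plain-text ground-truth tables (`truth_nuclei.csv`, `truth_effects.csv`)
#' that round-trip losslessly.
#'
#' @inheritParams sample_nuclei
#' @inheritParams render_plate
#' @param dir Output directory, created if needed; `NULL` keeps everything in
#'   memory.
#' @return A list with `truth`, `images` (tibble as in [render_plate()]) and
#'   `dir`.
#' @export
simulate_plate <- function(layout, effect_table = NULL,
                           params = synth_params(), seed = 1L,
                           noise = TRUE, dir = NULL) {
  truth <- sample_nuclei(layout, effect_table, params, seed)
  images <- render_plate(truth, layout, noise = noise)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_plate_layout(layout, file.path(dir, "layout.tsv"))
    for (i in seq_len(nrow(images))) {
      write_field_tiff(images$image[[i]],
                       file.path(dir, image_filename(images$well_id[i],
                                                     images$field[i],
                                                     images$channel[i])))
    }
    write_truth_table(truth$nuclei, file.path(dir, "truth_nuclei.csv"))
    write_truth_table(truth$effects, file.path(dir, "truth_effects.csv"))
  }
  list(truth = truth, images = images, dir = dir)
}

image_filename <- function(well_id, field, channel) {
  sprintf("%s_f%02d_%s.tif", well_id, field, channel)
}

#' Read or write a field image as 16-bit grayscale TIFF
#'
#' Images hold integer values in the camera's 11-bit range; the 16-bit TIFF
#' container stores them losslessly.
#'
#' @param img Integer-valued matrix in `[0, 65535]`.
#' @param path File path.
#' @return `read_field_tiff()` returns a numeric matrix of integer values.
#' @export
write_field_tiff <- function(img, path) {
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(img) <- "double"
  img
}

# Lossless plain-text serialisation of truth tables: doubles are written with
# 17 significant digits so read -> write -> read is the identity.
write_truth_table <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_truth_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) && all(!is.na(suppressWarnings(as.numeric(df[[j]]))) |
                                     is.na(df[[j]]))) {
      num <- suppressWarnings(as.numeric(df[[j]]))
      if (!anyNA(num[!is.na(df[[j]])])) df[[j]] <- num
    }
  }
  as_tibble(df)
}

#' Statistics-level simulation of replicate condition medians
#'
#' Skips image rendering and draws per-replicate well medians directly:
#' `median ~ Normal(baseline * multiplier, cv * baseline * multiplier)`.
#' Used for calibration studies (null false-positive rate, power) where
#' thousands of plates are needed.
#'
#' @param effect_table Named numeric vector or tibble as in [sample_nuclei()].
#' @param n_replicates Replicate wells per condition.
#' @param baseline Control-mean median intensity (a.u.).
#' @param cv Across-replicate coefficient of variation of the well medians.
#' @param channel Readout channel label.
#' @param seed Integer seed.
#' @return A tibble `condition`, `channel`, `replicate`, `well_median`.
#' @export
simulate_condition_medians <- function(effect_table, n_replicates = 3L,
                                       baseline = 10000, cv = 0.05,
                                       channel = "tf1", seed = 1L) {
  effects <- normalize_effect_table(effect_table,
                                    conditions = names(effect_table) %||%
                                      unique(effect_table$condition),
                                    tf_channels = channel)
  effects <- effects[effects$channel == channel, ]
  with_seed(seed, {
    tidyr::expand_grid(condition = effects$condition,
                       replicate = seq_len(n_replicates)) |>
      left_join(effects[, c("condition", "multiplier")], by = "condition") |>
      mutate(channel = channel,
             well_median = rnorm(dplyr::n(),
                                 baseline * .data$multiplier,
                                 cv * baseline * .data$multiplier)) |>
      select("condition", "channel", "replicate", "well_median")
  })
}
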