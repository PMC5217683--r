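# Image preprocessing: detector (dark-frame) subtraction, per-position
# multiplicative shading correction estimated from uniformly fluorescent
# reference wells, and quantile-based background subtraction.

#' Estimate the detector offset map from dark frames
#'
#' The detector value is the camera signal recorded without a light source;
#' it is an additive per-pixel offset, estimated as the pixel-wise mean over
#' all dark frames.
#'
#' @param dark_frames A list of matrices (dark frames), all the same shape.
#' @return A matrix of per-pixel offsets with the image shape.
#' @export
estimate_detector <- function(dark_frames) {
  if (is.matrix(dark_frames)) dark_frames <- list(dark_frames)
  if (!length(dark_frames)) {
    abort("at least one dark frame is required",
          class = "platetalk_missing_input")
  }
  shp <- dim(dark_frames[[1]])
  if (!all(vapply(dark_frames, function(x) identical(dim(x), shp), logical(1)))) {
    abort("dark frames differ in shape", class = "platetalk_config_error")
  }
  Reduce(`+`, dark_frames) / length(dark_frames)
}

#' Estimate per-position shading surfaces from reference wells
#'
#' Uneven illumination is modelled as a smooth multiplicative field that
#' depends on the within-well field position.  For each (position, channel),
#' all detector-subtracted reference-well images at that position are pooled
#' and averaged, lightly Gaussian-smoothed to suppress reference pixel noise,
#' and rescaled to mean 1 — so the estimate is invariant to the reference
#' wells' absolute brightness.
#'
#' @param reference_images A tibble as produced by [render_plate()] (columns
#'   `well_id`, `role`, `field`, `channel`, list-column `image`), restricted
#'   or not to reference wells — only rows with `role == "reference"` are
#'   used.
#' @param detector Per-pixel offset map from [estimate_detector()].
#' @param smooth_sigma SD of the Gaussian smoothing kernel in pixels; the
#'   default, 1/64 of the image width, suppresses pixel noise while leaving
#'   genuine low-frequency shading essentially unattenuated.
#' @return A nested list: `shading[[position]][[channel]]`, each a strictly
#'   positive unit-mean matrix.
#' @export
estimate_shading <- function(reference_images, detector, smooth_sigma = NULL) {
  refs <- reference_images[reference_images$role == "reference", ]
  if (!nrow(refs)) {
    abort("no reference-well images supplied",
          class = "platetalk_missing_reference")
  }
  smooth_sigma <- smooth_sigma %||% (ncol(detector) / 64)
  positions <- sort(unique(refs$field))
  channels <- unique(refs$channel)
  out <- lapply(positions, function(p) {
    chs <- lapply(channels, function(ch) {
      grp <- refs[refs$field == p & refs$channel == ch, ]
      avg <- Reduce(`+`, lapply(grp$image, function(im) im - detector)) /
        nrow(grp)
      sm <- smooth_gaussian(avg, smooth_sigma)
      if (any(sm <= 0)) {
        abort("shading estimate is not strictly positive; reference wells too dim",
              class = "platetalk_missing_reference")
      }
      sm / mean(sm)
    })
    setNames(chs, channels)
  })
  setNames(out, as.character(positions))
}

#' Estimate the image background level
#'
#' The background of a corrected image is the mean of all pixels strictly
#' below the 0.001 empirical quantile (linear-interpolation definition).  If
#' no pixel lies strictly below that quantile (ties, e.g. a constant image),
#' the image minimum is returned.
#'
#' @param image A numeric matrix with at least 1,000 pixels.
#' @param q Quantile defining the background pixel set.
#' @return The background scalar (a.u.).
#' @export
estimate_background <- function(image, q = 0.001) {
  if (!all(is.finite(image))) {
    abort("image contains non-finite pixels", class = "platetalk_invalid_image")
  }
  if (length(image) < 1000L) {
    abort("image must have at least 1,000 pixels for background estimation",
          class = "platetalk_invalid_image")
  }
  cut <- quantile(image, q, names = FALSE, type = 7)
  lo <- image[image < cut]
  if (!length(lo)) return(min(image))
  mean(lo)
}

#' Assemble a correction model from a rendered plate
#'
#' Fits the full correction model from the plate's own calibration images:
#' detector offset from dark frames and shading from reference wells.
#'
#' @param images A tibble of images as produced by [render_plate()], including
#'   `dark` and `reference` rows.
#' @inheritParams estimate_shading
#' @return An object of class `correction_model` with elements `detector` and
#'   `shading` (`[[position]][[channel]]`).
#' @export
fit_correction_model <- function(images, smooth_sigma = NULL) {
  darks <- images$image[images$role == "dark"]
  detector <- estimate_detector(darks)
  shading <- estimate_shading(images, detector, smooth_sigma = smooth_sigma)
  structure(list(detector = detector, shading = shading),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat("<correction_model> detector ", nrow(x$detector), "x", ncol(x$detector),
      " px; shading for ", length(x$shading), " position(s) x ",
      length(x$shading[[1]]), " channel(s)\n", sep = "")
  invisible(x)
}

#' Correct a raw field image
#'
#' Applies the three correction steps in their fixed order: subtract the
#' detector offset, divide by the position- and channel-specific shading
#' surface, then subtract the per-image background estimated *after* the
#' division.  Small negative pixels are retained (not clipped) so that
#' downstream total-intensity sums stay unbiased.
#'
#' @param raw Raw image matrix.
#' @param model A `correction_model` from [fit_correction_model()].
#' @param position Within-well field position of the image.
#' @param channel Channel label of the image.
#' @return The corrected image matrix, with the estimated background stored
#'   in attribute `"background"`.
#' @export
correct_image <- function(raw, model, position, channel) {
  sh <- model$shading[[as.character(position)]]
  if (is.null(sh) || is.null(sh[[channel]])) {
    abort(sprintf("no shading estimate for position %s, channel '%s'",
                  position, channel),
          class = "platetalk_missing_reference")
  }
  flat <- (raw - model$detector) / sh[[channel]]
  bg <- estimate_background(flat)
  out <- flat - bg
  attr(out, "background") <- bg
  out
}

#' Correct every cell-bearing and reference image of a plate
#'
#' @param images Image tibble from [render_plate()].
#' @param model A `correction_model`; fitted from `images` if omitted.
#' @inheritParams estimate_shading
#' @return The image tibble with `image` replaced by corrected matrices and a
#'   `background` column appended; dark frames are dropped.
#' @export
correct_plate <- function(images, model = NULL, smooth_sigma = NULL) {
  model <- model %||% fit_correction_model(images, smooth_sigma = smooth_sigma)
  out <- images[images$role != "dark", ]
  corrected <- pmap(out[, c("field", "channel", "image")],
                    function(field, channel, image) {
                      correct_image(image, model, field, channel)
                    })
  out$background <- map_dbl(corrected, attr, "background")
  out$image <- map(corrected, function(im) { attr(im, "background") <- NULL; im })
  out
}

#' Serialise or load a correction model
#'
#' The model directory holds the detector map and each shading surface as a
#' text matrix plus a JSON manifest describing positions and channels.
#'
#' @param model A `correction_model`.
#' @param dir Directory path.
#' @return `write_correction_model()` returns `dir` invisibly;
#'   `read_correction_model()` returns the model.
#' @export
write_correction_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_txt(model$detector, file.path(dir, "detector.txt"))
  manifest <- list(positions = names(model$shading),
                   channels = names(model$shading[[1]]))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  for (p in names(model$shading)) {
    for (ch in names(model$shading[[p]])) {
      write_matrix_txt(model$shading[[p]][[ch]],
                       file.path(dir, sprintf("shading_p%s_%s.txt", p, ch)))
    }
  }
  invisible(dir)
}

#' @rdname write_correction_model
#' @export
read_correction_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  detector <- read_matrix_txt(file.path(dir, "detector.txt"))
  shading <- lapply(manifest$positions, function(p) {
    setNames(lapply(manifest$channels, function(ch) {
      read_matrix_txt(file.path(dir, sprintf("shading_p%s_%s.txt", p, ch)))
    }), manifest$channels)
  })
  structure(list(detector = detector,
                 shading = setNames(shading, manifest$positions)),
            class = "correction_model")
}

write_matrix_txt <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
             con)
  invisible(path)
}

read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
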