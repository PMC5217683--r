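# Nuclear segmentation by automated threshold on the corrected Hoechst
# channel, and per-nucleus feature extraction across all channels.

#' Segment nuclei by automated thresholding
#'
#' Applies a global Otsu threshold to the corrected Hoechst image, labels
#' connected components (8-connectivity), removes components outside the
#' `[min_area, max_area]` pixel range or touching the image border (their
#' totals would be truncated), and relabels the survivors densely from 1.
#' No watershed splitting is attempted; touching clumps are left to the area
#' filter here and the texture filter downstream.
#'
#' @param hoechst Corrected Hoechst-channel image matrix.
#' @param min_area,max_area Component area limits, pixels.
#' @return An integer label matrix (0 = background, labels dense from 1).
#' @export
segment_nuclei <- function(hoechst, min_area = 10L, max_area = 600L) {
  stopifnot(min_area < max_area)
  rng <- range(hoechst)
  if (diff(rng) <= 0) {
    warn("image is constant; no nuclei found")
    return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  }
  norm <- (hoechst - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256L)
  mask <- norm > thr
  if (!any(mask)) {
    warn("no foreground above the automatic threshold")
    return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  lab <- matrix(as.integer(lab), nrow(hoechst))
  areas <- tabulate(lab[lab > 0L])
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep <- which(areas >= min_area & areas <= max_area &
                  !(seq_along(areas) %in% border))
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- relabel[lab[pos]]
  out
}

#' Extract per-nucleus features across channels
#'
#' Computes, for every labelled nucleus and every channel: total intensity
#' (sum of corrected pixels in the mask), mean intensity, and the coefficient
#' of variation of within-mask pixel intensities (population-SD convention,
#' divide by N) — a proxy for texture.  A channel whose within-mask mean is
#' not positive gets `NA` CV but the nucleus is retained.
#'
#' @param mask Integer label matrix from [segment_nuclei()].
#' @param channels Named list of corrected image matrices, one per channel,
#'   all the shape of `mask`.
#' @param well_id,field Identifiers copied into the output.
#' @return A tibble with one row per nucleus: `well_id`, `field`, `nucleus`,
#'   `area`, `centroid_row`, `centroid_col` (0-based pixel centers), and per
#'   channel `total_<ch>`, `mean_<ch>`, `cv_<ch>`.
#' @export
extract_features <- function(mask, channels, well_id = NA_character_,
                             field = NA_integer_) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  for (ch in names(channels)) {
    if (!identical(dim(channels[[ch]]), dim(mask))) {
      abort(sprintf("channel '%s' does not match the mask shape", ch),
            class = "platetalk_config_error")
    }
  }
  labs <- sort(unique(mask[mask > 0L]))
  if (!length(labs)) {
    return(empty_nucleus_table(names(channels)))
  }
  idx <- which(mask > 0L)
  lab_vec <- factor(mask[idx], levels = labs)
  rows0 <- (idx - 1L) %% nrow(mask)        # 0-based row
  cols0 <- (idx - 1L) %/% nrow(mask)       # 0-based col
  area <- as.integer(table(lab_vec))
  rec <- tibble(
    well_id = well_id, field = field, nucleus = as.integer(labs),
    area = area,
    centroid_row = as.numeric(tapply(rows0, lab_vec, mean)),
    centroid_col = as.numeric(tapply(cols0, lab_vec, mean))
  )
  for (ch in names(channels)) {
    v <- channels[[ch]][idx]
    tot <- as.numeric(tapply(v, lab_vec, sum))
    mn <- tot / area
    sdv <- as.numeric(tapply(v, lab_vec, population_sd))
    cv <- ifelse(mn > 0, sdv / mn, NA_real_)
    rec[[paste0("total_", ch)]] <- tot
    rec[[paste0("mean_", ch)]] <- mn
    rec[[paste0("cv_", ch)]] <- cv
  }
  rec
}

empty_nucleus_table <- function(channel_names) {
  rec <- tibble(well_id = character(), field = integer(), nucleus = integer(),
                area = integer(), centroid_row = numeric(),
                centroid_col = numeric())
  for (ch in channel_names) {
    rec[[paste0("total_", ch)]] <- numeric()
    rec[[paste0("mean_", ch)]] <- numeric()
    rec[[paste0("cv_", ch)]] <- numeric()
  }
  rec
}

#' Segment and quantify every field of a corrected plate
#'
#' Runs [segment_nuclei()] on the Hoechst channel of each (well, field) and
#' [extract_features()] across all channels, returning one combined nucleus
#' table for the plate.
#'
#' @param corrected Corrected image tibble from [correct_plate()].
#' @param hoechst_channel Label of the DNA channel used for segmentation.
#' @param mask_dir Optional directory; when given, each labelled mask is
#'   written there as 16-bit TIFF named `<well>_f<NN>_mask.tif`.
#' @inheritParams segment_nuclei
#' @return A tibble of nucleus records (see [extract_features()]), sample and
#'   control wells only.
#' @export
quantify_plate <- function(corrected, hoechst_channel = "hoechst",
                           min_area = 10L, max_area = 600L,
                           mask_dir = NULL) {
  cells <- corrected[corrected$role %in% c("sample", "control"), ]
  if (!nrow(cells)) {
    abort("no sample or control images to quantify",
          class = "platetalk_missing_input")
  }
  groups <- distinct(cells[, c("well_id", "field")])
  recs <- pmap(groups, function(well_id, field) {
    sub <- cells[cells$well_id == well_id & cells$field == field, ]
    chans <- setNames(sub$image, sub$channel)
    if (!hoechst_channel %in% names(chans)) {
      abort(sprintf("no '%s' channel for well %s field %d",
                    hoechst_channel, well_id, field),
            class = "platetalk_config_error")
    }
    mask <- segment_nuclei(chans[[hoechst_channel]], min_area, max_area)
    if (!is.null(mask_dir)) {
      dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
      write_field_tiff(mask, file.path(mask_dir,
                                       sprintf("%s_f%02d_mask.tif",
                                               well_id, field)))
    }
    extract_features(mask, chans, well_id = well_id, field = field)
  })
  bind_rows(recs)
}
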