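#' Construct a plate layout
#'
#' A plate layout maps each well of a multi-well plate to its role in the
#' experiment and, for sample wells, to a treatment condition.  Four roles are
#' recognised: `"sample"` (ligand-treated cells), `"control"` (cells without
#' ligand), `"reference"` (wells containing uniform fluorophore only, used to
#' estimate uneven illumination) and `"dark"` (frames acquired without a light
#' source, used to estimate the detector offset).
#'
#' @param wells A data frame with one row per well and columns `well_id`,
#'   `role` (one of `sample`, `control`, `reference`, `dark`), `condition`
#'   (treatment label; `NA` allowed for reference/dark wells), `ligands`
#'   (free-text ligand set with molar concentrations, e.g.
#'   `"Wnt3A=4.8e-09"`; `""` for untreated), `replicate` (positive integer)
#'   and `time_h` (treatment duration, hours).
#' @param fields_per_well Number of imaged fields of view per well.  Shading
#'   is modelled per within-well field position, so positions are comparable
#'   across wells.
#' @param image_shape Integer vector `c(rows, cols)` of each field image, in
#'   pixels.
#' @param channels Character vector of channel labels; the first is taken as
#'   the DNA (Hoechst-like) channel unless stated otherwise downstream.
#'
#' @return An object of class `plate_layout`: a list with elements `wells`
#'   (tibble), `fields_per_well`, `image_shape` and `channels`.
#' @examples
#' layout <- plate_layout(
#'   wells = tibble::tibble(
#'     well_id   = c("A01", "A02", "B01", "B02"),
#'     role      = c("control", "sample", "reference", "dark"),
#'     condition = c("control", "Wnt3A", NA, NA),
#'     ligands   = c("", "Wnt3A=4.8e-09", "", ""),
#'     replicate = c(1L, 1L, 1L, 1L),
#'     time_h    = c(2, 2, NA, NA)
#'   ),
#'   fields_per_well = 2, image_shape = c(128, 128),
#'   channels = c("hoechst", "tf1")
#' )
#' layout
#' @export
plate_layout <- function(wells, fields_per_well = 4L,
                         image_shape = c(256L, 256L),
                         channels = c("hoechst", "tf1")) {
  wells <- as_tibble(wells)
  required <- c("well_id", "role", "condition", "ligands", "replicate", "time_h")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    abort(paste0("layout wells are missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "platetalk_config_error")
  }
  wells$well_id <- as.character(wells$well_id)
  wells$role <- as.character(wells$role)
  wells$condition <- as.character(wells$condition)
  wells$ligands <- as.character(wells$ligands)
  wells$replicate <- as.integer(wells$replicate)
  wells$time_h <- as.numeric(wells$time_h)

  bad_role <- setdiff(unique(wells$role), c("sample", "control", "reference", "dark"))
  if (length(bad_role)) {
    abort(paste0("unknown well role(s): ", paste(bad_role, collapse = ", ")),
          class = "platetalk_config_error")
  }
  if (anyDuplicated(wells$well_id)) {
    abort("well ids must be unique", class = "platetalk_config_error")
  }
  smp <- wells[wells$role == "sample", ]
  if (any(is.na(smp$condition) | smp$condition == "")) {
    abort("every sample well needs exactly one condition label",
          class = "platetalk_config_error")
  }
  if (!any(wells$role == "control") || !any(wells$role == "reference")) {
    abort("a plate needs at least one control well and one reference well",
          class = "platetalk_config_error")
  }
  cells <- wells[wells$role %in% c("sample", "control"), ]
  if (any(!is.na(cells$replicate) & cells$replicate < 1L)) {
    abort("replicate indices must be positive integers",
          class = "platetalk_config_error")
  }
  fields_per_well <- as.integer(fields_per_well)
  stopifnot_scalar_number(fields_per_well, "fields_per_well", lower = 1)
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 8L)) {
    abort("`image_shape` must be two pixel dimensions of at least 8",
          class = "platetalk_config_error")
  }
  channels <- as.character(channels)
  if (!length(channels) || anyDuplicated(channels)) {
    abort("`channels` must be a non-empty set of unique labels",
          class = "platetalk_config_error")
  }
  structure(
    list(wells = wells, fields_per_well = fields_per_well,
         image_shape = image_shape, channels = channels),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  counts <- table(factor(x$wells$role,
                         levels = c("sample", "control", "reference", "dark")))
  cat("<plate_layout> ", nrow(x$wells), " wells (",
      paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
      ")\n", sep = "")
  cat("  fields/well: ", x$fields_per_well,
      "; image: ", x$image_shape[1], "x", x$image_shape[2], " px",
      "; channels: ", paste(x$channels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' A compact default crosstalk plate layout
#'
#' Builds a small layout for a three-pathway crosstalk experiment: one
#' no-ligand control well and one sample well per (condition, replicate),
#' plus reference and dark wells.  Conditions default to the canonical
#' single-ligand treatments; combinations may be added as `"A+B"` labels.
#'
#' @param conditions Character vector of sample condition labels (not
#'   including the control).
#' @param n_replicates Number of biological replicates (well per condition per
#'   replicate).  The no-ligand control is included automatically.
#' @param n_reference,n_dark Number of reference and dark wells.
#' @inheritParams plate_layout
#' @return A [plate_layout()].
#' @export
default_layout <- function(conditions = c("Wnt3A", "TGFb3", "BMP4"),
                           n_replicates = 3L,
                           n_reference = 2L, n_dark = 2L,
                           fields_per_well = 2L,
                           image_shape = c(256L, 256L),
                           channels = c("hoechst", "tf1")) {
  conds <- c("control", conditions)
  grid <- expand.grid(condition = conds, replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  wells <- tibble(
    well_id = sprintf("S%02d", seq_len(nrow(grid))),
    role = ifelse(grid$condition == "control", "control", "sample"),
    condition = grid$condition,
    ligands = ifelse(grid$condition == "control", "",
                     paste0(gsub("\\+", "=1e-09;", grid$condition), "=1e-09")),
    replicate = as.integer(grid$replicate),
    time_h = 2
  )
  refs <- tibble(well_id = sprintf("R%02d", seq_len(n_reference)),
                 role = "reference", condition = NA_character_,
                 ligands = "", replicate = NA_integer_, time_h = NA_real_)
  darks <- tibble(well_id = sprintf("D%02d", seq_len(n_dark)),
                  role = "dark", condition = NA_character_,
                  ligands = "", replicate = NA_integer_, time_h = NA_real_)
  plate_layout(bind_rows(wells, refs, darks),
               fields_per_well = fields_per_well,
               image_shape = image_shape, channels = channels)
}

#' Read or write a plate layout file
#'
#' Layouts are stored as plain tab-separated text: a header block of
#' `#key: value` lines (`fields_per_well`, `image_shape`, `channels`)
#' followed by one row per well.  Reading a written layout reproduces the
#' original exactly.
#'
#' @param layout A [plate_layout()].
#' @param path File path.
#' @return `write_plate_layout()` returns `path` invisibly;
#'   `read_plate_layout()` returns a [plate_layout()].
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  header <- c(
    sprintf("#fields_per_well: %d", layout$fields_per_well),
    sprintf("#image_shape: %d %d", layout$image_shape[1], layout$image_shape[2]),
    sprintf("#channels: %s", paste(layout$channels, collapse = " "))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(layout$wells, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#", key, ": "), hdr, value = TRUE)
    if (!length(m)) abort(paste0("layout file missing header '", key, "'"),
                          class = "platetalk_config_error")
    sub(paste0("^#", key, ": "), "", m[1])
  }
  wells <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                             header = TRUE, na.strings = "NA",
                             colClasses = c(well_id = "character",
                                            role = "character",
                                            condition = "character",
                                            ligands = "character"))
  wells$ligands[is.na(wells$ligands)] <- ""
  plate_layout(
    wells,
    fields_per_well = as.integer(get("fields_per_well")),
    image_shape = as.integer(strsplit(get("image_shape"), " ")[[1]]),
    channels = strsplit(get("channels"), " ")[[1]]
  )
}
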