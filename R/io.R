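# Readers and writers for the package's on-disk formats: profiles as TSV,
# traits as JSON, image sequences as multi-page TIFF with a JSON sidecar,
# expression tables as TSV.

#' Write a profile as TSV
#'
#' Writes any profile container (velocity, EER, brightness, cell length) as a
#' tab-separated file with a header row.
#'
#' @param profile A profile data frame.
#' @param path Output file path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a velocity profile from TSV
#'
#' Expects columns `position_mm` and `velocity_mm_per_h` (optionally
#' `n_obs`).
#'
#' @param path File path.
#' @return A [velocity_profile()].
#' @export
read_velocity_profile <- function(path) {
  d <- utils::read.delim(path)
  velocity_profile(d$position_mm, d$velocity_mm_per_h,
                   n_obs = d$n_obs)
}

#' Read a brightness profile from TSV
#' @param path File path (columns `position_mm`, `brightness`).
#' @return A [brightness_profile()].
#' @export
read_brightness_profile <- function(path) {
  d <- utils::read.delim(path)
  brightness_profile(d$position_mm, d$brightness)
}

#' Read a cell length profile from TSV
#' @param path File path (columns `position_mm`, `cell_length_um`).
#' @return A [cell_length_profile()].
#' @export
read_cell_length_profile <- function(path) {
  d <- utils::read.delim(path)
  cell_length_profile(d$position_mm, d$cell_length_um)
}

#' Write growth traits as JSON
#'
#' Serializes a [growth_traits()] object with the fixed key set
#' `growth_rate_mm_h`, `eer_max_h`, `eer_max_abscissa_mm`, `gz_length_mm`,
#' `dz_length_mm`, `ez_length_mm`, `cell_production_rate_h`.
#'
#' @param traits A [growth_traits()].
#' @param path Output file path.
#' @export
write_growth_traits <- function(traits, path) {
  stopifnot(inherits(traits, "growth_traits"))
  jsonlite::write_json(as.list(as.data.frame(traits)), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read growth traits from JSON
#' @param path File path written by [write_growth_traits()].
#' @return A [growth_traits()].
#' @export
read_growth_traits <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  growth_traits(growth_rate = as_na(j$growth_rate_mm_h),
                eer_max = as_na(j$eer_max_h),
                eer_max_abscissa = as_na(j$eer_max_abscissa_mm),
                gz_length = as_na(j$gz_length_mm),
                dz_length = as_na(j$dz_length_mm),
                ez_length = as_na(j$ez_length_mm),
                cell_production_rate = as_na(j$cell_production_rate_h))
}

#' Write an image sequence as multi-page TIFF plus JSON sidecar
#'
#' Frames are rescaled to [0, 1] jointly (the scale factor is stored in the
#' sidecar) and written as 16-bit multi-page TIFF; timestamps, pixel size and
#' the ground truth needed by downstream tests (tip track, QC track, division
#' zone length) go to the JSON sidecar.
#'
#' @param images An `image_sequence`.
#' @param tif_path Output TIFF path.
#' @param json_path Output sidecar path; default `tif_path` with `.json`.
#' @export
write_image_sequence <- function(images, tif_path,
                                 json_path = sub("\\.tiff?$", ".json", tif_path)) {
  stopifnot(inherits(images, "image_sequence"))
  mx <- max(vapply(images$frames, max, numeric(1)), 1e-12)
  tiff::writeTIFF(lapply(images$frames, function(f) pmin(f / mx, 1)),
                  tif_path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = images$pixel_size,
               timestamps_h = images$timestamps,
               axis = images$axis,
               intensity_scale = mx)
  if (!is.null(images$truth)) {
    meta$truth <- list(tip_px = images$truth$tip_px,
                       qc_px = images$truth$qc_px,
                       qc_offset_mm = images$truth$qc_offset,
                       dz_length_mm = images$truth$dz_length,
                       growth_rate_mm_h = images$truth$growth_rate)
  }
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tif_path)
}

#' Read an image sequence written by [write_image_sequence()]
#'
#' @param tif_path TIFF path.
#' @param json_path Sidecar path; default derived from `tif_path`.
#' @return An `image_sequence` (ground truth restored from the sidecar if
#'   present; particle-level truth is not serialized).
#' @export
read_image_sequence <- function(tif_path,
                                json_path = sub("\\.tiff?$", ".json", tif_path)) {
  frames <- tiff::readTIFF(tif_path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  sc <- meta$intensity_scale %||% 1
  frames <- lapply(frames, function(f) f * sc)
  truth <- NULL
  if (!is.null(meta$truth)) {
    truth <- list(tip_px = meta$truth$tip_px, qc_px = meta$truth$qc_px,
                  qc_offset = meta$truth$qc_offset_mm,
                  dz_length = meta$truth$dz_length_mm,
                  growth_rate = meta$truth$growth_rate_mm_h)
  }
  structure(list(frames = frames, timestamps = meta$timestamps_h,
                 pixel_size = meta$pixel_size_um,
                 axis = meta$axis %||% "tip-right", truth = truth),
            class = "image_sequence")
}

#' Write an expression table as TSV
#'
#' Genes in rows (first column `gene_id`), 32 sample columns named
#' `zone_treatment_time_Rrep`.
#'
#' @param table An `expression_table`.
#' @param path Output file path.
#' @param truth_path Optional path for the ground-truth labels TSV.
#' @export
write_expression_table <- function(table, path, truth_path = NULL) {
  stopifnot(inherits(table, "expression_table"))
  df <- data.frame(gene_id = rownames(table$fpkm), table$fpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth_path) && !is.null(table$truth)) {
    utils::write.table(table$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an expression table from TSV
#' @param path File written by [write_expression_table()].
#' @return An `expression_table`.
#' @export
read_expression_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  expression_table(m)
}
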