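# Reading and writing the pipeline's on-disk formats: multi-page TIFF fields
# with a JSON sidecar, ground-truth tables, and nucleus-level CSVs.

#' Write a field as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per channel (intensities clamped to \[0,1\]); the sidecar
#' records channel names, pixel size and identifiers, and optionally the
#' ground truth. Ground truth is also written as a flat CSV
#' (`<stem>_truth.csv`) when supplied.
#'
#' @param field a [field_image()].
#' @param path output TIFF path (`.tif`); the sidecar is `<stem>.json`.
#' @param truth optional ground truth from [synthesize_field()].
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path, truth = NULL) {
  stopifnot(inherits(field, "field_image"))
  pages <- lapply(field$channels, function(ch) pmin(pmax(ch, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  stem <- sub("\\.tiff?$", "", path)
  meta <- list(channels = names(field$channels),
               pixel_size_um = field$pixel_size, field_id = field$field_id,
               sample_id = field$sample_id, area_id = field$area_id)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(truth)) {
    tr <- merge(truth$foci,
                truth$nuclei[c("nucleus_id", "row", "col", "geminin")],
                by = "nucleus_id", suffixes = c("_focus", "_nucleus"))
    out <- data.frame(field_id = field$field_id,
                      nucleus_id = tr$nucleus_id,
                      x_px = tr$col_nucleus, y_px = tr$row_nucleus,
                      geminin = tr$geminin, marker = tr$marker,
                      focus_x_px = tr$col_focus, focus_y_px = tr$row_focus,
                      diameter_um = tr$diameter_um)
    write.csv(out, paste0(stem, "_truth.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a field written by [write_field_tiff()]
#'
#' @param path TIFF path; `<stem>.json` must exist beside it.
#' @return a [field_image()].
#' @export
read_field_tiff <- function(path) {
  stem <- sub("\\.tiff?$", "", path)
  sidecar <- paste0(stem, ".json")
  if (!file.exists(sidecar))
    abort(sprintf("sidecar %s not found", sidecar),
          class = "rad51score_data_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- setNames(lapply(pages, function(p) matrix(p, nrow(p), ncol(p))),
                       meta$channels)
  field_image(channels, pixel_size = meta$pixel_size_um,
              field_id = meta$field_id, sample_id = meta$sample_id,
              area_id = meta$area_id)
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path))
    abort(sprintf("%s table not found: %s", what, path),
          class = "rad51score_data_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    abort(sprintf("%s table %s lacks columns: %s", what, path,
                  paste(miss, collapse = ", ")),
          class = "rad51score_data_error")
  df
}

#' Read a nucleus-level cell table
#' @param path CSV with the [quantify_field()] schema.
#' @return data.frame.
#' @export
read_cells_csv <- function(path)
  read_table_checked(path, c("sample_id", "field_id", "area_id",
                             "nucleus_id", "geminin"), "cell")

#' Read a tumor-volume table
#' @param path CSV with `model_id`, `animal_id`, `arm`, `day` and
#'   `volume_mm3` (or `L_mm` + `l_mm`).
#' @return data.frame.
#' @export
read_volumes_csv <- function(path)
  read_table_checked(path, c("model_id", "animal_id", "arm", "day"),
                     "volume")
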