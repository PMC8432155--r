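#' Write a synthetic field and its ground truth to disk
#'
#' The field goes to a multi-page 16-bit TIFF (one page per channel); the
#' ground truth to a sidecar CSV with one row per planted object
#' (`object_type`, `field_id`, `row`, `col`, `radius`, `amplitude`,
#' `parent`).
#'
#' @param entry list with `field` and `truth` as produced by
#'   [make_field()].
#' @param tiff_path,truth_path output paths.
#' @return invisibly, the two paths.
#' @export
write_field <- function(entry, tiff_path, truth_path) {
  write_tiff16(entry$field$channels, tiff_path)
  tr <- entry$truth
  rows <- rbind(
    if (nrow(tr$nuclei) > 0)
      data.frame(object_type = "nucleus", field_id = entry$field$field_id,
                 row = tr$nuclei$row, col = tr$nuclei$col,
                 radius = tr$nuclei$radius,
                 amplitude = tr$nuclei$intensity,
                 parent = tr$nuclei$pair_id),
    if (nrow(tr$nuclear_spots) > 0)
      data.frame(object_type = "nuclear_spot",
                 field_id = entry$field$field_id,
                 row = tr$nuclear_spots$row, col = tr$nuclear_spots$col,
                 radius = NA_real_, amplitude = tr$nuclear_spots$peak,
                 parent = tr$nuclear_spots$nucleus),
    if (nrow(tr$extra_nuclear_spots) > 0)
      data.frame(object_type = "extra_nuclear_spot",
                 field_id = entry$field$field_id,
                 row = tr$extra_nuclear_spots$row,
                 col = tr$extra_nuclear_spots$col,
                 radius = NA_real_,
                 amplitude = tr$extra_nuclear_spots$peak,
                 parent = NA_integer_))
  if (is.null(rows))
    rows <- data.frame(object_type = character(0), field_id = integer(0),
                       row = numeric(0), col = numeric(0),
                       radius = numeric(0), amplitude = numeric(0),
                       parent = integer(0))
  write.csv(rows, truth_path, row.names = FALSE)
  invisible(c(tiff_path, truth_path))
}

#' Read a field image from a multi-page TIFF
#'
#' @param path TIFF written by [write_field()] / [write_tiff16()].
#' @param well_id,field_id,line_label,day metadata to attach.
#' @return a `field_image`.
#' @export
read_field <- function(path, well_id = "A01", field_id = 1L,
                       line_label = NA_character_, day = NA_integer_) {
  new_field_image(read_tiff16(path), well_id = well_id,
                  field_id = field_id, line_label = line_label, day = day)
}

#' Write OCR traces as tidy CSV
#'
#' One row per measurement: `well_id`, `line_label`, `phase`, `cycle`,
#' `time`, `ocr`, `cell_density`.
#'
#' @param traces list of `ocr_trace` objects.
#' @param path output CSV.
#' @export
write_ocr_csv <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(t)
    cbind(data.frame(well_id = t$well_id, line_label = t$line_label),
          t$measurements,
          data.frame(cell_density = t$cell_density))))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read OCR traces from tidy CSV
#'
#' @param path CSV as written by [write_ocr_csv()].
#' @return list of `ocr_trace` objects, one per well.
#' @export
read_ocr_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$well_id), function(d)
    ocr_trace(d[, c("phase", "cycle", "time", "ocr")],
              well_id = d$well_id[1], line_label = d$line_label[1],
              cell_density = d$cell_density[1]))
}
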