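# File-format helpers: TIFF images via the tiff package, tables as CSV.

#' Read and write kymographs as TIFF
#'
#' Kymographs are stored as 32-bit float TIFF with rows = frames and columns
#' = position bins; calibration travels separately (CSV/JSON sidecars or
#' function arguments), as TIFF tags are not relied upon.
#'
#' @param kymo A `kymograph`.
#' @param path File path.
#' @param pixel_nm,frame_s Calibration to attach on reading.
#' @return `read_kymograph_tiff` returns a `kymograph`.
#' @export
write_kymograph_tiff <- function(kymo, path) {
  img <- if (inherits(kymo, "kymograph")) kymo$img else kymo
  rng <- range(img)
  scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_kymograph_tiff
#' @export
read_kymograph_tiff <- function(path, pixel_nm, frame_s) {
  img <- tiff::readTIFF(path)
  structure(list(img = img, pixel_nm = pixel_nm, frame_s = frame_s),
            class = "kymograph")
}

#' Read/write bleach-step histograms as CSV (columns `k`, `count`)
#'
#' @param hist A `step_histogram`.
#' @param path File path.
#' @return `read_step_histogram_csv` returns a `step_histogram`.
#' @export
write_step_histogram_csv <- function(hist, path) {
  utils::write.csv(data.frame(k = 1:4, count = unname(hist$counts)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_step_histogram_csv
#' @export
read_step_histogram_csv <- function(path) {
  df <- utils::read.csv(path)
  counts <- integer(4)
  counts[df$k] <- df$count
  step_histogram(counts)
}

#' Read/write track tables as CSV (columns `track_id`, `t_s`, `x_um`)
#'
#' @param tracks data.frame with `track_id`, `t_s`, `x_um`.
#' @param path File path.
#' @export
write_track_csv <- function(tracks, path) {
  utils::write.csv(tracks[, c("track_id", "t_s", "x_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) utils::read.csv(path)

#' Read a binding series from CSV (columns `ligand_uM`, `signal`)
#'
#' @param path File path.
#' @param receptor_total Receptor concentration (uM) to attach.
#' @export
read_binding_csv <- function(path, receptor_total = 0.05) {
  df <- utils::read.csv(path)
  attr(df, "receptor_total") <- receptor_total
  class(df) <- c("binding_series", "data.frame")
  df
}

#' Read calibration standards from CSV
#' (columns `name`, `anchor_value`, `elution_volume_ml`)
#'
#' @param path File path.
#' @export
read_standards_csv <- function(path) utils::read.csv(path)
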