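#' Read an image-manifest CSV
#'
#' The manifest lists one angiogram per row with columns `id`, `path`,
#' `plexus`, `timepoint`, `extent_mm`. Paths are resolved relative to the
#' manifest's directory. Rows with unknown plexus values or missing image
#' files are rejected with an error naming the row.
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame of validated descriptors (possibly empty), with
#'   absolute image paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    oq_error(sprintf("manifest not found: %s", path), "octaquant_missing_file")
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "path", "plexus", "timepoint", "extent_mm")
  if (!all(need %in% names(man)))
    oq_error(sprintf("manifest must have columns %s",
                     paste(need, collapse = ", ")), "octaquant_bad_manifest")
  if (nrow(man) == 0L) return(man)
  base <- dirname(normalizePath(path))
  for (i in seq_len(nrow(man))) {
    if (!man$plexus[i] %in% c("SCP", "DCP"))
      oq_error(sprintf("manifest row %d: unknown plexus '%s'", i, man$plexus[i]),
               "octaquant_bad_manifest")
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p))
      oq_error(sprintf("manifest row %d: image file not found: %s",
                       i, man$path[i]), "octaquant_missing_file")
    man$path[i] <- normalizePath(p)
  }
  man
}

#' Read a grayscale PNG or TIFF angiogram
#'
#' Multichannel images are averaged to one channel. Intensities keep the
#' reader's native 0-1 scale; [to_eight_bit()] normalizes depth downstream.
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @param extent_mm,plexus,meta Passed to [enface_angiogram()].
#' @return An [enface_angiogram()].
#' @export
read_angiogram <- function(path, extent_mm = c(3, 3), plexus = "SCP",
                           meta = list()) {
  if (!file.exists(path))
    oq_error(sprintf("image not found: %s", path), "octaquant_missing_file")
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                oq_error(sprintf("unsupported image format: .%s", ext),
                         "octaquant_bad_format"))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  meta$id <- meta$id %||% basename(path)
  enface_angiogram(arr, extent_mm = extent_mm, plexus = plexus, meta = meta)
}

#' Write quantification results as CSV
#'
#' One row per image with a stable column order; undefined VDI values are
#' written as empty cells. The output round-trips through
#' `utils::read.csv`.
#'
#' @param metrics A `vessel_metrics` or a list of them.
#' @param path Output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
write_metrics_csv <- function(metrics, path) {
  if (inherits(metrics, "vessel_metrics")) metrics <- list(metrics)
  if (!length(metrics))
    oq_error("no metrics to write", "octaquant_bad_input")
  df <- do.call(rbind, lapply(metrics, function(m) data.frame(
    id = m$meta$id %||% NA_character_,
    plexus = m$plexus,
    timepoint = m$meta$timepoint %||% NA_character_,
    vad = m$vad, vsd = m$vsd,
    vdi_px = if (m$vdi_defined) m$vdi_px else NA_real_,
    vdi_um = if (m$vdi_defined) m$vdi_um else NA_real_,
    n_binary_px = m$n_binary_px, n_skeleton_px = m$n_skeleton_px,
    n_total_px = m$n_total_px, pitch_um = m$pitch_um,
    combine_rule = m$config$combine_rule,
    config_hash = config_hash(m$config))))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}

#' Write a binary or skeleton mask as PNG
#'
#' @param mask A `binary_vessel_map`, `skeleton_map`, or logical matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask(mask)
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Write / read a cohort table as CSV
#'
#' @param cohort Cohort data.frame (see [simulate_cohort()]).
#' @param path CSV path.
#' @return `write_cohort_csv` invisibly returns `path`; `read_cohort_csv`
#'   returns the cohort data.frame with `responder` restored to logical.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    oq_error(sprintf("cohort file not found: %s", path), "octaquant_missing_file")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("responder" %in% names(d)) d$responder <- as.logical(d$responder)
  d
}

# Short deterministic fingerprint of a configuration object, recorded in
# outputs so any two runs with equal settings are identifiable.
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 0xFFFFFFFF)
}
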