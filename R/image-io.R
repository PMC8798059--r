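#' Write and read kymographs or field images as multi-page TIFF
#'
#' Images are written as one 32-bit float TIFF page per channel, with a
#' structured-text (YAML) sidecar carrying the calibration: pixel size,
#' frame interval, channel names, seed extent and origin. `read_kymograph`
#' and `read_field_image` reconstruct the objects from the pair of files.
#'
#' @param x A `kymograph` or `field_image`.
#' @param path TIFF path; the sidecar is written at `paste0(path, ".meta.yaml")`.
#' @return The path, invisibly (writers); the reconstructed object (readers).
#' @export
write_kymograph <- function(x, path) {
  stopifnot(inherits(x, "kymograph"))
  sc <- write_channels_tiff(x$channels, path)
  meta <- list(
    type = "kymograph",
    intensity_offset = unname(sc["offset"]),
    intensity_scale = unname(sc["scale"]),
    pixel_size_nm = x$optics$pixel_size_nm,
    frame_interval_s = x$optics$frame_interval_s,
    channels = names(x$channels),
    seed_extent_um = as.numeric(x$seed_extent_um),
    origin = x$origin,
    n_frames = nrow(x$channels[[1]])
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  if (!identical(meta$type, "kymograph")) stop("not a kymograph TIFF: ", path)
  channels <- read_channels_tiff(path, meta$channels,
                                 meta$intensity_offset, meta$intensity_scale)
  optics <- optics_config(pixel_size_nm = meta$pixel_size_nm,
                          frame_interval_s = meta$frame_interval_s,
                          channels = meta$channels)
  structure(
    list(channels = channels, optics = optics,
         frame_times_s = (seq_len(meta$n_frames) - 1) * meta$frame_interval_s,
         seed_extent_um = meta$seed_extent_um, origin = meta$origin),
    class = "kymograph"
  )
}

#' @rdname write_kymograph
#' @export
write_field_image <- function(x, path) {
  stopifnot(inherits(x, "field_image"))
  sc <- write_channels_tiff(x$channels, path)
  meta <- list(
    type = "field_image",
    intensity_offset = unname(sc["offset"]),
    intensity_scale = unname(sc["scale"]),
    pixel_size_nm = x$optics$pixel_size_nm,
    frame_interval_s = x$optics$frame_interval_s,
    channels = names(x$channels),
    field_size_um = x$field_size_um
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_field_image <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  if (!identical(meta$type, "field_image")) stop("not a field TIFF: ", path)
  channels <- read_channels_tiff(path, meta$channels,
                                 meta$intensity_offset, meta$intensity_scale)
  optics <- optics_config(pixel_size_nm = meta$pixel_size_nm,
                          frame_interval_s = meta$frame_interval_s,
                          channels = meta$channels)
  structure(
    list(channels = channels, optics = optics,
         field_size_um = meta$field_size_um),
    class = "field_image"
  )
}

# Intensities are stored as 32-bit pages scaled into [0, 1] by a common
# factor (recorded in the sidecar) so that values survive writers that
# clamp to the unit interval.
write_channels_tiff <- function(channels, path) {
  lo <- min(0, min(vapply(channels, min, numeric(1))))
  hi <- max(1, max(vapply(channels, max, numeric(1))))
  pages <- lapply(channels, function(m) (m - lo) / (hi - lo))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  c(offset = lo, scale = hi - lo)
}

read_channels_tiff <- function(path, channel_names, offset = 0, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(pages, function(p) unclass(p) * scale + offset)
  stats::setNames(channels, channel_names)
}
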