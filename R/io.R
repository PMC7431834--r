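# File formats: multi-page TIFF for intensity/label volumes (one file per
# time point), CSV for all tabular artifacts, YAML/JSON for configs and
# reports. Time points are 1-based everywhere in user-facing outputs;
# voxel indices are 0-based only inside array code.

#' Write an intensity stack as multi-page TIFF
#'
#' One page per z-slice, 32-bit float; intensities are stored scaled to
#' the written `max_intensity` so that round-trips through the unit-range
#' TIFF representation are lossless to float precision.
#'
#' @param stack An [image_stack()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (length(d) == 2L) d <- c(d, 1L)
  mx <- max(stack$data, 1e-12)
  pages <- lapply(seq_len(d[3]), function(z)
    matrix(stack$data[, , z] / mx, d[1], d[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  attr(path, "max_intensity") <- mx
  invisible(path)
}

#' Read a multi-page TIFF as an intensity stack
#'
#' @param path TIFF file (pages = z-slices).
#' @param voxel_size Per-axis voxel size in um.
#' @param frame Optional 1-based frame index.
#' @param max_intensity Rescale factor applied after reading (the value
#'   passed when writing; 1 keeps the unit range).
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path, voxel_size, frame = NULL,
                            max_intensity = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  image_stack(arr * max_intensity, voxel_size, frame = frame)
}

#' Write a label volume as 16-bit multi-page TIFF
#'
#' @param labels A [label_volume()] (at most 65535 labels).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_labels_tiff <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  if (max(labels$labels) > 65535L) stop("more than 65535 labels", call. = FALSE)
  d <- dim(labels$labels)
  if (length(d) == 2L) d <- c(d, 1L)
  pages <- lapply(seq_len(d[3]), function(z)
    matrix(labels$labels[, , z] / 65535, d[1], d[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Read a 16-bit label TIFF back into a label volume
#'
#' @param path TIFF file written by [write_labels_tiff()].
#' @param voxel_size Per-axis voxel size in um.
#' @param connectivity Connectivity declared for the labels.
#' @param frame Optional frame index.
#' @return A [label_volume()].
#' @export
read_labels_tiff <- function(path, voxel_size, connectivity = 26L,
                             frame = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(as.integer(round(unlist(pages) * 65535)),
               dim = c(dim(pages[[1]]), length(pages)))
  label_volume(arr, voxel_size, connectivity = connectivity, frame = frame)
}

# CSV dialect: comma-separated, UTF-8, mandatory header, numerics at 6
# significant digits
write_table_csv <- function(x, path) {
  x <- as.data.frame(x)
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], signif, digits = 6)
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a scene (truth + rendered frames) to a directory
#'
#' Emits `frame_%04d.tif` per time point, `objects.csv` and `events.csv`
#' ground-truth tables, `counts.csv`, and the scene/optics configuration
#' as `config.yaml`.
#'
#' @param truth A `scene_truth`.
#' @param dir Output directory (created if missing).
#' @param optics An [optics_config()], or `NULL` to skip rendering.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(truth, dir, optics = optics_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(optics)) {
    for (k in seq_len(truth$config$n_frames)) {
      st <- render_frame(truth, k, optics)
      st$data <- st$data / max(optics$foreground, optics$background, 1)
      write_stack_tiff(st, file.path(dir, sprintf("frame_%04d.tif", k)))
    }
  }
  write_table_csv(truth$objects, file.path(dir, "objects.csv"))
  write_table_csv(truth$events, file.path(dir, "events.csv"))
  write_table_csv(truth$counts, file.path(dir, "counts.csv"))
  cfg <- truth$config
  cfg$events <- if (is.null(cfg$events)) NULL else as.data.frame(cfg$events)
  yaml::write_yaml(c(unclass(cfg),
                     if (!is.null(optics)) list(optics = unclass(optics))),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
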