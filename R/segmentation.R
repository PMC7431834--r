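#' Create an intensity stack
#'
#' Light-weight container for one imaged time point: a 2D or 3D array of
#' non-negative intensities plus the physical voxel size in micrometres.
#'
#' @param data Numeric array (2D or 3D) of finite, non-negative intensities.
#' @param voxel_size Numeric vector of per-axis voxel sizes in um (length
#'   matching `dim(data)`).
#' @param frame Optional 1-based time-point index.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size, frame = NULL) {
  data <- as.array(data)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, length(dim(data)))
  if (length(voxel_size) != length(dim(data)))
    stop("voxel_size must have one entry per array dimension", call. = FALSE)
  if (any(voxel_size <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 frame = frame),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack> ", paste(dim(x$data), collapse = " x "),
      " voxels @ (", paste(signif(x$voxel_size, 3), collapse = ", "),
      ") um", if (!is.null(x$frame)) paste0(", frame ", x$frame), "\n", sep = "")
  invisible(x)
}

#' Photobleaching correction of a time series
#'
#' Equalizes the global mean intensity of every frame to that of the first
#' frame by a per-frame multiplicative rescale. Within-frame voxel rank
#' order is unchanged, so downstream thresholding sees the same geometry at
#' a stable intensity scale.
#'
#' @param stacks List of [image_stack()] objects sharing shape and voxel size.
#' @return List of corrected `image_stack` objects.
#' @export
bleach_correct <- function(stacks) {
  if (length(stacks) < 1L) stop("need at least one frame", call. = FALSE)
  d1 <- dim(stacks[[1]]$data); v1 <- stacks[[1]]$voxel_size
  means <- vapply(stacks, function(s) {
    if (!identical(dim(s$data), d1) || !isTRUE(all.equal(s$voxel_size, v1)))
      stop("frames must share shape and voxel size", call. = FALSE)
    mean(s$data)
  }, numeric(1))
  if (any(means == 0))
    stop("frame with zero mean intensity cannot be rescaled", call. = FALSE)
  lapply(seq_along(stacks), function(k) {
    s <- stacks[[k]]
    s$data <- s$data * (means[1] / means[k])
    s
  })
}

#' Hysteresis-threshold segmentation
#'
#' Two-threshold segmentation: foreground is the set of voxels with
#' intensity `>= low` that are connected (under `connectivity`) to at least
#' one voxel with intensity `>= high`. Weak "skirt" voxels survive only when
#' attached to a strong core, which suppresses isolated background
#' fluctuations while keeping dim object peripheries.
#'
#' @param stack An [image_stack()].
#' @param low,high Thresholds with `0 <= low <= high`.
#' @param connectivity Voxel connectivity (6/18/26 in 3D, 4/8 in 2D).
#' @return A `label_volume`: integer labels (0 = background) plus voxel size.
#' @export
hysteresis_segment <- function(stack, low, high,
                               connectivity = if (length(dim(stack$data)) == 2L) 8L else 26L) {
  stopifnot(inherits(stack, "image_stack"))
  if (low > high) stop("low threshold must be <= high threshold", call. = FALSE)
  if (low < 0) stop("thresholds must be >= 0", call. = FALSE)
  lab <- label_components(stack$data >= low, connectivity)
  if (max(lab) > 0L) {
    strong <- unique(lab[stack$data >= high])
    strong <- strong[strong > 0L]
    relab <- integer(max(lab))
    relab[strong] <- seq_along(strong)
    lab[] <- ifelse(lab > 0L, relab[pmax(lab, 1L)], 0L)
    # renumber in raster order of first voxel
    lab <- renumber_labels(lab)
  }
  label_volume(lab, stack$voxel_size, connectivity, frame = stack$frame)
}

#' Construct a label volume
#'
#' @param labels Integer array of object labels, 0 = background.
#' @param voxel_size Per-axis voxel size in um.
#' @param connectivity Connectivity under which labels were formed.
#' @param frame Optional 1-based frame index.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size,
                         connectivity = if (length(dim(labels)) == 2L) 8L else 26L,
                         frame = NULL) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, length(dim(labels)))
  if (any(voxel_size <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 connectivity = connectivity, frame = frame),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels, ", max(x$labels), " objects",
      if (!is.null(x$frame)) paste0(", frame ", x$frame), "\n", sep = "")
  invisible(x)
}

# gap-free relabeling in raster order of first voxel
renumber_labels <- function(lab) {
  fg <- which(lab > 0L)
  if (length(fg) == 0L) return(lab)
  old <- lab[fg]
  uo <- unique(old)           # raster order of first occurrence
  relab <- integer(max(uo))
  relab[uo] <- seq_along(uo)
  lab[fg] <- relab[old]
  lab
}

#' Measure labeled objects
#'
#' One row per label: voxel count, physical volume and centroid in um, and
#' the fragmentation flag (volume strictly below `frag_threshold`).
#'
#' @param labels A [label_volume()].
#' @param frag_threshold Fragmentation volume cut in um^3 (default 0.05, the
#'   size below which a mitochondrion is called fragmented).
#' @return A tibble with columns `frame, id, voxels, volume_um3, cx, cy, cz,
#'   fragmented` (`cz` is `NA` for 2D input).
#' @export
measure_objects <- function(labels, frag_threshold = 0.05) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  vsz <- labels$voxel_size
  vox_vol <- prod(vsz)
  fg <- which(lab > 0L)
  frame <- if (is.null(labels$frame)) NA_integer_ else labels$frame
  if (length(fg) == 0L) {
    return(tibble::tibble(frame = integer(0), id = integer(0),
                          voxels = integer(0), volume_um3 = numeric(0),
                          cx = numeric(0), cy = numeric(0), cz = numeric(0),
                          fragmented = logical(0)))
  }
  ids <- lab[fg]
  co <- arrayInd(fg, dim(lab))
  counts <- tabulate(ids)
  keep <- which(counts > 0L)
  # centroid of voxel centres: (i - 0.5) * voxel size
  cx <- rowsum((co[, 1] - 0.5) * vsz[1], ids)[, 1] / counts[keep]
  cy <- rowsum((co[, 2] - 0.5) * vsz[2], ids)[, 1] / counts[keep]
  cz <- if (ncol(co) >= 3L)
    rowsum((co[, 3] - 0.5) * vsz[3], ids)[, 1] / counts[keep]
  else rep(NA_real_, length(keep))
  vol <- counts[keep] * vox_vol
  tibble::tibble(frame = frame, id = keep, voxels = counts[keep],
                 volume_um3 = vol, cx = unname(cx), cy = unname(cy),
                 cz = unname(cz),
                 fragmented = classify_fragmented(vol, frag_threshold))
}

#' Fragmentation classification
#'
#' A mitochondrion counts as fragmented when its volume is strictly smaller
#' than the threshold; an object exactly at the threshold is not fragmented.
#'
#' @param volume_um3 Numeric vector of object volumes (um^3).
#' @param threshold Volume cut in um^3 (default 0.05).
#' @return Logical vector.
#' @export
classify_fragmented <- function(volume_um3, threshold = 0.05) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (any(volume_um3 < 0)) stop("volumes must be >= 0", call. = FALSE)
  volume_um3 < threshold
}

#' Mitochondrial content of a cell
#'
#' Ratio of total mitochondrial volume to the cell volume, reported as a
#' percentage. The cell volume is a supplied number (cell boundaries are
#' identified independently of the mitochondrial channel).
#'
#' @param objects Tibble from [measure_objects()] (or any table with a
#'   `volume_um3` column).
#' @param cell_volume_um3 Cell volume in um^3, > 0.
#' @return Percentage (0-100 scale).
#' @export
mitochondrial_content <- function(objects, cell_volume_um3) {
  if (cell_volume_um3 <= 0) stop("cell volume must be > 0", call. = FALSE)
  100 * sum(objects$volume_um3) / cell_volume_um3
}

#' Heuristic automatic thresholds
#'
#' Sets `high` to the Otsu threshold of the first frame and `low = 0.5 *
#' high`. A convenience starting point only; threshold choice should be
#' reviewed per dataset.
#'
#' @param stack An [image_stack()] (typically frame 1 of a series).
#' @return Named numeric vector `c(low = , high = )`.
#' @export
auto_thresholds <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  high <- otsu_threshold(stack$data)
  c(low = 0.5 * high, high = high)
}
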