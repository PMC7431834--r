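# Rendering of ground-truth scenes into intensity stacks: binary ellipsoid
# voxelization, photobleaching decay, optional Gaussian blur and Poisson
# shot noise. Deliberately simple optics -- no instrument-specific point
# spread function and no anisotropic axial blur.

#' Optics configuration for scene rendering
#'
#' @param background Background intensity level (counts).
#' @param foreground Peak intensity of in-object voxels at frame 1.
#' @param blur_sigma Isotropic Gaussian blur scale in um (0 = none).
#' @param shot_noise If `TRUE`, voxel values are Poisson draws around the
#'   noiseless image.
#' @param bleach_rate Photobleaching rate b per frame: the foreground of
#'   frame k is scaled by `exp(-b * (k - 1))` (frame 1 unattenuated).
#' @return An `optics_config` list.
#' @export
optics_config <- function(background = 10, foreground = 120,
                          blur_sigma = 0, shot_noise = FALSE,
                          bleach_rate = 0) {
  if (background < 0 || foreground < 0)
    stop("intensity levels must be >= 0", call. = FALSE)
  if (bleach_rate < 0) stop("bleach rate must be >= 0", call. = FALSE)
  if (blur_sigma < 0) stop("blur sigma must be >= 0", call. = FALSE)
  structure(list(background = background, foreground = foreground,
                 blur_sigma = blur_sigma, shot_noise = shot_noise,
                 bleach_rate = bleach_rate),
            class = "optics_config")
}

# voxelize one ellipsoid into a logical array (voxel centres inside)
add_ellipsoid <- function(mask, center, semi, voxel_size) {
  d <- dim(mask)
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, floor((center[ax] - semi[ax]) / voxel_size[ax] + 0.5))
    hi <- min(d[ax], ceiling((center[ax] + semi[ax]) / voxel_size[ax] + 0.5))
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0L)) return(mask)
  xs <- ((rng[[1]] - 0.5) * voxel_size[1] - center[1]) / semi[1]
  ys <- ((rng[[2]] - 0.5) * voxel_size[2] - center[2]) / semi[2]
  zs <- ((rng[[3]] - 0.5) * voxel_size[3] - center[3]) / semi[3]
  sub <- outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= 1
  mask[rng[[1]], rng[[2]], rng[[3]]] <- mask[rng[[1]], rng[[2]], rng[[3]]] | sub
  mask
}

#' Render one frame of a scene
#'
#' Voxels whose centres fall inside any true ellipsoid receive the
#' foreground intensity attenuated by bleaching, `foreground *
#' exp(-b * (frame - 1))`; all other voxels receive the background level.
#' Optional Gaussian blur is applied before optional Poisson shot noise.
#'
#' @param truth A `scene_truth` from [generate_scene()].
#' @param frame 1-based frame index present in the truth.
#' @param optics An [optics_config()].
#' @param seed Seed for the shot-noise draw; defaults to the scene seed
#'   plus the frame index, so rendering is deterministic given (truth,
#'   optics, seed).
#' @return An [image_stack()].
#' @export
render_frame <- function(truth, frame, optics = optics_config(),
                         seed = NULL) {
  stopifnot(inherits(truth, "scene_truth"), inherits(optics, "optics_config"))
  if (!frame %in% truth$objects$frame)
    stop("frame ", frame, " not present in the scene", call. = FALSE)
  cfg <- truth$config
  obj <- truth$objects[truth$objects$frame == frame, ]
  tiny <- obj$sx < cfg$voxel_size[1] / 2 | obj$sy < cfg$voxel_size[2] / 2 |
          obj$sz < cfg$voxel_size[3] / 2
  if (any(tiny))
    warning(sum(tiny), " object(s) smaller than one voxel at frame ", frame,
            "; they may be unrecoverable", call. = FALSE)
  mask <- array(FALSE, dim = cfg$grid)
  for (r in seq_len(nrow(obj))) {
    mask <- add_ellipsoid(mask,
                          as.numeric(obj[r, c("cx", "cy", "cz")]),
                          as.numeric(obj[r, c("sx", "sy", "sz")]),
                          cfg$voxel_size)
  }
  fg <- optics$foreground * exp(-optics$bleach_rate * (frame - 1))
  img <- array(optics$background, dim = cfg$grid)
  img[mask] <- fg
  if (optics$blur_sigma > 0)
    img <- gaussian_blur(img, optics$blur_sigma, cfg$voxel_size)
  if (optics$shot_noise) {
    if (is.null(seed)) seed <- (cfg$seed + frame) %% .Machine$integer.max
    has_seed <- exists(".Random.seed", envir = globalenv())
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    img[] <- stats::rpois(length(img), img)
  }
  image_stack(img, cfg$voxel_size, frame = frame)
}

#' Render every frame of a scene
#'
#' @param truth A `scene_truth`.
#' @param optics An [optics_config()].
#' @return List of [image_stack()]s, one per frame.
#' @export
render_scene <- function(truth, optics = optics_config()) {
  lapply(seq_len(truth$config$n_frames), function(k)
    render_frame(truth, k, optics))
}
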