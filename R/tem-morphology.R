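# TEM-style 2D morphometry: per-profile area and width-to-height (W/H)
# measurement and the three-class scheme anchored at the reference (young)
# sample means -- elongated (large and long), medium (large but not long),
# fragmented (small area, whatever the shape).

#' Morphology class thresholds
#'
#' @param area Reference mean area A* in um^2 (> 0); default 0.11, the
#'   young-sample mean.
#' @param ratio Reference mean W/H ratio R* (>= 1); default 2.34.
#' @return A `morphology_thresholds` object.
#' @export
morphology_thresholds <- function(area = 0.11, ratio = 2.34) {
  if (area <= 0) stop("area threshold must be > 0", call. = FALSE)
  if (ratio < 1) stop("ratio threshold must be >= 1", call. = FALSE)
  structure(list(area = area, ratio = ratio), class = "morphology_thresholds")
}

#' Measure one 2D profile mask
#'
#' Area is pixel count times pixel area. W and H are the side lengths of
#' the minimum-area rotated bounding rectangle of the pixel set
#' (rotation-robust; an axis-aligned a x b rectangle measures exactly
#' a x b). One pixel size is added to each raw extent so that pixel extent,
#' not just pixel-centre spread, is measured. `mode = "feret"` uses the
#' maximum/minimum Feret diameters instead.
#'
#' @param mask Logical/0-1 matrix, non-empty.
#' @param pixel_size Pixel edge length in um (> 0).
#' @param id Optional record id.
#' @param mode `"rect"` (default, minimum-area bounding rectangle) or
#'   `"feret"`.
#' @return One-row tibble: `id, area_um2, w_um, h_um, ratio`.
#' @export
measure_profile <- function(mask, pixel_size, id = 1L, mode = c("rect", "feret")) {
  mode <- match.arg(mode)
  if (pixel_size <= 0) stop("pixel size must be > 0", call. = FALSE)
  mask <- as.matrix(mask) != 0
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("empty mask", call. = FALSE)
  area <- nrow(px) * pixel_size^2
  pts <- (px - 0.5) * pixel_size
  if (mode == "rect") {
    sides <- min_area_rect(pts)
    w <- sides[1] + pixel_size
    h <- sides[2] + pixel_size
  } else {
    w <- max_feret(pts) + pixel_size
    h <- min_feret(pts) + pixel_size
  }
  tibble::tibble(id = id, area_um2 = area, w_um = w, h_um = h, ratio = w / h)
}

#' Derive reference thresholds from a reference population
#'
#' The classification scheme is anchored at the mean area and mean W/H of
#' the reference (young) sample; those means are then frozen and applied
#' unchanged to every comparison sample.
#'
#' @param records Tibble with `area_um2` and `ratio` columns (>= 1 row).
#' @return A [morphology_thresholds()] object.
#' @export
reference_thresholds <- function(records) {
  if (nrow(records) == 0L) stop("empty reference population", call. = FALSE)
  morphology_thresholds(mean(records$area_um2), mean(records$ratio))
}

#' Classify profiles into elongated / medium / fragmented
#'
#' Area above the reference mean and ratio above the reference ratio:
#' elongated. Area above but ratio at/below: medium. Area at or below the
#' reference mean: fragmented, regardless of shape (boundary equalities
#' fall to the "smaller" class).
#'
#' @param records Tibble with `area_um2` and `ratio` columns.
#' @param thresholds A [morphology_thresholds()].
#' @return `records` with a `class` factor column appended.
#' @export
classify_morphology <- function(records, thresholds = morphology_thresholds()) {
  stopifnot(inherits(thresholds, "morphology_thresholds"))
  cls <- ifelse(records$area_um2 <= thresholds$area, "fragmented",
                ifelse(records$ratio > thresholds$ratio, "elongated", "medium"))
  records$class <- factor(cls, levels = c("elongated", "medium", "fragmented"))
  records
}

#' Compare two classified populations
#'
#' Builds the 2 x 3 population-by-class count table, the per-population
#' class percentages, and the Pearson chi-squared comparison. A class
#' empty in both populations is dropped from the test (margin
#' requirement) with a message.
#'
#' @param reference,query Record tibbles (`area_um2`, `ratio`).
#' @param thresholds Frozen [morphology_thresholds()] (derive them from
#'   the reference sample with [reference_thresholds()] before comparing).
#' @param labels Length-2 population labels.
#' @return List: `table` (2 x 3 counts), `percentages`, `test`
#'   (a `stat_result`).
#' @export
compare_populations <- function(reference, query,
                                thresholds = morphology_thresholds(),
                                labels = c("reference", "query")) {
  ra <- classify_morphology(reference, thresholds)
  qa <- classify_morphology(query, thresholds)
  tab <- rbind(table(ra$class), table(qa$class))
  rownames(tab) <- labels
  pct <- 100 * tab / rowSums(tab)
  test_tab <- tab
  empty <- colSums(test_tab) == 0
  if (any(empty)) {
    message("dropping class(es) with zero total count from the test: ",
            paste(colnames(tab)[empty], collapse = ", "))
    test_tab <- test_tab[, !empty, drop = FALSE]
  }
  list(table = tab, percentages = pct, test = chi_squared(test_tab))
}
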