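# Clonal-mosaic statistics: relative division rate of the marked (clone)
# lineage, GSC maintenance over weeks, and partial/full clone composition.
# Counts follow the marker-loss convention: marker-negative cells are the
# clone (homozygous mutant, or control in a mock mosaic), marker-positive
# cells are the unrecombined neighbours; a lineage's progeny units are its
# fusome-marked cystoblasts and cysts.

#' Per-germarium relative division rate
#'
#' `(progeny_A / GSC_A) / (progeny_B / GSC_B)`, with the numerator lineage
#' set by `orientation`. Default `"neg_over_pos"` puts the marker-negative
#' (clone) lineage in the numerator, so values below 1 mean the clone
#' divides slower. Germaria violating the preconditions (a lineage with no
#' GSC, or zero progeny in the denominator lineage) get `NA` with the
#' reason recorded in the `excluded` attribute.
#'
#' @param counts Tibble with columns `gsc_neg, gsc_pos, prog_neg,
#'   prog_pos` (one row per germarium).
#' @param orientation `"neg_over_pos"` (default) or `"pos_over_neg"`.
#' @return Numeric vector of per-germarium ratios (`NA` where excluded),
#'   with attribute `excluded`: a character vector of exclusion reasons
#'   (`""` for retained germaria).
#' @export
relative_division_rate <- function(counts,
                                   orientation = c("neg_over_pos",
                                                   "pos_over_neg")) {
  orientation <- match.arg(orientation)
  need <- c("gsc_neg", "gsc_pos", "prog_neg", "prog_pos")
  stopifnot(all(need %in% names(counts)))
  if (orientation == "neg_over_pos") {
    g_num <- counts$gsc_neg; p_num <- counts$prog_neg
    g_den <- counts$gsc_pos; p_den <- counts$prog_pos
  } else {
    g_num <- counts$gsc_pos; p_num <- counts$prog_pos
    g_den <- counts$gsc_neg; p_den <- counts$prog_neg
  }
  reason <- rep("", nrow(counts))
  reason[g_num == 0 | g_den == 0] <- "missing lineage (needs >= 1 GSC of each)"
  reason[reason == "" & p_den == 0] <- "zero progeny in denominator lineage"
  ratio <- ifelse(reason == "", (p_num / g_num) / (p_den / g_den), NA_real_)
  structure(ratio, excluded = reason)
}

#' Pooled relative division rate of a dataset
#'
#' Ratio of lineage-wide progeny per GSC, `(sum progeny_num / sum GSC_num)
#' / (sum progeny_den / sum GSC_den)`, over the germaria that satisfy the
#' preconditions (at least one GSC of each lineage). The ratio of pooled
#' means is a consistent estimator of the lineage rate ratio; the mean of
#' per-germarium ratios (also reported by [clonal_summary()]) is inflated
#' by the reciprocal-count bias at small progeny numbers.
#'
#' @inheritParams relative_division_rate
#' @return A single ratio.
#' @export
pooled_division_rate <- function(counts,
                                 orientation = c("neg_over_pos",
                                                 "pos_over_neg")) {
  orientation <- match.arg(orientation)
  keep <- counts$gsc_neg >= 1 & counts$gsc_pos >= 1
  counts <- counts[keep, ]
  if (nrow(counts) == 0L) stop("no germarium with both lineages", call. = FALSE)
  r_neg <- sum(counts$prog_neg) / sum(counts$gsc_neg)
  r_pos <- sum(counts$prog_pos) / sum(counts$gsc_pos)
  if (orientation == "neg_over_pos") r_neg / r_pos else r_pos / r_neg
}

#' GSC maintenance percentage at a week
#'
#' Percentage of assessed germaria retaining at least one marker-negative
#' GSC.
#'
#' @param dataset Tibble from [simulate_mosaic()] (or measured counts with
#'   the same columns).
#' @param week Observation week present in the dataset.
#' @return Percentage in `[0, 100]`.
#' @export
maintenance_percent <- function(dataset, week) {
  d <- dataset[dataset$week == week, ]
  if (nrow(d) == 0L) stop("no germaria observed at week ", week, call. = FALSE)
  100 * mean(d$gsc_neg >= 1)
}

#' Partial / full clone composition at a week
#'
#' Among clone-bearing germaria (>= 1 marker-negative GSC): full clones
#' have only marker-negative GSCs, partial clones a mixture. The two
#' percentages sum to 100.
#'
#' @inheritParams maintenance_percent
#' @return Named numeric vector `c(partial = , full = )`, percentages.
#' @export
clone_composition <- function(dataset, week) {
  d <- dataset[dataset$week == week, ]
  d <- d[d$gsc_neg >= 1, ]
  if (nrow(d) == 0L)
    stop("no clone-bearing germarium at week ", week, call. = FALSE)
  full <- 100 * mean(d$gsc_pos == 0)
  c(partial = 100 - full, full = full)
}

#' Clonal summary of a mosaic dataset
#'
#' Per week: pooled relative division rate, mean of per-germarium ratios
#' (+/- SEM) over included germaria, number included/excluded, maintenance
#' percentage, and partial/full clone composition among clone-bearing
#' germaria.
#'
#' @param dataset Tibble of germarium counts (`germarium, week, gsc_neg,
#'   gsc_pos, prog_neg, prog_pos`).
#' @param orientation Numerator convention, see
#'   [relative_division_rate()].
#' @return Tibble with one row per week.
#' @export
clonal_summary <- function(dataset,
                           orientation = c("neg_over_pos", "pos_over_neg")) {
  orientation <- match.arg(orientation)
  weeks <- sort(unique(dataset$week))
  rows <- lapply(weeks, function(w) {
    d <- dataset[dataset$week == w, ]
    r <- relative_division_rate(d, orientation)
    ok <- !is.na(r)
    comp <- if (any(d$gsc_neg >= 1)) clone_composition(dataset, w) else
      c(partial = NA_real_, full = NA_real_)
    tibble::tibble(
      week = w,
      n_germaria = nrow(d),
      n_rate = sum(ok),
      n_excluded = sum(!ok),
      pooled_rate = pooled_division_rate(d, orientation),
      mean_rate = mean(r[ok]),
      sem_rate = stats::sd(r[ok]) / sqrt(sum(ok)),
      maintenance_pct = maintenance_percent(dataset, w),
      partial_pct = comp[["partial"]],
      full_pct = comp[["full"]],
      orientation = orientation)
  })
  do.call(rbind, rows)
}
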