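# Synthetic 2D section populations: tabulated (area, W/H) records with
# controllable means and dispersions, emulating the per-profile measurements
# taken from thin-section electron micrographs. Defaults reproduce the
# young-sample reference statistics (mean area 0.11 um^2, sd 0.11; mean W/H
# 2.34, sd 1.9).

#' Configuration of a synthetic 2D profile population
#'
#' Areas are lognormal with the requested arithmetic mean and sd; W/H
#' ratios are 1 plus a lognormal with the requested mean and sd (so every
#' ratio is >= 1, as a longest/shortest extent must be). Zero dispersion
#' degenerates to the exact means.
#'
#' @param n Population size.
#' @param mean_area,sd_area Mean and sd of profile area (um^2).
#' @param mean_ratio,sd_ratio Mean and sd of the W/H ratio (>= 1).
#' @param seed Integer seed.
#' @return A `tem_pop_config` list.
#' @export
tem_pop_config <- function(n = 200L, mean_area = 0.11, sd_area = 0.11,
                           mean_ratio = 2.34, sd_ratio = 1.9, seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (mean_area <= 0 || sd_area < 0)
    stop("area parameters must be positive (sd >= 0)", call. = FALSE)
  if (mean_ratio < 1 || sd_ratio < 0)
    stop("mean ratio must be >= 1 and sd >= 0", call. = FALSE)
  structure(list(n = as.integer(n), mean_area = mean_area, sd_area = sd_area,
                 mean_ratio = mean_ratio, sd_ratio = sd_ratio,
                 seed = as.integer(seed)),
            class = "tem_pop_config")
}

# lognormal draws with given arithmetic mean and sd
rlnorm_moments <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic 2D profile population
#'
#' @param config A [tem_pop_config()].
#' @return Tibble of morphology records: `id, area_um2, ratio`.
#' @export
generate_tem_population <- function(config) {
  stopifnot(inherits(config, "tem_pop_config"))
  set.seed(config$seed)
  area <- rlnorm_moments(config$n, config$mean_area, config$sd_area)
  excess <- if (config$mean_ratio == 1) rep(0, config$n) else
    rlnorm_moments(config$n, config$mean_ratio - 1, config$sd_ratio)
  tibble::tibble(id = seq_len(config$n), area_um2 = area, ratio = 1 + excess)
}
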