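# Dynamics statistics over tracked mitochondria: window-capped event
# counts (at most one counted event per track per window, so a track can
# total at most as many events as there are windows -- 3 under the default
# 1-4 / 4-7 / 7-10 scheme), the three-class track typology, the
# proportional fission-fusion difference, the fragmented-count fluctuation
# series, trendline slopes, and chi-squared table comparisons.

#' Analysis window scheme
#'
#' Windows are inclusive 1-based time-point ranges. Consecutive windows
#' must share exactly their boundary time point, so the transition sets
#' (window `(a, b)` owns transitions `a .. b-1`) partition cleanly.
#'
#' @param windows List of length-2 integer vectors; default
#'   `list(c(1, 4), c(4, 7), c(7, 10))`.
#' @return A `window_scheme` object.
#' @export
window_scheme <- function(windows = list(c(1L, 4L), c(4L, 7L), c(7L, 10L))) {
  for (w in windows) {
    if (length(w) != 2L || w[2] - w[1] < 1L)
      stop("each window must span at least two time points", call. = FALSE)
  }
  if (length(windows) > 1L) {
    for (k in seq_len(length(windows) - 1L)) {
      if (windows[[k + 1L]][1] != windows[[k]][2])
        stop("consecutive windows must share exactly their boundary time point",
             call. = FALSE)
    }
  }
  structure(list(windows = lapply(windows, as.integer)),
            class = "window_scheme")
}

# window index owning a transition (left-frame indexed), NA if outside
window_of <- function(transition, scheme) {
  idx <- rep(NA_integer_, length(transition))
  for (k in seq_along(scheme$windows)) {
    w <- scheme$windows[[k]]
    sel <- transition >= w[1] & transition <= w[2] - 1L
    idx[sel] <- k
  }
  idx
}

#' Window-capped event counts per track
#'
#' Attributes each detected event to the track of its first parent and to
#' the window owning its transition, then applies the counting cap: at
#' most one event is counted per track per window (the earliest
#' transition's event; at a tied transition fission is counted before
#' fusion). Raw multiplicities are retained for diagnostics. Events
#' falling outside every window are dropped with a warning.
#'
#' @param events Event tibble from [detect_events()]`$events`.
#' @param tracks Object table with `frame`, `id`, `track` columns (from
#'   [assign_track_ids()]).
#' @param scheme A [window_scheme()].
#' @return Tibble with one row per track x window: `track, window, counted`
#'   ("none"/"fission"/"fusion"), `raw_fission`, `raw_fusion`.
#' @export
window_events <- function(events, tracks, scheme = window_scheme()) {
  stopifnot(inherits(scheme, "window_scheme"))
  all_tracks <- sort(unique(tracks$track))
  nw <- length(scheme$windows)
  grid <- expand.grid(track = all_tracks, window = seq_len(nw))
  out <- tibble::tibble(track = grid$track, window = grid$window,
                        counted = "none", raw_fission = 0L, raw_fusion = 0L)
  if (nrow(events) > 0) {
    key <- paste(tracks$frame, tracks$id, sep = ":")
    first_parent <- vapply(events$parents, function(p) split_ids(p)[1L],
                           integer(1))
    ev_track <- tracks$track[match(paste(events$transition, first_parent,
                                         sep = ":"), key)]
    if (anyNA(ev_track))
      stop("event references an object missing from the track table",
           call. = FALSE)
    ev_window <- window_of(events$transition, scheme)
    if (anyNA(ev_window)) {
      warning(sum(is.na(ev_window)),
              " event(s) outside every analysis window were ignored",
              call. = FALSE)
    }
    keep <- !is.na(ev_window)
    ev <- data.frame(track = ev_track[keep], window = ev_window[keep],
                     transition = events$transition[keep],
                     type = events$type[keep])
    for (r in seq_len(nrow(ev))) {
      i <- which(out$track == ev$track[r] & out$window == ev$window[r])
      if (ev$type[r] == "fission")
        out$raw_fission[i] <- out$raw_fission[i] + 1L
      else out$raw_fusion[i] <- out$raw_fusion[i] + 1L
    }
    # cap: earliest transition wins; fission before fusion at a tie
    ev <- ev[order(ev$track, ev$window, ev$transition,
                   match(ev$type, c("fission", "fusion"))), ]
    ev <- ev[!duplicated(ev[, c("track", "window")]), ]
    idx <- match(paste(ev$track, ev$window), paste(out$track, out$window))
    out$counted[idx] <- ev$type
  }
  out[order(out$track, out$window), ]
}

#' Three-class track typology
#'
#' Classifies every track from its window-capped event counts: `balanced`
#' (equal counted fissions and fusions, at least one of each),
#' `fission_dominant`, `fusion_dominant`, or `quiescent` (no counted
#' event). Reported proportions are over non-quiescent tracks; the
#' quiescent count is carried separately (its proportion is `NA`).
#'
#' @param summary Tibble from [window_events()].
#' @return List with `tracks` (per-track counted fissions/fusions and
#'   class) and `tally` (per-class `n` and `proportion`).
#' @export
classify_tracks <- function(summary) {
  fis <- rowsum(as.integer(summary$counted == "fission"), summary$track)
  fus <- rowsum(as.integer(summary$counted == "fusion"), summary$track)
  tr <- tibble::tibble(track = as.integer(rownames(fis)),
                       fissions = unname(fis[, 1]), fusions = unname(fus[, 1]))
  tr$class <- with(tr, ifelse(
    fissions + fusions == 0, "quiescent",
    ifelse(fissions > fusions, "fission_dominant",
           ifelse(fissions < fusions, "fusion_dominant", "balanced"))))
  lev <- c("balanced", "fission_dominant", "fusion_dominant", "quiescent")
  n <- vapply(lev, function(cl) sum(tr$class == cl), integer(1))
  active <- sum(n[1:3])
  tally <- tibble::tibble(
    class = lev, n = as.integer(n),
    proportion = c(if (active > 0) n[1:3] / active else rep(NA_real_, 3),
                   NA_real_))
  list(tracks = tr, tally = tally)
}

#' Proportional difference between fission and fusion counts
#'
#' `(F - f) / (F + f)`: +1 is all-fission, -1 all-fusion, 0 balanced.
#'
#' @param fissions,fusions Non-negative counts with a positive sum.
#' @return Number in `[-1, 1]`.
#' @export
proportional_difference <- function(fissions, fusions) {
  if (any(fissions < 0) || any(fusions < 0))
    stop("counts must be >= 0", call. = FALSE)
  tot <- fissions + fusions
  if (any(tot == 0))
    stop("proportional difference undefined when F + f = 0", call. = FALSE)
  (fissions - fusions) / tot
}

#' Fragmented-count fluctuation series
#'
#' Consecutive differences of the per-frame fragmented-object count. A
#' net move toward fission shows as positive differences (one fragmented
#' mitochondrion at one time point, two at the next: +1), a net move
#' toward fusion as negative ones. The telescoping identity
#' `sum(delta) = last - first` holds by construction.
#'
#' @param counts Integer vector of per-frame fragmented counts (>= 2
#'   frames).
#' @return A `fragmented_series` list: `counts`, `delta`.
#' @export
delta_fragmented <- function(counts) {
  if (length(counts) < 2L)
    stop("need counts for at least two frames", call. = FALSE)
  structure(list(counts = as.numeric(counts), delta = diff(as.numeric(counts))),
            class = "fragmented_series")
}

#' Ordinary least-squares trend slope
#'
#' @param series Numeric response values (>= 2 points).
#' @param x Predictor; defaults to the index `1..n` (frame or transition
#'   number).
#' @return The OLS slope.
#' @export
trend_slope <- function(series, x = seq_along(series)) {
  if (length(series) < 2L) stop("need at least two points", call. = FALSE)
  if (length(x) != length(series)) stop("x and series lengths differ",
                                        call. = FALSE)
  xc <- x - mean(x)
  sum(xc * (series - mean(series))) / sum(xc^2)
}

#' Pearson chi-squared test on a contingency table
#'
#' Expected counts from the row/column margins; no continuity correction
#' by default (Yates available for 2x2 tables).
#'
#' @param table Matrix of non-negative counts with positive row and column
#'   sums.
#' @param yates Apply the Yates continuity correction (2x2 only).
#' @return A `stat_result` list: `statistic`, `df`, `p_value`, `expected`,
#'   `table`.
#' @export
chi_squared <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all row and column sums must be > 0", call. = FALSE)
  if (yates && !all(dim(table) == 2L))
    stop("Yates correction applies to 2x2 tables only", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value), expected = ht$expected,
                 table = table),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("chi-squared = ", signif(x$statistic, 5), ", df = ", x$df,
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}
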