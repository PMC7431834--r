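# Independent oracles used to check the implementation by a different
# route: morphological reconstruction for hysteresis, exhaustive voxel
# loops for overlap, direction scans for Feret measures, a re-statement of
# the window-cap rule for event counting.

# Hysteresis by seeded morphological reconstruction: start from the
# strong (>= high) voxels and iteratively dilate into the weak (>= low)
# support until a fixed point. Independent of the component-labeling path.
oracle_hysteresis_mask <- function(x, low, high) {
  d <- dim(x)
  weak <- x >= low
  grown <- x >= high
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  repeat {
    dil <- grown
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      sx <- seq_len(d[1] - abs(o[1])); sy <- seq_len(d[2] - abs(o[2]))
      sz <- seq_len(d[3] - abs(o[3]))
      dst <- list(sx + max(0, o[1]), sy + max(0, o[2]), sz + max(0, o[3]))
      src <- list(sx + max(0, -o[1]), sy + max(0, -o[2]), sz + max(0, -o[3]))
      dil[dst[[1]], dst[[2]], dst[[3]]] <-
        dil[dst[[1]], dst[[2]], dst[[3]]] | grown[src[[1]], src[[2]], src[[3]]]
    }
    dil <- dil & weak
    if (identical(dil, grown)) break
    grown <- dil
  }
  grown
}

# Exhaustive voxel-loop overlap counts between two label arrays.
oracle_overlap_counts <- function(lab1, lab2) {
  out <- list()
  for (v in which(lab1 > 0 & lab2 > 0)) {
    key <- paste(lab1[v], lab2[v])
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  if (length(out) == 0L)
    return(data.frame(from = integer(0), to = integer(0),
                      overlap = integer(0)))
  ft <- do.call(rbind, lapply(strsplit(names(out), " "), as.integer))
  df <- data.frame(from = ft[, 1], to = ft[, 2],
                   overlap = unlist(out, use.names = FALSE))
  df[order(df$from, df$to), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force Feret measures: projection widths over a fine direction scan.
oracle_feret <- function(pts, n_dir = 360L) {
  th <- seq(0, pi, length.out = n_dir)
  w <- vapply(th, function(a) {
    p <- pts %*% c(cos(a), sin(a))
    max(p) - min(p)
  }, numeric(1))
  c(max = max(w), min = min(w))
}

# Independent statement of the window-cap rule: for one track, given raw
# events (transition, type), the counted event of each window is the one
# at the earliest transition, fission outranking fusion at a tie.
oracle_window_count <- function(events, scheme) {
  vapply(seq_along(scheme$windows), function(k) {
    w <- scheme$windows[[k]]
    e <- events[events$transition >= w[1] & events$transition <= w[2] - 1L, ,
                drop = FALSE]
    if (nrow(e) == 0L) return("none")
    e <- e[order(e$transition, match(e$type, c("fission", "fusion"))), ,
           drop = FALSE]
    e$type[1]
  }, character(1))
}

# Translate detected (segmentation-label) events into truth ids by
# matching objects to true objects per frame via nearest centroid, then
# canonicalize both event tables for set comparison.
match_events_to_truth <- function(truth, objects, events) {
  map <- list()
  for (f in sort(unique(objects$frame))) {
    so <- objects[objects$frame == f, ]
    to <- truth$objects[truth$objects$frame == f, ]
    m <- integer(nrow(so))
    for (i in seq_len(nrow(so))) {
      dd <- sqrt((to$cx - so$cx[i])^2 + (to$cy - so$cy[i])^2 +
                 (to$cz - so$cz[i])^2)
      m[i] <- to$id[which.min(dd)]
    }
    map[[as.character(f)]] <- stats::setNames(m, so$id)
  }
  tr <- function(ids_str, frame) {
    ids <- as.integer(strsplit(ids_str, "|", fixed = TRUE)[[1]])
    paste(sort(unname(map[[as.character(frame)]][as.character(ids)])),
          collapse = "|")
  }
  if (nrow(events) == 0L) return(character(0))
  vapply(seq_len(nrow(events)), function(r) {
    paste(events$transition[r], events$type[r],
          tr(events$parents[r], events$transition[r]),
          tr(events$children[r], events$transition[r] + 1L), sep = "~")
  }, character(1))
}

canonical_truth_events <- function(truth) {
  ev <- truth$events
  if (nrow(ev) == 0L) return(character(0))
  vapply(seq_len(nrow(ev)), function(r) {
    canon <- function(x) paste(sort(as.integer(
      strsplit(x, "|", fixed = TRUE)[[1]])), collapse = "|")
    paste(ev$transition[r], ev$type[r], canon(ev$parents[r]),
          canon(ev$children[r]), sep = "~")
  }, character(1))
}

# small helper: build a label_volume from an integer array at 0.1 um
lv <- function(arr, frame = NULL, voxel = 0.1) {
  label_volume(arr, voxel, frame = frame)
}

# run the standard noiseless segment+track pipeline on a truth
segment_and_track <- function(truth, low = 40, high = 80) {
  stacks <- render_scene(truth, optics_config(background = 10,
                                              foreground = 120))
  labs <- lapply(stacks, hysteresis_segment, low = low, high = high)
  objects <- do.call(rbind, lapply(labs, measure_objects))
  links <- link_series(labs)
  det <- detect_events(links, objects)
  list(labels = labs, objects = objects, links = links, det = det)
}
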