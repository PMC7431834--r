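# Overlap-based tracking: objects in adjacent time points are linked when
# their voxel masks share space; all linked objects share a track ID, and
# fission/fusion events fall out of the link multiplicities.

#' Link objects across one frame transition
#'
#' Records a link between object `a` at frame `t` and object `b` at frame
#' `t+1` whenever their voxel masks share at least `min_overlap` voxels.
#' Overlap is computed on the exact voxel masks, which makes linking
#' parameter-free at the default `min_overlap = 1`.
#'
#' @param labels_t,labels_t1 [label_volume()]s of the two frames (same shape
#'   and voxel size).
#' @param min_overlap Minimum number of shared voxels for a link.
#' @param transition 1-based index of the left frame of the transition;
#'   taken from `labels_t$frame` when present.
#' @return Tibble with columns `transition, from, to, overlap`.
#' @export
link_adjacent <- function(labels_t, labels_t1, min_overlap = 1L,
                          transition = NULL) {
  stopifnot(inherits(labels_t, "label_volume"),
            inherits(labels_t1, "label_volume"))
  if (!identical(dim(labels_t$labels), dim(labels_t1$labels)))
    stop("label volumes must share shape", call. = FALSE)
  if (!isTRUE(all.equal(labels_t$voxel_size, labels_t1$voxel_size)))
    stop("label volumes must share voxel size", call. = FALSE)
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)
  if (is.null(transition))
    transition <- if (is.null(labels_t$frame)) NA_integer_ else labels_t$frame
  a <- labels_t$labels; b <- labels_t1$labels
  both <- a > 0L & b > 0L
  if (!any(both)) {
    return(tibble::tibble(transition = integer(0), from = integer(0),
                          to = integer(0), overlap = integer(0)))
  }
  tab <- table(from = a[both], to = b[both])
  hit <- which(tab >= min_overlap, arr.ind = TRUE)
  out <- tibble::tibble(
    transition = as.integer(transition),
    from = as.integer(rownames(tab)[hit[, 1]]),
    to = as.integer(colnames(tab)[hit[, 2]]),
    overlap = as.integer(tab[hit]))
  out[order(out$from, out$to), ]
}

#' Link an entire segmented series
#'
#' @param label_series List of [label_volume()]s, one per frame, in time
#'   order; frame `k` of the series is time point `k` (1-based).
#' @param min_overlap Minimum shared voxels for a link.
#' @return Tibble of links over all transitions.
#' @export
link_series <- function(label_series, min_overlap = 1L) {
  n <- length(label_series)
  if (n < 2L) stop("need at least two frames to link", call. = FALSE)
  out <- lapply(seq_len(n - 1L), function(t) {
    link_adjacent(label_series[[t]], label_series[[t + 1L]],
                  min_overlap = min_overlap, transition = t)
  })
  do.call(rbind, out)
}

#' Assign track IDs
#'
#' Tracks are the connected components of the graph whose nodes are
#' `(frame, object)` pairs and whose edges are the overlap links; every
#' object belongs to exactly one track, and objects with no links form
#' singleton tracks.
#'
#' @param links Tibble from [link_series()] / [link_adjacent()].
#' @param objects Tibble with at least `frame` and `id` columns listing every
#'   segmented object (e.g. rbind of [measure_objects()] outputs).
#' @return `objects` with a `track` column appended (tracks numbered by
#'   first appearance in frame-then-id order).
#' @export
assign_track_ids <- function(links, objects) {
  stopifnot(all(c("frame", "id") %in% names(objects)))
  objects <- objects[order(objects$frame, objects$id), ]
  key <- paste(objects$frame, objects$id, sep = ":")
  if (anyDuplicated(key)) stop("duplicate (frame, id) in objects", call. = FALSE)
  if (nrow(links) > 0) {
    ek <- c(paste(links$transition, links$from, sep = ":"),
            paste(links$transition + 1L, links$to, sep = ":"))
    if (!all(ek %in% key))
      stop("links reference objects absent from the object table", call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = nrow(objects), directed = FALSE)
  if (nrow(links) > 0) {
    from <- match(paste(links$transition, links$from, sep = ":"), key)
    to <- match(paste(links$transition + 1L, links$to, sep = ":"), key)
    g <- igraph::add_edges(g, rbind(from, to))
  }
  comp <- igraph::components(g)$membership
  first <- match(unique(comp), comp)
  relab <- integer(max(comp))
  relab[comp[sort(first)]] <- seq_along(first)
  objects$track <- relab[comp]
  objects
}

#' Detect fission and fusion events from links
#'
#' At each transition, an object at `t` linked to `d >= 2` objects at `t+1`
#' yields one fission with those `d` children; an object at `t+1` linked to
#' `d >= 2` objects at `t` yields one fusion with those `d` parents.
#' One-to-one links yield no event. When `objects` is supplied, objects with
#' no outgoing link (other than in the last frame) are recorded as deaths
#' and objects with no incoming link (other than in the first frame) as
#' births; these are bookkeeping records, not dynamics events.
#'
#' @param links Tibble of links.
#' @param objects Optional object table (`frame`, `id`) for birth/death
#'   bookkeeping.
#' @return List with `events` (tibble: `transition, type, parents, children`,
#'   participants "|"-joined in increasing id order), `births` and `deaths`
#'   (tibbles with `frame`, `id`; empty unless `objects` given).
#' @export
detect_events <- function(links, objects = NULL) {
  ev <- list()
  if (nrow(links) > 0) {
    for (tr in sort(unique(links$transition))) {
      lk <- links[links$transition == tr, ]
      outdeg <- table(lk$from)
      for (p in as.integer(names(outdeg)[outdeg >= 2])) {
        ch <- sort(lk$to[lk$from == p])
        ev[[length(ev) + 1L]] <- tibble::tibble(
          transition = tr, type = "fission",
          parents = as.character(p),
          children = paste(ch, collapse = "|"))
      }
      indeg <- table(lk$to)
      for (cc in as.integer(names(indeg)[indeg >= 2])) {
        pa <- sort(lk$from[lk$to == cc])
        ev[[length(ev) + 1L]] <- tibble::tibble(
          transition = tr, type = "fusion",
          parents = paste(pa, collapse = "|"),
          children = as.character(cc))
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    tibble::tibble(transition = integer(0), type = character(0),
                   parents = character(0), children = character(0))
  events <- events[order(events$transition, events$type, events$parents), ]
  births <- deaths <- tibble::tibble(frame = integer(0), id = integer(0))
  if (!is.null(objects) && nrow(objects) > 0) {
    frames <- sort(unique(objects$frame))
    outk <- paste(links$transition, links$from, sep = ":")
    ink <- paste(links$transition + 1L, links$to, sep = ":")
    ok <- paste(objects$frame, objects$id, sep = ":")
    dead <- objects$frame < max(frames) & !(ok %in% outk)
    born <- objects$frame > min(frames) & !(ok %in% ink)
    deaths <- tibble::tibble(frame = objects$frame[dead], id = objects$id[dead])
    births <- tibble::tibble(frame = objects$frame[born], id = objects$id[born])
  }
  list(events = events, births = births, deaths = deaths)
}

# split a "|"-joined participant field into an integer vector
split_ids <- function(x) as.integer(strsplit(x, "|", fixed = TRUE)[[1L]])
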