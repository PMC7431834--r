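# Ground-truthed synthetic 4D scenes: ellipsoidal mitochondria moving in a
# voxel grid with a scheduled or stochastic fission/fusion program. The
# generator is the oracle for every downstream stage: it knows every true
# object, every event and every per-frame count.
#
# Geometry guarantees (so that overlap tracking on a noiseless rendering
# recovers the event log exactly; all ellipsoids are axis-aligned):
#   * distinct objects keep a bounding-sphere surface gap of >= `min_gap`
#     um within every frame, so 26-connected segmentation never merges
#     them (Euclidean gap > voxel diagonal);
#   * fission children are centred inside the parent's frame-t ellipsoid
#     (guaranteed parent-child voxel overlap) and separated along the
#     parent's longest axis by a slab of >= 0.3 * a_max;
#   * fusion parents are drawn to axis-aligned tangency-plus-gap at frame
#     t (approach feasibility is checked: each parent keeps a thick
#     self-overlap with its previous position, and neither lands next to a
#     bystander), and the fused child is a volume-conserving prolate
#     ellipsoid across the contact gap that penetrates both parents' old
#     masks by ~0.18 um.

#' Scene configuration
#'
#' @param grid Integer vector of voxels per axis (x, y, z).
#' @param voxel_size Voxel size per axis in um.
#' @param n_frames Number of time points (>= 2). The acquisition this
#'   emulates runs for hundreds of ~2 s frames; analysis-scale scenes
#'   default to 10 frames.
#' @param n_objects Initial mitochondrion count.
#' @param mean_volume,sdlog_volume Lognormal volume distribution of initial
#'   objects: arithmetic mean in um^3 and log-scale sd. Defaults give a
#'   mean individual volume of 0.4 um^3 with a wide spread whose lower tail
#'   falls under the 0.05 um^3 fragmentation cut.
#' @param volume_range Truncation bounds on initial volumes (um^3).
#' @param aspect_range Range of the long/short semi-axis ratio.
#' @param displacement_sd Per-axis Gaussian displacement per frame (um);
#'   small relative to object size so overlap tracking remains feasible at
#'   a ~2 s frame interval.
#' @param events Optional scheduled event table: columns `transition`
#'   (1-based left frame), `type` ("fission"/"fusion") and optionally
#'   `target` (object id for fission, "a|b" pair for fusion, NA = let the
#'   generator pick an eligible participant).
#' @param fission_rate,fusion_rate Expected stochastic events per
#'   transition (Poisson counts, on top of any schedule); realized counts
#'   are limited by eligibility.
#' @param split_frac Range of the uniform volume fraction taken by the
#'   first fission child.
#' @param min_gap Minimum surface gap between distinct objects (um).
#' @param frag_threshold Volume cut (um^3) used for the true fragmented
#'   counts.
#' @param seed Integer seed; every draw in the scene flows from it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(grid = c(96L, 96L, 48L),
                         voxel_size = c(0.1, 0.1, 0.1),
                         n_frames = 10L,
                         n_objects = 60L,
                         mean_volume = 0.4,
                         sdlog_volume = 1,
                         volume_range = c(0.02, 1.5),
                         aspect_range = c(1, 2.5),
                         displacement_sd = 0.05,
                         events = NULL,
                         fission_rate = 0,
                         fusion_rate = 0,
                         split_frac = c(0.3, 0.7),
                         min_gap = 0.2,
                         frag_threshold = 0.05,
                         seed = 1L) {
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (any(voxel_size <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  if (n_objects < 1L) stop("n_objects must be >= 1", call. = FALSE)
  if (mean_volume <= 0) stop("mean_volume must be > 0", call. = FALSE)
  if (fission_rate < 0 || fusion_rate < 0)
    stop("event rates must be >= 0", call. = FALSE)
  if (!is.null(events)) {
    events <- as.data.frame(events)
    if (!all(c("transition", "type") %in% names(events)))
      stop("events needs columns transition, type", call. = FALSE)
    if (is.null(events$target)) events$target <- NA_character_
    bad <- events$transition < 1L | events$transition > n_frames - 1L
    if (any(bad))
      stop("scheduled event outside transitions 1..", n_frames - 1L,
           " (row ", which(bad)[1], ")", call. = FALSE)
    if (!all(events$type %in% c("fission", "fusion")))
      stop("event type must be fission or fusion", call. = FALSE)
  }
  structure(list(grid = as.integer(grid), voxel_size = as.numeric(voxel_size),
                 n_frames = as.integer(n_frames),
                 n_objects = as.integer(n_objects),
                 mean_volume = mean_volume, sdlog_volume = sdlog_volume,
                 volume_range = volume_range, aspect_range = aspect_range,
                 displacement_sd = displacement_sd, events = events,
                 fission_rate = fission_rate, fusion_rate = fusion_rate,
                 split_frac = split_frac, min_gap = min_gap,
                 frag_threshold = frag_threshold, seed = as.integer(seed)),
            class = "scene_config")
}

# eligibility cutoffs for event participant selection
FISSION_MIN_AMAX <- 0.45   # um, longest semi-axis
FISSION_MIN_VOL <- 0.12    # um^3
FUSE_PENETRATION <- 0.18   # um, how deep the fused child reaches into parents
SELF_OVERLAP_CORE <- 0.09  # um, interior clearance kept when a parent jumps

# vectorized reflection into [lo, hi] (degenerate intervals collapse to mid)
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  s2 <- pmax(span, 1e-12)
  y <- (x - lo) %% (2 * s2)
  y <- ifelse(y > s2, 2 * s2 - y, y)
  ifelse(span <= 0, (lo + hi) / 2, lo + y)
}

# iterative push-apart so all pairs satisfy the bounding-radius gap;
# objects with fixed = TRUE are never moved, fixed-fixed pairs are trusted
# (their real surfaces are separated by construction)
resolve_collisions <- function(centers, rad, fixed, extent, min_gap,
                               max_iter = 200L) {
  n <- nrow(centers)
  if (n < 2L) return(centers)
  for (iter in seq_len(max_iter)) {
    moved <- FALSE
    dmat <- as.matrix(stats::dist(centers))
    need <- outer(rad, rad, "+") + min_gap
    diag(dmat) <- Inf
    viol <- which(dmat < need, arr.ind = TRUE)
    viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
    if (nrow(viol) == 0L) break
    for (k in seq_len(nrow(viol))) {
      i <- viol[k, 1]; j <- viol[k, 2]
      if (fixed[i] && fixed[j]) next
      d <- sqrt(sum((centers[j, ] - centers[i, ])^2))
      u <- if (d > 1e-9) (centers[j, ] - centers[i, ]) / d else
        { z <- stats::rnorm(3); z / sqrt(sum(z^2)) }
      push <- (need[i, j] - d) * 1.05
      if (push <= 0) next
      if (fixed[i]) {
        centers[j, ] <- centers[j, ] + u * push
      } else if (fixed[j]) {
        centers[i, ] <- centers[i, ] - u * push
      } else {
        centers[i, ] <- centers[i, ] - u * push / 2
        centers[j, ] <- centers[j, ] + u * push / 2
      }
      moved <- TRUE
    }
    for (ax in 1:3) {
      free <- !fixed
      centers[free, ax] <- reflect_into(centers[free, ax],
                                        rad[free] + 0.5 * min_gap,
                                        extent[ax] - rad[free] - 0.5 * min_gap)
    }
    if (!moved) break
  }
  centers
}

# Feasible placement of a fusion pair at the pre-event frame: both parents
# end up tangent-plus-gap along one coordinate axis (equal coordinates on
# the other two axes). Feasibility: (a) each parent's move keeps a thick
# overlap with its own previous position -- the midpoint lens retains an
# interior core of SELF_OVERLAP_CORE um, so the self-link always shares a
# voxel; (b) the pair was already separated along the chosen axis by its
# axis extents, so neither parent's new mask can touch the other's
# previous-frame mask; (c) neither new position lands within min_gap of a
# bystander; (d) both stay in the grid.
fusion_placement <- function(state, i, j, min_gap, extent, force = FALSE) {
  ci <- as.numeric(state[i, c("cx", "cy", "cz")])
  cj <- as.numeric(state[j, c("cx", "cy", "cz")])
  ai <- as.numeric(state[i, c("sx", "sy", "sz")])
  aj <- as.numeric(state[j, c("sx", "sy", "sz")])
  delta <- cj - ci
  for (k in order(abs(delta), decreasing = TRUE)) {
    s <- ai[k] + aj[k] + min_gap
    if (!force && abs(delta[k]) < ai[k] + aj[k]) next
    sgn <- if (delta[k] >= 0) 1 else -1
    m <- (ci + cj) / 2
    ni <- m; nj <- m
    ni[k] <- m[k] - sgn * s / 2
    nj[k] <- m[k] + sgn * s / 2
    di <- ni - ci; dj <- nj - cj
    lam_i <- sqrt(sum((di / (2 * ai))^2))
    lam_j <- sqrt(sum((dj / (2 * aj))^2))
    if (!force && ((1 - lam_i) * min(ai) < SELF_OVERLAP_CORE ||
                   (1 - lam_j) * min(aj) < SELF_OVERLAP_CORE)) next
    ri <- max(ai); rj <- max(aj)
    if (any(ni < ri + 0.01) || any(ni > extent - ri - 0.01) ||
        any(nj < rj + 0.01) || any(nj > extent - rj - 0.01)) next
    others <- setdiff(seq_len(nrow(state)), c(i, j))
    if (length(others) > 0) {
      co <- as.matrix(state[others, c("cx", "cy", "cz")])
      ro <- pmax(state$sx, state$sy, state$sz)[others]
      ok <- all(sqrt(colSums((t(co) - ni)^2)) >= ro + ri + min_gap) &&
            all(sqrt(colSums((t(co) - nj)^2)) >= ro + rj + min_gap)
      if (!ok) next
    }
    return(list(axis = k, new_i = ni, new_j = nj))
  }
  NULL
}

# Feasible pair for a stochastic fusion. Pairs involving a fragmented
# object (volume below the scene's fragmentation cut) are preferred, then
# proximity decides: fusion is the process that consumes fragmented
# mitochondria, so the fragmented-count series should respond to the
# fusion rate.
pick_fusion_pair <- function(state, busy, min_gap, extent,
                             frag_threshold = 0.05) {
  free <- which(!(state$id %in% busy))
  if (length(free) < 2L) return(NULL)
  cen <- as.matrix(state[free, c("cx", "cy", "cz")])
  dmat <- as.matrix(stats::dist(cen)); diag(dmat) <- Inf
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  frag <- state$volume[free] < frag_threshold
  has_frag <- frag[pairs[, 1]] | frag[pairs[, 2]]
  pairs <- pairs[order(!has_frag, dmat[pairs]), , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    i <- free[pairs[r, 1]]; j <- free[pairs[r, 2]]
    pl <- fusion_placement(state, i, j, min_gap, extent)
    if (!is.null(pl))
      return(list(ids = state$id[c(i, j)], placement = pl))
  }
  NULL
}

#' Generate a ground-truthed scene
#'
#' Runs the object program frame by frame and returns the full truth: every
#' object's centre, semi-axes and volume at every frame, the event log, and
#' per-frame total / fragmented counts. Count conservation,
#' `N(t+1) = N(t) + sum(children - 1) - sum(parents - 1)`, holds exactly
#' and is asserted before returning.
#'
#' @param config A [scene_config()].
#' @return A `scene_truth` list: `config`, `objects` (tibble: frame, id,
#'   cx, cy, cz, sx, sy, sz, volume), `events` (tibble: transition, type,
#'   parents, children, "|"-joined ids), `counts` (tibble: frame, n,
#'   n_fragmented).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  extent <- config$grid * config$voxel_size
  n0 <- config$n_objects

  # --- initial population -------------------------------------------------
  sdl <- config$sdlog_volume
  vol <- stats::rlnorm(n0, meanlog = log(config$mean_volume) - sdl^2 / 2,
                       sdlog = sdl)
  vol <- pmin(pmax(vol, config$volume_range[1]), config$volume_range[2])
  ar <- stats::runif(n0, config$aspect_range[1], config$aspect_range[2])
  cshort <- (3 * vol / (4 * pi * ar^1.5))^(1 / 3)
  semi <- cbind(cshort * ar, cshort * sqrt(ar), cshort)  # long, mid, short
  semi <- t(vapply(seq_len(n0), function(i) semi[i, sample.int(3L)],
                   numeric(3)))
  rad <- apply(semi, 1L, max)
  if (any(2 * rad + config$min_gap > min(extent)))
    stop("an object exceeds the grid extent", call. = FALSE)

  # place largest objects first: sequential rejection sampling jams far
  # later when the big spheres go in before the small ones
  ord <- order(rad, decreasing = TRUE)
  vol <- vol[ord]; semi <- semi[ord, , drop = FALSE]; rad <- rad[ord]
  centers <- matrix(NA_real_, n0, 3L)
  for (i in seq_len(n0)) {
    ok <- FALSE
    for (try in seq_len(5000L)) {
      p <- stats::runif(3, rad[i] + 0.5 * config$min_gap,
                        extent - rad[i] - 0.5 * config$min_gap)
      if (i == 1L) { ok <- TRUE } else {
        dd <- sqrt(colSums((t(centers[seq_len(i - 1L), , drop = FALSE]) - p)^2))
        ok <- all(dd >= rad[seq_len(i - 1L)] + rad[i] + config$min_gap)
      }
      if (ok) { centers[i, ] <- p; break }
    }
    if (!ok) stop("could not place ", n0, " objects without contact; ",
                  "reduce n_objects or enlarge the grid", call. = FALSE)
  }

  state <- data.frame(id = seq_len(n0), cx = centers[, 1], cy = centers[, 2],
                      cz = centers[, 3], sx = semi[, 1], sy = semi[, 2],
                      sz = semi[, 3], volume = vol)
  next_id <- n0 + 1L

  # --- event program ------------------------------------------------------
  sched <- config$events
  stoch <- NULL
  if (config$fission_rate > 0 || config$fusion_rate > 0) {
    for (tr in seq_len(config$n_frames - 1L)) {
      nf <- stats::rpois(1L, config$fission_rate)
      nu <- stats::rpois(1L, config$fusion_rate)
      if (nf + nu > 0)
        stoch <- rbind(stoch, data.frame(
          transition = tr,
          type = c(rep("fission", nf), rep("fusion", nu)),
          target = NA_character_, scheduled = FALSE))
    }
  }
  if (!is.null(sched)) {
    sched$scheduled <- TRUE
    sched <- sched[, c("transition", "type", "target", "scheduled")]
  }
  program <- rbind(sched, stoch)
  if (!is.null(program)) program <- program[order(program$transition), ]

  frames <- vector("list", config$n_frames)
  event_log <- list()

  for (t in seq_len(config$n_frames)) {
    todo <- if (!is.null(program)) program[program$transition == t, , drop = FALSE]
            else NULL
    plan <- list()
    if (!is.null(todo) && nrow(todo) > 0L) {
      busy <- integer(0)
      for (r in seq_len(nrow(todo))) {
        typ <- todo$type[r]; tgt <- todo$target[r]
        if (typ == "fission") {
          if (!is.na(tgt)) {
            pid <- as.integer(tgt)
            row <- match(pid, state$id)
            if (is.na(row))
              stop("scheduled fission at transition ", t,
                   " targets dead/unknown object ", pid, call. = FALSE)
            if (pid %in% busy)
              stop("object ", pid, " already participates at transition ", t,
                   call. = FALSE)
            if (max(state[row, c("sx", "sy", "sz")]) < FISSION_MIN_AMAX ||
                state$volume[row] < FISSION_MIN_VOL)
              stop("scheduled fission target ", pid,
                   " too small at transition ", t, call. = FALSE)
          } else {
            amax <- pmax(state$sx, state$sy, state$sz)
            elig <- state$id[amax >= FISSION_MIN_AMAX &
                             state$volume >= FISSION_MIN_VOL &
                             !(state$id %in% busy)]
            if (length(elig) == 0L) {
              if (isTRUE(todo$scheduled[r]))
                stop("no fission-eligible object at transition ", t,
                     call. = FALSE)
              next
            }
            pid <- if (length(elig) == 1L) elig else sample(elig, 1L)
          }
          busy <- c(busy, pid)
          plan[[length(plan) + 1L]] <- list(type = "fission", parents = pid)
        } else {
          if (!is.na(tgt)) {
            pids <- split_ids(tgt)
            if (length(pids) != 2L)
              stop("fusion target must name two objects", call. = FALSE)
            if (!all(pids %in% state$id))
              stop("scheduled fusion at transition ", t,
                   " references dead/unknown object ",
                   pids[!pids %in% state$id][1], call. = FALSE)
            if (any(pids %in% busy))
              stop("fusion participant already busy at transition ", t,
                   call. = FALSE)
            pl <- fusion_placement(state, match(pids[1], state$id),
                                   match(pids[2], state$id),
                                   config$min_gap, extent, force = TRUE)
          } else {
            if (nrow(state) < 2L) {
              if (isTRUE(todo$scheduled[r]))
                stop("fusion at transition ", t, " needs >= 2 objects",
                     call. = FALSE)
              next
            }
            pick <- pick_fusion_pair(state, busy, config$min_gap, extent,
                                     config$frag_threshold)
            if (is.null(pick)) {
              if (isTRUE(todo$scheduled[r]))
                stop("no feasible fusion pair at transition ", t, call. = FALSE)
              next
            }
            pids <- pick$ids; pl <- pick$placement
          }
          busy <- c(busy, pids)
          plan[[length(plan) + 1L]] <- list(type = "fusion", parents = pids,
                                            placement = pl)
        }
      }
    }

    # pre-event adjustment: move fusion parents to their tangency placement
    # before the frame is emitted
    for (ev in plan) {
      if (ev$type != "fusion") next
      i <- match(ev$parents[1], state$id); j <- match(ev$parents[2], state$id)
      state[i, c("cx", "cy", "cz")] <- ev$placement$new_i
      state[j, c("cx", "cy", "cz")] <- ev$placement$new_j
    }

    frames[[t]] <- cbind(frame = t, state)

    if (t == config$n_frames) break

    # --- build frame t + 1 ------------------------------------------------
    new_state <- state
    participating <- unlist(lapply(plan, `[[`, "parents"))
    born <- integer(0)

    for (ev in plan) {
      if (ev$type == "fission") {
        i <- match(ev$parents, new_state$id)
        par <- new_state[i, ]
        semi_p <- as.numeric(par[c("sx", "sy", "sz")])
        ax <- which.max(semi_p)
        amax <- semi_p[ax]
        f <- stats::runif(1L, config$split_frac[1], config$split_frac[2])
        vols <- par$volume * c(f, 1 - f)
        kids <- lapply(1:2, function(k) {
          alpha <- 0.35 * amax
          beta <- sqrt(3 * vols[k] / (4 * pi * alpha))
          s <- c(beta, beta, beta); s[ax] <- alpha
          ctr <- as.numeric(par[c("cx", "cy", "cz")])
          ctr[ax] <- ctr[ax] + c(0.6, -0.6)[k] * amax
          data.frame(id = NA_integer_, cx = ctr[1], cy = ctr[2], cz = ctr[3],
                     sx = s[1], sy = s[2], sz = s[3], volume = vols[k])
        })
        kid_ids <- next_id + 0:1; next_id <- next_id + 2L
        kids <- do.call(rbind, kids); kids$id <- kid_ids
        new_state <- rbind(new_state[-i, ], kids)
        born <- c(born, kid_ids)
        event_log[[length(event_log) + 1L]] <- tibble::tibble(
          transition = t, type = "fission",
          parents = as.character(ev$parents),
          children = paste(sort(kid_ids), collapse = "|"))
      } else {
        i <- match(ev$parents[1], new_state$id)
        j <- match(ev$parents[2], new_state$id)
        ci <- as.numeric(new_state[i, c("cx", "cy", "cz")])
        cj <- as.numeric(new_state[j, c("cx", "cy", "cz")])
        k <- ev$placement$axis
        ai <- as.numeric(new_state[i, c("sx", "sy", "sz")])
        sgn <- if (cj[k] >= ci[k]) 1 else -1
        vtot <- new_state$volume[i] + new_state$volume[j]
        # prolate child across the contact gap, reaching FUSE_PENETRATION
        # into each parent's old mask along axis k
        rc <- (3 * vtot / (4 * pi))^(1 / 3)
        ak <- max(rc, config$min_gap / 2 + FUSE_PENETRATION)
        bk <- sqrt(3 * vtot / (4 * pi * ak))
        s <- c(bk, bk, bk); s[k] <- ak
        ctr <- ci
        ctr[k] <- ci[k] + sgn * (ai[k] + config$min_gap / 2)
        kid_id <- next_id; next_id <- next_id + 1L
        kid <- data.frame(id = kid_id, cx = ctr[1], cy = ctr[2], cz = ctr[3],
                          sx = s[1], sy = s[2], sz = s[3], volume = vtot)
        new_state <- rbind(new_state[-c(i, j), ], kid)
        born <- c(born, kid_id)
        event_log[[length(event_log) + 1L]] <- tibble::tibble(
          transition = t, type = "fusion",
          parents = paste(sort(ev$parents), collapse = "|"),
          children = as.character(kid_id))
      }
    }

    # random motion for non-participants
    free <- !(new_state$id %in% c(participating, born))
    nf <- sum(free)
    if (nf > 0 && config$displacement_sd > 0) {
      new_state[free, c("cx", "cy", "cz")] <-
        new_state[free, c("cx", "cy", "cz")] +
        matrix(stats::rnorm(3 * nf, 0, config$displacement_sd), nf, 3L)
    }
    cen <- as.matrix(new_state[, c("cx", "cy", "cz")])
    radv <- pmax(new_state$sx, new_state$sy, new_state$sz)
    fixedv <- new_state$id %in% born
    for (ax in 1:3)
      cen[!fixedv, ax] <- reflect_into(
        cen[!fixedv, ax], radv[!fixedv] + 0.5 * config$min_gap,
        extent[ax] - radv[!fixedv] - 0.5 * config$min_gap)
    cen <- resolve_collisions(cen, radv, fixedv, extent, config$min_gap)
    new_state[, c("cx", "cy", "cz")] <- cen
    state <- new_state[order(new_state$id), ]
    rownames(state) <- NULL
  }

  objects <- tibble::as_tibble(do.call(rbind, frames))
  events <- if (length(event_log)) do.call(rbind, event_log) else
    tibble::tibble(transition = integer(0), type = character(0),
                   parents = character(0), children = character(0))
  counts <- tibble::tibble(
    frame = seq_len(config$n_frames),
    n = vapply(frames, nrow, integer(1)),
    n_fragmented = vapply(frames, function(f)
      sum(f$volume < config$frag_threshold), integer(1)))

  # count conservation against the event log
  for (t in seq_len(config$n_frames - 1L)) {
    evt <- events[events$transition == t, ]
    dn <- sum(vapply(evt$children[evt$type == "fission"],
                     function(x) length(split_ids(x)) - 1L, integer(1))) -
          sum(vapply(evt$parents[evt$type == "fusion"],
                     function(x) length(split_ids(x)) - 1L, integer(1)))
    if (counts$n[t + 1L] - counts$n[t] != dn)
      stop("internal error: count conservation violated at transition ", t)
  }

  structure(list(config = config, objects = objects, events = events,
                 counts = counts),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth> ", x$config$n_frames, " frames, ",
      x$counts$n[1], " -> ", x$counts$n[x$config$n_frames], " objects, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}
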