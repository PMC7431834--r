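# Tracking: overlap links (against an exhaustive voxel oracle), track-ID
# assignment as graph components, and event detection semantics.

test_that("overlap links follow the voxel masks", {
  a <- array(0L, c(12, 12, 4)); a[3:6, 3:6, 2] <- 1L
  # static object: one self link
  l <- link_adjacent(lv(a, 1), lv(a, 2))
  expect_equal(nrow(l), 1L)
  expect_equal(l$overlap, 16L)
  # displaced beyond its own extent: no link
  b <- array(0L, c(12, 12, 4)); b[9:12, 9:12, 2] <- 1L
  l2 <- link_adjacent(lv(a, 1), lv(b, 2))
  expect_equal(nrow(l2), 0L)
  obj <- rbind(cbind(measure_objects(lv(a, 1))),
               cbind(measure_objects(lv(b, 2))))
  det <- detect_events(l2, obj)
  expect_equal(nrow(det$events), 0L)
  expect_equal(det$deaths$frame, 1L)
  expect_equal(det$births$frame, 2L)
  # min_overlap filters thin contacts
  c1 <- array(0L, c(12, 12, 4)); c1[3:6, 4:6, 2] <- 1L
  expect_equal(nrow(link_adjacent(lv(a, 1), lv(c1, 2), min_overlap = 13L)),
               0L)
  expect_equal(nrow(link_adjacent(lv(a, 1), lv(c1, 2), min_overlap = 12L)),
               1L)
  expect_error(link_adjacent(lv(a), lv(array(0L, c(5, 5, 5)))), "share shape")
})

test_that("overlap counts match the exhaustive voxel-pair oracle", {
  for (s in 1:10) {
    set.seed(s)
    l1 <- array(sample(0:4, 20^3, TRUE, prob = c(0.7, rep(0.075, 4))),
                c(20, 20, 20))
    l2 <- array(sample(0:4, 20^3, TRUE, prob = c(0.7, rep(0.075, 4))),
                c(20, 20, 20))
    got <- link_adjacent(lv(l1, 1), lv(l2, 2))
    want <- oracle_overlap_counts(l1, l2)
    expect_equal(got$from, want$from)
    expect_equal(got$to, want$to)
    expect_equal(got$overlap, want$overlap)
  }
})

test_that("one parent covering two disjoint children links to both", {
  p <- array(0L, c(20, 20, 4)); p[4:15, 4:9, 2] <- 1L
  ch <- array(0L, c(20, 20, 4)); ch[4:8, 4:9, 2] <- 1L; ch[11:15, 4:9, 2] <- 2L
  l <- link_adjacent(lv(p, 1), lv(ch, 2))
  expect_equal(nrow(l), 2L)
  det <- detect_events(l)
  expect_equal(det$events$type, "fission")
  expect_equal(det$events$children, "1|2")
})

test_that("track ids are connected components over (frame, object) nodes", {
  # k disjoint one-to-one chains over 10 frames -> k tracks
  k <- 4L
  objects <- do.call(rbind, lapply(1:10, function(f)
    tibble::tibble(frame = f, id = 1:k)))
  links <- do.call(rbind, lapply(1:9, function(t)
    tibble::tibble(transition = t, from = 1:k, to = 1:k, overlap = 5L)))
  tracked <- assign_track_ids(links, objects)
  expect_equal(length(unique(tracked$track)), k)
  expect_equal(nrow(tracked), nrow(objects))
  # within a chain, one track id
  for (i in 1:k)
    expect_equal(length(unique(tracked$track[tracked$id == i])), 1L)

  # a 1 -> 2 split shares one track id; a bystander keeps its own
  objects2 <- tibble::tibble(frame = c(1L, 1L, 2L, 2L, 2L),
                             id = c(1L, 2L, 1L, 2L, 3L))
  links2 <- tibble::tibble(transition = 1L, from = c(1L, 1L, 2L),
                           to = c(1L, 2L, 3L), overlap = 1L)
  tr2 <- assign_track_ids(links2, objects2)
  split_ids <- tr2$track[(tr2$frame == 1 & tr2$id == 1) |
                         (tr2$frame == 2 & tr2$id %in% c(1, 2))]
  expect_equal(length(unique(split_ids)), 1L)
  expect_false(tr2$track[tr2$frame == 1 & tr2$id == 2] %in% split_ids)
  # partition: every object in exactly one track
  expect_false(anyNA(tr2$track))
  expect_error(assign_track_ids(tibble::tibble(transition = 1L, from = 9L,
                                               to = 1L, overlap = 1L),
                                objects2), "absent")
})

test_that("event detection implements the in/out-degree semantics", {
  mk <- function(from, to) tibble::tibble(transition = 1L, from = from,
                                          to = to, overlap = 1L)
  f <- detect_events(mk(c(1L, 1L), c(1L, 2L)))$events
  expect_equal(f$type, "fission")
  u <- detect_events(mk(c(1L, 2L), c(1L, 1L)))$events
  expect_equal(u$type, "fusion")
  expect_equal(u$parents, "1|2")
  # a crossing (two one-to-one links) is no event
  x <- detect_events(mk(c(1L, 2L), c(2L, 1L)))$events
  expect_equal(nrow(x), 0L)
})

test_that("count bookkeeping holds on enumerated bipartite link graphs", {
  check_graph <- function(adj) {
    m <- nrow(adj); n <- ncol(adj)
    idx <- which(adj == 1L, arr.ind = TRUE)
    links <- tibble::tibble(transition = 1L, from = as.integer(idx[, 1]),
                            to = as.integer(idx[, 2]), overlap = 1L)
    objects <- rbind(tibble::tibble(frame = 1L, id = seq_len(m)),
                     tibble::tibble(frame = 2L, id = seq_len(n)))
    det <- detect_events(links, objects)
    ev <- det$events
    n_child <- vapply(ev$children[ev$type == "fission"], function(x)
      length(strsplit(x, "|", fixed = TRUE)[[1]]), integer(1))
    n_par <- vapply(ev$parents[ev$type == "fusion"], function(x)
      length(strsplit(x, "|", fixed = TRUE)[[1]]), integer(1))
    rhs <- sum(n_child - 1L) - sum(n_par - 1L) +
      nrow(det$births) - nrow(det$deaths)
    expect_equal(n - m, rhs)
    # events mirror the degree sequences exactly
    expect_equal(sum(ev$type == "fission"), sum(rowSums(adj) >= 2))
    expect_equal(sum(ev$type == "fusion"), sum(colSums(adj) >= 2))
  }
  # exhaustive 3 + 3
  for (code in 0:(2^9 - 1)) {
    adj <- matrix(as.integer(intToBits(code))[1:9], 3, 3)
    check_graph(adj)
  }
  # sampled 4 + 4
  set.seed(42)
  for (r in 1:100) {
    adj <- matrix(rbinom(16, 1, 0.4), 4, 4)
    check_graph(adj)
  }
})

test_that("tracking is invariant to within-frame label permutation", {
  tr <- generate_scene(scene_config(
    n_objects = 20L, n_frames = 5L,
    events = data.frame(transition = c(2L, 3L),
                        type = c("fission", "fusion")), seed = 12))
  run <- segment_and_track(tr)
  # permute labels of frame 2 and rebuild
  labs <- run$labels
  K <- max(labs[[2]]$labels)
  perm <- sample(K)
  l2 <- labs[[2]]$labels
  l2[l2 > 0] <- perm[l2[l2 > 0]]
  labs[[2]] <- label_volume(l2, labs[[2]]$voxel_size, frame = 2L)
  objects <- do.call(rbind, lapply(labs, measure_objects))
  links <- link_series(labs)
  det <- detect_events(links, objects)
  expect_identical(sort(match_events_to_truth(tr, objects, det$events)),
                   sort(match_events_to_truth(tr, run$objects,
                                              run$det$events)))
  # determinism: identical inputs give identical outputs
  expect_identical(run$det$events,
                   detect_events(run$links, run$objects)$events)
})
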