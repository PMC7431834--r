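# Dynamics statistics: the window cap, track typology, proportional
# difference, fragmented-count fluctuation series, trend slopes and the
# chi-squared wrapper.

three_windows <- window_scheme()

mk_tracks <- function(n_frames = 10L, n_tracks = 1L) {
  do.call(rbind, lapply(seq_len(n_frames), function(f)
    tibble::tibble(frame = f, id = seq_len(n_tracks),
                   track = seq_len(n_tracks))))
}

mk_events <- function(transition, type, id = 1L) {
  tibble::tibble(transition = as.integer(transition), type = type,
                 parents = as.character(id), children = as.character(id))
}

test_that("window schemes must tile cleanly", {
  expect_error(window_scheme(list(c(1, 4), c(5, 8))), "boundary")
  expect_error(window_scheme(list(c(1, 1))), "two time points")
  expect_silent(window_scheme(list(c(1, 3), c(3, 6), c(6, 8))))
})

test_that("one event per window totals the maximum of three counted events", {
  ev <- mk_events(c(2, 5, 8), c("fission", "fusion", "fission"))
  ws <- window_events(ev, mk_tracks(), three_windows)
  expect_equal(sum(ws$counted != "none"), 3L)
  expect_equal(ws$counted, c("fission", "fusion", "fission"))
})

test_that("multiplicity within a window is capped to the earliest event", {
  ev <- mk_events(c(1, 3), c("fission", "fission"))
  ws <- window_events(ev, mk_tracks(), three_windows)
  expect_equal(ws$counted[ws$window == 1], "fission")
  expect_equal(ws$raw_fission[ws$window == 1], 2L)
  expect_equal(sum(ws$counted != "none"), 1L)
  # tie at one transition: fission outranks fusion
  ev2 <- rbind(mk_events(2, "fusion"), mk_events(2, "fission"))
  ws2 <- window_events(ev2, mk_tracks(), three_windows)
  expect_equal(ws2$counted[ws2$window == 1], "fission")
  # an event outside every window is ignored with a warning
  expect_warning(
    window_events(mk_events(10, "fission"), mk_tracks(11L), three_windows),
    "outside")
})

test_that("the window cap matches an enumerated oracle over event placements", {
  set.seed(7)
  for (r in 1:50) {
    n_ev <- sample(0:5, 1)
    ev <- mk_events(sample(1:9, n_ev, replace = TRUE),
                    sample(c("fission", "fusion"), n_ev, replace = TRUE))
    ws <- window_events(ev, mk_tracks(), three_windows)
    expect_equal(ws$counted[order(ws$window)],
                 oracle_window_count(ev, three_windows))
    expect_lte(sum(ws$counted != "none"), 3L)
  }
})

test_that("track typology partitions tracks and matches the definitions", {
  tracks <- mk_tracks(n_tracks = 4L)
  ev <- rbind(mk_events(c(2, 5), c("fission", "fusion"), id = 1L),  # balanced
              mk_events(c(2, 5), c("fission", "fission"), id = 2L), # fis > fus
              mk_events(3, "fusion", id = 3L))                      # fis < fus
  ws <- window_events(ev, tracks, three_windows)
  cl <- classify_tracks(ws)
  expect_equal(cl$tracks$class,
               c("balanced", "fission_dominant", "fusion_dominant",
                 "quiescent"))
  expect_equal(sum(cl$tally$n), 4L)
  expect_equal(sum(cl$tally$proportion[1:3]), 1)
  expect_true(is.na(cl$tally$proportion[4]))
})

test_that("proportional difference is (F - f)/(F + f)", {
  expect_equal(proportional_difference(3, 3), 0)
  expect_equal(proportional_difference(3, 1), 0.5)
  expect_equal(proportional_difference(0, 4), -1)
  expect_error(proportional_difference(0, 0), "undefined")
  expect_error(proportional_difference(-1, 2), ">= 0")
})

test_that("the fragmented-count series telescopes", {
  expect_equal(delta_fragmented(c(1, 2))$delta, 1)
  expect_equal(delta_fragmented(c(2, 1))$delta, -1)
  set.seed(3)
  for (r in 1:20) {
    counts <- sample(0:30, sample(2:15, 1), replace = TRUE)
    fs <- delta_fragmented(counts)
    expect_equal(length(fs$delta), length(counts) - 1L)
    expect_equal(sum(fs$delta), counts[length(counts)] - counts[1])
  }
  expect_error(delta_fragmented(3), "two frames")
})

test_that("trend slope is exact on lines and zero on constants", {
  expect_equal(trend_slope(rep(4, 7)), 0)
  expect_equal(trend_slope(3.5 * (1:9)), 3.5)
  expect_equal(trend_slope(2 - 0.25 * (1:6)), -0.25)
  expect_error(trend_slope(1), "two points")
})

test_that("chi-squared matches the closed-form Pearson computation", {
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  r0 <- chi_squared(prop)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(chi_squared(matrix(10, 2, 2))$statistic, 0)

  tab <- rbind(c(35, 27, 115), c(7, 1, 121))
  res <- chi_squared(tab)
  # independent closed form from the margins
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E))
  expect_equal(res$df, 2)
  expect_equal(res$p_value, stats::pchisq(sum((tab - E)^2 / E), 2,
                                          lower.tail = FALSE))
  expect_lt(res$p_value, 0.001)

  expect_error(chi_squared(rbind(c(0, 0), c(1, 2))), "sums")
  expect_error(chi_squared(prop, yates = TRUE), "2x2")
  # Yates correction shrinks the 2x2 statistic
  t22 <- rbind(c(12, 5), c(6, 14))
  expect_lt(chi_squared(t22, yates = TRUE)$statistic,
            chi_squared(t22)$statistic)
})
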