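# Scene generator: count bookkeeping, scheduling, reproducibility,
# rendering physics, and the auxiliary population/mosaic simulators.

test_that("event-free scenes conserve the object count at every frame", {
  tr <- generate_scene(scene_config(n_objects = 10L, n_frames = 10L,
                                    seed = 2))
  expect_equal(tr$counts$n, rep(10L, 10L))
  expect_equal(nrow(tr$events), 0L)
})

test_that("a scheduled program changes the count by fissions minus fusions", {
  ev <- data.frame(transition = c(2L, 4L, 6L, 8L),
                   type = c("fission", "fission", "fission", "fusion"))
  tr <- generate_scene(scene_config(n_objects = 50L, n_frames = 10L,
                                    events = ev, seed = 5))
  expect_equal(tr$counts$n[10], 52L)  # 50 + 3 - 1
  expect_equal(nrow(tr$events), 4L)
  # frame-by-frame conservation against the event log
  for (t in 1:9) {
    evt <- tr$events[tr$events$transition == t, ]
    dn <- sum(evt$type == "fission") - sum(evt$type == "fusion")
    expect_equal(tr$counts$n[t + 1] - tr$counts$n[t], dn)
  }
  # every participant exists in the stated frames
  for (r in seq_len(nrow(tr$events))) {
    t <- tr$events$transition[r]
    par <- as.integer(strsplit(tr$events$parents[r], "|", fixed = TRUE)[[1]])
    chl <- as.integer(strsplit(tr$events$children[r], "|", fixed = TRUE)[[1]])
    expect_true(all(par %in% tr$objects$id[tr$objects$frame == t]))
    expect_true(all(chl %in% tr$objects$id[tr$objects$frame == t + 1]))
  }
})

test_that("the same config and seed reproduce the scene exactly", {
  cfg <- scene_config(n_objects = 20L, n_frames = 6L, fission_rate = 0.5,
                      fusion_rate = 0.5, seed = 9)
  a <- generate_scene(cfg); b <- generate_scene(cfg)
  expect_identical(a$objects, b$objects)
  expect_identical(a$events, b$events)
  expect_identical(a$counts, b$counts)
})

test_that("infeasible schedules are rejected with the offending event named", {
  ev <- data.frame(transition = 2L, type = "fission", target = "999")
  expect_error(generate_scene(scene_config(n_objects = 5L, events = ev,
                                           seed = 1)),
               "dead/unknown object 999")
  ev2 <- data.frame(transition = 1L, type = "fusion")
  expect_error(generate_scene(scene_config(n_objects = 1L, events = ev2,
                                           seed = 1)),
               "needs >= 2 objects")
  expect_error(scene_config(events = data.frame(transition = 99L,
                                                type = "fission")),
               "outside transitions")
  expect_error(scene_config(n_frames = 1L), "n_frames")
})

test_that("stochastic scenes keep conservation under varied seeds", {
  for (s in 1:4) {
    tr <- generate_scene(scene_config(n_objects = 30L, n_frames = 8L,
                                      fission_rate = 1, fusion_rate = 0.5,
                                      seed = s))
    for (t in seq_len(7)) {
      evt <- tr$events[tr$events$transition == t, ]
      dn <- sum(vapply(evt$children[evt$type == "fission"], function(x)
        length(strsplit(x, "|", fixed = TRUE)[[1]]) - 1L, integer(1))) -
        sum(vapply(evt$parents[evt$type == "fusion"], function(x)
          length(strsplit(x, "|", fixed = TRUE)[[1]]) - 1L, integer(1)))
      expect_equal(tr$counts$n[t + 1] - tr$counts$n[t], dn)
    }
  }
})

test_that("rendering puts background outside objects and bleaches the foreground", {
  tr <- generate_scene(scene_config(n_objects = 1L, n_frames = 4L,
                                    displacement_sd = 0, seed = 3))
  b <- 0.25
  opt <- optics_config(background = 7, foreground = 100, bleach_rate = b)
  imgs <- lapply(1:4, function(k) render_frame(tr, k, opt))
  for (k in 1:4) {
    x <- imgs[[k]]$data
    fgv <- x[x > 7]
    expect_gt(length(fgv), 0)
    # all non-object voxels sit exactly at background
    expect_true(all(x %in% c(7, 100 * exp(-b * (k - 1)))))
    expect_equal(mean(fgv) / 100, exp(-b * (k - 1)), tolerance = 1e-12)
  }
})

test_that("a rendered ellipsoid recovers its analytic volume within a voxel shell", {
  tr <- generate_scene(scene_config(n_objects = 1L, n_frames = 2L,
                                    displacement_sd = 0, seed = 17))
  ob <- tr$objects[tr$objects$frame == 1, ]
  img <- render_frame(tr, 1, optics_config(background = 0, foreground = 1))
  measured <- sum(img$data > 0) * prod(tr$config$voxel_size)
  analytic <- 4 / 3 * pi * ob$sx * ob$sy * ob$sz
  # one-voxel shell: surface area (Thomsen approximation) x voxel size
  p <- 1.6075
  area <- 4 * pi * (((ob$sx * ob$sy)^p + (ob$sx * ob$sz)^p +
                     (ob$sy * ob$sz)^p) / 3)^(1 / p)
  expect_lt(abs(measured - analytic), area * 0.1)
  expect_equal(ob$volume, analytic, tolerance = 1e-12)
})

test_that("shot-noise rendering is reproducible given the same seed", {
  tr <- generate_scene(scene_config(n_objects = 5L, n_frames = 2L, seed = 4))
  opt <- optics_config(shot_noise = TRUE)
  a <- render_frame(tr, 1, opt, seed = 123)
  b <- render_frame(tr, 1, opt, seed = 123)
  expect_identical(a$data, b$data)
})

test_that("synthetic 2D populations hit their configured moments", {
  z <- generate_tem_population(tem_pop_config(n = 5L, sd_area = 0,
                                              sd_ratio = 0, seed = 1))
  expect_equal(z$area_um2, rep(0.11, 5))
  expect_equal(z$ratio, rep(2.34, 5))
  p <- generate_tem_population(tem_pop_config(n = 10000L, seed = 3))
  expect_equal(mean(p$area_um2), 0.11, tolerance = 0.02)
  expect_equal(mean(p$ratio), 2.34, tolerance = 0.02)
  expect_true(all(p$ratio >= 1))
  p2 <- generate_tem_population(tem_pop_config(n = 10000L, seed = 3))
  expect_identical(p, p2)
  expect_error(tem_pop_config(mean_area = -1), "area")
})

test_that("mosaic simulator matches closed-form survival and is seed-stable", {
  d0 <- simulate_mosaic(mosaic_config(n_germaria = 200L, hazard_neg = 0,
                                      hazard_pos = 0, weeks = 3L, seed = 2))
  for (w in 1:3) expect_equal(maintenance_percent(d0, w), 100)
  h <- 0.15
  d <- simulate_mosaic(mosaic_config(n_germaria = 1000L, gsc_neg = 1L,
                                     hazard_neg = h, weeks = 4L, seed = 8))
  for (w in 1:4) {
    expected <- 100 * (1 - h)^w
    se <- 100 * sqrt((1 - h)^w * (1 - (1 - h)^w) / 1000)
    expect_lt(abs(maintenance_percent(d, w) - expected), 4 * se + 0.5)
  }
  expect_identical(d, simulate_mosaic(mosaic_config(n_germaria = 1000L,
                                                    gsc_neg = 1L,
                                                    hazard_neg = h,
                                                    weeks = 4L, seed = 8)))
})

test_that("symmetric-mosaic deviation from the null shrinks roughly as 1/sqrt(n)", {
  dev_at <- function(n) {
    mean(vapply(1:8, function(s) {
      d <- simulate_mosaic(mosaic_config(n_germaria = n, rate_neg = 5,
                                         rate_pos = 5, weeks = 1L,
                                         seed = 100 + s))
      abs(pooled_division_rate(d) - 1)
    }, numeric(1)))
  }
  d50 <- dev_at(50L); d5000 <- dev_at(5000L)
  expect_lt(dev_at(500L), d50)
  expect_lt(d5000, d50 / 3)
})
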