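# Segmentation: bleach correction, hysteresis thresholding (against the
# reconstruction oracle), object measurement and fragmentation rules.

test_that("bleach correction equalizes frame means and preserves rank order", {
  const <- lapply(1:3, function(k)
    image_stack(array(5, c(6, 6, 3)), 0.1, frame = k))
  out <- bleach_correct(const)
  for (k in 1:3) expect_equal(out[[k]]$data, const[[k]]$data)

  set.seed(1)
  base <- array(runif(6 * 6 * 3, 1, 10), c(6, 6, 3))
  decayed <- lapply(1:5, function(k)
    image_stack(base * exp(-0.3 * (k - 1)), 0.1, frame = k))
  corr <- bleach_correct(decayed)
  m1 <- mean(corr[[1]]$data)
  for (k in 2:5) {
    expect_equal(mean(corr[[k]]$data), m1, tolerance = 1e-12)
    expect_identical(order(corr[[k]]$data), order(decayed[[k]]$data))
  }
  zero <- list(image_stack(array(0, c(4, 4, 2)), 0.1))
  expect_error(bleach_correct(zero), "zero mean")
  expect_error(bleach_correct(list(decayed[[1]],
                                   image_stack(array(1, c(2, 2, 2)), 0.1))),
               "share shape")
})

test_that("hysteresis keeps skirts attached to cores and drops isolated weak patches", {
  x <- array(0, c(20, 20, 20))
  # blob A: strong core with weak skirt touching it
  x[5:7, 5:7, 5:7] <- 100
  x[8, 5:7, 5:7] <- 50           # skirt in [low, high)
  # blob B: isolated weak patch, no core
  x[15:17, 15:17, 15:17] <- 50
  st <- image_stack(x, 0.1)
  seg <- hysteresis_segment(st, low = 40, high = 80)
  expect_equal(max(seg$labels), 1L)
  expect_true(all(seg$labels[8, 5:7, 5:7] == 1L))       # skirt kept
  expect_true(all(seg$labels[15:17, 15:17, 15:17] == 0L))  # patch dropped
  expect_identical(seg$labels > 0, oracle_hysteresis_mask(x, 40, 80))

  expect_equal(max(hysteresis_segment(image_stack(array(0, c(8, 8, 8)), 0.1),
                                      10, 20)$labels), 0L)
  expect_error(hysteresis_segment(st, low = 90, high = 40), "low threshold")
})

test_that("hysteresis equals the reconstruction oracle on random grids", {
  for (s in 1:20) {
    set.seed(s)
    x <- array(sample(0:100, 20^3, replace = TRUE), c(20, 20, 20))
    seg <- hysteresis_segment(image_stack(x, 0.1), low = 60, high = 90)
    expect_identical(seg$labels > 0, oracle_hysteresis_mask(x, 60, 90))
    # sandwich property: between the high- and low-threshold masks
    expect_true(all(!(seg$labels > 0) | (x >= 60)))
    expect_true(all(!(x >= 90) | (seg$labels > 0)))
  }
})

test_that("two separated blobs give exactly two labels", {
  x <- array(0, c(20, 20, 20))
  x[3:5, 3:5, 3:5] <- 100
  x[14:16, 14:16, 14:16] <- 100
  seg <- hysteresis_segment(image_stack(x, 0.1), 40, 80)
  expect_equal(max(seg$labels), 2L)
})

test_that("object measurement reports volumes, centroids and the partition", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:5, 1:5, 1:4] <- 1L   # 100 voxels
  lab[8:9, 8:9, 8:9] <- 2L   # 8 voxels
  obj <- measure_objects(label_volume(lab, 0.1))
  expect_equal(obj$volume_um3[1], 0.1)   # 100 x 0.001
  expect_equal(obj$voxels, c(100L, 8L))
  expect_equal(sum(obj$voxels), sum(lab > 0))
  # centrally symmetric object: centroid at its centre of symmetry
  expect_equal(unlist(obj[2, c("cx", "cy", "cz")]), c(cx = 0.8, cy = 0.8,
                                                      cz = 0.8))
  expect_equal(obj$fragmented, c(FALSE, TRUE))  # 0.008 < 0.05
})

test_that("fragmentation is a strict volume cut", {
  expect_true(classify_fragmented(0.04))
  expect_false(classify_fragmented(0.06))
  expect_false(classify_fragmented(0.05))   # boundary: not fragmented
  expect_error(classify_fragmented(0.1, threshold = -1), "threshold")
  # monotone non-increasing in the threshold
  vols <- runif(50, 0, 0.2)
  counts <- vapply(c(0.02, 0.05, 0.1, 0.2), function(th)
    sum(classify_fragmented(vols, th)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("mitochondrial content is a percentage invariant to label splits", {
  obj <- tibble::tibble(volume_um3 = c(3, 2))
  expect_equal(mitochondrial_content(obj, 100), 5)
  expect_equal(mitochondrial_content(obj[0, ], 100), 0)
  split_obj <- tibble::tibble(volume_um3 = c(3, 1.5, 0.5))
  expect_equal(mitochondrial_content(split_obj, 100),
               mitochondrial_content(obj, 100))
  expect_error(mitochondrial_content(obj, 0), "cell volume")
})

test_that("automatic thresholds separate a clean bimodal stack", {
  x <- array(10, c(15, 15, 15))
  x[5:10, 5:10, 5:10] <- 100
  thr <- auto_thresholds(image_stack(x, 0.1))
  expect_true(thr[["high"]] > 10 && thr[["high"]] < 100)
  expect_equal(thr[["low"]], 0.5 * thr[["high"]])
  seg <- hysteresis_segment(image_stack(x, 0.1), thr[["low"]], thr[["high"]])
  expect_equal(max(seg$labels), 1L)
})
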