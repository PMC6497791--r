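test_that("threshold_mask handles fixed thresholds and degenerate input", {
  z <- channel_image(matrix(0, 10, 10))
  expect_equal(sum(threshold_mask(z, "fixed", fixed_value = 1)), 0)
  expect_error(threshold_mask(z, "otsu"), "degenerate histogram")
  # fixed threshold at the maximum keeps only argmax pixels
  m <- matrix(1, 10, 10); m[3, 4] <- 7; m[8, 2] <- 7
  img <- channel_image(m)
  msk <- threshold_mask(img, "fixed", fixed_value = 7)
  expect_equal(which(msk), which(m == 7))
  expect_equal(attr(msk, "threshold"), 7)
})

test_that("otsu separates a two-level image and matches the brute-force oracle", {
  m <- matrix(c(rep(10, 60), rep(100, 40)), 10)
  img <- channel_image(m)
  msk <- threshold_mask(img, "otsu")
  expect_equal(which(msk), which(m == 100))
  # randomized <=256-level images against exhaustive search
  set.seed(42)
  for (i in 1:20) {
    x <- matrix(sample(0:255, 400, replace = TRUE,
                       prob = stats::runif(256)^2), 20)
    expect_equal(otsu_threshold(x), otsu_brute(x))
  }
})

test_that("otsu agrees with an independent implementation on 8-bit data", {
  set.seed(7)
  x <- matrix(c(stats::rbinom(200, 255, 0.2), stats::rbinom(200, 255, 0.7)),
              20) / 255
  ours <- otsu_threshold(x)
  ref <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256)
  # any threshold inside the inter-mode gap induces the same partition, so
  # compare the resulting foreground masks, not the raw threshold values
  expect_identical(which(x >= ours), which(x > ref))
})

test_that("detect_clusters applies 8-connectivity and the size window", {
  # two diagonally-touching pixels form one cluster under 8-connectivity
  m <- matrix(0, 10, 10); m[4, 4] <- 5; m[5, 5] <- 5
  img <- channel_image(m, pixel_size_um = 0.1)
  cl <- detect_clusters(m > 0, img)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_px, 2)
  # a 4-pixel component at 0.1 um/px has area 0.04 um^2: inside (0, 3]
  m2 <- matrix(0, 10, 10); m2[2:3, 2:3] <- 9
  img2 <- channel_image(m2, pixel_size_um = 0.1)
  cl2 <- detect_clusters(m2 > 0, img2)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$area_um2, 0.04)
  # a 4 um^2 component is excluded by the 0-3 um^2 window
  m3 <- matrix(0, 40, 40); m3[1:20, 1:20] <- 9   # 400 px = 4 um^2
  img3 <- channel_image(m3, pixel_size_um = 0.1)
  expect_equal(nrow(detect_clusters(m3 > 0, img3)), 0)
  expect_equal(nrow(detect_clusters(m3 > 0, img3,
                                    size_window_um2 = c(0, 5))), 1)
})

test_that("raising a fixed threshold never grows mask area or cluster count", {
  sc <- demo_scene(seed = 21)
  img <- sc$images$receptor
  prev_area <- Inf; prev_n <- Inf
  for (thr in c(20, 60, 120, 180)) {
    msk <- threshold_mask(img, "fixed", fixed_value = thr)
    n <- nrow(detect_clusters(msk, img, min_pixels = 1))
    expect_lte(sum(msk), prev_area)
    expect_lte(n, prev_n)
    prev_area <- sum(msk); prev_n <- n
  }
})

test_that("synaptic labeling follows marker overlap", {
  base <- matrix(0, 20, 20)
  rec <- base; rec[5:7, 5:7] <- 10; rec[12:14, 12:14] <- 10
  mar <- base; mar[5:7, 5:7] <- 10                    # overlaps first only
  rimg <- channel_image(rec); mimg <- channel_image(mar)
  rcl <- detect_clusters(rec > 0, rimg)
  mcl <- detect_clusters(mar > 0, mimg)
  out <- label_synaptic(rcl, mcl)
  expect_equal(sort(out$synaptic), c(FALSE, TRUE))
  # disjoint marker: nothing synaptic
  mar2 <- base; mar2[18:19, 1:2] <- 10
  out2 <- label_synaptic(rcl, detect_clusters(mar2 > 0, channel_image(mar2)))
  expect_false(any(out2$synaptic))
})

test_that("partition_intensity satisfies the stated formula and exact conservation", {
  # ROI total 1000, background_total 100, synaptic 400 -> extrasynaptic 500
  m <- matrix(1, 10, 100)                 # 1000 px of value 1 -> total 1000
  m[1:20] <- 20                           # one 20-px cluster, sum 400
  img <- channel_image(m, pixel_size_um = 0.1)
  cl <- detect_clusters(m > 1, img, size_window_um2 = c(0, 10))
  cl$synaptic <- TRUE
  roi <- roi_rect(0, 0, 100, 10, role = "whole_cell")
  p <- partition_intensity(img, roi, cl, background = 0.1)
  expect_equal(p$total_sum, 400 + 980)
  expect_equal(p$background_total, 100)
  expect_equal(p$synaptic_sum, 400)
  expect_equal(p$extrasynaptic_sum, p$total_sum - 100 - 400)
  expect_false(p$over_subtracted)
  # zero background and no synaptic clusters: extrasynaptic = total
  cl$synaptic <- FALSE
  p2 <- partition_intensity(img, roi, cl, background = 0)
  expect_equal(p2$extrasynaptic_sum, p2$total_sum)
})

test_that("partition conservation holds to machine precision on random scenes", {
  set.seed(99)
  for (i in 1:100) {
    sc <- make_dendrite_scene(scene_truth(
      random_puncta(sample(1:4, 1), sample(1:4, 1), seed = i),
      background = stats::runif(1, 1, 30), gaussian_sd = stats::runif(1, 0, 4),
      seed = i))
    img <- sc$images$receptor
    rcl <- segment_scene(sc)
    roi <- roi_rect(10, 10, 150, 190, role = "dendrite_segment")
    bg <- stats::runif(1, 0, 5)
    p <- partition_intensity(img, roi, rcl, background = bg)
    expect_equal(p$synaptic_sum + p$extrasynaptic_sum + p$background_total,
                 p$total_sum, tolerance = 1e-12)
  }
})

test_that("measured synaptic intensity matches planted punctum integrals", {
  # fixed-size puncta and a near-background threshold so the Gaussian tails
  # below threshold stay under a few percent of the integral
  pts <- data.frame(x_um = c(5, 10, 15), y_um = c(10, 10, 10), peak = 200,
                    sigma_um = 0.2, synaptic = TRUE)
  tr <- scene_truth(pts, background = 10, seed = 1)
  sc <- make_dendrite_scene(tr)
  img <- sc$images$receptor
  msk <- threshold_mask(img, "fixed", fixed_value = 11)
  cl <- detect_clusters(msk, img)
  cl$synaptic <- TRUE
  roi <- roi_rect(0, 0, 200, 200, role = "whole_cell")
  p <- partition_intensity(img, roi, cl, background = 10)
  planted <- sum(punctum_integral(tr))
  measured <- p$synaptic_sum - 10 * sum(cl$n_px)  # background under puncta
  expect_equal(measured, planted, tolerance = 0.05)
})

test_that("cell-level summaries average ROI values", {
  expect_equal(summarize_cell(c(10, 20, 30)), 20)
  expect_equal(summarize_cell(7), 7)
  expect_error(summarize_cell(numeric(0)), "at least one ROI")
  # uniform image: any ROI mean equals the cell mean
  img <- channel_image(matrix(5, 50, 50))
  cl <- detect_clusters(matrix(FALSE, 50, 50), img)
  vals <- vapply(list(roi_rect(0, 0, 20, 20), roi_rect(20, 20, 45, 45),
                      roi_rect(5, 30, 15, 48)), function(r) {
    idx <- synaptiq:::roi_pixel_index(r, c(50, 50))
    mean(img$pixels[idx])
  }, numeric(1))
  expect_equal(summarize_cell(vals), vals[1])
})

test_that("Grubbs test removes at most one outlier at the documented critical value", {
  res <- grubbs_remove_outlier(c(1.0, 1.1, 0.9, 5.0), alpha = 0.05)
  expect_equal(res$removed, 5.0)
  expect_equal(length(res$values), 3)
  # verify against the t-distribution formula at n = 4
  tq <- stats::qt(1 - 0.05 / 8, 2)
  expect_equal(res$G_crit, (3 / sqrt(4)) * sqrt(tq^2 / (2 + tq^2)))
  # symmetric data: nothing removed
  expect_null(grubbs_remove_outlier(c(1, 2, 3, 4, 5))$removed)
  # two extremes: still at most one removal
  res2 <- grubbs_remove_outlier(c(0, 10, 10.2, 9.9, 10.1, 25))
  expect_lte(length(res2$values), 6)
  expect_gte(length(res2$values), 5)
  expect_error(grubbs_remove_outlier(c(1, 2)), "at least 3")
})
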