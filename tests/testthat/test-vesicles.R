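test_that("surface/total ratio follows the stated formula", {
  s <- channel_image(matrix(3, 10, 10))
  t <- channel_image(matrix(6, 10, 10))
  r <- surface_total_ratio(s, t)
  expect_equal(r$ratio, 0.5)
  # all receptors on the surface: ratio 1
  r1 <- surface_total_ratio(s, s)
  expect_equal(r1$ratio, 1)
  # non-positive denominator flagged
  r2 <- surface_total_ratio(s, t, background_total = 7)
  expect_true(r2$flagged)
  expect_true(is.na(r2$ratio))
})

test_that("surface/total ratio is gain-invariant and recovers a planted fraction", {
  # planted surface fraction 0.7: total = surface / 0.7 on the puncta
  pts <- random_puncta(4, 4, seed = 3)
  tr_s <- scene_truth(pts, background = 0, seed = 3)
  pts_t <- pts; pts_t$peak <- pts$peak / 0.7
  tr_t <- scene_truth(pts_t, background = 0, seed = 3)
  s_img <- make_dendrite_scene(tr_s, list(list(name = "r",
                                               puncta = "all")))$images$r
  t_img <- make_dendrite_scene(tr_t, list(list(name = "r",
                                               puncta = "all")))$images$r
  r <- surface_total_ratio(s_img, t_img)
  expect_equal(r$ratio, 0.7, tolerance = 0.05)
  gain <- channel_image(s_img$pixels * 11, s_img$pixel_size_um)
  gain_t <- channel_image(t_img$pixels * 11, t_img$pixel_size_um)
  expect_equal(surface_total_ratio(gain, gain_t)$ratio, r$ratio)
})

test_that("detect_spots finds planted vesicles and rejects the blank image", {
  blank <- channel_image(matrix(2, 100, 100))
  expect_equal(nrow(detect_spots(blank, intensity_floor = 50)), 0)
  vp <- simulate_vesicle_pair(kinetic_truth(n_vesicles_pre = 25,
                                            n_vesicles_post = 25),
                              width_um = 40, height_um = 40,
                              gaussian_sd = 2, seed = 108)
  sp <- detect_spots(vp$pre, intensity_floor = 60)
  expect_gte(nrow(sp), 23)
  expect_lte(nrow(sp), 27)
  # detected positions match planted centres
  d <- vapply(seq_len(nrow(vp$truth_pre)), function(i)
    min(sqrt((sp$x_um - vp$truth_pre$x_um[i])^2 +
             (sp$y_um - vp$truth_pre$y_um[i])^2)), numeric(1))
  expect_lt(max(d), 0.5)
})

test_that("elongated objects fail the circularity check", {
  m <- matrix(2, 60, 60)
  m[28:33, 20:37] <- 300     # 6 x 18 px: 3:1 axis ratio
  img <- channel_image(m, pixel_size_um = 0.1)
  expect_equal(nrow(detect_spots(img, nominal_size_um = 1.0,
                                 intensity_floor = 100)), 0)
  # same area as a disc passes
  m2 <- matrix(2, 60, 60)
  m2[27:34, 27:34] <- 300
  img2 <- channel_image(m2, pixel_size_um = 0.1)
  expect_equal(nrow(detect_spots(img2, nominal_size_um = 1.0,
                                 intensity_floor = 100)), 1)
})

test_that("spot count is non-increasing in the intensity floor", {
  # floors start in the stringent-threshold regime the assay prescribes:
  # below it the above-threshold discs outgrow the diameter window and the
  # count is no longer a monotone function of the floor
  vp <- simulate_vesicle_pair(kinetic_truth(n_vesicles_pre = 8,
                                            n_vesicles_post = 8),
                              gaussian_sd = 2, min_sep_um = 4, seed = 15)
  prev <- Inf
  for (fl in c(60, 120, 250, 500)) {
    n <- nrow(detect_spots(vp$pre, intensity_floor = fl))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("new-vesicle counting matches greedily and is self-consistent", {
  mk_spots <- function(x, y) {
    df <- data.frame(id = seq_along(x), x_um = x, y_um = y,
                     diameter_um = 0.75, peak = 100, circularity = 1)
    structure(df, class = c("spot_set", class(df)))
  }
  pre <- mk_spots(c(2, 5), c(2, 5))
  post <- mk_spots(c(2, 5, 8, 11), c(2, 5, 8, 11))
  expect_equal(as.integer(count_new_vesicles(pre, post)), 2L)
  expect_equal(as.integer(count_new_vesicles(pre, pre)), 0L)
  # relabeling invariance
  post_shuffled <- post[c(3, 1, 4, 2), ]
  post_shuffled$id <- 1:4
  expect_equal(as.integer(count_new_vesicles(pre, post_shuffled)), 2L)
})

test_that("planted 5 -> 12 vesicle pairs give 7 +/- 1 new vesicles", {
  newc <- vapply(1:10, function(s) {
    vp <- simulate_vesicle_pair(kinetic_truth(n_vesicles_pre = 5,
                                              n_vesicles_post = 12),
                                gaussian_sd = 2, seed = s)
    as.integer(count_new_vesicles(detect_spots(vp$pre, intensity_floor = 60),
                                  detect_spots(vp$post, intensity_floor = 60)))
  }, integer(1))
  expect_true(all(newc >= 6 & newc <= 8))
})

test_that("lysosomal colocalization reports mask-restricted intensity and area", {
  m <- matrix(7, 50, 50)
  img <- channel_image(m, pixel_size_um = 0.1)
  mask <- matrix(FALSE, 50, 50); mask[10:19, 10:19] <- TRUE
  res <- lysosomal_colocalization(img, mask)
  expect_equal(res$coloc_mean, 7)            # uniform image: mean = v
  expect_equal(res$coloc_area_um2, 100 * 0.01)
  # empty mask: zero area, undefined mean, flagged
  res0 <- lysosomal_colocalization(img, matrix(FALSE, 50, 50))
  expect_true(res0$flagged)
  expect_equal(res0$coloc_area_um2, 0)
  expect_true(is.na(res0$coloc_mean))
})

test_that("receptor overlap area at lysosome regions matches planted overlap", {
  # 3 of 10 receptor puncta planted inside generous lysosome boxes, so the
  # planted overlap is the analytic above-threshold disc area of those 3
  pts <- random_puncta(10, 0, width_um = 30, height_um = 30,
                       band_halfwidth_um = 10, min_sep_um = 3, seed = 30)
  tr <- scene_truth(pts, width_um = 30, height_um = 30, background = 5,
                    seed = 30)
  sc <- make_dendrite_scene(tr, list(list(name = "mg", puncta = "all")))
  img <- sc$images$mg
  inside <- seq_len(3)
  mask <- matrix(FALSE, nrow(img$pixels), ncol(img$pixels))
  for (i in inside) {
    rr <- round(pts$y_um[i] / 0.1); cc <- round(pts$x_um[i] / 0.1)
    mask[pmax(1, rr - 15):pmin(nrow(mask), rr + 15),
         pmax(1, cc - 15):pmin(ncol(mask), cc + 15)] <- TRUE
  }
  thr <- 5 + 20   # 20 intensity units above background
  rec_mask <- threshold_mask(img, "fixed", fixed_value = thr)
  res <- lysosomal_colocalization(img, mask, receptor_mask = rec_mask)
  # analytic: peak * exp(-r^2 / (2 sigma^2)) + bg >= thr  =>  disc radius
  r2 <- 2 * pts$sigma_um[inside]^2 * log(pts$peak[inside] / (thr - 5))
  planted_area <- sum(pi * r2)
  expect_equal(res$coloc_area_um2, planted_area, tolerance = 0.1)
  expect_false(res$flagged)
})
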