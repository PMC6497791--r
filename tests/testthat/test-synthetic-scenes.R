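test_that("empty scene renders a uniform background in every channel", {
  tr <- scene_truth(background = 10, seed = 3)
  sc <- make_dendrite_scene(tr)
  for (img in sc$images)
    expect_true(all(img$pixels == 10))
  expect_identical(sc$truth, tr)
})

test_that("rendering is byte-identical for identical seed and parameters", {
  tr <- scene_truth(random_puncta(seed = 5), poisson_scale = 1,
                    gaussian_sd = 3, seed = 9)
  a <- make_dendrite_scene(tr)
  b <- make_dendrite_scene(tr)
  expect_identical(a$images$receptor$pixels, b$images$receptor$pixels)
  expect_identical(a$images$marker$pixels, b$images$marker$pixels)
})

test_that("scene generator rejects puncta outside the image extent", {
  p <- data.frame(x_um = 25, y_um = 5, peak = 100, sigma_um = 0.3,
                  synaptic = TRUE)
  tr <- scene_truth(p, width_um = 20, height_um = 20)
  expect_error(make_dendrite_scene(tr), "punctum 1")
})

test_that("planted synaptic puncta are recovered by marker colocalization", {
  sc <- demo_scene()
  rcl <- segment_scene(sc)
  expect_equal(nrow(rcl), 10)
  expect_equal(sum(rcl$synaptic), 5)
  # centroids within one pixel of planted centres
  px <- sc$truth$pixel_size_um
  d_px <- vapply(seq_len(nrow(sc$truth$puncta)), function(i)
    min(sqrt((rcl$centroid_x_px * px - sc$truth$puncta$x_um[i])^2 +
             (rcl$centroid_y_px * px - sc$truth$puncta$y_um[i])^2)) / px,
    numeric(1))
  expect_true(all(d_px <= 1))
})

test_that("FRAP simulator obeys the two-pool model limits and formula", {
  # no exchange: flat at pre * bleach_depth
  kin0 <- kinetic_truth(k_exchange = 0, mobile_fraction = 0.5,
                        bleach_depth = 0.2)
  tr0 <- simulate_frap(kin0, seq(0, 30, 2), pre_bleach = 100, noise_sd = 0)
  expect_true(all(tr0$series$intensity == 20))
  # full mobility: recovery approaches pre_bleach
  kin1 <- kinetic_truth(k_exchange = 0.5, mobile_fraction = 1,
                        bleach_depth = 0.2)
  expect_equal(frap_model(1e4, 100, 0.5, 1, 0.2), 100)
  # worked value: k=0.1, b=0.2, m=0.5, pre=100, t=10
  f10 <- simulate_frap(kinetic_truth(0.1, 0.5, 0.2), c(0, 10), 100,
                       0)$series$intensity[2]
  expect_equal(f10, 100 * (0.2 + 0.5 * 0.8 * (1 - exp(-1))))
  expect_equal(round(f10, 2), 45.28)
})

test_that("noiseless FRAP mean curve is monotone and bounded by pre-bleach", {
  t <- seq(0, 60, 0.5)
  for (k in c(0.01, 0.05, 0.3)) {
    f <- frap_model(t, 100, k, 0.8, 0.2)
    expect_true(all(diff(f) > 0))
    expect_true(all(f <= 100))
  }
})

test_that("FRET emission model conserves donor energy and bounds the FRET channel", {
  kin <- kinetic_truth(fret_efficiency = 0.2)
  v <- simulate_fret_pair(kin, donor_true = 100, acceptor_true = 100)
  expect_equal(unname(v["donor"]) + 100 * 0.2, 100)  # donor + transferred = total donor
  expect_equal(unname(v["donor"]), 80)
  expect_lte(unname(v["fret"]), unname(v["total"]))
  # E = 0: no transfer
  v0 <- simulate_fret_pair(kinetic_truth(fret_efficiency = 0), 100, 100)
  expect_equal(unname(v0["donor"]), 100)
  expect_equal(unname(v0["fret"]), 0)
  # acceptor bleach restores donor (25% dequench for E = 0.2)
  vb <- simulate_fret_pair(kin, 100, 100, bleached = TRUE)
  expect_equal(unname(vb["donor"]), 100)
  expect_equal(unname(vb["donor"]) / unname(v["donor"]) - 1, 0.25)
  expect_error(kinetic_truth(fret_efficiency = 1), "must be < 1")
})

test_that("spectral-count generator plants NF-V patterns and null ratios near 1", {
  # DZP-only protein: all vehicle counts zero, DZP counts positive in expectation
  tab <- simulate_spectral_counts(c(P001 = Inf), n_proteins = 30,
                                  library_sizes = 2e4, seed = 4)
  tr <- tab$sample_meta$treatment
  expect_true(all(tab$counts["P001", tr == "VEH"] == 0))
  expect_gt(sum(tab$counts["P001", tr == "DZP"]), 0)
  # null simulation: igg_background = 0, no planted effects
  tab0 <- simulate_spectral_counts(numeric(0), n_proteins = 200,
                                   igg_background = 0, dispersion = 0.1,
                                   library_sizes = 1e5, seed = 7)
  mv <- rowMeans(tab0$counts[, tr == "VEH"])
  md <- rowMeans(tab0$counts[, tr == "DZP"])
  ok <- mv > 0
  expect_equal(mean(md[ok] / mv[ok]), 1, tolerance = 0.05)
})

test_that("planted spectral-count ratios are recovered on average over seeds", {
  planted <- stats::setNames(rep(4, 20), sprintf("P%03d", 1:20))
  mean_ratio <- vapply(1:10, function(s) {
    tab <- simulate_spectral_counts(planted, n_proteins = 400,
                                    library_sizes = 1e4, dispersion = 0.3,
                                    seed = s)
    tr <- tab$sample_meta$treatment
    mv <- rowMeans(tab$counts[names(planted), tr == "VEH", drop = FALSE])
    md <- rowMeans(tab$counts[names(planted), tr == "DZP", drop = FALSE])
    mean(md[mv > 0] / mv[mv > 0])
  }, numeric(1))
  expect_gt(mean(mean_ratio), 3)
  expect_lt(mean(mean_ratio), 5)
})

test_that("per-group count means converge to planted ratios with library size", {
  planted <- stats::setNames(rep(4, 10), sprintf("P%03d", 1:10))
  err_at <- function(L) {
    e <- vapply(1:3, function(s) {
      tab <- simulate_spectral_counts(planted, n_proteins = 100,
                                      library_sizes = L, dispersion = 0.05,
                                      seed = 100 + s)
      tr <- tab$sample_meta$treatment
      mv <- rowMeans(tab$counts[names(planted), tr == "VEH", drop = FALSE])
      md <- rowMeans(tab$counts[names(planted), tr == "DZP", drop = FALSE])
      mean(abs(log(md[mv > 0] / mv[mv > 0] / 4)))
    }, numeric(1))
    mean(e)
  }
  expect_lt(err_at(1e5), err_at(1e3))
})

test_that("generator preconditions are enforced", {
  expect_error(simulate_frap(kinetic_truth(), c(2, 4, 6)), "start at 0")
  expect_error(simulate_frap(kinetic_truth(), noise_sd = -1), "noise_sd")
  bad_samples <- data.frame(sample = c("V1", "D1", "I1"),
                            treatment = c("VEH", "DZP", "IgG"),
                            animal = 1:3)
  expect_error(simulate_spectral_counts(samples = bad_samples),
               ">= 2 VEH")
})
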