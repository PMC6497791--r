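test_that("measure_synapse_fret keeps only clusters with both fluorophores", {
  base <- matrix(5, 30, 30)
  donor <- base; donor[5:8, 5:8] <- 800; donor[15:18, 15:18] <- 900
  total <- base; total[5:8, 5:8] <- 600          # second cluster: donor only
  fretm <- base; fretm[5:8, 5:8] <- 60
  dimg <- channel_image(donor, channel = "donor")
  timg <- channel_image(total, channel = "total")
  fimg <- channel_image(fretm, channel = "fret")
  cl <- detect_clusters(donor > 100, dimg, size_window_um2 = c(0, 3))
  rec <- measure_synapse_fret(dimg, fimg, timg, cl,
                              donor_mask = donor > 100,
                              total_mask = total > 100)
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "n_dropped"), 1)
  expect_equal(rec$donor_sum, sum(donor[5:8, 5:8]))
  expect_equal(rec$fret_sum / rec$total_acceptor_sum, 60 * 16 / (600 * 16))
})

test_that("synthetic FRET scene gives the expected participation ratio", {
  # E = 0.2, coupling 0.5: fret/total = 0.1 per cluster; E = 0 gives ~0
  kin <- kinetic_truth(fret_efficiency = 0.2)
  v <- simulate_fret_pair(kin, 1000, 800)
  expect_equal(unname(v["fret"] / v["total"]), 0.1)
  v0 <- simulate_fret_pair(kinetic_truth(fret_efficiency = 0), 1000, 800)
  expect_equal(unname(v0["fret"]), 0)
})

test_that("restriction criteria run in order on the designed 20-synapse cell", {
  cell <- designed_fret_cell()
  res <- apply_restriction_criteria(cell, cell_id = "designed")
  expect_false(res$rejected)
  expect_equal(unname(res$dropped),
               c(0L, 2L, 3L, 1L))
  expect_equal(nrow(res$records), 14)
  expect_true(all(res$records$synapse_id %in% 1:14))
  # 14-synapse cell rejected wholesale by criterion 1
  res14 <- apply_restriction_criteria(cell[1:14, ], cell_id = "small")
  expect_true(res14$rejected)
  expect_match(res14$reason, "14 synapses")
})

test_that("criterion boundaries follow the stated conventions", {
  cell <- designed_fret_cell()
  # donor mean exactly at the floor is kept; 499 dropped
  cell$donor_mean[1] <- 500
  res <- apply_restriction_criteria(cell)
  expect_true(1 %in% res$records$synapse_id)
  expect_false(17 %in% res$records$synapse_id)   # donor_mean 499
  # fret == total (ratio exactly 1) is dropped by the strict inequality
  expect_false(16 %in% res$records$synapse_id)
  # donor_sum exactly at the cap is kept
  rec <- data.frame(synapse_id = 1:16, donor_sum = 1000, donor_mean = 600,
                    fret_sum = 10, fret_mean = 1, total_acceptor_sum = 100)
  # x at the cap solves x = 3 * (15000 + x) / 16
  rec$donor_sum[16] <- 3 * 15000 / (16 - 3)
  res2 <- apply_restriction_criteria(rec)
  expect_true(16 %in% res2$records$synapse_id)
})

test_that("restriction criteria are idempotent and monotone in the donor floor", {
  cell <- designed_fret_cell()
  res <- apply_restriction_criteria(cell)
  res2 <- apply_restriction_criteria(res$records, min_synapses = 1)
  expect_equal(res2$records$synapse_id, res$records$synapse_id)
  expect_equal(sum(res2$dropped), 0)
  n_prev <- Inf
  for (floor in c(100, 500, 900, 1100)) {
    r <- apply_restriction_criteria(cell, donor_mean_floor = floor,
                                    min_synapses = 1)
    n <- if (r$rejected) 0 else nrow(r$records)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("fret_participation divides summed FRET by summed total acceptor", {
  rec <- data.frame(synapse_id = 1:2, donor_sum = 1, donor_mean = 1,
                    fret_sum = c(30, 20), fret_mean = 1,
                    total_acceptor_sum = c(60, 40))
  expect_equal(fret_participation(rec), 0.5)
  expect_error(fret_participation(rec[0, ]), "no surviving")
})

test_that("acceptor photobleaching recovers the transfer efficiency", {
  kin <- kinetic_truth(fret_efficiency = 0.2)
  ser <- simulate_bleach_series(kin, donor_true = 100)
  res <- acceptor_bleach_timecourse(ser, attr(ser, "bleach_index"))
  expect_equal(res$donor_dequench_pct, 25)
  expect_equal(res$fret_efficiency, 0.2)
  expect_false(res$incomplete_bleach)
  # E = 0: no dequench
  ser0 <- simulate_bleach_series(kinetic_truth(fret_efficiency = 0))
  res0 <- suppressWarnings(
    acceptor_bleach_timecourse(ser0, attr(ser0, "bleach_index")))
  expect_equal(res0$donor_dequench_pct, 0)
  expect_equal(res0$fret_efficiency, 0)
})

test_that("efficiency estimate is invariant to global intensity rescaling", {
  kin <- kinetic_truth(fret_efficiency = 0.15)
  ser <- simulate_bleach_series(kin, noise_frac = 0.02, seed = 8)
  ser2 <- ser
  ser2[c("donor", "fret", "total")] <- ser[c("donor", "fret", "total")] * 13
  r1 <- acceptor_bleach_timecourse(ser, attr(ser, "bleach_index"))
  r2 <- acceptor_bleach_timecourse(ser2, attr(ser, "bleach_index"))
  expect_equal(r1$fret_efficiency, r2$fret_efficiency)
})

test_that("incomplete acceptor bleach is flagged", {
  ser <- data.frame(donor = c(80, 80, 80, 82, 82),
                    fret = c(10, 10, 10, 8, 8))
  expect_warning(acceptor_bleach_timecourse(ser, 4), "incomplete bleach")
})

test_that("pH-quench control separates surface FRET from bleed-through", {
  expect_equal(ph_quench_control(100, 5), 0.05)
  # donor fully quenched: ratio -> 0
  kin <- kinetic_truth(fret_efficiency = 0.2)
  pq <- simulate_ph_quench(kin, noise_frac = 0.02, seed = 2)
  expect_lt(ph_quench_control(pq$hbs, pq$mes), 0.1)
  # bleed-through-only control stays near 1
  pq0 <- simulate_ph_quench(kinetic_truth(fret_efficiency = 0),
                            bleed_through = 20, noise_frac = 0.02, seed = 3)
  expect_equal(ph_quench_control(pq0$hbs, pq0$mes), 1, tolerance = 0.1)
  expect_error(ph_quench_control(numeric(0), 1), "at least one frame")
  expect_error(ph_quench_control(c(0, 0), c(1, 2)), "zero HBS")
})
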