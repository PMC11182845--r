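make_records <- function(n, vessel_id = "v01", seed = 1, length_um = 100) {
  set.seed(seed)
  data.frame(x = runif(n, 0, 40), y = runif(n, 0, 40),
             z = runif(n, 0, length_um),
             raw_intensity = rep(NA_real_, n), norm_intensity = runif(n, 0, 2),
             layer = sample(0:3, n, replace = TRUE),
             d_surface = runif(n, 0, 30),
             s_along = runif(n, 0, length_um),
             vessel_id = rep(vessel_id, n), stringsAsFactors = FALSE)
}

test_that("voxel export honors the 100 um closed boundary and shell oracle", {
  fx <- cylinder_fixture(radius = 5, length = 60, margin = 10)
  vm <- build_vessel_model("v01", fx$mask, fx$spacing)
  tau <- uniform_volume(dim(fx$mask), fx$spacing)
  cfg <- pipeline_config(shell_max_um = 8, export_max_um = 8)  # small grid, same logic
  rec <- extract_voxel_records(tau, vm, NULL, cfg)
  expect_equal(nrow(rec), sum(vm$distance_field <= 8))  # brute-force count
  expect_lte(max(rec$d_surface), 8)
  # voxels exactly at the threshold stay in (closed boundary)
  expect_true(any(rec$d_surface == 8))
  expect_true(all(rec$layer == 0L))

  # mismatched grids are rejected
  bad <- uniform_volume(dim(fx$mask) + c(1, 0, 0), fx$spacing)
  expect_error(extract_voxel_records(bad, vm, NULL, cfg), "shape mismatch")
})

test_that("voxels near two vessels are attributed to the nearer one only", {
  sp <- c(1, 1, 1)
  shape <- c(60, 24, 40)
  g1 <- generate_vessel(vessel_spec("straight", 30, 4, c(12, 12, 5)), shape, sp)
  g2 <- generate_vessel(vessel_spec("straight", 30, 4, c(46, 12, 5)), shape, sp)
  v1 <- build_vessel_model("v01", g1$mask, sp)
  v2 <- build_vessel_model("v02", g2$mask, sp)
  tau <- uniform_volume(shape, sp)
  cfg <- pipeline_config(export_max_um = 40)
  r1 <- extract_voxel_records(tau, v1, NULL, cfg, other_vessels = list(v2))
  r2 <- extract_voxel_records(tau, v2, NULL, cfg, other_vessels = list(v1))
  k1 <- paste(r1$x, r1$y, r1$z)
  k2 <- paste(r2$x, r2$y, r2$z)
  expect_length(intersect(k1, k2), 0)
  both <- sum(v1$distance_field <= 40 & v2$distance_field <= 40 &
                !v1$mask & !v2$mask)
  expect_gt(both, 0)           # the shells genuinely overlap
})

test_that("segment bins tile the vessel and average surface voxels exactly", {
  cfg <- pipeline_config()
  rec <- make_records(0)
  rec <- rbind(rec, data.frame(x = 0, y = 0, z = 0, raw_intensity = NA,
                               norm_intensity = c(1, 3, 5),
                               layer = c(2L, 2L, 3L),
                               d_surface = c(1, 2, 8),
                               s_along = c(12, 14, 15), vessel_id = "v01"))
  bins <- bin_segments(rec, 95, cfg)
  expect_equal(nrow(bins), 10L)
  expect_equal(bins$s_end[10], 95)
  expect_true(bins$short[10])
  expect_false(any(bins$short[1:9]))
  expect_equal(bins$surface_mean[2], 2)        # (1 + 3)/2; d = 8 not surface
  expect_equal(bins$layer[2], 2L)
  expect_true(is.na(bins$surface_mean[1]))

  # random records vs brute-force per-bin means
  r <- make_records(500, seed = 7)
  b <- bin_segments(r, 100, cfg)
  for (k in c(1, 4, 10)) {
    sel <- r$s_along >= (k - 1) * 10 & r$s_along < k * 10 & r$d_surface <= 3
    if (any(sel)) expect_lt(abs(b$surface_mean[k] - mean(r$norm_intensity[sel])),
                            1e-9)
  }
  # partition: every record falls in exactly one bin
  expect_equal(sum(b$n_voxels), nrow(r))
})

test_that("decile ranking partitions bins deterministically", {
  cfg <- pipeline_config()
  bins <- data.frame(vessel_id = "v01", bin_index = 1:20,
                     surface_mean = seq(0.1, 2, length.out = 20),
                     stringsAsFactors = FALSE)
  out <- assign_deciles(bins)
  expect_equal(out$decile[19:20], c(10L, 10L))
  expect_equal(out$decile[1:2], c(1L, 1L))
  expect_equal(as.vector(table(out$decile)), rep(2L, 10))

  # all-equal means: deterministic (vessel_id, bin_index) tie order
  bins$surface_mean <- 1
  out2 <- assign_deciles(bins)
  expect_equal(out2$decile, as.integer(ceiling(seq_len(20) / 2)))

  # sort-based oracle on random values
  set.seed(5)
  bins$surface_mean <- runif(20)
  out3 <- assign_deciles(bins)
  oracle <- ceiling(rank(bins$surface_mean, ties.method = "first") * 10 / 20)
  expect_equal(out3$decile, as.integer(oracle))

  expect_error(assign_deciles(bins[1:5, ]), "at least 10")
  # unrankable bins stay NA
  bins$surface_mean[3] <- NA
  out4 <- assign_deciles(bins)
  expect_true(is.na(out4$decile[3]))
})

test_that("radial profiles are zero for uniform fields and track known bumps", {
  cfg <- pipeline_config()
  r <- make_records(2000, seed = 11)
  r$norm_intensity <- 1
  bins <- assign_deciles(bin_segments(r, 100, cfg))
  prof <- radial_profile(r, bins, c(donor1 = 1), NULL, cfg)
  expect_true(all(abs(prof$per_donor$pct_change) < 1e-9))

  # field at 2x image mean below 5 um -> +100% at those steps
  r2 <- r
  r2$norm_intensity <- ifelse(r2$d_surface < 5, 2, 1)
  bins2 <- assign_deciles(bin_segments(r2, 100, cfg))
  prof2 <- radial_profile(r2, bins2, c(donor1 = 1), NULL, cfg)
  near <- prof2$per_donor[prof2$per_donor$distance_um < 5, ]
  far <- prof2$per_donor[prof2$per_donor$distance_um >= 5, ]
  expect_true(all(abs(near$pct_change - 100) < 1e-9))
  expect_true(all(abs(far$pct_change) < 1e-9))

  expect_error(radial_profile(r, bins, c(donor1 = 0), NULL, cfg), "> 0")
})

test_that("heatmap rows are log ratios padded to the longest vessel", {
  bins <- data.frame(vessel_id = rep(c("a", "b"), c(3, 5)),
                     bin_index = c(1:3, 1:5),
                     surface_mean = c(2, 20, NA, 2, 2, 2, 2, 2),
                     stringsAsFactors = FALSE)
  hm <- build_heatmap(bins, c(d1 = 2))
  expect_equal(dim(hm), c(2L, 5L))
  expect_equal(unname(hm["a", 1]), 0)
  expect_equal(unname(hm["a", 2]), 1)
  expect_true(is.na(hm["a", 3]))
  expect_equal(sum(is.na(hm["a", ])), 3L)      # one empty bin + 2 padding
})

test_that("layer summaries use the majority layer and exclude unassigned", {
  cfg <- pipeline_config()
  # bin straddling layers 2 (60%) and 3 (40%) -> layer 2
  rec <- data.frame(x = 0, y = 0, z = 0, raw_intensity = NA,
                    norm_intensity = 1,
                    layer = c(2L, 2L, 2L, 3L, 3L),
                    d_surface = 1, s_along = c(1, 2, 3, 4, 5),
                    vessel_id = "v01", stringsAsFactors = FALSE)
  bins <- bin_segments(rec, 10, cfg)
  expect_equal(bins$layer[1], 2L)

  # two donors with hand-computed per-layer means
  b <- data.frame(vessel_id = rep(c("v01", "v02"), each = 3),
                  bin_index = rep(1:3, 2),
                  surface_mean = c(1, 2, 6, 3, 5, NA),
                  layer = c(2L, 2L, 3L, 2L, 0L, 3L),
                  stringsAsFactors = FALSE)
  sm <- layer_surface_summary(b, donors = c(v01 = "dA", v02 = "dB"))
  expect_equal(sm$mean_surface_tau[sm$donor == "dA" & sm$layer == 2], 1.5)
  expect_equal(sm$mean_surface_tau[sm$donor == "dA" & sm$layer == 3], 6)
  expect_equal(sm$mean_surface_tau[sm$donor == "dB" & sm$layer == 2], 3)
  expect_false(any(sm$layer == 0))
})
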