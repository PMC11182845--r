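test_that("generated tubes honor the stated radius and analytic path length", {
  gv <- generate_vessel(vessel_spec("straight", length_um = 40, radius_um = 5,
                                    origin = c(10, 10, 5)),
                        c(21, 21, 51), c(1, 1, 1))
  idx <- arrayInd(which(as.vector(gv$mask)), dim(gv$mask))
  w <- idx - 1
  lat <- sqrt((w[, 1] - 10)^2 + (w[, 2] - 10)^2)
  inseg <- w[, 3] >= 5 & w[, 3] <= 45
  expect_true(all(lat[inseg] <= 5 + 1e-9))
  expect_equal(range(w[, 3]), c(0, 50))       # rounded caps reach +- radius

  # helix path arc length matches the closed form within 0.5%
  R <- 10; pitch <- 30; lt <- sqrt((2 * pi * R)^2 + pitch^2)
  gh <- generate_vessel(vessel_spec("helix", length_um = 2 * lt, radius_um = 3,
                                    origin = c(25, 15, 4), curve_radius_um = R,
                                    pitch_um = pitch),
                        c(36, 36, 72), c(1, 1, 1))
  seg <- diff(gh$path[, "s"])
  chord <- sqrt(rowSums((gh$path[-1, 1:3] - gh$path[-nrow(gh$path), 1:3])^2))
  expect_true(sum(gh$mask) > 0)
  expect_lt(abs(sum(chord) / (2 * lt) - 1), 0.005)
  expect_true(all(seg > 0 & seg <= 1))

  expect_error(generate_vessel(vessel_spec("straight", 10, radius_um = 500),
                               c(16, 16, 16), c(1, 1, 1)), "radius larger")
  expect_error(generate_vessel(vessel_spec("straight", 100, 3,
                                           origin = c(8, 8, 0)),
                               c(16, 16, 20), c(1, 1, 1)), "exits")
})

test_that("tau field reproduces the three intensity regimes and decay law", {
  sc <- example_scene_spec("enrichment", seed = 5)
  v <- generate_vessel(sc$vessels[[1]], sc$shape, sc$spacing)
  tau <- generate_tau_field(sc, list(v))
  comp <- attr(tau, "components")

  # deterministic given the seed
  tau2 <- generate_tau_field(sc, list(v))
  expect_identical(tau$data, tau2$data)

  # enrichment at the surface of a segment adds ~amplitude over local bg
  enr <- comp$enrichment
  d <- compute_distance_field(v$mask, sc$spacing)
  at_surface <- enr[d <= 1 & enr > 0]
  expect_lt(abs(mean(at_surface) / 90 - 1), 0.1)   # exp(-d/20) within 1 um

  # no-enrichment scene: mean near vessels matches global mean closely
  sc0 <- example_scene_spec("density", seed = 5)
  tau0 <- generate_tau_field(sc0, list(v))
  near <- mean(tau0$data[d <= 3])
  expect_lt(abs(near - mean(tau0$data)), 0.15 * mean(tau0$data))

  # exponential decay length recovered within 20% from the generated field
  sel <- which(enr > 0.5 & d > 0 & d <= 40)
  fit <- stats::lm(log(enr[sel]) ~ d[sel])
  expect_lt(abs(-1 / coef(fit)[2] / 20 - 1), 0.2)
})

test_that("object placement follows the Poisson and NFT probability models", {
  sc <- example_scene_spec("density", seed = 9)
  v <- generate_vessel(sc$vessels[[1]], sc$shape, sc$spacing)

  sc0 <- sc; sc0$neuron_rate_per_mm3 <- 0
  expect_equal(nrow(place_objects(sc0, list(v))), 0L)

  # slope 0: NFT fraction within 3 binomial SE of base_prob over ~1000 neurons
  scn <- sc
  vol_mm3 <- prod(sc$shape) * voxel_volume_mm3(sc$spacing)
  scn$neuron_rate_per_mm3 <- 1000 / vol_mm3
  obj <- place_objects(scn, list(v))
  n <- sum(obj$class == "neuron")
  k <- sum(obj$class == "nft")
  expect_gt(n, 800)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(k / n - 0.1), 3 * se)
  expect_true(all(obj$true_p == 0.1))

  # determinism
  obj2 <- place_objects(scn, list(v))
  expect_identical(obj, obj2)

  # neurons stay out of the vessel lumen
  neu <- obj[obj$class == "neuron", ]
  ij <- pmin(pmax(round(cbind(neu$x_um, neu$y_um, neu$z_um) /
                          rep(sc$spacing, each = nrow(neu))) + 1, 1),
             matrix(rep(sc$shape, each = nrow(neu)), ncol = 3))
  expect_false(any(v$mask[ij]))
})

test_that("scene bundles are complete, layered, and seed-reproducible", {
  sc <- scene_spec(shape = c(32, 32, 48), spacing = c(1, 1, 1.5),
                   vessels = list(vessel_spec("straight", 70.5, 6,
                                              c(15.5, 15.5, 0))),
                   neuron_rate_per_mm3 = 2e5, seed = 21)
  d1 <- tempfile(); d2 <- tempfile()
  sb <- generate_scene(sc, d1)
  files <- list.files(d1)
  expect_true(all(c("tau.h5", "layers.tif", "vessel_01_mask.tif",
                    "objects.csv", "truth.json", "scene_spec.json")
                  %in% files))
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_length(truth$centerlines, length(sc$vessels))

  # layer labels partition the volume into 1..6 with no unassigned voxels
  lay <- read_volume(file.path(d1, "layers.tif"))
  expect_setequal(unique(as.vector(lay$data)), 1:6)

  # identical spec + seed => bit-identical bundle
  generate_scene(sc, d2)
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e7),
                     readBin(file.path(d2, f), "raw", 2e7), label = f)
  }

  # different seed => different tau field
  d3 <- tempfile()
  sc3 <- sc; sc3$seed <- 22L
  generate_scene(sc3, d3)
  t1 <- read_volume(file.path(d1, "tau.h5"))
  t3 <- read_volume(file.path(d3, "tau.h5"))
  expect_gt(max(abs(t1$data - t3$data)), 0)
})

test_that("enriched arcs carry more surface tau than quiet arcs of the same vessel", {
  sc <- example_scene_spec("enrichment", seed = 13)
  v <- generate_vessel(sc$vessels[[1]], sc$shape, sc$spacing)
  tau <- generate_tau_field(sc, list(v))
  d <- compute_distance_field(v$mask, sc$spacing)
  f <- perivasc:::.vessel_fields(v$mask, v$path, sc$shape, sc$spacing, 10)
  surf <- d <= 3
  in_enr <- !is.na(f$s) & ((f$s >= 41 & f$s < 49) | (f$s >= 81 & f$s < 89))
  in_quiet <- !is.na(f$s) & f$s >= 10 & f$s < 35
  expect_gt(mean(tau$data[surf & in_enr]), mean(tau$data[surf & in_quiet]))
})
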