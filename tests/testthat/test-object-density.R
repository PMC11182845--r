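# simple reference flood fill (6/26) for component-count oracle
bf_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  cur <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(p, dm)
      nb <- sweep(offs, 2, as.vector(ijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
        nb[, 1] <= dm[1] & nb[, 2] <= dm[2] & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1) * dm[1] + (nb[, 3] - 1) * dm[1] * dm[2]
      new <- lin[mask[nb] & lab[lin] == 0]
      lab[new] <- cur
      queue <- c(queue, new)
    }
  }
  cur
}

test_that("threshold segmentation finds blobs at their centroids", {
  a <- array(0, c(20, 20, 20))
  a[6:10, 6:10, 6:10] <- 5
  vol <- image_volume(a, c(1, 1, 1), "neuron")
  obj <- segment_objects(vol, threshold = 1)
  expect_equal(nrow(obj), 1L)
  expect_equal(unlist(obj[1, c("x_um", "y_um", "z_um")]),
               c(x_um = 7, y_um = 7, z_um = 7))
  expect_equal(obj$class, "neuron")

  a[14:15, 14:15, 14:15] <- 5
  vol2 <- image_volume(a, c(1, 1, 1), "neuron")
  expect_equal(nrow(segment_objects(vol2, 1)), 2L)
  # min_size filters the small blob
  expect_equal(nrow(segment_objects(vol2, 1, min_size = 20)), 1L)
  expect_error(segment_objects(image_volume(a, c(1, 1, 1), "tau"), 1),
               "neuron")
})

test_that("connected-component counts match a reference flood fill", {
  for (seed in 1:4) {
    set.seed(seed)
    mask <- array(runif(8 * 8 * 8) < 0.25, c(8, 8, 8))
    got <- max(perivasc:::label3d_cpp(as.vector(mask), dim(mask), 26L))
    expect_equal(got, bf_components(mask))
  }
})

test_that("objects get nearest-vessel coordinates with a closed 30 um shell", {
  sp <- c(1, 1, 1)
  shape <- c(80, 24, 50)
  g1 <- generate_vessel(vessel_spec("straight", 40, 5, c(12, 12, 5)), shape, sp)
  g2 <- generate_vessel(vessel_spec("straight", 40, 5, c(68, 12, 5)), shape, sp)
  v1 <- build_vessel_model("v01", g1$mask, sp)
  v2 <- build_vessel_model("v02", g2$mask, sp)
  obj <- data.frame(id = c("a", "b", "c"),
                    x_um = c(12, 47, 47.5), y_um = 12, z_um = 20,
                    class = "neuron", layer = NA_integer_,
                    d_surface = NA_real_, s_along = NA_real_,
                    vessel_id = NA_character_, stringsAsFactors = FALSE)
  out <- assign_objects(obj, list(v1), pipeline_config())
  expect_equal(out$d_surface[1], 0)              # centroid on a mask voxel
  expect_equal(out$vessel_id[1], "v01")
  # "b" at exactly 30 um from the surface stays in (closed threshold)
  expect_equal(out$d_surface[2], 30)
  expect_equal(out$vessel_id[2], "v01")
  # "c" at 30.5 um: retained but unassigned
  expect_true(is.na(out$vessel_id[3]))
  expect_gt(out$d_surface[3], 30)

  # equidistant between two vessels: the lower vessel_id wins
  tie <- obj[1, ]; tie$x_um <- 40; tie$z_um <- 25
  out_tie <- assign_objects(tie, list(v2, v1), pipeline_config())
  expect_equal(out_tie$vessel_id, "v01")

  # exhaustive nearest-surface scan on random objects (away from the
  # threshold and tie boundaries, where interpolation may differ by a
  # fraction of a voxel)
  set.seed(6)
  n <- 300
  ro <- data.frame(id = sprintf("r%03d", 1:n),
                   x_um = runif(n, 0, 79), y_um = runif(n, 0, 23),
                   z_um = runif(n, 0, 49), class = "neuron",
                   layer = NA_integer_, d_surface = NA_real_,
                   s_along = NA_real_, vessel_id = NA_character_,
                   stringsAsFactors = FALSE)
  pts <- as.matrix(ro[, c("x_um", "y_um", "z_um")])
  bf_min <- function(vm) {
    w <- sweep(arrayInd(which(as.vector(vm$mask)), dim(vm$mask)) - 1, 2, sp, "*")
    apply(pts, 1, function(p)
      sqrt(min((w[, 1] - p[1])^2 + (w[, 2] - p[2])^2 + (w[, 3] - p[3])^2)))
  }
  d1 <- bf_min(v1); d2 <- bf_min(v2)
  clearcut <- abs(pmin(d1, d2) - 30) > 0.5 & abs(d1 - d2) > 0.5
  out2 <- assign_objects(ro, list(v1, v2), pipeline_config())
  want <- ifelse(pmin(d1, d2) > 30, NA_character_,
                 ifelse(d1 < d2, "v01", "v02"))
  expect_gt(sum(clearcut), 250)
  expect_identical(out2$vessel_id[clearcut], want[clearcut])
})

test_that("shell volumes match the analytic annulus and sum exactly", {
  # vessel clipped flat at the volume z-faces, wide lateral margin
  r <- 8
  mk_clipped <- function(sp) {
    lat <- 2 * ceiling((r + 32) / sp[1]) + 2
    ax <- floor(lat / 2) * sp[1]
    nz <- ceiling(66 / sp[3]) + 1
    ext_z <- (nz - 1) * sp[3]
    gv <- generate_vessel(vessel_spec("straight", ext_z, r, c(ax, ax, 0)),
                          c(lat, lat, nz), sp)
    build_vessel_model("v01", gv$mask, sp)
  }
  vm <- mk_clipped(c(1, 1, 1))
  cfg <- pipeline_config()
  sv <- compute_shell_volumes(vm, cfg)

  # total voxel count equals the brute-force shell count
  expect_equal(sum(sv$shell_voxel_count),
               sum(vm$distance_field <= 30 & !vm$mask))

  # interior bins against pi((r+30)^2 - r^2) * 10 um^3
  analytic <- pi * ((r + 30)^2 - r^2) * 10 * 1e-9
  interior <- sv$shell_volume_mm3[3:4]
  expect_true(all(abs(interior / analytic - 1) < 0.05))

  # the short trailing bin past the last full 10 um interval is truncated
  n <- nrow(sv)
  expect_lt(sv$shell_volume_mm3[n], min(interior))

  # coarser grid: same analytic volume within discretization error
  sv2 <- compute_shell_volumes(mk_clipped(c(2, 2, 2)), cfg)
  expect_true(all(abs(sv2$shell_volume_mm3[3:4] / analytic - 1) < 0.05))
})

test_that("densities divide counts by shell volume and flag NFT bearers", {
  cfg <- pipeline_config()
  shells <- data.frame(vessel_id = "v01", bin_index = 1:2,
                       shell_voxel_count = c(2e6, 2e6),
                       shell_volume_mm3 = c(0.002, 0.002),
                       stringsAsFactors = FALSE)
  mk <- function(n, cls, bin) {
    data.frame(id = sprintf("%s%02d_%d", cls, seq_len(n), bin),
               x_um = 50 * seq_len(n),
               y_um = bin * 500, z_um = 1, class = cls, layer = NA_integer_,
               d_surface = 5, s_along = (bin - 1) * 10 + 5,
               vessel_id = "v01", stringsAsFactors = FALSE)
  }
  obj <- rbind(mk(6, "neuron", 1), mk(10, "neuron", 2))
  # 3 NFTs colocated with the first three neurons of bin 2
  nft <- mk(3, "nft", 2)
  nft$x_um <- 50 * 1:3 + 2                      # within 5 um of those somata
  out <- compute_densities(rbind(obj, nft), shells, cfg)
  expect_equal(out$neuron_density_per_mm3, c(3000, 5000))
  expect_equal(out$pct_neurons_with_nft, c(0, 30))
  expect_equal(out$nft_count, c(0L, 3L))
  expect_true(all(out$neuron_count == round(out$neuron_count)))

  shells0 <- shells; shells0$shell_volume_mm3[1] <- 0
  expect_error(compute_densities(rbind(obj, nft), shells0, cfg),
               "zero shell volume")
})

test_that("NFT fractions pool counts per donor and decile", {
  dens <- data.frame(vessel_id = rep(c("v01", "v02"), each = 2),
                     bin_index = rep(1:2, 2),
                     neuron_count = c(6, 4, 5, 0),
                     neurons_with_nft = c(2, 2, 1, 0),
                     stringsAsFactors = FALSE)
  bins <- data.frame(vessel_id = rep(c("v01", "v02"), each = 2),
                     bin_index = rep(1:2, 2),
                     decile = c(10L, 10L, 3L, 4L), stringsAsFactors = FALSE)
  out <- nft_fraction_by_decile(dens, bins,
                                donors = c(v01 = "dA", v02 = "dA"))
  expect_equal(out$pct_neurons_with_nft[out$decile == 10], 40)  # 4/10
  expect_equal(out$pct_neurons_with_nft[out$decile == 3], 20)
  # decile 4 holds a bin without neurons -> missing cell
  expect_true(is.na(out$pct_neurons_with_nft[out$decile == 4]))
  expect_false(any(out$decile == 5))
})
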