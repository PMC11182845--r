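# Independent brute-force oracles and small fixture builders.

# minimum Euclidean distance (um) from every voxel centre to any mask voxel
# centre, by exhaustive scan
bf_distance_field <- function(mask, spacing) {
  dm <- dim(mask)
  wm <- sweep(arrayInd(which(as.vector(mask)), dm) - 1, 2, spacing, "*")
  wa <- sweep(arrayInd(seq_len(prod(dm)), dm) - 1, 2, spacing, "*")
  out <- numeric(prod(dm))
  for (v in seq_along(out)) {
    out[v] <- sqrt(min((wm[, 1] - wa[v, 1])^2 + (wm[, 2] - wa[v, 2])^2 +
                         (wm[, 3] - wa[v, 3])^2))
  }
  array(out, dm)
}

# exhaustive nearest-vertex arc length with ties toward the smaller s
bf_along_distance <- function(points, centerline) {
  apply(points, 1, function(p) {
    d2 <- (centerline[, 1] - p[1])^2 + (centerline[, 2] - p[2])^2 +
      (centerline[, 3] - p[3])^2
    centerline[which.min(d2), "s"]
  })
}

# random blobby masks (union of random balls), guaranteed nonempty
random_mask <- function(dm, spacing, n_balls = 3, seed = 1) {
  set.seed(seed)
  mask <- array(FALSE, dm)
  wa <- sweep(arrayInd(seq_len(prod(dm)), dm) - 1, 2, spacing, "*")
  ext <- (dm - 1) * spacing
  for (b in seq_len(n_balls)) {
    ctr <- runif(3) * ext
    r <- runif(1, 1, max(ext) / 3)
    mask <- mask | array((wa[, 1] - ctr[1])^2 + (wa[, 2] - ctr[2])^2 +
                           (wa[, 3] - ctr[3])^2 <= r^2, dm)
  }
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  mask
}

# straight z-aligned cylinder fixture with known axis
cylinder_fixture <- function(radius = 5, length = 100, spacing = c(1, 1, 1),
                             margin = 6) {
  lat <- 2 * ceiling((radius + margin) / min(spacing[1:2])) + 2
  nz <- ceiling((length + 2 * margin) / spacing[3]) + 1
  ax <- floor(lat / 2) * spacing[1]
  gv <- generate_vessel(
    vessel_spec("straight", length_um = length, radius_um = radius,
                origin = c(ax, ax, margin)),
    c(lat, lat, nz), spacing)
  list(mask = gv$mask, path = gv$path, spacing = spacing,
       axis_xy = c(ax, ax), z0 = margin, length = length, radius = radius)
}

# flat-field normalized tau volume for profile fixtures
uniform_volume <- function(dm, spacing, value = 1, channel = "tau_norm") {
  image_volume(array(value, dm), spacing, channel)
}
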