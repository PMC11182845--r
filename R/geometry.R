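#' Euclidean distance field of a vessel mask
#'
#' Distance (um) from every voxel center to the nearest mask voxel center,
#' anisotropy-aware, computed with a separable exact distance transform.
#' Voxels inside the mask are 0: tau is measured away from the vessel
#' surface, never with negative "inside" distances, so the 3 um surface
#' window covers the first 3 um of abluminal tissue plus the mask itself.
#'
#' @param mask logical 3D array (the vessel), at least one `TRUE` voxel.
#' @param spacing voxel spacing in um.
#' @return numeric 3D array of distances (um).
#' @export
compute_distance_field <- function(mask, spacing) {
  if (!any(mask)) stop("empty mask")
  d <- edt3d_cpp(as.logical(mask), dim(mask), as.numeric(spacing))
  array(d, dim(mask))
}

.moving_average <- function(m, window) {
  if (window <= 1L || nrow(m) < 3L) return(m)
  half <- window %/% 2
  out <- m
  n <- nrow(m)
  for (i in seq_len(n)) {
    w <- min(i - 1L, n - i, half)   # symmetric shrink: endpoints stay fixed
    out[i, ] <- colMeans(m[(i - w):(i + w), , drop = FALSE])
  }
  out
}

.resample_path <- function(m, step) {
  seg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 1e-9)          # drop duplicated points
  m <- m[keep, , drop = FALSE]
  cs <- cs[keep]
  if (nrow(m) < 2L) return(m)
  total <- cs[length(cs)]
  s_new <- unique(c(seq(0, total, by = step), total))
  out <- sapply(1:3, function(a) approx(cs, m[, a], xout = s_new)$y)
  matrix(out, ncol = 3)
}

.inside_mask <- function(p, mask, spacing) {
  dm <- dim(mask)
  ij <- round(p / spacing) + 1
  if (any(ij < 1) || any(ij > dm)) return(FALSE)
  mask[ij[1], ij[2], ij[3]]
}

#' Extract an arc-length parameterized centerline from a tubular mask
#'
#' The mask must be a single 26-connected tube. End regions are found by a
#' farthest-pair double sweep of geodesic (within-mask) distance; the medial
#' path interior is the sequence of centroids of geodesic-distance level
#' sets (which are near-planar cross sections away from the end caps), and
#' each medial endpoint is the voxel maximizing `g + 1.5 * depth` (geodesic
#' distance from the far end plus boundary distance), the point where the
#' medial axis meets the end cap, refined to sub-voxel position against the
#' mask boundary. The path is resampled at `step_um` steps,
#' smoothed with an end-preserving 5-point moving average, and oriented so
#' that s = 0 lies at the endpoint with the lexicographically smaller world
#' coordinates, which makes "start of the centerline" deterministic.
#'
#' @param mask logical 3D array, one connected tubular component.
#' @param spacing voxel spacing (um).
#' @param step_um resampling step, at most 1 um by default.
#' @param smooth_window moving-average window (points).
#' @return matrix with columns `x`, `y`, `z`, `s` (um); `s` strictly increasing
#'   from 0.
#' @export
extract_centerline <- function(mask, spacing, step_um = 1, smooth_window = 5) {
  if (!any(mask)) stop("empty mask: no skeleton")
  spacing <- as.numeric(spacing)
  labs <- label3d_cpp(as.logical(mask), dim(mask), 26L)
  if (max(labs) > 1L) stop("mask is disconnected (", max(labs), " components)")
  dm <- dim(mask)
  nvox <- prod(dm)

  depth <- array(edt3d_cpp(!mask, dm, spacing), dm)   # distance to background
  r_est <- max(depth)

  # farthest-pair end regions (double sweep from the deepest voxel)
  seed <- which.max(depth)
  g0 <- geodesic_cpp(as.logical(mask), dm, spacing, seed)
  a <- which.max(ifelse(is.finite(g0), g0, -1))
  ga <- geodesic_cpp(as.logical(mask), dm, spacing, a)
  b <- which.max(ifelse(is.finite(ga), ga, -1))
  gb <- geodesic_cpp(as.logical(mask), dm, spacing, b)
  total_g <- ga[b]

  idx <- which(as.vector(mask))
  ijk <- arrayInd(idx, dm)
  world <- sweep(ijk - 1, 2, spacing, "*")
  g <- ga[idx]
  dep <- as.vector(depth)[idx]

  # medial endpoints: geodesic reach plus centrality peaks where the medial
  # axis meets the end cap (past it, depth falls faster than g grows)
  i_b <- which.max(g + 1.5 * dep)
  i_a <- which.max(gb[idx] + 1.5 * dep)
  e_b <- world[i_b, ]
  e_a <- world[i_a, ]

  # interior path: geodesic level-set centroids away from the end caps (the
  # level sets of a corner source are spherical near the caps)
  h <- max(spacing)
  bin <- factor(floor(g / h), levels = sort(unique(floor(g / h))))
  cent <- rowsum(world, bin) / as.vector(table(bin))
  gmid <- (as.numeric(levels(bin)) + 0.5) * h
  trim <- 2 * r_est
  keep <- gmid > trim & gmid < total_g - trim
  if (sum(keep) < 4L) keep <- gmid > 0.75 * trim & gmid < total_g - 0.75 * trim
  if (sum(keep) < 2L) keep <- rep(TRUE, nrow(cent))
  interior <- cent[keep, , drop = FALSE]
  # sub-voxel end correction: on the medial axis, (distance to the mask exit
  # along the axis) minus (local depth) vanishes at the true endpoint, and
  # the voxelization inflations of the two terms cancel
  fix_end <- function(e, nb, de) {
    u <- e - nb
    nd <- sqrt(sum(u^2))
    if (nd < 1e-9) return(e)
    u <- u / nd
    st <- 0.25 * min(spacing)
    t <- 0
    while (t <= 3 * r_est && .inside_mask(e + (t + st) * u, mask, spacing))
      t <- t + st
    e + max(min(t - de, 1.5 * h), -1.5 * h) * u
  }
  e_a <- fix_end(e_a, interior[1, ], dep[i_a])
  e_b <- fix_end(e_b, interior[nrow(interior), ], dep[i_b])
  path <- rbind(e_a, interior, e_b)
  if (nrow(path) < 2L) stop("skeleton empty: mask too small for a centerline")
  path <- .resample_path(path, step_um)
  path <- .moving_average(path, smooth_window)
  path <- .resample_path(path, step_um)

  # deterministic orientation: s = 0 at the lexicographically smaller endpoint
  e1 <- path[1, ]
  e2 <- path[nrow(path), ]
  flip <- FALSE
  for (a in 1:3) {
    if (e1[a] < e2[a]) break
    if (e1[a] > e2[a]) { flip <- TRUE; break }
  }
  if (flip) path <- path[rev(seq_len(nrow(path))), , drop = FALSE]

  seg <- sqrt(rowSums((path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE])^2))
  out <- cbind(path, c(0, cumsum(seg)))
  colnames(out) <- c("x", "y", "z", "s")
  out
}

#' Arc-length coordinate of points relative to a centerline
#'
#' Each point gets the cumulative arc length `s` of its nearest centerline
#' vertex (Euclidean in um; anisotropy is already absorbed into the world
#' coordinates). Ties break toward the smaller `s`.
#'
#' @param points matrix of world positions (um), columns x, y, z.
#' @param centerline matrix as returned by [extract_centerline()].
#' @return numeric vector of `s` values (um).
#' @export
assign_along_distance <- function(points, centerline) {
  if (is.null(nrow(centerline)) || nrow(centerline) == 0L)
    stop("empty centerline")
  points <- matrix(as.numeric(points), ncol = 3)
  nv <- nearest_vertex_cpp(points, centerline[, 1:3, drop = FALSE])
  unname(centerline[nv$index, "s"])
}

#' Measure vessel diameter from cross-section chords
#'
#' At `n_sites` positions along the centerline (evenly spaced quartile
#' fractions of arc length, deterministic), the mask's maximal chord through
#' the site in the plane perpendicular to the local tangent is measured by
#' marching along sampled in-plane directions; the mean over sites is
#' returned, mirroring diameter measurement by averaging three line measures
#' at separate locations.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing (um).
#' @param centerline matrix from [extract_centerline()].
#' @param n_sites number of measurement sites.
#' @return diameter in um.
#' @export
measure_diameter <- function(mask, spacing, centerline, n_sites = 3) {
  if (nrow(centerline) < 3L) stop("centerline too short to measure a diameter")
  spacing <- as.numeric(spacing)
  total <- centerline[nrow(centerline), "s"]
  fr <- seq_len(n_sites) / (n_sites + 1)
  step <- 0.25 * min(spacing)
  n_dirs <- 36L
  vals <- numeric(0)
  for (f in fr) {
    i <- which.min(abs(centerline[, "s"] - f * total))
    lo <- max(1L, i - 2L)
    hi <- min(nrow(centerline), i + 2L)
    tang <- centerline[hi, 1:3] - centerline[lo, 1:3]
    nt <- sqrt(sum(tang^2))
    if (nt < 1e-9) next                       # degenerate tangent: skip site
    tang <- tang / nt
    ref <- if (abs(tang[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * tang) * tang
    u <- u / sqrt(sum(u^2))
    v <- c(tang[2] * u[3] - tang[3] * u[2],
           tang[3] * u[1] - tang[1] * u[3],
           tang[1] * u[2] - tang[2] * u[1])
    p0 <- centerline[i, 1:3]
    if (!.inside_mask(p0, mask, spacing)) next
    best <- 0
    for (th in seq(0, pi, length.out = n_dirs + 1)[-(n_dirs + 1)]) {
      d <- cos(th) * u + sin(th) * v
      reach <- function(sgn) {
        t <- 0
        while (.inside_mask(p0 + sgn * (t + step) * d, mask, spacing)) t <- t + step
        t
      }
      chord <- reach(1) + reach(-1) + step    # both end voxels half-covered
      if (chord > best) best <- chord
    }
    vals <- c(vals, best)
  }
  if (!length(vals)) stop("all diameter sites degenerate")
  mean(vals)
}

#' Build a complete vessel model from a binary mask
#'
#' Combines the distance field, the arc-length parameterized centerline, the
#' vessel length and the mean diameter into one object used by all
#' downstream stages.
#'
#' @param vessel_id identifier string.
#' @param mask logical 3D array (or an [image_volume()] with 0/1 data).
#' @param spacing voxel spacing (um); taken from the volume if omitted.
#' @param step_um centerline resampling step.
#' @return a `vessel_model` list: `vessel_id`, `mask`, `spacing`,
#'   `distance_field`, `centerline`, `length_um`, `diameter_um`.
#' @export
build_vessel_model <- function(vessel_id, mask, spacing = NULL, step_um = 1) {
  if (inherits(mask, "image_volume")) {
    spacing <- mask$spacing
    mask <- mask$data > 0
  }
  stopifnot(!is.null(spacing))
  mask <- array(as.logical(mask), dim(mask))
  df <- compute_distance_field(mask, spacing)
  cl <- extract_centerline(mask, spacing, step_um = step_um)
  structure(list(vessel_id = as.character(vessel_id), mask = mask,
                 spacing = as.numeric(spacing), distance_field = df,
                 centerline = cl,
                 length_um = cl[nrow(cl), "s"],
                 diameter_um = measure_diameter(mask, spacing, cl)),
            class = "vessel_model")
}

#' @export
print.vessel_model <- function(x, ...) {
  cat(sprintf("<vessel_model> '%s': length %.1f um, diameter %.1f um, %d mask voxels\n",
              x$vessel_id, x$length_um, x$diameter_um, sum(x$mask)))
  invisible(x)
}
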