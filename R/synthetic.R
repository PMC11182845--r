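#' Specification of one synthetic vessel
#'
#' Tubes emulate the traced vessels of interest: non-capillary vessels of
#' roughly 10-25 um diameter spanning cortical layers. Paths are straight
#' lines, circular arcs, or helices, all parameterized by arc length so the
#' true length is known in closed form.
#'
#' @param path_kind `"straight"`, `"arc"` or `"helix"`.
#' @param length_um path arc length (um).
#' @param radius_um tube radius (um).
#' @param origin path start (um, length 3).
#' @param orientation initial tangent (straight/arc) or helix axis; need not
#'   be normalized.
#' @param curve_radius_um radius of curvature (arc) or helix radius.
#' @param pitch_um axial advance per helix turn (um).
#' @return a `vessel_spec` list.
#' @export
vessel_spec <- function(path_kind = "straight", length_um = 100, radius_um = 8,
                        origin = c(0, 0, 0), orientation = c(0, 0, 1),
                        curve_radius_um = 40, pitch_um = 80) {
  stopifnot(path_kind %in% c("straight", "arc", "helix"),
            length_um > 0, radius_um > 0, curve_radius_um > 0, pitch_um > 0)
  structure(list(path_kind = path_kind, length_um = length_um,
                 radius_um = radius_um, origin = as.numeric(origin),
                 orientation = as.numeric(orientation),
                 curve_radius_um = curve_radius_um, pitch_um = pitch_um),
            class = "vessel_spec")
}

# orthonormal frame completing a unit axis
.frame <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(axis = axis, u = u, w = w)
}

.vessel_path <- function(spec, step = 0.5) {
  t <- seq(0, spec$length_um, by = step)
  if (t[length(t)] < spec$length_um) t <- c(t, spec$length_um)
  fr <- .frame(spec$orientation)
  o <- spec$origin
  p <- switch(spec$path_kind,
    straight = cbind(o[1] + t * fr$axis[1], o[2] + t * fr$axis[2],
                     o[3] + t * fr$axis[3]),
    arc = {
      R <- spec$curve_radius_um
      th <- t / R
      sweep(outer(R * sin(th), fr$axis) + outer(R * (1 - cos(th)), fr$u),
            2, o, "+")
    },
    helix = {
      R <- spec$curve_radius_um
      lt <- sqrt((2 * pi * R)^2 + spec$pitch_um^2)   # length of one turn
      phi <- t * 2 * pi / lt
      axial <- t * spec$pitch_um / lt
      sweep(outer(R * (cos(phi) - 1), fr$u) + outer(R * sin(phi), fr$w) +
              outer(axial, fr$axis), 2, o, "+")
    })
  cbind(p, s = t)
}

#' Rasterize a synthetic vessel into a binary mask
#'
#' The mask holds exactly the voxels whose center lies within `radius_um` of
#' the continuous path (evaluated against a <= 1 um polyline of the path).
#' The path must stay inside the volume; a tube radius that cannot fit in
#' the volume is an error.
#'
#' @param spec a [vessel_spec()].
#' @param shape volume dimensions (voxels).
#' @param spacing voxel spacing (um).
#' @return list with `path` (matrix x, y, z, s at <= 1 um steps) and `mask`
#'   (logical array).
#' @export
generate_vessel <- function(spec, shape, spacing) {
  extent <- (shape - 1) * spacing
  if (2 * spec$radius_um > max(extent))
    stop("radius larger than volume")
  path <- .vessel_path(spec)
  eps <- 1e-9
  for (a in 1:3) {
    if (any(path[, a] < -eps) || any(path[, a] > extent[a] + eps))
      stop("path exits volume (axis ", a, ")")
  }
  mask <- array(tube_mask_cpp(path[, 1:3, drop = FALSE], as.integer(shape),
                              as.numeric(spacing), spec$radius_um), shape)
  list(path = path, mask = mask)
}

#' Specification of a synthetic imaging scene
#'
#' Encodes the statistical structure the analysis assumes: tubular vessels,
#' three intensity regimes (background noise, low-frequency autofluorescence
#' blotches, and a tau-positive regime), surface-anchored tau enrichment
#' decaying exponentially with distance on chosen arc-length segments,
#' Poisson-placed neurons, and an NFT probability that increases linearly
#' with the local normalized surface tau (clamped to `[0, 1]`, so recovery
#' tests have a closed-form expectation).
#'
#' @param shape volume dimensions (voxels).
#' @param spacing voxel spacing (um), anisotropy allowed.
#' @param vessels list of [vessel_spec()]s.
#' @param tau_bg_mean,tau_bg_sd background regime (intensity units).
#' @param tau_auto_mean,tau_auto_sd autofluorescence regime.
#' @param tau_pos_mean tau-positive regime.
#' @param enrichment_segments per-vessel list of matrices/rows
#'   `(arc_start_um, arc_end_um, amplitude, decay_length_um)`.
#' @param neuron_rate_per_mm3 neuron placement intensity.
#' @param nft_model numeric `(base_prob, slope)`: NFT probability =
#'   `clamp(base_prob + slope * local normalized surface tau, 0, 1)`.
#' @param layer_boundaries z planes (um) splitting labels 1..6.
#' @param seed integer RNG seed; the whole bundle is a deterministic
#'   function of the spec including this seed.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(shape = c(64, 64, 96), spacing = c(1, 1, 1.5),
                       vessels = NULL, tau_bg_mean = 10, tau_bg_sd = 3,
                       tau_auto_mean = 40, tau_auto_sd = 5,
                       tau_pos_mean = 100,
                       enrichment_segments = NULL,
                       neuron_rate_per_mm3 = 30000,
                       nft_model = c(base_prob = 0.05, slope = 0.15),
                       layer_boundaries = NULL, seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  extent <- (shape - 1) * spacing
  if (is.null(vessels)) {
    vessels <- list(
      vessel_spec("straight", length_um = extent[3], radius_um = 8,
                  origin = c(extent[1] * 0.28, extent[2] * 0.28, 0)),
      vessel_spec("helix", length_um = extent[3] * 1.02, radius_um = 7,
                  origin = c(extent[1] * 0.72, extent[2] * 0.72, 0),
                  curve_radius_um = 5,
                  pitch_um = extent[3] * 0.97 * 2 * pi * 5 /
                    sqrt((extent[3] * 1.02)^2 - (extent[3] * 0.97)^2)))
  }
  if (is.null(enrichment_segments)) {
    enrichment_segments <- vector("list", length(vessels))
    enrichment_segments[[1]] <- matrix(c(40, 80, tau_pos_mean - tau_bg_mean, 10),
                                       nrow = 1,
                                       dimnames = list(NULL, c("arc_start_um",
                                         "arc_end_um", "amplitude",
                                         "decay_length_um")))
  }
  if (is.null(layer_boundaries)) layer_boundaries <- extent[3] * (1:5) / 6
  if (!(tau_bg_mean < tau_auto_mean && tau_auto_mean < tau_pos_mean))
    stop("need tau_bg_mean < tau_auto_mean < tau_pos_mean")
  for (segs in enrichment_segments) {
    if (is.null(segs)) next
    segs <- matrix(segs, ncol = 4)
    if (any(segs[, 3] < 0) || any(segs[, 4] <= 0))
      stop("enrichment amplitudes must be >= 0 and decay lengths > 0")
  }
  base_prob <- unname(nft_model[1])
  if (base_prob < 0 || base_prob > 1) stop("base_prob must be in [0, 1]")
  structure(list(shape = shape, spacing = spacing, vessels = vessels,
                 tau_bg_mean = tau_bg_mean, tau_bg_sd = tau_bg_sd,
                 tau_auto_mean = tau_auto_mean, tau_auto_sd = tau_auto_sd,
                 tau_pos_mean = tau_pos_mean,
                 enrichment_segments = enrichment_segments,
                 neuron_rate_per_mm3 = neuron_rate_per_mm3,
                 nft_model = c(base_prob = base_prob,
                               slope = unname(nft_model[2])),
                 layer_boundaries = as.numeric(layer_boundaries),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# per-vessel distance-from-surface and along-path arc length (true path),
# the latter only within `cutoff` um of the surface
.vessel_fields <- function(mask, path, shape, spacing, cutoff) {
  d <- array(edt3d_cpp(as.vector(mask), shape, spacing), shape)
  s <- array(NA_real_, shape)
  idx <- which(as.vector(d) <= cutoff)
  if (length(idx)) {
    ijk <- arrayInd(idx, shape)
    world <- sweep(ijk - 1, 2, spacing, "*")
    # thin the true path to ~1 um vertices for the nearest-vertex scan
    thin <- unique(c(seq(1, nrow(path), by = 2L), nrow(path)))
    nv <- nearest_vertex_cpp(world, path[thin, 1:3, drop = FALSE])
    s[idx] <- path[thin[nv$index], "s"]
  }
  list(d = d, s = s)
}

.segment_matrix <- function(segs) {
  if (is.null(segs) || !length(segs)) return(NULL)
  m <- matrix(unlist(segs), ncol = 4,
              byrow = is.list(segs) && !is.matrix(segs))
  if (is.matrix(segs)) m <- matrix(segs, ncol = 4)
  m
}

#' Generate the synthetic tau intensity field
#'
#' Intensity = Gaussian background noise + rectified low-frequency
#' autofluorescence blotches + per-segment surface enrichment
#' `amplitude * exp(-d_surface / decay_length)` applied to voxels whose
#' along-vessel coordinate lies in the segment, clipped at 0. Deterministic
#' given the scene seed.
#'
#' @param scene a [scene_spec()].
#' @param vessels list of `generate_vessel()` outputs matching
#'   `scene$vessels`.
#' @param fields optional precomputed `.vessel_fields` list (internal reuse).
#' @return an [image_volume()] (channel `"tau"`) with attribute
#'   `"components"` holding the texture and enrichment arrays for
#'   truth-anchored sampling.
#' @export
generate_tau_field <- function(scene, vessels, fields = NULL) {
  shape <- scene$shape
  spacing <- scene$spacing
  n <- prod(shape)
  set.seed(scene$seed + 1L)
  bg <- rnorm(n, scene$tau_bg_mean, scene$tau_bg_sd)

  # low-frequency blotches: coarse white noise, trilinearly upsampled, rectified
  cdim <- pmax(2L, ceiling(shape / 8))
  coarse <- array(rnorm(prod(cdim)), cdim)
  csp <- (shape - 1) * spacing / (cdim - 1)
  ijk <- arrayInd(seq_len(n), shape)
  world <- sweep(ijk - 1, 2, spacing, "*")
  t_up <- interp3(coarse, csp, world)
  tex <- pmax(t_up, 0) * (scene$tau_auto_mean - scene$tau_bg_mean)
  tex <- tex + rnorm(n, 0, scene$tau_auto_sd) * (t_up > 0.5)

  enr <- numeric(n)
  if (is.null(fields)) {
    cutoff <- .enrichment_cutoff(scene)
    fields <- lapply(seq_along(vessels), function(i)
      .vessel_fields(vessels[[i]]$mask, vessels[[i]]$path, shape, spacing, cutoff))
  }
  for (i in seq_along(vessels)) {
    segs <- .segment_matrix(scene$enrichment_segments[[i]])
    if (is.null(segs)) next
    d <- as.vector(fields[[i]]$d)
    s <- as.vector(fields[[i]]$s)
    for (r in seq_len(nrow(segs))) {
      inseg <- !is.na(s) & s >= segs[r, 1] & s < segs[r, 2]
      enr[inseg] <- enr[inseg] + segs[r, 3] * exp(-d[inseg] / segs[r, 4])
    }
  }
  data <- array(pmax(bg + tex + enr, 0), shape)
  vol <- image_volume(data, spacing, "tau")
  attr(vol, "components") <- list(texture = array(tex, shape),
                                  enrichment = array(enr, shape))
  vol
}

.enrichment_cutoff <- function(scene) {
  decays <- unlist(lapply(scene$enrichment_segments, function(s)
    if (is.null(s)) NULL else .segment_matrix(s)[, 4]))
  max(30, if (length(decays)) min(60, 8 * max(decays)) else 0)
}

# true normalized surface-tau score at along-path position s of vessel i:
# piecewise map of (background + summed segment amplitudes) on the canonical
# (0,1,2) scale
.true_surface_score <- function(scene, i, s) {
  segs <- .segment_matrix(scene$enrichment_segments[[i]])
  raw <- rep(scene$tau_bg_mean, length(s))
  if (!is.null(segs)) {
    for (r in seq_len(nrow(segs)))
      raw <- raw + segs[r, 3] * (s >= segs[r, 1] & s < segs[r, 2])
  }
  anch <- anchors_from_means(c(scene$tau_bg_mean, scene$tau_auto_mean,
                               scene$tau_pos_mean))
  piecewise_linear_normalize(raw, anch)
}

#' Place neurons and NFTs in a synthetic scene
#'
#' Neuron count ~ Poisson(rate x tissue volume); positions are uniform over
#' tissue (outside vessel lumina). Each neuron is flagged NFT-positive with
#' probability `clamp(base_prob + slope * score, 0, 1)`, where `score` is
#' the true normalized surface tau of the nearest vessel segment for
#' neurons within the 30 um shell and 0 elsewhere. NFT-positive neurons
#' contribute a colocated `nft` object (within 1 um of the soma).
#'
#' @param scene a [scene_spec()].
#' @param vessels list of `generate_vessel()` outputs.
#' @param fields optional precomputed vessel fields (internal reuse).
#' @param shell_max_um shell within which surface tau drives NFT risk.
#' @return data.frame of object records with ground-truth columns
#'   `true_score` and `true_p`.
#' @export
place_objects <- function(scene, vessels, fields = NULL, shell_max_um = 30) {
  shape <- scene$shape
  spacing <- scene$spacing
  set.seed(scene$seed + 2L)
  any_mask <- Reduce(`|`, lapply(vessels, `[[`, "mask"),
                     array(FALSE, shape))
  tissue <- which(!as.vector(any_mask))
  vol_mm3 <- length(tissue) * voxel_volume_mm3(spacing)
  n <- rpois(1, scene$neuron_rate_per_mm3 * vol_mm3)
  if (n == 0) {
    return(data.frame(id = character(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), class = character(0),
                      true_score = numeric(0), true_p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  pick <- sample(tissue, n, replace = TRUE)
  ijk <- arrayInd(pick, shape)
  jit <- matrix(runif(3 * n, -0.5, 0.5), ncol = 3)
  pos <- sweep((ijk - 1) + jit, 2, spacing, "*")
  pos <- pmax(pos, 0)
  pos <- pmin(pos, matrix(rep((shape - 1) * spacing, each = n), ncol = 3))
  # a jitter that crosses into a lumen falls back to the tissue voxel centre
  near <- pmin(pmax(round(sweep(pos, 2, spacing, "/")) + 1, 1),
               matrix(rep(shape, each = n), ncol = 3))
  bad <- any_mask[near]
  if (any(bad)) pos[bad, ] <- sweep(ijk[bad, , drop = FALSE] - 1, 2, spacing, "*")

  if (is.null(fields)) {
    cutoff <- max(shell_max_um, .enrichment_cutoff(scene))
    fields <- lapply(seq_along(vessels), function(i)
      .vessel_fields(vessels[[i]]$mask, vessels[[i]]$path, shape, spacing, cutoff))
  }
  dmat <- vapply(fields, function(f) f$d[ijk], numeric(n))
  dmat <- matrix(dmat, nrow = n)
  nearest <- apply(dmat, 1, which.min)
  dmin <- dmat[cbind(seq_len(n), nearest)]
  score <- numeric(n)
  for (i in seq_along(vessels)) {
    sel <- nearest == i & dmin <= shell_max_um
    if (!any(sel)) next
    s_here <- fields[[i]]$s[ijk[sel, , drop = FALSE]]
    s_here[is.na(s_here)] <- 0
    score[sel] <- .true_surface_score(scene, i, s_here)
  }
  p <- pmin(pmax(scene$nft_model["base_prob"] +
                   scene$nft_model["slope"] * score, 0), 1)
  is_nft <- rbinom(n, 1, p) == 1
  neurons <- data.frame(id = sprintf("neuron_%05d", seq_len(n)),
                        x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                        class = "neuron", true_score = score, true_p = unname(p),
                        stringsAsFactors = FALSE)
  if (any(is_nft)) {
    k <- sum(is_nft)
    off <- matrix(runif(3 * k, -0.5, 0.5), ncol = 3)
    nfts <- data.frame(id = sprintf("nft_%05d", seq_len(k)),
                       x_um = pmax(pos[is_nft, 1] + off[, 1], 0),
                       y_um = pmax(pos[is_nft, 2] + off[, 2], 0),
                       z_um = pmax(pos[is_nft, 3] + off[, 3], 0),
                       class = "nft",
                       true_score = score[is_nft], true_p = unname(p[is_nft]),
                       stringsAsFactors = FALSE)
    rbind(neurons, nfts)
  } else neurons
}

# deterministic per-category anchor sites from the ground-truth components:
# 10 voxels per category at each of three z-planes, nearest to the regime's
# target level
.anchor_sites <- function(scene, tau, vessels, fields) {
  shape <- scene$shape
  comp <- attr(tau, "components")
  zs <- unique(pmax(1L, pmin(shape[3], round(shape[3] * c(0.25, 0.5, 0.75)))))
  dall <- Reduce(pmin, lapply(fields, function(f) f$d))
  has_enr <- any(comp$enrichment > 0)
  out <- list(background = NULL, autofluorescence = NULL, positive = NULL)
  for (z in zs) {
    tex <- comp$texture[, , z]
    enr <- comp$enrichment[, , z]
    dz <- dall[, , z]
    grid <- as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2])))
    pickn <- function(score, ok, n = 10) {
      cand <- which(ok)
      cand[order(score[cand])][seq_len(min(n, length(cand)))]
    }
    bgk <- pickn(abs(tex) + abs(enr), dz > 10)
    auk <- pickn(abs(tex - (scene$tau_auto_mean - scene$tau_bg_mean)) + abs(enr),
                 dz > 10)
    add <- function(slot, k) {
      if (!length(k)) return(slot)
      rbind(slot, cbind(grid[k, , drop = FALSE], k = z))
    }
    out$background <- add(out$background, bgk)
    out$autofluorescence <- add(out$autofluorescence, auk)
    if (has_enr) {
      pok <- pickn(abs(enr - (scene$tau_pos_mean - scene$tau_bg_mean)), enr > 0)
      out$positive <- add(out$positive, pok)
    }
  }
  out
}

#' Generate a complete scene bundle on disk
#'
#' Writes the tau volume (HDF5, float), layer labels and per-vessel masks
#' (multi-page TIFF), the object table (CSV), the serialized scene spec, and
#' a ground-truth JSON (true centerlines, enrichment segments, NFT model,
#' anchor sites) for recovery tests. Identical spec + seed reproduces a
#' bit-identical bundle.
#'
#' @param spec a [scene_spec()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory scene
#'   (`tau`, `layers`, `vessels`, `fields`, `objects`, `spec`).
#' @export
generate_scene <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  shape <- spec$shape
  spacing <- spec$spacing
  vessels <- lapply(spec$vessels, generate_vessel, shape = shape,
                    spacing = spacing)
  cutoff <- .enrichment_cutoff(spec)
  fields <- lapply(seq_along(vessels), function(i)
    .vessel_fields(vessels[[i]]$mask, vessels[[i]]$path, shape, spacing, cutoff))
  tau <- generate_tau_field(spec, vessels, fields)
  objects <- place_objects(spec, vessels, fields)

  zw <- (seq_len(shape[3]) - 1) * spacing[3]
  lab_z <- findInterval(zw, spec$layer_boundaries) + 1L
  layers <- image_volume(array(rep(lab_z, each = shape[1] * shape[2]), shape),
                         spacing, "layers")

  write_volume(tau, file.path(outdir, "tau.h5"))
  write_volume(layers, file.path(outdir, "layers.tif"))
  for (i in seq_along(vessels)) {
    mv <- image_volume(array(as.integer(vessels[[i]]$mask), shape), spacing,
                       "vessel")
    write_volume(mv, file.path(outdir, sprintf("vessel_%02d_mask.tif", i)))
  }
  write.csv(objects[, c("id", "x_um", "y_um", "z_um", "class")],
            file.path(outdir, "objects.csv"), row.names = FALSE)

  truth <- list(
    spacing = spacing, shape = shape, seed = spec$seed,
    centerlines = lapply(vessels, function(v) unname(v$path)),
    enrichment_segments = lapply(spec$enrichment_segments, function(s)
      if (is.null(s)) NULL else unname(.segment_matrix(s))),
    nft_model = as.list(spec$nft_model),
    anchor_means = c(background = spec$tau_bg_mean,
                     autofluorescence = spec$tau_auto_mean,
                     positive = spec$tau_pos_mean),
    anchor_sites = lapply(.anchor_sites(spec, tau, vessels, fields),
                          function(m) if (is.null(m)) NULL else unname(m)),
    objects_truth = objects[, c("id", "class", "true_score", "true_p")],
    layer_boundaries = spec$layer_boundaries)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  sp <- unclass(spec)
  sp$vessels <- lapply(sp$vessels, unclass)
  sp$enrichment_segments <- lapply(sp$enrichment_segments, function(s)
    if (is.null(s)) NULL else unname(.segment_matrix(s)))
  jsonlite::write_json(sp, file.path(outdir, "scene_spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(tau = tau, layers = layers, vessels = vessels,
                 fields = fields, objects = objects, spec = spec))
}

#' Load a scene bundle from disk
#'
#' @param dir directory written by [generate_scene()].
#' @return list with `tau`, `layers`, `masks` (list of logical arrays),
#'   `objects`, `truth`, `spec_json`.
#' @export
read_scene <- function(dir) {
  tau <- read_volume(file.path(dir, "tau.h5"))
  layers <- read_volume(file.path(dir, "layers.tif"))
  mask_files <- sort(list.files(dir, pattern = "^vessel_[0-9]+_mask\\.tif$",
                                full.names = TRUE))
  if (!length(mask_files)) stop("no vessel masks found in ", dir)
  masks <- lapply(mask_files, function(f) {
    v <- read_volume(f)
    v$data > 0
  })
  objects <- read_object_table(file.path(dir, "objects.csv"))
  truth <- if (file.exists(file.path(dir, "truth.json")))
    jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  else NULL
  list(tau = tau, layers = layers, masks = masks, objects = objects,
       truth = truth,
       spec_json = if (file.exists(file.path(dir, "scene_spec.json")))
         jsonlite::read_json(file.path(dir, "scene_spec.json"),
                             simplifyVector = TRUE) else NULL)
}
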