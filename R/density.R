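#' Threshold-and-label object segmentation
#'
#' A plain stand-in segmenter for end-to-end runs: voxels above `threshold`
#' are grouped by 26-connectivity, components smaller than `min_size` voxels
#' are discarded as noise, and each surviving component becomes one object
#' at its mean voxel world position with the class given by the channel tag.
#'
#' @param volume an [image_volume()] (channel `"neuron"` or `"nft"`).
#' @param threshold intensity threshold (strictly above).
#' @param min_size minimum component size in voxels.
#' @param class object class; defaults to the channel tag.
#' @return data.frame of object records (columns as [read_object_table()]).
#' @export
segment_objects <- function(volume, threshold, min_size = 1,
                            class = volume$channel) {
  if (!class %in% c("neuron", "nft"))
    stop("object class must be 'neuron' or 'nft', got '", class, "'")
  mask <- volume$data > threshold
  labs <- label3d_cpp(as.vector(mask), dim(mask), 26L)
  n <- max(labs)
  if (n == 0L) {
    return(data.frame(id = character(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), class = character(0),
                      layer = integer(0), d_surface = numeric(0),
                      s_along = numeric(0), vessel_id = character(0)))
  }
  idx <- which(labs > 0)
  ijk <- arrayInd(idx, dim(mask))
  world <- sweep(ijk - 1, 2, volume$spacing, "*")
  lab <- labs[idx]
  size <- tabulate(lab, nbins = n)
  cent <- rowsum(world, lab) / size[sort(unique(lab))]
  keep <- which(size >= min_size)
  data.frame(id = sprintf("%s_%04d", class, seq_along(keep)),
             x_um = cent[keep, 1], y_um = cent[keep, 2], z_um = cent[keep, 3],
             class = class, layer = NA_integer_, d_surface = NA_real_,
             s_along = NA_real_, vessel_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Assign objects vessel-relative coordinates
#'
#' Each object's distance from a vessel surface is the trilinear lookup of
#' that vessel's distance field at the centroid; the object goes to the
#' nearest vessel (ties to the lower `vessel_id`). Objects within
#' `shell_max_um` (default 30 um, boundary included) additionally get an
#' along-vessel arc length; farther objects keep `vessel_id` unset but are
#' retained.
#'
#' @param objects object records (e.g. from [read_object_table()]).
#' @param vessels list of `vessel_model`s.
#' @param config a [pipeline_config()].
#' @param layers optional layer label [image_volume()] to fill `layer`.
#' @return object records with `d_surface`, `s_along`, `vessel_id`, `layer`.
#' @export
assign_objects <- function(objects, vessels, config = pipeline_config(),
                           layers = NULL) {
  if (!length(vessels)) stop("need at least one vessel")
  if (!nrow(objects)) return(objects)
  vessels <- vessels[order(vapply(vessels, `[[`, "", "vessel_id"))]
  pts <- as.matrix(objects[, c("x_um", "y_um", "z_um")])
  dmat <- vapply(vessels, function(v) interp3(v$distance_field, v$spacing, pts),
                 numeric(nrow(objects)))
  dmat <- matrix(dmat, nrow = nrow(objects))
  nearest <- apply(dmat, 1, which.min)         # ties -> first = lower vessel_id
  objects$d_surface <- dmat[cbind(seq_len(nrow(objects)), nearest)]
  objects$vessel_id <- NA_character_
  objects$s_along <- NA_real_
  within <- objects$d_surface <= config$shell_max_um
  for (k in seq_along(vessels)) {
    sel <- within & nearest == k
    if (!any(sel)) next
    objects$vessel_id[sel] <- vessels[[k]]$vessel_id
    objects$s_along[sel] <- assign_along_distance(pts[sel, , drop = FALSE],
                                                  vessels[[k]]$centerline)
  }
  if (!is.null(layers)) {
    ij <- sweep(pts, 2, layers$spacing, "/")
    ij <- pmin(pmax(round(ij) + 1, 1),
               matrix(rep(dim(layers$data), each = nrow(pts)), ncol = 3))
    objects$layer <- as.integer(layers$data[ij])
  }
  objects
}

#' Shell volume of each along-vessel bin
#'
#' The tissue volume available to objects in bin `k`: voxels within
#' `shell_max_um` of the vessel surface, outside the vessel mask itself
#' (objects cannot occupy the lumen), whose along-vessel coordinate falls in
#' the bin; counted voxels times voxel volume, in cubic millimeters. Voxels
#' nearer to another supplied vessel are excluded to match object
#' attribution.
#'
#' @param vessel a `vessel_model`.
#' @param config a [pipeline_config()].
#' @param other_vessels other `vessel_model`s competing for the same tissue.
#' @return data.frame with `vessel_id`, `bin_index`, `shell_voxel_count`,
#'   `shell_volume_mm3`.
#' @export
compute_shell_volumes <- function(vessel, config = pipeline_config(),
                                  other_vessels = list()) {
  d <- vessel$distance_field
  sel <- as.vector(d) <= config$shell_max_um & !as.vector(vessel$mask)
  for (ov in other_vessels) {
    sel <- sel & !as.vector(ov$mask)
    dother <- as.vector(ov$distance_field)
    nearer <- if (ov$vessel_id < vessel$vessel_id) as.vector(d) <= dother
              else as.vector(d) < dother
    sel <- sel & nearer
  }
  n_bins <- max(1L, ceiling(vessel$length_um / config$bin_length_um))
  idx <- which(sel)
  counts <- integer(n_bins)
  if (length(idx)) {
    ijk <- arrayInd(idx, dim(d))
    world <- sweep(ijk - 1, 2, vessel$spacing, "*")
    s <- assign_along_distance(world, vessel$centerline)
    b <- .bin_of(s, config$bin_length_um, n_bins)
    counts <- tabulate(b, nbins = n_bins)
  }
  data.frame(vessel_id = vessel$vessel_id, bin_index = seq_len(n_bins),
             shell_voxel_count = as.integer(counts),
             shell_volume_mm3 = counts * voxel_volume_mm3(vessel$spacing),
             stringsAsFactors = FALSE)
}

#' Per-bin neuron and NFT densities
#'
#' Counts assigned objects per (vessel, bin), divides by the bin's shell
#' volume, and computes the percent of neurons bearing an NFT, where a
#' neuron is NFT-bearing if any NFT centroid lies within
#' `coloc_radius_um` (default 5 um) of it. The percent is undefined (`NA`)
#' for bins without neurons.
#'
#' @param objects assigned object records from [assign_objects()].
#' @param shell_volumes row-bound tables from [compute_shell_volumes()].
#' @param config a [pipeline_config()].
#' @return data.frame, one row per (vessel_id, bin_index).
#' @export
compute_densities <- function(objects, shell_volumes,
                              config = pipeline_config()) {
  tab <- shell_volumes
  assigned <- objects[!is.na(objects$vessel_id), , drop = FALSE]
  neurons <- assigned[assigned$class == "neuron", , drop = FALSE]
  nfts <- objects[objects$class == "nft", , drop = FALSE]
  # NFT-bearing neurons: nearest NFT centroid within the colocalization radius
  bearing <- rep(FALSE, nrow(neurons))
  if (nrow(neurons) && nrow(nfts)) {
    nv <- nearest_vertex_cpp(as.matrix(neurons[, c("x_um", "y_um", "z_um")]),
                             as.matrix(nfts[, c("x_um", "y_um", "z_um")]))
    bearing <- nv$dist <= config$coloc_radius_um
  }
  nb <- setNames(vapply(split(tab$bin_index, tab$vessel_id), max, integer(1)),
                 unique(tab$vessel_id))
  count_by <- function(df) {
    if (!nrow(df)) return(integer(nrow(tab)))
    b <- .bin_of(df$s_along, config$bin_length_um, nb[df$vessel_id])
    key <- paste(df$vessel_id, b)
    as.integer(table(factor(key, levels = paste(tab$vessel_id, tab$bin_index))))
  }
  tab$neuron_count <- count_by(neurons)
  tab$nft_count <- count_by(assigned[assigned$class == "nft", , drop = FALSE])
  tab$neurons_with_nft <- count_by(neurons[bearing, , drop = FALSE])
  occupied <- tab$neuron_count + tab$nft_count > 0
  if (any(occupied & tab$shell_volume_mm3 <= 0))
    stop("object found in a bin with zero shell volume: inconsistent geometry")
  tab$neuron_density_per_mm3 <- ifelse(tab$shell_volume_mm3 > 0,
                                       tab$neuron_count / tab$shell_volume_mm3, NA_real_)
  tab$nft_density_per_mm3 <- ifelse(tab$shell_volume_mm3 > 0,
                                    tab$nft_count / tab$shell_volume_mm3, NA_real_)
  tab$pct_neurons_with_nft <- ifelse(tab$neuron_count > 0,
                                     100 * tab$neurons_with_nft / tab$neuron_count,
                                     NA_real_)
  tab
}

#' NFT-bearing neuron fraction per surface-tau decile
#'
#' Pools counts per donor and decile: 100 x (NFT-bearing neurons) / neurons
#' over the donor's bins in the decile, the quantity whose association with
#' surface tau the repeated-measures ANOVA tests. Donor-decile cells without
#' neurons are missing.
#'
#' @param density table from [compute_densities()].
#' @param bins decile-labeled segment bins from [assign_deciles()].
#' @param donors named character mapping vessel_id to donor; `NULL` = one
#'   donor `"donor1"`.
#' @return data.frame with `donor`, `decile`, `pct_neurons_with_nft`,
#'   `neuron_count`, `neurons_with_nft`.
#' @export
nft_fraction_by_decile <- function(density, bins, donors = NULL) {
  dec_map <- setNames(bins$decile, paste(bins$vessel_id, bins$bin_index))
  decile <- dec_map[paste(density$vessel_id, density$bin_index)]
  if (is.null(donors)) {
    vids <- unique(density$vessel_id)
    donors <- setNames(rep("donor1", length(vids)), vids)
  }
  donor <- donors[density$vessel_id]
  ok <- !is.na(decile)
  df <- data.frame(donor = donor[ok], decile = decile[ok],
                   n = density$neuron_count[ok],
                   w = density$neurons_with_nft[ok], stringsAsFactors = FALSE)
  agg <- aggregate(cbind(n, w) ~ donor + decile, df, sum)
  data.frame(donor = agg$donor, decile = agg$decile,
             pct_neurons_with_nft = ifelse(agg$n > 0, 100 * agg$w / agg$n, NA_real_),
             neuron_count = agg$n, neurons_with_nft = agg$w,
             stringsAsFactors = FALSE)[order(agg$donor, agg$decile), ]
}
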