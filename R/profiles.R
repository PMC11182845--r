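.majority <- function(x) {
  if (!length(x)) return(0L)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])   # ties -> smaller label (table order)
}

.bin_of <- function(s, bin_length, n_bins) {
  pmin(floor(s / bin_length) + 1L, n_bins)  # s == vessel length stays in last bin
}

#' Export vessel-relative voxel records
#'
#' One record per voxel within `export_max_um` (default 100 um, boundary
#' included) of the vessel surface: world position, raw and normalized
#' intensity, cortical layer, distance from the surface and arc-length
#' position along the vessel. Voxels inside other vessels' masks are
#' excluded, and a voxel closer to another vessel than to this one is
#' attributed to the nearer vessel only, so cohort tables never double-count
#' tissue.
#'
#' @param tau normalized tau [image_volume()].
#' @param vessel a `vessel_model` from [build_vessel_model()].
#' @param layers cortical-layer label [image_volume()] (integer labels,
#'   0 = unassigned) or `NULL`.
#' @param config a [pipeline_config()].
#' @param raw optional raw-intensity [image_volume()] for the audit column.
#' @param other_vessels list of other `vessel_model`s in the same grid.
#' @return data.frame of voxel records.
#' @export
extract_voxel_records <- function(tau, vessel, layers = NULL,
                                  config = pipeline_config(), raw = NULL,
                                  other_vessels = list()) {
  dm <- dim(tau$data)
  if (!identical(dm, dim(vessel$mask)))
    stop("shape mismatch between tau volume and vessel mask")
  if (!is.null(layers) && !identical(dim(layers$data), dm))
    stop("shape mismatch between tau volume and layer volume")
  d <- vessel$distance_field
  sel <- as.vector(d) <= config$export_max_um
  for (ov in other_vessels) {
    if (!identical(dim(ov$mask), dm)) stop("shape mismatch with other vessel mask")
    sel <- sel & !as.vector(ov$mask)
    dother <- as.vector(ov$distance_field)
    nearer <- if (ov$vessel_id < vessel$vessel_id) as.vector(d) <= dother
              else as.vector(d) < dother
    sel <- sel & nearer
  }
  idx <- which(sel)
  if (!length(idx)) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      raw_intensity = numeric(0), norm_intensity = numeric(0),
                      layer = integer(0), d_surface = numeric(0),
                      s_along = numeric(0), vessel_id = character(0)))
  }
  ijk <- arrayInd(idx, dm)
  world <- sweep(ijk - 1, 2, tau$spacing, "*")
  data.frame(
    x = world[, 1], y = world[, 2], z = world[, 3],
    raw_intensity = if (is.null(raw)) NA_real_ else raw$data[idx],
    norm_intensity = tau$data[idx],
    layer = if (is.null(layers)) 0L else as.integer(layers$data[idx]),
    d_surface = as.vector(d)[idx],
    s_along = assign_along_distance(world, vessel$centerline),
    vessel_id = vessel$vessel_id,
    stringsAsFactors = FALSE)
}

#' Bin voxel records into 10 um along-vessel segments
#'
#' Bins `[0,10), [10,20), ...` tile `[0, vessel length]`; a trailing bin
#' shorter than `bin_length_um` is kept and flagged `short`. `surface_mean`
#' is the mean normalized intensity of voxels within `surface_window_um`
#' (default 3 um) of the surface; bins without surface voxels have `NA`
#' surface mean and are excluded from decile ranking. Each bin also carries
#' the majority cortical layer of its surface voxels.
#'
#' @param records voxel records of one vessel from [extract_voxel_records()].
#' @param vessel_length vessel centerline length (um).
#' @param config a [pipeline_config()].
#' @return data.frame of segment bins.
#' @export
bin_segments <- function(records, vessel_length, config = pipeline_config()) {
  bl <- config$bin_length_um
  n_bins <- max(1L, ceiling(vessel_length / bl))
  if (length(unique(records$vessel_id)) > 1L)
    stop("records must come from a single vessel")
  vid <- if (nrow(records)) records$vessel_id[1] else NA_character_
  b <- .bin_of(records$s_along, bl, n_bins)
  surf <- records$d_surface <= config$surface_window_um
  out <- data.frame(vessel_id = vid, bin_index = seq_len(n_bins),
                    s_start = (seq_len(n_bins) - 1) * bl,
                    s_end = pmin(seq_len(n_bins) * bl, vessel_length),
                    stringsAsFactors = FALSE)
  out$short <- (out$s_end - out$s_start) < bl
  out$n_voxels <- as.integer(tabulate(b, nbins = n_bins))
  out$surface_voxel_count <- as.integer(tabulate(b[surf], nbins = n_bins))
  sums <- rep(0, n_bins)
  if (any(surf)) {
    agg <- rowsum(records$norm_intensity[surf], b[surf])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  out$surface_mean <- ifelse(out$surface_voxel_count > 0,
                             sums / out$surface_voxel_count, NA_real_)
  out$layer <- vapply(seq_len(n_bins), function(k) {
    .majority(records$layer[surf & b == k & records$layer > 0])
  }, integer(1))
  out
}

#' Rank segment bins into surface-tau percentile groups
#'
#' Bins from the pooled scope (by default all vessels and donors of a group,
#' since cross-donor comparisons rank segments on one common scale) are
#' ordered by `surface_mean` with deterministic ties broken by
#' `(vessel_id, bin_index)`, then split into `n_percentile_groups` groups of
#' near-equal size; group `n` (decile 10 by default) holds the highest
#' surface tau. Bins with no surface voxels stay `NA`.
#'
#' @param bins row-bound segment bins from one or many vessels.
#' @param n_groups number of percentile groups (defaults to deciles).
#' @return `bins` with a `decile` column.
#' @export
assign_deciles <- function(bins, n_groups = 10) {
  rankable <- which(!is.na(bins$surface_mean))
  if (length(rankable) < n_groups)
    stop("need at least ", n_groups, " rankable bins, got ", length(rankable))
  ord <- rankable[order(bins$surface_mean[rankable], bins$vessel_id[rankable],
                        bins$bin_index[rankable])]
  rk <- seq_along(ord)
  dec <- ceiling(rk * n_groups / length(ord))
  bins$decile <- NA_integer_
  bins$decile[ord] <- as.integer(dec)
  bins
}

#' Radial tau profiles by surface-tau decile
#'
#' Voxel records inherit the decile of their along-vessel bin; for each
#' distance step from the vessel surface the percent change of mean
#' normalized tau relative to the donor's whole-image mean is computed, so 0%
#' means vascular tau is no different from the average tau of the image.
#' Per-donor curves are returned together with the across-donor mean and
#' SEM.
#'
#' @param records row-bound voxel records (possibly many vessels/donors).
#' @param bins decile-labeled segment bins from [assign_deciles()].
#' @param image_means named numeric: per-donor whole-image mean normalized
#'   intensity (must be > 0).
#' @param donors named character: donor of each vessel_id; `NULL` = one donor.
#' @param config a [pipeline_config()].
#' @return list with `per_donor` and `summary` data.frames.
#' @export
radial_profile <- function(records, bins, image_means, donors = NULL,
                           config = pipeline_config()) {
  if (any(image_means <= 0)) stop("image means must be > 0")
  if (is.null(donors)) {
    donors <- setNames(rep(names(image_means)[1], length(unique(records$vessel_id))),
                       unique(records$vessel_id))
  }
  bl <- config$bin_length_um
  nb <- vapply(split(bins$bin_index, bins$vessel_id), max, integer(1))
  rec_bin <- .bin_of(records$s_along, bl, nb[records$vessel_id])
  key <- paste(records$vessel_id, rec_bin)
  dec_map <- setNames(bins$decile, paste(bins$vessel_id, bins$bin_index))
  decile <- dec_map[key]
  donor <- donors[records$vessel_id]
  step <- config$profile_step_um
  dstep <- floor(records$d_surface / step) * step
  ok <- !is.na(decile)
  df <- data.frame(donor = donor[ok], decile = decile[ok],
                   distance_um = dstep[ok],
                   v = records$norm_intensity[ok], stringsAsFactors = FALSE)
  per <- aggregate(v ~ donor + decile + distance_um, df, mean)
  per$pct_change <- (per$v / image_means[per$donor] - 1) * 100
  per$v <- NULL
  smry <- aggregate(pct_change ~ decile + distance_um, per,
                    function(x) c(mean = mean(x),
                                  sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
                                  n = length(x)))
  smry <- cbind(smry[c("decile", "distance_um")], as.data.frame(smry$pct_change))
  list(per_donor = per[order(per$donor, per$decile, per$distance_um), ],
       summary = smry[order(smry$decile, smry$distance_um), ])
}

#' Per-vessel heatmap of log-normalized surface tau
#'
#' One row per vessel, one column per 10 um bin, value
#' `log10(surface_mean / donor whole-image mean)`; bins without surface
#' voxels are `NA`, and rows are right-padded with `NA` to the longest
#' vessel.
#'
#' @param bins segment bins (many vessels).
#' @param image_means per-donor whole-image means (> 0), named.
#' @param donors named character mapping vessel_id to donor; `NULL` = all
#'   vessels belong to the first donor in `image_means`.
#' @return numeric matrix, rownames = vessel ids.
#' @export
build_heatmap <- function(bins, image_means, donors = NULL) {
  if (any(image_means <= 0)) stop("image means must be > 0")
  vids <- unique(bins$vessel_id)
  if (is.null(donors)) donors <- setNames(rep(names(image_means)[1], length(vids)), vids)
  ncol_max <- max(bins$bin_index)
  m <- matrix(NA_real_, nrow = length(vids), ncol = ncol_max,
              dimnames = list(vids, NULL))
  im <- image_means[donors[bins$vessel_id]]
  ratio <- bins$surface_mean / im
  val <- ifelse(!is.na(ratio) & ratio > 0, log10(pmax(ratio, 1e-300)), NA_real_)
  m[cbind(match(bins$vessel_id, vids), bins$bin_index)] <- val
  m
}

#' Per-donor, per-layer mean surface tau
#'
#' Each bin contributes its `surface_mean` to its majority cortical layer
#' (layer 0, unassigned, is excluded); means are reported per donor and
#' layer, mirroring layer-resolved summaries of vessel-surface tau.
#'
#' @param bins segment bins with `layer` column (from [bin_segments()]).
#' @param donors named character mapping vessel_id to donor; `NULL` = one
#'   donor `"donor1"`.
#' @return data.frame with `donor`, `layer`, `mean_surface_tau`, `n_bins`.
#' @export
layer_surface_summary <- function(bins, donors = NULL) {
  if (is.null(donors)) {
    vids <- unique(bins$vessel_id)
    donors <- setNames(rep("donor1", length(vids)), vids)
  }
  ok <- bins$layer > 0 & !is.na(bins$surface_mean)
  df <- data.frame(donor = donors[bins$vessel_id[ok]], layer = bins$layer[ok],
                   v = bins$surface_mean[ok], stringsAsFactors = FALSE)
  if (!nrow(df)) {
    return(data.frame(donor = character(0), layer = integer(0),
                      mean_surface_tau = numeric(0), n_bins = integer(0)))
  }
  out <- aggregate(v ~ donor + layer, df, function(x) c(mean(x), length(x)))
  res <- data.frame(donor = out$donor, layer = out$layer,
                    mean_surface_tau = out$v[, 1], n_bins = as.integer(out$v[, 2]),
                    stringsAsFactors = FALSE)
  res[order(res$donor, res$layer), ]
}
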