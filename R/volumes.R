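#' 3D image volume with voxel spacing
#'
#' The basic substrate of the pipeline: a 3D scalar grid plus per-axis voxel
#' edge lengths in micrometers and a channel tag. Axis order is (x, y, z);
#' the world position of voxel `(i, j, k)` (1-based R indices) is
#' `((i-1)*sx, (j-1)*sy, (k-1)*sz)` um, so all distances derived from a
#' volume are anisotropy-aware.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel edge lengths in um (x, y, z); all > 0.
#' @param channel tag string, e.g. `"tau"`, `"vessel"`, `"neuron"`, `"layers"`.
#' @return An `image_volume` object (list with `data`, `spacing`, `channel`).
#' @export
image_volume <- function(data, spacing, channel = "") {
  if (length(dim(data)) != 3L) stop("volume data must have 3 axes")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (um)")
  if (identical(channel, "layers")) {
    v <- as.vector(data)
    if (any(v < 0) || any(v != round(v)))
      stop("layer volumes must contain only non-negative integers")
  }
  structure(list(data = data, spacing = spacing, channel = as.character(channel)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> channel '%s', %s voxels, spacing (%s) um\n",
              x$channel, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

#' Voxel volume in cubic millimeters
#' @param spacing voxel spacing in um.
#' @return scalar, um^3 converted to mm^3.
#' @export
voxel_volume_mm3 <- function(spacing) prod(spacing) * 1e-9

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Read a 3D volume from multi-page TIFF or HDF5
#'
#' Multi-page TIFF stores unsigned integer data (as acquired images do); HDF5
#' stores any numeric data under dataset `data` with `spacing` and `channel`
#' datasets. TIFF spacing comes from a JSON sidecar (`<path>.json` with a
#' `spacing` field) or the `spacing` argument; a volume with no spacing from
#' any source is an error, never a guess.
#'
#' @param path file path ending in `.tif`/`.tiff` or `.h5`/`.hdf5`.
#' @param channel channel tag to attach; for HDF5 defaults to the stored tag.
#' @param spacing optional numeric length-3 override (um).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, channel = NULL, spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(dim(pages[[1]])) != 2L) stop("TIFF pages must be 2-D")
    data <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) data[, , k] <- pages[[k]]
    sc <- read_sidecar(path)
    if (is.null(spacing)) spacing <- sc$spacing
    if (is.null(channel)) channel <- if (!is.null(sc$channel)) sc$channel else ""
    if (is.null(spacing)) stop("spacing unknown for ", path,
                               " (no sidecar, no spacing argument)")
    image_volume(data, spacing, channel)
  } else if (ext %in% c("h5", "hdf5")) {
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    data <- rhdf5::h5read(path, "data")
    if (length(dim(data)) != 3L) stop("HDF5 dataset 'data' is not 3-D")
    stored <- rhdf5::h5ls(path)$name
    if (is.null(spacing)) {
      if ("spacing" %in% stored) spacing <- as.numeric(rhdf5::h5read(path, "spacing"))
      else spacing <- read_sidecar(path)$spacing
    }
    if (is.null(channel)) {
      channel <- if ("channel" %in% stored) as.character(rhdf5::h5read(path, "channel")) else ""
    }
    if (is.null(spacing)) stop("spacing unknown for ", path)
    image_volume(data, spacing, channel)
  } else stop("unsupported volume format: .", ext)
}

#' Write a 3D volume to multi-page TIFF or HDF5
#'
#' TIFF output is unsigned 8- or 16-bit integer (an error if the data are not
#' non-negative integers within 16-bit range) with spacing and channel in a
#' JSON sidecar; HDF5 output stores the data at full double precision.
#' Either way, `read_volume()` recovers shape, spacing and values exactly.
#'
#' @param vol an [image_volume()].
#' @param path destination ending in `.tif`/`.tiff` or `.h5`/`.hdf5`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- vol$data
    if (any(v < 0) || any(v != round(v)) || max(v) > 65535)
      stop("TIFF volumes must hold integers in [0, 65535]; use HDF5 for float data")
    bits <- if (max(v) > 255) 16L else 8L
    pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / (2^bits - 1))
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
    jsonlite::write_json(list(spacing = vol$spacing, channel = vol$channel),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("h5", "hdf5")) {
    if (file.exists(path)) unlink(path)
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    rhdf5::h5createFile(path)
    rhdf5::h5write(vol$data, path, "data")
    rhdf5::h5write(vol$spacing, path, "spacing")
    rhdf5::h5write(vol$channel, path, "channel")
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

#' Read a segmented-object table
#'
#' CSV with columns `id`, `x_um`, `y_um`, `z_um`, `class` (one of `neuron`,
#' `nft`), as exported by object segmentation. Vessel-relative fields
#' (`d_surface`, `s_along`, `vessel_id`) are added later by
#' [assign_objects()] and come back `NA` here.
#'
#' @param path CSV path.
#' @return data.frame of object records (0 rows for a header-only CSV).
#' @export
read_object_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x_um", "y_um", "z_um", "class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("object table missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!df$class %in% c("neuron", "nft"))
  if (length(bad))
    stop(sprintf("unknown object class '%s' in row %d of %s",
                 df$class[bad[1]], bad[1], path))
  if (!"layer" %in% names(df)) df$layer <- rep(NA_integer_, nrow(df))
  df$d_surface <- rep(NA_real_, nrow(df))
  df$s_along <- rep(NA_real_, nrow(df))
  df$vessel_id <- rep(NA_character_, nrow(df))
  df[, c(need, "layer", "d_surface", "s_along", "vessel_id")]
}

#' Trilinear interpolation of a volume at world positions
#'
#' @param field 3D array on the volume grid.
#' @param spacing voxel spacing (um).
#' @param pts matrix of world positions (um), columns x, y, z.
#' @return numeric vector of interpolated values (edge-clamped).
#' @export
interp3 <- function(field, spacing, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  dm <- dim(field)
  # continuous index coordinates (0-based)
  u <- sweep(pts, 2, spacing, "/")
  for (a in 1:3) u[, a] <- pmin(pmax(u[, a], 0), dm[a] - 1)
  i0 <- pmin(floor(u), matrix(rep(dm - 2, each = nrow(u)), ncol = 3))
  i0 <- pmax(i0, 0)
  fr <- u - i0
  idx <- function(dx, dy, dz) {
    cbind(pmin(i0[, 1] + dx + 1, dm[1]), pmin(i0[, 2] + dy + 1, dm[2]),
          pmin(i0[, 3] + dz + 1, dm[3]))
  }
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    out <- out + w * field[idx(dx, dy, dz)]
  }
  out
}
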