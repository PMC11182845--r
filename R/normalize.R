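#' Collect intensity anchors for cross-sample normalization
#'
#' Raw intensities are sampled per category (background, autofluorescence,
#' positive) at three image depths, by convention 10 measurements per depth;
#' the per-category grand means anchor the piecewise-linear map. Anchor means
#' must be strictly increasing.
#'
#' @param volume an [image_volume()] of raw tau intensity.
#' @param sites named list with elements `background`, `autofluorescence`,
#'   `positive`; each a matrix of 1-based voxel indices (columns i, j, k),
#'   covering three distinct z-planes.
#' @param targets canonical output values for the three anchors.
#' @return a `normalization_anchors` list: `raw` (per-category values),
#'   `means`, `targets`.
#' @export
collect_anchors <- function(volume, sites,
                            targets = c(background = 0, autofluorescence = 1,
                                        positive = 2)) {
  cats <- c("background", "autofluorescence", "positive")
  if (!all(cats %in% names(sites))) stop("sites must name ", paste(cats, collapse = ", "))
  raw <- lapply(sites[cats], function(m) {
    m <- matrix(as.integer(m), ncol = 3)
    if (nrow(m) < 1L) stop("each category needs at least one site per depth")
    volume$data[m]
  })
  means <- vapply(raw, mean, numeric(1))
  if (any(diff(means) <= 0))
    stop("anchor order violated: need background < autofluorescence < positive, got (",
         paste(format(means), collapse = ", "), ")")
  structure(list(raw = raw, means = means, targets = as.numeric(targets)),
            class = "normalization_anchors")
}

#' Build anchors directly from known category means
#'
#' Convenience constructor for synthetic use, where the three intensity
#' regimes are known by construction rather than sampled by an operator.
#'
#' @param means numeric length-3, strictly increasing
#'   (background, autofluorescence, positive).
#' @param targets canonical outputs for the anchors.
#' @return a `normalization_anchors`.
#' @export
anchors_from_means <- function(means, targets = c(0, 1, 2)) {
  means <- as.numeric(means)
  if (length(means) != 3L || any(diff(means) <= 0))
    stop("anchor order violated: need 3 strictly increasing means")
  structure(list(raw = as.list(means), means = means, targets = as.numeric(targets)),
            class = "normalization_anchors")
}

#' Piecewise-linear intensity normalization
#'
#' Maps raw intensity onto the canonical scale anchored at
#' (background, autofluorescence, positive) -> (0, 1, 2): linear within each
#' anchor segment and linear extrapolation beyond the end anchors with the
#' adjacent segment's slope, so the map is strictly monotone on the whole
#' real line and extreme tangle intensities keep their ordering.
#'
#' @param intensity numeric vector, array, or [image_volume()] of raw values.
#' @param anchors a `normalization_anchors`.
#' @return normalized values with the shape of the input (volumes come back
#'   as volumes with channel suffix `"_norm"`).
#' @export
piecewise_linear_normalize <- function(intensity, anchors) {
  stopifnot(inherits(anchors, "normalization_anchors"))
  m <- anchors$means
  tg <- anchors$targets
  apply_map <- function(x) {
    out <- numeric(length(x))
    slope1 <- (tg[2] - tg[1]) / (m[2] - m[1])
    slope2 <- (tg[3] - tg[2]) / (m[3] - m[2])
    lo <- x < m[2]
    out[lo] <- tg[1] + (x[lo] - m[1]) * slope1
    out[!lo] <- tg[2] + (x[!lo] - m[2]) * slope2
    out
  }
  if (inherits(intensity, "image_volume")) {
    v <- intensity
    v$data <- array(apply_map(as.vector(v$data)), dim(v$data))
    v$channel <- paste0(v$channel, "_norm")
    v
  } else if (is.array(intensity)) {
    array(apply_map(as.vector(intensity)), dim(intensity))
  } else {
    apply_map(as.numeric(intensity))
  }
}

#' Rescale summaries to a reference set
#'
#' Divides values by the mean of a reference subset (control samples, or a
#' whole-image mean), optionally as percent change, the convention used both
#' for control-normalized intensities and for radial profiles where 0%
#' change means "no different from the whole-image average".
#'
#' @param values numeric vector (optionally named).
#' @param reference_ids indices or names of the reference subset; or leave
#'   `NULL` and give `reference_mean` directly.
#' @param reference_mean explicit reference mean (overrides `reference_ids`).
#' @param percent_change if `TRUE`, return `(value/reference - 1) * 100`.
#' @return rescaled numeric vector.
#' @export
normalize_to_reference <- function(values, reference_ids = NULL,
                                   reference_mean = NULL,
                                   percent_change = FALSE) {
  if (is.null(reference_mean)) {
    if (is.null(reference_ids) || length(reference_ids) == 0L)
      stop("reference set is empty")
    reference_mean <- mean(values[reference_ids])
  }
  if (!is.finite(reference_mean) || reference_mean == 0)
    stop("reference mean is zero")
  if (percent_change) (values / reference_mean - 1) * 100
  else values / reference_mean
}
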