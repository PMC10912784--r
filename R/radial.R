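# Radial analysis of circular micropatterned colonies: concentric ring masks
# measured inward from the pattern edge, per-ring mock-normalized MFI, and
# the edge-versus-center split.

#' Build concentric ring masks for a circular pattern
#'
#' Rings are indexed from the pattern edge inward: ring 1 spans
#' \[0, ring_width) µm from the edge, ring 2 \[ring_width, 2 ring_width), and
#' so on; ring index 0 is the central disk holding the remainder. The number
#' of complete rings is chosen so that the central region is at least one
#' ring width wide: a 100 µm-radius pattern with 14 µm rings yields 6
#' complete rings plus a 16 µm center disk. A ring width larger than the
#' radius returns a single center region with a warning.
#'
#' @param pattern_radius_um Pattern radius R (µm, > 0).
#' @param ring_width_um Ring width (µm, > 0), default 14.
#' @return Data frame with one row per region: `ring_index` (1 = outermost,
#'   0 = center), `edge_dist_inner`/`edge_dist_outer` (µm from the pattern
#'   edge), `r_inner`/`r_outer` (radii), `area_um2`. Areas sum exactly to the
#'   disk area.
#' @examples
#' build_ring_masks(100, 14)
#' @export
build_ring_masks <- function(pattern_radius_um, ring_width_um = 14) {
  .check_number(pattern_radius_um, "pattern_radius_um", lower = 0,
                allow_equal_lower = FALSE)
  .check_number(ring_width_um, "ring_width_um", lower = 0,
                allow_equal_lower = FALSE)
  R <- pattern_radius_um; w <- ring_width_um
  if (w > R) {
    warning("ring width ", w, " um exceeds the pattern radius ", R,
            " um; returning a single center region", call. = FALSE)
    n_rings <- 0L
  } else {
    n_rings <- as.integer(floor(R / w))
    # keep the central disk at least one ring width wide
    if (R - n_rings * w < w) n_rings <- n_rings - 1L
    n_rings <- max(n_rings, 0L)
  }
  idx <- if (n_rings > 0L) c(seq_len(n_rings), 0L) else 0L
  inner_edge <- c(w * (seq_len(n_rings) - 1L), n_rings * w)
  outer_edge <- c(w * seq_len(n_rings), R)
  if (n_rings == 0L) { inner_edge <- 0; outer_edge <- R }
  out <- data.frame(ring_index = idx,
                    edge_dist_inner = inner_edge,
                    edge_dist_outer = outer_edge,
                    r_inner = R - outer_edge,
                    r_outer = R - inner_edge)
  out$area_um2 <- pi * (out$r_outer^2 - out$r_inner^2)
  out
}

# Map radial distances to ring indices per the ring table; distances beyond R
# are clipped into the outermost ring (flagged by the caller).
.assign_ring <- function(r, rings) {
  R <- max(rings$r_outer)
  edge_dist <- pmax(R - r, 0)
  idx <- rep(rings$ring_index[nrow(rings)], length(r))
  for (k in seq_len(nrow(rings))) {
    sel <- edge_dist >= rings$edge_dist_inner[k] &
      (edge_dist < rings$edge_dist_outer[k] |
         (k == nrow(rings) & edge_dist <= rings$edge_dist_outer[k]))
    idx[sel] <- rings$ring_index[k]
  }
  idx
}

.pattern_center <- function(cells, center) {
  if (!is.null(center)) return(center)
  c(mean(cells$x_um), mean(cells$y_um))
}

# Per-ring MFI for one pattern, cell-centroid mode.
.ring_mfi_cells <- function(cells, rings, center, channel) {
  r <- sqrt((cells$x_um - center[1])^2 + (cells$y_um - center[2])^2)
  R <- max(rings$r_outer)
  n_out <- sum(r > R + 1e-9)
  if (n_out)
    warning(n_out, " cell(s) outside the pattern disk assigned to the edge ring",
            call. = FALSE)
  ring <- .assign_ring(r, rings)
  f <- factor(ring, levels = rings$ring_index)
  data.frame(ring_index = rings$ring_index,
             n = as.integer(table(f)),
             mfi = as.numeric(tapply(cells[[channel]], f, mean)))
}

# Per-ring mean for an intensity image (pixel mode); pixels are restricted to
# the pattern disk.
.ring_mfi_image <- function(image, rings, center_px, pixel_size_um) {
  ny <- nrow(image); nx <- ncol(image)
  px <- (col(image) - 0.5) * pixel_size_um
  py <- (row(image) - 0.5) * pixel_size_um
  r <- sqrt((px - center_px[1])^2 + (py - center_px[2])^2)
  R <- max(rings$r_outer)
  inside <- r <= R
  ring <- .assign_ring(r[inside], rings)
  f <- factor(ring, levels = rings$ring_index)
  data.frame(ring_index = rings$ring_index,
             n = as.integer(table(f)),
             mfi = as.numeric(tapply(image[inside], f, mean)))
}

#' Radial intensity profile of micropatterned populations
#'
#' Computes the mean fluorescence intensity (MFI) per concentric ring for
#' each pattern, and normalizes each ring to the MFI of the corresponding
#' ring in the matched mock-treated pattern(s) (mock profiles are averaged
#' per ring when several mock patterns are supplied). Cell-centroid mode is
#' primary: a cell belongs to the ring containing its centroid. Pass a
#' numeric matrix instead of a cell table for pixel mode.
#'
#' @param cells Cell data frame with `x_um`, `y_um`, the intensity channel
#'   and optionally `pattern_id` (single pattern assumed otherwise); or a
#'   numeric matrix (pixel mode, needs `pixel_size_um`).
#' @param rings Ring table from [build_ring_masks()].
#' @param mock_reference Mock cells in the same format (or a precomputed ring
#'   profile with columns `ring_index`, `mfi`); `NULL` skips normalization.
#' @param channel Intensity column (default `"reporter"`).
#' @param center Pattern center `c(x, y)` in µm; default mean of centroids
#'   per pattern (pixel mode: disk center of the image).
#' @param pixel_size_um Pixel size for pixel mode.
#' @return Data frame: `pattern_id`, `ring_index`, ring bounds, `n`
#'   (cells or pixels), `mfi`, `normalized_mfi` (NA where a ring is empty,
#'   flagged by `empty`).
#' @export
radial_profile <- function(cells, rings, mock_reference = NULL,
                           channel = "reporter", center = NULL,
                           pixel_size_um = NULL) {
  one_profile <- function(obj, center) {
    if (is.matrix(obj)) {
      if (is.null(pixel_size_um))
        stop("pixel mode needs 'pixel_size_um'", call. = FALSE)
      if (is.null(center))
        center <- c(ncol(obj) / 2 * pixel_size_um, nrow(obj) / 2 * pixel_size_um)
      .ring_mfi_image(obj, rings, center, pixel_size_um)
    } else {
      .ring_mfi_cells(obj, rings, .pattern_center(obj, center), channel)
    }
  }
  split_patterns <- function(obj) {
    if (is.matrix(obj) || !"pattern_id" %in% names(obj)) return(list(`1` = obj))
    split(obj, obj$pattern_id)
  }
  mock_profile <- NULL
  if (!is.null(mock_reference)) {
    if (is.data.frame(mock_reference) && "mfi" %in% names(mock_reference) &&
        "ring_index" %in% names(mock_reference) &&
        !"x_um" %in% names(mock_reference)) {
      mock_profile <- stats::aggregate(mfi ~ ring_index, mock_reference, mean)
    } else {
      mocks <- lapply(split_patterns(mock_reference), one_profile, center = center)
      mock_all <- do.call(rbind, mocks)
      mock_profile <- stats::aggregate(mfi ~ ring_index, mock_all, mean)
    }
  }
  pats <- split_patterns(cells)
  out <- lapply(names(pats), function(pid) {
    prof <- one_profile(pats[[pid]], center = center)
    prof <- cbind(pattern_id = pid,
                  merge(rings, prof, by = "ring_index", sort = FALSE))
    prof$empty <- prof$n == 0L
    if (!is.null(mock_profile)) {
      mm <- mock_profile$mfi[match(prof$ring_index, mock_profile$ring_index)]
      prof$normalized_mfi <- prof$mfi / mm
    } else {
      prof$normalized_mfi <- NA_real_
    }
    prof
  })
  res <- do.call(rbind, out)
  res[order(res$pattern_id, res$edge_dist_inner), , drop = FALSE]
}

#' Edge-versus-center split of a micropatterned population
#'
#' Divides each pattern into an edge band (\[0, edge_band) µm from the
#' pattern edge, default 28 µm) and the remaining center disk, and returns
#' per-pattern paired mock-normalized MFI values suitable for a paired
#' comparison.
#'
#' @inheritParams radial_profile
#' @param pattern_radius_um Pattern radius (µm).
#' @param edge_band_um Edge band width (µm, < radius), default 28.
#' @return Data frame, two rows per pattern (`region` = `"edge"`,
#'   `"center"`): `pattern_id`, `region`, `n`, `mfi`, `normalized_mfi`.
#' @export
edge_center_split <- function(cells, pattern_radius_um, edge_band_um = 28,
                              mock_reference = NULL, channel = "reporter",
                              center = NULL) {
  .check_number(edge_band_um, "edge_band_um", lower = 0,
                allow_equal_lower = FALSE)
  if (edge_band_um >= pattern_radius_um)
    stop("edge band must be narrower than the pattern radius", call. = FALSE)
  R <- pattern_radius_um
  regions <- data.frame(ring_index = c(1L, 0L),
                        edge_dist_inner = c(0, edge_band_um),
                        edge_dist_outer = c(edge_band_um, R),
                        r_inner = c(R - edge_band_um, 0),
                        r_outer = c(R, R - edge_band_um))
  regions$area_um2 <- pi * (regions$r_outer^2 - regions$r_inner^2)
  prof <- radial_profile(cells, regions, mock_reference = mock_reference,
                         channel = channel, center = center)
  prof$region <- ifelse(prof$ring_index == 1L, "edge", "center")
  prof[, c("pattern_id", "region", "n", "mfi", "normalized_mfi", "empty")]
}
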