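# Ingest and export: CellProfiler-dialect object tables, LFQ TSVs, Ct tables,
# and the synthetic-image segmentation fixture path.
#
# Conventions: pixel coordinates are 0-based, y increases downward; all
# coordinates are converted to micrometers at ingest so downstream logic is
# unit-consistent. Missing LFQ values are encoded as NA, never as zero.

.cp_required <- c("ImageNumber", "ObjectNumber",
                  "Location_Center_X", "Location_Center_Y")

#' Read a per-cell object table (CellProfiler export dialect)
#'
#' Expects columns `ImageNumber`, `ObjectNumber`, `Location_Center_X`,
#' `Location_Center_Y` (pixels), any number of
#' `Intensity_MeanIntensity_<channel>` columns, and optional `Metadata_*`
#' columns (`Metadata_Well`, `Metadata_Condition`, `Metadata_Timepoint`).
#' Alternative column names can be supplied through `column_map`
#' (`list(standard_name = actual_name)`). Rows with a missing centroid are
#' dropped with a message. Output is ordered by (field, object) id.
#'
#' @param path CSV file path.
#' @param pixel_size_um Pixel edge length in µm; pixel coordinates are
#'   multiplied by this at ingest.
#' @param column_map Optional named list mapping standard column names to the
#'   file's column names.
#' @return Data frame with `cell_id`, `field_id`, `x_um`, `y_um`, one column
#'   per intensity channel (lower-case channel name), and `well_id`,
#'   `condition`, `timepoint` when present.
#' @export
read_object_table <- function(path, pixel_size_um, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .check_number(pixel_size_um, "pixel_size_um", lower = 0,
                allow_equal_lower = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(column_map))
    for (std in names(column_map)) {
      have <- column_map[[std]]
      if (!have %in% names(raw))
        stop("column_map names missing column '", have, "'", call. = FALSE)
      names(raw)[names(raw) == have] <- std
    }
  miss <- setdiff(.cp_required, names(raw))
  if (length(miss))
    stop("object table lacks required column(s): ",
         paste(miss, collapse = ", "),
         "; available: ", paste(names(raw), collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty object table: ", path, call. = FALSE)
    return(data.frame(cell_id = integer(0), field_id = integer(0),
                      x_um = numeric(0), y_um = numeric(0)))
  }
  bad <- !is.finite(raw$Location_Center_X) | !is.finite(raw$Location_Center_Y)
  if (any(bad)) {
    message("dropping ", sum(bad), " row(s) with missing centroid")
    raw <- raw[!bad, , drop = FALSE]
  }
  if (anyDuplicated(raw[, c("ImageNumber", "ObjectNumber")]))
    stop("duplicate (ImageNumber, ObjectNumber) ids in ", path, call. = FALSE)
  out <- data.frame(cell_id = as.integer(raw$ObjectNumber),
                    field_id = as.integer(raw$ImageNumber),
                    x_um = raw$Location_Center_X * pixel_size_um,
                    y_um = raw$Location_Center_Y * pixel_size_um)
  ichan <- grep("^Intensity_MeanIntensity_", names(raw), value = TRUE)
  for (cc in ichan) {
    v <- raw[[cc]]
    if (any(v < 0, na.rm = TRUE))
      stop("negative intensities in column ", cc, call. = FALSE)
    out[[tolower(sub("^Intensity_MeanIntensity_", "", cc))]] <- v
  }
  meta <- c(well_id = "Metadata_Well", condition = "Metadata_Condition",
            timepoint = "Metadata_Timepoint")
  for (std in names(meta))
    if (meta[[std]] %in% names(raw)) out[[std]] <- raw[[meta[[std]]]]
  out[order(out$field_id, out$cell_id), , drop = FALSE]
}

#' Write a synthetic field as a CellProfiler-dialect object table
#'
#' µm coordinates are divided by `pixel_size_um` on the way out, so a
#' round trip through [read_object_table()] is lossless. Ground-truth columns
#' (`true_*`) go to a sidecar CSV at `<path>` with suffix `_truth.csv`.
#'
#' @param field A `popc_field` (or a plain cell data frame).
#' @param path Output CSV path.
#' @param pixel_size_um Pixel size used for the µm -> pixel conversion.
#' @param well,condition,timepoint Metadata to stamp on every row (condition
#'   defaults to the field's `condition` column when present).
#' @param field_id Value of `ImageNumber` for all rows.
#' @return Invisibly, the paths written (main table, sidecar truth table).
#' @export
write_object_table <- function(field, path, pixel_size_um = 1,
                               well = "A1", condition = NULL,
                               timepoint = "24h", field_id = 1L) {
  cells <- if (inherits(field, "popc_field")) field$cells else field
  stopifnot(is.data.frame(cells))
  if (is.null(condition))
    condition <- if ("condition" %in% names(cells) && nrow(cells))
      cells$condition[1] else "treated"
  out <- data.frame(ImageNumber = field_id,
                    ObjectNumber = cells$cell_id,
                    Location_Center_X = cells$x_um / pixel_size_um,
                    Location_Center_Y = cells$y_um / pixel_size_um)
  for (ch in intersect(c("reporter", "virus"), names(cells)))
    out[[paste0("Intensity_MeanIntensity_", ch)]] <- cells[[ch]]
  out$Metadata_Well <- well
  out$Metadata_Condition <- condition
  out$Metadata_Timepoint <- timepoint
  utils::write.csv(out, path, row.names = FALSE)
  truth_cols <- grep("^true_", names(cells), value = TRUE)
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  if (length(truth_cols)) {
    truth <- cbind(data.frame(ImageNumber = field_id,
                              ObjectNumber = cells$cell_id),
                   cells[, truth_cols, drop = FALSE])
    utils::write.csv(truth, truth_path, row.names = FALSE)
  }
  invisible(c(path, if (length(truth_cols)) truth_path))
}

#' Segment a single-channel intensity image
#'
#' Fixture segmentation for synthetic images: global Otsu threshold (or a
#' manual value) followed by connected-component labelling, reporting per
#' object the centroid (pixels, 0-based) and mean intensity. An all-zero
#' image yields an empty table, not an error.
#'
#' @param image Numeric matrix (row = y, column = x).
#' @param threshold `"otsu"` (default) or a numeric intensity cutoff.
#' @return List with integer `labels` matrix and `objects` data frame
#'   (`object_id`, `x_px`, `y_px`, `mean_intensity`, `n_pixels`).
#' @export
segment_labels <- function(image, threshold = "otsu") {
  stopifnot(is.matrix(image))
  if (all(image == 0)) {
    return(list(labels = matrix(0L, nrow(image), ncol(image)),
                objects = data.frame(object_id = integer(0), x_px = numeric(0),
                                     y_px = numeric(0),
                                     mean_intensity = numeric(0),
                                     n_pixels = integer(0))))
  }
  if (identical(threshold, "otsu")) {
    rng <- range(image)
    norm <- (image - rng[1]) / (rng[2] - rng[1])
    thr_norm <- EBImage::otsu(EBImage::Image(t(norm)), range = c(0, 1))
    thr <- thr_norm * (rng[2] - rng[1]) + rng[1]
  } else {
    thr <- as.numeric(threshold)
  }
  mask <- image > thr
  # EBImage images are x-major; transpose in and out
  lab_img <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labels <- t(EBImage::imageData(lab_img))
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids))
    return(list(labels = labels,
                objects = data.frame(object_id = integer(0), x_px = numeric(0),
                                     y_px = numeric(0),
                                     mean_intensity = numeric(0),
                                     n_pixels = integer(0))))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  row_i <- (idx - 1L) %% nrow(labels) + 1L
  col_i <- (idx - 1L) %/% nrow(labels) + 1L
  # pixel centers: 0-based center of pixel (c-1 + 0.5)
  xs <- tapply(col_i - 0.5, lab, mean)
  ys <- tapply(row_i - 0.5, lab, mean)
  mi <- tapply(image[idx], lab, mean)
  np <- tapply(idx, lab, length)
  objects <- data.frame(object_id = as.integer(names(xs)),
                        x_px = as.numeric(xs), y_px = as.numeric(ys),
                        mean_intensity = as.numeric(mi),
                        n_pixels = as.integer(np))
  list(labels = labels, objects = objects[order(objects$object_id), ])
}

#' Write / read 16-bit TIFF images
#'
#' Thin wrappers around the tiff package for the synthetic fixture path.
#' Intensities are scaled by `scale` into \[0, 1\] for 16-bit storage.
#'
#' @param image Numeric matrix.
#' @param path File path.
#' @param scale Value mapped to the 16-bit maximum.
#' @return `read_image_tiff` returns the matrix back on the original scale.
#' @export
write_image_tiff <- function(image, path, scale = max(image, 1)) {
  img <- pmin(pmax(image / scale, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, scale = 1) {
  tiff::readTIFF(path) * scale
}

#' Read a label-free quantification (LFQ) protein table
#'
#' Reads a TSV of per-protein LFQ values (MaxQuant-style export). Zeros and
#' blanks encode "not detected" and are normalized to NA. Sample columns are
#' assigned to the apical / basolateral / background groups by
#' case-insensitive pattern match on the column name.
#'
#' @param path TSV path.
#' @param patterns Named list of regexes for the three groups.
#' @param id_column Protein id column name (default `protein_id`).
#' @return A `popc_lfq` data frame with `attr(, "groups")` listing the column
#'   names per group.
#' @export
read_lfq_table <- function(path,
                           patterns = list(apical = "apical",
                                           basolateral = "basolateral|basal",
                                           background = "background|bead"),
                           id_column = "protein_id") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_column %in% names(raw))
    stop("no '", id_column, "' column in ", path, call. = FALSE)
  groups <- lapply(patterns, function(p)
    grep(p, names(raw), ignore.case = TRUE, value = TRUE))
  # background patterns can collide with side patterns; make groups disjoint
  groups$apical <- setdiff(groups$apical, groups$background)
  groups$basolateral <- setdiff(groups$basolateral, groups$background)
  if (!length(groups$apical) || !length(groups$basolateral))
    stop("could not identify apical and basolateral sample columns in ",
         path, " (patterns: ", paste(unlist(patterns), collapse = ", "), ")",
         call. = FALSE)
  for (cc in unlist(groups)) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    v[!is.na(v) & v == 0] <- NA  # MaxQuant convention: 0 = not detected
    raw[[cc]] <- v
  }
  names(raw)[names(raw) == id_column] <- "protein_id"
  attr(raw, "groups") <- groups
  class(raw) <- c("popc_lfq", "data.frame")
  raw
}

#' Write an LFQ table as TSV
#'
#' NA values are written as 0 (MaxQuant convention), so a round trip through
#' [read_lfq_table()] restores them as missing.
#'
#' @param lfq A `popc_lfq` data frame.
#' @param path Output path.
#' @export
write_lfq_table <- function(lfq, path) {
  out <- as.data.frame(lfq)
  for (cc in unlist(attr(lfq, "groups")))
    out[[cc]][is.na(out[[cc]])] <- 0
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a qPCR Ct table
#'
#' @param ct Data frame with columns `sample`, `gene`, `ct`, `condition`,
#'   `timepoint` (and optionally `replicate`).
#' @return The validated data frame.
#' @export
validate_ct_table <- function(ct) {
  need <- c("sample", "gene", "ct", "condition", "timepoint")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  ct
}
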