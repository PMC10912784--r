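# Synthetic-data generator: epithelial colony fields, micropatterned disk
# populations, reporter/virus intensities and LFQ tables with known ground
# truth for every downstream analysis stage.

#' Generator configuration
#'
#' Parameterizes the synthetic-data generator: field geometry, colony and
#' single-cell counts, minimum centroid spacing, the probability that a cell
#' responds to interferon as a function of its edge degree, the reporter
#' intensity distributions of non-responders (mock-like) and responders, the
#' infected fraction for virus-channel simulation, and the micropattern
#' diameter. All randomness downstream derives deterministically from `seed`.
#'
#' The default `response_prob_by_degree` encodes an apical type I interferon
#' regime: 80% of isolated cells (edge degree 0) respond, with monotonically
#' decreasing probability for cells more deeply embedded in a colony. Use
#' [ifn_response_profile()] for the bundled type I / type III calibrations.
#'
#' Intensities are log-normal: `mock_intensity_dist` and
#' `responder_intensity_dist` are length-2 vectors `c(meanlog, sdlog)`, the
#' responder distribution stochastically larger. Virus-channel intensities use
#' `virus_control_dist` / `virus_infected_dist` in the same form.
#'
#' @param field_width_um,field_height_um Field size in micrometers.
#' @param n_colonies Number of colonies to place.
#' @param colony_cells_dist Integer range `c(min, max)`; cells per colony are
#'   drawn uniformly from it.
#' @param n_singles Number of isolated cells (no neighbor within twice the
#'   spacing).
#' @param cell_spacing_um Minimum center-to-center distance between any two
#'   cells (µm).
#' @param response_prob_by_degree Named numeric vector mapping edge degree
#'   (as name) to response probability in \[0, 1\].
#' @param mock_intensity_dist,responder_intensity_dist `c(meanlog, sdlog)` of
#'   the log-normal reporter intensity distributions.
#' @param infected_fraction Probability that a cell is infected in virus
#'   simulations.
#' @param virus_control_dist,virus_infected_dist `c(meanlog, sdlog)` of the
#'   log-normal virus-channel intensity distributions.
#' @param pattern_diameter_um Micropattern diameter (µm), default 200.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   tables.
#' @return An object of class `popc_config` (a validated list).
#' @examples
#' cfg <- generator_config(n_colonies = 2, n_singles = 5, seed = 1)
#' @export
generator_config <- function(field_width_um = 1500,
                             field_height_um = 1500,
                             n_colonies = 8,
                             colony_cells_dist = c(20, 60),
                             n_singles = 40,
                             cell_spacing_um = 15,
                             response_prob_by_degree = ifn_response_profile("IFNb1"),
                             mock_intensity_dist = c(meanlog = log(100), sdlog = 0.35),
                             responder_intensity_dist = c(meanlog = log(1200), sdlog = 0.35),
                             infected_fraction = 0.5,
                             virus_control_dist = c(meanlog = log(50), sdlog = 0.3),
                             virus_infected_dist = c(meanlog = log(800), sdlog = 0.3),
                             pattern_diameter_um = 200,
                             seed = 1L) {
  .check_number(field_width_um, "field_width_um", lower = 0, allow_equal_lower = FALSE)
  .check_number(field_height_um, "field_height_um", lower = 0, allow_equal_lower = FALSE)
  .check_number(n_colonies, "n_colonies", lower = 0)
  .check_number(n_singles, "n_singles", lower = 0)
  .check_number(cell_spacing_um, "cell_spacing_um", lower = 0, allow_equal_lower = FALSE)
  .check_number(pattern_diameter_um, "pattern_diameter_um", lower = 0, allow_equal_lower = FALSE)
  .check_prob(infected_fraction, "infected_fraction")
  .check_prob(response_prob_by_degree, "response_prob_by_degree")
  if (is.null(names(response_prob_by_degree)) ||
      anyNA(suppressWarnings(as.integer(names(response_prob_by_degree)))))
    stop("'response_prob_by_degree' must be named by integer edge degrees",
         call. = FALSE)
  stopifnot(length(colony_cells_dist) == 2L,
            colony_cells_dist[1] >= 1, colony_cells_dist[2] >= colony_cells_dist[1])
  for (nm in c("mock_intensity_dist", "responder_intensity_dist",
               "virus_control_dist", "virus_infected_dist")) {
    v <- get(nm)
    if (length(v) != 2L || !is.numeric(v) || v[2] < 0)
      stop(sprintf("'%s' must be c(meanlog, sdlog) with sdlog >= 0", nm),
           call. = FALSE)
  }
  cfg <- list(field_width_um = field_width_um,
              field_height_um = field_height_um,
              n_colonies = as.integer(n_colonies),
              colony_cells_dist = as.integer(colony_cells_dist),
              n_singles = as.integer(n_singles),
              cell_spacing_um = cell_spacing_um,
              response_prob_by_degree = response_prob_by_degree,
              mock_intensity_dist = unname(mock_intensity_dist),
              responder_intensity_dist = unname(responder_intensity_dist),
              infected_fraction = infected_fraction,
              virus_control_dist = unname(virus_control_dist),
              virus_infected_dist = unname(virus_infected_dist),
              pattern_diameter_um = pattern_diameter_um,
              seed = as.integer(seed))
  class(cfg) <- "popc_config"
  cfg
}

#' @export
print.popc_config <- function(x, ...) {
  cat("Synthetic field generator configuration\n")
  cat(sprintf("  field: %g x %g um, %d colonies (%d-%d cells), %d singles\n",
              x$field_width_um, x$field_height_um, x$n_colonies,
              x$colony_cells_dist[1], x$colony_cells_dist[2], x$n_singles))
  cat(sprintf("  spacing: %g um; pattern diameter: %g um; seed: %d\n",
              x$cell_spacing_um, x$pattern_diameter_um, x$seed))
  cat("  p(respond | degree):",
      paste(sprintf("%s:%.2f", names(x$response_prob_by_degree),
                    x$response_prob_by_degree), collapse = " "), "\n")
  invisible(x)
}

#' Degree-dependent response probability calibrations
#'
#' Bundled response-probability profiles for apical interferon treatment.
#' The edge-degree-0 values are anchored to the reported single-cell response
#' fractions under saturating apical treatment (80% for IFN-beta1, 40% for
#' IFN-lambda1-3); the decline over higher degrees is a monotone assumption,
#' since per-degree probabilities beyond isolated cells are not published.
#'
#' @param treatment `"IFNb1"` (type I) or `"IFNl1_3"` (type III).
#' @return Named numeric vector, degree -> response probability.
#' @export
ifn_response_profile <- function(treatment = c("IFNb1", "IFNl1_3")) {
  treatment <- match.arg(treatment)
  degrees <- 0:10
  p <- switch(treatment,
    IFNb1  = c(0.80, 0.60, 0.40, 0.25, 0.15, 0.10, 0.07, 0.05, 0.04, 0.03, 0.02),
    IFNl1_3 = c(0.40, 0.28, 0.18, 0.11, 0.07, 0.05, 0.04, 0.03, 0.02, 0.02, 0.01))
  stats::setNames(p, degrees)
}

## Placement primitives -------------------------------------------------------

# Triangular lattice covering a disk of radius r (centered at origin),
# pitch p, including the origin. Returns a 2-column matrix.
.tri_lattice_disk <- function(r, p) {
  dy <- p * sqrt(3) / 2
  rows <- seq(-ceiling(r / dy), ceiling(r / dy))
  pts <- lapply(rows, function(k) {
    yy <- k * dy
    off <- if (k %% 2 == 0) 0 else p / 2
    xs <- seq(-ceiling((r + p) / p), ceiling((r + p) / p)) * p + off
    cbind(xs, yy)
  })
  pts <- do.call(rbind, pts)
  pts[pts[, 1]^2 + pts[, 2]^2 <= r^2, , drop = FALSE]
}

# Jitter lattice points, preserving a minimum pairwise distance of `spacing`
# provided pitch - 2*jitter >= spacing.
.jitter_points <- function(pts, jitter) {
  n <- nrow(pts)
  if (n == 0L || jitter <= 0) return(pts)
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- jitter * sqrt(stats::runif(n))
  pts + cbind(rad * cos(ang), rad * sin(ang))
}

# Compact disk colony of n cells: jittered triangular lattice, n points
# nearest the colony center. Pitch 1.05 x spacing keeps the exact spacing
# invariant after jittering.
.place_colony <- function(n, spacing) {
  pitch <- 1.05 * spacing
  jitter <- (pitch - spacing) / 2 * 0.95
  r <- spacing * sqrt(n / pi) * 1.15
  for (k in 1:20) {
    pts <- .tri_lattice_disk(r, pitch)
    if (nrow(pts) >= n) break
    r <- r * 1.1
  }
  if (nrow(pts) < n)
    stop("colony packing infeasible: cannot fit ", n,
         " cells at spacing ", spacing, call. = FALSE)
  d2 <- pts[, 1]^2 + pts[, 2]^2
  pts <- pts[order(d2)[seq_len(n)], , drop = FALSE]
  list(xy = .jitter_points(pts, jitter), radius = r)
}

# Dart-throwing placement of n points in [0,w]x[0,h] keeping distance
# >= min_dist from `existing` points and from each other, grid-accelerated.
.dart_throw <- function(n, w, h, min_dist, existing = NULL,
                        max_tries = 200L * max(n, 1L)) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  cell <- min_dist
  gx <- function(x) as.integer(floor(x / cell))
  grid <- new.env(parent = emptyenv(), hash = TRUE)
  put <- function(x, y) {
    k <- paste(gx(x), gx(y))
    grid[[k]] <- rbind(grid[[k]], c(x, y))
  }
  ok <- function(x, y) {
    kx <- gx(x); ky <- gx(y)
    for (dx in -1:1) for (dy in -1:1) {
      pts <- grid[[paste(kx + dx, ky + dy)]]
      if (!is.null(pts)) {
        if (any((pts[, 1] - x)^2 + (pts[, 2] - y)^2 < min_dist^2))
          return(FALSE)
      }
    }
    TRUE
  }
  if (!is.null(existing) && nrow(existing))
    for (k in seq_len(nrow(existing))) put(existing[k, 1], existing[k, 2])
  out <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    x <- stats::runif(1, 0, w); y <- stats::runif(1, 0, h)
    if (ok(x, y)) {
      placed <- placed + 1L
      out[placed, ] <- c(x, y)
      put(x, y)
    }
  }
  if (placed < n)
    stop("placement infeasible: placed ", placed, " of ", n,
         " points at min distance ", min_dist,
         " in a ", w, " x ", h, " um field (packing constraint violated)",
         call. = FALSE)
  out
}

.new_field <- function(cells, config, mode) {
  structure(list(cells = cells, config = config, mode = mode),
            class = "popc_field")
}

#' @export
print.popc_field <- function(x, ...) {
  cat(sprintf("Synthetic %s field: %d cells", x$mode, nrow(x$cells)))
  if (nrow(x$cells)) {
    ns <- sum(x$cells$true_is_single)
    cat(sprintf(" (%d singles, %d colony cells)", ns, nrow(x$cells) - ns))
  }
  cat("\n")
  invisible(x)
}

#' Generate a synthetic colony field
#'
#' Places `n_colonies` compact disk-shaped colonies (jittered triangular
#' packing at just above the minimum spacing, emulating confluent epithelial
#' colonies) plus `n_singles` isolated cells at least twice the spacing away
#' from any other cell, on a rectangular field. Ground-truth colony membership
#' and single status are recorded per cell.
#'
#' @param config A [generator_config()].
#' @return A `popc_field`: list with `cells` (data frame: `cell_id`, `x_um`,
#'   `y_um`, `true_colony_id`, `true_is_single`) and the config used.
#' @export
generate_colony_field <- function(config) {
  stopifnot(inherits(config, "popc_config"))
  set.seed(config$seed)
  s <- config$cell_spacing_um
  w <- config$field_width_um; h <- config$field_height_um
  xs <- ys <- numeric(0)
  colony_id <- integer(0)
  if (config$n_colonies > 0L) {
    sizes <- sample(seq(config$colony_cells_dist[1], config$colony_cells_dist[2]),
                    config$n_colonies, replace = TRUE)
    blobs <- lapply(sizes, .place_colony, spacing = s)
    radii <- vapply(blobs, `[[`, numeric(1), "radius")
    # colony centers: keep whole blob inside the field, blobs >= 2 spacing apart
    margin <- radii + 2 * s
    if (any(w - 2 * margin <= 0) || any(h - 2 * margin <= 0))
      stop("field too small for requested colonies (colony radius ",
           round(max(radii), 1), " um exceeds the field margin)", call. = FALSE)
    maxr <- max(margin)
    centers <- .dart_throw(config$n_colonies, w - 2 * maxr, h - 2 * maxr,
                           min_dist = 2 * maxr) + maxr
    for (k in seq_len(config$n_colonies)) {
      xy <- blobs[[k]]$xy
      xs <- c(xs, xy[, 1] + centers[k, 1])
      ys <- c(ys, xy[, 2] + centers[k, 2])
      colony_id <- c(colony_id, rep.int(k, nrow(xy)))
    }
  }
  if (config$n_singles > 0L) {
    singles <- .dart_throw(config$n_singles, w, h, min_dist = 2 * s,
                           existing = cbind(xs, ys))
    xs <- c(xs, singles[, 1]); ys <- c(ys, singles[, 2])
    colony_id <- c(colony_id, rep.int(NA_integer_, config$n_singles))
  }
  cells <- data.frame(cell_id = seq_along(xs),
                      x_um = xs, y_um = ys,
                      true_colony_id = colony_id,
                      true_is_single = is.na(colony_id))
  .new_field(cells, config, mode = "colony")
}

#' Generate a micropatterned disk population
#'
#' Fills a circular micropattern (default 200 µm diameter) with cells at the
#' packing permitted by the minimum spacing: a jittered triangular lattice,
#' all centroids within the pattern radius. A pattern smaller than the spacing
#' holds exactly one cell at its center.
#'
#' @param config A [generator_config()]; `pattern_diameter_um` sets the disk.
#' @return A `popc_field` with cells centered on the pattern center
#'   (`pattern_radius_um/2`-origin coordinates are positive: the center sits at
#'   (R, R)).
#' @export
generate_micropattern_population <- function(config) {
  stopifnot(inherits(config, "popc_config"))
  set.seed(config$seed)
  R <- config$pattern_diameter_um / 2
  s <- config$cell_spacing_um
  if (config$pattern_diameter_um < s) {
    cells <- data.frame(cell_id = 1L, x_um = R, y_um = R,
                        true_colony_id = 1L, true_is_single = FALSE)
    return(.new_field(cells, config, mode = "micropattern"))
  }
  pitch <- 1.05 * s
  jitter <- (pitch - s) / 2 * 0.95
  pts <- .tri_lattice_disk(R - jitter, pitch)
  pts <- .jitter_points(pts, jitter)
  cells <- data.frame(cell_id = seq_len(nrow(pts)),
                      x_um = pts[, 1] + R, y_um = pts[, 2] + R,
                      true_colony_id = 1L,
                      true_is_single = FALSE)
  .new_field(cells, config, mode = "micropattern")
}

#' Assign reporter intensities and responder ground truth
#'
#' Draws each cell's responder label Bernoulli(p(degree)) from the config's
#' `response_prob_by_degree`, then draws reporter intensities: responders from
#' the responder log-normal, non-responders from the mock log-normal. Under
#' `condition = "mock"` every cell gets mock-distribution intensity and
#' `true_responder = FALSE` (the reporter is only expressed upon interferon
#' signaling).
#'
#' @param field A `popc_field`.
#' @param config A [generator_config()].
#' @param truth_degrees Integer vector of ground-truth edge degrees, one per
#'   cell, typically from [reference_annotation()] (not from the pipeline
#'   annotator under test).
#' @param condition `"treated"` or `"mock"`.
#' @return The field with `true_edge_degree`, `true_responder` and `reporter`
#'   columns added.
#' @export
assign_response_intensities <- function(field, config, truth_degrees,
                                        condition = c("treated", "mock")) {
  stopifnot(inherits(field, "popc_field"), inherits(config, "popc_config"))
  condition <- match.arg(condition)
  cells <- field$cells
  n <- nrow(cells)
  if (n > 0 && length(truth_degrees) != n)
    stop("'truth_degrees' must have one entry per cell", call. = FALSE)
  set.seed(.child_seed(config$seed, "intensities"))
  if (n == 0L) {
    cells$true_edge_degree <- integer(0)
    cells$true_responder <- logical(0)
    cells$reporter <- numeric(0)
  } else {
    probs <- config$response_prob_by_degree
    key <- as.character(truth_degrees)
    missing_deg <- setdiff(unique(key), names(probs))
    if (length(missing_deg))
      stop("no response probability configured for edge degree(s): ",
           paste(missing_deg, collapse = ", "), call. = FALSE)
    p <- unname(probs[key])
    responder <- if (condition == "mock") rep.int(FALSE, n)
                 else stats::runif(n) < p
    md <- config$mock_intensity_dist
    rd <- config$responder_intensity_dist
    intensity <- stats::rlnorm(n, md[1], md[2])
    if (any(responder))
      intensity[responder] <- stats::rlnorm(sum(responder), rd[1], rd[2])
    cells$true_edge_degree <- as.integer(truth_degrees)
    cells$true_responder <- responder
    cells$reporter <- intensity
  }
  cells$condition <- condition
  field$cells <- cells
  field
}

#' Assign virus-channel intensities and infection ground truth
#'
#' Each cell is infected with probability `infected_fraction` (set it to 0 for
#' a non-infected control field); infected cells draw virus-channel intensity
#' from the infected log-normal, the rest from the control log-normal.
#'
#' @inheritParams assign_response_intensities
#' @param infected_fraction Optional override of the config value.
#' @return The field with `true_infected` and `virus` columns added.
#' @export
assign_infection <- function(field, config, infected_fraction = NULL) {
  stopifnot(inherits(field, "popc_field"), inherits(config, "popc_config"))
  p <- if (is.null(infected_fraction)) config$infected_fraction else infected_fraction
  .check_prob(p, "infected_fraction")
  set.seed(.child_seed(config$seed, "infection"))
  cells <- field$cells
  n <- nrow(cells)
  infected <- if (n) stats::runif(n) < p else logical(0)
  cd <- config$virus_control_dist
  id <- config$virus_infected_dist
  v <- if (n) stats::rlnorm(n, cd[1], cd[2]) else numeric(0)
  if (any(infected)) v[infected] <- stats::rlnorm(sum(infected), id[1], id[2])
  cells$true_infected <- infected
  cells$virus <- v
  field$cells <- cells
  field
}

#' Generate a synthetic label-free quantification (LFQ) table
#'
#' Emulates a surface-biotinylation proteomics experiment: per-protein
#' replicate log2 LFQ values for apical, basolateral and bead-background
#' samples. Each protein has a ground-truth apical fraction `f`; its apical
#' linear mean is `f * T` and basolateral `(1 - f) * T` for a per-protein
#' total abundance `T`, so the ground-truth apical index A/(A+B) equals `f`
#' exactly when `noise_sd = 0`. A designated contaminant subset carries high
#' background signal; all other proteins have background missing. Values can
#' additionally be missing completely at random.
#'
#' @param n_proteins Number of proteins.
#' @param polarity_spec Numeric vector of apical fractions in \[0, 1\]
#'   (recycled to `n_proteins`).
#' @param n_replicates Replicates per side group (>= 2).
#' @param noise_sd Replicate noise SD in log2 units.
#' @param seed Integer seed.
#' @param n_background Background replicates (default 3).
#' @param contaminants Integer indices of contaminant proteins (default none).
#' @param missing_prob Per-value missing-completely-at-random probability.
#' @return A data frame of class `popc_lfq`: `protein_id`, `terms`,
#'   ground-truth columns, and log2 LFQ columns named
#'   `LFQ_apical_<i>`, `LFQ_basolateral_<i>`, `LFQ_background_<i>` (NA =
#'   missing). Group columns are recorded in `attr(, "groups")`.
#' @export
generate_lfq_table <- function(n_proteins, polarity_spec = 0.5,
                               n_replicates = 4, noise_sd = 0.3, seed = 1L,
                               n_background = 3, contaminants = integer(0),
                               missing_prob = 0) {
  .check_number(n_proteins, "n_proteins", lower = 1)
  .check_number(n_replicates, "n_replicates", lower = 2)
  .check_prob(polarity_spec, "polarity_spec")
  .check_prob(missing_prob, "missing_prob")
  set.seed(.child_seed(seed, "lfq"))
  f <- rep_len(polarity_spec, n_proteins)
  total_log2 <- stats::rnorm(n_proteins, mean = 25, sd = 1.5)
  A <- f * 2^total_log2
  B <- (1 - f) * 2^total_log2
  draw_side <- function(mean_lin) {
    m <- matrix(NA_real_, n_proteins, n_replicates)
    pos <- mean_lin > 0
    for (k in seq_len(n_replicates))
      m[pos, k] <- log2(mean_lin[pos]) + stats::rnorm(sum(pos), 0, noise_sd)
    m
  }
  ap <- draw_side(A)
  bl <- draw_side(B)
  bg <- matrix(NA_real_, n_proteins, n_background)
  if (length(contaminants)) {
    side_max <- pmax(A, B)[contaminants]
    for (k in seq_len(n_background))
      bg[contaminants, k] <- log2(side_max) + stats::rnorm(length(contaminants), 0, max(noise_sd, 0.1))
  }
  if (missing_prob > 0) {
    ap[matrix(stats::runif(length(ap)) < missing_prob, nrow(ap))] <- NA
    bl[matrix(stats::runif(length(bl)) < missing_prob, nrow(bl))] <- NA
  }
  colnames(ap) <- paste0("LFQ_apical_", seq_len(n_replicates))
  colnames(bl) <- paste0("LFQ_basolateral_", seq_len(n_replicates))
  colnames(bg) <- paste0("LFQ_background_", seq_len(n_background))
  out <- data.frame(protein_id = sprintf("P%05d", seq_len(n_proteins)),
                    terms = "plasma membrane",
                    true_apical_fraction = f,
                    true_contaminant = seq_len(n_proteins) %in% contaminants,
                    ap, bl, bg, check.names = FALSE)
  attr(out, "groups") <- list(apical = colnames(ap),
                              basolateral = colnames(bl),
                              background = colnames(bg))
  class(out) <- c("popc_lfq", "data.frame")
  out
}

#' Render a synthetic field to label and intensity images
#'
#' Draws each cell as a disk (radius just under half the spacing) labeled with
#' its id, and an intensity image carrying the cell's reporter intensity.
#' Round-tripping through [segment_labels()] recovers centroids within one
#' pixel.
#'
#' @param field A `popc_field` whose cells carry a `reporter` column (or all
#'   zeros if absent).
#' @param pixel_size_um Pixel edge length in µm (> 0).
#' @param radius_um Disk radius; default 40% of the configured spacing.
#' @return List with integer `labels` and numeric `intensity` matrices
#'   (row = y, column = x, 0-based pixel origin at the field corner).
#' @export
render_field_images <- function(field, pixel_size_um,
                                radius_um = 0.4 * field$config$cell_spacing_um) {
  stopifnot(inherits(field, "popc_field"))
  .check_number(pixel_size_um, "pixel_size_um", lower = 0, allow_equal_lower = FALSE)
  if (2 * radius_um >= field$config$cell_spacing_um)
    stop("disk radius ", radius_um, " um would overlap at spacing ",
         field$config$cell_spacing_um, " um; choose a smaller radius",
         call. = FALSE)
  w <- if (field$mode == "micropattern") field$config$pattern_diameter_um else field$config$field_width_um
  h <- if (field$mode == "micropattern") field$config$pattern_diameter_um else field$config$field_height_um
  nx <- as.integer(ceiling(w / pixel_size_um))
  ny <- as.integer(ceiling(h / pixel_size_um))
  labels <- matrix(0L, nrow = ny, ncol = nx)
  intensity <- matrix(0, nrow = ny, ncol = nx)
  cells <- field$cells
  if (nrow(cells) == 0L) return(list(labels = labels, intensity = intensity))
  vals <- if ("reporter" %in% names(cells)) cells$reporter else rep(0, nrow(cells))
  rpx <- radius_um / pixel_size_um
  for (k in seq_len(nrow(cells))) {
    cx <- cells$x_um[k] / pixel_size_um
    cy <- cells$y_um[k] / pixel_size_um
    xr <- max(1L, floor(cx - rpx)):min(nx, ceiling(cx + rpx) + 1L)
    yr <- max(1L, floor(cy - rpx)):min(ny, ceiling(cy + rpx) + 1L)
    # pixel centers at (col - 0.5, row - 0.5)
    px <- xr - 0.5; py <- yr - 0.5
    dd <- outer((py - cy)^2, (px - cx)^2, `+`)
    inside <- dd <= rpx^2
    labels[yr, xr][inside] <- cells$cell_id[k]
    intensity[yr, xr][inside] <- vals[k]
  }
  list(labels = labels, intensity = intensity)
}
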