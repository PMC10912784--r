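# Spatial annotation of cell centroids: DBSCAN clustering, angular-gap edge
# classification, and edge-degree assignment by iterative peeling.
#
# Edge-degree semantics: 0 = single cell (no neighbor within eps); 1 = cell at
# the border of its colony; d >= 2 = cell d peeling rounds away from the
# border. Within a cluster, degrees form a contiguous set {1..d_max}.

#' Annotation parameters
#'
#' @param eps Neighborhood radius in µm (> 0).
#' @param min_pts DBSCAN core threshold: a core cell has at least
#'   `min_pts - 1` neighbors within `eps` (>= 2).
#' @param theta_edge Angular-gap threshold in degrees: a clustered cell is an
#'   edge cell when the largest gap between bearings to its within-`eps`
#'   same-cluster neighbors exceeds this (0 < theta < 360).
#' @return A `popc_params` list.
#' @export
annotation_params <- function(eps, min_pts = 4, theta_edge = 120) {
  .check_number(eps, "eps", lower = 0, allow_equal_lower = FALSE)
  .check_number(min_pts, "min_pts", lower = 2)
  .check_number(theta_edge, "theta_edge", lower = 0, upper = 360,
                allow_equal_lower = FALSE)
  if (theta_edge >= 360) stop("'theta_edge' must be < 360", call. = FALSE)
  structure(list(eps = eps, min_pts = as.integer(min_pts),
                 theta_edge = theta_edge),
            class = "popc_params")
}

.cells_df <- function(cells) {
  if (inherits(cells, "popc_field")) cells <- cells$cells
  stopifnot(is.data.frame(cells), all(c("x_um", "y_um") %in% names(cells)))
  if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um)))
    stop("cell coordinates must be finite", call. = FALSE)
  if (is.null(cells$cell_id)) cells$cell_id <- seq_len(nrow(cells))
  d <- duplicated(cells[, c("x_um", "y_um")])
  if (any(d))
    stop("coincident cell centroids found (distance 0); ",
         "reject or jitter duplicates at ingest", call. = FALSE)
  cells
}

#' Estimate the DBSCAN neighborhood radius from the data
#'
#' Heuristic: 1.5 times the median distance to the k-th nearest neighbor
#' (default k = 4). On a square lattice of spacing s this gives eps = 1.5 s,
#' which reaches the diagonal neighbors but not the second shell.
#'
#' @param cells Data frame with `x_um`, `y_um` (or a `popc_field`).
#' @param k Neighbor rank (default 4). Requires at least `k + 1` cells.
#' @return eps in µm, with the per-cell k-th neighbor distances attached as
#'   `attr(, "knn_distances")` for diagnostics.
#' @export
estimate_eps <- function(cells, k = 4) {
  cells <- .cells_df(cells)
  n <- nrow(cells)
  if (n < k + 1)
    stop("need at least k + 1 = ", k + 1, " cells to estimate eps; ",
         "supply eps manually via annotation_params()", call. = FALSE)
  x <- cells$x_um; y <- cells$y_um
  kd <- numeric(n)
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(x[s:e], x, "-"); dy <- outer(y[s:e], y, "-")
    dm <- sqrt(dx * dx + dy * dy)
    kd[s:e] <- apply(dm, 1L, function(r) sort(r)[k + 1L])  # self at rank 1
  }
  eps <- 1.5 * stats::median(kd)
  attr(eps, "knn_distances") <- kd
  attr(eps, "k") <- k
  eps
}

## DBSCAN ---------------------------------------------------------------------

#' Cluster cells with DBSCAN semantics
#'
#' Core cells have at least `min_pts - 1` neighbors within `eps`; clusters are
#' the density-connected components; non-core cells with a core neighbor join
#' the cluster of their nearest core neighbor. Non-core cells with neighbors
#' but no core neighbor form "micro-colonies" (connected components of the
#' neighbor graph among themselves) so that only truly isolated cells are
#' singles. Cluster labels are deterministic: ordered by the smallest cell
#' index they contain.
#'
#' @param cells Data frame with `x_um`, `y_um` (or a `popc_field`).
#' @param params An [annotation_params()].
#' @return List with `cluster` (integer, NA for singles), `n_neighbors`, and
#'   the pair table used (internal).
#' @export
cluster_cells <- function(cells, params) {
  cells <- .cells_df(cells)
  stopifnot(inherits(params, "popc_params"))
  n <- nrow(cells)
  pairs <- .neighbor_pairs(cells$x_um, cells$y_um, params$eps)
  nb <- tabulate(pairs$i, nbins = n)
  core <- nb >= params$min_pts - 1L
  comp <- seq_len(n)
  ce <- pairs[core[pairs$i] & core[pairs$j] & pairs$i < pairs$j, , drop = FALSE]
  comp <- .uf_components(n, ce$i, ce$j)
  cluster <- rep(NA_integer_, n)
  if (any(core)) cluster[core] <- comp[core]
  # border cells: nearest core neighbor, ties by smallest neighbor index
  bp <- pairs[!core[pairs$i] & core[pairs$j], , drop = FALSE]
  if (nrow(bp)) {
    bp <- bp[order(bp$i, bp$d, bp$j), , drop = FALSE]
    first <- bp[!duplicated(bp$i), , drop = FALSE]
    cluster[first$i] <- comp[first$j]
  }
  # micro-colonies among remaining neighbor-having cells
  left <- is.na(cluster) & nb > 0L
  if (any(left)) {
    lp <- pairs[left[pairs$i] & left[pairs$j] & pairs$i < pairs$j, , drop = FALSE]
    lcomp <- .uf_components(n, lp$i, lp$j)
    # offset so micro-colony components never collide with core components
    cluster[left] <- lcomp[left] + n
  }
  # deterministic relabeling by smallest member index
  lab <- cluster[!is.na(cluster)]
  if (length(lab)) {
    mins <- tapply(which(!is.na(cluster)), cluster[!is.na(cluster)], min)
    newid <- stats::setNames(rank(mins, ties.method = "first"), names(mins))
    cluster[!is.na(cluster)] <- as.integer(newid[as.character(cluster[!is.na(cluster)])])
  }
  list(cluster = cluster, n_neighbors = nb, pairs = pairs)
}

# Edge flags among the active subset. Returns logical over all n (FALSE for
# inactive cells). A cell is edge when its remaining cluster has <= 2 members,
# when it has no remaining same-cluster neighbor, or when the largest angular
# gap between bearings to remaining same-cluster neighbors exceeds theta.
.edge_flags <- function(n, pairs, cluster, active, theta) {
  edge <- rep(FALSE, n)
  act_idx <- which(active & !is.na(cluster))
  if (!length(act_idx)) return(edge)
  csize <- table(cluster[act_idx])
  small <- act_idx[csize[as.character(cluster[act_idx])] <= 2]
  edge[small] <- TRUE
  keep <- active[pairs$i] & active[pairs$j] &
    !is.na(cluster[pairs$i]) & !is.na(cluster[pairs$j]) &
    cluster[pairs$i] == cluster[pairs$j]
  pp <- pairs[keep, , drop = FALSE]
  has_nb <- rep(FALSE, n)
  if (nrow(pp)) {
    o <- order(pp$i, pp$bearing)
    gaps <- .max_angular_gap(pp$i[o], pp$bearing[o])
    ids <- as.integer(names(gaps))
    has_nb[ids] <- TRUE
    edge[ids[gaps > theta]] <- TRUE
  }
  edge[act_idx[!has_nb[act_idx]]] <- TRUE
  edge
}

#' Classify edge cells
#'
#' A clustered cell is an edge cell when the largest angular gap between the
#' bearings to its within-eps same-cluster neighbors exceeds `theta_edge`
#' (default 120 degrees); members of clusters of size <= 2 are always edge.
#'
#' @inheritParams cluster_cells
#' @param clustering Result of [cluster_cells()].
#' @return Logical vector, one per cell (FALSE for singles).
#' @export
classify_edge <- function(cells, clustering, params) {
  cells <- .cells_df(cells)
  n <- nrow(cells)
  .edge_flags(n, clustering$pairs, clustering$cluster,
              active = rep(TRUE, n), theta = params$theta_edge)
}

#' Assign edge degrees by iterative peeling
#'
#' Current edge cells of each cluster receive degree d and are removed;
#' neighborhoods and edge status are recomputed among the remaining cells and
#' d increments, until the cluster is exhausted. Singles get degree 0.
#' Termination is guaranteed: if a pass removes no cell (cannot happen for
#' point sets in general position), all remaining cells receive the current
#' degree and a warning is emitted.
#'
#' @inheritParams classify_edge
#' @return Integer vector of edge degrees.
#' @export
assign_edge_degree <- function(cells, clustering, params) {
  cells <- .cells_df(cells)
  n <- nrow(cells)
  degree <- rep(0L, n)
  active <- !is.na(clustering$cluster)
  d <- 1L
  while (any(active)) {
    edge <- .edge_flags(n, clustering$pairs, clustering$cluster,
                        active = active, theta = params$theta_edge)
    edge <- edge & active
    if (!any(edge)) {
      warning("peeling pass removed no cell; assigning degree ", d,
              " to all remaining cells", call. = FALSE)
      degree[active] <- d
      break
    }
    degree[edge] <- d
    active[edge] <- FALSE
    d <- d + 1L
  }
  degree
}

#' Annotate cells with cluster, edge and edge-degree labels
#'
#' One-call wrapper running [cluster_cells()], [classify_edge()] and
#' [assign_edge_degree()], returning the position class per cell:
#' `"single"` (degree 0, no neighbors), `"edge"` (degree 1) or `"center"`
#' (degree >= 2).
#'
#' @param cells Data frame with `x_um`, `y_um` and optional `cell_id`
#'   (or a `popc_field`).
#' @param params An [annotation_params()]; if `NULL`, `eps` is estimated with
#'   [estimate_eps()] and `min_pts = 4`, `theta_edge = 120` are used.
#' @return A data frame of class `popc_annotation`: `cell_id`, `x_um`, `y_um`,
#'   `cluster_id`, `n_neighbors`, `is_edge`, `edge_degree`, `position_class`,
#'   with the parameters in `attr(, "params")`.
#' @examples
#' f <- generate_colony_field(generator_config(n_colonies = 2, n_singles = 5,
#'                                             seed = 7))
#' ann <- annotate_cells(f)
#' table(ann$position_class)
#' @export
annotate_cells <- function(cells, params = NULL) {
  cells <- .cells_df(cells)
  if (is.null(params)) {
    eps <- as.numeric(estimate_eps(cells))
    params <- annotation_params(eps = eps)
  }
  cl <- cluster_cells(cells, params)
  edge <- classify_edge(cells, cl, params)
  degree <- assign_edge_degree(cells, cl, params)
  pc <- ifelse(degree == 0L, "single", ifelse(degree == 1L, "edge", "center"))
  out <- data.frame(cell_id = cells$cell_id,
                    x_um = cells$x_um, y_um = cells$y_um,
                    cluster_id = cl$cluster,
                    n_neighbors = cl$n_neighbors,
                    is_edge = edge,
                    edge_degree = degree,
                    position_class = pc)
  attr(out, "params") <- params
  class(out) <- c("popc_annotation", "data.frame")
  out
}

#' @export
print.popc_annotation <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Spatial annotation of %d cells (eps = %.2f um, min_pts = %d, theta = %g deg)\n",
              nrow(x), p$eps, p$min_pts, p$theta_edge))
  print(table(position_class = x$position_class))
  invisible(x)
}

#' @export
summary.popc_annotation <- function(object, ...) {
  cl <- object$cluster_id[!is.na(object$cluster_id)]
  res <- list(n_cells = nrow(object),
              n_clusters = length(unique(cl)),
              n_singles = sum(object$position_class == "single"),
              degree_table = table(edge_degree = object$edge_degree))
  class(res) <- "summary.popc_annotation"
  res
}

#' @export
print.summary.popc_annotation <- function(x, ...) {
  cat(sprintf("%d cells in %d clusters, %d singles\n",
              x$n_cells, x$n_clusters, x$n_singles))
  print(x$degree_table)
  invisible(x)
}

#' @export
plot.popc_annotation <- function(x, ...) {
  cols <- c(single = "#D55E00", edge = "#0072B2", center = "#999999")
  graphics::plot(x$x_um, x$y_um, col = cols[x$position_class], pch = 19,
                 cex = 0.6, asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(x)
}

## Literal reference implementation -------------------------------------------

#' Brute-force reference annotator
#'
#' A deliberately literal O(n^2) implementation of the same annotation
#' semantics (full distance matrix, breadth-first density connectivity,
#' per-cell angular-gap loops, explicit peeling). It shares no code with the
#' grid-based pipeline annotator and serves as the ground-truth labeler for
#' the synthetic-data generator and as a cross-check in validation.
#'
#' @inheritParams annotate_cells
#' @param eps Neighborhood radius (µm).
#' @param min_pts DBSCAN core threshold.
#' @param theta_edge Angular-gap threshold (degrees).
#' @return Data frame `cell_id`, `cluster_id`, `n_neighbors`, `is_edge`,
#'   `edge_degree`, `position_class`.
#' @export
reference_annotation <- function(cells, eps, min_pts = 4, theta_edge = 120) {
  cells <- .cells_df(cells)
  n <- nrow(cells)
  x <- cells$x_um; y <- cells$y_um
  if (n == 0L)
    return(data.frame(cell_id = integer(0), cluster_id = integer(0),
                      n_neighbors = integer(0), is_edge = logical(0),
                      edge_degree = integer(0), position_class = character(0)))
  dm2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2  # squared distances
  eps2 <- eps^2
  nbl <- lapply(seq_len(n), function(i) {
    j <- which(dm2[i, ] <= eps2)
    j[j != i]
  })
  nnb <- lengths(nbl)
  core <- nnb >= min_pts - 1L
  cluster <- rep(NA_integer_, n)
  lab <- 0L
  queue <- integer(n)
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(cluster[i])) next
    lab <- lab + 1L
    queue[1] <- i; qh <- 1L; qt <- 1L
    cluster[i] <- lab
    while (qh <= qt) {
      cur <- queue[qh]; qh <- qh + 1L
      for (j in nbl[[cur]]) {
        if (core[j] && is.na(cluster[j])) {
          cluster[j] <- lab
          qt <- qt + 1L; queue[qt] <- j
        }
      }
    }
  }
  # border cells -> nearest core neighbor
  for (i in seq_len(n)) {
    if (core[i] || !nnb[i]) next
    cnb <- nbl[[i]][core[nbl[[i]]]]
    if (length(cnb)) {
      o <- order(dm2[i, cnb], cnb)
      cluster[i] <- cluster[cnb[o[1]]]
    }
  }
  # micro-colonies among leftovers
  for (i in seq_len(n)) {
    if (!is.na(cluster[i]) || !nnb[i]) next
    lab <- lab + 1L
    queue[1] <- i; qh <- 1L; qt <- 1L
    cluster[i] <- lab
    while (qh <= qt) {
      cur <- queue[qh]; qh <- qh + 1L
      for (j in nbl[[cur]]) {
        if (is.na(cluster[j]) && nnb[j] > 0L && !core[j]) {
          cluster[j] <- lab
          qt <- qt + 1L; queue[qt] <- j
        }
      }
    }
  }
  # relabel by smallest member
  if (any(!is.na(cluster))) {
    mins <- tapply(which(!is.na(cluster)), cluster[!is.na(cluster)], min)
    newid <- rank(mins, ties.method = "first")
    names(newid) <- names(mins)
    cluster[!is.na(cluster)] <- as.integer(newid[as.character(cluster[!is.na(cluster)])])
  }
  # peeling; per pass the remaining cluster sizes are computed once so each
  # cell's edge test costs only its neighbor count
  is_edge_of <- function(i, active, csize) {
    if (csize[[as.character(cluster[i])]] <= 2L) return(TRUE)
    nb <- nbl[[i]]
    nb <- nb[active[nb] & !is.na(cluster[nb]) & cluster[nb] == cluster[i]]
    if (!length(nb)) return(TRUE)
    b <- sort((atan2(y[nb] - y[i], x[nb] - x[i]) * 180 / pi) %% 360)
    gaps <- if (length(b) == 1L) 360 else c(diff(b), b[1] + 360 - b[length(b)])
    max(gaps) > theta_edge
  }
  degree <- rep(0L, n)
  active <- !is.na(cluster)
  first_pass <- rep(FALSE, n)
  d <- 1L
  while (any(active)) {
    csize <- table(cluster[active])
    idx <- which(active)
    edge_now <- idx[vapply(idx, is_edge_of, logical(1),
                           active = active, csize = csize)]
    if (d == 1L) first_pass[edge_now] <- TRUE
    if (!length(edge_now)) {
      degree[active] <- d
      break
    }
    degree[edge_now] <- d
    active[edge_now] <- FALSE
    d <- d + 1L
  }
  data.frame(cell_id = cells$cell_id,
             cluster_id = cluster,
             n_neighbors = nnb,
             is_edge = first_pass,
             edge_degree = degree,
             position_class = ifelse(degree == 0L, "single",
                                     ifelse(degree == 1L, "edge", "center")))
}
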