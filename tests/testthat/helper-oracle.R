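# Independent brute-force oracle for the spatial annotation semantics.
# Deliberately naive (full distance matrix, explicit loops, literal peeling);
# written from the definitions, sharing no code with the package internals.

oracle_annotate <- function(x, y, eps, min_pts = 4, theta = 120) {
  n <- length(x)
  D <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)  # full O(n^2) matrix
  neigh <- function(i, alive = rep(TRUE, n))
    setdiff(which(D[i, ] <= eps & alive), i)
  nnb <- sapply(seq_len(n), function(i) length(neigh(i)))
  core <- nnb >= min_pts - 1

  # density-connected components over core points
  cl <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(cl[i])) next
    nxt <- nxt + 1L
    todo <- i
    while (length(todo)) {
      c0 <- todo[1]; todo <- todo[-1]
      if (!is.na(cl[c0])) next
      cl[c0] <- nxt
      todo <- c(todo, intersect(neigh(c0), which(core & is.na(cl))))
    }
  }
  # border points: nearest core neighbor (ties -> smallest index)
  for (i in which(!core & nnb > 0)) {
    cn <- intersect(neigh(i), which(core))
    if (length(cn)) {
      cn <- cn[order(D[i, cn], cn)]
      cl[i] <- cl[cn[1]]
    }
  }
  # micro-colonies among the remaining neighbor-having cells
  for (i in seq_len(n)) {
    if (!is.na(cl[i]) || nnb[i] == 0) next
    nxt <- nxt + 1L
    todo <- i
    while (length(todo)) {
      c0 <- todo[1]; todo <- todo[-1]
      if (!is.na(cl[c0])) next
      cl[c0] <- nxt
      todo <- c(todo, intersect(neigh(c0), which(is.na(cl) & !core & nnb > 0)))
    }
  }
  # canonical labels: by smallest member index
  if (any(!is.na(cl))) {
    first_seen <- sapply(sort(unique(cl[!is.na(cl)])),
                         function(k) min(which(cl == k)))
    remap <- rank(first_seen, ties.method = "first")
    names(remap) <- sort(unique(cl[!is.na(cl)]))
    cl[!is.na(cl)] <- remap[as.character(cl[!is.na(cl)])]
  }

  is_edge <- function(i, alive) {
    mates <- which(alive & !is.na(cl) & cl == cl[i])
    if (length(mates) <= 2) return(TRUE)
    nb <- intersect(neigh(i, alive), mates)
    if (!length(nb)) return(TRUE)
    ang <- sort((atan2(y[nb] - y[i], x[nb] - x[i]) * 180 / pi) %% 360)
    gaps <- if (length(ang) == 1) 360 else c(diff(ang), 360 - (ang[length(ang)] - ang[1]))
    max(gaps) > theta
  }

  deg <- rep(0L, n)
  alive <- !is.na(cl)
  d <- 0L
  while (any(alive)) {
    d <- d + 1L
    peel <- which(alive)[sapply(which(alive), is_edge, alive = alive)]
    if (!length(peel)) { deg[alive] <- d; break }
    deg[peel] <- d
    alive[peel] <- FALSE
  }
  edge1 <- sapply(seq_len(n), function(i)
    if (is.na(cl[i])) FALSE else is_edge(i, !is.na(cl)))
  list(cluster = cl, n_neighbors = nnb, is_edge = edge1, degree = deg)
}

# small deterministic random field with a guaranteed minimum spacing
random_field <- function(n, w = 400, h = 400, min_d = 8, seed = 1) {
  set.seed(seed)
  xs <- ys <- numeric(0)
  while (length(xs) < n) {
    px <- runif(1, 0, w); py <- runif(1, 0, h)
    if (!length(xs) || min(sqrt((xs - px)^2 + (ys - py)^2)) >= min_d) {
      xs <- c(xs, px); ys <- c(ys, py)
    }
  }
  data.frame(x_um = xs, y_um = ys)
}
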