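# Internal geometry and bookkeeping helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Simple scalar checks -------------------------------------------------------

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok_lower <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_lower || x > upper)
    stop(sprintf("'%s' = %g is outside its allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must contain probabilities in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

## Neighbor search ------------------------------------------------------------

# All ordered point pairs (i -> j, i != j) with distance <= eps, found by grid
# binning so fields of several thousand cells stay cheap. Bearings are in
# degrees, measured counter-clockwise from +x, in [0, 360).
.neighbor_pairs <- function(x, y, eps) {
  n <- length(x)
  empty <- data.frame(i = integer(0), j = integer(0),
                      d = numeric(0), bearing = numeric(0))
  if (n < 2L) return(empty)
  cx <- as.integer(floor(x / eps))
  cy <- as.integer(floor(y / eps))
  key <- paste(cx, cy, sep = ",")
  bins <- split(seq_len(n), key)
  bin_of <- function(kx, ky) bins[[paste(kx, ky, sep = ",")]]
  # unordered pair collection: bin with itself + 4 of the 8 neighbor offsets
  offs <- list(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  ii <- jj <- vector("list", 0L)
  ubins <- unique(key)
  coords <- do.call(rbind, strsplit(ubins, ",", fixed = TRUE))
  ukx <- as.integer(coords[, 1]); uky <- as.integer(coords[, 2])
  for (b in seq_along(ubins)) {
    a <- bins[[ubins[b]]]
    for (o in offs) {
      if (o[1] == 0L && o[2] == 0L) {
        if (length(a) > 1L) {
          cmb <- utils::combn(a, 2L)
          ii <- c(ii, list(cmb[1, ])); jj <- c(jj, list(cmb[2, ]))
        }
      } else {
        bpts <- bin_of(ukx[b] + o[1], uky[b] + o[2])
        if (!is.null(bpts)) {
          g <- expand.grid(a = a, b = bpts, KEEP.OUT.ATTRS = FALSE)
          ii <- c(ii, list(g$a)); jj <- c(jj, list(g$b))
        }
      }
    }
  }
  if (!length(ii)) return(empty)
  i <- unlist(ii, use.names = FALSE)
  j <- unlist(jj, use.names = FALSE)
  dx <- x[j] - x[i]; dy <- y[j] - y[i]
  d <- sqrt(dx * dx + dy * dy)
  keep <- d <= eps
  if (!any(keep)) return(empty)
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  dx <- dx[keep]; dy <- dy[keep]
  # both directions
  bearing_ij <- (atan2(dy, dx) * 180 / pi) %% 360
  bearing_ji <- (bearing_ij + 180) %% 360
  out <- data.frame(i = c(i, j), j = c(j, i), d = c(d, d),
                    bearing = c(bearing_ij, bearing_ji))
  out[order(out$i, out$j), , drop = FALSE]
}

# Largest angular gap (degrees) between bearings, per group. `i` must be
# sorted, `bearing` sorted within each group. Returns a named vector keyed by
# the group ids. A group with a single bearing has gap 360.
.max_angular_gap <- function(i, bearing) {
  if (!length(i)) return(stats::setNames(numeric(0), character(0)))
  n <- length(i)
  newg <- c(TRUE, i[-1L] != i[-n])
  gid <- cumsum(newg)
  lastg <- c(newg[-1L], TRUE)
  gaps <- numeric(n)
  mid <- which(!lastg)
  gaps[mid] <- bearing[mid + 1L] - bearing[mid]
  firstb <- bearing[newg][gid]
  wl <- which(lastg)
  gaps[wl] <- firstb[wl] + 360 - bearing[wl]
  res <- vapply(split(gaps, gid), max, numeric(1))
  names(res) <- as.character(i[newg])
  res
}

## Union-find -----------------------------------------------------------------

.uf_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_along(from)) {
    ra <- find(from[k]); rb <- find(to[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, integer(1))
}

## Seed handling --------------------------------------------------------------

# Deterministic child seeds so that adding a stage never perturbs the
# randomness of earlier stages.
.child_seed <- function(seed, stage) {
  offsets <- c(generate = 101L, intensities = 211L, infection = 307L,
               lfq = 401L, annotate = 503L, respond = 601L,
               radial = 701L, polarity = 809L)
  if (!stage %in% names(offsets))
    stop("unknown stage for seed derivation: ", stage, call. = FALSE)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
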