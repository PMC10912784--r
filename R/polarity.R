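# Apical-versus-basolateral surface proteome comparison: background and
# validity filtering, randomized two-sample t-tests with permutation-based
# FDR, log2 apical/basolateral ratio, and the apical index.

.lfq_groups <- function(lfq) {
  g <- attr(lfq, "groups")
  if (is.null(g) || !all(c("apical", "basolateral") %in% names(g)))
    stop("LFQ table lacks its group attribute; read it with read_lfq_table() ",
         "or generate it with generate_lfq_table()", call. = FALSE)
  g
}

.lfq_matrix <- function(lfq, cols) {
  m <- as.matrix(as.data.frame(lfq)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# Linear-scale side mean: mean of 2^log2 over detected replicates, 0 when
# none detected.
.linear_mean <- function(m) {
  lin <- 2^m
  out <- rowMeans(lin, na.rm = TRUE)
  out[!is.finite(out)] <- 0
  out[rowSums(!is.na(m)) == 0L] <- 0
  out
}

#' Filter proteins dominated by bead background
#'
#' Removes proteins whose mean background LFQ (linear scale) exceeds
#' `max_ratio` (default 25%) of the larger of the apical and basolateral
#' linear means — non-specific binders to the pulldown beads. Proteins absent
#' from all background replicates are always retained.
#'
#' @param lfq A `popc_lfq` table with a background group.
#' @param max_ratio Background dominance cutoff (default 0.25).
#' @return The filtered table; removed protein ids in `attr(, "removed")`.
#' @export
filter_background <- function(lfq, max_ratio = 0.25) {
  g <- .lfq_groups(lfq)
  if (is.null(g$background) || !length(g$background))
    stop("no background sample group in the LFQ table", call. = FALSE)
  bg <- .linear_mean(.lfq_matrix(lfq, g$background))
  ap <- .linear_mean(.lfq_matrix(lfq, g$apical))
  bl <- .linear_mean(.lfq_matrix(lfq, g$basolateral))
  drop <- bg > max_ratio * pmax(ap, bl)
  out <- lfq[!drop, , drop = FALSE]
  attr(out, "groups") <- g
  attr(out, "removed") <- lfq$protein_id[drop]
  class(out) <- class(lfq)
  out
}

#' Filter proteins by replicate support and annotation terms
#'
#' A protein is kept when it is detected in at least `min_replicates`
#' replicates of at least one side group, and carries at least one of the
#' required annotation terms (case-insensitive exact term match on the
#' semicolon-separated `terms` column). Both failure reasons are reported per
#' dropped protein.
#'
#' @param lfq A `popc_lfq` table.
#' @param min_replicates Minimum detections in one side group (default 3).
#' @param required_terms Character vector of acceptable terms; the default is
#'   the plasma-membrane / cell-surface set used for surface proteome
#'   filtering. Set `NULL` to skip term filtering.
#' @return Filtered table; drop reasons in `attr(, "dropped")`.
#' @export
filter_valid <- function(lfq, min_replicates = 3,
                         required_terms = c("plasma membrane",
                                            "plasma membrane part",
                                            "cell surface",
                                            "cell outer membrane")) {
  g <- .lfq_groups(lfq)
  if (!is.null(required_terms) && !length(required_terms))
    stop("'required_terms' is empty; pass NULL to disable term filtering",
         call. = FALSE)
  nap <- rowSums(!is.na(.lfq_matrix(lfq, g$apical)))
  nbl <- rowSums(!is.na(.lfq_matrix(lfq, g$basolateral)))
  enough <- pmax(nap, nbl) >= min_replicates
  if (is.null(required_terms)) {
    has_term <- rep(TRUE, nrow(lfq))
  } else {
    req <- tolower(trimws(required_terms))
    has_term <- vapply(strsplit(tolower(as.character(lfq$terms)), ";"),
                       function(tt) any(trimws(tt) %in% req), logical(1))
    has_term[is.na(has_term)] <- FALSE
  }
  keep <- enough & has_term
  dropped <- data.frame(protein_id = lfq$protein_id[!keep],
                        too_few_replicates = !enough[!keep],
                        no_required_term = !has_term[!keep])
  out <- lfq[keep, , drop = FALSE]
  attr(out, "groups") <- g
  attr(out, "dropped") <- dropped
  class(out) <- class(lfq)
  out
}

# Row-wise Welch t statistics, apical vs basolateral, NA-aware. Rows with
# fewer than 2 detections on either side give NA.
.row_t <- function(ap, bl) {
  na_ <- rowSums(!is.na(ap)); nb_ <- rowSums(!is.na(bl))
  ma <- rowSums(ap, na.rm = TRUE) / na_
  mb <- rowSums(bl, na.rm = TRUE) / nb_
  va <- pmax(rowSums(ap^2, na.rm = TRUE) - na_ * ma^2, 0) / (na_ - 1L)
  vb <- pmax(rowSums(bl^2, na.rm = TRUE) - nb_ * mb^2, 0) / (nb_ - 1L)
  se <- sqrt(va / na_ + vb / nb_)
  t <- (ma - mb) / se
  t[se == 0 & ma == mb] <- 0  # degenerate: identical values both sides
  t[na_ < 2L | nb_ < 2L] <- NA
  t
}

#' Apical index
#'
#' Fraction of a protein's surface abundance on the apical membrane:
#' `A / (A + B)` with `A`, `B` the linear-scale mean LFQ of the apical and
#' basolateral side. A side with no detected replicate contributes 0; a side
#' with a single detection contributes that value. Both sides undetected
#' gives NA.
#'
#' @param apical,basolateral Linear-scale side values (numeric vectors), or
#'   pass an `popc_lfq` table as the single first argument.
#' @return Numeric vector of apical indices in \[0, 1\].
#' @examples
#' apical_index(1, 3)   # 0.25: "75% basolateral"
#' @export
apical_index <- function(apical, basolateral = NULL) {
  if (inherits(apical, "popc_lfq")) {
    g <- .lfq_groups(apical)
    A <- .linear_mean(.lfq_matrix(apical, g$apical))
    B <- .linear_mean(.lfq_matrix(apical, g$basolateral))
  } else {
    A <- apical; B <- basolateral
    if (any(c(A, B) < 0, na.rm = TRUE))
      stop("LFQ values must be non-negative on the linear scale", call. = FALSE)
  }
  out <- A / (A + B)
  out[A + B == 0] <- NA_real_
  out
}

#' Differential apical/basolateral enrichment with permutation FDR
#'
#' Per protein, a Welch two-sample t statistic on log2 LFQ (apical vs
#' basolateral, detected replicates only). The null distribution comes from
#' group-label randomization applied across all proteins (whole-column label
#' shuffles, default 250 randomizations, fixed seed); the q-value of a
#' protein is the permutation-based FDR at its |t|:
#' (mean number of null |t| >= |t| per randomization) / (number of observed
#' |t| >= |t|), monotonized so q never decreases as |t| decreases
#' (Perseus-style). Proteins with fewer than 2 detections on a side are
#' reported untested rather than dropped.
#'
#' @param lfq A `popc_lfq` table (typically after [filter_background()] and
#'   [filter_valid()]).
#' @param n_randomizations Number of label randomizations (default 250).
#' @param fdr_level Significance level on the q-value (default 0.05).
#' @param seed Seed for the randomizations (default 1).
#' @return A `popc_polarity` data frame: `protein_id`, `log2_ratio_AP_BL`,
#'   `t_stat`, `q_value`, `significant`, `apical_index`,
#'   `n_detected_apical`, `n_detected_basolateral`, `tested`.
#' @export
differential_polarity <- function(lfq, n_randomizations = 250,
                                  fdr_level = 0.05, seed = 1L) {
  g <- .lfq_groups(lfq)
  ap <- .lfq_matrix(lfq, g$apical)
  bl <- .lfq_matrix(lfq, g$basolateral)
  nap <- rowSums(!is.na(ap)); nbl <- rowSums(!is.na(bl))
  t_obs <- .row_t(ap, bl)
  tested <- !is.na(t_obs)
  comb <- cbind(ap, bl)
  n_ap <- ncol(ap); n_tot <- ncol(comb)
  set.seed(.child_seed(seed, "polarity"))
  abs_obs <- abs(t_obs[tested])
  null_counts <- numeric(length(abs_obs))  # total null stats >= each obs |t|
  for (b in seq_len(n_randomizations)) {
    perm <- sample.int(n_tot)
    ap_p <- comb[, perm[seq_len(n_ap)], drop = FALSE]
    bl_p <- comb[, perm[-seq_len(n_ap)], drop = FALSE]
    t_null <- abs(.row_t(ap_p, bl_p))
    t_null <- t_null[!is.na(t_null)]
    if (length(t_null) && length(abs_obs)) {
      st <- sort(t_null)
      # for each observed |t|: count null >= it
      null_counts <- null_counts +
        (length(st) - findInterval(abs_obs - 1e-12, st))
    }
  }
  q <- rep(NA_real_, length(t_obs))
  if (any(tested)) {
    mean_null_ge <- null_counts / n_randomizations
    obs_ge <- vapply(abs_obs, function(tt) sum(abs_obs >= tt - 1e-12),
                     numeric(1))
    fdr <- pmin(mean_null_ge / obs_ge, 1)
    # monotonize: q non-increasing in |t|
    o <- order(abs_obs, decreasing = TRUE)
    fdr_sorted <- cummax(fdr[o])
    qt <- numeric(length(abs_obs))
    qt[o] <- fdr_sorted
    q[tested] <- qt
  }
  log2_ratio <- rowMeans(ap, na.rm = TRUE) - rowMeans(bl, na.rm = TRUE)
  log2_ratio[nap == 0L | nbl == 0L] <- NA_real_
  out <- data.frame(protein_id = lfq$protein_id,
                    log2_ratio_AP_BL = log2_ratio,
                    t_stat = t_obs,
                    q_value = q,
                    significant = !is.na(q) & q <= fdr_level,
                    apical_index = apical_index(lfq),
                    n_detected_apical = nap,
                    n_detected_basolateral = nbl,
                    tested = tested)
  attr(out, "n_randomizations") <- n_randomizations
  attr(out, "fdr_level") <- fdr_level
  class(out) <- c("popc_polarity", "data.frame")
  out
}

#' @export
print.popc_polarity <- function(x, ...) {
  cat(sprintf("Apical/basolateral polarity: %d proteins, %d tested, %d significant at FDR %.2g (%d randomizations)\n",
              nrow(x), sum(x$tested), sum(x$significant),
              attr(x, "fdr_level"), attr(x, "n_randomizations")))
  invisible(x)
}

#' Volcano-plot-ready table
#'
#' @param polarity A `popc_polarity` result.
#' @return Data frame with `protein_id`, `log2_ratio_AP_BL`,
#'   `neg_log10_q` and `significant`.
#' @export
volcano_table <- function(polarity) {
  stopifnot(inherits(polarity, "popc_polarity"))
  data.frame(protein_id = polarity$protein_id,
             log2_ratio_AP_BL = polarity$log2_ratio_AP_BL,
             neg_log10_q = -log10(pmax(polarity$q_value, 1e-300)),
             significant = polarity$significant)
}
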