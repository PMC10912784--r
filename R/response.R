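# Responder classification against mock, per-group response summaries,
# rank correlation with edge degree, infected-cell counting and qPCR fold
# change.

#' Responder intensity threshold from mock-treated cells
#'
#' The reporter is only expressed upon interferon signaling, so the mock
#' condition defines the negative intensity distribution. The default rule is
#' the 99th percentile of mock reporter intensities (the mock false-positive
#' rate is then 1% by construction); `"mean_sd"` uses mean + 3 SD instead.
#'
#' @param mock_intensities Numeric vector of mock-condition reporter
#'   intensities (same timepoint as the treated cells to classify).
#' @param method `"quantile"` (default) or `"mean_sd"`.
#' @param level Quantile level (default 0.99) or SD multiplier (default 3).
#' @return The threshold (a.u.), with mock summary statistics attached as
#'   attributes (`n`, `mock_mean`, `mock_sd`, `method`, `level`).
#' @export
responder_threshold <- function(mock_intensities,
                                method = c("quantile", "mean_sd"),
                                level = NULL) {
  method <- match.arg(method)
  mock_intensities <- mock_intensities[is.finite(mock_intensities)]
  n <- length(mock_intensities)
  if (n == 0L) stop("empty mock intensity set", call. = FALSE)
  if (method == "quantile") {
    if (is.null(level)) level <- 0.99
    if (n < 50L)
      stop("quantile threshold needs >= 50 mock cells (have ", n,
           "); use method = 'mean_sd' or pool more mock fields", call. = FALSE)
    thr <- unname(stats::quantile(mock_intensities, level))
  } else {
    if (is.null(level)) level <- 3
    thr <- mean(mock_intensities) + level * stats::sd(mock_intensities)
  }
  structure(thr, n = n, mock_mean = mean(mock_intensities),
            mock_sd = stats::sd(mock_intensities),
            method = method, level = level)
}

.join_annotation <- function(cells, annotations) {
  stopifnot(is.data.frame(cells))
  ann_cols <- c("cell_id", "cluster_id", "n_neighbors", "is_edge",
                "edge_degree", "position_class")
  ann <- as.data.frame(annotations)[, intersect(ann_cols, names(annotations))]
  by <- "cell_id"
  if ("field_id" %in% names(cells) && "field_id" %in% names(annotations)) {
    ann$field_id <- annotations$field_id
    by <- c("field_id", "cell_id")
  }
  merge(cells, ann, by = by, sort = FALSE)
}

#' Percent responder cells per group
#'
#' Joins the annotation onto the cell table and computes, per well and group
#' (edge degree or position class), the number and percentage of cells whose
#' reporter intensity exceeds the responder threshold. Fields of view within
#' a well are pooled before the percentage is taken. Groups with fewer than
#' `n_min` cells are flagged `low_confidence`, never dropped silently.
#'
#' @param cells Cell data frame (needs the intensity channel and, if present,
#'   `well_id`; a single well is assumed otherwise).
#' @param annotations A `popc_annotation` (joined by `cell_id`, and
#'   `field_id` when both sides carry it).
#' @param threshold Responder threshold from [responder_threshold()].
#' @param group_by Grouping column: `"edge_degree"` (default) or
#'   `"position_class"` (any annotation column works).
#' @param channel Intensity column name (default `"reporter"`).
#' @param n_min Minimum cells per group before flagging (default 10).
#' @return Data frame: `well_id`, group column, `n_cells`, `n_positive`,
#'   `percent_positive`, `mean_intensity`, `low_confidence`.
#' @export
percent_positive_by_group <- function(cells, annotations, threshold,
                                      group_by = "edge_degree",
                                      channel = "reporter", n_min = 10) {
  joined <- .join_annotation(cells, annotations)
  if (!group_by %in% names(joined))
    stop("grouping column '", group_by, "' not found after join", call. = FALSE)
  if (!channel %in% names(joined))
    stop("intensity channel '", channel, "' not found", call. = FALSE)
  if (!"well_id" %in% names(joined)) joined$well_id <- "well1"
  pos <- joined[[channel]] > as.numeric(threshold)
  key <- interaction(joined$well_id, joined[[group_by]], drop = TRUE)
  agg <- data.frame(well_id = tapply(as.character(joined$well_id), key, `[`, 1),
                    group = tapply(as.character(joined[[group_by]]), key, `[`, 1),
                    n_cells = as.integer(tapply(pos, key, length)),
                    n_positive = as.integer(tapply(pos, key, sum)),
                    mean_intensity = as.numeric(tapply(joined[[channel]], key, mean)))
  names(agg)[names(agg) == "group"] <- group_by
  agg$percent_positive <- 100 * agg$n_positive / agg$n_cells
  agg$low_confidence <- agg$n_cells < n_min
  rownames(agg) <- NULL
  # numeric groups (edge degree) come back as character from interaction()
  if (group_by == "edge_degree")
    agg[[group_by]] <- as.integer(agg[[group_by]])
  agg[order(agg$well_id, agg[[group_by]]),
      c("well_id", group_by, "n_cells", "n_positive", "percent_positive",
        "mean_intensity", "low_confidence")]
}

#' Spearman rank correlation between edge degree and percent positive
#'
#' Midrank Spearman correlation over per-well per-degree points (one point
#' per well per degree, as produced by [percent_positive_by_group()]).
#' Two-sided p-value: exact for n <= 10 without ties, t-approximation
#' otherwise. Both the signed coefficient and its magnitude are reported; the
#' association between embedding depth and responsiveness is negative, and
#' its strength is conventionally quoted as the magnitude.
#'
#' @param summary Data frame with the two variables.
#' @param x,y Column names (defaults `edge_degree`, `percent_positive`).
#' @return `popc_corr` list: `rho`, `abs_rho`, `p_value`, `n`, `method`.
#' @export
spearman_degree_correlation <- function(summary, x = "edge_degree",
                                        y = "percent_positive") {
  stopifnot(is.data.frame(summary), x %in% names(summary),
            y %in% names(summary))
  xv <- as.numeric(summary[[x]]); yv <- as.numeric(summary[[y]])
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 5L) stop("need >= 5 points for the correlation", call. = FALSE)
  if (stats::var(xv) == 0 || stats::var(yv) == 0)
    stop("zero variance in '", if (stats::var(xv) == 0) x else y,
         "': rank correlation undefined", call. = FALSE)
  rx <- rank(xv); ry <- rank(yv)  # midranks for ties
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(xv) > 0 || anyDuplicated(yv) > 0
  if (n <= 10L && !ties) {
    p <- stats::cor.test(xv, yv, method = "spearman", exact = TRUE)$p.value
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(rho = rho, abs_rho = abs(rho), p_value = p, n = n,
                 method = "Spearman rank correlation (midranks, two-sided)"),
            class = "popc_corr")
}

#' @export
print.popc_corr <- function(x, ...) {
  cat(sprintf("%s\n  rho = %.4f (|rho| = %.4f), p = %.3g, n = %d\n",
              x$method, x$rho, x$abs_rho, x$p_value, x$n))
  invisible(x)
}

#' Mock-normalized mean fluorescence intensity
#'
#' Mean intensity per treated group divided by the mean intensity of the
#' matched mock group (matched by the grouping columns, typically timepoint).
#'
#' @param treated,mock Cell data frames with the intensity channel.
#' @param group_by Character vector of grouping columns present in both
#'   (default none: one global fold value).
#' @param channel Intensity column (default `"reporter"`).
#' @return Data frame with the group columns and `fold` (treated MFI / mock
#'   MFI).
#' @export
normalized_mfi <- function(treated, mock, group_by = character(0),
                           channel = "reporter") {
  mean_by <- function(df) {
    if (!length(group_by)) return(data.frame(mfi = mean(df[[channel]])))
    a <- stats::aggregate(df[[channel]], by = df[group_by], FUN = mean)
    names(a)[ncol(a)] <- "mfi"
    a
  }
  tm <- mean_by(treated); mm <- mean_by(mock)
  if (!length(group_by)) return(data.frame(fold = tm$mfi / mm$mfi))
  merged <- merge(tm, mm, by = group_by, suffixes = c("_treated", "_mock"),
                  all.x = TRUE)
  if (anyNA(merged$mfi_mock)) {
    bad <- merged[is.na(merged$mfi_mock), group_by, drop = FALSE]
    stop("no matched mock group for: ",
         paste(apply(bad, 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  merged$fold <- merged$mfi_treated / merged$mfi_mock
  merged[, c(group_by, "fold")]
}

#' Infected-cell fraction from a control-derived threshold
#'
#' Sets the virus-channel threshold from non-infected control cells (default
#' the 99.9th percentile of the control distribution, `method = "max"` uses
#' the control maximum) and counts, per condition, the percentage of nuclei
#' with higher virus-channel fluorescence.
#'
#' @param cells Data frame with the virus channel and optionally a
#'   `condition` column.
#' @param control Data frame (or numeric vector) of non-infected control
#'   intensities.
#' @param channel Virus channel column name (default `"virus"`).
#' @param method `"quantile"` (default) or `"max"`.
#' @param level Quantile level (default 0.999).
#' @return Data frame: `condition`, `n_cells`, `n_infected`,
#'   `percent_infected`; the threshold is attached as an attribute.
#' @export
infected_fraction <- function(cells, control, channel = "virus",
                              method = c("quantile", "max"), level = 0.999) {
  method <- match.arg(method)
  ctl <- if (is.data.frame(control)) control[[channel]] else control
  ctl <- ctl[is.finite(ctl)]
  if (!length(ctl)) stop("empty non-infected control set", call. = FALSE)
  thr <- if (method == "quantile") unname(stats::quantile(ctl, level)) else max(ctl)
  v <- cells[[channel]]
  cond <- if ("condition" %in% names(cells)) cells$condition
          else rep("sample", length(v))
  key <- factor(cond)
  out <- data.frame(condition = levels(key),
                    n_cells = as.integer(tapply(v, key, length)),
                    n_infected = as.integer(tapply(v > thr, key, sum)))
  out$percent_infected <- 100 * out$n_infected / out$n_cells
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' qPCR fold change by the delta-delta-Ct method
#'
#' Per sample, the gene Ct is normalized to the housekeeping gene
#' (delta Ct = Ct_gene - Ct_housekeeping); the treated delta Ct is then
#' normalized to the mean mock delta Ct of the matched gene and timepoint
#' (delta-delta Ct), and fold change = 2^(-delta-delta Ct). Replicate mean
#' and SD of the fold change are reported per gene x condition x timepoint.
#'
#' @param ct Ct table (see [validate_ct_table()]).
#' @param housekeeping_gene Housekeeping gene name (e.g. `"TBP"`).
#' @param mock_condition Name of the mock condition (default `"mock"`).
#' @return Data frame: `gene`, `condition`, `timepoint`, `n`, `fold_mean`,
#'   `fold_sd`, plus per-sample folds in `attr(, "per_sample")`.
#' @export
qpcr_fold_change <- function(ct, housekeeping_gene = "TBP",
                             mock_condition = "mock") {
  ct <- validate_ct_table(ct)
  hk <- ct[ct$gene == housekeeping_gene, ]
  if (!nrow(hk)) stop("housekeeping gene '", housekeeping_gene,
                      "' absent from the Ct table", call. = FALSE)
  genes <- ct[ct$gene != housekeeping_gene, ]
  m <- merge(genes, hk[, c("sample", "ct")], by = "sample",
             suffixes = c("", "_hk"))
  if (nrow(m) < nrow(genes))
    stop("housekeeping Ct missing for sample(s): ",
         paste(setdiff(genes$sample, hk$sample), collapse = ", "),
         call. = FALSE)
  m$dct <- m$ct - m$ct_hk
  mock <- m[m$condition == mock_condition, ]
  if (!nrow(mock)) stop("no '", mock_condition, "' rows in the Ct table",
                        call. = FALSE)
  mock_key <- interaction(mock$gene, mock$timepoint, drop = TRUE)
  mock_dct <- tapply(mock$dct, mock_key, mean)
  m$key <- paste(m$gene, m$timepoint, sep = ".")
  if (!all(m$key %in% names(mock_dct)))
    stop("no matched mock for: ",
         paste(unique(m$key[!m$key %in% names(mock_dct)]), collapse = ", "),
         call. = FALSE)
  m$ddct <- m$dct - as.numeric(mock_dct[m$key])
  m$fold <- 2^(-m$ddct)
  gkey <- interaction(m$gene, m$condition, m$timepoint, drop = TRUE)
  out <- data.frame(gene = tapply(m$gene, gkey, `[`, 1),
                    condition = tapply(as.character(m$condition), gkey, `[`, 1),
                    timepoint = tapply(as.character(m$timepoint), gkey, `[`, 1),
                    n = as.integer(tapply(m$fold, gkey, length)),
                    fold_mean = as.numeric(tapply(m$fold, gkey, mean)),
                    fold_sd = as.numeric(tapply(m$fold, gkey, stats::sd)))
  rownames(out) <- NULL
  attr(out, "per_sample") <- m[, c("sample", "gene", "condition", "timepoint",
                                   "dct", "ddct", "fold")]
  out
}

#' Two-group and one-way comparisons used in figure-style summaries
#'
#' Thin standard-definition wrappers: Welch's unpaired t-test and one-way
#' ANOVA, for parity with the usual per-figure statistics.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector.
#' @return For `welch_test`, the `htest` from [stats::t.test()] (two groups
#'   required); for `oneway_anova`, the `aov` fit summary p-value.
#' @export
welch_test <- function(values, groups) {
  g <- unique(groups)
  if (length(g) != 2L) stop("welch_test needs exactly two groups", call. = FALSE)
  stats::t.test(values[groups == g[1]], values[groups == g[2]])
}

#' @rdname welch_test
#' @export
oneway_anova <- function(values, groups) {
  fit <- stats::aov(values ~ factor(groups))
  summary(fit)[[1]][["Pr(>F)"]][1]
}
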