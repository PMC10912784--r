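# Responder classification, per-group summaries, rank correlation, infected
# fraction and qPCR fold change.

test_that("threshold on constant mock equals the constant", {
  thr <- responder_threshold(rep(7, 100))
  expect_equal(as.numeric(thr), 7)
  expect_error(responder_threshold(numeric(0)), "empty mock")
  expect_error(responder_threshold(rep(1, 10)), ">= 50 mock cells")
  # mean + 3 SD alternative works on small sets
  thr2 <- responder_threshold(c(1, 2, 3), method = "mean_sd")
  expect_equal(as.numeric(thr2), 2 + 3 * 1)
})

test_that("99th-percentile threshold classifies about 1% of held-out mock positive", {
  set.seed(41)
  mock_a <- rlnorm(1000, log(100), 0.35)
  mock_b <- rlnorm(10000, log(100), 0.35)  # independent held-out sample
  thr <- responder_threshold(mock_a)
  frac <- mean(mock_b > as.numeric(thr))
  expect_lt(abs(frac - 0.01), 0.005)
})

test_that("per-group percentages pool fields within a well and flag small groups", {
  cells <- data.frame(cell_id = 1:40,
                      well_id = rep(c("A", "B"), each = 20),
                      reporter = c(rep(10, 15), rep(100, 5),
                                   rep(10, 10), rep(100, 10)))
  ann <- data.frame(cell_id = 1:40, edge_degree = rep(c(0L, 1L), 20))
  s <- percent_positive_by_group(cells, ann, threshold = 50)
  expect_identical(nrow(s), 4L)
  a0 <- s[s$well_id == "A" & s$edge_degree == 0, ]
  expect_equal(a0$percent_positive, 100 * a0$n_positive / a0$n_cells)
  expect_true(all(s$percent_positive >= 0 & s$percent_positive <= 100))
  expect_true(all(s$n_positive <= s$n_cells))
  # all below threshold: zero percent everywhere
  s0 <- percent_positive_by_group(within(cells, reporter <- 1), ann, 50)
  expect_true(all(s0$percent_positive == 0))
  # small groups flagged, not dropped
  expect_true(all(s$low_confidence[s$n_cells < 10]))
  expect_error(percent_positive_by_group(cells, ann, 50, group_by = "nope"),
               "not found")
})

test_that("spearman correlation: rank identities, errors, and midrank oracle", {
  mono <- data.frame(edge_degree = 0:5, percent_positive = c(90, 70, 50, 30, 20, 5))
  r <- spearman_degree_correlation(mono)
  expect_equal(r$rho, -1)
  expect_equal(r$abs_rho, 1)

  flat <- data.frame(edge_degree = 0:5, percent_positive = 50)
  expect_error(spearman_degree_correlation(flat), "zero variance")
  expect_error(spearman_degree_correlation(mono[1:3, ]), ">= 5 points")

  # independent O(n^2) midrank computation on a tied 20-point table
  set.seed(13)
  tab <- data.frame(edge_degree = rep(0:4, 4),
                    percent_positive = round(runif(20, 0, 100) / 5) * 5)
  r2 <- spearman_degree_correlation(tab)
  midrank <- function(v) {
    n <- length(v); out <- numeric(n)
    for (i in seq_len(n)) out[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    out
  }
  rx <- midrank(tab$edge_degree); ry <- midrank(tab$percent_positive)
  rho_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(r2$rho, rho_oracle)
})

test_that("per-degree percentages decrease when generator probabilities do", {
  probs <- c(`0` = 0.8, `1` = 0.55, `2` = 0.3)
  cfg <- generator_config(response_prob_by_degree = probs, seed = 19)
  g <- expand.grid(x_um = (0:44) * 40, y_um = (0:44) * 40)  # 2025 cells
  degrees <- rep(0:2, length.out = nrow(g))
  f <- structure(list(cells = data.frame(cell_id = seq_len(nrow(g)), g,
                                         true_colony_id = NA_integer_,
                                         true_is_single = TRUE),
                      config = cfg, mode = "colony"), class = "popc_field")
  f <- assign_response_intensities(f, cfg, degrees)
  mock_cfg <- cfg; mock_cfg$seed <- 777L
  m <- assign_response_intensities(f, mock_cfg, degrees, condition = "mock")
  thr <- responder_threshold(m$cells$reporter)
  ann <- data.frame(cell_id = f$cells$cell_id, edge_degree = degrees)
  s <- percent_positive_by_group(f$cells, ann, thr)
  expect_true(all(diff(s$percent_positive[order(s$edge_degree)]) < 0))
  expect_true(all(abs(s$percent_positive / 100 -
                        probs[as.character(s$edge_degree)]) < 0.05))
})

test_that("normalized MFI reproduces trivial and closed-form mixture folds", {
  treated <- data.frame(reporter = rep(c(2, 4), 50))
  mock <- data.frame(reporter = rep(c(2, 4), 50))
  expect_equal(normalized_mfi(treated, mock)$fold, 1)
  expect_equal(normalized_mfi(within(treated, reporter <- reporter * 2),
                              mock)$fold, 2)
  # 40% responders at fold 3.5 over baseline: group fold = 1 + 0.4 * 2.5 = 2
  n <- 10000
  base <- 100
  treated2 <- data.frame(reporter = c(rep(base * 3.5, 0.4 * n),
                                      rep(base, 0.6 * n)))
  mock2 <- data.frame(reporter = rep(base, n))
  expect_equal(normalized_mfi(treated2, mock2)$fold, 2)
  # missing matched mock group is an error naming the group
  t3 <- data.frame(reporter = 1, timepoint = "48h")
  m3 <- data.frame(reporter = 1, timepoint = "24h")
  expect_error(normalized_mfi(t3, m3, group_by = "timepoint"), "48h")
})

test_that("infected fraction: quantile tail, separation recovery, zero case", {
  set.seed(59)
  ctl <- rlnorm(20000, log(50), 0.3)
  same <- data.frame(virus = rlnorm(20000, log(50), 0.3))
  f_same <- infected_fraction(same, ctl)
  expect_lt(abs(f_same$percent_infected - 0.1), 0.1)  # 99.9th pct tail
  mixed <- data.frame(virus = c(rlnorm(5000, log(50), 0.3),
                                rlnorm(5000, log(800), 0.3)))
  f_mix <- infected_fraction(mixed, ctl)
  expect_lt(abs(f_mix$percent_infected - 50), 2)
  below <- data.frame(virus = rep(1, 100))
  expect_equal(infected_fraction(below, ctl, method = "max")$percent_infected, 0)
  expect_error(infected_fraction(below, numeric(0)), "empty")
})

test_that("delta-delta-Ct folds match a hand-computed oracle", {
  # treated == mock -> fold 1; ddCt = -3 -> fold 8
  ct <- data.frame(sample = rep(c("m1", "t1"), each = 2),
                   gene = rep(c("TBP", "IFIT1"), 2),
                   ct = c(20, 28, 20, 25),
                   condition = rep(c("mock", "IFN"), each = 2),
                   timepoint = "24h")
  out <- qpcr_fold_change(ct)
  expect_equal(out$fold_mean[out$condition == "mock"], 1)
  expect_equal(out$fold_mean[out$condition == "IFN"], 8)

  # randomized toy table against a literal spreadsheet-style computation
  set.seed(3)
  genes <- c("IFIT1", "MX1")
  samples <- expand.grid(cond = c("mock", "IFN"), rep = 1:3, tp = c("6h", "24h"))
  rows <- list()
  for (k in seq_len(nrow(samples))) {
    sm <- paste0(samples$cond[k], samples$rep[k], samples$tp[k])
    hk_ct <- runif(1, 18, 22)
    rows[[length(rows) + 1]] <- data.frame(sample = sm, gene = "TBP", ct = hk_ct,
      condition = as.character(samples$cond[k]), timepoint = as.character(samples$tp[k]))
    for (gn in genes)
      rows[[length(rows) + 1]] <- data.frame(sample = sm, gene = gn,
        ct = runif(1, 22, 34), condition = as.character(samples$cond[k]),
        timepoint = as.character(samples$tp[k]))
  }
  ct2 <- do.call(rbind, rows)
  out2 <- qpcr_fold_change(ct2)
  per <- attr(out2, "per_sample")
  for (k in sample(nrow(per), 5)) {
    r <- per[k, ]
    hk <- ct2$ct[ct2$sample == r$sample & ct2$gene == "TBP"]
    dct <- ct2$ct[ct2$sample == r$sample & ct2$gene == r$gene] - hk
    mock_rows <- ct2[ct2$condition == "mock" & ct2$gene == r$gene &
                       ct2$timepoint == r$timepoint, ]
    mock_hk <- sapply(mock_rows$sample, function(s)
      ct2$ct[ct2$sample == s & ct2$gene == "TBP"])
    mock_dct <- mean(mock_rows$ct - mock_hk)
    expect_equal(r$fold, 2^(-(dct - mock_dct)))
  }
  expect_error(qpcr_fold_change(ct, housekeeping_gene = "GAPDH"), "GAPDH")
})

test_that("figure-style comparison utilities give standard results", {
  set.seed(8)
  v <- c(rnorm(20, 0), rnorm(20, 2))
  g <- rep(c("a", "b"), each = 20)
  w <- welch_test(v, g)
  expect_equal(w$p.value, t.test(v[g == "a"], v[g == "b"])$p.value)
  expect_lt(oneway_anova(v, g), 0.01)
  expect_error(welch_test(v, rep("a", 40)), "two groups")
})
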