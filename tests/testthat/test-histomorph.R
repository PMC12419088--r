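# Textbook 2x2 chi-square with (optionally) the Yates continuity correction as
# implemented in standard statistical environments: the correction term is
# capped at |O - E|.
chisq_oracle <- function(tab, correct = TRUE) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- if (correct) pmin(0.5, abs(tab - E)) else 0
  x2 <- sum((abs(tab - E) - adj)^2 / E)
  list(statistic = x2, p = pchisq(x2, df = 1, lower.tail = FALSE))
}

test_that("distance binning applies half-open 50-um bins with a closed last edge
           and conserves counts", {
  cells <- data.frame(distance_um = c(0, 49.9, 50, 120, 499.99, 500, 500.01, 700))
  bc <- bin_distances(cells)
  counts <- unlist(bc$counts[1, sprintf("bin%02d", 1:10)])
  expect_equal(unname(counts[1]), 2)    # 0 and 49.9
  expect_equal(unname(counts[2]), 1)    # 50 opens bin 2
  expect_equal(unname(counts[3]), 1)    # 120
  expect_equal(unname(counts[10]), 2)   # 499.99 and the closed edge 500
  expect_equal(bc$counts$overflow, 2)   # 500.01 and 700
  expect_equal(bc$counts$total, 8)
  expect_error(bin_distances(data.frame(distance_um = -1)), ">= 0")
})

test_that("binning conserves counts for random inputs", {
  set.seed(3)
  for (rep in 1:5) {
    cells <- data.frame(
      model = sample(c("CTRL", "GB"), 300, replace = TRUE),
      roi_id = sample(c("r1", "r2"), 300, replace = TRUE),
      distance_um = runif(300, 0, 800))
    bc <- bin_distances(cells)
    expect_equal(sum(bc$counts[sprintf("bin%02d", 1:10)]) + sum(bc$counts$overflow),
                 300)
    expect_true(all(unlist(bc$counts[sprintf("bin%02d", 1:10)]) >= 0))
  }
})

test_that("proliferation rate is count per 100 um and scale invariant", {
  expect_equal(proliferation_rate(10, 500), 2)
  expect_equal(proliferation_rate(0, 350), 0)
  expect_equal(proliferation_rate(14, 700), proliferation_rate(28, 1400))
  expect_error(proliferation_rate(5, 0), "> 0")
  expect_error(proliferation_rate(-1, 100), ">= 0")
})

test_that("proportional re-entry tables give statistic ~0 and removing the
           correction increases the statistic", {
  rt <- reentry_test(c(10, 90), c(20, 180))
  expect_lt(rt$statistic, 0.05)
  expect_gt(rt$p, 0.9)
  expect_equal(unname(rt$fractions), c(0.1, 0.1))

  rt2 <- reentry_test(c(10, 90), c(20, 80))
  orc <- chisq_oracle(rt2$table)
  expect_equal(rt2$statistic, orc$statistic, tolerance = 1e-9)
  expect_equal(rt2$p, orc$p, tolerance = 1e-9)

  set.seed(6)
  for (rep in 1:20) {
    a <- rbinom(2, 60, 0.4) + 1; b <- rbinom(2, 60, 0.6) + 1
    with_c <- reentry_test(a, b, continuity_correction = TRUE)
    without <- reentry_test(a, b, continuity_correction = FALSE)
    tab <- with_c$table
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (max(abs(tab - E)) > 1e-9) {
      expect_gt(without$statistic, with_c$statistic)
    }
  }
  expect_error(reentry_test(c(0, 0), c(5, 5)), "zero margin")
})

test_that("the chi-square implementation matches the textbook oracle on random
           small tables", {
  set.seed(11)
  for (rep in 1:100) {
    a <- c(sample(1:40, 1), sample(1:40, 1))
    b <- c(sample(1:40, 1), sample(1:40, 1))
    for (corr in c(TRUE, FALSE)) {
      got <- reentry_test(a, b, continuity_correction = corr)
      orc <- chisq_oracle(got$table, correct = corr)
      expect_equal(got$statistic, orc$statistic, tolerance = 1e-9)
      expect_equal(got$p, orc$p, tolerance = 1e-9)
    }
  }
})

test_that("one-way ANOVA reduces to the pooled t-test for two groups (F = t^2)", {
  set.seed(12)
  x <- rnorm(8); y <- rnorm(7, mean = 1)
  res <- ablayers:::one_way_tukey(c(x, y), rep(c("a", "b"), c(8, 7)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey HSD matches the studentized-range computation", {
  set.seed(13)
  vals <- rnorm(18, mean = rep(c(0, 0.5, 2), each = 6))
  grp <- rep(c("a", "b", "c"), each = 6)
  res <- ablayers:::one_way_tukey(vals, grp)
  s2 <- sum(res$anova[["Sum Sq"]][2]) / res$anova[["Df"]][2]
  means <- tapply(vals, grp, mean)
  for (pair in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
    diff <- means[pair[1]] - means[pair[2]]
    se <- sqrt(s2 / 2 * (1 / 6 + 1 / 6))
    p_manual <- unname(ptukey(abs(diff) / se, nmeans = 3,
                              df = res$anova[["Df"]][2], lower.tail = FALSE))
    row <- paste(pair, collapse = "-")
    expect_equal(res$tukey[row, "p adj"], p_manual, tolerance = 1e-9)
  }
  # adjusted pairwise p >= the unadjusted two-sample comparison p
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    praw <- t.test(vals[grp == pair[1]], vals[grp == pair[2]],
                   var.equal = TRUE)$p.value
    row <- paste(rev(pair), collapse = "-")
    expect_gte(res$tukey[row, "p adj"], praw - 1e-9)
  }
})

test_that("identical groups give F ~ 0 and p ~ 1", {
  vals <- rep(c(1, 2, 3, 4), times = 3)
  grp <- rep(c("a", "b", "c"), each = 4)
  res <- ablayers:::one_way_tukey(vals, grp)
  expect_lt(res$F, 1e-20)
  expect_gt(res$p, 1 - 1e-10)
})

test_that("the default cell simulation reproduces the printed group parameters and
           the published significance pattern", {
  cfg <- cell_sim_config()
  expect_equal(unname(cfg$distance_mean["CTRL"]), 171.94)
  expect_equal(unname(cfg$distance_mean["GB"]), 107.15)
  expect_equal(unname(cfg$distance_mean["GL"]), 182.90)
  expect_equal(unname(cfg$distance_mean["GBL"]), 112.85)
  expect_equal(unname(cfg$thickness_mean["CTRL"]), 456.83)

  cs <- simulate_cells(cfg, seed = 3)
  ms <- migration_summary(cs$cells, cs$rois)
  tk <- ms$distance$test$tukey
  expect_lt(tk["GB-CTRL", "p adj"], 0.05)
  expect_lt(tk["GBL-CTRL", "p adj"], 0.05)
  expect_gt(tk["GL-CTRL", "p adj"], 0.05)
  # thickness: both CTNNB1 models are thinner
  tkt <- ms$thickness$test$tukey
  expect_lt(tkt["GB-CTRL", "p adj"], 0.05)
  expect_lt(tkt["GBL-CTRL", "p adj"], 0.05)
  expect_gt(tkt["GL-CTRL", "p adj"], 0.05)
})

test_that("simulated distances respect truncation and seeded reproducibility;
           zero-rate markers never appear", {
  cfg <- cell_sim_config(marker_rates = list(
    CTRL = c(Ki67 = 0.3, pHH3 = 0, Reelin = 0.1),
    GL = c(Ki67 = 0.3, pHH3 = 0, Reelin = 0.1),
    GB = c(Ki67 = 0.3, pHH3 = 0, Reelin = 0.1),
    GBL = c(Ki67 = 0.3, pHH3 = 0, Reelin = 0.1)))
  a <- simulate_cells(cfg, seed = 8)
  b <- simulate_cells(cfg, seed = 8)
  expect_identical(a$cells, b$cells)
  expect_true(all(a$cells$distance_um >= 0))
  expect_false(any(a$cells$pHH3))
  for (r in unique(a$cells$roi_id)) {
    thick <- mean(a$rois$thickness_um[a$rois$roi_id == r])
    expect_true(all(a$cells$distance_um[a$cells$roi_id == r] <= thick))
  }
  expect_error(cell_sim_config(n_roi = 0), "n_roi")
})

test_that("the empirical mean of many simulated distances matches the truncated
           normal expectation", {
  cfg <- cell_sim_config(cells_per_roi = c(CTRL = 10000, GL = 10, GB = 10, GBL = 10),
                         roi_mean_sd = 0, thickness_sd = 0, n_roi = 1L)
  cs <- simulate_cells(cfg, seed = 10)
  d <- cs$cells$distance_um[cs$cells$model == "CTRL"]
  mu <- 171.94; s <- 80; lo <- 0; hi <- 456.83
  a <- (lo - mu) / s; b <- (hi - mu) / s
  trunc_mean <- mu + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  trunc_var <- s^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / (pnorm(b) - pnorm(a)) -
                        ((dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a)))^2)
  se <- sqrt(trunc_var / length(d))
  expect_lt(abs(mean(d) - trunc_mean), 3 * se)
})

test_that("under the null the one-way ANOVA p-value is calibrated", {
  set.seed(14)
  hits <- 0; n_sim <- 1000
  for (i in seq_len(n_sim)) {
    vals <- rnorm(12)
    grp <- rep(c("a", "b", "c", "d"), each = 3)
    fit <- aov(vals ~ factor(grp))
    if (anova(fit)[1, "Pr(>F)"] < 0.05) hits <- hits + 1
  }
  rate <- hits / n_sim
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / n_sim))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("marker-positive binning produces per-genotype mean heat-map rows", {
  cells <- data.frame(
    model = rep(c("CTRL", "GBL"), each = 6),
    roi_id = rep(c("c1", "c2", "g1", "g2"), each = 3),
    distance_um = c(10, 20, 30, 15, 25, 35, 10, 160, 310, 60, 210, 460),
    SOX2 = c(rep(TRUE, 6), rep(TRUE, 6)),
    TBR2 = FALSE)
  hm <- bin_positive_cells(cells, "SOX2")
  expect_equal(unname(hm["CTRL", 1]), 3)  # all six cells in bin 1, 2 ROIs
  expect_true(all(hm["CTRL", 2:10] == 0))
  # planted scattering: GBL occupies more bins than CTRL
  expect_gt(sum(hm["GBL", ] > 0), sum(hm["CTRL", ] > 0))
  # empty marker subset: all-zero rows
  hm2 <- bin_positive_cells(cells, "TBR2")
  expect_true(all(hm2 == 0))
  # single replicate: means equal raw counts
  one <- cells[cells$roi_id == "g1", ]
  hm3 <- bin_positive_cells(one, "SOX2")
  expect_equal(unname(hm3["GBL", c(1, 4, 7)]), c(1, 1, 1))
})
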