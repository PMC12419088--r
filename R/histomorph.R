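#' Bin migration distances into 50-um depth bins
#'
#' Distances from the ventricular margin are assigned to ten half-open bins
#' `[0,50), [50,100), ..., [450,500]`; the last bin is closed at 500 um and
#' anything beyond 500 um is counted separately as overflow, so counts are
#' conserved.
#'
#' @param cells per-cell data.frame with `distance_um` and, if present,
#'   `model` and `roi_id` used for grouping.
#' @param bin_width bin width in um (default 50).
#' @param n_bins number of bins (default 10).
#' @return List with `counts` (one row per (model, roi) group, columns
#'   `bin01`..`bin10`, `overflow`, `total`) and `edges`.
#' @export
bin_distances <- function(cells, bin_width = 50, n_bins = 10L) {
  stop_if(!"distance_um" %in% names(cells), "cells need a distance_um column")
  stop_if(any(cells$distance_um < 0, na.rm = TRUE), "distances must be >= 0")
  edges <- seq(0, bin_width * n_bins, by = bin_width)
  grp <- interaction(
    if ("model" %in% names(cells)) cells$model else "all",
    if ("roi_id" %in% names(cells)) cells$roi_id else "all",
    drop = TRUE, sep = "|")
  rows <- lapply(levels(grp), function(g) {
    d <- cells$distance_um[grp == g]
    idx <- floor(d / bin_width) + 1
    idx[d == bin_width * n_bins] <- n_bins       # closed upper edge
    counts <- tabulate(idx[idx <= n_bins], nbins = n_bins)
    overflow <- sum(d > bin_width * n_bins)
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    out <- data.frame(model = parts[1], roi_id = parts[2],
                      stringsAsFactors = FALSE)
    out[sprintf("bin%02d", seq_len(n_bins))] <- as.list(counts)
    out$overflow <- overflow
    out$total <- length(d)
    out
  })
  counts <- do.call(rbind, rows)
  stopifnot(all(rowSums(counts[sprintf("bin%02d", seq_len(n_bins))]) +
                  counts$overflow == counts$total))
  list(counts = counts, edges = edges)
}

#' One-way group comparison with Tukey HSD
#'
#' @param values numeric response (e.g. per-ROI means).
#' @param group factor of group labels.
#' @return List with `means`, `F`, `p`, `tukey` (pairwise table with
#'   `diff`, `p_adj`), `anova` and the fitted `aov` object.
#' @keywords internal
one_way_tukey <- function(values, group) {
  group <- factor(group)
  fit <- aov(values ~ group)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$group
  list(means = tapply(values, group, mean),
       F = an[1, "F value"], p = an[1, "Pr(>F)"],
       tukey = tk, anova = an, fit = fit)
}

#' Migration-distance and cortex-thickness comparison across genotypes
#'
#' Replicate (ROI) mean migration distances and thickness measurements are
#' compared across genotypes by one-way ANOVA with Tukey's HSD; per-bin cell
#' counts are additionally compared by a two-way ANOVA (genotype x bin) with
#' Tukey-adjusted genotype comparisons within each bin (via
#' [emmeans::emmeans()]). With a single replicate per genotype only
#' descriptive means are returned.
#'
#' @param cells per-cell table (needs `model`, `roi_id`, `distance_um`).
#' @param rois per-ROI table with `model`, `roi_id`, `thickness_um`.
#' @param bin_width,n_bins binning parameters (see [bin_distances()]).
#' @return List: `distance` and `thickness` (each per-genotype means plus a
#'   `one_way_tukey` result, or `NULL` when untestable), `bins` (bin counts),
#'   `bin_anova` (two-way ANOVA table), `bin_tukey` (per-bin pairwise
#'   genotype contrasts).
#' @export
migration_summary <- function(cells, rois, bin_width = 50, n_bins = 10L) {
  roi_mean <- aggregate(distance_um ~ model + roi_id, cells, mean)
  reps <- table(roi_mean$model)
  distance <- list(means = tapply(roi_mean$distance_um, roi_mean$model, mean),
                   test = NULL)
  if (all(reps >= 2)) {
    distance$test <- one_way_tukey(roi_mean$distance_um, roi_mean$model)
  }
  thick_mean <- aggregate(thickness_um ~ model + roi_id, rois, mean)
  thickness <- list(means = tapply(thick_mean$thickness_um, thick_mean$model, mean),
                    test = NULL)
  if (all(table(thick_mean$model) >= 2)) {
    thickness$test <- one_way_tukey(thick_mean$thickness_um, thick_mean$model)
  }

  bins <- bin_distances(cells, bin_width, n_bins)
  long <- stats::reshape(
    bins$counts[, c("model", "roi_id", sprintf("bin%02d", seq_len(n_bins)))],
    direction = "long", varying = sprintf("bin%02d", seq_len(n_bins)),
    v.names = "count", timevar = "bin", idvar = c("model", "roi_id"))
  long$bin <- factor(long$bin)
  long$model <- factor(long$model)
  bin_anova <- NULL
  bin_tukey <- NULL
  if (all(reps >= 2)) {
    fit2 <- aov(count ~ model * bin, data = long)
    bin_anova <- anova(fit2)
    emm <- emmeans::emmeans(fit2, ~ model | bin)
    bin_tukey <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                                 adjust = "tukey"))
  }
  list(distance = distance, thickness = thickness, bins = bins,
       bin_anova = bin_anova, bin_tukey = bin_tukey)
}

#' Proliferation rate: positive cells per 100 um of ventricular margin
#'
#' @param positive_count number of marker-positive cells counted along the
#'   margin.
#' @param margin_length_um measured margin length (> 0).
#' @return Rate in cells per 100 um.
#' @export
proliferation_rate <- function(positive_count, margin_length_um) {
  stop_if(any(margin_length_um <= 0), "margin length must be > 0")
  stop_if(any(positive_count < 0), "counts must be >= 0")
  positive_count / margin_length_um * 100
}

#' Cell-cycle re-entry test (BrdU+/Ki67+ fractions, 2x2 chi-square)
#'
#' Compares the fraction of BrdU+ cells that re-enter the cycle (Ki67+)
#' between CTRL and one genotype, on counts summed over replicates, using the
#' chi-square test with Yates continuity correction by default.
#'
#' @param ctrl_counts integer vector `c(double_pos, single_pos)` for CTRL.
#' @param model_counts same for the compared genotype.
#' @param continuity_correction apply Yates correction (default TRUE).
#' @param model_label label for the second column.
#' @return List with `table` (2x2), `fractions`, `statistic`, `p`.
#' @export
reentry_test <- function(ctrl_counts, model_counts,
                         continuity_correction = TRUE, model_label = "model") {
  stop_if(length(ctrl_counts) != 2 || length(model_counts) != 2,
          "counts must be (double_pos, single_pos) pairs")
  stop_if(any(c(ctrl_counts, model_counts) < 0), "counts must be >= 0")
  tab <- cbind(CTRL = ctrl_counts, model = model_counts)
  rownames(tab) <- c("BrdU+Ki67+", "BrdU+Ki67-")
  colnames(tab)[2] <- model_label
  stop_if(any(rowSums(tab) == 0) || any(colSums(tab) == 0),
          "test undefined: zero margin in the 2x2 table")
  ct <- suppressWarnings(chisq.test(tab, correct = continuity_correction))
  list(table = tab,
       fractions = tab[1, ] / colSums(tab),
       statistic = unname(ct$statistic), p = ct$p.value)
}

#' Per-genotype mean binned counts of marker-positive cells
#'
#' Restricts the cell table to cells positive for `marker`, bins their
#' distances ([bin_distances()]) and averages counts over replicate ROIs,
#' giving the heat-map table of mean cell count per bin and genotype.
#'
#' @param cells per-cell table with a logical column named after `marker`.
#' @param marker marker column (e.g. `"Ki67"`, or `"SOX2"`/`"TBR2"` in
#'   progenitor tables).
#' @param bin_width,n_bins binning parameters.
#' @return genotypes x bins matrix of mean counts (all-zero rows for
#'   genotypes without positive cells).
#' @export
bin_positive_cells <- function(cells, marker, bin_width = 50, n_bins = 10L) {
  stop_if(!marker %in% names(cells), "no column '", marker, "' in cells")
  models <- unique(cells$model)
  rois <- unique(cells[, c("model", "roi_id")])
  pos <- cells[cells[[marker]], , drop = FALSE]
  bin_cols <- sprintf("bin%02d", seq_len(n_bins))
  out <- base::matrix(0, length(models), n_bins,
                      dimnames = list(models, bin_cols))
  if (nrow(pos) > 0) {
    bc <- bin_distances(pos, bin_width, n_bins)$counts
    for (m in models) {
      sub <- bc[bc$model == m, bin_cols, drop = FALSE]
      n_roi <- sum(rois$model == m)  # ROIs without positives count as zeros
      if (nrow(sub) > 0 && n_roi > 0) {
        out[m, ] <- colSums(sub) / n_roi
      }
    }
  }
  out
}
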