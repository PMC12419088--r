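#' ANCOVA screen: genotype effect on depth profiles within a layer cluster
#'
#' For each protein with sufficient validity over the contrast samples, fits
#' abundance ~ layer + group (additive) and abundance ~ layer * group
#' (interaction) over the cluster's layers, comparing CTRL against one other
#' genotype. The interaction term tests a difference in rate of change with
#' depth (slope); the group term of the additive model tests a difference in
#' abundance level (intercept). A protein is significant when either p-value
#' is below `p_max` and the full (interaction) model's R-squared exceeds
#' `r2_min`. Missing values are dropped casewise per protein.
#'
#' @param matrix proteins x samples matrix.
#' @param manifest manifest covering the columns.
#' @param cluster_layers integer layer indices of the cluster (>= 3).
#' @param contrast_model genotype compared against CTRL (`"GL"`, `"GB"`,
#'   `"GBL"`).
#' @param timepoint timepoint of the cluster.
#' @param min_validity validity fraction over the contrast samples (0.70).
#' @param p_max,r2_min significance thresholds (0.05, 0.1).
#' @return data.frame per tested protein: `protein`, `cluster_layers`,
#'   `contrast`, `slope_diff`, `intercept_diff`, `p_slope`, `p_intercept`,
#'   `r_squared`, `significant`; attribute `n_skipped` counts proteins
#'   failing validity.
#' @export
ancova_fit <- function(matrix, manifest, cluster_layers, contrast_model,
                       timepoint = "E14.5", min_validity = 0.7,
                       p_max = 0.05, r2_min = 0.1) {
  check_matrix(matrix)
  stop_if(length(cluster_layers) < 3, "need >= 3 layers in the cluster")
  contrast_model <- match.arg(contrast_model, setdiff(MODEL_LEVELS, "CTRL"))
  man <- manifest_for_matrix(matrix, manifest)
  keep <- man$timepoint == timepoint &
    man$layer_index %in% cluster_layers &
    man$model %in% c("CTRL", contrast_model)
  man <- man[keep, , drop = FALSE]
  stop_if(!all(c("CTRL", contrast_model) %in% man$model),
          "both CTRL and ", contrast_model, " samples are required")
  sub <- matrix[, man$sample_id, drop = FALSE]

  n_scope <- nrow(man)
  valid <- rowSums(!is.na(sub)) / n_scope >= min_validity - 1e-12
  n_skipped <- sum(!valid)
  sub <- sub[valid, , drop = FALSE]

  layer <- man$layer_index
  group <- factor(man$model, levels = c("CTRL", contrast_model))
  lab <- paste0("L", min(cluster_layers), "-L", max(cluster_layers))

  rows <- lapply(rownames(sub), function(pr) {
    y <- sub[pr, ]
    ok <- !is.na(y)
    # both groups and some depth spread needed for the two fits
    if (length(unique(group[ok])) < 2 || length(unique(layer[ok])) < 2) {
      return(NULL)
    }
    full <- lm(y[ok] ~ layer[ok] * group[ok])
    addi <- lm(y[ok] ~ layer[ok] + group[ok])
    cf <- summary(full)$coefficients
    ca <- summary(addi)$coefficients
    int_name <- grep(":", rownames(cf), value = TRUE)
    grp_name <- grep("^group", rownames(ca), value = TRUE)
    p_slope <- if (length(int_name) == 1 && !is.na(cf[int_name, 4])) cf[int_name, 4] else NA_real_
    p_int <- if (length(grp_name) == 1 && !is.na(ca[grp_name, 4])) ca[grp_name, 4] else NA_real_
    r2 <- summary(full)$r.squared
    data.frame(
      protein = pr, cluster_layers = lab, contrast = paste0("CTRL vs ", contrast_model),
      slope_diff = if (length(int_name) == 1) unname(cf[int_name, 1]) else NA_real_,
      intercept_diff = if (length(grp_name) == 1) unname(ca[grp_name, 1]) else NA_real_,
      p_slope = p_slope, p_intercept = p_int, r_squared = r2,
      significant = isTRUE(min(p_slope, p_int, na.rm = TRUE) < p_max && r2 > r2_min),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein = character(0), cluster_layers = character(0),
                      contrast = character(0), slope_diff = numeric(0),
                      intercept_diff = numeric(0), p_slope = numeric(0),
                      p_intercept = numeric(0), r_squared = numeric(0),
                      significant = logical(0))
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Genotype-specific protein sets from pooled ANCOVA results
#'
#' Pools the significant proteins of each CTRL-vs-genotype contrast over all
#' layer clusters and partitions their union as a three-way Venn diagram.
#' "Specific" proteins are significant in exactly one contrast.
#'
#' @param results named list with elements `GL`, `GB`, `GBL`, each a
#'   data.frame (or rbind of data.frames) from [ancova_fit()].
#' @return List with `specific` (named list of protein vectors, pairwise
#'   disjoint), `shared` (named list for every multi-contrast region) and
#'   `counts` (named integer vector over the 7 Venn regions).
#' @export
model_specific_sets <- function(results) {
  need <- c("GL", "GB", "GBL")
  stop_if(!all(need %in% names(results)), "results must cover GL, GB and GBL")
  sig <- lapply(results[need], function(r) unique(r$protein[r$significant]))
  all_prot <- unique(unlist(sig))
  member <- sapply(sig, function(s) all_prot %in% s)
  if (length(all_prot) == 1) member <- base::matrix(member, nrow = 1,
                                                   dimnames = list(NULL, need))
  region <- apply(member, 1, function(b) paste(need[b], collapse = ":"))
  part <- split(all_prot, factor(region, levels = c(
    "GL", "GB", "GBL", "GL:GB", "GL:GBL", "GB:GBL", "GL:GB:GBL")))
  list(
    specific = part[need],
    shared = part[c("GL:GB", "GL:GBL", "GB:GBL", "GL:GB:GBL")],
    counts = vapply(part, length, integer(1))
  )
}

#' Annotate candidate proteins with interaction-partner and literature labels
#'
#' Attaches optional LIN28A interaction-partner annotations (protein-level
#' partner or mRNA target) and literature-miner categories to each
#' genotype-specific set, reports the fraction of potential partners per set,
#' and flags sets where that fraction exceeds `flag_threshold` (the workflow
#' highlights panels above 40%).
#'
#' @param specific_sets named list of protein id vectors (from
#'   [model_specific_sets()]`$specific`).
#' @param interaction_table optional data.frame (`protein`, `partner_type`).
#' @param litminer_table optional data.frame (`protein`, `category` in 1:3).
#' @param flag_threshold partner-fraction flag level (default 0.4).
#' @return List per set: data.frame `protein`, `partner_type`, `category`
#'   (missing annotations become `"unknown"`), plus `partner_fraction`
#'   (percent) and `flagged`.
#' @export
annotate_candidates <- function(specific_sets, interaction_table = NULL,
                                litminer_table = NULL, flag_threshold = 0.4) {
  lapply(specific_sets, function(prot) {
    df <- data.frame(protein = prot, stringsAsFactors = FALSE)
    df$partner_type <- if (is.null(interaction_table)) {
      rep("unknown", nrow(df))
    } else {
      pt <- interaction_table$partner_type[match(prot, interaction_table$protein)]
      ifelse(is.na(pt), "unknown", pt)
    }
    df$category <- if (is.null(litminer_table)) {
      rep("unknown", nrow(df))
    } else {
      ct <- litminer_table$category[match(prot, litminer_table$protein)]
      ifelse(is.na(ct), "unknown", as.character(ct))
    }
    frac <- if (nrow(df) == 0) 0 else mean(df$partner_type != "unknown") * 100
    list(annotations = df, partner_fraction = frac,
         flagged = frac > flag_threshold * 100)
  })
}

#' Export rule for downstream enrichment queries
#'
#' Significantly altered proteins ordered by decreasing log fold change (or
#' absolute effect), truncated to at most `max_n` entries, matching the
#' workflow's "ordered by log fold change, max. 50 proteins" submission rule.
#'
#' @param table data.frame with columns `protein` and an effect column.
#' @param effect_col column to order by (descending).
#' @param max_n truncation limit (default 50).
#' @return Character vector of protein ids.
#' @export
enrichment_export <- function(table, effect_col = "logFC", max_n = 50L) {
  stop_if(!effect_col %in% names(table), "missing effect column ", effect_col)
  ord <- table[order(-table[[effect_col]]), ]
  head(ord$protein, max_n)
}
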