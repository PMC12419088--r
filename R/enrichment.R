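#' Single-sample gene-set scoring by combined z
#'
#' For one genotype/timepoint, each gene's per-layer mean abundance is
#' z-scored across layers; the score of a set with m quantified member genes
#' is the per-layer sum of member z-scores divided by sqrt(m) (Stouffer-style
#' combined z). Genes with zero variance across layers contribute 0; sets
#' without any quantified member are skipped.
#'
#' @param layer_means proteins x layers matrix of mean abundances (use the
#'   100%-valid proteins, per the workflow).
#' @param genesets named list of character vectors (e.g. from [read_gmt()]).
#' @return List with `scores` (terms x layers matrix) and `set_size` (number
#'   of quantified members per term).
#' @export
ssgsea_zscore <- function(layer_means, genesets) {
  stop_if(!is.matrix(layer_means), "layer_means must be a matrix")
  stop_if(is.null(names(genesets)), "gene sets must be named")
  z <- t(apply(layer_means, 1, function(v) {
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v, na.rm = TRUE)) / s
  }))
  colnames(z) <- colnames(layer_means)

  quantified <- lapply(genesets, function(g) {
    unique(intersect(g, rownames(z)))
  })
  keep <- vapply(quantified, length, integer(1)) >= 1
  quantified <- quantified[keep]
  scores <- t(vapply(quantified, function(g) {
    colSums(z[g, , drop = FALSE], na.rm = TRUE) / sqrt(length(g))
  }, numeric(ncol(z))))
  dimnames(scores) <- list(names(quantified), colnames(z))
  list(scores = scores, set_size = vapply(quantified, length, integer(1)))
}

#' Linear depth-gradient filter on enrichment scores
#'
#' Ordinary least squares of each term's score on layer index over the
#' cortex-related layers; terms are kept when the slope is significant
#' (p < `p_max`) and the fit explains enough variance (R-squared >
#' `r2_min`).
#'
#' @param scores terms x layers matrix (columns `L<index>`), e.g. from
#'   [ssgsea_zscore()].
#' @param cortex_layers contiguous layer indices to fit over (E14.5: 5-9;
#'   E18.5: 10-18); at least 3.
#' @param p_max,r2_min filter thresholds (defaults 0.05 and 0.1).
#' @return data.frame per term: `term`, `slope`, `intercept`, `p_slope`,
#'   `r_squared`, `direction` (`"positive"`/`"negative"`), `kept`.
#' @export
gradient_filter <- function(scores, cortex_layers, p_max = 0.05, r2_min = 0.1) {
  stop_if(length(cortex_layers) < 3, "need >= 3 layers for a gradient fit")
  cols <- paste0("L", cortex_layers)
  stop_if(!all(cols %in% colnames(scores)),
          "scores lack layers: ", paste(setdiff(cols, colnames(scores)), collapse = ", "))
  y_all <- scores[, cols, drop = FALSE]
  x <- as.numeric(cortex_layers)
  out <- lapply(rownames(y_all), function(term) {
    y <- y_all[term, ]
    ok <- is.finite(y)
    if (sum(ok) < 3 || sd(y[ok]) == 0) {
      return(data.frame(term = term, slope = 0, intercept = mean(y[ok]),
                        p_slope = 1, r_squared = 0,
                        direction = "none", kept = FALSE,
                        stringsAsFactors = FALSE))
    }
    fit <- lm(y[ok] ~ x[ok])
    sm <- summary(fit)
    slope <- coef(fit)[2]
    data.frame(term = term, slope = slope, intercept = coef(fit)[1],
               p_slope = sm$coefficients[2, 4], r_squared = sm$r.squared,
               direction = if (slope >= 0) "positive" else "negative",
               kept = sm$coefficients[2, 4] < p_max & sm$r.squared > r2_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-timepoint gradient-direction classification
#'
#' Terms kept by the gradient filter at both timepoints are classified by the
#' agreement of their slope signs; terms kept at only one (or neither)
#' timepoint are `"absent"`.
#'
#' @param fits_early,fits_late data.frames from [gradient_filter()].
#' @return data.frame `term`, `class` in
#'   `{"same-direction", "opposite", "absent"}`.
#' @export
cross_timepoint_direction <- function(fits_early, fits_late) {
  terms <- union(fits_early$term, fits_late$term)
  cls <- vapply(terms, function(t) {
    e <- fits_early[fits_early$term == t, ]
    l <- fits_late[fits_late$term == t, ]
    if (nrow(e) == 0 || nrow(l) == 0 || !any(e$kept) || !any(l$kept)) {
      return("absent")
    }
    if (sign(e$slope[1]) == sign(l$slope[1])) "same-direction" else "opposite"
  }, character(1))
  data.frame(term = terms, class = unname(cls), stringsAsFactors = FALSE)
}

check_term_representation <- function(rep, n_layers = NULL) {
  need <- c("term", "model", "layer", "adj_p")
  stop_if(!all(need %in% names(rep)),
          "term representation needs columns: ", paste(need, collapse = ", "))
  stop_if(any(rep$adj_p <= 0 | rep$adj_p > 1), "adjusted p-values must be in (0, 1]")
  stop_if(!all(rep$model %in% MODEL_LEVELS), "unknown model in term representation")
  if (!is.null(n_layers)) {
    stop_if(any(rep$layer < 1 | rep$layer > n_layers),
            "layer index outside [1, ", n_layers, "]")
  }
  invisible(rep)
}

#' Best Match: which (genotype, layer) represents a term best
#'
#' For every (term, genotype, layer) the score is -log10 of the mean adjusted
#' p-value recorded there; the best match is the highest-scoring site. Ties
#' are broken deterministically: genotype order CTRL < GL < GB < GBL, then
#' lower layer.
#'
#' @param rep term-representation data.frame (`term`, `model`, `layer`,
#'   `adj_p`; several rows per site allowed).
#' @return data.frame per term: `term`, `model`, `layer`, `score`.
#' @export
best_match <- function(rep) {
  check_term_representation(rep)
  agg <- aggregate(adj_p ~ term + model + layer, rep, mean)
  agg$score <- -log10(agg$adj_p)
  agg$model_rank <- match(agg$model, MODEL_LEVELS)
  out <- do.call(rbind, lapply(split(agg, agg$term), function(a) {
    a <- a[order(-a$score, a$model_rank, a$layer), ]
    a[1, c("term", "model", "layer", "score")]
  }))
  rownames(out) <- NULL
  out
}

#' DiffScore placeholder for a genotype without any represented layer
#'
#' A genotype not representing a term at all is assigned the negative of the
#' full layer-index sum, `-n(n+1)/2`: -45 for the nine-layer (E14.5)
#' configuration and -171 for the eighteen-layer (E18.5) one.
#'
#' @param n_layers number of ablated layers (9 or 18).
#' @return The placeholder sum (negative integer-valued numeric).
#' @export
diffscore_placeholder <- function(n_layers) {
  stop_if(n_layers < 1, "n_layers must be positive")
  -(n_layers * (n_layers + 1) / 2)
}

#' DiffScore: spread of layer representation across genotypes
#'
#' Per genotype, the represented layer indices of a term are summed (each
#' layer counted once); genotypes without any representation receive the
#' placeholder [diffscore_placeholder()]. The DiffScore is the range
#' (maximum minus minimum) of the four genotype sums: 0 means identical
#' representation, large values mean strong displacement or missing
#' representation.
#'
#' @param rep term-representation data.frame.
#' @param n_layers layers in the timepoint (9 or 18).
#' @param models genotypes considered (default all four).
#' @return data.frame per term: `term`, one sum column per genotype,
#'   `diff_score`.
#' @export
diff_score <- function(rep, n_layers, models = MODEL_LEVELS) {
  check_term_representation(rep, n_layers)
  terms <- unique(rep$term)
  placeholder <- diffscore_placeholder(n_layers)
  rows <- lapply(terms, function(t) {
    sums <- vapply(models, function(m) {
      layers <- unique(rep$layer[rep$term == t & rep$model == m])
      if (length(layers) == 0) placeholder else sum(layers)
    }, numeric(1))
    cbind(data.frame(term = t, stringsAsFactors = FALSE),
          as.data.frame(as.list(sums)),
          data.frame(diff_score = max(sums) - min(sums)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
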