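#' Per-layer mean abundances
#'
#' Averages replicate samples of each ablated layer for one genotype and
#' timepoint.
#'
#' @param matrix proteins x samples matrix.
#' @param manifest manifest covering the columns.
#' @param model genotype to average; `NULL` keeps all columns.
#' @param timepoint timepoint to restrict to; `NULL` keeps all.
#' @return proteins x layers matrix with columns `L1`, `L2`, ...
#' @export
layer_means <- function(matrix, manifest, model = NULL, timepoint = NULL) {
  check_matrix(matrix)
  man <- manifest_for_matrix(matrix, manifest)
  keep <- rep(TRUE, nrow(man))
  if (!is.null(model)) keep <- keep & man$model == model
  if (!is.null(timepoint)) keep <- keep & man$timepoint == timepoint
  stop_if(!any(keep), "no samples match the requested model/timepoint")
  man <- man[keep, , drop = FALSE]
  sub <- matrix[, man$sample_id, drop = FALSE]
  layers <- sort(unique(man$layer_index))
  out <- vapply(layers, function(L) {
    row_means_na(sub[, man$layer_index == L, drop = FALSE])
  }, numeric(nrow(sub)))
  base::matrix(out, nrow = nrow(sub),
               dimnames = list(rownames(sub), paste0("L", layers)))
}

#' Moderated one-vs-rest differential abundance for one layer
#'
#' Compares the replicates of layer `layer` against all other layers of the
#' same genotype/timepoint. Per protein the group-mean difference is the log
#' fold change; residual variances are shrunk toward a common prior by
#' empirical Bayes (inverse-gamma moment matching of the variance
#' distribution, as in moderated-t analysis), giving a moderated t with
#' augmented degrees of freedom. P-values are Benjamini-Hochberg adjusted
#' across the tested proteins.
#'
#' @param matrix proteins x samples matrix.
#' @param manifest manifest covering the columns.
#' @param layer layer index to contrast against all remaining layers.
#' @param model,timepoint genotype and timepoint defining the scope.
#' @param min_validity validity fraction over the scope samples (default 0.70).
#' @param prior_df prior degrees of freedom: `NULL` estimates them from the
#'   variance distribution ([limma::fitFDist()]); `0` gives the ordinary
#'   pooled two-sample t-test.
#' @return data.frame of class `differential_table` with columns `protein`,
#'   `layer`, `logFC`, `t`, `df`, `p`, `adj_p`, sorted by decreasing `|t|`.
#'   Proteins with fewer than two observed values in either group are skipped.
#' @export
moderated_layer_de <- function(matrix, manifest, layer, model = "CTRL",
                               timepoint = "E14.5", min_validity = 0.7,
                               prior_df = NULL) {
  check_matrix(matrix)
  man <- manifest_for_matrix(matrix, manifest)
  keep <- man$model == model & man$timepoint == timepoint
  man <- man[keep, , drop = FALSE]
  stop_if(sum(man$layer_index == layer) < 2,
          "layer ", layer, " has fewer than 2 samples")
  sub <- matrix[, man$sample_id, drop = FALSE]
  sub <- filter_by_validity(sub, min_validity)
  in_layer <- man$layer_index == layer

  n1 <- rowSums(!is.na(sub[, in_layer, drop = FALSE]))
  n0 <- rowSums(!is.na(sub[, !in_layer, drop = FALSE]))
  testable <- n1 >= 2 & n0 >= 2
  sub <- sub[testable, , drop = FALSE]
  n1 <- n1[testable]; n0 <- n0[testable]

  m1 <- row_means_na(sub[, in_layer, drop = FALSE])
  m0 <- row_means_na(sub[, !in_layer, drop = FALSE])
  v1 <- apply(sub[, in_layer, drop = FALSE], 1, var, na.rm = TRUE)
  v0 <- apply(sub[, !in_layer, drop = FALSE], 1, var, na.rm = TRUE)
  df_resid <- n1 + n0 - 2
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df_resid

  if (is.null(prior_df)) {
    fit <- limma::fitFDist(s2, df1 = df_resid)
    d0 <- fit$df2
    s02 <- fit$scale
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2) else 0
  }
  if (is.finite(d0) && d0 > 0) {
    s2_post <- (d0 * s02 + df_resid * s2) / (d0 + df_resid)
    # cap the augmented df at the total residual df across proteins
    df_total <- pmin(df_resid + d0, sum(df_resid))
  } else if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- rep(sum(df_resid), length(s2))
  } else {
    s2_post <- s2
    df_total <- df_resid
  }

  logFC <- m1 - m0
  tstat <- logFC / sqrt(s2_post * (1 / n1 + 1 / n0))
  tstat[s2_post == 0 & logFC == 0] <- 0
  p <- 2 * pt(abs(tstat), df = df_total, lower.tail = FALSE)
  out <- data.frame(protein = rownames(sub), layer = layer,
                    logFC = logFC, t = tstat, df = df_total, p = p,
                    adj_p = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-abs(out$t)), ]
  rownames(out) <- NULL
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Unique top-k layer signatures (first come, first serve)
#'
#' Layers are processed in ascending order. For each layer, candidates are
#' the significantly high-abundant proteins (positive logFC, raw p below
#' `sig_threshold`) ranked by decreasing logFC (ties: smaller p, then protein
#' id); the first `k` candidates not already claimed by an earlier layer form
#' the layer's signature. A protein claimed once is skipped by all later
#' layers, so signatures are pairwise disjoint; layers can end up with fewer
#' than `k` proteins.
#'
#' @param tables list of `differential_table`s, one per layer (any order;
#'   layers are taken from the tables).
#' @param k signature size cap (default 10).
#' @param sig_threshold raw p-value gate (default 0.05).
#' @return Object of class `layer_signature`: data.frame with columns
#'   `layer`, `rank`, `protein`, `logFC`, `p`.
#' @export
unique_top_signatures <- function(tables, k = 10L, sig_threshold = 0.05) {
  stop_if(length(tables) == 0, "no differential tables given")
  layers <- vapply(tables, function(tb) tb$layer[1], numeric(1))
  stop_if(anyDuplicated(layers) > 0, "multiple tables for the same layer")
  ord <- order(layers)
  claimed <- character(0)
  rows <- list()
  for (i in ord) {
    tb <- tables[[i]]
    cand <- tb[tb$logFC > 0 & tb$p < sig_threshold, , drop = FALSE]
    cand <- cand[order(-cand$logFC, cand$p, cand$protein), , drop = FALSE]
    cand <- cand[!cand$protein %in% claimed, , drop = FALSE]
    take <- head(cand, k)
    if (nrow(take) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        layer = take$layer, rank = seq_len(nrow(take)),
        protein = take$protein, logFC = take$logFC, p = take$p,
        stringsAsFactors = FALSE)
      claimed <- c(claimed, take$protein)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(layer = integer(0), rank = integer(0), protein = character(0),
               logFC = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("layer_signature", "data.frame")
  out
}

#' @export
print.layer_signature <- function(x, ...) {
  cat("Unique layer signatures:", length(unique(x$layer)), "layers,",
      nrow(x), "proteins (disjoint)\n")
  sizes <- table(x$layer)
  cat(paste(sprintf("L%s:%d", names(sizes), sizes), collapse = "  "), "\n")
  invisible(x)
}

#' Correlation-based layer-identity mapping
#'
#' Correlates, over the signature proteins, each query layer's mean-abundance
#' vector of a genotype against every reference (CTRL) layer's vector, and
#' reports the best-correlated reference layer. Pairing is pairwise-complete;
#' an assignment requires at least `min_pairs` paired values. Ties are broken
#' toward the lower reference layer index.
#'
#' @param signature a `layer_signature` built from the reference genotype.
#' @param ref_means proteins x layers mean-abundance matrix of the reference
#'   genotype (from [layer_means()]).
#' @param query_means proteins x layers mean-abundance matrix of the query
#'   genotype.
#' @param method correlation method (default Pearson).
#' @param min_pairs minimum paired observations per correlation.
#' @return data.frame with one row per query layer: `query_layer`,
#'   `best_ref_layer`, `best_r`, plus attribute `correlations` (query x ref
#'   correlation matrix). Query layers with undefined correlations everywhere
#'   (zero variance) get NA with a warning.
#' @export
signature_correlation_map <- function(signature, ref_means, query_means,
                                      method = "pearson", min_pairs = 3L) {
  stop_if(!inherits(signature, "layer_signature"), "need a layer_signature")
  prot <- intersect(unique(signature$protein), rownames(ref_means))
  prot <- intersect(prot, rownames(query_means))
  stop_if(length(prot) < min_pairs, "too few signature proteins shared with the matrices")
  R <- ref_means[prot, , drop = FALSE]
  Q <- query_means[prot, , drop = FALSE]

  cors <- base::matrix(NA_real_, ncol(Q), ncol(R),
                       dimnames = list(colnames(Q), colnames(R)))
  for (qi in seq_len(ncol(Q))) {
    for (ri in seq_len(ncol(R))) {
      ok <- complete.cases(Q[, qi], R[, ri])
      if (sum(ok) < min_pairs) next
      if (sd(Q[ok, qi]) == 0 || sd(R[ok, ri]) == 0) next
      cors[qi, ri] <- cor(Q[ok, qi], R[ok, ri], method = method)
    }
  }

  best <- lapply(seq_len(nrow(cors)), function(qi) {
    v <- cors[qi, ]
    if (all(is.na(v))) {
      warning("no defined correlation for query layer ", rownames(cors)[qi],
              call. = FALSE)
      return(data.frame(query_layer = layer_num(rownames(cors)[qi]),
                        best_ref_layer = NA_integer_, best_r = NA_real_))
    }
    i <- which(v == max(v, na.rm = TRUE))[1]  # ties: lowest reference layer
    data.frame(query_layer = layer_num(rownames(cors)[qi]),
               best_ref_layer = layer_num(colnames(cors)[i]),
               best_r = v[i])
  })
  out <- do.call(rbind, best)
  rownames(out) <- NULL
  attr(out, "correlations") <- cors
  out
}

layer_num <- function(x) as.integer(sub("^L", "", x))

#' Signature overlap across genotypes
#'
#' Pairwise and joint intersection sizes of the per-layer signatures of
#' several genotypes (same timepoint).
#'
#' @param signatures named list of `layer_signature` objects, one per
#'   genotype.
#' @return data.frame with one row per (layer, genotype pair) plus rows
#'   `pair = "all"` carrying the joint intersection size per layer.
#' @export
signature_overlap <- function(signatures) {
  stop_if(length(signatures) < 2, "need at least two signatures")
  layers <- sort(unique(unlist(lapply(signatures, function(s) s$layer))))
  models <- names(signatures)
  rows <- list()
  for (L in layers) {
    sets <- lapply(signatures, function(s) s$protein[s$layer == L])
    for (i in seq_along(models)) {
      for (j in seq_along(models)) {
        if (j <= i) next
        rows[[length(rows) + 1L]] <- data.frame(
          layer = L, pair = paste(models[i], models[j], sep = ":"),
          overlap = length(intersect(sets[[i]], sets[[j]])),
          stringsAsFactors = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      layer = L, pair = "all",
      overlap = length(Reduce(intersect, sets)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
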