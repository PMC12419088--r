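#' Resampling consensus clustering of ablated layers
#'
#' Repeatedly subsamples the control samples, clusters each subsample
#' hierarchically (pairwise-complete Euclidean distance, Ward linkage), and
#' records for every sample pair the fraction of co-clusterings among
#' co-selections. The number of clusters is chosen by stability: the largest
#' `k` whose proportion of ambiguous consensus entries (PAC, entries strictly
#' between `pac_limits`) stays at or below `pac_max`; the Monti delta-area
#' statistic of the consensus CDF is also reported. Each ablated layer is then
#' assigned to the cluster holding the majority of its replicate samples, and
#' clusters are labelled C1, C2, ... by increasing mean layer index (most
#' superficial first).
#'
#' @param matrix proteins x samples matrix (typically CTRL samples of one
#'   timepoint); proteins with under `min_validity` observed values are
#'   dropped before distances are computed, missing values are tolerated via
#'   pairwise-complete distances.
#' @param manifest manifest covering the matrix columns (for layer indices).
#' @param k_range candidate cluster numbers, within `[2, n_samples - 1]`.
#' @param n_resamples number of subsampling iterations.
#' @param subsample_fraction fraction of samples drawn (without replacement)
#'   per iteration.
#' @param linkage hierarchical linkage method (see [stats::hclust()]).
#' @param min_validity minimum observed fraction for a protein to enter the
#'   distance computation.
#' @param pac_max stability tolerance on the PAC score.
#' @param pac_limits interval whose interior counts as ambiguous.
#' @param seed integer seed.
#' @return Object of class `consensus_result`: list with `consensus` (one
#'   sample x sample matrix per k), `area`, `delta_area`, `pac` (named by k),
#'   `selected_k`, `sample_clusters` (named integer vector at the selected k),
#'   `layer_cluster_map` (data.frame `timepoint`, `layer_index`, `cluster`).
#' @export
consensus_cluster <- function(matrix, manifest, k_range = 2:6,
                              n_resamples = 250L, subsample_fraction = 0.8,
                              linkage = "ward.D2", min_validity = 0.5,
                              pac_max = 0.05, pac_limits = c(0.1, 0.9),
                              seed = 1L) {
  check_matrix(matrix)
  man <- manifest_for_matrix(matrix, manifest)
  n <- ncol(matrix)
  stop_if(max(k_range) > n - 1 || min(k_range) < 2,
          "k_range must lie within [2, n_samples - 1]")
  set.seed(as.integer(seed))

  kept <- filter_by_validity(matrix, min_validity)
  d_full <- as.matrix(dist(t(kept)))  # pairwise-complete Euclidean, NA-scaled
  stop_if(anyNA(d_full), "distance undefined for some sample pair (too much missingness)")

  n_sub <- max(2L, round(subsample_fraction * n))
  co_cluster <- lapply(k_range, function(k) base::matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  co_select <- base::matrix(0, n, n)

  for (r in seq_len(n_resamples)) {
    idx <- sort(sample(n, n_sub))
    co_select[idx, idx] <- co_select[idx, idx] + 1
    hc <- hclust(as.dist(d_full[idx, idx]), method = linkage)
    for (k in k_range) {
      cl <- cutree(hc, k = k)
      same <- outer(cl, cl, "==")
      ck <- as.character(k)
      co_cluster[[ck]][idx, idx] <- co_cluster[[ck]][idx, idx] + same
    }
  }

  consensus <- lapply(co_cluster, function(cc) {
    cons <- cc / pmax(co_select, 1)
    cons[co_select == 0] <- 0
    dimnames(cons) <- list(colnames(matrix), colnames(matrix))
    cons
  })

  ut <- upper.tri(co_select)
  area <- vapply(consensus, function(cons) consensus_cdf_area(cons[ut]), numeric(1))
  pac <- vapply(consensus, function(cons) {
    mean(cons[ut] > pac_limits[1] & cons[ut] < pac_limits[2])
  }, numeric(1))
  delta <- area
  if (length(k_range) > 1) {
    delta[-1] <- diff(area) / area[-length(area)]
  }

  # nested-stability rule: grow k while the consensus stays unambiguous and
  # stop at the first unstable k; a clean k-cluster structure keeps every
  # coarser cut stable too, so the run up to the first unstable k identifies
  # the finest supported partition. Falls back to the least ambiguous k when
  # even the coarsest cut is unstable.
  stable_run <- cumprod(pac <= pac_max) == 1
  sel_idx <- if (any(stable_run)) max(which(stable_run)) else which.min(pac)
  selected_k <- k_range[sel_idx]

  # final partition: hierarchical clustering of the selected consensus matrix
  cons_sel <- consensus[[as.character(selected_k)]]
  hc_final <- hclust(as.dist(1 - cons_sel), method = linkage)
  cl_final <- cutree(hc_final, k = selected_k)

  # majority vote per layer, then relabel by mean layer index (superficial first)
  layer_map <- do.call(rbind, lapply(split(seq_len(n), list(man$timepoint, man$layer_index),
                                           drop = TRUE), function(ix) {
    votes <- table(cl_final[ix])
    data.frame(timepoint = man$timepoint[ix[1]],
               layer_index = man$layer_index[ix[1]],
               raw_cluster = as.integer(names(votes)[which.max(votes)]),
               stringsAsFactors = FALSE)
  }))
  mean_layer <- tapply(rep(layer_map$layer_index, 1), layer_map$raw_cluster, mean)
  relabel <- setNames(rank(mean_layer, ties.method = "first"),
                      names(mean_layer))
  layer_map$cluster <- paste0("C", relabel[as.character(layer_map$raw_cluster)])
  layer_map$raw_cluster <- NULL
  layer_map <- layer_map[order(layer_map$timepoint, layer_map$layer_index), ]
  rownames(layer_map) <- NULL

  sample_clusters <- setNames(
    paste0("C", relabel[as.character(cl_final)]), colnames(matrix))

  res <- list(consensus = consensus, area = area, delta_area = delta, pac = pac,
              k_range = k_range, selected_k = selected_k,
              sample_clusters = sample_clusters,
              layer_cluster_map = layer_map,
              n_resamples = n_resamples,
              subsample_fraction = subsample_fraction)
  class(res) <- "consensus_result"
  res
}

## Area under the empirical CDF of consensus entries on [0, 1].
consensus_cdf_area <- function(entries) {
  x <- sort(entries)
  # step-function integral over [0, 1]
  xs <- c(0, x, 1)
  cdf <- c(0, seq_along(x) / length(x), 1)
  sum(diff(xs) * cdf[-length(cdf)])
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering over k =", paste(x$k_range, collapse = ", "),
      "(", x$n_resamples, "resamples )\n")
  cat("PAC:", paste(sprintf("k=%s %.3f", x$k_range, x$pac), collapse = "  "), "\n")
  cat("Selected k =", x$selected_k, "\n")
  agg <- aggregate(layer_index ~ timepoint + cluster, x$layer_cluster_map,
                   function(v) paste0("L", min(v), "-L", max(v)))
  cat("Layer clusters:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Layers belonging to each consensus cluster
#'
#' @param result a `consensus_result`.
#' @return Named list of integer layer vectors, one per cluster label.
#' @export
cluster_layers <- function(result) {
  stop_if(!inherits(result, "consensus_result"), "need a consensus_result")
  split(result$layer_cluster_map$layer_index, result$layer_cluster_map$cluster)
}

#' Marker-panel abundance profile along depth
#'
#' Per layer, proteins are averaged over replicate samples; each protein's
#' layer profile is then z-scaled across layers and the scaled profiles are
#' averaged within each anatomical panel. Zero-variance proteins contribute 0
#' to their panel (their scaled profile is undefined); panel proteins missing
#' from the matrix are skipped with a warning.
#'
#' @param matrix proteins x samples matrix (one timepoint, typically CTRL).
#' @param manifest manifest covering the matrix columns.
#' @param panels named list of marker protein ids per compartment (default
#'   [default_marker_panels()]).
#' @return Matrix compartments x layers of scaled mean abundances; all-absent
#'   panels yield a row of NA.
#' @export
marker_panel_profile <- function(matrix, manifest,
                                 panels = default_marker_panels()) {
  check_matrix(matrix)
  man <- manifest_for_matrix(matrix, manifest)
  stop_if(length(intersect(unlist(panels), rownames(matrix))) == 0,
          "no panel protein present in the matrix")
  layers <- sort(unique(man$layer_index))
  layer_mean <- vapply(layers, function(L) {
    row_means_na(matrix[, man$layer_index == L, drop = FALSE])
  }, numeric(nrow(matrix)))
  layer_mean <- base::matrix(layer_mean, nrow = nrow(matrix),
                             dimnames = list(rownames(matrix), paste0("L", layers)))

  prof <- base::matrix(NA_real_, length(panels), length(layers),
                       dimnames = list(names(panels), paste0("L", layers)))
  for (comp in names(panels)) {
    present <- intersect(panels[[comp]], rownames(matrix))
    if (length(present) < length(panels[[comp]])) {
      warning("panel '", comp, "': missing protein(s) ",
              paste(setdiff(panels[[comp]], present), collapse = ", "),
              call. = FALSE)
    }
    if (length(present) == 0) next
    z <- t(apply(layer_mean[present, , drop = FALSE], 1, function(v) {
      s <- sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) return(rep(0, length(v)))
      (v - mean(v, na.rm = TRUE)) / s
    }))
    prof[comp, ] <- colMeans(z, na.rm = TRUE)
  }
  prof
}
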