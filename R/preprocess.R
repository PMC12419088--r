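#' Median normalization over samples
#'
#' Subtracts each sample's (column's) median over observed values so that
#' every column has median zero; the missingness pattern is untouched. Values
#' are expected on the log2 scale; with `assume_log2 = FALSE` a log2 transform
#' is applied first (all observed values must then be positive).
#'
#' @param matrix proteins x samples numeric matrix (NA = missing).
#' @param assume_log2 set `FALSE` for raw intensities.
#' @return The normalized matrix.
#' @export
normalize_median <- function(matrix, assume_log2 = TRUE) {
  check_matrix(matrix)
  if (!assume_log2) {
    stop_if(any(matrix <= 0, na.rm = TRUE),
            "raw intensities must be > 0 for log2 transform")
    matrix <- log2(matrix)
  }
  n_obs <- colSums(!is.na(matrix))
  if (any(n_obs == 0)) {
    stop("sample(s) with no observed values: ",
         paste(colnames(matrix)[n_obs == 0], collapse = ", "), call. = FALSE)
  }
  med <- apply(matrix, 2, median, na.rm = TRUE)
  sweep(matrix, 2, med, "-")
}

#' Default reference classes for batch correction
#'
#' Assigns every non-excluded sample to a genotype x layer-block class, the
#' blocks being the superficial/deep split used as correction references
#' (E14.5: L1-L4 vs L5-L9; E18.5: L1-L9 vs L10-L18).
#'
#' @param manifest a manifest.
#' @return data.frame with columns `sample_id`, `class`.
#' @export
reference_classes <- function(manifest) {
  check_manifest(manifest)
  m <- manifest[!manifest$excluded, , drop = FALSE]
  half <- ifelse(m$timepoint == "E14.5",
                 ifelse(m$layer_index <= 4, "L1-L4", "L5-L9"),
                 ifelse(m$layer_index <= 9, "L1-L9", "L10-L18"))
  data.frame(sample_id = m$sample_id,
             class = paste(m$model, half),
             stringsAsFactors = FALSE)
}

#' Batch-effect correction with optional reference classes
#'
#' Location adjustment per (protein, batch). With reference classes, the
#' per-batch offset of a protein is estimated from class-mean-centred
#' residuals of the reference samples only, then subtracted from every sample
#' of the batch. Without references, batch effects are estimated by a linear
#' model with the class labels as covariates (via
#' [limma::removeBatchEffect()]). Matrix shape and missingness are preserved.
#'
#' @param matrix proteins x samples matrix.
#' @param manifest manifest covering the matrix columns.
#' @param batch_key `"la_batch"` or `"m_batch"`.
#' @param references optional data.frame (`sample_id`, `class`); `NULL` uses
#'   the covariate-model route with classes from [reference_classes()].
#' @param scale also equalize per-batch residual scale (default off: with few
#'   samples per batch the variance estimates are unstable).
#' @return Corrected matrix. Per-(protein, batch) combinations with no
#'   observed reference values keep an offset of 0 (recorded in attribute
#'   `n_unestimated`).
#' @export
batch_correct <- function(matrix, manifest, batch_key = c("la_batch", "m_batch"),
                          references = NULL, scale = FALSE) {
  check_matrix(matrix)
  batch_key <- match.arg(batch_key)
  man <- manifest_for_matrix(matrix, manifest)
  batch <- man[[batch_key]]
  tab <- table(batch)
  stop_if(any(tab < 2), "each batch needs >= 2 samples")
  if (length(tab) < 2) return(matrix)  # single batch: nothing to correct

  cls_map <- if (is.null(references)) reference_classes(manifest) else references
  cls <- cls_map$class[match(colnames(matrix), cls_map$sample_id)]

  if (is.null(references)) {
    stop_if(anyNA(cls), "every sample in the matrix needs a class label")
    # covariate route: protein-wise linear model abundance ~ class + batch
    design <- model.matrix(~ factor(cls))
    out <- limma::removeBatchEffect(matrix, batch = factor(batch), design = design)
    dimnames(out) <- dimnames(matrix)
    attr(out, "n_unestimated") <- 0L
    return(out)
  }

  # reference route: class-centred residuals of reference samples per batch.
  # Samples without a reference class are corrected but do not contribute to
  # the estimates; classes confined to a single batch are skipped for
  # estimation (their class mean would absorb the batch offset).
  spans <- tapply(batch, cls, function(b) length(unique(b)))
  cls_est <- cls
  cls_est[cls %in% names(spans)[spans < 2]] <- NA
  stop_if(all(is.na(cls_est)), "no usable reference class spans >= 2 batches")
  out <- matrix
  n_unest <- 0L
  lev <- unique(cls_est[!is.na(cls_est)])
  class_mean <- vapply(lev, function(L) {
    row_means_na(matrix[, which(cls_est == L), drop = FALSE])
  }, numeric(nrow(matrix)))
  class_mean <- base::matrix(class_mean, nrow = nrow(matrix),
                             dimnames = list(rownames(matrix), lev))
  resid <- base::matrix(NA_real_, nrow(matrix), ncol(matrix),
                        dimnames = dimnames(matrix))
  ok <- !is.na(cls_est)
  resid[, ok] <- matrix[, ok, drop = FALSE] - class_mean[, cls_est[ok], drop = FALSE]
  for (b in names(tab)) {
    in_b <- batch == b
    off <- row_means_na(resid[, in_b, drop = FALSE])
    n_unest <- n_unest + sum(is.na(off))
    off[is.na(off)] <- 0
    out[, in_b] <- out[, in_b] - off
    if (isTRUE(scale)) {
      s_b <- apply(resid[, in_b, drop = FALSE], 1, sd, na.rm = TRUE)
      s_all <- apply(resid, 1, sd, na.rm = TRUE)
      fac <- s_all / s_b
      fac[!is.finite(fac) | fac <= 0] <- 1
      ctr <- row_means_na(out[, in_b, drop = FALSE])
      ctr[is.na(ctr)] <- 0
      out[, in_b] <- (out[, in_b] - ctr) * fac + ctr
    }
  }
  attr(out, "n_unestimated") <- n_unest
  out
}

#' Filter proteins by fraction of valid (observed) values
#'
#' Keeps proteins observed in at least `min_fraction` of the samples in
#' `scope` (>= semantics: a protein observed in exactly
#' `ceiling(min_fraction * n)` samples is kept). Row order is preserved.
#'
#' @param matrix proteins x samples matrix.
#' @param min_fraction required fraction in (0, 1]; the study uses 0.70 for
#'   differential testing and 1.0 for ordination/enrichment.
#' @param scope sample ids defining the denominator; default all columns.
#' @return The filtered matrix (possibly with zero rows).
#' @export
filter_by_validity <- function(matrix, min_fraction = 0.7,
                               scope = colnames(matrix)) {
  check_matrix(matrix)
  stop_if(min_fraction <= 0 || min_fraction > 1, "min_fraction must be in (0, 1]")
  stop_if(length(scope) == 0, "scope must be non-empty")
  stop_if(!all(scope %in% colnames(matrix)), "scope contains unknown samples")
  sub <- matrix[, scope, drop = FALSE]
  frac <- rowSums(!is.na(sub)) / length(scope)
  matrix[frac >= min_fraction - 1e-12, , drop = FALSE]
}
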