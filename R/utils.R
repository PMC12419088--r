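## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

check_manifest <- function(manifest) {
  need <- c("sample_id", "model", "timepoint", "hemisphere_id", "layer_index",
            "la_batch", "m_batch", "excluded")
  missing <- setdiff(need, names(manifest))
  stop_if(length(missing) > 0,
          "manifest is missing columns: ", paste(missing, collapse = ", "))
  stop_if(anyDuplicated(manifest$sample_id) > 0,
          "manifest sample_id values must be unique")
  invisible(manifest)
}

check_matrix <- function(x) {
  stop_if(!is.matrix(x) || !is.numeric(x), "abundance matrix must be a numeric matrix")
  stop_if(is.null(rownames(x)) || is.null(colnames(x)),
          "abundance matrix needs protein row names and sample column names")
  stop_if(anyDuplicated(rownames(x)) > 0, "duplicate protein ids in matrix")
  stop_if(anyDuplicated(colnames(x)) > 0, "duplicate sample ids in matrix")
  invisible(x)
}

## Align a manifest to the columns of a matrix (non-excluded samples only).
manifest_for_matrix <- function(matrix, manifest) {
  check_matrix(matrix)
  check_manifest(manifest)
  idx <- match(colnames(matrix), manifest$sample_id)
  stop_if(anyNA(idx), "matrix contains samples absent from the manifest")
  manifest[idx, , drop = FALSE]
}

## Row means that return NA (not NaN) for all-missing rows.
row_means_na <- function(x) {
  m <- rowMeans(x, na.rm = TRUE)
  m[!is.finite(m)] <- NA_real_
  m
}
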