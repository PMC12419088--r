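#' Default study design: hemisphere counts per genotype and timepoint
#'
#' The reference design ablates 9 layers per hemisphere at E14.5 and 18 at
#' E18.5, with 5 control hemispheres (4 biological replicates plus one
#' additional animal contributing left and right hemispheres as technical
#' replicates) and 3 hemispheres for each of GL, GB and GBL.
#'
#' @return A data.frame with columns `model`, `timepoint`, `n_hemispheres`,
#'   `n_layers`.
#' @export
default_design <- function() {
  data.frame(
    model = rep(MODEL_LEVELS, times = 2),
    timepoint = rep(TIMEPOINT_LEVELS, each = 4),
    n_hemispheres = rep(c(5L, 3L, 3L, 3L), 2),
    n_layers = rep(c(9L, 18L), each = 4),
    stringsAsFactors = FALSE
  )
}

#' Default sample exclusions
#'
#' Three quality-control exclusions: one E14.5 GBL sample lost to an ROI shift
#' during ablation, one E14.5 CTRL sample contaminated with human keratins,
#' and the nine deep layers (10-18) of one E18.5 CTRL hemisphere lost to an
#' ROI shift.
#'
#' @return A list of exclusion selectors; each selector is a list with fields
#'   `model`, `timepoint`, `hemisphere` (1-based index within the model),
#'   `layers` (integer vector) and `reason`.
#' @export
default_exclusions <- function() {
  list(
    list(model = "GBL", timepoint = "E14.5", hemisphere = 3L, layers = 9L,
         reason = "ROI shift during sampling"),
    list(model = "CTRL", timepoint = "E14.5", hemisphere = 5L, layers = 4L,
         reason = "high abundance of human keratins"),
    list(model = "CTRL", timepoint = "E18.5", hemisphere = 5L, layers = 10:18,
         reason = "ROI shift during sampling")
  )
}

#' Build a sample manifest from a hemisphere/layer design
#'
#' Creates one record per (model, timepoint, hemisphere, layer) and flags
#' records matched by exclusion selectors. Ablation batches emulate the study
#' logistics: hemispheres 1-3 of every genotype are spread over three ablation
#' batches each containing all genotypes and timepoints, while the additional
#' control hemispheres (4+) form a separate fourth batch. Measurement batches
#' split each ablation batch by timepoint (8 levels).
#'
#' @param design data.frame as returned by [default_design()].
#' @param exclusions list of selectors as returned by [default_exclusions()];
#'   use `list()` for no exclusions.
#' @return A data.frame manifest with columns `sample_id`, `model`,
#'   `timepoint`, `hemisphere_id`, `layer_index`, `la_batch`, `m_batch`,
#'   `excluded`, `exclusion_reason`, with attribute `n_retained` giving the
#'   non-excluded sample count.
#' @export
build_manifest <- function(design = default_design(),
                           exclusions = default_exclusions()) {
  stop_if(!all(c("model", "timepoint", "n_hemispheres", "n_layers") %in% names(design)),
          "design needs columns model, timepoint, n_hemispheres, n_layers")
  stop_if(any(design$n_hemispheres < 1), "hemisphere counts must be >= 1")
  stop_if(!all(design$n_layers %in% c(9L, 18L)),
          "layer counts must be 9 (E14.5) or 18 (E18.5)")
  stop_if(!all(design$model %in% MODEL_LEVELS),
          "unknown model in design")
  stop_if(!all(design$timepoint %in% TIMEPOINT_LEVELS),
          "unknown timepoint in design")

  rows <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    g <- expand.grid(hemisphere = seq_len(d$n_hemispheres),
                     layer_index = seq_len(d$n_layers),
                     KEEP.OUT.ATTRS = FALSE)
    g$model <- d$model
    g$timepoint <- d$timepoint
    g
  })
  m <- do.call(rbind, rows)
  m <- m[order(match(m$timepoint, TIMEPOINT_LEVELS),
               match(m$model, MODEL_LEVELS),
               m$hemisphere, m$layer_index), ]
  m$hemisphere_id <- sprintf("%s.%s.h%d", m$model, m$timepoint, m$hemisphere)
  m$sample_id <- sprintf("%s.L%02d", m$hemisphere_id, m$layer_index)
  # hemispheres 1-3 rotate through ablation batches 1-3; extras go to batch 4.
  # Each ablation batch is measured in two MS runs (odd vs even layers),
  # giving 8 measurement batches that cut across genotypes and layer blocks.
  m$la_batch <- ifelse(m$hemisphere <= 3L, paste0("LA", m$hemisphere), "LA4")
  m$m_batch <- paste0("M.", m$la_batch, ".", c("even", "odd")[m$layer_index %% 2 + 1])

  m$excluded <- FALSE
  m$exclusion_reason <- ""
  for (sel in exclusions) {
    stop_if(is.null(sel$model) || !sel$model %in% MODEL_LEVELS,
            "exclusion selector has unknown model: ", sel$model %||% "<missing>")
    stop_if(is.null(sel$timepoint) || !sel$timepoint %in% TIMEPOINT_LEVELS,
            "exclusion selector has unknown timepoint: ", sel$timepoint %||% "<missing>")
    hit <- m$model == sel$model & m$timepoint == sel$timepoint
    if (!is.null(sel$hemisphere)) hit <- hit & m$hemisphere %in% sel$hemisphere
    if (!is.null(sel$layers)) hit <- hit & m$layer_index %in% sel$layers
    m$excluded[hit] <- TRUE
    m$exclusion_reason[hit] <- sel$reason %||% "excluded"
  }

  m <- m[, c("sample_id", "model", "timepoint", "hemisphere_id", "layer_index",
             "la_batch", "m_batch", "excluded", "exclusion_reason")]
  rownames(m) <- NULL
  attr(m, "n_retained") <- sum(!m$excluded)
  check_manifest(m)
  m
}

#' Count non-excluded samples in a manifest
#'
#' @param manifest a manifest from [build_manifest()].
#' @param by optional column names to tabulate by (e.g. `c("timepoint", "model")`).
#' @return Total count, or a data.frame of counts when `by` is given.
#' @export
manifest_counts <- function(manifest, by = NULL) {
  check_manifest(manifest)
  keep <- manifest[!manifest$excluded, , drop = FALSE]
  if (is.null(by)) return(nrow(keep))
  agg <- aggregate(list(n = keep$sample_id), by = keep[by], FUN = length)
  agg[do.call(order, agg[by]), , drop = FALSE]
}

#' Read / write manifest TSV
#'
#' @param path file path.
#' @param manifest manifest data.frame.
#' @return `read_manifest()` returns the manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  m$excluded <- as.logical(m$excluded)
  m$exclusion_reason[is.na(m$exclusion_reason)] <- ""
  check_manifest(m)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  check_manifest(manifest)
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
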