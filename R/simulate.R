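#' Default anatomical marker panels
#'
#' Marker proteins used to annotate the anatomical identity of ablated layers:
#' skin (FLG, KRT14, LOR), bone (COL1A1, COL1A2, SERPINF1), meninges (CDH11,
#' CRABP2, TAGLN) and cerebral cortex (TBR1, MAP2, BCL11B).
#'
#' @return Named list of character vectors, one per compartment.
#' @export
default_marker_panels <- function() {
  list(
    skin     = c("FLG", "KRT14", "LOR"),
    bone     = c("COL1A1", "COL1A2", "SERPINF1"),
    meninges = c("CDH11", "CRABP2", "TAGLN"),
    cortex   = c("TBR1", "MAP2", "BCL11B")
  )
}

## Anatomical compartment of each layer, per timepoint. Superficial layers
## cover skin, bone and meningeal structures before the laser reaches cortex.
anatomy_layout <- function(timepoint) {
  if (timepoint == "E14.5") {
    c("skin", "bone", "meninges", "meninges", rep("cortex", 5))
  } else {
    c("skin", "bone", rep("meninges", 7), rep("cortex", 9))
  }
}

## Layer-block layout driving the bulk of between-layer proteome differences;
## blocks correspond to the consensus clusters recovered downstream
## (E14.5: layers 1-4 / 5-9; E18.5: 1-2 / 3-9 / 10-18).
default_block_layout <- function() {
  list(
    "E14.5" = rep(c("B1", "B2"), times = c(4, 5)),
    "E18.5" = rep(c("B1", "B2", "B3"), times = c(2, 7, 9))
  )
}

#' Configuration for the synthetic abundance generator
#'
#' Defines the planted structure of a simulated log2 abundance matrix: layer
#' blocks (giving cluster structure), anatomical marker panels, linear depth
#' gradients, two nested batch effects, an intensity-dependent (left-censored)
#' missingness mechanism, and genotype-specific perturbations.
#'
#' @param n_proteins total proteins simulated (marker proteins included).
#' @param block_layout per-timepoint layer-block labels (see
#'   `default_block_layout()`); blocks receive independent per-protein offsets
#'   for `block_fraction` of proteins (sd `block_sd`), which is what makes the
#'   layer clusters separable.
#' @param marker_panels anatomical marker panels; each marker is boosted by
#'   `marker_effect` log2 units in its compartment's layers.
#' @param gradient_fraction fraction of proteins given a linear depth trend.
#' @param gradient_range absolute slope range (log2 units per layer); signs
#'   are random.
#' @param block_fraction,block_sd fraction of proteins with layer-block
#'   offsets, and the sd of those offsets.
#' @param marker_effect log2 boost of a marker in its own compartment.
#' @param marker_maturation multiplier applied to `marker_effect` at E14.5;
#'   the default 0.5 emulates the structural immaturity of skin, bone and
#'   meninges at the earlier timepoint (anatomical markers are weaker there),
#'   which is also why the earlier timepoint supports a coarser layer
#'   clustering.
#' @param noise_sd residual sd (log2 units) per measurement.
#' @param la_batch_sd,m_batch_sd sd of additive per-(batch, protein) offsets.
#' @param batch_scale logical; also apply multiplicative per-batch scale
#'   (drawn around 1); default off.
#' @param mnar_mid,mnar_scale logistic missingness: a value x is missing with
#'   probability `plogis((mnar_mid - x)/mnar_scale)`, so missingness rises as
#'   abundance falls. Set `mnar_scale = 0` to disable missingness.
#' @param perturbations list of planted genotype effects; each element is a
#'   list with `model`, `timepoint`, `proteins`, `layers`, and either
#'   `effect` (additive log2 shift), `type = "slope_inversion"` (flip the
#'   protein's planted depth gradient for that genotype), or
#'   `type = "slope_delta"` with `slope` (add an extra log2-per-layer trend). The default plants the two headline effects:
#'   an identity shift in GBL (superficial E18.5 layers carry deep-layer
#'   profiles) and a drop of the ECM protein LAMB1 in GBL meningeal layers,
#'   plus slope inversions of the laminin receptor axis (RPSA, ITGB1).
#' @param shift_layers integer layers of GBL E18.5 whose systematic profile is
#'   replaced by the mirrored deep layer (`n_layers + 1 - layer`); `NULL`
#'   disables the identity shift.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 1000L,
                             block_layout = default_block_layout(),
                             marker_panels = default_marker_panels(),
                             gradient_fraction = 0.3,
                             gradient_range = c(0.02, 0.08),
                             block_fraction = 0.4,
                             block_sd = 1.0,
                             marker_effect = 3.0,
                             marker_maturation = 0.5,
                             noise_sd = 0.5,
                             la_batch_sd = 0.4,
                             m_batch_sd = 0.25,
                             batch_scale = FALSE,
                             mnar_mid = -4.0,
                             mnar_scale = 0.6,
                             perturbations = default_perturbations(),
                             shift_layers = 1:6) {
  panels <- marker_panels
  all_markers <- unlist(panels, use.names = FALSE)
  stop_if(anyDuplicated(all_markers) > 0,
          "every marker protein must appear in exactly one panel")
  stop_if(mnar_scale < 0, "mnar_scale must be >= 0")
  for (p in perturbations) {
    stop_if(!is.null(p$effect) && !all(is.finite(p$effect)),
            "perturbation effect sizes must be finite")
  }
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    block_layout = block_layout,
    marker_panels = panels,
    gradient_fraction = gradient_fraction,
    gradient_range = gradient_range,
    block_fraction = block_fraction,
    block_sd = block_sd,
    marker_effect = marker_effect,
    marker_maturation = marker_maturation,
    noise_sd = noise_sd,
    la_batch_sd = la_batch_sd,
    m_batch_sd = m_batch_sd,
    batch_scale = batch_scale,
    mnar_mid = mnar_mid,
    mnar_scale = mnar_scale,
    perturbations = perturbations,
    shift_layers = shift_layers
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Default genotype-specific perturbations
#'
#' @return List of perturbation descriptors (see [generator_config()]).
#' @export
default_perturbations <- function() {
  list(
    # ECM collapse at the pial border: LAMB1 drops in GBL meningeal layers
    list(model = "GBL", timepoint = "E14.5", proteins = "LAMB1",
         layers = 3:4, effect = -2.5),
    list(model = "GBL", timepoint = "E18.5", proteins = "LAMB1",
         layers = 3:9, effect = -2.5),
    # laminin receptor axis: depth gradient inverted in GBL
    list(model = "GBL", timepoint = "E18.5", proteins = c("RPSA", "ITGB1"),
         type = "slope_inversion"),
    list(model = "GBL", timepoint = "E14.5", proteins = c("RPSA", "ITGB1"),
         type = "slope_inversion")
  )
}

## Protein id vector: named markers plus LAMB1/RPSA/ITGB1, padded with P####.
protein_ids <- function(cfg) {
  named <- c(unlist(cfg$marker_panels, use.names = FALSE),
             "LAMB1", "RPSA", "ITGB1")
  n_pad <- cfg$n_proteins - length(named)
  stop_if(n_pad < 0, "n_proteins smaller than the number of named proteins")
  c(named, sprintf("P%04d", seq_len(n_pad)))
}

#' Simulate a log2 abundance matrix with planted ground truth
#'
#' Each value is built as baseline + layer-block offset + marker boost +
#' gradient x layer + genotype perturbation + batch offsets + Gaussian noise,
#' then masked by a logistic missing-not-at-random mechanism in the true
#' abundance. All planted parameters are returned as ground truth so
#' downstream stages can be verified against them.
#'
#' @param config a [generator_config()].
#' @param manifest a manifest from [build_manifest()]; only non-excluded
#'   samples receive columns.
#' @param seed integer seed; the single source of randomness.
#' @return List with `matrix` (proteins x samples, NAs for missing),
#'   `truth` (list of planted parameter tables) and `config`.
#' @export
simulate_abundance <- function(config = generator_config(),
                               manifest = build_manifest(),
                               seed = 1L) {
  stop_if(!inherits(config, "generator_config"), "config must be a generator_config")
  check_manifest(manifest)
  stop_if(nrow(manifest) == 0, "manifest is empty")
  for (tp in unique(manifest$timepoint)) {
    stop_if(is.null(config$block_layout[[tp]]) ||
              length(config$block_layout[[tp]]) != layers_per_timepoint(tp),
            "block_layout for ", tp, " must cover all ",
            layers_per_timepoint(tp), " layers")
  }

  set.seed(as.integer(seed))
  samples <- manifest[!manifest$excluded, , drop = FALSE]
  prot <- protein_ids(config)
  np <- length(prot)

  baseline <- rnorm(np, mean = 0, sd = 1.5)
  names(baseline) <- prot

  # linear depth gradients for a random subset; the ECM receptors always get a
  # positive gradient so their planted inversion is well-defined
  slope <- numeric(np)
  names(slope) <- prot
  is_grad <- runif(np) < config$gradient_fraction
  slope[is_grad] <- sample(c(-1, 1), sum(is_grad), replace = TRUE) *
    runif(sum(is_grad), config$gradient_range[1], config$gradient_range[2])
  slope[c("RPSA", "ITGB1")] <- 0.15
  slope["MAP2"] <- abs(slope["MAP2"]) + 0.10  # cortex marker rises with depth
  slope[c("TBR1", "BCL11B")] <- abs(slope[c("TBR1", "BCL11B")]) + 0.05

  # per-(protein, block) offsets giving layer-cluster structure
  blocks <- unique(unlist(lapply(config$block_layout, unique)))
  has_block <- runif(np) < config$block_fraction
  block_off <- matrix(0, np, length(blocks), dimnames = list(prot, blocks))
  block_off[has_block, ] <- rnorm(sum(has_block) * length(blocks),
                                  sd = config$block_sd)
  # meningeal ECM protein: planted high where meninges are ablated
  block_off["LAMB1", ] <- 0

  # batch offsets
  la_levels <- sort(unique(samples$la_batch))
  m_levels <- sort(unique(samples$m_batch))
  la_off <- matrix(rnorm(np * length(la_levels), sd = config$la_batch_sd),
                   np, length(la_levels), dimnames = list(prot, la_levels))
  m_off <- matrix(rnorm(np * length(m_levels), sd = config$m_batch_sd),
                  np, length(m_levels), dimnames = list(prot, m_levels))
  if (length(la_levels) < 2) la_off[] <- 0
  la_scale <- matrix(1, np, length(la_levels), dimnames = list(prot, la_levels))
  if (isTRUE(config$batch_scale)) {
    la_scale[] <- exp(rnorm(np * length(la_levels), sd = 0.1))
  }

  # systematic (noise- and batch-free) expected value for (protein set, model,
  # timepoint, layer); used both for simulation and for the ground truth
  systematic_layer <- function(tp, layer, model) {
    lay <- layer
    if (model == "GBL" && tp == "E18.5" && !is.null(config$shift_layers) &&
        layer %in% config$shift_layers) {
      lay <- layers_per_timepoint(tp) + 1L - layer  # mirrored deep layer
    }
    anat <- anatomy_layout(tp)[lay]
    blk <- config$block_layout[[tp]][lay]
    v <- baseline + block_off[, blk] + slope * lay
    boost <- config$marker_effect *
      if (tp == "E14.5") config$marker_maturation else 1
    for (comp in names(config$marker_panels)) {
      if (comp == anat) {
        v[config$marker_panels[[comp]]] <-
          v[config$marker_panels[[comp]]] + boost
      }
    }
    if (anat == "meninges") v["LAMB1"] <- v["LAMB1"] + boost
    # genotype perturbations
    for (p in config$perturbations) {
      if (!is.null(p$timepoint) && p$timepoint != tp) next
      if (p$model != model) next
      pr <- intersect(p$proteins, prot)
      if (identical(p$type, "slope_inversion")) {
        v[pr] <- v[pr] - 2 * slope[pr] * lay
      } else if (identical(p$type, "slope_delta")) {
        v[pr] <- v[pr] + p$slope * lay
      } else if (is.null(p$layers) || layer %in% p$layers) {
        v[pr] <- v[pr] + p$effect
      }
    }
    v
  }

  mat <- matrix(NA_real_, np, nrow(samples),
                dimnames = list(prot, samples$sample_id))
  true_mean <- mat
  for (j in seq_len(nrow(samples))) {
    s <- samples[j, ]
    mu <- systematic_layer(s$timepoint, s$layer_index, s$model)
    true_mean[, j] <- mu
    x <- mu * la_scale[, s$la_batch] + la_off[, s$la_batch] + m_off[, s$m_batch]
    x <- x + rnorm(np, sd = config$noise_sd)
    mat[, j] <- x
  }

  if (config$mnar_scale > 0) {
    p_miss <- plogis((config$mnar_mid - mat) / config$mnar_scale)
    miss <- matrix(runif(length(mat)) < p_miss, nrow(mat), ncol(mat))
    mat[miss] <- NA_real_
  }

  truth <- list(
    baseline = baseline,
    slope = slope,
    block_offsets = block_off,
    la_offsets = la_off,
    m_offsets = m_off,
    la_scale = la_scale,
    true_mean = true_mean,
    block_layout = config$block_layout,
    anatomy = lapply(setNames(TIMEPOINT_LEVELS, TIMEPOINT_LEVELS), anatomy_layout),
    shift_layers = config$shift_layers,
    perturbations = config$perturbations,
    seed = as.integer(seed)
  )
  list(matrix = mat, truth = truth, config = config)
}

#' Simulate gene sets matched to the planted depth gradients
#'
#' Builds a GMT-style collection: sets of proteins sharing a positive planted
#' gradient, sets sharing a negative gradient, and random (null) sets.
#'
#' @param truth ground truth from [simulate_abundance()].
#' @param n_sets sets per category.
#' @param set_size proteins per set.
#' @param seed integer seed.
#' @return Named list of character vectors with attribute `direction`
#'   (`"up"`, `"down"`, `"null"` per set).
#' @export
simulate_genesets <- function(truth, n_sets = 10L, set_size = 15L, seed = 1L) {
  set.seed(as.integer(seed))
  up <- names(truth$slope)[truth$slope > 0.03]
  down <- names(truth$slope)[truth$slope < -0.03]
  all <- names(truth$slope)
  sets <- list()
  dir <- character(0)
  for (i in seq_len(n_sets)) {
    sets[[sprintf("GRADIENT_UP_%02d", i)]] <- sample(up, min(set_size, length(up)))
    sets[[sprintf("GRADIENT_DOWN_%02d", i)]] <- sample(down, min(set_size, length(down)))
    sets[[sprintf("RANDOM_%02d", i)]] <- sample(all, set_size)
    dir <- c(dir, "up", "down", "null")
  }
  # order as inserted: up/down/null interleaved
  attr(sets, "direction") <- setNames(dir, names(sets))
  sets
}

#' Fabricate a term-representation table
#'
#' Stands in for precomputed GO:BP parent-term enrichment: for each term and
#' genotype a set of represented layers with adjusted p-values. Useful for
#' exercising [best_match()] and [diff_score()] without external databases.
#'
#' @param n_terms number of parent terms.
#' @param n_layers layers in the timepoint (9 or 18).
#' @param models genotypes to include.
#' @param absent_prob probability a (term, model) is unrepresented.
#' @param seed integer seed.
#' @return data.frame with columns `term`, `model`, `layer`, `adj_p`.
#' @export
simulate_term_representation <- function(n_terms = 20L, n_layers = 9L,
                                         models = MODEL_LEVELS,
                                         absent_prob = 0.2, seed = 1L) {
  set.seed(as.integer(seed))
  out <- list()
  for (t in sprintf("TERM_%03d", seq_len(n_terms))) {
    for (m in models) {
      if (runif(1) < absent_prob) next
      layers <- sort(sample(n_layers, sample(1:4, 1)))
      out[[length(out) + 1L]] <- data.frame(
        term = t, model = m, layer = layers,
        adj_p = 10^runif(length(layers), -6, log10(0.05)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
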