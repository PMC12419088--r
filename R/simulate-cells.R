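#' Configuration for simulated cell measurements
#'
#' Per-genotype parameters for the migration/proliferation tables: BrdU+ cell
#' migration distances are drawn from a normal truncated to
#' `[0, cortex thickness]`; marker positivity is Bernoulli per cell. Default
#' distance and thickness means are the study's printed group means; the
#' spreads and positivity rates are package choices of realistic magnitude.
#'
#' @param distance_mean,distance_sd named per-genotype mean/sd of migration
#'   distance (um from the ventricular margin).
#' @param roi_mean_sd between-ROI (between-animal) sd of the distance mean
#'   (um); each ROI draws its own mean around the genotype mean.
#' @param thickness_mean,thickness_sd per-genotype cortex thickness (um);
#'   three thickness measurements are taken per ROI.
#' @param cells_per_roi expected BrdU+ cells per ROI (Poisson).
#' @param n_roi replicate ROIs (animals) per genotype.
#' @param margin_length_um ventricular-margin length measured per ROI.
#' @param marker_rates per-genotype named list of positivity rates for
#'   `Ki67`, `pHH3`, `Reelin` (BrdU is implicit: all tracked cells are BrdU+).
#'   The Ki67 rate doubles as the cell-cycle re-entry fraction.
#' @return List of class `cell_sim_config`.
#' @export
cell_sim_config <- function(
    distance_mean = c(CTRL = 171.94, GL = 182.90, GB = 107.15, GBL = 112.85),
    distance_sd = c(CTRL = 80, GL = 80, GB = 60, GBL = 75),
    roi_mean_sd = 15,
    thickness_mean = c(CTRL = 456.83, GL = 447.38, GB = 240.92, GBL = 225.12),
    thickness_sd = c(CTRL = 25, GL = 25, GB = 20, GBL = 30),
    cells_per_roi = c(CTRL = 607, GL = 545, GB = 380, GBL = 371),
    n_roi = 3L,
    margin_length_um = 800,
    marker_rates = list(
      CTRL = c(Ki67 = 0.30, pHH3 = 0.05, Reelin = 0.02),
      GL   = c(Ki67 = 0.32, pHH3 = 0.08, Reelin = 0.02),
      GB   = c(Ki67 = 0.45, pHH3 = 0.03, Reelin = 0.01),
      GBL  = c(Ki67 = 0.45, pHH3 = 0.04, Reelin = 0.02)
    )) {
  stop_if(any(distance_mean < 0), "distance means must be >= 0")
  stop_if(any(unlist(marker_rates) < 0 | unlist(marker_rates) > 1),
          "marker positivity rates must lie in [0, 1]")
  stop_if(n_roi < 1, "n_roi must be >= 1")
  models <- names(distance_mean)
  stop_if(is.null(models), "distance_mean must be a named per-genotype vector")
  recycle <- function(v) {
    if (length(v) == 1 && is.null(names(v))) v <- setNames(rep(v, length(models)), models)
    stop_if(!all(models %in% names(v)), "per-genotype parameter missing a genotype")
    v[models]
  }
  distance_sd <- recycle(distance_sd)
  thickness_mean <- recycle(thickness_mean)
  thickness_sd <- recycle(thickness_sd)
  cells_per_roi <- recycle(cells_per_roi)
  cfg <- list(distance_mean = distance_mean, distance_sd = distance_sd,
              roi_mean_sd = roi_mean_sd,
              thickness_mean = thickness_mean, thickness_sd = thickness_sd,
              cells_per_roi = cells_per_roi, n_roi = n_roi,
              margin_length_um = margin_length_um, marker_rates = marker_rates)
  class(cfg) <- "cell_sim_config"
  cfg
}

## normal truncated to [lo, hi] by inverse-CDF sampling
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

#' Simulate a per-cell measurement table
#'
#' @param config a [cell_sim_config()].
#' @param timepoint label stored in the table (no effect on the draws).
#' @param seed integer seed.
#' @return List with `cells` (one row per cell: `cell_id`, `model`,
#'   `timepoint`, `roi_id`, `distance_um`, logical marker columns `BrdU`,
#'   `Ki67`, `pHH3`, `Reelin`) and `rois` (per-ROI `margin_length_um` and
#'   three `thickness_um` measurements in long form).
#' @export
simulate_cells <- function(config = cell_sim_config(), timepoint = "E16.5",
                           seed = 1L) {
  stop_if(!inherits(config, "cell_sim_config"), "config must be a cell_sim_config")
  set.seed(as.integer(seed))
  cells <- list()
  rois <- list()
  for (model in names(config$distance_mean)) {
    for (r in seq_len(config$n_roi)) {
      roi_id <- sprintf("%s.roi%d", model, r)
      thick <- rnorm(3, config$thickness_mean[[model]], config$thickness_sd[[model]])
      n_cells <- stats::rpois(1, config$cells_per_roi[[model]])
      roi_mu <- config$distance_mean[[model]] + rnorm(1, 0, config$roi_mean_sd)
      d <- rtruncnorm(n_cells, roi_mu,
                      config$distance_sd[[model]], 0, mean(thick))
      rates <- config$marker_rates[[model]]
      tab <- data.frame(
        cell_id = sprintf("%s.c%05d", roi_id, seq_len(n_cells)),
        model = model, timepoint = timepoint, roi_id = roi_id,
        distance_um = d,
        BrdU = TRUE,
        Ki67 = runif(n_cells) < rates[["Ki67"]],
        pHH3 = runif(n_cells) < rates[["pHH3"]],
        Reelin = runif(n_cells) < rates[["Reelin"]],
        stringsAsFactors = FALSE)
      cells[[roi_id]] <- tab
      rois[[roi_id]] <- data.frame(
        roi_id = roi_id, model = model, timepoint = timepoint,
        margin_length_um = config$margin_length_um,
        measurement = 1:3, thickness_um = thick,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells)
  rois <- do.call(rbind, rois)
  rownames(cells) <- rownames(rois) <- NULL
  stopifnot(all(cells$distance_um >= 0), all(rois$margin_length_um > 0))
  list(cells = cells, rois = rois)
}
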