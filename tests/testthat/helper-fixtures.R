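# Shared fixtures: small designs and configs used across test files.

# reduced design: all four genotypes, two hemispheres each, one timepoint
mini_design <- function(timepoint = "E14.5", n_hemispheres = 2L) {
  data.frame(
    model = c("CTRL", "GL", "GB", "GBL"),
    timepoint = timepoint,
    n_hemispheres = n_hemispheres,
    n_layers = if (timepoint == "E14.5") 9L else 18L,
    stringsAsFactors = FALSE
  )
}

mini_manifest <- function(timepoint = "E14.5", n_hemispheres = 2L) {
  build_manifest(mini_design(timepoint, n_hemispheres), exclusions = list())
}

# deterministic generator: no noise, batches, missingness or perturbations
clean_config <- function(n_proteins = 60L, perturbations = list(),
                         shift_layers = NULL, noise_sd = 0, ...) {
  generator_config(
    n_proteins = n_proteins, noise_sd = noise_sd, la_batch_sd = 0,
    m_batch_sd = 0, mnar_scale = 0, perturbations = perturbations,
    shift_layers = shift_layers, ...
  )
}

# standard preprocessing used by the workflow
preprocess_pipeline <- function(matrix, manifest) {
  x <- normalize_median(matrix)
  x <- suppressWarnings(
    batch_correct(x, manifest, "la_batch", references = reference_classes(manifest)))
  suppressWarnings(batch_correct(x, manifest, "m_batch", references = NULL))
}

# small hand-set abundance matrix with named proteins/samples
toy_matrix <- function(values, proteins, samples) {
  matrix(values, nrow = length(proteins), byrow = TRUE,
         dimnames = list(proteins, samples))
}
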