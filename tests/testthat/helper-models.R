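# Scaled training of the detector + Siamese pair is the expensive part of
# the suite; one shared pair (memoized here) serves both the detector
# accuracy property and the end-to-end occlusion study.

.model_cache <- new.env(parent = emptyenv())

acceptanceConfig <- function() {
  cfg <- loadConfig(NULL)
  cfg$seed <- 1L
  cfg$arena_frames <- 300L
  cfg$train_frames <- 200L
  cfg$epochs <- 55L
  cfg$batch_size <- 4L
  cfg$learning_rate <- 0.02
  cfg$siamese_epochs <- 6L
  cfg$confidence_threshold <- 0.2
  cfg
}

acceptanceModels <- function() {
  if (is.null(.model_cache$models)) {
    .model_cache$models <- MRTrack:::trainModelsOnSynthetic(acceptanceConfig())
  }
  .model_cache$models
}
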