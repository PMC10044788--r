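# End-to-end orchestration: simulate -> preprocess -> (train) -> track ->
# link -> evaluate -> behaviour, under one configuration and one seed. A
# single global seed fans out to per-stage seeds by fixed offsets so each
# stage is individually reproducible.

seedOffsets <- c(simulate = 0L, trainvideo = 101L, detector = 202L,
                 siamese = 303L)

arenaSpecFromConfig <- function(config, nSubjects, nFrames, seed,
                                minSeparation = 0) {
  ArenaSpec(width = config$img_size, height = config$img_size,
            nSubjects = nSubjects, bodyAxes = c(config$body_major,
                                                config$body_minor),
            earRadius = config$ear_radius, speedScale = config$speed_scale,
            nFrames = nFrames, frameRate = config$frame_rate,
            noiseSd = config$noise_sd, minSeparation = minSeparation,
            seed = seed)
}

# Train detector + siamese on an auto-labelled single-subject synthetic
# video, mirroring the double-threshold labelling route.
trainModelsOnSynthetic <- function(config) {
  tcfg <- config
  # the single-subject training clip uses a brisker walk than the study
  # video: more pose and location diversity per frame, and a cleaner
  # background model
  if (!is.null(config$train_speed_scale))
    tcfg$speed_scale <- config$train_speed_scale
  spec <- arenaSpecFromConfig(tcfg, nSubjects = 1,
                              nFrames = config$train_frames,
                              seed = config$seed + seedOffsets[["trainvideo"]])
  video <- simulateArena(spec)
  labels <- autoLabelEars(arenaFrames(video), config)
  dcfg <- detectorConfig(imgSize = config$img_size,
                         improved = config$improved_neck,
                         baseWidth = config$base_width,
                         confidenceThreshold = config$confidence_threshold,
                         nmsIoU = config$nms_iou, epochs = config$epochs,
                         batchSize = config$batch_size,
                         learningRate = config$learning_rate,
                         finalLrFactor = config$final_lr_factor,
                         momentum = config$momentum,
                         seed = config$seed + seedOffsets[["detector"]])
  detector <- buildDetector(dcfg, labels)
  detector <- trainDetector(detector, arenaFrames(video), labels)
  scfg <- siameseConfig(cropSize = config$crop_size,
                        embedDim = config$embed_dim, margin = config$margin,
                        epochs = config$siamese_epochs,
                        minScore = config$min_score,
                        negGapSeconds = config$neg_gap_seconds,
                        seed = config$seed + seedOffsets[["siamese"]])
  obs <- lapply(seq_len(nrow(labels)), function(r)
    makeObservation(getFrame(arenaFrames(video), labels$frame[r] + 1L),
                    labels$frame[r],
                    as.numeric(labels[r, c("x0", "y0", "x1", "y1")]),
                    id = labels$id[r], cropSize = config$crop_size))
  frate <- frameRate(arenaFrames(video))
  gap <- config$neg_gap_seconds
  # at desk scale the video may be shorter than the full negative gap;
  # shrink the gap to half the clip when necessary (logged)
  max_gap_frames <- max(diff(range(labels$frame)) - 1, 1)
  if (gap * frate > max_gap_frames) {
    gap <- floor(max_gap_frames / 2) / frate
    logMsg("info", "negative-pair gap shrunk to %.1f s for a short clip", gap)
  }
  pairs <- makePairs(obs, frate, negGapSeconds = gap,
                     nPos = min(config$siamese_pairs,
                                sum(table(labels$id) - 1)),
                     nNeg = config$siamese_pairs,
                     seed = config$seed + seedOffsets[["siamese"]])
  sim <- buildSiamese(scfg)
  sim <- trainSimilarity(sim, obs, pairs,
                         frameDims = c(config$img_size, config$img_size))
  list(detector = detector, siamese = sim, labels = labels,
       trainVideo = video)
}

# Ear-track one occlusion fragment (flank-to-flank) with the trained
# models; returns the per-individual position table the linker consumes.
earTrackOcclusion <- function(fragment, seq, blobsPerFrame, detector,
                              siamese, config) {
  f0 <- if (!is.na(fragment$flank_before)) fragment$flank_before else
    fragment$start
  f1 <- if (!is.na(fragment$flank_after)) fragment$flank_after else
    fragment$end
  frames <- f0:f1
  W <- frameDim(seq)[2]; H <- frameDim(seq)[1]
  # during occlusion tracking a missed ear is costlier than a spurious
  # detection (unmatched detections stay unassigned), so detect at a lower
  # threshold than the general-purpose default
  thr <- if (!is.null(config$track_confidence)) config$track_confidence else
    max(0.1, config$confidence_threshold / 2)
  obsPerFrame <- lapply(frames, function(fr) {
    det <- detectEars(detector, getFrame(seq, fr + 1L),
                      confidenceThreshold = thr)
    lapply(seq_len(nrow(det)), function(r)
      makeObservation(getFrame(seq, fr + 1L), fr,
                      as.numeric(det[r, c("x0", "y0", "x1", "y1")]),
                      cropSize = config$crop_size))
  })
  first <- obsPerFrame[[1]]
  if (length(first) == 0)
    return(data.frame(frame = integer(), ind = integer(), x = numeric(),
                      y = numeric()))
  initIds <- seq_along(first)
  et <- trackEarFragment(siamese, obsPerFrame, initIds, c(W, H),
                         frames = frames)
  # each ear belongs to the individual (blob index) containing it on the
  # initialization frame
  blobs0 <- blobsPerFrame[[f0 + 1L]]
  pos0 <- data.frame(ind = initIds,
                     x = vapply(first, function(o) o$centroid[1], 1.0),
                     y = vapply(first, function(o) o$centroid[2], 1.0))
  e2i <- matchEarsToBlobs(pos0, blobs0, H)
  ear2ind <- setNames(e2i, initIds)
  ok <- !is.na(ear2ind[as.character(et$ear)])
  et <- et[ok, , drop = FALSE]
  if (nrow(et) == 0)
    return(data.frame(frame = integer(), ind = integer(), x = numeric(),
                      y = numeric()))
  grouped <- groupEarsToIndividuals(et, ear2ind)
  grouped
}

# Non-bijective containment/nearest mapping of ear positions to blobs
# (several ears share one blob).
matchEarsToBlobs <- function(pos, blobs, frameHeight) {
  vapply(seq_len(nrow(pos)), function(i) {
    scores <- vapply(seq_along(blobs), function(j) {
      b <- blobs[[j]]
      d <- sqrt((pos$x[i] - b$centroid[1])^2 + (pos$y[i] - b$centroid[2])^2)
      px <- round(pos$x[i]); py <- round(pos$y[i])
      flat <- py + frameHeight * px + 1
      inside <- flat %in% b$pixels
      d - if (inside) 1e3 else 0
    }, 1.0)
    if (length(scores) == 0) return(NA_integer_)
    which.min(scores)
  }, 1L)
}

#' Run the full tracking pipeline
#'
#' Simulates (or accepts) a video, trains the ear detector and the
#' dual-Siamese model on an auto-labelled single-subject synthetic clip,
#' classifies frames, tracks non-occlusion fragments by blob overlap and
#' occlusion fragments by ear detection plus similarity assignment, links
#' the fragments, and evaluates against ground truth when available.
#'
#' @param config configuration list (see \code{\link{loadConfig}}).
#' @param video optional \linkS4class{ArenaVideo}; simulated from the
#'   config when NULL.
#' @param models optional list(detector, siamese) of pre-trained models.
#' @param outDir optional directory for stage artifacts (tracks CSV,
#'   fragments CSV, report JSON).
#' @return list with elements \code{config}, \code{seed}, \code{video},
#'   \code{models}, \code{fragments}, \code{tracks}, \code{metrics},
#'   \code{behavior}, \code{timings} (seconds per stage), \code{report}.
#' @export
runPipeline <- function(config = loadConfig(NULL), video = NULL,
                        models = NULL, outDir = NULL) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  if (is.null(video)) {
    spec <- arenaSpecFromConfig(config, nSubjects = config$n_subjects,
                                nFrames = config$arena_frames,
                                seed = config$seed +
                                  seedOffsets[["simulate"]])
    video <- simulateArena(spec)
  }
  timings["simulate"] <- tic() - t0
  t0 <- tic()
  if (is.null(models)) models <- trainModelsOnSynthetic(config)
  timings["train"] <- tic() - t0
  t0 <- tic()
  seq <- arenaFrames(video)
  sg <- segmentSequence(seq, config)
  counts <- vapply(sg$blobs, length, 1L)
  kinds <- classifyFrames(counts, config$n_subjects)
  fragments <- splitFragments(kinds)
  timings["preprocess"] <- tic() - t0
  t0 <- tic()
  earTracks <- vector("list", nrow(fragments))
  if (any(fragments$kind == "occlusion") &&
      (is.null(models$detector) || is.null(models$siamese)))
    stop("configuration error: occlusion fragments present but no ",
         "detector/similarity model supplied and training is disabled")
  for (k in seq_len(nrow(fragments))) {
    if (fragments$kind[k] != "occlusion") next
    earTracks[[k]] <- earTrackOcclusion(fragments[k, ], seq, sg$blobs,
                                        models$detector, models$siamese,
                                        config)
  }
  timings["track"] <- tic() - t0
  t0 <- tic()
  tracks <- linkFragments(fragments, sg$blobs, earTracks,
                          config$n_subjects, frameDim(seq)[1])
  timings["link"] <- tic() - t0
  t0 <- tic()
  metrics <- NULL
  if (nrow(video@truth) > 0) {
    counts_ <- scoreTracks(tracks, arenaTracks(video),
                           matchRadius = config$match_radius,
                           driftRadius = config$drift_radius,
                           window = config$mapping_window)
    metrics <- list(counts = counts_, icr = icr(counts_),
                    mota = mota(counts_))
  }
  W <- frameDim(seq)[2]; H <- frameDim(seq)[1]
  behavior <- lapply(sort(unique(tracks$id)), function(id) {
    tr <- tracks[tracks$id == id, , drop = FALSE]
    vs <- velocitySeries(tr, frameRate(seq), config$px_per_cm,
                         config$block_seconds)
    ss <- spatialSD(tr$x / config$px_per_cm, tr$y / config$px_per_cm)
    occ <- regionOccupancy(tr, xRange = c(W / 4, 3 * W / 4),
                           yRange = c(H * 5 / 16, H * 11 / 16),
                           cellSize = W / 8)
    list(id = id, meanSpeed = mean(vs$speeds$speed),
         blockMeans = vs$blockMeans, sigma2d = ss$sigma2d,
         occupancy = occ$fractions)
  })
  timings["evaluate"] <- tic() - t0
  run <- list(config = config, seed = config$seed, video = video,
              models = models, fragments = fragments, tracks = tracks,
              metrics = metrics, behavior = behavior, timings = timings,
              report = attr(tracks, "report"))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTracks(tracks, file.path(outDir, "tracks.csv"))
    write.csv(fragments, file.path(outDir, "fragments.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           icr = if (!is.null(metrics)) metrics$icr,
           mota = if (!is.null(metrics)) metrics$mota,
           timings = as.list(timings)),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  run
}
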