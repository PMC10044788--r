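# Fuse per-fragment tracks into global per-individual trajectories. Global
# identities are carried by the non-occlusion (blob) fragments; every
# occlusion fragment is bridged by its ear-based individual tracks, which
# are matched to blob identities on the flanking non-occlusion frames
# (spatial containment with a nearest-centroid fallback) and relabelled.
# When the two flanks disagree, the earlier flank wins and the conflict is
# logged; an individual unmatched on both flanks leaves an explicit gap.

# Bijective match of individual positions to blobs of one frame; cost is
# centroid distance with a strong bonus for containment in the blob mask.
matchIndividualsToBlobs <- function(pos, blobs, frameHeight) {
  ni <- nrow(pos); nb <- length(blobs)
  C <- matrix(0, ni, nb)
  for (i in seq_len(ni)) {
    for (j in seq_len(nb)) {
      b <- blobs[[j]]
      d <- sqrt((pos$x[i] - b$centroid[1])^2 + (pos$y[i] - b$centroid[2])^2)
      px <- round(pos$x[i]); py <- round(pos$y[i])
      flat <- py + frameHeight * px + 1
      inside <- !is.na(flat) && flat >= 1 && flat %in% b$pixels
      C[i, j] <- d - if (inside) 1e3 else 0
    }
  }
  if (ni <= nb) {
    solveAssignment(C)
  } else {
    as_ <- solveAssignment(t(C))
    out <- rep(NA_integer_, ni)
    out[as_] <- seq_len(nb)
    out
  }
}

#' Link fragment tracks into global trajectories
#'
#' @param fragments fragment table from \code{\link{splitFragments}}.
#' @param blobsPerFrame list over all frames (1-based position = frame + 1)
#'   of blob lists from \code{\link{segmentBlobs}}.
#' @param earTracksPerFragment list indexed by fragment row; for each
#'   occlusion fragment, a data.frame (frame, ind, x, y) of fragment-local
#'   individual positions covering at least the flank frames reachable by
#'   the ear tracker.
#' @param nSubjects declared number of subjects.
#' @param frameHeight frame height in pixels (for mask containment tests).
#' @return data.frame (frame, id, x, y, source) with source
#'   \code{blob} or \code{ear}; attribute \code{gaps} lists (frame, id)
#'   pairs without a position, and attribute \code{report} the per-fragment
#'   linkage audit list.
#' @export
linkFragments <- function(fragments, blobsPerFrame, earTracksPerFragment,
                          nSubjects, frameHeight) {
  nfrag <- nrow(fragments)
  rows <- list()
  report <- list()
  pending_seed <- NULL       # ids per blob (area order) for next non-occ frag
  frag_results <- vector("list", nfrag)
  # forward pass over fragments
  for (k in seq_len(nfrag)) {
    fr <- fragments[k, ]
    if (fr$kind == "non_occlusion") {
      idxs <- (fr$start:fr$end) + 1L
      seed <- if (!is.null(pending_seed)) pending_seed else seq_len(nSubjects)
      res <- trackFragment(blobsPerFrame[idxs], seedIds = seed,
                           startFrame = fr$start)
      res$tracks$conf <- NULL
      res$tracks$source <- "blob"
      frag_results[[k]] <- res
      rows[[length(rows) + 1]] <- res$tracks
      pending_seed <- NULL
      report[[k]] <- list(kind = "non_occlusion", seed = seed)
    } else {
      et <- earTracksPerFragment[[k]]
      mapping <- NULL
      conflict <- FALSE
      if (!is.na(fr$flank_before) && k > 1 &&
          !is.null(frag_results[[k - 1]])) {
        prev <- frag_results[[k - 1]]
        blob_ids <- prev$idsPerFrame[[length(prev$idsPerFrame)]]
        posb <- et[et$frame == fr$flank_before, , drop = FALSE]
        if (nrow(posb) > 0) {
          mb <- matchIndividualsToBlobs(posb,
                                        blobsPerFrame[[fr$flank_before + 1L]],
                                        frameHeight)
          mapping <- setNames(blob_ids[mb], posb$ind)
          mapping <- mapping[!is.na(mapping)]
        }
      }
      if (is.null(mapping) || length(mapping) == 0) {
        # occlusion fragment at the sequence start (or unmatched before):
        # seed the following fragment canonically and map on the after flank
        if (!is.na(fr$flank_after)) {
          posa <- et[et$frame == fr$flank_after, , drop = FALSE]
          blobs_a <- blobsPerFrame[[fr$flank_after + 1L]]
          if (nrow(posa) > 0 && length(blobs_a) == nSubjects) {
            ma <- matchIndividualsToBlobs(posa, blobs_a, frameHeight)
            mapping <- setNames(ma, posa$ind)   # blob area order = ids 1..n
            mapping <- mapping[!is.na(mapping)]
            pending_seed <- seq_len(nSubjects)
          }
        }
      } else if (!is.na(fr$flank_after)) {
        # seed the next fragment from the after flank, under the mapping
        # fixed by the earlier flank (earlier flank wins on disagreement)
        posa <- et[et$frame == fr$flank_after, , drop = FALSE]
        blobs_a <- blobsPerFrame[[fr$flank_after + 1L]]
        if (nrow(posa) > 0 && length(blobs_a) == nSubjects) {
          ma <- matchIndividualsToBlobs(posa, blobs_a, frameHeight)
          seed <- rep(NA_integer_, nSubjects)
          for (r in seq_len(nrow(posa))) {
            gid <- mapping[as.character(posa$ind[r])]
            if (!is.na(ma[r]) && !is.na(gid)) {
              if (!is.na(seed[ma[r]]) && seed[ma[r]] != gid) conflict <- TRUE
              if (is.na(seed[ma[r]])) seed[ma[r]] <- gid
            }
          }
          if (anyNA(seed)) seed[is.na(seed)] <-
              setdiff(seq_len(nSubjects), seed[!is.na(seed)])
          pending_seed <- seed
          if (conflict)
            logMsg("warn",
                   "fragment %d: flank disagreement; earlier flank kept", k)
        }
      }
      report[[k]] <- list(kind = "occlusion", mapping = mapping,
                          conflict = conflict)
      if (!is.null(mapping) && length(mapping) > 0) {
        inner <- et[et$frame >= fr$start & et$frame <= fr$end, , drop = FALSE]
        gid <- mapping[as.character(inner$ind)]
        ok <- !is.na(gid)
        if (any(ok))
          rows[[length(rows) + 1]] <- data.frame(
            frame = inner$frame[ok], id = as.integer(gid[ok]),
            x = inner$x[ok], y = inner$y[ok], source = "ear")
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = integer(), id = integer(), x = numeric(),
                      y = numeric(), source = character())
  # collapse duplicate (frame, id) rows (a flank frame appears in both a
  # blob fragment and an ear fragment): blob positions take precedence
  out <- out[order(out$frame, out$id, out$source != "blob"), , drop = FALSE]
  out <- out[!duplicated(out[, c("frame", "id")]), , drop = FALSE]
  rownames(out) <- NULL
  all_frames <- fragments$start[1]:fragments$end[nfrag]
  want <- expand.grid(frame = all_frames, id = seq_len(nSubjects))
  have <- paste(out$frame, out$id)
  gaps <- want[!paste(want$frame, want$id) %in% have, , drop = FALSE]
  if (nrow(gaps) > 0)
    logMsg("info", "%d (frame, identity) gaps left unfilled", nrow(gaps))
  attr(out, "gaps") <- gaps
  attr(out, "report") <- report
  out
}
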