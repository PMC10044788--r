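# Shared fixtures: tiny deterministic arenas and helper constructors used
# across the suite. Everything is generated in code at test time.

tinyArena <- function(nSubjects = 2, nFrames = 30, seed = 3, noiseSd = 0,
                      width = 128, height = 128, speedScale = 2,
                      minSeparation = 0) {
  simulateArena(ArenaSpec(width = width, height = height,
                          nSubjects = nSubjects, nFrames = nFrames,
                          noiseSd = noiseSd, seed = seed,
                          speedScale = speedScale,
                          minSeparation = minSeparation))
}

# brute-force IoU-free reference for assignment problems
bruteAssign <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(ncol(cost)))) {
    p <- p[seq_len(n)]
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost - 1e-12) { best_cost <- cst; best <- p }
  }
  list(assign = best, cost = best_cost)
}

box <- function(x0, y0, x1, y1) c(x0, y0, x1, y1)
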