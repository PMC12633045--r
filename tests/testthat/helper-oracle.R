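# Independent brute-force oracle for the interval search: enumerate a dense
# grid of candidate loci, read each recombinant's state by explicit nearest
# flank scanning, and return the minimum discordance and the positions
# achieving it. Written deliberately from scratch.
oracle_min_discordance <- function(gmat, pos, suppressed) {
  gmat <- as.matrix(gmat)
  grid <- sort(unique(c(pos, pos - 0.25, pos + 0.25,
                        (head(pos, -1) + tail(pos, -1)) / 2)))
  state_one <- function(g, locus) {
    if (locus %in% pos && !is.na(g[which(pos == locus)])) {
      return(g[which(pos == locus)])
    }
    lf <- rf <- NA_character_
    for (j in seq_along(pos)) if (pos[j] <= locus && !is.na(g[j])) lf <- g[j]
    for (j in rev(seq_along(pos))) if (pos[j] > locus && !is.na(g[j])) rf <- g[j]
    if (is.na(lf)) return(rf)
    if (is.na(rf)) return(lf)
    if (identical(lf, rf)) lf else NA_character_
  }
  scores <- vapply(grid, function(locus) {
    s <- 0
    for (i in seq_len(nrow(gmat))) {
      st <- state_one(gmat[i, ], locus)
      if (!is.na(st) && ((st == "donor") != suppressed[i])) s <- s + 1
    }
    s
  }, numeric(1))
  list(min_score = min(scores), argmin = grid[scores == min(scores)])
}
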