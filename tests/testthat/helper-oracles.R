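# Independent test oracles and small corpus builders. These deliberately
# use different algorithms from the package code they check.

# Brute-force non-dominated sorting: rank = 1 + max rank over explicit
# dominator scans, processed in a dominator-respecting order. O(n^2).
bruteNdsRank <- function(x, y, mode = "weak") {
  n <- length(x)
  rank <- integer(n)
  ord <- order(-x, -y)
  for (i in ord) {
    dom <- if (mode == "weak")
      which(x >= x[i] & y >= y[i] & (x > x[i] | y > y[i]))
    else
      which(x > x[i] & y > y[i])
    rank[i] <- if (length(dom)) 1L + max(rank[dom]) else 1L
  }
  rank
}

# Pareto-maximal mask (weak dominance) by a single staircase sweep:
# a point survives iff it has the max y within its x value and beats
# the best y of every strictly larger x.
staircaseParetoMask <- function(x, y) {
  ux <- sort(unique(x), decreasing = TRUE)
  besty <- vapply(ux, function(v) max(y[x == v]), numeric(1))
  run <- cummax(c(-Inf, besty))[seq_along(ux)]  # best y over larger x
  i <- match(x, ux)
  y == besty[i] & y > run[i]
}

# Random mention table (in-memory, no files) with optional disease-free
# publications; returns the data.frame readMentions() would produce.
randomMentions <- function(nPubs = 40, nTargets = 8, nDiseases = 6,
                           tMean = 2, dMean = 1.5) {
  rows <- list()
  for (k in seq_len(nPubs)) {
    ts <- sample(sprintf("T%02d", seq_len(nTargets)),
                 min(rpois(1, tMean), nTargets))
    ds <- sample(sprintf("DOID:%04d", seq_len(nDiseases)),
                 min(rpois(1, dMean), nDiseases))
    if (!length(ts) && !length(ds)) next
    rows[[length(rows) + 1L]] <- data.frame(
      pub_id = sprintf("P%03d", k),
      entity_kind = c(rep("target", length(ts)), rep("disease", length(ds))),
      entity_id = c(ts, ds), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(pub_id = character(0), entity_kind = character(0),
                      entity_id = character(0)))
  do.call(rbind, rows)
}

# Canonical form of a support table for set comparisons.
canonSupport <- function(s) {
  s <- s[order(s$target_id, s$disease_id, s$pub_id), ]
  rownames(s) <- NULL
  s
}

goldenPaths <- function() makeGoldenFixture(file.path(tempdir(), "corpusG"))

writeObo <- function(lines) {
  f <- tempfile(fileext = ".obo")
  writeLines(lines, f)
  f
}
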