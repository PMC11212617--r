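#' Pareto dominance between two score points
#'
#' Both axes are maximized. Under the default weak convention, p
#' dominates q when p is at least as good in both coordinates and
#' strictly better in at least one; a point never dominates its equal.
#' Under the strict convention p must be strictly better in both.
#'
#' @param p,q numeric length-2 vectors `(novelty, importance)`, finite.
#' @param mode `"weak"` (default) or `"strict"`.
#' @return logical: does p dominate q?
#' @examples
#' dominates(c(2, 2), c(1, 1))   # TRUE
#' dominates(c(1, 2), c(2, 1))   # FALSE either way
#' dominates(c(2, 2), c(2, 2))   # FALSE
#' @export
dominates <- function(p, q, mode = c("weak", "strict")) {
  mode <- match.arg(mode)
  stopifnot(length(p) == 2L, length(q) == 2L,
            all(is.finite(p)), all(is.finite(q)))
  if (mode == "strict") all(p > q) else all(p >= q) && any(p > q)
}

#' Non-dominated-solution (NDS) front ranks
#'
#' Assigns Pareto front ranks over two maximized objectives: rank 1 is
#' the non-dominated set, rank 2 the non-dominated set once rank 1 is
#' removed, and so on. Co-located duplicate points share a rank (equal
#' points never dominate one another).
#'
#' The assignment is the 2-D special case of non-dominated sorting:
#' points are sorted by the first objective descending and each point is
#' placed on the earliest front by binary search over the per-front
#' maxima of the second objective (a patience-sorting sweep), which is
#' O(n log n) overall. Equivalent to, and tested against, brute-force
#' front peeling.
#'
#' @param novelty,importance equal-length finite numeric vectors.
#' @param mode dominance convention, see [dominates()].
#' @return integer vector of front ranks (>= 1), aligned with the input.
#' @examples
#' ndsRank(c(1, 2, 3, 2, 1), c(5, 3, 1, 2, 1))  # 1 1 1 2 3
#' @export
ndsRank <- function(novelty, importance, mode = c("weak", "strict")) {
  mode <- match.arg(mode)
  n <- length(novelty)
  stopifnot(length(importance) == n)
  if (n == 0L) return(integer(0))
  stopifnot(all(is.finite(novelty)), all(is.finite(importance)))
  dt <- data.table(x = as.numeric(novelty), y = as.numeric(importance))
  ux <- unique(dt)
  grp <- ux[dt, on = c("x", "y"), which = TRUE]  # row in ux per input point
  ord <- order(-ux$x, -ux$y)
  xs <- ux$x[ord]; ys <- ux$y[ord]
  m <- length(ord)
  rank_sorted <- integer(m)
  fmax <- numeric(0)  # fmax[f]: max y among points assigned to front f
  if (mode == "weak") {
    for (i in seq_len(m)) {
      # dominators of point i are all earlier points with y >= ys[i];
      # deepest front containing one = count of fronts with fmax >= ys[i]
      f <- findInterval(-ys[i], -fmax) + 1L
      rank_sorted[i] <- f
      if (f > length(fmax)) fmax <- c(fmax, ys[i])
      else if (ys[i] > fmax[f]) fmax[f] <- ys[i]
    }
  } else {
    # strict mode: points with equal x never dominate each other, so
    # process equal-x batches against the fronts of strictly-greater x
    i <- 1L
    while (i <= m) {
      j <- i
      while (j < m && xs[j + 1L] == xs[i]) j <- j + 1L
      batch <- i:j
      f <- integer(length(batch))
      for (b in seq_along(batch)) {
        # fronts holding a strict dominator: fmax > y
        f[b] <- findInterval(-ys[batch[b]], -fmax, left.open = TRUE) + 1L
      }
      for (b in seq_along(batch)) {
        fb <- f[b]; yb <- ys[batch[b]]
        rank_sorted[batch[b]] <- fb
        if (fb > length(fmax)) fmax <- c(fmax, yb)
        else if (yb > fmax[fb]) fmax[fb] <- yb
      }
      i <- j + 1L
    }
  }
  rank_unique <- integer(m)
  rank_unique[ord] <- rank_sorted
  rank_unique[grp]
}

#' Rank and order an association table
#'
#' Adds NDS ranks over the chosen novelty axis and importance, imposes
#' the deterministic total order (rank ascending, importance descending,
#' novelty descending, then target and disease ids), numbers rows within
#' each front, and truncates to the top `k`. If fewer than `k` rows
#' exist, all are returned.
#'
#' Ranks are meant to be computed per browse query — over the targets of
#' one disease or the diseases of one target — which is what
#' [queryAssociations()] does; this function ranks whatever table it is
#' given.
#'
#' @param records data.frame of scored associations.
#' @param noveltyCol which novelty column defines the novelty axis
#'   (`"target_novelty"` when comparing targets, `"disease_novelty"`
#'   when comparing diseases).
#' @param k maximum number of rows returned (default 300, the display
#'   budget of the interactive tool); must be >= 1.
#' @param mode dominance convention, see [dominates()].
#' @return `records` with `nds_rank` and 0-based `within_rank_order`
#'   columns, ordered and truncated.
#' @export
rankAssociations <- function(records,
                             noveltyCol = c("target_novelty", "disease_novelty"),
                             k = 300L, mode = c("weak", "strict")) {
  noveltyCol <- match.arg(noveltyCol)
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop("k must be a single integer >= 1")
  k <- as.integer(k)
  if (!nrow(records)) {
    records$nds_rank <- integer(0)
    records$within_rank_order <- integer(0)
    return(records)
  }
  nov <- records[[noveltyCol]]
  imp <- records$importance
  r <- ndsRank(nov, imp, mode = mode)
  ord <- order(r, -imp, -nov, records$target_id, records$disease_id)
  out <- records[ord, , drop = FALSE]
  out$nds_rank <- r[ord]
  out$within_rank_order <- stats::ave(seq_len(nrow(out)), out$nds_rank,
                                      FUN = seq_along) - 1L
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Rank one browse query
#'
#' The per-query view of an [AssociationSet-class]: for a disease, its
#' associated targets ranked over (target novelty, importance); for a
#' target, its associated diseases ranked over (disease novelty,
#' importance). Log plot coordinates `log_novelty`/`log_importance` in
#' the requested base are appended.
#'
#' @param x an [AssociationSet-class].
#' @param disease,target exactly one of the two: the query id.
#' @param k top-K cut, see [rankAssociations()].
#' @param mode dominance convention.
#' @param logBase base for the plot coordinates, 10 (default) or exp(1).
#' @return ranked data.frame as in [rankAssociations()] plus log
#'   coordinate columns.
#' @export
queryAssociations <- function(x, disease = NULL, target = NULL, k = 300L,
                              mode = c("weak", "strict"), logBase = 10) {
  mode <- match.arg(mode)
  a <- x@associations
  if (is.null(disease) == is.null(target))
    stop("give exactly one of 'disease' or 'target'")
  if (!is.null(disease)) {
    rec <- a[a$disease_id == disease, , drop = FALSE]
    if (!nrow(rec)) stop("unknown or unsupported disease id: ", disease)
    axis <- "target_novelty"
  } else {
    rec <- a[a$target_id == target, , drop = FALSE]
    if (!nrow(rec)) stop("unknown or unsupported target id: ", target)
    axis <- "disease_novelty"
  }
  out <- rankAssociations(rec, noveltyCol = axis, k = k, mode = mode)
  out$log_novelty <- log(out[[axis]], base = logBase)
  out$log_importance <- log(out$importance, base = logBase)
  out
}
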