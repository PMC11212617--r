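# Reference scorer: a deliberately naive, loop-based evaluation of the
# novelty and importance definitions, kept free of the data.table
# machinery in scoring.R so simulated corpora carry ground truth computed
# by an independent route. Used by simulateCorpus() and the test suite.

#' Naive reference scoring of a mention table
#'
#' Straight-from-the-definitions evaluation: per-publication entity sets
#' are built with base R, ancestor closures by recursive walks over a
#' parent list, and every score by an explicit loop over publications.
#' Quadratic and slow by design — it exists as an independent
#' cross-check for [scoreAssociations()], not as the implementation.
#'
#' @param mentions data.frame (pub_id, entity_kind, entity_id).
#' @param parents optional named list doid -> character vector of parent
#'   doids describing an is_a hierarchy (no alt-id/obsolete handling:
#'   synthetic and fixture inputs use primary ids only).
#' @return list with `novelty` (named numeric), `disease_novelty` (named
#'   numeric, propagated publication sets), `importance` (data.frame
#'   target_id, disease_id, importance, n_pubs) and `support` (data.frame
#'   of triples).
#' @export
naiveAssociationScores <- function(mentions, parents = NULL) {
  mentions <- unique(mentions[c("pub_id", "entity_kind", "entity_id")])
  pub_ids <- sort(unique(mentions$pub_id))
  tsets <- lapply(pub_ids, function(p)
    sort(unique(mentions$entity_id[mentions$pub_id == p &
                                   mentions$entity_kind == "target"])))
  dsets <- lapply(pub_ids, function(p)
    sort(unique(mentions$entity_id[mentions$pub_id == p &
                                   mentions$entity_kind == "disease"])))
  names(tsets) <- names(dsets) <- pub_ids
  Tk <- lengths(tsets); Dk <- lengths(dsets)

  anc_of <- function(d) {
    if (is.null(parents) || is.null(parents[[d]])) return(character(0))
    out <- character(0)
    frontier <- parents[[d]]
    while (length(frontier)) {
      frontier <- setdiff(frontier, out)
      out <- c(out, frontier)
      frontier <- unique(unlist(parents[frontier], use.names = FALSE))
    }
    sort(unique(out))
  }
  # propagated disease set per publication (direct + ancestors)
  dprop <- lapply(dsets, function(ds)
    sort(unique(c(ds, unlist(lapply(ds, anc_of), use.names = FALSE)))))

  all_targets <- sort(unique(unlist(tsets, use.names = FALSE)))
  novelty <- vapply(all_targets, function(t) {
    s <- 0
    for (p in pub_ids) if (t %in% tsets[[p]]) s <- s + 1 / Tk[[p]]
    1 / s
  }, numeric(1))

  all_d <- sort(unique(unlist(dprop, use.names = FALSE)))
  disease_novelty <- vapply(all_d, function(d) {
    s <- 0
    for (p in pub_ids) if (d %in% dprop[[p]]) s <- s + 1 / Dk[[p]]
    1 / s
  }, numeric(1))

  rows <- list(); sup <- list()
  for (t in all_targets) for (d in all_d) {
    ids <- character(0); imp <- 0
    for (p in pub_ids)
      if (t %in% tsets[[p]] && d %in% dprop[[p]]) {
        ids <- c(ids, p)
        imp <- imp + 1 / (Tk[[p]] * Dk[[p]])
      }
    if (length(ids)) {
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = t, disease_id = d, importance = imp,
        n_pubs = length(ids), stringsAsFactors = FALSE)
      sup[[length(sup) + 1L]] <- data.frame(
        target_id = t, disease_id = d, pub_id = ids,
        stringsAsFactors = FALSE)
    }
  }
  importance <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(0), disease_id = character(0),
               importance = numeric(0), n_pubs = integer(0))
  support <- if (length(sup)) do.call(rbind, sup) else
    data.frame(target_id = character(0), disease_id = character(0),
               pub_id = character(0))
  rownames(importance) <- rownames(support) <- NULL
  list(novelty = novelty, disease_novelty = disease_novelty,
       importance = importance, support = support)
}
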