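#' Target novelty scores
#'
#' Fractional-counting novelty of a target i:
#' \deqn{N_i = 1 / \sum_k 1/T_k}
#' summed over every publication k mentioning i, where T_k is the number
#' of distinct targets tagged in k. A publication devoted to a single
#' target contributes a full count (1/1); a publication tagging many
#' targets is split fractionally among them. High novelty means little
#' has been published about the target. The sum includes publications
#' with no disease mentions — the denominator is about targets only.
#'
#' Summation order is fixed (sorted pub_id) so results are
#' bit-reproducible and independent of input row order.
#'
#' @param corpus a [PublicationCorpus-class].
#' @param targets character vector of target ids, or `NULL` (default)
#'   for every target in the corpus. A target with zero publications is
#'   an error — its novelty is undefined, not 0 or Inf.
#' @return named numeric vector of novelty scores.
#' @examples
#' rows <- data.frame(pub_id = "P1", entity_kind = "target", entity_id = "A")
#' targetNovelty(buildCorpus(rows))  # single-target publication: N = 1
#' @export
targetNovelty <- function(corpus, targets = NULL) {
  tm <- as.data.table(corpus@targetMentions)
  pubs <- as.data.table(corpus@publications)
  dt <- merge(tm, pubs[, list(pub_id, n_targets)], by = "pub_id")
  setkeyv(dt, c("target_id", "pub_id"))  # stable summation order
  nov <- dt[, list(novelty = 1 / sum(1 / n_targets)), by = "target_id"]
  out <- stats::setNames(nov$novelty, nov$target_id)
  if (is.null(targets)) return(out)
  miss <- setdiff(targets, names(out))
  if (length(miss))
    stop("novelty undefined for target(s) with no publications: ",
         paste(miss, collapse = ", "))
  out[targets]
}

#' Disease novelty scores
#'
#' Symmetric analogue of [targetNovelty()] on the disease axis:
#' \eqn{N_j = 1 / \sum_k 1/D_k} over publications mentioning disease j,
#' with D_k the number of distinct diseases tagged in publication k.
#' When an ontology is supplied, the publication set of a term is its
#' propagated set — publications mentioning the term or any descendant,
#' each counted once — while D_k stays the direct-mention count; for
#' leaves and directly mentioned terms this reduces to the plain
#' definition.
#'
#' @inheritParams targetNovelty
#' @param diseases character vector of disease term ids, or `NULL` for
#'   all (propagated) terms with support.
#' @param ontology optional [DiseaseOntology-class] for propagation.
#' @return named numeric vector of disease novelty scores.
#' @export
diseaseNovelty <- function(corpus, diseases = NULL, ontology = NULL) {
  dx <- .expandDiseaseMentions(corpus, ontology)
  pubs <- as.data.table(corpus@publications)
  dt <- merge(dx, pubs[, list(pub_id, n_diseases)], by = "pub_id")
  setkeyv(dt, c("disease_id", "pub_id"))
  nov <- dt[, list(novelty = 1 / sum(1 / n_diseases)), by = "disease_id"]
  out <- stats::setNames(nov$novelty, nov$disease_id)
  if (is.null(diseases)) return(out)
  miss <- setdiff(diseases, names(out))
  if (length(miss))
    stop("novelty undefined for disease(s) with no publications: ",
         paste(miss, collapse = ", "))
  out[diseases]
}

#' Importance scores for supported target-disease pairs
#'
#' Importance of the association between target i and disease j:
#' \deqn{I_{ij} = \sum_k 1/(T_k D_k)}
#' summed over the supporting publications k of the pair (direct
#' co-mentions, plus ontology-propagated support when the support table
#' was built with an ontology). T_k and D_k are always the
#' direct-mention counts of publication k; propagation changes which
#' pairs a publication supports, never its denominators. High importance
#' means much has been published tying the target to the disease.
#'
#' @param corpus a [PublicationCorpus-class].
#' @param support support triples from [propagateSupport()].
#' @return data.frame (target_id, disease_id, importance, n_pubs),
#'   sorted by target then disease; empty support yields an empty
#'   data.frame.
#' @export
importanceScores <- function(corpus, support) {
  stopifnot(all(c("target_id", "disease_id", "pub_id") %in% names(support)))
  if (!nrow(support))
    return(data.frame(target_id = character(0), disease_id = character(0),
                      importance = numeric(0), n_pubs = integer(0),
                      stringsAsFactors = FALSE))
  tri <- as.data.table(support)
  pubs <- as.data.table(corpus@publications)
  dt <- merge(tri, pubs[, list(pub_id, n_targets, n_diseases)], by = "pub_id")
  if (any(dt$n_targets < 1L) || any(dt$n_diseases < 1L))
    stop("supporting publication with T_k = 0 or D_k = 0; support table ",
         "inconsistent with the corpus")
  setkeyv(dt, c("target_id", "disease_id", "pub_id"))  # stable order
  imp <- dt[, list(importance = sum(1 / (n_targets * n_diseases)),
                   n_pubs = .N),
            by = c("target_id", "disease_id")]
  as.data.frame(imp)
}

#' Single-pair importance
#'
#' Convenience scalar form of [importanceScores()]; errors if the pair
#' has no supporting publication (the association does not exist).
#'
#' @inheritParams importanceScores
#' @param targetId,diseaseId the pair to score.
#' @return a single positive number.
#' @export
importanceScore <- function(corpus, support, targetId, diseaseId) {
  sel <- support[support$target_id == targetId &
                 support$disease_id == diseaseId, , drop = FALSE]
  if (!nrow(sel))
    stop("no supporting publications for (", targetId, ", ", diseaseId, ")")
  importanceScores(corpus, sel)$importance
}

#' Score all supported associations
#'
#' Runs the full scoring pass: propagates support through the ontology,
#' computes importance for every supported (target, disease) pair and
#' novelty for every target and disease involved, and annotates each row
#' with gene symbol, Target Development Level and IDG family from the
#' catalog (`unknown` where absent) plus the ontology term name.
#'
#' @param corpus a [PublicationCorpus-class].
#' @param ontology optional [DiseaseOntology-class]; `NULL` scores
#'   direct co-mentions only.
#' @param catalog optional [TargetCatalog-class] for annotation.
#' @return an [AssociationSet-class]; empty corpus gives an empty set.
#' @examples
#' rows <- data.frame(pub_id = c("P1", "P1"),
#'                    entity_kind = c("target", "disease"),
#'                    entity_id = c("A", "DOID:1"))
#' associations(scoreAssociations(buildCorpus(rows)))
#' @export
scoreAssociations <- function(corpus, ontology = NULL, catalog = NULL) {
  support <- propagateSupport(corpus, ontology)
  imp <- importanceScores(corpus, support)
  if (!nrow(imp)) {
    empty <- data.frame(
      target_id = character(0), symbol = character(0), tdl = character(0),
      idg_family = character(0), disease_id = character(0),
      disease_name = character(0), importance = numeric(0),
      target_novelty = numeric(0), disease_novelty = numeric(0),
      n_pubs = integer(0), stringsAsFactors = FALSE)
    return(new("AssociationSet", associations = empty, support = support))
  }
  tnov <- targetNovelty(corpus)
  dnov <- diseaseNovelty(corpus, ontology = ontology)
  a <- imp
  a$target_novelty <- unname(tnov[a$target_id])
  a$disease_novelty <- unname(dnov[a$disease_id])
  a$symbol <- a$target_id
  a$tdl <- "unknown"
  a$idg_family <- "unknown"
  if (!is.null(catalog)) {
    tg <- catalog@targets
    i <- match(a$target_id, tg$target_id)
    hit <- !is.na(i)
    a$symbol[hit] <- tg$symbol[i[hit]]
    a$tdl[hit] <- tg$tdl[i[hit]]
    a$idg_family[hit] <- tg$idg_family[i[hit]]
  }
  a$disease_name <- a$disease_id
  if (!is.null(ontology)) {
    terms <- ontology@terms
    i <- match(a$disease_id, terms$doid)
    hit <- !is.na(i) & terms$name[ifelse(is.na(i), 1L, i)] != ""
    a$disease_name[hit] <- terms$name[i[hit]]
  }
  a <- a[order(a$target_id, a$disease_id), .ASSOC_COLS]
  rownames(a) <- NULL
  new("AssociationSet", associations = a, support = support)
}

#' @rdname accessors
setMethod("associations", "AssociationSet", function(x) x@associations)

#' @rdname accessors
setMethod("supportTriples", "AssociationSet", function(x) x@support)

#' @rdname accessors
setMethod("targetIds", "AssociationSet",
          function(x) sort(unique(x@associations$target_id)))

#' @rdname accessors
setMethod("diseaseIds", "AssociationSet",
          function(x) sort(unique(x@associations$disease_id)))

#' @export
setMethod("show", "AssociationSet", function(object) {
  a <- object@associations
  cat("AssociationSet with", nrow(a), "associations (",
      length(unique(a$target_id)), "targets x",
      length(unique(a$disease_id)), "diseases )\n")
  if (nrow(a)) {
    cat("  importance range: [",
        format(min(a$importance), digits = 4), ", ",
        format(max(a$importance), digits = 4), "]\n", sep = "")
  }
})

#' Supporting publications of one association
#'
#' The publication ids behind a single (target, disease) row, optionally
#' joined with dates/titles and sorted newest first (missing dates
#' last; ties broken by pub_id).
#'
#' @param x an [AssociationSet-class].
#' @param targetId,diseaseId the association to look up.
#' @param pubMeta optional data.frame from [readPubMeta()].
#' @return data.frame (pub_id, date, title) sorted by date descending.
#' @export
associationArticles <- function(x, targetId, diseaseId, pubMeta = NULL) {
  s <- x@support
  ids <- s$pub_id[s$target_id == targetId & s$disease_id == diseaseId]
  if (!length(ids))
    stop("no association (", targetId, ", ", diseaseId, ")")
  out <- data.frame(pub_id = sort(ids), date = NA_character_,
                    title = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(pubMeta)) {
    i <- match(out$pub_id, pubMeta$pub_id)
    out$date <- as.character(pubMeta$date[i])
    out$title <- as.character(pubMeta$title[i])
  }
  out <- out[order(is.na(out$date),
                   -xtfrm(ifelse(is.na(out$date), "", out$date)),
                   out$pub_id), ]
  rownames(out) <- NULL
  out
}
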