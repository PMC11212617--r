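#' @import methods
#' @importFrom data.table data.table setDT setkeyv as.data.table := .N .SD fread fwrite
NULL

# Column layouts shared by validity checks and constructors
.MENTION_COLS <- c("pub_id", "entity_kind", "entity_id")
.PUB_COLS     <- c("pub_id", "n_targets", "n_diseases", "date", "title")
.TARGET_COLS  <- c("target_id", "symbol", "tdl", "idg_family")

.TDL_LEVELS    <- c("Tclin", "Tchem", "Tbio", "Tdark", "unknown")
.FAMILY_LEVELS <- c("GPCR", "Kinase", "IonChannel", "NuclearReceptor",
                    "Other", "unknown")

#' PublicationCorpus: per-publication entity index
#'
#' Holds one row per publication together with the deduplicated sets of
#' target and disease identifiers tagged in it. The per-publication entity
#' counts `n_targets` (the number of distinct targets, T_k) and
#' `n_diseases` (distinct diseases, D_k) are the fractional-counting
#' denominators used by [targetNovelty()] and [importanceScores()].
#'
#' @slot publications data.frame with columns pub_id, n_targets,
#'   n_diseases, date, title (date/title may be NA).
#' @slot targetMentions data.frame (pub_id, target_id), unique rows.
#' @slot diseaseMentions data.frame (pub_id, disease_id), unique rows.
#'
#' @seealso [buildCorpus()], [readMentions()]
#' @exportClass PublicationCorpus
setClass("PublicationCorpus",
  representation(
    publications    = "data.frame",
    targetMentions  = "data.frame",
    diseaseMentions = "data.frame"
  )
)

setValidity("PublicationCorpus", function(object) {
  msgs <- character(0)
  pubs <- object@publications
  tm <- object@targetMentions
  dm <- object@diseaseMentions
  if (!identical(names(pubs), .PUB_COLS))
    msgs <- c(msgs, "publications must have columns pub_id, n_targets, n_diseases, date, title")
  if (anyDuplicated(pubs$pub_id))
    msgs <- c(msgs, "duplicate pub_id in publications")
  if (anyDuplicated(tm) || anyDuplicated(dm))
    msgs <- c(msgs, "mention tables must be duplicate-free")
  if (!all(tm$pub_id %in% pubs$pub_id) || !all(dm$pub_id %in% pubs$pub_id))
    msgs <- c(msgs, "mention rows reference unknown publications")
  # index consistency: stored counts equal the set sizes
  tcount <- table(factor(tm$pub_id, levels = pubs$pub_id))
  dcount <- table(factor(dm$pub_id, levels = pubs$pub_id))
  if (!all(pubs$n_targets == as.integer(tcount)) ||
      !all(pubs$n_diseases == as.integer(dcount)))
    msgs <- c(msgs, "n_targets/n_diseases inconsistent with mention sets")
  if (any(pubs$n_targets + pubs$n_diseases == 0))
    msgs <- c(msgs, "publications with no tagged entities must be dropped")
  if (length(msgs)) msgs else TRUE
})

#' DiseaseOntology: the Disease Ontology is_a DAG
#'
#' Parsed representation of an OBO 1.2 ontology restricted to the
#' information the scoring pipeline needs: term ids and names, `is_a`
#' parent edges among non-obsolete terms, `alt_id` aliases and
#' `replaced_by` redirects for obsolete terms.
#'
#' @slot terms data.frame with columns doid, name, obsolete.
#' @slot parents named list: doid -> character vector of parent doids
#'   (empty for roots and obsolete terms).
#' @slot altIds named character: alternative id -> primary id.
#' @slot replacedBy named character: obsolete id -> replacement id.
#'
#' @seealso [readOntology()], [ancestors()]
#' @exportClass DiseaseOntology
setClass("DiseaseOntology",
  representation(
    terms      = "data.frame",
    parents    = "list",
    altIds     = "character",
    replacedBy = "character",
    cache      = "environment"
  )
)

setValidity("DiseaseOntology", function(object) {
  msgs <- character(0)
  terms <- object@terms
  if (!identical(names(terms), c("doid", "name", "obsolete")))
    msgs <- c(msgs, "terms must have columns doid, name, obsolete")
  if (anyDuplicated(terms$doid))
    msgs <- c(msgs, "duplicate doid")
  if (!all(names(object@parents) %in% terms$doid))
    msgs <- c(msgs, "parents list keyed by unknown doid")
  refs <- unique(unlist(object@parents, use.names = FALSE))
  if (length(refs) && !all(refs %in% terms$doid))
    msgs <- c(msgs, "dangling is_a parent reference")
  obs <- terms$doid[terms$obsolete]
  if (any(lengths(object@parents[names(object@parents) %in% obs]) > 0))
    msgs <- c(msgs, "obsolete terms must carry no parents")
  if (length(msgs)) msgs else TRUE
})

#' TargetCatalog: protein target annotation
#'
#' Target metadata in the style of a TCRD export: one record per target
#' accession with its gene symbol, Target Development Level (TDL:
#' Tclin/Tchem/Tbio/Tdark) and IDG protein family. Used only to annotate
#' association tables; absent targets are annotated as `unknown`.
#'
#' @slot targets data.frame with columns target_id, symbol, tdl,
#'   idg_family.
#'
#' @seealso [readTargets()]
#' @exportClass TargetCatalog
setClass("TargetCatalog",
  representation(targets = "data.frame")
)

setValidity("TargetCatalog", function(object) {
  tg <- object@targets
  msgs <- character(0)
  if (!identical(names(tg), .TARGET_COLS))
    msgs <- c(msgs, "targets must have columns target_id, symbol, tdl, idg_family")
  if (anyDuplicated(tg$target_id))
    msgs <- c(msgs, "duplicate target_id")
  if (!all(tg$tdl %in% .TDL_LEVELS))
    msgs <- c(msgs, "tdl outside allowed levels")
  if (!all(tg$idg_family %in% .FAMILY_LEVELS))
    msgs <- c(msgs, "idg_family outside allowed levels")
  if (length(msgs)) msgs else TRUE
})

#' AssociationSet: scored target-disease associations
#'
#' The result container of [scoreAssociations()]: one row per (target,
#' disease) pair with at least one supporting publication, carrying the
#' importance score, the target and disease novelty scores, annotation,
#' and the supporting publication sets.
#'
#' @slot associations data.frame with columns target_id, symbol, tdl,
#'   idg_family, disease_id, disease_name, importance, target_novelty,
#'   disease_novelty, n_pubs.
#' @slot support data.frame of supporting triples (target_id, disease_id,
#'   pub_id), unique rows; the publication-set evidence behind every
#'   association row.
#'
#' @seealso [scoreAssociations()], [rankAssociations()]
#' @exportClass AssociationSet
setClass("AssociationSet",
  representation(
    associations = "data.frame",
    support      = "data.frame"
  )
)

.ASSOC_COLS <- c("target_id", "symbol", "tdl", "idg_family",
                 "disease_id", "disease_name", "importance",
                 "target_novelty", "disease_novelty", "n_pubs")

setValidity("AssociationSet", function(object) {
  a <- object@associations
  s <- object@support
  msgs <- character(0)
  if (!identical(names(a), .ASSOC_COLS))
    msgs <- c(msgs, "association columns out of contract")
  if (!identical(names(s), c("target_id", "disease_id", "pub_id")))
    msgs <- c(msgs, "support columns must be target_id, disease_id, pub_id")
  if (anyDuplicated(a[c("target_id", "disease_id")]))
    msgs <- c(msgs, "duplicate (target, disease) association")
  if (anyDuplicated(s))
    msgs <- c(msgs, "support triples must be unique")
  if (nrow(a)) {
    if (any(a$n_pubs < 1L))
      msgs <- c(msgs, "every association needs >= 1 supporting publication")
    if (any(!is.finite(a$importance)) || any(a$importance <= 0) ||
        any(a$target_novelty <= 0) || any(a$disease_novelty <= 0))
      msgs <- c(msgs, "scores must be positive and finite")
    cnt <- stats::aggregate(pub_id ~ target_id + disease_id, s, length)
    m <- merge(a[c("target_id", "disease_id", "n_pubs")], cnt,
               by = c("target_id", "disease_id"), all.x = TRUE)
    if (any(is.na(m$pub_id)) || any(m$pub_id != m$n_pubs))
      msgs <- c(msgs, "n_pubs inconsistent with support triples")
  }
  if (length(msgs)) msgs else TRUE
})
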