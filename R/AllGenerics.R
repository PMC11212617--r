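#' Accessors for the core classes
#'
#' Small generic accessors so downstream code never touches slots
#' directly: publication, mention and term tables come back as plain
#' data.frames, id vectors as character.
#'
#' @param x a [PublicationCorpus-class], [DiseaseOntology-class],
#'   [TargetCatalog-class] or [AssociationSet-class] object.
#' @return `publications()`, `targetMentions()`, `diseaseMentions()`,
#'   `ontologyTerms()`, `targetRecords()`, `associations()` and
#'   `supportTriples()` return data.frames; `targetIds()` and
#'   `diseaseIds()` return character vectors; `nPublications()` an
#'   integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("publications", function(x) standardGeneric("publications"))

#' @rdname accessors
#' @export
setGeneric("targetMentions", function(x) standardGeneric("targetMentions"))

#' @rdname accessors
#' @export
setGeneric("diseaseMentions", function(x) standardGeneric("diseaseMentions"))

#' @rdname accessors
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname accessors
#' @export
setGeneric("nPublications", function(x) standardGeneric("nPublications"))

#' @rdname accessors
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' @rdname accessors
#' @export
setGeneric("targetRecords", function(x) standardGeneric("targetRecords"))

#' @rdname accessors
#' @export
setGeneric("associations", function(x) standardGeneric("associations"))

#' @rdname accessors
#' @export
setGeneric("supportTriples", function(x) standardGeneric("supportTriples"))

#' Ancestors and descendants of an ontology term
#'
#' All terms reachable from `doid` via `is_a` edges (`ancestors`), or all
#' terms from which `doid` is reachable (`descendants`), excluding the
#' term itself. Results are memoized inside the object and returned
#' sorted, so repeated calls are cheap and deterministic.
#'
#' @param x a [DiseaseOntology-class].
#' @param doid a single term id; alternative ids are resolved to their
#'   primary id and `replaced_by` redirects of obsolete terms are
#'   followed once.
#' @return sorted character vector of term ids.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: DOID:1", "name: root", "",
#'              "[Term]", "id: DOID:2", "name: child", "is_a: DOID:1"), obo)
#' g <- readOntology(obo)
#' ancestors(g, "DOID:2")
#' @export
setGeneric("ancestors", function(x, doid) standardGeneric("ancestors"))

#' @rdname ancestors
#' @export
setGeneric("descendants", function(x, doid) standardGeneric("descendants"))
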