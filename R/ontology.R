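#' Parse a Disease Ontology OBO file
#'
#' Minimal OBO 1.2 flat-file reader covering the fields the pipeline
#' uses: `[Term]` stanzas with `id`, `name`, `is_a`, `alt_id`,
#' `is_obsolete` and `replaced_by`. Only `is_a` edges define the
#' hierarchy; other relationship types are ignored. Obsolete terms are
#' loaded but excluded from the DAG (their parents are dropped). A
#' dangling `is_a` reference or a cycle among non-obsolete terms is an
#' error; the cycle error reports one offending path.
#'
#' @param path path to the `.obo` file.
#' @return a [DiseaseOntology-class].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: DOID:1", "name: disease", "",
#'              "[Term]", "id: DOID:2", "name: subtype", "is_a: DOID:1 ! disease"),
#'            obo)
#' readOntology(obo)
#' @export
readOntology <- function(path) {
  if (!file.exists(path))
    stop("ontology file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("\\s+$", "", lines)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts))
    stop("no stanzas found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  is_term <- lines[starts] == "[Term]"

  ids <- character(0); names_ <- character(0); obsolete <- logical(0)
  parents <- list(); altIds <- character(0); replacedBy <- character(0)

  strip_comment <- function(x) sub("\\s*!.*$", "", x)
  for (s in which(is_term)) {
    chunk <- if (ends[s] > starts[s]) lines[(starts[s] + 1L):ends[s]] else character(0)
    tagval <- regmatches(chunk, regexec("^([A-Za-z_]+):\\s*(.*)$", chunk))
    tags <- vapply(tagval, function(z) if (length(z)) z[2L] else NA_character_, "")
    vals <- vapply(tagval, function(z) if (length(z)) z[3L] else NA_character_, "")
    id <- vals[which(tags == "id")[1L]]
    if (is.na(id) || id == "")
      stop("[Term] stanza without id in ", path)
    id <- strip_comment(id)
    obs <- any(tags == "is_obsolete" & grepl("^true", vals))
    ids <- c(ids, id)
    nm <- vals[which(tags == "name")[1L]]
    names_ <- c(names_, if (is.na(nm)) "" else nm)
    obsolete <- c(obsolete, obs)
    isa <- strip_comment(vals[tags == "is_a" & !is.na(tags)])
    parents[[id]] <- if (obs) character(0) else unique(isa[isa != ""])
    alts <- strip_comment(vals[tags == "alt_id" & !is.na(tags)])
    if (length(alts)) altIds[alts] <- id
    rb <- strip_comment(vals[tags == "replaced_by" & !is.na(tags)])
    if (length(rb)) replacedBy[id] <- rb[1L]
  }
  if (anyDuplicated(ids))
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  refs <- unique(unlist(parents, use.names = FALSE))
  missing_refs <- setdiff(refs, ids)
  if (length(missing_refs))
    stop("dangling is_a reference(s): ", paste(missing_refs, collapse = ", "))

  g <- new("DiseaseOntology",
           terms = data.frame(doid = ids, name = names_, obsolete = obsolete,
                              stringsAsFactors = FALSE),
           parents = parents, altIds = altIds, replacedBy = replacedBy,
           cache = new.env(parent = emptyenv()))
  cyc <- .findCycle(parents)
  if (!is.null(cyc))
    stop("is_a cycle detected: ", paste(cyc, collapse = " -> "))
  g
}

# DFS cycle detection returning one cycle path, or NULL for a DAG.
.findCycle <- function(parents) {
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- get0(v, envir = state)
    if (identical(st, 2L)) return()
    if (identical(st, 1L)) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (p in parents[[v]]) visit(p)
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
  }
  for (v in names(parents)) {
    visit(v)
    if (!is.null(found)) break
  }
  found
}

#' Resolve a term id to its primary, current form
#'
#' Maps `alt_id` aliases to their primary term and follows the
#' `replaced_by` pointer of an obsolete term once. Unknown ids return
#' `NA`.
#'
#' @param x a [DiseaseOntology-class].
#' @param doid character vector of term ids.
#' @return character vector of resolved primary ids (`NA` where
#'   unresolvable).
#' @export
resolveDoid <- function(x, doid) {
  terms <- x@terms
  out <- doid
  alt <- out %in% names(x@altIds)
  out[alt] <- unname(x@altIds[out[alt]])
  known <- out %in% terms$doid
  out[!known] <- NA_character_
  obs <- known & out %in% terms$doid[terms$obsolete]
  if (any(obs)) {
    rep_ <- unname(x@replacedBy[out[obs]])
    keep <- is.na(rep_) | !(rep_ %in% terms$doid)
    rep_[keep] <- out[obs][keep]  # no valid replacement: keep the obsolete id
    out[obs] <- rep_
  }
  out
}

#' @rdname accessors
setMethod("ontologyTerms", "DiseaseOntology", function(x) x@terms)

#' @rdname accessors
setMethod("diseaseIds", "DiseaseOntology",
          function(x) sort(x@terms$doid[!x@terms$obsolete]))

#' @export
setMethod("show", "DiseaseOntology", function(object) {
  terms <- object@terms
  cat("DiseaseOntology with", sum(!terms$obsolete), "terms (",
      sum(terms$obsolete), "obsolete ),",
      sum(lengths(object@parents)), "is_a edges\n")
})

.reachable <- function(x, doid, dir = c("up", "down")) {
  dir <- match.arg(dir)
  key <- paste0(dir, "|", doid)
  hit <- get0(key, envir = x@cache)
  if (!is.null(hit)) return(hit)
  adj <- if (dir == "up") x@parents else {
    ckey <- ".children"
    ch <- get0(ckey, envir = x@cache)
    if (is.null(ch)) {
      edges <- data.frame(
        child = rep(names(x@parents), lengths(x@parents)),
        parent = unlist(x@parents, use.names = FALSE),
        stringsAsFactors = FALSE)
      ch <- split(edges$child, edges$parent)
      assign(ckey, ch, envir = x@cache)
    }
    ch
  }
  seen <- character(0)
  frontier <- doid
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, doid))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  out <- sort(seen)
  assign(key, out, envir = x@cache)
  out
}

#' @rdname ancestors
setMethod("ancestors", "DiseaseOntology", function(x, doid) {
  id <- resolveDoid(x, doid)
  if (length(id) != 1L || is.na(id))
    stop("unknown ontology term: ", doid)
  .reachable(x, id, "up")
})

#' @rdname ancestors
setMethod("descendants", "DiseaseOntology", function(x, doid) {
  id <- resolveDoid(x, doid)
  if (length(id) != 1L || is.na(id))
    stop("unknown ontology term: ", doid)
  .reachable(x, id, "down")
})

# Expand each (pub, disease mention) to (pub, term) for the term itself
# plus all ancestors; unknown doids are kept as hierarchy-less leaves.
# Returns a unique data.table(pub_id, disease_id).
.expandDiseaseMentions <- function(corpus, ontology = NULL) {
  dm <- as.data.table(corpus@diseaseMentions)
  if (is.null(ontology) || !nrow(dm)) {
    out <- unique(dm[, list(pub_id, disease_id)])
    setkeyv(out, c("pub_id", "disease_id"))
    return(out)
  }
  raw <- unique(dm$disease_id)
  resolved <- resolveDoid(ontology, raw)
  unknown <- is.na(resolved)
  if (any(unknown))
    message("propagateSupport: ", sum(unknown),
            " disease id(s) not in the ontology kept as leaves")
  primary <- ifelse(unknown, raw, resolved)
  anc <- lapply(seq_along(raw), function(i) {
    if (unknown[i]) raw[i]
    else c(primary[i], ancestors(ontology, primary[i]))
  })
  names(anc) <- raw
  reps <- lengths(anc)[match(dm$disease_id, raw)]
  out <- data.table(
    pub_id = rep(dm$pub_id, reps),
    disease_id = unlist(anc[dm$disease_id], use.names = FALSE))
  out <- unique(out)
  setkeyv(out, c("pub_id", "disease_id"))
  out
}

#' Propagate publication support through the ontology
#'
#' Builds the evidence behind every (target, disease) association: a
#' publication p mentioning target t and disease d supports (t, a) for
#' every term a in `{d} union ancestors(d)`. Propagation happens at the
#' publication-set level, so a publication mentioning two siblings
#' contributes a single supporting publication to their shared parent —
#' never two. Disease ids absent from the ontology are kept as
#' hierarchy-less leaves. With `ontology = NULL` the support reduces to
#' the direct co-mention pairs.
#'
#' @param corpus a [PublicationCorpus-class].
#' @param ontology a [DiseaseOntology-class], or `NULL` for no
#'   propagation.
#' @return data.frame of unique support triples (target_id, disease_id,
#'   pub_id), sorted.
#' @export
propagateSupport <- function(corpus, ontology = NULL) {
  tm <- as.data.table(corpus@targetMentions)
  dx <- .expandDiseaseMentions(corpus, ontology)
  if (!nrow(tm) || !nrow(dx))
    return(data.frame(target_id = character(0), disease_id = character(0),
                      pub_id = character(0), stringsAsFactors = FALSE))
  tri <- merge(tm, dx, by = "pub_id", allow.cartesian = TRUE)
  tri <- unique(tri[, list(target_id, disease_id, pub_id)])
  setkeyv(tri, c("target_id", "disease_id", "pub_id"))
  as.data.frame(tri)
}
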