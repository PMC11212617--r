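#' Read a tagged-mention table
#'
#' Reads the 3-column tab-separated mention dialect produced by
#' entity-tagging pipelines: `pub_id`, `entity_kind` (`"target"` or
#' `"disease"`) and `entity_id` (a target accession or a DOID). Lines
#' starting with `#` and blank lines are skipped. The reader performs no
#' aggregation — duplicate rows are returned as-is and collapse later in
#' [buildCorpus()].
#'
#' @param path path to the mentions TSV.
#' @param strict if `TRUE` (default) any malformed row (wrong column
#'   count, empty field, unknown entity kind) is an error; if `FALSE`
#'   such rows are skipped with a message reporting the count.
#' @return data.frame with columns pub_id, entity_kind, entity_id and an
#'   attribute `n_skipped` giving the number of rows dropped in lenient
#'   mode.
#' @examples
#' f <- tempfile()
#' writeLines(c("# demo", "P1\ttarget\tA", "P1\tdisease\tDOID:1"), f)
#' readMentions(f)
#' @export
readMentions <- function(path, strict = TRUE) {
  if (!file.exists(path))
    stop("mentions file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- data.frame(pub_id = character(0), entity_kind = character(0),
                      entity_id = character(0), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_ncol <- lengths(parts) != 3L
  flat <- parts
  flat[bad_ncol] <- list(c(NA_character_, NA_character_, NA_character_))
  m <- matrix(unlist(flat, use.names = FALSE), ncol = 3L, byrow = TRUE)
  pub_id <- m[, 1L]; kind <- m[, 2L]; entity_id <- m[, 3L]
  bad <- bad_ncol | is.na(pub_id) | pub_id == "" | entity_id == "" |
    !(kind %in% c("target", "disease")) | is.na(entity_id)
  if (any(bad)) {
    if (strict)
      stop(sum(bad), " malformed mention row(s); first bad line: ",
           lines[which(bad)[1L]])
    message("readMentions: skipped ", sum(bad), " malformed row(s)")
  }
  out <- data.frame(pub_id = pub_id[!bad], entity_kind = kind[!bad],
                    entity_id = entity_id[!bad], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Assemble the per-publication entity index
#'
#' Collapses mention rows into per-publication sets of distinct target
#' and disease identifiers. Duplicate (pub, kind, entity) rows count
#' once; the distinct-set sizes become the fractional-count denominators
#' T_k and D_k. Publications mentioning only one kind of entity are kept
#' (they still enter the novelty sums); publications with no tagged
#' entities at all cannot arise from valid mention rows and are dropped.
#'
#' @param mentions data.frame from [readMentions()] (columns pub_id,
#'   entity_kind, entity_id).
#' @param pubMeta optional data.frame from [readPubMeta()] supplying
#'   `date` and `title` per pub_id.
#' @return a [PublicationCorpus-class].
#' @examples
#' rows <- data.frame(pub_id = c("P1", "P1", "P1"),
#'                    entity_kind = c("target", "target", "disease"),
#'                    entity_id = c("A", "A", "DOID:1"))
#' publications(buildCorpus(rows))
#' @export
buildCorpus <- function(mentions, pubMeta = NULL) {
  stopifnot(all(.MENTION_COLS %in% names(mentions)))
  dt <- unique(as.data.table(mentions)[, .MENTION_COLS, with = FALSE])
  tm <- dt[dt$entity_kind == "target",
           list(pub_id = pub_id, target_id = entity_id)]
  dm <- dt[dt$entity_kind == "disease",
           list(pub_id = pub_id, disease_id = entity_id)]
  setkeyv(tm, c("pub_id", "target_id"))
  setkeyv(dm, c("pub_id", "disease_id"))
  ids <- sort(unique(c(tm$pub_id, dm$pub_id)))
  pubs <- data.table(pub_id = ids)
  tc <- tm[, list(n_targets = .N), by = "pub_id"]
  dc <- dm[, list(n_diseases = .N), by = "pub_id"]
  pubs <- merge(pubs, tc, by = "pub_id", all.x = TRUE)
  pubs <- merge(pubs, dc, by = "pub_id", all.x = TRUE)
  pubs[is.na(pubs$n_targets), "n_targets" := 0L]
  pubs[is.na(pubs$n_diseases), "n_diseases" := 0L]
  pubs[, `:=`(date = NA_character_, title = NA_character_)]
  if (!is.null(pubMeta) && nrow(pubMeta)) {
    meta <- as.data.table(pubMeta)
    i <- match(pubs$pub_id, meta$pub_id)
    if ("date" %in% names(meta))  pubs[, "date" := as.character(meta$date[i])]
    if ("title" %in% names(meta)) pubs[, "title" := as.character(meta$title[i])]
  }
  empty <- pubs$n_targets + pubs$n_diseases == 0L
  if (any(empty)) {
    message("buildCorpus: dropped ", sum(empty), " empty publication(s)")
    pubs <- pubs[!empty, ]
  }
  setkeyv(pubs, "pub_id")
  new("PublicationCorpus",
      publications = as.data.frame(pubs),
      targetMentions = as.data.frame(tm),
      diseaseMentions = as.data.frame(dm))
}

#' Write a corpus back to the mention dialect
#'
#' Inverse of [readMentions()] + [buildCorpus()] up to row order and
#' duplicates: emits one row per (publication, entity) set member, sorted.
#'
#' @param corpus a [PublicationCorpus-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMentions <- function(corpus, path) {
  tm <- corpus@targetMentions
  dm <- corpus@diseaseMentions
  rows <- rbind(
    data.frame(pub_id = tm$pub_id, entity_kind = "target",
               entity_id = tm$target_id, stringsAsFactors = FALSE),
    data.frame(pub_id = dm$pub_id, entity_kind = "disease",
               entity_id = dm$disease_id, stringsAsFactors = FALSE))
  rows <- rows[order(rows$pub_id, rows$entity_kind, rows$entity_id), ]
  lines <- sprintf("%s\t%s\t%s", rows$pub_id, rows$entity_kind, rows$entity_id)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a target metadata table
#'
#' Header-bearing TSV in the style of a TCRD export with columns
#' target_id, symbol, tdl, idg_family. TDL or family values outside the
#' recognised vocabularies map to `"unknown"` with a warning; duplicate
#' target ids are an error.
#'
#' @param path path to the targets TSV.
#' @return a [TargetCatalog-class].
#' @export
readTargets <- function(path) {
  if (!file.exists(path))
    stop("targets file not found: ", path)
  tg <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- .TARGET_COLS
  if (!all(need %in% names(tg)))
    stop("targets file must have columns ", paste(need, collapse = ", "))
  tg <- tg[need]
  if (anyDuplicated(tg$target_id))
    stop("duplicate target_id in ", path)
  bad_tdl <- !(tg$tdl %in% .TDL_LEVELS)
  bad_fam <- !(tg$idg_family %in% .FAMILY_LEVELS)
  if (any(bad_tdl))
    warning(sum(bad_tdl), " unrecognised TDL value(s) mapped to 'unknown'")
  if (any(bad_fam))
    warning(sum(bad_fam), " unrecognised IDG family value(s) mapped to 'unknown'")
  tg$tdl[bad_tdl] <- "unknown"
  tg$idg_family[bad_fam] <- "unknown"
  rownames(tg) <- NULL
  new("TargetCatalog", targets = tg)
}

#' Read publication metadata
#'
#' Optional TSV with columns pub_id, date (ISO-8601) and title, used for
#' article listings in query output.
#'
#' @param path path to the metadata TSV.
#' @return data.frame with columns pub_id, date, title.
#' @export
readPubMeta <- function(path) {
  if (!file.exists(path))
    stop("publication metadata file not found: ", path)
  meta <- utils::read.delim(path, colClasses = "character",
                            stringsAsFactors = FALSE, comment.char = "#")
  if (!"pub_id" %in% names(meta))
    stop("publication metadata must have a pub_id column")
  if (!"date" %in% names(meta)) meta$date <- NA_character_
  if (!"title" %in% names(meta)) meta$title <- NA_character_
  meta[c("pub_id", "date", "title")]
}

# ---- methods ---------------------------------------------------------------

#' @rdname accessors
setMethod("publications", "PublicationCorpus", function(x) x@publications)

#' @rdname accessors
setMethod("targetMentions", "PublicationCorpus", function(x) x@targetMentions)

#' @rdname accessors
setMethod("diseaseMentions", "PublicationCorpus", function(x) x@diseaseMentions)

#' @rdname accessors
setMethod("targetIds", "PublicationCorpus",
          function(x) sort(unique(x@targetMentions$target_id)))

#' @rdname accessors
setMethod("diseaseIds", "PublicationCorpus",
          function(x) sort(unique(x@diseaseMentions$disease_id)))

#' @rdname accessors
setMethod("nPublications", "PublicationCorpus",
          function(x) nrow(x@publications))

#' @rdname accessors
setMethod("targetRecords", "TargetCatalog", function(x) x@targets)

#' @export
setMethod("show", "PublicationCorpus", function(object) {
  cat("PublicationCorpus with", nrow(object@publications), "publications,",
      length(unique(object@targetMentions$target_id)), "targets,",
      length(unique(object@diseaseMentions$disease_id)), "diseases\n")
})

#' @export
setMethod("show", "TargetCatalog", function(object) {
  tg <- object@targets
  cat("TargetCatalog with", nrow(tg), "targets\n")
  if (nrow(tg)) {
    tab <- table(factor(tg$tdl, levels = .TDL_LEVELS))
    cat("  TDL:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
})
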