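# Export surface: full-precision TSV/CSV tables, JSON documents with a
# stable key order, and a checksummed run manifest. All writers format
# numbers with %.17g so values round-trip and identical inputs give
# byte-identical outputs.

.fmtNum <- function(x) sprintf("%.17g", x)

.writeTable <- function(df, path, sep) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) .fmtNum(col) else as.character(col)
  })
  m <- do.call(cbind, cols)
  lines <- c(paste(names(df), collapse = sep),
             if (nrow(df)) apply(m, 1L, paste, collapse = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.schemaVersion <- "1.0"

.writeManifest <- function(path, inputs, config) {
  checksums <- lapply(inputs[!vapply(inputs, is.null, logical(1))],
                      function(p) unname(tools::md5sum(p)))
  manifest <- list(
    tool = "biblioRank",
    version = as.character(utils::packageVersion("biblioRank")),
    schema_version = .schemaVersion,
    inputs = checksums,
    config = config)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Run the full scoring pipeline and write its artifacts
#'
#' Reads the inputs, scores every supported association with ontology
#' propagation, and writes to `outDir`:
#' \itemize{
#'   \item `associations.tsv` — the scored table (fixed column order,
#'     full-precision decimals);
#'   \item `ranked.tsv` / `ranked.csv` — the same rows with `nds_rank`
#'     and `within_rank_order`, ranked per disease over (target novelty,
#'     importance) and cell-for-cell identical between the two formats;
#'   \item `manifest.json` — input MD5 checksums, configuration, tool
#'     and schema versions.
#' }
#' All paths are validated before any computation, so a missing input
#' leaves no partial outputs; identical inputs produce byte-identical
#' outputs.
#'
#' @param mentionsPath,oboPath,targetsPath,pubMetaPath input files;
#'   `oboPath`, `targetsPath` and `pubMetaPath` may be `NULL`.
#' @param outDir output directory (created if needed).
#' @param k top-K used by downstream queries, recorded in the manifest.
#' @param mode dominance convention for ranking.
#' @param logBase log base recorded for plot-coordinate export.
#' @param strict mention-reader strictness, see [readMentions()].
#' @return invisibly, a list with the [AssociationSet-class], the loaded
#'   inputs and the artifact paths.
#' @export
runCompute <- function(mentionsPath, oboPath = NULL, targetsPath = NULL,
                       pubMetaPath = NULL, outDir, k = 300L,
                       mode = c("weak", "strict"), logBase = 10,
                       strict = TRUE) {
  mode <- match.arg(mode)
  for (p in c(mentionsPath, oboPath, targetsPath, pubMetaPath))
    if (!file.exists(p)) stop("input file not found: ", p)
  ontology <- if (!is.null(oboPath)) readOntology(oboPath)
  catalog <- if (!is.null(targetsPath)) readTargets(targetsPath)
  pubMeta <- if (!is.null(pubMetaPath)) readPubMeta(pubMetaPath)
  corpus <- buildCorpus(readMentions(mentionsPath, strict = strict), pubMeta)
  assoc <- scoreAssociations(corpus, ontology, catalog)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  a <- associations(assoc)
  assocPath <- file.path(outDir, "associations.tsv")
  .writeTable(a, assocPath, "\t")

  ranked <- .rankPerDisease(a, mode)
  rankedTsv <- file.path(outDir, "ranked.tsv")
  rankedCsv <- file.path(outDir, "ranked.csv")
  .writeTable(ranked, rankedTsv, "\t")
  .writeTable(ranked, rankedCsv, ",")

  manifestPath <- file.path(outDir, "manifest.json")
  .writeManifest(manifestPath,
                 list(mentions = mentionsPath, obo = oboPath,
                      targets = targetsPath, pubmeta = pubMetaPath),
                 list(k = as.integer(k), dominance_mode = mode,
                      log_base = if (logBase == 10) "10" else "e",
                      strictness = if (strict) "strict" else "lenient"))

  invisible(list(associations = assoc, corpus = corpus, ontology = ontology,
                 catalog = catalog, pubMeta = pubMeta,
                 paths = c(associations = assocPath, ranked_tsv = rankedTsv,
                           ranked_csv = rankedCsv, manifest = manifestPath)))
}

# Rank targets within each disease group (the Browse-Diseases view);
# rows ordered by disease_id, then the within-query rank order.
.rankPerDisease <- function(a, mode = "weak") {
  if (!nrow(a)) {
    a$nds_rank <- integer(0)
    a$within_rank_order <- integer(0)
    return(a)
  }
  parts <- lapply(split(a, a$disease_id), rankAssociations,
                  noveltyCol = "target_novelty", k = .Machine$integer.max,
                  mode = mode)
  out <- do.call(rbind, parts[sort(names(parts))])
  rownames(out) <- NULL
  out
}

#' Export one browse query to files
#'
#' Writes the per-query ranked table (with log plot coordinates) and,
#' for every association in it, the supporting article list sorted
#' newest first.
#'
#' @param computed result of [runCompute()].
#' @param disease,target exactly one of the two: the query id.
#' @param outDir output directory.
#' @param k,mode,logBase see [queryAssociations()].
#' @return invisibly, list with the query table and the article table.
#' @export
runQuery <- function(computed, disease = NULL, target = NULL, outDir,
                     k = 300L, mode = c("weak", "strict"), logBase = 10) {
  mode <- match.arg(mode)
  tab <- queryAssociations(computed$associations, disease = disease,
                           target = target, k = k, mode = mode,
                           logBase = logBase)
  arts <- lapply(seq_len(nrow(tab)), function(i) {
    al <- associationArticles(computed$associations, tab$target_id[i],
                              tab$disease_id[i], computed$pubMeta)
    cbind(data.frame(target_id = tab$target_id[i],
                     disease_id = tab$disease_id[i],
                     stringsAsFactors = FALSE),
          al)
  })
  arts <- if (length(arts)) do.call(rbind, arts) else
    data.frame(target_id = character(0), disease_id = character(0),
               pub_id = character(0), date = character(0),
               title = character(0), stringsAsFactors = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  qname <- gsub("[^A-Za-z0-9_.-]", "_",
                if (!is.null(disease)) disease else target)
  tabPath <- file.path(outDir, paste0("query_", qname, ".tsv"))
  artPath <- file.path(outDir, paste0("query_", qname, "_articles.tsv"))
  .writeTable(tab, tabPath, "\t")
  .writeTable(arts, artPath, "\t")
  invisible(list(table = tab, articles = arts,
                 paths = c(table = tabPath, articles = artPath)))
}

#' Export the computed data as JSON documents
#'
#' Writes `targets.json`, `diseases.json` and `associations.json` with a
#' stable key order (re-export is byte-identical). An empty corpus
#' yields valid documents with empty arrays.
#'
#' @param computed result of [runCompute()].
#' @param outDir output directory.
#' @return invisibly, the three file paths.
#' @export
exportJSON <- function(computed, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  a <- associations(computed$associations)

  tg <- unique(a[c("target_id", "symbol", "tdl", "idg_family")])
  tg <- tg[order(tg$target_id), , drop = FALSE]
  tnov <- if (nrow(a)) targetNovelty(computed$corpus)[tg$target_id] else numeric(0)
  targetsDoc <- lapply(seq_len(nrow(tg)), function(i) list(
    target_id = tg$target_id[i], symbol = tg$symbol[i], tdl = tg$tdl[i],
    idg_family = tg$idg_family[i], novelty = unname(tnov[i])))

  dg <- unique(a[c("disease_id", "disease_name", "disease_novelty")])
  dg <- dg[order(dg$disease_id), , drop = FALSE]
  diseasesDoc <- lapply(seq_len(nrow(dg)), function(i) list(
    disease_id = dg$disease_id[i], name = dg$disease_name[i],
    novelty = dg$disease_novelty[i]))

  assocDoc <- lapply(seq_len(nrow(a)), function(i) list(
    target_id = a$target_id[i], disease_id = a$disease_id[i],
    importance = a$importance[i], target_novelty = a$target_novelty[i],
    disease_novelty = a$disease_novelty[i], n_pubs = a$n_pubs[i]))

  paths <- c(targets = file.path(outDir, "targets.json"),
             diseases = file.path(outDir, "diseases.json"),
             associations = file.path(outDir, "associations.json"))
  for (doc in list(list(paths[["targets"]], targetsDoc),
                   list(paths[["diseases"]], diseasesDoc),
                   list(paths[["associations"]], assocDoc))) {
    json <- jsonlite::toJSON(doc[[2]], auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    writeLines(json, doc[[1]], useBytes = TRUE)
  }
  invisible(paths)
}
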