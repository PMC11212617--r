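#' Write the hand-checkable golden fixture ("corpus G")
#'
#' A four-publication corpus small enough to score by hand, used
#' throughout the test suite and documentation:
#' P1 tags target A and disease X; P2 tags A, B and X, Y; P3 tags B, C
#' and Y; P4 tags C and no disease. The mention file carries one
#' deliberate duplicate row (P1/target/A twice, 11 rows in all) to
#' exercise the reader-keeps / builder-collapses contract. Targets A, B,
#' C carry TDLs Tclin, Tbio, Tdark; the ontology makes Z the parent of
#' X and Y; publication dates are fixed. The files are byte-identical
#' across runs.
#'
#' Hand-derived scores: N_A = N_C = 2/3, N_B = 1; I_AX = 1.25,
#' I_AY = I_BX = 0.25, I_BY = 0.75, I_CY = 0.5; with propagation
#' I_AZ = 1.25, I_BZ = 0.75, I_CZ = 0.5 (8 associations).
#'
#' @param dir directory to write into (created if needed).
#' @return named character vector of the four file paths (mentions,
#'   targets, obo, pubmeta).
#' @examples
#' paths <- makeGoldenFixture(tempfile())
#' readMentions(paths[["mentions"]])
#' @export
makeGoldenFixture <- function(dir = tempfile("corpusG")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- "DOID:0000101"; Y <- "DOID:0000102"; Z <- "DOID:0000100"
  mentions <- c(
    "# golden fixture corpus G",
    paste("P1", "target", "A", sep = "\t"),
    paste("P1", "target", "A", sep = "\t"),  # deliberate duplicate
    paste("P1", "disease", X, sep = "\t"),
    paste("P2", "target", "A", sep = "\t"),
    paste("P2", "target", "B", sep = "\t"),
    paste("P2", "disease", X, sep = "\t"),
    paste("P2", "disease", Y, sep = "\t"),
    paste("P3", "target", "B", sep = "\t"),
    paste("P3", "target", "C", sep = "\t"),
    paste("P3", "disease", Y, sep = "\t"),
    paste("P4", "target", "C", sep = "\t"))
  targets <- c(
    paste(c("target_id", "symbol", "tdl", "idg_family"), collapse = "\t"),
    paste(c("A", "GENE_A", "Tclin", "GPCR"), collapse = "\t"),
    paste(c("B", "GENE_B", "Tbio", "Kinase"), collapse = "\t"),
    paste(c("C", "GENE_C", "Tdark", "Other"), collapse = "\t"))
  obo <- c(
    "format-version: 1.2",
    "",
    "[Term]",
    paste0("id: ", Z),
    "name: progressive motor syndrome",
    "",
    "[Term]",
    paste0("id: ", X),
    "name: early-onset motor syndrome",
    paste0("is_a: ", Z, " ! progressive motor syndrome"),
    "",
    "[Term]",
    paste0("id: ", Y),
    "name: late-onset motor syndrome",
    paste0("is_a: ", Z, " ! progressive motor syndrome"))
  pubmeta <- c(
    paste(c("pub_id", "date", "title"), collapse = "\t"),
    paste(c("P1", "2019-03-05", "Flippase loss in early-onset disease"), collapse = "\t"),
    paste(c("P2", "2020-07-21", "Two transporters across disease subtypes"), collapse = "\t"),
    paste(c("P3", "2021-11-02", "Kinase variants in a late-onset cohort"), collapse = "\t"),
    paste(c("P4", "2022-05-16", "Structure of an orphan transporter"), collapse = "\t"))
  paths <- c(mentions = file.path(dir, "mentions.tsv"),
             targets = file.path(dir, "targets.tsv"),
             obo = file.path(dir, "ontology.obo"),
             pubmeta = file.path(dir, "pubmeta.tsv"))
  writeLines(mentions, paths[["mentions"]], useBytes = TRUE)
  writeLines(targets, paths[["targets"]], useBytes = TRUE)
  writeLines(obo, paths[["obo"]], useBytes = TRUE)
  writeLines(pubmeta, paths[["pubmeta"]], useBytes = TRUE)
  paths
}

#' Build a simulation configuration
#'
#' Parameters of the synthetic tagged-literature generator. Per-pub
#' entity counts are drawn from Poisson distributions (truncated at the
#' number of available entities; zero counts are allowed to occur so
#' disease-free publications arise naturally, as they do in real
#' corpora) or held constant. Target selection is Zipf-weighted
#' (weight 1/rank^s) so a few targets are heavily studied and many are
#' rarely mentioned — the skew the novelty score exists to expose;
#' disease selection is uniform. The ontology is a random is_a tree of
#' bounded depth.
#'
#' @param nTargets,nDiseases,nPubs corpus dimensions; entity counts must
#'   be >= 1, `nPubs` may be 0.
#' @param targetsPerPub,diseasesPerPub either a single positive number
#'   (Poisson mean) or `list(constant = k)` for a fixed count per
#'   publication.
#' @param targetZipf Zipf exponent s >= 0 for target popularity
#'   (0 = uniform).
#' @param ontologyDepth maximum depth of the random is_a tree (1 = no
#'   edges).
#' @param seed mandatory integer seed; the single source of randomness.
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nTargets = 25L, nDiseases = 15L, nPubs = 200L,
                             targetsPerPub = 2, diseasesPerPub = 1.5,
                             targetZipf = 1, ontologyDepth = 3L, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer seed is mandatory")
  if (nTargets < 1L || nDiseases < 1L)
    stop("nTargets and nDiseases must be >= 1")
  if (nPubs < 0L) stop("nPubs must be >= 0")
  checkDist <- function(d, what) {
    if (is.list(d)) {
      if (is.null(d$constant) || d$constant < 1)
        stop(what, ": constant distribution needs a value >= 1")
    } else if (!is.numeric(d) || length(d) != 1L || d <= 0) {
      stop(what, ": Poisson mean must be a single positive number")
    }
  }
  checkDist(targetsPerPub, "targetsPerPub")
  checkDist(diseasesPerPub, "diseasesPerPub")
  if (targetZipf < 0) stop("targetZipf must be >= 0")
  if (ontologyDepth < 1L) stop("ontologyDepth must be >= 1")
  structure(list(nTargets = as.integer(nTargets),
                 nDiseases = as.integer(nDiseases),
                 nPubs = as.integer(nPubs),
                 targetsPerPub = targetsPerPub,
                 diseasesPerPub = diseasesPerPub,
                 targetZipf = targetZipf,
                 ontologyDepth = as.integer(ontologyDepth),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

.drawCounts <- function(spec, n, cap) {
  if (is.list(spec)) rep(min(as.integer(spec$constant), cap), n)
  else pmin(stats::rpois(n, spec), cap)
}

#' Simulate a tagged-literature corpus with ground truth
#'
#' Generates a complete input set — mentions, target catalog, OBO
#' ontology and publication metadata — in the exact dialects consumed by
#' [readMentions()], [readTargets()], [readOntology()] and
#' [readPubMeta()], together with ground-truth scores computed by the
#' independent reference scorer [naiveAssociationScores()]. Every
#' generated disease id resolves in the generated ontology. All
#' randomness flows from `cfg$seed`; the same configuration produces
#' byte-identical files.
#'
#' @param cfg a [simulationConfig()].
#' @param dir directory for the generated files.
#' @return list with `paths` (named as in [makeGoldenFixture()]),
#'   `mentions` (the mention data.frame), `parents` (the generated is_a
#'   list) and `truth` (the [naiveAssociationScores()] result plus
#'   `target_pub_counts`).
#' @export
simulateCorpus <- function(cfg, dir = tempfile("simcorpus")) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  target_ids <- sprintf("T%04d", seq_len(cfg$nTargets))
  doids <- sprintf("DOID:%07d", seq_len(cfg$nDiseases))

  # random is_a tree of bounded depth: term 1 is the root
  level <- integer(cfg$nDiseases); level[1L] <- 1L
  parents <- stats::setNames(vector("list", cfg$nDiseases), doids)
  parents[[1L]] <- character(0)
  for (i in seq_len(cfg$nDiseases)[-1L]) {
    eligible <- which(level[seq_len(i - 1L)] < cfg$ontologyDepth)
    if (length(eligible) && cfg$ontologyDepth > 1L) {
      p <- eligible[sample.int(length(eligible), 1L)]
      parents[[i]] <- doids[p]
      level[i] <- level[p] + 1L
    } else {
      parents[[i]] <- character(0)
      level[i] <- 1L
    }
  }

  w <- 1 / seq_len(cfg$nTargets)^cfg$targetZipf
  tk <- .drawCounts(cfg$targetsPerPub, cfg$nPubs, cfg$nTargets)
  dk <- .drawCounts(cfg$diseasesPerPub, cfg$nPubs, cfg$nDiseases)
  pub_ids <- sprintf("PMID%06d", seq_len(cfg$nPubs))

  rows <- vector("list", cfg$nPubs)
  for (k in seq_len(cfg$nPubs)) {
    ts <- if (tk[k] > 0L) target_ids[sample.int(cfg$nTargets, tk[k], prob = w)]
          else character(0)
    ds <- if (dk[k] > 0L) doids[sample.int(cfg$nDiseases, dk[k])]
          else character(0)
    if (!length(ts) && !length(ds)) next
    rows[[k]] <- data.frame(
      pub_id = pub_ids[k],
      entity_kind = c(rep("target", length(ts)), rep("disease", length(ds))),
      entity_id = c(ts, ds), stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  mentions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pub_id = character(0), entity_kind = character(0),
               entity_id = character(0), stringsAsFactors = FALSE)

  tdl <- sample(c("Tclin", "Tchem", "Tbio", "Tdark"), cfg$nTargets,
                replace = TRUE, prob = c(0.05, 0.1, 0.3, 0.55))
  fam <- sample(c("GPCR", "Kinase", "IonChannel", "NuclearReceptor", "Other"),
                cfg$nTargets, replace = TRUE,
                prob = c(0.1, 0.15, 0.1, 0.05, 0.6))
  dates <- sprintf("%04d-%02d-%02d",
                   sample(2000:2023, cfg$nPubs, replace = TRUE),
                   sample(1:12, cfg$nPubs, replace = TRUE),
                   sample(1:28, cfg$nPubs, replace = TRUE))

  paths <- c(mentions = file.path(dir, "mentions.tsv"),
             targets = file.path(dir, "targets.tsv"),
             obo = file.path(dir, "ontology.obo"),
             pubmeta = file.path(dir, "pubmeta.tsv"))
  writeLines(sprintf("%s\t%s\t%s", mentions$pub_id, mentions$entity_kind,
                     mentions$entity_id),
             paths[["mentions"]], useBytes = TRUE)
  writeLines(c("target_id\tsymbol\ttdl\tidg_family",
               sprintf("%s\tGENE%04d\t%s\t%s", target_ids,
                       seq_len(cfg$nTargets), tdl, fam)),
             paths[["targets"]], useBytes = TRUE)
  obo <- c("format-version: 1.2", "")
  for (i in seq_len(cfg$nDiseases)) {
    obo <- c(obo, "[Term]", paste0("id: ", doids[i]),
             paste0("name: synthetic disease ", i),
             if (length(parents[[i]])) paste0("is_a: ", parents[[i]]), "")
  }
  writeLines(obo[-length(obo)], paths[["obo"]], useBytes = TRUE)
  writeLines(c("pub_id\tdate\ttitle",
               sprintf("%s\t%s\tSynthetic article %d", pub_ids, dates,
                       seq_len(cfg$nPubs))),
             paths[["pubmeta"]], useBytes = TRUE)

  truth <- naiveAssociationScores(mentions, parents)
  tset <- unique(mentions[mentions$entity_kind == "target",
                          c("pub_id", "entity_id")])
  truth$target_pub_counts <- table(tset$entity_id)

  list(paths = paths, mentions = mentions, parents = parents, truth = truth)
}
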