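computeGolden <- function(outDir = tempfile()) {
  p <- goldenPaths()
  runCompute(mentionsPath = p[["mentions"]], oboPath = p[["obo"]],
             targetsPath = p[["targets"]], pubMetaPath = p[["pubmeta"]],
             outDir = outDir)
}

test_that("compute writes the association and ranked tables deterministically", {
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- computeGolden(d1); r2 <- computeGolden(d2)
  tab <- read.delim(file.path(d1, "associations.tsv"),
                    colClasses = c(importance = "numeric"))
  expect_identical(nrow(tab), 8L)
  for (f in c("associations.tsv", "ranked.tsv", "ranked.csv", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # full-precision round trip of a known score
  expect_identical(tab$importance[tab$target_id == "A" &
                                  tab$disease_id == "DOID:0000101"], 1.25)
  # missing input: error before any output is written
  d3 <- tempfile()
  p <- goldenPaths()
  expect_error(runCompute(p[["mentions"]], oboPath = tempfile(),
                          outDir = d3), "not found")
  expect_false(dir.exists(d3))
})

test_that("CSV and TSV exports agree cell for cell", {
  d <- tempfile()
  computeGolden(d)
  tsv <- read.delim(file.path(d, "ranked.tsv"), colClasses = "character")
  csv <- read.csv(file.path(d, "ranked.csv"), colClasses = "character")
  expect_identical(tsv, csv)
  expect_true(all(c("nds_rank", "within_rank_order") %in% names(tsv)))
})

test_that("queries export ranked listings with dated article lists", {
  d <- tempfile()
  res <- computeGolden(d)
  q <- runQuery(res, disease = "DOID:0000101", outDir = d)
  expect_identical(q$table$target_id, c("A", "B"))
  qc <- runQuery(res, target = "C", outDir = d)
  expect_setequal(qc$table$disease_id, c("DOID:0000100", "DOID:0000102"))
  # article lists: members of that association's support, newest first
  s <- supportTriples(res$associations)
  for (i in seq_len(nrow(q$articles))) {
    row <- q$articles[i, ]
    expect_true(row$pub_id %in% s$pub_id[s$target_id == row$target_id &
                                         s$disease_id == row$disease_id])
  }
  az <- q$articles[q$articles$target_id == "A", ]
  expect_false(is.unsorted(rev(az$date[az$disease_id == "DOID:0000101"])))
  expect_error(runQuery(res, disease = "DOID:404", outDir = d), "unknown")
})

test_that("JSON export is complete, stable across re-export, valid when empty", {
  d <- tempfile()
  res <- computeGolden(d)
  paths <- exportJSON(res, d)
  assoc <- jsonlite::fromJSON(paths[["associations"]], simplifyVector = FALSE)
  expect_length(assoc, 8L)
  expect_identical(names(assoc[[1]]),
                   c("target_id", "disease_id", "importance",
                     "target_novelty", "disease_novelty", "n_pubs"))
  first <- readLines(paths[["associations"]])
  exportJSON(res, d)
  expect_identical(readLines(paths[["associations"]]), first)

  # empty corpus: valid JSON, empty arrays
  mfile <- tempfile(); writeLines(character(0), mfile)
  dEmpty <- tempfile()
  resE <- runCompute(mfile, outDir = dEmpty)
  pe <- exportJSON(resE, dEmpty)
  expect_identical(jsonlite::fromJSON(pe[["associations"]]), list())
})

test_that("manifest checksums change iff an input byte changes", {
  p <- makeGoldenFixture(tempfile())
  d1 <- tempfile()
  args <- list(mentionsPath = p[["mentions"]], oboPath = p[["obo"]],
               targetsPath = p[["targets"]], pubMetaPath = p[["pubmeta"]])
  do.call(runCompute, c(args, outDir = d1))
  m1 <- jsonlite::fromJSON(file.path(d1, "manifest.json"))
  do.call(runCompute, c(args, outDir = d1))
  m2 <- jsonlite::fromJSON(file.path(d1, "manifest.json"))
  expect_identical(m1$inputs, m2$inputs)
  cat("\n# a trailing comment\n", file = p[["mentions"]], append = TRUE)
  do.call(runCompute, c(args, outDir = d1))
  m3 <- jsonlite::fromJSON(file.path(d1, "manifest.json"))
  expect_false(identical(m1$inputs$mentions, m3$inputs$mentions))
  expect_identical(m1$inputs$obo, m3$inputs$obo)
})

test_that("the command-line wrapper runs the fixture pipeline end to end", {
  cli <- system.file("cli", "bibliorank.R", package = "biblioRank")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  fixdir <- tempfile(); outdir <- tempfile()
  out <- system2(rscript, c(cli, "fixture", "--dir", fixdir),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(fixdir, "mentions.tsv")))
  out <- system2(rscript, c(cli, "compute",
                            "--mentions", file.path(fixdir, "mentions.tsv"),
                            "--obo", file.path(fixdir, "ontology.obo"),
                            "--targets", file.path(fixdir, "targets.tsv"),
                            "--pubmeta", file.path(fixdir, "pubmeta.tsv"),
                            "--out", outdir),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(attr(out, "status"), NULL)
  tab <- read.delim(file.path(outdir, "associations.tsv"))
  expect_identical(nrow(tab), 8L)
  # unknown input exits non-zero
  bad <- suppressWarnings(
    system2(rscript, c(cli, "compute", "--mentions", tempfile(),
                       "--out", tempfile()),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(bad, "status")))
})
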