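X <- "DOID:0000101"; Y <- "DOID:0000102"; Z <- "DOID:0000100"

goldenCorpus <- function() {
  p <- goldenPaths()
  buildCorpus(readMentions(p[["mentions"]]))
}

test_that("novelty matches hand evaluation and its closed forms", {
  solo <- buildCorpus(data.frame(pub_id = "P1", entity_kind = "target",
                                 entity_id = "A"))
  expect_equal(targetNovelty(solo, "A"), c(A = 1))

  corpus <- goldenCorpus()
  expect_equal(targetNovelty(corpus, c("A", "B", "C")),
               c(A = 2/3, B = 1, C = 2/3), tolerance = 1e-12)
  expect_error(targetNovelty(corpus, "NOPE"), "undefined")

  # m publications each tagging exactly t targets incl. i -> N_i = t/m
  for (t in c(1, 3)) for (m in c(2, 5)) {
    rows <- do.call(rbind, lapply(seq_len(m), function(k) data.frame(
      pub_id = sprintf("P%d", k), entity_kind = "target",
      entity_id = sprintf("T%d", seq_len(t)))))
    expect_equal(unname(targetNovelty(buildCorpus(rows), "T1")), t / m,
                 tolerance = 1e-12)
  }
})

test_that("disease novelty is the symmetric analogue over D_k", {
  solo <- buildCorpus(data.frame(pub_id = "P1", entity_kind = "disease",
                                 entity_id = X))
  expect_equal(unname(diseaseNovelty(solo, X)), 1)
  corpus <- goldenCorpus()
  expect_equal(unname(diseaseNovelty(corpus, c(X, Y))), c(2/3, 2/3),
               tolerance = 1e-12)
})

test_that("importance matches hand evaluation, with and without propagation", {
  pair <- buildCorpus(data.frame(pub_id = "P1",
                                 entity_kind = c("target", "disease"),
                                 entity_id = c("A", X)))
  s <- propagateSupport(pair, NULL)
  expect_equal(importanceScore(pair, s, "A", X), 1)

  corpus <- goldenCorpus()
  s <- propagateSupport(corpus, NULL)
  expect_equal(importanceScore(corpus, s, "A", X), 1.25, tolerance = 1e-12)
  expect_equal(importanceScore(corpus, s, "A", Y), 0.25, tolerance = 1e-12)
  expect_equal(importanceScore(corpus, s, "B", X), 0.25, tolerance = 1e-12)
  expect_equal(importanceScore(corpus, s, "B", Y), 0.75, tolerance = 1e-12)
  expect_equal(importanceScore(corpus, s, "C", Y), 0.50, tolerance = 1e-12)
  expect_error(importanceScore(corpus, s, "C", X), "no supporting")

  g <- readOntology(goldenPaths()[["obo"]])
  sp <- propagateSupport(corpus, g)
  # P2 mentions both X and Y yet counts once toward (A, Z)
  expect_equal(importanceScore(corpus, sp, "A", Z), 1.25, tolerance = 1e-12)
})

test_that("scoreAssociations enumerates exactly the supported pairs", {
  corpus <- goldenCorpus()
  expect_identical(nrow(associations(scoreAssociations(corpus))), 5L)
  g <- readOntology(goldenPaths()[["obo"]])
  a <- associations(scoreAssociations(corpus, g))
  expect_identical(nrow(a), 8L)
  expect_setequal(paste(a$target_id, a$disease_id),
                  c(paste("A", c(X, Y, Z)), paste("B", c(X, Y, Z)),
                    paste("C", c(Y, Z))))
  empty <- buildCorpus(data.frame(pub_id = character(0),
                                  entity_kind = character(0),
                                  entity_id = character(0)))
  expect_identical(nrow(associations(scoreAssociations(empty))), 0L)
})

test_that("conservation: sum_j I_ij = 1/N_i iff every publication of i has a disease", {
  corpus <- goldenCorpus()
  a <- associations(scoreAssociations(corpus))  # direct pairs only
  nov <- targetNovelty(corpus)
  sumI <- tapply(a$importance, a$target_id, sum)
  # A and B: all their publications mention >= 1 disease
  expect_equal(unname(sumI["A"]), 1 / nov[["A"]], tolerance = 1e-9)
  expect_equal(unname(sumI["B"]), 1 / nov[["B"]], tolerance = 1e-9)
  # C: P4 has D = 0, so the law must fail
  expect_gt(abs(sumI[["C"]] - 1 / nov[["C"]]), 1e-6)
})

test_that("adding publications moves the scores strictly and boundedly", {
  set.seed(23)
  for (rep in 1:10) {
    rows <- randomMentions(nPubs = 30)
    corpus <- buildCorpus(rows)
    tgt <- sample(targetIds(corpus), 1)
    extra <- data.frame(pub_id = "PNEW", entity_kind = c("target", "disease"),
                        entity_id = c(tgt, "DOID:0001"))
    corpus2 <- buildCorpus(rbind(rows, extra))
    # one more publication mentioning i strictly decreases N_i
    expect_lt(targetNovelty(corpus2, tgt), targetNovelty(corpus, tgt))
    # one more co-mention strictly increases I_ij
    s2 <- propagateSupport(corpus2, NULL)
    i2 <- importanceScore(corpus2, s2, tgt, "DOID:0001")
    s1 <- propagateSupport(corpus, NULL)
    i1 <- tryCatch(importanceScore(corpus, s1, tgt, "DOID:0001"),
                   error = function(e) 0)
    expect_gt(i2, i1)
    # scale bounds: 0 < N_i <= max T_k; each publication adds at most 1 to I
    nov <- targetNovelty(corpus)
    expect_true(all(nov > 0 & nov <= max(publications(corpus)$n_targets)))
    a <- associations(scoreAssociations(corpus))
    expect_true(all(a$importance <= a$n_pubs + 1e-12))
  }
})

test_that("pipeline equals the naive double-loop oracle on random corpora", {
  set.seed(31)
  for (rep in 1:8) {
    rows <- randomMentions(nPubs = 50)
    corpus <- buildCorpus(rows)
    truth <- naiveAssociationScores(rows)
    expect_equal(targetNovelty(corpus)[names(truth$novelty)], truth$novelty,
                 tolerance = 1e-12)
    a <- associations(scoreAssociations(corpus))
    key <- paste(a$target_id, a$disease_id)
    tkey <- paste(truth$importance$target_id, truth$importance$disease_id)
    expect_setequal(key, tkey)
    expect_equal(a$importance[match(tkey, key)], truth$importance$importance,
                 tolerance = 1e-12)
    # shuffling input rows changes nothing
    a2 <- associations(scoreAssociations(buildCorpus(rows[sample(nrow(rows)), ])))
    expect_identical(a2$importance, a$importance)
  }
})

test_that("catalog annotation lands on association rows, unknown where absent", {
  p <- goldenPaths()
  corpus <- goldenCorpus()
  a <- associations(scoreAssociations(corpus, readOntology(p[["obo"]]),
                                      readTargets(p[["targets"]])))
  expect_identical(unique(a$tdl[a$target_id == "C"]), "Tdark")
  expect_identical(unique(a$symbol[a$target_id == "A"]), "GENE_A")
  expect_identical(unique(a$disease_name[a$disease_id == Z]),
                   "progressive motor syndrome")
  a0 <- associations(scoreAssociations(corpus))  # no catalog
  expect_true(all(a0$tdl == "unknown"))
})
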