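test_that("OBO parsing: stanzas, obsolete terms, cycles, dangling refs", {
  g <- readOntology(writeObo(c(
    "[Term]", "id: Z", "name: root", "",
    "[Term]", "id: X", "name: x", "is_a: Z ! root", "",
    "[Term]", "id: Y", "name: y", "is_a: Z")))
  expect_identical(nrow(ontologyTerms(g)), 3L)
  expect_identical(ancestors(g, "X"), "Z")
  expect_identical(ancestors(g, "Z"), character(0))

  g2 <- readOntology(writeObo(c(
    "[Term]", "id: A", "name: live", "",
    "[Term]", "id: B", "name: dead", "is_a: A", "is_obsolete: true")))
  terms <- ontologyTerms(g2)
  expect_true(terms$obsolete[terms$doid == "B"])
  expect_identical(ancestors(g2, "B"), character(0))  # excluded from DAG

  expect_error(readOntology(writeObo(c(
    "[Term]", "id: X", "is_a: Y", "",
    "[Term]", "id: Y", "is_a: X"))), "cycle")
  expect_error(readOntology(writeObo(c(
    "[Term]", "id: X", "is_a: NOPE"))), "dangling")
})

test_that("diamond ancestors are reported once and match brute-force reachability", {
  g <- readOntology(writeObo(c(
    "[Term]", "id: A", "",
    "[Term]", "id: B", "is_a: A", "",
    "[Term]", "id: C", "is_a: A", "",
    "[Term]", "id: D", "is_a: B", "is_a: C")))
  expect_identical(ancestors(g, "D"), c("A", "B", "C"))
  expect_identical(descendants(g, "A"), c("B", "C", "D"))
})

test_that("alt_id resolves to primary; replaced_by is followed once", {
  g <- readOntology(writeObo(c(
    "[Term]", "id: NEW", "name: current", "",
    "[Term]", "id: PRIM", "name: primary", "alt_id: OLD", "",
    "[Term]", "id: GONE", "name: retired", "is_obsolete: true",
    "replaced_by: NEW")))
  expect_identical(resolveDoid(g, c("OLD", "GONE", "PRIM", "nope")),
                   c("PRIM", "NEW", "PRIM", NA))
  expect_identical(ancestors(g, "OLD"), character(0))
  expect_error(ancestors(g, "nope"), "unknown")
})

test_that("support propagates to ancestors at the publication-set level", {
  p <- goldenPaths()
  corpus <- buildCorpus(readMentions(p[["mentions"]]))
  g <- readOntology(p[["obo"]])
  s <- propagateSupport(corpus, g)
  Z <- "DOID:0000100"
  # P2 mentions both children of Z but contributes once
  expect_identical(sort(s$pub_id[s$target_id == "A" & s$disease_id == Z]),
                   c("P1", "P2"))
  # without ontology: direct co-mention pairs only
  s0 <- propagateSupport(corpus, NULL)
  expect_identical(sort(unique(paste(s0$target_id, s0$disease_id))),
                   sort(c("A DOID:0000101", "A DOID:0000102",
                          "B DOID:0000101", "B DOID:0000102",
                          "C DOID:0000102")))
  # a publication with a disease but no target supports nothing
  solo <- buildCorpus(data.frame(pub_id = "P9", entity_kind = "disease",
                                 entity_id = "DOID:0000101"))
  expect_identical(nrow(propagateSupport(solo, g)), 0L)
})

test_that("unknown disease ids degrade to hierarchy-less leaves", {
  corpus <- buildCorpus(data.frame(
    pub_id = c("P1", "P1"), entity_kind = c("target", "disease"),
    entity_id = c("A", "DOID:9999999")))
  g <- readOntology(writeObo(c("[Term]", "id: DOID:1", "name: root")))
  expect_message(s <- propagateSupport(corpus, g), "not in the ontology")
  expect_identical(s$disease_id, "DOID:9999999")
})

test_that("propagation properties: superset up edges, idempotence, order invariance", {
  set.seed(7)
  for (seed in 1:5) {
    sim <- simulateCorpus(simulationConfig(nTargets = 8, nDiseases = 12,
                                           nPubs = 60, ontologyDepth = 4,
                                           seed = seed))
    corpus <- buildCorpus(sim$mentions)
    g <- readOntology(sim$paths[["obo"]])
    s <- propagateSupport(corpus, g)
    key <- paste(s$target_id, s$disease_id)
    for (child in names(sim$parents)) {
      for (parent in sim$parents[[child]]) {
        for (t in unique(s$target_id[s$disease_id == child])) {
          expect_true(all(
            s$pub_id[s$target_id == t & s$disease_id == child] %in%
            s$pub_id[s$target_id == t & s$disease_id == parent]))
        }
      }
    }
    # idempotent: support of the propagated pairs does not change on re-run
    expect_identical(canonSupport(propagateSupport(corpus, g)), canonSupport(s))
    # OBO stanza order does not matter: rebuild the same terms shuffled
    stanzas <- lapply(seq_along(sim$parents), function(i) {
      c("[Term]", paste0("id: ", names(sim$parents)[i]),
        paste0("name: synthetic disease ", i),
        if (length(sim$parents[[i]])) paste0("is_a: ", sim$parents[[i]]), "")
    })
    f2 <- tempfile(fileext = ".obo")
    writeLines(c("format-version: 1.2", "",
                 unlist(stanzas[sample(length(stanzas))])), f2)
    g2 <- readOntology(f2)
    expect_identical(canonSupport(propagateSupport(corpus, g2)), canonSupport(s))
  }
})
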