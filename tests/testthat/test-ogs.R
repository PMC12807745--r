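test_that("the 70% retention rule is inclusive and tree-wide", {
  ## duplication subtree holds 7 of the 10 root-lineage leaves: retained
  fx7 <- retentionFixture(7)
  ann7 <- annotateEvents(fx7$tree, fx7$tax)
  d7 <- duplicationNodes(ann7)
  expect_length(d7, 1L)
  expect_identical(retainedDuplications(ann7, fx7$tax), d7)
  ## 6 of 10: dropped
  fx6 <- retentionFixture(6)
  ann6 <- annotateEvents(fx6$tree, fx6$tax)
  expect_length(duplicationNodes(ann6), 1L)
  expect_length(retainedDuplications(ann6, fx6$tax), 0L)
  ## a retained-at-the-root duplication always has fraction 1
  tax <- flatTaxonomy(c("s1", "s2"))
  g <- annotateEvents(parseNewick("((s1.a:1,s2.a:1):1,(s1.b:1,s2.b:1):1);"),
                      tax)
  expect_identical(retainedDuplications(g, tax), 5L)
})

test_that("OG extraction: no retained duplications give a single basal OG;
           the textbook family gives a root OG plus two children", {
  tax <- flatTaxonomy(c("s1", "s2", "s3"))
  g0 <- annotateEvents(parseNewick("((s1.a:1,s2.a:1):1,s3.a:1);"), tax)
  ogs0 <- extractOGs(g0, tax)
  expect_identical(length(ogs0), 1L)
  expect_true(all(isBasal(ogs0)))
  expect_identical(unname(ogLevels(ogs0)), "root")

  taxB <- flatTaxonomy(c("s1", "s2"))
  gB <- annotateEvents(parseNewick("((s1.a:1,s2.a:1):1,(s1.b:1,s2.b:1):1);"),
                       taxB)
  ogs <- extractOGs(gB, taxB, familyId = "fam9")
  expect_identical(length(ogs), 3L)
  expect_identical(sum(isBasal(ogs)), 1L)
  tab <- ogTable(ogs)
  rootRow <- tab[tab$is_basal, ]
  expect_identical(rootRow$n_members, 4L)
  expect_setequal(tab$parent_og[!tab$is_basal], rootRow$og_id)
  expect_setequal(tab$n_members[!tab$is_basal], c(2L, 2L))
  expect_match(tab$og_id, "^fam9@")
  ## a single-sequence family yields one single-member basal OG
  g1 <- parseNewick("(s1.only:1);")
  ogs1 <- extractOGs(annotateNodeLCAs(g1, taxB), taxB)
  expect_identical(length(ogs1), 1L)
  expect_identical(unname(ogMembers(ogs1)[[1]]), "s1.only")
})

test_that("OG sets are nested-or-disjoint, basal OGs partition the leaves,
           and levels sit on the root lineage", {
  for (seed in c(1:8)) {
    p <- simulationParams(nSpecies = 15, duplicationRate = 0.25,
                          lossRate = 0.05,
                          nTransplants = seed %% 3, seed = seed + 100)
    sim <- tryCatch(simulateFamily(p),
                    phylOG_all_lineages_lost = function(e) NULL)
    if (is.null(sim)) next
    ann <- annotateEvents(sim$tree, sim$taxonomy)
    ogs <- extractOGs(ann, sim$taxonomy)
    mem <- lapply(seq_len(length(ogs)), function(i) ogs@members[[i]])
    if (length(mem) > 1)
      for (i in seq_len(length(mem) - 1))
        for (j in seq(i + 1, length(mem))) {
          ov <- length(intersect(mem[[i]], mem[[j]]))
          expect_true(ov == 0 ||
                      ov == min(length(mem[[i]]), length(mem[[j]])))
        }
    basal <- basalOGs(ogs)
    expect_setequal(unlist(ogMembers(basal)), leafLabels(ann))
    expect_identical(anyDuplicated(unlist(ogMembers(basal))), 0L)
    ## every OG level lies on the lineage of the tree root's LCA
    rootLca <- nodeLCAs(ann)[length(leafLabels(ann)) + 1L]
    for (lvl in unname(ogLevels(ogs)))
      expect_true(rootLca %in% taxLineage(sim$taxonomy, lvl))
    ## finest partition covers each leaf exactly once
    part <- leafPartition(ogs)
    expect_false(anyNA(part))
    expect_setequal(names(part), leafLabels(ann))
  }
})

test_that("zero thresholds split maximally: one OG per internal-node child
           plus the root", {
  p0 <- delineationParams(soDuplicationThreshold = 0,
                          duplicationRetentionFraction = 0)
  sim <- cleanFamily(17, nSpecies = 10, dupRate = 0.15)
  ann <- annotateEvents(sim$tree, sim$taxonomy, p0)
  ogs <- extractOGs(ann, sim$taxonomy, p0)
  phy <- asPhylo(ann)
  n <- length(phy$tip.label)
  expect_identical(length(ogs), n + phy$Nnode)
})

test_that("pairwise relations follow the event at each pair's tree LCA", {
  tax <- flatTaxonomy(c("s1", "s2"))
  g2 <- annotateEvents(parseNewick("(s1.a:1,s2.b:1);"), tax)
  po2 <- pairwiseOrthologs(g2, "s1.a")
  expect_identical(po2$target, "s2.b")
  expect_identical(po2$relation, "ortholog")
  expect_identical(po2$scope_taxid, "root")

  gB <- annotateEvents(parseNewick("((s1.a:1,s2.a:1):1,(s1.b:1,s2.b:1):1);"),
                       tax)
  po <- pairwiseOrthologs(gB, "s1.a")
  expect_identical(po$relation[po$target == "s2.a"], "ortholog")
  expect_setequal(po$target[po$relation == "in-paralog"],
                  c("s1.b", "s2.b"))
  expect_error(pairwiseOrthologs(gB, "s9.z"),
               class = "phylOG_unknown_leaf")

  ## brute force on a simulated family: event at ape::getMRCA per pair
  sim <- cleanFamily(23, nSpecies = 10, dupRate = 0.2)
  ann <- annotateEvents(sim$tree, sim$taxonomy)
  labs <- leafLabels(ann)
  q <- labs[1]
  po <- pairwiseOrthologs(ann, q)
  for (i in seq_len(nrow(po))) {
    mr <- ape::getMRCA(asPhylo(ann), c(q, po$target[i]))
    expected <- if (nodeEvents(ann)[mr] == "duplication") "in-paralog"
                else "ortholog"
    expect_identical(po$relation[i], expected)
    expect_identical(po$scope_taxid[i], nodeLCAs(ann)[mr])
  }
})
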