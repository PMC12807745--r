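test_that("species-overlap score: disjoint children 0, identical children 1,
           symmetric and bounded", {
  tax <- flatTaxonomy(c("A", "B", "C", "D"))
  g1 <- parseNewick("((A.1:1,B.1:1):1,(C.1:1,D.1:1):1);")
  n1 <- length(leafLabels(g1))
  expect_identical(speciesOverlap(g1, n1 + 1), 0)
  g2 <- parseNewick("((A.1:1,B.1:1,C.1:1):1,(A.2:1,B.2:1,C.2:1):1);")
  expect_identical(speciesOverlap(g2, length(leafLabels(g2)) + 1), 1)
  ## exclusion that empties a child is unscorable
  expect_error(speciesOverlap(g1, n1 + 2, excluded = c("A.1", "B.1")),
               class = "phylOG_degenerate_node")
})

test_that("the duplication threshold is inclusive at exactly 10% overlap", {
  sp19 <- c(LETTERS[1:10], LETTERS[11:19])
  tax <- flatTaxonomy(unique(sp19))
  ## children {A..J} vs {A,K..S}: overlap 1 / union 19 < 0.10 -> speciation
  left <- paste(paste0(LETTERS[1:10], ".l:1"), collapse = ",")
  right <- paste(c("A.r:1", paste0(LETTERS[11:19], ".r:1")), collapse = ",")
  gBelow <- annotateEvents(
    parseNewick(sprintf("((%s):1,(%s):1);", left, right)), tax)
  n <- length(leafLabels(gBelow))
  expect_equal(soScores(gBelow)[n + 1], 1 / 19, tolerance = 1e-12)
  expect_identical(nodeEvents(gBelow)[n + 1], "speciation")
  ## children {A..J} vs {A}: overlap 1 / union 10 = 0.10 exactly -> dup
  gAt <- annotateEvents(
    parseNewick(sprintf("((%s):1,A.r:1);", left)), tax)
  nA <- length(leafLabels(gAt))
  expect_equal(soScores(gAt)[nA + 1], 0.1, tolerance = 1e-12)
  expect_identical(nodeEvents(gAt)[nA + 1], "duplication")
})

test_that("reference LCA is the deepest taxon covering >=90% (inclusive)", {
  ## all leaves one species -> the species itself
  taxA <- flatTaxonomy("s1")
  gA <- parseNewick("(s1.a:1,s1.b:1);")
  expect_identical(referenceLCA(gA, taxA, 3), "s1")
  ## 10 leaves, 9 under clade X, 1 outside: 9/10 >= 0.9 -> X
  df <- data.frame(
    taxid = c("r", "X", paste0("x", 1:9), "z"),
    parent = c("r", "r", rep("X", 9), "r"))
  tax <- Taxonomy(df)
  tips <- paste(c(paste0("x", 1:9, ".p:1"), "z.p:1"), collapse = ",")
  g <- parseNewick(sprintf("(%s);", tips))
  expect_identical(referenceLCA(g, tax, 11), "X")
  ## with 8/10 it falls back to the root
  tips2 <- paste(c(paste0("x", 1:8, ".p:1"), "z.p1:1", "z.p2:1"),
                 collapse = ",")
  g2 <- parseNewick(sprintf("(%s);", tips2))
  expect_identical(referenceLCA(g2, tax, 11), "r")
})

test_that("reference LCA matches the brute-force taxon scan on simulations", {
  for (seed in 1:6) {
    sim <- cleanFamily(seed, nSpecies = 15, dupRate = 0.2)
    gt <- sim$tree
    taxF <- data.frame(taxid = taxIds(sim$taxonomy),
                       parent = sim$taxonomy@parent,
                       stringsAsFactors = FALSE)
    phy <- asPhylo(gt)
    n <- length(phy$tip.label)
    for (node in sample(seq(n + 1, n + phy$Nnode), min(6, phy$Nnode)))
      expect_identical(referenceLCA(gt, sim$taxonomy, node),
                       bruteRefLCA(gt, taxF, node))
  }
})

test_that("outlier detection applies the >=95% external rule", {
  ## taxonomy: root -> {X, Y}; X -> x1..; Y -> y1..y9
  mkTax <- function() Taxonomy(data.frame(
    taxid = c("r", "X", "Y", "x1", paste0("y", 1:9)),
    parent = c("r", "r", "r", "X", rep("Y", 9))))
  ## node = (9 Y-leaves + 1 x1 leaf); 20 x1 leaves outside:
  ## external fraction for taxon x1 = 20/21 >= 0.95 -> outlier
  inNode <- paste(c(paste0("y", 1:9, ".p:1"), "x1.in:1"), collapse = ",")
  outX20 <- paste(paste0("x1.o", 1:20, ":1"), collapse = ",")
  g <- parseNewick(sprintf("((%s):1,(%s):1);", inNode, outX20))
  node <- length(leafLabels(g)) + 2L   # the (Y..,x1.in) child of the root
  out <- detectOutliers(g, mkTax(), node)
  expect_identical(names(out), "x1.in")
  ## with only 10 external copies: 10/11 < 0.95 -> not an outlier
  outX10 <- paste(paste0("x1.o", 1:10, ":1"), collapse = ",")
  g2 <- parseNewick(sprintf("((%s):1,(%s):1);", inNode, outX10))
  node2 <- length(leafLabels(g2)) + 2L
  expect_length(detectOutliers(g2, mkTax(), node2), 0L)
  ## a node spanning the whole tree has nothing external
  expect_length(detectOutliers(g, mkTax(), length(leafLabels(g)) + 1L), 0L)
})

test_that("event annotation: species-tree-like families have no duplications,
           the textbook two-copy family has exactly the root", {
  sim <- cleanFamily(3, nSpecies = 12, dupRate = 0)
  ann <- annotateEvents(sim$tree, sim$taxonomy)
  expect_length(duplicationNodes(ann), 0L)
  tax <- flatTaxonomy(c("s1", "s2"))
  g <- annotateEvents(parseNewick("((s1.a:1,s2.a:1):1,(s1.b:1,s2.b:1):1);"),
                      tax)
  expect_identical(duplicationNodes(g), 5L)
  expect_identical(soScores(g)[5], 1)
  expect_identical(nodeEvents(g)[6:7], c("speciation", "speciation"))
})

test_that("on loss-free, noise-free simulations the detected duplication set
           equals the simulator's ground truth", {
  for (seed in 1:20) {
    sim <- cleanFamily(seed)
    ann <- annotateEvents(sim$tree, sim$taxonomy)
    truthNodes <- matchGroundTruth(ann, sim$truth)
    expect_false(anyNA(truthNodes))
    expect_setequal(duplicationNodes(ann), truthNodes)
    ## same result with outlier detection disabled (clean trees have no
    ## candidates)
    annOff <- annotateEvents(sim$tree, sim$taxonomy,
                             delineationParams(outlierDetection = FALSE))
    expect_identical(nodeEvents(annOff), nodeEvents(ann))
  }
})

test_that("recorded per-node scores are reproducible from each node's own
           exclusion set (temporary-exclusion contract)", {
  p <- simulationParams(nSpecies = 15, duplicationRate = 0.2,
                        nTransplants = 2, seed = 31)
  sim <- simulateFamily(p)
  ann <- annotateEvents(sim$tree, sim$taxonomy)
  phy <- asPhylo(ann)
  n <- length(phy$tip.label)
  for (node in seq(n + 1, n + phy$Nnode)) {
    ex <- nodeOutliers(ann)[[node]]
    got <- tryCatch(speciesOverlap(ann, node, excluded = ex),
                    phylOG_degenerate_node = function(e) 0)
    expect_equal(soScores(ann)[node], got, tolerance = 1e-12)
    ## and the standalone score without exclusions matches brute force
    expect_equal(speciesOverlap(ann, node), bruteSO(ann, node),
                 tolerance = 1e-12)
  }
})
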