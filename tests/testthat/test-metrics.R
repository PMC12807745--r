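test_that("duplication rate ignores species-specific duplications", {
  tax <- flatTaxonomy(c("s1", "s2"))
  ## no duplications at all
  g0 <- annotateEvents(parseNewick("(s1.a:1,s2.a:1);"), tax)
  r0 <- duplicationRate(extractOGs(g0, tax))
  expect_identical(r0$perOg$n_duplications, 0L)
  expect_identical(r0$meanRate, 0)
  ## one duplication whose leaves are all one species: ignored
  gs <- annotateEvents(parseNewick("((s1.a:1,s1.b:1):1,s2.c:1);"), tax)
  expect_length(duplicationNodes(gs), 1L)
  rs <- duplicationRate(extractOGs(gs, tax))
  expect_identical(rs$perOg$n_duplications, 0L)
  ## a two-species duplication at the root: counted once
  gd <- annotateEvents(parseNewick("((s1.a:1,s2.a:1):1,(s1.b:1,s2.b:1):1);"),
                       tax)
  rd <- duplicationRate(extractOGs(gd, tax))
  expect_identical(rd$perOg$n_duplications, 1L)
  expect_identical(rd$meanRate, 1)
})

test_that("duplication counts equal the simulator's multi-species ground
           truth on loss-free families", {
  for (seed in 1:10) {
    sim <- cleanFamily(seed)
    ann <- annotateEvents(sim$tree, sim$taxonomy)
    ogs <- extractOGs(ann, sim$taxonomy)
    rep <- duplicationRate(ogs)
    phy <- asPhylo(ann)
    sp <- unname(leafSpecies(ann))
    truthNodes <- matchGroundTruth(ann, sim$truth)
    nMulti <- sum(vapply(truthNodes, function(d)
      length(unique(sp[tipsUnderNode(phy, d)])) > 1, TRUE))
    expect_identical(sum(rep$perOg$n_duplications), nMulti)
  }
})

test_that("the toy benchmark table gives precision = recall = F = 0.8", {
  og <- c(setNames(rep("OG1", 10), c(letters[1:8], "x", "y")),
          setNames(rep("OG2", 2), c("i", "j")),
          setNames(rep("OG3", 10), paste0("m", 1:10)))
  ref <- c(setNames(rep("K1", 10), letters[1:10]),
           setNames(rep("K2", 2), c("x", "y")),
           setNames(rep("K3", 10), paste0("m", 1:10)))
  res <- fscoreBenchmark(og, ref)
  row <- res$perGroup[res$perGroup$group == "K1", ]
  expect_identical(row$best_og, "OG1")
  expect_identical(c(row$tp, row$fp, row$fn), c(8L, 2L, 2L))
  expect_equal(c(row$precision, row$recall, row$f_score), c(0.8, 0.8, 0.8))
  ## K2's two proteins share OG1 with 8 annotated K1 proteins:
  ## P = 2/10, R = 1, F = 1/3
  resK2 <- res$perGroup[res$perGroup$group == "K2", ]
  expect_equal(resK2$f_score, 1 / 3)
  ## an exactly matching group scores 1 everywhere
  resK3 <- res$perGroup[res$perGroup$group == "K3", ]
  expect_equal(c(resK3$precision, resK3$recall, resK3$f_score), c(1, 1, 1))
  expect_equal(res$meanF, mean(c(0.8, 1 / 3, 1)))
})

test_that("proteins without reference annotation are neither TP nor FP", {
  og <- setNames(rep("OG1", 4), c("a", "b", "u1", "u2"))  # u* unannotated
  ref <- setNames(rep("K1", 2), c("a", "b"))
  res <- fscoreBenchmark(og, ref)
  expect_identical(res$perGroup$fp, 0L)
  expect_equal(res$perGroup$f_score, 1)
})

test_that("best-OG selection matches brute-force enumeration on random
           membership tables", {
  bruteBest <- function(ogDf, refDf, k) {
    annotated <- unique(refDf$protein)
    kProt <- unique(refDf$protein[refDf$group == k])
    ogs <- sort(unique(ogDf$og[ogDf$protein %in% kProt]))
    best <- NULL
    for (o in ogs) {
      oProt <- ogDf$protein[ogDf$og == o]
      tp <- length(intersect(kProt, oProt))
      fn <- length(setdiff(intersect(kProt, ogDf$protein), oProt))
      fp <- length(intersect(setdiff(oProt, kProt), annotated))
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      f <- if (p + r > 0) 2 * p * r / (p + r) else 0
      cand <- list(og = o, f = f, tp = tp)
      if (is.null(best) || f > best$f + 1e-12 ||
          (abs(f - best$f) <= 1e-12 && (tp > best$tp ||
           (tp == best$tp && o < best$og)))) best <- cand
    }
    best
  }
  set.seed(77)
  for (k in 1:5) {
    prot <- paste0("p", 1:40)
    ogDf <- data.frame(protein = prot,
                       og = sample(paste0("OG", 1:6), 40, replace = TRUE))
    refProt <- sample(prot, 30)
    refDf <- data.frame(protein = refProt,
                        group = sample(paste0("K", 1:4), 30, replace = TRUE))
    res <- fscoreBenchmark(ogDf, refDf)
    for (g in res$perGroup$group) {
      expected <- bruteBest(ogDf, refDf, g)
      row <- res$perGroup[res$perGroup$group == g, ]
      expect_identical(row$best_og, expected$og)
      expect_equal(row$f_score, expected$f, tolerance = 1e-12)
      ## permutation invariance in protein order
      perm <- sample(nrow(ogDf))
      res2 <- fscoreBenchmark(ogDf[perm, ], refDf[sample(nrow(refDf)), ])
      expect_equal(res2$perGroup[res2$perGroup$group == g, "f_score"],
                   row$f_score, tolerance = 1e-12)
      expect_true(row$f_score >= 0 && row$f_score <= 1)
    }
  }
})

test_that("size distribution tallies singletons and oversized OGs", {
  tax <- flatTaxonomy(c("s1", "s2"))
  gd <- annotateEvents(parseNewick("((s1.a:1,s2.a:1):1,(s1.b:1,s2.b:1):1);"),
                       tax)
  ogs <- extractOGs(gd, tax)
  sd1 <- sizeDistribution(ogs)
  expect_identical(sd1$histogram$size, 4L)  # one basal OG of size 4
  expect_identical(sd1$nSingletons, 0L)
  expect_identical(sd1$nOverThreshold, 0L)
  expect_identical(sizeDistribution(ogs, sizeThreshold = 3)$nOverThreshold,
                   1L)
  ## singletons counted over basal OGs of several families
  g1 <- extractOGs(annotateNodeLCAs(parseNewick("(s1.a:1);"), tax), tax,
                   familyId = "f1")
  g2 <- extractOGs(annotateNodeLCAs(parseNewick("(s2.b:1);"), tax), tax,
                   familyId = "f2")
  sd2 <- sizeDistribution(list(g1, g2, ogs))
  expect_identical(sd2$nSingletons, 2L)
  ## empty input gives an empty table
  sd0 <- sizeDistribution(list())
  expect_identical(nrow(sd0$histogram), 0L)
})
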