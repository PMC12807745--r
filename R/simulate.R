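## Gene-family simulator: a Yule species tree whose internal nodes double
## as ancestral taxa (so the taxonomy is perfectly consistent with the
## species tree), gene duplication/loss as Poisson processes along
## species-tree branches (a Gillespie walk), and two noise operators.
## Ground truth (duplication clades, transplanted leaves) is tracked as
## leaf-label sets so it survives tree surgery.

#' Simulate a species tree and its matching taxonomy
#'
#' A pure-birth (Yule) species tree with `nSpecies` leaves; every internal
#' node becomes an ancestral taxon of the returned taxonomy, so lineage
#' queries over the taxonomy agree exactly with the species-tree topology.
#'
#' @param params a [SimulationParams-class] (fields `nSpecies`,
#'   `birthRate` used).
#' @param seed optional integer; if given, the RNG is seeded here, making
#'   the tree reproducible in isolation.
#' @return list with `tree` (an [ape::phylo] with tip labels `s1..sN` and
#'   node labels) and `taxonomy` (a [Taxonomy-class]).
#' @export
simulateSpeciesTree <- function(params = simulationParams(), seed = NULL) {
  stopifnot(is(params, "SimulationParams"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(params@nSpecies)
  phy <- ape::rphylo(n, birth = params@birthRate, death = 0)
  phy$tip.label <- paste0("s", seq_len(n))
  phy$node.label <- paste0("n", seq_len(phy$Nnode) + n)
  nodeTax <- c(phy$tip.label, phy$node.label)
  parent <- .parentVec(phy)
  pidx <- parent
  pidx[is.na(parent)] <- which(is.na(parent))  # root points to itself
  df <- data.frame(
    taxid = nodeTax,
    parent = nodeTax[pidx],
    rank = c(rep("species", n), rep("clade", phy$Nnode)),
    name = nodeTax, stringsAsFactors = FALSE)
  list(tree = phy, taxonomy = Taxonomy(df))
}

#' Simulate a gene tree along a species tree
#'
#' One gene lineage (two with `nRootLineages = 2`, forcing a root
#' duplication) enters the species-tree root and evolves downwards:
#' duplications fork the lineage at rate `duplicationRate`, losses prune
#' it at rate `lossRate` (per lineage per unit branch length), and
#' lineages split at every species node. Surviving lineages become leaves
#' labelled `<species>.g<k>`. Unary nodes left by losses are suppressed
#' with branch lengths summed, so every internal node of the emitted tree
#' is a bifurcation. Duplication nodes with two surviving children are the
#' ground truth.
#'
#' @param speciesTree an [ape::phylo] from [simulateSpeciesTree()].
#' @param taxonomy the matching [Taxonomy-class].
#' @param params a [SimulationParams-class].
#' @param seed optional integer seed.
#' @return list with `tree` (a [GeneTree-class]) and `truth` (class
#'   `"groundTruth"`: `duplicationLeafSets`, `transplanted`, `inflated`).
#' @export
simulateGeneTree <- function(speciesTree, taxonomy,
                             params = simulationParams(), seed = NULL) {
  stopifnot(is(params, "SimulationParams"))
  if (!is.null(seed)) set.seed(seed)
  phy <- speciesTree
  n <- .nTips(phy)
  kids <- .childrenList(phy)
  elen <- rep(NA_real_, n + phy$Nnode)
  elen[phy$edge[, 2L]] <- phy$edge.length
  lambda <- params@duplicationRate
  mu <- params@lossRate
  rate <- lambda + mu
  counter <- new.env(parent = emptyenv())

  geneLabel <- function(sp) {
    k <- (get0(sp, envir = counter, ifnotfound = 0L)) + 1L
    assign(sp, k, envir = counter)
    paste0(sp, ".g", k)
  }

  evolve <- function(spNode, tIn) {
    tEvent <- if (rate > 0) rexp(1L, rate) else Inf
    if (tEvent < tIn) {
      if (runif(1L) < lambda / rate) {
        left <- evolve(spNode, tIn - tEvent)
        right <- evolve(spNode, tIn - tEvent)
        if (is.null(left) && is.null(right)) return(NULL)
        if (is.null(left)) { right$len <- right$len + tEvent; return(right) }
        if (is.null(right)) { left$len <- left$len + tEvent; return(left) }
        return(list(children = list(left, right), len = tEvent, dup = TRUE))
      }
      return(NULL)  # loss
    }
    if (spNode <= n)
      return(list(leaf = geneLabel(phy$tip.label[spNode]), len = tIn))
    sub <- lapply(kids[[spNode]], function(ch) evolve(ch, elen[ch]))
    sub <- sub[!vapply(sub, is.null, TRUE)]
    if (length(sub) == 0L) return(NULL)
    if (length(sub) == 1L) {
      sub[[1L]]$len <- sub[[1L]]$len + tIn
      return(sub[[1L]])
    }
    list(children = sub, len = tIn, dup = FALSE)
  }

  root <- .rootNode(phy)
  tops <- lapply(seq_len(as.integer(params@nRootLineages)),
                 function(i) evolve(root, 0))
  tops <- tops[!vapply(tops, is.null, TRUE)]
  if (length(tops) == 0L)
    .phylogError("phylOG_all_lineages_lost",
                 "every gene lineage was lost; retry with another seed")
  topNode <- if (length(tops) == 1L) tops[[1L]]
             else list(children = tops, len = 0, dup = TRUE)

  ## serialize + collect ground-truth duplication clades
  dupSets <- list()
  leavesOf <- function(nd) {
    if (!is.null(nd$leaf)) return(nd$leaf)
    unlist(lapply(nd$children, leavesOf), use.names = FALSE)
  }
  toNewick <- function(nd, isRoot = FALSE) {
    if (!is.null(nd$leaf))
      return(sprintf("%s:%.10g", nd$leaf, nd$len))
    if (isTRUE(nd$dup))
      dupSets[[length(dupSets) + 1L]] <<- leavesOf(nd)
    inner <- paste(vapply(nd$children, toNewick, ""), collapse = ",")
    if (isRoot) paste0("(", inner, ");")
    else sprintf("(%s):%.10g", inner, nd$len)
  }
  if (!is.null(topNode$leaf)) {
    gt <- new("GeneTree",
              tree = .singleTipPhylo(topNode$leaf, topNode$len),
              species = sub("\\..*$", "", topNode$leaf),
              protein = sub("^[^.]*\\.", "", topNode$leaf))
  } else {
    nwk <- toNewick(topNode, isRoot = TRUE)
    gt <- parseNewick(nwk, sep = ".")
  }
  truth <- structure(list(duplicationLeafSets = dupSets,
                          transplanted = character(0),
                          inflated = character(0)),
                     class = "groundTruth")
  list(tree = gt, truth = truth)
}

#' @export
print.groundTruth <- function(x, ...) {
  cat("Ground truth:", length(x$duplicationLeafSets),
      "duplication clade(s),", length(x$transplanted), "transplanted,",
      length(x$inflated), "inflated leaf/leaves\n")
  invisible(x)
}

#' Inject noise into a simulated gene tree
#'
#' Two operators emulating the artifacts the event classifier must
#' tolerate: (i) `nTransplants` leaves are detached and re-attached onto
#' an edge inside a uniformly chosen foreign speciation clade (one whose
#' species set does not contain the leaf's species), emulating horizontal
#' transfer or misplacement — the leaf multiset is conserved; (ii) the
#' pendant branches of `inflateFraction` of the leaves are multiplied by
#' `inflateMultiplier`, emulating long-branch artifacts.
#'
#' @param x a [GeneTree-class] from [simulateGeneTree()].
#' @param truth the matching `"groundTruth"` object (updated and
#'   returned).
#' @param params a [SimulationParams-class].
#' @param seed optional integer seed.
#' @return list with `tree` and `truth`.
#' @export
injectNoise <- function(x, truth, params = simulationParams(),
                        seed = NULL) {
  stopifnot(is(x, "GeneTree"), inherits(truth, "groundTruth"))
  if (!is.null(seed)) set.seed(seed)
  gt <- x
  nT <- as.integer(params@nTransplants)
  for (t in seq_len(nT)) {
    phy <- gt@tree
    n <- .nTips(phy)
    if (n < 3L) break
    tipIdx <- sample.int(n, 1L)
    tipLabel <- phy$tip.label[tipIdx]
    sp <- gt@species[tipIdx]
    pend <- .pendantLengths(phy)[tipIdx]
    phy2 <- ape::drop.tip(phy, tipIdx)
    n2 <- .nTips(phy2)
    tipsUnder <- .tipsUnder(phy2)
    sp2 <- gt@species[match(phy2$tip.label, phy$tip.label)]
    labs2 <- phy2$tip.label
    dupSets <- lapply(truth$duplicationLeafSets,
                      function(s) intersect(s, labs2))
    isDupClade <- function(v) {
      lv <- labs2[tipsUnder[[v]]]
      any(vapply(dupSets, function(s)
        length(s) == length(lv) && setequal(s, lv), TRUE))
    }
    cand <- setdiff(seq_len(n2 + phy2$Nnode), .rootNode(phy2))
    foreign <- vapply(cand, function(v)
      !(sp %in% sp2[tipsUnder[[v]]]) && !isDupClade(v), TRUE)
    cand <- cand[foreign]
    if (!length(cand)) next
    v <- cand[sample.int(length(cand), 1L)]
    eAbove <- phy2$edge.length[match(v, phy2$edge[, 2L])]
    phy3 <- phytools::bind.tip(phy2, tipLabel, edge.length = pend,
                               where = v, position = eAbove / 2)
    gt <- .rebuildGeneTree(phy3, gt)
    truth$transplanted <- union(truth$transplanted, tipLabel)
  }
  frac <- params@inflateFraction
  if (frac > 0 && params@inflateMultiplier != 1) {
    phy <- gt@tree
    n <- .nTips(phy)
    m <- floor(frac * n)
    if (m > 0) {
      picks <- sample.int(n, m)
      ei <- match(picks, phy$edge[, 2L])
      phy$edge.length[ei] <- phy$edge.length[ei] * params@inflateMultiplier
      gt@tree <- phy
      truth$inflated <- union(truth$inflated, phy$tip.label[picks])
    }
  }
  list(tree = gt, truth = truth)
}

#' Locate ground-truth duplication clades in a (possibly noisy) gene tree
#'
#' Maps each recorded duplication leaf set to a node of `x`, ignoring
#' transplanted leaves on both sides. A clade destroyed by noise (no
#' matching node) maps to `NA`.
#'
#' @param x a [GeneTree-class].
#' @param truth a `"groundTruth"` object.
#' @return integer vector of node indices (NA where unrecoverable),
#'   parallel to `truth$duplicationLeafSets`.
#' @export
matchGroundTruth <- function(x, truth) {
  stopifnot(is(x, "GeneTree"), inherits(truth, "groundTruth"))
  phy <- x@tree
  labs <- leafLabels(x)
  n <- .nTips(phy)
  tipsUnder <- .tipsUnder(phy)
  vapply(truth$duplicationLeafSets, function(s) {
    s2 <- setdiff(intersect(s, labs), truth$transplanted)
    if (length(s2) < 2L) return(NA_integer_)
    nd <- ape::getMRCA(phy, s2)
    if (is.null(nd)) return(NA_integer_)
    have <- setdiff(labs[tipsUnder[[nd]]], truth$transplanted)
    if (setequal(have, s2)) nd else NA_integer_
  }, 1L)
}

#' Simulate a complete gene family
#'
#' Seeds the RNG from `params@seed` and runs
#' [simulateSpeciesTree()] -> [simulateGeneTree()] -> [injectNoise()].
#' Identical parameters (seed included) give byte-identical Newick output.
#'
#' @param params a [SimulationParams-class].
#' @return list: `speciesTree`, `taxonomy`, `tree` (the noisy
#'   [GeneTree-class]), `truth`.
#' @export
simulateFamily <- function(params = simulationParams()) {
  stopifnot(is(params, "SimulationParams"))
  set.seed(as.integer(params@seed))
  st <- simulateSpeciesTree(params)
  sim <- simulateGeneTree(st$tree, st$taxonomy, params)
  noisy <- injectNoise(sim$tree, sim$truth, params)
  list(speciesTree = st$tree, taxonomy = st$taxonomy,
       tree = noisy$tree, truth = noisy$truth)
}

#' Write simulation artifacts to a directory
#'
#' Emits `species.nwk`, `taxonomy.tsv`, `genetree.nwk` and `truth.json`.
#'
#' @param sim result of [simulateFamily()].
#' @param dir output directory (created if needed).
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ape::write.tree(sim$speciesTree, file.path(dir, "species.nwk"))
  tax <- sim$taxonomy
  write.table(
    data.frame(taxid = tax@taxid, parent = tax@parent, rank = tax@rank,
               name = tax@sciname),
    file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeNewick(sim$tree, file.path(dir, "genetree.nwk"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(duplication_leaf_sets = sim$truth$duplicationLeafSets,
           transplanted = sim$truth$transplanted,
           inflated = sim$truth$inflated),
      file.path(dir, "truth.json"), auto_unbox = FALSE)
  }
  invisible(dir)
}
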