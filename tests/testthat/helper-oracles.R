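## Independent oracles and fixture builders. These deliberately avoid the
## package's own traversal code: they work on raw parent maps and plain
## ape structures with brute-force loops, so they can arbitrate what the
## implementation should produce.

## -- taxonomy fixtures ------------------------------------------------------

## a flat taxonomy: root plus one species taxon per id
flatTaxonomy <- function(species, root = "root") {
  Taxonomy(data.frame(
    taxid = c(root, species), parent = c(root, rep(root, length(species))),
    rank = c("root", rep("species", length(species))),
    name = c(root, species), stringsAsFactors = FALSE))
}

## random parent-pointer table: each taxon's parent drawn from earlier ones
randomTaxonomyFrame <- function(nTaxa, seed) {
  set.seed(seed)
  ids <- paste0("t", seq_len(nTaxa))
  parent <- c(ids[1], vapply(2:nTaxa, function(i)
    ids[sample.int(i - 1L, 1L)], ""))
  data.frame(taxid = ids, parent = parent, rank = "", name = ids,
             stringsAsFactors = FALSE)
}

## root-to-taxon lineage by repeated parent lookups on the raw frame
bruteLineage <- function(df, id) {
  pmap <- setNames(df$parent, df$taxid)
  chain <- id
  while (pmap[[chain[1]]] != chain[1]) chain <- c(pmap[[chain[1]]], chain)
  chain
}

## LCA as the deepest element of the intersection of lineage lists
bruteLCA <- function(df, ids) {
  lins <- lapply(ids, function(i) bruteLineage(df, i))
  common <- Reduce(intersect, lins)
  depths <- vapply(common, function(t) length(bruteLineage(df, t)), 1L)
  common[which.max(depths)]
}

## -- tree oracles -----------------------------------------------------------

tipsUnderNode <- function(phy, node) {
  phangorn::Descendants(phy, node, type = "tips")[[1]]
}

## species-overlap score recomputed from scratch (binary and multifurcating)
bruteSO <- function(gt, node, excluded = integer(0)) {
  phy <- asPhylo(gt)
  sp <- unname(leafSpecies(gt))
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  sets <- lapply(kids, function(ch) {
    tips <- setdiff(tipsUnderNode(phy, ch), excluded)
    unique(sp[tips])
  })
  if (any(lengths(sets) == 0)) return(NA_real_)
  best <- 0
  for (i in seq_len(length(sets) - 1))
    for (j in seq(i + 1, length(sets))) {
      sc <- length(intersect(sets[[i]], sets[[j]])) /
            length(union(sets[[i]], sets[[j]]))
      best <- max(best, sc)
    }
  best
}

## reference LCA by scanning every taxon in the union of leaf lineages
bruteRefLCA <- function(gt, taxFrame, node, coverage = 0.9) {
  phy <- asPhylo(gt)
  sp <- unname(leafSpecies(gt))[tipsUnderNode(phy, node)]
  lins <- lapply(sp, function(s) bruteLineage(taxFrame, s))
  taxa <- unique(unlist(lins))
  covered <- vapply(taxa, function(t)
    mean(vapply(lins, function(l) t %in% l, TRUE)), 1)
  ok <- taxa[covered >= coverage - 1e-12]
  depths <- vapply(ok, function(t) length(bruteLineage(taxFrame, t)), 1L)
  ok[order(-depths, ok)][1]
}

## per-node species LCA by brute force over the clade's species
bruteNodeLCA <- function(gt, taxFrame, node) {
  phy <- asPhylo(gt)
  sp <- unique(unname(leafSpecies(gt))[tipsUnderNode(phy, node)])
  bruteLCA(taxFrame, sp)
}

## independent numeric-scan minimum of the root-to-tip variance over all
## edges of the unrooted tree (stats::optimize per edge, not closed form)
bruteMinVar <- function(gt) {
  u <- ape::unroot(asPhylo(gt))
  n <- length(u$tip.label)
  D <- ape::dist.nodes(u)
  best <- Inf
  for (i in seq_len(nrow(u$edge))) {
    a <- u$edge[i, 1]; v <- u$edge[i, 2]; L <- u$edge.length[i]
    below <- tipsUnderNode(u, v)
    s <- rep(1, n); s[below] <- -1
    d <- D[a, seq_len(n)]
    f <- function(x) { z <- d + s * x; mean(z^2) - mean(z)^2 }
    cand <- f(c(0))
    if (L > 0) cand <- c(cand, f(L), stats::optimize(f, c(0, L))$objective)
    best <- min(best, cand)
  }
  best
}

## population variance of root-to-tip distances of a rooted tree
tipVariance <- function(phy) {
  n <- length(phy$tip.label)
  d <- ape::dist.nodes(phy)[n + 1, seq_len(n)]
  mean(d^2) - mean(d)^2
}

## -- OG reconstruction from ground truth ------------------------------------

## Rebuilds the expected OG structure directly from a set of duplication
## nodes: applies the >=70% retention rule by recounting lineage
## membership, seeds OGs at the root and at children of retained nodes,
## and derives nesting/partition with plain set arithmetic.
bruteOgsFromDups <- function(gt, taxFrame, dupNodes, retention = 0.7,
                             coverage = 0.9) {
  phy <- asPhylo(gt)
  n <- length(phy$tip.label)
  labs <- leafLabels(gt)
  sp <- unname(leafSpecies(gt))
  lins <- lapply(sp, function(s) bruteLineage(taxFrame, s))
  hasTax <- function(tips, t) sum(vapply(lins[tips], function(l)
    t %in% l, TRUE))
  retained <- dupNodes[vapply(dupNodes, function(d) {
    r <- bruteRefLCA(gt, taxFrame, d, coverage)
    hasTax(tipsUnderNode(phy, d), r) / hasTax(seq_len(n), r) >=
      retention - 1e-12
  }, TRUE)]
  seeds <- unique(c(n + 1L,
                    unlist(lapply(retained, function(d)
                      phy$edge[phy$edge[, 1] == d, 2]))))
  memberSets <- lapply(seeds, function(s) sort(labs[tipsUnderNode(phy, s)]))
  ## finest partition: each leaf -> smallest containing member set
  part <- vapply(labs, function(l) {
    sizes <- lengths(memberSets)
    hit <- which(vapply(memberSets, function(m) l %in% m, TRUE))
    hit[which.min(sizes[hit])]
  }, 1L)
  list(seeds = seeds, memberSets = memberSets, partition = part,
       retained = retained)
}

## -- misc -------------------------------------------------------------------

## canonical form of a set of member sets, for comparison across routes
canonicalSets <- function(sets) {
  unname(sort(vapply(sets, function(s) paste(sort(s), collapse = ","), "")))
}

## fixture: 10 leaves all on one lineage (flat taxonomy), a duplication
## node holding k of them; retention = k/10 against the 70% rule
retentionFixture <- function(k) {
  insideSpecies <- c("a", letters[2:(k - 1)])
  inside <- paste(c("a.p1:1",
                    sprintf("(%s):1",
                            paste(c("a.p2:1",
                                    paste0(insideSpecies[-1], ".q:1")),
                                  collapse = ","))),
                  collapse = ",")
  outsideSpecies <- letters[seq(k, 9)]
  outside <- paste(paste0(outsideSpecies, ".q:1"), collapse = ",")
  nwk <- sprintf("((%s):1,(%s):1);", inside, outside)
  list(tree = parseNewick(nwk), tax = flatTaxonomy(letters[1:9]))
}

## a simulated clean family (loss-free, noise-free) for property tests
cleanFamily <- function(seed, nSpecies = 20, dupRate = 0.1) {
  simulateFamily(simulationParams(nSpecies = nSpecies,
                                  duplicationRate = dupRate,
                                  lossRate = 0, seed = seed))
}

## expected number of duplication events for a fixed species tree under a
## pure-birth duplication process: sum over branches of
## E[lineages entering] * (exp(lambda * t) - 1)
expectedDupCount <- function(speciesTree, lambda) {
  phy <- speciesTree
  n <- length(phy$tip.label)
  parent <- rep(NA_integer_, n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  elen <- rep(NA_real_, n + phy$Nnode)
  elen[phy$edge[, 2]] <- phy$edge.length
  entering <- function(node) {
    p <- parent[node]
    if (is.na(p)) return(1)
    entering(p) * exp(lambda * elen[node])
  }
  sum(vapply(phy$edge[, 2], function(v)
    entering(parent[v]) * (exp(lambda * elen[v]) - 1), 1))
}
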