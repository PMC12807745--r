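## Internal helpers shared by the tree-facing modules. All take/return
## plain ape 'phylo' objects and ape node indices (tips 1..n, internal
## nodes n+1 .. n+Nnode).

.nTips <- function(phy) length(phy$tip.label)

.rootNode <- function(phy) .nTips(phy) + 1L

.childrenList <- function(phy) {
  nn <- .nTips(phy) + phy$Nnode
  out <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge)))
    out[[phy$edge[i, 1L]]] <- c(out[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  out
}

.parentVec <- function(phy) {
  nn <- .nTips(phy) + phy$Nnode
  p <- rep(NA_integer_, nn)
  p[phy$edge[, 2L]] <- phy$edge[, 1L]
  p
}

## tips under every node (a tip is under itself); list indexed by node id
.tipsUnder <- function(phy) {
  n <- .nTips(phy)
  all <- phangorn::Descendants(phy, seq_len(n + phy$Nnode), type = "tips")
  all
}

## internal nodes in postorder (children before parents)
.postorderInternal <- function(phy) {
  ord <- ape::reorder.phylo(phy, "postorder")$edge[, 1L]
  unique(ord)
}

## pendant edge length of each tip
.pendantLengths <- function(phy) {
  len <- rep(0, .nTips(phy))
  isTip <- phy$edge[, 2L] <= .nTips(phy)
  if (!is.null(phy$edge.length))
    len[phy$edge[isTip, 2L]] <- phy$edge.length[isTip]
  len
}

## normalize: missing/NA branch lengths -> 0
.normalizeLengths <- function(phy) {
  if (is.null(phy$edge.length))
    phy$edge.length <- rep(0, nrow(phy$edge))
  phy$edge.length[is.na(phy$edge.length)] <- 0
  phy
}

## rebuild a GeneTree around a surgically modified phylo, carrying the
## (species, protein) mapping over by tip label; annotations are dropped
## because node identities changed
.rebuildGeneTree <- function(phy, gt) {
  old <- gt@tree$tip.label
  hit <- match(phy$tip.label, old)
  if (anyNA(hit))
    .phylogError("phylOG_internal_error",
                 "tip labels lost during tree surgery")
  new("GeneTree", tree = .normalizeLengths(phy),
      species = gt@species[hit], protein = gt@protein[hit])
}

## single-tip phylo (ape has no constructor for it)
.singleTipPhylo <- function(label, len = 0) {
  structure(list(
    edge = matrix(c(2L, 1L), 1L, 2L),
    edge.length = len,
    tip.label = label,
    Nnode = 1L
  ), class = "phylo", order = "cladewise")
}
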