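## Species-overlap event classification with two-step taxonomic outlier
## exclusion. The per-tree "context" precomputes, for every node and every
## taxon occurring on any leaf lineage, the number of leaves under the node
## whose species lineage contains that taxon; all scoring rules are then
## counting arithmetic on that matrix.

.eventContext <- function(x, taxonomy) {
  phy <- x@tree
  n <- .nTips(phy)
  nn <- n + phy$Nnode
  spp <- unique(x@species)
  missing <- setdiff(spp, taxIds(taxonomy))
  if (length(missing))
    .phylogError("phylOG_unknown_species", paste0(
      "leaf species not in taxonomy: ",
      paste(head(missing, 10L), collapse = ", ")))
  spLineage <- taxonomy@lineages[spp]
  taxa <- unique(unlist(spLineage, use.names = FALSE))
  tIdx <- setNames(seq_along(taxa), taxa)
  Tn <- length(taxa)

  cnt <- matrix(0L, nrow = nn, ncol = Tn, dimnames = list(NULL, taxa))
  for (i in seq_len(n))
    cnt[i, tIdx[spLineage[[x@species[i]]]]] <- 1L
  kids <- .childrenList(phy)
  for (node in .postorderInternal(phy)) {
    cs <- kids[[node]]
    cnt[node, ] <- if (length(cs) == 1L) cnt[cs, ]
                   else colSums(cnt[cs, , drop = FALSE])
  }
  tipsUnder <- .tipsUnder(phy)
  nLeaves <- lengths(tipsUnder)
  root <- .rootNode(phy)
  list(
    n = n, nn = nn, phy = phy, kids = kids, tipsUnder = tipsUnder,
    nLeaves = nLeaves, species = x@species,
    spLineage = spLineage, taxa = taxa, cnt = cnt,
    totals = cnt[root, ], depth = lengths(taxonomy@lineages[taxa]),
    rootTax = taxRoot(taxonomy)
  )
}

.refLcaForNode <- function(ctx, node, coverage) {
  ok <- ctx$cnt[node, ] / ctx$nLeaves[node] >= coverage - 1e-12 &
        ctx$cnt[node, ] > 0L
  cand <- which(ok)
  ## qualifying taxa form a chain for coverage > 0.5; pick the deepest,
  ## breaking hypothetical ties by taxon id for determinism
  cand <- cand[order(-ctx$depth[cand], ctx$taxa[cand])]
  ctx$taxa[cand[1L]]
}

.outliersForNode <- function(ctx, node, refLca, params) {
  tips <- ctx$tipsUnder[[node]]
  sp <- ctx$species[tips]
  uspp <- unique(sp)
  candSp <- uspp[!vapply(uspp, function(s) refLca %in% ctx$spLineage[[s]],
                         TRUE)]
  if (!length(candSp)) return(integer(0))
  thr <- params@outlierExternalFraction
  isOut <- vapply(candSp, function(s) {
    lin <- setdiff(ctx$spLineage[[s]], ctx$rootTax)
    if (!params@outlierLineageIncludesSpecies) lin <- setdiff(lin, s)
    if (!length(lin)) return(FALSE)
    tot <- ctx$totals[lin]
    ext <- (tot - ctx$cnt[node, lin]) / tot
    any(ext >= thr - 1e-12)
  }, TRUE)
  tips[sp %in% candSp[isOut]]
}

## SO score at a node given excluded tip indices; NA when a child clade
## loses all its leaves to exclusion (unscorable)
.soForNode <- function(ctx, node, excluded, mode = "max") {
  cs <- ctx$kids[[node]]
  if (length(cs) < 2L) return(NA_real_)
  sets <- lapply(cs, function(ch) {
    tips <- setdiff(ctx$tipsUnder[[ch]], excluded)
    unique(ctx$species[tips])
  })
  if (any(lengths(sets) == 0L)) return(NA_real_)
  pairScores <- c()
  for (i in seq_len(length(sets) - 1L))
    for (j in seq(i + 1L, length(sets))) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      pairScores <- c(pairScores, inter / uni)
    }
  if (mode == "mean") mean(pairScores) else max(pairScores)
}

#' Species-overlap score of an internal node
#'
#' The fraction of species shared between the species sets of a node's two
#' child clades, `|Sa n Sb| / |Sa u Sb|`, optionally after removing
#' excluded leaves. For multifurcating nodes the maximum pairwise child
#' score is returned (or the mean with `mode = "mean"`). A high overlap is
#' evidence that the node is a gene duplication.
#'
#' @param x a [GeneTree-class].
#' @param node internal node index (ape numbering).
#' @param excluded tip indices or leaf labels to ignore.
#' @param mode "max" (default) or "mean" pairwise score for
#'   multifurcations.
#' @return the score in \[0,1\].
#' @export
speciesOverlap <- function(x, node, excluded = integer(0), mode = "max") {
  stopifnot(is(x, "GeneTree"))
  phy <- x@tree
  n <- .nTips(phy)
  if (node <= n || node > n + phy$Nnode)
    .phylogError("phylOG_usage_error", "node must be an internal node index")
  if (is.character(excluded))
    excluded <- match(excluded, leafLabels(x))
  kids <- .childrenList(phy)
  tipsUnder <- .tipsUnder(phy)
  ctx <- list(kids = kids, tipsUnder = tipsUnder, species = x@species)
  so <- .soForNode(ctx, node, excluded, mode)
  if (is.na(so))
    .phylogError("phylOG_degenerate_node",
      "a child clade has no leaves left after exclusion; the node is unscorable")
  so
}

#' Reference LCA of a node
#'
#' The deepest taxon whose lineage covers at least `coverage` (default
#' 90%) of the node's leaf sequences. Always defined, because the taxonomy
#' root covers every sequence.
#'
#' @param x a [GeneTree-class].
#' @param taxonomy a [Taxonomy-class].
#' @param node a node index (tip or internal).
#' @param coverage required fraction of sequences (inclusive bound).
#' @return a taxon id.
#' @export
referenceLCA <- function(x, taxonomy, node, coverage = 0.9) {
  ctx <- .eventContext(x, taxonomy)
  if (node < 1L || node > ctx$nn)
    .phylogError("phylOG_usage_error", "node index out of range")
  .refLcaForNode(ctx, node, coverage)
}

#' Detect taxonomic outlier leaves at a node
#'
#' Candidates are the node's leaves whose species lineage does not contain
#' the node's reference LCA. A candidate is an outlier if any taxon on its
#' species lineage (the taxonomy root excluded; the species itself included
#' by default) is represented mostly outside the node: at least
#' `outlierExternalFraction` (default 95%) of all tree leaves carrying that
#' taxon lie outside. Outliers are excluded only temporarily, for the SO
#' score of this node.
#'
#' @param x a [GeneTree-class].
#' @param taxonomy a [Taxonomy-class].
#' @param node internal node index.
#' @param params a [DelineationParams-class].
#' @return integer vector of outlier tip indices (possibly empty), named
#'   by leaf label.
#' @export
detectOutliers <- function(x, taxonomy, node,
                           params = delineationParams()) {
  ctx <- .eventContext(x, taxonomy)
  refLca <- .refLcaForNode(ctx, node, params@referenceLcaCoverage)
  out <- .outliersForNode(ctx, node, refLca, params)
  setNames(out, leafLabels(x)[out])
}

#' Annotate speciation and duplication events on every node
#'
#' For each internal node the reference LCA is computed, taxonomic
#' outliers are detected and temporarily excluded, and the species-overlap
#' score of the remaining leaves decides the event: duplication when the
#' score is at least `soDuplicationThreshold` (default 10%, inclusive),
#' speciation otherwise. Nodes left unscorable by exclusion (a child clade
#' emptied) default to speciation with a score of 0, so duplication calls
#' always require positive evidence. Exclusion at one node never affects
#' any other node.
#'
#' @param x a rooted [GeneTree-class]; node LCAs are computed first if
#'   absent.
#' @param taxonomy a [Taxonomy-class].
#' @param params a [DelineationParams-class]; set
#'   `outlierDetection = FALSE` to score without the exclusion step.
#' @return the `GeneTree` with `event`, `soScore`, `refLCA` and
#'   `outliers` slots filled.
#' @export
annotateEvents <- function(x, taxonomy, params = delineationParams()) {
  stopifnot(is(x, "GeneTree"), is(taxonomy, "Taxonomy"),
            is(params, "DelineationParams"))
  if (!length(x@nodeLCA)) x <- annotateNodeLCAs(x, taxonomy)
  ctx <- .eventContext(x, taxonomy)
  n <- ctx$n; nn <- ctx$nn
  event <- c(rep("leaf", n), rep(NA_character_, nn - n))
  so <- rep(NA_real_, nn)
  refl <- rep(NA_character_, nn)
  outl <- rep(list(integer(0)), nn)
  for (node in .postorderInternal(ctx$phy)) {
    r <- .refLcaForNode(ctx, node, params@referenceLcaCoverage)
    refl[node] <- r
    ex <- if (params@outlierDetection)
      .outliersForNode(ctx, node, r, params) else integer(0)
    outl[[node]] <- ex
    s <- .soForNode(ctx, node, ex, params@multifurcationMode)
    if (is.na(s)) {
      so[node] <- 0
      event[node] <- "speciation"
    } else {
      so[node] <- s
      event[node] <- if (s >= params@soDuplicationThreshold - 1e-12)
        "duplication" else "speciation"
    }
  }
  x@event <- event
  x@soScore <- so
  x@refLCA <- refl
  x@outliers <- outl
  x
}

#' Duplication nodes of an annotated tree
#'
#' @param x an annotated [GeneTree-class].
#' @return integer vector of internal node indices called duplication.
#' @export
duplicationNodes <- function(x) {
  stopifnot(is(x, "GeneTree"))
  if (!length(x@event))
    .phylogError("phylOG_usage_error", "tree has no event annotation")
  which(x@event == "duplication")
}

#' Write the per-node events table
#'
#' TSV with columns `node_id`, `event`, `so_score`, `reference_lca`,
#' `n_outliers`, `outlier_leaves` (comma-separated labels).
#'
#' @param x an annotated [GeneTree-class].
#' @param file output path.
#' @export
writeEventsTable <- function(x, file) {
  stopifnot(is(x, "GeneTree"))
  if (!length(x@event))
    .phylogError("phylOG_usage_error", "tree has no event annotation")
  n <- .nTips(x@tree)
  nodes <- seq(n + 1L, n + x@tree$Nnode)
  labs <- leafLabels(x)
  df <- data.frame(
    node_id = nodes,
    event = x@event[nodes],
    so_score = x@soScore[nodes],
    reference_lca = x@refLCA[nodes],
    n_outliers = lengths(x@outliers[nodes]),
    outlier_leaves = vapply(x@outliers[nodes], function(i)
      paste(labs[i], collapse = ","), ""),
    stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
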