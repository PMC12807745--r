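#' Delineate orthologous groups from a gene tree
#'
#' The full pipeline on one family: minimum-variance rooting, long-branch
#' leaf removal, per-node taxonomic LCA annotation, speciation/duplication
#' classification with outlier-tolerant species-overlap scoring, and
#' extraction of nested, dated OGs.
#'
#' @param x a [GeneTree-class], or a path to a Newick file.
#' @param taxonomy a [Taxonomy-class], or a path to a taxonomy TSV.
#' @param params a [DelineationParams-class].
#' @param familyId family identifier used in OG ids.
#' @param root apply minimum-variance rooting first (default TRUE).
#' @param prune remove long-branch leaves (default TRUE); the tree is not
#'   re-rooted after pruning unless `rerootAfterPrune` is set.
#' @param rerootAfterPrune re-run rooting on the pruned tree.
#' @param sep leaf-label separator when `x` is a file path.
#' @return list of class `"delineationResult"`: `tree` (annotated
#'   [GeneTree-class]), `ogs` ([OGSet-class]), `prune` (the
#'   `"pruneResult"`, or NULL).
#' @examples
#' tax <- Taxonomy(data.frame(
#'   taxid = c("r", "x", "s1", "s2"),
#'   parent = c("r", "r", "x", "x"),
#'   rank = "", name = ""))
#' gt <- parseNewick("((s1.a:1,s2.a:1):1,(s1.b:1,s2.b:1):1);")
#' res <- delineateOGs(gt, tax, familyId = "toy")
#' ogTable(res$ogs)
#' @export
delineateOGs <- function(x, taxonomy, params = delineationParams(),
                         familyId = "fam1", root = TRUE, prune = TRUE,
                         rerootAfterPrune = FALSE, sep = ".") {
  if (is.character(x)) x <- readGeneTree(x, sep = sep)
  if (is.character(taxonomy)) taxonomy <- readTaxonomy(taxonomy)
  stopifnot(is(x, "GeneTree"), is(taxonomy, "Taxonomy"))
  gt <- x
  if (root && .nTips(gt@tree) >= 2L) gt <- minvarRoot(gt)
  pr <- NULL
  if (prune && .nTips(gt@tree) >= 2L) {
    pr <- pruneLongBranches(gt, params@longBranchFactor)
    gt <- pr$tree
    if (rerootAfterPrune && .nTips(gt@tree) >= 2L) gt <- minvarRoot(gt)
  }
  gt <- annotateNodeLCAs(gt, taxonomy)
  if (.nTips(gt@tree) >= 2L) gt <- annotateEvents(gt, taxonomy, params)
  ogs <- extractOGs(gt, taxonomy, params, familyId = familyId)
  structure(list(tree = gt, ogs = ogs, prune = pr),
            class = "delineationResult")
}

#' @export
print.delineationResult <- function(x, ...) {
  show(x$ogs)
  invisible(x)
}

#' Write pairwise orthology relations to TSV
#'
#' Columns: `query`, `target`, `relation`, `scope_taxid`.
#'
#' @param x an annotated [GeneTree-class].
#' @param query leaf label.
#' @param file output path.
#' @export
writePairwiseOrthologs <- function(x, query, file) {
  po <- pairwiseOrthologs(x, query)
  df <- cbind(query = if (is.character(query)) query
                      else leafLabels(x)[query], po)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
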