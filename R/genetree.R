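#' Parse a Newick gene tree with species-tagged leaves
#'
#' Leaf labels are split into `(species, protein)` at the FIRST occurrence
#' of `sep`, following the `taxid.protein` naming convention; protein ids
#' may therefore themselves contain the separator. Multifurcations are
#' preserved. Support values and internal node labels are parsed if present
#' but not used by the event-annotation algorithm.
#'
#' @param text a Newick string.
#' @param sep leaf-label separator (default `"."`).
#' @return a [GeneTree-class].
#' @examples
#' gt <- parseNewick("((9606.p1:1,10090.p2:1):1,7227.p3:2);")
#' leafSpecies(gt)
#' @export
parseNewick <- function(text, sep = ".") {
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) {
    ## ape returns NULL (with a warning) on syntax errors; locate the
    ## offending character crudely for the message
    off <- regexpr("[^(),:;[:alnum:]._ \t\n'\"&\\[\\]=|-]", text)
    .phylogError("phylOG_parse_error", paste0(
      "cannot parse Newick string",
      if (off > 0) paste0(" (unexpected character at offset ", off, ")")))
  }
  .geneTreeFromPhylo(phy, sep)
}

#' @rdname parseNewick
#' @param file path to a Newick file (first tree is used).
#' @export
readGeneTree <- function(file, sep = ".") {
  if (!file.exists(file))
    .phylogError("phylOG_io_error", paste0("file not found: ", file))
  parseNewick(paste(readLines(file, warn = FALSE), collapse = ""), sep = sep)
}

.geneTreeFromPhylo <- function(phy, sep = ".") {
  phy <- .normalizeLengths(phy)
  labs <- phy$tip.label
  pos <- regexpr(sep, labs, fixed = TRUE)
  bad <- labs[pos <= 0]
  if (length(bad))
    .phylogError("phylOG_leaf_label_error", paste0(
      "leaf label(s) lack the '", sep, "' species separator: ",
      paste(head(bad, 5L), collapse = ", ")))
  species <- substr(labs, 1L, pos - 1L)
  protein <- substr(labs, pos + nchar(sep), nchar(labs))
  new("GeneTree", tree = phy, species = species, protein = protein)
}

#' Serialize a gene tree to Newick
#'
#' With `annotations = TRUE`, internal nodes carry NHX comment tags of the
#' form `[&&NHX:Ev=D:LCA=<taxid>:SO=<float>]` (`Ev=S` for speciations);
#' the tree must have been annotated with [annotateEvents()] first.
#'
#' @param x a [GeneTree-class].
#' @param file optional output path; if `NULL` the string is returned.
#' @param annotations emit NHX event/LCA/score tags on internal nodes.
#' @return the Newick string, invisibly when `file` is given.
#' @export
writeNewick <- function(x, file = NULL, annotations = FALSE) {
  stopifnot(is(x, "GeneTree"))
  if (annotations && !length(x@event))
    .phylogError("phylOG_usage_error",
                 "annotations requested but the tree has no event calls")
  phy <- x@tree
  n <- .nTips(phy)
  kids <- .childrenList(phy)
  plen <- rep(NA_real_, n + phy$Nnode)
  plen[phy$edge[, 2L]] <- phy$edge.length

  fmtLen <- function(node) {
    if (is.na(plen[node])) "" else sprintf(":%.10g", plen[node])
  }
  fmtTag <- function(node) {
    if (!annotations) return("")
    ev <- switch(x@event[node], duplication = "D", speciation = "S", "S")
    sprintf("[&&NHX:Ev=%s:LCA=%s:SO=%.6g]", ev,
            x@nodeLCA[node], x@soScore[node])
  }
  rec <- function(node) {
    if (node <= n)
      return(paste0(phy$tip.label[node], fmtLen(node)))
    inner <- paste(vapply(kids[[node]], rec, ""), collapse = ",")
    paste0("(", inner, ")", fmtLen(node), fmtTag(node))
  }
  out <- paste0(rec(.rootNode(phy)), ";")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Annotate every node with the LCA of the species beneath it
#'
#' Assigns taxonomic information to all branches: each tip gets its own
#' species taxon, and each internal node the last common ancestor (in the
#' taxonomy) of the species of its leaves. This is the per-clade dating
#' used by event classification and OG extraction.
#'
#' @param x a [GeneTree-class].
#' @param taxonomy a [Taxonomy-class] containing every leaf species.
#' @return the `GeneTree` with the `nodeLCA` slot filled.
#' @export
annotateNodeLCAs <- function(x, taxonomy) {
  stopifnot(is(x, "GeneTree"), is(taxonomy, "Taxonomy"))
  missing <- setdiff(unique(x@species), taxIds(taxonomy))
  if (length(missing)) {
    offenders <- leafLabels(x)[x@species %in% missing]
    .phylogError("phylOG_unknown_species", paste0(
      "leaf species not in taxonomy: ",
      paste(head(offenders, 10L), collapse = ", ")))
  }
  phy <- x@tree
  n <- .nTips(phy)
  nn <- n + phy$Nnode
  lca <- rep(NA_character_, nn)
  lca[seq_len(n)] <- x@species
  kids <- .childrenList(phy)
  for (node in .postorderInternal(phy))
    lca[node] <- taxLCA(taxonomy, unique(lca[kids[[node]]]))
  x@nodeLCA <- lca
  x
}
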