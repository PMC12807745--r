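#' Retained duplication nodes
#'
#' A duplication node with reference LCA `r` is retained for OG delineation
#' only if its subtree holds at least `duplicationRetentionFraction`
#' (default 70%, inclusive) of ALL tree leaves whose species lineage
#' contains `r`. Weakly supported duplications therefore never split OGs.
#'
#' @param x an annotated [GeneTree-class].
#' @param taxonomy a [Taxonomy-class].
#' @param params a [DelineationParams-class].
#' @return integer vector of retained duplication node indices.
#' @export
retainedDuplications <- function(x, taxonomy,
                                 params = delineationParams()) {
  stopifnot(is(x, "GeneTree"))
  if (!length(x@event))
    .phylogError("phylOG_usage_error", "tree has no event annotation")
  dups <- duplicationNodes(x)
  if (!length(dups)) return(integer(0))
  ctx <- .eventContext(x, taxonomy)
  keep <- vapply(dups, function(d) {
    r <- x@refLCA[d]
    ctx$cnt[d, r] / ctx$totals[r] >=
      params@duplicationRetentionFraction - 1e-12
  }, TRUE)
  dups[keep]
}

#' Extract hierarchically consistent, dated orthologous groups
#'
#' OG seeds are the tree root plus every child of every retained
#' duplication node, so each OG is duplication-free at its top and all OGs
#' from one tree are nested or disjoint. An OG's members are all leaves
#' under its seed (members of nested child OGs included; nesting is
#' recorded through `parent_og` links). Each OG is dated at the taxonomy
#' LCA of its members' species. Outlier leaves excluded during scoring
#' remain OG members: exclusion only ever affects event calls. A
#' single-leaf family yields one single-member basal OG.
#'
#' OG ids have the form `<familyId>@<levelTaxid>@<ordinal>` with ordinals
#' assigned in preorder, so extraction is deterministic.
#'
#' @param x an annotated [GeneTree-class].
#' @param taxonomy a [Taxonomy-class].
#' @param params a [DelineationParams-class].
#' @param familyId identifier of the source family (default "fam1").
#' @return an [OGSet-class].
#' @export
extractOGs <- function(x, taxonomy, params = delineationParams(),
                       familyId = "fam1") {
  stopifnot(is(x, "GeneTree"))
  phy <- x@tree
  n <- .nTips(phy)
  if (n == 1L) {
    tab <- S4Vectors::DataFrame(
      og_id = paste(familyId, x@species[1], 1L, sep = "@"),
      level = x@species[1], parent_og = NA_character_,
      is_basal = TRUE, n_members = 1L, source_node = 1L)
    return(new("OGSet", familyId = familyId, table = tab,
               members = IRanges::CharacterList(list(leafLabels(x))),
               tree = x))
  }
  if (!length(x@event))
    .phylogError("phylOG_usage_error", "tree has no event annotation")
  retained <- retainedDuplications(x, taxonomy, params)
  kids <- .childrenList(phy)
  seeds <- unique(c(.rootNode(phy),
                    unlist(kids[retained], use.names = FALSE)))
  ## order seeds by depth-first preorder so ids are deterministic
  full <- integer(0)
  stack <- .rootNode(phy)
  while (length(stack)) {
    nd <- stack[1L]; stack <- stack[-1L]
    full <- c(full, nd)
    if (nd > n) stack <- c(kids[[nd]], stack)
  }
  seeds <- full[full %in% seeds]

  tipsUnder <- .tipsUnder(phy)
  parent <- .parentVec(phy)
  labs <- leafLabels(x)
  nodeLca <- x@nodeLCA

  seedOfNode <- rep(NA_integer_, n + phy$Nnode)
  seedOfNode[seeds] <- seq_along(seeds)
  parentSeed <- vapply(seeds, function(s) {
    p <- parent[s]
    while (!is.na(p)) {
      if (!is.na(seedOfNode[p])) return(seedOfNode[p])
      p <- parent[p]
    }
    NA_integer_
  }, 1L)

  level <- nodeLca[seeds]
  ogId <- paste(familyId, level, seq_along(seeds), sep = "@")
  memb <- lapply(seeds, function(s) labs[tipsUnder[[s]]])
  tab <- S4Vectors::DataFrame(
    og_id = ogId,
    level = level,
    parent_og = ifelse(is.na(parentSeed), NA_character_, ogId[parentSeed]),
    is_basal = is.na(parentSeed),
    n_members = lengths(memb),
    source_node = seeds)
  new("OGSet", familyId = familyId, table = tab,
      members = IRanges::CharacterList(memb), tree = x)
}

#' Basal orthologous groups
#'
#' The OGs of a set contained in no other OG from the same phylogeny,
#' i.e. those without a `parent_og` link.
#'
#' @param x an [OGSet-class].
#' @return an [OGSet-class] restricted to the basal OGs.
#' @export
basalOGs <- function(x) {
  stopifnot(is(x, "OGSet"))
  keep <- x@table$is_basal
  new("OGSet", familyId = x@familyId, table = x@table[keep, ],
      members = x@members[keep], tree = x@tree)
}

#' Finest OG assignment of each leaf
#'
#' Maps every leaf to the smallest OG containing it (the OG seeded nearest
#' above the leaf). Because OG member sets are nested or disjoint and the
#' root always seeds an OG, this is a partition of the leaves.
#'
#' @param x an [OGSet-class].
#' @return named character vector, leaf label -> og_id.
#' @export
leafPartition <- function(x) {
  stopifnot(is(x, "OGSet"))
  sizes <- x@table$n_members
  ord <- order(sizes)  # smallest first
  labs <- leafLabels(x@tree)
  out <- setNames(rep(NA_character_, length(labs)), labs)
  for (i in rev(ord))  # largest first, smaller overwrite
    out[unlist(x@members[[i]])] <- x@table$og_id[i]
  out
}

#' Pairwise orthology relations for a query protein
#'
#' For every other leaf, the relation is decided by the event at the tree
#' LCA of the pair: speciation makes the pair orthologs, duplication makes
#' them in-paralogs. The mediating node's taxonomic LCA is reported as the
#' scope of the relation.
#'
#' @param x an annotated [GeneTree-class].
#' @param query a leaf label (`species.protein`) or tip index.
#' @return data.frame with `target`, `relation`
#'   (`"ortholog"`/`"in-paralog"`) and `scope_taxid`.
#' @export
pairwiseOrthologs <- function(x, query) {
  stopifnot(is(x, "GeneTree"))
  if (!length(x@event))
    .phylogError("phylOG_usage_error", "tree has no event annotation")
  labs <- leafLabels(x)
  qi <- if (is.character(query)) match(query, labs) else as.integer(query)
  if (is.na(qi) || qi < 1L || qi > length(labs))
    .phylogError("phylOG_unknown_leaf",
                 paste0("query leaf not found: ", query))
  if (length(labs) == 1L)
    return(data.frame(target = character(0), relation = character(0),
                      scope_taxid = character(0)))
  M <- ape::mrca(x@tree)
  others <- setdiff(seq_along(labs), qi)
  mr <- M[qi, others]
  data.frame(
    target = labs[others],
    relation = ifelse(x@event[mr] == "duplication", "in-paralog",
                      "ortholog"),
    scope_taxid = x@nodeLCA[mr],
    stringsAsFactors = FALSE)
}

#' OG table as a data.frame / TSV
#'
#' Columns: `og_id`, `family_id`, `level_taxid`, `level_name`,
#' `parent_og`, `is_basal`, `n_members`, `members` (comma-separated
#' `species.protein` labels).
#'
#' @param x an [OGSet-class].
#' @param taxonomy optional [Taxonomy-class] supplying level names.
#' @return data.frame, one row per OG.
#' @export
ogTable <- function(x, taxonomy = NULL) {
  stopifnot(is(x, "OGSet"))
  lvl <- x@table$level
  lvlName <- if (!is.null(taxonomy)) unname(taxNames(taxonomy, lvl)) else lvl
  data.frame(
    og_id = x@table$og_id,
    family_id = x@familyId,
    level_taxid = lvl,
    level_name = lvlName,
    parent_og = x@table$parent_og,
    is_basal = x@table$is_basal,
    n_members = x@table$n_members,
    members = vapply(x@members, function(m) paste(m, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' @rdname ogTable
#' @param file output TSV path.
#' @export
writeOGTable <- function(x, file, taxonomy = NULL) {
  df <- ogTable(x, taxonomy)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
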