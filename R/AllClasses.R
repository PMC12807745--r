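#' @import methods
#' @importFrom stats var rexp runif setNames
#' @importFrom utils head read.delim write.table
NULL

## ---------------------------------------------------------------------------
## Taxonomy
## ---------------------------------------------------------------------------

#' Taxonomy: a parent-pointer taxonomic hierarchy
#'
#' Stores a set of taxa, each with a parent pointer, a rank label and a
#' scientific name, and supports lineage and last-common-ancestor queries.
#' Taxon identifiers are opaque strings, so NCBI numeric taxids and synthetic
#' labels share one code path. Rank labels are carried but never interpreted.
#'
#' @slot taxid character vector of unique taxon identifiers.
#' @slot parent character vector, parallel to `taxid`; the root points to
#'   itself.
#' @slot rank character vector of rank labels (may be empty strings).
#' @slot sciname character vector of scientific names.
#' @slot rootId the identifier of the single root taxon.
#' @slot lineages named list; for each taxon the root-to-taxon chain of
#'   identifiers (precomputed at construction, which also proves the table
#'   is cycle-free).
#'
#' @seealso [readTaxonomy()], [taxLineage()], [taxLCA()]
#' @export
setClass("Taxonomy",
  representation(
    taxid    = "character",
    parent   = "character",
    rank     = "character",
    sciname  = "character",
    rootId   = "character",
    lineages = "list"
  )
)

setValidity("Taxonomy", function(object) {
  msg <- character(0)
  n <- length(object@taxid)
  if (anyDuplicated(object@taxid))
    msg <- c(msg, "taxon ids must be unique")
  if (length(object@parent) != n || length(object@rank) != n ||
      length(object@sciname) != n)
    msg <- c(msg, "taxid, parent, rank and sciname must have equal length")
  if (length(object@rootId) != 1L || !(object@rootId %in% object@taxid))
    msg <- c(msg, "rootId must name exactly one taxon in the table")
  unknown <- setdiff(object@parent, object@taxid)
  if (length(unknown))
    msg <- c(msg, paste0("orphaned parent pointer(s): ",
                         paste(head(unknown, 5L), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GeneTree
## ---------------------------------------------------------------------------

#' GeneTree: a gene tree with species-tagged leaves
#'
#' Wraps an [ape::phylo] tree whose leaves carry a `(species, protein)`
#' label pair. Event annotation ([annotateEvents()]) fills the per-node
#' slots: the taxonomic LCA of the species under each node, the
#' speciation/duplication call, the species-overlap score, the reference
#' LCA used for outlier detection and the leaves temporarily excluded at
#' each node.
#'
#' Nodes are indexed ape-style: tips `1..n`, internal nodes
#' `(n+1)..(n+Nnode)`, root `n+1`.
#'
#' @slot tree an [ape::phylo] object (rooted unless just parsed from an
#'   unrooted source); missing branch lengths are normalized to 0.
#' @slot species character, species taxon id per tip.
#' @slot protein character, protein id per tip; `(species, protein)` pairs
#'   are unique within the tree.
#' @slot nodeLCA character of length tips+nodes, or empty before
#'   [annotateNodeLCAs()].
#' @slot event character ("leaf", "speciation", "duplication"), empty before
#'   [annotateEvents()].
#' @slot soScore numeric species-overlap score per node (NA for leaves).
#' @slot refLCA character reference LCA per node (NA for leaves).
#' @slot outliers list of integer tip indices excluded per node.
#'
#' @seealso [parseNewick()], [annotateEvents()], [extractOGs()]
#' @export
setClass("GeneTree",
  representation(
    tree     = "ANY",
    species  = "character",
    protein  = "character",
    nodeLCA  = "character",
    event    = "character",
    soScore  = "numeric",
    refLCA   = "character",
    outliers = "list"
  )
)

setValidity("GeneTree", function(object) {
  msg <- character(0)
  phy <- object@tree
  if (!inherits(phy, "phylo"))
    return("slot 'tree' must be an ape 'phylo' object")
  n <- length(phy$tip.label)
  if (length(object@species) != n || length(object@protein) != n)
    msg <- c(msg, "species and protein must have one entry per tip")
  if (any(!nzchar(object@species)) || any(!nzchar(object@protein)))
    msg <- c(msg, "species and protein ids must be non-empty")
  if (anyDuplicated(paste(object@species, object@protein, sep = "\r")))
    msg <- c(msg, "(species, protein) pairs must be unique within the tree")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    msg <- c(msg, "branch lengths must be non-negative")
  nn <- n + phy$Nnode
  for (sl in c("nodeLCA", "event", "refLCA")) {
    v <- slot(object, sl)
    if (length(v) != 0L && length(v) != nn)
      msg <- c(msg, paste0("slot '", sl, "' must be empty or of length ",
                           "tips + internal nodes"))
  }
  if (length(object@soScore) != 0L && length(object@soScore) != nn)
    msg <- c(msg, "slot 'soScore' must be empty or of length tips + nodes")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Delineation parameters
#'
#' Threshold and mode settings for event annotation and OG extraction.
#' The defaults are the published operating point of the algorithm:
#' duplication when the species-overlap score is >= 0.10, reference LCA
#' as the deepest taxon covering >= 90% of a node's sequences, outlier
#' when >= 95% of a candidate lineage's sequences lie outside the node,
#' duplication retained when its subtree holds >= 70% of all reference-LCA
#' sequences in the tree, long-branch removal at 50x the mean branch
#' length, and alignment columns dropped when strictly more than 90% gaps.
#'
#' @slot soDuplicationThreshold fraction in \[0,1\].
#' @slot referenceLcaCoverage fraction in \[0,1\].
#' @slot outlierExternalFraction fraction in \[0,1\].
#' @slot duplicationRetentionFraction fraction in \[0,1\].
#' @slot longBranchFactor positive real.
#' @slot maxGapFraction fraction in \[0,1\].
#' @slot outlierDetection logical; disable to score nodes without the
#'   two-step exclusion.
#' @slot multifurcationMode "max" (default) or "mean" pairwise child score.
#' @slot outlierLineageIncludesSpecies logical; whether the candidate's own
#'   species taxon is scanned in the exclusion test (the taxonomy root never
#'   is).
#' @export
setClass("DelineationParams",
  representation(
    soDuplicationThreshold        = "numeric",
    referenceLcaCoverage          = "numeric",
    outlierExternalFraction       = "numeric",
    duplicationRetentionFraction  = "numeric",
    longBranchFactor              = "numeric",
    maxGapFraction                = "numeric",
    outlierDetection              = "logical",
    multifurcationMode            = "character",
    outlierLineageIncludesSpecies = "logical"
  ),
  prototype(
    soDuplicationThreshold        = 0.10,
    referenceLcaCoverage          = 0.90,
    outlierExternalFraction       = 0.95,
    duplicationRetentionFraction  = 0.70,
    longBranchFactor              = 50,
    maxGapFraction                = 0.90,
    outlierDetection              = TRUE,
    multifurcationMode            = "max",
    outlierLineageIncludesSpecies = TRUE
  )
)

setValidity("DelineationParams", function(object) {
  msg <- character(0)
  for (sl in c("soDuplicationThreshold", "referenceLcaCoverage",
               "outlierExternalFraction", "duplicationRetentionFraction",
               "maxGapFraction")) {
    v <- slot(object, sl)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, paste0(sl, " must be a single fraction in [0,1]"))
  }
  if (length(object@longBranchFactor) != 1L || object@longBranchFactor <= 0)
    msg <- c(msg, "longBranchFactor must be a single positive number")
  if (!object@multifurcationMode %in% c("max", "mean"))
    msg <- c(msg, "multifurcationMode must be 'max' or 'mean'")
  if (length(msg)) msg else TRUE
})

#' @describeIn DelineationParams-class constructor; any slot can be
#'   overridden by name.
#' @param ... named slot values overriding the published defaults.
#' @export
delineationParams <- function(...) {
  new("DelineationParams", ...)
}

#' Simulation parameters
#'
#' Settings for the gene-family simulator: a Yule species tree with
#' `nSpecies` leaves, gene birth by duplication and death by loss as
#' Poisson processes along species-tree branches, and two noise operators
#' (leaf transplants emulating HGT/misplacement, pendant-branch inflation
#' emulating long-branch artifacts).
#'
#' @slot nSpecies integer >= 2.
#' @slot birthRate speciation rate of the Yule species tree (per lineage
#'   per unit time).
#' @slot duplicationRate gene duplication rate (events per gene lineage per
#'   unit time).
#' @slot lossRate gene loss rate (same units).
#' @slot nTransplants number of leaves to move to a foreign speciation
#'   clade.
#' @slot inflateFraction fraction of leaves whose pendant branch is
#'   inflated.
#' @slot inflateMultiplier multiplier applied to inflated pendant branches.
#' @slot nRootLineages number of gene lineages entering the species-tree
#'   root; 2 forces a duplication at the gene-tree root.
#' @slot seed integer seed fixing all randomness.
#' @export
setClass("SimulationParams",
  representation(
    nSpecies          = "numeric",
    birthRate         = "numeric",
    duplicationRate   = "numeric",
    lossRate          = "numeric",
    nTransplants      = "numeric",
    inflateFraction   = "numeric",
    inflateMultiplier = "numeric",
    nRootLineages     = "numeric",
    seed              = "numeric"
  ),
  prototype(
    nSpecies          = 20,
    birthRate         = 1,
    duplicationRate   = 0.1,
    lossRate          = 0,
    nTransplants      = 0,
    inflateFraction   = 0,
    inflateMultiplier = 1,
    nRootLineages     = 1,
    seed              = 1
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character(0)
  if (object@nSpecies < 2) msg <- c(msg, "nSpecies must be >= 2")
  for (sl in c("birthRate", "duplicationRate", "lossRate", "nTransplants",
               "inflateFraction", "inflateMultiplier"))
    if (slot(object, sl) < 0)
      msg <- c(msg, paste0(sl, " must be >= 0"))
  if (!object@nRootLineages %in% c(1, 2))
    msg <- c(msg, "nRootLineages must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationParams-class constructor.
#' @param ... named slot values overriding the defaults.
#' @export
simulationParams <- function(...) {
  new("SimulationParams", ...)
}

## ---------------------------------------------------------------------------
## OGSet
## ---------------------------------------------------------------------------

#' OGSet: the orthologous groups extracted from one family tree
#'
#' All OGs in a set come from one gene tree, so any two member sets are
#' either disjoint or nested. OGs are seeded at the tree root and at every
#' child of a retained duplication node; nesting is expressed through
#' `parent_og` links (a parent OG's members include those of its nested
#' children). Basal OGs are those contained in no other OG of the set;
#' because the root always seeds an OG, each family has exactly one.
#'
#' @slot familyId the source family/tree identifier.
#' @slot table an [S4Vectors::DataFrame] with one row per OG: `og_id`,
#'   `level` (taxon dating the OG: the LCA of its members' species),
#'   `parent_og` (NA for basal), `is_basal`, `n_members`, `source_node`
#'   (ape node index in the source tree).
#' @slot members an [IRanges::CharacterList] of member leaf labels
#'   (`species.protein`), parallel to `table`.
#' @slot tree the annotated source [GeneTree-class].
#' @seealso [extractOGs()], [basalOGs()], [leafPartition()]
#' @export
setClass("OGSet",
  representation(
    familyId = "character",
    table    = "ANY",
    members  = "ANY",
    tree     = "GeneTree"
  )
)

setValidity("OGSet", function(object) {
  msg <- character(0)
  tab <- object@table
  if (!is(tab, "DataFrame"))
    return("slot 'table' must be an S4Vectors DataFrame")
  need <- c("og_id", "level", "parent_og", "is_basal", "n_members",
            "source_node")
  if (!all(need %in% colnames(tab)))
    msg <- c(msg, paste0("table must have columns: ",
                         paste(need, collapse = ", ")))
  if (length(object@members) != nrow(tab))
    msg <- c(msg, "members must be parallel to the table")
  if (nrow(tab) && anyDuplicated(tab$og_id))
    msg <- c(msg, "og_id values must be unique")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Generics
## ---------------------------------------------------------------------------

#' @rdname Taxonomy-class
#' @param x a `Taxonomy`.
#' @export
setGeneric("taxIds", function(x) standardGeneric("taxIds"))
#' @rdname Taxonomy-class
#' @export
setGeneric("taxRoot", function(x) standardGeneric("taxRoot"))

#' Root-to-taxon lineage
#'
#' Returns the ordered chain of taxon ids from the root of the taxonomy to
#' `taxid` (both included).
#'
#' @param x a [Taxonomy-class].
#' @param taxid a single taxon id present in the table.
#' @return character vector of taxon ids, root first.
#' @export
setGeneric("taxLineage", function(x, taxid) standardGeneric("taxLineage"))

#' Last common ancestor of a set of taxa
#'
#' The deepest taxon lying on every lineage of `taxids`.
#'
#' @param x a [Taxonomy-class].
#' @param taxids non-empty character vector of taxon ids.
#' @return a single taxon id.
#' @export
setGeneric("taxLCA", function(x, taxids) standardGeneric("taxLCA"))

#' @rdname GeneTree-class
#' @param x a `GeneTree`.
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))
#' @rdname GeneTree-class
#' @export
setGeneric("leafSpecies", function(x) standardGeneric("leafSpecies"))
#' @rdname GeneTree-class
#' @export
setGeneric("leafProteins", function(x) standardGeneric("leafProteins"))
#' @rdname GeneTree-class
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))
#' @rdname GeneTree-class
#' @export
setGeneric("nodeEvents", function(x) standardGeneric("nodeEvents"))
#' @rdname GeneTree-class
#' @export
setGeneric("soScores", function(x) standardGeneric("soScores"))
#' @rdname GeneTree-class
#' @export
setGeneric("nodeLCAs", function(x) standardGeneric("nodeLCAs"))
#' @rdname GeneTree-class
#' @export
setGeneric("refLCAs", function(x) standardGeneric("refLCAs"))
#' @rdname GeneTree-class
#' @export
setGeneric("nodeOutliers", function(x) standardGeneric("nodeOutliers"))

#' @rdname OGSet-class
#' @param x an `OGSet`.
#' @export
setGeneric("ogIds", function(x) standardGeneric("ogIds"))
#' @rdname OGSet-class
#' @export
setGeneric("ogMembers", function(x) standardGeneric("ogMembers"))
#' @rdname OGSet-class
#' @export
setGeneric("ogLevels", function(x) standardGeneric("ogLevels"))
#' @rdname OGSet-class
#' @export
setGeneric("isBasal", function(x) standardGeneric("isBasal"))
#' @rdname OGSet-class
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' @rdname Taxonomy-class
setMethod("taxIds", "Taxonomy", function(x) x@taxid)
#' @rdname Taxonomy-class
setMethod("taxRoot", "Taxonomy", function(x) x@rootId)

setMethod("show", "Taxonomy", function(object) {
  cat("Taxonomy with", length(object@taxid), "taxa; root:",
      object@rootId, "\n")
  depth <- lengths(object@lineages)
  cat("  lineage depth: ", min(depth), "-", max(depth), "\n", sep = "")
})

#' @rdname GeneTree-class
setMethod("asPhylo", "GeneTree", function(x) x@tree)
#' @rdname GeneTree-class
setMethod("leafSpecies", "GeneTree", function(x)
  setNames(x@species, x@tree$tip.label))
#' @rdname GeneTree-class
setMethod("leafProteins", "GeneTree", function(x)
  setNames(x@protein, x@tree$tip.label))
#' @rdname GeneTree-class
setMethod("leafLabels", "GeneTree", function(x) x@tree$tip.label)
#' @rdname GeneTree-class
setMethod("nodeEvents", "GeneTree", function(x) x@event)
#' @rdname GeneTree-class
setMethod("soScores", "GeneTree", function(x) x@soScore)
#' @rdname GeneTree-class
setMethod("nodeLCAs", "GeneTree", function(x) x@nodeLCA)
#' @rdname GeneTree-class
setMethod("refLCAs", "GeneTree", function(x) x@refLCA)
#' @rdname GeneTree-class
setMethod("nodeOutliers", "GeneTree", function(x) x@outliers)

setMethod("show", "GeneTree", function(object) {
  n <- length(object@tree$tip.label)
  cat("GeneTree with", n, "leaves from",
      length(unique(object@species)), "species\n")
  if (length(object@event)) {
    ev <- object@event[(n + 1):(n + object@tree$Nnode)]
    cat("  events:", sum(ev == "duplication"), "duplication,",
        sum(ev == "speciation"), "speciation\n")
  } else {
    cat("  (events not annotated)\n")
  }
})

setMethod("show", "DelineationParams", function(object) {
  cat("DelineationParams:\n",
      "  SO duplication threshold : ", object@soDuplicationThreshold, "\n",
      "  reference LCA coverage   : ", object@referenceLcaCoverage, "\n",
      "  outlier external fraction: ", object@outlierExternalFraction, "\n",
      "  duplication retention    : ", object@duplicationRetentionFraction,
      "\n",
      "  long-branch factor       : ", object@longBranchFactor, "\n",
      "  max gap fraction         : ", object@maxGapFraction, "\n",
      "  outlier detection        : ", object@outlierDetection, "\n",
      sep = "")
})

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams: ", object@nSpecies, " species, birth ",
      object@birthRate, ", dup ", object@duplicationRate, ", loss ",
      object@lossRate, ", transplants ", object@nTransplants,
      ", seed ", object@seed, "\n", sep = "")
})

#' @rdname OGSet-class
setMethod("ogIds", "OGSet", function(x) x@table$og_id)
#' @rdname OGSet-class
setMethod("ogMembers", "OGSet", function(x)
  setNames(x@members, x@table$og_id))
#' @rdname OGSet-class
setMethod("ogLevels", "OGSet", function(x)
  setNames(x@table$level, x@table$og_id))
#' @rdname OGSet-class
setMethod("isBasal", "OGSet", function(x)
  setNames(x@table$is_basal, x@table$og_id))
#' @rdname OGSet-class
setMethod("familyId", "OGSet", function(x) x@familyId)

#' @rdname OGSet-class
#' @export
setMethod("length", "OGSet", function(x) nrow(x@table))

setMethod("show", "OGSet", function(object) {
  cat("OGSet '", object@familyId, "': ", nrow(object@table), " OGs (",
      sum(object@table$is_basal), " basal) over ",
      length(object@tree@tree$tip.label), " leaves\n", sep = "")
})

## Error helper: all package conditions carry a subclass for programmatic
## handling.
.phylogError <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "phylOG_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
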