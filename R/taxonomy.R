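#' Build a Taxonomy from a parent-pointer table
#'
#' @param df data.frame with columns `taxid`, `parent`, `rank`, `name`
#'   (rank/name optional). The root row points to itself or has an
#'   empty/NA parent.
#' @return a validated [Taxonomy-class].
#' @details Construction resolves every taxon's root-to-taxon lineage and
#'   fails with a cycle error (naming one taxon on the cycle) if the
#'   parent chain does not terminate at a single root.
#' @export
Taxonomy <- function(df) {
  taxid  <- as.character(df$taxid)
  parent <- as.character(df$parent)
  rank   <- if ("rank" %in% names(df)) as.character(df$rank)
            else rep("", length(taxid))
  nm     <- if ("name" %in% names(df)) as.character(df$name)
            else taxid
  if (anyDuplicated(taxid))
    .phylogError("phylOG_parse_error", paste0(
      "duplicated taxon id(s): ",
      paste(unique(taxid[duplicated(taxid)]), collapse = ", ")))
  ## normalize absent parents to self-pointers
  absent <- is.na(parent) | parent == ""
  parent[absent] <- taxid[absent]
  isRoot <- parent == taxid
  if (sum(isRoot) != 1L)
    .phylogError("phylOG_parse_error", paste0(
      "taxonomy must have exactly one root, found ", sum(isRoot)))
  rootId <- taxid[isRoot]
  unknown <- setdiff(parent, taxid)
  if (length(unknown))
    .phylogError("phylOG_parse_error", paste0(
      "orphaned parent id(s) not present as taxa: ",
      paste(head(unknown, 5L), collapse = ", ")))

  ## lineage resolution with cycle detection (memoized walk-up)
  pmap <- setNames(parent, taxid)
  lineages <- vector("list", length(taxid))
  names(lineages) <- taxid
  for (id in taxid) {
    if (!is.null(lineages[[id]])) next
    chain <- character(0)
    cur <- id
    repeat {
      if (cur %in% chain)
        .phylogError("phylOG_cycle_error",
                     paste0("cycle detected in taxonomy at taxon '", cur, "'"))
      ## reuse an already-resolved prefix (stored root..cur)
      if (!is.null(lineages[[cur]])) {
        chain <- c(lineages[[cur]], chain)
        break
      }
      chain <- c(cur, chain)
      if (cur == rootId) break
      cur <- pmap[[cur]]
    }
    ## chain is root..id; fill prefixes for every taxon on it
    for (k in seq_along(chain)) {
      tk <- chain[k]
      if (is.null(lineages[[tk]])) lineages[[tk]] <- chain[seq_len(k)]
    }
  }
  new("Taxonomy", taxid = taxid, parent = parent, rank = rank,
      sciname = nm, rootId = rootId, lineages = lineages)
}

#' Read a taxonomy table from disk
#'
#' @param path for the `"tsv"` dialect, a UTF-8 tab-separated file with a
#'   header row `taxid  parent  rank  name`; for `"ncbi"`, the path to an
#'   NCBI-style `nodes.dmp` (pipe-delimited, fields
#'   `taxid | parent | rank | ...`).
#' @param dialect `"tsv"` (default) or `"ncbi"`.
#' @param namesDmp optional path to a `names.dmp` supplying scientific
#'   names for the NCBI dialect.
#' @return a [Taxonomy-class].
#' @export
readTaxonomy <- function(path, dialect = c("tsv", "ncbi"), namesDmp = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    .phylogError("phylOG_io_error", paste0("file not found: ", path))
  if (dialect == "tsv") {
    df <- tryCatch(
      read.delim(path, header = TRUE, sep = "\t", quote = "",
                 colClasses = "character", fileEncoding = "UTF-8"),
      error = function(e) .phylogError("phylOG_parse_error",
        paste0("cannot parse taxonomy TSV '", path, "': ",
               conditionMessage(e))))
    need <- c("taxid", "parent", "rank", "name")
    if (!all(need %in% names(df)))
      .phylogError("phylOG_parse_error", paste0(
        "taxonomy TSV must have header columns: ",
        paste(need, collapse = ", ")))
    bad <- which(!nzchar(df$taxid))
    if (length(bad))
      .phylogError("phylOG_parse_error", paste0(
        "malformed taxonomy row at line ", bad[1] + 1L, ": empty taxid"))
    return(Taxonomy(df))
  }
  ## NCBI nodes.dmp dialect: fields separated by "\t|\t", rows end "\t|"
  lines <- readLines(path, encoding = "UTF-8")
  fields <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
  nf <- lengths(fields)
  if (any(nf < 3L))
    .phylogError("phylOG_parse_error", paste0(
      "malformed nodes.dmp row at line ", which(nf < 3L)[1],
      ": expected at least 3 pipe-delimited fields"))
  df <- data.frame(
    taxid  = vapply(fields, `[[`, "", 1L),
    parent = vapply(fields, `[[`, "", 2L),
    rank   = vapply(fields, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  ## NCBI convention: the root points to itself already (1 | 1 | no rank)
  df$name <- df$taxid
  if (!is.null(namesDmp) && file.exists(namesDmp)) {
    nl <- strsplit(sub("\t\\|$", "", readLines(namesDmp, encoding = "UTF-8")),
                   "\t\\|\t")
    keep <- vapply(nl, function(f)
      length(f) >= 4L && f[[4]] == "scientific name", TRUE)
    ids <- vapply(nl[keep], `[[`, "", 1L)
    nms <- vapply(nl[keep], `[[`, "", 2L)
    hit <- match(df$taxid, ids)
    df$name[!is.na(hit)] <- nms[hit[!is.na(hit)]]
  }
  Taxonomy(df)
}

.checkTaxa <- function(x, taxids) {
  unknown <- setdiff(taxids, x@taxid)
  if (length(unknown))
    .phylogError("phylOG_unknown_taxon", paste0(
      "unknown taxon id(s): ", paste(head(unknown, 5L), collapse = ", ")))
}

#' @rdname taxLineage
setMethod("taxLineage", "Taxonomy", function(x, taxid) {
  if (length(taxid) != 1L)
    .phylogError("phylOG_usage_error", "taxLineage takes a single taxon id")
  .checkTaxa(x, taxid)
  x@lineages[[taxid]]
})

#' @rdname taxLCA
setMethod("taxLCA", "Taxonomy", function(x, taxids) {
  taxids <- unique(as.character(taxids))
  if (length(taxids) == 0L)
    .phylogError("phylOG_usage_error", "taxLCA needs a non-empty taxon set")
  .checkTaxa(x, taxids)
  if (length(taxids) == 1L) return(taxids)
  ## lineages share a root prefix; the LCA is the last position at which
  ## all lineages agree
  lins <- x@lineages[taxids]
  ref <- lins[[1]]
  kmax <- min(lengths(lins))
  lca <- ref[1]
  for (k in seq_len(kmax)) {
    tk <- ref[k]
    if (all(vapply(lins, function(l) l[k] == tk, TRUE))) lca <- tk
    else break
  }
  lca
})

#' Depth of taxa in the taxonomy
#'
#' Lineage length of each taxon (root has depth 1). Used to pick the
#' "deepest" taxon in reference-LCA scans.
#'
#' @param x a [Taxonomy-class].
#' @param taxids character vector of taxon ids.
#' @return integer vector parallel to `taxids`.
#' @export
taxDepth <- function(x, taxids) {
  .checkTaxa(x, taxids)
  lengths(x@lineages[taxids])
}

#' Scientific names for taxa
#' @param x a [Taxonomy-class].
#' @param taxids character vector of taxon ids.
#' @return character vector of names.
#' @export
taxNames <- function(x, taxids) {
  .checkTaxa(x, taxids)
  setNames(x@sciname[match(taxids, x@taxid)], taxids)
}
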