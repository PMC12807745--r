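#' Minimum-variance rooting
#'
#' Roots the tree at the point, anywhere along any edge, that minimizes the
#' variance of root-to-leaf path lengths. On each edge the variance is a
#' quadratic in the root offset and is minimized in closed form; the best
#' edge/offset pair over the whole tree wins. Ties in variance (within
#' 1e-12) are broken by the edge whose leaf-name set below is
#' lexicographically smallest, then by the smaller offset, so the result is
#' deterministic. Existing branch lengths are conserved except for the
#' rooted edge, which is split at the root point. Any previous rooting is
#' discarded (the tree is treated as unrooted).
#'
#' @param x a [GeneTree-class] with at least 2 leaves and branch lengths.
#' @return a rooted [GeneTree-class]; event annotations are cleared.
#' @export
minvarRoot <- function(x) {
  stopifnot(is(x, "GeneTree"))
  phy <- x@tree
  n <- .nTips(phy)
  if (n < 2L)
    .phylogError("phylOG_degenerate_tree",
                 "minimum-variance rooting needs at least 2 leaves")
  if (n == 2L) {
    ## the root is the midpoint of the single path between the two tips
    tot <- sum(phy$edge.length)
    out <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
      phy$tip.label[1], tot / 2, phy$tip.label[2], tot / 2))
    return(.rebuildGeneTree(out, x))
  }
  u <- ape::unroot(ape::collapse.singles(phy))
  u <- .normalizeLengths(u)
  D <- ape::dist.nodes(u)
  tipsUnder <- .tipsUnder(u)

  best <- NULL   # list(var, key, offset, edge)
  for (i in seq_len(nrow(u$edge))) {
    a <- u$edge[i, 1L]; v <- u$edge[i, 2L]; L <- u$edge.length[i]
    below <- tipsUnder[[v]]
    s <- rep(1, n); s[below] <- -1
    d <- D[a, seq_len(n)]
    ## population variance of d + s*x:  c + b*x + a2*x^2
    mS <- mean(s); mD <- mean(d)
    a2 <- mean(s^2) - mS^2            # = 1 - mS^2
    b <- 2 * (mean(d * s) - mD * mS)
    xStar <- if (a2 > 0) min(max(-b / (2 * a2), 0), L) else 0
    vr <- stats::var(d + s * xStar) * (n - 1) / n
    key <- paste(sort(u$tip.label[below]), collapse = "|")
    if (is.null(best) ||
        vr < best$var - 1e-12 ||
        (abs(vr - best$var) <= 1e-12 &&
         (key < best$key ||
          (key == best$key && xStar < best$offset)))) {
      best <- list(var = vr, key = key, offset = xStar, edge = i,
                   child = v, len = L)
    }
  }
  rooted <-
    if (best$offset <= 1e-12) {
      ## root sits on the parent node of the chosen edge
      parent <- u$edge[best$edge, 1L]
      if (parent == .rootNode(u)) {
        r <- phytools::reroot(u, node.number = best$child,
                              position = 0)
        r
      } else {
        ape::root(u, node = parent, resolve.root = TRUE)
      }
    } else {
      phytools::reroot(u, node.number = best$child, position = best$offset)
    }
  rooted <- ape::collapse.singles(rooted)
  .rebuildGeneTree(rooted, x)
}

#' Remove leaves with excessively long pendant branches
#'
#' Leaves whose pendant branch length is at least `factor` times the mean
#' branch length are removed. The mean is taken over ALL branches (pendant
#' and internal) of the input tree, in a single pass before any removal.
#' Unary nodes created by the removal are suppressed with their branch
#' lengths summed. With the default factor of 50 the rule is deliberately
#' strict: it fires only on branches that dwarf the rest of the tree.
#'
#' @param x a rooted [GeneTree-class].
#' @param factor positive multiplier on the mean branch length
#'   (default 50); `Inf` makes the operation the identity.
#' @return a list of class `"pruneResult"`: `tree` (the pruned
#'   [GeneTree-class]), `removed` (data.frame with `species`, `protein`,
#'   `branchLength`), `meanBranchLength`, and `factor`.
#' @export
pruneLongBranches <- function(x, factor = 50) {
  stopifnot(is(x, "GeneTree"), factor > 0)
  phy <- x@tree
  n <- .nTips(phy)
  meanLen <- mean(phy$edge.length)
  pend <- .pendantLengths(phy)
  drop <- if (is.finite(factor)) which(pend >= factor * meanLen)
          else integer(0)
  ## a zero-length tree (all branches 0) has mean 0: every pendant branch
  ## would satisfy >= 0; treat that degenerate case as nothing-to-remove
  if (meanLen == 0) drop <- integer(0)
  report <- data.frame(
    species = x@species[drop], protein = x@protein[drop],
    branchLength = pend[drop], stringsAsFactors = FALSE)
  if (length(drop) == n)
    .phylogError("phylOG_all_leaves_removed",
                 "long-branch pruning would remove every leaf")
  out <- x
  if (length(drop)) {
    if (n - length(drop) == 1L) {
      keep <- setdiff(seq_len(n), drop)
      ## distance from root to the surviving tip
      len <- ape::dist.nodes(phy)[.rootNode(phy), keep]
      newPhy <- .singleTipPhylo(phy$tip.label[keep], len)
    } else {
      newPhy <- ape::drop.tip(phy, drop, trim.internal = TRUE,
                              collapse.singles = TRUE)
    }
    out <- .rebuildGeneTree(newPhy, x)
  }
  structure(list(tree = out, removed = report,
                 meanBranchLength = meanLen, factor = factor),
            class = "pruneResult")
}

#' @export
print.pruneResult <- function(x, ...) {
  cat("Long-branch pruning: removed", nrow(x$removed), "leaf/leaves",
      sprintf("(mean branch length %.4g, factor %g)\n",
              x$meanBranchLength, x$factor))
  invisible(x)
}

#' Trim alignment columns by gap content
#'
#' Removes columns whose gap fraction is strictly greater than
#' `maxGapFraction` (default 0.9): a column with exactly 90% gaps is kept.
#' Gap characters are `-` and `.`; residue case is ignored. The order of
#' the remaining columns is preserved and the operation is idempotent.
#'
#' @param msa an [Biostrings::AAStringSet] of equal-width aligned
#'   sequences, or a character matrix (one row per sequence).
#' @param maxGapFraction fraction in \[0,1\].
#' @return list with `msa` (trimmed, same class as input) and
#'   `removedColumns` (0-based indices of the removed columns).
#' @export
trimAlignment <- function(msa, maxGapFraction = 0.9) {
  stopifnot(maxGapFraction >= 0, maxGapFraction <= 1)
  fromXSS <- is(msa, "XStringSet")
  if (fromXSS) {
    if (length(msa) == 0L)
      .phylogError("phylOG_empty_alignment", "alignment has no sequences")
    if (length(unique(Biostrings::width(msa))) != 1L)
      .phylogError("phylOG_parse_error",
                   "aligned sequences must all have the same length")
    m <- as.matrix(msa)
  } else if (is.matrix(msa) && is.character(msa)) {
    if (nrow(msa) == 0L)
      .phylogError("phylOG_empty_alignment", "alignment has no sequences")
    m <- msa
  } else {
    .phylogError("phylOG_usage_error",
                 "msa must be an AAStringSet or a character matrix")
  }
  if (ncol(m) == 0L)
    .phylogError("phylOG_empty_alignment", "alignment has zero columns")
  isGap <- m == "-" | m == "."
  gapFrac <- colMeans(isGap)
  removed <- which(gapFrac > maxGapFraction)
  keep <- setdiff(seq_len(ncol(m)), removed)
  m2 <- m[, keep, drop = FALSE]
  out <- if (fromXSS) {
    seqs <- apply(m2, 1L, paste, collapse = "")
    if (ncol(m2) == 0L) seqs <- rep("", nrow(m2))
    res <- Biostrings::AAStringSet(seqs)
    names(res) <- names(msa)
    res
  } else m2
  list(msa = out, removedColumns = removed - 1L)
}

#' Read / write an aligned FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O used by the trimming step.
#'
#' @param file path to a FASTA file.
#' @return `readMsa`: an [Biostrings::AAStringSet].
#' @export
readMsa <- function(file) {
  if (!file.exists(file))
    .phylogError("phylOG_io_error", paste0("file not found: ", file))
  Biostrings::readAAStringSet(file)
}

#' @rdname readMsa
#' @param msa an [Biostrings::AAStringSet].
#' @export
writeMsa <- function(msa, file) {
  Biostrings::writeXStringSet(msa, filepath = file)
  invisible(file)
}
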