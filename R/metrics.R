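#' Duplication rate of basal orthologous groups
#'
#' Counts, inside each basal OG's subtree, the duplication nodes whose
#' leaves span more than one species; duplications whose leaves all belong
#' to a single species are species-specific and ignored. The mean count
#' over the basal OGs is the duplication rate, a proxy for the number of
#' in-paralogs per OG.
#'
#' @param x an [OGSet-class] or a list of them (one per family).
#' @return list of class `"dupRateReport"`: `perOg` (data.frame with
#'   `og_id`, `family_id`, `n_duplications`) and `meanRate`.
#' @export
duplicationRate <- function(x) {
  sets <- if (is(x, "OGSet")) list(x) else x
  stopifnot(all(vapply(sets, is, TRUE, "OGSet")))
  rows <- lapply(sets, function(s) {
    b <- basalOGs(s)
    gt <- s@tree
    if (!length(gt@event))
      .phylogError("phylOG_usage_error",
                   "OGSet source tree has no event annotation")
    phy <- gt@tree
    n <- .nTips(phy)
    tipsUnder <- .tipsUnder(phy)
    counts <- vapply(seq_len(nrow(b@table)), function(i) {
      seed <- b@table$source_node[i]
      nodes <- if (seed <= n) integer(0)
               else intersect(phangorn::Descendants(phy, seed,
                                                    type = "all"),
                              which(gt@event == "duplication"))
      if (seed > n && gt@event[seed] == "duplication")
        nodes <- union(nodes, seed)
      multi <- vapply(nodes, function(d)
        length(unique(gt@species[tipsUnder[[d]]])) > 1L, TRUE)
      sum(multi)
    }, 1L)
    data.frame(og_id = b@table$og_id, family_id = s@familyId,
               n_duplications = counts, stringsAsFactors = FALSE)
  })
  perOg <- do.call(rbind, rows)
  structure(list(perOg = perOg,
                 meanRate = if (nrow(perOg)) mean(perOg$n_duplications)
                            else NaN),
            class = "dupRateReport")
}

#' @export
print.dupRateReport <- function(x, ...) {
  cat("Duplication rate over", nrow(x$perOg), "basal OGs:",
      sprintf("%.4g", x$meanRate),
      "non-species-specific duplications per OG\n")
  invisible(x)
}

.membershipFrame <- function(x, what) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L)
      .phylogError("phylOG_usage_error",
                   paste0(what, " needs columns (protein, group)"))
    df <- data.frame(protein = as.character(x[[1]]),
                     group = as.character(x[[2]]),
                     stringsAsFactors = FALSE)
  } else {
    if (is.null(names(x)) || !length(x))
      .phylogError("phylOG_usage_error",
                   paste0(what, " must be a named vector or data.frame"))
    df <- data.frame(protein = names(x), group = as.character(x),
                     stringsAsFactors = FALSE)
  }
  unique(df)
}

#' Benchmark OGs against reference functional groups
#'
#' For each reference group (e.g. a KEGG KO) and each OG sharing at least
#' one protein with it: true positives are the group's proteins assigned
#' to that OG, false negatives are the group's proteins assigned to a
#' different OG, and false positives are the OG's proteins that belong to
#' a different reference group — proteins with no reference annotation are
#' neither TP nor FP. The OG with the highest F-score is selected as the
#' group's equivalent (ties broken by larger TP, then lexicographic
#' og_id). Proteins mapping to several reference groups are counted
#' independently per group.
#'
#' @param ogMembership protein-to-OG assignment: a named character vector
#'   (names are proteins) or a 2-column data.frame `(protein, og_id)`.
#' @param refMembership protein-to-reference-group assignment, same
#'   formats; may map a protein to several groups (data.frame form).
#' @return list of class `"benchmarkResult"`: `perGroup` (data.frame with
#'   `group`, `best_og`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score`) and `meanF`.
#' @export
fscoreBenchmark <- function(ogMembership, refMembership) {
  og <- .membershipFrame(ogMembership, "ogMembership")
  ref <- .membershipFrame(refMembership, "refMembership")
  annotated <- unique(ref$protein)
  ogOf <- split(og$group, og$protein)   # protein -> og ids (usually 1)
  ogProteins <- split(og$protein, og$group)

  groups <- sort(unique(ref$group))
  rows <- lapply(groups, function(k) {
    kProt <- unique(ref$protein[ref$group == k])
    kAssigned <- kProt[kProt %in% names(ogOf)]
    candidateOgs <- sort(unique(unlist(ogOf[kAssigned], use.names = FALSE)))
    if (!length(candidateOgs))
      return(data.frame(group = k, best_og = NA_character_, tp = 0L,
                        fp = 0L, fn = length(kAssigned), precision = 0,
                        recall = 0, f_score = 0, stringsAsFactors = FALSE))
    stats <- lapply(candidateOgs, function(o) {
      oProt <- ogProteins[[o]]
      tp <- length(intersect(kProt, oProt))
      fn <- length(setdiff(kAssigned, oProt))
      fpSet <- setdiff(oProt, kProt)
      fp <- length(intersect(fpSet, annotated))
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      f <- if (p + r > 0) 2 * p * r / (p + r) else 0
      c(tp = tp, fp = fp, fn = fn, p = p, r = r, f = f)
    })
    sm <- do.call(rbind, stats)
    best <- order(-sm[, "f"], -sm[, "tp"], candidateOgs)[1L]
    data.frame(group = k, best_og = candidateOgs[best],
               tp = as.integer(sm[best, "tp"]),
               fp = as.integer(sm[best, "fp"]),
               fn = as.integer(sm[best, "fn"]),
               precision = sm[best, "p"], recall = sm[best, "r"],
               f_score = sm[best, "f"], stringsAsFactors = FALSE)
  })
  perGroup <- do.call(rbind, rows)
  structure(list(perGroup = perGroup, meanF = mean(perGroup$f_score)),
            class = "benchmarkResult")
}

#' @export
print.benchmarkResult <- function(x, ...) {
  cat("F-score benchmark over", nrow(x$perGroup), "reference groups;",
      sprintf("mean F = %.4f\n", x$meanF))
  invisible(x)
}

#' Size distribution of basal OGs
#'
#' @param x an [OGSet-class] or a list of them.
#' @param sizeThreshold size above which an OG counts as "extremely
#'   large" (default 100000).
#' @return list: `histogram` (data.frame `size`, `count`), `nSingletons`,
#'   `nOverThreshold`.
#' @export
sizeDistribution <- function(x, sizeThreshold = 100000) {
  sets <- if (is(x, "OGSet")) list(x) else x
  sizes <- unlist(lapply(sets, function(s) basalOGs(s)@table$n_members))
  if (!length(sizes))
    return(list(histogram = data.frame(size = integer(0),
                                       count = integer(0)),
                nSingletons = 0L, nOverThreshold = 0L))
  tab <- table(sizes)
  list(
    histogram = data.frame(size = as.integer(names(tab)),
                           count = as.integer(tab)),
    nSingletons = sum(sizes == 1L),
    nOverThreshold = sum(sizes > sizeThreshold))
}
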