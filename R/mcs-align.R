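# Iterative component-wise alignment of the carbon-rich side X against the
# carbon-poor side Y, and the five-configuration ensemble.

.emptyCuts <- function() {
  data.frame(atom = integer(0), order = integer(0),
             partnerElement = character(0), stringsAsFactors = FALSE)
}

.fragmentBoundaries <- function(frag) nrow(frag@cuts)

# Split the unmatched residue of a component into connected fragments, each
# carrying its cut edges (with original bond order and the element of the
# matched partner atom).
.fragmentsFromMatch <- function(g, matchedX) {
  n <- igraph::vcount(g)
  unmatched <- setdiff(seq_len(n), matchedX)
  if (!length(unmatched)) return(list())
  el <- igraph::V(g)$element
  ends <- if (igraph::ecount(g) > 0)
    igraph::ends(g, igraph::E(g), names = FALSE) else matrix(integer(0), 0, 2)
  ord <- if (igraph::ecount(g) > 0) igraph::E(g)$order else integer(0)
  cutRows <- which(xor(ends[, 1] %in% matchedX, ends[, 2] %in% matchedX))
  sub <- igraph::induced_subgraph(g, unmatched)
  comp <- igraph::components(sub)
  out <- list()
  for (ci in seq_len(comp$no)) {
    localVs <- which(comp$membership == ci)
    origVs <- unmatched[localVs]
    res <- igraph::induced_subgraph(sub, localVs)
    cuts <- .emptyCuts()
    for (e in cutRows) {
      a <- ends[e, 1]; b <- ends[e, 2]
      inRes <- if (a %in% origVs) a else if (b %in% origVs) b else NA
      if (is.na(inRes)) next
      partner <- if (inRes == a) b else a
      cuts <- rbind(cuts, data.frame(
        atom = match(inRes, origVs), order = ord[e],
        partnerElement = el[partner], stringsAsFactors = FALSE))
    }
    out[[length(out) + 1L]] <- methods::new("Fragment", residue = res,
                                            cuts = cuts)
  }
  out
}

#' Iterative component-wise MCS alignment
#'
#' Components of the carbon-rich side are processed in order of decreasing
#' vertex count; after aligning each component against the remaining target
#' graph the matched target vertices are removed, so no target atom is ever
#' matched twice. A component with no compatible atom contributes itself
#' wholly as a fragment with an empty cut set.
#'
#' @param xMols list of [Molecule-class]s on the carbon-rich side (caller
#'   orients).
#' @param yMols list of [Molecule-class]s on the carbon-poor side.
#' @param config an [MCSConfig-class].
#' @param nodeBudget per-component search budget, see [findMCS()].
#' @return a [FragmentSet-class]; `diagnostics$atomMap` holds the
#'   accumulated partial atom-atom map (per component, target indices refer
#'   to the concatenated original Y graph).
#' @export
iterativeAlign <- function(xMols, yMols, config = mcsConfig(),
                           nodeBudget = 2e5) {
  sizes <- vapply(xMols, function(m) as.integer(igraph::vcount(m@graph)), integer(1))
  xMols <- xMols[order(-sizes)]
  ycur <- do.call(igraph::disjoint_union, lapply(yMols, function(m) m@graph))
  igraph::V(ycur)$.orig <- seq_len(igraph::vcount(ycur))
  fragments <- list()
  matched <- 0L
  timeout <- FALSE
  atomMap <- list()
  for (i in seq_along(xMols)) {
    g <- xMols[[i]]@graph
    res <- findMCS(g, ycur, config, nodeBudget)
    timeout <- timeout || isTRUE(attr(res, "timeout"))
    if (!length(res)) {
      fragments <- c(fragments, .fragmentsFromMatch(g, integer(0)))
      next
    }
    emb <- selectEmbedding(res, g, ycur)
    matched <- matched + emb$size
    atomMap[[length(atomMap) + 1L]] <- data.frame(
      component = i, xVertex = emb$mapX,
      yVertex = igraph::V(ycur)$.orig[emb$mapY])
    fragments <- c(fragments, .fragmentsFromMatch(g, emb$mapX))
    ycur <- igraph::delete_vertices(ycur, emb$mapY)
    if (igraph::vcount(ycur) == 0 && i < length(xMols)) {
      for (j in seq.int(i + 1L, length(xMols))) {
        fragments <- c(fragments,
                       .fragmentsFromMatch(xMols[[j]]@graph, integer(0)))
      }
      break
    }
  }
  nb <- sum(vapply(fragments, .fragmentBoundaries, integer(1)))
  methods::new("FragmentSet", fragments = fragments,
               matchedSize = as.integer(matched), config = config@label,
               diagnostics = list(timeout = timeout, numBoundary = nb,
                                  fragmentCount = length(fragments),
                                  atomMap = atomMap))
}

#' Ensemble MCS over the five configurations
#'
#' Runs [iterativeAlign()] under each configuration of [mcsConfigs()] and
#' amalgamates the outcomes: the candidate with the largest total matched
#' size wins; ties go to the fewest fragments, then the fewest cut edges,
#' then the earliest configuration (deterministic). A configuration that
#' exhausts its search budget is excluded; if all five are excluded the
#' ensemble signals no solution by returning `NULL`.
#'
#' @param xMols,yMols molecule lists, carbon-rich side first.
#' @param nodeBudget per-component search budget.
#' @return the winning [FragmentSet-class] (with per-configuration summaries
#'   in `diagnostics$perConfig`), or `NULL`.
#' @export
ensembleMCS <- function(xMols, yMols, nodeBudget = 2e5) {
  configs <- mcsConfigs()
  cands <- lapply(configs, function(cfg)
    iterativeAlign(xMols, yMols, cfg, nodeBudget))
  summarise <- function(fs) {
    list(config = fs@config, matchedSize = fs@matchedSize,
         nFragments = length(fs@fragments),
         nCuts = as.integer(sum(vapply(fs@fragments, .fragmentBoundaries,
                                       integer(1)))),
         timeout = isTRUE(fs@diagnostics$timeout))
  }
  per <- lapply(cands, summarise)
  ok <- which(!vapply(per, `[[`, logical(1), "timeout"))
  if (!length(ok)) return(NULL)
  o <- ok[order(-vapply(per[ok], `[[`, integer(1), "matchedSize"),
                vapply(per[ok], `[[`, integer(1), "nFragments"),
                vapply(per[ok], `[[`, numeric(1), "nCuts"),
                ok)]
  win <- cands[[o[1]]]
  win@diagnostics$perConfig <- per
  win@diagnostics$winningConfig <- o[1]
  structure(win, rankedCandidates = lapply(o, function(i) {
    fs <- cands[[i]]
    fs@diagnostics$configIndex <- i
    fs
  }))
}
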