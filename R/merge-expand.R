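# Expand and merge rules: reconstruct whole compounds from MCS fragments.
# Both rule tables are plain-text data files under inst/extdata and can be
# extended by users; rules are tried in declaration order, first match wins.

.expandRulesCache <- new.env(parent = emptyenv())
.mergeRulesCache <- new.env(parent = emptyenv())

#' Read the expand-rule table
#'
#' Columns: `boundaryElement` (element of the residue boundary atom),
#' `carbonylNeighbor` (must the boundary atom carry a double-bonded oxygen;
#' `NA` = don't care), `partnerElement` (element of the matched atom the cut
#' edge pointed to), `cutOrder` (`NA` = any), `appendElement`/`appendCharge`
#' (the atom appended as a new single-atom fragment with its own boundary).
#'
#' @param path file path; default: the shipped table.
#' @return data.frame of expand rules.
#' @export
readExpandRules <- function(path = NULL) {
  if (is.null(path)) {
    hit <- get0("rules", envir = .expandRulesCache)
    if (!is.null(hit)) return(hit)
    path <- system.file("extdata", "expand_rules.tsv",
                        package = "RxnRebalance", mustWork = TRUE)
    rules <- utils::read.delim(path, stringsAsFactors = FALSE)
    assign("rules", rules, envir = .expandRulesCache)
    return(rules)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read the merge-rule table
#'
#' Columns: `elementA`/`elementB` (unordered boundary-element pair, `*` is a
#' wildcard), `requireDoubleCut` (at least one of the two consumed cut edges
#' must have been a double bond; `NA` = don't care) and `bondOrder` (the
#' inserted bond). The last row is the default single-bond merge.
#'
#' @param path file path; default: the shipped table.
#' @return data.frame of merge rules.
#' @export
readMergeRules <- function(path = NULL) {
  if (is.null(path)) {
    hit <- get0("rules", envir = .mergeRulesCache)
    if (!is.null(hit)) return(hit)
    path <- system.file("extdata", "merge_rules.tsv",
                        package = "RxnRebalance", mustWork = TRUE)
    rules <- utils::read.delim(path, stringsAsFactors = FALSE)
    assign("rules", rules, envir = .mergeRulesCache)
    return(rules)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.hasCarbonylAt <- function(g, v) {
  nb <- as.integer(igraph::neighbors(g, v))
  for (u in nb) {
    if (igraph::V(g)$element[u] != "O") next
    eid <- igraph::get_edge_ids(g, c(v, u))
    if (igraph::E(g)$order[eid] == 2L) return(TRUE)
  }
  FALSE
}

.singleAtomFragment <- function(element, charge, cutOrder, partnerElement) {
  g <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g)$element <- element
  igraph::V(g)$charge <- as.integer(charge)
  igraph::V(g)$hcount <- 0L
  methods::new("Fragment", residue = g, cuts = data.frame(
    atom = 1L, order = as.integer(cutOrder),
    partnerElement = partnerElement, stringsAsFactors = FALSE))
}

#' Apply expand rules to saturate unresolvable cut edges
#'
#' When the cut edges are concentrated on a single fragment (so there is no
#' second fragment to merge with), each cut is matched against the expand
#' rule table and, on a match, a new single-atom fragment with its own
#' boundary is appended; the actual bond is formed later by a merge rule.
#' Cuts with no matching rule are left open and reported via the
#' `unresolved` attribute.
#'
#' @param fragmentSet a [FragmentSet-class].
#' @param context optional [Reaction-class] (reserved for context-sensitive
#'   rules).
#' @param rules expand-rule table, see [readExpandRules()].
#' @return the (possibly extended) [FragmentSet-class]; attribute
#'   `unresolved` counts cuts no rule could saturate.
#' @export
applyExpandRules <- function(fragmentSet, context = NULL,
                             rules = readExpandRules()) {
  frs <- fragmentSet@fragments
  withCuts <- which(vapply(frs, .fragmentBoundaries, integer(1)) > 0L)
  unresolved <- 0L
  if (length(withCuts) == 1L) {
    fr <- frs[[withCuts]]
    g <- fr@residue
    for (k in seq_len(nrow(fr@cuts))) {
      cut <- fr@cuts[k, ]
      bel <- igraph::V(g)$element[cut$atom]
      carbonyl <- .hasCarbonylAt(g, cut$atom)
      hitRule <- NULL
      for (r in seq_len(nrow(rules))) {
        rr <- rules[r, ]
        if (rr$boundaryElement != "*" && rr$boundaryElement != bel) next
        if (!is.na(rr$carbonylNeighbor) &&
            as.logical(rr$carbonylNeighbor) != carbonyl) next
        if (!is.na(rr$partnerElement) && rr$partnerElement != "*" &&
            rr$partnerElement != cut$partnerElement) next
        if (!is.na(rr$cutOrder) && rr$cutOrder != cut$order) next
        hitRule <- rr
        break
      }
      if (is.null(hitRule)) {
        unresolved <- unresolved + 1L
      } else {
        frs[[length(frs) + 1L]] <- .singleAtomFragment(
          hitRule$appendElement, hitRule$appendCharge, cut$order, bel)
      }
    }
  }
  fragmentSet@fragments <- frs
  fragmentSet@diagnostics$fragmentCountAfterExpand <- length(frs)
  structure(fragmentSet, unresolved = unresolved)
}

#' Merge fragments into whole compounds
#'
#' Repeatedly pairs boundaries located on distinct compounds and inserts the
#' bond dictated by the first matching merge rule, consuming one cut edge
#' from each side; every merge strictly decreases the number of open cuts,
#' so termination is guaranteed. Open boundaries on the same compound are
#' never merged with each other. Fragments without cut edges pass through as
#' standalone compounds.
#'
#' @param fragmentSet a [FragmentSet-class] (normally after
#'   [applyExpandRules()]).
#' @param rules merge-rule table, see [readMergeRules()].
#' @return on success `list(success = TRUE, molecules = <list of Molecule>,
#'   mergedBonds = <count>)`; on failure `list(success = FALSE,
#'   openBoundaries = <count>, reason = ...)`.
#' @export
applyMergeRules <- function(fragmentSet, rules = readMergeRules()) {
  comp <- lapply(fragmentSet@fragments, function(fr)
    list(graph = fr@residue, cuts = fr@cuts))
  mergedBonds <- 0L
  repeat {
    nCuts <- vapply(comp, function(cc) nrow(cc$cuts), integer(1))
    if (sum(nCuts) == 0L) break
    hit <- NULL
    for (r in seq_len(nrow(rules))) {
      rr <- rules[r, ]
      for (ci in seq_along(comp)) {
        if (nCuts[ci] == 0L) next
        for (cj in seq_along(comp)) {
          if (cj == ci || nCuts[cj] == 0L) next
          if (cj < ci) next
          for (bi in seq_len(nCuts[ci])) for (bj in seq_len(nCuts[cj])) {
            ea <- igraph::V(comp[[ci]]$graph)$element[comp[[ci]]$cuts$atom[bi]]
            eb <- igraph::V(comp[[cj]]$graph)$element[comp[[cj]]$cuts$atom[bj]]
            pairOk <- (rr$elementA == "*" || rr$elementB == "*") ||
              (rr$elementA == ea && rr$elementB == eb) ||
              (rr$elementA == eb && rr$elementB == ea)
            if (!pairOk) next
            if (!is.na(rr$requireDoubleCut) && as.logical(rr$requireDoubleCut) &&
                comp[[ci]]$cuts$order[bi] != 2L &&
                comp[[cj]]$cuts$order[bj] != 2L) next
            hit <- list(r = r, ci = ci, cj = cj, bi = bi, bj = bj)
            break
          }
          if (!is.null(hit)) break
        }
        if (!is.null(hit)) break
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) {
      return(list(success = FALSE, openBoundaries = sum(nCuts),
                  reason = "no-applicable-merge-rule"))
    }
    a <- comp[[hit$ci]]; b <- comp[[hit$cj]]
    na <- igraph::vcount(a$graph)
    g <- igraph::disjoint_union(a$graph, b$graph)
    g <- igraph::add_edges(g, c(a$cuts$atom[hit$bi], na + b$cuts$atom[hit$bj]))
    igraph::E(g)$order[igraph::ecount(g)] <- rules$bondOrder[hit$r]
    mergedBonds <- mergedBonds + 1L
    bcuts <- b$cuts[-hit$bj, , drop = FALSE]
    if (nrow(bcuts)) bcuts$atom <- bcuts$atom + na
    newCuts <- rbind(a$cuts[-hit$bi, , drop = FALSE], bcuts)
    comp[[hit$ci]] <- list(graph = g, cuts = newCuts)
    comp <- comp[-hit$cj]
  }
  molecules <- list()
  for (cc in comp) {
    smi <- .graphToSmiles(cc$graph)
    if (is.na(smi))
      return(list(success = FALSE, openBoundaries = 0L,
                  reason = "unserializable-compound"))
    molecules <- c(molecules, list(parseMolecule(smi)))
  }
  list(success = TRUE, molecules = molecules, mergedBonds = mergedBonds)
}
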