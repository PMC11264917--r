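# Connected maximum common subgraph search between two labeled molecular
# graphs. Two problem variants are provided: the induced-subgraph solver
# (atom-count objective, MCIS) and the edge-subgraph solver (bond-count
# objective, MCES). Both enumerate ALL maximum connected embeddings, which
# the embedding-selection step then reduces by the principle of minimum
# chemical distance.

#' Construct an MCS configuration
#'
#' @param ringMatchesRingOnly ring atoms/bonds only match ring atoms/bonds.
#' @param completeRingsOnly matched ring systems must be matched completely
#'   (enforced as a filter on maximum embeddings).
#' @param ignoreBondOrder drop bond-order equality on matched edges.
#' @param algorithm `"induced"` (MCIS) or `"edge"` (MCES).
#' @param label diagnostic label.
#' @return an [MCSConfig-class].
#' @export
mcsConfig <- function(ringMatchesRingOnly = FALSE, completeRingsOnly = FALSE,
                      ignoreBondOrder = FALSE, algorithm = "induced",
                      label = "custom") {
  methods::new("MCSConfig", ringMatchesRingOnly = ringMatchesRingOnly,
               completeRingsOnly = completeRingsOnly,
               ignoreBondOrder = ignoreBondOrder,
               algorithm = match.arg(algorithm, c("induced", "edge")),
               label = label)
}

#' The five-configuration ensemble
#'
#' Four induced-subgraph configurations crossing the ring constraints with
#' the bond-order constraint, plus one unconstrained edge-subgraph
#' configuration.
#'
#' @return list of five [MCSConfig-class] objects.
#' @export
mcsConfigs <- function() {
  list(
    mcsConfig(TRUE,  TRUE,  TRUE,  "induced", "ring+completeRings+anyOrder"),
    mcsConfig(TRUE,  TRUE,  FALSE, "induced", "ring+completeRings+order"),
    mcsConfig(FALSE, FALSE, TRUE,  "induced", "anyRing+anyOrder"),
    mcsConfig(FALSE, FALSE, FALSE, "induced", "anyRing+order"),
    mcsConfig(FALSE, FALSE, FALSE, "edge",    "edgeSubgraph")
  )
}

# Dense search-friendly view of a molecular igraph: order matrix (0 = no
# bond), ring membership from bridge detection (an edge lies on a cycle iff
# it is not a bridge).
.prepGraph <- function(g) {
  n <- igraph::vcount(g)
  adj <- matrix(0L, n, n)
  ringE <- matrix(FALSE, n, n)
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    ord <- igraph::E(g)$order
    bridge <- rep(FALSE, igraph::ecount(g))
    bridge[igraph::bridges(g)] <- TRUE
    for (e in seq_len(nrow(ends))) {
      i <- ends[e, 1]; j <- ends[e, 2]
      adj[i, j] <- adj[j, i] <- ord[e]
      if (!bridge[e]) ringE[i, j] <- ringE[j, i] <- TRUE
    }
  }
  list(n = n, el = igraph::V(g)$element, adj = adj, ringE = ringE,
       ringA = apply(ringE, 1, any), graph = g)
}

# Core backtracking enumeration. Returns list of matches, each
# list(mapX, mapY, size, edges); `mapX[k]` and `mapY[k]` are paired vertex
# ids. Duplicate-free by construction (each candidate pair, once skipped at
# a branch point, is banned in the whole subtree). A node budget guards
# against combinatorial blow-up; exceeding it sets the `timeout` attribute.
.mcsSearch <- function(px, py, cfg, nodeBudget = 2e5) {
  nx <- px$n; ny <- py$n
  vComp <- outer(seq_len(nx), seq_len(ny), Vectorize(function(u, v) {
    if (px$el[u] != py$el[v]) return(FALSE)
    if (cfg@ringMatchesRingOnly && px$ringA[u] != py$ringA[v]) return(FALSE)
    TRUE
  }))
  if (!any(vComp)) return(structure(list(), timeout = FALSE))
  eComp <- function(u1, u2, v1, v2) {
    ox <- px$adj[u1, u2]; oy <- py$adj[v1, v2]
    if (ox == 0L || oy == 0L) return(FALSE)
    if (cfg@ringMatchesRingOnly && px$ringE[u1, u2] != py$ringE[v1, v2])
      return(FALSE)
    if (!cfg@ignoreBondOrder && ox != oy) return(FALSE)
    TRUE
  }
  induced <- cfg@algorithm == "induced"
  best <- 0L
  results <- list()
  seen <- new.env(parent = emptyenv())
  nodes <- 0L
  timedOut <- FALSE
  record <- function(mapX, mapY, size) {
    if (size > best) { best <<- size; results <<- list(); rm(list = ls(seen), envir = seen) }
    if (size == best) {
      key <- paste(c(sort(mapX), sort(mapY)), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        nE <- 0L
        for (a in seq_along(mapX)) for (b in seq_len(a - 1L)) {
          if (px$adj[mapX[a], mapX[b]] > 0L &&
              eComp(mapX[a], mapX[b], mapY[a], mapY[b])) nE <- nE + 1L
        }
        results[[length(results) + 1L]] <<-
          list(mapX = mapX, mapY = mapY, size = length(mapX), edges = nE)
      }
    }
  }
  objective <- function(mapX, mapY, nEdges) {
    if (induced) length(mapX) else nEdges
  }
  extend <- function(mapX, mapY, usedX, usedY, banned, nEdges) {
    nodes <<- nodes + 1L
    if (nodes > nodeBudget) { timedOut <<- TRUE; return(invisible(NULL)) }
    record(mapX, mapY, objective(mapX, mapY, nEdges))
    # candidate pairs adjacent to the current mapping via a compatible edge
    cands <- list()
    for (k in seq_along(mapX)) {
      us <- which(px$adj[mapX[k], ] > 0L & !usedX)
      vs <- which(py$adj[mapY[k], ] > 0L & !usedY)
      for (u in us) for (v in vs) {
        if (!vComp[u, v]) next
        if (!eComp(mapX[k], u, mapY[k], v)) next
        id <- (u - 1L) * ny + v
        if (!is.na(banned[id]) && banned[id]) next
        cands[[as.character(id)]] <- c(u, v)
      }
    }
    if (!length(cands)) return(invisible(NULL))
    ids <- as.integer(names(cands))
    o <- order(ids)
    ids <- ids[o]; cands <- cands[o]
    for (i in seq_along(cands)) {
      u <- cands[[i]][1]; v <- cands[[i]][2]
      if (induced) {
        ok <- TRUE
        for (k in seq_along(mapX)) {
          ex <- px$adj[u, mapX[k]] > 0L
          ey <- py$adj[v, mapY[k]] > 0L
          if (ex != ey) { ok <- FALSE; break }
          if (ex && !eComp(u, mapX[k], v, mapY[k])) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      addE <- 0L
      for (k in seq_along(mapX)) {
        if (px$adj[u, mapX[k]] > 0L && eComp(u, mapX[k], v, mapY[k]))
          addE <- addE + 1L
      }
      usedX2 <- usedX; usedX2[u] <- TRUE
      usedY2 <- usedY; usedY2[v] <- TRUE
      banned2 <- banned
      if (i > 1L) for (j in seq_len(i - 1L)) banned2[ids[j]] <- TRUE
      extend(c(mapX, u), c(mapY, v), usedX2, usedY2, banned2, nEdges + addE)
    }
    invisible(NULL)
  }
  banned0 <- rep(FALSE, nx * ny)
  seeds <- which(vComp, arr.ind = TRUE)
  seeds <- seeds[order(seeds[, 1], seeds[, 2]), , drop = FALSE]
  for (s in seq_len(nrow(seeds))) {
    u <- seeds[s, 1]; v <- seeds[s, 2]
    usedX <- rep(FALSE, nx); usedX[u] <- TRUE
    usedY <- rep(FALSE, ny); usedY[v] <- TRUE
    extend(u, v, usedX, usedY, banned0, 0L)
    banned0[(u - 1L) * ny + v] <- TRUE
    if (timedOut) break
  }
  structure(results, timeout = timedOut)
}

# CompleteRingsOnly filter: in every non-trivial biconnected component (ring
# system) of either graph, the matched vertex set must be all-or-nothing.
.completeRingsOk <- function(g, matched) {
  bc <- igraph::biconnected_components(g)
  for (comp in bc$components) {
    vs <- as.integer(comp)
    if (length(vs) < 3L) next
    k <- sum(vs %in% matched)
    if (k > 0L && k < length(vs)) return(FALSE)
  }
  TRUE
}

#' Find all maximum connected common subgraph embeddings
#'
#' @param component igraph of one reactant-side component.
#' @param target igraph of the (remaining) opposite side.
#' @param config an [MCSConfig-class].
#' @param nodeBudget search-node cap; exhausting it returns the best
#'   embeddings found so far with a `timeout` attribute.
#' @return list of matches `list(mapX, mapY, size, edges)`, empty when the
#'   graphs share no compatible atom.
#' @export
findMCS <- function(component, target, config = mcsConfig(),
                    nodeBudget = 2e5) {
  if (igraph::vcount(component) == 0 || igraph::vcount(target) == 0)
    return(structure(list(), timeout = FALSE))
  px <- .prepGraph(component)
  py <- .prepGraph(target)
  res <- .mcsSearch(px, py, config, nodeBudget)
  if (config@completeRingsOnly && length(res)) {
    keep <- vapply(res, function(m) {
      .completeRingsOk(component, m$mapX) && .completeRingsOk(target, m$mapY)
    }, logical(1))
    res <- structure(res[keep], timeout = attr(res, "timeout"))
  }
  res
}

#' Select an embedding by the principle of minimum chemical distance
#'
#' Among equal-size maximum embeddings, picks the one whose removal leaves
#' the fewest connected residue fragments in the component; ties are broken
#' by fewest cut edges, then (when the target graph is supplied) by the
#' fewest bond-order mismatches among matched edges -- both echo the
#' principle that reactions involve minimal bond changes -- and finally by
#' the lexicographically smallest matched vertex set (deterministic).
#'
#' @param matches non-empty list of matches from [findMCS()].
#' @param component the igraph the matches embed into.
#' @param target optional igraph of the opposite side, enabling the
#'   bond-order-mismatch tie-break.
#' @return the selected match, with `nFragments` and `nCuts` fields added.
#' @export
selectEmbedding <- function(matches, component, target = NULL) {
  if (!length(matches)) stop("selectEmbedding: no matches")
  adjX <- .prepGraph(component)$adj
  adjY <- if (!is.null(target)) .prepGraph(target)$adj else NULL
  stats <- lapply(matches, function(m) {
    unmatched <- setdiff(seq_len(igraph::vcount(component)), m$mapX)
    nf <- if (length(unmatched)) {
      sub <- igraph::induced_subgraph(component, unmatched)
      as.integer(igraph::components(sub)$no)
    } else 0L
    ends <- if (igraph::ecount(component) > 0)
      igraph::ends(component, igraph::E(component), names = FALSE)
    else matrix(integer(0), 0, 2)
    cut <- as.integer(sum(xor(ends[, 1] %in% m$mapX, ends[, 2] %in% m$mapX)))
    mism <- 0L
    if (!is.null(adjY)) {
      for (a in seq_along(m$mapX)) for (b in seq_len(a - 1L)) {
        ox <- adjX[m$mapX[a], m$mapX[b]]
        oy <- adjY[m$mapY[a], m$mapY[b]]
        if (ox > 0L && oy > 0L && ox != oy) mism <- mism + 1L
      }
    }
    list(nFragments = nf, nCuts = cut, mismatches = mism,
         key = paste(sort(m$mapX), collapse = ","))
  })
  o <- order(vapply(stats, `[[`, integer(1), "nFragments"),
             vapply(stats, function(s) s$nCuts, numeric(1)),
             vapply(stats, `[[`, integer(1), "mismatches"),
             vapply(stats, `[[`, character(1), "key"))
  m <- matches[[o[1]]]
  m$nFragments <- stats[[o[1]]]$nFragments
  m$nCuts <- stats[[o[1]]]$nCuts
  m
}
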