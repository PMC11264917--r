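# Independent oracles and shared fixtures for the test suite.

# ---- composition as a plain named vector (independent of CompositionDict) --

cdVec <- function(x) {
  v <- c(x@entries, Q = x@charge)
  v[order(names(v))]
}

expectComposition <- function(cd, expected) {
  ev <- unlist(expected)
  ev <- ev[ev != 0 | names(ev) == "Q"]
  if (!"Q" %in% names(ev)) ev <- c(ev, Q = 0)
  ev <- stats::setNames(as.integer(ev), names(ev))
  expect_identical(cdVec(cd), ev[order(names(ev))])
}

# ---- brute-force rule-multiset enumeration oracle --------------------------

# Enumerates all multisets of library rules up to `maxSize` and tabulates
# their element/charge sums directly from the rule table patterns, without
# using applyRule/dfsBalance.
bruteForceSolutions <- function(maxSize = 4L) {
  path <- system.file("extdata", "imputation_rules.tsv",
                      package = "RxnRebalance")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  parse1 <- function(s) {
    kv <- strsplit(strsplit(s, ",")[[1]], ":")
    stats::setNames(vapply(kv, function(x) as.integer(x[2]), integer(1)),
                    vapply(kv, function(x) x[1], character(1)))
  }
  pats <- lapply(tab$pattern, parse1)
  keys <- sort(unique(unlist(lapply(pats, names))))
  mat <- t(vapply(pats, function(p) {
    v <- stats::setNames(integer(length(keys)), keys)
    v[names(p)] <- p
    v
  }, stats::setNames(integer(length(keys)), keys)))
  nR <- nrow(mat)
  out <- new.env(parent = emptyenv())
  recurse <- function(start, picked) {
    if (length(picked)) {
      s <- colSums(mat[picked, , drop = FALSE])
      key <- paste(s, collapse = ",")
      sol <- paste(sort(tab$name[picked]), collapse = "+")
      out[[key]] <- union(out[[key]], sol)
    }
    if (length(picked) >= maxSize) return(invisible(NULL))
    for (i in seq.int(start, nR)) recurse(i, c(picked, i))
    invisible(NULL)
  }
  recurse(1L, integer(0))
  list(index = out, keys = keys)
}

# sum-vector key of a delta over the oracle's element axes
oracleKey <- function(entries, keys) {
  v <- stats::setNames(integer(length(keys)), keys)
  ent <- unlist(entries)
  v[names(ent)] <- ent
  paste(v, collapse = ",")
}

# all element-count vectors over `elements` with total in 1..maxAtoms
enumerateDeltas <- function(elements, maxAtoms) {
  out <- list()
  recurse <- function(i, left, acc) {
    if (i > length(elements)) {
      if (sum(acc) > 0) out[[length(out) + 1L]] <<-
          stats::setNames(acc, elements)
      return(invisible(NULL))
    }
    for (k in 0:left) recurse(i + 1L, left - k, c(acc, k))
    invisible(NULL)
  }
  recurse(1L, maxAtoms, integer(0))
  out
}

# ---- independent connected-component counter -------------------------------

# Counts connected components among `vertices` of an edge list, by plain
# union-find (independent of igraph).
countComponents <- function(edges, vertices) {
  if (!length(vertices)) return(0L)
  parent <- stats::setNames(vertices, as.character(vertices))
  find <- function(v) {
    while (parent[[as.character(v)]] != v) v <- parent[[as.character(v)]]
    v
  }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (a %in% vertices && b %in% vertices) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[[as.character(ra)]] <- rb
    }
  }
  length(unique(vapply(vertices, find, numeric(1))))
}

# ---- shared closed-loop benchmark (computed once per test run) -------------

.benchCache <- new.env(parent = emptyenv())

sharedClosedLoop <- function() {
  hit <- get0("bench", envir = .benchCache)
  if (!is.null(hit)) return(hit)
  bench <- closedLoopBenchmark(n = 500, seed = 42,
                               removeSmallerProduct = FALSE)
  assign("bench", bench, envir = .benchCache)
  bench
}

`%||%` <- function(a, b) if (is.null(a)) b else a
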