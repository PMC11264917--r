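# MCS search, embedding selection, iterative alignment, expand/merge rules.

g <- function(smi) moleculeGraph(parseMolecule(smi))

test_that("findMCS covers the basic alignment cases", {
  # identical asymmetric graphs: a single full embedding
  resSame <- findMCS(g("CCO"), g("CCO"), mcsConfig())
  expect_length(resSame, 1L)
  expect_equal(resSame[[1]]$size, 3L)

  # disjoint alphabets: no match at all
  expect_length(findMCS(g("C"), g("O"), mcsConfig()), 0L)

  # ethyl acetate vs ethanol under the order-respecting config: the best
  # embeddings cover the ethoxy overlap (3 heavy atoms)
  res <- findMCS(g("CC(=O)OCC"), g("CCO"), mcsConfig())
  expect_true(all(vapply(res, `[[`, integer(1), "size") == 3L))
  expect_true(length(res) >= 2L)
})

test_that("embedding selection minimizes residue fragments (PMCD)", {
  # amide vs its acyl part: matching the acyl block leaves one fragment,
  # the isomorphic alternative leaves more
  comp <- g("CC(=O)NC")
  res <- findMCS(comp, g("CC(=O)O"), mcsConfig(ignoreBondOrder = TRUE))
  emb <- selectEmbedding(res, comp)
  nf <- vapply(res, function(m) {
    keep <- setdiff(seq_len(igraph::vcount(comp)), m$mapX)
    countComponents(igraph::as_edgelist(comp, names = FALSE), keep)
  }, integer(1))
  expect_equal(emb$nFragments, min(nf))
  expect_identical(selectEmbedding(res[1], comp)$mapX, res[[1]]$mapX)
  expect_error(selectEmbedding(list(), comp), "no matches")
})

test_that("selectEmbedding agrees with a brute-force fragment minimizer", {
  pairs <- list(
    c("CC(=O)OCC", "CCO"), c("CCC(=O)OC", "CO"), c("CC(=O)NCC", "CCN"),
    c("CCCCO", "CCO"), c("CC(C)CC(=O)O", "CC(C)C"), c("c1ccccc1CC", "CC"),
    c("CCOC(=O)CC", "CCO"), c("CC(=O)C", "CC(O)C"))
  for (p in pairs) {
    comp <- g(p[1]); targ <- g(p[2])
    for (cfg in mcsConfigs()[c(3, 4)]) {
      res <- findMCS(comp, targ, cfg)
      if (!length(res)) next
      emb <- selectEmbedding(res, comp, targ)
      nf <- vapply(res, function(m) {
        keep <- setdiff(seq_len(igraph::vcount(comp)), m$mapX)
        countComponents(igraph::as_edgelist(comp, names = FALSE), keep)
      }, integer(1))
      expect_equal(emb$nFragments, min(nf))
    }
  }
})

test_that("matched maps are injective and never reuse a target vertex", {
  fs <- iterativeAlign(list(parseMolecule("CC(=O)OCC"),
                            parseMolecule("CCN")),
                       list(parseMolecule("CCO"), parseMolecule("CN")),
                       mcsConfig())
  for (am in fs@diagnostics$atomMap) {
    expect_false(anyDuplicated(am$xVertex) > 0)
  }
  yAll <- unlist(lapply(fs@diagnostics$atomMap, `[[`, "yVertex"))
  expect_false(anyDuplicated(yAll) > 0)
})

test_that("iterative alignment extracts the expected fragments", {
  # ethyl acetate vs ethanol: one acetyl fragment, one single-bond cut at
  # the ester oxygen
  fs <- iterativeAlign(list(parseMolecule("CC(=O)OCC")),
                       list(parseMolecule("CCO")), mcsConfig())
  expect_length(fs@fragments, 1L)
  fr <- fs@fragments[[1]]
  expect_identical(sort(igraph::V(fr@residue)$element), c("C", "C", "O"))
  expect_equal(nrow(fr@cuts), 1L)
  expect_equal(fr@cuts$order, 1L)
  expect_equal(fr@cuts$partnerElement, "O")
  # the boundary atom is the carbonyl carbon
  expect_equal(igraph::V(fr@residue)$element[fr@cuts$atom], "C")

  # identical component: zero fragments
  fsSame <- iterativeAlign(list(parseMolecule("CCO")),
                           list(parseMolecule("CCO")), mcsConfig())
  expect_length(fsSame@fragments, 0L)

  # disjoint component contributes itself wholly with empty cuts
  fsDisj <- iterativeAlign(list(parseMolecule("CCO"),
                                parseMolecule("BrCBr")),
                           list(parseMolecule("CCO")), mcsConfig())
  expect_length(fsDisj@fragments, 1L)
  expect_equal(nrow(fsDisj@fragments[[1]]@cuts), 0L)
  expect_identical(sort(igraph::V(fsDisj@fragments[[1]]@residue)$element),
                   c("Br", "Br", "C"))
})

test_that("the ensemble runs exactly five configurations", {
  fs <- ensembleMCS(list(parseMolecule("CC(=O)OCC")),
                    list(parseMolecule("CCO")))
  expect_length(fs@diagnostics$perConfig, 5L)
  expect_length(mcsConfigs(), 5L)
  algos <- vapply(mcsConfigs(), function(c) c@algorithm, character(1))
  expect_identical(algos, c(rep("induced", 4), "edge"))
})

test_that("ignoring bond order can find strictly larger matches", {
  # ketone vs alcohol differ only in the C-O bond order
  withOrder <- findMCS(g("CC(=O)C"), g("CC(O)C"), mcsConfigs()[[4]])
  anyOrder <- findMCS(g("CC(=O)C"), g("CC(O)C"), mcsConfigs()[[3]])
  expect_equal(max(vapply(withOrder, `[[`, integer(1), "size")), 3L)
  expect_equal(max(vapply(anyOrder, `[[`, integer(1), "size")), 4L)
  fs <- ensembleMCS(list(parseMolecule("CC(=O)C")),
                    list(parseMolecule("CC(O)C")))
  expect_equal(fs@matchedSize, 4L)
})

test_that("expand rules append the missing atom for acyl and amide cuts", {
  fs <- iterativeAlign(list(parseMolecule("CC(=O)OCC")),
                       list(parseMolecule("CCO")), mcsConfig())
  expanded <- applyExpandRules(fs)
  expect_equal(attr(expanded, "unresolved"), 0L)
  expect_length(expanded@fragments, 2L)
  appended <- expanded@fragments[[2]]
  expect_identical(igraph::V(appended@residue)$element, "O")

  # amide bond cut also appends O
  fsAmide <- iterativeAlign(list(parseMolecule("CC(=O)NCC")),
                            list(parseMolecule("CCN")), mcsConfig())
  expAmide <- applyExpandRules(fsAmide)
  expect_equal(attr(expAmide, "unresolved"), 0L)
  newFrag <- expAmide@fragments[[length(expAmide@fragments)]]
  expect_identical(igraph::V(newFrag@residue)$element, "O")

  # fragment sets with paired boundaries are left unchanged
  twoSided <- iterativeAlign(list(parseMolecule("CCO"),
                                  parseMolecule("BrCBr")),
                             list(parseMolecule("CCO")), mcsConfig())
  same <- applyExpandRules(twoSided)
  expect_length(same@fragments, length(twoSided@fragments))
})

test_that("merge rules assemble compounds and consume cut edges", {
  # {Br fragment, ethyl fragment}, one single-bond cut each -> bromoethane
  brF <- RxnRebalance:::.singleAtomFragment("Br", 0L, 1L, "C")
  etG <- g("CC")
  etF <- methods::new("Fragment", residue = etG,
                      cuts = data.frame(atom = 1L, order = 1L,
                                        partnerElement = "C",
                                        stringsAsFactors = FALSE))
  fs <- methods::new("FragmentSet", fragments = list(brF, etF),
                     matchedSize = 0L, config = "test",
                     diagnostics = list())
  merged <- applyMergeRules(fs)
  expect_true(merged$success)
  expect_length(merged$molecules, 1L)
  expect_equal(smiles(merged$molecules[[1]]), canonicalSmiles("CCBr"))

  # acetyl fragment + appended O -> acetic acid (the Fig. 2 assembly)
  est <- applyExpandRules(
    iterativeAlign(list(parseMolecule("CC(=O)OCC")),
                   list(parseMolecule("CCO")), mcsConfig()))
  mergedEst <- applyMergeRules(est)
  expect_true(mergedEst$success)
  expect_equal(smiles(mergedEst$molecules[[1]]), canonicalSmiles("CC(=O)O"))

  # a fragment with zero cuts passes through unchanged
  lone <- methods::new("FragmentSet",
                       fragments = list(methods::new("Fragment",
                                                     residue = g("CCO"),
                                                     cuts = RxnRebalance:::.emptyCuts())),
                       matchedSize = 0L, config = "test", diagnostics = list())
  out <- applyMergeRules(lone)
  expect_true(out$success)
  expect_equal(smiles(out$molecules[[1]]), "CCO")

  # unresolved boundaries on a single compound cannot merge
  single <- methods::new("FragmentSet", fragments = list(etF),
                         matchedSize = 0L, config = "test",
                         diagnostics = list())
  fail <- applyMergeRules(single)
  expect_false(fail$success)
  expect_equal(fail$openBoundaries, 1L)
})

test_that("every merge strictly decreases the number of open cuts", {
  est <- applyExpandRules(
    iterativeAlign(list(parseMolecule("CC(=O)OCC")),
                   list(parseMolecule("CCO")), mcsConfig()))
  before <- sum(vapply(est@fragments, function(f) nrow(f@cuts), integer(1)))
  merged <- applyMergeRules(est)
  expect_true(merged$success)
  expect_equal(merged$mergedBonds, before / 2 + before %% 2)
})

test_that("mcsRebalance reproduces the ethyl acetate worked example", {
  out <- mcsRebalance(parseReaction("CC(=O)OCC>>CCO"))
  expect_true(out@solved)
  expect_equal(out@method, "mcs")
  expect_true(sameReaction(out@outputReaction,
                           parseReaction("CC(=O)OCC.O>>CCO.CC(=O)O")))
  # acetic acid imputed by MCS, water by the rule-based delegation
  expect_identical(vapply(out@imputedProducts, smiles, character(1)),
                   canonicalSmiles("CC(=O)O"))
  expect_identical(vapply(out@imputedReactants, smiles, character(1)), "O")
  expect_equal(out@diagnostics$numBoundary, 1L)
  expect_equal(out@diagnostics$fragmentCount, 1L)
})

test_that("mcsRebalance failure modes return unsolved outcomes", {
  # already balanced: trivial solve
  triv <- mcsRebalance(parseReaction("CCO>>CCO"))
  expect_true(triv@solved)
  expect_equal(triv@method, "already-balanced")

  # ring closure with carbon loss: no fragment interpretation exists
  ring <- mcsRebalance(parseReaction("OCCCCO>>C1CCO1"))
  expect_false(ring@solved)
  expect_identical(reactionSmiles(ring@outputReaction),
                   reactionSmiles(ring@inputReaction))

  # a plain missing-alkane cut points at carbon, which no expand rule
  # saturates
  alkane <- mcsRebalance(parseReaction("CCCCCC>>CCC"))
  expect_false(alkane@solved)
  expect_equal(alkane@reason, "unresolved-boundary")

  # more compounds than the reliability envelope allows
  crowded <- mcsRebalance(parseReaction("C.CC.CCC.CCCC>>C.CC.CCC"))
  expect_false(crowded@solved)
  expect_equal(crowded@reason, "too-many-compounds")
})

test_that("carbon balance holds for X vs Y plus Z on success", {
  cases <- c("CC(=O)OCC>>CCO", "CCC(=O)OCC>>CCO", "CCOC(=O)CC>>CCC(=O)O")
  for (txt in cases) {
    out <- mcsRebalance(parseReaction(txt))
    expect_true(out@solved)
    expect_true(isCarbonBalanced(out@outputReaction))
    expect_true(isBalanced(out@outputReaction))
  }
})
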