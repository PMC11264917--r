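# Reaction parsing, composition dictionaries and balance classification.

test_that("reaction SMILES parsing handles both dialects and bad input", {
  rxn <- parseReaction("CC(=O)O.CCO>>CC(=O)OCC")
  expect_length(reactants(rxn), 2)
  expect_length(products(rxn), 1)
  expect_length(agents(rxn), 0)

  triv <- parseReaction("C>>C")
  expect_equal(smiles(reactants(triv)[[1]]), smiles(products(triv)[[1]]))

  withAgent <- parseReaction("CC(=O)O>[Na+]>CCO")
  expect_length(agents(withAgent), 1)
  expect_equal(smiles(agents(withAgent)[[1]]), "[Na+]")

  expect_error(parseReaction("C1C(>>C"), "unparseable")
  expect_error(parseReaction(">>CCO"), "empty reactant or product")
  expect_error(parseReaction("CCO"), "separators")
})

test_that("compositions count implicit hydrogens and formal charges", {
  rxn <- parseReaction("CC(=O)O.CCO>>CC(=O)OCC")
  expectComposition(composition(rxn, side = "reactants"),
                    c(C = 4, H = 10, O = 3, Q = 0))
  expectComposition(composition(rxn, side = "products"),
                    c(C = 4, H = 8, O = 2, Q = 0))
  expectComposition(composition(parseMolecule("[OH-]")),
                    c(O = 1, H = 1, Q = -1))
  expectComposition(composition(list()), c(Q = 0))
})

test_that("composition is additive over multiset union", {
  mols <- lapply(c("CCO", "[NH4+]", "BrCCBr", "O=S(=O)(O)O"), parseMolecule)
  whole <- composition(mols)
  parts <- cdAdd(composition(mols[1:2]), composition(mols[3:4]))
  expect_identical(cdVec(whole), cdVec(parts))
  # commutativity
  expect_identical(cdVec(cdAdd(composition(mols[[1]]), composition(mols[[2]]))),
                   cdVec(cdAdd(composition(mols[[2]]), composition(mols[[1]]))))
})

test_that("difference dictionaries implement the four-case classification", {
  dm <- compositionDict(c(C = 4, H = 10, O = 3))
  dp <- compositionDict(c(C = 4, H = 8, O = 2))
  dd <- diffDictionaries(dm, dp)
  expectComposition(dd@deltaMinus, c(O = 1, H = 2))
  expect_true(cdIsEmpty(dd@deltaPlus))
  expect_equal(dd@balanceClass, "reactant_dominated")

  same <- diffDictionaries(dm, dm)
  expect_equal(same@balanceClass, "balanced")

  elim <- reactionDiff(parseReaction("CC(Br)C(Br)C>>CC#CC"))
  expectComposition(elim@deltaMinus, c(H = 2, Br = 2))
  expect_equal(elim@balanceClass, "reactant_dominated")

  both <- diffDictionaries(compositionDict(c(O = 1)),
                           compositionDict(c(H = 2)))
  expect_equal(both@balanceClass, "both_sides")
})

test_that("charge differences fold into the side that has element entries", {
  # product side has elements, reactant side only charge excess
  dd <- diffDictionaries(compositionDict(charge = 1L),
                         compositionDict(c(H = 1)))
  expect_true(cdIsEmpty(dd@deltaMinus))
  expectComposition(dd@deltaPlus, c(H = 1, Q = -1))
  expect_equal(dd@balanceClass, "product_dominated")
  # pure charge difference folds into delta minus by convention
  dd2 <- diffDictionaries(compositionDict(charge = -1L), compositionDict())
  expectComposition(dd2@deltaMinus, c(Q = -1))
  expect_equal(dd2@balanceClass, "reactant_dominated")
})

test_that("agents never contribute to balance arithmetic", {
  plain <- reactionDiff(parseReaction("CC(=O)O>>CCO"))
  withAgent <- reactionDiff(parseReaction("CC(=O)O>[Na+]>CCO"))
  expect_identical(cdVec(plain@deltaMinus), cdVec(withAgent@deltaMinus))
  expect_identical(cdVec(plain@deltaPlus), cdVec(withAgent@deltaPlus))
})

test_that("carbon balance checks match the paper's examples", {
  expect_true(isCarbonBalanced(parseReaction("CC(=O)O.CCO>>CC(=O)OCC")))
  expect_false(isCarbonBalanced(parseReaction("CC(=O)OCC>>CCO")))
  expect_true(isCarbonBalanced(parseReaction("CCO>>CCO")))
})

test_that("serialization round-trips preserve per-side compositions", {
  texts <- c("CC(=O)O.CCO>>CC(=O)OCC", "CC(Br)C(Br)C>>CC#CC",
             "[NH4+].[OH-]>>N.O", "CC(=O)O>[Na+]>CCO")
  for (txt in texts) {
    rxn <- parseReaction(txt)
    back <- parseReaction(reactionSmiles(rxn))
    expect_identical(cdVec(composition(rxn, side = "reactants")),
                     cdVec(composition(back, side = "reactants")))
    expect_identical(cdVec(composition(rxn, side = "products")),
                     cdVec(composition(back, side = "products")))
  }
})

test_that("reconstruction identity: D- minus D+ decomposes into the deltas", {
  set.seed(7)
  pool <- c("CCO", "O", "[H+]", "[Br-]", "CC(=O)OCC", "N", "O=O", "[Na+]")
  for (i in 1:20) {
    r <- sample(pool, sample(1:3, 1), replace = TRUE)
    p <- sample(pool, sample(1:3, 1), replace = TRUE)
    rxn <- parseReaction(paste0(paste(r, collapse = "."), ">>",
                                paste(p, collapse = ".")))
    dm <- composition(rxn, side = "reactants")
    dp <- composition(rxn, side = "products")
    dd <- diffDictionaries(dm, dp)
    # adding delta minus to products and delta plus to reactants rebalances
    lhs <- cdAdd(dp, dd@deltaMinus)
    rhs <- cdAdd(dm, dd@deltaPlus)
    expect_identical(cdVec(lhs), cdVec(rhs))
  }
})
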