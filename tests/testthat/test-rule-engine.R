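# DFS imputation over the rule library, ranking, post-processing and redox
# refinement.

lib <- defaultRuleLibrary()
ruleByName <- function(name) Filter(function(r) r@name == name, lib@rules)[[1]]

test_that("rule application subtracts element entries, charge is exempt", {
  oh <- ruleByName("hydroxide")
  reduced <- applyRule(compositionDict(c(O = 1, H = 2)), oh)
  expectComposition(reduced, c(H = 1, Q = 1))
  emptied <- applyRule(reduced, ruleByName("proton"))
  expect_true(cdIsEmpty(emptied))
  # element shortfall signals not-applicable, not an error
  expect_null(applyRule(compositionDict(c(Br = 2)), oh))
})

test_that("the electron rule only moves charge toward zero", {
  e <- ruleByName("electron")
  expectComposition(applyRule(compositionDict(charge = -1L), e), c(Q = 0))
  expect_null(applyRule(compositionDict(c(Br = 1)), e))
  expect_null(applyRule(compositionDict(charge = 1L), e))
})

test_that("DFS enumerates all balancing multisets, deduplicated", {
  sols <- dfsBalance(compositionDict(c(O = 1, H = 2)), lib)
  keys <- vapply(sols, function(s)
    paste(sort(vapply(s@compounds, smiles, character(1))), collapse = "+"),
    character(1))
  expect_true("[H+]+[OH-]" %in% keys)     # the paper's first DFS output
  expect_true("O" %in% keys)              # water in one step
  expect_false(anyDuplicated(keys) > 0)
})

test_that("dibromobutane delta has exactly two minimal solutions, ion wins", {
  sols <- dfsBalance(compositionDict(c(H = 2, Br = 2)), lib)
  counts <- vapply(sols, function(s) s@ruleCount, integer(1))
  minimal <- sols[counts == min(counts)]
  expect_equal(min(counts), 2L)
  expect_length(minimal, 2L)
  minKeys <- sort(vapply(minimal, function(s)
    paste(sort(vapply(s@compounds, smiles, character(1))), collapse = "+"),
    character(1)))
  expect_identical(minKeys, c("BrBr+[H][H]", "[Br-]+[Br-]+[H+]+[H+]"))
  best <- rankSolutions(sols)
  expect_true(best@containsIon)
  expect_identical(sort(vapply(best@compounds, smiles, character(1))),
                   c("[Br-]", "[Br-]", "[H+]", "[H+]"))
})

test_that("ranking prefers fewest distinct rules, then ions", {
  sols <- dfsBalance(compositionDict(c(O = 1, H = 2)), lib)
  expect_equal(smiles(rankSolutions(sols)@compounds[[1]]), "O")  # water, 1 rule
  single <- sols[1]
  expect_identical(rankSolutions(single), single[[1]])
  expect_error(rankSolutions(list()), "empty")
})

test_that("an empty delta yields the single empty solution", {
  sols <- dfsBalance(compositionDict(), lib)
  expect_length(sols, 1L)
  expect_length(sols[[1]]@compounds, 0L)
})

test_that("the reduced dictionary is independent of rule application order", {
  multiset <- c("water", "hydroxide", "proton", "bromide")
  delta <- compositionDict(c(O = 2, H = 4, Br = 1), charge = -1L)
  for (perm in list(multiset, rev(multiset), multiset[c(3, 1, 4, 2)])) {
    d <- delta
    for (nm in perm) d <- applyRule(d, ruleByName(nm))
    expect_true(cdIsEmpty(d))
  }
})

test_that("every DFS solution restores exact balance (soundness)", {
  set.seed(11)
  for (i in 1:25) {
    ent <- c(H = sample(0:3, 1), O = sample(0:2, 1), Br = sample(0:2, 1),
             N = sample(0:1, 1))
    ent <- ent[ent > 0]
    if (!length(ent)) next
    delta <- compositionDict(ent)
    for (s in dfsBalance(delta, lib)) {
      total <- composition(s@compounds)
      expect_identical(cdVec(total), cdVec(delta))
    }
  }
})

test_that("post-processing rejects free halogens and rewrites O and H2", {
  base <- parseReaction("CCO>>CCO")
  rejected <- postprocess(base, list(reactants = list(),
                                     products = list(parseMolecule("BrBr"))))
  expect_true(rejected$rejected)
  expect_equal(rejected$rule, "i")

  oxo <- postprocess(base, list(reactants = list(),
                                products = list(parseMolecule("[O]"))))
  expect_false(oxo$rejected)
  expect_equal(oxo$applied, "ii")
  expect_equal(smiles(oxo$imputation$products[[1]]), "O")
  expect_equal(smiles(oxo$imputation$reactants[[1]]), "[H][H]")

  h2 <- postprocess(base, list(reactants = list(),
                               products = list(parseMolecule("[H][H]"))))
  expect_equal(h2$applied, "iii")
  expect_equal(smiles(h2$imputation$products[[1]]), "O")
  expect_equal(smiles(h2$imputation$reactants[[1]]), "[O]")

  # alkali metal among the reactants suppresses rule (iii)
  sodium <- parseReaction("CCO.[Na+]>>CCO")
  kept <- postprocess(sodium, list(reactants = list(),
                                   products = list(parseMolecule("[H][H]"))))
  expect_length(kept$applied, 0L)
  expect_equal(smiles(kept$imputation$products[[1]]), "[H][H]")
  # ... and so does a hydride reagent
  hydride <- parseReaction("CCO.[AlH4-]>>CCO")
  kept2 <- postprocess(hydride, list(reactants = list(),
                                     products = list(parseMolecule("[H][H]"))))
  expect_length(kept2$applied, 0L)
})

test_that("rule-based rebalance reproduces the worked examples", {
  # esterification: missing water on the product side
  est <- ruleBasedRebalance(parseReaction("CC(=O)O.CCO>>CC(=O)OCC"))
  expect_true(est@solved)
  expect_equal(est@method, "rule")
  expect_identical(vapply(est@imputedProducts, smiles, character(1)), "O")
  expect_true(isBalanced(est@outputReaction))

  # elimination: two protons and two bromides
  elim <- ruleBasedRebalance(parseReaction("CC(Br)C(Br)C>>CC#CC"))
  expect_true(elim@solved)
  expect_identical(sort(vapply(elim@imputedProducts, smiles, character(1))),
                   c("[Br-]", "[Br-]", "[H+]", "[H+]"))

  # already balanced input short-circuits
  triv <- ruleBasedRebalance(parseReaction("CCO>>CCO"))
  expect_true(triv@solved)
  expect_equal(triv@method, "already-balanced")
  expect_equal(triv@reason, "solved-trivially")

  # carbon-imbalanced input is refused (never handled by this branch)
  refused <- ruleBasedRebalance(parseReaction("CC(=O)OCC>>CCO"))
  expect_false(refused@solved)
  expect_equal(refused@reason, "carbon-imbalanced")
})

test_that("acetic acid reduction gains 2 H2 and water, refined to 4 [H]", {
  raw <- ruleBasedRebalance(parseReaction("CC(=O)O>>CCO"),
                            applyRedoxRefine = FALSE)
  expect_true(raw@solved)
  expect_identical(sort(vapply(raw@imputedReactants, smiles, character(1))),
                   c("[H][H]", "[H][H]"))
  expect_identical(vapply(raw@imputedProducts, smiles, character(1)), "O")
  expect_true(isBalanced(raw@outputReaction))

  refined <- redoxRefine(raw)
  expect_identical(vapply(refined@imputedReactants, smiles, character(1)),
                   rep("[H]", 4))
  expect_true(isBalanced(refined@outputReaction))
  # element counts and charge preserved by refinement
  expect_identical(
    cdVec(composition(refined@outputReaction, side = "reactants")),
    cdVec(composition(raw@outputReaction, side = "reactants")))
})

test_that("redox refinement leaves reactions without imputed H2/O2 alone", {
  est <- ruleBasedRebalance(parseReaction("CC(=O)O.CCO>>CC(=O)OCC"))
  expect_identical(reactionSmiles(redoxRefine(est)@outputReaction),
                   reactionSmiles(est@outputReaction))
})
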