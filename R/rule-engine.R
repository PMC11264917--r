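# Rule-based imputation of missing non-carbon compounds: DFS over the rule
# library, solution ranking, chemical-plausibility post-processing and the
# [H]/[O] redox notation refinement.

#' Apply an imputation rule to a difference dictionary
#'
#' Element entries of the pattern are subtracted (the rule is applicable only
#' when every element entry is covered); the charge entry is exempt from the
#' coverage requirement and may change sign freely, which is what makes the
#' ion-centric library work.
#'
#' @param delta a [CompositionDict-class].
#' @param rule an [ImputationRule-class].
#' @return the reduced [CompositionDict-class], or `NULL` when the rule is
#'   not applicable (a signal, not an error: the DFS just skips).
#' @examples
#' lib <- defaultRuleLibrary()
#' oh <- Filter(function(r) r@name == "hydroxide", lib@rules)[[1]]
#' applyRule(compositionDict(c(O = 1, H = 2)), oh)  # {H:1, Q:1}
#' @export
applyRule <- function(delta, rule) {
  p <- rule@pattern
  if (length(p@entries)) {
    have <- delta@entries[names(p@entries)]
    if (any(is.na(have)) || any(have < p@entries)) return(NULL)
    rest <- delta@entries
    rest[names(p@entries)] <- rest[names(p@entries)] - p@entries
    compositionDict(rest, delta@charge - p@charge)
  } else {
    # pure-charge rule (the electron): admissible only when it moves the
    # charge strictly toward zero, which bounds the search.
    newQ <- delta@charge - p@charge
    if (abs(newQ) >= abs(delta@charge)) return(NULL)
    compositionDict(delta@entries, newQ)
  }
}

#' Enumerate all rule multisets that empty a difference dictionary
#'
#' Depth-first search over the rule library. At each depth only rules at or
#' after the previously applied rule's library position are tried; since the
#' final dictionary is independent of the order of application, this
#' order-canonical enumeration visits every solution multiset exactly once.
#'
#' @param delta a non-empty [CompositionDict-class].
#' @param library a [RuleLibrary-class].
#' @param maxDepth cap on the number of rule applications (default 8; the
#'   search tree is shallow in practice, the cap guards pathological input).
#' @return list of [Solution-class] objects (side unset); empty list when no
#'   solution exists within the depth cap. An empty `delta` yields a single
#'   empty solution.
#' @examples
#' sols <- dfsBalance(compositionDict(c(H = 2, Br = 2)), defaultRuleLibrary())
#' length(sols)
#' @export
dfsBalance <- function(delta, library, maxDepth = 8L) {
  rules <- library@rules
  nR <- length(rules)
  out <- list()
  emit <- function(ruleIdx) {
    used <- rules[ruleIdx]
    compounds <- lapply(used, function(r) r@compound)
    nm <- vapply(used, function(r) r@name, character(1))
    methods::new("Solution", compounds = compounds, rules = nm,
                 ruleCount = length(unique(nm)),
                 containsIon = any(vapply(used, function(r) r@isIon,
                                          logical(1))),
                 side = NA_character_)
  }
  recurse <- function(delta, startIdx, path) {
    if (cdIsEmpty(delta)) {
      out[[length(out) + 1L]] <<- emit(path)
      return(invisible(NULL))
    }
    if (length(path) >= maxDepth) return(invisible(NULL))
    for (i in seq.int(startIdx, nR)) {
      reduced <- applyRule(delta, rules[[i]])
      if (!is.null(reduced)) recurse(reduced, i, c(path, i))
    }
    invisible(NULL)
  }
  if (cdIsEmpty(delta)) return(list(emit(integer(0))))
  recurse(delta, 1L, integer(0))
  out
}

.solutionKey <- function(s) {
  paste(sort(vapply(s@compounds, smiles, character(1))), collapse = ".")
}

.solutionOrder <- function(solutions) {
  counts <- vapply(solutions, function(s) s@ruleCount, integer(1))
  ions <- vapply(solutions, function(s) s@containsIon, logical(1))
  keys <- vapply(solutions, .solutionKey, character(1))
  order(counts, !ions, keys)
}

#' Rank candidate solutions
#'
#' Selects a solution with the minimal number of distinct rules; among ties,
#' one containing an ion is preferred; remaining ties are broken by
#' lexicographic order of the sorted canonical SMILES, which makes the choice
#' deterministic.
#'
#' @param solutions non-empty list of [Solution-class] objects.
#' @return the best [Solution-class].
#' @export
rankSolutions <- function(solutions) {
  if (!length(solutions)) stop("rankSolutions: empty solution list")
  solutions[[.solutionOrder(solutions)[1L]]]
}

# ---- post-processing ------------------------------------------------------

.freeHalogenSmiles <- c("FF", "ClCl", "BrBr", "II",
                        "[F]", "[Cl]", "[Br]", "[I]")
.alkaliMetals <- c("Li", "Na", "K", "Rb", "Cs")
.hydrideCarriers <- c("B", "Al", "Si", "Sn", "Li", "Na", "K", "Rb", "Cs",
                      "Mg", "Ca", "Zn", "Ti", "Fe", "Cu", "Ni", "Pd", "Pt")

.hasAlkaliOrHydride <- function(mols) {
  for (m in mols) {
    el <- igraph::V(m@graph)$element
    hc <- igraph::V(m@graph)$hcount
    ch <- igraph::V(m@graph)$charge
    if (any(el %in% .alkaliMetals)) return(TRUE)
    if (any(el %in% .hydrideCarriers & hc > 0L)) return(TRUE)
    if (any(el == "H" & ch < 0L)) return(TRUE)            # explicit hydride ion
  }
  FALSE
}

# Imputation state: molecules added to each side, plus bookkeeping.
.newImputation <- function() list(reactants = list(), products = list())

#' Chemical-plausibility post-processing of an imputed solution
#'
#' Applies the three post-processing rules to the compounds the engine added
#' to the product side: (i) an imputed free halogen as product invalidates
#' the solution; (ii) imputed atomic oxygen as product is replaced by water
#' and molecular hydrogen is added to the reactants; (iii) imputed molecular
#' hydrogen as product, absent an alkali metal or hydride among the
#' reactants, is replaced by water with atomic oxygen added to the reactants.
#' Both rewrites preserve stoichiometric balance.
#'
#' @param reaction the base [Reaction-class] (before imputation).
#' @param imputation list with `reactants`/`products` molecule lists (the
#'   compounds added to each side).
#' @return list with elements `imputation` (possibly rewritten), `rejected`
#'   (logical), `rule` (triggering rule id on rejection) and `applied`
#'   (character vector of post-processing rule ids that fired).
#' @export
postprocess <- function(reaction, imputation) {
  applied <- character(0)
  prods <- imputation$products
  reacts <- imputation$reactants
  i <- 1L
  while (i <= length(prods)) {
    s <- prods[[i]]@smiles
    if (s %in% .freeHalogenSmiles) {
      return(list(imputation = imputation, rejected = TRUE, rule = "i",
                  applied = applied))
    } else if (s == "[O]") {
      prods[[i]] <- parseMolecule("O")
      reacts <- c(reacts, list(parseMolecule("[H][H]")))
      applied <- c(applied, "ii")
    } else if (s == "[H][H]" &&
               !.hasAlkaliOrHydride(c(reaction@reactants, reacts))) {
      prods[[i]] <- parseMolecule("O")
      reacts <- c(reacts, list(parseMolecule("[O]")))
      applied <- c(applied, "iii")
    }
    i <- i + 1L
  }
  list(imputation = list(reactants = reacts, products = prods),
       rejected = FALSE, rule = NA_character_, applied = applied)
}

#' Redox notation refinement
#'
#' Rewrites each imputed molecular hydrogen on the reactant side as two
#' unbonded `[H]` atoms, and each imputed molecular oxygen as two `[O]`
#' atoms: the convention signalling an unspecified reducing or oxidizing
#' agent. Only engine-imputed compounds are touched, never original input
#' molecules; element counts and total charge are preserved.
#'
#' @param outcome a solved [RebalanceOutcome-class].
#' @return the refined [RebalanceOutcome-class].
#' @export
redoxRefine <- function(outcome) {
  if (!outcome@solved) return(outcome)
  refine <- function(mols) {
    out <- list()
    for (m in mols) {
      if (m@smiles == "[H][H]") {
        out <- c(out, list(parseMolecule("[H]"), parseMolecule("[H]")))
      } else if (m@smiles == "O=O") {
        out <- c(out, list(parseMolecule("[O]"), parseMolecule("[O]")))
      } else {
        out <- c(out, list(m))
      }
    }
    out
  }
  old <- outcome@imputedReactants
  new <- refine(old)
  if (length(new) == length(old)) return(outcome)
  base <- outcome@outputReaction
  for (m in old) {
    base@reactants <- .removeMoleculeOnce(base@reactants, m@smiles)
  }
  base@reactants <- c(base@reactants, new)
  outcome@outputReaction <- base
  outcome@imputedReactants <- new
  outcome
}

# ---- the full rule-based branch -------------------------------------------

.makeOutcome <- function(input, output, solved, method, imputation,
                         reason = NA_character_, rules = character(0),
                         diagnostics = list()) {
  methods::new("RebalanceOutcome",
               inputReaction = input, outputReaction = output,
               solved = solved, method = method,
               imputedReactants = imputation$reactants,
               imputedProducts = imputation$products,
               confidence = NA_real_, reason = reason,
               rulesApplied = rules, diagnostics = diagnostics)
}

.unsolved <- function(reaction, reason, method = "none") {
  .makeOutcome(reaction, reaction, FALSE, method, .newImputation(),
               reason = reason)
}

.applyImputation <- function(reaction, imputation) {
  reaction <- .addMolecules(reaction, imputation$reactants, "reactants")
  .addMolecules(reaction, imputation$products, "products")
}

#' Rule-based rebalancing of a carbon-balanced reaction
#'
#' Runs the DFS over the rule library on the non-empty difference
#' dictionary, ranks the solutions, applies the winner, post-processes and
#' (optionally) applies the redox notation refinement. Carbon-balanced
#' both-sides instances are attempted by independent per-side searches.
#' Chemical failure never raises: an unsolved outcome with a reason code is
#' returned and the output reaction equals the input.
#'
#' @param reaction a [Reaction-class]; must be carbon-balanced.
#' @param library a [RuleLibrary-class].
#' @param maxDepth DFS application cap, see [dfsBalance()].
#' @param applyPostprocess run the three post-processing rules.
#' @param applyRedoxRefine rewrite imputed H2/O2 as unbonded [H]/[O].
#' @return a [RebalanceOutcome-class] with method `"rule"` on success.
#' @examples
#' out <- ruleBasedRebalance(parseReaction("CC(Br)C(Br)C>>CC#CC"))
#' reactionSmiles(out@outputReaction)
#' @export
ruleBasedRebalance <- function(reaction, library = defaultRuleLibrary(),
                               maxDepth = 8L, applyPostprocess = TRUE,
                               applyRedoxRefine = TRUE) {
  dd <- reactionDiff(reaction)
  if (dd@balanceClass == "balanced") {
    return(.makeOutcome(reaction, reaction, TRUE, "already-balanced",
                        .newImputation(), reason = "solved-trivially"))
  }
  if (!isCarbonBalanced(reaction)) {
    return(.unsolved(reaction, "carbon-imbalanced"))
  }
  # candidate imputations, ranked
  candidates <- switch(dd@balanceClass,
    reactant_dominated = {
      sols <- dfsBalance(dd@deltaMinus, library, maxDepth)
      lapply(sols[.solutionOrder(sols)], function(s) {
        list(reactants = list(), products = s@compounds,
             rules = s@rules)
      })
    },
    product_dominated = {
      sols <- dfsBalance(dd@deltaPlus, library, maxDepth)
      lapply(sols[.solutionOrder(sols)], function(s) {
        list(reactants = s@compounds, products = list(),
             rules = s@rules)
      })
    },
    both_sides = {
      sm <- dfsBalance(dd@deltaMinus, library, maxDepth)
      sp <- dfsBalance(dd@deltaPlus, library, maxDepth)
      if (!length(sm) || !length(sp)) list() else {
        sm <- sm[.solutionOrder(sm)]
        sp <- sp[.solutionOrder(sp)]
        combos <- expand.grid(i = seq_along(sm), j = seq_along(sp))
        tot <- vapply(seq_len(nrow(combos)), function(k) {
          length(unique(c(sm[[combos$i[k]]]@rules, sp[[combos$j[k]]]@rules)))
        }, integer(1))
        combos <- combos[order(tot, combos$i, combos$j), , drop = FALSE]
        combos <- utils::head(combos, 50L)
        lapply(seq_len(nrow(combos)), function(k) {
          a <- sm[[combos$i[k]]]; b <- sp[[combos$j[k]]]
          list(reactants = b@compounds, products = a@compounds,
               rules = c(a@rules, b@rules))
        })
      }
    }
  )
  if (!length(candidates)) return(.unsolved(reaction, "no-rule-solution"))
  for (cand in candidates) {
    imputation <- list(reactants = cand$reactants, products = cand$products)
    post <- list(applied = character(0))
    if (applyPostprocess) {
      post <- postprocess(reaction, imputation)
      if (post$rejected) next
      imputation <- post$imputation
    }
    output <- .applyImputation(reaction, imputation)
    if (!isBalanced(output)) next   # defensive; post-processing preserves balance
    out <- .makeOutcome(reaction, output, TRUE, "rule", imputation,
                        rules = cand$rules,
                        diagnostics = list(postRules = post$applied,
                                           balanceClass = dd@balanceClass))
    if (applyRedoxRefine) out <- redoxRefine(out)
    return(out)
  }
  .unsolved(reaction, "postprocess-rejected")
}
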