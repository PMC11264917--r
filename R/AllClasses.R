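#' @import methods
NULL

#' CompositionDict: element counts with a signed charge key
#'
#' A molecular sum formula represented as a map from element symbol to a
#' strictly positive atom count, together with an integer net charge stored
#' under the reserved key `Q`. The charge is the only entry allowed to be
#' negative; zero-count element entries are never stored.
#'
#' @slot entries named integer vector of element counts (no zeros, no `Q`).
#' @slot charge integer net charge.
#' @export
setClass("CompositionDict",
  representation(entries = "integer", charge = "integer"),
  prototype(entries = stats::setNames(integer(0), character(0)), charge = 0L)
)

setValidity("CompositionDict", function(object) {
  e <- object@entries
  if (length(e) && is.null(names(e))) return("entries must be named")
  if (any(names(e) == "Q")) return("charge must live in the charge slot, not entries")
  if (any(e <= 0L)) return("element counts must be strictly positive")
  if (anyDuplicated(names(e))) return("duplicate element keys")
  TRUE
})

#' Molecule: a hydrogen-complete molecular graph
#'
#' Heavy atoms are vertices of an igraph with attributes `element`, `charge`
#' and `hcount` (collapsed hydrogens); bonds carry an integer `order` edge
#' attribute. The canonical SMILES is produced by [canonicalSmiles()] and is
#' idempotent under re-canonicalization.
#'
#' @slot smiles canonical SMILES string.
#' @slot graph igraph molecular graph.
#' @slot formalCharge integer sum of atomic formal charges.
#' @export
setClass("Molecule",
  representation(smiles = "character", graph = "ANY", formalCharge = "integer")
)

setValidity("Molecule", function(object) {
  if (length(object@smiles) != 1L) return("smiles must be length 1")
  if (!igraph::is_igraph(object@graph)) return("graph must be an igraph")
  TRUE
})

#' Reaction: reactant/product/agent molecule multisets
#'
#' Stoichiometric multiplicity is represented by molecule repetition
#' (dot-separated duplicates), matching reaction-SMILES convention. Agents
#' (the middle segment of `A>B>C`) are carried through unchanged and never
#' contribute to balance arithmetic.
#'
#' @slot reactants,products,agents lists of [Molecule-class] objects.
#' @slot sourceText the original reaction SMILES.
#' @export
setClass("Reaction",
  representation(reactants = "list", products = "list", agents = "list",
                 sourceText = "character")
)

setValidity("Reaction", function(object) {
  ok <- function(x) all(vapply(x, methods::is, logical(1), "Molecule"))
  if (!ok(object@reactants) || !ok(object@products) || !ok(object@agents))
    return("reactants, products and agents must be lists of Molecule objects")
  TRUE
})

#' DiffDictionaries: reactant/product excess and balance class
#'
#' @slot deltaMinus [CompositionDict-class] of reactant excess.
#' @slot deltaPlus [CompositionDict-class] of product excess.
#' @slot balanceClass one of `"balanced"`, `"reactant_dominated"`,
#'   `"product_dominated"`, `"both_sides"`.
#' @export
setClass("DiffDictionaries",
  representation(deltaMinus = "CompositionDict", deltaPlus = "CompositionDict",
                 balanceClass = "character")
)

setValidity("DiffDictionaries", function(object) {
  if (!object@balanceClass %in%
      c("balanced", "reactant_dominated", "product_dominated", "both_sides"))
    return("invalid balance class")
  shared <- intersect(names(object@deltaMinus@entries),
                      names(object@deltaPlus@entries))
  if (length(shared)) return("deltaMinus and deltaPlus share element keys")
  TRUE
})

#' ImputationRule: a pattern dictionary that emits a compound
#'
#' @slot pattern [CompositionDict-class] subtracted from a difference
#'   dictionary when the rule applies.
#' @slot compound the [Molecule-class] added to the deficient side.
#' @slot isIon whether the compound carries net charge (or is the electron).
#' @slot size number of atoms in the pattern.
#' @slot name short identifier used in diagnostics.
#' @export
setClass("ImputationRule",
  representation(pattern = "CompositionDict", compound = "Molecule",
                 isIon = "logical", size = "integer", name = "character")
)

#' RuleLibrary: ordered list of imputation rules
#'
#' Rules are kept in non-increasing pattern-size order; the DFS exploits this
#' ordering for its order-canonical enumeration.
#'
#' @slot rules list of [ImputationRule-class] objects.
#' @export
setClass("RuleLibrary", representation(rules = "list"))

setValidity("RuleLibrary", function(object) {
  sizes <- vapply(object@rules, function(r) r@size, integer(1))
  if (is.unsorted(rev(sizes))) return("rules must be in non-increasing pattern size order")
  TRUE
})

#' Solution: a multiset of compounds that empties a difference dictionary
#'
#' @slot compounds list of [Molecule-class] objects (with repetition).
#' @slot rules character vector of applied rule names (with repetition).
#' @slot ruleCount number of distinct rules used.
#' @slot containsIon whether any compound is an ion.
#' @slot side which reaction side the compounds are added to
#'   (`"reactants"` or `"products"`).
#' @export
setClass("Solution",
  representation(compounds = "list", rules = "character", ruleCount = "integer",
                 containsIon = "logical", side = "character")
)

#' MCSConfig: one configuration of the MCS ensemble
#'
#' @slot ringMatchesRingOnly ring atoms/bonds may only match ring atoms/bonds.
#' @slot completeRingsOnly matched rings must be matched completely.
#' @slot ignoreBondOrder drop the bond-order constraint on matched edges.
#' @slot algorithm `"induced"` (atom-count MCIS) or `"edge"` (bond-count MCES).
#' @slot label short description used in diagnostics.
#' @export
setClass("MCSConfig",
  representation(ringMatchesRingOnly = "logical", completeRingsOnly = "logical",
                 ignoreBondOrder = "logical", algorithm = "character",
                 label = "character")
)

#' Fragment: residue graph with its cut edges
#'
#' The residue is the subgraph of a reactant-side component induced by the
#' atoms not covered by the MCS match; each cut records the broken bond to the
#' matched part (boundary vertex, original bond order, and the element of the
#' matched partner atom, which drives expand-rule conditions).
#'
#' @slot residue igraph residue graph.
#' @slot cuts data.frame with columns `atom` (residue vertex index),
#'   `order`, `partnerElement`.
#' @export
setClass("Fragment", representation(residue = "ANY", cuts = "data.frame"))

#' FragmentSet: all fragments from one alignment plus diagnostics
#'
#' @slot fragments list of [Fragment-class] objects.
#' @slot matchedSize total number of matched vertices.
#' @slot config label of the ensemble configuration that produced the set.
#' @slot diagnostics list (per-config sizes, timeout flags, ...).
#' @export
setClass("FragmentSet",
  representation(fragments = "list", matchedSize = "integer",
                 config = "character", diagnostics = "list")
)

#' RebalanceOutcome: result of rebalancing one reaction
#'
#' When `solved` is `TRUE` the output reaction satisfies element-wise and
#' charge balance; otherwise the output reaction equals the input.
#'
#' @slot inputReaction,outputReaction [Reaction-class] objects.
#' @slot solved logical.
#' @slot method one of `"rule"`, `"mcs"`, `"none"`, `"already-balanced"`.
#' @slot imputedReactants,imputedProducts lists of imputed [Molecule-class]s.
#' @slot confidence numeric score in `[0, 1]`, or `NA` when not scored.
#' @slot reason failure/diagnostic code.
#' @slot rulesApplied character vector of applied rule names.
#' @slot diagnostics list of method-specific diagnostics (fragment counts,
#'   boundary counts, winning MCS configuration, ...).
#' @export
setClass("RebalanceOutcome",
  representation(inputReaction = "Reaction", outputReaction = "Reaction",
                 solved = "logical", method = "character",
                 imputedReactants = "list", imputedProducts = "list",
                 confidence = "numeric", reason = "character",
                 rulesApplied = "character", diagnostics = "list")
)

setValidity("RebalanceOutcome", function(object) {
  if (!object@method %in% c("rule", "mcs", "none", "already-balanced"))
    return("invalid method tag")
  TRUE
})

#' ConfidenceModel: boosted-tree confidence classifier
#'
#' @slot booster fitted xgboost model.
#' @slot featureNames feature column order expected by the booster.
#' @slot metadata list with seed, split sizes, resampling counts and held-out
#'   metrics.
#' @export
setClass("ConfidenceModel",
  representation(booster = "ANY", featureNames = "character", metadata = "list")
)
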