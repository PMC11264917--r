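# The MCS-based branch: infer missing carbon-containing compounds.

.sideCarbons <- function(mols) sum(vapply(mols, .molCarbons, integer(1)))
.sideAtoms <- function(mols) sum(vapply(mols, .molAtoms, integer(1)))

#' MCS-based rebalancing
#'
#' Orients the reaction so that X is the side with more carbons (ties broken
#' by total atom count, then reactants), aligns X against Y with the
#' five-configuration ensemble, saturates unresolved cuts with expand rules,
#' merges fragments into the missing compound(s) Z, and adds Z to the Y
#' side. The result is carbon-balanced by construction but not necessarily
#' balanced; any residual non-carbon imbalance is delegated to the
#' rule-based branch. All failure modes (no boundary found, too many
#' compounds or boundaries, unresolved cuts, post-merge carbon imbalance)
#' return an unsolved outcome with a reason code, never an error.
#'
#' @param reaction a [Reaction-class].
#' @param library rule library for the residual-imbalance delegation.
#' @param maxCompounds reject reactions with more molecules than this
#'   (default 6).
#' @param maxBoundaries reject fragment sets where any fragment carries more
#'   boundaries than this (default 2).
#' @param nodeBudget MCS search budget per component, see [findMCS()].
#' @param applyPostprocess,applyRedoxRefine passed to the rule-based
#'   delegation.
#' @return a [RebalanceOutcome-class] with method `"mcs"` on success.
#' @examples
#' out <- mcsRebalance(parseReaction("CC(=O)OCC>>CCO"))
#' reactionSmiles(out@outputReaction, sorted = TRUE)
#' @export
mcsRebalance <- function(reaction, library = defaultRuleLibrary(),
                         maxCompounds = 6L, maxBoundaries = 2L,
                         nodeBudget = 2e5, applyPostprocess = TRUE,
                         applyRedoxRefine = TRUE) {
  if (isBalanced(reaction)) {
    return(.makeOutcome(reaction, reaction, TRUE, "already-balanced",
                        .newImputation(), reason = "solved-trivially"))
  }
  nMols <- length(reaction@reactants) + length(reaction@products)
  if (nMols > maxCompounds) {
    return(.unsolved(reaction, "too-many-compounds"))
  }
  cr <- .sideCarbons(reaction@reactants)
  cp <- .sideCarbons(reaction@products)
  xIsReactants <- if (cr != cp) cr > cp else {
    ar <- .sideAtoms(reaction@reactants); ap <- .sideAtoms(reaction@products)
    if (ar != ap) ar > ap else TRUE
  }
  xMols <- if (xIsReactants) reaction@reactants else reaction@products
  yMols <- if (xIsReactants) reaction@products else reaction@reactants
  ySide <- if (xIsReactants) "products" else "reactants"

  win <- ensembleMCS(xMols, yMols, nodeBudget)
  if (is.null(win)) return(.unsolved(reaction, "mcs-timeout"))
  # attempt the expand/merge pipeline on the ranked ensemble candidates; the
  # first fragment set that completes (and stays carbon-balanced) wins
  reason <- "no-boundary"
  for (fs in attr(win, "rankedCandidates")) {
    diag <- list(fragmentCount = length(fs@fragments),
                 numBoundary = fs@diagnostics$numBoundary,
                 winningConfig = fs@diagnostics$configIndex,
                 perConfig = win@diagnostics$perConfig,
                 xIsReactants = xIsReactants)
    if (!length(fs@fragments)) {
      # X and Y fully align; any leftover imbalance is non-carbon only
      out <- ruleBasedRebalance(reaction, library,
                                applyPostprocess = applyPostprocess,
                                applyRedoxRefine = applyRedoxRefine)
      out@diagnostics <- c(out@diagnostics, diag)
      return(out)
    }
    if (fs@diagnostics$numBoundary == 0L) {
      reason <- "no-boundary"
      next
    }
    if (any(vapply(fs@fragments, .fragmentBoundaries, integer(1)) >
            maxBoundaries)) {
      reason <- "too-many-boundaries"
      next
    }
    fs <- applyExpandRules(fs, reaction)
    if (attr(fs, "unresolved") > 0L) {
      reason <- "unresolved-boundary"
      next
    }
    merged <- applyMergeRules(fs)
    if (!isTRUE(merged$success)) {
      reason <- paste0("merge-failure:", merged$reason)
      next
    }
    z <- merged$molecules
    intermediate <- .addMolecules(reaction, z, ySide)
    if (!isCarbonBalanced(intermediate)) {
      reason <- "carbon-imbalance-after-merge"
      next
    }
    diag$mergedBonds <- merged$mergedBonds
    imputation <- .newImputation()
    imputation[[ySide]] <- z
    if (isBalanced(intermediate)) {
      return(.makeOutcome(reaction, intermediate, TRUE, "mcs", imputation,
                          diagnostics = diag))
    }
    resid <- ruleBasedRebalance(intermediate, library,
                                applyPostprocess = applyPostprocess,
                                applyRedoxRefine = applyRedoxRefine)
    if (!resid@solved) {
      reason <- paste0("residual-imbalance:", resid@reason)
      next
    }
    imputation$reactants <- c(imputation$reactants, resid@imputedReactants)
    imputation$products <- c(imputation$products, resid@imputedProducts)
    return(.makeOutcome(reaction, resid@outputReaction, TRUE, "mcs",
                        imputation, rules = resid@rulesApplied,
                        diagnostics = diag))
  }
  .unsolved(reaction, reason)
}
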