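# Fixture generation, artificial unbalancing and evaluation metrics.

# Balanced reaction templates over small alkyl substituents. Each template
# returns a ground-truth balanced reaction SMILES; non-carbon co-products
# are written in the dissociated ion convention matching the ion-centric
# rule library (e.g. eliminated HBr as [H+].[Br-]).
.fixtureTemplates <- list(
  esterification = function(r1, r2)
    paste0(r1, "C(=O)O.", r2, "O>>", r1, "C(=O)O", r2, ".O"),
  ester_hydrolysis = function(r1, r2)
    paste0(r1, "C(=O)O", r2, ".O>>", r1, "C(=O)O.", r2, "O"),
  amide_coupling = function(r1, r2)
    paste0(r1, "C(=O)O.", r2, "N>>", r1, "C(=O)N", r2, ".O"),
  halide_elimination = function(r1, r2)
    paste0(r1, "CC(Br)", r2, ">>", r1, "C=C", r2, ".[H+].[Br-]"),
  alcohol_oxidation = function(r1, r2)
    paste0(r1, "C(O)", r2, ".[O]>>", r1, "C(=O)", r2, ".O"),
  grignard_addition = function(r1, r2)
    paste0(r1, "C(=O)", r2, ".C[Mg]Br>>", r1, "C(C)(O[Mg]Br)", r2)
)

# Linear alkyls only: a substituent written as a SMILES prefix (R + "O")
# attaches at its last atom, while as a suffix ("O" + R) it attaches at its
# first; linear chains are the substituents for which both orientations
# denote the same structure, keeping the templates self-consistent.
.fixtureSubstituents <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC")

#' Generate a deterministic set of balanced fixture reactions
#'
#' Instantiates balanced reaction templates (esterification, ester
#' hydrolysis, amide coupling, halide elimination, alcohol oxidation,
#' Grignard-like addition) over enumerated small alkyl substituents. Every
#' emitted reaction is verified balanced by composition arithmetic before it
#' is returned; generation is deterministic under the seed.
#'
#' @param n number of reactions.
#' @param seed integer seed.
#' @return named list of balanced [Reaction-class] objects (names encode the
#'   template family).
#' @examples
#' fx <- generateFixtureSet(5, seed = 42)
#' names(fx)
#' @export
generateFixtureSet <- function(n, seed = 42L) {
  stopifnot(n >= 1)
  set.seed(seed)
  fams <- names(.fixtureTemplates)
  subs <- .fixtureSubstituents
  out <- vector("list", n)
  nm <- character(n)
  for (i in seq_len(n)) {
    fam <- fams[(i - 1L) %% length(fams) + 1L]
    r1 <- sample(subs, 1)
    r2 <- sample(subs, 1)
    smi <- .fixtureTemplates[[fam]](r1, r2)
    rxn <- parseReaction(smi)
    if (!isBalanced(rxn))
      stop("fixture generator produced an unbalanced reaction: ", smi)
    out[[i]] <- rxn
    nm[i] <- paste0(fam, "_", i)
  }
  stats::setNames(out, nm)
}

.isCarbonFree <- function(m) .molCarbons(m) == 0L

#' Artificially unbalance a reaction
#'
#' Mimics the benchmark perturbation for balanced reference data: in
#' reactions with exactly two products the smaller product (fewest atoms
#' including hydrogens; ties by fewest heavy atoms, then lexicographic
#' canonical SMILES) is removed, and every distinct non-carbon compound is
#' removed exactly once per side. A side is never emptied completely. The
#' removal record is returned as ground truth.
#'
#' @param reaction a balanced [Reaction-class].
#' @param removeSmallerProduct apply the two-product removal step.
#' @param removeNonCarbon apply the non-carbon removal step.
#' @return list with `perturbed` ([Reaction-class]), `removedReactants` and
#'   `removedProducts` (molecule lists; empty when nothing was removable).
#' @export
unbalanceReaction <- function(reaction, removeSmallerProduct = TRUE,
                              removeNonCarbon = TRUE) {
  removedR <- list()
  removedP <- list()
  rxn <- reaction
  if (removeSmallerProduct && length(rxn@products) == 2L) {
    atoms <- vapply(rxn@products, .molAtoms, integer(1))
    heavy <- vapply(rxn@products, .molHeavyAtoms, integer(1))
    smi <- vapply(rxn@products, smiles, character(1))
    pick <- order(atoms, heavy, smi)[1]
    removedP <- c(removedP, rxn@products[pick])
    rxn@products <- rxn@products[-pick]
  }
  if (removeNonCarbon) {
    for (side in c("reactants", "products")) {
      mols <- methods::slot(rxn, side)
      targets <- unique(vapply(Filter(.isCarbonFree, mols), smiles,
                               character(1)))
      for (s in targets) {
        if (length(mols) <= 1L) break
        i <- which(vapply(mols, smiles, character(1)) == s)[1]
        rec <- mols[[i]]
        mols <- mols[-i]
        if (side == "reactants") removedR <- c(removedR, list(rec))
        else removedP <- c(removedP, list(rec))
      }
      methods::slot(rxn, side) <- mols
    }
  }
  list(perturbed = rxn, removedReactants = removedR,
       removedProducts = removedP)
}

#' Success rate and accuracy from raw counts
#'
#' Success rate is the fraction of (unbalanced) input instances for which a
#' balanced reaction was proposed; accuracy is the fraction of proposed
#' solutions that are correct. Both are reported as percentages rounded to
#' two decimals; accuracy is `NA` when nothing was solved.
#'
#' @param input,solved,correct non-negative counts.
#' @return list with `input`, `solved`, `correct`, `successRate`,
#'   `accuracy`.
#' @examples
#' successAccuracy(83366, 78692, 77088)  # 94.39 / 97.96
#' @export
successAccuracy <- function(input, solved, correct) {
  list(input = input, solved = solved, correct = correct,
       successRate = if (input > 0) round(100 * solved / input, 2)
                     else NA_real_,
       accuracy = if (solved > 0) round(100 * correct / solved, 2)
                  else NA_real_)
}

#' Evaluate a set of closed-loop records
#'
#' @param records list of lists (or data.frame) with logical elements
#'   `solved` and `correct` per instance.
#' @return metrics as in [successAccuracy()].
#' @export
evaluateOutcomes <- function(records) {
  if (is.data.frame(records)) {
    solved <- records$solved; correct <- records$correct
  } else {
    solved <- vapply(records, `[[`, logical(1), "solved")
    correct <- vapply(records, `[[`, logical(1), "correct")
  }
  successAccuracy(length(solved), sum(solved), sum(correct & solved))
}

#' Closed-loop benchmark on generated fixtures
#'
#' Generates balanced fixtures, perturbs each with [unbalanceReaction()],
#' rebalances the perturbation and scores the prediction against the ground
#' truth by exact canonical-match equality.
#'
#' @param n,seed forwarded to [generateFixtureSet()].
#' @param removeSmallerProduct,removeNonCarbon forwarded to
#'   [unbalanceReaction()].
#' @param ... forwarded to [rebalance()].
#' @return list with per-instance `records` (ground truth, perturbed input,
#'   prediction, solved, correct, method) and aggregate `metrics`.
#' @export
closedLoopBenchmark <- function(n = 500, seed = 42L,
                                removeSmallerProduct = TRUE,
                                removeNonCarbon = TRUE, ...) {
  fixtures <- generateFixtureSet(n, seed)
  records <- vector("list", length(fixtures))
  for (i in seq_along(fixtures)) {
    gt <- fixtures[[i]]
    pert <- unbalanceReaction(gt, removeSmallerProduct, removeNonCarbon)
    changed <- length(pert$removedReactants) + length(pert$removedProducts) > 0
    out <- rebalance(pert$perturbed, ...)
    records[[i]] <- list(
      name = names(fixtures)[i],
      groundTruth = gt, perturbed = pert$perturbed, outcome = out,
      perturbedAtAll = changed,
      solved = out@solved,
      correct = out@solved && sameReaction(out@outputReaction, gt),
      method = out@method)
  }
  list(records = records, metrics = evaluateOutcomes(records))
}
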