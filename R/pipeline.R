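# Orchestration: route each reaction to the rule-based or MCS-based branch
# and expose batch processing.

#' Rebalance a single reaction
#'
#' Routing: already-balanced inputs short-circuit; the rule-based method is
#' applied when the reaction is carbon-balanced (including a per-side
#' attempt for carbon-balanced both-sides instances); the MCS-based method
#' is used when the reaction has a carbon imbalance or the rule-based method
#' fails. Optionally scores MCS outcomes with a confidence model and turns
#' below-threshold solutions into unsolved outcomes.
#'
#' @param x a [Reaction-class] or a reaction SMILES string.
#' @param library a [RuleLibrary-class].
#' @param confidenceModel optional [ConfidenceModel-class] used to score MCS
#'   outcomes.
#' @param threshold optional confidence threshold; scored MCS outcomes below
#'   it are returned unsolved (reason `"low-confidence"`).
#' @param applyPostprocess,applyRedoxRefine toggles forwarded to the
#'   rule-based branch.
#' @param ... forwarded to [mcsRebalance()].
#' @return a [RebalanceOutcome-class].
#' @examples
#' out <- rebalance("CC(=O)O.CCO>>CC(=O)OCC")
#' reactionSmiles(out@outputReaction)
#' @export
rebalance <- function(x, library = defaultRuleLibrary(),
                      confidenceModel = NULL, threshold = NULL,
                      applyPostprocess = TRUE, applyRedoxRefine = TRUE, ...) {
  reaction <- if (methods::is(x, "Reaction")) x else parseReaction(x)
  dd <- reactionDiff(reaction)
  if (dd@balanceClass == "balanced") {
    return(.makeOutcome(reaction, reaction, TRUE, "already-balanced",
                        .newImputation(), reason = "solved-trivially"))
  }
  out <- NULL
  if (isCarbonBalanced(reaction)) {
    out <- ruleBasedRebalance(reaction, library,
                              applyPostprocess = applyPostprocess,
                              applyRedoxRefine = applyRedoxRefine)
    if (!out@solved) out <- NULL
  }
  if (is.null(out)) {
    out <- mcsRebalance(reaction, library,
                        applyPostprocess = applyPostprocess,
                        applyRedoxRefine = applyRedoxRefine, ...)
  }
  if (out@solved && out@method == "mcs" && !is.null(confidenceModel)) {
    out@confidence <- as.numeric(
      scoreConfidence(confidenceModel, extractFeatures(out)))
    if (!is.null(threshold) && out@confidence < threshold) {
      low <- .unsolved(reaction, "low-confidence")
      low@confidence <- out@confidence
      out <- low
    }
  }
  out
}

.moleculeListString <- function(mols)
  paste(vapply(mols, smiles, character(1)), collapse = ".")

#' Batch rebalancing of a reaction file
#'
#' Reads reactions from a SMILES file (one reaction per line) or a CSV with
#' a reaction column, rebalances each, and writes one outcome row per
#' reaction. Malformed rows are skipped and logged; row order is preserved.
#'
#' @param inputPath input file (`.csv` with `column`, otherwise plain
#'   SMILES lines).
#' @param outputPath output CSV path (columns: input, output, solved,
#'   method, confidence, imputed_reactants, imputed_products, reason), or
#'   `NULL` to skip writing.
#' @param referencePath optional file of ground-truth reaction SMILES
#'   (aligned with the input rows); enables accuracy scoring.
#' @param column reaction column name for CSV input.
#' @param ... forwarded to [rebalance()].
#' @return invisibly, a list with the outcome table (`results`), the outcome
#'   objects (`outcomes`) and a `summary` (counts, success rate, accuracy).
#' @export
runBatch <- function(inputPath, outputPath = NULL, referencePath = NULL,
                     column = "reaction", ...) {
  lines <- if (grepl("\\.csv$", inputPath, ignore.case = TRUE)) {
    tab <- utils::read.csv(inputPath, stringsAsFactors = FALSE)
    if (!column %in% names(tab))
      stop("column '", column, "' not found in ", inputPath)
    tab[[column]]
  } else {
    l <- readLines(inputPath)
    l[nzchar(trimws(l))]
  }
  refs <- if (!is.null(referencePath)) readLines(referencePath) else NULL
  rows <- list()
  outcomes <- list()
  skipped <- 0L
  correct <- 0L
  nRef <- 0L
  for (i in seq_along(lines)) {
    out <- tryCatch(rebalance(lines[i], ...), error = function(e) e)
    if (inherits(out, "error")) {
      skipped <- skipped + 1L
      message("skipping row ", i, ": ", conditionMessage(out))
      next
    }
    isCorrect <- NA
    if (!is.null(refs) && i <= length(refs) && nzchar(trimws(refs[i]))) {
      nRef <- nRef + 1L
      isCorrect <- out@solved &&
        sameReaction(out@outputReaction, parseReaction(refs[i]))
      if (isTRUE(isCorrect)) correct <- correct + 1L
    }
    outcomes[[length(outcomes) + 1L]] <- out
    rows[[length(rows) + 1L]] <- data.frame(
      input = lines[i],
      output = reactionSmiles(out@outputReaction),
      solved = out@solved,
      method = out@method,
      confidence = out@confidence,
      imputed_reactants = .moleculeListString(out@imputedReactants),
      imputed_products = .moleculeListString(out@imputedProducts),
      reason = out@reason,
      correct = isCorrect,
      stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (!is.null(outputPath)) utils::write.csv(results, outputPath,
                                             row.names = FALSE)
  nSolved <- if (nrow(results)) sum(results$solved) else 0L
  summary <- list(
    input = length(lines), processed = nrow(results), skipped = skipped,
    solved = nSolved,
    successRate = if (nrow(results)) round(100 * nSolved / nrow(results), 2)
                  else NA_real_,
    correct = if (!is.null(refs)) correct else NA_integer_,
    accuracy = if (!is.null(refs) && nSolved > 0)
      round(100 * correct / nSolved, 2) else NA_real_)
  invisible(list(results = results, outcomes = outcomes, summary = summary))
}

setMethod("show", "RebalanceOutcome", function(object) {
  cat(sprintf("RebalanceOutcome [%s] %s\n", object@method,
              if (object@solved) "solved" else
                paste0("unsolved (", object@reason, ")")))
  cat("  in:  ", reactionSmiles(object@inputReaction), "\n")
  cat("  out: ", reactionSmiles(object@outputReaction), "\n")
  if (length(object@imputedReactants))
    cat("  + reactants:", .moleculeListString(object@imputedReactants), "\n")
  if (length(object@imputedProducts))
    cat("  + products: ", .moleculeListString(object@imputedProducts), "\n")
  if (!is.na(object@confidence))
    cat(sprintf("  confidence: %.3f\n", object@confidence))
})
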