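#!/usr/bin/env Rscript
# Command-line front end over the RxnRebalance package.
#
#   Rscript scripts/rebalance.R run  --input FILE --output FILE
#       [--column reaction] [--rules FILE] [--threshold 0.5]
#       [--no-postprocess] [--no-redox-refine] [--seed 42]
#   Rscript scripts/rebalance.R eval --pred FILE --ref FILE

suppressPackageStartupMessages({
  library(optparse)
  library(RxnRebalance)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("run", "eval")) {
  stop("usage: rebalance.R {run|eval} [options]; see script header")
}
mode <- args[1]

if (mode == "run") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--input", type = "character"),
    make_option("--output", type = "character"),
    make_option("--column", type = "character", default = "reaction"),
    make_option("--rules", type = "character", default = NULL),
    make_option("--threshold", type = "double", default = NULL),
    make_option("--no-postprocess", action = "store_true", default = FALSE,
                dest = "noPostprocess"),
    make_option("--no-redox-refine", action = "store_true", default = FALSE,
                dest = "noRedox"),
    make_option("--seed", type = "integer", default = 42L)
  )), args = args[-1])
  if (is.null(opts$input)) stop("--input is required")
  set.seed(opts$seed)
  library <- if (is.null(opts$rules)) defaultRuleLibrary()
             else readRuleLibrary(opts$rules)
  res <- runBatch(opts$input, opts$output, column = opts$column,
                  library = library,
                  applyPostprocess = !opts$noPostprocess,
                  applyRedoxRefine = !opts$noRedox)
  s <- res$summary
  message(sprintf("processed %d reaction(s): %d solved (%.2f%%), %d skipped",
                  s$processed, s$solved, s$successRate, s$skipped))
} else {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--pred", type = "character"),
    make_option("--ref", type = "character")
  )), args = args[-1])
  if (is.null(opts$pred) || is.null(opts$ref))
    stop("--pred and --ref are required")
  preds <- readLines(opts$pred)
  refs <- readLines(opts$ref)
  if (length(preds) != length(refs))
    stop("prediction and reference files differ in length")
  solved <- nzchar(trimws(preds))
  correct <- logical(length(preds))
  for (i in which(solved)) {
    correct[i] <- tryCatch(
      sameReaction(parseReaction(preds[i]), parseReaction(refs[i])),
      error = function(e) FALSE)
  }
  m <- successAccuracy(length(preds), sum(solved), sum(correct))
  message(sprintf("input %d | solved %d | correct %d | success %.2f%% | accuracy %s",
                  m$input, m$solved, m$correct, m$successRate,
                  if (is.na(m$accuracy)) "NA"
                  else sprintf("%.2f%%", m$accuracy)))
}
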