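# The ion-centric imputation rule library.

.parsePatternString <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(trimws(parts), ":", fixed = TRUE)
  v <- stats::setNames(
    vapply(kv, function(x) as.integer(x[2]), integer(1)),
    vapply(kv, function(x) x[1], character(1))
  )
  compositionDict(v)
}

# The free electron has no SMILES representation; it is modelled as a
# zero-atom molecule with charge -1 under the package-level token "[e-]".
.electronMolecule <- function() {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  igraph::V(g)$element <- character(0)
  igraph::V(g)$charge <- integer(0)
  igraph::V(g)$hcount <- integer(0)
  methods::new("Molecule", smiles = "[e-]", graph = g, formalCharge = -1L)
}

#' Create an imputation rule
#'
#' @param name short identifier.
#' @param pattern a [CompositionDict-class] (or pattern string like
#'   `"O:1,H:1,Q:-1"`) subtracted from the difference dictionary.
#' @param smiles SMILES of the emitted compound (`"[e-]"` for the electron).
#' @param ion whether the compound is an ion.
#' @return an [ImputationRule-class].
#' @export
imputationRule <- function(name, pattern, smiles, ion = NA) {
  if (is.character(pattern)) pattern <- .parsePatternString(pattern)
  compound <- if (identical(smiles, "[e-]")) .electronMolecule()
              else parseMolecule(smiles)
  if (is.na(ion)) ion <- compound@formalCharge != 0L
  comp <- composition(compound)
  pv <- .cdAsVector(pattern)
  cv <- .cdAsVector(comp)
  if (!identical(pv[sort(names(pv))], cv[sort(names(cv))]))
    stop("rule '", name, "': compound composition does not match pattern")
  methods::new("ImputationRule", pattern = pattern, compound = compound,
               isIon = as.logical(ion), size = as.integer(cdAtoms(pattern)),
               name = name)
}

#' Read a rule library from a TSV file
#'
#' The file has columns `name`, `pattern` (comma-separated `element:count`
#' entries, `Q` for charge), `smiles` and `ion`. Rules are re-sorted into
#' non-increasing pattern-size order on load.
#'
#' @param path file path.
#' @return a [RuleLibrary-class].
#' @export
readRuleLibrary <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  rules <- lapply(seq_len(nrow(tab)), function(i) {
    imputationRule(tab$name[i], tab$pattern[i], tab$smiles[i],
                   as.logical(tab$ion[i]))
  })
  ruleLibrary(rules)
}

#' Assemble a rule library
#'
#' @param rules list of [ImputationRule-class] objects; sorted into
#'   non-increasing pattern-size order (stable within equal sizes).
#' @return a [RuleLibrary-class].
#' @export
ruleLibrary <- function(rules) {
  sizes <- vapply(rules, function(r) r@size, integer(1))
  methods::new("RuleLibrary", rules = rules[order(-sizes)])
}

.defaultLibraryCache <- new.env(parent = emptyenv())

#' The default ion-centric rule library
#'
#' Small species and elementary ions covering the common non-carbon
#' imputations: water, ammonia/ammonium, hydroxide, proton, molecular and
#' atomic oxygen, molecular hydrogen, halogen diatomics and halide anions,
#' alkali/alkaline-earth counter-ions, and the free-electron rule. Hydrogen
#' halides are deliberately absent: the library explains HX as H+ plus X-,
#' keeping it compact and making ranked solutions ion-first.
#'
#' @return a [RuleLibrary-class].
#' @export
defaultRuleLibrary <- function() {
  hit <- get0("lib", envir = .defaultLibraryCache)
  if (!is.null(hit)) return(hit)
  path <- system.file("extdata", "imputation_rules.tsv",
                      package = "RxnRebalance", mustWork = TRUE)
  lib <- readRuleLibrary(path)
  assign("lib", lib, envir = .defaultLibraryCache)
  lib
}

setMethod("show", "RuleLibrary", function(object) {
  cat(sprintf("RuleLibrary with %d rules:\n", length(object@rules)))
  for (r in object@rules) {
    v <- .cdAsVector(r@pattern)
    cat(sprintf("  %-12s {%s} -> %s%s\n", r@name,
                paste(sprintf("%s:%d", names(v), v), collapse = ","),
                r@compound@smiles, if (r@isIon) "  (ion)" else ""))
  }
})
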