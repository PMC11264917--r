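# Reaction SMILES parsing and serialization.

#' Parse a reaction SMILES
#'
#' Accepts both the two-segment `reactants>>products` and the three-segment
#' `reactants>agents>products` dialects. Dot-separated fragments become
#' multiset members; the middle segment, if any, becomes the agent list,
#' which is carried through unchanged and excluded from all balance
#' arithmetic.
#'
#' @param text a single reaction SMILES.
#' @return a [Reaction-class].
#' @examples
#' rxn <- parseReaction("CC(=O)O.CCO>>CC(=O)OCC")
#' length(reactants(rxn))  # 2
#' @export
parseReaction <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, ">", fixed = TRUE)[[1]]
  if (length(parts) == 2L) parts <- c(parts[1], "", parts[2])
  if (length(parts) != 3L)
    stop("reaction SMILES must contain '>>' or two '>' separators: '",
         text, "'")
  parseSide <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(list())
    lapply(strsplit(s, ".", fixed = TRUE)[[1]], parseMolecule)
  }
  reactants <- parseSide(parts[1])
  agents <- parseSide(parts[2])
  products <- parseSide(parts[3])
  if (length(reactants) == 0L || length(products) == 0L)
    stop("empty reactant or product side in '", text, "'")
  methods::new("Reaction", reactants = reactants, products = products,
               agents = agents, sourceText = text)
}

#' @describeIn parseReaction reactant molecule list.
#' @param x a Reaction.
#' @export
reactants <- function(x) x@reactants

#' @describeIn parseReaction product molecule list.
#' @export
products <- function(x) x@products

#' @describeIn parseReaction agent molecule list.
#' @export
agents <- function(x) x@agents

#' Serialize a Reaction back to reaction SMILES
#'
#' Molecules within each side are emitted in canonical form. With
#' `sorted = TRUE` molecules are additionally sorted lexicographically, which
#' gives a canonical form of the whole reaction used for equality tests.
#'
#' @param x a [Reaction-class].
#' @param sorted sort molecules within each side.
#' @return a single reaction SMILES string (three-segment form only when
#'   agents are present).
#' @export
reactionSmiles <- function(x, sorted = FALSE) {
  side <- function(mols) {
    s <- vapply(mols, smiles, character(1))
    if (sorted) s <- sort(s)
    paste(s, collapse = ".")
  }
  if (length(x@agents)) {
    paste0(side(x@reactants), ">", side(x@agents), ">", side(x@products))
  } else {
    paste0(side(x@reactants), ">>", side(x@products))
  }
}

#' Canonical equality of two reactions
#'
#' Two reactions are considered equal when the canonical-SMILES multisets of
#' their reactant and product sides agree (agents ignored). This is the
#' exact-match criterion used for accuracy scoring.
#'
#' @param a,b [Reaction-class] objects.
#' @return logical.
#' @export
sameReaction <- function(a, b) {
  ms <- function(mols) sort(vapply(mols, smiles, character(1)))
  identical(ms(a@reactants), ms(b@reactants)) &&
    identical(ms(a@products), ms(b@products))
}

# Non-mutating helpers used by the engines: return a new Reaction with
# molecules added to / removed from one side.
.addMolecules <- function(reaction, molecules, side) {
  stopifnot(side %in% c("reactants", "products"))
  methods::slot(reaction, side) <- c(methods::slot(reaction, side), molecules)
  reaction
}

.removeMoleculeOnce <- function(mols, canSmiles) {
  i <- which(vapply(mols, smiles, character(1)) == canSmiles)
  if (!length(i)) return(mols)
  mols[-i[1]]
}

setMethod("show", "Reaction", function(object) {
  cat(sprintf("Reaction: %d reactant(s), %d product(s), %d agent(s)\n",
              length(object@reactants), length(object@products),
              length(object@agents)))
  cat(" ", reactionSmiles(object), "\n")
})
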