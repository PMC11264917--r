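# Molecule construction and accessors.

#' Parse a SMILES string into a Molecule
#'
#' Hydrogens are completed explicitly during parsing and collapsed into
#' per-atom hydrogen counts, so compositions are computed on the
#' hydrogen-complete molecule even when the input SMILES leaves hydrogens
#' implicit. Formal charges are taken per atom.
#'
#' @param smiles a single SMILES string (one molecule; no dots).
#' @return a [Molecule-class].
#' @examples
#' m <- parseMolecule("[OH-]")
#' composition(m)  # {H:1, O:1, Q:-1}
#' @export
parseMolecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  key <- smiles
  hit <- get0(key, envir = .molCache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  can <- canonicalSmiles(smiles)
  if (is.na(can)) stop("unparseable molecule fragment: '", smiles, "'")
  g <- .smilesToGraph(smiles)
  if (is.null(g)) stop("unparseable molecule fragment: '", smiles, "'")
  m <- methods::new("Molecule", smiles = can, graph = g,
                    formalCharge = as.integer(sum(igraph::V(g)$charge)))
  assign(key, m, envir = .molCache)
  if (can != key) assign(can, m, envir = .molCache)
  m
}

#' @describeIn parseMolecule canonical SMILES accessor.
#' @param x a Molecule.
#' @export
smiles <- function(x) x@smiles

#' @describeIn parseMolecule formal charge accessor.
#' @export
formalCharge <- function(x) x@formalCharge

#' @describeIn parseMolecule heavy-atom igraph accessor.
#' @export
moleculeGraph <- function(x) x@graph

# carbon count helper
.molCarbons <- function(m) sum(igraph::V(m@graph)$element == "C")

# total atom count including hydrogens (used by the unbalancing procedure's
# "smaller product" selection)
.molAtoms <- function(m) {
  as.integer(igraph::vcount(m@graph) + sum(igraph::V(m@graph)$hcount))
}

.molHeavyAtoms <- function(m) {
  as.integer(sum(igraph::V(m@graph)$element != "H"))
}

setMethod("show", "Molecule", function(object) {
  v <- .cdAsVector(composition(object))
  cat(sprintf("Molecule %s  {%s}\n", object@smiles,
              paste(sprintf("%s:%d", names(v), v), collapse = ", ")))
})
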