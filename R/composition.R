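# Composition dictionaries and difference-dictionary arithmetic.

#' Construct a composition dictionary
#'
#' @param entries named integer vector of element counts; zero counts are
#'   dropped. A `Q` entry, if present, is folded into `charge`.
#' @param charge integer net charge.
#' @return a [CompositionDict-class].
#' @examples
#' compositionDict(c(O = 1, H = 1), charge = -1)  # hydroxide
#' @export
compositionDict <- function(entries = integer(0), charge = 0L) {
  entries <- unlist(entries)
  if (length(entries)) {
    storage.mode(entries) <- "integer"
    if ("Q" %in% names(entries)) {
      charge <- charge + entries[["Q"]]
      entries <- entries[names(entries) != "Q"]
    }
    entries <- entries[entries != 0L]
    entries <- entries[order(names(entries))]
  } else {
    entries <- stats::setNames(integer(0), character(0))
  }
  methods::new("CompositionDict", entries = entries, charge = as.integer(charge))
}

#' @describeIn compositionDict total atom count (charge excluded).
#' @param x a `CompositionDict`.
#' @export
cdAtoms <- function(x) sum(x@entries)

#' @describeIn compositionDict `TRUE` when no element entries and zero charge.
#' @export
cdIsEmpty <- function(x) length(x@entries) == 0L && x@charge == 0L

#' @describeIn compositionDict commutative, associative addition.
#' @param y a second `CompositionDict`.
#' @export
cdAdd <- function(x, y) {
  keys <- union(names(x@entries), names(y@entries))
  v <- stats::setNames(integer(length(keys)), keys)
  v[names(x@entries)] <- v[names(x@entries)] + x@entries
  v[names(y@entries)] <- v[names(y@entries)] + y@entries
  compositionDict(v, x@charge + y@charge)
}

# Named integer view (with Q) used by tests and diagnostics.
.cdAsVector <- function(x) {
  c(x@entries, stats::setNames(x@charge, "Q"))
}

setMethod("show", "CompositionDict", function(object) {
  v <- .cdAsVector(object)
  cat("{", paste(sprintf("%s:%d", names(v), v), collapse = ", "), "}\n")
})

#' Aggregate composition of molecules
#'
#' Computes the multiplicity-weighted element-wise sum over a molecule
#' multiset, counting every atom including collapsed implicit hydrogens; the
#' charge slot is the sum of formal charges. Dispatches on [Molecule-class],
#' plain lists of molecules, and [Reaction-class] (via `side`).
#'
#' @param x a Molecule, list of Molecules, or Reaction.
#' @param ... passed on; for a Reaction, `side` selects `"reactants"`
#'   (default) or `"products"` (agents never contribute).
#' @return a [CompositionDict-class].
#' @examples
#' rxn <- parseReaction("CC(=O)O.CCO>>CC(=O)OCC")
#' composition(rxn, side = "reactants")  # {C:4, H:10, O:3, Q:0}
#' @export
setGeneric("composition", function(x, ...) standardGeneric("composition"))

#' @rdname composition
#' @export
setMethod("composition", "Molecule", function(x, ...) {
  g <- x@graph
  el <- igraph::V(g)$element
  tab <- table(el)
  v <- stats::setNames(as.integer(tab), names(tab))
  h <- sum(igraph::V(g)$hcount)
  if (h > 0) {
    if ("H" %in% names(v)) v[["H"]] <- v[["H"]] + h else v <- c(v, H = h)
  }
  compositionDict(v, x@formalCharge)
})

#' @rdname composition
#' @export
setMethod("composition", "list", function(x, ...) {
  out <- compositionDict()
  for (m in x) out <- cdAdd(out, composition(m))
  out
})

#' @rdname composition
#' @param side `"reactants"` or `"products"`.
#' @export
setMethod("composition", "Reaction", function(x, side = "reactants", ...) {
  side <- match.arg(side, c("reactants", "products"))
  composition(methods::slot(x, side))
})

#' Difference dictionaries and the four-case balance classification
#'
#' Computes the reactant-excess dictionary (delta minus) and product-excess
#' dictionary (delta plus) from two aggregated compositions. When exactly one
#' side has element entries, the whole charge difference is folded into that
#' side; when neither side has element entries but charges differ, the charge
#' difference is folded into delta minus by convention.
#'
#' @param dMinus,dPlus aggregated [CompositionDict-class]s of the reactant and
#'   product side.
#' @return a [DiffDictionaries-class].
#' @examples
#' dm <- compositionDict(c(C = 4, H = 10, O = 3))
#' dp <- compositionDict(c(C = 4, H = 8, O = 2))
#' diffDictionaries(dm, dp)  # delta minus {O:1, H:2}, reactant_dominated
#' @export
diffDictionaries <- function(dMinus, dPlus) {
  keys <- union(names(dMinus@entries), names(dPlus@entries))
  a <- stats::setNames(integer(length(keys)), keys)
  b <- a
  a[names(dMinus@entries)] <- dMinus@entries
  b[names(dPlus@entries)] <- dPlus@entries
  d <- a - b
  minusEntries <- d[d > 0L]
  plusEntries <- -d[d < 0L]
  qd <- dMinus@charge - dPlus@charge
  qMinus <- 0L
  qPlus <- 0L
  if (qd != 0L) {
    if (length(minusEntries) == 0L && length(plusEntries) > 0L) {
      qPlus <- -qd
    } else {
      qMinus <- qd
    }
  }
  dm <- compositionDict(minusEntries, qMinus)
  dp <- compositionDict(plusEntries, qPlus)
  cls <- if (cdIsEmpty(dm) && cdIsEmpty(dp)) "balanced"
    else if (!cdIsEmpty(dm) && cdIsEmpty(dp)) "reactant_dominated"
    else if (cdIsEmpty(dm) && !cdIsEmpty(dp)) "product_dominated"
    else "both_sides"
  methods::new("DiffDictionaries", deltaMinus = dm, deltaPlus = dp,
               balanceClass = cls)
}

#' @describeIn diffDictionaries classification for a whole reaction.
#' @param reaction a [Reaction-class].
#' @export
reactionDiff <- function(reaction) {
  diffDictionaries(composition(reaction, side = "reactants"),
                   composition(reaction, side = "products"))
}

#' Carbon balance check
#'
#' @param reaction a [Reaction-class].
#' @return `TRUE` iff the total reactant carbon count equals the total product
#'   carbon count.
#' @examples
#' isCarbonBalanced(parseReaction("CC(=O)O.CCO>>CC(=O)OCC"))  # TRUE
#' @export
isCarbonBalanced <- function(reaction) {
  nc <- function(side) {
    e <- composition(reaction, side = side)@entries
    if ("C" %in% names(e)) e[["C"]] else 0L
  }
  nc("reactants") == nc("products")
}

#' Stoichiometric balance check
#'
#' @param reaction a [Reaction-class].
#' @return `TRUE` iff per-element atom counts and total charge agree between
#'   the two sides.
#' @export
isBalanced <- function(reaction) {
  reactionDiff(reaction)@balanceClass == "balanced"
}
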