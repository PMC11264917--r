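# Bridge to OpenBabel (via ChemmineOB/ChemmineR) for SMILES parsing,
# implicit-hydrogen completion and canonical SMILES writing. All molecular
# graphs in the package are igraph objects over heavy atoms with vertex
# attributes `element`, `charge`, `hcount` and edge attribute `order`;
# hydrogen atoms survive as vertices only when they cannot be collapsed onto
# a heavy neighbour ([H][H], [H+], bare [H]).

.molCache <- new.env(parent = emptyenv())

# MDL old-style charge codes (atom block field); OpenBabel writes these
# consistently alongside M CHG lines, which ChemmineR does not retain.
.chargeFromCode <- function(code) {
  map <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  out <- map[code + 1L]
  out[is.na(out)] <- 0L
  out
}

.obConvert <- function(from, to, source, addH = FALSE) {
  opts <- if (addH) data.frame(names = c("h", "gen2D"), args = c("", ""))
          else data.frame(names = "gen2D", args = "")
  tryCatch(
    ChemmineOB::convertFormat(from, to, source, options = opts),
    error = function(e) ""
  )
}

#' Canonicalize a SMILES string
#'
#' Applies the package's single fixed canonical SMILES writer (OpenBabel's
#' `can` format). All equality comparisons between predicted and reference
#' molecules use this writer, so predictions and references are always
#' canonicalized identically.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` for unparseable input.
#' @examples
#' canonicalSmiles("OCC")  # "CCO"
#' @export
canonicalSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- .obConvert("SMI", "CAN", s)
    out <- sub("[ \t].*$", "", sub("\n.*$", "", out))
    out <- trimws(out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Parse a V2000 molblock (as written by OpenBabel) into an igraph. A small
# fixed-width reader is used here because the molecules this package deals
# in include single-atom, zero-bond species (elementary ions such as [Br-]),
# which ChemmineR's SDF container rejects as invalid.
.molblockToGraph <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  nAtoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nBonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(nAtoms) || nAtoms < 1L) return(NULL)
  atomLines <- lines[4L + seq_len(nAtoms)]
  element <- trimws(substr(atomLines, 32, 34))
  chargeCode <- suppressWarnings(as.integer(substr(atomLines, 37, 39)))
  chargeCode[is.na(chargeCode)] <- 0L
  charge <- .chargeFromCode(chargeCode)
  edges <- integer(0)
  order <- integer(0)
  if (!is.na(nBonds) && nBonds > 0L) {
    bondLines <- lines[4L + nAtoms + seq_len(nBonds)]
    a <- as.integer(substr(bondLines, 1, 3))
    b <- as.integer(substr(bondLines, 4, 6))
    order <- as.integer(substr(bondLines, 7, 9))
    edges <- as.vector(rbind(a, b))
  }
  # M CHG lines supersede the old-style atom-block codes
  chgLines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chgLines)) {
    charge <- integer(nAtoms)
    for (ln in chgLines) {
      vals <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                  "\\s+")[[1]])
      k <- vals[1]
      for (i in seq_len(k)) charge[vals[2 * i]] <- vals[2 * i + 1]
    }
  }
  g <- igraph::make_empty_graph(n = nAtoms, directed = FALSE)
  igraph::V(g)$element <- element
  igraph::V(g)$charge <- charge
  igraph::V(g)$hcount <- 0L
  if (length(edges)) {
    g <- igraph::add_edges(g, edges)
    igraph::E(g)$order <- order
  }
  g
}

# Parse one SMILES fragment into a heavy-atom igraph; NULL on failure.
.smilesToGraph <- function(smiles) {
  sdftxt <- .obConvert("SMI", "SDF", smiles, addH = TRUE)
  if (!nzchar(sdftxt)) return(NULL)
  g <- .molblockToGraph(sdftxt)
  if (is.null(g)) return(NULL)
  .collapseHydrogens(g)
}

# Fold neutral, singly-bonded hydrogen atoms into the `hcount` of their heavy
# neighbour. Hydrogens bonded only to hydrogens (or charged / unbonded ones)
# are kept as graph vertices.
.collapseHydrogens <- function(g) {
  el <- igraph::V(g)$element
  drop <- integer(0)
  for (v in seq_along(el)) {
    if (el[v] != "H" || igraph::V(g)$charge[v] != 0L) next
    nb <- as.integer(igraph::neighbors(g, v))
    if (length(nb) != 1L || el[nb] == "H") next
    eid <- igraph::get_edge_ids(g, c(v, nb))
    if (igraph::E(g)$order[eid] != 1L) next
    igraph::V(g)$hcount[nb] <- igraph::V(g)$hcount[nb] + 1L
    drop <- c(drop, v)
  }
  if (length(drop)) g <- igraph::delete_vertices(g, drop)
  g
}

# Serialize a heavy-atom igraph to a V2000 molblock. Hydrogen counts are left
# implicit: OpenBabel re-derives them from standard valences and the formal
# charges carried in M CHG lines. This is exact for graphs whose atoms have
# their full complement of heavy bonds (the post-merge situation).
.graphToMolblock <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  lines <- c("", "  RxnRebalance", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  el <- igraph::V(g)$element
  for (v in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, el[v]))
  }
  if (m > 0) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    ord <- igraph::E(g)$order
    for (e in seq_len(m)) {
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                ends[e, 1], ends[e, 2], ord[e]))
    }
  }
  chg <- igraph::V(g)$charge
  idx <- which(chg != 0L)
  while (length(idx)) {
    take <- idx[seq_len(min(8, length(idx)))]
    idx <- idx[-seq_len(min(8, length(idx)))]
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(take)),
                             paste0(sprintf("%4d%4d", take, chg[take]),
                                    collapse = "")))
  }
  paste(c(lines, "M  END"), collapse = "\n")
}

# Canonical SMILES for a constructed heavy-atom graph.
.graphToSmiles <- function(g) {
  out <- .obConvert("MOL", "CAN", .graphToMolblock(g))
  out <- trimws(sub("[ \t].*$", "", sub("\n.*$", "", out)))
  if (!nzchar(out)) NA_character_ else out
}
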