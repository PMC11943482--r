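#' Atom-type vocabulary and valence bookkeeping
#'
#' Atoms carry a categorical \code{atom_type} label that encodes the element
#' together with its local bonding environment, in the spirit of
#' environment-aware chemical-function atom typing. Operators match on these
#' labels, so the vocabulary is part of the package contract. Labels outside
#' the vocabulary are accepted (and preserved verbatim, e.g. when reading
#' KCF-style records) but flagged with a message.
#'
#' Hydrogens are implicit throughout: \code{implicit_h} is derived from a
#' fixed element-to-default-valence table, with aromatic bonds contributing
#' 1.5 to the used valence (so a benzene carbon keeps one implicit hydrogen
#' and a ring-fusion carbon with three aromatic bonds keeps none).
#'
#' @section Shipped vocabulary:
#' \itemize{
#'   \item Carbon: \code{C.alkyl} (sp3), \code{C.vinyl} (sp2, non-aromatic),
#'     \code{C.alkynyl}, \code{C.arom}, \code{C.carbonyl} (C=O),
#'     \code{C.carboxyl} (C=O with a single-bonded O).
#'   \item Oxygen: \code{O.hydroxyl}, \code{O.ether}, \code{O.carbonyl} (=O),
#'     \code{O.arom} (aromatic ring O).
#'   \item Nitrogen: \code{N.amine}, \code{N.imine}, \code{N.arom}.
#'   \item Sulfur: \code{S.thiol}, \code{S.ether}; phosphorus \code{P.any};
#'     halogens \code{F}, \code{Cl}, \code{Br}, \code{I}.
#' }
#'
#' @return \code{atomTypeVocabulary()} returns a character vector of the
#'   closed vocabulary labels.
#' @export
atomTypeVocabulary <- function() {
  c("C.alkyl", "C.vinyl", "C.alkynyl", "C.arom", "C.carbonyl", "C.carboxyl",
    "O.hydroxyl", "O.ether", "O.carbonyl", "O.arom",
    "N.amine", "N.imine", "N.arom",
    "S.thiol", "S.ether", "P.any",
    "F", "Cl", "Br", "I")
}

BOND_ORDERS <- c("single", "double", "triple", "aromatic")
BOND_WEIGHTS <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 5,
                     F = 1, Cl = 1, Br = 1, I = 1, B = 3, H = 1)

#' Element implied by an atom-type label
#'
#' For vocabulary labels the element is the prefix before the dot (or the
#' label itself for halogens); for unknown labels the leading element-like
#' token is used.
#'
#' @param atom_type character vector of atom-type labels.
#' @return character vector of element symbols.
#' @export
elementOf <- function(atom_type) {
  pre <- sub("\\..*$", "", atom_type)
  ifelse(pre %in% names(DEFAULT_VALENCE), pre,
         vapply(pre, function(x) {
           m <- regmatches(x, regexpr("^[A-Z][a-z]?", x))
           if (length(m)) m else "C"
         }, character(1)))
}

defaultValence <- function(element) {
  v <- DEFAULT_VALENCE[element]
  v[is.na(v)] <- 4
  unname(v)
}

bondWeight <- function(order) unname(BOND_WEIGHTS[order])

# used valence per atom given the bond table; atoms indexed by position
.usedValence <- function(atoms, bonds) {
  used <- numeric(nrow(atoms))
  if (nrow(bonds)) {
    w <- bondWeight(bonds$order)
    p1 <- match(bonds$a1, atoms$index)
    p2 <- match(bonds$a2, atoms$index)
    for (k in seq_len(nrow(bonds))) {
      used[p1[k]] <- used[p1[k]] + w[k]
      used[p2[k]] <- used[p2[k]] + w[k]
    }
  }
  used
}

# implicit hydrogens from the fixed valence table; floor() so that three
# aromatic bonds (4.5) still fit tetravalent carbon
.implicitH <- function(atoms, bonds) {
  used <- floor(.usedValence(atoms, bonds))
  val <- defaultValence(elementOf(atoms$atom_type))
  pmax(0L, as.integer(val - used + ifelse(atoms$charge > 0 &
    elementOf(atoms$atom_type) == "N", atoms$charge, -abs(atoms$charge))))
}

# TRUE per atom if the declared valence is not exceeded
.valenceOK <- function(atoms, bonds) {
  used <- floor(.usedValence(atoms, bonds))
  val <- defaultValence(elementOf(atoms$atom_type)) + ifelse(
    atoms$charge > 0 & elementOf(atoms$atom_type) == "N", atoms$charge, 0)
  used <= val
}

#' Perceive atom types from element and bonding environment
#'
#' Assigns vocabulary labels from the element plus incident bond orders and
#' neighbouring elements: aromatic bonds dominate, then multiple bonds
#' (carbonyl/carboxyl carbons distinguished by an additional single-bonded
#' oxygen), then the saturated defaults.
#'
#' @param atoms data.frame with columns \code{index}, \code{element},
#'   \code{charge}.
#' @param bonds data.frame with columns \code{a1}, \code{a2}, \code{order}.
#' @return character vector of atom-type labels, one per atom row.
#' @export
perceiveAtomTypes <- function(atoms, bonds) {
  n <- nrow(atoms)
  types <- character(n)
  inc <- lapply(seq_len(n), function(i) {
    idx <- atoms$index[i]
    sel <- bonds$a1 == idx | bonds$a2 == idx
    if (!any(sel)) return(data.frame(other = integer(), order = character()))
    other <- ifelse(bonds$a1[sel] == idx, bonds$a2[sel], bonds$a1[sel])
    data.frame(other = other, order = bonds$order[sel],
               stringsAsFactors = FALSE)
  })
  for (i in seq_len(n)) {
    el <- atoms$element[i]
    b <- inc[[i]]
    oel <- atoms$element[match(b$other, atoms$index)]
    arom <- any(b$order == "aromatic")
    types[i] <- switch(el,
      C = if (arom) "C.arom"
          else if (any(b$order == "triple")) "C.alkynyl"
          else if (any(b$order == "double" & oel == "O")) {
            if (any(b$order == "single" & oel == "O")) "C.carboxyl"
            else "C.carbonyl"
          }
          else if (any(b$order == "double")) "C.vinyl"
          else "C.alkyl",
      O = if (arom) "O.arom"
          else if (any(b$order == "double")) "O.carbonyl"
          else if (nrow(b) >= 2) "O.ether"
          else "O.hydroxyl",
      N = if (arom) "N.arom"
          else if (any(b$order %in% c("double", "triple"))) "N.imine"
          else "N.amine",
      S = if (nrow(b) >= 2) "S.ether" else "S.thiol",
      P = "P.any",
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      el)
  }
  types
}
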