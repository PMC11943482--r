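#' @import methods
NULL

#' MolecularGraph: a labelled molecular graph
#'
#' Heavy-atom molecular graph with typed atoms and ordered bonds. Hydrogens
#' are implicit (see \code{\link{atomTypeVocabulary}}); aromatic bonds are a
#' distinct bond-order label, normalised at parse time so that matching is
#' independent of Kekule representation; stereochemistry is ignored.
#'
#' @slot atoms data.frame with columns \code{index} (unique positive
#'   integers), \code{element}, \code{atom_type}, \code{charge},
#'   \code{implicit_h}.
#' @slot bonds data.frame with columns \code{a1}, \code{a2}, \code{order}
#'   (one of single/double/triple/aromatic); the graph is simple.
#' @slot name free-text compound name.
#' @slot external_id optional catalogue identifier.
#' @export
setClass("MolecularGraph",
  representation(atoms = "data.frame", bonds = "data.frame",
                 name = "character", external_id = "character"),
  prototype(atoms = data.frame(index = integer(), element = character(),
                               atom_type = character(), charge = integer(),
                               implicit_h = integer()),
            bonds = data.frame(a1 = integer(), a2 = integer(),
                               order = character()),
            name = "", external_id = NA_character_))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  need_a <- c("index", "element", "atom_type", "charge", "implicit_h")
  need_b <- c("a1", "a2", "order")
  if (!all(need_a %in% names(a))) return("atoms is missing required columns")
  if (!all(need_b %in% names(b))) return("bonds is missing required columns")
  if (anyDuplicated(a$index)) msgs <- c(msgs, "duplicate atom index")
  if (nrow(b)) {
    if (any(b$a1 == b$a2)) msgs <- c(msgs, "bond endpoints must be distinct")
    if (!all(c(b$a1, b$a2) %in% a$index))
      msgs <- c(msgs, "bond endpoint does not resolve to an atom")
    if (!all(b$order %in% BOND_ORDERS))
      msgs <- c(msgs, "unknown bond order")
    key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    if (anyDuplicated(key)) msgs <- c(msgs, "more than one bond per atom pair")
  }
  if (length(msgs)) msgs else TRUE
})

#' ReactionPair: an atom-mapped reactant/product pair
#'
#' @slot id pair identifier.
#' @slot reactant,product \code{MolecularGraph} objects.
#' @slot atom_map two-column integer matrix (reactant index, product index);
#'   a partial injective map over conserved atoms.
#' @slot ec_numbers character vector of EC numbers (nonempty).
#' @slot reversible logical; reactions are assumed reversible unless stated
#'   otherwise, so reverse-direction operators are derived by default.
#' @export
setClass("ReactionPair",
  representation(id = "character", reactant = "MolecularGraph",
                 product = "MolecularGraph", atom_map = "matrix",
                 ec_numbers = "character", reversible = "logical"),
  prototype(reversible = TRUE))

setValidity("ReactionPair", function(object) {
  m <- object@atom_map
  msgs <- character()
  if (!is.numeric(m) || ncol(m) != 2) return("atom_map must be a 2-column matrix")
  if (anyDuplicated(m[, 1]) || anyDuplicated(m[, 2]))
    msgs <- c(msgs, "atom_map must be injective")
  if (!all(m[, 1] %in% object@reactant@atoms$index))
    msgs <- c(msgs, "atom_map references missing reactant atoms")
  if (!all(m[, 2] %in% object@product@atoms$index))
    msgs <- c(msgs, "atom_map references missing product atoms")
  if (!length(object@ec_numbers))
    msgs <- c(msgs, "ec_numbers must be nonempty")
  if (length(msgs)) msgs else TRUE
})

#' TransformationOperator: reaction-center pattern plus edit script
#'
#' The pattern is the reactant-side neighbourhood of the reaction center
#' (center, first and second shell, with the bonds induced among them); the
#' edit script is an ordered list of primitive edits expressed against
#' pattern node ids (new atoms get ids beyond the pattern).
#'
#' @slot id operator identifier.
#' @slot center_type atom type of the reaction-center atom.
#' @slot pattern data.frame (node, atom_type, shell) with shell 0 = center.
#' @slot pattern_bonds data.frame (n1, n2, order) induced on pattern nodes.
#' @slot edits list of primitive edits: \code{add_atom}, \code{remove_atom},
#'   \code{add_bond}, \code{remove_bond}, \code{change_bond_order},
#'   \code{change_atom_type}.
#' @slot ec_numbers EC numbers inherited from the source pair.
#' @slot source_pair id of the source \code{ReactionPair}.
#' @slot direction "forward" or "reverse".
#' @slot source_site named integer vector mapping pattern nodes to atom
#'   indices of the source substrate (reactant for forward operators).
#' @slot reaction_class optional reaction-class label used when tabulating
#'   taxon capabilities (e.g. "methylation", "C-ring cleavage").
#' @export
setClass("TransformationOperator",
  representation(id = "character", center_type = "character",
                 pattern = "data.frame", pattern_bonds = "data.frame",
                 edits = "list", ec_numbers = "character",
                 source_pair = "character", direction = "character",
                 source_site = "integer", reaction_class = "character"),
  prototype(direction = "forward", reaction_class = NA_character_))

setValidity("TransformationOperator", function(object) {
  msgs <- character()
  if (!object@direction %in% c("forward", "reverse"))
    msgs <- c(msgs, "direction must be forward or reverse")
  if (nrow(object@pattern) && object@pattern$shell[1] != 0L)
    msgs <- c(msgs, "first pattern node must be the center (shell 0)")
  if (length(msgs)) msgs else TRUE
})

#' OperatorLibrary: a collection of transformation operators
#'
#' @slot operators list of \code{TransformationOperator}.
#' @slot provenance free text describing where the operators came from.
#' @export
setClass("OperatorLibrary",
  representation(operators = "list", provenance = "character"),
  prototype(operators = list(), provenance = ""))

setValidity("OperatorLibrary", function(object) {
  ids <- vapply(object@operators, function(o) o@id, character(1))
  if (anyDuplicated(ids)) "operator ids must be unique" else TRUE
})

#' FilterPolicy: trivial-product blocklist and optional catalogue
#'
#' Products whose canonical key is on the blocklist are eliminated (simple
#' sugars, CO2, water and the like); if a catalogue is supplied only
#' catalogued keys are retained. The blocklist wins over the catalogue.
#'
#' @slot blocklist character vector of canonical keys to eliminate.
#' @slot catalog optional character vector of allowed canonical keys
#'   (\code{NA_character_}-free; length 0 means "no catalogue filter").
#' @export
setClass("FilterPolicy",
  representation(blocklist = "character", catalog = "character"),
  prototype(blocklist = character(), catalog = character()))

#' OrganismEnzymeMatrix: strain-by-EC incidence with taxonomy
#'
#' @slot strains character vector of unique strain identifiers.
#' @slot ec_sets named list (per strain) of EC-number sets.
#' @slot taxonomy data.frame with columns \code{phylum}, \code{family},
#'   \code{genus}, one row per strain (same order as \code{strains}).
#' @export
setClass("OrganismEnzymeMatrix",
  representation(strains = "character", ec_sets = "list",
                 taxonomy = "data.frame"))

setValidity("OrganismEnzymeMatrix", function(object) {
  msgs <- character()
  if (anyDuplicated(object@strains)) msgs <- c(msgs, "strain ids must be unique")
  if (length(object@ec_sets) != length(object@strains))
    msgs <- c(msgs, "one EC set per strain required")
  if (!all(c("phylum", "family", "genus") %in% names(object@taxonomy)))
    msgs <- c(msgs, "taxonomy needs phylum/family/genus columns")
  if (nrow(object@taxonomy) != length(object@strains))
    msgs <- c(msgs, "one taxonomy row per strain required")
  bad <- unlist(lapply(object@ec_sets, function(e) e[!isValidEC(e)]))
  if (length(bad))
    msgs <- c(msgs, paste("malformed EC number(s):",
                          paste(utils::head(unique(bad), 3), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})
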