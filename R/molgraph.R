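#' Construct a MolecularGraph
#'
#' @param atoms data.frame with at least \code{index}, and either
#'   \code{atom_type} or \code{element}; \code{charge} defaults to 0.
#' @param bonds data.frame with \code{a1}, \code{a2}, \code{order}.
#' @param name compound name.
#' @param external_id optional catalogue identifier.
#' @param normalize apply the aromatic normalisation pass (alternating
#'   single/double six-membered carbocycles are relabelled aromatic).
#' @param perceive recompute \code{atom_type} labels from the bonding
#'   environment (used by the SMILES reader; KCF labels are kept verbatim).
#' @return a \code{MolecularGraph}.
#' @export
molecularGraph <- function(atoms, bonds = NULL, name = "",
                           external_id = NA_character_,
                           normalize = TRUE, perceive = FALSE) {
  if (is.null(bonds) || !nrow(bonds))
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = character(),
                        stringsAsFactors = FALSE)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds[, c("a1", "a2", "order")],
                         stringsAsFactors = FALSE)
  atoms$index <- as.integer(atoms$index)
  bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  atoms$charge <- as.integer(atoms$charge)
  if (is.null(atoms$element)) {
    if (is.null(atoms$atom_type)) stop("atoms need atom_type or element")
    atoms$element <- elementOf(atoms$atom_type)
  }
  if (normalize) bonds <- .normalizeAromatic(atoms, bonds)
  if (perceive || is.null(atoms$atom_type))
    atoms$atom_type <- perceiveAtomTypes(atoms, bonds)
  unknown <- setdiff(unique(atoms$atom_type), atomTypeVocabulary())
  if (length(unknown))
    message("atom_type label(s) outside the shipped vocabulary: ",
            paste(unknown, collapse = ", "))
  atoms$implicit_h <- .implicitH(atoms, bonds)
  new("MolecularGraph",
      atoms = atoms[, c("index", "element", "atom_type", "charge",
                        "implicit_h")],
      bonds = bonds, name = name, external_id = external_id)
}

# Relabel as aromatic every bond of a six-membered all-carbon ring whose
# bonds alternate single/double around the cycle (Kekule benzene input).
.normalizeAromatic <- function(atoms, bonds) {
  if (nrow(bonds) < 6) return(bonds)
  bkey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  bmap <- stats::setNames(seq_len(nrow(bonds)), bkey(bonds$a1, bonds$a2))
  carbon <- atoms$index[atoms$element == "C"]
  cb <- bonds[bonds$a1 %in% carbon & bonds$a2 %in% carbon, , drop = FALSE]
  if (nrow(cb) < 6) return(bonds)
  adj <- lapply(stats::setNames(nm = carbon), function(i)
    c(cb$a2[cb$a1 == i], cb$a1[cb$a2 == i]))
  for (v in .sixCycles(adj, carbon)) {
    ord <- vapply(seq_len(6), function(k) {
      bonds$order[bmap[[bkey(v[k], v[k %% 6 + 1])]]]
    }, character(1))
    if (all(ord %in% c("single", "double")) &&
        all(ord != c(ord[-1], ord[1]))) {
      for (k in seq_len(6))
        bonds$order[bmap[[bkey(v[k], v[k %% 6 + 1])]]] <- "aromatic"
    }
  }
  bonds
}

# enumerate simple 6-cycles once each: smallest vertex first, second vertex
# smaller than last to fix the traversal direction
.sixCycles <- function(adj, vertices) {
  res <- list()
  path <- integer(6)
  visit <- function(start, v, depth) {
    path[depth] <<- v
    if (depth == 6) {
      if (start %in% adj[[as.character(v)]] && path[2] < path[6])
        res[[length(res) + 1]] <<- path
      return(invisible())
    }
    for (w in adj[[as.character(v)]]) {
      if (w > start && !(w %in% path[seq_len(depth)]))
        visit(start, w, depth + 1L)
    }
  }
  for (s in sort(vertices)) visit(s, s, 1L)
  res
}

#' @describeIn molecularGraph number of heavy atoms.
#' @param g a \code{MolecularGraph}.
#' @export
atomCount <- function(g) nrow(g@atoms)

#' @describeIn molecularGraph number of bonds.
#' @export
bondCount <- function(g) nrow(g@bonds)

#' @describeIn molecularGraph atom table accessor.
#' @export
atoms <- function(g) g@atoms

#' @describeIn molecularGraph bond table accessor.
#' @export
bonds <- function(g) g@bonds

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph", if (nzchar(object@name)) sQuote(object@name) else "",
      "with", nrow(object@atoms), "atoms and", nrow(object@bonds), "bonds\n")
  tt <- table(object@atoms$atom_type)
  cat("  atom types:", paste(names(tt), tt, sep = ":", collapse = " "), "\n")
})

# ---- igraph bridge --------------------------------------------------------

# vertex label used for isomorphism/canonicalisation (type + charge)
.atomLabels <- function(g) paste0(g@atoms$atom_type, "/", g@atoms$charge)

.asIgraph <- function(g) {
  v <- data.frame(name = as.character(g@atoms$index),
                  label = .atomLabels(g), stringsAsFactors = FALSE)
  e <- g@bonds
  if (nrow(e)) {
    e <- data.frame(from = as.character(e$a1), to = as.character(e$a2),
                    order = e$order, stringsAsFactors = FALSE)
  } else e <- data.frame(from = character(), to = character(),
                         order = character())
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

# integer colors for VF2 given a shared label universe
.colorsFor <- function(labels, universe) match(labels, universe)

#' Test two molecular graphs for isomorphism
#'
#' TRUE iff an atom-label- and bond-order-preserving bijection exists
#' (labels are atom_type plus formal charge). Uses VF2 with vertex and edge
#' colors.
#'
#' @param a,b \code{MolecularGraph} objects.
#' @return logical.
#' @export
graphsIsomorphic <- function(a, b) {
  if (nrow(a@atoms) != nrow(b@atoms) || nrow(a@bonds) != nrow(b@bonds))
    return(FALSE)
  la <- sort(.atomLabels(a)); lb <- sort(.atomLabels(b))
  if (!identical(la, lb)) return(FALSE)
  if (!identical(sort(a@bonds$order), sort(b@bonds$order))) return(FALSE)
  if (nrow(a@atoms) == 0) return(TRUE)
  vuniv <- unique(c(.atomLabels(a), .atomLabels(b)))
  euniv <- BOND_ORDERS
  ga <- .asIgraph(a); gb <- .asIgraph(b)
  igraph::isomorphic(ga, gb, method = "vf2",
    vertex.color1 = .colorsFor(.atomLabels(a), vuniv),
    vertex.color2 = .colorsFor(.atomLabels(b), vuniv),
    edge.color1 = if (nrow(a@bonds)) .colorsFor(a@bonds$order, euniv) else NULL,
    edge.color2 = if (nrow(b@bonds)) .colorsFor(b@bonds$order, euniv) else NULL)
}

# subdivided graph (bond -> colored vertex) for BLISS canonicalisation,
# which supports vertex colors only
.subdividedForCanon <- function(g) {
  n <- nrow(g@atoms); m <- nrow(g@bonds)
  labels <- c(paste0("A:", .atomLabels(g)),
              if (m) paste0("B:", g@bonds$order))
  el <- NULL
  if (m) {
    p1 <- match(g@bonds$a1, g@atoms$index)
    p2 <- match(g@bonds$a2, g@atoms$index)
    bv <- n + seq_len(m)
    el <- rbind(cbind(p1, bv), cbind(p2, bv))
  }
  gg <- igraph::make_empty_graph(n + m, directed = FALSE)
  if (!is.null(el)) gg <- igraph::add_edges(gg, t(el))
  list(graph = gg, labels = labels, n_atoms = n)
}

#' Canonical key of a molecular graph
#'
#' An opaque string equal for isomorphic graphs and (with overwhelming
#' probability) unequal otherwise; stable across runs. Computed by BLISS
#' canonical labelling of a colored graph in which bonds are subdivided into
#' order-colored vertices, then serialising labels and edges in canonical
#' order.
#'
#' @param g a \code{MolecularGraph}.
#' @return character scalar.
#' @export
canonicalKey <- function(g) {
  if (nrow(g@atoms) == 0) return("empty")
  sd <- .subdividedForCanon(g)
  colors <- match(sd$labels, sort(unique(sd$labels)))
  cp <- igraph::canonical_permutation(sd$graph, colors = colors)
  gg <- igraph::permute(sd$graph, cp$labeling)
  lab <- character(length(sd$labels))
  lab[cp$labeling] <- sd$labels
  el <- igraph::as_edgelist(gg, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0("v", length(lab), ";", paste(lab, collapse = ","), ";",
         paste(el[, 1], el[, 2], sep = "-", collapse = ","))
}

# connected components as list of atom-index vectors (deterministic order)
.components <- function(g) {
  if (!nrow(g@atoms)) return(list())
  ig <- .asIgraph(g)
  comp <- igraph::components(ig)$membership
  idx <- as.integer(igraph::V(ig)$name)
  split(idx, comp)
}

# subgraph induced on a set of atom indices
.inducedSubgraph <- function(g, keep) {
  a <- g@atoms[g@atoms$index %in% keep, , drop = FALSE]
  b <- g@bonds[g@bonds$a1 %in% keep & g@bonds$a2 %in% keep, , drop = FALSE]
  new("MolecularGraph", atoms = a, bonds = b, name = g@name,
      external_id = g@external_id)
}

#' Split a molecular graph into connected components
#'
#' @param g a \code{MolecularGraph}.
#' @return list of \code{MolecularGraph}, one per connected component, in a
#'   deterministic order (by canonical key).
#' @export
splitComponents <- function(g) {
  comps <- .components(g)
  if (length(comps) <= 1) return(list(g))
  out <- lapply(comps, function(keep) .inducedSubgraph(g, keep))
  out[order(vapply(out, canonicalKey, character(1)))]
}

# all-pairs shortest-path (topological) distances over atom indices
.topoDistances <- function(g) {
  ig <- .asIgraph(g)
  d <- igraph::distances(ig)
  idx <- as.integer(igraph::V(ig)$name)
  dimnames(d) <- list(idx, idx)
  d
}

# canonical rank of each atom (position in canonical order); used as a
# deterministic tie-break
.canonicalRanks <- function(g) {
  sd <- .subdividedForCanon(g)
  colors <- match(sd$labels, sort(unique(sd$labels)))
  cp <- igraph::canonical_permutation(sd$graph, colors = colors)
  r <- cp$labeling[seq_len(sd$n_atoms)]
  stats::setNames(rank(r), g@atoms$index)
}
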