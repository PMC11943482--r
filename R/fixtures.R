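#' Named flavonoid fixture structures
#'
#' Returns the compound panel used throughout the package: the naringenin
#' C-ring cleavage pathway members (naringenin, naringenin chalcone,
#' phloretin, 3-(4-hydroxyphenyl)propionic acid, phloroglucinol), the
#' quercetin methylation products (isorhamnetin, tamarixetin), small test
#' molecules (benzene, phenol, catechol, guaiacol), fifteen flavonoid
#' aglycones spanning the flavanone, flavonol, flavone and isoflavone
#' subclasses, and four 7-O/3-O-glucosides. All are built from SMILES at
#' call time; names are stable.
#'
#' @return named list of \code{MolecularGraph} objects.
#' @export
flavonoidFixtures <- function() {
  smi <- c(
    benzene = "c1ccccc1",
    phenol = "Oc1ccccc1",
    catechol = "Oc1ccccc1O",
    guaiacol = "COc1ccccc1O",
    phloroglucinol = "Oc1cc(O)cc(O)c1",
    hppa = "O=C(O)CCc1ccc(O)cc1",
    naringenin = "O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c12",
    naringenin_chalcone = "O=C(C=Cc1ccc(O)cc1)c1c(O)cc(O)cc1O",
    phloretin = "O=C(CCc1ccc(O)cc1)c1c(O)cc(O)cc1O",
    eriodictyol = "O=C1CC(c2ccc(O)c(O)c2)Oc2cc(O)cc(O)c12",
    liquiritigenin = "O=C1CC(c2ccc(O)cc2)Oc2cc(O)ccc12",
    quercetin = "O=C1C(O)=C(c2ccc(O)c(O)c2)Oc2cc(O)cc(O)c12",
    isorhamnetin = "O=C1C(O)=C(c2ccc(O)c(OC)c2)Oc2cc(O)cc(O)c12",
    tamarixetin = "O=C1C(O)=C(c2ccc(OC)c(O)c2)Oc2cc(O)cc(O)c12",
    kaempferol = "O=C1C(O)=C(c2ccc(O)cc2)Oc2cc(O)cc(O)c12",
    fisetin = "O=C1C(O)=C(c2ccc(O)c(O)c2)Oc2cc(O)ccc12",
    myricetin = "O=C1C(O)=C(c2cc(O)c(O)c(O)c2)Oc2cc(O)cc(O)c12",
    morin = "O=C1C(O)=C(c2ccc(O)cc2O)Oc2cc(O)cc(O)c12",
    robinetin = "O=C1C(O)=C(c2cc(O)c(O)c(O)c2)Oc2cc(O)ccc12",
    gossypetin = "O=C1C(O)=C(c2ccc(O)c(O)c2)Oc2c(O)c(O)cc(O)c12",
    luteolin = "O=C1C=C(c2ccc(O)c(O)c2)Oc2cc(O)cc(O)c12",
    apigenin = "O=C1C=C(c2ccc(O)cc2)Oc2cc(O)cc(O)c12",
    baicalein = "O=C1C=C(c2ccccc2)Oc2cc(O)c(O)c(O)c12",
    genistein = "O=C1c2c(O)cc(O)cc2OC=C1c1ccc(O)cc1",
    daidzein = "O=C1c2ccc(O)cc2OC=C1c1ccc(O)cc1",
    prunin = "O=C1CC(c2ccc(O)cc2)Oc2cc(OC3OC(CO)C(O)C(O)C3O)cc(O)c12",
    isoquercitrin =
      "O=C1C(OC3OC(CO)C(O)C(O)C3O)=C(c2ccc(O)c(O)c2)Oc2cc(O)cc(O)c12",
    apigetrin = "O=C1C=C(c2ccc(O)cc2)Oc2cc(OC3OC(CO)C(O)C(O)C3O)cc(O)c12",
    genistin =
      "O=C1c2c(O)cc(OC3OC(CO)C(O)C(O)C3O)cc2OC=C1c1ccc(O)cc1")
  out <- lapply(names(smi), function(nm) parseSmiles(smi[[nm]], name = nm))
  stats::setNames(out, names(smi))
}

#' The fifteen aglycones of the fixture panel
#'
#' @return character vector of fixture names: three flavanones, seven
#'   flavonols, three flavones and two isoflavones.
#' @export
aglyconeNames <- function() {
  c("naringenin", "eriodictyol", "liquiritigenin",
    "quercetin", "kaempferol", "fisetin", "myricetin", "morin",
    "robinetin", "gossypetin",
    "luteolin", "apigenin", "baicalein",
    "genistein", "daidzein")
}

# edit helper used to build fixture products from reactants so that the
# atom map is the identity on conserved atoms
.editGraph <- function(g, drop_bonds = NULL, set_order = NULL,
                       set_type = NULL, add_atoms = NULL, add_bonds = NULL,
                       name = "") {
  a <- g@atoms[, c("index", "element", "atom_type", "charge")]
  b <- g@bonds
  if (!is.null(drop_bonds)) {
    for (k in seq_len(nrow(drop_bonds))) {
      i <- drop_bonds[k, 1]; j <- drop_bonds[k, 2]
      b <- b[!(pmin(b$a1, b$a2) == min(i, j) &
               pmax(b$a1, b$a2) == max(i, j)), , drop = FALSE]
    }
  }
  if (!is.null(set_order)) {
    for (k in seq_len(nrow(set_order))) {
      i <- as.integer(set_order[k, 1]); j <- as.integer(set_order[k, 2])
      sel <- pmin(b$a1, b$a2) == min(i, j) & pmax(b$a1, b$a2) == max(i, j)
      b$order[sel] <- set_order[k, 3]
    }
  }
  if (!is.null(set_type))
    for (nm in names(set_type)) {
      a$atom_type[a$index == as.integer(nm)] <- set_type[[nm]]
      a$element[a$index == as.integer(nm)] <- elementOf(set_type[[nm]])
    }
  if (!is.null(add_atoms)) a <- rbind(a, add_atoms)
  if (!is.null(add_bonds)) b <- rbind(b, add_bonds)
  molecularGraph(a, b, name = name, normalize = FALSE)
}

#' Fixture reaction pairs for the naringenin degradation pathway
#'
#' Five atom-mapped reactant/product pairs, each built by an explicit graph
#' edit so the conserved-atom map is exact:
#' \itemize{
#'   \item \code{ring_open}: naringenin to naringenin chalcone (C-ring
#'     C-O cleavage by a chalcone-isomerase/chalcone-synthase-like
#'     activity).
#'   \item \code{chalcone_reduction}: naringenin chalcone to phloretin
#'     (hydrogenation of the alpha,beta double bond).
#'   \item \code{direct_reduction}: naringenin straight to phloretin
#'     (flavanone-cleaving reduction of the C-ring).
#'   \item \code{retro_claisen}: phloretin to
#'     3-(4-hydroxyphenyl)propionic acid plus phloroglucinol (hydrolytic
#'     ring-fission by a phloretin-hydrolase-like activity; the product
#'     graph is the disconnected union of the two products).
#'   \item \code{o_methylation}: catechol to guaiacol (hydroxyl
#'     O-methylation).
#' }
#' Pairs are marked irreversible: they describe the catabolic direction of
#' the pathway.
#'
#' @param fixtures optionally, the list from \code{\link{flavonoidFixtures}}
#'   (recomputed when missing).
#' @return named list of \code{ReactionPair}.
#' @export
fixtureReactionPairs <- function(fixtures = flavonoidFixtures()) {
  nar <- fixtures$naringenin
  # atom indices in the naringenin SMILES order:
  # 1 O(=O), 2 C4, 3 C3, 4 C2, 5-11 B-ring (8 C4', 9 O4'), 12 O1,
  # 13 C8a, 14 C8, 15 C7, 16 O7, 17 C6, 18 C5, 19 O5, 20 C4a
  chal <- .editGraph(nar,
    drop_bonds = cbind(4L, 12L),
    set_order = cbind(3L, 4L, "double"),
    set_type = list(`3` = "C.vinyl", `4` = "C.vinyl", `12` = "O.hydroxyl"),
    name = "naringenin_chalcone")
  phl <- .editGraph(chal,
    set_order = cbind(3L, 4L, "single"),
    set_type = list(`3` = "C.alkyl", `4` = "C.alkyl"),
    name = "phloretin")
  cleaved <- .editGraph(phl,
    drop_bonds = cbind(2L, 20L),
    set_type = list(`2` = "C.carboxyl"),
    add_atoms = data.frame(index = 21L, element = "O",
                           atom_type = "O.hydroxyl", charge = 0L),
    add_bonds = data.frame(a1 = 2L, a2 = 21L, order = "single"),
    name = "hppa_plus_phloroglucinol")
  phl_direct <- .editGraph(nar,
    drop_bonds = cbind(4L, 12L),
    set_type = list(`12` = "O.hydroxyl"),
    name = "phloretin")
  cte <- fixtures$catechol
  gua <- .editGraph(cte,
    set_type = list(`1` = "O.ether"),
    add_atoms = data.frame(index = 9L, element = "C",
                           atom_type = "C.alkyl", charge = 0L),
    add_bonds = data.frame(a1 = 1L, a2 = 9L, order = "single"),
    name = "guaiacol")
  idmap <- function(n) cbind(seq_len(n), seq_len(n))
  list(
    ring_open = reactionPair("ring_open", nar, chal, idmap(20),
                             c("5.5.1.6", "2.3.1.74"), reversible = FALSE),
    chalcone_reduction = reactionPair("chalcone_reduction", chal, phl,
                                      idmap(20), "1.3.1.-",
                                      reversible = FALSE),
    direct_reduction = reactionPair("direct_reduction", nar, phl_direct,
                                    idmap(20), "1.3.1.-",
                                    reversible = FALSE),
    retro_claisen = reactionPair("retro_claisen", phl, cleaved, idmap(20),
                                 "3.7.1.4", reversible = FALSE),
    o_methylation = reactionPair("o_methylation", cte, gua, idmap(8),
                                 "2.1.1.6", reversible = FALSE))
}

#' Fixture operator library
#'
#' Derives one forward operator from each fixture reaction pair (see
#' \code{\link{fixtureReactionPairs}}) and returns them as a library with
#' stable ids \code{op.ring_open}, \code{op.chalcone_reduction},
#' \code{op.direct_reduction}, \code{op.retro_claisen},
#' \code{op.o_methylation}, annotated with reaction classes.
#'
#' @param pairs optionally, the list from \code{\link{fixtureReactionPairs}}.
#' @return an \code{OperatorLibrary}.
#' @export
fixtureOperatorLibrary <- function(pairs = fixtureReactionPairs()) {
  classes <- c(ring_open = "C-ring cleavage",
               chalcone_reduction = "hydrogenation",
               direct_reduction = "C-ring cleavage",
               retro_claisen = "hydrolysis",
               o_methylation = "methylation")
  ops <- lapply(names(pairs), function(nm) {
    o <- deriveOperators(pairs[[nm]], reaction_class = classes[[nm]])
    stopifnot(length(o) == 1L)
    op <- o[[1]]
    op@id <- paste0("op.", nm)
    op
  })
  operatorLibrary(ops, provenance = "fixture naringenin degradation pathway")
}
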