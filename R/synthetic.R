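#' Planted operator templates for synthetic corpora
#'
#' Three small, chemically plausible transformations whose reaction center
#' is structurally forced (exactly one changed mapped atom per direction),
#' so recovery of the planted patterns from a generated corpus is exact:
#' \itemize{
#'   \item \code{arom_hydroxylation}: para-hydroxylation of a toluene
#'     scaffold (EC 1.14.13.39-like monooxygenase).
#'   \item \code{o_methylation}: phenolic O-methylation (EC 2.1.1.6).
#'   \item \code{n_acetylation}: arylamine N-acetylation (EC 2.3.1.5).
#' }
#' Each template records its reaction pair (reversible), the reaction
#' center, and a decoration attachment atom lying at least three bonds from
#' the center, so random decoration never enters the two matching shells.
#' A fourth, decoy template (\code{arom_chlorination}) is used for
#' label-shuffled non-instances and is not part of the planted set.
#'
#' @return named list of templates; each has \code{id}, \code{pair},
#'   \code{attach}, \code{edit} (function graph -> product graph),
#'   \code{operators} (derived forward + reverse), \code{decoy}.
#' @export
plantedOperatorTemplates <- function() {
  ring <- function(extra_atoms, extra_bonds, name) {
    a <- rbind(data.frame(index = 1:6, element = "C", atom_type = "C.arom",
                          charge = 0L), extra_atoms)
    b <- rbind(data.frame(a1 = 1:6, a2 = c(2:6, 1L), order = "aromatic"),
               extra_bonds)
    molecularGraph(a, b, name = name, normalize = FALSE)
  }
  addO <- function(g, at, idx, type = "O.hydroxyl") {
    .editGraph(g, add_atoms = data.frame(index = idx, element = "O",
                                         atom_type = type, charge = 0L),
               add_bonds = data.frame(a1 = at, a2 = idx, order = "single"),
               name = paste0(g@name, "_prod"))
  }
  idmap <- function(n) cbind(seq_len(n), seq_len(n))
  # toluene: methyl C7 on ring atom 1; center = para atom 4
  toluene <- ring(data.frame(index = 7L, element = "C",
                             atom_type = "C.alkyl", charge = 0L),
                  data.frame(a1 = 1L, a2 = 7L, order = "single"), "toluene")
  hydrox_edit <- function(g) addO(g, 4L, max(g@atoms$index) + 1L)
  hydrox <- reactionPair("tmpl_arom_hydroxylation", toluene,
                         hydrox_edit(toluene), idmap(7), "1.14.13.39")
  # phenol: O7 on ring atom 1; center = O7; attach = para atom 4
  phenol <- ring(data.frame(index = 7L, element = "O",
                            atom_type = "O.hydroxyl", charge = 0L),
                 data.frame(a1 = 1L, a2 = 7L, order = "single"), "phenol")
  ometh_edit <- function(g) {
    g2 <- .editGraph(g, set_type = list(`7` = "O.ether"),
                     add_atoms = data.frame(index = max(g@atoms$index) + 1L,
                                            element = "C",
                                            atom_type = "C.alkyl",
                                            charge = 0L),
                     add_bonds = data.frame(a1 = 7L,
                                            a2 = max(g@atoms$index) + 1L,
                                            order = "single"),
                     name = paste0(g@name, "_prod"))
    g2
  }
  ometh <- reactionPair("tmpl_o_methylation", phenol, ometh_edit(phenol),
                        idmap(7), "2.1.1.6")
  # aniline: N7 on ring atom 1; center = N7; attach = para atom 4
  aniline <- ring(data.frame(index = 7L, element = "N",
                             atom_type = "N.amine", charge = 0L),
                  data.frame(a1 = 1L, a2 = 7L, order = "single"), "aniline")
  nacet_edit <- function(g) {
    base <- max(g@atoms$index)
    .editGraph(g,
      add_atoms = data.frame(index = base + 1:3,
                             element = c("C", "O", "C"),
                             atom_type = c("C.carbonyl", "O.carbonyl",
                                           "C.alkyl"),
                             charge = 0L),
      add_bonds = data.frame(a1 = c(7L, base + 1L, base + 1L),
                             a2 = base + 1:3,
                             order = c("single", "double", "single")),
      name = paste0(g@name, "_prod"))
  }
  nacet <- reactionPair("tmpl_n_acetylation", aniline, nacet_edit(aniline),
                        idmap(7), "2.3.1.5")
  chlor_edit <- function(g) {
    .editGraph(g, add_atoms = data.frame(index = max(g@atoms$index) + 1L,
                                         element = "Cl", atom_type = "Cl",
                                         charge = 0L),
               add_bonds = data.frame(a1 = 4L,
                                      a2 = max(g@atoms$index) + 1L,
                                      order = "single"),
               name = paste0(g@name, "_prod"))
  }
  chlor <- reactionPair("tmpl_arom_chlorination", toluene,
                        chlor_edit(toluene), idmap(7), "1.97.1.10")
  mk <- function(id, pair, attach, edit, decoy = FALSE) {
    list(id = id, pair = pair, attach = attach, edit = edit,
         operators = deriveOperators(pair), decoy = decoy)
  }
  list(
    arom_hydroxylation = mk("arom_hydroxylation", hydrox, 7L, hydrox_edit),
    o_methylation = mk("o_methylation", ometh, 4L, ometh_edit),
    n_acetylation = mk("n_acetylation", nacet, 4L, nacet_edit),
    arom_chlorination = mk("arom_chlorination", chlor, 7L, chlor_edit,
                           decoy = TRUE))
}

#' Specification for a synthetic reaction corpus
#'
#' @param seed RNG seed (all generation is a pure function of seed + spec).
#' @param n_scaffolds number of distinct decorated scaffolds (>= 1).
#' @param n_reactions number of reaction pairs to emit (>= 1).
#' @param templates planted operator templates (default
#'   \code{\link{plantedOperatorTemplates}}; decoy templates are used only
#'   for the decoy fraction).
#' @param decoy_fraction fraction of reactions generated from the decoy
#'   template, in [0, 1] (default 0).
#' @return list of class \code{"CorpusSpec"}.
#' @export
corpusSpec <- function(seed, n_scaffolds = 10, n_reactions = 50,
                       templates = plantedOperatorTemplates(),
                       decoy_fraction = 0) {
  stopifnot(n_scaffolds >= 1, n_reactions >= 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  structure(list(seed = as.integer(seed), n_scaffolds = n_scaffolds,
                 n_reactions = n_reactions, templates = templates,
                 decoy_fraction = decoy_fraction),
            class = "CorpusSpec")
}

# random alkyl/hydroxy chain decoration at the template's attachment atom;
# the attachment lies >= 3 bonds from the reaction center, so decoration
# never alters the matching shells
.decorate <- function(g, attach) {
  n_extra <- sample(0:3, 1)
  if (!n_extra) return(g)
  base <- max(g@atoms$index)
  idx <- base + seq_len(n_extra)
  a <- data.frame(index = idx, element = "C", atom_type = "C.alkyl",
                  charge = 0L)
  b <- data.frame(a1 = c(attach, idx[-n_extra]), a2 = idx, order = "single")
  if (stats::runif(1) < 0.4) {
    a <- rbind(a, data.frame(index = base + n_extra + 1L, element = "O",
                             atom_type = "O.hydroxyl", charge = 0L))
    b <- rbind(b, data.frame(a1 = idx[n_extra], a2 = base + n_extra + 1L,
                             order = "single"))
  }
  .editGraph(g, add_atoms = a, add_bonds = b, name = g@name)
}

#' Generate a synthetic reaction corpus with planted operators
#'
#' Each reaction is built by decorating a template scaffold (random alkyl
#' or hydroxyalkyl chains at an attachment atom outside the matching
#' shells) and applying the template's transformation at its fixed site,
#' recording the exact conserved-atom map. Every generated pair therefore
#' round-trips under its own planted operator, and operator derivation over
#' the non-decoy pairs recovers exactly the planted pattern set in both
#' directions. Fully reproducible from the seed.
#'
#' @param spec a \code{\link{corpusSpec}}.
#' @return list with \code{pairs} (list of \code{ReactionPair}),
#'   \code{truth} (data.frame pair_id, template_id, is_decoy) and
#'   \code{planted} (list of planted \code{TransformationOperator}, both
#'   directions, decoys excluded).
#' @export
genReactionCorpus <- function(spec) {
  stopifnot(inherits(spec, "CorpusSpec"))
  set.seed(spec$seed)
  templates <- spec$templates
  planted <- templates[!vapply(templates, `[[`, logical(1), "decoy")]
  decoys <- templates[vapply(templates, `[[`, logical(1), "decoy")]
  if (!length(planted)) stop("no non-decoy templates", call. = FALSE)
  # scaffold pool: template cycled, decoration random
  pool <- vector("list", spec$n_scaffolds)
  pool_tmpl <- character(spec$n_scaffolds)
  for (i in seq_len(spec$n_scaffolds)) {
    tid <- names(planted)[(i - 1) %% length(planted) + 1]
    t <- planted[[tid]]
    sc <- .decorate(t$pair@reactant, t$attach)
    fwd <- t$operators[[which(vapply(t$operators, function(o)
      o@direction == "forward", logical(1)))[1]]]
    if (!length(matchSites(sc, fwd)))
      stop("planted pattern ", t$id, " matches no generated scaffold",
           call. = FALSE)
    pool[[i]] <- sc
    pool_tmpl[i] <- tid
  }
  n_decoy <- round(spec$decoy_fraction * spec$n_reactions)
  is_decoy <- rep(FALSE, spec$n_reactions)
  if (n_decoy > 0) {
    if (!length(decoys)) stop("decoy_fraction > 0 but no decoy template",
                              call. = FALSE)
    is_decoy[sample(spec$n_reactions, n_decoy)] <- TRUE
  }
  pairs <- vector("list", spec$n_reactions)
  truth <- data.frame(pair_id = character(spec$n_reactions),
                      template_id = character(spec$n_reactions),
                      is_decoy = is_decoy, stringsAsFactors = FALSE)
  for (j in seq_len(spec$n_reactions)) {
    si <- (j - 1) %% spec$n_scaffolds + 1
    if (is_decoy[j]) {
      t <- decoys[[(j - 1) %% length(decoys) + 1]]
      # decoy instances are built on the decoy template's own scaffold
      sc <- .decorate(t$pair@reactant, t$attach)
    } else {
      t <- planted[[pool_tmpl[si]]]
      sc <- pool[[si]]
    }
    prod <- t$edit(sc)
    pid <- sprintf("rx%04d_%s", j, t$id)
    pairs[[j]] <- reactionPair(pid, sc, prod,
                               cbind(sc@atoms$index, sc@atoms$index),
                               t$pair@ec_numbers, reversible = TRUE)
    truth$pair_id[j] <- pid
    truth$template_id[j] <- t$id
  }
  planted_ops <- unlist(lapply(planted, `[[`, "operators"),
                        recursive = FALSE)
  list(pairs = pairs, truth = truth, planted = unname(planted_ops))
}

#' Generate a synthetic organism-enzyme matrix
#'
#' Strains carry planted ECs (exact assignments supplied by the caller)
#' plus random background ECs drawn from a pool whose three-digit classes
#' are disjoint from the planted ones, so planted-carrier recovery is
#' exact. Taxonomy assigns each strain a phylum (round-robin with random
#' permutation), with families and genera nested inside phyla.
#'
#' @param seed RNG seed.
#' @param n_strains number of strains (>= 1).
#' @param phyla character vector of phylum names.
#' @param planted named list: EC number -> integer vector of strain
#'   positions carrying it.
#' @param background_density per-strain inclusion probability of each
#'   background pool EC (default 0.15).
#' @param background_pool character vector of background EC numbers.
#' @return an \code{OrganismEnzymeMatrix}.
#' @export
genOrganismMatrix <- function(seed, n_strains = 20,
                              phyla = c("Firmicutes", "Bacteroidetes",
                                        "Actinobacteria", "Proteobacteria"),
                              planted = list(),
                              background_density = 0.15,
                              background_pool = c("1.1.1.1", "2.7.1.2",
                                                  "3.2.1.21", "4.2.1.11",
                                                  "5.3.1.9", "6.3.4.2")) {
  stopifnot(n_strains >= 1)
  set.seed(seed)
  planted3 <- .ec3(names(planted))
  pool <- background_pool[!.ec3(background_pool) %in% planted3]
  ids <- sprintf("strain_%03d", seq_len(n_strains))
  phylum <- sample(rep(phyla, length.out = n_strains))
  family <- paste0(substr(phylum, 1, 4), "_fam",
                   1 + (match(ids, ids) %% 2))
  genus <- paste0(substr(phylum, 1, 4), "_gen",
                  1 + (seq_len(n_strains) %% 3))
  ec_sets <- lapply(seq_len(n_strains), function(i) {
    bg <- pool[stats::runif(length(pool)) < background_density]
    pl <- names(planted)[vapply(planted, function(v) i %in% v, logical(1))]
    sort(unique(c(bg, pl)))
  })
  organismEnzymeMatrix(ids, ec_sets,
                       data.frame(phylum = phylum, family = family,
                                  genus = genus, stringsAsFactors = FALSE))
}

#' Generate a reference protein and mutated homologs at target identities
#'
#' The reference is a uniform random 20-letter sequence; each candidate is
#' produced by substituting \code{round(length * (1 - target/100))}
#' distinct positions with a different residue, so the realised
#' substitution-level identity equals the target up to rounding (global
#' alignment can only recover or tie this, hence the declared tolerance of
#' one alignment column).
#'
#' @param seed RNG seed.
#' @param reference_length residues in the reference (default 120).
#' @param target_identities percent identities in (0, 100].
#' @return list with \code{reference} (character), \code{candidates}
#'   (named character vector, names \code{mut<k>_<target>}), and
#'   \code{truth} (data.frame id, target, n_substitutions).
#' @export
genHomologSet <- function(seed, reference_length = 120,
                          target_identities = c(95, 85, 70)) {
  stopifnot(all(target_identities > 0), all(target_identities <= 100))
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- paste(sample(aa, reference_length, replace = TRUE), collapse = "")
  cand <- character(); truth <- list()
  refv <- strsplit(ref, "")[[1]]
  for (k in seq_along(target_identities)) {
    t <- target_identities[k]
    nsub <- round(reference_length * (1 - t / 100))
    v <- refv
    if (nsub > 0) {
      pos <- sample(reference_length, nsub)
      for (p in pos) v[p] <- sample(setdiff(aa, v[p]), 1)
    }
    id <- sprintf("mut%d_%g", k, t)
    cand[id] <- paste(v, collapse = "")
    truth[[k]] <- data.frame(id = id, target = t, n_substitutions = nsub,
                             stringsAsFactors = FALSE)
  }
  list(reference = ref, candidates = cand, truth = do.call(rbind, truth))
}
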