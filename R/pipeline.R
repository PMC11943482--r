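#' Run one pipeline stage
#'
#' Orchestrates the analysis stages behind a single entry point with a
#' structured configuration, deterministic seeding and a run manifest. Each
#' stage writes its declared artifacts into \code{out_dir} together with
#' \code{manifest.json} (stage, config hash, package version, seed); given
#' the same config and seed every stage is byte-reproducible. Stages:
#' \describe{
#'   \item{simulate}{writes a synthetic reaction corpus (JSONL + ground
#'     truth), an organism-enzyme matrix (TSV) and a homolog set (FASTA).}
#'   \item{derive}{reads a corpus and writes the derived operator library
#'     (JSON).}
#'   \item{predict}{reads an operator library and a substrate (fixture
#'     name, SMILES, or KCF file) and writes two-round predictions (TSV).}
#'   \item{match-taxa}{reads an operator library plus organism matrix and
#'     writes the taxon-normalised capability table (TSV).}
#'   \item{cluster}{clusters fixture aglycones (or a corpus's reactant
#'     sides) by atom-pair dissimilarity; writes the dissimilarity matrix,
#'     merge list and Newick dendrogram, and the co-cluster candidates of a
#'     query compound.}
#'   \item{mds}{reads a dissimilarity TSV and writes the classical MDS
#'     embedding (TSV).}
#'   \item{screen}{reads (or simulates) a protein FASTA and writes homolog
#'     hits above the identity threshold (TSV) plus a neighbour-joining
#'     tree (Newick).}
#' }
#'
#' @param stage one of \code{"simulate"}, \code{"derive"},
#'   \code{"predict"}, \code{"match-taxa"}, \code{"cluster"}, \code{"mds"},
#'   \code{"screen"}.
#' @param config named list; recognised fields (with defaults) include
#'   \code{seed} (mandatory for stochastic stages), \code{out_dir},
#'   \code{rounds} (2), \code{descriptor_cap} (7), \code{cut_height}
#'   (0.6), \code{identity_threshold} (80), \code{n_reactions} (50),
#'   \code{n_scaffolds} (10), \code{decoy_fraction} (0), \code{n_strains}
#'   (20), \code{substrate} ("naringenin"), \code{library},
#'   \code{corpus}, \code{matrix}, \code{fasta}, \code{dissimilarity},
#'   \code{use_default_blocklist} (TRUE), \code{mds_dim} (2).
#' @param config_file optional YAML file merged under \code{config}
#'   (explicit \code{config} entries win).
#' @return invisibly, a named list of written artifact paths.
#' @export
runPipelineStage <- function(stage, config = list(), config_file = NULL) {
  stages <- c("simulate", "derive", "predict", "match-taxa", "cluster",
              "mds", "screen")
  if (!stage %in% stages)
    stop("unknown stage ", sQuote(stage), "; valid: ",
         paste(stages, collapse = ", "), call. = FALSE)
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    config <- utils::modifyList(file_cfg, config)
  }
  cfg <- utils::modifyList(list(
    out_dir = ".", rounds = 2, descriptor_cap = 7, cut_height = 0.6,
    identity_threshold = 80, n_reactions = 50, n_scaffolds = 10,
    decoy_fraction = 0, n_strains = 20, substrate = "naringenin",
    use_default_blocklist = TRUE, mds_dim = 2), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  needs_seed <- stage %in% c("simulate", "cluster", "screen", "mds")
  if (needs_seed && is.null(cfg$seed))
    stop("config$seed is mandatory for stage ", stage, call. = FALSE)
  artifacts <- switch(stage,
    "simulate" = .stageSimulate(cfg, p),
    "derive" = .stageDerive(cfg, p),
    "predict" = .stagePredict(cfg, p),
    "match-taxa" = .stageMatchTaxa(cfg, p),
    "cluster" = .stageCluster(cfg, p),
    "mds" = .stageMds(cfg, p),
    "screen" = .stageScreen(cfg, p))
  manifest <- list(stage = stage,
                   package = "FlavoPredict",
                   version = as.character(utils::packageVersion(
                     "FlavoPredict")),
                   seed = cfg$seed,
                   config_hash = .configHash(cfg),
                   artifacts = unname(unlist(artifacts)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  message("[", stage, "] wrote ", length(unlist(artifacts)),
          " artifact(s) to ", cfg$out_dir)
  invisible(c(artifacts, list(manifest = p("manifest.json"))))
}

.configHash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  cfg <- cfg[!vapply(cfg, is.function, logical(1))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.stageSimulate <- function(cfg, p) {
  spec <- corpusSpec(cfg$seed, n_scaffolds = cfg$n_scaffolds,
                     n_reactions = cfg$n_reactions,
                     decoy_fraction = cfg$decoy_fraction)
  corpus <- genReactionCorpus(spec)
  writeReactionCorpus(corpus$pairs, p("corpus.jsonl"))
  utils::write.table(corpus$truth, p("corpus_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  m <- genOrganismMatrix(cfg$seed + 1L, n_strains = cfg$n_strains,
                         planted = list("2.3.1.74" = c(1L, 2L, 3L)))
  writeOrganismMatrix(m, p("organism_matrix.tsv"))
  hs <- genHomologSet(cfg$seed + 2L)
  writeProteinFasta(c(reference = hs$reference, hs$candidates),
                    p("homologs.fasta"))
  utils::write.table(hs$truth, p("homologs_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(corpus = p("corpus.jsonl"), truth = p("corpus_truth.tsv"),
       matrix = p("organism_matrix.tsv"), fasta = p("homologs.fasta"),
       homolog_truth = p("homologs_truth.tsv"))
}

.stageDerive <- function(cfg, p) {
  if (is.null(cfg$corpus)) stop("config$corpus (JSONL path) required",
                                call. = FALSE)
  pairs <- readReactionCorpus(cfg$corpus)
  ops <- list()
  for (rp in pairs) ops <- c(ops, deriveOperators(rp))
  lib <- operatorLibrary(ops, provenance = paste("derived from",
                                                 basename(cfg$corpus)))
  writeOperatorLibrary(lib, p("operators.json"))
  list(library = p("operators.json"))
}

.resolveSubstrate <- function(x) {
  fx <- flavonoidFixtures()
  if (x %in% names(fx)) return(fx[[x]])
  if (file.exists(x)) return(parseKCF(paste(readLines(x), collapse = "\n")))
  parseSmiles(x, name = "substrate")
}

.stagePredict <- function(cfg, p) {
  lib <- if (is.null(cfg$library)) fixtureOperatorLibrary()
         else readOperatorLibrary(cfg$library)
  substrate <- .resolveSubstrate(cfg$substrate)
  policy <- if (isTRUE(cfg$use_default_blocklist)) defaultFilterPolicy()
            else filterPolicy()
  rec <- predictMetabolites(substrate, lib, rounds = cfg$rounds,
                            policy = policy)
  writePredictions(rec, p("predictions.tsv"))
  list(predictions = p("predictions.tsv"))
}

.stageMatchTaxa <- function(cfg, p) {
  if (is.null(cfg$matrix)) stop("config$matrix (TSV path) required",
                                call. = FALSE)
  m <- readOrganismMatrix(cfg$matrix)
  lib <- if (is.null(cfg$library)) fixtureOperatorLibrary()
         else readOperatorLibrary(cfg$library)
  classes <- operatorClassEnzymes(lib)
  if (!length(classes))
    stop("operator library declares no reaction classes", call. = FALSE)
  tab <- capabilityTable(classes, m, level = "phylum")
  utils::write.table(tab, p("capability_phylum.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tab_g <- capabilityTable(classes, m, level = "genus")
  utils::write.table(tab_g, p("capability_genus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(phylum = p("capability_phylum.tsv"), genus = p("capability_genus.tsv"))
}

.stageCluster <- function(cfg, p) {
  set.seed(cfg$seed)
  if (!is.null(cfg$corpus)) {
    pairs <- readReactionCorpus(cfg$corpus)
    query <- .resolveSubstrate(cfg$substrate)
    cand <- coclusterCandidates(query, pairs, cfg$cut_height,
                                cap = cfg$descriptor_cap)
    items <- c(list(query = query),
               stats::setNames(lapply(pairs, function(rp) rp@reactant),
                               vapply(pairs, function(rp) rp@id,
                                      character(1))))
  } else {
    fx <- flavonoidFixtures()
    items <- fx[aglyconeNames()]
    cand <- character()
  }
  d <- pairwiseDissimilarity(items, cap = cfg$descriptor_cap)
  writeDissimilarity(d, p("dissimilarity.tsv"))
  h <- singleLinkage(d)
  writeDendrogram(h, p("dendrogram_merges.tsv"), p("dendrogram.nwk"))
  writeLines(cand, p("cocluster_candidates.txt"))
  list(dissimilarity = p("dissimilarity.tsv"),
       merges = p("dendrogram_merges.tsv"),
       newick = p("dendrogram.nwk"),
       candidates = p("cocluster_candidates.txt"))
}

.stageMds <- function(cfg, p) {
  if (is.null(cfg$dissimilarity))
    stop("config$dissimilarity (TSV path) required", call. = FALSE)
  d <- readDissimilarity(cfg$dissimilarity)
  emb <- classicalMds(d, dim = cfg$mds_dim)
  writeEmbedding(emb, p("embedding.tsv"))
  list(embedding = p("embedding.tsv"))
}

.stageScreen <- function(cfg, p) {
  if (!is.null(cfg$fasta)) {
    seqs <- as.character(readProteinFasta(cfg$fasta))
  } else {
    hs <- genHomologSet(cfg$seed)
    seqs <- c(reference = hs$reference, hs$candidates)
  }
  if (!"reference" %in% names(seqs))
    stop("FASTA must contain a sequence named 'reference'", call. = FALSE)
  ref <- seqs[["reference"]]
  cand <- seqs[setdiff(names(seqs), "reference")]
  hits <- screenHomologs(ref, cand, threshold = cfg$identity_threshold)
  utils::write.table(hits, p("homolog_hits.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(seqs) >= 3) {
    im <- identityMatrix(seqs)
    tree <- njTree(im)
    ape::write.tree(tree, p("homolog_tree.nwk"))
    utils::write.table(data.frame(id = rownames(im), im,
                                  check.names = FALSE),
                       p("identity_matrix.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(hits = p("homolog_hits.tsv"), tree = p("homolog_tree.nwk"),
         identities = p("identity_matrix.tsv"))
  } else list(hits = p("homolog_hits.tsv"))
}
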