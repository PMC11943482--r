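#' Read and write reaction corpora as JSON lines
#'
#' One \code{ReactionPair} per line: graphs inline as KCF-style records,
#' the atom map as index pairs, plus EC numbers and reversibility.
#'
#' @param pairs list of \code{ReactionPair}.
#' @param path output path.
#' @return \code{readReactionCorpus}: list of \code{ReactionPair}.
#' @export
writeReactionCorpus <- function(pairs, path) {
  lines <- vapply(pairs, function(rp) {
    jsonlite::toJSON(list(
      id = rp@id,
      reactant_kcf = writeKCF(rp@reactant),
      product_kcf = writeKCF(rp@product),
      atom_map = unname(split(rp@atom_map, row(rp@atom_map))),
      ec_numbers = rp@ec_numbers,
      reversible = rp@reversible), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeReactionCorpus
#' @export
readReactionCorpus <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    am <- x$atom_map
    if (is.list(am)) am <- do.call(rbind, lapply(am, as.integer))
    if (!length(am)) am <- matrix(integer(), 0, 2)
    reactionPair(x$id, parseKCF(x$reactant_kcf), parseKCF(x$product_kcf),
                 am, x$ec_numbers, isTRUE(x$reversible))
  })
}

OPERATOR_SCHEMA_VERSION <- "1.0"

#' Read and write operator libraries as JSON
#'
#' Serialises every operator's pattern, induced pattern bonds, edit script,
#' EC annotations, provenance and a schema version field.
#'
#' @param lib an \code{OperatorLibrary}.
#' @param path file path.
#' @return \code{readOperatorLibrary}: an \code{OperatorLibrary}.
#' @export
writeOperatorLibrary <- function(lib, path) {
  obj <- list(
    schema_version = OPERATOR_SCHEMA_VERSION,
    provenance = lib@provenance,
    operators = lapply(lib@operators, function(op) list(
      id = op@id, center_type = op@center_type,
      pattern = op@pattern, pattern_bonds = op@pattern_bonds,
      edits = op@edits, ec_numbers = op@ec_numbers,
      source_pair = op@source_pair, direction = op@direction,
      source_site = list(node = as.integer(names(op@source_site)),
                         atom = unname(op@source_site)),
      reaction_class = op@reaction_class)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeOperatorLibrary
#' @export
readOperatorLibrary <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(x$schema_version, OPERATOR_SCHEMA_VERSION))
    stop("operator library schema version mismatch: ", x$schema_version,
         call. = FALSE)
  ops <- lapply(x$operators, function(o) {
    patt <- do.call(rbind, lapply(o$pattern, as.data.frame))
    pb <- if (length(o$pattern_bonds))
      do.call(rbind, lapply(o$pattern_bonds, as.data.frame))
    else data.frame(n1 = integer(), n2 = integer(), order = character())
    edits <- lapply(o$edits, function(e) {
      for (f in c("n1", "n2", "node", "charge"))
        if (!is.null(e[[f]])) e[[f]] <- as.integer(e[[f]])
      e
    })
    site <- stats::setNames(
      as.integer(unlist(o$source_site$atom)),
      as.character(unlist(o$source_site$node)))
    new("TransformationOperator", id = o$id, center_type = o$center_type,
        pattern = transform(patt, node = as.integer(node),
                            charge = as.integer(charge),
                            shell = as.integer(shell)),
        pattern_bonds = if (nrow(pb))
          transform(pb, n1 = as.integer(n1), n2 = as.integer(n2)) else pb,
        edits = edits,
        ec_numbers = as.character(unlist(o$ec_numbers)),
        source_pair = o$source_pair, direction = o$direction,
        source_site = site,
        reaction_class = if (is.null(o$reaction_class)) NA_character_
                         else o$reaction_class)
  })
  operatorLibrary(ops, provenance = if (is.null(x$provenance)) ""
                                    else x$provenance)
}

#' Write prediction records as TSV
#'
#' Drops the product-graph list column; columns are substrate_key,
#' operator_id, product_key, round, ec_numbers, substrate_name.
#'
#' @param records prediction data.frame from
#'   \code{\link{predictMetabolites}}.
#' @param path file path.
#' @return \code{readPredictions}: the data.frame (without graphs).
#' @export
writePredictions <- function(records, path) {
  cols <- c("substrate_key", "operator_id", "product_key", "round",
            "ec_numbers", "substrate_name")
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write an MDS embedding as TSV
#'
#' @param emb an \code{MdsEmbedding}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeEmbedding <- function(emb, path) {
  co <- emb$coordinates
  df <- data.frame(id = rownames(co), co)
  names(df) <- c("id", paste0("dim", seq_len(ncol(co))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
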