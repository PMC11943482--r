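#' EC number syntax check
#'
#' Valid ECs have four numeric fields; a dash wildcard is permitted in the
#' fourth field only (it is irrelevant to three-digit matching; wildcards
#' in the first three fields are rejected).
#'
#' @param ec character vector.
#' @return logical vector.
#' @export
isValidEC <- function(ec) grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$", ec)

#' Match two EC numbers at three-digit resolution
#'
#' TRUE iff the first three numeric fields agree. The fourth field, which
#' encodes the natural substrate or cofactor, is deliberately ignored: the
#' premise of promiscuity prediction is that an enzyme of the same
#' three-digit class can act on a non-natural substrate.
#'
#' @param a,b EC strings.
#' @return logical.
#' @export
ecMatch3 <- function(a, b) {
  if (!isValidEC(a) || !isValidEC(b))
    stop("malformed EC number: ", paste(c(a, b)[!isValidEC(c(a, b))],
                                        collapse = ", "), call. = FALSE)
  f <- function(x) paste(strsplit(x, ".", fixed = TRUE)[[1]][1:3],
                         collapse = ".")
  f(a) == f(b)
}

.ec3 <- function(ec) sub("^([0-9]+\\.[0-9]+\\.[0-9]+)\\..*$", "\\1", ec)

#' Construct an OrganismEnzymeMatrix
#'
#' @param strains character vector of unique strain ids.
#' @param ec_sets list of EC-number character vectors, one per strain.
#' @param taxonomy data.frame with \code{phylum}, \code{family},
#'   \code{genus} columns, one row per strain.
#' @return an \code{OrganismEnzymeMatrix}.
#' @export
organismEnzymeMatrix <- function(strains, ec_sets, taxonomy) {
  new("OrganismEnzymeMatrix", strains = strains,
      ec_sets = stats::setNames(lapply(ec_sets, unique), strains),
      taxonomy = as.data.frame(taxonomy, stringsAsFactors = FALSE))
}

setMethod("show", "OrganismEnzymeMatrix", function(object) {
  cat("OrganismEnzymeMatrix:", length(object@strains), "strains,",
      length(unique(unlist(object@ec_sets))), "distinct ECs,",
      length(unique(object@taxonomy$phylum)), "phyla\n")
})

#' @describeIn organismEnzymeMatrix strain ids.
#' @param m an \code{OrganismEnzymeMatrix}.
#' @export
strains <- function(m) m@strains

#' @describeIn organismEnzymeMatrix per-strain EC sets.
#' @export
ecSets <- function(m) m@ec_sets

#' @describeIn organismEnzymeMatrix taxonomy table.
#' @export
taxonomy <- function(m) m@taxonomy

#' Organisms carrying an enzyme matching a predicted operator
#'
#' A strain qualifies when any EC in its set matches any EC of the operator
#' at three-digit resolution.
#'
#' @param op_ecs character vector of EC numbers attached to an operator.
#' @param m an \code{OrganismEnzymeMatrix}.
#' @return sorted, deduplicated character vector of strain ids.
#' @export
organismsFor <- function(op_ecs, m) {
  if (!length(op_ecs)) return(character())
  if (!all(isValidEC(op_ecs)))
    stop("malformed EC number: ",
         paste(op_ecs[!isValidEC(op_ecs)], collapse = ", "), call. = FALSE)
  q3 <- unique(.ec3(op_ecs))
  hit <- vapply(m@ec_sets, function(ecs) any(.ec3(ecs) %in% q3), logical(1))
  sort(m@strains[hit])
}

#' Taxon-normalised reaction-capability table
#'
#' For each taxon at the requested level and each reaction class, counts
#' strain-enzyme incidences (a strain carrying k distinct matching ECs
#' contributes k) and divides by the number of strains in the taxon.
#'
#' @param class_ecs named list: reaction class -> character vector of EC
#'   numbers predicted for that class (see
#'   \code{\link{operatorClassEnzymes}}).
#' @param m an \code{OrganismEnzymeMatrix}.
#' @param level one of \code{"phylum"}, \code{"family"}, \code{"genus"}.
#' @return data.frame with columns \code{taxon}, \code{reaction_class},
#'   \code{n_strains}, \code{n_enzymes}, \code{value} (= n_enzymes /
#'   n_strains).
#' @export
capabilityTable <- function(class_ecs, m, level = c("phylum", "family",
                                                    "genus")) {
  if (!is.character(level) || !length(level) ||
      !level[1] %in% c("phylum", "family", "genus"))
    stop("unknown taxonomic level: ", level[1], call. = FALSE)
  level <- level[1]
  tax <- m@taxonomy[[level]]
  taxa <- sort(unique(tax))
  rows <- list()
  for (tx in taxa) {
    members <- which(tax == tx)
    for (cls in sort(names(class_ecs))) {
      q3 <- unique(.ec3(class_ecs[[cls]]))
      n_enz <- sum(vapply(members, function(i)
        sum(.ec3(m@ec_sets[[i]]) %in% q3), numeric(1)))
      rows[[length(rows) + 1]] <- data.frame(
        taxon = tx, reaction_class = cls, n_strains = length(members),
        n_enzymes = n_enz, value = n_enz / length(members),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' EC numbers per reaction class in an operator library
#'
#' Collects, for each declared \code{reaction_class}, the union of EC
#' numbers over the library's operators (optionally restricted to operator
#' ids that actually fired in a prediction run).
#'
#' @param lib an \code{OperatorLibrary}.
#' @param operator_ids optional character vector restricting the operators.
#' @return named list: reaction class -> EC character vector.
#' @export
operatorClassEnzymes <- function(lib, operator_ids = NULL) {
  out <- list()
  for (op in lib@operators) {
    if (!is.null(operator_ids) && !op@id %in% operator_ids) next
    cls <- op@reaction_class
    if (is.na(cls)) next
    out[[cls]] <- sort(unique(c(out[[cls]], op@ec_numbers)))
  }
  out
}

#' Read / write an organism-enzyme matrix as TSV
#'
#' Columns: strain, phylum, family, genus, ecs (semicolon-joined).
#'
#' @param m an \code{OrganismEnzymeMatrix}.
#' @param path file path.
#' @return \code{readOrganismMatrix}: an \code{OrganismEnzymeMatrix};
#'   \code{writeOrganismMatrix}: \code{path}, invisibly.
#' @export
writeOrganismMatrix <- function(m, path) {
  df <- data.frame(strain = m@strains,
                   phylum = m@taxonomy$phylum,
                   family = m@taxonomy$family,
                   genus = m@taxonomy$genus,
                   ecs = vapply(m@ec_sets, paste, character(1),
                                collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOrganismMatrix
#' @export
readOrganismMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ec_sets <- lapply(strsplit(as.character(df$ecs), ";", fixed = TRUE),
                    function(x) x[!is.na(x) & nzchar(x)])
  organismEnzymeMatrix(df$strain, ec_sets,
                       df[, c("phylum", "family", "genus")])
}
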