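#' Construct a FilterPolicy
#'
#' @param blocklist canonical keys (or \code{MolecularGraph} objects, whose
#'   keys are taken) of trivial products to eliminate.
#' @param catalog optional canonical keys (or graphs) of allowed products;
#'   when supplied, only catalogued products are retained. The blocklist
#'   wins where both apply.
#' @return a \code{FilterPolicy}.
#' @export
filterPolicy <- function(blocklist = character(), catalog = character()) {
  as_keys <- function(x) {
    if (is.character(x)) return(x)
    vapply(x, function(g) if (is(g, "MolecularGraph")) canonicalKey(g)
           else as.character(g), character(1))
  }
  new("FilterPolicy", blocklist = unique(as_keys(blocklist)),
      catalog = unique(as_keys(catalog)))
}

#' Default trivial-product blocklist
#'
#' Water, carbon dioxide, ammonia and glucose: the detached co-products a
#' promiscuity prediction should not report as metabolites.
#'
#' @return a \code{FilterPolicy} with those canonical keys blocklisted.
#' @export
defaultFilterPolicy <- function() {
  triv <- list(parseSmiles("O", "water"),
               parseSmiles("O=C=O", "carbon dioxide"),
               parseSmiles("N", "ammonia"),
               parseSmiles("OCC1OC(O)C(O)C(O)C1O", "glucose"))
  filterPolicy(blocklist = triv)
}

#' Filter prediction records by a policy
#'
#' @param records prediction data.frame as returned by
#'   \code{\link{predictMetabolites}}.
#' @param policy a \code{FilterPolicy}.
#' @return the surviving subset of \code{records} (order preserved).
#' @export
filterProducts <- function(records, policy) {
  if (!nrow(records)) return(records)
  keep <- !(records$product_key %in% policy@blocklist)
  if (length(policy@catalog))
    keep <- keep & records$product_key %in% policy@catalog
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict metabolites by two-round operator application
#'
#' Applies every operator of the library at every matched site of the
#' substrate (round 1); unique round-1 products are then used as substrates
#' for a second round, mimicking two-step activation/metabolism. Products
#' are split into connected components (detached co-products become their
#' own records), filtered by the policy, deduplicated by canonical key and
#' returned in a deterministic order (substrate key, operator id, product
#' key). Products violating the valence table are dropped and counted in
#' the \code{"dropped_valence"} attribute.
#'
#' @param substrate a \code{MolecularGraph}.
#' @param lib an \code{OperatorLibrary}.
#' @param rounds 1 or 2 (two rounds maximum, by design).
#' @param policy a \code{FilterPolicy}; defaults to no filtering.
#' @return data.frame with columns \code{substrate_key}, \code{operator_id},
#'   \code{product_key}, \code{round}, \code{ec_numbers}
#'   (semicolon-joined), \code{substrate_name}, and a list-column
#'   \code{product} holding the product graphs.
#' @export
predictMetabolites <- function(substrate, lib, rounds = 2,
                               policy = filterPolicy()) {
  if (!rounds %in% c(1, 2))
    stop("rounds must be 1 or 2 (two-round cap, mirroring phase I/II ",
         "xenobiotic metabolism)", call. = FALSE)
  dropped <- 0L
  r1 <- .predictOneRound(substrate, lib, 1L)
  dropped <- dropped + attr(r1, "dropped_valence")
  records <- r1
  if (rounds == 2 && nrow(r1)) {
    seen <- character()
    for (i in order(r1$product_key)) {
      pk <- r1$product_key[i]
      if (pk %in% seen) next
      seen <- c(seen, pk)
      r2 <- .predictOneRound(r1$product[[i]], lib, 2L)
      dropped <- dropped + attr(r2, "dropped_valence")
      records <- rbind(records, r2)
    }
  }
  records <- filterProducts(records, policy)
  if (nrow(records)) {
    key <- paste(records$substrate_key, records$operator_id,
                 records$product_key, records$round)
    records <- records[!duplicated(key), , drop = FALSE]
    records <- records[order(records$round, records$substrate_key,
                             records$operator_id, records$product_key), ,
                       drop = FALSE]
    rownames(records) <- NULL
  }
  attr(records, "dropped_valence") <- dropped
  records
}

.emptyPredictions <- function() {
  out <- data.frame(substrate_key = character(), operator_id = character(),
                    product_key = character(), round = integer(),
                    ec_numbers = character(), substrate_name = character(),
                    stringsAsFactors = FALSE)
  out$product <- list()
  out
}

.predictOneRound <- function(substrate, lib, round) {
  skey <- canonicalKey(substrate)
  rows <- list()
  dropped <- 0L
  ids <- vapply(lib@operators, function(o) o@id, character(1))
  for (oi in order(ids)) {
    op <- lib@operators[[oi]]
    sites <- matchSites(substrate, op)
    for (site in sites) {
      prod <- tryCatch(applyOperator(substrate, op, site),
                       flavopredict_valence_error = function(e) {
                         dropped <<- dropped + 1L
                         NULL
                       })
      if (is.null(prod)) next
      for (comp in splitComponents(prod)) {
        rows[[length(rows) + 1]] <- list(
          substrate_key = skey, operator_id = op@id,
          product_key = canonicalKey(comp), round = round,
          ec_numbers = paste(op@ec_numbers, collapse = ";"),
          substrate_name = substrate@name, product = comp)
      }
    }
  }
  if (!length(rows)) {
    out <- .emptyPredictions()
    attr(out, "dropped_valence") <- dropped
    return(out)
  }
  out <- data.frame(
    substrate_key = vapply(rows, `[[`, character(1), "substrate_key"),
    operator_id = vapply(rows, `[[`, character(1), "operator_id"),
    product_key = vapply(rows, `[[`, character(1), "product_key"),
    round = vapply(rows, `[[`, integer(1), "round"),
    ec_numbers = vapply(rows, `[[`, character(1), "ec_numbers"),
    substrate_name = vapply(rows, `[[`, character(1), "substrate_name"),
    stringsAsFactors = FALSE)
  out$product <- lapply(rows, `[[`, "product")
  out <- out[!duplicated(paste(out$operator_id, out$product_key)), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_valence") <- dropped
  out
}
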