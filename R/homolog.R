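#' Global percent identity between two protein sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5 by default, via \code{Biostrings::pairwiseAlignment});
#' identity is the number of identical aligned positions divided by the
#' total number of alignment columns (gaps included), times 100. The
#' "sequence similarity score" of a homolog screen is operationalised as
#' this percent identity; positive-substitution similarity is available as
#' an alternative.
#'
#' @param a,b protein sequences (character or \code{Biostrings::AAString});
#'   20-letter alphabet plus X.
#' @param substitutionMatrix scoring matrix name (default "BLOSUM62").
#' @param gapOpening,gapExtension gap penalties (Biostrings conventions).
#' @param mode \code{"identity"} (default) or \code{"similarity"}
#'   (positive-scoring aligned pairs also count).
#' @return numeric percent in [0, 100].
#' @export
globalIdentity <- function(a, b, substitutionMatrix = "BLOSUM62",
                           gapOpening = 10, gapExtension = 0.5,
                           mode = c("identity", "similarity")) {
  mode <- match.arg(mode)
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b))
    stop("empty sequence", call. = FALSE)
  mat <- .substMatrix(substitutionMatrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = gapOpening,
    gapExtension = gapExtension)
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol_aln <- length(sa)
  if (mode == "identity") {
    100 * sum(sa == sb) / ncol_aln
  } else {
    both <- sa != "-" & sb != "-"
    pos <- both
    pos[both] <- mat[cbind(sa[both], sb[both])] > 0
    100 * sum(pos) / ncol_aln
  }
}

.substMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Screen candidate proteins for homologs of a reference
#'
#' Returns the candidates whose global percent identity to the reference is
#' strictly greater than the threshold, sorted by descending identity.
#'
#' @param reference a protein sequence (character or AAString).
#' @param candidates named character vector, list, or
#'   \code{Biostrings::AAStringSet}.
#' @param threshold percent in (0, 100]; strict inequality is applied.
#' @param ... passed to \code{\link{globalIdentity}}.
#' @return data.frame with columns \code{id} and \code{identity}.
#' @export
.asSeqVector <- function(x) {
  nm <- names(x)
  out <- if (is.list(x)) vapply(x, as.character, character(1))
         else as.character(x)
  if (is.null(names(out))) names(out) <- nm
  out
}

screenHomologs <- function(reference, candidates, threshold = 80, ...) {
  stopifnot(threshold > 0, threshold <= 100)
  seqs <- .asSeqVector(candidates)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  idy <- vapply(seqs, function(s) globalIdentity(reference, s, ...),
                numeric(1))
  keep <- idy > threshold
  out <- data.frame(id = ids[keep], identity = unname(idy[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$identity, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise identity matrix for a set of protein sequences
#'
#' @param seqs named character vector, list, or AAStringSet.
#' @param ... passed to \code{\link{globalIdentity}}.
#' @return symmetric matrix of percent identities with 100 on the diagonal.
#' @export
identityMatrix <- function(seqs, ...) {
  seqs <- .asSeqVector(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- globalIdentity(seqs[[i]], seqs[[j]], ...)
  }
  m
}

#' Neighbour-joining tree from an identity matrix
#'
#' Identities are converted to distances (100 - identity) and agglomerated
#' with the standard neighbour-joining Q-criterion (\code{ape::nj});
#' neighbour joining reconstructs any additive distance matrix exactly.
#'
#' @param identity symmetric percent-identity matrix (>= 3 sequences), or a
#'   distance matrix if \code{is_distance = TRUE}.
#' @param is_distance interpret the input as distances directly.
#' @return an unrooted \code{ape::phylo} tree.
#' @export
njTree <- function(identity, is_distance = FALSE) {
  stopifnot(is.matrix(identity))
  if (nrow(identity) < 3)
    stop("neighbour joining needs at least 3 leaves", call. = FALSE)
  d <- if (is_distance) identity else 100 - identity
  ape::nj(stats::as.dist(d))
}

#' Read / write protein FASTA
#'
#' Thin wrappers over Biostrings so the screen can consume standard files.
#'
#' @param path FASTA file path.
#' @param seqs named character vector or AAStringSet.
#' @return \code{readProteinFasta}: an \code{AAStringSet}.
#' @export
readProteinFasta <- function(path) Biostrings::readAAStringSet(path)

#' @rdname readProteinFasta
#' @export
writeProteinFasta <- function(seqs, path) {
  if (!methods::is(seqs, "AAStringSet"))
    seqs <- Biostrings::AAStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
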