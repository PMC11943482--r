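#' Parse a SMILES string into a MolecularGraph
#'
#' Reads the constitutional subset of SMILES sufficient for polyphenols and
#' related small molecules: organic-subset atoms (\code{B C N O P S F Cl Br
#' I}), aromatic lowercase atoms (\code{b c n o p s}), bracket atoms with
#' charge and explicit H counts, bonds \code{- = # :}, branches and ring
#' closures (\code{1}-\code{9} and \code{\%nn}). Stereo markers (\code{/ \\
#' @}) and isotopes are accepted and ignored; atom classes are ignored.
#' A bond between two aromatic atoms with no explicit bond symbol is
#' aromatic, otherwise single. Atom types are perceived from the bonding
#' environment (see \code{\link{perceiveAtomTypes}}) and atoms are numbered
#' in order of appearance.
#'
#' @param smiles character scalar.
#' @param name compound name to attach.
#' @param external_id optional catalogue identifier.
#' @return a \code{MolecularGraph}.
#' @export
parseSmiles <- function(smiles, name = "", external_id = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  err <- function(pos, msg)
    stop(sprintf("SMILES parse error near position %d in %s: %s",
                 pos, sQuote(smiles), msg), call. = FALSE)
  atoms <- list()           # list of (element, aromatic, charge)
  bonds <- list()           # list of (a1, a2, order)
  prev <- NA_integer_       # current attachment atom
  stack <- integer()        # branch stack
  ring <- list()            # ring-closure slots: id -> c(atom, order or NA)
  pending <- NA_character_  # explicit bond symbol awaiting next atom
  i <- 1L
  addAtom <- function(el, aromatic, charge = 0L) {
    atoms[[length(atoms) + 1L]] <<- list(element = el, aromatic = aromatic,
                                         charge = charge)
    length(atoms)
  }
  addBond <- function(a1, a2, order) {
    bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, order = order)
  }
  connect <- function(at, pos) {
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord))
        ord <- if (atoms[[prev]]$aromatic && atoms[[at]]$aromatic)
          "aromatic" else "single"
      addBond(prev, at, ord)
    }
    pending <<- NA_character_
    prev <<- at
  }
  twoLetter <- c("Cl", "Br")
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("/", "\\")) { i <- i + 1L; next }  # stereo bond: single
    if (ch == "-") { pending <- "single"; i <- i + 1L; next }
    if (ch == "=") { pending <- "double"; i <- i + 1L; next }
    if (ch == "#") { pending <- "triple"; i <- i + 1L; next }
    if (ch == ":") { pending <- "aromatic"; i <- i + 1L; next }
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(stack)) err(i, "unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch == ".") { prev <- NA_integer_; i <- i + 1L; next }
    if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) err(i, "truncated %nn ring closure")
        id <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { id <- ch; i <- i + 1L }
      if (is.na(prev)) err(i, "ring closure before any atom")
      slot <- ring[[id]]
      if (is.null(slot)) {
        ring[[id]] <- list(atom = prev, order = pending)
        pending <- NA_character_
      } else {
        ord <- pending
        if (is.na(ord)) ord <- slot$order
        if (is.na(ord))
          ord <- if (atoms[[slot$atom]]$aromatic && atoms[[prev]]$aromatic)
            "aromatic" else "single"
        addBond(slot$atom, prev, ord)
        ring[[id]] <- NULL
        pending <- NA_character_
      }
      next
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) err(i, "unterminated bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      body <- gsub("^[0-9]+", "", body)          # isotope
      m <- regexpr("^([A-Z][a-z]?|[bcnops])", body)
      if (m == -1) err(i, "bracket atom without element")
      el_raw <- regmatches(body, m)
      rest <- sub("^([A-Z][a-z]?|[bcnops])", "", body)
      aromatic <- el_raw %in% c("b", "c", "n", "o", "p", "s")
      el <- if (aromatic) toupper(el_raw) else el_raw
      rest <- gsub("@+", "", rest)               # stereo
      rest <- sub(":\\d+$", "", rest)            # atom class
      charge <- 0L
      cm <- regmatches(rest, regexpr("[+-]+\\d*", rest))
      if (length(cm) && nzchar(cm)) {
        sign <- if (startsWith(cm, "-")) -1L else 1L
        num <- suppressWarnings(as.integer(gsub("[+-]", "", cm)))
        charge <- if (!is.na(num)) sign * num
                  else sign * nchar(gsub("[^+-]", "", cm))
      }
      at <- addAtom(el, aromatic, charge)
      connect(at, i)
      i <- j + 1L
      next
    }
    # organic-subset atom
    el <- NA_character_
    if (i < n && paste0(ch, chars[i + 1L]) %in% twoLetter) {
      el <- paste0(ch, chars[i + 1L]); i <- i + 2L
      at <- addAtom(el, FALSE); connect(at, i); next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      at <- addAtom(ch, FALSE); connect(at, i); i <- i + 1L; next
    }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      at <- addAtom(toupper(ch), TRUE); connect(at, i); i <- i + 1L; next
    }
    err(i, paste("unexpected character", sQuote(ch)))
  }
  if (length(stack)) err(n, "unbalanced '('")
  open_rings <- names(ring)[!vapply(ring, is.null, logical(1))]
  if (length(open_rings))
    err(n, paste("unclosed ring bond(s):", paste(open_rings, collapse = ",")))
  if (!length(atoms)) err(1L, "no atoms")
  adf <- data.frame(
    index = seq_along(atoms),
    element = vapply(atoms, `[[`, character(1), "element"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    stringsAsFactors = FALSE)
  bdf <- if (length(bonds)) data.frame(
    a1 = vapply(bonds, `[[`, integer(1), "a1"),
    a2 = vapply(bonds, `[[`, integer(1), "a2"),
    order = vapply(bonds, `[[`, character(1), "order"),
    stringsAsFactors = FALSE) else NULL
  molecularGraph(adf, bdf, name = name, external_id = external_id,
                 normalize = TRUE, perceive = TRUE)
}
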