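#' Read and write KCF-style structure records
#'
#' A KCF-style record encodes one compound as an ATOM block and a BOND block
#' with declared counts, in the tradition of chemical-function formats:
#'
#' \preformatted{
#' ENTRY       C00001  Compound
#' NAME        benzene
#' ATOM        6
#'             1  C.arom  C
#'             ...
#' BOND        6
#'             1  1  2  aromatic
#'             ...
#' ///
#' }
#'
#' Atom lines carry index, atom_type, optional element (derived from the
#' type when absent) and optional charge; bond lines carry a serial, the two
#' atom indices and a bond order (names, or 1/2/3/4 where 4 = aromatic).
#' ENTRY/NAME and the terminator are optional. Atom-type labels are
#' preserved verbatim; a single aromatic normalisation pass is applied so
#' matching is independent of Kekule representation.
#'
#' @param text character scalar (or vector of lines) holding one record.
#' @return \code{parseKCF}: a \code{MolecularGraph}.
#' @export
parseKCF <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  stopLine <- function(i, msg)
    stop(sprintf("KCF parse error at line %d: %s", i, msg), call. = FALSE)
  name <- ""; external_id <- NA_character_
  atom_n <- NA_integer_; bond_n <- NA_integer_
  atoms <- NULL; bonds <- NULL
  mode <- ""
  a_rows <- list(); b_rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "///")) next
    head_tok <- regmatches(ln, regexpr("^[A-Z]+", ln))
    if (length(head_tok) && nzchar(head_tok)) {
      rest <- trimws(sub("^[A-Z]+", "", ln))
      if (head_tok == "ENTRY") {
        external_id <- strsplit(rest, "\\s+")[[1]][1]; mode <- ""
      } else if (head_tok == "NAME") {
        name <- rest; mode <- ""
      } else if (head_tok == "ATOM") {
        atom_n <- suppressWarnings(as.integer(rest))
        if (is.na(atom_n)) stopLine(i, "malformed ATOM block header")
        mode <- "atom"
      } else if (head_tok == "BOND") {
        bond_n <- suppressWarnings(as.integer(rest))
        if (is.na(bond_n)) stopLine(i, "malformed BOND block header")
        mode <- "bond"
      } else stopLine(i, paste("unknown block", head_tok))
      next
    }
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (mode == "atom") {
      if (length(tok) < 2) stopLine(i, "atom line needs index and atom_type")
      idx <- suppressWarnings(as.integer(tok[1]))
      if (is.na(idx)) stopLine(i, "non-integer atom index")
      a_rows[[length(a_rows) + 1]] <- list(
        line = i, index = idx, atom_type = tok[2],
        element = if (length(tok) >= 3) tok[3] else elementOf(tok[2]),
        charge = if (length(tok) >= 4) as.integer(tok[4]) else 0L)
    } else if (mode == "bond") {
      if (length(tok) < 4) stopLine(i, "bond line needs serial, atoms, order")
      a1 <- suppressWarnings(as.integer(tok[2]))
      a2 <- suppressWarnings(as.integer(tok[3]))
      if (is.na(a1) || is.na(a2)) stopLine(i, "non-integer bond endpoint")
      ord <- tok[4]
      if (ord %in% c("1", "2", "3", "4"))
        ord <- BOND_ORDERS[as.integer(ord)]
      if (!ord %in% BOND_ORDERS) stopLine(i, paste("unknown bond order", ord))
      b_rows[[length(b_rows) + 1]] <- list(line = i, a1 = a1, a2 = a2,
                                           order = ord)
    } else stopLine(i, "data line outside ATOM/BOND block")
  }
  if (is.na(atom_n)) stop("KCF parse error: missing ATOM block", call. = FALSE)
  if (length(a_rows) != atom_n)
    stop(sprintf("KCF parse error: ATOM declares %d atoms but %d lines found",
                 atom_n, length(a_rows)), call. = FALSE)
  if (!is.na(bond_n) && length(b_rows) != bond_n)
    stop(sprintf("KCF parse error: BOND declares %d bonds but %d lines found",
                 bond_n, length(b_rows)), call. = FALSE)
  idxs <- vapply(a_rows, function(r) r$index, integer(1))
  dup <- which(duplicated(idxs))
  if (length(dup))
    stopLine(a_rows[[dup[1]]]$line, paste("duplicate atom index", idxs[dup[1]]))
  for (r in b_rows) {
    if (!(r$a1 %in% idxs) || !(r$a2 %in% idxs))
      stopLine(r$line, "dangling bond index")
  }
  atoms <- data.frame(
    index = idxs,
    atom_type = vapply(a_rows, function(r) r$atom_type, character(1)),
    element = vapply(a_rows, function(r) r$element, character(1)),
    charge = vapply(a_rows, function(r) r$charge, integer(1)),
    stringsAsFactors = FALSE)
  bonds <- if (length(b_rows)) data.frame(
    a1 = vapply(b_rows, function(r) r$a1, integer(1)),
    a2 = vapply(b_rows, function(r) r$a2, integer(1)),
    order = vapply(b_rows, function(r) r$order, character(1)),
    stringsAsFactors = FALSE) else NULL
  suppressMessages(
    molecularGraph(atoms, bonds, name = name, external_id = external_id))
}

#' @rdname parseKCF
#' @param g a \code{MolecularGraph}.
#' @return \code{writeKCF}: a character scalar holding the record; it
#'   re-parses to a graph isomorphic to \code{g}.
#' @export
writeKCF <- function(g) {
  out <- character()
  if (!is.na(g@external_id))
    out <- c(out, sprintf("ENTRY       %s  Compound", g@external_id))
  if (nzchar(g@name)) out <- c(out, sprintf("NAME        %s", g@name))
  out <- c(out, sprintf("ATOM        %d", nrow(g@atoms)))
  if (nrow(g@atoms)) {
    a <- g@atoms
    out <- c(out, sprintf("            %-4d %-12s %-2s %d",
                          a$index, a$atom_type, a$element, a$charge))
  }
  out <- c(out, sprintf("BOND        %d", nrow(g@bonds)))
  if (nrow(g@bonds)) {
    b <- g@bonds
    out <- c(out, sprintf("            %-4d %-4d %-4d %s",
                          seq_len(nrow(b)), b$a1, b$a2, b$order))
  }
  paste(c(out, "///"), collapse = "\n")
}
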