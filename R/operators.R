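#' Construct a ReactionPair
#'
#' @param id pair identifier.
#' @param reactant,product \code{MolecularGraph} objects.
#' @param atom_map two-column matrix or data.frame of (reactant index,
#'   product index) rows over conserved atoms; must be injective.
#' @param ec_numbers character vector of EC numbers.
#' @param reversible logical; if TRUE reverse-direction operators are also
#'   derived.
#' @return a \code{ReactionPair}.
#' @export
reactionPair <- function(id, reactant, product, atom_map, ec_numbers,
                         reversible = TRUE) {
  m <- as.matrix(atom_map)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  new("ReactionPair", id = id, reactant = reactant, product = product,
      atom_map = m, ec_numbers = ec_numbers, reversible = reversible)
}

setMethod("show", "ReactionPair", function(object) {
  cat("ReactionPair", sQuote(object@id), ":",
      nrow(object@reactant@atoms), "->", nrow(object@product@atoms),
      "atoms,", nrow(object@atom_map), "mapped;",
      "EC", paste(object@ec_numbers, collapse = ","),
      if (object@reversible) "(reversible)" else "(irreversible)", "\n")
})

setMethod("show", "OperatorLibrary", function(object) {
  cat("OperatorLibrary with", length(object@operators), "operators\n")
  if (nzchar(object@provenance)) cat("  provenance:", object@provenance, "\n")
})

#' @describeIn operatorLibrary operator list accessor.
#' @export
operators <- function(lib) lib@operators

#' Construct an OperatorLibrary
#'
#' @param operators list of \code{TransformationOperator}.
#' @param provenance free text.
#' @return an \code{OperatorLibrary}.
#' @export
operatorLibrary <- function(operators, provenance = "") {
  new("OperatorLibrary", operators = operators, provenance = provenance)
}

# ---- pair diff ------------------------------------------------------------

# unordered bond lookup table: key "i|j" (i<j) -> order
.bondTable <- function(g) {
  b <- g@bonds
  if (!nrow(b)) return(stats::setNames(character(), character()))
  stats::setNames(b$order, paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2),
                                 sep = "|"))
}

.bkey <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "|")

# classify atoms of a mapped pair; returns the changed reactant atoms, the
# added product atoms, and the union-graph edges used for region finding
.diffPair <- function(rp) {
  r <- rp@reactant; p <- rp@product
  m <- stats::setNames(rp@atom_map[, 2], rp@atom_map[, 1])       # r -> p
  pm <- stats::setNames(rp@atom_map[, 1], rp@atom_map[, 2])      # p -> r
  rb <- .bondTable(r); pb <- .bondTable(p)
  mappedR <- rp@atom_map[, 1]; mappedP <- rp@atom_map[, 2]
  changed <- character()  # union-graph node names ("r<i>" / "p<q>")
  mark <- function(x) changed <<- c(changed, x)
  rnode <- function(i) paste0("r", i)
  pnodeName <- function(q) if (as.character(q) %in% names(pm))
    paste0("r", pm[[as.character(q)]]) else paste0("p", q)
  # unmapped atoms on either side
  for (i in setdiff(r@atoms$index, mappedR)) mark(rnode(i))
  for (q in setdiff(p@atoms$index, mappedP)) mark(paste0("p", q))
  # mapped atoms with label changes
  for (k in seq_len(nrow(rp@atom_map))) {
    i <- rp@atom_map[k, 1]; q <- rp@atom_map[k, 2]
    ra <- r@atoms[r@atoms$index == i, ]; pa <- p@atoms[p@atoms$index == q, ]
    if (ra$atom_type != pa$atom_type || ra$charge != pa$charge) mark(rnode(i))
  }
  # bond-level changes
  for (k in seq_along(rb)) {
    ij <- as.integer(strsplit(names(rb)[k], "|", fixed = TRUE)[[1]])
    i <- ij[1]; j <- ij[2]
    mi <- as.character(i) %in% names(m); mj <- as.character(j) %in% names(m)
    if (!mi || !mj) {
      # bond to a disappearing atom: both endpoints are in the change set
      mark(rnode(i)); mark(rnode(j)); next
    }
    pk <- .bkey(m[[as.character(i)]], m[[as.character(j)]])
    if (!pk %in% names(pb) || pb[[pk]] != rb[[k]]) {
      mark(rnode(i)); mark(rnode(j))
    }
  }
  for (k in seq_along(pb)) {
    uv <- as.integer(strsplit(names(pb)[k], "|", fixed = TRUE)[[1]])
    u <- uv[1]; v <- uv[2]
    mu <- as.character(u) %in% names(pm); mv <- as.character(v) %in% names(pm)
    if (!mu || !mv) { mark(pnodeName(u)); mark(pnodeName(v)); next }
    rk <- .bkey(pm[[as.character(u)]], pm[[as.character(v)]])
    if (!rk %in% names(rb) || rb[[rk]] != pb[[k]]) {
      mark(pnodeName(u)); mark(pnodeName(v))
    }
  }
  # union-graph edges
  e1 <- if (nrow(r@bonds)) cbind(rnode(r@bonds$a1), rnode(r@bonds$a2))
  e2 <- if (nrow(p@bonds))
    cbind(vapply(p@bonds$a1, pnodeName, character(1)),
          vapply(p@bonds$a2, pnodeName, character(1)))
  edges <- rbind(e1, e2)
  list(m = m, pm = pm, rb = rb, pb = pb,
       changed = unique(changed), edges = edges)
}

# connected components of the change set within the union graph
.changeRegions <- function(diff) {
  ch <- diff$changed
  if (!length(ch)) return(list())
  g <- igraph::make_empty_graph(length(ch), directed = FALSE)
  igraph::V(g)$name <- ch
  if (!is.null(diff$edges)) {
    sel <- diff$edges[, 1] %in% ch & diff$edges[, 2] %in% ch
    if (any(sel)) {
      el <- rbind(match(diff$edges[sel, 1], ch), match(diff$edges[sel, 2], ch))
      g <- igraph::add_edges(g, el)
    }
  }
  comp <- igraph::components(g)$membership
  regs <- split(ch, comp)
  # deterministic region order: by smallest member name
  regs[order(vapply(regs, function(x) min(sort(x)), character(1)))]
}

# ---- operator derivation --------------------------------------------------

#' Derive transformation operators from a reaction pair
#'
#' Identifies the change regions (maximal connected sets of atoms whose
#' atom type, charge, incident-bond multiset or mapped existence differs
#' between the two sides), picks a reaction center per region (the changed
#' mapped atom with the largest conserved neighbourhood within two bonds;
#' ties broken by smallest canonical atom rank) and emits one operator per
#' region and direction. Each operator's pattern is the substrate-side
#' neighbourhood of the center (two shells, induced bonds) and its edit
#' script regenerates the recorded product when applied at the source site.
#' Regions whose edits would reach beyond the second shell of every
#' candidate center, or that contain no mapped atom (detached co-substrate
#' or co-product), yield no operator and are reported via \code{message()}.
#'
#' @param rp a \code{ReactionPair}; reverse-direction operators are also
#'   emitted when \code{rp@reversible} is TRUE.
#' @param reaction_class optional class label copied onto the operators.
#' @return list of \code{TransformationOperator} (possibly empty).
#' @export
deriveOperators <- function(rp, reaction_class = NA_character_) {
  validObject(rp)
  if (!nrow(rp@atom_map)) stop("unmappable pair: empty atom_map", call. = FALSE)
  out <- .deriveDirection(rp, "forward", reaction_class)
  if (rp@reversible) {
    rev_rp <- reactionPair(rp@id, rp@product, rp@reactant,
                           rp@atom_map[, 2:1, drop = FALSE],
                           rp@ec_numbers, reversible = FALSE)
    out <- c(out, .deriveDirection(rev_rp, "reverse", reaction_class))
  }
  out
}

.deriveDirection <- function(rp, direction, reaction_class) {
  diff <- .diffPair(rp)
  regions <- .changeRegions(diff)
  if (!length(regions)) return(list())
  dists <- .topoDistances(rp@reactant)
  ranks <- .canonicalRanks(rp@reactant)
  changed_r <- as.integer(sub("^r", "", grep("^r", diff$changed, value = TRUE)))
  conserved <- setdiff(rp@atom_map[, 1], changed_r)
  ops <- list()
  for (ri in seq_along(regions)) {
    region <- regions[[ri]]
    op <- .deriveRegion(rp, diff, region, dists, ranks, conserved,
                        direction, ri, reaction_class)
    if (!is.null(op)) ops[[length(ops) + 1]] <- op
  }
  ops
}

.deriveRegion <- function(rp, diff, region, dists, ranks, conserved,
                          direction, ordinal, reaction_class) {
  r <- rp@reactant; p <- rp@product
  reg_r <- as.integer(sub("^r", "", grep("^r", region, value = TRUE)))
  reg_p_added <- as.integer(sub("^p", "", grep("^p", region, value = TRUE)))
  candidates <- intersect(reg_r, rp@atom_map[, 1])
  if (!length(candidates)) {
    message("region with no mapped atom skipped for pair ", rp@id,
            " (detached co-substrate/co-product)")
    return(NULL)
  }
  dch <- as.character(candidates)
  nb_size <- vapply(dch, function(cc)
    sum(dists[cc, as.character(conserved)] <= 2), numeric(1))
  best <- candidates[nb_size == max(nb_size)]
  center <- best[which.min(ranks[as.character(best)])]
  patt_atoms <- as.integer(colnames(dists)[dists[as.character(center), ] <= 2])
  if (!all(reg_r %in% patt_atoms)) {
    message("region beyond the second shell of its center skipped for pair ",
            rp@id)
    return(NULL)
  }
  # added atoms must attach to pattern atoms (or to each other)
  for (q in reg_p_added) {
    nb <- p@bonds[p@bonds$a1 == q | p@bonds$a2 == q, , drop = FALSE]
    others <- setdiff(c(nb$a1, nb$a2), q)
    pre <- diff$pm[as.character(others)]
    mapped_others <- pre[!is.na(pre)]
    added_others <- others[is.na(pre)]
    if (!all(mapped_others %in% patt_atoms) ||
        !all(added_others %in% reg_p_added)) {
      message("added atoms reach beyond the pattern; region skipped for pair ",
              rp@id)
      return(NULL)
    }
  }
  # pattern node numbering: center first, then by (shell, type, canon rank)
  shell <- dists[as.character(center), as.character(patt_atoms)]
  a_tab <- r@atoms[match(patt_atoms, r@atoms$index), ]
  ord <- order(shell, a_tab$atom_type, ranks[as.character(patt_atoms)])
  patt_atoms <- patt_atoms[ord]; shell <- shell[ord]
  node_of <- stats::setNames(seq_along(patt_atoms), patt_atoms)
  a_tab <- r@atoms[match(patt_atoms, r@atoms$index), ]
  pattern <- data.frame(node = seq_along(patt_atoms),
                        atom_type = a_tab$atom_type,
                        charge = a_tab$charge,
                        shell = as.integer(shell),
                        stringsAsFactors = FALSE)
  pb_sel <- r@bonds$a1 %in% patt_atoms & r@bonds$a2 %in% patt_atoms
  pb <- r@bonds[pb_sel, , drop = FALSE]
  pattern_bonds <- data.frame(
    n1 = pmin(node_of[as.character(pb$a1)], node_of[as.character(pb$a2)]),
    n2 = pmax(node_of[as.character(pb$a1)], node_of[as.character(pb$a2)]),
    order = pb$order, stringsAsFactors = FALSE)
  pattern_bonds <- pattern_bonds[order(pattern_bonds$n1, pattern_bonds$n2), ,
                                 drop = FALSE]
  rownames(pattern_bonds) <- NULL
  # new nodes for added product atoms, deterministic by product canon rank
  new_nodes <- integer()
  if (length(reg_p_added)) {
    pranks <- .canonicalRanks(p)
    reg_p_added <- reg_p_added[order(pranks[as.character(reg_p_added)])]
    new_nodes <- stats::setNames(
      length(patt_atoms) + seq_along(reg_p_added), reg_p_added)
  }
  pnode <- function(q) {
    # product atom -> edit node id
    qc <- as.character(q)
    if (qc %in% names(diff$pm)) node_of[[as.character(diff$pm[[qc]])]]
    else new_nodes[[qc]]
  }
  edits <- list()
  add <- function(e) edits[[length(edits) + 1]] <<- e
  m <- diff$m; rb <- diff$rb; pbt <- diff$pb
  # bonds among mapped pattern atoms: removed or order-changed
  for (k in seq_along(rb)) {
    ij <- as.integer(strsplit(names(rb)[k], "|", fixed = TRUE)[[1]])
    if (!all(ij %in% patt_atoms)) next
    if (!all(as.character(ij) %in% names(m))) next
    pk <- .bkey(m[[as.character(ij[1])]], m[[as.character(ij[2])]])
    n1 <- node_of[[as.character(ij[1])]]; n2 <- node_of[[as.character(ij[2])]]
    if (!pk %in% names(pbt)) {
      if (all(ij %in% reg_r))
        add(list(type = "remove_bond", n1 = min(n1, n2), n2 = max(n1, n2)))
    } else if (pbt[[pk]] != rb[[k]]) {
      if (all(ij %in% reg_r))
        add(list(type = "change_bond_order", n1 = min(n1, n2),
                 n2 = max(n1, n2), order = pbt[[pk]]))
    }
  }
  # unmapped reactant atoms in the region are removed
  for (i in setdiff(reg_r, rp@atom_map[, 1]))
    add(list(type = "remove_atom", node = node_of[[as.character(i)]]))
  # label changes on mapped region atoms
  for (i in intersect(reg_r, rp@atom_map[, 1])) {
    q <- m[[as.character(i)]]
    ra <- r@atoms[r@atoms$index == i, ]
    pa <- p@atoms[p@atoms$index == q, ]
    if (ra$atom_type != pa$atom_type || ra$charge != pa$charge)
      add(list(type = "change_atom_type", node = node_of[[as.character(i)]],
               atom_type = pa$atom_type, charge = pa$charge))
  }
  # added atoms and new bonds
  for (q in reg_p_added) {
    pa <- p@atoms[p@atoms$index == q, ]
    add(list(type = "add_atom", node = unname(new_nodes[[as.character(q)]]),
             atom_type = pa$atom_type, element = pa$element,
             charge = pa$charge))
  }
  for (k in seq_along(pbt)) {
    uv <- as.integer(strsplit(names(pbt)[k], "|", fixed = TRUE)[[1]])
    known <- vapply(uv, function(q) {
      qc <- as.character(q)
      (qc %in% names(diff$pm) && diff$pm[[qc]] %in% patt_atoms) ||
        qc %in% names(new_nodes)
    }, logical(1))
    if (!all(known)) next
    mapped_uv <- vapply(uv, function(q) as.character(q) %in% names(diff$pm),
                        logical(1))
    if (all(mapped_uv)) {
      rk <- .bkey(diff$pm[[as.character(uv[1])]],
                  diff$pm[[as.character(uv[2])]])
      if (rk %in% names(rb)) next  # kept or order-changed, handled above
      if (!all(c(diff$pm[[as.character(uv[1])]],
                 diff$pm[[as.character(uv[2])]]) %in% reg_r)) next
    }
    n1 <- pnode(uv[1]); n2 <- pnode(uv[2])
    add(list(type = "add_bond", n1 = min(n1, n2), n2 = max(n1, n2),
             order = pbt[[k]]))
  }
  edits <- .sortEdits(edits)
  site <- stats::setNames(patt_atoms, seq_along(patt_atoms))
  new("TransformationOperator",
      id = sprintf("%s.%s%d", rp@id,
                   if (direction == "forward") "f" else "r", ordinal),
      center_type = pattern$atom_type[1],
      pattern = pattern, pattern_bonds = pattern_bonds, edits = edits,
      ec_numbers = rp@ec_numbers, source_pair = rp@id, direction = direction,
      source_site = site, reaction_class = reaction_class)
}

.editRankKey <- function(e) {
  ord <- c(remove_bond = 1, remove_atom = 2, change_bond_order = 3,
           change_atom_type = 4, add_atom = 5, add_bond = 6)
  sprintf("%d|%05d|%05d", ord[[e$type]],
          if (!is.null(e$n1)) e$n1 else e$node,
          if (!is.null(e$n2)) e$n2 else 0L)
}

.sortEdits <- function(edits) {
  if (!length(edits)) return(edits)
  edits[order(vapply(edits, .editRankKey, character(1)))]
}

# ---- matching -------------------------------------------------------------

#' Find the sites of a substrate matching an operator's pattern
#'
#' Anchored monomorphism search: pattern atoms are assigned to distinct
#' substrate atoms with exact atom-type/charge agreement and every pattern
#' bond present in the substrate with the same order. Sites equivalent
#' under a substrate automorphism are deduplicated (exact test: the two
#' site colorings of the substrate are isomorphic as colored graphs).
#'
#' @param substrate a \code{MolecularGraph}.
#' @param op a \code{TransformationOperator}.
#' @return list of site mappings (named integer vectors pattern node ->
#'   substrate atom index); empty list when nothing matches.
#' @export
matchSites <- function(substrate, op) {
  patt <- op@pattern; pbonds <- op@pattern_bonds
  k <- nrow(patt)
  if (!k) return(list())
  at <- substrate@atoms; bt <- .bondTable(substrate)
  # adjacency: atom index -> data.frame(other, order)
  nb_of <- function(i) {
    sel <- substrate@bonds$a1 == i | substrate@bonds$a2 == i
    b <- substrate@bonds[sel, , drop = FALSE]
    data.frame(other = ifelse(b$a1 == i, b$a2, b$a1), order = b$order,
               stringsAsFactors = FALSE)
  }
  # BFS order over pattern nodes with a parent edge for candidate generation
  parent <- rep(NA_integer_, k); porder <- rep(NA_character_, k)
  visit <- 1L; seen <- c(1L, rep(NA_integer_, k - 1L)); head <- 1L
  while (head <= visit && visit < k) {
    v <- seen[head]
    adj <- pbonds[pbonds$n1 == v | pbonds$n2 == v, , drop = FALSE]
    for (j in seq_len(nrow(adj))) {
      w <- if (adj$n1[j] == v) adj$n2[j] else adj$n1[j]
      if (!w %in% seen[seq_len(visit)]) {
        visit <- visit + 1L
        seen[visit] <- w
        parent[w] <- v; porder[w] <- adj$order[j]
      }
    }
    head <- head + 1L
  }
  if (visit < k) stop("disconnected operator pattern")
  check_edges <- function(assign, v, atom_idx) {
    adj <- pbonds[pbonds$n1 == v | pbonds$n2 == v, , drop = FALSE]
    for (j in seq_len(nrow(adj))) {
      w <- if (adj$n1[j] == v) adj$n2[j] else adj$n1[j]
      if (!is.na(assign[w])) {
        key <- .bkey(atom_idx, assign[w])
        if (!key %in% names(bt) || bt[[key]] != adj$order[j]) return(FALSE)
      }
    }
    TRUE
  }
  results <- list()
  assign <- rep(NA_integer_, k)
  recurse <- function(pos) {
    if (pos > k) {
      results[[length(results) + 1]] <<- stats::setNames(assign, seq_len(k))
      return(invisible())
    }
    v <- seen[pos]
    cands <- if (pos == 1L) {
      at$index[at$atom_type == patt$atom_type[v] & at$charge == patt$charge[v]]
    } else {
      nb <- nb_of(assign[parent[v]])
      cand <- nb$other[nb$order == porder[v]]
      cand[at$atom_type[match(cand, at$index)] == patt$atom_type[v] &
           at$charge[match(cand, at$index)] == patt$charge[v]]
    }
    for (a in sort(cands)) {
      if (a %in% assign) next
      if (!check_edges(assign, v, a)) next
      assign[v] <<- a
      recurse(pos + 1L)
      assign[v] <<- NA_integer_
    }
  }
  recurse(1L)
  if (length(results) <= 1) return(results)
  results <- results[order(vapply(results, paste, character(1),
                                  collapse = ","))]
  .dedupSites(substrate, results, op)
}

# automorphism dedup: sites are equivalent when the substrate, vertex-
# colored by (atom label, orbit of the assigned pattern node), is
# isomorphic to itself across the two colorings; the orbit coloring also
# collapses assignments that only permute symmetric spectator shell atoms
.dedupSites <- function(substrate, sites, op) {
  base <- .atomLabels(substrate)
  ig <- .asIgraph(substrate)
  idx <- as.integer(igraph::V(ig)$name)
  euniv <- BOND_ORDERS
  ecol <- if (nrow(substrate@bonds))
    .colorsFor(substrate@bonds$order, euniv) else NULL
  orbit <- .patternOrbits(op)
  labelled <- function(site) {
    node_at <- rep("", length(idx))
    node_at[match(site, idx)] <- orbit[as.integer(names(site))]
    paste0(base[match(idx, substrate@atoms$index)], "#", node_at)
  }
  kept <- list(); kept_lab <- list()
  for (s in sites) {
    lab <- labelled(s)
    dup <- FALSE
    for (j in seq_along(kept)) {
      lab2 <- kept_lab[[j]]
      if (!identical(sort(lab), sort(lab2))) next
      univ <- unique(c(lab, lab2))
      if (igraph::isomorphic(ig, ig, method = "vf2",
                             vertex.color1 = match(lab, univ),
                             vertex.color2 = match(lab2, univ),
                             edge.color1 = ecol, edge.color2 = ecol)) {
        dup <- TRUE; break
      }
    }
    if (!dup) { kept[[length(kept) + 1]] <- s
                kept_lab[[length(kept_lab) + 1]] <- lab }
  }
  kept
}

# ---- application ----------------------------------------------------------

#' Apply a transformation operator at a matched site
#'
#' Executes the operator's edit script against the substrate: bonds are
#' removed or change order, atoms named by the pattern are removed (with
#' their incident bonds) or relabelled, and new atoms/bonds are introduced
#' with fresh indices. The edited graph must respect the valence table; a
#' violation raises a condition of class \code{"flavopredict_valence_error"}
#' (the prediction pipeline drops and logs such products).
#'
#' @param substrate a \code{MolecularGraph}.
#' @param op a \code{TransformationOperator}.
#' @param site a site mapping from \code{\link{matchSites}}.
#' @return the product \code{MolecularGraph} (possibly disconnected).
#' @export
applyOperator <- function(substrate, op, site) {
  .applyOperatorInternal(substrate, op, site)$graph
}

.applyOperatorInternal <- function(substrate, op, site) {
  a <- substrate@atoms; b <- substrate@bonds
  atom_of <- as.list(stats::setNames(as.integer(site), names(site)))
  next_idx <- if (nrow(a)) max(a$index) else 0L
  touched <- integer()
  dropBond <- function(b, i, j) b[!(pmin(b$a1, b$a2) == min(i, j) &
                                    pmax(b$a1, b$a2) == max(i, j)), ,
                                  drop = FALSE]
  for (e in op@edits) {
    if (e$type == "remove_bond") {
      i <- atom_of[[as.character(e$n1)]]; j <- atom_of[[as.character(e$n2)]]
      b <- dropBond(b, i, j); touched <- c(touched, i, j)
    } else if (e$type == "remove_atom") {
      i <- atom_of[[as.character(e$node)]]
      nbrs <- c(b$a1[b$a2 == i], b$a2[b$a1 == i])
      touched <- c(touched, nbrs)
      a <- a[a$index != i, , drop = FALSE]
      b <- b[b$a1 != i & b$a2 != i, , drop = FALSE]
    } else if (e$type == "change_bond_order") {
      i <- atom_of[[as.character(e$n1)]]; j <- atom_of[[as.character(e$n2)]]
      sel <- pmin(b$a1, b$a2) == min(i, j) & pmax(b$a1, b$a2) == max(i, j)
      if (!any(sel)) stop("edit references a missing bond", call. = FALSE)
      b$order[sel] <- e$order; touched <- c(touched, i, j)
    } else if (e$type == "change_atom_type") {
      i <- atom_of[[as.character(e$node)]]
      sel <- a$index == i
      a$atom_type[sel] <- e$atom_type
      a$element[sel] <- elementOf(e$atom_type)
      a$charge[sel] <- e$charge
      touched <- c(touched, i)
    } else if (e$type == "add_atom") {
      next_idx <- next_idx + 1L
      atom_of[[as.character(e$node)]] <- next_idx
      a <- rbind(a, data.frame(index = next_idx, element = e$element,
                               atom_type = e$atom_type, charge = e$charge,
                               implicit_h = 0L))
      touched <- c(touched, next_idx)
    } else if (e$type == "add_bond") {
      i <- atom_of[[as.character(e$n1)]]; j <- atom_of[[as.character(e$n2)]]
      b <- rbind(b, data.frame(a1 = i, a2 = j, order = e$order))
      touched <- c(touched, i, j)
    } else stop("unknown edit type ", e$type, call. = FALSE)
  }
  ok <- .valenceOK(a, b)
  if (!all(ok)) {
    bad <- a$index[!ok][1]
    cond <- structure(
      class = c("flavopredict_valence_error", "error", "condition"),
      list(message = sprintf(
        "operator %s would exceed the valence of atom %d (%s)",
        op@id, bad, a$atom_type[a$index == bad]), call = NULL))
    stop(cond)
  }
  a$implicit_h <- .implicitH(a, b)
  rownames(a) <- NULL; rownames(b) <- NULL
  g <- new("MolecularGraph", atoms = a, bonds = b,
           name = "", external_id = NA_character_)
  validObject(g)
  list(graph = g, kept = stats::setNames(a$index, a$index))
}

# ---- canonical operator signature ----------------------------------------

#' Canonical signature of an operator's pattern and edit script
#'
#' A string invariant under renumbering of pattern nodes: the pattern graph
#' and edit script are folded into one colored graph (vertex colors encode
#' shell, atom type, charge and atom-level edits; edge colors encode order
#' and bond-level edits) which is canonicalised the same way as
#' \code{\link{canonicalKey}}. Operators with the same signature describe
#' the same atom-group transformation, so report-level deduplication uses
#' this key.
#'
#' @param op a \code{TransformationOperator}.
#' @return character scalar.
#' @export
operatorSignature <- function(op) {
  cg <- .operatorColoredGraph(op)
  colors <- match(cg$labels, sort(unique(cg$labels)))
  cp <- igraph::canonical_permutation(cg$graph, colors = colors)
  gg2 <- igraph::permute(cg$graph, cp$labeling)
  lab2 <- character(length(cg$labels)); lab2[cp$labeling] <- cg$labels
  el <- igraph::as_edgelist(gg2, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0(op@direction, ";", paste(lab2, collapse = ","), ";",
         paste(el[, 1], el[, 2], sep = "-", collapse = ","))
}

# fold pattern + edit script into one colored graph (bonds subdivided into
# edge-vertices so BLISS vertex colors suffice); node k of the operator is
# vertex k of the graph
.operatorColoredGraph <- function(op) {
  patt <- op@pattern
  vlab <- sprintf("s%d|%s|%d|keep|.", patt$shell, patt$atom_type, patt$charge)
  names(vlab) <- patt$node
  elab <- stats::setNames(
    sprintf("%s|keep", op@pattern_bonds$order),
    .bkey(op@pattern_bonds$n1, op@pattern_bonds$n2))
  for (e in op@edits) {
    if (e$type == "remove_atom") {
      vlab[as.character(e$node)] <- sub("keep\\|\\.$", "rm|.",
                                        vlab[as.character(e$node)])
    } else if (e$type == "change_atom_type") {
      vlab[as.character(e$node)] <- sub("keep\\|\\.$",
        sprintf("tc|%s/%d", e$atom_type, e$charge),
        vlab[as.character(e$node)])
    } else if (e$type == "add_atom") {
      vlab[as.character(e$node)] <- sprintf("new|%s|%d", e$atom_type,
                                            e$charge)
    } else if (e$type == "remove_bond") {
      k <- .bkey(e$n1, e$n2)
      elab[k] <- sub("keep$", "rm", elab[k])
    } else if (e$type == "change_bond_order") {
      k <- .bkey(e$n1, e$n2)
      elab[k] <- sub("keep$", paste0("chg:", e$order), elab[k])
    } else if (e$type == "add_bond") {
      elab[.bkey(e$n1, e$n2)] <- sprintf("%s|addbond", e$order)
    }
  }
  nodes <- names(vlab)
  n <- length(nodes)
  ek <- strsplit(names(elab), "|", fixed = TRUE)
  p1 <- match(vapply(ek, `[`, character(1), 1), nodes)
  p2 <- match(vapply(ek, `[`, character(1), 2), nodes)
  labels <- c(paste0("V:", unname(vlab)), paste0("E:", unname(elab)))
  gg <- igraph::make_empty_graph(n + length(elab), directed = FALSE)
  if (length(elab)) {
    bv <- n + seq_along(elab)
    gg <- igraph::add_edges(gg, t(rbind(cbind(p1, bv), cbind(p2, bv))))
  }
  list(graph = gg, labels = labels, n_pattern = nrow(patt))
}

# orbit id per pattern node under automorphisms of the pattern+edit colored
# graph; sites that permute nodes within an orbit describe the same edit
.patternOrbits <- function(op) {
  cg <- .operatorColoredGraph(op)
  k <- cg$n_pattern
  colors <- match(cg$labels, sort(unique(cg$labels)))
  gens <- igraph::automorphism_group(cg$graph, colors = colors)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (gperm in gens) {
    pp <- as.integer(gperm)
    for (v in seq_len(k)) {
      a <- find(v); b <- find(pp[v])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(k), find, integer(1))
}

setMethod("show", "TransformationOperator", function(object) {
  cat("TransformationOperator", sQuote(object@id), "(", object@direction, ")\n")
  cat("  center:", object@center_type,
      "| shell1:", sum(object@pattern$shell == 1),
      "| shell2:", sum(object@pattern$shell == 2), "atoms\n")
  cat("  edits:", paste(vapply(object@edits, `[[`, character(1), "type"),
                        collapse = ", "), "\n")
  cat("  EC:", paste(object@ec_numbers, collapse = ","), "\n")
})
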