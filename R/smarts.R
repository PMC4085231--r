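# SMARTS reader and substructure matcher. Supported atom primitives:
# wildcard *, aromatic a / aliphatic A, element symbols (aliphatic
# uppercase, aromatic lowercase), atomic number #n, charge +/-, degree Dn,
# total H count Hn, ring membership R / R0; logical operators ! (not),
# & and ; (and), , (or); default conjunction inside brackets. Bond
# primitives: - = # : ~ and the single-or-aromatic default. Anything else
# raises an explicit unsupported-token error. Recursive SMARTS are out of
# scope.

#' Read a SMARTS pattern
#'
#' Parses a SMARTS substructure query into a molecule-like query graph:
#' query atoms carry predicate trees (stored as `"a"`-kind properties),
#' query bonds carry order predicates. Branches and ring closures follow
#' SMILES syntax.
#'
#' @param text a single SMARTS string.
#' @return an object of class `"query_graph"`.
#' @export
read_smarts <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  q <- new_molecule(text)
  class(q) <- c("query_graph", class(q))
  n <- nchar(text)
  i <- 1L
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NULL
  rings <- list()

  add_qatom <- function(pred) {
    a <- create_object(q, "atom")
    set_a(a, "pred", pred)
    if (!is.na(prev)) {
      b <- create_object(q, "bond")
      relate(b, .morf(q, "atom", prev)); relate(b, a)
      relate(.morf(q, "atom", prev), a)
      set_a(b, "bpred", if (is.null(pending)) list(kind = "default") else pending)
    }
    prev <<- a$id
    pending <<- NULL
    a$id
  }
  close_ring <- function(lab) {
    if (is.na(prev)) stop("SMARTS parse error at position ", i, ": ring digit before any atom")
    key <- as.character(lab)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bpred = pending)
    } else {
      open <- rings[[key]]; rings[[key]] <<- NULL
      bp <- if (!is.null(pending)) pending else open$bpred
      b <- create_object(q, "bond")
      relate(b, .morf(q, "atom", open$atom)); relate(b, .morf(q, "atom", prev))
      relate(.morf(q, "atom", open$atom), .morf(q, "atom", prev))
      set_a(b, "bpred", if (is.null(bp)) list(kind = "default") else bp)
    }
    pending <<- NULL
  }

  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(text, i + 1L, n), fixed = TRUE)
      if (close < 0) stop("SMARTS parse error at position ", i, ": unclosed bracket")
      body <- substr(text, i + 1L, i + close - 1L)
      add_qatom(.parse_qatom_expr(body, i))
      i <- i + close + 1L
    } else if (ch == "-") { pending <- list(kind = "order", order = 1L); i <- i + 1L
    } else if (ch == "=") { pending <- list(kind = "order", order = 2L); i <- i + 1L
    } else if (ch == "#") { pending <- list(kind = "order", order = 3L); i <- i + 1L
    } else if (ch == ":") { pending <- list(kind = "aromatic"); i <- i + 1L
    } else if (ch == "~") { pending <- list(kind = "any"); i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) stop("SMARTS parse error at position ", i, ": unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      lab <- substr(text, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", lab))
        stop("SMARTS parse error at position ", i, ": '%' needs two digits")
      close_ring(as.integer(lab)); i <- i + 3L
    } else if (ch == "*") {
      add_qatom(list(op = "leaf", kind = "any")); i <- i + 1L
    } else {
      two <- substr(text, i, i + 1L)
      if (two %in% names(.organic_elems)) {
        add_qatom(.leaf_elem(.organic_elems[[two]], FALSE)); i <- i + 2L
      } else if (ch %in% names(.organic_elems)) {
        add_qatom(.leaf_elem(.organic_elems[[ch]], FALSE)); i <- i + 1L
      } else if (ch %in% names(.arom_elems)) {
        add_qatom(.leaf_elem(.arom_elems[[ch]], TRUE)); i <- i + 1L
      } else if (ch == "a") {
        add_qatom(list(op = "leaf", kind = "arom", value = TRUE)); i <- i + 1L
      } else if (ch == "A") {
        add_qatom(list(op = "leaf", kind = "arom", value = FALSE)); i <- i + 1L
      } else {
        stop("SMARTS parse error: unsupported token '", ch, "' at position ", i)
      }
    }
  }
  if (length(rings))
    stop("SMARTS parse error: unclosed ring digit(s) ", paste(names(rings), collapse = ", "))
  q
}

.leaf_elem <- function(num, arom) {
  list(op = "and",
       args = list(list(op = "leaf", kind = "elem", value = num),
                   list(op = "leaf", kind = "arom", value = arom)))
}

# bracket atom expression: ',' (or, lowest) > ';' (and, low) > implicit/& (and) > '!'
.parse_qatom_expr <- function(body, pos) {
  toks <- .qatom_tokens(body, pos)
  idx <- 1L
  peek <- function() if (idx <= length(toks)) toks[[idx]] else NULL
  take <- function() { t <- toks[[idx]]; idx <<- idx + 1L; t }
  parse_or <- function() {
    args <- list(parse_semi())
    while (!is.null(peek()) && identical(peek()$op, ",")) {
      take(); args <- c(args, list(parse_semi()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_semi <- function() {
    args <- list(parse_and())
    while (!is.null(peek()) && identical(peek()$op, ";")) {
      take(); args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_and <- function() {
    args <- list(parse_not())
    repeat {
      p <- peek()
      if (is.null(p) || identical(p$op, ",") || identical(p$op, ";")) break
      if (identical(p$op, "&")) { take(); next }
      args <- c(args, list(parse_not()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_not <- function() {
    p <- peek()
    if (identical(p$op, "!")) { take(); return(list(op = "not", arg = parse_not())) }
    if (is.null(p) || p$op %in% c(",", ";", "&"))
      stop("SMARTS parse error near position ", pos, ": dangling operator")
    take()
  }
  out <- parse_or()
  if (idx <= length(toks))
    stop("SMARTS parse error near position ", pos, ": trailing tokens in bracket")
  out
}

.qatom_tokens <- function(body, pos) {
  toks <- list()
  i <- 1L; n <- nchar(body)
  push <- function(t) toks[[length(toks) + 1L]] <<- t
  while (i <= n) {
    ch <- substr(body, i, i)
    rest <- substr(body, i, n)
    if (ch %in% c("!", "&", ";", ",")) { push(list(op = ch)); i <- i + 1L
    } else if (ch == "*") { push(list(op = "leaf", kind = "any")); i <- i + 1L
    } else if (ch == "#") {
      m <- regmatches(rest, regexpr("^#[0-9]+", rest))
      if (!length(m) || !nzchar(m))
        stop("SMARTS parse error at position ", pos, ": '#' needs an atomic number")
      push(list(op = "leaf", kind = "anum", value = as.integer(substr(m, 2, nchar(m)))))
      i <- i + nchar(m)
    } else if (ch == "D") {
      m <- regmatches(rest, regexpr("^D[0-9]*", rest))
      v <- if (nchar(m) > 1L) as.integer(substr(m, 2, nchar(m))) else 1L
      push(list(op = "leaf", kind = "degree", value = v)); i <- i + nchar(m)
    } else if (ch == "H") {
      m <- regmatches(rest, regexpr("^H[0-9]*", rest))
      v <- if (nchar(m) > 1L) as.integer(substr(m, 2, nchar(m))) else 1L
      push(list(op = "leaf", kind = "hcount", value = v)); i <- i + nchar(m)
    } else if (ch == "R") {
      m <- regmatches(rest, regexpr("^R[0-9]*", rest))
      v <- if (nchar(m) > 1L) as.integer(substr(m, 2, nchar(m))) else -1L
      push(list(op = "leaf", kind = "ring",
                value = if (v == 0L) FALSE else TRUE))
      i <- i + nchar(m)
    } else if (ch == "+" || ch == "-") {
      m <- regmatches(rest, regexpr("^(\\++[0-9]*|-+[0-9]*)", rest))
      sign <- if (ch == "+") 1L else -1L
      digits <- gsub("[+-]", "", m)
      v <- if (nzchar(digits)) sign * as.integer(digits)
           else sign * nchar(gsub("[0-9]", "", m))
      push(list(op = "leaf", kind = "charge", value = v)); i <- i + nchar(m)
    } else if (ch == "a") { push(list(op = "leaf", kind = "arom", value = TRUE)); i <- i + 1L
    } else if (ch == "A") { push(list(op = "leaf", kind = "arom", value = FALSE)); i <- i + 1L
    } else {
      m <- regmatches(rest, regexpr("^([A-Z][a-z]?|[a-z])", rest))
      if (length(m) && nzchar(m)) {
        if (m %in% names(.arom_elems)) {
          push(.leaf_elem(.arom_elems[[m]], TRUE)); i <- i + nchar(m); next
        }
        num <- element_number(m)
        if (num == 0L && nchar(m) == 2L) { m <- substr(m, 1, 1); num <- element_number(m) }
        if (num > 0L) {
          push(.leaf_elem(num, FALSE)); i <- i + nchar(m); next
        }
      }
      stop("SMARTS parse error: unsupported primitive '", ch,
           "' in bracket near position ", pos)
    }
  }
  toks
}

# ---- matching -------------------------------------------------------------

#' Match a SMARTS query against a molecule
#'
#' Enumerates all subgraph monomorphisms (injective atom mappings) of the
#' query into the molecule for which every atom and bond predicate holds.
#' Symmetric duplicates are retained; results are ordered lexicographically
#' by the mapped molecule-atom ids. The molecule needs `element` and
#' integer bond orders (run [fixbond()] first if needed).
#'
#' @param query a query graph from [read_smarts()] (or a SMARTS string).
#' @param mol a molecule.
#' @return list of integer vectors; element `k` of a vector is the molecule
#'   atom matched by query atom `k`.
#' @export
match_smarts <- function(query, mol) {
  if (is.character(query)) query <- read_smarts(query)
  stopifnot(inherits(query, "query_graph"), is_molecule(mol))
  nq <- n_atoms(query)
  if (nq == 0L) return(list())
  feats <- .atom_features(mol)
  qpred <- lapply(seq_len(nq), function(k) get_a(.morf(query, "atom", k), "pred"))
  qbt <- bond_table(query)
  qb_pred <- lapply(seq_len(nrow(qbt)), function(b)
    get_a(.morf(query, "bond", b), "bpred"))
  # query bonds incident to atom k against already-mapped atoms
  bt <- bond_table(mol)
  nmol <- n_atoms(mol)
  madj <- matrix(0L, nmol, nmol)
  for (b in seq_len(nrow(bt))) {
    madj[bt[b, 1], bt[b, 2]] <- bt[b, 3]
    madj[bt[b, 2], bt[b, 1]] <- bt[b, 3]
  }
  arom_bond <- matrix(FALSE, nmol, nmol)
  if (nrow(bt)) {
    ab <- bt[, 3] == 4L |
      (feats$arom[bt[, 1]] == 1L & feats$arom[bt[, 2]] == 1L & feats$ring_bond)
    for (b in which(ab)) {
      arom_bond[bt[b, 1], bt[b, 2]] <- TRUE
      arom_bond[bt[b, 2], bt[b, 1]] <- TRUE
    }
  }
  results <- list()
  map <- integer(nq)
  used <- logical(nmol)
  candidates <- lapply(seq_len(nq), function(k)
    which(vapply(seq_len(nmol), function(a) .eval_qpred(qpred[[k]], feats, a), logical(1))))
  bond_ok <- function(bp, i, j) {
    o <- madj[i, j]
    if (o == 0L) return(FALSE)
    switch(bp$kind,
      any = TRUE,
      default = o == 1L || o == 4L || o == 5L || arom_bond[i, j],
      order = (o == bp$order) ||
        (bp$order == 1L && o == 5L),
      aromatic = arom_bond[i, j] || o == 4L,
      stop("unknown bond predicate"))
  }
  # precompute query adjacency constraints per step
  qcons <- lapply(seq_len(nq), function(k) {
    out <- list()
    for (b in seq_len(nrow(qbt))) {
      i <- qbt[b, 1]; j <- qbt[b, 2]
      if (i == k && j < k) out[[length(out) + 1L]] <- list(other = j, bp = qb_pred[[b]])
      if (j == k && i < k) out[[length(out) + 1L]] <- list(other = i, bp = qb_pred[[b]])
    }
    out
  })
  recurse <- function(k) {
    if (k > nq) {
      results[[length(results) + 1L]] <<- map
      return(invisible(NULL))
    }
    for (a in candidates[[k]]) {
      if (used[a]) next
      ok <- TRUE
      for (cn in qcons[[k]]) {
        if (!bond_ok(cn$bp, map[cn$other], a)) { ok <- FALSE; break }
      }
      if (!ok) next
      map[k] <<- a; used[a] <<- TRUE
      recurse(k + 1L)
      used[a] <<- FALSE
    }
  }
  recurse(1L)
  if (length(results) > 1L) {
    keys <- vapply(results, function(r) paste(sprintf("%08d", r), collapse = ""), character(1))
    results <- results[order(keys)]
  }
  results
}

.eval_qpred <- function(p, feats, a) {
  if (is.null(p$op)) stop("malformed query predicate")
  switch(p$op,
    leaf = switch(p$kind,
      any = TRUE,
      elem = feats$elem[a] == p$value,
      anum = feats$elem[a] == p$value,
      arom = (feats$arom[a] == 1L) == p$value,
      charge = feats$fchg[a] == p$value,
      degree = feats$degree[a] == p$value,
      hcount = feats$hcount[a] == p$value,
      ring = feats$in_ring[a] == p$value,
      stop("unknown atom primitive '", p$kind, "'")),
    and = all(vapply(p$args, .eval_qpred, logical(1), feats = feats, a = a)),
    or = any(vapply(p$args, .eval_qpred, logical(1), feats = feats, a = a)),
    not = !.eval_qpred(p$arg, feats, a),
    stop("unknown predicate op '", p$op, "'"))
}

# per-atom match features: element, aromatic flag, formal charge, heavy
# degree, total H count (implicit + explicit), ring membership (bridge
# analysis: an atom is in a ring iff it has a non-bridge incident bond)
.atom_features <- function(mol) {
  n <- n_atoms(mol)
  elem <- col_or(mol, "atom", "element", "i", 0L)
  arom <- col_or(mol, "atom", "arom", "i", 0L)
  fchg <- col_or(mol, "atom", "fchg", "i", 0L)
  nh <- col_or(mol, "atom", "nh", "i", 0L)
  nbr <- neighbors(mol)
  degree <- lengths(nbr)
  hexp_n <- vapply(seq_len(n), function(i) sum(elem[nbr[[i]]] == 1L), integer(1))
  hcount <- nh + hexp_n
  rb <- .ring_bonds(mol)
  bt <- bond_table(mol)
  in_ring <- rep(FALSE, n)
  if (length(rb)) {
    in_ring[unique(as.vector(bt[rb, 1:2]))] <- TRUE
  }
  list(elem = elem, arom = arom, fchg = fchg, degree = degree,
       hcount = hcount, in_ring = in_ring,
       ring_bond = if (nrow(bt)) seq_len(nrow(bt)) %in% rb else logical(0))
}

# bond indices that lie on a cycle (non-bridges), via iterative DFS lowlinks
.ring_bonds <- function(mol) {
  bt <- bond_table(mol)
  n <- n_atoms(mol)
  if (nrow(bt) == 0L || n == 0L) return(integer(0))
  adj <- replicate(n, list(), simplify = FALSE)
  for (b in seq_len(nrow(bt))) {
    i <- bt[b, 1]; j <- bt[b, 2]
    adj[[i]] <- c(adj[[i]], list(c(j, b)))
    adj[[j]] <- c(adj[[j]], list(c(i, b)))
  }
  disc <- rep(0L, n); low <- rep(0L, n)
  bridges <- logical(nrow(bt))
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root] > 0L) next
    stack <- list(list(v = root, pe = 0L, it = 1L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$it == 1L) {
        timer <- timer + 1L
        disc[v] <- low[v] <- timer
      }
      if (fr$it <= length(adj[[v]])) {
        stack[[length(stack)]]$it <- fr$it + 1L
        e <- adj[[v]][[fr$it]]
        w <- e[1]; be <- e[2]
        if (be == fr$pe) next
        if (disc[w] > 0L) {
          low[v] <- min(low[v], disc[w])
        } else {
          stack[[length(stack) + 1L]] <- list(v = w, pe = be, it = 1L)
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          u <- stack[[length(stack)]]$v
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) bridges[fr$pe] <- TRUE
        }
      }
    }
  }
  # parallel (duplicate) bonds are never bridges
  which(!bridges)
}
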