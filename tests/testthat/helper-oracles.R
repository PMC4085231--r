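# Independent oracles and random-structure generators used across the suite.

# positional base-40 oracle for the name hash, written against the digit
# values directly (not the running-sum update)
oracle_encode <- function(s) {
  codes <- utf8ToInt(s)
  vals <- ifelse(codes >= 97 & codes <= 122, codes - 97,
          ifelse(codes >= 65 & codes <= 90, codes - 65,
          ifelse(codes >= 48 & codes <= 57, codes - 48,
          ifelse(codes == 95, 36, NA))))
  vals <- vals[!is.na(vals)]
  sum(vals * 40^(rev(seq_along(vals)) - 1))
}

# random molecule for mask fuzzing: 10-12 residues, up to ~100 atoms,
# random coordinates, single-letter element names with counters
random_mask_mol <- function(seed) {
  set.seed(seed)
  mol <- new_molecule(paste0("fuzz", seed))
  nres <- sample(10:12, 1)
  names_pool <- c("CA", "CB", "N", "O", "C", "H1", "HB2")
  for (r in seq_len(nres)) {
    res <- create_object(mol, "resd")
    set_s(res, "name", sample(c("ALA", "GLY", "WAT", "LIG"), 1))
    set_i(res, "seq", r)
    for (k in seq_len(sample(3:8, 1))) {
      a <- create_object(mol, "atom")
      set_s(a, "name", sample(names_pool, 1))
      set_i(a, "element", sample(c(6L, 7L, 8L), 1))
      set_v(a, "position", runif(3, -15, 15))
      relate(res, a)
    }
  }
  mol
}

# brute-force mask interpreter over the same parse tree: per-atom loops,
# no vectorization, independent of the package evaluator
naive_mask_eval <- function(node, mol) {
  n <- n_atoms(mol)
  res_of <- integer(n)
  for (r in seq_len(n_residues(mol))) {
    for (id in related_ids(handle(mol, "resd", r), "atom")) res_of[id] <- r
  }
  anames <- vapply(seq_len(n), function(i) {
    v <- try_prop(handle(mol, "atom", i), "name", "s")
    if (v$found) v$value else ""
  }, character(1))
  rnames <- vapply(seq_len(n_residues(mol)), function(r) {
    v <- try_prop(handle(mol, "resd", r), "name", "s")
    if (v$found) v$value else ""
  }, character(1))
  item_hit <- function(it, idx, nms, count) {
    if (it$type == "id") { stopifnot(it$id >= 1, it$id <= count); idx == it$id }
    else if (it$type == "range") {
      stopifnot(it$lo >= 1, it$hi <= count)
      idx >= it$lo & idx <= it$hi
    } else if (endsWith(it$name, "*"))
      startsWith(nms[idx], substr(it$name, 1, nchar(it$name) - 1))
    else nms[idx] == it$name
  }
  ev <- function(nd) {
    if (nd$kind == "atom_node") {
      out <- rep(FALSE, n)
      for (i in seq_len(n)) for (it in nd$items)
        if (item_hit(it, i, anames, n)) out[i] <- TRUE
      out
    } else if (nd$kind == "resd_node") {
      out <- rep(FALSE, n)
      for (i in seq_len(n)) {
        r <- res_of[i]
        if (r == 0) next
        for (it in nd$items) if (item_hit(it, r, rnames, n_residues(mol)))
          out[i] <- TRUE
      }
      out
    } else if (nd$kind == "and") ev(nd$a) & ev(nd$b)
    else if (nd$kind == "or") ev(nd$a) | ev(nd$b)
    else if (nd$kind == "not") !ev(nd$a)
    else if (nd$kind == "dist") {
      core <- which(ev(nd$core))
      pos <- positions(mol)
      out <- rep(FALSE, n)
      for (i in seq_len(n)) {
        dmin <- Inf
        for (c_at in core)
          dmin <- min(dmin, sqrt(sum((pos[i, ] - pos[c_at, ])^2)))
        out[i] <- dmin <= nd$r
      }
      if (nd$op == ">") out <- !out
      if (nd$gran == "resd") {
        hit <- unique(res_of[out & res_of > 0])
        for (i in seq_len(n)) if (res_of[i] %in% hit) out[i] <- TRUE
      }
      out
    } else stop("bad node")
  }
  which(ev(node))
}

# random mask expression generator (always valid for random_mask_mol output)
random_mask_expr <- function(mol, depth = 2) {
  n <- n_atoms(mol)
  nres <- n_residues(mol)
  leaf <- function() {
    switch(sample(4, 1),
      { i <- sample(n, 1); paste0("@", i) },
      { lo <- sample(n, 1); hi <- lo + sample.int(n - lo + 1, 1) - 1
        paste0("@", lo, "-", hi) },
      { lo <- sample(nres, 1); hi <- lo + sample.int(nres - lo + 1, 1) - 1
        paste0(":", lo, "-", hi) },
      paste0("@", sample(c("CA", "N", "O", "H*"), 1)))
  }
  gen <- function(d) {
    if (d <= 0 || runif(1) < 0.35) return(leaf())
    switch(sample(5, 1),
      paste0("(", gen(d - 1), "&", gen(d - 1), ")"),
      paste0("(", gen(d - 1), "|", gen(d - 1), ")"),
      paste0("!", gen(d - 1)),
      paste0("(", gen(d - 1), ")<@", sprintf("%.1f", runif(1, 2, 12))),
      paste0("(", gen(d - 1), ")>:", sprintf("%.1f", runif(1, 2, 12))))
  }
  gen(depth)
}

# random small organic molecule for format round-trips (tree-shaped bonds)
random_format_mol <- function(seed) {
  set.seed(seed)
  mol <- new_molecule(paste0("rf", seed))
  na <- sample(3:12, 1)
  elems <- sample(c(6L, 7L, 8L, 16L), na, replace = TRUE)
  res <- create_object(mol, "resd")
  set_s(res, "name", "LIG"); set_i(res, "seq", 1L)
  nres <- 1L
  for (i in seq_len(na)) {
    if (i > 1 && runif(1) < 0.2) {
      res <- create_object(mol, "resd")
      nres <- nres + 1L
      set_s(res, "name", sample(c("RES", "MOL"), 1)); set_i(res, "seq", nres)
    }
    a <- create_object(mol, "atom")
    set_s(a, "name", paste0(element_symbol(elems[i]), i))
    set_i(a, "element", elems[i])
    set_s(a, "type", element_symbol(elems[i]))
    set_d(a, "pchg", round(runif(1, -0.5, 0.5), 4))
    set_i(a, "fchg", sample(c(0L, 0L, 0L, 1L, -1L), 1))
    set_v(a, "position", round(runif(3, -50, 50), 3))
    relate(res, a)
  }
  for (i in 2:na) add_bond(mol, sample(i - 1, 1), i, sample(1:3, 1))
  mol
}

# O(n^2) brute-force nonbonded oracle: plain loops, exclusion classes
# rederived by BFS bond-path length, no reuse of the package's pair lists
oracle_nonbond <- function(mol, ff, cutoff = Inf, box = NULL,
                           scee = 1.2, scnb = 2.0) {
  n <- n_atoms(mol)
  pos <- positions(mol)
  q <- col_or(mol, "atom", "pchg", "d", 0)
  ty <- col_of(mol, "atom", "type", "s")
  nbr <- neighbors(mol)
  dist_bonds <- function(i, j) {
    # BFS shortest bond-path length up to 3
    if (i == j) return(0L)
    frontier <- i; seen <- i
    for (d in 1:3) {
      nxt <- unique(unlist(nbr[frontier]))
      nxt <- setdiff(nxt, seen)
      if (j %in% nxt) return(d)
      frontier <- nxt; seen <- c(seen, nxt)
      if (!length(frontier)) break
    }
    99L
  }
  elec <- 0; vdw <- 0
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    sep <- dist_bonds(i, j)
    if (sep <= 2) next
    dv <- pos[j, ] - pos[i, ]
    if (!is.null(box)) dv <- dv - box * round(dv / box)
    r <- sqrt(sum(dv^2))
    if (r > cutoff) next
    we <- if (sep == 3) 1 / scee else 1
    wv <- if (sep == 3) 1 / scnb else 1
    elec <- elec + we * relmol::INVCHG2 * q[i] * q[j] / r
    pi_ <- ff_vdw(ff, ty[i]); pj <- ff_vdw(ff, ty[j])
    ep <- sqrt(pi_[["eps"]] * pj[["eps"]])
    rm <- pi_[["rmin2"]] + pj[["rmin2"]]
    if (ep > 0) vdw <- vdw + wv * ep * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  c(elec = elec, vdw = vdw)
}

# ---- prmtop reference evaluator -------------------------------------------
# Reads the %FLAG sections of a written prmtop + inpcrd and recomputes the
# energies purely from the file arrays (CHARGE used directly, so no package
# constants are involved).
read_prmtop_sections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  flags <- grep("^%FLAG", lines)
  out <- list()
  for (k in seq_along(flags)) {
    name <- trimws(sub("^%FLAG", "", lines[flags[k]]))
    from <- flags[k] + 2L
    to <- if (k < length(flags)) flags[k + 1L] - 1L else length(lines)
    fmt <- trimws(sub("^%FORMAT", "", lines[flags[k] + 1L]))
    body <- lines[from:to]
    body <- body[nzchar(body)]
    if (grepl("a4", fmt)) {
      vals <- unlist(lapply(body, function(l) {
        starts <- seq(1, nchar(l), by = 4)
        trimws(substring(l, starts, pmin(starts + 3, nchar(l))))
      }))
    } else {
      vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
    }
    out[[name]] <- vals
  }
  out
}

read_inpcrd_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[2]))
  vals <- numeric(0)
  k <- 3L
  while (length(vals) < 3 * n) {
    l <- lines[k]
    starts <- seq(1, nchar(l), by = 12)
    vals <- c(vals, as.numeric(substring(l, starts, pmin(starts + 11, nchar(l)))))
    k <- k + 1L
  }
  matrix(vals[seq_len(3 * n)], ncol = 3, byrow = TRUE)
}

prmtop_energy <- function(prmtop_path, inpcrd_path) {
  s <- read_prmtop_sections(prmtop_path)
  crd <- read_inpcrd_coords(inpcrd_path)
  p <- as.integer(s$POINTERS)
  natom <- p[1]; ntypes <- p[2]
  dih_of <- function(arr) if (is.null(arr)) numeric(0) else arr
  ebond <- 0
  for (arr in list(s$BONDS_INC_HYDROGEN, s$BONDS_WITHOUT_HYDROGEN)) {
    arr <- dih_of(arr)
    if (!length(arr)) next
    m <- matrix(arr, ncol = 3, byrow = TRUE)
    for (r in seq_len(nrow(m))) {
      i <- m[r, 1] / 3 + 1; j <- m[r, 2] / 3 + 1; k <- m[r, 3]
      d <- sqrt(sum((crd[i, ] - crd[j, ])^2))
      ebond <- ebond + s$BOND_FORCE_CONSTANT[k] * (d - s$BOND_EQUIL_VALUE[k])^2
    }
  }
  eang <- 0
  for (arr in list(s$ANGLES_INC_HYDROGEN, s$ANGLES_WITHOUT_HYDROGEN)) {
    arr <- dih_of(arr)
    if (!length(arr)) next
    m <- matrix(arr, ncol = 4, byrow = TRUE)
    for (r in seq_len(nrow(m))) {
      i <- m[r, 1] / 3 + 1; j <- m[r, 2] / 3 + 1; kk <- m[r, 3] / 3 + 1
      k <- m[r, 4]
      v1 <- crd[i, ] - crd[j, ]; v2 <- crd[kk, ] - crd[j, ]
      th <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
      eang <- eang + s$ANGLE_FORCE_CONSTANT[k] * (th - s$ANGLE_EQUIL_VALUE[k])^2
    }
  }
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  dihed <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
    atan2(sum(m1 * n2), sum(n1 * n2))
  }
  edih <- 0; e14e <- 0; e14v <- 0
  charge <- s$CHARGE
  tidx <- as.integer(s$ATOM_TYPE_INDEX)
  ico <- as.integer(s$NONBONDED_PARM_INDEX)
  lj <- function(i, j, r, w = 1) {
    k <- ico[ntypes * (tidx[i] - 1) + tidx[j]]
    a <- s$LENNARD_JONES_ACOEF[k]; b <- s$LENNARD_JONES_BCOEF[k]
    w * (a / r^12 - b / r^6)
  }
  for (arr in list(s$DIHEDRALS_INC_HYDROGEN, s$DIHEDRALS_WITHOUT_HYDROGEN)) {
    arr <- dih_of(arr)
    if (!length(arr)) next
    m <- matrix(arr, ncol = 5, byrow = TRUE)
    for (r in seq_len(nrow(m))) {
      i <- m[r, 1] / 3 + 1; j <- m[r, 2] / 3 + 1
      kk <- abs(m[r, 3]) / 3 + 1; l <- abs(m[r, 4]) / 3 + 1
      k <- m[r, 5]
      phi <- dihed(crd[i, ], crd[j, ], crd[kk, ], crd[l, ])
      edih <- edih + s$DIHEDRAL_FORCE_CONSTANT[k] *
        (1 + cos(s$DIHEDRAL_PERIODICITY[k] * phi - s$DIHEDRAL_PHASE[k]))
      if (m[r, 3] >= 0 && m[r, 4] >= 0) {     # 1-4 pair counted here
        r14 <- sqrt(sum((crd[i, ] - crd[l, ])^2))
        e14e <- e14e + charge[i] * charge[l] / r14 / s$SCEE_SCALE_FACTOR[k]
        e14v <- e14v + lj(i, l, r14, 1 / s$SCNB_SCALE_FACTOR[k])
      }
    }
  }
  # non-excluded pair sum
  nexc <- as.integer(s$NUMBER_EXCLUDED_ATOMS)
  exlist <- as.integer(s$EXCLUDED_ATOMS_LIST)
  excl <- vector("list", natom)
  off <- 0L
  for (i in seq_len(natom)) {
    v <- exlist[(off + 1):(off + nexc[i])]
    excl[[i]] <- v[v > 0]
    off <- off + nexc[i]
  }
  eel <- 0; evdw <- 0
  for (i in seq_len(max(0, natom - 1))) for (j in (i + 1):natom) {
    if (j %in% excl[[i]]) next
    r <- sqrt(sum((crd[i, ] - crd[j, ])^2))
    eel <- eel + charge[i] * charge[j] / r
    evdw <- evdw + lj(i, j, r)
  }
  list(bond = ebond, angle = eang, dihedral = edih,
       elec = eel + e14e, vdw = evdw + e14v,
       total = ebond + eang + edih + eel + e14e + evdw + e14v)
}

# brute-force per-solvent shell filter oracle (plain loops)
oracle_shell_keep <- function(solute_pos, solute_elem, spos, selem, res_of,
                              closeness, extent) {
  keep <- logical(max(res_of))
  for (r in seq_len(max(res_of))) {
    rows <- which(res_of == r)
    clash <- FALSE; dmin <- Inf
    for (a in rows) for (b in seq_len(nrow(solute_pos))) {
      d <- sqrt(sum((spos[a, ] - solute_pos[b, ])^2))
      cut <- closeness * (element_vdw(selem[a]) + element_vdw(solute_elem[b]))
      if (d < cut) clash <- TRUE
      dmin <- min(dmin, d)
    }
    keep[r] <- !clash && dmin <= extent
  }
  keep
}
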