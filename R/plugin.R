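# LEaP-like command layer. Every command is a function registered by name
# in a single registry and invoked through a uniform execute entry point;
# a script is a sequence of `[name =] command args...` lines.

#' Command registry
#'
#' `register_command()` installs (or replaces) a command; every command
#' is a `function(args, state)` returning its result (assigned when the
#' script line has a `name =` prefix). `command_names()` lists the
#' registry. The interpreter state carries `db` (a molecule database) and
#' `ff` (the currently loaded force field).
#'
#' @param name command name.
#' @param fun `function(args, state)`.
#' @export
register_command <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  .relmol$commands[[name]] <- fun
  invisible(name)
}

#' @rdname register_command
#' @export
command_names <- function() sort(names(.relmol$commands))

#' Run a command script
#'
#' Executes newline-separated commands in order; `#` starts a comment.
#' A line `w = load water.pdb` stores the result under `w` in the state
#' database. The first failing command aborts the script with its message
#' (prefixed by the line number) and a nonzero status.
#'
#' @param file script path (or `text` lines).
#' @param text character vector of script lines.
#' @param state optional interpreter state to reuse (a `new_script_state()`).
#' @param quiet suppress per-command logging.
#' @return invisibly, a list with `status` (0 on success), `message`, and
#'   the final `state`.
#' @export
run_script <- function(file = NULL, text = NULL, state = NULL, quiet = FALSE) {
  lines <- .input_lines(file, text)
  if (is.null(state)) state <- new_script_state()
  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    line <- sub("#.*$", "", raw)
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", line))[[1]]
    target <- NULL
    if (length(m) == 3 && !grepl("^\\s*\\S+\\s*==", line)) {
      target <- m[2]; line <- m[3]
    }
    toks <- tryCatch(scan(text = line, what = "character", quiet = TRUE),
                     error = function(e) NULL)
    if (is.null(toks) || length(toks) == 0)
      return(invisible(list(status = 1L,
                            message = paste0("line ", ln, ": cannot tokenize"),
                            state = state)))
    cmd <- toks[1]; args <- toks[-1]
    if (cmd == "quit") break
    fun <- .relmol$commands[[cmd]]
    if (is.null(fun))
      return(invisible(list(status = 1L,
                            message = paste0("line ", ln, ": unknown command '", cmd, "'"),
                            state = state)))
    res <- tryCatch(fun(args, state), error = function(e)
      structure(list(msg = conditionMessage(e)), class = "relmol_cmd_error"))
    if (inherits(res, "relmol_cmd_error"))
      return(invisible(list(status = 1L,
                            message = paste0("line ", ln, " (", cmd, "): ", res$msg),
                            state = state)))
    if (!is.null(target) && is_molecule(res)) {
      res$name <- target
      db_put(state$db, target, res)
    } else if (!is.null(target)) {
      state$vars[[target]] <- res
    }
    if (!quiet) message("[relmol] ", cmd, if (length(args)) paste0(" ", paste(args, collapse = " ")))
  }
  invisible(list(status = 0L, message = "ok", state = state))
}

#' @rdname run_script
#' @export
new_script_state <- function() {
  st <- new.env(parent = emptyenv())
  st$db <- new_database()
  st$ff <- NULL
  st$vars <- list()
  st
}

.need_mol <- function(args, state, k = 1L) {
  if (length(args) < k) stop("missing molecule argument")
  db_get_mol(state$db, args[k])
}

.need_ff <- function(state) {
  if (is.null(state$ff))
    stop("no force field loaded (use 'loadfrc <file>' first)")
  state$ff
}

.load_any <- function(path, format = NULL) {
  if (is.null(format))
    format <- tolower(sub("^.*\\.", "", path))
  switch(format,
    pdb = , ent = read_pdb(path),
    mol2 = read_mol2(path),
    sdf = , mol = read_sdf(path),
    stop("cannot infer format of '", path, "' (use pdb/mol2/sdf)"))
}

# Gasteiger-style charging is out of scope (it shells out to Antechamber in
# the original tool chain); this stub assigns packaged per-element fallback
# charges, shifted uniformly so the net charge equals the total formal charge.
.setpchg_stub <- function(mol) {
  elem <- col_or(mol, "atom", "element", "i", 0L)
  base <- c(`1` = 0.10, `6` = -0.10, `7` = -0.40, `8` = -0.40, `16` = -0.20,
            `15` = 0.40, `9` = -0.20, `17` = -0.15, `35` = -0.12, `53` = -0.10,
            `11` = 1.0, `19` = 1.0, `12` = 2.0, `20` = 2.0)
  q <- base[as.character(elem)]
  q[is.na(q)] <- 0
  fchg <- col_or(mol, "atom", "fchg", "i", 0L)
  n <- length(q)
  if (n > 0) q <- q + (sum(fchg) - sum(q)) / n
  set_col(mol, "atom", "pchg", "d", q)
  invisible(mol)
}

# parmchk analogue: reports missing parameters instead of generating them
.parmchk_stub <- function(mol, ff) {
  ty <- col_or(mol, "atom", "type", "s", "")
  missing <- character(0)
  chk <- function(expr, what) {
    tryCatch({ expr; NULL }, error = function(e) what)
  }
  bt <- bond_table(mol)
  for (b in seq_len(nrow(bt))) {
    m <- chk(ff_bond(ff, ty[bt[b, 1]], ty[bt[b, 2]]),
             paste0("bond ", ty[bt[b, 1]], "-", ty[bt[b, 2]]))
    if (!is.null(m)) missing <- c(missing, m)
  }
  ta <- try(.term_atoms(mol, "angl", 3L), silent = TRUE)
  if (!inherits(ta, "try-error")) for (t in seq_len(nrow(ta))) {
    m <- chk(ff_angle(ff, ty[ta[t, 1]], ty[ta[t, 2]], ty[ta[t, 3]]),
             paste0("angle ", paste(ty[ta[t, ]], collapse = "-")))
    if (!is.null(m)) missing <- c(missing, m)
  }
  tt <- try(.term_atoms(mol, "tors", 4L), silent = TRUE)
  if (!inherits(tt, "try-error")) for (t in seq_len(nrow(tt))) {
    m <- chk(ff_torsion(ff, ty[tt[t, 1]], ty[tt[t, 2]], ty[tt[t, 3]], ty[tt[t, 4]]),
             paste0("torsion ", paste(ty[tt[t, ]], collapse = "-")))
    if (!is.null(m)) missing <- c(missing, m)
  }
  for (t in unique(ty)) {
    m <- chk(ff_vdw(ff, t), paste0("vdw ", t))
    if (!is.null(m)) missing <- c(missing, m)
  }
  unique(missing)
}

.register_builtin_commands <- function() {
  reg <- register_command
  reg("source", function(args, state) {
    if (length(args) < 1) stop("usage: source <script-file>")
    res <- run_script(args[1], state = state, quiet = TRUE)
    if (res$status != 0) stop("nested script failed: ", res$message)
    invisible(NULL)
  })
  reg("loadfrc", function(args, state) {
    if (length(args) < 1) stop("usage: loadfrc <parameter-file>")
    state$ff <- read_frc(args[1], base = state$ff)
    invisible(state$ff)
  })
  reg("loadamberparams", function(args, state)
    .relmol$commands[["loadfrc"]](args, state))
  reg("load", function(args, state) {
    if (length(args) < 1) stop("usage: load <file> [format]")
    mol <- .load_any(args[1], if (length(args) >= 2) args[2] else NULL)
    db_put(state$db, mol$name, mol)
    mol
  })
  reg("loadsmiles", function(args, state) {
    if (length(args) < 1) stop("usage: loadsmiles <smiles>")
    read_smiles(args[1])
  })
  reg("merge", function(args, state) {
    if (length(args) < 1) stop("usage: merge <mol> [<mol> ...]")
    merge_mols(lapply(args, function(a) db_get_mol(state$db, a)))
  })
  reg("solvate", function(args, state) {
    if (length(args) < 2) stop("usage: solvate <mol> shell|box|oct|cap <params...>")
    mol <- .need_mol(args, state)
    mode <- args[2]
    tmpl <- water_box_template()
    num <- function(k, what) {
      if (length(args) < k) stop("solvate ", mode, ": missing ", what)
      v <- suppressWarnings(as.numeric(args[k]))
      if (is.na(v)) stop("solvate ", mode, ": non-numeric ", what)
      v
    }
    added <- switch(mode,
      shell = solvate_shell(mol, tmpl, num(3, "closeness"), num(4, "extent")),
      box = solvate_box(mol, tmpl, num(3, "buffer")),
      oct = solvate_oct(mol, tmpl, num(3, "buffer")),
      cap = solvate_cap(mol, tmpl, c(num(3, "x"), num(4, "y"), num(5, "z")),
                        num(6, "radius")),
      stop("unknown solvate mode '", mode, "'"))
    message("[relmol] added ", added, " solvent residues")
    mol
  })
  reg("addions", function(args, state) {
    if (length(args) < 3) stop("usage: addions <mol> <Na+|Cl-> <count|auto>")
    mol <- .need_mol(args, state)
    cnt <- if (identical(args[3], "auto")) "auto" else as.integer(args[3])
    placed <- addions(mol, fx_ion(args[2]), cnt)
    message("[relmol] placed ", placed, " ", args[2], " ions")
    mol
  })
  reg("fixbond", function(args, state) fixbond(.need_mol(args, state)))
  reg("addhs", function(args, state) addHs(.need_mol(args, state)))
  reg("setpchg", function(args, state) .setpchg_stub(.need_mol(args, state)))
  reg("moloper", function(args, state) {
    mol <- .need_mol(args, state)
    fixbond(mol); addHs(mol); .setpchg_stub(mol)
    mol
  })
  reg("parmchk", function(args, state) {
    mol <- .need_mol(args, state)
    miss <- .parmchk_stub(mol, .need_ff(state))
    if (length(miss)) {
      message("[relmol] missing parameters:\n  ", paste(miss, collapse = "\n  "))
    } else message("[relmol] all parameters resolved")
    miss
  })
  reg("mask", function(args, state) {
    if (length(args) < 2) stop("usage: mask <mol> <expression>")
    mol <- .need_mol(args, state)
    sel <- mask_atom(mol, paste(args[-1], collapse = " "))
    message("[relmol] ", length(sel$atoms), " atoms: ",
            paste(utils::head(sel$atoms, 20), collapse = " "),
            if (length(sel$atoms) > 20) " ...")
    sel
  })
  reg("energy", function(args, state) {
    mol <- .need_mol(args, state)
    ff <- .need_ff(state)
    enumerate_terms(mol)
    rep <- energy_report(mol, ff)
    print(rep)
    rep
  })
  reg("saveamberparm", function(args, state) {
    if (length(args) < 3) stop("usage: saveamberparm <mol> <prmtop> <inpcrd>")
    mol <- .need_mol(args, state)
    ff <- .need_ff(state)
    enumerate_terms(mol)
    write_amber_prmtop(mol, ff, args[2])
    write_inpcrd(mol, args[3])
    invisible(NULL)
  })
  reg("savepdb", function(args, state) {
    if (length(args) < 2) stop("usage: savepdb <mol> <file>")
    write_pdb(.need_mol(args, state), args[2]); invisible(NULL)
  })
  reg("savemol2", function(args, state) {
    if (length(args) < 2) stop("usage: savemol2 <mol> <file>")
    write_mol2(.need_mol(args, state), args[2]); invisible(NULL)
  })
  reg("savesdf", function(args, state) {
    if (length(args) < 2) stop("usage: savesdf <mol> <file>")
    write_sdf(.need_mol(args, state), args[2]); invisible(NULL)
  })
  reg("fixtures", function(args, state) {
    if (length(args) < 1) stop("usage: fixtures <output-dir>")
    generate_fixtures(args[1])
  })
  invisible(NULL)
}
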