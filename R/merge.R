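#' Concatenate molecules
#'
#' Puts the atoms, bonds and residues of several molecules together into
#' one, preserving per-object properties and relations; residues are
#' renumbered sequentially (1..n) across the inputs. Bonded terms
#' (angles, torsions) are not copied - re-run [enumerate_terms()] on the
#' result.
#'
#' @param mols list of molecules (or several molecules as `...`).
#' @param name name of the merged molecule.
#' @return a new molecule.
#' @export
merge_mols <- function(mols, name = "merged") {
  if (is_molecule(mols)) mols <- list(mols)
  stopifnot(all(vapply(mols, is_molecule, logical(1))))
  out <- new_molecule(name)
  for (src in mols) {
    offs <- c(atom = n_atoms(out), bond = n_bonds(out), resd = n_residues(out))
    for (type in c("atom", "bond", "resd")) {
      nsrc <- mol_count(src, type)
      if (nsrc == 0L) next
      .ensure_cmp(out, type)
      n0 <- mol_count(out, type)
      # grow existing columns with defaults
      cmp <- out$cmp[[type]]
      cmp$n <- n0 + nsrc
      cmp$cols <- lapply(cmp$cols, function(col) {
        col$data <- c(col$data, if (col$kind == "a") vector("list", nsrc)
                      else if (col$kind == "v") numeric(col$width * nsrc)
                      else rep(.col_default(col$kind), nsrc))
        col
      })
      out$cmp[[type]] <- cmp
      pre <- paste0(type, ".")
      for (key in names(out$adj))
        if (startsWith(key, pre))
          out$adj[[key]] <- c(out$adj[[key]],
                              replicate(nsrc, integer(0), simplify = FALSE))
      # copy source columns (any-kind columns are carried over as-is)
      for (k in names(src$cmp[[type]]$cols)) {
        scol <- src$cmp[[type]]$cols[[k]]
        key <- if (!is.na(scol$name)) scol$name else as.numeric(k)
        col <- .make_col(out, type, key, scol$kind, scol$width)
        if (scol$kind == "v") {
          col$data[(n0 * col$width + 1):((n0 + nsrc) * col$width)] <- scol$data
        } else {
          col$data[(n0 + 1):(n0 + nsrc)] <- scol$data
        }
        out$cmp[[type]]$cols[[.col_key(key)]] <- col
      }
    }
    # standard adjacencies with offsets
    pairs <- list(c("atom", "atom"), c("atom", "bond"), c("bond", "atom"),
                  c("resd", "atom"), c("atom", "resd"))
    for (p in pairs) {
      skey <- .adj_key(p[1], p[2])
      rows <- src$adj[[skey]]
      if (is.null(rows)) next
      okey <- .ensure_adj(out, p[1], p[2])
      for (i in seq_along(rows)) {
        out$adj[[okey]][[offs[p[1]] + i]] <- rows[[i]] + offs[p[2]]
      }
    }
  }
  # renumber residues 1..n
  if (n_residues(out) > 0)
    set_col(out, "resd", "seq", "i", seq_len(n_residues(out)))
  out
}
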