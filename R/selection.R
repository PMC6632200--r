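#' Atom selections
#'
#' A selection is a declarative predicate over the atom table of a
#' [topology]: optional chain, residue numbers, residue names and atom
#' names, plus a heavy-atom filter. Resolving the same selection against
#' the same topology always yields the same ordered index vector.
#'
#' @param chain optional character vector of chain identifiers.
#' @param resid optional integer vector of residue numbers (author
#'   numbering, as read from the input file).
#' @param resname optional character vector of 3-letter residue codes or
#'   ion residue names.
#' @param name optional character vector of atom names (e.g. `"OD1"`,
#'   `"NZ"`).
#' @param heavy_only drop hydrogens? Defaults to `TRUE`: cation
#'   coordination is mediated by O/N heavy atoms, and hydrogens are absent
#'   from most structure templates anyway.
#' @return an object of class `atom_selection`.
#' @examples
#' sel <- atom_selection(resid = c(71, 75, 501, 504))
#' @export
atom_selection <- function(chain = NULL, resid = NULL, resname = NULL,
                           name = NULL, heavy_only = TRUE) {
  stopifnot(is.logical(heavy_only), length(heavy_only) == 1L)
  structure(
    list(chain = chain, resid = if (is.null(resid)) NULL else as.integer(resid),
         resname = resname, name = name, heavy_only = heavy_only),
    class = "atom_selection")
}

#' Resolve a selection against a topology
#'
#' @param sel an [atom_selection()].
#' @param top a [topology].
#' @return integer vector of atom indices (1-based, in topology order).
#' @export
resolve_selection <- function(sel, top) {
  stopifnot(inherits(sel, "atom_selection"), inherits(top, "topology"))
  at <- top$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$chain))   keep <- keep & at$chain %in% sel$chain
  if (!is.null(sel$resid))   keep <- keep & at$resid %in% sel$resid
  if (!is.null(sel$resname)) keep <- keep & at$resname %in% sel$resname
  if (!is.null(sel$name))    keep <- keep & at$name %in% sel$name
  if (isTRUE(sel$heavy_only)) keep <- keep & !at$is_hydrogen
  which(keep)
}

#' @export
print.atom_selection <- function(x, ...) {
  fields <- Filter(Negate(is.null), x[c("chain", "resid", "resname", "name")])
  desc <- if (length(fields) == 0L) "all atoms" else
    paste(vapply(names(fields), function(f)
      paste0(f, "=", paste(fields[[f]], collapse = ",")), ""), collapse = " ")
  cat("<atom_selection> ", desc,
      if (x$heavy_only) " (heavy atoms only)" else "", "\n", sep = "")
  invisible(x)
}
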