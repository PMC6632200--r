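## Alignment-column conservation at positions mapped from a reference
## sequence's ungapped numbering. Raw percentages only: phylogenetic
## rate-based grades (e.g. ConSurf's 1-9 scale) are display pass-throughs,
## not recomputed, because they are not a function of the column
## composition alone.

.default_classes <- list(negative = c("D", "E"), positive = c("K", "R", "H"))

#' Load or build a multiple sequence alignment
#'
#' @param x path to an aligned FASTA file (read with Biostrings) or a
#'   named character vector of equal-length aligned sequences.
#' @param ref_name name of the reference sequence used for position
#'   mapping.
#' @return object of class `msa_alignment`: list with `seqs` (named
#'   character, uppercase) and `ref_name`.
#' @export
read_alignment <- function(x, ref_name) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- Biostrings::readAAStringSet(x)
    stats::setNames(as.character(set), names(set))
  } else if (is.character(x) && !is.null(names(x))) {
    x
  } else stop("supply an aligned FASTA path or a named character vector")
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences differ in length: ",
         paste(range(widths), collapse = " vs "))
  if (!ref_name %in% names(seqs))
    stop("reference sequence '", ref_name, "' not in alignment")
  structure(list(seqs = seqs, ref_name = ref_name), class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("<msa_alignment> ", length(x$seqs), " sequences x ",
      nchar(x$seqs[[1]]), " columns (reference: ", x$ref_name, ")\n",
      sep = "")
  invisible(x)
}

#' Map an ungapped reference position to an alignment column
#'
#' @param aln an `msa_alignment`.
#' @param ref_pos 1-based position in the ungapped reference sequence.
#' @return 1-based alignment column index.
#' @examples
#' aln <- read_alignment(c(ref = "M-KT", other = "MAKT"), "ref")
#' map_position(aln, 2)  # column 3
#' @export
map_position <- function(aln, ref_pos) {
  stopifnot(inherits(aln, "msa_alignment"))
  ref <- strsplit(aln$seqs[[aln$ref_name]], "")[[1]]
  non_gap <- which(!ref %in% c("-", "."))
  vapply(ref_pos, function(p) {
    if (p < 1L || p > length(non_gap))
      stop("reference position ", p, " outside ungapped length ",
           length(non_gap))
    non_gap[p]
  }, 0L)
}

#' Conservation of one alignment column
#'
#' @param aln an `msa_alignment`.
#' @param column 1-based alignment column.
#' @param classes named list of residue classes whose pooled percentage
#'   is reported (default: negative = D/E, positive = K/R/H).
#' @param ignore_gaps when `FALSE` (default) gaps stay in the denominator
#'   and count as mismatches — the conservative convention; when `TRUE`
#'   percentages are over non-gap sequences only.
#' @return list: `column`, `ref_residue`, `identity_pct` (percent of
#'   sequences matching the reference residue), `class_pct` (named
#'   vector), `composition` (named percentage vector over residues,
#'   including a `"-"` gap category, summing to 100), `denominator`.
#' @export
column_conservation <- function(aln, column, classes = .default_classes,
                                ignore_gaps = FALSE) {
  stopifnot(inherits(aln, "msa_alignment"))
  chars <- stats::setNames(toupper(substr(aln$seqs, column, column)),
                           names(aln$seqs))
  chars[chars == "."] <- "-"
  if (any(chars == ""))
    stop("column ", column, " outside alignment width")
  ref_res <- chars[[aln$ref_name]]
  denom_chars <- if (ignore_gaps) chars[chars != "-"] else chars
  denom <- length(denom_chars)
  comp <- table(chars) / length(chars) * 100
  class_pct <- vapply(classes, function(cl)
    sum(denom_chars %in% cl) / denom * 100, 0)
  list(column = column,
       ref_residue = ref_res,
       identity_pct = sum(denom_chars == ref_res) / denom * 100,
       class_pct = class_pct,
       composition = stats::setNames(as.numeric(comp), names(comp)),
       denominator = denom)
}

#' Conservation profile at mapped reference positions
#'
#' @param aln an `msa_alignment`.
#' @param positions 1-based positions in the ungapped reference sequence
#'   (e.g. `c(71, 75, 501, 504)`).
#' @inheritParams column_conservation
#' @return data.frame with one row per position: `ref_pos`, `column`,
#'   `ref_residue`, `identity_pct`, one `pct_<class>` column per class,
#'   and `composition` as a compact `res:pct` string.
#' @export
conservation_profile <- function(aln, positions,
                                 classes = .default_classes,
                                 ignore_gaps = FALSE) {
  cols <- map_position(aln, positions)
  rows <- lapply(seq_along(positions), function(k) {
    cc <- column_conservation(aln, cols[k], classes, ignore_gaps)
    out <- data.frame(ref_pos = positions[k], column = cc$column,
                      ref_residue = cc$ref_residue,
                      identity_pct = cc$identity_pct)
    for (cl in names(cc$class_pct))
      out[[paste0("pct_", cl)]] <- cc$class_pct[[cl]]
    out$composition <- paste(names(cc$composition),
                             format(cc$composition, trim = TRUE,
                                    digits = 4),
                             sep = ":", collapse = " ")
    out
  })
  do.call(rbind, rows)
}
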