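## Domain model and I/O for topologies and multi-frame coordinate sets.
## Conventions: coordinates in Angstrom, frames 0-based, residue numbers
## kept exactly as read (author numbering), orthorhombic boxes only.

.default_ion_aliases <- c(
  "NA" = "Na", "SOD" = "Na",
  "K"  = "K",  "POT" = "K",
  "CL" = "Cl", "CLA" = "Cl")

#' Build a topology from an atom table
#'
#' @param atoms data.frame with columns `serial` (integer, unique), `name`
#'   (atom name), `element`, `resname`, `resid` (integer residue number),
#'   `chain`; an `is_hydrogen` column is derived from `element` (falling
#'   back to the first letter of the atom name) when absent.
#' @param ion_aliases named character vector mapping residue names of
#'   monatomic ions to canonical species labels. The default covers PDB
#'   and CHARMM conventions (`NA`/`SOD` -> `Na`, `K`/`POT` -> `K`,
#'   `CL`/`CLA` -> `Cl`). Extend it to declare additional species.
#' @return object of class `topology`: a list with the validated `atoms`
#'   table and `ion_sets`, a named list of atom indices per ion species.
#'   Only single-atom residues are accepted as ions.
#' @export
topology <- function(atoms, ion_aliases = .default_ion_aliases) {
  required <- c("serial", "name", "element", "resname", "resid", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("empty topology: no atoms")
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  for (col in c("name", "element", "resname", "chain"))
    atoms[[col]] <- as.character(atoms[[col]])
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers are not unique")
  if (any(is.na(atoms$element) | atoms$element == ""))
    stop("every atom needs a non-empty element symbol")
  if (is.null(atoms$is_hydrogen)) {
    first_alpha <- sub("^[0-9]*", "", atoms$name)
    atoms$is_hydrogen <- toupper(atoms$element) == "H" |
      (toupper(atoms$element) == "" & startsWith(toupper(first_alpha), "H"))
  }
  rownames(atoms) <- NULL
  top <- structure(list(atoms = atoms, ion_aliases = ion_aliases),
                   class = "topology")
  top$ion_sets <- .detect_ions(top)
  top
}

.residue_key <- function(atoms) paste(atoms$chain, atoms$resid, atoms$resname)

.detect_ions <- function(top) {
  at <- top$atoms
  aliases <- top$ion_aliases
  key <- .residue_key(at)
  res_size <- table(key)
  hit <- unname(toupper(at$resname) %in% names(aliases) &
                  res_size[key] == 1L)
  species <- unname(aliases[toupper(at$resname[hit])])
  split(which(hit), factor(species, levels = unique(unname(aliases))),
        drop = TRUE)
}

#' @export
print.topology <- function(x, ...) {
  ions <- vapply(x$ion_sets, length, 0L)
  cat("<topology> ", nrow(x$atoms), " atoms, ",
      length(unique(.residue_key(x$atoms))), " residues",
      if (length(ions) > 0L)
        paste0("; ions: ", paste(names(ions), ions, sep = "=", collapse = " ")),
      "\n", sep = "")
  invisible(x)
}

#' Number of atoms / frames
#' @param x a `topology` or `trajectory`.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' @rdname n_atoms
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "trajectory"))
  dim(x$coords)[3]
}

#' Residue table of a topology
#'
#' One row per residue in order of first appearance, with the atom indices
#' belonging to it.
#' @param top a [topology].
#' @param heavy_only restrict member atom lists to heavy atoms.
#' @return data.frame with columns chain, resid, resname and a list column
#'   `atom_idx`.
#' @export
residue_table <- function(top, heavy_only = TRUE) {
  at <- top$atoms
  key <- .residue_key(at)
  first <- !duplicated(key)
  idx <- split(seq_len(nrow(at)), factor(key, levels = key[first]))
  if (heavy_only) idx <- lapply(idx, function(i) i[!at$is_hydrogen[i]])
  data.frame(chain = at$chain[first], resid = at$resid[first],
             resname = at$resname[first], atom_idx = I(unname(idx)),
             stringsAsFactors = FALSE)
}

#' Assemble a trajectory
#'
#' @param top a [topology].
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param box optional orthorhombic box lengths, length-3 numeric
#'   (Angstrom), applied to every frame; `NULL` means non-periodic.
#' @param times optional per-frame times in picoseconds.
#' @param replicate_id label distinguishing independent replicates.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(top, coords, box = NULL, times = NULL,
                       replicate_id = "rep1") {
  stopifnot(inherits(top, "topology"))
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(top$atoms))
    stop("coordinate array has ", dim(coords)[1], " atoms but topology has ",
         nrow(top$atoms))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(box)) box <- .check_box(box)
  if (!is.null(times)) {
    stopifnot(length(times) == dim(coords)[3])
    if (is.unsorted(times, strictly = TRUE)) stop("frame times must increase")
  }
  structure(list(topology = top, coords = coords, box = box, times = times,
                 replicate_id = replicate_id),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_atoms(x), " atoms x ", n_frames(x), " frames",
      if (!is.null(x$box))
        paste0(", box ", paste(format(x$box), collapse = " x "), " A"),
      " [", x$replicate_id, "]\n", sep = "")
  invisible(x)
}

.check_box <- function(box) {
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive orthorhombic edge lengths")
  box
}

#' Pairwise distance with optional minimum-image convention
#'
#' Euclidean distance between two points; when orthorhombic box lengths are
#' supplied, the minimum-image distance (each Cartesian component wrapped
#' into `[-L/2, L/2]`).
#'
#' @param a,b numeric length-3 coordinates (Angstrom).
#' @param box optional length-3 box lengths; `NULL` for non-periodic.
#' @return distance in Angstrom.
#' @examples
#' pair_distance(c(0, 0, 0), c(3, 4, 0))              # 5
#' pair_distance(c(1, 0, 0), c(9, 0, 0), box = rep(10, 3))  # 2
#' @export
pair_distance <- function(a, b, box = NULL) {
  stopifnot(length(a) == 3L, length(b) == 3L)
  d <- as.numeric(a) - as.numeric(b)
  if (!all(is.finite(d))) stop("non-finite coordinates")
  if (!is.null(box)) {
    box <- .check_box(box)
    d <- d - box * round(d / box)
  }
  sqrt(sum(d * d))
}

## Squared distances between two 3 x n coordinate matrices, column-wise.
.dist_sq <- function(a, b, box = NULL) {
  d <- a - b
  if (!is.null(box)) d <- d - box * round(d / box)
  colSums(d * d)
}

## 3 x n_frames coordinate series of one atom.
.atom_series <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

## Per-frame minimum distance from atom `ion` to any atom in `members`.
.min_dist_series <- function(traj, ion, members) {
  ion_xyz <- .atom_series(traj, ion)
  best <- rep(Inf, n_frames(traj))
  for (m in members)
    best <- pmin(best, .dist_sq(.atom_series(traj, m), ion_xyz, traj$box))
  sqrt(best)
}

## one-letter residue code for labels ("D75:OD1"); ions and unknown
## residue names fall back to their first character
.res_letter <- function(resname) {
  out <- suppressWarnings(bio3d::aa321(resname))
  bad <- is.na(out) | out == "X"
  out[bad] <- substr(resname[bad], 1, 1)
  out
}

## "D75:OD1"-style labels for a set of atom indices
.atom_labels <- function(top, idx) {
  at <- top$atoms
  paste0(.res_letter(at$resname[idx]), at$resid[idx], ":", at$name[idx])
}

## ---- file I/O -------------------------------------------------------------

.read_cryst1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0L) return(NULL)
  f <- function(i, j) suppressWarnings(as.numeric(substr(cl[1], i, j)))
  lens <- c(f(7, 15), f(16, 24), f(25, 33))
  angs <- c(f(34, 40), f(41, 47), f(48, 54))
  if (any(is.na(lens))) stop("malformed CRYST1 record in ", path)
  if (any(abs(angs - 90) > 1e-6))
    stop("triclinic box (angles != 90 deg) not supported; ",
         "only orthorhombic boxes are handled")
  lens
}

#' Read a topology from file
#'
#' Supported formats: `pdb` (ATOM/HETATM records, parsed by bio3d), `xyz`
#' (element + Cartesian lines; each atom becomes its own residue, so ion
#' species are picked up from the element symbol) and `table` (TSV with
#' columns serial, name, element, resname, resid, chain).
#'
#' Monatomic ions are auto-detected from residue names via `ion_aliases`,
#' and a CRYST1 record (PDB) is returned as attribute `"box"`.
#'
#' @inheritParams topology
#' @param path input file.
#' @param format one of `"pdb"`, `"xyz"`, `"table"`; default guessed from
#'   the file extension.
#' @return a [topology]; attribute `"box"` holds orthorhombic box lengths
#'   when the file declares them.
#' @export
read_topology <- function(path, format = c("auto", "pdb", "xyz", "table"),
                          ion_aliases = .default_ion_aliases) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  top <- switch(format,
    pdb = .read_topology_pdb(path, ion_aliases),
    xyz = .read_topology_xyz(path, ion_aliases),
    table = .read_topology_table(path, ion_aliases))
  top
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, pdb = "pdb", ent = "pdb", xyz = "xyz",
         tsv = "table", txt = "table",
         stop("cannot guess trajectory format from extension '", ext, "'"))
}

.read_topology_pdb <- function(path, ion_aliases) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty topology: no atoms in ", path)
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <-
    sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety[is.na(elem) | elem == ""])
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(serial = at$eleno, name = at$elety, element = elem,
                      resname = at$resid, resid = at$resno, chain = chain,
                      stringsAsFactors = FALSE)
  top <- topology(atoms, ion_aliases)
  box <- .read_cryst1(path)
  if (!is.null(box)) attr(top, "box") <- box
  top
}

.read_topology_xyz <- function(path, ion_aliases) {
  fr <- .parse_xyz(path)
  el <- fr$elements
  atoms <- data.frame(serial = seq_along(el), name = el, element = el,
                      resname = toupper(el), resid = seq_along(el),
                      chain = "A", stringsAsFactors = FALSE)
  topology(atoms, ion_aliases)
}

.read_topology_table <- function(path, ion_aliases) {
  # na.strings = "" so the sodium element/residue name "NA" survives
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  topology(tab, ion_aliases)
}

#' Write a topology (single reference frame) to file
#'
#' @param top a [topology].
#' @param path output file.
#' @param coords optional `n_atoms x 3` coordinate matrix (defaults to the
#'   origin for every atom, which suffices for table output).
#' @param format `"pdb"` or `"table"`.
#' @param box optional box lengths written as a CRYST1 record (pdb only).
#' @export
write_topology <- function(top, path, coords = NULL,
                           format = c("pdb", "table"), box = NULL) {
  format <- match.arg(format)
  if (format == "table") {
    utils::write.table(top$atoms[, c("serial", "name", "element", "resname",
                                     "resid", "chain")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(coords)) coords <- matrix(0, nrow(top$atoms), 3)
  traj <- trajectory(top, coords, box = box)
  write_frames(traj, path, format = "pdb")
}

#' Read trajectory frames against a known topology
#'
#' @param path multi-model PDB, multi-frame XYZ, or tabular trajectory
#'   (TSV with columns frame, atom_serial, x, y, z).
#' @param top the [topology] the frames must match; an atom-count mismatch
#'   in any frame is an error naming the (0-based) frame.
#' @param format file format; `"auto"` guesses from the extension.
#' @param replicate_id label stored on the trajectory.
#' @return a [trajectory]; box taken from CRYST1 (PDB) when present.
#' @export
read_frames <- function(path, top, format = c("auto", "pdb", "xyz", "table"),
                        replicate_id = "rep1") {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  na <- nrow(top$atoms)
  box <- NULL
  times <- NULL
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    if (ncol(pdb$xyz) != 3L * nrow(pdb$atom))
      stop("inconsistent multi-model PDB: ", path)
    if (nrow(pdb$atom) != na)
      stop("atom-count mismatch at frame 0: file has ", nrow(pdb$atom),
           " atoms, topology has ", na)
    nf <- nrow(pdb$xyz)
    coords <- array(NA_real_, c(na, 3L, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
    box <- .read_cryst1(path)
  } else if (format == "xyz") {
    frames <- .parse_xyz_frames(path)
    for (f in seq_along(frames))
      if (nrow(frames[[f]]$xyz) != na)
        stop("atom-count mismatch at frame ", f - 1L, ": file has ",
             nrow(frames[[f]]$xyz), " atoms, topology has ", na)
    coords <- array(NA_real_, c(na, 3L, length(frames)))
    for (f in seq_along(frames)) coords[, , f] <- frames[[f]]$xyz
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("frame", "atom_serial", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("tabular trajectory needs columns: ", paste(need, collapse = ", "))
    fids <- sort(unique(tab$frame))
    coords <- array(NA_real_, c(na, 3L, length(fids)))
    serial_pos <- match(tab$atom_serial, top$atoms$serial)
    if (anyNA(serial_pos))
      stop("atom_serial values not present in topology")
    for (f in seq_along(fids)) {
      rows <- which(tab$frame == fids[f])
      if (length(rows) != na)
        stop("atom-count mismatch at frame ", fids[f], ": file has ",
             length(rows), " atoms, topology has ", na)
      coords[serial_pos[rows], , f] <- as.matrix(tab[rows, c("x", "y", "z")])
    }
    if ("time_ps" %in% names(tab))
      times <- vapply(fids, function(f) tab$time_ps[tab$frame == f][1], 0)
  }
  trajectory(top, coords, box = box, times = times,
             replicate_id = replicate_id)
}

#' Write trajectory frames
#'
#' PDB output uses MODEL/ENDMDL records (via bio3d) with a CRYST1 record
#' when the trajectory carries a box; coordinates are written at PDB
#' precision (3 decimals). XYZ and tabular output keep full precision.
#'
#' @param traj a [trajectory].
#' @param path output file.
#' @param format `"pdb"`, `"xyz"` or `"table"`.
#' @export
write_frames <- function(traj, path, format = c("pdb", "xyz", "table")) {
  format <- match.arg(format)
  at <- traj$topology$atoms
  nf <- n_frames(traj)
  if (format == "pdb") {
    xyz <- t(apply(traj$coords, 3, function(m) as.numeric(t(m))))
    if (nf == 1L) xyz <- matrix(xyz, nrow = 1L)
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(file = tmp, xyz = xyz, eleno = at$serial,
                     elety = at$name, resid = at$resname, resno = at$resid,
                     chain = at$chain, elesy = at$element)
    lines <- readLines(tmp, warn = FALSE)
    unlink(tmp)
    if (!is.null(traj$box))
      lines <- c(sprintf(
        "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
        traj$box[1], traj$box[2], traj$box[3]), lines)
    writeLines(lines, path)
  } else if (format == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(nf)) {
      writeLines(c(as.character(nrow(at)), paste("frame", f - 1L)), con)
      writeLines(sprintf("%s %.6f %.6f %.6f", at$element,
                         traj$coords[, 1, f], traj$coords[, 2, f],
                         traj$coords[, 3, f]), con)
    }
  } else {
    tab <- do.call(rbind, lapply(seq_len(nf), function(f)
      data.frame(frame = f - 1L, atom_serial = at$serial,
                 x = traj$coords[, 1, f], y = traj$coords[, 2, f],
                 z = traj$coords[, 3, f])))
    utils::write.table(format(tab, digits = 12, scientific = FALSE,
                              trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

.parse_xyz <- function(path) {
  frames <- .parse_xyz_frames(path)
  list(elements = frames[[1]]$elements, n_frames = length(frames))
}

.parse_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("XYZ parse error at line ", i, ": expected atom count")
    if (i + 1L + n > length(lines))
      stop("XYZ parse error: truncated frame starting at line ", i)
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(parts, length, 0L) < 4L)
    if (length(bad) > 0L)
      stop("XYZ parse error at line ", i + 1L + bad[1],
           ": expected 'element x y z'")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop("XYZ parse error: non-numeric coordinates in frame at line ", i)
    frames[[length(frames) + 1L]] <-
      list(elements = vapply(parts, `[`, "", 1L), xyz = xyz)
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("empty XYZ file: ", path)
  frames
}
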