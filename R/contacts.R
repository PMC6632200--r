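## Species-resolved ion-residue contact frequency tables and candidate
## coordination-site identification.

#' Contact counting parameters
#'
#' @param cutoff contact cutoff in Angstrom; an ion "approaches" a residue
#'   in a frame when its minimum distance to any residue heavy atom is
#'   `<= cutoff`. Default 4.0 A, the conventional first-shell contact
#'   criterion for cation-protein interactions.
#' @param heavy_only exclude hydrogens from residue atoms (default TRUE).
#' @param counting `"ion_frame_pairs"` counts every (ion, frame) pair
#'   within the cutoff, so two simultaneous ions contribute twice;
#'   `"any_ion_per_frame"` counts a frame at most once per residue.
#' @return object of class `contact_parameters`.
#' @export
contact_parameters <- function(cutoff = 4.0, heavy_only = TRUE,
                               counting = c("ion_frame_pairs",
                                            "any_ion_per_frame")) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  counting <- match.arg(counting)
  structure(list(cutoff = cutoff, heavy_only = heavy_only,
                 counting = counting),
            class = "contact_parameters")
}

#' Count ion-residue contacts over a trajectory
#'
#' For every residue and ion species, counts the frames in which an ion of
#' that species lies within the cutoff of the residue, and expresses the
#' count relative to the number of frames (in percent). Under the default
#' `ion_frame_pairs` convention the relative frequency of a heavily
#' visited residue can exceed 100% when several ions sit there at once.
#'
#' @param traj a [trajectory] whose topology declares at least one ion.
#' @param params [contact_parameters()].
#' @param residues optional [atom_selection()] restricting which residues
#'   are profiled (ions and any unselected residues are skipped).
#' @param species character vector of ion species labels to profile;
#'   defaults to the cations `c("Na", "K")` intersected with the ions
#'   present.
#' @return a `contact_table`: data.frame with one row per residue (chain,
#'   resid, resname), per-species absolute and relative columns (e.g.
#'   `na_abs`, `na_rel`), and attributes `n_frames`, `species`, `params`,
#'   `replicate_ids`.
#' @export
count_contacts <- function(traj, params = contact_parameters(),
                           residues = NULL, species = NULL) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(params, "contact_parameters"))
  top <- traj$topology
  avail <- names(top$ion_sets)
  if (is.null(species)) species <- intersect(c("Na", "K"), avail)
  if (length(species) == 0L || !all(species %in% avail))
    stop("no ions of the requested species declared in the topology ",
         "(available: ", paste(avail, collapse = ", "), ")")
  ion_atoms <- unlist(top$ion_sets, use.names = FALSE)
  res <- residue_table(top, heavy_only = params$heavy_only)
  res$atom_idx <- lapply(res$atom_idx, setdiff, y = ion_atoms)
  keep <- lengths(res$atom_idx) > 0L
  if (!is.null(residues)) {
    sel_idx <- resolve_selection(residues, top)
    keep <- keep & vapply(res$atom_idx,
                          function(i) any(i %in% sel_idx), TRUE)
  }
  res <- res[keep, , drop = FALSE]
  if (nrow(res) == 0L) stop("residue selection resolves to no residues")
  nf <- n_frames(traj)
  out <- res[, c("chain", "resid", "resname")]
  for (sp in species) {
    ions <- top$ion_sets[[sp]]
    abs_count <- integer(nrow(res))
    for (r in seq_len(nrow(res))) {
      members <- res$atom_idx[[r]]
      if (params$counting == "ion_frame_pairs") {
        n <- 0L
        for (ion in ions)
          n <- n + sum(.min_dist_series(traj, ion, members) <= params$cutoff)
      } else {
        hit <- rep(FALSE, nf)
        for (ion in ions)
          hit <- hit | .min_dist_series(traj, ion, members) <= params$cutoff
        n <- sum(hit)
      }
      abs_count[r] <- n
    }
    out[[paste0(tolower(sp), "_abs")]] <- abs_count
    out[[paste0(tolower(sp), "_rel")]] <- abs_count / nf * 100
  }
  rownames(out) <- NULL
  structure(out, class = c("contact_table", "data.frame"),
            n_frames = nf, species = species, params = params,
            replicate_ids = traj$replicate_id)
}

#' Construct a contact table from given counts
#'
#' Mainly for loading published contact-frequency tables (where only the
#' printed counts and percentages are known) into the same container the
#' profiler produces. `n_frames = NA` marks the frame total as unknown.
#'
#' @param df data.frame with columns chain, resid, resname and per-species
#'   `<sp>_abs` / `<sp>_rel` columns.
#' @param species species labels present (default `c("Na", "K")`).
#' @param n_frames total frames behind the counts, or `NA` if unknown.
#' @param params the [contact_parameters()] the counts correspond to.
#' @param replicate_ids contributing replicate labels.
#' @return a `contact_table`.
#' @export
as_contact_table <- function(df, species = c("Na", "K"), n_frames = NA,
                             params = contact_parameters(),
                             replicate_ids = character()) {
  need <- c("chain", "resid", "resname",
            paste0(tolower(species), "_abs"), paste0(tolower(species), "_rel"))
  if (!all(need %in% names(df)))
    stop("contact table needs columns: ", paste(setdiff(need, names(df)),
                                                collapse = ", "))
  structure(as.data.frame(df), class = c("contact_table", "data.frame"),
            n_frames = n_frames, species = species, params = params,
            replicate_ids = replicate_ids)
}

#' Merge per-replicate contact tables
#'
#' Absolute counts and frame totals are summed; relative frequencies are
#' recomputed from the merged totals, so the merge of three 100-frame
#' replicates equals one recount over the 300-frame concatenation.
#'
#' @param tables list of `contact_table`s over identical residue keys,
#'   species and parameters.
#' @return merged `contact_table`.
#' @export
merge_replicates <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  lapply(tables, function(t) stopifnot(inherits(t, "contact_table")))
  ref <- tables[[1]]
  species <- attr(ref, "species")
  key <- function(t) paste(t$chain, t$resid, t$resname)
  for (t in tables[-1]) {
    if (!identical(key(t), key(ref)) ||
        !identical(attr(t, "species"), species))
      stop("cannot merge: residue keys or species differ (",
           paste(union(setdiff(key(t), key(ref)),
                       setdiff(key(ref), key(t))), collapse = "; "), ")")
    if (!identical(attr(t, "params"), attr(ref, "params")))
      stop("cannot merge: contact parameters differ")
  }
  out <- ref[, c("chain", "resid", "resname")]
  nf <- sum(vapply(tables, attr, 0, which = "n_frames"))
  for (sp in tolower(species)) {
    acol <- paste0(sp, "_abs")
    total <- Reduce(`+`, lapply(tables, `[[`, acol))
    out[[acol]] <- total
    out[[paste0(sp, "_rel")]] <- total / nf * 100
  }
  if (all(paste0(c("sum_abs", "sum_rel")) %in% names(ref)))
    out <- combine_species(as_contact_table(out, species, nf,
                                            attr(ref, "params")))
  structure(as.data.frame(out), class = c("contact_table", "data.frame"),
            n_frames = nf, species = species, params = attr(ref, "params"),
            replicate_ids = unlist(lapply(tables, attr,
                                          which = "replicate_ids")))
}

#' Add combined-species columns to a contact table
#'
#' Appends `sum_abs` and `sum_rel` columns accumulating all species.
#' Combined absolutes are the integer sums; combined relatives are
#' recomputed from the summed counts when the frame total is known, and
#' fall back to summing the per-species relative columns (2-decimal
#' printed arithmetic) when it is not.
#'
#' @param table a `contact_table`.
#' @return the table with `sum_abs` / `sum_rel` columns populated;
#'   per-species columns unchanged.
#' @export
combine_species <- function(table) {
  stopifnot(inherits(table, "contact_table"))
  species <- tolower(attr(table, "species"))
  stopifnot(length(species) >= 1L)
  abs_cols <- paste0(species, "_abs")
  rel_cols <- paste0(species, "_rel")
  table$sum_abs <- Reduce(`+`, lapply(abs_cols, function(c) table[[c]]))
  nf <- attr(table, "n_frames")
  table$sum_rel <- if (!is.na(nf)) table$sum_abs / nf * 100 else
    Reduce(`+`, lapply(rel_cols, function(c) table[[c]]))
  table
}

#' Identify candidate coordination sites from a contact table
#'
#' Residues whose combined relative contact frequency reaches
#' `rel_threshold` are clustered by single linkage on minimum heavy-atom
#' inter-residue distance; every cluster becomes a candidate site. The
#' default threshold (1%) and linkage cutoff (8 A) group residues a few
#' Angstrom apart on the protein surface into one site while keeping
#' spatially separate hot spots distinct.
#'
#' @param table a `contact_table` (combined columns added if absent).
#' @param top the [topology] the table refers to.
#' @param ref_coords `n_atoms x 3` reference coordinates for residue
#'   positions (a representative frame or a mean structure).
#' @param rel_threshold minimum combined relative frequency, percent.
#' @param link_cutoff single-linkage distance cutoff in Angstrom
#'   (inclusive).
#' @param box optional box lengths for periodic distances.
#' @return list of [site_definition()]s, possibly empty; each named by its
#'   member residues (ordered by residue number).
#' @export
identify_candidate_sites <- function(table, top, ref_coords,
                                     rel_threshold = 1.0, link_cutoff = 8.0,
                                     box = NULL) {
  stopifnot(inherits(table, "contact_table"), inherits(top, "topology"))
  if (!"sum_rel" %in% names(table)) table <- combine_species(table)
  hits <- table[table$sum_rel >= rel_threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(list())
  res <- residue_table(top, heavy_only = TRUE)
  rk <- paste(res$chain, res$resid, res$resname)
  hit_idx <- match(paste(hits$chain, hits$resid, hits$resname), rk)
  if (anyNA(hit_idx)) stop("contact table rows not found in topology")
  n <- length(hit_idx)
  cluster <- if (n == 1L) 1L else {
    dmin <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ai <- res$atom_idx[[hit_idx[i]]]
      aj <- res$atom_idx[[hit_idx[j]]]
      d <- outer(ai, aj, function(p, q)
        sqrt(.dist_sq(t(ref_coords[p, , drop = FALSE]),
                      t(ref_coords[q, , drop = FALSE]), box)))
      dmin[i, j] <- dmin[j, i] <- min(d)
    }
    stats::cutree(stats::hclust(stats::as.dist(dmin), method = "single"),
                  h = link_cutoff)
  }
  lapply(unname(split(seq_len(n), cluster)), function(members) {
    ord <- members[order(hits$resid[members])]
    site_definition(
      name = paste0(.res_letter(hits$resname[ord]), hits$resid[ord],
                    collapse = "-"),
      members = atom_selection(chain = unique(hits$chain[ord]),
                               resid = hits$resid[ord]))
  })
}
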