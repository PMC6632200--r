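## Approach/dwell-event extraction at a defined surface site and summary
## statistics per ion species.

#' Define a coordination site
#'
#' A site is a named set of member atoms (typically the heavy atoms of a
#' handful of surface residues) plus the contact cutoff that defines "in
#' the site".
#'
#' @param name site label, e.g. `"P71-D75-D501-K504"`.
#' @param members an [atom_selection()] resolving to the member atoms.
#' @param cutoff in-site cutoff in Angstrom (inclusive), default 4.0.
#' @return object of class `site_definition`.
#' @export
site_definition <- function(name, members, cutoff = 4.0) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(members, "atom_selection"),
            is.numeric(cutoff), cutoff > 0)
  structure(list(name = name, members = members, cutoff = cutoff),
            class = "site_definition")
}

#' @export
print.site_definition <- function(x, ...) {
  cat("<site_definition> ", x$name, " (cutoff ", x$cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Per-frame site occupancy of one ion
#'
#' @param traj a [trajectory].
#' @param site a [site_definition()].
#' @param ion atom index of the ion.
#' @return logical vector of length `n_frames(traj)`: `TRUE` where the
#'   ion's minimum distance to any site member atom is `<= cutoff`.
#' @export
occupancy_mask <- function(traj, site, ion) {
  stopifnot(inherits(traj, "trajectory"), inherits(site, "site_definition"))
  members <- resolve_selection(site$members, traj$topology)
  members <- setdiff(members, ion)
  if (length(members) == 0L)
    stop("site '", site$name, "' resolves to no member atoms")
  .min_dist_series(traj, ion, members) <= site$cutoff
}

#' Extract approach events from an occupancy mask
#'
#' Maximal runs of `TRUE` frames become events. With `debounce_gap > 0`,
#' two runs separated by at most that many `FALSE` frames are fused into
#' one event whose duration includes the gap frames (a brief single-frame
#' exit then does not terminate an approach).
#'
#' @param mask logical per-frame occupancy vector.
#' @param debounce_gap maximum number of out-of-site frames bridged
#'   between two runs, default 0.
#' @return data.frame with columns `start_frame`, `end_frame` (0-based,
#'   inclusive) and `duration_frames`; zero rows when the mask is all
#'   `FALSE`.
#' @export
extract_events <- function(mask, debounce_gap = 0L) {
  stopifnot(is.logical(mask), debounce_gap >= 0L)
  if (anyNA(mask)) stop("mask contains NA")
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0L)
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      duration_frames = integer()))
  ev_start <- starts[on]
  ev_end <- ends[on]
  if (debounce_gap > 0L && length(on) > 1L) {
    fuse <- ev_start[-1L] - ev_end[-length(ev_end)] - 1L <= debounce_gap
    grp <- cumsum(c(TRUE, !fuse))
    ev_start <- tapply(ev_start, grp, min)
    ev_end <- tapply(ev_end, grp, max)
  }
  data.frame(start_frame = as.integer(ev_start) - 1L,
             end_frame = as.integer(ev_end) - 1L,
             duration_frames = as.integer(ev_end - ev_start + 1L))
}

#' Site occupancy masks and events for every ion
#'
#' @param traj a [trajectory].
#' @param site a [site_definition()].
#' @param species ion species to include (default all declared cations
#'   `c("Na", "K")` intersected with the topology's ions).
#' @param debounce_gap passed to [extract_events()].
#' @return list with `masks` (named by ion atom index), `events`
#'   (data.frame with ion, species, site, start_frame, end_frame,
#'   duration_frames) and `species_of` (species label per ion).
#' @export
site_events <- function(traj, site, species = NULL, debounce_gap = 0L) {
  top <- traj$topology
  avail <- names(top$ion_sets)
  if (is.null(species)) species <- intersect(c("Na", "K"), avail)
  if (length(species) == 0L || !all(species %in% avail))
    stop("no ions of the requested species in the topology")
  ions <- unlist(top$ion_sets[species], use.names = FALSE)
  species_of <- rep(species, vapply(top$ion_sets[species], length, 0L))
  masks <- lapply(ions, function(i) occupancy_mask(traj, site, i))
  names(masks) <- as.character(ions)
  ev <- do.call(rbind, lapply(seq_along(ions), function(k) {
    e <- extract_events(masks[[k]], debounce_gap)
    if (nrow(e) == 0L) return(NULL)
    cbind(data.frame(ion = ions[k], species = species_of[k],
                     site = site$name), e)
  }))
  if (is.null(ev))
    ev <- data.frame(ion = integer(), species = character(),
                     site = character(), start_frame = integer(),
                     end_frame = integer(), duration_frames = integer())
  list(masks = masks, events = ev, species_of = stats::setNames(
    species_of, as.character(ions)))
}

#' Summarize approach events per ion species
#'
#' Dwell percentage follows the `"mean"` convention by default: the mean
#' over the species' ions of each ion's occupied-frame fraction (so it is
#' a per-ion average residence). The `"union"` convention instead reports
#' the fraction of frames in which at least one ion of the species is in
#' the site.
#'
#' @param ev result of [site_events()].
#' @param n_frames total frame count of the underlying trajectory.
#' @param dwell_statistic `"mean"` or `"union"`.
#' @return data.frame with one row per species: `n_ions`, `n_approaches`,
#'   `dwell_pct`, `mean_dwell` (frames; `NA` when there are no
#'   approaches) and `max_dwell`.
#' @export
summarize_events <- function(ev, n_frames,
                             dwell_statistic = c("mean", "union")) {
  dwell_statistic <- match.arg(dwell_statistic)
  species <- unique(unname(ev$species_of))
  do.call(rbind, lapply(species, function(sp) {
    ions <- names(ev$species_of)[ev$species_of == sp]
    if (length(ions) == 0L) {
      warning("species ", sp, " has no ions; omitted")
      return(NULL)
    }
    e <- ev$events[ev$events$species == sp, , drop = FALSE]
    occ <- if (dwell_statistic == "mean") {
      mean(vapply(ev$masks[ions], mean, 0))
    } else {
      mean(Reduce(`|`, ev$masks[ions]))
    }
    total_dwell <- sum(vapply(ev$masks[ions], sum, 0L))
    data.frame(species = sp, n_ions = length(ions), n_approaches = nrow(e),
               dwell_pct = occ * 100,
               mean_dwell = if (nrow(e) > 0L) total_dwell / nrow(e) else NA_real_,
               max_dwell = if (nrow(e) > 0L) max(e$duration_frames) else NA_integer_)
  }))
}

#' Per-residue dwell breakdown at a site
#'
#' Re-evaluates occupancy against each member residue alone (same cutoff),
#' reporting per-species dwell percentages under the union convention.
#' With single-residue sites this reproduces the contact profiler's
#' `any_ion_per_frame` relative frequencies.
#'
#' @param traj a [trajectory].
#' @param site a [site_definition()].
#' @param species species labels (default declared cations).
#' @return data.frame: residue key columns plus one `dwell_pct_<species>`
#'   column per species.
#' @export
per_residue_dwell <- function(traj, site, species = NULL) {
  top <- traj$topology
  members <- resolve_selection(site$members, top)
  res <- residue_table(top, heavy_only = TRUE)
  in_site <- vapply(res$atom_idx, function(i) any(i %in% members), TRUE)
  res <- res[in_site, , drop = FALSE]
  avail <- names(top$ion_sets)
  if (is.null(species)) species <- intersect(c("Na", "K"), avail)
  out <- res[, c("chain", "resid", "resname")]
  for (sp in species) {
    ions <- top$ion_sets[[sp]]
    pct <- vapply(seq_len(nrow(res)), function(r) {
      sub <- site_definition(paste0(site$name, ":", res$resid[r]),
                             atom_selection(resid = res$resid[r],
                                            chain = res$chain[r]),
                             cutoff = site$cutoff)
      hit <- Reduce(`|`, lapply(ions, function(i)
        occupancy_mask(traj, sub, i)))
      mean(hit) * 100
    }, 0)
    out[[paste0("dwell_pct_", tolower(sp))]] <- pct
  }
  rownames(out) <- NULL
  out
}
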