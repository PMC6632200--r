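## Ion-atom distance series and in-site coordination statistics: which
## protein atoms actually coordinate the cation while it sits in the site.

#' Ion-atom distance series
#'
#' Full-trajectory, periodic-aware distance between one ion and each atom
#' of a selection — the per-atom traces from which coordination is judged.
#'
#' @param traj a [trajectory].
#' @param ion atom index of the ion.
#' @param atoms an [atom_selection()] for the candidate coordinating
#'   atoms (e.g. carbonyl and carboxylate oxygens plus the lysine NZ).
#' @return object of class `atom_pair_series`: list with `distances`
#'   (matrix `n_frames x n_atoms`), `labels` (`"D75:OD1"` style),
#'   `atom_idx` and `ion`.
#' @export
distance_series <- function(traj, ion, atoms) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- resolve_selection(atoms, traj$topology)
  if (ion %in% idx) stop("selection includes the ion atom itself")
  if (length(idx) == 0L) stop("atom selection resolves to no atoms")
  d <- vapply(idx, function(i) .min_dist_series(traj, ion, i),
              numeric(n_frames(traj)))
  if (n_frames(traj) == 1L) d <- matrix(d, nrow = 1L)
  labels <- .atom_labels(traj$topology, idx)
  structure(list(distances = d, labels = labels, atom_idx = idx, ion = ion),
            class = "atom_pair_series")
}

#' In-site coordination statistics
#'
#' Mean, spread and close-contact fraction of each ion-atom distance,
#' restricted to frames in which the ion occupies the site. The standard
#' deviation is the population form (divide by n) by default, matching a
#' statistic over the full in-site population rather than a sample.
#'
#' @param series an `atom_pair_series` from [distance_series()].
#' @param mask logical in-site mask (e.g. from [occupancy_mask()]), same
#'   length as the series.
#' @param proximity close-contact threshold in Angstrom used for
#'   `fraction_below_proximity` (species-specific; see
#'   [coordination_call()] for defaults).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return data.frame with one row per atom: `atom`, `mean_distance`,
#'   `sd_distance`, `n_frames_used`, `fraction_below_proximity`; `NULL`
#'   with a warning when the mask selects no frames.
#' @export
in_site_stats <- function(series, mask, proximity = 2.6,
                          sd_type = c("population", "sample")) {
  stopifnot(inherits(series, "atom_pair_series"),
            length(mask) == nrow(series$distances))
  sd_type <- match.arg(sd_type)
  n <- sum(mask)
  if (n == 0L) {
    warning("no in-site frames; statistics withheld")
    return(NULL)
  }
  d <- series$distances[mask, , drop = FALSE]
  mu <- colMeans(d)
  sdv <- sqrt(colMeans(sweep(d, 2, mu)^2))
  if (sd_type == "sample" && n > 1L) sdv <- sdv * sqrt(n / (n - 1))
  data.frame(atom = series$labels,
             mean_distance = mu,
             sd_distance = sdv,
             n_frames_used = n,
             fraction_below_proximity = colMeans(d < proximity),
             proximity_threshold = proximity,
             row.names = NULL)
}

#' Call coordinating atoms
#'
#' An atom is called coordinating for a species when the ion sits within
#' the species-specific first-shell proximity of it for at least
#' `occupancy_fraction` of the in-site frames (inclusive thresholds). The
#' proximity defaults (Na 2.6 A, K 3.0 A) reflect first-shell
#' cation-oxygen distances; K+ coordinates at systematically longer range
#' than Na+. Positively charged atoms still appear in the output — they
#' are simply called non-coordinating when they fail the criterion, which
#' is itself informative (cation-cation repulsion).
#'
#' @param stats data.frame from [in_site_stats()].
#' @param species ion species label (`"Na"` or `"K"`, or any label with
#'   an entry in `proximity`).
#' @param proximity named numeric of per-species proximity thresholds in
#'   Angstrom.
#' @param occupancy_fraction minimum close-contact fraction (inclusive).
#' @param min_frames minimum `n_frames_used` below which calls are
#'   withheld (default 50).
#' @return data.frame with `atom`, `species`, `is_coordinating`,
#'   `fraction_below_proximity`, plus the thresholds used; `NULL` with a
#'   warning when there are too few in-site frames.
#' @export
coordination_call <- function(stats, species,
                              proximity = c(Na = 2.6, K = 3.0),
                              occupancy_fraction = 0.25,
                              min_frames = 50L) {
  if (is.null(stats)) return(NULL)
  if (!species %in% names(proximity))
    stop("no proximity threshold configured for species ", species)
  if (any(stats$n_frames_used < min_frames)) {
    warning("fewer than ", min_frames,
            " in-site frames; coordination call withheld")
    return(NULL)
  }
  if (!is.null(stats$proximity_threshold) &&
      any(abs(stats$proximity_threshold - proximity[species]) > 1e-9))
    warning("stats were computed with proximity ",
            stats$proximity_threshold[1], " A but species ", species,
            " is configured at ", proximity[species],
            " A; recompute in_site_stats with the matching threshold")
  data.frame(atom = stats$atom, species = species,
             is_coordinating = stats$fraction_below_proximity >=
               occupancy_fraction,
             fraction_below_proximity = stats$fraction_below_proximity,
             proximity_threshold = unname(proximity[species]),
             occupancy_fraction = occupancy_fraction,
             row.names = NULL)
}
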