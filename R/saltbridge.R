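## Donor-acceptor distance series, formation thresholds, occupancy and
## carboxylate-oxygen orientation analysis for candidate salt bridges.

#' Define a candidate salt bridge
#'
#' @param basic an [atom_selection()] for the positively charged nitrogen
#'   (e.g. the lysine NZ); must resolve to exactly one atom per series
#'   (use [bridge_series()] once per basic atom otherwise).
#' @param acidic an [atom_selection()] for the carboxylate oxygen(s)
#'   (one or two atoms, e.g. OD1/OD2 of an aspartate).
#' @param label bridge label, e.g. `"K504-D75"`.
#' @return object of class `salt_bridge_pair`.
#' @export
salt_bridge_pair <- function(basic, acidic, label) {
  stopifnot(inherits(basic, "atom_selection"),
            inherits(acidic, "atom_selection"),
            is.character(label), length(label) == 1L)
  structure(list(basic = basic, acidic = acidic, label = label),
            class = "salt_bridge_pair")
}

#' Per-frame donor-acceptor distances of a salt bridge
#'
#' Computes the distance from the basic nitrogen to each acidic oxygen in
#' every frame, the per-frame minimum, and which oxygen is currently the
#' nearer ("oriented") one. Carboxylate oxygens swap orientation as the
#' side chain rotates; ties go to the lower atom index.
#'
#' @param traj a [trajectory].
#' @param pair a [salt_bridge_pair()].
#' @return object of class `bridge_series` (one per basic atom; a list of
#'   them if the basic selection resolves to several atoms): `distances`
#'   (matrix `n_frames x n_oxygens`), `min_distance`, `oriented_oxygen`
#'   (column index of the nearer oxygen per frame), `oxygen_labels`,
#'   `label`.
#' @export
bridge_series <- function(traj, pair) {
  stopifnot(inherits(traj, "trajectory"), inherits(pair, "salt_bridge_pair"))
  top <- traj$topology
  basic_idx <- resolve_selection(pair$basic, top)
  acidic_idx <- resolve_selection(pair$acidic, top)
  if (length(basic_idx) == 0L || length(acidic_idx) == 0L)
    stop("bridge '", pair$label, "': selection resolves to no atoms")
  one <- function(b) {
    d <- vapply(acidic_idx, function(o) .min_dist_series(traj, b, o),
                numeric(n_frames(traj)))
    if (n_frames(traj) == 1L) d <- matrix(d, nrow = 1L)
    structure(list(
      distances = d,
      min_distance = do.call(pmin, lapply(seq_len(ncol(d)),
                                          function(j) d[, j])),
      oriented_oxygen = max.col(-d, ties.method = "first"),
      oxygen_labels = .atom_labels(top, acidic_idx),
      label = pair$label),
      class = "bridge_series")
  }
  if (length(basic_idx) == 1L) one(basic_idx) else lapply(basic_idx, one)
}

#' Salt-bridge occupancy and distance statistics
#'
#' A bridge is counted as formed in a frame when the minimum
#' nitrogen-oxygen distance is strictly below `formed_cutoff` (3.2 A) and
#' as possible when strictly below `possible_cutoff` (4.0 A). Per-oxygen
#' medians are computed twice: over that oxygen's full series, and
#' restricted to the frames in which it is the oriented (nearer) oxygen —
#' the relevant statistic when the two carboxylate oxygens alternate.
#'
#' @param series a `bridge_series` from [bridge_series()].
#' @param formed_cutoff formation threshold in Angstrom (strict `<`).
#' @param possible_cutoff loose threshold in Angstrom (strict `<`).
#' @return list of class `bridge_stats`: `occupancy_formed` and
#'   `occupancy_possible` (percent of frames, from the per-frame minimum),
#'   `median_min`, `fivenum_min`, and a per-oxygen data.frame with
#'   occupancies, full-series medians and oriented-frame medians.
#' @export
bridge_stats <- function(series, formed_cutoff = 3.2, possible_cutoff = 4.0) {
  stopifnot(inherits(series, "bridge_series"),
            nrow(series$distances) >= 1L)
  mind <- series$min_distance
  per_ox <- do.call(rbind, lapply(seq_len(ncol(series$distances)),
    function(j) {
      dj <- series$distances[, j]
      orient <- series$oriented_oxygen == j
      data.frame(
        oxygen = series$oxygen_labels[j],
        occupancy_formed = mean(dj < formed_cutoff) * 100,
        occupancy_possible = mean(dj < possible_cutoff) * 100,
        median_full = stats::median(dj),
        n_oriented = sum(orient),
        median_oriented = if (any(orient)) stats::median(dj[orient])
                          else NA_real_)
    }))
  structure(list(
    label = series$label,
    occupancy_formed = mean(mind < formed_cutoff) * 100,
    occupancy_possible = mean(mind < possible_cutoff) * 100,
    median_min = stats::median(mind),
    fivenum_min = stats::fivenum(mind),
    per_oxygen = per_ox,
    formed_cutoff = formed_cutoff,
    possible_cutoff = possible_cutoff,
    orientation_rule = "nearest oxygen per frame (approximation)"),
    class = "bridge_stats")
}

#' @export
print.bridge_stats <- function(x, ...) {
  cat("<bridge_stats> ", x$label, ": formed ",
      format(x$occupancy_formed, digits = 4), "% (< ", x$formed_cutoff,
      " A), possible ", format(x$occupancy_possible, digits = 4),
      "% (< ", x$possible_cutoff, " A), median min ",
      format(x$median_min, digits = 4), " A\n", sep = "")
  invisible(x)
}
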