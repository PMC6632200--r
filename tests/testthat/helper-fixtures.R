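# Shared fixtures and independent oracles.

# tiny hand-built topology: two residues (GLY with CA+O, ASP with OD1)
# plus one Na+ and one K+ ion
make_tiny_topology <- function() {
  topology(data.frame(
    serial = 1:5,
    name = c("CA", "O", "OD1", "NA", "K"),
    element = c("C", "O", "O", "NA", "K"),
    resname = c("GLY", "GLY", "ASP", "NA", "K"),
    resid = c(10L, 10L, 20L, 601L, 602L),
    chain = c("A", "A", "A", "I", "I")))
}

# trajectory with explicit per-frame ion positions; protein atoms static
# at the given coordinates
make_tiny_traj <- function(ion_na, ion_k = NULL, box = NULL,
                           protein_xyz = rbind(c(0, 0, 0), c(2, 0, 0),
                                               c(0, 3, 0))) {
  top <- make_tiny_topology()
  nf <- nrow(ion_na)
  if (is.null(ion_k)) ion_k <- matrix(rep(c(50, 50, 50), nf), ncol = 3,
                                      byrow = TRUE)
  coords <- array(NA_real_, c(5, 3, nf))
  for (f in seq_len(nf)) {
    coords[1:3, , f] <- protein_xyz
    coords[4, , f] <- ion_na[f, ]
    coords[5, , f] <- ion_k[f, ]
  }
  trajectory(top, coords, box = box)
}

# random trajectory over a random topology; some ions, some protein atoms
random_trajectory <- function(n_atoms, n_frames, n_ions, box = NULL,
                              span = 20) {
  n_prot <- n_atoms - n_ions
  n_res <- max(1L, n_prot %/% 3L)
  atoms <- data.frame(
    serial = seq_len(n_atoms),
    name = c(rep(c("CA", "CB", "O"), length.out = n_prot),
             rep("NA", n_ions)),
    element = c(rep(c("C", "C", "O"), length.out = n_prot),
                rep("NA", n_ions)),
    resname = c(rep("GLY", n_prot), rep("NA", n_ions)),
    resid = c(sort(sample.int(n_res, n_prot, replace = TRUE)),
              900L + seq_len(n_ions)),
    chain = c(rep("A", n_prot), rep("I", n_ions)))
  top <- topology(atoms)
  lim <- if (is.null(box)) rep(span, 3) else box
  coords <- array(stats::runif(n_atoms * 3 * n_frames) *
                    rep(lim, each = n_atoms), c(n_atoms, 3, n_frames))
  trajectory(top, coords, box = box)
}

# brute-force minimum-image distance: wrap the displacement into one
# period, then take the minimum over all 27 image shifts
dist_27 <- function(a, b, box) {
  d0 <- (a - b) %% box
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- d0 + c(i, j, k) * box
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# all-pairs brute-force contact recount, structured frame-by-frame
# (deliberately different from the profiler's frame-vectorized path)
brute_force_contacts <- function(traj, cutoff = 4.0,
                                 counting = "ion_frame_pairs") {
  top <- traj$topology
  res <- residue_table(top, heavy_only = TRUE)
  ion_idx <- unlist(top$ion_sets, use.names = FALSE)
  res$atom_idx <- lapply(res$atom_idx, setdiff, y = ion_idx)
  res <- res[lengths(res$atom_idx) > 0L, , drop = FALSE]
  species <- intersect(c("Na", "K"), names(top$ion_sets))
  counts <- matrix(0L, nrow(res), length(species),
                   dimnames = list(NULL, species))
  box <- traj$box
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f]
    for (r in seq_len(nrow(res))) {
      ratoms <- xyz[res$atom_idx[[r]], , drop = FALSE]
      for (sp in species) {
        hits <- 0L
        for (ion in top$ion_sets[[sp]]) {
          d <- sweep(ratoms, 2, xyz[ion, ])
          if (!is.null(box)) d <- d - rep(box, each = nrow(d)) * round(
            d / rep(box, each = nrow(d)))
          dmin <- sqrt(min(rowSums(d * d)))
          if (dmin <= cutoff) hits <- hits + 1L
        }
        if (counting == "any_ion_per_frame") hits <- min(hits, 1L)
        counts[r, sp] <- counts[r, sp] + hits
      }
    }
  }
  data.frame(resid = res$resid, counts)
}

# run-length-encoding oracle for event extraction at debounce 0
rle_events <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_frame = starts[keep] - 1L, end_frame = ends[keep] - 1L,
             duration_frames = r$lengths[keep])
}
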