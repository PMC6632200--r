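## Synthetic-data generators with closed-form ground truth. Site visits
## follow a two-state Markov chain per ion (bulk -> site entry probability
## a, site -> site stay probability s), so occupancy and dwell statistics
## have exact expectations: stationary occupancy a/(a + 1 - s), mean dwell
## 1/(1 - s) frames. Ions teleport between placements rather than diffuse;
## this sacrifices path realism for exact ground truth.

#' Toy pocket topology
#'
#' A 12-atom, 4-residue surface pocket (P71 backbone with its carbonyl
#' oxygen, D75 and D501 carboxylates, the K504 ammonium nitrogen) plus a
#' configurable pool of Na+ and K+ ions. Atom names follow PDB
#' conventions (O, OD1/OD2, NZ) so downstream reports read like real
#' coordination-site output.
#'
#' @param n_ions named integer vector of ions per species, default
#'   `c(Na = 6, K = 6)` (the ionic pool used to mimic a 10 mM NaCl +
#'   10 mM KCl box around one protein).
#' @return list with `top` (a [topology]), `protein_xyz` (12 x 3 matrix,
#'   pocket centered at (30, 30, 30)), `site_residues` (71, 75, 501,
#'   504), and `oxygen_labels` (the shell-placement anchor atoms).
#' @export
toy_pocket_topology <- function(n_ions = c(Na = 6, K = 6)) {
  prot <- data.frame(
    name    = c("CA", "CB", "C", "O",
                "CB", "OD1", "OD2",
                "CB", "OD1", "OD2",
                "CE", "NZ"),
    element = c("C", "C", "C", "O", "C", "O", "O", "C", "O", "O", "C", "N"),
    resname = c(rep("PRO", 4), rep("ASP", 3), rep("ASP", 3), rep("LYS", 2)),
    resid   = c(rep(71L, 4), rep(75L, 3), rep(501L, 3), rep(504L, 2)),
    stringsAsFactors = FALSE)
  xyz <- rbind(
    c(27.5, 30.0, 31.0), c(26.6, 30.9, 31.7), c(28.4, 29.1, 31.8),
    c(29.2, 28.4, 31.2),
    c(28.0, 32.5, 28.5), c(29.3, 31.9, 28.2), c(27.8, 33.3, 27.5),
    c(32.5, 29.0, 28.8), c(31.5, 28.3, 29.4), c(33.0, 28.6, 27.7),
    c(31.0, 31.8, 27.9), c(30.8, 30.6, 26.6))
  ion_resname <- c(Na = "NA", K = "K")
  ions <- do.call(rbind, lapply(names(n_ions), function(sp)
    data.frame(name = ion_resname[[sp]], element = ion_resname[[sp]],
               resname = ion_resname[[sp]],
               resid = seq_len(n_ions[[sp]]), stringsAsFactors = FALSE)))
  ions$resid <- 600L + seq_len(nrow(ions))
  atoms <- rbind(cbind(prot, chain = "A"), cbind(ions, chain = "I"))
  atoms$serial <- seq_len(nrow(atoms))
  list(top = topology(atoms),
       protein_xyz = xyz,
       site_residues = c(71L, 75L, 501L, 504L),
       oxygen_labels = c("P71:O", "D75:OD1", "D75:OD2",
                         "D501:OD1", "D501:OD2"))
}

#' Trajectory simulation configuration
#'
#' @param box orthorhombic box lengths, Angstrom.
#' @param n_frames frames to generate.
#' @param n_ions named integer vector of ions per species.
#' @param entry_prob `a`, per-frame bulk-to-site entry probability (open
#'   interval (0, 1)).
#' @param stay_prob `s`, per-frame site-to-site stay probability.
#' @param site_shell `(r_min, r_max)` placement shell around a site
#'   oxygen for in-site frames, Angstrom; `r_max` must not exceed the
#'   contact cutoff meant for recovery (default shell 2.0-3.5 A under a
#'   4 A cutoff).
#' @param bulk_exclusion minimum distance of bulk placements from any
#'   pocket atom, Angstrom; must exceed the contact cutoff so that bulk
#'   frames can never register as in-site.
#' @param coordination optional list `(atom = "D75:OD1", mu = , sigma = )`:
#'   when set, in-site frames sit at a Gaussian(mu, sigma) distance from
#'   that anchor atom instead of uniformly in the shell.
#' @param smooth use an Ornstein-Uhlenbeck tether for consecutive in-site
#'   frames (smoother geometry; placements are radially clipped to the
#'   shell so the occupancy ground truth still holds exactly).
#' @param seed integer seed; identical configs reproduce bit-identical
#'   output.
#' @return list of class `traj_sim_config`.
#' @export
traj_sim_config <- function(box = c(60, 60, 60), n_frames = 10000L,
                            n_ions = c(Na = 6, K = 6),
                            entry_prob = 0.02, stay_prob = 0.9,
                            site_shell = c(2.0, 3.5), bulk_exclusion = 6.0,
                            coordination = NULL, smooth = FALSE,
                            seed = 1L) {
  stopifnot(entry_prob > 0, entry_prob < 1, stay_prob > 0, stay_prob < 1,
            site_shell[1] > 0, site_shell[2] >= site_shell[1],
            bulk_exclusion > site_shell[2], n_frames >= 1L)
  structure(list(box = .check_box(box), n_frames = as.integer(n_frames),
                 n_ions = n_ions, entry_prob = entry_prob,
                 stay_prob = stay_prob, site_shell = site_shell,
                 bulk_exclusion = bulk_exclusion,
                 coordination = coordination, smooth = smooth,
                 seed = as.integer(seed)),
            class = "traj_sim_config")
}

## one mask from the alternating-renewal form of the two-state chain
.simulate_mask <- function(n, a, s) {
  occ <- a / (a + 1 - s)
  state <- stats::runif(1) < occ
  runs <- logical(0)
  lens <- integer(0)
  total <- 0L
  while (total < n) {
    len <- if (state) stats::rgeom(1, 1 - s) + 1 else
      stats::rgeom(1, a) + 1
    # rgeom overflows to NA for tiny probabilities; clamp to what is left
    len <- min(if (is.na(len)) n else len, n - total)
    runs <- c(runs, state)
    lens <- c(lens, len)
    total <- total + len
    state <- !state
  }
  rep(runs, lens)[seq_len(n)]
}

.runif_sphere <- function(n) {
  z <- stats::rnorm(3 * n)
  m <- matrix(z, nrow = 3)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Simulate an ion trajectory with known site-visit ground truth
#'
#' Each ion carries an independent two-state Markov chain gating whether
#' it is "in" the pocket. In-site frames are placed inside a spherical
#' shell around a randomly chosen site oxygen (or at a Gaussian radial
#' distance from a designated anchor atom); bulk frames are uniform in
#' the box, rejecting placements within `bulk_exclusion` of any pocket
#' atom. Because the shell lies inside the contact cutoff and the bulk
#' exclusion outside it, the chain's mask equals the geometric occupancy
#' mask by construction.
#'
#' @param config a [traj_sim_config()].
#' @param replicate_id label for the generated trajectory.
#' @return list with `traj` (a [trajectory]), `site` (the pocket
#'   [site_definition()], cutoff 4 A) and `truth`: per-ion true masks,
#'   `stationary_occupancy` = a/(a+1-s), `mean_dwell` = 1/(1-s) frames,
#'   `expected_approaches` per ion, and the config.
#' @export
simulate_trajectory <- function(config = traj_sim_config(),
                                replicate_id = "sim1") {
  stopifnot(inherits(config, "traj_sim_config"))
  set.seed(config$seed)
  pocket <- toy_pocket_topology(config$n_ions)
  top <- pocket$top
  box <- config$box
  if (any(apply(pocket$protein_xyz, 2, max) + config$site_shell[2] >
          box) || any(apply(pocket$protein_xyz, 2, min) -
                      config$site_shell[2] < 0))
    stop("placement shell does not fit inside the box")
  nf <- config$n_frames
  n_prot <- nrow(pocket$protein_xyz)
  ions <- unlist(top$ion_sets, use.names = FALSE)
  coords <- array(NA_real_, c(nrow(top$atoms), 3L, nf))
  coords[seq_len(n_prot), , ] <- pocket$protein_xyz  # static scaffold
  labels <- .atom_labels(top, seq_len(n_prot))
  anchor_pool <- match(pocket$oxygen_labels, labels)
  coord_cfg <- config$coordination
  if (!is.null(coord_cfg)) {
    anchor_fixed <- match(coord_cfg$atom, labels[seq_len(n_prot)])
    if (is.na(anchor_fixed))
      stop("unknown coordination anchor atom: ", coord_cfg$atom)
  }
  masks <- vector("list", length(ions))
  names(masks) <- as.character(ions)
  for (k in seq_along(ions)) {
    mask <- .simulate_mask(nf, config$entry_prob, config$stay_prob)
    masks[[k]] <- mask
    xyz <- matrix(NA_real_, 3L, nf)
    n_in <- sum(mask)
    if (n_in > 0L) {
      if (!is.null(coord_cfg)) {
        anchors <- rep(anchor_fixed, n_in)
        r <- pmax(stats::rnorm(n_in, coord_cfg$mu, coord_cfg$sigma), 0.1)
        r <- pmin(r, 3.95)  # keep inside the 4 A cutoff
      } else {
        anchors <- sample(anchor_pool, n_in, replace = TRUE)
        # uniform in the shell volume
        u <- stats::runif(n_in)
        r3 <- config$site_shell^3
        r <- (r3[1] + u * (r3[2] - r3[1]))^(1 / 3)
      }
      dirs <- .runif_sphere(n_in)
      pos <- t(pocket$protein_xyz[anchors, , drop = FALSE]) + dirs *
        rep(r, each = 3L)
      if (config$smooth) {
        # OU tether: relax each in-site run toward its previous offset
        in_idx <- which(mask)
        off <- pos - t(pocket$protein_xyz[anchors, , drop = FALSE])
        for (j in seq_along(in_idx)[-1]) {
          if (in_idx[j] == in_idx[j - 1] + 1L &&
              anchors[j] == anchors[j - 1]) {
            off[, j] <- 0.8 * off[, j - 1] + 0.2 * off[, j]
            rr <- sqrt(sum(off[, j]^2))
            rr_clip <- min(max(rr, config$site_shell[1]),
                           config$site_shell[2])
            off[, j] <- off[, j] / rr * rr_clip
          }
        }
        pos <- t(pocket$protein_xyz[anchors, , drop = FALSE]) + off
      }
      xyz[, mask] <- pos
    }
    n_out <- nf - n_in
    if (n_out > 0L) {
      need <- n_out
      placed <- matrix(NA_real_, 3L, 0L)
      while (need > 0L) {
        cand <- matrix(stats::runif(3L * ceiling(need * 1.3)) *
                         rep(box, ceiling(need * 1.3)), nrow = 3L)
        dmin2 <- rep(Inf, ncol(cand))
        for (p in seq_len(n_prot))
          dmin2 <- pmin(dmin2, .dist_sq(cand, pocket$protein_xyz[p, ], box))
        ok <- cand[, dmin2 > config$bulk_exclusion^2, drop = FALSE]
        placed <- cbind(placed, ok)
        need <- n_out - ncol(placed)
      }
      xyz[, !mask] <- placed[, seq_len(n_out)]
    }
    coords[ions[k], , ] <- xyz
  }
  traj <- trajectory(top, coords, box = box, replicate_id = replicate_id)
  a <- config$entry_prob; s <- config$stay_prob
  occ <- a / (a + 1 - s)
  list(traj = traj,
       site = site_definition("P71-D75-D501-K504",
                              atom_selection(chain = "A",
                                             resid = pocket$site_residues),
                              cutoff = 4.0),
       truth = list(masks = masks,
                    stationary_occupancy = occ,
                    mean_dwell = 1 / (1 - s),
                    expected_approaches = (nf - 1) * a * (1 - occ) +
                      occ,  # entries plus a possible in-site start
                    config = config))
}

## ---- voltage-clamp simulator ---------------------------------------------

#' Default simulated bath solutions
#'
#' Conductances, reversal potentials and deactivating fractions chosen to
#' mimic the wild-type phenomenology of a class II HKT transporter in
#' oocytes: microampere Na+ inward currents that roughly double with 1 mM
#' K+, K+-only solutions indistinguishable from background, V_rev shifting
#' with the Na+ concentration, and partial deactivation at high Na+ that
#' shrinks as K+ rises (fractions 0.120, 0.107 and 0.032 at Na30K0,
#' Na30K1 and Na30K30).
#'
#' @return data.frame with columns `label`, `na_mm`, `k_mm`, `g_uS`
#'   (chord conductance, microsiemens), `vrev_mV`, `deact_f` (asymptotic
#'   deactivating fraction), `tau_s`.
#' @export
default_solutions <- function() {
  data.frame(
    label  = c("Na0K1", "Na0K30", "Na03K0", "Na03K1", "Na30K0", "Na30K1",
               "Na30K30"),
    na_mm  = c(0, 0, 0.3, 0.3, 30, 30, 30),
    k_mm   = c(1, 30, 0, 1, 0, 1, 30),
    g_uS   = c(0.2, 0.3, 3, 6, 15, 30, 16),
    vrev_mV = c(-30, -20, -120, -100, -50, -45, -35),
    deact_f = c(0, 0, 0, 0, 0.120, 0.107, 0.032),
    tau_s  = 0.2,
    stringsAsFactors = FALSE)
}

#' Voltage-clamp simulation configuration
#'
#' @param protocol a [sweep_protocol()].
#' @param solutions data.frame in the format of [default_solutions()].
#' @param sample_rate sampling rate, Hz.
#' @param noise_sd Gaussian white current noise, uA.
#' @param seed integer seed.
#' @return list of class `tevc_sim_config`.
#' @export
tevc_sim_config <- function(protocol = sweep_protocol(),
                            solutions = default_solutions(),
                            sample_rate = 5000, noise_sd = 0.02,
                            seed = 1L) {
  stopifnot(all(solutions$tau_s > 0), all(solutions$deact_f >= 0),
            all(solutions$deact_f < 1), sample_rate > 0)
  structure(list(protocol = protocol, solutions = solutions,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "tevc_sim_config")
}

#' Simulate voltage-clamp recordings with known ground truth
#'
#' Sweep currents follow a linear chord-conductance model with
#' exponential partial deactivation at voltages negative to the reversal
#' potential:
#' `I(t) = g * (V - V_rev) * [f_ss + (1 - f_ss) * exp(-t / tau)] / 1000`
#' with `f_ss = 1 - f` for deactivating sweeps (`V < V_rev`) and
#' `f_ss = 1` otherwise, plus Gaussian white noise. Currents are in uA
#' (g in uS, V in mV).
#'
#' @param config a [tevc_sim_config()].
#' @param cell_id cell label attached to all recordings.
#' @return list with `recordings` (one [tevc_recording()] per solution)
#'   and `truth` (the solutions table plus the config).
#' @export
simulate_recording <- function(config = tevc_sim_config(),
                               cell_id = "simcell1") {
  stopifnot(inherits(config, "tevc_sim_config"))
  set.seed(config$seed)
  proto <- config$protocol
  nsamp <- round(proto$pulse_duration * config$sample_rate)
  t <- (seq_len(nsamp) - 1L) / config$sample_rate
  recs <- lapply(seq_len(nrow(config$solutions)), function(i) {
    sol <- config$solutions[i, ]
    sweeps <- lapply(proto$voltages, function(v) {
      f_ss <- if (v < sol$vrev_mV) 1 - sol$deact_f else 1
      ideal <- sol$g_uS * (v - sol$vrev_mV) *
        (f_ss + (1 - f_ss) * exp(-t / sol$tau_s)) / 1000
      noisy <- ideal + if (config$noise_sd > 0)
        stats::rnorm(nsamp, 0, config$noise_sd) else 0
      current_sweep(v, noisy, config$sample_rate)
    })
    tevc_recording(sol$label, sol$na_mm, sol$k_mm, sweeps, proto, cell_id)
  })
  names(recs) <- config$solutions$label
  list(recordings = recs,
       truth = list(solutions = config$solutions, config = config))
}

#' Closed-form window mean of a simulated sweep
#'
#' The analytic value of [window_currents()] applied to a noise-free
#' simulated sweep: the time average of
#' `g * (V - V_rev) * [f_ss + (1 - f_ss) * exp(-t / tau)] / 1000` over
#' `[t0, t1]`.
#'
#' @param g_uS,vrev_mV,deact_f,tau_s solution parameters (see
#'   [default_solutions()]).
#' @param v step voltage, mV.
#' @param t0,t1 window bounds, s.
#' @return mean current in uA.
#' @export
analytic_window_mean <- function(g_uS, vrev_mV, deact_f, tau_s, v, t0, t1) {
  f_ss <- if (v < vrev_mV) 1 - deact_f else 1
  expo <- tau_s * (exp(-t0 / tau_s) - exp(-t1 / tau_s)) / (t1 - t0)
  g_uS * (v - vrev_mV) * (f_ss + (1 - f_ss) * expo) / 1000
}

## ---- synthetic conservation alignment ------------------------------------

#' Synthetic HKT family alignment with published column compositions
#'
#' Builds a deterministic, fully synthetic 20-sequence scaffold alignment
#' (named after experimentally characterized HKT accessions, reference
#' `OsHKT2;2_Q93XI5`) whose columns at the reference coordination-site
#' positions carry the reported family compositions: P71 conserved in 18
#' of 20 sequences (one K, one S), D75 and K504 invariant, and position
#' 501 holding 12 D, 3 E, 2 N, 1 P, 1 K and 1 W. All other columns are a
#' uniform scaffold; five gap columns are inserted in the reference so
#' that position mapping is exercised. The sequences are NOT the real HKT
#' sequences — only the site-column compositions are meaningful.
#'
#' @return an `msa_alignment` (see [read_alignment()]).
#' @export
synthetic_hkt_alignment <- function() {
  acc <- c("AtHKT1_Q84TI7", "EcHKT1;1_Q9LLM4", "EcHKT1;2_Q9FVK0",
           "HvHKT2;1_Q4VWZ3", "McHKT1;1_Q84UZ6", "OsHKT1;1_Q7XPF8",
           "OsHKT1;3_Q6H501", "OsHKT1;4_Q7XPF7", "OsHKT1;5_Q0JNB6",
           "OsHKT2;1_Q0D9S3", "OsHKT2;2_Q93XI5", "OsHKT2;3_Q8L481",
           "OsHKT2;4_Q8L4K5", "PhaHKT2;1_AB234305", "PutHKT2;1_C7B119",
           "SlHKT1;1_CCJ09641", "SlHKT1;2_CCJ09642", "TaHKT1;4_A0N0D7",
           "TaHKT1;5_A6XCE1", "TaHKT2;1_Q41515")
  ref_name <- "OsHKT2;2_Q93XI5"
  len <- 520L
  ref_idx <- match(ref_name, acc)
  # per-sequence residue at the four site positions (reference first kept
  # at the canonical P/D/D/K)
  col71 <- rep("P", 20); col71[c(3, 8)] <- c("K", "S")
  # 12 D (the reference among them), 3 E, 2 N, 1 P, 1 K, 1 W
  col501 <- c(rep("D", 12), rep("E", 3), rep("N", 2), "P", "K", "W")
  seqs <- vapply(seq_along(acc), function(i) {
    s <- rep("A", len)
    s[71] <- col71[i]
    s[75] <- "D"
    s[501] <- col501[i]
    s[504] <- "K"
    paste(s, collapse = "")
  }, "")
  # five alignment columns present in the other sequences but gapped in
  # the reference (an insertion the reference lacks), placed before the
  # site region so mapped columns differ from reference positions
  insert_at <- 40L
  seqs <- vapply(seq_along(acc), function(i) {
    filler <- if (i == ref_idx) "-----" else "SSSSS"
    paste0(substr(seqs[i], 1, insert_at), filler,
           substr(seqs[i], insert_at + 1L, len))
  }, "")
  read_alignment(stats::setNames(seqs, acc), ref_name)
}
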