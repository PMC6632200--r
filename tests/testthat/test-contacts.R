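test_that("contacts count (ion, frame) pairs with an inclusive cutoff", {
  # Na ion at nearest-atom distances 3.9, 4.1, 2.0 A from residue GLY10
  traj <- make_tiny_traj(rbind(c(3.9, 0, 0) + c(2, 0, 0),
                               c(4.1 + 2, 0, 0),
                               c(2 + 2, 0, 0)))
  tab <- count_contacts(traj)
  gly <- tab[tab$resid == 10, ]
  expect_equal(gly$na_abs, 2L)
  expect_equal(gly$na_rel, 2 / 3 * 100, tolerance = 1e-12)
  expect_equal(gly$k_abs, 0L)
})

test_that("an ion never in range yields all-zero counts", {
  traj <- make_tiny_traj(matrix(rep(c(30, 30, 30), 5), ncol = 3,
                                byrow = TRUE))
  tab <- count_contacts(traj)
  expect_true(all(tab$na_abs == 0))
  expect_true(all(tab$na_rel == 0))
})

test_that("topologies without declared ions are a configuration error", {
  top <- topology(data.frame(serial = 1:2, name = c("CA", "O"),
                             element = c("C", "O"), resname = "GLY",
                             resid = 1L, chain = "A"))
  traj <- trajectory(top, array(0, c(2, 3, 1)))
  expect_error(count_contacts(traj), "no ions")
})

test_that("contact tables match an all-pairs brute-force recount", {
  set.seed(101)
  for (rep in 1:8) {
    box <- if (rep %% 2 == 0) c(15, 18, 21) else NULL
    traj <- random_trajectory(n_atoms = sample(10:30, 1),
                              n_frames = sample(20:60, 1),
                              n_ions = sample(1:3, 1), box = box,
                              span = 15)
    for (counting in c("ion_frame_pairs", "any_ion_per_frame")) {
      tab <- count_contacts(traj, contact_parameters(counting = counting))
      oracle <- brute_force_contacts(traj, 4.0, counting)
      expect_equal(tab$na_abs, oracle$Na,
                   info = paste("rep", rep, counting))
    }
  }
})

test_that("cutoff growth never decreases counts", {
  set.seed(55)
  traj <- random_trajectory(25, 40, 2, span = 12)
  cuts <- c(2, 3.5, 4, 5, 8)
  tabs <- lapply(cuts, function(cu)
    count_contacts(traj, contact_parameters(cutoff = cu)))
  for (k in seq_along(cuts)[-1])
    expect_true(all(tabs[[k]]$na_abs >= tabs[[k - 1]]$na_abs))
})

test_that("under any_ion_per_frame counts never exceed the frame total", {
  set.seed(56)
  traj <- random_trajectory(20, 30, 3, span = 8)  # crowded: many contacts
  tab <- count_contacts(traj,
                        contact_parameters(counting = "any_ion_per_frame"))
  expect_true(all(tab$na_abs <= n_frames(traj)))
})

test_that("merging replicates equals recounting the concatenation", {
  set.seed(77)
  top_traj <- random_trajectory(15, 25, 2, span = 10)
  traj_b <- trajectory(top_traj$topology,
                       top_traj$coords[, , sample(25), drop = FALSE],
                       replicate_id = "rep2")
  ta <- count_contacts(top_traj)
  tb <- count_contacts(traj_b)
  merged <- merge_replicates(list(ta, tb))
  concat <- trajectory(top_traj$topology,
                       array(c(top_traj$coords, traj_b$coords),
                             c(15, 3, 50)))
  recount <- count_contacts(concat)
  expect_equal(merged$na_abs, recount$na_abs)
  expect_equal(merged$na_rel, recount$na_rel, tolerance = 1e-12)
  expect_equal(attr(merged, "n_frames"), 50)
  expect_equal(attr(merged, "replicate_ids"), c("rep1", "rep2"))

  # identity and arithmetic cases
  expect_equal(merge_replicates(list(ta))$na_abs, ta$na_abs)
  three <- merge_replicates(list(ta, ta, ta))
  expect_equal(three$na_abs, 3L * ta$na_abs)
  expect_equal(three$na_rel, ta$na_rel, tolerance = 1e-12)
})

test_that("mismatched residue keys refuse to merge", {
  set.seed(78)
  ta <- count_contacts(random_trajectory(15, 5, 2, span = 10))
  tb <- ta[-1, ]
  attributes(tb)[c("n_frames", "species", "params", "replicate_ids")] <-
    attributes(ta)[c("n_frames", "species", "params", "replicate_ids")]
  class(tb) <- class(ta)
  expect_error(merge_replicates(list(ta, tb)), "keys")
})

test_that("combined-species columns reproduce the published sums", {
  tab <- oshkt22_contact_table()
  printed_abs <- tab$sum_abs
  printed_rel <- tab$sum_rel
  tab$sum_abs <- NULL
  tab$sum_rel <- NULL
  out <- combine_species(tab)
  expect_equal(out$sum_abs, printed_abs)            # integer arithmetic
  expect_equal(out$sum_rel, printed_rel, tolerance = 1e-12)
  # the two spot values: F69 and K70
  expect_equal(out$sum_abs[out$resid == 69], 76L)
  expect_equal(out$sum_abs[out$resid == 70], 579L)
})

test_that("single-species tables combine to themselves", {
  set.seed(5)
  traj <- random_trajectory(12, 10, 1, span = 8)
  tab <- combine_species(count_contacts(traj, species = "Na"))
  expect_equal(tab$sum_abs, tab$na_abs)
  expect_equal(tab$sum_rel, tab$na_rel)
})

test_that("combine then merge commutes with merge then combine", {
  set.seed(91)
  ta <- count_contacts(random_trajectory(15, 20, 2, span = 10))
  tb <- count_contacts(random_trajectory(15, 20, 2, span = 10))
  # force identical keys/params by rebuilding tb over ta's topology shape
  tb[c("chain", "resid", "resname")] <- ta[c("chain", "resid", "resname")]
  attr(tb, "params") <- attr(ta, "params")
  a <- combine_species(merge_replicates(list(ta, tb)))
  b <- merge_replicates(list(combine_species(ta), combine_species(tb)))
  expect_equal(a$sum_abs, b$sum_abs)
  expect_equal(a$sum_rel, b$sum_rel, tolerance = 1e-12)
})

test_that("candidate sites recover the planted pocket", {
  sim <- simulate_trajectory(traj_sim_config(n_frames = 3000, seed = 3))
  tab <- count_contacts(sim$traj)
  sites <- identify_candidate_sites(tab, sim$traj$topology,
                                    sim$traj$coords[, , 1],
                                    rel_threshold = 1.0, link_cutoff = 8.0,
                                    box = sim$traj$box)
  expect_length(sites, 1)
  got <- sort(sites[[1]]$members$resid)
  expect_equal(got, c(71L, 75L, 501L, 504L))

  # one residue above threshold: a single single-member site
  tab1 <- tab
  hot <- which.max(combine_species(tab)$sum_rel)
  tab1$na_abs[-hot] <- 0L
  tab1$na_rel[-hot] <- 0
  tab1$k_abs[-hot] <- 0L
  tab1$k_rel[-hot] <- 0
  sites1 <- identify_candidate_sites(tab1, sim$traj$topology,
                                     sim$traj$coords[, , 1])
  expect_length(sites1, 1)
  expect_length(sites1[[1]]$members$resid, 1)

  # nothing above threshold is an empty list, not an error
  expect_equal(identify_candidate_sites(tab, sim$traj$topology,
                                        sim$traj$coords[, , 1],
                                        rel_threshold = 1e9), list())
})

test_that("two planted hot spots far apart form two disjoint sites", {
  # duplicate the pocket 30 A away by editing topology and coordinates
  sim <- simulate_trajectory(traj_sim_config(n_frames = 2000, seed = 9))
  traj <- sim$traj
  top <- traj$topology
  at <- top$atoms
  prot <- at$chain == "A"
  shifted <- at[prot, ]
  shifted$serial <- max(at$serial) + seq_len(nrow(shifted))
  shifted$resid <- shifted$resid + 1000L
  at2 <- rbind(at, shifted)
  top2 <- topology(at2)
  nf <- n_frames(traj)
  coords2 <- array(NA_real_, c(nrow(at2), 3, nf))
  coords2[seq_len(nrow(at)), , ] <- traj$coords
  coords2[nrow(at) + seq_len(nrow(shifted)), , ] <-
    traj$coords[which(prot), , , drop = FALSE] +
    rep(c(0, 0, -28), each = nrow(shifted))
  # park half the Na ions at the shifted pocket's carbonyl oxygen
  shifted_o <- nrow(at) + 4L
  na_ions <- top2$ion_sets$Na
  for (ion in na_ions[1:3])
    coords2[ion, , ] <- coords2[shifted_o, , ] + c(2.5, 0, 0)
  traj2 <- trajectory(top2, coords2, box = traj$box)
  tab2 <- count_contacts(traj2)
  sites <- identify_candidate_sites(tab2, top2, coords2[, , 1],
                                    rel_threshold = 1.0, link_cutoff = 8.0,
                                    box = traj$box)
  expect_length(sites, 2)
  resids <- lapply(sites, function(s) sort(s$members$resid))
  expect_true(any(vapply(resids, function(r) all(r <= 504), TRUE)))
  expect_true(any(vapply(resids, function(r) all(r > 1000), TRUE)))
})
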