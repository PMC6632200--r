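test_that("pairwise distances are Euclidean and minimum-image aware", {
  expect_equal(pair_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(pair_distance(c(1, 0, 0), c(9, 0, 0), box = c(10, 10, 10)),
               2)
  expect_error(pair_distance(c(0, 0, NA), c(1, 1, 1)), "non-finite")
  expect_error(pair_distance(c(0, 0, 0), c(1, 1, 1), box = c(10, -1, 10)),
               "positive")
})

test_that("minimum-image distance matches 27-image enumeration", {
  set.seed(42)
  box <- c(7, 9, 11)
  for (i in 1:200) {
    a <- runif(3) * box * 3 - box       # points deliberately outside box
    b <- runif(3) * box * 3 - box
    expect_equal(pair_distance(a, b, box), dist_27(a, b, box),
                 tolerance = 1e-12)
  }
})

test_that("periodic distance never exceeds the non-periodic one and is symmetric", {
  set.seed(7)
  box <- c(12, 15, 9)
  for (i in 1:100) {
    a <- runif(3) * 30
    b <- runif(3) * 30
    d <- pair_distance(a, b, box)
    expect_lte(d, pair_distance(a, b) + 1e-12)
    expect_equal(d, pair_distance(b, a, box))
    expect_gte(d, 0)
  }
  expect_equal(pair_distance(c(1, 1, 1), c(13, 16, 10), c(12, 15, 9)), 0)
})

test_that("PDB topology parsing detects ions and the box", {
  pdb <- c(
    "CRYST1   60.000   60.000   60.000  90.00  90.00  90.00 P 1        1",
    "ATOM      1  CA  PRO A  71      10.000  10.000  10.000  1.00  0.00           C",
    "ATOM      2  O   PRO A  71      12.380  10.000  10.000  1.00  0.00           O",
    "ATOM      3  OD1 ASP A  75      14.000  12.000  10.000  1.00  0.00           O",
    "HETATM    4 NA    NA A 601      14.000  10.000  10.000  1.00  0.00          NA",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  top <- read_topology(path)
  expect_s3_class(top, "topology")
  expect_equal(n_atoms(top), 4)
  expect_equal(top$ion_sets$Na, 4L)
  expect_equal(attr(top, "box"), c(60, 60, 60))
  expect_equal(top$atoms$resid[1], 71L)   # author numbering preserved

  # without CRYST1: no box
  writeLines(pdb[-1], path)
  expect_null(attr(read_topology(path), "box"))

  # triclinic boxes rejected
  writeLines(c(sub("90.00  90.00  90.00", "90.00  95.00  90.00", pdb[1]),
               pdb[-1]), path)
  expect_error(read_topology(path), "triclinic|orthorhombic")
})

test_that("CHARMM ion aliases map to canonical species", {
  top <- topology(data.frame(
    serial = 1:3, name = c("SOD", "POT", "CLA"),
    element = c("NA", "K", "CL"), resname = c("SOD", "POT", "CLA"),
    resid = 1:3, chain = "I"))
  expect_equal(top$ion_sets, list(Na = 1L, K = 2L, Cl = 3L))
})

test_that("multi-atom residues named like ions are not ions", {
  top <- topology(data.frame(
    serial = 1:2, name = c("CA", "CB"), element = c("C", "C"),
    resname = "NA", resid = 1L, chain = "A"))
  expect_length(top$ion_sets, 0)
})

test_that("multi-model PDB frames read in order with atom-count checks", {
  traj <- make_tiny_traj(rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
                         box = c(40, 40, 40))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_frames(traj, path, "pdb")
  top2 <- read_topology(path)
  traj2 <- read_frames(path, top2)
  expect_equal(n_frames(traj2), 3)
  expect_equal(traj2$box, c(40, 40, 40))
  expect_equal(traj2$coords, traj$coords, tolerance = 1e-3)

  # a topology with the wrong atom count is rejected
  bad_top <- topology(traj$topology$atoms[1:4, ])
  expect_error(read_frames(path, bad_top), "frame 0")
})

test_that("XYZ atom-count mismatch is reported with the frame index", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "frame 0",
               paste("C", 1:5, 0, 0), "5", "frame 1",
               paste("C", 1:5, 1, 1)), path)
  top4 <- topology(data.frame(serial = 1:4, name = "C", element = "C",
                              resname = "UNK", resid = 1:4, chain = "A"))
  expect_error(read_frames(path, top4, format = "xyz"), "frame 0")
})

test_that("topology and trajectory round-trips are lossless per format", {
  set.seed(11)
  traj <- random_trajectory(n_atoms = 50, n_frames = 4, n_ions = 3,
                            box = c(20, 20, 20))
  top <- traj$topology

  # pdb round-trip: identity on all topology fields, coords to 1e-3
  p <- withr::local_tempfile(fileext = ".pdb")
  write_frames(traj, p, "pdb")
  top2 <- read_topology(p)
  expect_equal(top2$atoms, top$atoms)
  expect_equal(top2$ion_sets, top$ion_sets)
  traj2 <- read_frames(p, top2)
  expect_equal(traj2$coords, traj$coords, tolerance = 1e-3)

  # tabular round-trips keep full precision
  t1 <- withr::local_tempfile(fileext = ".tsv")
  write_topology(top, t1, format = "table")
  expect_equal(read_topology(t1, format = "table")$atoms, top$atoms)
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_frames(traj, t2, "table")
  traj3 <- read_frames(t2, top, format = "table")
  expect_equal(traj3$coords, traj$coords, tolerance = 1e-9)

  # xyz round-trip (topology collapses to per-atom residues)
  x <- withr::local_tempfile(fileext = ".xyz")
  write_frames(traj, x, "xyz")
  topx <- read_topology(x, format = "xyz")
  trajx <- read_frames(x, topx, format = "xyz")
  expect_equal(trajx$coords, traj$coords, tolerance = 1e-6)
})

test_that("selections are deterministic, ordered, and heavy-only by default", {
  top <- topology(data.frame(
    serial = 1:6, name = c("CA", "HA", "OD1", "OD2", "NZ", "HZ1"),
    element = c("C", "H", "O", "O", "N", "H"),
    resname = c("GLY", "GLY", "ASP", "ASP", "LYS", "LYS"),
    resid = c(1L, 1L, 2L, 2L, 3L, 3L), chain = "A"))
  sel <- atom_selection(resid = c(2, 3))
  expect_equal(resolve_selection(sel, top), c(3L, 4L, 5L))
  expect_equal(resolve_selection(sel, top), resolve_selection(sel, top))
  sel_h <- atom_selection(resid = c(2, 3), heavy_only = FALSE)
  expect_equal(resolve_selection(sel_h, top), 3:6)
  expect_equal(resolve_selection(atom_selection(name = "OD1"), top), 3L)
})

test_that("hydrogens are recognized from element or name fallback", {
  top <- topology(data.frame(
    serial = 1:3, name = c("1HB", "CA", "HG1"),
    element = c("H", "C", "H"), resname = "XXX", resid = 1L, chain = "A"))
  expect_equal(top$atoms$is_hydrogen, c(TRUE, FALSE, TRUE))
})
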