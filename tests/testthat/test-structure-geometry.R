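test_that("PDB reader round-trips the toy structure and rejects junk", {
  toy <- make_toy_structure(toy_site_spec())
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy$structure, tmp)
  s2 <- read_pdb(tmp)
  expect_equal(nrow(s2), nrow(toy$structure))
  expect_lt(max(abs(as.matrix(s2[, c("x", "y", "z")]) -
                      as.matrix(toy$structure[, c("x", "y", "z")]))), 1e-3)
  expect_error(read_pdb("REMARK nothing here"), "no ATOM/HETATM")
})

test_that("minimal two-atom PDB text parses to two atoms", {
  s <- read_pdb(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C"))
  expect_equal(nrow(s), 2L)
  expect_equal(s$element, c("N", "C"))
  expect_equal(s$x, c(0, 1.458))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  s <- read_pdb(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.70  0.00           C"))
  expect_equal(nrow(s), 1L)
  expect_equal(s$x, 2.0)
})

test_that("metal site finder groups cluster irons and filters elements", {
  toy <- make_toy_structure(toy_site_spec())
  sites <- find_metal_sites(toy$structure)
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$cluster, c(1L, 1L))
  expect_error(find_metal_sites(toy$structure, elements = "ZN"),
               "no metal site")
  # two irons far apart belong to different clusters
  far <- toy$structure
  far$x[far$atom == "FE2"] <- 50
  expect_equal(find_metal_sites(far)$cluster, c(1L, 2L))
})

test_that("metal-proton distances: hand-computed Euclidean case", {
  pdb <- c(
    "HETATM    1 FE1  FES A 901       0.000   0.000   0.000  1.00  0.00          FE",
    "HETATM    2 FE2  FES A 901      10.000   0.000   0.000  1.00  0.00          FE",
    "ATOM      3  H1  PRB A 101       3.000   4.000   0.000  1.00  0.00           H")
  s <- read_pdb(pdb)
  d <- metal_proton_distances(s, compute_bonds = FALSE)
  expect_equal(d$r_angstrom, 5.0)
  expect_equal(d$fe_label, "FE1")
})

test_that("toy-site distance table echoes the requested placements", {
  spec <- toy_site_spec()
  toy <- make_toy_structure(spec)
  d <- metal_proton_distances(toy$structure, compute_bonds = FALSE)
  probe <- d[grepl("^H", d$atom), ]
  expect_equal(probe$r_angstrom, spec$proton_r, tolerance = 1e-9)
  expect_equal(probe$fe_label, toy$truth$fe_label)
})

test_that("distances are invariant under rigid transforms", {
  set.seed(42)
  toy <- make_toy_structure(toy_site_spec())
  d0 <- metal_proton_distances(toy$structure, compute_bonds = FALSE)
  for (k in 1:5) {
    s <- toy$structure
    xyz <- random_rigid_transform(as.matrix(s[, c("x", "y", "z")]))
    s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
    d1 <- metal_proton_distances(s, compute_bonds = FALSE)
    expect_equal(d1$r_angstrom, d0$r_angstrom, tolerance = 1e-6)
  }
})

test_that("coincident proton-metal geometry is flagged degenerate", {
  pdb <- c(
    "HETATM    1 FE1  FES A 901       0.000   0.000   0.000  1.00  0.00          FE",
    "ATOM      2  H1  PRB A 101       0.000   0.000   0.000  1.00  0.00           H")
  s <- read_pdb(pdb)
  expect_warning(metal_proton_distances(s, compute_bonds = FALSE),
                 "degenerate")
})

test_that("empty hydrogen selection warns and returns an empty table", {
  toy <- make_toy_structure(toy_site_spec())
  expect_warning(
    d <- metal_proton_distances(toy$structure, selection = "HZ9"),
    "no hydrogens")
  expect_equal(nrow(d), 0L)
})

test_that("bond counts follow the covalent path Fe-S-C-H", {
  pdb <- c(
    "HETATM    1 FE1  FES A 901       0.000   0.000   0.000  1.00  0.00          FE",
    "ATOM      2  SG  CYS A  10       2.300   0.000   0.000  1.00  0.00           S",
    "ATOM      3  CB  CYS A  10       3.400   1.300   0.000  1.00  0.00           C",
    "ATOM      4  HB2 CYS A  10       3.900   1.500   0.900  1.00  0.00           H")
  s <- read_pdb(pdb)
  d <- metal_proton_distances(s)
  expect_equal(d$bonds, 3L)
  # a proton of a non-coordinating residue has no defined bond count
  pdb2 <- c(pdb[1],
    "ATOM      2  CB  ALA A  20       8.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  HB1 ALA A  20       8.500   0.800   0.000  1.00  0.00           H")
  d2 <- metal_proton_distances(read_pdb(pdb2))
  expect_true(is.na(d2$bonds))
})

test_that("amide protons are built with ideal in-plane geometry and idempotently", {
  s <- read_pdb(tripeptide_pdb())
  sp <- build_amide_protons(s)
  h <- sp[sp$atom == "H" & sp$resnum == 2, ]
  expect_equal(nrow(h), 1L)
  N <- unlist(sp[sp$atom == "N" & sp$resnum == 2, c("x", "y", "z")])
  CA <- unlist(sp[sp$atom == "CA" & sp$resnum == 2, c("x", "y", "z")])
  Cp <- unlist(sp[sp$atom == "C" & sp$resnum == 1, c("x", "y", "z")])
  H <- unlist(h[, c("x", "y", "z")])
  expect_equal(sqrt(sum((H - N)^2)), 1.01, tolerance = 1e-3)
  ang <- function(a, b) acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  expect_equal(ang(H - N, CA - N), ang(H - N, Cp - N), tolerance = 1e-9)
  # in the C(i-1)-N-CA plane (here z = 0)
  expect_equal(unname(H[3]), 0, tolerance = 1e-9)
  # idempotence: an existing H is preserved
  sp2 <- build_amide_protons(sp)
  expect_equal(nrow(sp2), nrow(sp))
  expect_equal(sp2$x, sp$x)
})

test_that("count_protons_within is strict and monotone in radius", {
  d <- read_distance_table(fixture_path("distances"))
  expect_equal(count_protons_within(d, 4.0), 9L)
  # strictness: the His HNe2 proton at exactly 4.94 is not counted
  expect_equal(count_protons_within(d, 4.94), 14L)
  expect_equal(count_protons_within(d, 4.95), 15L)
  counts <- vapply(seq(1, 12, by = 0.25),
                   function(r) count_protons_within(d, r), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(count_protons_within(d, -1), "positive")
  empty <- d[0, ]
  expect_equal(count_protons_within(empty, 10), 0L)
})

test_that("blind-sphere radius applies the outlier cutoff and rounding", {
  d <- data.frame(chain = "A", resnum = 1:4, resname = "ALA", atom = "H",
                  fe_label = "FE1", r_angstrom = c(3.0, 5.5, 7.9, 14.0),
                  bonds = NA_integer_, ring = FALSE)
  class(d) <- c("distance_table", "data.frame")
  bs <- blind_sphere_radius(d, paste0("A:", 1:4))
  expect_equal(bs$radius, 8.0)
  expect_equal(bs$outliers, "A:4:H")
  # empty undetected set
  bs0 <- blind_sphere_radius(d, character())
  expect_equal(bs0$radius, 0)
  expect_true(bs0$no_paramagnetic_blind_sphere)
  # all undetected beyond cutoff
  bs2 <- blind_sphere_radius(d, "A:4")
  expect_true(bs2$no_paramagnetic_blind_sphere)
  expect_equal(bs2$radius, 0)
  expect_error(blind_sphere_radius(d, "B:9"), "not all present")
})

test_that("blind-sphere radius is monotone in the undetected set", {
  set.seed(7)
  d <- data.frame(chain = "A", resnum = 1:30, resname = "ALA", atom = "H",
                  fe_label = "FE1",
                  r_angstrom = runif(30, 2, 15),
                  bonds = NA_integer_, ring = FALSE)
  class(d) <- c("distance_table", "data.frame")
  ids <- paste0("A:", 1:30)
  for (k in 1:20) {
    u2 <- sample(ids, sample(5:20, 1))
    u1 <- sample(u2, sample(seq_along(u2), 1))
    expect_lte(blind_sphere_radius(d, u1)$radius,
               blind_sphere_radius(d, u2)$radius)
  }
})
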