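test_that("PDB atoms parse with exact coordinates", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(
    atom_name = c("N", "CA", "C"), resname = "GLY", chain = "A",
    resnum = 1L, x = c(1.5, 2.25, 3.125), y = c(-0.5, 0, 0.5),
    z = c(10, 11, 12), element = c("N", "C", "C"))
  write_mini_pdb(tmp, atoms)
  model <- read_pdb_atoms(tmp)
  expect_identical(nrow(model), 3L)
  expect_equal(model$x, atoms$x)
  expect_equal(model$z, atoms$z)
  expect_identical(model$element, c("N", "C", "C"))
})

test_that("alternate locations resolve to the highest occupancy", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "END"), tmp)
  model <- read_pdb_atoms(tmp)
  expect_identical(nrow(model), 1L)
  expect_equal(model$x, 2)
})

test_that("unreadable PDB input fails loudly", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", tmp)
  expect_error(read_pdb_atoms(tmp), "no ATOM")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   bad..   0.000  1.00  0.00           C"),
    tmp)
  expect_error(read_pdb_atoms(tmp), "line 1")
})

test_that("Kabsch superposition is exact under rigid motion", {
  set.seed(17)
  a <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_rmsd(a, a)$rmsd, 0, tolerance = 1e-10)
  for (seed in 1:5) {
    rot <- random_rotation(seed)
    b <- a %*% t(rot) + matrix(rep(c(3, -2, 7), each = 10), ncol = 3)
    k <- kabsch_rmsd(a, b)
    expect_lt(k$rmsd, 1e-8)
    expect_equal(det(k$rotation), 1, tolerance = 1e-8)
  }
})

test_that("Kabsch RMSD is symmetric and matches a numeric-minimization oracle", {
  set.seed(23)
  a <- matrix(rnorm(12, sd = 3), ncol = 3)
  b <- a %*% t(random_rotation(5)) + matrix(rnorm(12, sd = 0.3), ncol = 3)
  k <- kabsch_rmsd(a, b)
  expect_equal(k$rmsd, kabsch_rmsd(b, a)$rmsd, tolerance = 1e-9)
  expect_equal(k$rmsd, oracle_min_rmsd(a, b), tolerance = 1e-6)
})

test_that("degenerate coordinate sets are rejected", {
  a <- matrix(rnorm(30), ncol = 3)
  expect_error(kabsch_rmsd(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_rmsd(line, line), "collinear")
})

test_that("single-sphere SASA matches the analytic area", {
  m <- struct_model("C", 0, 0, 0)
  total <- sum(sasa(m, probe_radius = 1.4))
  expect_equal(total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
})

test_that("a tightly caged atom has zero accessible area", {
  # central C surrounded by a close shell of 26 carbons on a cubic grid
  g <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  m <- struct_model(rep("C", 27), g$x, g$y, g$z)
  central <- which(g$x == 0 & g$y == 0 & g$z == 0)
  expect_equal(sasa(m)[central], 0)
})

test_that("two-sphere SASA agrees with the closed-form cap oracle", {
  for (d in c(2.0, 3.5, 5.0)) {
    m <- struct_model(c("C", "N"), c(0, d), c(0, 0), c(0, 0))
    got <- sasa(m, probe_radius = 1.4, n_points = 2000L)
    want <- oracle_two_sphere_sasa(1.70, 1.55, 1.4, d)
    expect_equal(got[1], want[1], tolerance = 0.01)
    expect_equal(got[2], want[2], tolerance = 0.01)
  }
})

test_that("total SASA is invariant under rigid motion", {
  set.seed(13)
  m <- struct_model(sample(c("C", "N", "O"), 12, replace = TRUE),
                    rnorm(12, sd = 3), rnorm(12, sd = 3), rnorm(12, sd = 3))
  t1 <- sum(sasa(m))
  rot <- random_rotation(3)
  xyz <- coords_matrix(m) %*% t(rot)
  m2 <- struct_model(m$element, xyz[, 1] + 5, xyz[, 2] - 1, xyz[, 3] + 2)
  expect_equal(sum(sasa(m2)), t1, tolerance = 0.005)
})

test_that("unknown elements are reported by atom", {
  m <- struct_model(c("C", "QQ"), c(0, 3), c(0, 0), c(0, 0))
  expect_error(sasa(m), "QQ")
})

test_that("interface burial is zero for distant partners, symmetric for mirrored ones", {
  far <- struct_model(c("C", "C"), c(0, 100), c(0, 0), c(0, 0))
  b <- buried_interface_area(far, 1, 2)
  expect_equal(unname(b), c(0, 0))

  # mirror-symmetric pair of diatomic groups facing each other
  dim_model <- struct_model(rep("C", 4), c(-2.4, -2.4, 2.4, 2.4),
                            c(-1, 1, -1, 1), rep(0, 4),
                            chain = c("A", "A", "B", "B"))
  bb <- buried_interface_area(dim_model, "A", "B")
  expect_gt(bb["buried_a"], 0)
  # the two burials are mirror images; agreement is limited only by the
  # (non-mirror-symmetric) sphere quadrature
  expect_equal(unname(bb["buried_a"]), unname(bb["buried_b"]),
               tolerance = 0.02)
  expect_error(buried_interface_area(dim_model, 1:3, 3:4), "overlap")
})

test_that("burial becomes positive exactly when expanded spheres touch", {
  # contact distance for two C atoms with a 1.4 A probe: 1.7*2 + 2*1.4 = 6.2
  just_out <- struct_model(c("C", "C"), c(0, 6.3), c(0, 0), c(0, 0))
  expect_equal(unname(buried_interface_area(just_out, 1, 2)), c(0, 0))
  just_in <- struct_model(c("C", "C"), c(0, 6.1), c(0, 0), c(0, 0))
  expect_true(all(buried_interface_area(just_in, 1, 2) > 0))
})

test_that("metal geometry calls octahedral against tetrahedral sites", {
  oct <- struct_model(
    c("NI", rep("N", 3), rep("O", 3)),
    c(0, 2.1, -2.1, 0, 0, 0, 0), c(0, 0, 0, 2.1, -2.1, 0, 0),
    c(0, 0, 0, 0, 0, 2.1, -2.1))
  rep_oct <- metal_site(oct, "NI", distance_cutoff = 2.6)
  expect_length(rep_oct, 1)
  expect_identical(rep_oct[[1]]$geometry, "octahedral")
  expect_identical(nrow(rep_oct[[1]]$ligands), 6L)
  expect_equal(max(rep_oct[[1]]$angle_deviations), 0, tolerance = 1e-8)
  expect_identical(sort(rep_oct[[1]]$ligands$element), rep(c("N", "O"), each = 3))

  s <- 2.1 / sqrt(3)
  tet <- struct_model(
    c("NI", rep("N", 4)),
    c(0, s, s, -s, -s), c(0, s, -s, s, -s), c(0, s, -s, -s, s))
  rep_tet <- metal_site(tet, "NI", distance_cutoff = 2.6)
  expect_identical(rep_tet[[1]]$geometry, "other")

  expect_length(metal_site(oct, "ZN"), 0)
})
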