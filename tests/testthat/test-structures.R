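test_that("PDB round trip preserves elements and coordinates to 3 decimals", {
  s <- make_random_globule(10, 5, seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(n_atoms(s2), 10)
  expect_lte(max(abs(coords(s) - coords(s2))), 1e-3)
  expect_equal(s2$atoms$element, s$atoms$element)

  cnt <- build_cnt(6, 6, 1)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cnt, f2)
  expect_equal(n_atoms(read_pdb(f2)), n_atoms(cnt))
})

test_that("coordinates too large for the PDB fields are rejected", {
  s <- make_two_body(5)
  s$atoms$x[2] <- 12000
  expect_error(write_pdb(s, tempfile()), "10000")
})

test_that("read_pdb reads only the first model of a multi-model file", {
  s <- make_random_globule(6, 4, seed = 2)
  tr <- make_trajectory(s, 3, noise_sigma = 0.5, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  # write a 3-model PDB by hand from the trajectory frames
  con <- file(f, "w")
  for (k in 1:3) {
    writeLines(sprintf("MODEL     %4d", k), con)
    for (i in 1:6) {
      writeLines(sprintf("ATOM  %5d  C   MOL A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                         i, i, tr$coords[i, 1, k], tr$coords[i, 2, k], tr$coords[i, 3, k]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  s1 <- read_pdb(f)
  expect_equal(n_atoms(s1), 6)
  expect_lte(max(abs(coords(s1) - tr$coords[, , 1])), 1e-3)
  traj <- read_trajectory_pdb(f)
  expect_equal(n_frames(traj), 3)
  expect_lte(max(abs(traj$coords - tr$coords)), 1e-3)
})

test_that("read_pdb rejects files without atom records", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), f)
  expect_error(read_pdb(f))
  expect_error(read_pdb(tempfile()), "not found")
})

test_that("hydrogen stripping removes H and D, preserves order, is idempotent", {
  atoms <- data.frame(
    element = c("C", "H", "H", "O", "D", "N"),
    atom_name = c("CA", "HA1", "HA2", "O", "D1", "N"),
    chain_id = "A", residue_id = 1,
    x = 1:6, y = 0, z = 0, stringsAsFactors = FALSE
  )
  s <- mol_structure(atoms)
  s1 <- strip_hydrogens(s)
  expect_equal(s1$atoms$element, c("C", "O", "N"))
  expect_equal(s1$atoms$x, c(1, 4, 6))
  expect_identical(strip_hydrogens(s1)$atoms, s1$atoms)
  # water
  w <- mol_structure(data.frame(element = c("O", "H", "H"), atom_name = c("O", "H1", "H2"),
                                chain_id = "A", residue_id = 1, x = 0:2, y = 0, z = 0))
  expect_equal(strip_hydrogens(w)$atoms$element, "O")
})

test_that("mass assignment uses standard atomic weights and flags unknowns", {
  s <- mol_structure(data.frame(element = c("C", "N", "O", "FE"),
                                atom_name = c("C", "N", "O", "FE"),
                                chain_id = "A", residue_id = 1,
                                x = c(0, 3, 6, 9), y = 0, z = 0))
  s <- assign_masses(s)
  expect_equal(s$atoms$mass, c(12.011, 14.007, 15.999, 55.845))
  bad <- mol_structure(data.frame(element = "XX", atom_name = "XX", chain_id = "A",
                                  residue_id = 1, x = 0, y = 0, z = 0))
  expect_error(assign_masses(bad), "XX")
  cnt <- build_cnt(6, 5, 1)
  expect_equal(sum(cnt$atoms$mass), n_atoms(cnt) * 12.011)
})

test_that("element inference falls back to atom-name conventions", {
  expect_equal(infer_element(c("CA", "N", "OXT", "FE", "CL1", "1HG2")),
               c("C", "N", "O", "FE", "CL", "H"))
})

test_that("graphene sheets are planar honeycombs with exact 1.42 A bonds", {
  g <- build_graphene(2, 2, "armchair")
  expect_true(all(g$atoms$element == "C"))
  expect_true(all(g$atoms$z == 0))
  nn <- neighbor_pairs(coords(g), 1.6)
  expect_gt(nrow(nn), 0)
  expect_lte(max(abs(nn$r - 1.42)), 1e-6)
  gz <- build_graphene(2, 2, "zigzag")
  nnz <- neighbor_pairs(coords(gz), 1.6)
  expect_lte(max(abs(nnz$r - 1.42)), 1e-6)
})

test_that("graphene atom count matches the areal density of the honeycomb lattice", {
  g <- build_graphene(6, 6, "armchair")
  expected <- 2 * 3600 / (3 * sqrt(3) / 2 * 1.42^2)
  expect_lt(abs(n_atoms(g) - expected) / expected, 0.05)
})

test_that("degenerate graphene rectangles are rejected", {
  expect_error(build_graphene(0.1, 0.1), "hexagon")
  expect_error(build_graphene(-1, 2))
})

test_that("CNT diameters follow the roll-up formula", {
  for (nm in list(c(6, 6), c(6, 5), c(7, 6), c(10, 0), c(8, 3))) {
    # reference formula with the conventional a = 2.46 A; the builder
    # derives its lattice constant from the 1.42 A bond (2.4595 A),
    # which agrees within the 0.01 A contract
    d_formula <- 2.46 / pi * sqrt(nm[1]^2 + nm[1] * nm[2] + nm[2]^2)
    expect_lt(abs(cnt_diameter(nm[1], nm[2]) - d_formula), 0.01)
    tube <- build_cnt(nm[1], nm[2], 1)
    xy <- coords(tube)[, 1:2]
    radii <- sqrt(rowSums(xy^2))
    # every atom sits on the cylinder; measured diameter matches the formula
    expect_lt(max(abs(2 * radii - d_formula)), 0.01)
  }
  expect_equal(cnt_diameter(6, 6), 8.14, tolerance = 0.01 / 8.14)
  expect_equal(cnt_diameter(6, 5), 7.47, tolerance = 0.01 / 7.47)
  expect_gt(cnt_diameter(7, 6), cnt_diameter(6, 6))
  expect_gt(cnt_diameter(7, 6), cnt_diameter(6, 5))
})

test_that("CNT bonds survive rolling to within chord tolerance", {
  for (nm in list(c(6, 6), c(6, 5))) {
    tube <- build_cnt(nm[1], nm[2], 1.2)
    nn <- neighbor_pairs(coords(tube), 1.6)
    expect_gt(nrow(nn), 0)
    # arc-length mapping: chord lengths shrink slightly, never grow
    expect_lte(max(nn$r), 1.42 + 1e-9)
    expect_lte(max(abs(nn$r - 1.42)), 0.05)
    # each interior atom has 3 neighbors
    deg <- tabulate(c(nn$i, nn$j), n_atoms(tube))
    expect_true(all(deg <= 3))
    expect_gt(mean(deg == 3), 0.5)
  }
  expect_error(build_cnt(3, 5, 1), "chiral")
  expect_error(build_cnt(6, 6, -1))
})
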