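modes_of <- function(s, n_modes = NULL, ...) {
  solve_modes(mass_weight(assemble_hessian(build_network(s, ...))), n_modes = n_modes)
}

test_that("diatomic frequency matches the closed form", {
  m <- modes_of(make_two_body(5, 12, 16), n_modes = 6)
  expect_equal(sum(m$rigid), 5)  # collinear fixture
  omega <- nonrigid_frequencies(m, 1)
  expect_equal(omega, sqrt(100 * (1 / 12 + 1 / 16)), tolerance = 1e-10)
})

test_that("the cm^-1 conversion agrees with an SI hand computation", {
  # diatomic: k in kcal/(mol A^2) and masses in amu, converted to SI
  k_SI <- 100 * (4184 / 6.02214076e23) / 1e-20          # J/m^2 per molecule
  mu_SI <- (12 * 16 / 28) * 1.66053906660e-27           # kg
  nu_cm1 <- sqrt(k_SI / mu_SI) / (2 * pi * 2.99792458e10)
  m <- modes_of(make_two_body(5, 12, 16), n_modes = 6)
  omega_internal <- nonrigid_frequencies(m, 1)
  expect_equal(omega_internal * freq_unit_to_cm1(), nu_cm1, tolerance = 1e-10)
})

test_that("isolated networks have exactly six rigid modes (five if collinear)", {
  g <- modes_of(make_random_globule(40, 8, seed = 3), n_modes = 15)
  expect_equal(sum(g$rigid), 6)
  expect_lt(max(abs(g$eigenvalues[1:6])), 1e-8 * g$lambda_max)
  expect_gt(g$eigenvalues[7], 1e-8 * g$lambda_max)
  # the canonical collinear fixture: a diatomic has exactly 5 zero modes
  dia <- modes_of(make_two_body(4), n_modes = 6)
  expect_equal(sum(dia$rigid), 5)
  # longer collinear chains additionally have transverse zero modes
  # (pairwise distances are insensitive to transverse displacement):
  # 2N floppy + 1 axial translation
  chain <- suppressWarnings(modes_of(make_linear_chain(6, 3), n_modes = 18))
  expect_equal(sum(chain$eigenvalues < 1e-8 * chain$lambda_max), 2 * 6 + 1)
  # a perfectly planar sheet is likewise degenerate (out-of-plane motion
  # is free in a pairwise-distance network), so 3-D fixtures are the
  # ones that carry the exactly-six-rigid-modes property
  g2 <- modes_of(make_random_globule(12, 4, seed = 44), n_modes = 15)
  expect_equal(sum(g2$rigid), 6)
})

test_that("eigenvalues are sorted and mode vectors orthonormal", {
  m <- modes_of(make_random_globule(30, 7, seed = 5), n_modes = 20)
  expect_true(all(diff(m$eigenvalues) >= -1e-12))
  G <- crossprod(m$vectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # sign convention: largest-magnitude component positive
  for (k in seq_len(ncol(m$vectors))) {
    expect_gt(m$vectors[which.max(abs(m$vectors[, k])), k], 0)
  }
})

test_that("frequencies scale as sqrt(k0) and 1/sqrt(mass)", {
  g <- make_random_globule(100, 12, seed = 10)
  m1 <- modes_of(g, n_modes = 12)
  m4 <- modes_of(g, n_modes = 12, k0 = 400)
  f1 <- nonrigid_frequencies(m1); f4 <- nonrigid_frequencies(m4)
  expect_equal(f4, 2 * f1, tolerance = 1e-8)
  h <- assemble_hessian(build_network(g))
  mheavy <- solve_modes(mass_weight(h, masses = rep(9 * 12.011, 100)), n_modes = 12)
  expect_equal(nonrigid_frequencies(mheavy), f1 / 3, tolerance = 1e-8)
})

test_that("rigid rotation of the structure leaves frequencies unchanged", {
  g <- make_random_globule(50, 9, seed = 12)
  R <- random_rotation(31)
  gr <- g
  gr$atoms[, c("x", "y", "z")] <- coords(g) %*% t(R)
  f0 <- nonrigid_frequencies(modes_of(g, n_modes = 12))
  f1 <- nonrigid_frequencies(modes_of(gr, n_modes = 12))
  expect_equal(f1, f0, tolerance = 1e-8)
})

test_that("sparse and dense solver paths agree", {
  g <- make_random_globule(80, 11, seed = 15)
  h <- mass_weight(assemble_hessian(build_network(g)))
  md <- solve_modes(h, n_modes = 12, method = "dense")
  ms <- solve_modes(h, n_modes = 12, method = "sparse")
  expect_equal(ms$eigenvalues[7:12], md$eigenvalues[7:12], tolerance = 1e-6)
  ov <- mode_overlap(md, ms, k_modes = 4)
  expect_true(all(diag(ov) > 0.999))
})

test_that("anchored systems have no rigid modes and a lifted spectrum", {
  g <- make_random_globule(25, 5, seed = 18)
  net <- build_network(g)
  m <- solve_modes(mass_weight(assemble_hessian(net, fixed = 21:25)), n_modes = 10)
  expect_equal(sum(m$rigid), 0)
  expect_gt(m$eigenvalues[1], 1e-6)
})

test_that("mode overlap is the identity for a set against itself and bounded in [0,1]", {
  m <- modes_of(make_random_globule(30, 7, seed = 20), n_modes = 12)
  O <- mode_overlap(m, m, k_modes = 5)
  expect_equal(O, diag(5), tolerance = 1e-10)
  m2 <- modes_of(make_random_globule(30, 7, seed = 21), n_modes = 12)
  O2 <- mode_overlap(m, m2, k_modes = 5)
  expect_true(all(O2 >= 0 & O2 <= 1 + 1e-12))
  expect_error(mode_overlap(m, m2, k_modes = 5, atoms_a = integer(0), atoms_b = integer(0)),
               "empty")
  expect_error(mode_overlap(m, m2, k_modes = 40), "exceeds")
})

test_that("modes of a rotated structure overlap the originals after back-rotation", {
  g <- make_random_globule(60, 10, seed = 22)
  R <- random_rotation(77)
  gr <- g
  gr$atoms[, c("x", "y", "z")] <- coords(g) %*% t(R)
  ma <- modes_of(g, n_modes = 14)
  mb <- rotate_mode_vectors(modes_of(gr, n_modes = 14), t(R))
  lam <- ma$eigenvalues[!ma$rigid][1:6]
  gaps <- pmin(abs(c(Inf, diff(lam))), abs(c(diff(lam), Inf))) / lam
  O <- mode_overlap(ma, mb, k_modes = 6)
  nondeg <- gaps > 1e-3
  expect_gt(sum(nondeg), 0)
  expect_true(all(diag(O)[nondeg] > 0.99))
})

test_that("adding springs never lowers frequencies (immobilization stiffening)", {
  base <- make_random_globule(30, 9, seed = 33)
  net1 <- build_network(base, cutoff = 8, switch_start = 6)
  net2 <- build_network(base, cutoff = 12, switch_start = 6)  # superset of springs
  expect_gt(nrow(net2$pairs), nrow(net1$pairs))
  m1 <- solve_modes(mass_weight(assemble_hessian(net1)), n_modes = 3 * 30)
  m2 <- solve_modes(mass_weight(assemble_hessian(net2)), n_modes = 3 * 30)
  expect_true(all(m2$eigenvalues - m1$eigenvalues >= -1e-9 * m1$lambda_max))
  cmp <- compare_frequencies(m1, m2, k_modes = 3)
  expect_true(all(cmp$ratio >= 1 - 1e-9))
})

test_that("frequency comparison handles identity and over-asking", {
  m <- modes_of(make_random_globule(20, 6, seed = 40), n_modes = 12)
  cmp <- compare_frequencies(m, m, k_modes = 3)
  expect_equal(cmp$ratio, rep(1, 3))
  dia <- modes_of(make_two_body(5), n_modes = 6)
  expect_error(compare_frequencies(dia, dia, k_modes = 3), "non-rigid")
})

test_that("NMD export writes one line per requested mode", {
  m <- modes_of(make_random_globule(10, 4, seed = 2), n_modes = 10)
  f <- withr::local_tempfile(fileext = ".nmd")
  write_nmd(m, f, n_modes = 3)
  lines <- readLines(f)
  expect_equal(sum(grepl("^mode ", lines)), 3)
  expect_equal(sum(grepl("^coordinates ", lines)), 1)
  comp <- as.numeric(strsplit(lines[grepl("^mode 1 ", lines)], " ")[[1]][-(1:3)])
  expect_equal(length(comp), 30)
})
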