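test_that("Kabsch superposition recovers rigid transforms exactly", {
  g <- make_random_globule(40, 8, seed = 2)
  X <- coords(g)
  expect_equal(kabsch_superpose(X, X)$rmsd, 0)
  R <- random_rotation(5)
  Y <- X %*% t(R) + matrix(c(3, -2, 7), nrow(X), 3, byrow = TRUE)
  fit <- kabsch_superpose(X, Y)
  expect_lt(fit$rmsd, 1e-10)
  expect_lt(max(abs(fit$fitted - X)), 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  expect_error(kabsch_superpose(X, Y[1:10, ]), "differ in size")
})

test_that("Kabsch RMSD equals the exhaustive rotation-grid minimum on a perturbed toy", {
  X <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  Y <- X
  Y[4, ] <- Y[4, ] + c(0.4, -0.2, 0.3)  # displace one atom
  Y <- Y %*% t(random_rotation(9))
  ours <- kabsch_superpose(X, Y)$rmsd
  grid <- grid_min_rmsd(X, Y, step_deg = 4)
  expect_lte(ours, grid + 1e-12)          # Kabsch is the true optimum
  expect_lt(grid - ours, 0.02)            # grid search approaches it
})

test_that("Kabsch agrees with an established superposition implementation", {
  g <- make_random_globule(25, 6, seed = 8)
  X <- coords(g)
  set.seed(1)
  Y <- X + matrix(rnorm(75, sd = 0.3), 25, 3)
  ours <- kabsch_superpose(X, Y)$rmsd
  fitted <- suppressWarnings(bio3d::fit.xyz(as.numeric(t(X)), as.numeric(t(Y))))
  ref <- sqrt(mean(colSums(matrix((fitted - as.numeric(t(X)))^2, nrow = 3))))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("radius of gyration matches closed forms and scales with dilation", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3), 5), 0)
  d <- 7
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(d, 0, 0)), c(1, 1)), d / 2 / 10)
  s <- 4
  sq <- rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0))
  expect_equal(radius_of_gyration(sq, rep(1, 4)), s / sqrt(2) / 10)
  g <- make_random_globule(30, 8, seed = 3)
  rg1 <- radius_of_gyration(g)
  rot <- coords(g) %*% t(random_rotation(4)) + 11
  expect_equal(radius_of_gyration(rot, g$atoms$mass), rg1, tolerance = 1e-12)
  expect_equal(radius_of_gyration(coords(g) * 2.5, g$atoms$mass), 2.5 * rg1)
  expect_error(radius_of_gyration(sq, rep(0, 4)), "total mass")
})

test_that("grid contact counts equal brute force on many random fixtures", {
  for (seed in 1:25) {
    set.seed(seed)
    xyz <- matrix(runif(40 * 3, 0, 18), 40, 3)
    a <- 1:20; b <- 21:40
    cutoff <- runif(1, 2, 8)
    bf <- brute_force_pairs(xyz, cutoff)
    bf_cross <- sum((bf$i %in% a & bf$j %in% b) | (bf$i %in% b & bf$j %in% a))
    expect_equal(count_contacts(a, b, xyz, cutoff), bf_cross)
    expect_equal(count_contacts(b, a, xyz, cutoff), bf_cross)  # symmetry
  }
  xyz <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(count_contacts(1, 2, xyz, 6), 0)
  expect_error(count_contacts(1:3, 3:4, xyz), "overlap")
})

test_that("unique-atom contact mode counts atoms, not pairs", {
  # one a-atom close to three b-atoms: 3 pairs but 4 contact atoms
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(50, 0, 0))
  expect_equal(count_contacts(c(1, 5), 2:4, xyz, 2), 3)
  expect_equal(count_contacts(c(1, 5), 2:4, xyz, 2, mode = "atoms"), 4)
})

test_that("minimum distances equal brute force and geometric closed forms", {
  for (seed in 1:25) {
    set.seed(seed)
    xyz <- rbind(matrix(rnorm(30, sd = 5), 10, 3),
                 matrix(rnorm(30, mean = 12, sd = 5), 10, 3))
    d2 <- outer(rowSums(xyz[1:10, ]^2), rowSums(xyz[11:20, ]^2), "+") -
      2 * xyz[1:10, ] %*% t(xyz[11:20, ])
    expect_equal(min_distance(1:10, 11:20, xyz), sqrt(min(d2)) / 10, tolerance = 1e-12)
  }
  # two parallel planes separated by d
  g <- build_graphene(1, 1)
  top <- coords(g); top[, 3] <- 3.4
  xyz <- rbind(coords(g), top)
  n <- n_atoms(g)
  expect_equal(min_distance(1:n, n + 1:n, xyz), 0.34)
  # shared position -> zero
  xyz2 <- rbind(c(1, 1, 1), c(1, 1, 1), c(9, 9, 9))
  expect_equal(min_distance(1, 2:3, xyz2), 0)
  expect_error(min_distance(integer(0), 1:2, xyz2), "empty")
})

test_that("rmsd series recovers the generator displacement contract", {
  base <- make_random_globule(1500, 20, seed = 30)
  tr <- make_trajectory(base, 10, noise_sigma = 0.25, seed = 31)
  r <- rmsd_series(tr)
  expect_equal(length(r), 10)
  expect_equal(r[1], 0)
  expect_lt(abs(mean(r[-1]) * 10 - 0.25 * sqrt(3)) / (0.25 * sqrt(3)), 0.03)
  expect_error(rmsd_series(tr, mask = integer(0)), "empty")
})

test_that("tail-window averaging covers exactly the trailing window", {
  expect_equal(window_average(rep(4.2, 10), 0:9, 5), 4.2)
  expect_equal(window_average(0:9, 0:9, 2), 8.5)
  expect_equal(window_average(0:9, 0:9, 9), mean(1:9))
  expect_error(window_average(0:9, 0:9, 10), "exceeds")
  expect_error(window_average(1:3, c(0, 0, 1), 1), "increasing")
})

test_that("interface statistics return a tidy per-frame table", {
  sheet <- build_graphene(1, 1)
  enz <- make_random_globule(20, 4, seed = 12)
  xyz <- coords(enz); coords(enz) <- sweep(xyz, 2, c(5, 5, 6 - min(xyz[, 3])), "+")
  comb <- combine_structures(enz, sheet)
  tr <- make_trajectory(comb, 4, noise_sigma = 0.1, seed = 13)
  st <- interface_statistics(tr, 1:20, 20 + seq_len(n_atoms(sheet)))
  expect_equal(nrow(st), 4 * 4)
  expect_setequal(unique(st$metric), c("rmsd_nm", "rg_nm", "contacts", "min_dist_nm"))
  expect_true(all(st$value[st$metric == "min_dist_nm"] > 0))
})
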