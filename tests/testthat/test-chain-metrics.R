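test_that("radius of gyration and end-to-end distance on simple point sets", {
  two <- point_traj(rbind(c(0, 0, 0), c(6, 0, 0)))
  expect_equal(radius_of_gyration(two), 3)
  one <- point_traj(rbind(c(1, 2, 3)))
  expect_equal(radius_of_gyration(one), 0)
  expect_error(radius_of_gyration(two, integer(0)), "empty")

  # 10 equidistant beads, l = 8.85, all beads averaged: sqrt(l^2 * 99 / 12)
  beads <- cbind(0, 0, (0:9) * 8.85)
  expect_equal(rg_points(beads), sqrt(8.85^2 * 99 / 12), tolerance = 1e-12)
  expect_equal(round(rg_points(beads), 2), 25.42)

  ca <- point_traj(rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 10)))
  ca$topology$name <- "CA"
  expect_equal(end_to_end_distance(ca, "A"), 10)
  loop <- point_traj(rbind(c(0, 0, 0), c(3, 3, 0), c(0, 0, 0)))
  loop$topology$name <- "CA"
  expect_equal(end_to_end_distance(loop, "A"), 0)
  expect_error(end_to_end_distance(ca, "A", "CB"), "CB")
})

test_that("pyramidal numbers match brute-force sums of squares", {
  expect_equal(pyramidal_number(0), 0)
  for (k in 1:20) expect_equal(pyramidal_number(k), sum((1:k)^2))
  expect_error(pyramidal_number(-1), "non-negative")
})

test_that("bead-model ratio and Rg closed forms reproduce the printed values", {
  expect_equal(round(bead_ratio_squared(bead_model(9)), 3), 0.117)
  expect_equal(round(sqrt(bead_ratio_squared(bead_model(9))), 3), 0.342)
  expect_equal(round(bead_ratio_squared(bead_model(10)), 3), 0.102)
  expect_equal(round(sqrt(bead_ratio_squared(bead_model(10))), 3), 0.319)
  expect_equal(round(sqrt(bead_ratio_squared(bead_model(2 * 1000000 + 1))), 4),
               0.2887)
  expect_equal(round(bead_ratio_limit(), 4), 0.2887)

  expect_equal(round(bead_rg(bead_model(9, 8.85)), 2), 24.24)
  expect_equal(round(bead_rg(bead_model(10, 8.85)), 2), 25.42)
  # n = 2 consistency with the two-point radius of gyration
  expect_equal(bead_rg(bead_model(2, 1)), 0.5)
  expect_error(bead_model(1), "n >= 2")
  expect_error(bead_model(5, 0), "positive")
})

test_that("bead-model branches are algebraically consistent and ordered", {
  for (n in 2:200) {
    m <- bead_model(n, 2.9)
    expect_equal(bead_rg(m) / bead_ree(m), sqrt(bead_ratio_squared(m)),
                 tolerance = 1e-12)
  }
  # odd curve above even at equal k; both tend to 1/sqrt(12)
  for (k in 2:60) {
    odd <- sqrt(bead_ratio_squared(bead_model(2 * k + 1)))
    even <- sqrt(bead_ratio_squared(bead_model(2 * k)))
    expect_gt(odd, even)
    expect_gt(odd, 1 / sqrt(12))
  }
  expect_equal(sqrt(bead_ratio_squared(bead_model(2 * 10^6))), 1 / sqrt(12),
               tolerance = 1e-6)
})

test_that("spacing estimation recovers l from end-to-end distances", {
  expect_equal(estimate_spacing(c(`9` = 72.56, `10` = 81.41)), 8.85,
               tolerance = 1e-12)
  l0 <- 3.12; c0 <- 4.4
  expect_equal(estimate_spacing(c(`4` = 4 * l0 + c0, `10` = 10 * l0 + c0)), l0)
  expect_warning(z <- estimate_spacing(c(`3` = 7, `5` = 7, `8` = 7)), "equal")
  expect_equal(z, 0)
  expect_error(estimate_spacing(c(`9` = 72.56)), "two")
})

test_that("globular scaling law evaluates as printed", {
  expect_equal(round(globular_rg(90), 1), 13.1)
  expect_equal(globular_rg(1), 0.395 + 7.257)
  expect_error(globular_rg(0), ">= 1")
})

test_that("Kabsch superposition recovers rigid transforms and noise level", {
  set.seed(31)
  ref <- matrix(rnorm(60, sd = 5), 20, 3)
  expect_equal(superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)

  # arbitrary rotation + translation: RMSD ~ 0, invariant under common
  # rigid transforms of both inputs
  ang <- c(0.4, -1.1, 2.2)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  R <- Rx %*% Rz
  mob <- ref %*% R + matrix(c(3, -7, 11), 20, 3, byrow = TRUE)
  expect_lt(superpose(mob, ref)$rmsd, 1e-10)

  noisy <- ref + matrix(rnorm(60, sd = 0.3), 20, 3)
  r1 <- superpose(noisy, ref)$rmsd
  common <- function(x) x %*% Rz + matrix(c(5, 5, -2), nrow(x), 3, byrow = TRUE)
  expect_equal(superpose(common(noisy), common(ref))$rmsd, r1, tolerance = 1e-10)

  # the Kabsch residual is the global optimum: no sampled rotation beats it
  set.seed(32)
  for (i in 1:50) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2)); th <- runif(1, 0, pi)
    K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
    Rr <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    cand <- sweep(noisy, 2, colMeans(noisy)) %*% Rr
    resid <- sqrt(mean(rowSums((cand - sweep(ref, 2, colMeans(ref)))^2)))
    expect_gte(resid, r1 - 1e-9)
  }
  expect_error(superpose(ref[1:5, ], ref), "counts differ")
})

test_that("RMSF isolates per-atom fluctuation after alignment", {
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(4, 4, 4))
  up <- base; up[5, 3] <- up[5, 3] + 1
  dn <- base; dn[5, 3] <- dn[5, 3] - 1
  top <- make_topology(rep("CA", 5), rep("C", 5), rep("GLY", 5), 1:5,
                       rep("A", 5))
  tr <- trajectory(top, rep(list(up, dn), 10))
  out <- rmsf(tr, fit_subset = 1:4)
  expect_equal(out[1:4], rep(0, 4), tolerance = 1e-10)
  expect_equal(out[5], 1, tolerance = 1e-10)
  expect_error(rmsf(trajectory(top, list(base))), "two frames")

  # isotropic noise of sd sigma per axis gives RMSF ~ sigma * sqrt(3); use
  # enough atoms that the 6 rigid-body DOF absorbed by the fit are negligible
  set.seed(33)
  nat <- 40; sigma <- 0.1
  big <- matrix(rnorm(3 * nat, sd = 6), nat, 3)
  topn <- make_topology(rep("CA", nat), rep("C", nat), rep("GLY", nat),
                        seq_len(nat), rep("A", nat))
  frames <- lapply(1:2000, function(i) big + matrix(rnorm(3 * nat, sd = sigma), nat, 3))
  trn <- trajectory(topn, frames)
  expect_equal(mean(rmsf(trn)), sigma * sqrt(3), tolerance = 0.05)
})

test_that("static trajectories have zero RMSD and RMSF", {
  sc <- generate_scaffold(scaffold_config(3, chains = 1))
  tr <- trajectory(sc$topology, rep(sc$frames, 3))
  expect_equal(rmsd_series(tr), rep(0, 3), tolerance = 1e-12)
  expect_equal(max(rmsf(tr)), 0, tolerance = 1e-12)
})
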