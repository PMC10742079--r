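test_that("ideal-gas water has g(r) = 1 and the analytic running integral", {
  # four independent uniform frames pooled for statistics
  frames <- lapply(1:4, function(s) generate_bulk_water(30, 0.0334,
                                                        seed = s)$frames[[1]])
  b1 <- generate_bulk_water(30, 0.0334, seed = 1)
  tr <- trajectory(b1$topology, frames, box = diag(3) * 30)
  wo <- water_oxygens(tr)
  p <- rdf(tr, wo, wo, r_max = 8, bin_width = 0.5)
  expect_true(all(abs(p$g[p$r > 2] - 1) < 0.05))
  # n(r) at a cutoff equals (4/3) pi r^3 rho within sampling error
  expect_equal(coordination_number(p, 3.25), 4 / 3 * pi * 3.25^3 * 0.0334,
               tolerance = 0.05)
  expect_equal(second_shell_integral(p, 3.225, 5.61),
               4 / 3 * pi * 0.0334 * (5.61^3 - 3.225^3), tolerance = 0.05)
  expect_error(rdf(tr, wo, wo, r_max = 16), "half")
  expect_error(coordination_number(p, 9), "range")
  expect_error(second_shell_integral(p, 5, 4), "below")
})

test_that("rdf matches a brute-force double-loop histogram bin by bin", {
  set.seed(17)
  box <- diag(3) * 12
  xyz <- matrix(runif(3 * 40, 0, 12), 40, 3)
  tr <- point_traj(xyz, water = rep(TRUE, 40), box = box)
  wo <- water_oxygens(tr)
  centers <- wo[1:10]; others <- wo
  p <- rdf(tr, centers, others, r_max = 5, bin_width = 0.25)
  edges <- p$bin_edges
  self <- outer(centers, others, "==")
  ref_counts <- brute_pair_hist(xyz[centers, ], xyz[others, ], box, edges, self)
  rho <- length(others) / 12^3
  shell <- 4 / 3 * pi * diff(edges^3)
  expect_equal(p$g, ref_counts / (length(centers) * shell * rho),
               tolerance = 1e-10)
  expect_equal(p$n_cumulative, cumsum(ref_counts) / length(centers),
               tolerance = 1e-10)
})

test_that("a single neighbour produces a unit step in n(r)", {
  xyz <- rbind(c(25, 25, 25), c(25, 25, 27.6))
  tr <- point_traj(xyz, water = c(FALSE, TRUE), box = diag(3) * 50)
  p <- rdf(tr, 1, 2, r_max = 5, bin_width = 0.1)
  expect_equal(coordination_number(p, 3.25), 1)
  expect_equal(coordination_number(p, 2.0), 0)
  expect_equal(utils::tail(p$n_cumulative, 1), 1)
})

test_that("extrema detection finds constructed peaks and handles monotone g", {
  r <- seq(0.025, 8, by = 0.05)
  g <- 2.2 * exp(-((r - 2.65) / 0.3)^2) + 1.15 * exp(-((r - 4.5) / 0.6)^2) +
    (1 - exp(-((r) / 3)^2)) * 0.2
  prof <- structure(list(bin_edges = seq(0, 8, 0.05), r = r, g = g,
                         n_cumulative = cumsum(g), reference_count = 1,
                         density_used = 1), class = "hs_rdf")
  ex <- find_extrema(prof, smoothing_window = 3)
  expect_equal(ex$first_max, 2.65, tolerance = 0.11)
  expect_gt(ex$first_min, 3.0); expect_lt(ex$first_min, 4.0)
  expect_equal(ex$second_max, 4.5, tolerance = 0.16)
  expect_true(ex$first_max < ex$first_min & ex$first_min < ex$second_max)

  mono <- prof; mono$g <- r / 8
  exm <- find_extrema(mono)
  expect_true(is.na(exm$first_max) && is.na(exm$second_min))

  # agreement with an exhaustive scan on the smoothed noisy curve
  set.seed(7)
  noisy <- prof; noisy$g <- g + rnorm(length(g), sd = 0.02)
  w <- 5
  gs <- as.numeric(stats::filter(noisy$g, rep(1 / w, w), sides = 2))
  exn <- find_extrema(noisy, smoothing_window = w)
  ok <- which(!is.na(gs))
  scan_max <- ok[-c(1, length(ok))][which(
    gs[ok[-c(1, length(ok))]] >= gs[ok[-c(1, length(ok))] - 1] &
    gs[ok[-c(1, length(ok))]] > gs[ok[-c(1, length(ok))] + 1])]
  expect_equal(exn$first_max, r[scan_max[1]])
})

test_that("site occupancy counts hand-placed waters and is cutoff-monotone", {
  sc <- generate_scaffold(scaffold_config(1, chains = 1))
  s <- select_carbonyl_sites(sc)
  g_atom <- s$atom[s$role == "G"]
  site <- sc$frames[[1]][g_atom, ]
  out <- sqrt(sum(site[1:2]^2)); u <- c(site[1:2] / out, 0)
  w1 <- site + 3.0 * u; w2 <- site + 3.4 * u
  top <- make_topology(c(sc$topology$name, "O", "O"),
                       c(sc$topology$element, "O", "O"),
                       c(sc$topology$residue_name, "HOH", "HOH"),
                       c(sc$topology$residue_seq, 1, 2),
                       c(sc$topology$chain_id, "W", "W"))
  tr <- trajectory(top, list(rbind(sc$frames[[1]], w1, w2)))
  expect_equal(site_occupancy(tr, s, 3.225)$per_site$mean_count[s$role == "G"], 1)
  expect_equal(site_occupancy(tr, s, 3.5)$per_site$mean_count[s$role == "G"], 2)
  # monotone non-decreasing in cutoff
  cuts <- c(2, 2.8, 3.1, 3.3, 3.6, 4.5)
  counts <- vapply(cuts, function(ct)
    sum(site_occupancy(tr, s, ct)$per_site$mean_count), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(site_occupancy(sc, s, 3.225), "water")
})

test_that("structured hydration recovers its pattern; vacancies dilute it predictably", {
  sc <- generate_scaffold(scaffold_config(4, chains = 3))
  hy <- generate_hydration_trajectory(sc, exchange_config(
    n_frames = 100, vacancy_prob = 0, seed = 12))
  occ <- site_occupancy(hy$trajectory, hy$sites, 3.225)
  expect_equal(unname(occ$per_role[c("X", "Y", "G")]), c(0, 2, 1))
  # route (b) cutoff counting == route (c) RDF running-integral at the same
  # cutoff on identical input: relabel some bulk waters as carbonyl sites
  b <- generate_bulk_water(20, 0.0334, seed = 15)
  topb <- b$topology
  topb$is_water[1:25] <- FALSE
  topb$residue_name[1:25] <- "GLY"
  trb <- trajectory(topb, b$frames, box = diag(3) * 20)
  sb <- suppressWarnings(select_carbonyl_sites(trb, chains = "W"))
  route_b <- mean(site_occupancy(trb, sb, 3.25)$per_site$mean_count)
  prof <- rdf(trb, sb$atom, water_oxygens(trb), r_max = 6, bin_width = 0.05)
  route_c <- coordination_number(prof, 3.25)
  expect_equal(route_b, route_c, tolerance = 1e-10)

  # vacancy-induced dilution: each sojourn is followed by a 1-frame gap with
  # probability v, so occupancy drops by about n_gap_frames / n_frames
  hyv <- generate_hydration_trajectory(sc, exchange_config(
    n_frames = 400, pattern = c(Y = 2, G = 1),
    mean_sojourn = c(Y = 20, G = 20), vacancy_prob = 0.5, seed = 13))
  occv <- site_occupancy(hyv$trajectory, hyv$sites, 3.225)
  eps <- 0.5 / 20        # vacancy_prob * (1 frame) / mean sojourn frames
  expect_equal(unname(occv$per_role["Y"]), 2 * (1 - eps), tolerance = 0.12)
  expect_equal(unname(occv$per_role["G"]), 1 * (1 - eps), tolerance = 0.12)

  # crystal-like regime: sojourns far longer than the trajectory give
  # frame-constant counts identical to the single-frame count
  hyc <- generate_hydration_trajectory(sc, exchange_config(
    n_frames = 50, mean_sojourn = c(X = 1e6, Y = 1e6, G = 1e6), seed = 14))
  first <- site_occupancy(hyc$trajectory, hyc$sites, 3.225, frames = 1L)
  alltime <- site_occupancy(hyc$trajectory, hyc$sites, 3.225)
  expect_equal(alltime$per_site$mean_count, first$per_site$mean_count)
})

test_that("second-shell hydrogen-bonded counting follows the two-hop rule", {
  # hand-built chain: site -> w1 (2.6 A) -> w2 (2.8 A from w1, far from site)
  site <- c(10, 10, 10)
  w1 <- site + c(2.6, 0, 0)
  w2 <- w1 + c(2.8, 0, 0)
  far <- site + c(0, 15, 0)
  atoms <- rbind(site, w1, w2, far)
  top <- make_topology(c("O", "O", "O", "O"), rep("O", 4),
                       c("GLY", "HOH", "HOH", "HOH"), 1:4,
                       c("A", "W", "W", "W"))
  tr <- trajectory(top, list(atoms))
  s <- suppressWarnings(select_carbonyl_sites(tr))
  expect_equal(nrow(s), 1)
  occ1 <- site_occupancy(tr, s, 3.225)
  ss <- second_shell_hbonded(tr, s, 3.225)
  expect_equal(occ1$per_site$mean_count, 1)
  expect_equal(ss$per_site$mean_count, 1)

  # X sites (empty first shell) contribute zero second shell
  sc <- generate_scaffold(scaffold_config(3, chains = 3))
  hy <- generate_hydration_trajectory(sc, exchange_config(n_frames = 20, seed = 8))
  ss2 <- second_shell_hbonded(hy$trajectory, hy$sites, 3.225, frames = 1:5)
  expect_equal(unname(ss2$per_role["X"]), 0)

  # equality with a brute-force two-hop neighbour search on random boxes
  set.seed(19)
  for (rep in 1:5) {
    nw <- 25
    xyz <- rbind(c(6, 6, 6), matrix(runif(3 * nw, 0, 12), nw, 3))
    topr <- make_topology(c("O", rep("O", nw)), rep("O", nw + 1),
                          c("GLY", rep("HOH", nw)), seq_len(nw + 1),
                          c("A", rep("W", nw)))
    trr <- trajectory(topr, list(xyz))
    sr <- suppressWarnings(select_carbonyl_sites(trr))
    got <- second_shell_hbonded(trr, sr, 3.4)$per_site$mean_count
    d <- as.matrix(dist(xyz))
    shell1 <- which(d[1, -1] < 3.4)
    ref <- if (!length(shell1)) 0 else {
      two_hop <- unique(unlist(lapply(shell1, function(j)
        which(d[j + 1, -1] < 3.4 & seq_len(nw) != j))))
      length(setdiff(two_hop, shell1))
    }
    expect_equal(got, ref)
  }
})
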