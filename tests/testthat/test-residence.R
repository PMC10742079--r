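test_that("grace rule: single-frame absences bridge, longer gaps split", {
  s <- sojourns(pattern_trace(c(1, 1, 0, 1, 1)))
  expect_equal(nrow(s), 1)
  expect_equal(s$duration_frames, 5)

  s2 <- sojourns(pattern_trace(c(1, 1, 0, 0, 1)))
  expect_equal(sort(s2$duration_frames), c(1, 2))

  # alternating pattern: each gap individually bridged (transitive rule)
  s3 <- sojourns(pattern_trace(c(1, 0, 1, 0, 1)))
  expect_equal(s3$duration_frames, 5)

  # grace = 0 disables bridging
  s0 <- sojourns(pattern_trace(c(1, 1, 0, 1, 1)), grace = 0)
  expect_equal(sort(s0$duration_frames), c(2, 2))

  # duration scales with the frame interval
  s4 <- sojourns(pattern_trace(c(0, 1, 1, 1, 0), frame_interval = 2.5))
  expect_equal(s4$duration_ps, 7.5)
  expect_false(s4$censored)
})

test_that("sojourn splitting agrees with a literal reference implementation", {
  set.seed(55)
  for (rep in 1:30) {
    presence <- rbinom(40, 1, 0.55)
    for (g in 0:2) {
      got <- sojourns(pattern_trace(presence), grace = g)$duration_frames
      ref <- brute_sojourns(presence, grace = g)
      expect_equal(sort(got), sort(ref))
    }
  }
})

test_that("grace monotonicity: bridging merges sojourns and lengthens them", {
  set.seed(56)
  for (rep in 1:10) {
    presence <- rbinom(60, 1, 0.5)
    if (!any(presence > 0)) next
    tr <- pattern_trace(presence)
    s0 <- sojourns(tr, grace = 0); s1 <- sojourns(tr, grace = 1)
    expect_lte(nrow(s1), nrow(s0))
    if (nrow(s1) && nrow(s0))
      expect_gte(mean(s1$duration_frames), mean(s0$duration_frames))
  }
})

test_that("censoring flags trajectory-truncated episodes; means exclude them", {
  s <- sojourns(pattern_trace(c(1, 1, 0, 0, 1, 1, 0, 0, 1)))
  expect_equal(s$censored, c(TRUE, FALSE, TRUE))
  expect_equal(mean_residence(s), 2)
  expect_equal(mean_residence(s, include_censored = TRUE), mean(c(2, 2, 1)))
  all_cens <- sojourns(pattern_trace(c(1, 1, 1)))
  expect_error(mean_residence(all_cens), "uncensored")

  durations <- data.frame(duration_ps = c(10, 20, 30),
                          censored = c(FALSE, FALSE, FALSE))
  attr(durations, "frame_interval") <- 1
  class(durations) <- c("hs_sojourns", "data.frame")
  expect_equal(mean_residence(durations), 20)
})

test_that("residence histogram bins durations and trims empty tails", {
  d <- data.frame(duration_ps = c(2, 2, 4), censored = rep(FALSE, 3))
  attr(d, "frame_interval") <- 1
  class(d) <- c("hs_sojourns", "data.frame")
  h <- residence_histogram(d, bin_width = 2)
  expect_equal(h$counts, c(2, 1))
  expect_equal(h$t, c(1, 3))

  single <- d[3, , drop = FALSE]
  class(single) <- c("hs_sojourns", "data.frame")
  attr(single, "frame_interval") <- 1
  hs <- residence_histogram(single, bin_width = 2)
  expect_equal(sum(hs$counts > 0), 1)
})

test_that("exponential fits recover known decay constants", {
  # noiseless recovery from exact samples of 100 * exp(-t / 25.68)
  t <- seq(2.5, 125, by = 5)
  counts <- round(1e6 * exp(-t / 25.68))
  h <- structure(list(breaks = seq(0, 125, 5), t = t, counts = counts,
                      bin_width = 5), class = "hs_hist")
  f <- fit_exponential(h)
  expect_equal(f$tau_mean, 25.68, tolerance = 1e-3)
  expect_gt(f$r_squared, 0.9999)

  # synthetic exponential sojourns, mean 81.72 ps: fit within a few percent
  set.seed(61)
  d <- data.frame(duration_ps = ceiling(rexp(1e4, 1 / 81.72)),
                  censored = rep(FALSE, 1e4))
  attr(d, "frame_interval") <- 1
  class(d) <- c("hs_sojourns", "data.frame")
  f2 <- fit_exponential(residence_histogram(d, bin_width = 10))
  expect_equal(f2$tau_mean, 81.72, tolerance = 0.1)
  # both estimators of the mean residence time agree
  expect_equal(mean_residence(d), f2$tau_mean, tolerance = 0.1)

  flat <- structure(list(breaks = 0:6, t = (0:5) + 0.5,
                         counts = rep(5L, 6), bin_width = 1),
                    class = "hs_hist")
  ff <- fit_exponential(flat)
  expect_lt(ff$r_squared, 0.5)
  expect_error(fit_exponential(structure(list(t = 1:2, counts = c(1L, 1L),
                                              breaks = 0:2, bin_width = 1),
                                         class = "hs_hist")), "3 nonzero")
})

test_that("identity tracking through the trajectory matches a brute-force scan", {
  sc <- generate_scaffold(scaffold_config(3, chains = 2))
  hy <- generate_hydration_trajectory(sc, exchange_config(
    n_frames = 30, mean_sojourn = c(X = 8, Y = 8, G = 8), seed = 77))
  tr <- occupancy_trace(hy$trajectory, hy$sites, 3.5)
  wat <- water_oxygens(hy$trajectory)
  site_xyz <- lapply(1:30, function(f) hy$trajectory$frames[[f]][hy$sites$atom, ])
  for (f in c(1, 11, 29)) {
    ref <- c()
    for (si in seq_len(nrow(hy$sites)))
      for (w in wat) {
        d <- sqrt(sum((hy$trajectory$frames[[f]][w, ] - site_xyz[[f]][si, ])^2))
        if (d < 3.5) ref <- rbind(ref, c(f, si, w))
      }
    got <- tr$hits[tr$hits$frame == f, ]
    expect_equal(nrow(got), nrow(ref))
    expect_setequal(paste(got$site, got$water), paste(ref[, 2], ref[, 3]))
  }
  # every Y site holds exactly 2 identities each frame (no vacancies)
  ycounts <- table(tr$hits$site[tr$hits$site %in% which(hy$sites$role == "Y")],
                   tr$hits$frame[tr$hits$site %in% which(hy$sites$role == "Y")])
  expect_true(all(ycounts == 2))
})

test_that("three-frame in-out-in water is bridged into one episode", {
  # one site, one water stepping 3.0 -> 3.6 -> 3.0 A
  site <- c(0, 0, 0)
  top <- make_topology(c("O", "O"), c("O", "O"), c("GLY", "HOH"), 1:2,
                       c("A", "W"))
  frames <- list(rbind(site, c(3.0, 0, 0)), rbind(site, c(3.6, 0, 0)),
                 rbind(site, c(3.0, 0, 0)))
  tr <- trajectory(top, frames)
  s <- suppressWarnings(select_carbonyl_sites(tr))
  trace <- occupancy_trace(tr, s, 3.5)
  expect_equal(trace$hits$frame, c(1, 3))
  sj <- sojourns(trace)
  expect_equal(nrow(sj), 1)
  expect_equal(sj$duration_frames, 3)
})

test_that("substitution fraction tracks the generator's vacancy probability", {
  sc <- generate_scaffold(scaffold_config(4, chains = 3))
  hy0 <- generate_hydration_trajectory(sc, exchange_config(
    n_frames = 150, mean_sojourn = c(X = 10, Y = 10, G = 10),
    vacancy_prob = 0, seed = 81))
  f0 <- substitution_fraction(occupancy_trace(hy0$trajectory, hy0$sites, 3.5))
  expect_equal(unname(f0[c("G", "Y")]), c(1, 1))

  hy1 <- generate_hydration_trajectory(sc, exchange_config(
    n_frames = 150, pattern = c(G = 1), mean_sojourn = c(G = 10),
    vacancy_prob = 1, seed = 82))
  f1 <- substitution_fraction(occupancy_trace(hy1$trajectory, hy1$sites, 3.5))
  expect_equal(unname(f1[["G"]]), 0)

  hy3 <- generate_hydration_trajectory(sc, exchange_config(
    n_frames = 800, pattern = c(G = 1, Y = 2), mean_sojourn = c(G = 10, Y = 10),
    vacancy_prob = 0.3, seed = 83))
  f3 <- substitution_fraction(occupancy_trace(hy3$trajectory, hy3$sites, 3.5))
  expect_equal(mean(f3[c("G", "Y")]), 0.7, tolerance = 0.08)
})

test_that("longer-lived sites are correctly ordered across 100 seeded runs", {
  sc <- generate_scaffold(scaffold_config(5, chains = 1))
  wins <- 0L
  for (seed in 1:100) {
    hy <- generate_hydration_trajectory(sc, exchange_config(
      n_frames = 1000, pattern = c(Y = 2, G = 1),
      mean_sojourn = c(Y = 25, G = 80), seed = seed), materialise = FALSE)
    occ <- hy$ground_truth$occupants
    ok <- !occ$censored
    tau_g <- mean(occ$sojourn_frames[ok & occ$role == "G"])
    tau_y <- mean(occ$sojourn_frames[ok & occ$role == "Y"])
    if (tau_g > tau_y) wins <- wins + 1L
  }
  expect_equal(wins, 100L)
})
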