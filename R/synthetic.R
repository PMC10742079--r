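# Synthetic ground-truth generators. These emulate the statistical structure
# the hydration analysis assumes — a rigid triplet-periodic scaffold, a
# structured first shell with a programmable X-Y-G occupancy pattern,
# exponential site-exchange kinetics, and uniform bulk water — without any
# force-field physics. Single-point waters (oxygen only) suffice because
# every analysis criterion is distance-based on the water oxygen.

#' Scaffold configuration
#'
#' @param n_triplets number of X-Y-G triplets per chain (>= 1).
#' @param spacing_l axial spacing between triplet centres, Angstrom. The
#'   default 8.85 is the per-triplet rise of a collagen-mimetic (PPG)n
#'   triple helix.
#' @param chains number of peptide chains wound about the common axis.
#' @param radial_offset distance of carbonyl-O sites from the axis, Angstrom.
#' @param seed RNG seed.
#' @return list of class \code{hs_scaffold_config}.
#' @export
scaffold_config <- function(n_triplets, spacing_l = 8.85, chains = 3,
                            radial_offset = 5.0, seed = 1L) {
  stopifnot(n_triplets >= 1, spacing_l > 0, chains >= 1, radial_offset > 0)
  structure(list(n_triplets = as.integer(n_triplets), spacing_l = spacing_l,
                 chains = as.integer(chains), radial_offset = radial_offset,
                 seed = as.integer(seed)),
            class = "hs_scaffold_config")
}

#' Generate a rigid triplet-periodic scaffold
#'
#' Builds a single-frame trajectory containing (i) one pseudo-atom per
#' triplet centre ("bead", chain "Z", atom name "CA") on a straight line
#' with exact spacing l — so the bead end-to-end distance is (n-1)l — and
#' (ii) per-residue backbone atoms (CA and carbonyl O) for \code{chains}
#' peptide chains wound helically about the same axis (60 degrees twist per
#' residue, chain phase 2*pi/chains), with residue names PRO, PRO, GLY
#' repeating so that [select_carbonyl_sites()] recovers the X/Y/G roles.
#' The twist/radius defaults keep every pair of site oxygens more than
#' 5.5 Angstrom apart, so a first-shell water is unambiguous about which
#' site it belongs to. Each X-site oxygen additionally carries a cluster of
#' blocker pseudo-atoms (name "BLK") capping its outward face — the
#' geometric stand-in for the inter-chain amide that occupies the space
#' above the X carbonyl — and each G site a partial shade, so carbonyl-O
#' solvent accessibility is ordered Y > G > X ~ 0 by construction.
#' Coordinates are deterministic (no randomness is consumed).
#'
#' @param cfg an [scaffold_config()].
#' @return single-frame \code{hs_trajectory}, no box.
#' @export
generate_scaffold <- function(cfg) {
  stopifnot(inherits(cfg, "hs_scaffold_config"))
  n <- cfg$n_triplets; l <- cfg$spacing_l; R <- cfg$radial_offset
  nres <- 3L * n
  # beads: triplet centres on the axis
  name <- rep("CA", n); elem <- rep("C", n)
  resname <- rep("BEA", n); resseq <- seq_len(n); chain <- rep("Z", n)
  xyz <- cbind(0, 0, (seq_len(n) - 1) * l)
  res_names <- rep(c("PRO", "PRO", "GLY"), n)
  roles <- rep(c("X", "Y", "G"), n)
  # blocker offsets (unit vectors in the local frame: e_r outward, e_t
  # tangential, e_z axial) and distances from the site oxygen
  shades <- list(
    X = list(dirs = rbind(c(1, 0, 0),
                          c(cos(0.9), sin(0.9) * cos(0), sin(0.9) * sin(0)),
                          c(cos(0.9), sin(0.9) * cos(2 * pi / 3), sin(0.9) * sin(2 * pi / 3)),
                          c(cos(0.9), sin(0.9) * cos(4 * pi / 3), sin(0.9) * sin(4 * pi / 3))),
             dist = 2.6),
    G = list(dirs = rbind(c(cos(1.15), sin(1.15), 0),
                          c(cos(1.15), -sin(1.15), 0)),
             dist = 3.0),
    Y = list(dirs = NULL, dist = NA))
  for (c_i in seq_len(cfg$chains)) {
    ch <- LETTERS[c_i]
    m <- seq_len(nres)
    theta <- pi / 3 * (m - 1) + 2 * pi * (c_i - 1) / cfg$chains
    z <- (m - 2) * l / 3          # triplet i centred at z = (i-1) l
    e_r <- cbind(cos(theta), sin(theta), 0)
    e_t <- cbind(-sin(theta), cos(theta), 0)
    ca <- 0.55 * R * e_r + cbind(0, 0, z)
    ox <- R * e_r + cbind(0, 0, z)
    for (mm in m) {
      xyz <- rbind(xyz, ca[mm, ], ox[mm, ])
      name <- c(name, "CA", "O")
      elem <- c(elem, "C", "O")
      resname <- c(resname, res_names[mm], res_names[mm])
      resseq <- c(resseq, mm, mm)
      chain <- c(chain, ch, ch)
      sh <- shades[[roles[mm]]]
      if (!is.null(sh$dirs)) {
        for (dd in seq_len(nrow(sh$dirs))) {
          u <- sh$dirs[dd, 1] * e_r[mm, ] + sh$dirs[dd, 2] * e_t[mm, ] +
            sh$dirs[dd, 3] * c(0, 0, 1)
          xyz <- rbind(xyz, ox[mm, ] + sh$dist * u)
          name <- c(name, "BLK"); elem <- c(elem, "N")
          resname <- c(resname, res_names[mm])
          resseq <- c(resseq, mm); chain <- c(chain, ch)
        }
      }
    }
  }
  top <- make_topology(name, elem, resname, resseq, chain)
  tr <- trajectory(top, list(xyz), frame_interval = 1)
  attr(tr, "scaffold_config") <- cfg
  tr
}

#' Exchange (hydration kinetics) configuration
#'
#' Defines the structured first shell and its substitution kinetics: each
#' site of role r carries \code{pattern[r]} bound-water slots; every slot's
#' occupant persists for an exponentially distributed sojourn of mean
#' \code{mean_sojourn[r]} ps (discretised to frames by ceiling, minimum one
#' frame), after which it is replaced by a fresh water — immediately when
#' \code{substitution} is TRUE, leaving the slot empty for exactly one frame
#' with probability \code{vacancy_prob}. With \code{substitution = FALSE}
#' the refill is instead delayed by an independent exponential vacancy of
#' the same mean. Default sojourn means are the liquid-water scales of the
#' two hydrated roles (about 82 ps at Gly-CO, about 26 ps at Pro(Y)-CO).
#'
#' @param n_frames number of saved frames.
#' @param frame_interval ps between frames.
#' @param pattern named occupancy per role, default \code{c(X=0, Y=2, G=1)}.
#' @param mean_sojourn named mean sojourn per role, ps.
#' @param substitution logical; departures instantly replaced.
#' @param vacancy_prob probability a departure leaves the slot empty for one
#'   frame.
#' @param bulk_density number density of additional free waters, per cubic
#'   Angstrom (0 disables bulk water).
#' @param seed RNG seed.
#' @return list of class \code{hs_exchange_config}.
#' @export
exchange_config <- function(n_frames, frame_interval = 1,
                            pattern = c(X = 0, Y = 2, G = 1),
                            mean_sojourn = c(X = 25.68, Y = 25.68, G = 81.72),
                            substitution = TRUE, vacancy_prob = 0,
                            bulk_density = 0, seed = 1L) {
  stopifnot(n_frames >= 1, frame_interval > 0, all(mean_sojourn > 0),
            vacancy_prob >= 0, vacancy_prob <= 1, bulk_density >= 0)
  if (any(frame_interval >= mean_sojourn[names(pattern)[pattern > 0]] / 2))
    warning("frame_interval >= mean_sojourn/2 for an occupied role: ",
            "sojourn discretisation will be strongly biased")
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, pattern = pattern,
                 mean_sojourn = mean_sojourn, substitution = substitution,
                 vacancy_prob = vacancy_prob, bulk_density = bulk_density,
                 seed = as.integer(seed)),
            class = "hs_exchange_config")
}

# Draw one slot's renewal sequence covering frames 1..n_frames.
# Returns a data.frame of occupants with start/end frames and the continuous
# sojourn length in ps.
.slot_schedule <- function(n_frames, frame_interval, mean_ps, substitution,
                           vacancy_prob) {
  out <- list(); f <- 1L; i <- 0L
  while (f <= n_frames) {
    i <- i + 1L
    s <- stats::rexp(1, rate = 1 / mean_ps)
    nf <- max(1L, as.integer(ceiling(s / frame_interval)))
    end <- min(f + nf - 1L, n_frames)
    out[[i]] <- data.frame(start_frame = f, end_frame = end, sojourn_ps = s,
                           sojourn_frames = nf,
                           censored = (f == 1L) || (end == n_frames))
    f <- end + 1L
    if (f > n_frames) break
    if (substitution) {
      if (vacancy_prob > 0 && stats::runif(1) < vacancy_prob) f <- f + 1L
    } else {
      gap <- max(1L, as.integer(ceiling(stats::rexp(1, 1 / mean_ps) / frame_interval)))
      f <- f + gap
    }
  }
  do.call(rbind, out)
}

# Unit vector on the spherical cap (half-angle cap_deg) about direction u.
.cap_direction <- function(u, cap_deg = 60) {
  u <- u / sqrt(sum(u^2))
  cosmax <- cos(cap_deg * pi / 180)
  ct <- stats::runif(1, cosmax, 1)
  st <- sqrt(1 - ct^2)
  phi <- stats::runif(1, 0, 2 * pi)
  # orthonormal frame about u
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  ct * u + st * (cos(phi) * e1 + sin(phi) * e2)
}

#' Generate a structured-hydration trajectory with known ground truth
#'
#' Populates every carbonyl-O site of the scaffold with \code{pattern[role]}
#' bound-water slots exchanging by the kinetics of the configuration. Bound
#' waters sit at 2.65 Angstrom from their site oxygen (the first-shell RDF
#' maximum), in a direction drawn once per occupant on the outward-facing
#' spherical cap; between sojourns each water is parked far from the
#' scaffold. Optional bulk waters are placed uniformly, rejected within
#' 3.5 Angstrom of any site oxygen, and held static.
#'
#' @param scaffold a trajectory from [generate_scaffold()].
#' @param cfg an [exchange_config()].
#' @param materialise build the full per-frame coordinate trajectory
#'   (default). With \code{FALSE} only the kinetic ground truth and site
#'   table are generated (\code{trajectory} is NULL) — useful when
#'   statistics on many thousands of sojourns are wanted without holding
#'   every frame in memory.
#' @return list with \code{trajectory} (an \code{hs_trajectory}),
#'   \code{sites} (the site table used), and \code{ground_truth}: the full
#'   occupant table (site, slot, role, water topology row, start/end frame,
#'   continuous sojourn ps, discretised frames, censoring), the per-role
#'   mean occupancy actually realised, the requested pattern and the seed.
#' @export
generate_hydration_trajectory <- function(scaffold, cfg, materialise = TRUE) {
  stopifnot(inherits(cfg, "hs_exchange_config"))
  set.seed(cfg$seed)
  sites <- select_carbonyl_sites(scaffold)
  ped_top <- scaffold$topology
  site_xyz <- scaffold$frames[[1]][sites$atom, , drop = FALSE]
  nf <- cfg$n_frames

  # schedule all slots
  sched <- list(); k <- 0L
  for (si in seq_len(nrow(sites))) {
    role <- sites$role[si]
    if (!role %in% names(cfg$pattern)) next
    nslots <- cfg$pattern[[role]]
    if (is.na(nslots) || nslots < 1) next
    for (sl in seq_len(nslots)) {
      k <- k + 1L
      sc <- .slot_schedule(nf, cfg$frame_interval, cfg$mean_sojourn[[role]],
                           cfg$substitution, cfg$vacancy_prob)
      sc$site <- si; sc$slot <- sl; sc$role <- role
      sched[[k]] <- sc
    }
  }
  occ <- if (length(sched)) do.call(rbind, sched) else
    data.frame(start_frame = integer(), end_frame = integer(),
               sojourn_ps = numeric(), sojourn_frames = integer(),
               censored = logical(), site = integer(), slot = integer(),
               role = character())

  n_occ <- nrow(occ)
  if (!materialise) {
    occ$water <- NA_integer_
    frame_counts <- matrix(0L, nrow(sites), nf)
    for (i in seq_len(n_occ))
      frame_counts[occ$site[i], occ$start_frame[i]:occ$end_frame[i]] <-
        frame_counts[occ$site[i], occ$start_frame[i]:occ$end_frame[i]] + 1L
    mean_occ <- c(tapply(rowMeans(frame_counts), sites$role, mean))
    return(list(trajectory = NULL, sites = sites,
                ground_truth = list(occupants = occ, mean_occupancy = mean_occ,
                                    pattern = cfg$pattern, seed = cfg$seed,
                                    config = cfg)))
  }
  # bound position per occupant: site + 2.65 A along an outward cap direction
  bound_pos <- matrix(0, n_occ, 3)
  for (i in seq_len(n_occ)) {
    s <- site_xyz[occ$site[i], ]
    radial <- c(s[1], s[2], 0)
    if (sum(radial^2) < 1e-12) radial <- c(1, 0, 0)
    bound_pos[i, ] <- s + 2.65 * .cap_direction(radial)
  }

  # optional static bulk water
  bulk_pos <- matrix(numeric(0), 0, 3)
  if (cfg$bulk_density > 0) {
    lim <- apply(scaffold$frames[[1]], 2, range)
    lo <- lim[1, ] - 6; hi <- lim[2, ] + 6
    vol <- prod(hi - lo)
    n_bulk <- as.integer(round(cfg$bulk_density * vol))
    cand <- cbind(stats::runif(2 * n_bulk, lo[1], hi[1]),
                  stats::runif(2 * n_bulk, lo[2], hi[2]),
                  stats::runif(2 * n_bulk, lo[3], hi[3]))
    dmin <- apply(pair_distances(site_xyz, cand), 2, min)
    bulk_pos <- cand[dmin > 3.5, , drop = FALSE]
    bulk_pos <- bulk_pos[seq_len(min(n_bulk, nrow(bulk_pos))), , drop = FALSE]
  }
  n_bulk <- nrow(bulk_pos)

  # topology: scaffold atoms, then one water O per occupant, then bulk
  n_w <- n_occ + n_bulk
  top <- make_topology(
    c(ped_top$name, rep("O", n_w)),
    c(ped_top$element, rep("O", n_w)),
    c(ped_top$residue_name, rep("HOH", n_w)),
    c(ped_top$residue_seq, seq_len(n_w)),
    c(ped_top$chain_id, rep("W", n_w)))
  w_rows <- nrow(ped_top) + seq_len(n_occ)

  # park unbound waters on a grid far from the scaffold yet inside the
  # fixed-width PDB coordinate range
  pk <- seq_len(max(n_occ, 1L)) - 1L
  park <- cbind(200 + 8 * (pk %% 90L), 200 + 8 * ((pk %/% 90L) %% 90L),
                200 + 8 * (pk %/% 8100L))
  base <- rbind(scaffold$frames[[1]],
                if (n_occ) park[seq_len(n_occ), , drop = FALSE],
                bulk_pos)
  frames <- vector("list", nf)
  # per-frame list of occupants bound in that frame
  bound_at <- vector("list", nf)
  for (i in seq_len(n_occ))
    for (f in occ$start_frame[i]:occ$end_frame[i])
      bound_at[[f]] <- c(bound_at[[f]], i)
  for (f in seq_len(nf)) {
    m <- base
    b <- bound_at[[f]]
    if (length(b)) m[w_rows[b], ] <- bound_pos[b, , drop = FALSE]
    frames[[f]] <- m
  }
  traj <- trajectory(top, frames, frame_interval = cfg$frame_interval)

  occ$water <- if (n_occ) w_rows else integer(0)
  # realised mean occupancy per role over all frames and sites of that role
  frame_counts <- matrix(0L, nrow(sites), nf)
  for (i in seq_len(n_occ))
    frame_counts[occ$site[i], occ$start_frame[i]:occ$end_frame[i]] <-
      frame_counts[occ$site[i], occ$start_frame[i]:occ$end_frame[i]] + 1L
  mean_occ <- c(tapply(rowMeans(frame_counts), sites$role, mean))

  list(trajectory = traj, sites = sites,
       ground_truth = list(occupants = occ, mean_occupancy = mean_occ,
                           pattern = cfg$pattern, seed = cfg$seed,
                           config = cfg))
}

#' Freely-jointed ideal-chain ensemble
#'
#' Monte-Carlo 3D random walks with unit steps drawn uniformly on the
#' sphere. For such chains the ensemble ratio
#' \eqn{\sqrt{\langle Rg^2\rangle}/\sqrt{\langle Ree^2\rangle}} tends to
#' \eqn{1/\sqrt 6 = 0.408}, the classic ideal-chain reference against which
#' rigid-rod values (~0.29–0.34) are judged.
#'
#' @param n_steps steps per chain (>= 1).
#' @param n_chains ensemble size.
#' @param seed RNG seed.
#' @param chunk chains generated per vectorised block (memory control).
#' @return list with per-chain \code{rg2}, \code{ree2}, and the summary
#'   \code{ratio} = sqrt(mean rg2)/sqrt(mean ree2).
#' @export
generate_ideal_chain <- function(n_steps, n_chains, seed = 1L,
                                 chunk = 2000L) {
  stopifnot(n_steps >= 1, n_chains >= 1)
  set.seed(seed)
  rg2 <- numeric(n_chains); ree2 <- numeric(n_chains)
  done <- 0L
  while (done < n_chains) {
    m <- min(chunk, n_chains - done)
    # unit steps: normalised Gaussian triples, one column per chain
    sx <- matrix(stats::rnorm(n_steps * m), n_steps, m)
    sy <- matrix(stats::rnorm(n_steps * m), n_steps, m)
    sz <- matrix(stats::rnorm(n_steps * m), n_steps, m)
    nrm <- sqrt(sx * sx + sy * sy + sz * sz)
    sx <- sx / nrm; sy <- sy / nrm; sz <- sz / nrm
    px <- apply(sx, 2, cumsum); py <- apply(sy, 2, cumsum); pz <- apply(sz, 2, cumsum)
    if (n_steps == 1L) { px <- rbind(px); py <- rbind(py); pz <- rbind(pz) }
    idx <- done + seq_len(m)
    ree2[idx] <- px[n_steps, ]^2 + py[n_steps, ]^2 + pz[n_steps, ]^2
    # Rg^2 about the walk's centroid; the origin vertex is part of the chain
    # (its coordinates are zero, so it only enters through the divisor)
    np <- n_steps + 1
    mx <- colSums(px) / np; my <- colSums(py) / np; mz <- colSums(pz) / np
    rg2[idx] <- (colSums(px^2) + colSums(py^2) + colSums(pz^2)) / np -
      (mx^2 + my^2 + mz^2)
    done <- done + m
  }
  list(rg2 = rg2, ree2 = ree2,
       ratio = sqrt(mean(rg2)) / sqrt(mean(ree2)))
}

#' Uniform bulk-water box
#'
#' Ideal-gas water: uniformly random oxygen positions in a cubic periodic
#' box at the requested number density (count = round(density * volume);
#' liquid water at ambient conditions is 0.0334 per cubic Angstrom).
#'
#' @param box_edge cube edge, Angstrom.
#' @param density molecules per cubic Angstrom.
#' @param seed RNG seed.
#' @return single-frame \code{hs_trajectory} with a cubic box.
#' @export
generate_bulk_water <- function(box_edge, density = 0.0334, seed = 1L) {
  stopifnot(box_edge > 0)
  if (density <= 0) stop("density must be positive (empty frame otherwise)")
  n <- as.integer(round(density * box_edge^3))
  if (n > 1e7) stop("refusing to generate more than 1e7 molecules")
  if (n < 1) stop("density and box too small: zero molecules")
  set.seed(seed)
  xyz <- matrix(stats::runif(3 * n, 0, box_edge), n, 3)
  top <- make_topology(rep("O", n), rep("O", n), rep("HOH", n),
                       seq_len(n), rep("W", n))
  trajectory(top, list(xyz), frame_interval = 1, box = diag(3) * box_edge)
}
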