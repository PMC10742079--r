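# Fixtures and independent oracles, all built in code at test time.

# A minimal hand-written PDB with the given atoms (list of lists with
# name, resname, chain, resseq, xyz) and optional extra raw lines.
write_toy_pdb <- function(path, atoms, models = 1, cryst1 = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cryst1)) writeLines(cryst1, con)
  fmt <- function(a, serial) {
    rec <- if (a$resname %in% c("HOH", "SOL", "WAT")) "HETATM" else "ATOM  "
    sprintf("%s%5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, serial, a$name, a$resname, a$chain, a$resseq,
            a$xyz[1], a$xyz[2], a$xyz[3], a$element)
  }
  for (m in seq_len(models)) {
    if (models > 1) writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_along(atoms)) {
      a <- atoms[[i]]
      if (models > 1) a$xyz <- a$xyz + (m - 1)  # shift per model
      writeLines(fmt(a, i), con)
    }
    if (models > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

toy_atom <- function(name, resname, chain, resseq, xyz,
                     element = substr(name, 1, 1)) {
  list(name = name, resname = resname, chain = chain, resseq = resseq,
       xyz = xyz, element = element)
}

# A bare trajectory around explicit coordinates, all non-water "C" atoms
# unless flagged.
point_traj <- function(xyz, water = rep(FALSE, nrow(xyz)), box = NULL,
                       n_frames = 1, frame_interval = 1) {
  n <- nrow(xyz)
  top <- make_topology(
    name = ifelse(water, "O", "C"),
    element = ifelse(water, "O", "C"),
    residue_name = ifelse(water, "HOH", "ALA"),
    residue_seq = seq_len(n), chain_id = rep("A", n))
  trajectory(top, rep(list(xyz), n_frames), frame_interval = frame_interval,
             box = box)
}

# Brute-force minimum image: exhaustive search over a wide image range
# (points in the tests lie within +/- 2 cells, so +/- 3 shifts suffice).
brute_min_image <- function(a, b, box) {
  sh <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  dmin <- Inf
  for (i in seq_len(nrow(sh))) {
    bb <- b + as.numeric(sh[i, ] %*% box)
    dmin <- min(dmin, sqrt(sum((bb - a)^2)))
  }
  dmin
}

# Brute-force double-loop distance histogram for RDF cross-checks.
brute_pair_hist <- function(centers, others, box, edges, self_pairs) {
  d <- c()
  for (i in seq_len(nrow(centers)))
    for (j in seq_len(nrow(others))) {
      if (!is.null(self_pairs) && self_pairs[i, j]) next
      d <- c(d, brute_min_image(centers[i, ], others[j, ], box))
    }
  d <- d[d <= max(edges)]
  tabulate(findInterval(d, edges, rightmost.closed = TRUE),
           nbins = length(edges) - 1L)
}

# Analytic accessible area of sphere 1 (radius R1) occluded by a single
# sphere of radius R2 at centre distance d: full area minus the spherical cap
# cut off by the intersection plane.
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d + R1 <= R2) return(0)
  # height of the buried cap on sphere 1
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Single-site occupancy trace from a 0/1 presence pattern of one water.
pattern_trace <- function(presence, frame_interval = 1) {
  frames <- which(presence > 0)
  hits <- data.frame(frame = frames, site = 1L, water = 99L)
  sites <- data.frame(atom = 1L, index = 0L, chain_id = "A",
                      residue_seq = 1L, role = "G", stringsAsFactors = FALSE)
  class(sites) <- c("hs_sites", "data.frame")
  structure(list(hits = hits, sites = sites, n_frames = length(presence),
                 frame_interval = frame_interval, cutoff_used = 3.5),
            class = "hs_trace")
}

# Reference sojourn splitter: literal statement of the grace rule applied
# to a 0/1 presence vector.
brute_sojourns <- function(presence, grace = 1L) {
  f <- which(presence > 0)
  if (!length(f)) return(integer(0))
  runs <- list(); cur_start <- f[1]; cur_end <- f[1]
  for (x in f[-1]) {
    if (x - cur_end - 1L <= grace) cur_end <- x
    else { runs <- c(runs, list(c(cur_start, cur_end))); cur_start <- x; cur_end <- x }
  }
  runs <- c(runs, list(c(cur_start, cur_end)))
  vapply(runs, function(r) r[2] - r[1] + 1L, integer(1))
}
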