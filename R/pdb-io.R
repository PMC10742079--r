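# Fixed-width PDB reading/writing. Kept deliberately strict: the analysis
# code downstream assumes coordinates in Angstrom and honest MODEL blocks.

.cryst1_to_box <- function(a, b, c, alpha, beta, gamma) {
  # standard crystallographic cell -> lattice row-vectors
  ar <- alpha * pi / 180; br <- beta * pi / 180; gr <- gamma * pi / 180
  v1 <- c(a, 0, 0)
  v2 <- c(b * cos(gr), b * sin(gr), 0)
  cx <- c * cos(br)
  cy <- c * (cos(ar) - cos(br) * cos(gr)) / sin(gr)
  cz <- sqrt(max(c^2 - cx^2 - cy^2, 0))
  rbind(v1, v2, c(cx, cy, cz), deparse.level = 0)
}

.box_to_cryst1 <- function(box) {
  a <- sqrt(sum(box[1, ]^2)); b <- sqrt(sum(box[2, ]^2)); c <- sqrt(sum(box[3, ]^2))
  alpha <- acos(sum(box[2, ] * box[3, ]) / (b * c)) * 180 / pi
  beta  <- acos(sum(box[1, ] * box[3, ]) / (a * c)) * 180 / pi
  gamma <- acos(sum(box[1, ] * box[2, ]) / (a * b)) * 180 / pi
  c(a, b, c, alpha, beta, gamma)
}

.parse_num <- function(s, what, lineno) {
  v <- suppressWarnings(as.numeric(s))
  bad <- is.na(v) & nzchar(trimws(s))
  bad <- bad | !nzchar(trimws(s))
  if (any(bad))
    stop(sprintf("malformed ATOM/HETATM record at line %d: bad %s field",
                 lineno[which(bad)[1]], what))
  v
}

#' Read a PDB file into a trajectory
#'
#' Parses ATOM/HETATM records (fixed-width columns), one frame per MODEL
#' block (or a single frame when no MODEL records are present), and CRYST1
#' into a periodic box. HETATM waters are included and flagged via the
#' water residue set.
#'
#' @param path PDB file.
#' @param model_policy \code{"all"} (default) keeps every MODEL as a frame;
#'   \code{"first"} keeps only the first.
#' @param frame_interval ps between models (metadata only).
#' @param water_residues residue names treated as water.
#' @return an \code{hs_trajectory}.
#' @export
read_pdb <- function(path, model_policy = c("all", "first"), frame_interval = 1,
                     water_residues = .default_water_residues) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty input: no ATOM/HETATM records in ", path)

  box <- NULL
  cl <- which(startsWith(lines, "CRYST1"))
  if (length(cl)) {
    f <- lines[cl[1]]
    cell <- suppressWarnings(as.numeric(c(
      substr(f, 7, 15), substr(f, 16, 24), substr(f, 25, 33),
      substr(f, 34, 40), substr(f, 41, 47), substr(f, 48, 54))))
    if (!anyNA(cell) && all(cell[1:3] > 0) &&
        !(all(abs(cell[1:3] - 1) < 1e-6)))   # dummy 1 1 1 cell means "no box"
      box <- .cryst1_to_box(cell[1], cell[2], cell[3], cell[4], cell[5], cell[6])
  }

  model_starts <- which(rec == "MODEL ")
  atom_lines <- which(is_atom)
  if (length(model_starts)) {
    # assign each atom line to the MODEL block it follows
    grp <- findInterval(atom_lines, model_starts)
    if (any(grp == 0)) stop("ATOM record before first MODEL at line ", atom_lines[grp == 0][1])
    n_models <- length(model_starts)
  } else {
    grp <- rep(1L, length(atom_lines))
    n_models <- 1L
  }

  first <- atom_lines[grp == 1L]
  parse_block <- function(idx) {
    ln <- lines[idx]
    x <- .parse_num(substr(ln, 31, 38), "x", idx)
    y <- .parse_num(substr(ln, 39, 46), "y", idx)
    z <- .parse_num(substr(ln, 47, 54), "z", idx)
    cbind(x, y, z, deparse.level = 0)
  }

  ln1 <- lines[first]
  name <- trimws(substr(ln1, 13, 16))
  residue_name <- trimws(substr(ln1, 18, 20))
  chain_id <- substr(ln1, 22, 22)
  residue_seq <- suppressWarnings(as.integer(trimws(substr(ln1, 23, 26))))
  if (anyNA(residue_seq))
    stop("malformed ATOM/HETATM record at line ",
         first[which(is.na(residue_seq))[1]], ": bad residue number")
  element <- trimws(substr(ln1, 77, 78))
  # infer element from the atom name when column 77-78 is blank
  blank <- !nzchar(element)
  element[blank] <- substr(gsub("[^A-Za-z].*$", "", sub("^[0-9 ]+", "", name[blank])), 1, 1)
  top <- suppressWarnings(
    make_topology(name, element, residue_name, residue_seq, chain_id,
                  water_residues = water_residues))

  keep_models <- if (model_policy == "first") 1L else seq_len(n_models)
  frames <- lapply(keep_models, function(m) {
    idx <- atom_lines[grp == m]
    if (length(idx) != nrow(top))
      stop(sprintf("MODEL %d has %d atoms; expected %d", m, length(idx), nrow(top)))
    parse_block(idx)
  })
  trajectory(top, frames, frame_interval = frame_interval, box = box)
}

#' Write a trajectory as (multi-model) PDB
#'
#' One MODEL/ENDMDL block per frame when the trajectory has more than one
#' frame; CRYST1 written when a box is present. Round-trips coordinates at
#' the format's 3-decimal precision.
#'
#' @param traj an \code{hs_trajectory}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_pdb <- function(traj, path) {
  if (!inherits(traj, "hs_trajectory")) stop("traj must be an hs_trajectory")
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  box <- frame_box(traj, 1L)
  if (!is.null(box)) {
    cc <- .box_to_cryst1(box)
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       cc[1], cc[2], cc[3], cc[4], cc[5], cc[6]), con)
  }
  rec <- ifelse(top$is_water, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(top$name) < 4, sprintf(" %-3s", top$name),
                  substr(top$name, 1, 4))
  serial <- (seq_len(nrow(top)) - 1L) %% 99999L + 1L
  multi <- n_frames(traj) > 1L
  for (fi in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL     %4d", fi), con)
    xyz <- traj$frames[[fi]]
    writeLines(sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       rec, serial, name4, top$residue_name, top$chain_id,
                       top$residue_seq, xyz[, 1], xyz[, 2], xyz[, 3],
                       substr(top$element, 1, 2)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' Plain XYZ: atom count line, comment line, then element x y z rows,
#' repeated per frame. All atoms are treated as non-water unless their
#' element row carries a name found in \code{water_residues} — XYZ carries
#' no residue information, so a uniform residue name is assigned.
#'
#' @param path XYZ file.
#' @param frame_interval ps between frames.
#' @param residue_name residue name assigned to every atom.
#' @return an \code{hs_trajectory} (no box).
#' @export
read_xyz <- function(path, frame_interval = 1, residue_name = "UNK") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("malformed XYZ: bad atom count on line 1")
  per <- n + 2L
  nfr <- length(lines) %/% per
  if (nfr < 1) stop("malformed XYZ: truncated first frame")
  first <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  element <- vapply(first, `[[`, "", 1L)
  frames <- lapply(seq_len(nfr), function(fi) {
    off <- (fi - 1L) * per + 2L
    rows <- strsplit(trimws(lines[(off + 1):(off + n)]), "[[:space:]]+")
    m <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(m)) stop("malformed XYZ coordinates in frame ", fi)
    m
  })
  top <- make_topology(element, element, rep(residue_name, n),
                       seq_len(n), rep("A", n))
  trajectory(top, frames, frame_interval = frame_interval)
}

#' Write a multi-frame XYZ file
#' @param traj an \code{hs_trajectory}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj$topology
  for (fi in seq_len(n_frames(traj))) {
    writeLines(as.character(nrow(top)), con)
    writeLines(sprintf("frame %d t=%g ps", fi, traj$times[fi]), con)
    xyz <- traj$frames[[fi]]
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", top$element,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
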