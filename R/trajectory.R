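#' @keywords internal
"_PACKAGE"

# Residue names recognised as water by default. Only the water OXYGEN atom
# ever participates in site-distance logic; hydrogens are ignored throughout.
.default_water_residues <- c("HOH", "SOL", "WAT", "TIP3", "TIP4")

# Standard atomic weights (u) keyed on element symbol.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, NA_ = 22.990, CL = 35.45, K = 39.098, MG = 24.305,
  CA = 40.078, FE = 55.845, ZN = 65.38
)

#' Atomic mass lookup
#'
#' Returns standard atomic weights for element symbols. Unknown elements get
#' mass 0 with a warning and are thereby excluded from mass-weighted sums.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in unified atomic mass units.
#' @export
atomic_mass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA_"
  m <- .atomic_masses[key]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning("unknown element(s): ", paste(unique(element[unknown]), collapse = ", "),
            "; assigning mass 0 (excluded from mass-weighted sums)")
    m[unknown] <- 0
  }
  unname(m)
}

#' Build a topology table
#'
#' The topology is a data frame with one row per atom: 0-based \code{index},
#' PDB-style \code{name}, \code{element}, \code{mass} (u), 3-letter
#' \code{residue_name}, 1-based \code{residue_seq}, single-character
#' \code{chain_id} and logical \code{is_water}. Water is flagged by residue
#' name membership in \code{water_residues}.
#'
#' @param name,element,residue_name,residue_seq,chain_id per-atom vectors.
#' @param water_residues residue names treated as water.
#' @return data.frame of class \code{hs_topology}.
#' @export
make_topology <- function(name, element, residue_name, residue_seq, chain_id,
                          water_residues = .default_water_residues) {
  n <- length(name)
  stopifnot(length(element) == n, length(residue_name) == n,
            length(residue_seq) == n, length(chain_id) == n)
  top <- data.frame(
    index = seq_len(n) - 1L,
    name = as.character(name),
    element = as.character(element),
    mass = atomic_mass(element),
    residue_name = as.character(residue_name),
    residue_seq = as.integer(residue_seq),
    chain_id = as.character(chain_id),
    is_water = as.character(residue_name) %in% water_residues,
    stringsAsFactors = FALSE
  )
  class(top) <- c("hs_topology", "data.frame")
  top
}

#' Construct a trajectory
#'
#' A trajectory couples one topology with an ordered list of frames. Each
#' frame is an n_atoms x 3 coordinate matrix in Angstrom; an optional
#' \code{box} attribute on each frame holds 3 lattice row-vectors (Angstrom).
#'
#' @param topology a topology from [make_topology()].
#' @param frames list of n_atoms x 3 numeric matrices.
#' @param frame_interval time between saved frames, ps.
#' @param box optional 3x3 lattice matrix applied to every frame, or a list
#'   of per-frame matrices, or NULL for no periodic box.
#' @param times optional per-frame times (ps); defaults to
#'   \code{(0:(n-1)) * frame_interval}.
#' @return object of class \code{hs_trajectory}.
#' @export
trajectory <- function(topology, frames, frame_interval = 1, box = NULL,
                       times = NULL) {
  if (!length(frames)) stop("trajectory must contain at least one frame")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  n_atoms <- nrow(topology)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != n_atoms || ncol(f) != 3)
      stop("each frame must be an n_atoms x 3 coordinate matrix")
    storage.mode(f) <- "double"
    dimnames(f) <- NULL
    f
  })
  if (!is.null(box)) {
    boxes <- if (is.list(box)) box else rep(list(box), length(frames))
    if (length(boxes) != length(frames)) stop("one box per frame required")
    boxes <- lapply(boxes, .check_box)
  } else boxes <- NULL
  if (is.null(times)) times <- (seq_along(frames) - 1) * frame_interval
  structure(list(topology = topology, frames = frames, boxes = boxes,
                 frame_interval = frame_interval, times = times),
            class = "hs_trajectory")
}

.check_box <- function(box) {
  box <- as.matrix(box)
  if (!all(dim(box) == c(3, 3))) stop("box must be a 3x3 lattice matrix")
  if (abs(det(box)) < 1e-9) stop("degenerate box: zero volume")
  box
}

#' @export
print.hs_trajectory <- function(x, ...) {
  cat(sprintf("<hs_trajectory> %d atoms (%d water), %d frame(s), dt = %g ps, box: %s\n",
              nrow(x$topology), sum(x$topology$is_water), length(x$frames),
              x$frame_interval, if (is.null(x$boxes)) "none" else "periodic"))
  invisible(x)
}

#' Number of frames / atoms
#' @param traj an \code{hs_trajectory}.
#' @return integer count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$topology)

#' Frame box accessor
#' @param traj an \code{hs_trajectory}.
#' @param i frame index (1-based).
#' @return 3x3 lattice matrix or NULL.
#' @export
frame_box <- function(traj, i = 1L) {
  if (is.null(traj$boxes)) NULL else traj$boxes[[i]]
}

#' Select atom indices by attribute
#'
#' Convenience filter over the topology; all arguments are optional and
#' combined with AND.
#'
#' @param traj an \code{hs_trajectory}.
#' @param name,element,residue_name,chain_id values to match.
#' @param water TRUE/FALSE to restrict to (non-)water atoms.
#' @return integer vector of row positions (1-based) into the topology.
#' @export
atom_select <- function(traj, name = NULL, element = NULL, residue_name = NULL,
                        chain_id = NULL, water = NULL) {
  top <- traj$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(name)) keep <- keep & top$name %in% name
  if (!is.null(element)) keep <- keep & top$element %in% element
  if (!is.null(residue_name)) keep <- keep & top$residue_name %in% residue_name
  if (!is.null(chain_id)) keep <- keep & top$chain_id %in% chain_id
  if (!is.null(water)) keep <- keep & (top$is_water == water)
  which(keep)
}

#' Water oxygen atom positions (1-based rows)
#'
#' Water molecules participate in all distance-based analyses through their
#' oxygen atom only.
#'
#' @param traj an \code{hs_trajectory}.
#' @return integer vector of topology row positions.
#' @export
water_oxygens <- function(traj) {
  top <- traj$topology
  which(top$is_water & top$element == "O")
}
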