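# Periodic-boundary distance arithmetic. Boxes are 3x3 matrices whose ROWS
# are the lattice vectors; orthorhombic and triclinic cells are supported.
# The triclinic minimum image wraps displacements into the central cell in
# fractional coordinates and then searches the 27 neighbouring images, which
# is exact for any reasonable MD cell.

.image_shifts <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dimnames(g) <- NULL
  g
})

#' Minimum-image distance between two points
#'
#' Shortest distance between \code{a} and any periodic image of \code{b}.
#' Without a box this is the plain Euclidean distance.
#'
#' @param a,b numeric 3-vectors (Angstrom).
#' @param box 3x3 lattice matrix (rows are lattice vectors) or NULL.
#' @return distance in Angstrom.
#' @export
minimum_image_distance <- function(a, b, box = NULL) {
  d <- rbind(as.numeric(b) - as.numeric(a))
  sqrt(min_image_sq(d, box))
}

#' Squared minimum-image lengths of displacement vectors
#'
#' Vectorised workhorse behind all neighbour searches: given an m x 3 matrix
#' of displacement vectors, returns the squared length of the nearest
#' periodic image of each.
#'
#' @param d m x 3 matrix of displacements (Angstrom).
#' @param box 3x3 lattice matrix or NULL.
#' @return numeric vector of m squared distances.
#' @export
min_image_sq <- function(d, box = NULL) {
  d <- matrix(as.numeric(d), ncol = 3)
  if (is.null(box)) return(rowSums(d * d))
  box <- .check_box(box)
  inv <- solve(box)
  frac <- d %*% inv
  frac <- frac - round(frac)            # wrap into [-0.5, 0.5)
  wrapped <- frac %*% box
  best <- rowSums(wrapped * wrapped)
  off_diag <- sum(abs(box[lower.tri(box) | upper.tri(box)]))
  if (off_diag < 1e-12) return(best)    # orthorhombic: wrap is already minimal
  for (s in seq_len(nrow(.image_shifts))) {
    sh <- .image_shifts[s, ]
    if (all(sh == 0)) next
    cand <- wrapped + matrix(sh %*% box, nrow(wrapped), 3, byrow = TRUE)
    best <- pmin(best, rowSums(cand * cand))
  }
  best
}

#' Minimum-image distances from a set of centres to a set of points
#'
#' @param centers nc x 3 coordinate matrix.
#' @param others no x 3 coordinate matrix.
#' @param box 3x3 lattice matrix or NULL.
#' @return nc x no matrix of distances (Angstrom).
#' @export
pair_distances <- function(centers, others, box = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  others <- matrix(as.numeric(others), ncol = 3)
  nc <- nrow(centers); no <- nrow(others)
  d <- matrix(0, nc, no)
  # one row of displacements per centre keeps memory bounded
  for (i in seq_len(nc)) {
    disp <- others - matrix(centers[i, ], no, 3, byrow = TRUE)
    d[i, ] <- sqrt(min_image_sq(disp, box))
  }
  d
}
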