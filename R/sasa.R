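# Solvent-accessible surface area by the rolling-probe point-sampling
# construction: each atom's accessible sphere (van der Waals radius + probe)
# is sampled on a deterministic golden-spiral lattice and a point counts as
# accessible when it lies outside every other occluder's expanded sphere.

#' Bondi van der Waals radii (Angstrom)
#'
#' Default occluder radii; configurable per call.
#' @export
bondi_radii <- c(C = 1.70, N = 1.55, O = 1.52, H = 1.20, S = 1.80, P = 1.80)

# Deterministic quasi-uniform unit-sphere lattice (golden spiral).
.sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area of one frame
#'
#' @param traj an \code{hs_trajectory}.
#' @param targets 1-based topology rows to report; must be a subset of the
#'   occluders.
#' @param occluders 1-based topology rows forming the surface; default all
#'   non-water atoms (waters and ions are not part of the peptide surface).
#' @param probe probe radius, Angstrom (1.4 = water).
#' @param n_points lattice points per atom.
#' @param frame frame index.
#' @param radii named van der Waals radii table keyed on element.
#' @return object of class \code{hs_sasa}: \code{per_atom} data.frame
#'   (atom, chain_id, residue_seq, name, role-free area in Angstrom^2),
#'   \code{per_residue} sums, \code{probe_radius}, \code{n_points}.
#' @export
atom_sasa <- function(traj, targets = NULL, occluders = NULL, probe = 1.4,
                      n_points = 960, frame = 1L, radii = bondi_radii) {
  top <- traj$topology
  if (is.null(occluders)) occluders <- which(!top$is_water)
  if (is.null(targets)) targets <- occluders
  if (!all(targets %in% occluders)) stop("targets must be a subset of occluders")
  elem <- top$element[occluders]
  unknown <- setdiff(unique(elem), names(radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  rv <- unname(radii[elem]) + probe
  xyz <- traj$frames[[frame]][occluders, , drop = FALSE]
  lat <- .sphere_lattice(n_points)
  tpos <- match(targets, occluders)
  area <- numeric(length(targets))
  for (k in seq_along(targets)) {
    i <- tpos[k]
    ri <- rv[i]
    # only occluders whose expanded sphere can reach this atom's surface
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ri + rv)^2 & seq_along(rv) != i)
    if (!length(nb)) { area[k] <- 4 * pi * ri^2; next }
    pts <- lat * ri + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(pts[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj >= rv[j]^2
    }
    area[k] <- sum(acc) / n_points * 4 * pi * ri^2
  }
  per_atom <- data.frame(atom = targets, chain_id = top$chain_id[targets],
                         residue_seq = top$residue_seq[targets],
                         name = top$name[targets], area = area,
                         stringsAsFactors = FALSE)
  per_residue <- stats::aggregate(area ~ chain_id + residue_seq, per_atom, sum)
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 probe_radius = probe, n_points = n_points),
            class = "hs_sasa")
}

#' Time-averaged solvent-accessible surface area
#'
#' [atom_sasa()] per frame, averaged.
#'
#' @inheritParams atom_sasa
#' @param frames frame indices (default all).
#' @return an \code{hs_sasa} with frame-averaged areas.
#' @export
sasa_series <- function(traj, targets = NULL, occluders = NULL, probe = 1.4,
                        n_points = 960, frames = NULL, radii = bondi_radii) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  acc <- NULL
  for (fi in frames) {
    s <- atom_sasa(traj, targets, occluders, probe, n_points, fi, radii)
    if (is.null(acc)) acc <- s else acc$per_atom$area <- acc$per_atom$area + s$per_atom$area
  }
  acc$per_atom$area <- acc$per_atom$area / length(frames)
  acc$per_residue <- stats::aggregate(area ~ chain_id + residue_seq,
                                      acc$per_atom, sum)
  acc
}

#' Pearson correlation with least-squares line
#'
#' Product-moment correlation between two per-site quantities (e.g. the
#' carbonyl-oxygen SASA and its first-shell water count), with the slope
#' and intercept of the least-squares line and \eqn{R^2 = r^2}.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list of class \code{hs_correlation}: \code{pearson_r},
#'   \code{r_squared}, \code{n}, \code{slope}, \code{intercept}.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance input")
  r <- stats::cor(x, y)
  fit <- stats::lm(y ~ x)
  structure(list(pearson_r = r, r_squared = r^2, n = length(x),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "hs_correlation")
}

#' @export
print.hs_correlation <- function(x, ...) {
  cat(sprintf("<correlation> r = %.4f (R^2 = %.4f, n = %d), y = %.4g x + %.4g\n",
              x$pearson_r, x$r_squared, x$n, x$slope, x$intercept))
  invisible(x)
}
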