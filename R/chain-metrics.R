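# Numerical chain-shape metrics: Rg, Ree, Kabsch superposition, RMSD, RMSF.

#' Radius of gyration of an atom subset
#'
#' Root-mean-square distance of the subset's atoms from their (weighted)
#' centroid. Default is the equal-mass convention (all masses 1); with
#' \code{mass_weighted = TRUE} atomic masses from the topology weight both
#' the centroid and the average. Atoms with unknown mass (0) drop out of
#' mass-weighted sums.
#'
#' @param traj an \code{hs_trajectory}.
#' @param subset 1-based topology rows; default all atoms.
#' @param frame frame index.
#' @param mass_weighted logical.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(traj, subset = NULL, frame = 1L,
                               mass_weighted = FALSE) {
  if (is.null(subset)) subset <- seq_len(n_atoms(traj))
  if (!length(subset)) stop("empty atom subset")
  xyz <- traj$frames[[frame]][subset, , drop = FALSE]
  w <- if (mass_weighted) traj$topology$mass[subset] else rep(1, length(subset))
  if (sum(w) <= 0) stop("total weight is zero")
  rg_points(xyz, w)
}

#' Radius of gyration of a point set
#'
#' @param xyz m x 3 coordinate matrix.
#' @param w optional weights (default equal); the reference point is the
#'   weighted centroid of the same points.
#' @param center optional fixed reference point overriding the centroid —
#'   used e.g. to average over a subset of beads about the full chain's
#'   centre of mass.
#' @return Rg in the units of \code{xyz}.
#' @export
rg_points <- function(xyz, w = NULL, center = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (is.null(w)) w <- rep(1, nrow(xyz))
  w <- w / sum(w)
  if (is.null(center)) center <- colSums(xyz * w)
  d2 <- rowSums(sweep(xyz, 2, center)^2)
  sqrt(sum(w * d2))
}

#' End-to-end distance of a chain
#'
#' Euclidean distance (no minimum image — a chain is kept whole) between
#' the first and last residue of the chain bearing the terminal atom name.
#'
#' @param traj an \code{hs_trajectory}.
#' @param chain chain id.
#' @param atom_name terminal atom name (default "CA").
#' @param frame frame index.
#' @return Ree in Angstrom.
#' @export
end_to_end_distance <- function(traj, chain, atom_name = "CA", frame = 1L) {
  top <- traj$topology
  idx <- which(top$chain_id == chain & top$name == atom_name & !top$is_water)
  if (length(idx) < 2)
    stop(sprintf("chain %s has fewer than two '%s' atoms", chain, atom_name))
  idx <- idx[order(top$residue_seq[idx])]
  xyz <- traj$frames[[frame]]
  sqrt(sum((xyz[idx[length(idx)], ] - xyz[idx[1], ])^2))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping \code{mobile} onto
#' \code{reference}; the returned RMSD is the post-fit residual.
#'
#' @param mobile,reference m x 3 coordinate matrices, m >= 3.
#' @return list with \code{rotation} (3x3), \code{translation} (length 3;
#'   apply as \code{mobile \%*\% rotation + translation}), \code{rmsd}
#'   (Angstrom), and \code{fitted} coordinates.
#' @export
superpose <- function(mobile, reference) {
  mobile <- matrix(as.numeric(mobile), ncol = 3)
  reference <- matrix(as.numeric(reference), ncol = 3)
  if (nrow(mobile) != nrow(reference)) stop("atom counts differ")
  if (nrow(mobile) < 3) stop("need at least 3 atoms to superpose")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- A %*% R + matrix(cr, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = cr - as.numeric(cm %*% R),
       rmsd = rmsd, fitted = fitted)
}

#' RMSD of each frame to a reference frame
#'
#' @param traj an \code{hs_trajectory} with >= 1 frame.
#' @param subset atoms used for both fitting and the residual (default all).
#' @param reference_frame frame index to superpose onto.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, subset = NULL, reference_frame = 1L) {
  if (is.null(subset)) subset <- seq_len(n_atoms(traj))
  ref <- traj$frames[[reference_frame]][subset, , drop = FALSE]
  vapply(traj$frames, function(f) superpose(f[subset, , drop = FALSE], ref)$rmsd,
         numeric(1))
}

#' Root-mean-square fluctuation per atom
#'
#' Every frame is rigidly superposed onto the alignment frame over the
#' subset; each atom's RMSF is then the square root of its time-averaged
#' squared displacement from its own time-mean position.
#'
#' @param traj an \code{hs_trajectory} with >= 2 frames.
#' @param subset atoms to report (default all).
#' @param align_to alignment frame index.
#' @param fit_subset atoms the rigid fit is computed on (default
#'   \code{subset}); pass e.g. the rigid core so that a mobile atom's own
#'   motion is not absorbed into the superposition.
#' @return numeric vector of per-atom RMSF (Angstrom), one per subset atom.
#' @export
rmsf <- function(traj, subset = NULL, align_to = 1L, fit_subset = subset) {
  if (n_frames(traj) < 2) stop("RMSF needs at least two frames")
  if (is.null(subset)) subset <- seq_len(n_atoms(traj))
  if (is.null(fit_subset)) fit_subset <- subset
  ref <- traj$frames[[align_to]][fit_subset, , drop = FALSE]
  aligned <- lapply(traj$frames, function(f) {
    sp <- superpose(f[fit_subset, , drop = FALSE], ref)
    f[subset, , drop = FALSE] %*% sp$rotation +
      matrix(sp$translation, length(subset), 3, byrow = TRUE)
  })
  nfr <- length(aligned)
  mean_pos <- Reduce(`+`, aligned) / nfr
  ssq <- Reduce(`+`, lapply(aligned, function(a) rowSums((a - mean_pos)^2)))
  sqrt(ssq / nfr)
}

#' Chain-shape summary against the bead model
#'
#' Computes numerical Rg (all atoms of the subset) and Ree for each chain
#' and compares their ratio with the analytical bead-model prediction.
#'
#' @param traj an \code{hs_trajectory}.
#' @param chains chain ids; default all non-water chains.
#' @param model optional \code{hs_bead_model} for the analytical columns.
#' @param atom_name terminal atom name for Ree.
#' @param frame frame index.
#' @return data.frame with per-chain Rg, Ree, ratio, and (when a model is
#'   given) the closed-form Rg, Ree and ratio.
#' @export
chain_summary <- function(traj, chains = NULL, model = NULL,
                          atom_name = "CA", frame = 1L) {
  top <- traj$topology
  if (is.null(chains)) chains <- unique(top$chain_id[!top$is_water])
  rows <- lapply(chains, function(ch) {
    sub <- which(top$chain_id == ch & !top$is_water)
    rg <- radius_of_gyration(traj, sub, frame = frame)
    ree <- tryCatch(end_to_end_distance(traj, ch, atom_name, frame),
                    error = function(e) NA_real_)
    data.frame(chain = ch, rg = rg, ree = ree, ratio = rg / ree,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(model)) {
    out$model_rg <- bead_rg(model)
    out$model_ree <- bead_ree(model)
    out$model_ratio <- sqrt(bead_ratio_squared(model))
  }
  out
}
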