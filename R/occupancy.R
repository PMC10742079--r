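# Per-site first- and second-shell water occupancy.

.site_coords <- function(traj, sites, frame) {
  traj$frames[[frame]][sites$atom, , drop = FALSE]
}

.terminal_filter <- function(sites, exclude_termini) {
  if (!exclude_termini) return(rep(TRUE, nrow(sites)))
  keep <- rep(TRUE, nrow(sites))
  for (ch in unique(sites$chain_id)) {
    in_ch <- sites$chain_id == ch
    res <- sites$residue_seq[in_ch]
    lo <- sort(unique(res))
    first3 <- utils::head(lo, 3); last3 <- utils::tail(lo, 3)
    keep[in_ch & sites$residue_seq %in% c(first3, last3)] <- FALSE
  }
  keep
}

#' First-shell water occupancy per site and role
#'
#' Counts water oxygens within \code{cutoff} of every carbonyl-O site
#' (minimum image when a box is present), per frame, and averages over
#' frames. The ensemble-average first minimum of the water-site g(r),
#' 3.225 Angstrom, is the default; 3.5 Angstrom is the conventional
#' single-frame/crystal cutoff.
#'
#' @param traj an \code{hs_trajectory} containing water.
#' @param sites an \code{hs_sites} table.
#' @param cutoff Angstrom.
#' @param frames frame indices (default all).
#' @param exclude_termini drop the first and last triplet (three residues)
#'   of each chain from the per-role averages.
#' @return object of class \code{hs_occupancy}: \code{per_site} data.frame
#'   (chain_id, residue_seq, role, mean_count), \code{per_role} named means,
#'   \code{cutoff_used}.
#' @export
site_occupancy <- function(traj, sites, cutoff = 3.225, frames = NULL,
                           exclude_termini = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  wat <- water_oxygens(traj)
  if (!length(wat)) stop("no water oxygens in topology")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  counts <- matrix(0, nrow(sites), length(frames))
  for (j in seq_along(frames)) {
    fi <- frames[j]
    d <- pair_distances(.site_coords(traj, sites, fi),
                        traj$frames[[fi]][wat, , drop = FALSE],
                        frame_box(traj, fi))
    counts[, j] <- rowSums(d < cutoff)
  }
  per_site <- data.frame(chain_id = sites$chain_id,
                         residue_seq = sites$residue_seq, role = sites$role,
                         mean_count = rowMeans(counts),
                         stringsAsFactors = FALSE)
  keep <- .terminal_filter(sites, exclude_termini)
  per_role <- c(tapply(per_site$mean_count[keep], per_site$role[keep], mean))
  structure(list(per_site = per_site,
                 per_role = per_role[order(names(per_role))],
                 cutoff_used = cutoff, exclude_termini = exclude_termini),
            class = "hs_occupancy")
}

#' @export
print.hs_occupancy <- function(x, ...) {
  cat(sprintf("<occupancy> cutoff %.3f A, %d sites; per role: %s\n",
              x$cutoff_used, nrow(x$per_site),
              paste(sprintf("%s=%.3f", names(x$per_role), x$per_role),
                    collapse = ", ")))
  invisible(x)
}

#' Second-shell coordination restricted to hydrogen-bonded waters
#'
#' Per frame and site: find the first-shell water oxygens (within
#' \code{cutoff} of the site oxygen), then count the distinct OTHER water
#' oxygens within \code{cutoff} of any of those first-shell oxygens — the
#' population of second-layer waters hydrogen-bonded to the first layer. A
#' water bonded to two first-shell ligands of the same site counts once; a
#' site with an empty first shell contributes zero that frame.
#'
#' @inheritParams site_occupancy
#' @return an \code{hs_occupancy} (mean second-shell counts).
#' @export
second_shell_hbonded <- function(traj, sites, cutoff = 3.225, frames = NULL,
                                 exclude_termini = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  wat <- water_oxygens(traj)
  if (!length(wat)) stop("no water oxygens in topology")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  counts <- matrix(0, nrow(sites), length(frames))
  for (j in seq_along(frames)) {
    fi <- frames[j]
    box <- frame_box(traj, fi)
    wxyz <- traj$frames[[fi]][wat, , drop = FALSE]
    d1 <- pair_distances(.site_coords(traj, sites, fi), wxyz, box)
    for (si in seq_len(nrow(sites))) {
      shell1 <- which(d1[si, ] < cutoff)
      if (!length(shell1)) next
      d2 <- pair_distances(wxyz[shell1, , drop = FALSE], wxyz, box)
      near <- which(apply(d2 < cutoff, 2, any))
      counts[si, j] <- length(setdiff(near, shell1))
    }
  }
  per_site <- data.frame(chain_id = sites$chain_id,
                         residue_seq = sites$residue_seq, role = sites$role,
                         mean_count = rowMeans(counts),
                         stringsAsFactors = FALSE)
  keep <- .terminal_filter(sites, exclude_termini)
  per_role <- c(tapply(per_site$mean_count[keep], per_site$role[keep], mean))
  structure(list(per_site = per_site,
                 per_role = per_role[order(names(per_role))],
                 cutoff_used = cutoff, exclude_termini = exclude_termini),
            class = "hs_occupancy")
}
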