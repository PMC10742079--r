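# Analytical model of a rigid linear chain of n equal-mass beads with equal
# spacing l: the idealisation of a (PPG)n triple helix as a linear array of
# triplet centres. Closed forms differ for odd and even n because the centre
# of mass falls on a bead (odd) or mid-way between two beads (even).
#
# Odd n = 2k+1:  Ree = 2kl,       Rg^2 = (l^2/k) * sum_{i=1..k} i^2
# Even n = 2k:   Ree = (2k-1)l,   Rg^2 = (l^2/k) * sum_{i=1..k} (i-1/2)^2
#
# giving Rg^2/Ree^2 = (1/6)(k+1)(2k+1)/(2k)^2   (odd)
#                   = (1/12)(2k+1)/(2k-1)       (even)
# and Rg^2 = (l^2/12)(n+1)n (odd), (l^2/12)(n+1)(n-1) (even). Both branches
# converge to Rg/Ree = 1/sqrt(12) = 0.2887 as k grows, well below the
# ideal-chain value 1/sqrt(6) = 0.408 — the signature of a rigid rod.
#
# NOTE the odd-branch average runs over the 2k non-central beads only (the
# centre bead, at the centre of mass, is excluded from the normalisation).
# This differs from the all-bead radius of gyration; both conventions are
# available numerically (see radius_of_gyration) and only the bead-model
# convention reproduces the closed forms above for odd n.

#' Equidistant-bead chain model
#'
#' @param n_triplets number of beads (triplet centres), n >= 2.
#' @param spacing_l inter-bead spacing, Angstrom.
#' @return object of class \code{hs_bead_model} with fields \code{n},
#'   \code{l}, \code{k = floor(n/2)} and \code{parity}.
#' @export
bead_model <- function(n_triplets, spacing_l = 8.85) {
  n <- as.integer(n_triplets)
  if (is.na(n) || n < 2) stop("bead model requires n >= 2 beads")
  if (spacing_l <= 0) stop("spacing l must be positive")
  structure(list(n = n, l = spacing_l, k = n %/% 2L,
                 parity = if (n %% 2L) "odd" else "even"),
            class = "hs_bead_model")
}

#' @export
print.hs_bead_model <- function(x, ...) {
  cat(sprintf("<bead model> n = %d (%s, k = %d), l = %g A: Rg = %.4f A, Ree = %.4f A, Rg/Ree = %.4f\n",
              x$n, x$parity, x$k, x$l, bead_rg(x), bead_ree(x),
              sqrt(bead_ratio_squared(x))))
  invisible(x)
}

#' Square pyramidal number
#'
#' Sum of the first k squares, \eqn{P_k = k(k+1)(2k+1)/6} — the count of
#' balls in a k-level square pyramid, and the combinatorial core of the
#' bead-model radius of gyration.
#'
#' @param k non-negative integer (vectorised).
#' @return exact integer-valued numeric.
#' @export
pyramidal_number <- function(k) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  k * (k + 1) * (2 * k + 1) / 6
}

#' Bead-model squared ratio Rg^2/Ree^2
#'
#' Odd branch \eqn{(1/6)(k+1)(2k+1)/(2k)^2}; even branch
#' \eqn{(1/12)(2k+1)/(2k-1)}.
#'
#' @param model an \code{hs_bead_model} (n >= 3 for the odd branch).
#' @return dimensionless squared ratio.
#' @export
bead_ratio_squared <- function(model) {
  k <- model$k
  if (model$parity == "odd") {
    if (model$n < 3) stop("odd branch requires n >= 3")
    (1 / 6) * (k + 1) * (2 * k + 1) / (2 * k)^2
  } else {
    (1 / 12) * (2 * k + 1) / (2 * k - 1)
  }
}

#' Bead-model radius of gyration
#'
#' \eqn{Rg = l\sqrt{(n+1)n/12}} for odd n, \eqn{l\sqrt{(n+1)(n-1)/12}} for
#' even n.
#'
#' @param model an \code{hs_bead_model}.
#' @return Rg in Angstrom.
#' @export
bead_rg <- function(model) {
  n <- model$n
  if (n %% 2L) model$l * sqrt((n + 1) * n / 12) else
    model$l * sqrt((n + 1) * (n - 1) / 12)
}

#' Bead-model end-to-end distance
#'
#' \eqn{(n-1)l} for a linear chain of n beads (equivalently 2kl odd,
#' (2k-1)l even).
#'
#' @param model an \code{hs_bead_model}.
#' @return Ree in Angstrom.
#' @export
bead_ree <- function(model) (model$n - 1) * model$l

#' Large-k limit of the bead-model Rg/Ree ratio
#'
#' Both parity branches converge to \eqn{1/\sqrt{12}}.
#'
#' @return the limit, dimensionless.
#' @export
bead_ratio_limit <- function() 1 / sqrt(12)

#' Estimate the bead spacing from end-to-end distances
#'
#' For a rigid linear chain \eqn{Ree(n) = (n-1)l}, so the spacing is the
#' slope of Ree against n. With exactly two consecutive n this reduces to
#' the difference of the two Ree values.
#'
#' @param ree_by_n named numeric vector: names are triplet counts n, values
#'   Ree in Angstrom.
#' @return least-squares slope, Angstrom per triplet.
#' @export
estimate_spacing <- function(ree_by_n) {
  n <- as.numeric(names(ree_by_n))
  if (length(n) < 2 || anyNA(n) || anyDuplicated(n))
    stop("need Ree for at least two distinct n")
  fit <- stats::lm(as.numeric(ree_by_n) ~ n)
  slope <- unname(stats::coef(fit)[2])
  if (abs(slope) < .Machine$double.eps^0.5 && stats::var(as.numeric(ree_by_n)) == 0)
    warning("all Ree equal: estimated spacing is 0")
  slope
}

#' Globular-protein radius of gyration scaling law
#'
#' Empirical Flory-type scaling for compact single-chain proteins,
#' \eqn{Rg = 0.395 N^{3/5} + 7.257} Angstrom with N the residue count.
#' Elongated molecules such as collagen-mimetic triple helices lie far
#' above this curve.
#'
#' @param N residue count, N >= 1 (vectorised).
#' @return Rg in Angstrom.
#' @export
globular_rg <- function(N) {
  if (any(N < 1)) stop("residue count N must be >= 1")
  0.395 * N^(3 / 5) + 7.257
}
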